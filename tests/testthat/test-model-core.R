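# FBA / pFBA / FVA / knockout on hand-enumerable networks, plus the
# steady-state, containment and monotonicity properties on seeded toys.

test_that("fba solves the linear chain and degenerate edge cases", {
  m <- chain3_model()
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes[c("T", "SINK")]), c(10, 10))
  expect_equal(unname(sol$fluxes["EX_A"]), -10)
  expect_silent(check_flux_solution(m, sol))

  # all bounds zero: only feasible point is v = 0
  m0 <- m
  for (id in names(m0$reactions)) m0 <- set_bounds(m0, id, 0, 0)
  sol0 <- fba(m0)
  expect_equal(sol0$objective_value, 0)
  expect_equal(max(abs(sol0$fluxes)), 0)

  # forcing flux with no substrate supply is infeasible
  mi <- set_bounds(m, "T", 0, 0)
  mi <- set_bounds(mi, "SINK", lb = 1)
  expect_equal(fba(mi)$status, "infeasible")

  # malformed models are rejected at construction
  expect_error(metabolic_model(list(metabolite("A")),
                               list(reaction("R", c(B = -1))),
                               c(R = 1)),
               "unknown metabolite")
})

test_that("pfba minimizes total flux while holding the optimum", {
  m <- parallel_model()
  sol <- pfba(m)
  expect_equal(sol$objective_value, fba(m)$objective_value)
  # all flux through the one-reaction path; two-step route unused
  expect_equal(unname(sol$fluxes["DIRECT"]), 10, tolerance = 1e-7)
  expect_equal(unname(sol$fluxes["VIA1"]), 0, tolerance = 1e-7)
  expect_equal(unname(sol$fluxes["VIA2"]), 0, tolerance = 1e-7)
  # strictly smaller than the alternative extreme point (40 vs 50)
  expect_lt(attr(sol, "total_flux"), 45)

  # on the chain, pfba reproduces the fba optimum
  expect_equal(pfba(chain3_model())$objective_value, 10)

  # zero optimum (uptake closed): minimal-flux solution is identically 0,
  # even though an internal cycle could circulate flux
  mc <- metabolic_model(
    list(metabolite("A"), metabolite("B")),
    list(reaction("CYC1", c(A = -1, B = 1), -1000, 1000),
         reaction("CYC2", c(B = -1, A = 1), -1000, 1000),
         reaction("SINK", c(B = -1), 0, 0)),
    c(SINK = 1))
  solc <- pfba(mc)
  expect_equal(solc$objective_value, 0)
  expect_equal(max(abs(solc$fluxes)), 0, tolerance = 1e-9)
})

test_that("fva matches the hand-enumerated ranges", {
  rng <- fva(chain3_model())
  expect_equal(rng["SINK", "min_flux"], 10, tolerance = 1e-7)
  expect_equal(rng["SINK", "max_flux"], 10, tolerance = 1e-7)
  expect_equal(unname(unlist(rng["EX_A", c("min_flux", "max_flux")])),
               c(-10, -10), tolerance = 1e-7)

  rng2 <- fva(parallel_model())
  for (id in c("DIRECT", "VIA1", "VIA2")) {
    expect_equal(rng2[id, "min_flux"], 0, tolerance = 1e-7)
    expect_equal(rng2[id, "max_flux"], 10, tolerance = 1e-7)
  }

  # blocked / disconnected reaction pins to [0, 0]
  rng3 <- fva(disconnected_model())
  expect_equal(unname(unlist(rng3["LONE", c("min_flux", "max_flux")])),
               c(0, 0), tolerance = 1e-9)
})

test_that("fba and fva agree with the vertex-enumeration oracle", {
  for (m in small_fixture_models()) {
    expect_equal(fba(m)$objective_value, fba_oracle(m)$objective_value,
                 tolerance = 1e-7)
    expect_ranges_equal(fva(m), fva_oracle(m))
  }
})

test_that("knock_out blocks mapped reactions and leaves the input untouched", {
  host <- make_toy_host(seed = 42)
  ko <- knock_out(host, "metB")
  expect_equal(ko$reactions$METSYN$ub, 0)
  expect_equal(host$reactions$METSYN$ub, 1000)   # original unmodified
  expect_equal(fba(ko)$objective_value, 0, tolerance = 1e-9)

  # knocking out an already-blocked reaction changes nothing
  ko2 <- knock_out(ko, "metB")
  expect_equal(fba(ko2)$objective_value, fba(ko)$objective_value)

  expect_error(knock_out(host, "not_a_gene"), "unknown gene or reaction")
})

test_that("steady state and FVA-contains-pFBA hold on seeded toy hosts", {
  for (seed in c(1, 7, 1729)) {
    m <- make_toy_host(seed)
    sol <- pfba(m)
    expect_silent(check_flux_solution(m, sol))
    rng <- fva(m)
    ids <- rng$reaction_id
    expect_true(all(sol$fluxes[ids] >= rng[ids, "min_flux"] - 1e-6))
    expect_true(all(sol$fluxes[ids] <= rng[ids, "max_flux"] + 1e-6))
  }
})

test_that("raising a lower bound never increases the optimum", {
  for (seed in 1:20) {
    m <- make_toy_host(seed)
    base <- fba(m)$objective_value
    set.seed(seed + 1000)
    id <- sample(names(m$reactions), 1)
    r <- m$reactions[[id]]
    bumped <- set_bounds(m, id, lb = r$lb + 0.25 * (min(r$ub, r$lb + 4) - r$lb))
    sol <- fba(bumped)
    if (sol$status == "optimal") expect_lte(sol$objective_value, base + 1e-7)
    else expect_equal(sol$status, "infeasible")
  }
})
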