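# FVA range-overlap conflict detection and pFBA subsystem demand
# fold-changes, checked against interval arithmetic, the certified
# branch-point fixture, and hand-computed fold-change examples.

ranges_df <- function(ids, mins, maxs) {
  structure(data.frame(reaction_id = ids, min_flux = mins, max_flux = maxs,
                       row.names = ids, stringsAsFactors = FALSE),
            class = c("flux_ranges", "data.frame"))
}

two_rxn_model <- function() {
  metabolic_model(
    list(metabolite("A")),
    list(reaction("R1", c(A = 1), -1000, 1000, subsystem = "S1",
                  is_exchange = FALSE),
         reaction("R2", c(A = -1), -1000, 1000, subsystem = "S2",
                  is_exchange = FALSE)),
    c(R2 = 1))
}

test_that("interval overlap decides conflict, with closed endpoints", {
  m <- two_rxn_model()
  # disjoint ranges on R1 -> conflict; shared endpoint on R2 -> none
  h <- ranges_df(c("R1", "R2"), c(0, 0), c(1, 2))
  g <- ranges_df(c("R1", "R2"), c(2, 2), c(3, 3))
  rep <- find_conflicts(h, g, m)
  expect_equal(rep$conflict_reactions, "R1")
  expect_equal(rep$total_reactions, 2)
  expect_equal(rep$fraction_of_total, 0.5)
  expect_equal(subsystem_conflict_fraction(rep), c(S1 = 1, S2 = 0))

  # symmetry in the two states
  rep2 <- find_conflicts(g, h, m)
  expect_equal(rep2$conflict_reactions, rep$conflict_reactions)

  # shrinking the tolerance never shrinks the conflict set
  wide <- find_conflicts(h, g, m, tol = 1.5)
  expect_true(all(wide$conflict_reactions %in% rep$conflict_reactions))

  expect_error(find_conflicts(h, ranges_df("R1", 0, 1), m),
               "different reactions")
})

test_that("the branch-point fixture reproduces its certified ground truth", {
  fx <- make_conflict_fixture()
  host <- set_objective(fx$model, fx$host_objective)
  mge <- set_objective(fx$model, fx$mge_objective)

  # certify the fixture against the brute-force oracle, then the pipeline
  fva_h <- fva(host); fva_m <- fva(mge)
  expect_ranges_equal(fva_h, fva_oracle(host))
  expect_ranges_equal(fva_m, fva_oracle(mge))

  rep <- find_conflicts(fva_h, fva_m, fx$model)
  expect_setequal(rep$conflict_reactions, fx$expected_conflicts)
  got <- subsystem_conflict_fraction(rep)
  expect_equal(got[sort(names(got))],
               fx$expected_fractions[sort(names(fx$expected_fractions))])

  # an element whose demands coincide with biomass shows no conflict
  fx0 <- make_conflict_fixture(identical_objectives = TRUE)
  rep0 <- find_conflicts(fva(set_objective(fx0$model, fx0$host_objective)),
                         fva(set_objective(fx0$model, fx0$mge_objective)),
                         fx0$model)
  expect_length(rep0$conflict_reactions, 0)
})

test_that("subsystem demand fold-changes match hand arithmetic", {
  # model of 3 labelled reactions; identical states -> all fold changes 0
  mets <- list(metabolite("A"), metabolite("B"))
  rxns <- list(
    reaction("a1", c(A = 1), -1000, 1000, subsystem = "AA biosynthesis",
             is_exchange = FALSE),
    reaction("a2", c(A = -1, B = 1), -1000, 1000,
             subsystem = "AA biosynthesis", is_exchange = FALSE),
    reaction("o1", c(B = -1), -1000, 1000, subsystem = "Other",
             is_exchange = FALSE))
  m <- metabolic_model(mets, rxns, c(o1 = 1))

  same <- manual_solution(c(a1 = 1, a2 = 1, o1 = 8))
  d0 <- subsystem_demand_fold_change(same, same, m)
  expect_equal(d0$per_subsystem$log2_fold_change, c(0, 0))
  expect_length(d0$dropped_reactions, 0)

  # host: subsystem carries {1,1} of total 10; MGE: {2,2} of total 10
  host <- manual_solution(c(a1 = 1, a2 = 1, o1 = 8))
  mge <- manual_solution(c(a1 = 2, a2 = 2, o1 = 6))
  d1 <- subsystem_demand_fold_change(mge, host, m)
  aa <- d1$per_subsystem[d1$per_subsystem$subsystem == "AA biosynthesis", ]
  expect_equal(aa$log2_fold_change, 1.0)
  # shares sum to one in each state when every reaction is labelled
  expect_equal(sum(d1$per_subsystem$share_mge), 1)
  expect_equal(sum(d1$per_subsystem$share_host), 1)

  # a sign flip above the zero tolerance is dropped from every sum
  flip_h <- manual_solution(c(a1 = 1, a2 = 1, o1 = 8))
  flip_m <- manual_solution(c(a1 = -1, a2 = 2, o1 = 6))
  d2 <- subsystem_demand_fold_change(flip_m, flip_h, m)
  expect_equal(d2$dropped_reactions, "a1")
  expect_equal(d2$total_mge, 8)     # |2| + |6|
  expect_equal(d2$total_host, 9)    # |1| + |8|

  # magnitudes below zero_tol never count as direction changes
  tiny_h <- manual_solution(c(a1 = 1e-12, a2 = 1, o1 = 8))
  tiny_m <- manual_solution(c(a1 = -1e-12, a2 = 1, o1 = 8))
  expect_length(subsystem_demand_fold_change(tiny_m, tiny_h, m)$dropped_reactions, 0)

  # a subsystem active in exactly one state is flagged undefined, not an error
  one_sided_m <- manual_solution(c(a1 = 0, a2 = 0, o1 = 6))
  d3 <- subsystem_demand_fold_change(one_sided_m, host, m)
  aa3 <- d3$per_subsystem[d3$per_subsystem$subsystem == "AA biosynthesis", ]
  expect_false(aa3$defined)
  expect_true(is.na(aa3$log2_fold_change))
})

test_that("fold changes on the conflict fixture match the enumerated optima", {
  fx <- make_conflict_fixture()
  host <- set_objective(fx$model, fx$host_objective)
  mge <- set_objective(fx$model, fx$mge_objective)
  d <- subsystem_demand_fold_change(pfba(mge), pfba(host), fx$model)
  per <- d$per_subsystem
  # shared supply path carries 10 in both states: shares are equal -> 0
  for (s in c("Exchange", "Transport")) {
    expect_equal(per$log2_fold_change[per$subsystem == s], 0, tolerance = 1e-9)
  }
  # host-only branches vanish under the MGE objective and vice versa
  expect_false(per$defined[per$subsystem == "Host biosynthesis"])
  expect_false(per$defined[per$subsystem == "MGE production"])
})
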