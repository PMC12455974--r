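# Hand-built micro-networks shared across tests. All are small enough for
# the vertex-enumeration oracle to be exact.

# linear chain: bounded uptake of A (10), A -> B, B -> sink (objective);
# unique optimal vertex with every flux at 10.
chain3_model <- function(uptake = 10) {
  metabolic_model(
    list(metabolite("A"), metabolite("B")),
    list(reaction("EX_A", c(A = -1), lb = -uptake, ub = 0),
         reaction("T", c(A = -1, B = 1), 0, 1000),
         reaction("SINK", c(B = -1), 0, 1000)),
    c(SINK = 1), id = "chain3")
}

# two parallel routes A -> B: direct (one reaction) vs via X (two
# reactions); same capacity, so FVA swings each branch over [0, 10] while
# pFBA must route everything through the direct branch.
parallel_model <- function(uptake = 10) {
  metabolic_model(
    list(metabolite("A"), metabolite("X"), metabolite("B")),
    list(reaction("EX_A", c(A = -1), lb = -uptake, ub = 0),
         reaction("DIRECT", c(A = -1, B = 1), 0, 1000),
         reaction("VIA1", c(A = -1, X = 1), 0, 1000),
         reaction("VIA2", c(X = -1, B = 1), 0, 1000),
         reaction("SINK", c(B = -1), 0, 1000)),
    c(SINK = 1), id = "parallel")
}

# chain plus a reaction disconnected from everything it could feed
disconnected_model <- function() {
  metabolic_model(
    list(metabolite("A"), metabolite("B"), metabolite("Z")),
    list(reaction("EX_A", c(A = -1), lb = -10, ub = 0),
         reaction("T", c(A = -1, B = 1), 0, 1000),
         reaction("SINK", c(B = -1), 0, 1000),
         reaction("LONE", c(Z = -1), 0, 1000)),
    c(SINK = 1), id = "disconnected")
}

# every <= 6-reaction fixture used for oracle-equivalence sweeps
small_fixture_models <- function() {
  fx <- make_conflict_fixture()
  list(chain3 = chain3_model(),
       parallel = parallel_model(),
       disconnected = disconnected_model(),
       conflict_host = set_objective(fx$model, fx$host_objective),
       conflict_mge = set_objective(fx$model, fx$mge_objective))
}

expect_ranges_equal <- function(got, want, tol = 1e-6) {
  ids <- sort(want$reaction_id)
  expect_setequal(got$reaction_id, want$reaction_id)
  expect_equal(got[ids, "min_flux"], want[ids, "min_flux"], tolerance = tol,
               ignore_attr = TRUE)
  expect_equal(got[ids, "max_flux"], want[ids, "max_flux"], tolerance = tol,
               ignore_attr = TRUE)
}

# flux_solution built by hand (for the conflict-metric arithmetic tests)
manual_solution <- function(fluxes) {
  structure(list(status = "optimal",
                 objective_value = NA_real_, fluxes = fluxes),
            class = "flux_solution")
}
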