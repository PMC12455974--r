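# Composition counting, polymerization costs, mass normalization and the
# frozen spreadsheet oracle for the canonical toy element.

# independently computed (spreadsheet-style, outside this code path) for
# genome "ACGT" (ssDNA, C_g = 1, no intermediates) + protein "MK" x 2
ORACLE_TOTAL_MASS <- 2538.49
ORACLE_NT_COEFF <- 0.3939349770926811
ORACLE_MK_COEFF <- 0.7878699541853622
ORACLE_ATP_COEFF <- 6.302959633482898
ORACLE_PPI_COEFF <- 1.5757399083707244

test_that("nucleotide counting handles strandedness, copies and intermediates", {
  g1 <- mge_genome("ACGT", "ssDNA", copy_number = 1)
  expect_equal(count_nucleotides(g1), c(A = 1, C = 1, G = 1, T = 1))

  # dsDNA counts both strands: complement of AACG is TTGC, so totals
  # equalize across base pairs
  g2 <- mge_genome("AACG", "dsDNA", copy_number = 1)
  expect_equal(count_nucleotides(g2), c(A = 2, C = 2, G = 2, T = 2))

  # C_g scales linearly
  g3 <- mge_genome("AACG", "dsDNA", copy_number = 2)
  expect_equal(count_nucleotides(g3), 2 * count_nucleotides(g2))

  # ssDNA with the replicative-form intermediate adds one complement copy
  g4 <- mge_genome("AAAC", "ssDNA", replicative_form = TRUE)
  expect_equal(count_nucleotides(g4), c(A = 3, C = 1, G = 1, T = 3))

  expect_error(mge_genome("ACGU", "ssDNA"), "invalid nucleotide")
  expect_error(mge_genome("ACGT", "ssDNA", copy_number = 0), "C_g")
})

test_that("amino-acid counting scales residue counts by protein copies", {
  expect_equal(count_amino_acids(list(protein_spec("p", "MK", 3)))[c("M", "K")],
               c(M = 3, K = 3))
  two <- count_amino_acids(list(protein_spec("p1", "MK", 3),
                                protein_spec("p2", "MMA", 2)))
  expect_equal(two[c("M", "K", "A")], c(M = 7, K = 3, A = 2))
  expect_equal(sum(count_amino_acids(list())), 0)
  expect_error(protein_spec("bad", "MKZ", 1), "invalid amino-acid")
  expect_error(protein_spec("bad", "", 1), "empty sequence")
})

test_that("polymerization costs follow 4 ATP per amino acid, 1 PPi per nucleotide", {
  aa <- count_amino_acids(list(protein_spec("p", "MK", 1)))
  nt0 <- stats::setNames(numeric(4), c("A", "C", "G", "T"))
  expect_equal(polymerization_costs(nt0, aa),
               list(atp = 8, ppi = 0))
  nt <- count_nucleotides(mge_genome("ACGT", "ssDNA"))
  aa0 <- stats::setNames(numeric(20), mgeflux:::AA_ALPHABET)
  expect_equal(polymerization_costs(nt, aa0), list(atp = 0, ppi = 4))
  expect_equal(polymerization_costs(nt0, aa0), list(atp = 0, ppi = 0))
  expect_error(polymerization_costs(nt0 - 1, aa0), "nonnegative")
})

test_that("total molar mass is the mass-weighted monomer sum and is linear in copies", {
  tab <- default_monomer_table()
  one_a <- count_nucleotides(mge_genome("A", "ssDNA"))
  expect_equal(total_molar_mass(one_a, count_amino_acids(list()), tab),
               tab$molar_mass[tab$monomer == "A" & tab$class == "nt"])
  fix <- toy_mge_fixture()
  m1 <- total_molar_mass(count_nucleotides(fix$genome),
                         count_amino_acids(fix$proteome), tab)
  expect_equal(m1, ORACLE_TOTAL_MASS)
  g2 <- mge_genome("ACGT", "ssDNA", copy_number = 2)
  m2 <- total_molar_mass(count_nucleotides(g2),
                         count_amino_acids(fix$proteome), tab)
  genome_part <- total_molar_mass(count_nucleotides(fix$genome),
                                  count_amino_acids(list()), tab)
  expect_equal(m2 - m1, genome_part)
})

test_that("pseudoreaction coefficients match the spreadsheet oracle to 1e-9 relative", {
  fix <- toy_mge_fixture()
  built <- build_pseudoreaction(fix$genome, fix$proteome)
  sp <- built$spec
  expect_equal(sp$total_molar_mass, ORACLE_TOTAL_MASS, tolerance = 1e-9)
  for (ntc in sp$nucleotide_coeffs)
    expect_equal(ntc, ORACLE_NT_COEFF, tolerance = 1e-9)
  expect_equal(unname(sp$aa_coeffs["M"]), ORACLE_MK_COEFF, tolerance = 1e-9)
  expect_equal(unname(sp$aa_coeffs["K"]), ORACLE_MK_COEFF, tolerance = 1e-9)
  expect_equal(sp$atp_coeff, ORACLE_ATP_COEFF, tolerance = 1e-9)
  expect_equal(sp$ppi_coeff, ORACLE_PPI_COEFF, tolerance = 1e-9)
  # reaction side: consumed monomers negative, polymerization products positive
  st <- built$reaction$stoichiometry
  expect_equal(unname(st["datp_c"]), -ORACLE_NT_COEFF, tolerance = 1e-9)
  expect_equal(unname(st["met__L_c"]), -ORACLE_MK_COEFF, tolerance = 1e-9)
  expect_equal(unname(st["ppi_c"]), ORACLE_PPI_COEFF, tolerance = 1e-9)
  expect_true(built$reaction$is_pseudoreaction)
  expect_equal(c(built$reaction$lb, built$reaction$ub), c(0, 1000))
})

test_that("mass normalization: one mmol of flux drains exactly one gram, for any spec", {
  tab <- default_monomer_table()
  nt_mass <- stats::setNames(tab$molar_mass[tab$class == "nt"],
                             tab$monomer[tab$class == "nt"])
  aa_mass <- stats::setNames(tab$molar_mass[tab$class == "aa"],
                             tab$monomer[tab$class == "aa"])
  for (seed in 1:50) {
    mge <- make_toy_mge(seed, genome_length = 5 + seed %% 40,
                        n_proteins = seed %% 4,
                        strandedness = if (seed %% 2) "dsDNA" else "ssDNA")
    sp <- build_pseudoreaction(mge$genome, mge$proteome)$spec
    total <- sum(sp$nucleotide_coeffs * nt_mass[names(sp$nucleotide_coeffs)]) +
             sum(sp$aa_coeffs * aa_mass[names(sp$aa_coeffs)])
    expect_equal(total, 1000, tolerance = 1e-6)
  }
})

test_that("phosphate bookkeeping and linearity hold by construction", {
  mge <- make_toy_mge(3, genome_length = 12, n_proteins = 2)
  sp <- build_pseudoreaction(mge$genome, mge$proteome)$spec
  expect_equal(sp$adp_coeff, sp$atp_coeff)
  expect_equal(sp$pi_coeff, sp$atp_coeff)
  expect_equal(sp$h_coeff, sp$atp_coeff)
  expect_equal(sp$h2o_coeff, sp$atp_coeff)
  expect_equal(sp$ppi_coeff, sum(sp$nucleotide_coeffs))

  # doubling C_g doubles counts, so mmol/g coefficients of a pure-genome
  # element are unchanged while total mass doubles
  g1 <- build_pseudoreaction(mge_genome("ACCGT", "dsDNA", 1), list())$spec
  g2 <- build_pseudoreaction(mge_genome("ACCGT", "dsDNA", 2), list())$spec
  expect_equal(g2$total_molar_mass, 2 * g1$total_molar_mass)
  expect_equal(g2$nucleotide_coeffs, g1$nucleotide_coeffs)

  # no proteome: every ATP-hydrolysis coefficient vanishes
  expect_equal(g1$atp_coeff, 0)
  expect_equal(g1$adp_coeff, 0)
  expect_equal(g1$h2o_coeff, 0)
})

test_that("pilin copy number follows the helix geometry", {
  expect_equal(pilin_copy_number(0, 12.8, 1.28), 0L)
  # one full turn of pitch 1.28 nm -> 12.8 subunits -> rounds to 13
  expect_equal(pilin_copy_number(1.28e-3, 12.8, 1.28), 13L)
  expect_error(pilin_copy_number(20, 12.8, 0), "pitch")
  expect_error(pilin_copy_number(-1, 12.8, 1), ">= 0")
})

test_that("attaching a pseudoreaction preserves or monotonically lowers growth", {
  host <- make_toy_host(seed = 11)
  mge <- make_toy_mge(seed = 11, genome_length = 20, n_proteins = 2)
  pr <- build_pseudoreaction(mge$genome, mge$proteome, toy_monomer_table(),
                             id = "MGE")
  base <- fba(host)$objective_value

  attached <- attach_pseudoreaction(host, pr$reaction)
  expect_true(attached$reactions$MGE$is_pseudoreaction)
  expect_equal(fba(attached)$objective_value, base, tolerance = 1e-7)

  forced <- attach_pseudoreaction(host, pr$reaction, lower_bound = 0.9)
  sol <- fba(forced)
  expect_true(sol$status != "optimal" || sol$objective_value <= base + 1e-7)

  expect_error(attach_pseudoreaction(attached, pr$reaction), "already present")
  bad <- reaction("BAD", c(nowhere_c = -1), 0, 10, is_exchange = FALSE)
  expect_error(attach_pseudoreaction(host, bad), "lacks metabolite")
})
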