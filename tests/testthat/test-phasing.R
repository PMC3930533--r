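# Pairwise calls, chained phasing, verdicts.

test_that("a clean diagonal matrix phases cis with probability one", {
  m <- toy_matrix(cell_counts(list("G", "A", 500), list("A", "G", 500)),
                  up_ref = "G", up_alt = "A", dn_ref = "A", dn_alt = "G")
  pp <- phase_pair(m, error_mass = 0, seed = 4)
  expect_equal(pp$call, "cis")
  expect_equal(unname(pp$ref_row$probs["A"]), 1)
  expect_equal(unname(pp$alt_row$probs["G"]), 1)
  expect_true(pp$confident)
})

test_that("7% recombinant mass gives trans with step probability 0.9257", {
  m <- toy_matrix(cell_counts(list("G", "G", 930), list("G", "A", 70),
                              list("A", "A", 930), list("A", "G", 70)),
                  up_ref = "G", up_alt = "A", dn_ref = "A", dn_alt = "G")
  pp <- phase_pair(m, error_mass = 0.01, seed = 4)
  expect_equal(pp$call, "trans")
  expect_equal(unname(pp$ref_row$probs["G"]), 0.99 * 0.93 + 0.0025,
               tolerance = 1e-15)
  expect_equal(unname(pp$alt_row$probs["A"]), 0.99 * 0.93 + 0.0025,
               tolerance = 1e-15)
})

test_that("zero coverage in an allele row is unphaseable", {
  m <- toy_matrix(cell_counts(list("G", "G", 100)),
                  up_ref = "G", up_alt = "A")
  pp <- phase_pair(m, seed = 1)
  expect_equal(pp$call, "unphaseable")
})

test_that("both rows selecting one base, or CI overlap, is ambiguous", {
  same <- toy_matrix(cell_counts(list("G", "G", 80), list("A", "G", 80)),
                     up_ref = "G", up_alt = "A", dn_ref = "A", dn_alt = "G")
  expect_equal(phase_pair(same, seed = 2)$call, "ambiguous")

  # row total 5 with a recombinant call: rejected-base CI overlaps
  low <- toy_matrix(cell_counts(list("G", "G", 4), list("G", "A", 1),
                                list("A", "A", 4), list("A", "G", 1)),
                    up_ref = "G", up_alt = "A", dn_ref = "A", dn_alt = "G")
  pp <- phase_pair(low, seed = 2)
  expect_equal(pp$call, "ambiguous")
  expect_false(pp$confident)
})

test_that("cumulative probability is the exact product of step probabilities", {
  # two junctions with adjusted step probabilities 0.9 and 0.8 (eps = 0)
  m1 <- toy_matrix(cell_counts(list("G", "G", 90), list("G", "A", 10),
                               list("A", "A", 90), list("A", "G", 10)),
                   up_pos = 100L, dn_pos = 200L,
                   up_ref = "G", up_alt = "A", dn_ref = "A", dn_alt = "G")
  m2 <- toy_matrix(cell_counts(list("G", "G", 80), list("G", "A", 20),
                               list("A", "A", 80), list("A", "G", 20)),
                   up_pos = 200L, dn_pos = 300L,
                   up_ref = "A", up_alt = "G", dn_ref = "A", dn_alt = "G")
  hc <- chain_phase(list(m1, m2), error_mass = 0, n_iter = 500, seed = 6)
  bb <- hc$allele1
  expect_equal(bb$step_prob, c(0.9, 0.8), tolerance = 1e-15)
  expect_lt(abs(bb$cum_prob[2] - 0.72), 1e-12)
  # single-matrix chain: cumulative equals the step
  h1 <- chain_phase(list(m1), error_mass = 0, n_iter = 500, seed = 6)
  expect_equal(h1$allele1$cum_prob, h1$allele1$step_prob)
  expect_equal(h1$allele1$cum_ci_low, h1$allele1$step_ci_low)
  expect_equal(h1$allele1$cum_ci_high, h1$allele1$step_ci_high)
})

test_that("disconnected matrices are rejected", {
  m1 <- toy_matrix(cell_counts(list("G", "G", 50)), up_pos = 100L,
                   dn_pos = 200L)
  m3 <- toy_matrix(cell_counts(list("G", "G", 50)), up_pos = 300L,
                   dn_pos = 400L)
  expect_error(chain_phase(list(m1, m3), seed = 1), "connected")
})

test_that("chained phasing recovers both haplotypes on simulated data", {
  cfg <- sim_config(n_sites = 6L, coverage = 300, seed = 52)
  sim <- simulate_fragments(cfg)
  sites <- sim$reference$sites
  ch <- adjacent_pairs_matrices(sim$observations, sites)
  hc <- chain_phase(ch, seed = 19)
  sp <- hc$site_phase
  expect_true(all(sp$phased))
  expect_true(all(sp$complementary))
  # chain 2 is the haplotype complement of chain 1
  expect_true(all(sp$hap1 == sites$hap1) || all(sp$hap1 == sites$hap2))
  expect_true(all(sp$hap2 == ifelse(sp$hap1 == sites$ref, sites$alt,
                                    sites$ref)))
  # exact product identity and monotone cumulative decay, both alleles
  for (bb in list(hc$allele1, hc$allele2)) {
    expect_lt(max(abs(bb$cum_prob - cumprod(bb$step_prob))), 1e-12)
    expect_true(all(diff(bb$cum_prob) <= 1e-12))
    expect_true(all(bb$verdict == "confident"))
  }
  # verdicts recompute identically from the stored intervals
  expect_equal(confidence_verdict(hc$allele1)$verdict, hc$allele1$verdict)
})

test_that("a zero-coverage row mid-chain breaks the phase set", {
  sites <- het_sites(rep("amplicon", 3), c(1000L, 2000L, 3000L),
                     c("G", "A", "C"), c("A", "G", "T"))
  # sites 1-2 linked G->C / A->A; between 2 and 3 only the A row is covered,
  # so the allele following C at site 2 hits an empty row
  frs <- c(
    lapply(1:30, function(i) c(`1000` = "G", `2000` = "C")),
    lapply(1:30, function(i) c(`1000` = "A", `2000` = "A")),
    lapply(1:30, function(i) c(`2000` = "A", `3000` = "T"))
  )
  fr <- do.call(make_fragments, frs)
  ch <- adjacent_pairs_matrices(fr, sites, min_total = 20L)
  expect_length(ch$links, 2L)
  hc <- chain_phase(ch, seed = 31)
  a1 <- hc$allele1
  expect_equal(a1$verdict[2], "break")
  sp <- hc$site_phase
  expect_true(all(sp$phased[1:2]))
  expect_false(sp$phased[3])      # stranded behind the break, singleton set
  expect_equal(sp$phase_set[1:2], c(1000L, 1000L))
})

test_that("an ambiguous junction splits the phase set in the site table", {
  m1 <- toy_matrix(cell_counts(list("G", "G", 450), list("G", "A", 50),
                               list("A", "A", 450), list("A", "G", 50)),
                   up_pos = 100L, dn_pos = 200L,
                   up_ref = "G", up_alt = "A", dn_ref = "A", dn_alt = "G")
  # junction 2 is nearly uninformative: selected and rejected CIs overlap
  m2 <- toy_matrix(cell_counts(list("G", "G", 3), list("G", "C", 2),
                               list("A", "C", 3), list("A", "G", 2)),
                   up_pos = 200L, dn_pos = 300L,
                   up_ref = "A", up_alt = "G", dn_ref = "C", dn_alt = "G")
  m3 <- toy_matrix(cell_counts(list("G", "G", 450), list("G", "C", 50),
                               list("C", "C", 450), list("C", "G", 50)),
                   up_pos = 300L, dn_pos = 400L,
                   up_ref = "C", up_alt = "G", dn_ref = "A", dn_alt = "G")
  hc <- chain_phase(list(m1, m2, m3), seed = 77)
  a1 <- hc$allele1
  expect_equal(a1$verdict[2], "ambiguous")
  expect_true(a1$downstream_of_ambiguity[3])
  sp <- hc$site_phase
  expect_equal(length(unique(na.omit(sp$phase_set))), 2L)
})
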