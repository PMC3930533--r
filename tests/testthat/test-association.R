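# Association matrices: tallies, pair enumeration, chain construction.

test_that("build_association_matrix tallies co-observed base calls", {
  sites <- het_sites(rep("amplicon", 2), c(60L, 2100L), c("G", "A"),
                     c("A", "G"), label = c("c.60", "IVS2-13"))
  fr <- make_fragments(
    c(`60` = "G", `2100` = "G"),
    c(`60` = "G", `2100` = "G"),
    c(`60` = "A", `2100` = "A"),
    c(`60` = "G", `2100` = "A"),
    c(`60` = "A", `2100` = "G")
  )
  m <- build_association_matrix(fr, sites[1, ], sites[2, ])
  expect_equal(m$counts["G", "G"], 2L)
  expect_equal(m$counts["A", "A"], 1L)
  expect_equal(m$counts["G", "A"], 1L)
  expect_equal(m$counts["A", "G"], 1L)
  expect_equal(m$total, 5L)
  expect_equal(sum(m$counts), 5L)

  # fragments observing only one site contribute nothing
  lone <- data.frame(fragment_id = "lone", pos = 60L, base = "G",
                     stringsAsFactors = FALSE)
  fr2 <- rbind(as.data.frame(fr), lone)
  class(fr2) <- class(fr)
  m2 <- build_association_matrix(fr2, sites[1, ], sites[2, ])
  expect_equal(m2$counts, m$counts)

  # no shared fragment -> all-zero matrix
  fr3 <- make_fragments(c(`60` = "G"), c(`2100` = "A"))
  m3 <- build_association_matrix(fr3, sites[1, ], sites[2, ])
  expect_equal(m3$total, 0L)
  expect_true(all(m3$counts == 0L))

  expect_error(build_association_matrix(fr, sites[1, ], sites[1, ]),
               "must differ")
  expect_error(build_association_matrix(fr, sites[2, ], sites[1, ]),
               "must precede")
})

test_that("matrix building is invariant to fragment order", {
  sites <- het_sites(rep("amplicon", 2), c(60L, 2100L), c("G", "A"),
                     c("A", "G"))
  fr <- make_fragments(
    c(`60` = "G", `2100` = "G"), c(`60` = "A", `2100` = "A"),
    c(`60` = "G", `2100` = "A"), c(`60` = "T", `2100` = "C")
  )
  m1 <- build_association_matrix(fr, sites[1, ], sites[2, ])
  set.seed(9)
  shuffled <- fr[sample(nrow(fr)), ]
  class(shuffled) <- class(fr)
  m2 <- build_association_matrix(shuffled, sites[1, ], sites[2, ])
  expect_identical(m1$counts, m2$counts)
})

test_that("all_pairs_matrices enumerates C(k,2) ordered pairs", {
  pos <- seq(500L, 5000L, length.out = 10L)
  sites <- het_sites(rep("amplicon", 10), as.integer(pos),
                     rep("G", 10), rep("A", 10))
  fr <- make_fragments(c(`500` = "G"))
  expect_length(all_pairs_matrices(fr, sites[1:3, ]), 3L)
  expect_length(all_pairs_matrices(fr, sites), 45L)
})

test_that("matrix totals match a brute-force double loop over fragments", {
  cfg <- sim_config(region_length = 6000L,
                    het_positions = data.frame(pos = c(800L, 2000L, 3500L, 5000L)),
                    mp_size_range = c(500L, 4000L), mp_size_mean = 1800,
                    coverage = 40, seed = 88)
  sim <- simulate_fragments(cfg)
  sites <- sim$reference$sites
  obs_by_frag <- split(sim$observations$pos, sim$observations$fragment_id)
  mats <- all_pairs_matrices(sim$observations, sites)
  n <- 0L
  for (i in 1:3) for (j in (i + 1):4) {
    n <- n + 1L
    brute <- sum(vapply(obs_by_frag, function(p) {
      sites$pos[i] %in% p && sites$pos[j] %in% p
    }, logical(1)))
    expect_equal(mats[[n]]$total, brute)
  }
})

test_that("error-free simulation puts mass only in the two truth cells", {
  cfg <- trans_pair_config(coverage = 80, seed = 17,
                           recombination_rate = 0, random_error_rate = 0)
  sim <- simulate_fragments(cfg)
  st <- sim$reference$sites
  m <- build_association_matrix(sim$observations, st[1, ], st[2, ])
  truth_cells <- rbind(c(st$hap1[1], st$hap1[2]), c(st$hap2[1], st$hap2[2]))
  off <- m$counts
  off[truth_cells] <- 0L
  expect_true(all(off == 0L))
  expect_gt(m$counts[st$hap1[1], st$hap1[2]], 0L)
  expect_gt(m$counts[st$hap2[1], st$hap2[2]], 0L)
})

test_that("adjacent chain covers K sites with K-1 links when coverage is good", {
  cfg <- sim_config(region_length = 6000L,
                    het_positions = data.frame(pos = c(800L, 2000L, 3500L, 5000L)),
                    mp_size_range = c(500L, 4000L), mp_size_mean = 1800,
                    coverage = 60, seed = 123)
  sim <- simulate_fragments(cfg)
  ch <- adjacent_pairs_matrices(sim$observations, sim$reference$sites,
                                min_total = 20L)
  expect_length(ch$links, 3L)
  expect_equal(vapply(ch$links, `[[`, integer(1), "from"), 1:3)
  expect_equal(vapply(ch$links, `[[`, integer(1), "to"), 2:4)
  expect_length(ch$breaks, 0L)
  expect_true(all(vapply(ch$links, function(l) l$matrix$total, integer(1)) >= 20L))
})

test_that("an uncovered middle site is bridged and a dead junction breaks the chain", {
  sites <- het_sites(rep("amplicon", 3), c(1000L, 2000L, 3000L),
                     rep("G", 3), rep("A", 3))
  # 30 fragments link sites 1 and 3; site 2 never observed -> bridge
  frs <- lapply(1:30, function(i) c(`1000` = "G", `3000` = "G"))
  fr <- do.call(make_fragments, frs)
  ch <- adjacent_pairs_matrices(fr, sites, min_total = 20L)
  expect_length(ch$links, 1L)
  expect_equal(ch$links[[1]]$from, 1L)
  expect_equal(ch$links[[1]]$to, 3L)
  expect_equal(ch$links[[1]]$skipped, 2L)
  expect_named(ch$links[[1]]$branch_matrices, "2")

  # no fragment reaches past site 1 at all -> declared break, then 2-3 links
  frs2 <- c(lapply(1:25, function(i) c(`1000` = "G")),
            lapply(1:25, function(i) c(`2000` = "A", `3000` = "A")))
  fr2 <- do.call(make_fragments, frs2)
  ch2 <- adjacent_pairs_matrices(fr2, sites, min_total = 20L)
  expect_equal(ch2$breaks, 2L)
  expect_length(ch2$links, 1L)
  expect_equal(ch2$links[[1]]$from, 2L)
  expect_true(ch2$links[[1]]$new_segment)
})

test_that("matrix TSV report is bit-exact and row-major", {
  m <- toy_matrix(cell_counts(list("G", "G", 7), list("A", "A", 3),
                              list("G", "A", 1)))
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(list(m), f)
  tab <- utils::read.delim(f)
  expect_equal(tab$GG, 7L)
  expect_equal(tab$AA, 3L)
  expect_equal(tab$GA, 1L)
  expect_equal(tab$total, 11L)
})
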