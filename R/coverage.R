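# Linked-coverage profiling and the CI-width-versus-coverage simulation.

#' Linked coverage as a function of inter-position distance
#'
#' For each offset `delta`, counts over positions `x` in the region the
#' number of fragments whose reads cover both `x` and `x + delta`, and
#' reports the mean over the region length (so mean times region length
#' recovers the total incidence count). Coverage by a fragment is the
#' union of its two read intervals, so intra-read pairs (delta below the
#' read length) are counted too; the default grid starts at 101 bp,
#' which excludes them.
#'
#' @param fragments an `mp_sim` object, or a data frame with read
#'   intervals `r1_start`, `r1_end`, `r2_start`, `r2_end`.
#' @param region_length region length in bp (taken from the simulation
#'   when `fragments` is an `mp_sim`).
#' @param delta integer offsets in bp (default 101:3000).
#' @return data frame of class `linked_coverage_profile` with columns
#'   `delta` and `mean_linked_coverage`.
#' @export
linked_coverage_profile <- function(fragments, region_length = NULL,
                                    delta = 101:3000) {
  if (inherits(fragments, "mp_sim")) {
    region_length <- region_length %||% fragments$config$region_length
    fragments <- fragments$fragments
  }
  stopifnot(!is.null(region_length),
            all(c("r1_start", "r1_end", "r2_start", "r2_end")
                %in% names(fragments)))
  delta <- as.integer(delta)
  if (length(delta) == 0L || any(delta < 1L)) stop("delta must be >= 1")
  if (is.unsorted(delta)) stop("delta grid must be sorted ascending")

  a1 <- fragments$r1_start; b1 <- fragments$r1_end
  a2 <- fragments$r2_start; b2 <- fragments$r2_end
  # coverage footprint of a fragment = union of the two read intervals;
  # merge when they touch or overlap
  merged <- a2 <= b1 + 1L
  u1a <- a1[merged]; u1b <- pmax(b1, b2)[merged]
  a1s <- a1[!merged]; b1s <- b1[!merged]
  a2s <- a2[!merged]; b2s <- b2[!merged]
  len_m <- u1b - u1a + 1L
  len1 <- b1s - a1s + 1L
  len2 <- b2s - a2s + 1L

  counts <- vapply(delta, function(d) {
    # single merged interval: pairs entirely inside it
    n_m <- sum(pmax(len_m - d, 0L))
    # two disjoint intervals: within each, plus across them
    n_intra <- sum(pmax(len1 - d, 0L)) + sum(pmax(len2 - d, 0L))
    lo <- pmax(a1s, a2s - d)
    hi <- pmin(b1s, b2s - d)
    n_cross <- sum(pmax(hi - lo + 1L, 0L))
    n_m + n_intra + n_cross
  }, numeric(1))

  out <- data.frame(delta = delta,
                    mean_linked_coverage = counts / region_length)
  class(out) <- c("linked_coverage_profile", "data.frame")
  out
}

#' Average bootstrap CI width as a function of coverage
#'
#' Mirrors the diminishing-returns simulation: for each coverage `N` in
#' the grid, multinomial counts are drawn from a fixed row probability
#' vector (taken from a real or simulated association-matrix row), the
#' row bootstrap is run, and the CI width `ci_high - ci_low` is averaged
#' over all four bases and over replicates. Replicate seeds are paired
#' across coverages so the curve is smooth in `N`.
#'
#' @param row_probs 4 probabilities summing to 1 (base order A, C, G, T).
#' @param coverage_grid positive integer coverages to evaluate.
#' @inheritParams bootstrap_row
#' @param replicates outer multinomial replicates per coverage.
#' @return data frame with columns `coverage` and `mean_ci_width`.
#' @export
ci_width_vs_coverage <- function(row_probs, coverage_grid,
                                 error_mass = 0.01, n_iter = 1000L,
                                 replicates = 100L, seed = NULL) {
  stopifnot(length(row_probs) == 4L, all(row_probs >= 0),
            abs(sum(row_probs) - 1) < 1e-8,
            all(coverage_grid >= 1))
  if (is.null(seed)) stop("ci_width_vs_coverage() requires an explicit seed")

  widths <- vapply(seq_along(coverage_grid), function(gi) {
    N <- as.integer(coverage_grid[gi])
    w <- vapply(seq_len(replicates), function(r) {
      counts <- withr::with_seed(sub_seed(seed, 7000L + r),
        as.vector(stats::rmultinom(1L, N, row_probs)))
      bs <- bootstrap_row(counts, error_mass, n_iter,
                          seed = sub_seed(seed, 8000L + r),
                          keep_draws = FALSE)
      mean(bs$ci_high - bs$ci_low)
    }, numeric(1))
    mean(w)
  }, numeric(1))

  data.frame(coverage = as.integer(coverage_grid), mean_ci_width = widths)
}

#' Write a linked-coverage profile as TSV
#'
#' @param profile a [linked_coverage_profile] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_profile_tsv <- function(profile, file) {
  utils::write.table(as.data.frame(profile), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
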