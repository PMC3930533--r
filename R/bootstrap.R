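# Row-wise multinomial bootstrap with injected error mass.

#' Bootstrap one association-matrix row
#'
#' Converts the observed counts of one upstream-base row into downstream
#' base-call probabilities, adds a small error mass to absorb random
#' sequencing error, and resamples: the adjusted probabilities are
#' `p_b = (1 - eps) * c_b / n + eps / 4`, and each of `n_iter` iterations
#' draws `multinomial(n, p)` counts and converts them back to proportions
#' (`n` = the observed row total). The reported confidence interval per
#' base is the 1st and 99th nearest-rank percentile of those proportion
#' draws — the literal "1% and 99% values" rule; it is labelled a 99% CI
#' even though the nominal coverage of a 1st–99th percentile band is 98%.
#'
#' @param row_counts 4 non-negative integers in base order A, C, G, T (a
#'   named vector is reordered by name).
#' @param error_mass total injected error probability `eps` in `[0, 1)`
#'   (default 0.01), split uniformly over the four bases.
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed integer seed (mandatory).
#' @param keep_draws keep the 4 x `n_iter` draw matrix (needed for
#'   cumulative chain intervals).
#' @return object of class `row_bootstrap`: list with `probs`, `ci_low`,
#'   `ci_high` (named length-4), `n_row`, `n_iter`, `error_mass` and
#'   optionally `draws`. When the row total is zero, a zero-coverage
#'   marker (`n_row = 0`, all else `NA`) is returned; callers must treat
#'   it as a chain break.
#' @export
bootstrap_row <- function(row_counts, error_mass = 0.01, n_iter = 1000L,
                          seed = NULL, keep_draws = TRUE) {
  stopifnot(length(row_counts) == 4L, all(row_counts >= 0),
            error_mass >= 0, error_mass < 1, n_iter >= 100L)
  if (!is.null(names(row_counts))) {
    stopifnot(setequal(names(row_counts), BASES))
    row_counts <- row_counts[BASES]
  }
  counts <- as.numeric(row_counts)
  n_row <- sum(counts)
  if (n_row == 0) {
    return(structure(list(
      probs = stats::setNames(rep(NA_real_, 4L), BASES),
      ci_low = stats::setNames(rep(NA_real_, 4L), BASES),
      ci_high = stats::setNames(rep(NA_real_, 4L), BASES),
      n_row = 0L, n_iter = as.integer(n_iter), error_mass = error_mass,
      draws = NULL
    ), class = "row_bootstrap"))
  }
  if (is.null(seed)) stop("bootstrap_row() requires an explicit seed")

  p <- (1 - error_mass) * counts / n_row + error_mass / 4
  draws <- withr::with_seed(as.integer(seed),
    stats::rmultinom(n_iter, size = n_row, prob = p) / n_row)
  rownames(draws) <- BASES

  ci_low <- apply(draws, 1L, pctile_nearest_rank, q = 0.01)
  ci_high <- apply(draws, 1L, pctile_nearest_rank, q = 0.99)
  structure(list(
    probs = stats::setNames(p, BASES),
    ci_low = stats::setNames(ci_low, BASES),
    ci_high = stats::setNames(ci_high, BASES),
    n_row = as.integer(n_row),
    n_iter = as.integer(n_iter),
    error_mass = error_mass,
    draws = if (keep_draws) draws else NULL
  ), class = "row_bootstrap")
}

#' @export
print.row_bootstrap <- function(x, ...) {
  if (x$n_row == 0L) {
    cat("row_bootstrap: zero coverage\n")
    return(invisible(x))
  }
  df <- data.frame(base = BASES, prob = x$probs,
                   ci_low = x$ci_low, ci_high = x$ci_high)
  rownames(df) <- NULL
  cat(sprintf("row_bootstrap: n_row = %d, n_iter = %d, error_mass = %g\n",
              x$n_row, x$n_iter, x$error_mass))
  print(df, digits = 4)
  invisible(x)
}

#' Cumulative confidence intervals along a phasing chain
#'
#' Given the per-step bootstrap proportion draws of the selected base,
#' forms the per-iteration running product (iterations paired by index;
#' the steps' resamples are independent, matching the physical
#' independence of each matrix's fragment set) and reports the 1st/99th
#' nearest-rank percentile of the product distribution at every step.
#'
#' @param step_draws list of numeric vectors, one per step, all of the
#'   same length `n_iter`.
#' @return data frame with columns `step`, `low`, `high`.
#' @export
cumulative_ci <- function(step_draws) {
  stopifnot(length(step_draws) >= 1L)
  n_iter <- unique(vapply(step_draws, length, integer(1)))
  stopifnot(length(n_iter) == 1L)
  prod_draws <- rep(1, n_iter)
  out <- data.frame(step = seq_along(step_draws), low = NA_real_,
                    high = NA_real_)
  for (k in seq_along(step_draws)) {
    prod_draws <- prod_draws * step_draws[[k]]
    out$low[k] <- pctile_nearest_rank(prod_draws, 0.01)
    out$high[k] <- pctile_nearest_rank(prod_draws, 0.99)
  }
  out
}

# argmax with the fixed-order tie-break; returns list(base, tie)
select_base <- function(probs) {
  mx <- max(probs)
  winners <- which(probs == mx)
  list(base = BASES[winners[1L]], tie = length(winners) > 1L)
}
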