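# Decomposition of association-matrix error into recombinant and random
# components, given a known phase.

#' Classify linked base-call pairs against a known phase
#'
#' Every pair of base calls co-observed by one fragment at two
#' heterozygous sites is classified: `concordant` when both bases belong
#' to the same haplotype, `recombinant` when each base is a valid allele
#' but they come from different haplotypes (the chimera signature), and
#' `other` when either base is not a valid allele of its site (random
#' base-call error). The three categories are disjoint and exhaustive;
#' their definitions are symmetric under swapping the haplotype labels.
#'
#' @param fragments a `linked_fragments` table (or `mp_sim`, whose
#'   observations are used).
#' @param sites a [het_sites] table carrying the known phase as columns
#'   `hap1` and `hap2` (e.g. the simulator truth, or a confident chain's
#'   `site_phase`).
#' @param pairs `"all"` (default) to pool every ordered site pair, or
#'   `"adjacent"` for consecutive sites only.
#' @return object of class `error_decomposition`: list with `per_pair`
#'   (data frame: pair, counts, fractions) and `overall` (named totals
#'   and fractions).
#' @export
decompose_errors <- function(fragments, sites, pairs = c("all", "adjacent")) {
  pairs <- match.arg(pairs)
  if (inherits(fragments, "mp_sim")) fragments <- fragments$observations
  if (!all(c("hap1", "hap2") %in% names(sites))) {
    stop("sites must carry a known phase (hap1/hap2 columns)")
  }
  if (any(is.na(sites$hap1)) || any(is.na(sites$hap2))) {
    stop("known phase is incomplete (NA haplotype alleles)")
  }

  obs <- as.data.frame(fragments)
  srow <- match(obs$pos, sites$pos)
  stopifnot(!anyNA(srow))
  obs$hap_of_base <- ifelse(obs$base == sites$hap1[srow], 1L,
                            ifelse(obs$base == sites$hap2[srow], 2L, NA_integer_))

  both <- merge(obs, obs, by = "fragment_id", suffixes = c("_1", "_2"))
  both <- both[both$pos_1 < both$pos_2, , drop = FALSE]
  if (pairs == "adjacent") {
    i1 <- match(both$pos_1, sites$pos)
    i2 <- match(both$pos_2, sites$pos)
    both <- both[i2 == i1 + 1L, , drop = FALSE]
  }

  cls <- ifelse(is.na(both$hap_of_base_1) | is.na(both$hap_of_base_2),
                "other",
                ifelse(both$hap_of_base_1 == both$hap_of_base_2,
                       "concordant", "recombinant"))

  tab_for <- function(ix) {
    n <- length(ix)
    conc <- sum(cls[ix] == "concordant")
    rec <- sum(cls[ix] == "recombinant")
    oth <- n - conc - rec
    c(total = n, concordant = conc, recombinant = rec, other = oth)
  }

  key <- paste(both$pos_1, both$pos_2, sep = "-")
  groups <- split(seq_along(cls), key)
  per_pair <- do.call(rbind, lapply(names(groups), function(k) {
    v <- tab_for(groups[[k]])
    p <- strsplit(k, "-", fixed = TRUE)[[1]]
    data.frame(pos_1 = as.integer(p[1]), pos_2 = as.integer(p[2]),
               total = v["total"], concordant = v["concordant"],
               recombinant = v["recombinant"], other = v["other"],
               frac_concordant = if (v["total"] > 0) v["concordant"] / v["total"] else NA_real_,
               frac_recombinant = if (v["total"] > 0) v["recombinant"] / v["total"] else NA_real_,
               frac_other = if (v["total"] > 0) v["other"] / v["total"] else NA_real_,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (!is.null(per_pair)) {
    per_pair <- per_pair[order(per_pair$pos_1, per_pair$pos_2), , drop = FALSE]
    rownames(per_pair) <- NULL
  } else {
    per_pair <- data.frame(pos_1 = integer(0), pos_2 = integer(0),
                           total = integer(0), concordant = integer(0),
                           recombinant = integer(0), other = integer(0),
                           frac_concordant = numeric(0),
                           frac_recombinant = numeric(0),
                           frac_other = numeric(0))
  }

  v <- tab_for(seq_along(cls))
  overall <- list(
    total = unname(v["total"]),
    concordant = unname(v["concordant"]),
    recombinant = unname(v["recombinant"]),
    other = unname(v["other"]),
    frac_concordant = if (v["total"] > 0) unname(v["concordant"] / v["total"]) else NA_real_,
    frac_recombinant = if (v["total"] > 0) unname(v["recombinant"] / v["total"]) else NA_real_,
    frac_other = if (v["total"] > 0) unname(v["other"] / v["total"]) else NA_real_
  )
  structure(list(per_pair = per_pair, overall = overall, pairs = pairs),
            class = "error_decomposition")
}

#' @export
print.error_decomposition <- function(x, ...) {
  o <- x$overall
  cat(sprintf("error_decomposition over %d linked pairs (%s site pairs)\n",
              o$total, x$pairs))
  if (o$total > 0) {
    cat(sprintf("  concordant  %6d  (%.2f%%)\n", o$concordant, 100 * o$frac_concordant))
    cat(sprintf("  recombinant %6d  (%.2f%%)\n", o$recombinant, 100 * o$frac_recombinant))
    cat(sprintf("  other       %6d  (%.2f%%)\n", o$other, 100 * o$frac_other))
  }
  invisible(x)
}

#' Write an error decomposition as TSV
#'
#' @param decomposition an [decompose_errors] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_decomposition_tsv <- function(decomposition, file) {
  utils::write.table(decomposition$per_pair, file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
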