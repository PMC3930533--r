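# Pairwise and chained phase calls from association matrices.

#' Phase one pair of heterozygous sites
#'
#' Bootstraps the two rows of an association matrix that correspond to the
#' upstream site's ref and alt alleles and compares the selected
#' downstream bases with the downstream site's alleles. The configuration
#' is `cis` when ref associates with ref and alt with alt, `trans` when
#' ref associates with alt and alt with ref, and `ambiguous` when both
#' rows pick the same base, when a row's argmax is tied, or when a
#' selected base's CI lower bound does not clear every rejected base's CI
#' upper bound in its row. Zero coverage in either allele row yields an
#' `unphaseable` call.
#'
#' @param matrix an `assoc_matrix` whose sites carry `ref`/`alt` columns.
#' @inheritParams bootstrap_row
#' @return object of class `pair_phase`: list with `call` (one of `cis`,
#'   `trans`, `ambiguous`, `unphaseable`), `ref_row` and `alt_row`
#'   ([bootstrap_row] results), `ref_select`, `alt_select` (selected
#'   downstream bases) and `confident` (logical).
#' @export
phase_pair <- function(matrix, error_mass = 0.01, n_iter = 1000L,
                       seed = NULL) {
  if (is.null(seed)) stop("phase_pair() requires an explicit seed")
  up <- matrix$upstream; dn <- matrix$downstream
  ref_counts <- matrix$counts[up$ref, ]
  alt_counts <- matrix$counts[up$alt, ]
  if (sum(ref_counts) == 0 || sum(alt_counts) == 0) {
    return(structure(list(call = "unphaseable",
                          ref_row = NULL, alt_row = NULL,
                          ref_select = NA_character_,
                          alt_select = NA_character_,
                          confident = FALSE,
                          matrix = matrix), class = "pair_phase"))
  }
  ref_bs <- bootstrap_row(ref_counts, error_mass, n_iter,
                          seed = sub_seed(seed, 11L))
  alt_bs <- bootstrap_row(alt_counts, error_mass, n_iter,
                          seed = sub_seed(seed, 12L))
  ref_sel <- select_base(ref_bs$probs)
  alt_sel <- select_base(alt_bs$probs)

  row_clear <- function(bs, sel) {
    rej <- setdiff(BASES, sel$base)
    !sel$tie && bs$ci_low[sel$base] > max(bs$ci_high[rej])
  }
  confident <- row_clear(ref_bs, ref_sel) && row_clear(alt_bs, alt_sel)

  call <- if (ref_sel$base == alt_sel$base || !confident) {
    "ambiguous"
  } else if (ref_sel$base == dn$ref && alt_sel$base == dn$alt) {
    "cis"
  } else if (ref_sel$base == dn$alt && alt_sel$base == dn$ref) {
    "trans"
  } else {
    "ambiguous"
  }
  structure(list(call = call, ref_row = ref_bs, alt_row = alt_bs,
                 ref_select = ref_sel$base, alt_select = alt_sel$base,
                 confident = confident, matrix = matrix),
            class = "pair_phase")
}

#' @export
print.pair_phase <- function(x, ...) {
  m <- x$matrix
  cat(sprintf("pair_phase %s / %s: %s\n",
              m$upstream$label, m$downstream$label, toupper(x$call)))
  if (!is.null(x$ref_row)) {
    cat(sprintf("  %s row -> %s  p = %.4f  CI [%.4f, %.4f]\n",
                m$upstream$ref, x$ref_select,
                x$ref_row$probs[x$ref_select],
                x$ref_row$ci_low[x$ref_select],
                x$ref_row$ci_high[x$ref_select]))
    cat(sprintf("  %s row -> %s  p = %.4f  CI [%.4f, %.4f]\n",
                m$upstream$alt, x$alt_select,
                x$alt_row$probs[x$alt_select],
                x$alt_row$ci_low[x$alt_select],
                x$alt_row$ci_high[x$alt_select]))
  }
  invisible(x)
}

start_base_for <- function(site, allele, rule) {
  first <- switch(rule,
    ref = site$ref,
    alt = site$alt,
    lex = min(site$ref, site$alt)
  )
  second <- if (first == site$ref) site$alt else site$ref
  if (allele == 1L) first else second
}

#' Chain association matrices into two phased haplotypes
#'
#' Walks the matrix chain Markov-style: at each junction the row of the
#' current base is bootstrapped, the highest-probability downstream base
#' is selected and becomes the current base for the next junction. The
#' allele-1 chain starts from the base chosen by `start_base_rule` at the
#' first site; the allele-2 chain starts from the other base, phasing the
#' opposite allele as a cross-check. Each step records the step
#' probability and CI, the running cumulative probability (exact product
#' of step probabilities) and the cumulative CI (per-iteration product of
#' the bootstrap draws), plus the confidence verdict: a step is confident
#' while the cumulative CI lower bound stays above the CI upper bound of
#' every rejected base at that step. A zero-coverage row breaks the chain
#' and phasing restarts at the next site with a fresh phase set. Sites
#' bridged over by a low-coverage junction are phased as side branches
#' from their upstream anchor.
#'
#' @param chain an `assoc_chain` from [adjacent_pairs_matrices], or a
#'   plain connected list of `assoc_matrix` (downstream of one = upstream
#'   of the next).
#' @inheritParams bootstrap_row
#' @param start_base_rule which base anchors the allele-1 chain at the
#'   first site of each segment: the site's `"ref"` (default), `"alt"`,
#'   or the `"lex"`icographically smaller allele.
#' @return object of class `haplotype_chains`: list with `allele1`,
#'   `allele2` (per-step data frames), `site_phase` (per-site haplotype
#'   assignment with phase sets) and `sites`.
#' @export
chain_phase <- function(chain, error_mass = 0.01, n_iter = 1000L,
                        seed = NULL,
                        start_base_rule = c("ref", "alt", "lex")) {
  start_base_rule <- match.arg(start_base_rule)
  if (is.null(seed)) stop("chain_phase() requires an explicit seed")
  chain <- as_assoc_chain(chain)
  sites <- chain$sites

  alleles <- lapply(1:2, function(a) {
    walk_chain(chain, a, error_mass, n_iter, seed, start_base_rule)
  })
  site_phase <- build_site_phase(chain, alleles[[1]], alleles[[2]])
  structure(list(allele1 = alleles[[1]], allele2 = alleles[[2]],
                 site_phase = site_phase, sites = sites),
            class = "haplotype_chains")
}

as_assoc_chain <- function(chain) {
  if (inherits(chain, "assoc_chain")) return(chain)
  stopifnot(is.list(chain), length(chain) >= 1L,
            all(vapply(chain, inherits, logical(1), "assoc_matrix")))
  pos <- unlist(lapply(chain, function(m) c(m$upstream$pos, m$downstream$pos)))
  for (k in seq_len(length(chain) - 1L)) {
    if (chain[[k]]$downstream$pos != chain[[k + 1L]]$upstream$pos) {
      stop("matrices do not form a connected chain")
    }
  }
  site_rows <- c(lapply(chain, `[[`, "upstream"),
                 list(chain[[length(chain)]]$downstream))
  sites <- do.call(rbind, site_rows)
  class(sites) <- c("het_sites", "data.frame")
  links <- lapply(seq_along(chain), function(k) {
    list(matrix = chain[[k]], from = k, to = k + 1L,
         skipped = integer(0), new_segment = (k == 1L))
  })
  structure(list(links = links, sites = sites, min_total = 0L,
                 breaks = integer(0)), class = "assoc_chain")
}

empty_chain_df <- function() {
  data.frame(
    allele = integer(0), segment = integer(0), step = integer(0),
    from_pos = integer(0), to_pos = integer(0),
    from_base = character(0), to_base = character(0),
    n_row = integer(0), step_prob = numeric(0),
    step_ci_low = numeric(0), step_ci_high = numeric(0),
    max_rej_ci_high = numeric(0),
    cum_prob = numeric(0), cum_ci_low = numeric(0), cum_ci_high = numeric(0),
    tie = logical(0), verdict = character(0),
    downstream_of_ambiguity = logical(0), branch = logical(0),
    stringsAsFactors = FALSE
  )
}

walk_chain <- function(chain, allele, error_mass, n_iter, seed, rule) {
  sites <- chain$sites
  rows <- list()
  segment <- 0L
  cum_prob <- NA_real_
  cum_draws <- NULL
  current_base <- NA_character_
  pending_new <- TRUE
  ambiguous_seen <- FALSE
  step_no <- 0L

  for (li in seq_along(chain$links)) {
    link <- chain$links[[li]]
    m <- link$matrix
    from_site <- sites[link$from, , drop = FALSE]
    to_site <- sites[link$to, , drop = FALSE]
    if (link$new_segment || pending_new) {
      segment <- segment + 1L
      current_base <- start_base_for(from_site, allele, rule)
      cum_prob <- 1
      cum_draws <- rep(1, n_iter)
      ambiguous_seen <- FALSE
      pending_new <- FALSE
    }
    step_no <- step_no + 1L
    row_counts <- m$counts[current_base, ]
    n_row <- sum(row_counts)

    if (n_row == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        allele = allele, segment = segment, step = step_no,
        from_pos = from_site$pos, to_pos = to_site$pos,
        from_base = current_base, to_base = NA_character_,
        n_row = 0L, step_prob = NA_real_,
        step_ci_low = NA_real_, step_ci_high = NA_real_,
        max_rej_ci_high = NA_real_,
        cum_prob = NA_real_, cum_ci_low = NA_real_, cum_ci_high = NA_real_,
        tie = FALSE, verdict = "break",
        downstream_of_ambiguity = ambiguous_seen, branch = FALSE,
        stringsAsFactors = FALSE
      )
      pending_new <- TRUE
      next
    }

    bs <- bootstrap_row(row_counts, error_mass, n_iter,
                        seed = sub_seed(seed, 100L + allele * 1000L + li))
    sel <- select_base(bs$probs)
    step_prob <- unname(bs$probs[sel$base])
    cum_prob <- cum_prob * step_prob
    cum_draws <- cum_draws * bs$draws[sel$base, ]
    cum_low <- pctile_nearest_rank(cum_draws, 0.01)
    cum_high <- pctile_nearest_rank(cum_draws, 0.99)
    rej <- setdiff(BASES, sel$base)
    max_rej <- max(bs$ci_high[rej])
    confident <- !sel$tie && cum_low > max_rej
    verdict <- if (confident) "confident" else "ambiguous"
    rows[[length(rows) + 1L]] <- data.frame(
      allele = allele, segment = segment, step = step_no,
      from_pos = from_site$pos, to_pos = to_site$pos,
      from_base = current_base, to_base = sel$base,
      n_row = as.integer(n_row), step_prob = step_prob,
      step_ci_low = unname(bs$ci_low[sel$base]),
      step_ci_high = unname(bs$ci_high[sel$base]),
      max_rej_ci_high = max_rej,
      cum_prob = cum_prob, cum_ci_low = cum_low, cum_ci_high = cum_high,
      tie = sel$tie, verdict = verdict,
      downstream_of_ambiguity = ambiguous_seen, branch = FALSE,
      stringsAsFactors = FALSE
    )
    if (!confident) ambiguous_seen <- TRUE

    # side branches: bridged sites phased from the upstream anchor
    for (sk in link$skipped) {
      step_no <- step_no + 1L
      rows[[length(rows) + 1L]] <- branch_step(
        chain, link, sk, allele, segment, step_no, current_base,
        cum_prob / step_prob, cum_draws / bs$draws[sel$base, ],
        error_mass, n_iter,
        sub_seed(seed, 100L + allele * 1000L + 500L + sk),
        ambiguous_seen)
    }
    current_base <- sel$base
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else empty_chain_df()
  rownames(out) <- NULL
  out
}

# Phase one bridged site from its upstream anchor (the `from` site of the
# link that skipped it). The branch does not extend the backbone chain.
branch_step <- function(chain, link, sk, allele, segment, step_no,
                        anchor_base, cum_before, cum_draws_before,
                        error_mass, n_iter, seed, ambiguous_seen) {
  sites <- chain$sites
  anchor <- sites[link$from, , drop = FALSE]
  sk_site <- sites[sk, , drop = FALSE]
  bm <- link$branch_matrices[[as.character(sk)]]
  row_counts <- if (is.null(bm)) stats::setNames(rep(0L, 4L), BASES) else
    bm$counts[anchor_base, ]
  n_row <- sum(row_counts)
  base <- data.frame(
    allele = allele, segment = segment, step = step_no,
    from_pos = anchor$pos, to_pos = sk_site$pos,
    from_base = anchor_base, to_base = NA_character_,
    n_row = as.integer(n_row), step_prob = NA_real_,
    step_ci_low = NA_real_, step_ci_high = NA_real_,
    max_rej_ci_high = NA_real_,
    cum_prob = NA_real_, cum_ci_low = NA_real_, cum_ci_high = NA_real_,
    tie = FALSE, verdict = "break",
    downstream_of_ambiguity = ambiguous_seen, branch = TRUE,
    stringsAsFactors = FALSE
  )
  if (n_row == 0L) return(base)
  bs <- bootstrap_row(row_counts, error_mass, n_iter, seed = seed)
  sel <- select_base(bs$probs)
  step_prob <- unname(bs$probs[sel$base])
  cum_draws <- cum_draws_before * bs$draws[sel$base, ]
  cum_low <- pctile_nearest_rank(cum_draws, 0.01)
  cum_high <- pctile_nearest_rank(cum_draws, 0.99)
  rej <- setdiff(BASES, sel$base)
  max_rej <- max(bs$ci_high[rej])
  confident <- !sel$tie && cum_low > max_rej
  base$to_base <- sel$base
  base$step_prob <- step_prob
  base$step_ci_low <- unname(bs$ci_low[sel$base])
  base$step_ci_high <- unname(bs$ci_high[sel$base])
  base$max_rej_ci_high <- max_rej
  base$cum_prob <- cum_before * step_prob
  base$cum_ci_low <- cum_low
  base$cum_ci_high <- cum_high
  base$tie <- sel$tie
  base$verdict <- if (confident) "confident" else "ambiguous"
  base
}

# Per-site haplotype assignment with VCF-style phase sets. Phase sets
# break at declared chain breaks and at junctions whose pairwise step CI
# overlaps a rejected base (relative phase across that junction is
# unsupported); singleton sets are reported unphased. Note the chain
# report's verdict is anchored at the segment start (the paper's
# cumulative rule), whereas phase-set membership only requires each
# junction inside the set to be individually clean — the set re-anchors
# the cumulative product at its first site.
build_site_phase <- function(chain, c1, c2) {
  sites <- chain$sites
  k <- nrow(sites)
  hap1 <- hap2 <- rep(NA_character_, k)
  ps <- rep(NA_integer_, k)

  step_ok <- function(st) {
    nrow(st) == 1L && st$verdict != "break" && !st$tie &&
      !is.na(st$step_ci_low) && st$step_ci_low > st$max_rej_ci_high
  }

  backbone <- c1[!c1$branch, , drop = FALSE]
  backbone2 <- c2[!c2$branch, , drop = FALSE]
  current_ps <- NA_integer_
  for (r in seq_len(nrow(backbone))) {
    st <- backbone[r, ]
    st2 <- backbone2[backbone2$step == st$step, , drop = FALSE]
    i_from <- match(st$from_pos, sites$pos)
    i_to <- match(st$to_pos, sites$pos)
    if (!step_ok(st) || !step_ok(st2)) {
      # junction unusable: the downstream site starts a fresh phase set
      current_ps <- NA_integer_
      next
    }
    fresh <- is.na(current_ps) || is.na(ps[i_from])
    if (fresh) {
      current_ps <- st$from_pos
      hap1[i_from] <- st$from_base
      hap2[i_from] <- st2$from_base
      ps[i_from] <- current_ps
    }
    hap1[i_to] <- st$to_base
    hap2[i_to] <- st2$to_base
    ps[i_to] <- current_ps
  }
  # clean side branches join their anchor's phase set
  branches <- c1[c1$branch, , drop = FALSE]
  branches2 <- c2[c2$branch, , drop = FALSE]
  for (r in seq_len(nrow(branches))) {
    st <- branches[r, ]
    i_anchor <- match(st$from_pos, sites$pos)
    i_sk <- match(st$to_pos, sites$pos)
    st2 <- branches2[branches2$to_pos == st$to_pos, , drop = FALSE]
    if (!step_ok(st) || !step_ok(st2) || is.na(ps[i_anchor])) next
    hap1[i_sk] <- st$to_base
    hap2[i_sk] <- st2$to_base
    ps[i_sk] <- ps[i_anchor]
  }

  # a phase set needs at least two phased sites to mean anything
  phased <- !is.na(hap1) & !is.na(ps)
  for (v in unique(ps[!is.na(ps)])) {
    members <- which(ps == v & phased)
    if (length(members) < 2L) {
      phased[members] <- FALSE
      ps[members] <- NA_integer_
      hap1[members] <- NA_character_
      hap2[members] <- NA_character_
    }
  }
  complementary <- phased & !is.na(hap2) & hap1 != hap2
  data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    label = sites$label,
    hap1 = hap1, hap2 = hap2, phased = phased, phase_set = ps,
    complementary = complementary,
    stringsAsFactors = FALSE
  )
}

#' Recompute per-step confidence verdicts for a chain
#'
#' A step is confident while the cumulative CI lower bound exceeds the CI
#' upper bound of every rejected base at that step; once a step turns
#' ambiguous, later steps in the segment are additionally flagged as
#' downstream of the ambiguity.
#'
#' @param chain_df a per-allele step data frame from [chain_phase].
#' @return the data frame with refreshed `verdict` and
#'   `downstream_of_ambiguity` columns.
#' @export
confidence_verdict <- function(chain_df) {
  stopifnot(all(c("cum_ci_low", "max_rej_ci_high", "segment")
                %in% names(chain_df)))
  out <- chain_df
  for (seg in unique(out$segment)) {
    idx <- which(out$segment == seg & !out$branch)
    seen <- FALSE
    for (i in idx) {
      if (out$verdict[i] == "break") { out$downstream_of_ambiguity[i] <- seen; next }
      ok <- !out$tie[i] &&
        !is.na(out$cum_ci_low[i]) &&
        out$cum_ci_low[i] > out$max_rej_ci_high[i]
      out$verdict[i] <- if (ok) "confident" else "ambiguous"
      out$downstream_of_ambiguity[i] <- seen
      if (!ok) seen <- TRUE
    }
  }
  out
}

#' @export
print.haplotype_chains <- function(x, ...) {
  sp <- x$site_phase
  cat(sprintf("haplotype_chains: %d sites, %d phased, %d phase set(s)\n",
              nrow(sp), sum(sp$phased),
              length(unique(stats::na.omit(sp$phase_set)))))
  bb <- x$allele1[!x$allele1$branch, ]
  if (nrow(bb) > 0L) {
    cat(sprintf("  allele-1 chain: %d steps, %d confident, final cumulative p = %.4f\n",
                nrow(bb), sum(bb$verdict == "confident"),
                bb$cum_prob[nrow(bb)]))
  }
  invisible(x)
}

#' Write the per-step chain report as TSV
#'
#' One row per step and allele: sites, chosen bases, step probability and
#' CI, cumulative probability and CI, verdict. Floating point is printed
#' at 6 significant digits.
#'
#' @param chains a `haplotype_chains` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_chain_tsv <- function(chains, file) {
  df <- rbind(chains$allele1, chains$allele2)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write phased genotypes as VCF
#'
#' Emits pipe-separated genotypes (`0|1` / `1|0`) with a `PS` FORMAT tag
#' anchored at the first site of each confidently phased segment; sites in
#' ambiguous or unphased segments stay `0/1`.
#'
#' @param sites a [het_sites] table covering all reported sites.
#' @param chains a `haplotype_chains` object (or its `site_phase` data
#'   frame).
#' @param file output path.
#' @param region_length contig length for the VCF header; defaults to the
#'   largest site position.
#' @param sample_name sample column name.
#' @return `file`, invisibly.
#' @export
write_phased_vcf <- function(sites, chains, file,
                             region_length = NULL,
                             sample_name = "SAMPLE") {
  sp <- if (inherits(chains, "haplotype_chains")) chains$site_phase else chains
  idx <- match(sites$pos, sp$pos)
  hap1 <- sp$hap1[idx]
  phased <- !is.na(idx) & sp$phased[idx] & !is.na(hap1)
  ps <- ifelse(phased, sp$phase_set[idx], NA_integer_)

  bad <- phased & !(hap1 == sites$ref | hap1 == sites$alt)
  if (any(bad)) {
    stop("internal consistency error: site phased to a base that is ",
         "neither ref nor alt at ", paste(sites$pos[bad], collapse = ", "))
  }
  gt <- ifelse(!phased, "0/1", ifelse(hap1 == sites$ref, "0|1", "1|0"))
  write_simple_vcf(sites, gt = gt, ps = ps,
                   contig_len = region_length %||% max(sites$pos),
                   file = file, sample_name = sample_name)
}
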