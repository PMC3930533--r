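#' Configuration for the diploid amplicon read simulator
#'
#' Describes a two-allele (diploid) amplicon of `region_length` bp carrying
#' `n_sites` heterozygous SNVs, sequenced as a mixture of paired-end (PE)
#' and mate-pair (MP) fragments with `read_length`-bp reads at both fragment
#' ends. Fragment-level chimerism (template switching between the two
#' alleles at a uniform internal breakpoint, the signature of long-range
#' PCR recombination) and per-site random base-call error complete the
#' error model.
#'
#' `coverage` is the target mean *linked* coverage: the expected number of
#' fragments whose reads co-observe an adjacent pair of heterozygous sites
#' (i.e. the expected association-matrix total). This is the depth scale on
#' which phasing confidence is measured; the fragment count needed to reach
#' it is calibrated internally from the fragment-size mixture.
#'
#' @param region_length amplicon length in bp.
#' @param n_sites number of heterozygous sites (ignored when
#'   `het_positions` is given).
#' @param het_positions optional data frame with columns `pos` and
#'   optionally `ref`, `alt`, `hap1` (the allele carried by haplotype 1)
#'   fixing the sites and the truth phase.
#' @param coverage target mean linked coverage between adjacent het sites.
#' @param pe_fraction proportion of PE-type fragments in the library.
#' @param pe_size_range PE fragment size range, bp (uniform).
#' @param mp_size_range,mp_size_mean MP fragment size support and mean, bp
#'   (truncated log-normal solved for the mean).
#' @param read_length bases sequenced from each fragment end.
#' @param recombination_rate per-fragment probability of a chimeric
#'   template switch.
#' @param random_error_rate per het-site base-call substitution probability.
#' @param mp_size_law `"lognormal"` (default) or `"uniform"` on
#'   `mp_size_range` (handy for analytic checks).
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(region_length = 10000L,
                       n_sites = 12L,
                       het_positions = NULL,
                       coverage = 500,
                       pe_fraction = 0.3,
                       pe_size_range = c(100L, 600L),
                       mp_size_range = c(500L, 5000L),
                       mp_size_mean = 2000,
                       read_length = 101L,
                       recombination_rate = 0.07,
                       random_error_rate = 0.02,
                       mp_size_law = c("lognormal", "uniform"),
                       seed = NULL) {
  mp_size_law <- match.arg(mp_size_law)
  if (is.null(seed)) stop("sim_config() requires an explicit integer seed")
  stopifnot(
    region_length >= 2L * read_length,
    coverage > 0,
    pe_fraction >= 0, pe_fraction <= 1,
    recombination_rate >= 0, recombination_rate <= 1,
    random_error_rate >= 0, random_error_rate <= 1,
    pe_size_range[1] <= pe_size_range[2],
    mp_size_range[1] <= mp_size_range[2],
    mp_size_mean >= mp_size_range[1], mp_size_mean <= mp_size_range[2],
    max(pe_size_range[2], mp_size_range[2]) <= region_length,
    read_length >= 1L
  )
  if (!is.null(het_positions)) {
    stopifnot(is.data.frame(het_positions), "pos" %in% names(het_positions))
    pos <- as.integer(het_positions$pos)
    stopifnot(all(diff(pos) > 0), all(pos >= 1L), all(pos <= region_length))
  } else {
    stopifnot(n_sites >= 0L)
  }
  structure(list(
    region_length = as.integer(region_length),
    n_sites = as.integer(n_sites),
    het_positions = het_positions,
    coverage = coverage,
    pe_fraction = pe_fraction,
    pe_size_range = as.integer(pe_size_range),
    mp_size_range = as.integer(mp_size_range),
    mp_size_mean = mp_size_mean,
    read_length = as.integer(read_length),
    recombination_rate = recombination_rate,
    random_error_rate = random_error_rate,
    mp_size_law = mp_size_law,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# meanlog of a log-normal whose truncation to [lo, hi] has the target mean;
# sdlog is fixed at 0.6 so the size distribution spans the support broadly.
MP_SDLOG <- 0.6

mp_meanlog <- function(lo, hi, target_mean, sdlog = MP_SDLOG) {
  trunc_mean <- function(mu) {
    num <- exp(mu + sdlog^2 / 2) *
      (stats::pnorm((log(hi) - mu - sdlog^2) / sdlog) -
         stats::pnorm((log(lo) - mu - sdlog^2) / sdlog))
    den <- stats::pnorm((log(hi) - mu) / sdlog) -
      stats::pnorm((log(lo) - mu) / sdlog)
    num / den - target_mean
  }
  stats::uniroot(trunc_mean, c(log(lo), log(hi)), tol = 1e-10)$root
}

# Draw fragment types and sizes for n fragments (no RNG scoping here;
# callers wrap in withr::with_seed).
draw_fragment_sizes <- function(config, n) {
  is_pe <- stats::runif(n) < config$pe_fraction
  size <- integer(n)
  npe <- sum(is_pe)
  if (npe > 0L) {
    size[is_pe] <- config$pe_size_range[1] +
      as.integer(floor(stats::runif(npe) * (diff(config$pe_size_range) + 1L)))
  }
  nmp <- n - npe
  if (nmp > 0L) {
    lo <- config$mp_size_range[1]; hi <- config$mp_size_range[2]
    if (config$mp_size_law == "uniform") {
      size[!is_pe] <- lo + as.integer(floor(stats::runif(nmp) * (hi - lo + 1L)))
    } else {
      mu <- mp_meanlog(lo, hi, config$mp_size_mean)
      u <- stats::runif(nmp,
                        stats::plnorm(lo, mu, MP_SDLOG),
                        stats::plnorm(hi, mu, MP_SDLOG))
      size[!is_pe] <- pmin(hi, pmax(lo, as.integer(floor(stats::qlnorm(u, mu, MP_SDLOG)))))
    }
  }
  list(is_pe = is_pe, size = size)
}

#' Build the two haplotype sequences and the heterozygous-site truth
#'
#' Generates a random background sequence and derives haplotypes 1 and 2,
#' identical everywhere except at the heterozygous positions, where each
#' haplotype carries the allele assigned by the truth phase. Site
#' positions, alleles and phase come from `config$het_positions` when
#' given, otherwise sites are spread over the central 90% of the region
#' with seeded jitter and phased at random.
#'
#' @param config a [sim_config].
#' @return a list of class `diploid_reference` with elements `chrom`,
#'   `region_length`, `hap1`, `hap2` (sequences as single strings) and
#'   `sites` (a [het_sites] table with truth columns `hap1`, `hap2`).
#' @export
make_diploid_reference <- function(config) {
  withr::with_seed(sub_seed(config$seed, 1L), {
    L <- config$region_length
    background <- sample(BASES, L, replace = TRUE)

    hp <- config$het_positions
    if (is.null(hp)) {
      k <- config$n_sites
      if (k > 0L) {
        anchors <- round(seq(0.05, 0.95, length.out = k) * L)
        jitter <- round(stats::runif(k, -0.02, 0.02) * L)
        pos <- sort(as.integer(pmin(L, pmax(1L, anchors + jitter))))
        if (anyDuplicated(pos)) pos <- sort(unique(pos))
        hp <- data.frame(pos = pos)
      } else {
        hp <- data.frame(pos = integer(0))
      }
    }
    pos <- as.integer(hp$pos)
    if (anyDuplicated(pos)) stop("heterozygous positions collide")
    k <- length(pos)

    ref <- if ("ref" %in% names(hp)) toupper(hp$ref) else background[pos]
    background[pos] <- ref
    alt <- if ("alt" %in% names(hp)) {
      toupper(hp$alt)
    } else {
      other_base(ref, stats::runif(k))
    }
    stopifnot(all(ref != alt))
    hap1_allele <- if ("hap1" %in% names(hp)) {
      toupper(hp$hap1)
    } else {
      ifelse(stats::runif(k) < 0.5, ref, alt)
    }
    stopifnot(all(hap1_allele == ref | hap1_allele == alt))
    hap2_allele <- ifelse(hap1_allele == ref, alt, ref)

    h1 <- background; h2 <- background
    h1[pos] <- hap1_allele
    h2[pos] <- hap2_allele

    sites <- het_sites(rep("amplicon", k), pos, ref, alt)
    sites$hap1 <- hap1_allele
    sites$hap2 <- hap2_allele

    structure(list(
      chrom = "amplicon",
      region_length = L,
      hap1 = paste(h1, collapse = ""),
      hap2 = paste(h2, collapse = ""),
      sites = sites
    ), class = "diploid_reference")
  })
}

# Pilot-based calibration: how many fragments give the target mean linked
# coverage across adjacent het-site pairs? Uses its own seed stream so the
# main fragment draws are unaffected.
calibrate_n_fragments <- function(config, sites, pilot = 200000L) {
  L <- config$region_length
  R <- config$read_length
  withr::with_seed(sub_seed(config$seed, 2L), {
    d <- draw_fragment_sizes(config, pilot)
    size <- d$size
    start <- 1L + as.integer(floor(stats::runif(pilot) * (L - size + 1L)))
    rl <- pmin(R, size)
    r1e <- start + rl - 1L
    r2s <- start + size - rl
    r2e <- start + size - 1L
    covers <- function(p) (p >= start & p <= r1e) | (p >= r2s & p <= r2e)

    pos <- sites$pos
    if (length(pos) >= 2L) {
      plink <- vapply(seq_len(length(pos) - 1L), function(i) {
        mean(covers(pos[i]) & covers(pos[i + 1L]))
      }, numeric(1))
      plink <- plink[plink > 0]
    } else {
      p1 <- as.integer(L / 2 - 500); p2 <- p1 + 1000L
      plink <- mean(covers(p1) & covers(p2))
      plink <- plink[plink > 0]
    }
    if (length(plink) == 0L) {
      warning("no fragment size can link the het sites; ",
              "falling back to sequence-coverage scaling")
      return(as.integer(ceiling(config$coverage * L / (2 * R))))
    }
    as.integer(ceiling(config$coverage / mean(plink)))
  })
}

#' Simulate a PE+MP fragment library from a diploid reference
#'
#' Draws fragments (type, size, start, source haplotype), applies the
#' chimera model (with probability `recombination_rate` the template
#' switches to the other haplotype at a uniform internal breakpoint) and
#' records the base call observed at every heterozygous site covered by
#' either end read, substituting a random different base with probability
#' `random_error_rate`. Each source of randomness draws from its own
#' seed-derived stream, so e.g. changing the error rate leaves fragment
#' placement unchanged.
#'
#' @param config a [sim_config].
#' @param reference a [make_diploid_reference] result; built from `config`
#'   when omitted.
#' @param n_fragments override the calibrated fragment count (mainly for
#'   tests and profiling fixtures).
#' @return a list of class `mp_sim` with elements `config`, `reference`,
#'   `fragments` (one row per fragment: placement, haplotype, chimera
#'   status, read intervals), `observations` (fragment_id, pos, base — the
#'   emitted calls, the extractor's target), and `truth` (observations plus
#'   source base and error flag).
#' @export
simulate_fragments <- function(config, reference = NULL, n_fragments = NULL) {
  if (is.null(reference)) reference <- make_diploid_reference(config)
  sites <- reference$sites
  L <- config$region_length
  R <- config$read_length

  n <- if (!is.null(n_fragments)) as.integer(n_fragments) else
    calibrate_n_fragments(config, sites)

  dr <- withr::with_seed(sub_seed(config$seed, 3L), draw_fragment_sizes(config, n))
  size <- dr$size
  start <- withr::with_seed(sub_seed(config$seed, 4L),
    1L + as.integer(floor(stats::runif(n) * (L - size + 1L))))
  hap <- withr::with_seed(sub_seed(config$seed, 5L),
    1L + as.integer(stats::runif(n) < 0.5))
  chim <- withr::with_seed(sub_seed(config$seed, 6L), {
    flag <- stats::runif(n) < config$recombination_rate
    bp <- start + 1L + as.integer(floor(stats::runif(n) * pmax(size - 1L, 1L)))
    bp[!flag] <- NA_integer_
    list(flag = flag, bp = bp)
  })

  rl <- pmin(R, size)
  fragments <- data.frame(
    fragment_id = seq_len(n),
    type = ifelse(dr$is_pe, "PE", "MP"),
    start = start,
    size = size,
    hap = hap,
    chimera = chim$flag,
    breakpoint = chim$bp,
    r1_start = start,
    r1_end = start + rl - 1L,
    r2_start = start + size - rl,
    r2_end = start + size - 1L,
    stringsAsFactors = FALSE
  )

  # per-site coverage and source base
  k <- nrow(sites)
  obs_frag <- obs_pos <- obs_hap <- vector("list", k)
  for (i in seq_len(k)) {
    p <- sites$pos[i]
    idx <- which((p >= fragments$r1_start & p <= fragments$r1_end) |
                   (p >= fragments$r2_start & p <= fragments$r2_end))
    if (length(idx) == 0L) next
    srch <- hap[idx]
    sw <- chim$flag[idx] & !is.na(chim$bp[idx]) & chim$bp[idx] <= p
    srch[sw] <- 3L - srch[sw]
    obs_frag[[i]] <- idx
    obs_pos[[i]] <- rep.int(p, length(idx))
    obs_hap[[i]] <- srch
  }
  fid <- unlist(obs_frag) %||% integer(0)
  opos <- unlist(obs_pos) %||% integer(0)
  ohap <- unlist(obs_hap) %||% integer(0)
  site_row <- match(opos, sites$pos)
  true_base <- ifelse(ohap == 1L, sites$hap1[site_row], sites$hap2[site_row])

  m <- length(fid)
  emitted <- true_base
  err <- logical(m)
  if (m > 0L) {
    eu <- withr::with_seed(sub_seed(config$seed, 7L),
      list(e = stats::runif(m), pick = stats::runif(m)))
    err <- eu$e < config$random_error_rate
    if (any(err)) emitted[err] <- other_base(true_base[err], eu$pick[err])
  }

  truth <- data.frame(
    fragment_id = fid, pos = opos,
    true_base = true_base, base = emitted, error = err,
    stringsAsFactors = FALSE
  )
  ord <- order(truth$fragment_id, truth$pos)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL

  observations <- truth[, c("fragment_id", "pos", "base")]
  class(observations) <- c("linked_fragments", "data.frame")

  if (k >= 2L) {
    linked <- nrow(truth) > 0L && any(duplicated(truth$fragment_id))
    if (!linked) warning("no fragment links two het sites at this coverage")
  }

  structure(list(
    config = config,
    reference = reference,
    fragments = fragments,
    observations = observations,
    truth = truth,
    n_fragments = n
  ), class = "mp_sim")
}

#' @export
print.mp_sim <- function(x, ...) {
  cat("mp_sim:", x$n_fragments, "fragments over", x$config$region_length,
      "bp,", nrow(x$reference$sites), "het sites\n")
  cat("  observations:", nrow(x$observations),
      " chimeric fragments:", sum(x$fragments$chimera), "\n")
  invisible(x)
}
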