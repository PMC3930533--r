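# 4x4 base-call association matrices between ordered pairs of het sites.

#' Build the base-call association matrix for one ordered site pair
#'
#' Tallies, over all fragments observing both sites, the co-occurrence of
#' base calls: `counts[b1, b2]` is the number of fragments calling `b1` at
#' the upstream site and `b2` at the downstream site. The full 4x4 table
#' (fixed base order A, C, G, T) is kept: in a clean diploid only two
#' cells carry mass, and the off-allele cells are exactly what the error
#' decomposition measures.
#'
#' @param fragments a `linked_fragments` table.
#' @param upstream,downstream single rows of a [het_sites] table (or the
#'   sites table plus `upstream`/`downstream` given as positions);
#'   `upstream$pos < downstream$pos`.
#' @return an object of class `assoc_matrix`: list with `upstream`,
#'   `downstream` (site rows), `counts` (4x4 integer matrix) and `total`.
#' @export
build_association_matrix <- function(fragments, upstream, downstream) {
  upstream <- as_site_row(upstream)
  downstream <- as_site_row(downstream)
  if (upstream$pos == downstream$pos) {
    stop("upstream and downstream sites must differ")
  }
  if (upstream$pos > downstream$pos) {
    stop("upstream site must precede downstream site")
  }
  up <- fragments[fragments$pos == upstream$pos, c("fragment_id", "base")]
  dn <- fragments[fragments$pos == downstream$pos, c("fragment_id", "base")]
  both <- merge(up, dn, by = "fragment_id", suffixes = c("_up", "_dn"))
  counts <- table(factor(both$base_up, levels = BASES),
                  factor(both$base_dn, levels = BASES))
  counts <- matrix(as.integer(counts), 4L, 4L, dimnames = list(BASES, BASES))
  structure(list(
    upstream = upstream,
    downstream = downstream,
    counts = counts,
    total = sum(counts)
  ), class = "assoc_matrix")
}

as_site_row <- function(site) {
  stopifnot(is.data.frame(site), nrow(site) == 1L)
  site
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("assoc_matrix %s -> %s (total %d)\n",
              x$upstream$label, x$downstream$label, x$total))
  print(x$counts)
  invisible(x)
}

#' Association matrices for every ordered site pair
#'
#' One matrix per pair (i < j); zero-total matrices are retained so that
#' coverage holes are visible.
#'
#' @inheritParams build_association_matrix
#' @param sites a [het_sites] table with at least two rows.
#' @return list of `assoc_matrix`.
#' @export
all_pairs_matrices <- function(fragments, sites) {
  stopifnot(nrow(sites) >= 2L)
  k <- nrow(sites)
  out <- vector("list", k * (k - 1L) / 2L)
  n <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      n <- n + 1L
      out[[n]] <- build_association_matrix(fragments,
                                           sites[i, , drop = FALSE],
                                           sites[j, , drop = FALSE])
    }
  }
  out
}

#' Chain of association matrices over successive het sites
#'
#' Builds the tandem chain A_1 = (h_0, h_1), A_2 = (h_1, h_2), ... used
#' for whole-region phasing. When an adjacent pair has fewer than
#' `min_total` linked fragments, the low-coverage junction is bridged by
#' skipping ahead to the next site that restores `total >= min_total`;
#' skipped sites are recorded so they can be phased from their nearest
#' anchored neighbour. If no downstream site can be reached, a chain break
#' is declared at that junction and the chain restarts at the next site.
#'
#' @inheritParams all_pairs_matrices
#' @param min_total minimum linked-fragment count for a usable junction
#'   (default 20, below which the bootstrap interval is too coarse to act
#'   on).
#' @return an object of class `assoc_chain`: list with `links` (each a
#'   list `matrix`, `from`, `to`, `skipped`, `new_segment`), `sites`,
#'   `min_total` and `breaks` (site indices before which a break occurs).
#' @export
adjacent_pairs_matrices <- function(fragments, sites, min_total = 20L) {
  stopifnot(nrow(sites) >= 2L)
  k <- nrow(sites)
  links <- list()
  breaks <- integer(0)
  i <- 1L
  new_segment <- TRUE
  while (i < k) {
    found <- NULL
    m_found <- NULL
    for (j in seq(i + 1L, k)) {
      m <- build_association_matrix(fragments,
                                    sites[i, , drop = FALSE],
                                    sites[j, , drop = FALSE])
      if (m$total >= min_total) { found <- j; m_found <- m; break }
    }
    if (is.null(found)) {
      breaks <- c(breaks, i + 1L)
      i <- i + 1L
      new_segment <- TRUE
    } else {
      skipped <- if (found > i + 1L) seq(i + 1L, found - 1L) else integer(0)
      branch_matrices <- NULL
      if (length(skipped) > 0L) {
        branch_matrices <- lapply(skipped, function(s) {
          build_association_matrix(fragments,
                                   sites[i, , drop = FALSE],
                                   sites[s, , drop = FALSE])
        })
        names(branch_matrices) <- as.character(skipped)
      }
      links[[length(links) + 1L]] <- list(
        matrix = m_found,
        from = i,
        to = found,
        skipped = skipped,
        branch_matrices = branch_matrices,
        new_segment = new_segment
      )
      new_segment <- FALSE
      i <- found
    }
  }
  structure(list(links = links, sites = sites, min_total = as.integer(min_total),
                 breaks = breaks), class = "assoc_chain")
}

#' Write association matrices as a TSV report
#'
#' One row per matrix: site positions and labels, the 16 cell counts in
#' fixed A,C,G,T-by-A,C,G,T order, and the total.
#'
#' @param matrices list of `assoc_matrix` (or an `assoc_chain`).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_matrix_tsv <- function(matrices, file) {
  if (inherits(matrices, "assoc_chain")) {
    matrices <- lapply(matrices$links, `[[`, "matrix")
  }
  cell_names <- paste0(rep(BASES, each = 4L), rep(BASES, 4L))
  rows <- lapply(matrices, function(m) {
    cells <- as.vector(t(m$counts))  # row-major: upstream base varies slowest
    out <- data.frame(
      up_pos = m$upstream$pos, up_label = m$upstream$label,
      dn_pos = m$downstream$pos, dn_label = m$downstream$label,
      stringsAsFactors = FALSE
    )
    out[cell_names] <- as.list(cells)
    out$total <- m$total
    out
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
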