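# Per-fragment base-call extraction from aligned reads.

# Accept SAM or BAM; return a sorted, indexed BAM path.
ensure_indexed_bam <- function(file) {
  if (!file.exists(file)) stop("alignment file not found: ", file)
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(file, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
    return(bam)
  }
  bai <- paste0(file, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", file))) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::sortBam(file, destination = dest)
    Rsamtools::indexBam(bam)
    return(bam)
  }
  file
}

#' Extract per-fragment base calls at heterozygous sites
#'
#' Groups primary alignments by read name (the sequenced fragment) and
#' records, for every heterozygous site covered by either read, the base
#' the fragment reports there. Secondary, supplementary, duplicate and
#' unmapped alignments are ignored. If both mates cover the same site and
#' agree, one call is recorded; if they disagree, the fragment gets no
#' call at that site. Calls below the base- or mapping-quality floors, and
#' calls that are not A, C, G or T, are dropped.
#'
#' @param file SAM or BAM path (SAM is converted on the fly; BAM is sorted
#'   and indexed in a temporary location when no index is present).
#' @param sites a [het_sites] table.
#' @param min_base_quality,min_mapping_quality Phred floors (default 20).
#' @return a data frame of class `linked_fragments` with columns
#'   `fragment_id`, `pos`, `base`: one row per retained fragment-site
#'   observation. Fragments with zero observations do not appear.
#' @export
extract_linked_fragments <- function(file, sites,
                                     min_base_quality = 20,
                                     min_mapping_quality = 20) {
  stopifnot(inherits(sites, "het_sites"), nrow(sites) > 0L)
  bam <- ensure_indexed_bam(file)

  gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  param <- Rsamtools::ScanBamParam(
    which = gr,
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE,
      isDuplicate = FALSE,
      isUnmappedQuery = FALSE
    )
  )
  res <- Rsamtools::scanBam(bam, param = param)

  calls <- vector("list", length(res))
  for (i in seq_along(res)) {
    x <- res[[i]]
    if (length(x$qname) == 0L) next
    site_pos <- sites$pos[i]
    lay_seq <- GenomicAlignments::sequenceLayer(x$seq, x$cigar)
    lay_qual <- GenomicAlignments::sequenceLayer(
      Biostrings::BStringSet(x$qual), x$cigar)
    off <- site_pos - x$pos + 1L
    ok <- off >= 1L & off <= Biostrings::width(lay_seq)
    if (!any(ok)) next
    base <- substring(as.character(lay_seq[ok]), off[ok], off[ok])
    qch <- substring(as.character(lay_qual[ok]), off[ok], off[ok])
    bq <- vapply(qch, function(ch) {
      if (nchar(ch) == 1L) utf8ToInt(ch) - 33L else -1L
    }, integer(1), USE.NAMES = FALSE)
    calls[[i]] <- data.frame(
      fragment_id = x$qname[ok],
      pos = rep.int(site_pos, sum(ok)),
      base = base,
      bq = bq,
      mapq = as.integer(x$mapq[ok]),
      stringsAsFactors = FALSE
    )
  }
  calls <- do.call(rbind, calls)
  if (is.null(calls) || nrow(calls) == 0L) return(empty_linked_fragments())

  keep <- calls$base %in% BASES &
    calls$bq >= min_base_quality &
    !is.na(calls$mapq) & calls$mapq >= min_mapping_quality
  calls <- calls[keep, , drop = FALSE]
  if (nrow(calls) == 0L) return(empty_linked_fragments())

  # collapse duplicate coverage of one site by one fragment: keep the call
  # only if all copies agree
  key <- paste(calls$fragment_id, calls$pos, sep = "\r")
  n_bases <- vapply(split(calls$base, key), function(b) length(unique(b)),
                    integer(1))
  first <- !duplicated(key)
  out <- calls[first, c("fragment_id", "pos", "base"), drop = FALSE]
  out <- out[n_bases[paste(out$fragment_id, out$pos, sep = "\r")] == 1L, ,
             drop = FALSE]
  out <- out[order(out$fragment_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("linked_fragments", "data.frame")
  out
}

empty_linked_fragments <- function() {
  out <- data.frame(fragment_id = character(0), pos = integer(0),
                    base = character(0), stringsAsFactors = FALSE)
  class(out) <- c("linked_fragments", "data.frame")
  out
}

#' Dump fragment observations as TSV
#'
#' Debug view of the fragment/site/base observation table.
#'
#' @param fragments a `linked_fragments` table.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fragment_tsv <- function(fragments, file) {
  utils::write.table(as.data.frame(fragments), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
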