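#' Construct a table of heterozygous SNV sites
#'
#' A `het_sites` table is the ordered list of biallelic heterozygous
#' positions (the h_0, h_1, ... of the phasing chain). It is an ordinary
#' data frame with columns `chrom`, `pos`, `ref`, `alt`, `label`, sorted by
#' position, and is the site container consumed by every other function in
#' the package.
#'
#' @param chrom contig name (recycled to length of `pos`).
#' @param pos 1-based genomic positions, strictly increasing after sorting.
#' @param ref,alt single reference/alternate bases in `A,C,G,T`; `ref[i] !=
#'   alt[i]` (biallelic SNVs only).
#' @param label display names, e.g. `"c.60G>A"`; default `chrom:posREF>ALT`.
#' @return a data frame of class `het_sites`.
#' @export
het_sites <- function(chrom, pos, ref, alt, label = NULL) {
  chrom <- rep_len(as.character(chrom), length(pos))
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (length(pos) > 0L) {
    stopifnot(
      all(pos >= 1L),
      all(ref %in% BASES), all(alt %in% BASES),
      all(ref != alt),
      length(unique(chrom)) <= 1L,
      !anyDuplicated(pos)
    )
  }
  if (is.null(label)) label <- sprintf("%s:%d%s>%s", chrom, pos, ref, alt)
  out <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    label = as.character(label), stringsAsFactors = FALSE
  )
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("het_sites", "data.frame")
  out
}

empty_het_sites <- function() {
  het_sites(character(0), integer(0), character(0), character(0))
}

#' Read heterozygous biallelic SNVs from a VCF
#'
#' Keeps only records that are single-base substitutions with a heterozygous
#' genotype (`0/1`, `1/0`, `0|1` or `1|0`) in the chosen sample.
#' Multi-allelic records, indels and homozygous genotypes are skipped and
#' counted in a message. An empty result (zero-row table) is returned, not
#' an error, when no record qualifies.
#'
#' @param vcf_file path to a VCF 4.x file (plain or gzipped).
#' @param region optional `"chrom"` or `"chrom:start-end"` filter.
#' @param sample sample column to take genotypes from (default: first).
#' @return a [het_sites] table sorted by position.
#' @export
read_het_sites <- function(vcf_file, region = NULL, sample = 1L) {
  if (!file.exists(vcf_file)) stop("VCF not found: ", vcf_file)
  v <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_het_sites())
  fix$POS <- as.integer(fix$POS)

  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    rg <- parse_region(region)
    keep <- fix$CHROM == rg$chrom
    if (!is.na(rg$start)) keep <- keep & fix$POS >= rg$start & fix$POS <= rg$end
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- if (is.null(dim(gt))) gt else gt[, sample]
  is_het <- !is.na(gt) & gt %in% c("0/1", "1/0", "0|1", "1|0")
  is_snv <- fix$REF %in% BASES & fix$ALT %in% BASES
  skipped <- sum(keep) - sum(keep & is_het & is_snv)
  if (skipped > 0L) {
    message(skipped, " VCF record(s) skipped (non-SNV, multi-allelic or not heterozygous)")
  }
  keep <- keep & is_het & is_snv
  if (!any(keep)) return(empty_het_sites())

  id <- fix$ID[keep]
  lab <- ifelse(is.na(id) | id == ".",
                sprintf("%s:%d%s>%s", fix$CHROM[keep], fix$POS[keep],
                        fix$REF[keep], fix$ALT[keep]),
                id)
  het_sites(fix$CHROM[keep], fix$POS[keep], fix$REF[keep], fix$ALT[keep],
            label = lab)
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (length(m) == 0L) stop("cannot parse region: ", region)
  list(
    chrom = m[2],
    start = if (m[4] == "") NA_integer_ else as.integer(m[4]),
    end = if (m[5] == "") NA_integer_ else as.integer(m[5])
  )
}
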