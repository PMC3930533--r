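# Simulator output: SAM and plain-text truth files.

# Template sequence of one read interval, honouring the chimera model
# (positions before the breakpoint come from the source haplotype, the
# rest from the other one). Vectorised over fragments.
template_substring <- function(reference, hap, chimera, breakpoint, from, to) {
  hs <- c(reference$hap1, reference$hap2)
  out <- substring(hs[hap], from, to)
  ix <- which(chimera & !is.na(breakpoint))
  if (length(ix) > 0L) {
    bp <- breakpoint[ix]
    all_b <- ix[bp <= from[ix]]                       # entire read past the switch
    out[all_b] <- substring(hs[3L - hap[all_b]], from[all_b], to[all_b])
    mid <- ix[bp > from[ix] & bp <= to[ix]]           # switch inside the read
    if (length(mid) > 0L) {
      bpm <- breakpoint[mid]
      out[mid] <- paste0(
        substring(hs[hap[mid]], from[mid], bpm - 1L),
        substring(hs[3L - hap[mid]], bpm, to[mid])
      )
    }
  }
  out
}

#' Write a simulated library as a coordinate-sorted SAM file
#'
#' Emits both reads of every fragment with correct FLAG/POS/CIGAR
#' (all-match alignments, constant Q37 qualities). Base-call errors
#' injected at heterozygous sites are patched into the read sequences, so
#' the SAM round-trips exactly to the simulator's observation table.
#'
#' @param sim an `mp_sim` object.
#' @param file output path (`.sam`).
#' @return `file`, invisibly.
#' @export
write_sam <- function(sim, file) {
  fr <- sim$fragments
  ref <- sim$reference
  seq1 <- template_substring(ref, fr$hap, fr$chimera, fr$breakpoint,
                             fr$r1_start, fr$r1_end)
  seq2 <- template_substring(ref, fr$hap, fr$chimera, fr$breakpoint,
                             fr$r2_start, fr$r2_end)

  # patch in erroneous het-site calls (both mates carry the fragment call)
  tr <- sim$truth[sim$truth$error, , drop = FALSE]
  if (nrow(tr) > 0L) {
    for (j in seq_len(nrow(tr))) {
      i <- tr$fragment_id[j]; p <- tr$pos[j]
      if (p >= fr$r1_start[i] && p <= fr$r1_end[i]) {
        substr(seq1[i], p - fr$r1_start[i] + 1L, p - fr$r1_start[i] + 1L) <- tr$base[j]
      }
      if (p >= fr$r2_start[i] && p <= fr$r2_end[i]) {
        substr(seq2[i], p - fr$r2_start[i] + 1L, p - fr$r2_start[i] + 1L) <- tr$base[j]
      }
    }
  }

  qname <- sprintf("F%07d", fr$fragment_id)
  l1 <- nchar(seq1); l2 <- nchar(seq2)
  rec <- function(flag, pos, seq, len, pnext, tlen) {
    paste(qname, flag, ref$chrom, pos, 60L, paste0(len, "M"), "=",
          pnext, tlen, seq, strrep("F", len), sep = "\t")
  }
  lines <- c(
    rec(99L, fr$r1_start, seq1, l1, fr$r2_start, fr$size),
    rec(147L, fr$r2_start, seq2, l2, fr$r1_start, -fr$size)
  )
  pos_all <- c(fr$r1_start, fr$r2_start)
  lines <- lines[order(pos_all)]

  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$chrom, ref$region_length)
  )
  writeLines(c(header, lines), file)
  invisible(file)
}

#' Write the simulator's truth files
#'
#' Writes `<prefix>.truth.vcf` (unphased het genotypes — the phasing
#' input), `<prefix>.truth_phase.tsv` (which allele sits on which
#' haplotype), and `<prefix>.truth_fragments.tsv` /
#' `<prefix>.truth_calls.tsv` (per-fragment provenance and per-site emitted
#' calls with error flags).
#'
#' @param sim an `mp_sim` object.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_truth <- function(sim, prefix) {
  ref <- sim$reference
  sites <- ref$sites

  vcf <- paste0(prefix, ".truth.vcf")
  write_simple_vcf(sites, gt = rep("0/1", nrow(sites)), ps = NULL,
                   contig_len = ref$region_length, file = vcf,
                   sample_name = "SIM")

  phase <- paste0(prefix, ".truth_phase.tsv")
  utils::write.table(
    sites[, c("chrom", "pos", "ref", "alt", "hap1", "hap2")],
    phase, sep = "\t", quote = FALSE, row.names = FALSE)

  frg <- paste0(prefix, ".truth_fragments.tsv")
  utils::write.table(
    sim$fragments[, c("fragment_id", "type", "start", "size", "hap",
                      "chimera", "breakpoint")],
    frg, sep = "\t", quote = FALSE, row.names = FALSE)

  calls <- paste0(prefix, ".truth_calls.tsv")
  utils::write.table(sim$truth, calls, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(c(vcf, phase, frg, calls))
}

# Minimal VCFv4.2 emitter shared by the truth writer and the phased-VCF
# writer. `gt` is the genotype string per site; `ps` an optional integer
# phase-set vector (NA = no PS for that site).
write_simple_vcf <- function(sites, gt, ps, contig_len, file,
                             sample_name = "SAMPLE") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=matephase",
    sprintf("##contig=<ID=%s,length=%d>",
            if (nrow(sites) > 0L) sites$chrom[1] else "amplicon",
            as.integer(contig_len)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  has_ps <- !is.null(ps) && any(!is.na(ps))
  if (has_ps) {
    header <- c(header,
      "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">")
  }
  header <- c(header, paste0(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name))

  if (nrow(sites) > 0L) {
    if (has_ps) {
      fmt <- ifelse(is.na(ps), "GT", "GT:PS")
      val <- ifelse(is.na(ps), gt, paste0(gt, ":", ps))
    } else {
      fmt <- "GT"; val <- gt
    }
    body <- paste(sites$chrom, sites$pos, sites$label, sites$ref, sites$alt,
                  ".", "PASS", ".", fmt, val, sep = "\t")
  } else {
    body <- character(0)
  }
  writeLines(c(header, body), file)
  invisible(file)
}
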