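# Fixture builders shared across the test files. Everything is generated
# in code; no binary fixtures.

# A minimal VCF with arbitrary records. `records` is a data frame with
# columns chrom, pos, id, ref, alt, gt.
write_toy_vcf <- function(records, file = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=amplicon,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"
  )
  body <- with(records, paste(chrom, pos, id, ref, alt, ".", "PASS", ".",
                              "GT", gt, sep = "\t"))
  writeLines(c(header, body), file)
  file
}

# A SAM file from hand-specified alignment rows. `reads` is a data frame
# with columns qname, flag, pos, cigar, seq and optionally qual, mapq.
write_toy_sam <- function(reads, file = tempfile(fileext = ".sam"),
                          chrom = "amplicon", len = 10000L) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    strrep("F", nchar(reads$seq))
  mapq <- if ("mapq" %in% names(reads)) reads$mapq else
    rep(60L, nrow(reads))
  lines <- paste(reads$qname, reads$flag, chrom, reads$pos, mapq,
                 reads$cigar, "*", 0L, 0L, reads$seq, qual, sep = "\t")
  lines <- lines[order(reads$pos)]
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, len),
               lines), file)
  file
}

# linked_fragments table from a compact spec: list of per-fragment named
# base vectors, names = positions.
make_fragments <- function(...) {
  frs <- list(...)
  rows <- lapply(seq_along(frs), function(i) {
    data.frame(fragment_id = sprintf("f%03d", i),
               pos = as.integer(names(frs[[i]])),
               base = unname(frs[[i]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("linked_fragments", "data.frame")
  out
}

# Two-site trans fixture: hap1 carries ref at site 1 and alt at site 2.
trans_pair_config <- function(coverage, seed, d = 2000L,
                              region_length = 10000L, ...) {
  p1 <- as.integer((region_length - d) / 2)
  sim_config(
    region_length = region_length,
    het_positions = data.frame(pos = c(p1, p1 + d),
                               ref = c("G", "A"), alt = c("A", "G"),
                               hap1 = c("G", "G")),
    coverage = coverage, seed = seed, ...)
}

# assoc_matrix built directly from a 4x4 count matrix (A,C,G,T order).
toy_matrix <- function(counts, up_pos = 100L, dn_pos = 200L,
                       up_ref = "G", up_alt = "A",
                       dn_ref = "A", dn_alt = "G") {
  sites <- het_sites(rep("amplicon", 2), c(up_pos, dn_pos),
                     c(up_ref, dn_ref), c(up_alt, dn_alt))
  counts <- matrix(as.integer(counts), 4L, 4L,
                   dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  structure(list(upstream = sites[1, , drop = FALSE],
                 downstream = sites[2, , drop = FALSE],
                 counts = counts, total = sum(counts)),
            class = "assoc_matrix")
}

# Brute-force linked-coverage oracle: enumerate positions directly per
# fragment (independent of the interval arithmetic in the implementation).
brute_profile <- function(fragments, region_length, delta) {
  counts <- stats::setNames(numeric(length(delta)), delta)
  for (i in seq_len(nrow(fragments))) {
    cov <- logical(region_length)
    cov[fragments$r1_start[i]:fragments$r1_end[i]] <- TRUE
    cov[fragments$r2_start[i]:fragments$r2_end[i]] <- TRUE
    for (j in seq_along(delta)) {
      d <- delta[j]
      if (d < region_length) {
        counts[j] <- counts[j] +
          sum(cov[1:(region_length - d)] & cov[(1 + d):region_length])
      }
    }
  }
  counts / region_length
}

# Counts matrix helper: place `n` in cell (up_base, dn_base).
cell_counts <- function(...) {
  cells <- list(...)
  m <- matrix(0L, 4L, 4L, dimnames = list(c("A","C","G","T"),
                                          c("A","C","G","T")))
  for (cl in cells) m[cl[[1]], cl[[2]]] <- as.integer(cl[[3]])
  m
}
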