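## File emitters/readers for the simulator and pipeline: SAM (paired,
## truth-placed, ZP-tagged), FASTQ, FASTA genome, truth tables.

#' Write read pairs as a SAM file
#'
#' Emits a coordinate-unsorted SAM with @HD/@SQ headers, one pair of
#' primary alignment records per read pair, correct paired-end flags and
#' strands, and a `ZP:i` tag when the pair is probe-indexed. Reverse-
#' strand records store the as-sequenced (reverse-complemented) bases per
#' the SAM convention, so the file round-trips through standard tools.
#'
#' @param reads an `str_reads` data.frame.
#' @param path output path.
#' @param genome named character vector of reference sequences (for @SQ
#'   lengths).
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, path, genome) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(genome))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(genome[[nm]])), con)
  flag <- function(strand, mate_strand, first) {
    1L + 2L +                       # paired, proper pair
      (if (strand == "-") 16L else 0L) +
      (if (mate_strand == "-") 32L else 0L) +
      (if (first) 64L else 128L)
  }
  fmt <- function(qname, fl, chrom, pos, mapq, cigar, mchrom, mpos,
                  seq, qual, zp) {
    base <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                    qname, fl, chrom, pos, mapq, cigar,
                    if (mchrom == chrom) "=" else mchrom, mpos, seq, qual)
    if (!is.na(zp)) paste0(base, "\tZP:i:", zp) else base
  }
  revq <- function(q) vapply(q, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
  lines <- character(2L * nrow(reads))
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    s1 <- if (r$r1_strand == "-") .revcomp(r$r1_seq) else r$r1_seq
    q1 <- if (r$r1_strand == "-") revq(r$r1_qual) else r$r1_qual
    s2 <- if (r$r2_strand == "-") .revcomp(r$r2_seq) else r$r2_seq
    q2 <- if (r$r2_strand == "-") revq(r$r2_qual) else r$r2_qual
    lines[2L * i - 1L] <- fmt(r$pair_id,
                              flag(r$r1_strand, r$r2_strand, TRUE),
                              r$r1_chrom, r$r1_pos, r$r1_mapq, r$r1_cigar,
                              r$r2_chrom, r$r2_pos, s1, q1, r$zp)
    lines[2L * i] <- fmt(r$pair_id,
                         flag(r$r2_strand, r$r1_strand, FALSE),
                         r$r2_chrom, r$r2_pos, r$r2_mapq, r$r2_cigar,
                         r$r1_chrom, r$r1_pos, s2, q2, r$zp)
  }
  writeLines(lines, con)
  invisible(path)
}

#' Write the synthetic genome as FASTA
#' @param sim_panel an [build_synthetic_panel()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(sim_panel, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim_panel$genome), path)
  invisible(path)
}

#' Write read pairs as a FASTQ pair
#'
#' As-sequenced orientation: reverse-strand reads are
#' reverse-complemented.
#'
#' @param reads an `str_reads` data.frame.
#' @param r1_path,r2_path output paths.
#' @return invisibly, c(r1_path, r2_path).
#' @export
write_reads_fastq <- function(reads, r1_path, r2_path) {
  emit <- function(seqs, quals, strands, ids, path) {
    rc <- strands == "-"
    s <- Biostrings::DNAStringSet(seqs)
    s[rc] <- Biostrings::reverseComplement(s[rc])
    q <- quals
    q[rc] <- vapply(q[rc], function(x)
      paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
      USE.NAMES = FALSE)
    names(s) <- ids
    Biostrings::writeXStringSet(s, path, format = "fastq",
                                qualities = Biostrings::BStringSet(q))
  }
  emit(reads$r1_seq, reads$r1_qual, reads$r1_strand, reads$pair_id, r1_path)
  emit(reads$r2_seq, reads$r2_qual, reads$r2_strand, reads$pair_id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Write / read a simulation truth table
#' @param truth an `str_truth` data.frame.
#' @param path TSV path.
#' @return `path` (write) or the `str_truth` (read).
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("str_truth", "data.frame")
  out
}

#' Read a SAM/BAM file into an `str_reads`-style pair table
#'
#' Thin wrapper over Rsamtools (required): primary alignments are paired
#' by name, reverse-strand records are restored to reference orientation,
#' and an existing `ZP` tag is recovered. Secondary and supplementary
#' records are skipped.
#'
#' @param path SAM or BAM path (SAM is converted via
#'   `Rsamtools::asBam()`).
#' @return data.frame with the `str_reads` alignment columns (truth
#'   columns absent).
#' @export
read_pairs_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_pairs_sam requires the Rsamtools package")
  if (grepl("\\.sam$", path)) {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "qual", "strand"),
    tag = "ZP", flag = flags)
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  first <- bitwAnd(b$flag, 64L) > 0L
  d <- data.frame(qname = b$qname,
                  chrom = as.character(b$rname), pos = b$pos,
                  strand = as.character(b$strand), mapq = b$mapq,
                  cigar = b$cigar, seq = as.character(b$seq),
                  qual = as.character(b$qual),
                  zp = if (is.null(b$tag$ZP)) NA_integer_ else b$tag$ZP,
                  stringsAsFactors = FALSE)
  # restore reference orientation for reverse-strand records
  rc <- d$strand == "-"
  d$seq[rc] <- vapply(d$seq[rc], .revcomp, character(1), USE.NAMES = FALSE)
  d$qual[rc] <- vapply(d$qual[rc], function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
  r1 <- d[first, ]; r2 <- d[!first, ]
  m <- match(r1$qname, r2$qname)
  out <- data.frame(pair_id = r1$qname,
                    r1_seq = r1$seq, r1_qual = r1$qual,
                    r1_chrom = r1$chrom, r1_pos = r1$pos,
                    r1_strand = r1$strand, r1_mapq = r1$mapq,
                    r1_cigar = r1$cigar,
                    r2_seq = r2$seq[m], r2_qual = r2$qual[m],
                    r2_chrom = r2$chrom[m], r2_pos = r2$pos[m],
                    r2_strand = r2$strand[m], r2_mapq = r2$mapq[m],
                    r2_cigar = r2$cigar[m],
                    zp = r1$zp, stringsAsFactors = FALSE)
  class(out) <- c("str_reads", "data.frame")
  out
}
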