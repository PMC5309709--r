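## Panel design filters: candidate STR selection, Willems microsatellite
## criteria, probe uniqueness screening and guide-RNA candidate
## enumeration. All filters are pure functions of their inputs.

#' Candidate STR selection
#'
#' Keeps short repeats (tract length <= `max_repeat_len` bases) having at
#' least one validated SNP within `snp_window` bases whose additive
#' genotype frequency exceeds `min_additive_freq`. The additive genotype
#' frequency of a SNP is taken as the sum across surveyed populations of
#' its non-reference genotype frequency (heterozygote + minor-homozygote),
#' so a value above 1 demands polymorphism across several populations.
#'
#' @param repeats data.frame (`chrom`, `start`, `end`, `motif`, ...) of
#'   repeat annotations (1-based inclusive).
#' @param snps data.frame (`chrom`, `pos`, plus one numeric column per
#'   population named in `populations`) of per-population non-reference
#'   genotype frequencies.
#' @param populations names of the population frequency columns; default
#'   every numeric column except `pos`.
#' @param max_repeat_len maximum tract length in bases.
#' @param snp_window maximum SNP distance from the tract in bases.
#' @param min_additive_freq additive genotype frequency bound (exclusive).
#' @return the rows of `repeats` passing both filters, with an
#'   `n_proximal_snps` column appended.
#' @export
select_candidate_strs <- function(repeats, snps, populations = NULL,
                                  max_repeat_len = 100L, snp_window = 100L,
                                  min_additive_freq = 1.0) {
  if (is.null(populations))
    populations <- setdiff(names(snps)[vapply(snps, is.numeric, logical(1))],
                           c("pos", "start", "end"))
  if (!length(populations)) stop("no population frequency columns found")
  addfreq <- rowSums(as.matrix(snps[populations]))
  good_snp <- snps[addfreq > min_additive_freq, , drop = FALSE]
  len <- repeats$end - repeats$start + 1L
  n_prox <- vapply(seq_len(nrow(repeats)), function(i) {
    sum(good_snp$chrom == repeats$chrom[i] &
          good_snp$pos >= repeats$start[i] - snp_window &
          good_snp$pos <= repeats$end[i] + snp_window)
  }, integer(1))
  out <- repeats[len <= max_repeat_len & n_prox >= 1L, , drop = FALSE]
  out$n_proximal_snps <- n_prox[len <= max_repeat_len & n_prox >= 1L]
  rownames(out) <- NULL
  out
}

# per-unit-size minimum alignment scores of the Willems criteria
.WILLEMS_MIN_SCORE <- c("2" = 22, "3" = 28, "4" = 28, "5" = 32, "6" = 34)

#' Willems microsatellite filter
#'
#' TRUE iff the repeat annotation satisfies the published microsatellite
#' definition: unit size with a defined score minimum (2-6; callers may
#' restrict to 2-5), match percentage >= 80, indel percentage <= 10, and
#' alignment score at or above the unit-size-specific minimum (2:22,
#' 3:28, 4:28, 5:32, 6:34). Homopolymers (unit size 1) are candidate
#' STRs, not Willems microsatellites.
#'
#' @param unit_size,pct_match,pct_indel,alignment_score Tandem Repeat
#'   Finder-style annotation fields (vectorized).
#' @param allowed_units unit sizes admitted (default 2:6).
#' @return logical vector; attribute `reason` carries the first failing
#'   criterion per element.
#' @export
willems_microsatellite_filter <- function(unit_size, pct_match, pct_indel,
                                          alignment_score,
                                          allowed_units = 2:6) {
  n <- max(length(unit_size), length(pct_match))
  reason <- rep(NA_character_, n)
  min_score <- .WILLEMS_MIN_SCORE[as.character(unit_size)]
  ok_unit <- unit_size %in% allowed_units & !is.na(min_score)
  reason[!ok_unit] <- "unit_size"
  ok <- ok_unit
  fail <- ok & pct_match < 80
  reason[fail] <- "pct_match"; ok <- ok & !fail
  fail <- ok & pct_indel > 10
  reason[fail] <- "pct_indel"; ok <- ok & !fail
  fail <- ok & alignment_score < min_score
  reason[fail] <- "alignment_score"; ok <- ok & !fail
  structure(ok, reason = reason)
}

#' Probe uniqueness screen
#'
#' TRUE iff no off-target location in the reference matches the 40-mer
#' probe with fewer than `min_edits` substitutions, on either strand
#' (exhaustive scan; intended for desk-scale synthetic references). The
#' probe's own location (0 mismatches, expected once) is tolerated when
#' `own_sites = 1`.
#'
#' @param probe_seq the 40-base probe.
#' @param ref named character vector or `Biostrings::DNAStringSet` of
#'   reference sequences.
#' @param min_edits minimum substitution distance demanded of any other
#'   matching location.
#' @param own_sites number of exact self-matches tolerated (default 1).
#' @return logical scalar.
#' @export
screen_probe_uniqueness <- function(probe_seq, ref, min_edits = 2L,
                                    own_sites = 1L) {
  if (nchar(probe_seq) != 40L) stop("probe must be exactly 40 bases")
  .screen_unique(probe_seq, ref, min_edits, own_sites)
}

.screen_unique <- function(seq, ref, min_edits, own_sites) {
  if (!methods::is(ref, "DNAStringSet"))
    ref <- Biostrings::DNAStringSet(unlist(ref))
  pat <- Biostrings::DNAString(seq)
  n_exact <- 0L
  n_near <- 0L
  for (i in seq_along(ref)) {
    for (p in list(pat, Biostrings::reverseComplement(pat))) {
      hits <- Biostrings::matchPattern(p, ref[[i]],
                                       max.mismatch = min_edits - 1L)
      if (length(hits) == 0L) next
      pc <- strsplit(as.character(p), "", fixed = TRUE)[[1]]
      mm <- vapply(as.character(hits), function(s) {
        sc <- strsplit(s, "", fixed = TRUE)[[1]]
        sum(sc != pc[seq_along(sc)]) + (length(pc) - length(sc))
      }, integer(1), USE.NAMES = FALSE)
      n_exact <- n_exact + sum(mm == 0L)
      n_near <- n_near + sum(mm > 0L)
    }
  }
  n_near == 0L && n_exact <= own_sites
}

#' Enumerate guide-RNA candidates for a locus
#'
#' Scans both strands for NGG protospacer-adjacent motifs around the
#' repeat tract and keeps 20-mer protospacers that satisfy the three
#' design criteria: (i) the blunt cut (3 bases 5' of the PAM) places the
#' entire repeat tract within `read_len` bases, (ii) the 20-mer binding
#' sequence is uniquely represented in the reference (substitution
#' distance >= 2 anywhere else), and (iii) the protospacer overlaps the
#' tract by at most `max_overlap` bases. Candidates on both sides of the
#' tract are returned.
#'
#' @param locus one row of a panel locus table (`chrom`, `start`, `end`).
#' @param ref named character vector of reference sequences covering the
#'   locus +/- `read_len` + 23.
#' @param read_len sequencing read length the cut must serve.
#' @param max_overlap maximum protospacer/tract overlap in bases.
#' @param pam PAM regular expression on the protospacer strand
#'   (default NGG).
#' @return data.frame of class `grna_candidates`: `str_name`, `chrom`,
#'   `protospacer`, `strand`, `cut_pos` (boundary coordinate: first base
#'   downstream of the blunt cut), `side` (`upstream`/`downstream` of the
#'   tract), `overlap_bp`, `unique`; zero rows when the locus is
#'   undesignable.
#' @export
design_grnas <- function(locus, ref, read_len = 100L, max_overlap = 6L,
                         pam = "[ACGT]GG") {
  chrom_seq <- ref[[locus$chrom]]
  S <- locus$start; E <- locus$end
  win_lo <- max(1L, S - read_len - 23L)
  win_hi <- min(nchar(chrom_seq), E + read_len + 23L)
  win <- substr(chrom_seq, win_lo, win_hi)
  out <- list()
  scan_strand <- function(strand) {
    seq <- if (strand == "+") win else .revcomp(win)
    starts <- gregexpr(sprintf("(?=%s)", pam), seq, perl = TRUE)[[1]]
    if (starts[1] == -1L) return()
    for (pst in as.integer(starts)) {
      if (pst < 21L) next   # need a full 20-mer protospacer 5' of the PAM
      proto <- substr(seq, pst - 20L, pst - 1L)
      # genomic coordinates of the protospacer
      if (strand == "+") {
        g_start <- win_lo + pst - 21L
        g_end <- g_start + 19L
        cut <- g_end - 2L          # boundary: first base right of the cut
      } else {
        g_end <- win_hi - (pst - 21L)
        g_start <- g_end - 19L
        cut <- g_start + 3L        # blunt cut 3 bp 5' of the PAM
      }
      overlap <- max(0L, min(g_end, E) - max(g_start, S) + 1L)
      if (overlap > max_overlap) next
      # criterion (i): full tract within read_len of the cut boundary
      within <- if (cut <= S) E - cut + 1L <= read_len
                else cut - 1L - S + 1L <= read_len
      if (!isTRUE(within)) next
      side <- if (cut <= S) "upstream" else "downstream"
      uniq <- .screen_unique(proto, ref, min_edits = 2L, own_sites = 1L)
      out[[length(out) + 1L]] <<- data.frame(
        str_name = locus$str_name %||% NA_character_, chrom = locus$chrom,
        protospacer = proto, strand = strand, cut_pos = cut, side = side,
        overlap_bp = overlap, unique = uniq, stringsAsFactors = FALSE)
    }
  }
  scan_strand("+")
  scan_strand("-")
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(str_name = character(0), chrom = character(0),
               protospacer = character(0), strand = character(0),
               cut_pos = integer(0), side = character(0),
               overlap_bp = integer(0), unique = logical(0))
  res <- res[res$unique, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("grna_candidates", "data.frame")
  res
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
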