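## STR genotyping from tagged Read 1 sequences: variable-region extraction
## between exact 15-base flanks (with SNP-substituted flank alternates),
## motif repeat counting, allele histograms, threshold-based diploid calls,
## threshold calibration, stutter fraction and dosage.

#' Default secondary-allele threshold table
#'
#' Read-count thresholds, as a fraction of the major-allele reads, that a
#' candidate secondary allele must reach for a heterozygous call, keyed by
#' its allelic distance from the major allele: 0.35 at distance -1, 0.15
#' at +1, 0.45 below -1 and 0.02 above +1. The asymmetry reflects
#' deletion-biased stutter and read-length truncation of long alleles.
#'
#' @param minus1,plus1,below,above per-class fractions in (0, 1].
#' @return named numeric vector of class `str_thresholds` with entries
#'   `"-1"`, `"+1"`, `"<-1"`, `">+1"`.
#' @export
threshold_table <- function(minus1 = 0.35, plus1 = 0.15,
                            below = 0.45, above = 0.02) {
  v <- c("-1" = minus1, "+1" = plus1, "<-1" = below, ">+1" = above)
  if (any(v <= 0 | v > 1)) stop("thresholds must lie in (0, 1]")
  structure(v, class = "str_thresholds")
}

.distance_class <- function(d) {
  ifelse(d == -1L, "-1",
         ifelse(d == 1L, "+1", ifelse(d < -1L, "<-1", ">+1")))
}

#' Enumerate accepted flank variants from called flank SNPs
#'
#' The reference 15-base flanks are always accepted; for every biallelic
#' substitution called inside a flank interval, the alternate-substituted
#' flank is added. Complex/multi-base variants are excluded upstream.
#'
#' @param panel an [str_panel()].
#' @param flank_snps NULL, or a data.frame (`chrom`, `pos`, `ref`, `alt`)
#'   of substitution calls (e.g. filtered output of [call_snps_pileup()]).
#' @return named list per locus with character vectors `flank5`, `flank3`.
#' @export
flank_variants <- function(panel, flank_snps = NULL) {
  loci <- panel$loci
  variants_for <- function(ref_flank, bed) {
    v <- ref_flank
    if (is.null(flank_snps) || nrow(flank_snps) == 0L) return(v)
    for (j in seq_len(nrow(bed))) {
      hit <- which(flank_snps$chrom == bed$chrom[j] &
                     flank_snps$pos >= bed$start[j] &
                     flank_snps$pos <= bed$end[j] &
                     nchar(flank_snps$ref) == 1L &
                     nchar(flank_snps$alt) == 1L)
      for (k in hit) {
        off <- flank_snps$pos[k] - bed$start[j] + 1L
        alt <- ref_flank
        substr(alt, off, off) <- flank_snps$alt[k]
        v <- c(v, alt)
      }
    }
    unique(v)
  }
  out <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    list(flank5 = variants_for(l$flank5,
                               panel$flank5[panel$flank5$name == l$str_name, ,
                                            drop = FALSE]),
         flank3 = variants_for(l$flank3,
                               panel$flank3[panel$flank3$name == l$str_name, ,
                                            drop = FALSE]))
  })
  setNames(out, loci$str_name)
}

#' Extract the variable region between the flanking sequences
#'
#' Returns the bases strictly between the first exact occurrence of an
#' accepted 5' flank variant and the next exact occurrence of an accepted
#' 3' flank variant; `NA` when either flank is absent (tallied by the
#' callers as missing-5' / missing-3').
#'
#' @param r1_seq character vector of Read 1 sequences (reference
#'   orientation).
#' @param flank5,flank3 character vectors of accepted 15-base variants
#'   (reference flank first).
#' @return list with `region` (character, `NA` on failure) and `reason`
#'   (`"ok"`, `"missing_5p"`, `"missing_3p"`).
#' @export
extract_variable_region <- function(r1_seq, flank5, flank3) {
  n <- length(r1_seq)
  # first match over the variant set: take the minimum position
  first_hit <- function(seqs, patterns, from = NULL) {
    best <- rep(NA_integer_, length(seqs))
    for (p in patterns) {
      if (is.null(from)) {
        m <- regexpr(p, seqs, fixed = TRUE)
        pos <- ifelse(m > 0L, as.integer(m), NA_integer_)
      } else {
        sub <- substr(seqs, from, nchar(seqs))
        m <- regexpr(p, sub, fixed = TRUE)
        pos <- ifelse(m > 0L, as.integer(m) + from - 1L, NA_integer_)
      }
      best <- ifelse(is.na(best) | (!is.na(pos) & pos < best), pos, best)
    }
    best
  }
  p5 <- first_hit(r1_seq, flank5)
  reason <- ifelse(is.na(p5), "missing_5p", "ok")
  after <- ifelse(is.na(p5), 1L, p5 + nchar(flank5[1]))
  p3 <- rep(NA_integer_, n)
  ok5 <- which(!is.na(p5))
  if (length(ok5))
    p3[ok5] <- first_hit(r1_seq[ok5], flank3, from = after[ok5])
  reason[!is.na(p5) & is.na(p3)] <- "missing_3p"
  region <- rep(NA_character_, n)
  good <- !is.na(p5) & !is.na(p3)
  region[good] <- substr(r1_seq[good], after[good], p3[good] - 1L)
  list(region = region, reason = reason)
}

#' Count motif repeats in a variable region
#'
#' The repeat count is the number of bases in the variable region divided
#' by the motif length (floor; a non-integral remainder is flagged). The
#' region must contain at least `min_repeats` exact tandem copies of the
#' motif, otherwise the read is rejected.
#'
#' @param region character vector of variable regions (`NA` allowed).
#' @param motif repeat unit (1-6 bases).
#' @param min_repeats minimum tandem copies for the STR to be present.
#' @return list with integer `repeats` (`NA` where rejected), logical
#'   `remainder` (region length not a motif multiple), and `accepted`.
#' @export
count_motif_repeats <- function(region, motif, min_repeats) {
  mlen <- nchar(motif)
  len <- nchar(region)
  tandem <- strrep(motif, min_repeats)
  has_min <- !is.na(region) & grepl(tandem, region, fixed = TRUE)
  reps <- ifelse(has_min, len %/% mlen, NA_integer_)
  list(repeats = as.integer(reps),
       remainder = ifelse(has_min, len %% mlen != 0L, NA),
       accepted = has_min)
}

#' Per-read repeat counts for tagged pairs
#'
#' Runs flank extraction and repeat counting for every tagged pair,
#' against its own locus. The workhorse behind [build_allele_histogram()]
#' and the phasing stage (which needs the repeat count of each pair, not
#' just the histogram).
#'
#' @param tagged result of [tag_read_pairs()].
#' @param panel an [str_panel()].
#' @param variants optional [flank_variants()] result.
#' @return `tagged` with columns `locus`, `repeats` (NA where the read
#'   does not present an intact STR), `strand` (probe strand) and
#'   `filter_reason`.
#' @export
read_repeat_counts <- function(tagged, panel, variants = NULL) {
  if (is.null(variants)) variants <- flank_variants(panel)
  locus <- tagged_locus(tagged, panel)
  strand <- panel$probes$strand[match(tagged$zp, panel$probes$probe_id)]
  reps <- rep(NA_integer_, nrow(tagged))
  reason <- rep(NA_character_, nrow(tagged))
  for (nm in unique(locus)) {
    idx <- which(locus == nm)
    l <- panel$loci[panel$loci$str_name == nm, ]
    v <- variants[[nm]]
    ex <- extract_variable_region(tagged$r1_seq[idx], v$flank5, v$flank3)
    ct <- count_motif_repeats(ex$region, l$motif, l$min_repeats)
    reps[idx] <- ct$repeats
    reason[idx] <- ifelse(ex$reason != "ok", ex$reason,
                          ifelse(!ct$accepted, "below_min_repeats",
                                 ifelse(ct$remainder, "remainder", "ok")))
  }
  out <- tagged
  out$locus <- locus
  out$strand <- strand
  out$repeats <- reps
  out$filter_reason <- reason
  for (a in c("panel_sig", "r2_len", "read_len"))
    attr(out, a) <- attr(tagged, a)
  class(out) <- c("str_reads", "data.frame")
  out
}

#' Build a per-locus allele histogram
#'
#' Spanning reads only; counts are kept per probe strand (both
#' orientations accumulate in the same histogram, and per-strand support
#' allows a strict both-strand mode downstream).
#'
#' @param counted result of [read_repeat_counts()], or any data.frame
#'   with `locus`, `repeats`, `strand`.
#' @param locus locus name.
#' @return data.frame of class `allele_hist` (`repeats`, `n_fwd`,
#'   `n_rev`, `n`), or `NULL` when the locus has no accepted read.
#' @export
build_allele_histogram <- function(counted, locus) {
  x <- counted[!is.na(counted$repeats) & counted$locus == locus, ,
               drop = FALSE]
  if (nrow(x) == 0L) return(NULL)
  reps <- sort(unique(x$repeats))
  f <- factor(x$repeats, levels = reps)
  h <- data.frame(repeats = reps,
                  n_fwd = as.integer(table(f[x$strand == "+"])),
                  n_rev = as.integer(table(f[x$strand == "-"])))
  h$n <- h$n_fwd + h$n_rev
  attr(h, "locus") <- locus
  class(h) <- c("allele_hist", "data.frame")
  h
}

#' Call a diploid STR genotype from an allele histogram
#'
#' The major allele is the repeat count with maximal read support (ties
#' break to the shorter repeat, flagged). Every other repeat count is a
#' candidate secondary allele with allelic distance `d = candidate -
#' major`; it passes when `count / major_count >= thresholds[class(d)]`
#' with class in `{-1, +1, <-1, >+1}`. If any candidate passes, the call
#' is heterozygous with the best passing candidate (most reads, then
#' smallest |distance|, then shorter allele); otherwise homozygous.
#'
#' @param hist an [build_allele_histogram()] result.
#' @param thresholds a [threshold_table()].
#' @param min_total_reads no-call below this total spanning-read count.
#' @param strict_strand require each called allele to be seen on both
#'   strands (off by default).
#' @return list of class `str_call`: `locus`, `alleles` (1 or 2 repeat
#'   counts, major first), `zygosity`, `major_allele`, `support` (reads
#'   per called allele), `total`, `stutter_fraction`, `flags`; or `NULL`
#'   (no-call) when `total < min_total_reads`.
#' @export
call_str_genotype <- function(hist, thresholds = threshold_table(),
                              min_total_reads = 5L, strict_strand = FALSE) {
  if (is.null(hist) || nrow(hist) == 0L) return(NULL)
  total <- sum(hist$n)
  if (total < min_total_reads) return(NULL)
  flags <- character(0)
  mx <- max(hist$n)
  majors <- hist$repeats[hist$n == mx]
  if (length(majors) > 1L) flags <- c(flags, "major_tie")
  major <- min(majors)
  major_n <- mx
  cand <- hist[hist$repeats != major, , drop = FALSE]
  if (nrow(cand) > 0L) {
    d <- cand$repeats - major
    pass <- cand$n / major_n >= unclass(thresholds)[.distance_class(d)]
    if (strict_strand)
      pass <- pass & cand$n_fwd > 0L & cand$n_rev > 0L
    cand <- cand[pass, , drop = FALSE]
  }
  if (nrow(cand) > 0L) {
    d <- abs(cand$repeats - major)
    o <- order(-cand$n, d, cand$repeats)
    sec <- cand$repeats[o[1]]
    alleles <- c(major, sec)
    support <- c(major_n, cand$n[o[1]])
    zyg <- "het"
  } else {
    alleles <- major
    support <- major_n
    zyg <- "hom"
  }
  sf <- (total - sum(hist$n[hist$repeats %in% alleles])) / total
  structure(list(locus = attr(hist, "locus"), alleles = alleles,
                 zygosity = zyg, major_allele = major, support = support,
                 total = total, stutter_fraction = sf, flags = flags),
            class = "str_call")
}

#' @export
print.str_call <- function(x, ...) {
  cat(sprintf("%s: %s (%s), support %s / %d reads, stutter %.3f\n",
              x$locus, paste(x$alleles, collapse = "/"), x$zygosity,
              paste(x$support, collapse = "+"), x$total,
              x$stutter_fraction))
  invisible(x)
}

#' Stutter fraction of a called histogram
#'
#' Non-allelic reads divided by total STR-spanning reads:
#' `(total - sum(reads at called alleles)) / total`.
#'
#' @param hist an `allele_hist`.
#' @param call the [call_str_genotype()] result for `hist`.
#' @return fraction in `[0, 1]`.
#' @export
stutter_fraction <- function(hist, call) {
  total <- sum(hist$n)
  (total - sum(hist$n[hist$repeats %in% call$alleles])) / total
}

#' STR dosage of a genotype call
#'
#' Sum over both allele copies of (allele length - reference tract
#' length) in base pairs; a homozygote contributes its allele twice. A
#' reference-homozygous call has dosage 0. Example: reference tract 18 bp
#' with heterozygous alleles of 16 bp and 24 bp gives -2 + 6 = 4.
#'
#' @param call an `str_call` (alleles in repeat units).
#' @param motif_len motif length in bases.
#' @param ref_len_bp reference tract length in base pairs.
#' @return signed integer dosage in base pairs.
#' @export
str_dosage <- function(call, motif_len, ref_len_bp) {
  bp <- call$alleles * motif_len
  if (length(bp) == 1L) bp <- rep(bp, 2L)
  sum(bp - ref_len_bp)
}

#' Genotype every locus of a tagged read set
#'
#' @param tagged result of [tag_read_pairs()].
#' @param panel an [str_panel()].
#' @param variants optional [flank_variants()] result.
#' @param thresholds a [threshold_table()].
#' @param min_total_reads no-call floor (default 5 spanning reads).
#' @param strict_strand see [call_str_genotype()].
#' @return list of class `str_genotypes`: `calls` data.frame (`locus`,
#'   `allele1`, `allele2`, `zygosity`, `support1`, `support2`, `total`,
#'   `stutter_fraction`, `dosage_bp`, `flags`), `histograms` (named list
#'   of `allele_hist`), `reads` (the [read_repeat_counts()] table),
#'   `uncovered` (loci with no accepted read or below the floor).
#' @export
genotype_reads <- function(tagged, panel, variants = NULL,
                           thresholds = threshold_table(),
                           min_total_reads = 5L, strict_strand = FALSE) {
  counted <- read_repeat_counts(tagged, panel, variants)
  loci <- panel$loci
  calls <- vector("list", nrow(loci))
  hists <- list()
  uncovered <- character(0)
  for (i in seq_len(nrow(loci))) {
    nm <- loci$str_name[i]
    h <- build_allele_histogram(counted, nm)
    if (is.null(h)) { uncovered <- c(uncovered, nm); next }
    hists[[nm]] <- h
    cl <- call_str_genotype(h, thresholds, min_total_reads, strict_strand)
    if (is.null(cl)) { uncovered <- c(uncovered, nm); next }
    mlen <- nchar(loci$motif[i])
    ref_bp <- loci$end[i] - loci$start[i] + 1L
    calls[[i]] <- data.frame(
      locus = nm,
      allele1 = cl$alleles[1],
      allele2 = if (length(cl$alleles) > 1L) cl$alleles[2] else cl$alleles[1],
      zygosity = cl$zygosity,
      support1 = cl$support[1],
      support2 = if (length(cl$support) > 1L) cl$support[2] else cl$support[1],
      total = cl$total,
      stutter_fraction = cl$stutter_fraction,
      dosage_bp = str_dosage(cl, mlen, ref_bp),
      flags = paste(cl$flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  structure(list(calls = calls, histograms = hists, reads = counted,
                 uncovered = uncovered),
            class = "str_genotypes")
}

#' @export
print.str_genotypes <- function(x, ...) {
  cat(sprintf("str_genotypes: %d loci called (%d het, %d hom), %d uncovered\n",
              nrow(x$calls), sum(x$calls$zygosity == "het"),
              sum(x$calls$zygosity == "hom"), length(x$uncovered)))
  invisible(x)
}

#' Calibrate secondary-allele thresholds from labelled histograms
#'
#' For each allelic-distance class, sweeps every observed
#' secondary-to-major read fraction and selects the smallest threshold
#' whose false-call rate on homozygous controls stays at or below
#' `max_false_positive`, thereby maximizing sensitivity on heterozygous
#' cases. Returns the full ROC alongside the chosen table.
#'
#' @param cases data.frame (`class`, `fraction`) of true-secondary-allele
#'   read fractions, `class` in `c("-1","+1","<-1",">+1")`.
#' @param controls data.frame (`class`, `fraction`) of the largest
#'   same-distance artifact fractions observed in known homozygotes.
#' @param max_false_positive tolerated control false-call rate.
#' @return list of class `str_calibration`: `thresholds` (a
#'   [threshold_table()]; classes with no data are dropped with a
#'   warning), `roc` data.frame (`class`, `threshold`, `sensitivity`,
#'   `false_rate`).
#' @export
calibrate_thresholds <- function(cases, controls, max_false_positive = 0.01) {
  classes <- c("-1", "+1", "<-1", ">+1")
  chosen <- c()
  roc <- list()
  for (cl in classes) {
    ca <- cases$fraction[cases$class == cl]
    co <- controls$fraction[controls$class == cl]
    if (length(ca) == 0L || length(co) == 0L) {
      warning("no cases or controls for distance class ", cl,
              "; class omitted")
      next
    }
    grid <- sort(unique(c(ca, co)))
    sens <- vapply(grid, function(t) mean(ca >= t), numeric(1))
    fpr <- vapply(grid, function(t) mean(co >= t), numeric(1))
    roc[[cl]] <- data.frame(class = cl, threshold = grid,
                            sensitivity = sens, false_rate = fpr)
    ok <- which(fpr <= max_false_positive)
    if (length(ok) == 0L) {
      warning("no threshold meets the false-positive bound for class ", cl)
      next
    }
    chosen[cl] <- min(grid[ok])
  }
  th <- unclass(threshold_table())
  th[names(chosen)] <- chosen
  th <- th[names(th) %in% names(chosen)]
  structure(list(thresholds = structure(th, class = "str_thresholds"),
                 roc = do.call(rbind, roc)),
            class = "str_calibration")
}
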