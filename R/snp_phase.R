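## SNP calling and STR-SNP haplotyping: probe-base masking, a pileup SNP
## caller honoring the published filter cascade, read-level linkage of
## the Read 2 SNP base to the Read 1 repeat count, and haplotype calls.

#' Usable (unmasked) alignment range of each Read 2
#'
#' The synthetic probe DNA matches the reference by design, so the first
#' 40 sequenced bases of every Read 2 must not influence variant
#' discovery: forward reads mask their first 40 aligned bases, reverse
#' reads their last 40. Reads shorter than `n` are fully masked (with a
#' warning).
#'
#' @param r2_pos,r2_len,r2_strand alignment start, length and strand
#'   vectors.
#' @param n number of probe bases to mask.
#' @return data.frame `use_start`, `use_end` (1-based inclusive genomic
#'   range of usable bases; `use_start > use_end` means fully masked).
#' @export
mask_probe_bases <- function(r2_pos, r2_len, r2_strand, n = 40L) {
  if (any(r2_len < n))
    warning(sum(r2_len < n), " read(s) shorter than the probe mask; ",
            "fully masked")
  use_start <- ifelse(r2_strand == "+", r2_pos + n, r2_pos)
  use_end <- ifelse(r2_strand == "+", r2_pos + r2_len - 1L,
                    r2_pos + r2_len - 1L - n)
  data.frame(use_start = as.integer(use_start),
             use_end = as.integer(use_end))
}

#' Pileup SNP caller over probe-masked Read 2 alignments
#'
#' A deliberate simplification of a Bayesian caller: per-site biallelic
#' substitution calls from base frequencies, honoring the published
#' filter parameters. A site is called when, among unmasked bases with
#' base quality >= `min_base_quality` from reads with mapping quality >=
#' `min_mapping_quality`: coverage >= `min_coverage`, the top alternate
#' base has frequency >= `pvar`, the supporting mapping-quality sum is >=
#' `min_supporting_mapping_qsum` and the supporting base-quality sum is
#' >= `min_supporting_allele_qsum`. Indel and multi-nucleotide evidence
#' is never generated (alignments are ungapped here), matching the
#' no-mnps/no-complex setting. Sites failing a filter are reported with
#' reasons rather than dropped, so the downstream PASS filter is honest.
#'
#' @param reads data.frame with `r2_chrom`, `r2_pos`, `r2_strand`,
#'   `r2_seq`, `r2_qual`, `r2_mapq`.
#' @param intervals data.frame (`chrom`, `start`, `end`) restricting the
#'   examined sites (typically the panel's no-STR target bed).
#' @param ref named character vector of reference chromosome sequences.
#' @param pvar minimum alternate allele fraction.
#' @param min_coverage,min_base_quality,min_mapping_quality,
#'   min_supporting_mapping_qsum,min_supporting_allele_qsum filter
#'   parameters.
#' @param mask_n probe bases masked per read (see [mask_probe_bases()]).
#' @param hom_alt_min alternate fraction at or above which the genotype
#'   is homozygous-alternate rather than heterozygous.
#' @return data.frame of class `snp_calls`: `chrom`, `pos`, `ref`, `alt`,
#'   `coverage`, `ref_count`, `alt_count`, `alt_qual_sum`, `genotype`
#'   (`"het"`/`"hom_alt"`), `ref_freq`, `alt_freq`, `filter` (`"PASS"` or
#'   semicolon-joined reasons). Only sites with at least one alternate
#'   base are reported.
#' @export
call_snps_pileup <- function(reads, intervals, ref,
                             pvar = 0.05, min_coverage = 3L,
                             min_base_quality = 15L,
                             min_mapping_quality = 25L,
                             min_supporting_mapping_qsum = 90L,
                             min_supporting_allele_qsum = 60L,
                             mask_n = 40L, hom_alt_min = 0.8) {
  r2_len <- nchar(reads$r2_seq)
  use <- mask_probe_bases(reads$r2_pos, r2_len, reads$r2_strand, mask_n)
  keep <- reads$r2_mapq >= min_mapping_quality & use$use_start <= use$use_end
  reads <- reads[keep, , drop = FALSE]
  use <- use[keep, , drop = FALSE]
  if (nrow(reads) == 0L)
    return(structure(data.frame(), class = c("snp_calls", "data.frame")))
  r2_len <- r2_len[keep]

  bases4 <- c("A", "C", "G", "T")
  acc <- new.env(parent = emptyenv())   # key "chrom:pos" -> tallies
  # interval membership test per chromosome
  iv_by_chrom <- split(intervals, intervals$chrom)
  in_intervals <- function(chrom, pos) {
    iv <- iv_by_chrom[[chrom]]
    if (is.null(iv)) return(rep(FALSE, length(pos)))
    res <- rep(FALSE, length(pos))
    for (j in seq_len(nrow(iv)))
      res <- res | (pos >= iv$start[j] & pos <= iv$end[j])
    res
  }

  # reads are ungapped; group identically placed reads and tabulate
  # column-wise, which turns the pileup into a handful of matrix passes
  grp <- paste(reads$r2_chrom, reads$r2_pos, r2_len, reads$r2_strand)
  for (g in unique(grp)) {
    gi <- which(grp == g)
    chrom <- reads$r2_chrom[gi[1]]
    gpos <- reads$r2_pos[gi[1]]
    glen <- r2_len[gi[1]]
    cols <- (use$use_start[gi[1]] - gpos + 1L):(use$use_end[gi[1]] - gpos + 1L)
    pos_of <- gpos + cols - 1L
    want <- in_intervals(chrom, pos_of)
    cols <- cols[want]; pos_of <- pos_of[want]
    if (!length(cols)) next
    M <- matrix(unlist(strsplit(reads$r2_seq[gi], "", fixed = TRUE),
                       use.names = FALSE), nrow = glen)
    Q <- matrix(unlist(lapply(reads$r2_qual[gi], utf8ToInt),
                       use.names = FALSE), nrow = glen) - 33L
    mapq <- reads$r2_mapq[gi]
    ref_cols <- strsplit(substr(ref[[chrom]], gpos, gpos + glen - 1L),
                         "", fixed = TRUE)[[1]]
    for (k in seq_along(cols)) {
      b <- M[cols[k], ]
      q <- Q[cols[k], ]
      ok <- q >= min_base_quality & b %in% bases4
      if (!any(ok)) next
      b <- b[ok]; q <- q[ok]; mq <- mapq[ok]
      cnt <- qs <- ms <- numeric(4)
      is_alt <- b != ref_cols[cols[k]]
      if (!any(is_alt)) {
        cnt[match(ref_cols[cols[k]], bases4)] <- length(b)
      } else {
        bf <- factor(b, levels = bases4)
        cnt <- tabulate(bf, 4L)
        # quality/mapq sums are only consumed for alternate bases
        for (ab in unique(b[is_alt])) {
          z <- match(ab, bases4)
          qs[z] <- sum(q[b == ab])
          ms[z] <- sum(mq[b == ab])
        }
      }
      key <- paste0(chrom, ":", pos_of[k])
      prev <- acc[[key]]
      if (is.null(prev)) prev <- list(chrom = chrom, pos = pos_of[k],
                                      cnt = numeric(4), qs = numeric(4),
                                      ms = numeric(4))
      prev$cnt <- prev$cnt + cnt
      prev$qs <- prev$qs + qs
      prev$ms <- prev$ms + ms
      acc[[key]] <- prev
    }
  }

  out <- list()
  for (key in ls(acc)) {
    a <- acc[[key]]
    ref_base <- substr(ref[[a$chrom]], a$pos, a$pos)
    cnt <- setNames(a$cnt, bases4)
    alt_cnt <- cnt
    alt_cnt[ref_base] <- -1
    alt_base <- bases4[which.max(alt_cnt)]
    if (cnt[alt_base] == 0) next
    cov <- sum(cnt)
    ref_n <- unname(cnt[ref_base])
    alt_n <- unname(cnt[alt_base])
    aq <- unname(setNames(a$qs, bases4)[alt_base])
    mq <- unname(setNames(a$ms, bases4)[alt_base])
    fail <- character(0)
    if (cov < min_coverage) fail <- c(fail, "min_coverage")
    if (alt_n / cov < pvar) fail <- c(fail, "pvar")
    if (mq < min_supporting_mapping_qsum) fail <- c(fail, "mapping_qsum")
    if (aq < min_supporting_allele_qsum) fail <- c(fail, "allele_qsum")
    af <- alt_n / cov
    out[[length(out) + 1L]] <- data.frame(
      chrom = a$chrom, pos = a$pos, ref = ref_base, alt = alt_base,
      coverage = cov, ref_count = ref_n, alt_count = alt_n,
      alt_qual_sum = aq,
      genotype = if (af >= hom_alt_min) "hom_alt" else "het",
      ref_freq = ref_n / cov, alt_freq = af,
      filter = if (length(fail)) paste(fail, collapse = ";") else "PASS",
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame()
  if (nrow(res) > 0L) {
    res <- res[order(res$chrom, res$pos), ]
    rownames(res) <- NULL
  }
  structure(res, class = c("snp_calls", "data.frame"))
}

# vectorized single-character extraction from equal-position strings
utf8ToInt_at <- function(s, at) {
  vapply(seq_along(s), function(i) utf8ToInt(substr(s[i], at[i], at[i])),
         integer(1))
}

#' Filter SNP calls: exclusion bed, proximity thinning, PASS, alt quality
#'
#' Removes calls falling in the exclusion intervals (repeat tracts + 5 b),
#' any pair of calls closer than `thin` bases (both removed; the boundary
#' at exactly `thin` is kept), non-PASS calls, and calls whose average
#' alternate base quality (`alt_qual_sum / alt_count`) is not above
#' `min_avg_alt_qual`.
#'
#' @param calls a [call_snps_pileup()] result.
#' @param exclusion_intervals data.frame (`chrom`, `start`, `end`) of
#'   repeat tracts (padded); NULL to skip.
#' @param thin minimum pairwise distance in bases.
#' @param min_avg_alt_qual average alternate base-quality floor.
#' @return the filtered `snp_calls` data.frame.
#' @export
filter_snps <- function(calls, exclusion_intervals = NULL, thin = 6L,
                        min_avg_alt_qual = 8) {
  if (nrow(calls) == 0L) return(calls)
  keep <- calls$filter == "PASS"
  keep <- keep & calls$alt_qual_sum / calls$alt_count > min_avg_alt_qual
  if (!is.null(exclusion_intervals) && nrow(exclusion_intervals) > 0L) {
    q <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos, calls$pos))
    s <- GenomicRanges::GRanges(exclusion_intervals$chrom,
                                IRanges::IRanges(exclusion_intervals$start,
                                                 exclusion_intervals$end))
    keep <- keep & GenomicRanges::countOverlaps(q, s) == 0L
  }
  x <- calls[keep, , drop = FALSE]
  if (nrow(x) > 1L) {
    drop <- rep(FALSE, nrow(x))
    o <- order(x$chrom, x$pos)
    xo <- x[o, ]
    close_next <- c(xo$chrom[-nrow(xo)] == xo$chrom[-1] &
                      diff(xo$pos) < thin, FALSE)
    close_prev <- c(FALSE, close_next[-length(close_next)])
    drop[o] <- close_next | close_prev
    x <- x[!drop, , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

#' Link intact-STR read pairs to phased (SNP base, repeat count) counts
#'
#' For every read pair whose Read 1 presented an intact STR (a repeat
#' count) and whose masked Read 2 covers a called SNP, accumulates the
#' (Read 2 base at the SNP, Read 1 repeat count) pair. Reads carrying a
#' third base at the SNP, or an allele whose called frequency is 0, are
#' dropped.
#'
#' @param counted result of [read_repeat_counts()] (needs `locus`,
#'   `repeats`, Read 2 alignment columns).
#' @param snp_calls filtered [call_snps_pileup()] output.
#' @param panel an [str_panel()] (locus lookup for each SNP uses probe
#'   targeting: the SNP is assigned to the locus whose tagged reads cover
#'   it).
#' @param mask_n probe bases masked per read.
#' @param min_base_quality ignore SNP bases below this quality.
#' @return data.frame of class `phased_counts`: `locus`, `chrom`, `pos`,
#'   `snp_base`, `repeats`, `n`.
#' @export
link_reads_to_haplotypes <- function(counted, snp_calls, panel,
                                     mask_n = 40L, min_base_quality = 15L) {
  intact <- counted[!is.na(counted$repeats), , drop = FALSE]
  if (nrow(intact) == 0L || nrow(snp_calls) == 0L)
    return(structure(data.frame(), class = c("phased_counts", "data.frame")))
  r2_len <- nchar(intact$r2_seq)
  use <- mask_probe_bases(intact$r2_pos, r2_len, intact$r2_strand, mask_n)
  out <- list()
  for (s in seq_len(nrow(snp_calls))) {
    sc <- snp_calls[s, ]
    cov <- which(intact$r2_chrom == sc$chrom &
                   use$use_start <= sc$pos & use$use_end >= sc$pos)
    if (!length(cov)) next
    off <- sc$pos - intact$r2_pos[cov] + 1L
    base <- substr(intact$r2_seq[cov], off, off)
    qual <- utf8ToInt_at(intact$r2_qual[cov], off) - 33L
    ok <- qual >= min_base_quality & base %in% c(sc$ref, sc$alt)
    # drop alleles whose called frequency is zero
    if (sc$ref_freq == 0) ok <- ok & base != sc$ref
    if (sc$alt_freq == 0) ok <- ok & base != sc$alt
    if (!any(ok)) next
    d <- data.frame(locus = intact$locus[cov][ok],
                    snp_base = base[ok],
                    repeats = intact$repeats[cov][ok],
                    stringsAsFactors = FALSE)
    agg <- stats::aggregate(list(n = rep(1L, nrow(d))),
                            by = d[c("locus", "snp_base", "repeats")],
                            FUN = sum)
    agg$chrom <- sc$chrom
    agg$pos <- sc$pos
    out[[length(out) + 1L]] <-
      agg[c("locus", "chrom", "pos", "snp_base", "repeats", "n")]
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame()
  rownames(res) <- NULL
  structure(res, class = c("phased_counts", "data.frame"))
}

#' Call STR-SNP haplotypes from phased counts
#'
#' For a homozygous SNP, the repeat-count margin is evaluated with the
#' genotype threshold logic: one passing secondary allele yields two
#' haplotypes sharing the SNP base, none yields one. For a heterozygous
#' SNP, each base is paired with its majority repeat count (ties break to
#' the smaller repeat, flagged); a base with zero reads leaves a
#' single-haplotype result flagged incomplete.
#'
#' @param phased a [link_reads_to_haplotypes()] result for one locus/SNP
#'   (columns `snp_base`, `repeats`, `n`).
#' @param snp_genotype `"het"` or `"hom"` (from the SNP caller: `hom_alt`
#'   or an all-reference site both count as homozygous here).
#' @param thresholds a [threshold_table()].
#' @return list of class `hap_call`: `haplotypes` data.frame (`snp_base`,
#'   `repeats`, `support`), `zygosity`, `flags`.
#' @export
call_haplotypes <- function(phased, snp_genotype = c("het", "hom"),
                            thresholds = threshold_table()) {
  snp_genotype <- match.arg(snp_genotype)
  stopifnot(nrow(phased) > 0L)
  flags <- character(0)
  if (snp_genotype == "hom") {
    agg <- stats::aggregate(n ~ repeats, data = phased, FUN = sum)
    h <- data.frame(repeats = agg$repeats, n_fwd = agg$n, n_rev = 0L,
                    n = agg$n)
    attr(h, "locus") <- phased$locus[1] %||% NA_character_
    class(h) <- c("allele_hist", "data.frame")
    cl <- call_str_genotype(h, thresholds, min_total_reads = 1L)
    base <- names(sort(table(phased$snp_base), decreasing = TRUE))[1]
    haps <- data.frame(snp_base = base, repeats = cl$alleles,
                       support = cl$support, stringsAsFactors = FALSE)
    zyg <- if (nrow(haps) > 1L) "het" else "hom"
  } else {
    bases <- sort(unique(phased$snp_base))
    if (length(bases) == 1L) flags <- c(flags, "incomplete")
    haps <- do.call(rbind, lapply(bases, function(b) {
      sub <- phased[phased$snp_base == b, , drop = FALSE]
      agg <- stats::aggregate(n ~ repeats, data = sub, FUN = sum)
      mx <- max(agg$n)
      winners <- agg$repeats[agg$n == mx]
      if (length(winners) > 1L) flags <<- c(flags, "repeat_tie")
      data.frame(snp_base = b, repeats = min(winners), support = mx,
                 stringsAsFactors = FALSE)
    }))
    zyg <- "het"
  }
  structure(list(haplotypes = haps, zygosity = zyg, flags = unique(flags)),
            class = "hap_call")
}

#' Haplotype every locus/SNP of a genotyped sample
#'
#' Driver: filters SNP calls, links intact-STR pairs to SNP bases, and
#' calls one haplotype set per (locus, SNP).
#'
#' @param genotypes a [genotype_reads()] result.
#' @param snp_calls raw [call_snps_pileup()] output (filtering applied
#'   here).
#' @param panel an [str_panel()].
#' @param thresholds a [threshold_table()].
#' @param thin,min_avg_alt_qual see [filter_snps()].
#' @return list of class `str_haplotypes`: `haplotypes` data.frame
#'   (`locus`, `chrom`, `pos`, `snp_base`, `repeats`, `support`,
#'   `zygosity`, `flags`), `phased` (the `phased_counts`), `snps` (the
#'   filtered calls).
#' @export
haplotype_reads <- function(genotypes, snp_calls, panel,
                            thresholds = threshold_table(),
                            thin = 6L, min_avg_alt_qual = 8) {
  loci <- panel$loci
  excl <- data.frame(chrom = loci$chrom, start = loci$start - 5L,
                     end = loci$end + 5L)
  snps <- filter_snps(snp_calls, excl, thin, min_avg_alt_qual)
  phased <- link_reads_to_haplotypes(genotypes$reads, snps, panel)
  out <- list()
  if (nrow(phased) > 0L) {
    key <- unique(phased[c("locus", "chrom", "pos")])
    for (i in seq_len(nrow(key))) {
      sub <- phased[phased$locus == key$locus[i] &
                      phased$pos == key$pos[i], , drop = FALSE]
      sc <- snps[snps$chrom == key$chrom[i] & snps$pos == key$pos[i], ]
      gt <- if (nrow(sc) == 1L && sc$genotype == "het") "het" else "hom"
      hc <- call_haplotypes(sub, gt, thresholds)
      out[[i]] <- cbind(key[i, , drop = FALSE], hc$haplotypes,
                        zygosity = hc$zygosity,
                        flags = paste(hc$flags, collapse = ";"),
                        row.names = NULL)
    }
  }
  haps <- if (length(out)) do.call(rbind, out) else data.frame()
  rownames(haps) <- NULL
  structure(list(haplotypes = haps, phased = phased, snps = snps),
            class = "str_haplotypes")
}

#' @export
print.str_haplotypes <- function(x, ...) {
  cat(sprintf("str_haplotypes: %d haplotypes at %d (locus, SNP) sites\n",
              nrow(x$haplotypes),
              nrow(unique(x$haplotypes[c("locus", "pos")]))))
  invisible(x)
}
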