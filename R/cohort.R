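## Cross-sample analyses: CE concordance with per-locus median offset
## correction, Mendelian trio concordance, informative-haplotype discovery
## and mixture minor-fraction quantification.

#' Capillary electrophoresis concordance with median offset correction
#'
#' Sequencing and CE annotations of the same locus often differ by a
#' constant number of repeat units (annotation boundary differences), so
#' a per-locus offset -- the median over samples of (sequencing allele -
#' CE allele), pairing sorted alleles positionally -- is computed and
#' subtracted before the genotype equality test. Dosage pairs are emitted
#' for regression diagnostics.
#'
#' @param seq_calls data.frame (`sample`, `locus`, `allele1`, `allele2`)
#'   of sequencing repeat-count genotypes.
#' @param ce_calls data.frame (`sample`, `locus`, `allele1_bp`,
#'   `allele2_bp`) of CE genotypes in base pairs.
#' @param loci the panel locus table (`str_name`, `motif`, `start`,
#'   `end`) used to convert CE base pairs to repeat units; loci absent
#'   from the CE table are skipped.
#' @return list of class `ce_comparison`: `offsets` (per-locus data.frame
#'   `locus`, `offset`, `n_samples`), `per_sample` (data.frame `sample`,
#'   `n_compared`, `n_concordant`, `concordance`), `concordance` (overall
#'   fraction), `dosage_pairs` (`sample`, `locus`, `dosage_seq_bp`,
#'   `dosage_ce_bp`).
#' @export
ce_offset_concordance <- function(seq_calls, ce_calls, loci) {
  mlen <- setNames(nchar(loci$motif), loci$str_name)
  ref_bp <- setNames(loci$end - loci$start + 1L, loci$str_name)
  shared <- merge(seq_calls, ce_calls, by = c("sample", "locus"))
  if (nrow(shared) == 0L) stop("no (sample, locus) shared between call sets")
  shared$ce1 <- shared$allele1_bp / mlen[shared$locus]
  shared$ce2 <- shared$allele2_bp / mlen[shared$locus]
  # pair sorted alleles positionally
  s_lo <- pmin(shared$allele1, shared$allele2)
  s_hi <- pmax(shared$allele1, shared$allele2)
  c_lo <- pmin(shared$ce1, shared$ce2)
  c_hi <- pmax(shared$ce1, shared$ce2)
  off_each <- cbind(s_lo - c_lo, s_hi - c_hi)

  offsets <- do.call(rbind, lapply(split(seq_len(nrow(shared)),
                                         shared$locus), function(ii) {
    data.frame(locus = shared$locus[ii[1]],
               offset = stats::median(as.vector(off_each[ii, , drop = FALSE])),
               n_samples = length(ii), stringsAsFactors = FALSE)
  }))
  rownames(offsets) <- NULL
  shared$offset <- offsets$offset[match(shared$locus, offsets$locus)]
  shared$concordant <- (s_lo - shared$offset == c_lo) &
    (s_hi - shared$offset == c_hi)

  per_sample <- do.call(rbind, lapply(split(shared, shared$sample),
                                      function(x) {
    data.frame(sample = x$sample[1], n_compared = nrow(x),
               n_concordant = sum(x$concordant),
               concordance = mean(x$concordant), stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  dosage <- data.frame(
    sample = shared$sample, locus = shared$locus,
    dosage_seq_bp = (shared$allele1 + shared$allele2) * mlen[shared$locus] -
      2 * ref_bp[shared$locus],
    dosage_ce_bp = shared$allele1_bp + shared$allele2_bp -
      2 * ref_bp[shared$locus],
    stringsAsFactors = FALSE)
  structure(list(offsets = offsets, per_sample = per_sample,
                 concordance = mean(shared$concordant),
                 dosage_pairs = dosage),
            class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("CE comparison: %.2f%% concordant over %d genotypes (%d loci)\n",
              100 * x$concordance, sum(x$per_sample$n_compared),
              nrow(x$offsets)))
  invisible(x)
}

.hap_key <- function(df) paste(df$snp_base, df$repeats, sep = "-")

#' Mendelian trio concordance of genotypes and haplotypes
#'
#' A child locus genotype is concordant when its two repeat alleles can
#' be partitioned into one carried by the father and one by the mother; a
#' child haplotype set is concordant when one haplotype is explained by
#' each parent (a homozygous child haplotype must be present in both).
#' Parents are re-evaluated at the child's variant sites: a parent is
#' considered to carry a haplotype when it holds at least
#' `parent_het_fraction` of the parent's phased reads at that site, which
#' tolerates STR-length-biased read loss and stutter dispersion. Only
#' loci with coverage of at least `min_cov` in all three members qualify.
#'
#' @param child,father,mother per-member lists with `calls` (a
#'   [genotype_reads()] `calls` data.frame), `haplotypes` (a
#'   [haplotype_reads()] `haplotypes` data.frame) and `phased` (its
#'   `phased_counts`).
#' @param parent_het_fraction secondary-allele read fraction at which a
#'   parent is considered heterozygous (default 0.15).
#' @param min_cov per-member coverage floor at a qualifying site.
#' @return list of class `trio_report`: `genotype` data.frame (`locus`,
#'   `concordant`), `haplotype` data.frame (`locus`, `pos`,
#'   `concordant`), `genotype_concordance`, `haplotype_concordance`
#'   (percentages over qualifying loci/sites).
#' @export
trio_concordance <- function(child, father, mother,
                             parent_het_fraction = 0.15, min_cov = 10L) {
  ## genotypes -------------------------------------------------------
  g <- merge(merge(child$calls[c("locus", "allele1", "allele2", "total")],
                   father$calls[c("locus", "allele1", "allele2", "total")],
                   by = "locus", suffixes = c("_c", "_f")),
             stats::setNames(mother$calls[c("locus", "allele1", "allele2",
                                            "total")],
                             c("locus", "allele1_m", "allele2_m", "total_m")),
             by = "locus")
  g <- g[g$total_c >= min_cov & g$total_f >= min_cov & g$total_m >= min_cov, ]
  geno_ok <- function(i) {
    cc <- c(g$allele1_c[i], g$allele2_c[i])
    fa <- c(g$allele1_f[i], g$allele2_f[i])
    mo <- c(g$allele1_m[i], g$allele2_m[i])
    (cc[1] %in% fa && cc[2] %in% mo) || (cc[2] %in% fa && cc[1] %in% mo)
  }
  genotype <- data.frame(locus = g$locus,
                         concordant = vapply(seq_len(nrow(g)), geno_ok,
                                             logical(1)))

  ## haplotypes ------------------------------------------------------
  # parent haplotype sets re-evaluated at the child's sites with the
  # 15%-of-reads rule applied to the parent's phased counts
  parent_set <- function(parent, locus, pos) {
    ph <- parent$phased
    if (is.null(ph) || nrow(ph) == 0L) return(character(0))
    sub <- ph[ph$locus == locus & ph$pos == pos, , drop = FALSE]
    tot <- sum(sub$n)
    if (tot == 0L) return(character(0))
    .hap_key(sub[sub$n / tot >= parent_het_fraction |
                   sub$n == max(sub$n), , drop = FALSE])
  }
  parent_cov <- function(parent, locus, pos) {
    ph <- parent$phased
    if (is.null(ph) || nrow(ph) == 0L) return(0L)
    sum(ph$n[ph$locus == locus & ph$pos == pos])
  }
  ch <- child$haplotypes
  hap_rows <- list()
  if (!is.null(ch) && nrow(ch) > 0L) {
    key <- unique(ch[c("locus", "pos")])
    for (i in seq_len(nrow(key))) {
      locus <- key$locus[i]; pos <- key$pos[i]
      sub <- ch[ch$locus == locus & ch$pos == pos, , drop = FALSE]
      if (sum(sub$support) < min_cov ||
          parent_cov(father, locus, pos) < min_cov ||
          parent_cov(mother, locus, pos) < min_cov) next
      fset <- parent_set(father, locus, pos)
      mset <- parent_set(mother, locus, pos)
      hk <- .hap_key(sub)
      ok <- if (length(hk) == 1L) {
        hk %in% fset && hk %in% mset          # homozygous child
      } else {
        (hk[1] %in% fset && hk[2] %in% mset) ||
          (hk[2] %in% fset && hk[1] %in% mset)
      }
      hap_rows[[length(hap_rows) + 1L]] <-
        data.frame(locus = locus, pos = pos, concordant = ok)
    }
  }
  haplotype <- if (length(hap_rows)) do.call(rbind, hap_rows)
               else data.frame(locus = character(0), pos = integer(0),
                               concordant = logical(0))
  structure(list(
    genotype = genotype, haplotype = haplotype,
    genotype_concordance = if (nrow(genotype))
      100 * mean(genotype$concordant) else NA_real_,
    haplotype_concordance = if (nrow(haplotype))
      100 * mean(haplotype$concordant) else NA_real_),
    class = "trio_report")
}

#' @export
print.trio_report <- function(x, ...) {
  cat(sprintf("trio: genotype concordance %.2f%% (%d loci), haplotype %.2f%% (%d sites)\n",
              x$genotype_concordance, nrow(x$genotype),
              x$haplotype_concordance, nrow(x$haplotype)))
  invisible(x)
}

#' Informative haplotypes: present in the minor, absent from every major
#'
#' @param minor_haps `haplotypes` data.frame of the minor contributor
#'   ([haplotype_reads()] output).
#' @param major_haps one `haplotypes` data.frame, or a list of them (one
#'   per major contributor).
#' @return subset of `minor_haps` whose (locus, SNP base, repeat count)
#'   triples occur in no major contributor.
#' @export
informative_haplotypes <- function(minor_haps, major_haps) {
  if (is.data.frame(major_haps)) major_haps <- list(major_haps)
  key <- function(df) paste(df$locus, df$snp_base, df$repeats)
  seen <- unique(unlist(lapply(major_haps, key)))
  out <- minor_haps[!key(minor_haps) %in% seen, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantify a minor mixture component from informative haplotypes
#'
#' For each informative haplotype, the observed fraction is its
#' supporting reads over all phased reads at the locus/SNP site in the
#' mixture. The expected fraction under a nominal minor ratio r is r/2
#' for a haplotype the minor carries heterozygously and r for a
#' homozygous one. A haplotype is detected when its support reaches
#' `min_reads` (default 2, guarding against singleton sequencing error).
#' When truth ratios are given, a log-log regression of observed on
#' expected is reported (zero observations excluded).
#'
#' @param mixture_phased `phased_counts` of the mixture (from
#'   [haplotype_reads()] or [link_reads_to_haplotypes()]).
#' @param informative result of [informative_haplotypes()].
#' @param minor_zygosity optional character vector parallel to
#'   `informative` rows (`"het"`/`"hom"` in the minor sample); defaults
#'   to the `zygosity` column of `informative`.
#' @param truth_ratio optional nominal minor fraction (scalar or
#'   per-haplotype).
#' @param min_reads detection floor in supporting reads.
#' @return data.frame of class `mixture_report`: `locus`, `pos`,
#'   `snp_base`, `repeats`, `support`, `locus_total`, `observed_fraction`
#'   (NA when the locus has zero phased coverage), `detected`, and (with
#'   truth) `expected_fraction`; regression slope/R2 on log10 scale in
#'   attributes `log_slope`, `log_r2`.
#' @export
mixture_quantification <- function(mixture_phased, informative,
                                   minor_zygosity = NULL,
                                   truth_ratio = NULL, min_reads = 2L) {
  stopifnot(nrow(informative) > 0L)
  zyg <- minor_zygosity %||% informative$zygosity
  ph <- mixture_phased
  rows <- lapply(seq_len(nrow(informative)), function(i) {
    h <- informative[i, ]
    at <- ph[ph$locus == h$locus & ph$pos == h$pos, , drop = FALSE]
    tot <- sum(at$n)
    sup <- sum(at$n[at$snp_base == h$snp_base & at$repeats == h$repeats])
    data.frame(locus = h$locus, pos = h$pos, snp_base = h$snp_base,
               repeats = h$repeats, support = sup, locus_total = tot,
               observed_fraction = if (tot > 0L) sup / tot else NA_real_,
               detected = tot > 0L && sup >= min_reads,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(truth_ratio)) {
    out$expected_fraction <- ifelse(zyg == "het", truth_ratio / 2,
                                    truth_ratio)
    pos_i <- which(!is.na(out$observed_fraction) & out$observed_fraction > 0)
    if (length(pos_i) >= 2L &&
        length(unique(out$expected_fraction[pos_i])) > 1L) {
      fit <- stats::lm(log10(observed_fraction) ~ log10(expected_fraction),
                       data = out[pos_i, ])
      attr(out, "log_slope") <- unname(stats::coef(fit)[2])
      attr(out, "log_r2") <- summary(fit)$r.squared
    }
  }
  class(out) <- c("mixture_report", "data.frame")
  out
}
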