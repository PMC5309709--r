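## Read-pair indexing: assign each pair to its target STR through the
## Read 2 probe alignment position (the ZP tag), and classify Read 1
## fragment ends as CRISPR on-/off-target.

#' Tag read pairs with their probe index (ZP)
#'
#' A pair is tagged when its Read 2 alignment start lies within
#' `tolerance` bases of a probe's expected position on the same
#' chromosome and strand; Read 1 inherits the tag from its mate and need
#' not be aligned. The match is a function of alignment position only --
#' mismatch tolerance is the aligner's job. When two probes fall within
#' tolerance the nearest wins; an exact tie is discarded with a warning.
#' Untagged pairs are discarded and counted.
#'
#' @param pairs an `str_reads` data.frame (columns `r2_chrom`, `r2_pos`,
#'   `r2_strand` required).
#' @param panel an [str_panel()].
#' @param tolerance maximum |Read 2 start - expected position| in bases.
#' @return the tagged subset of `pairs` with `zp` set, plus attributes
#'   `n_input`, `n_discarded`, `n_ambiguous` and a per-probe `index_summary`
#'   data.frame (`probe_id`, `str_name`, `n_pairs`).
#' @export
tag_read_pairs <- function(pairs, panel, tolerance = 2L) {
  stopifnot(is.data.frame(pairs), inherits(panel, "str_panel"))
  pr <- panel$probes
  key <- paste(pairs$r2_chrom, pairs$r2_strand)
  pkey <- paste(pr$chrom, pr$strand)
  zp <- rep(NA_integer_, nrow(pairs))
  tie <- rep(FALSE, nrow(pairs))
  for (k in unique(pkey)) {
    pi <- which(pkey == k)
    ri <- which(key == k)
    if (!length(ri)) next
    exp_pos <- pr$expected_pos[pi]
    o <- order(exp_pos)
    exp_sorted <- exp_pos[o]
    id_sorted <- pr$probe_id[pi][o]
    # nearest expected position for each read via findInterval
    pos <- pairs$r2_pos[ri]
    lo <- findInterval(pos, exp_sorted)
    hi <- pmin(lo + 1L, length(exp_sorted))
    lo <- pmax(lo, 1L)
    d_lo <- abs(pos - exp_sorted[lo])
    d_hi <- abs(pos - exp_sorted[hi])
    best <- ifelse(d_hi < d_lo, hi, lo)
    best_d <- pmin(d_lo, d_hi)
    is_tie <- d_lo == d_hi & lo != hi & d_lo <= tolerance
    ok <- best_d <= tolerance & !is_tie
    zp[ri[ok]] <- id_sorted[best[ok]]
    tie[ri[is_tie]] <- TRUE
  }
  if (any(tie))
    warning(sum(tie), " pair(s) equidistant between two probes; discarded")
  tagged <- pairs[!is.na(zp), , drop = FALSE]
  tagged$zp <- zp[!is.na(zp)]
  idx <- match(tagged$zp, pr$probe_id)
  tab <- table(factor(tagged$zp, levels = pr$probe_id))
  summary <- data.frame(probe_id = pr$probe_id, str_name = pr$str_name,
                        n_pairs = as.integer(tab), stringsAsFactors = FALSE)
  for (a in c("panel_sig", "r2_len", "read_len"))
    attr(tagged, a) <- attr(pairs, a)
  attr(tagged, "n_input") <- nrow(pairs)
  attr(tagged, "n_discarded") <- nrow(pairs) - nrow(tagged)
  attr(tagged, "n_ambiguous") <- sum(tie)
  attr(tagged, "index_summary") <- summary
  attr(tagged, "locus") <- pr$str_name[idx]
  class(tagged) <- c("str_reads", "data.frame")
  tagged
}

#' Locus name for each tagged pair
#' @param tagged result of [tag_read_pairs()].
#' @param panel the panel used for tagging.
#' @return character vector of `str_name`, one per pair.
#' @export
tagged_locus <- function(tagged, panel) {
  panel$probes$str_name[match(tagged$zp, panel$probes$probe_id)]
}

#' Classify Read 1 fragment ends against guide-RNA cut sites
#'
#' A tagged pair is on-target when its fragmentation-side boundary falls
#' within `tolerance` bases of the expected blunt cut boundary for its
#' probe orientation (plus probes pair with the upstream cut, minus
#' probes with the downstream cut). Pairs at loci without a matching cut
#' site are excluded from the denominator.
#'
#' @param tagged result of [tag_read_pairs()] (needs `frag_bound`).
#' @param panel an [str_panel()] with `cut_sites`.
#' @param tolerance maximum |boundary - cut| in bases (read classification
#'   default 4; use 2 for the stricter per-site summary).
#' @return list of class `frag_summary`: `per_site` data.frame
#'   (`str_name`, `side`, `cut_pos`, `n_on`, `n_off`, `on_fraction`),
#'   `n_on_target`, `n_off_target`, `on_target_fraction` (NA when no pair
#'   is classifiable).
#' @export
classify_fragmentation <- function(tagged, panel, tolerance = 4L) {
  stopifnot(inherits(panel, "str_panel"))
  cs <- panel$cut_sites
  if (is.null(cs)) stop("panel has no cut sites")
  locus <- tagged_locus(tagged, panel)
  strand <- panel$probes$strand[match(tagged$zp, panel$probes$probe_id)]
  side <- ifelse(strand == "+", "upstream", "downstream")
  m <- match(paste(locus, side), paste(cs$str_name, cs$side))
  has <- !is.na(m)
  off <- tagged$frag_bound[has] - cs$cut_pos[m[has]]
  on <- abs(off) <= tolerance
  grp <- m[has]
  per <- data.frame(str_name = cs$str_name, side = cs$side,
                    cut_pos = cs$cut_pos,
                    n_on = as.integer(tabulate(grp[on], nbins = nrow(cs))),
                    n_off = as.integer(tabulate(grp[!on], nbins = nrow(cs))),
                    stringsAsFactors = FALSE)
  per$on_fraction <- ifelse(per$n_on + per$n_off > 0,
                            per$n_on / (per$n_on + per$n_off), NA_real_)
  n_on <- sum(on); n_off <- sum(!on)
  structure(list(per_site = per, n_on_target = n_on, n_off_target = n_off,
                 on_target_fraction = if (n_on + n_off > 0)
                   n_on / (n_on + n_off) else NA_real_,
                 tolerance = tolerance),
            class = "frag_summary")
}

#' @export
print.frag_summary <- function(x, ...) {
  cat(sprintf("fragmentation: %d on-target / %d off-target (%.1f%%) at +/-%d b\n",
              x$n_on_target, x$n_off_target,
              100 * (x$on_target_fraction %||% NA_real_), x$tolerance))
  invisible(x)
}
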