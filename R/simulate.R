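## Read simulator: synthetic panels, individuals, trios, mixtures, and
## truth-placed paired-end reads with configurable stutter and
## CRISPR-targeted vs random fragmentation.
##
## Per-locus layout on the synthetic chromosome (1-based, tract [S, E]):
##
##   minus R2 span          plus R2 span
##   [S-120 ...... S-21]    [E+21 .............. E+120]
##         probe- [S-60,S-21]    probe+ [E+21,E+60]   SNP at E+71
##   cut(upstream) boundary S-25; cut(downstream) boundary E+26
##   flank5 [S-15,S-1]  flank3 [E+1,E+15]
##
## A "+" probe binds downstream of the STR: Read 1 is a forward read from
## the fragmentation end (left of the tract) and spans flank5-tract-flank3;
## Read 2 is a forward read starting at the probe. A "-" probe is the
## mirror image. Fragment boundaries are expressed as the coordinate of
## the first base downstream of the break, so an on-target boundary equals
## cut_pos exactly.

.SIM_STRIDE <- 1000L
.SIM_CTX <- 250L   # context kept either side of the tract when composing reads

#' Stutter noise model
#'
#' Per-read probability model of polymerase slippage. A stutter event
#' shifts the observed repeat count by a signed number of motif units:
#' deletion with probability `p_deletion`, magnitude `1 + Geometric(1 -
#' step_decay)` so steps beyond one unit are rare.
#'
#' Defaults echo the observed cohort medians for PCR-amplified libraries
#' (3.2% stutter); use `p_stutter = 0.009` for a PCR-free library model.
#'
#' @param p_stutter per-read probability that a stutter event occurs.
#' @param p_deletion probability the event deletes (rather than inserts)
#'   motif units; stutter is deletion-biased.
#' @param step_decay geometric decay for step magnitudes beyond 1 unit;
#'   `P(|step| = k) = (1 - step_decay) * step_decay^(k-1)`.
#' @return list of class `stutter_model`.
#' @export
stutter_model <- function(p_stutter = 0.032, p_deletion = 0.8,
                          step_decay = 0.05) {
  stopifnot(p_stutter >= 0, p_stutter <= 1,
            p_deletion >= 0, p_deletion <= 1,
            step_decay >= 0, step_decay < 1)
  structure(list(p_stutter = p_stutter, p_deletion = p_deletion,
                 step_decay = step_decay), class = "stutter_model")
}

#' Fragmentation model
#'
#' Governs where the non-probe end of each fragment falls. In `crispr`
#' mode a fragment end derives from the locus guide-RNA cut site with
#' probability `on_target_prob` (jittered by a rounded normal of sd
#' `jitter_sd`), otherwise -- and always in `random` mode -- the end is
#' uniform over the read-length window next to the tract. The defaults
#' echo the observed 56% on-target read fraction under CRISPR-targeted
#' fragmentation.
#'
#' @param mode `"crispr"` or `"random"`.
#' @param jitter_sd base-pair dispersion of fragment ends around the cut.
#' @param on_target_prob probability a fragment end derives from the cut.
#' @return list of class `fragmentation_model`.
#' @export
fragmentation_model <- function(mode = c("crispr", "random"), jitter_sd = 1,
                                on_target_prob = 0.56) {
  mode <- match.arg(mode)
  stopifnot(jitter_sd >= 0, on_target_prob >= 0, on_target_prob <= 1)
  structure(list(mode = mode, jitter_sd = jitter_sd,
                 on_target_prob = on_target_prob),
            class = "fragmentation_model")
}

.rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.is_primitive_motif <- function(m) {
  n <- nchar(m)
  if (n == 1L) return(TRUE)
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L &&
        strrep(substr(m, 1L, p), n %/% p) == m) return(FALSE)
  }
  TRUE
}

.object_sig <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Build a synthetic STR panel with its reference genome
#'
#' Generates `n_loci` repeat loci on one synthetic chromosome, each with a
#' primitive random motif, unique 15-base flanks, one plus and one minus
#' 40-mer probe, one guide-RNA cut site per probe orientation (upstream
#' and downstream, each placing the full repeat within 100 bases of the
#' cut), and one proximal SNP covered by the plus-probe Read 2.
#' Deterministic under `seed`.
#'
#' @param n_loci number of loci (>= 1).
#' @param motif_len_weights sampling weights for motif lengths 1-6.
#' @param seed integer seed.
#' @param r2_len design Read 2 length (fixes the minus-probe expected
#'   alignment position).
#' @return list of class `str_sim_panel`: `panel` (an [str_panel()]),
#'   `genome` (named character vector of chromosome sequences), `snps`
#'   (data.frame `str_name`, `chrom`, `pos`, `ref`, `alt`), `layout`
#'   (per-locus tract coordinates and reference repeat count),
#'   `allele_freqs` (per-locus repeat-count frequency tables), `r2_len`.
#' @export
build_synthetic_panel <- function(n_loci,
                                  motif_len_weights = c(0.05, 0.25, 0.20,
                                                        0.35, 0.10, 0.05),
                                  seed = 1L, r2_len = 100L) {
  stopifnot(n_loci >= 1, length(motif_len_weights) == 6L)
  set.seed(seed)
  chrom <- .SIM_CHROM
  blocks <- character(n_loci)
  loci <- vector("list", n_loci)
  probes <- vector("list", n_loci)
  beds5 <- vector("list", n_loci)
  beds3 <- vector("list", n_loci)
  nostr <- vector("list", n_loci)
  cuts <- vector("list", n_loci)
  snps <- vector("list", n_loci)
  freqs <- vector("list", n_loci)

  for (i in seq_len(n_loci)) {
    motif_len <- sample(1:6, 1L, prob = motif_len_weights)
    repeat {
      motif <- .rand_bases(motif_len)
      if (.is_primitive_motif(motif)) break
    }
    min_repeats <- 3L
    max_rep <- max(min_repeats + 2L, min(25L, 60L %/% motif_len))
    lo <- min(max_rep - 2L, max(min_repeats, if (motif_len == 1L) 12L else 6L))
    ref_repeats <- if (lo >= max_rep) max_rep else sample(lo:max_rep, 1L)
    tract <- strrep(motif, ref_repeats)
    L <- nchar(tract)

    S <- (i - 1L) * .SIM_STRIDE + 401L
    E <- S + L - 1L
    S_loc <- 401L
    block <- .rand_bases(.SIM_STRIDE)
    # Forbid accidental motif continuation at the annotated boundaries so
    # the tract is maximal and flank matching cannot shift by a period.
    last_m <- substr(motif, motif_len, motif_len)
    first_m <- substr(motif, 1L, 1L)
    fix_base <- function(avoid) sample(setdiff(c("A","C","G","T"), avoid), 1L)
    substr(block, S_loc - 1L, S_loc - 1L) <- fix_base(last_m)
    block <- paste0(substr(block, 1L, S_loc - 1L), tract,
                    substr(block, S_loc + L, .SIM_STRIDE))
    p_after <- S_loc + L
    substr(block, p_after, p_after) <- fix_base(first_m)

    flank5 <- substr(block, S_loc - 15L, S_loc - 1L)
    flank3 <- substr(block, S_loc + L, S_loc + L + 14L)
    probe_plus <- substr(block, S_loc + L + 20L, S_loc + L + 59L)
    probe_minus <- substr(block, S_loc - 60L, S_loc - 21L)
    snp_loc <- S_loc + L + 70L
    snp_ref <- substr(block, snp_loc, snp_loc)
    snp_alt <- sample(setdiff(c("A", "C", "G", "T"), snp_ref), 1L)
    blocks[i] <- block

    name <- sprintf("trf%04d", i)
    loci[[i]] <- data.frame(str_name = name, motif = motif, chrom = chrom,
                            start = S, end = E, min_repeats = min_repeats,
                            flank5 = flank5, flank3 = flank3,
                            stringsAsFactors = FALSE)
    probes[[i]] <- data.frame(
      probe_id = c(2L * i - 1L, 2L * i),
      chrom = chrom,
      expected_pos = c(E + 21L, S - 21L - r2_len + 1L),
      strand = c("+", "-"),
      str_name = name,
      probe_seq = c(probe_plus, probe_minus),
      stringsAsFactors = FALSE)
    beds5[[i]] <- data.frame(chrom = chrom, start = S - 15L, end = S - 1L,
                             name = name)
    beds3[[i]] <- data.frame(chrom = chrom, start = E + 1L, end = E + 15L,
                             name = name)
    nostr[[i]] <- data.frame(chrom = chrom,
                             start = c(S - 150L, E + 6L),
                             end = c(S - 6L, E + 150L),
                             name = paste0(name, c("_5p", "_3p")))
    cuts[[i]] <- data.frame(str_name = name, chrom = chrom,
                            cut_pos = c(S - 25L, E + 26L),
                            side = c("upstream", "downstream"),
                            stringsAsFactors = FALSE)
    snps[[i]] <- data.frame(str_name = name, chrom = chrom, pos = S + L + 70L,
                            ref = snp_ref, alt = snp_alt,
                            stringsAsFactors = FALSE)
    # 2-4 segregating repeat alleles around the reference count
    cand <- ref_repeats + (-2L:2L)
    cand <- cand[cand >= min_repeats & cand * motif_len <= 70L]
    k <- sample(2:min(4L, length(cand)), 1L)
    alleles <- sort(cand[sample.int(length(cand), k)])
    if (!ref_repeats %in% alleles) alleles <- sort(c(alleles[-1], ref_repeats))
    w <- stats::rgamma(length(alleles), shape = 2)
    freqs[[i]] <- data.frame(repeats = alleles, freq = w / sum(w))
  }

  loci <- do.call(rbind, loci)
  flanks <- c(loci$flank5, loci$flank3)
  if (anyDuplicated(flanks))
    stop("flank uniqueness unattainable at this scale; ",
         "use a longer synthetic genome (fewer loci per base)")
  panel <- str_panel(loci, do.call(rbind, probes),
                     flank5 = do.call(rbind, beds5),
                     flank3 = do.call(rbind, beds3),
                     nostr = do.call(rbind, nostr),
                     cut_sites = do.call(rbind, cuts))
  layout <- data.frame(str_name = loci$str_name, chrom = loci$chrom,
                       start = loci$start, end = loci$end,
                       motif = loci$motif, motif_len = nchar(loci$motif),
                       ref_repeats = (loci$end - loci$start + 1L) %/%
                         nchar(loci$motif),
                       stringsAsFactors = FALSE)
  structure(list(panel = panel,
                 genome = setNames(paste(blocks, collapse = ""), chrom),
                 snps = do.call(rbind, snps),
                 layout = layout,
                 allele_freqs = setNames(freqs, loci$str_name),
                 r2_len = as.integer(r2_len)),
            class = "str_sim_panel")
}

#' @export
print.str_sim_panel <- function(x, ...) {
  cat(sprintf("str_sim_panel: %d loci on %d-base synthetic genome\n",
              nrow(x$panel$loci), sum(nchar(x$genome))))
  invisible(x)
}

#' Draw a diploid individual's phased genotypes
#'
#' Two independent allele draws per locus from the locus repeat-count
#' frequency table; each chromosome also receives a SNP allele, so the
#' (SNP base, repeat count) pair on each haplotype is phased truth.
#'
#' @param sim_panel an [build_synthetic_panel()] result.
#' @param individual sample label carried into read truth.
#' @param allele_freqs optional override: a single data.frame
#'   (`repeats`, `freq`) applied to every locus, or a named list per
#'   locus. Frequencies must sum to 1.
#' @param snp_alt_freq population frequency of the alternate SNP base.
#' @param seed integer seed.
#' @return data.frame of class `str_truth`: `individual`, `str_name`,
#'   `hap1_repeats`, `hap2_repeats`, `hap1_snp`, `hap2_snp`.
#' @export
draw_individual_genotypes <- function(sim_panel, individual = "ind1",
                                      allele_freqs = NULL,
                                      snp_alt_freq = 0.5, seed = 1L) {
  stopifnot(inherits(sim_panel, "str_sim_panel"))
  set.seed(seed)
  loci <- sim_panel$layout$str_name
  freqs <- sim_panel$allele_freqs
  if (!is.null(allele_freqs)) {
    freqs <- if (is.data.frame(allele_freqs))
      setNames(rep(list(allele_freqs), length(loci)), loci)
    else allele_freqs
  }
  draw2 <- function(nm) {
    f <- freqs[[nm]]
    if (is.null(f) || nrow(f) == 0L)
      stop("empty allele frequency table for locus ", nm)
    if (abs(sum(f$freq) - 1) > 1e-6)
      stop("allele frequencies for ", nm, " do not sum to 1")
    f$repeats[sample.int(nrow(f), 2L, replace = TRUE, prob = f$freq)]
  }
  reps <- vapply(loci, draw2, numeric(2))
  snp <- sim_panel$snps
  pick <- function() ifelse(runif(length(loci)) < snp_alt_freq,
                            snp$alt, snp$ref)
  out <- data.frame(individual = individual, str_name = loci,
                    hap1_repeats = as.integer(reps[1, ]),
                    hap2_repeats = as.integer(reps[2, ]),
                    hap1_snp = pick(), hap2_snp = pick(),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("str_truth", "data.frame")
  out
}

#' Mate a trio: child genotypes by Mendelian inheritance
#'
#' The child inherits one phased (repeat count, SNP base) haplotype per
#' parent per locus. With `mutation_rate > 0` a transmitted repeat count
#' is perturbed by one motif unit (sign at random) at that rate.
#'
#' @param father_truth,mother_truth `str_truth` objects on the same panel.
#' @param individual child sample label.
#' @param mutation_rate per-haplotype, per-locus repeat mutation rate.
#' @param seed integer seed.
#' @return `str_truth` for the child; haplotype 1 is paternal.
#' @export
make_trio <- function(father_truth, mother_truth, individual = "child",
                      mutation_rate = 0, seed = 1L) {
  stopifnot(inherits(father_truth, "str_truth"),
            inherits(mother_truth, "str_truth"))
  if (!identical(father_truth$str_name, mother_truth$str_name))
    stop("parents were simulated on different panels")
  set.seed(seed)
  n <- nrow(father_truth)
  fh <- sample(1:2, n, replace = TRUE)
  mh <- sample(1:2, n, replace = TRUE)
  pick <- function(tr, hap, col)
    ifelse(hap == 1L, tr[[paste0("hap1_", col)]], tr[[paste0("hap2_", col)]])
  h1r <- pick(father_truth, fh, "repeats")
  h2r <- pick(mother_truth, mh, "repeats")
  h1s <- pick(father_truth, fh, "snp")
  h2s <- pick(mother_truth, mh, "snp")
  if (mutation_rate > 0) {
    mut1 <- runif(n) < mutation_rate
    mut2 <- runif(n) < mutation_rate
    h1r <- ifelse(mut1, pmax(1L, h1r + sample(c(-1L, 1L), n, TRUE)), h1r)
    h2r <- ifelse(mut2, pmax(1L, h2r + sample(c(-1L, 1L), n, TRUE)), h2r)
  }
  out <- data.frame(individual = individual,
                    str_name = father_truth$str_name,
                    hap1_repeats = as.integer(h1r),
                    hap2_repeats = as.integer(h2r),
                    hap1_snp = h1s, hap2_snp = h2s,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("str_truth", "data.frame")
  out
}

.apply_base_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A","C","G","T"), cur), 1L)
    }
  }
  seqs
}

#' Generate truth-placed paired-end read pairs
#'
#' For each locus, read pairs are drawn across the two haplotypes and the
#' two probe orientations. Read 2 starts with the 40-mer probe at its
#' expected alignment position and (plus orientation) covers the proximal
#' SNP; Read 1 runs from the fragmentation end of the fragment and, when
#' the fragment spans, contains `flank5 + motif x (true repeats + stutter
#' offset) + flank3`. Under `crispr` fragmentation Read 1 fragment ends
#' cluster at the orientation-matched cut site. Records are
#' SAM-convertible; the simulator knows truth, so no aligner is involved.
#'
#' @param truth an `str_truth` from [draw_individual_genotypes()].
#' @param sim_panel the matching `str_sim_panel`.
#' @param coverage read pairs per locus (> 0).
#' @param stutter a [stutter_model()].
#' @param frag a [fragmentation_model()].
#' @param read_len Read 1 length; must satisfy
#'   `read_len >= 31 + motif_len * min_repeats` at every locus.
#' @param base_error per-base substitution error rate.
#' @param base_qual constant Phred base quality.
#' @param seed integer seed.
#' @return data.frame of class `str_reads`, one row per pair: alignment
#'   fields for both mates (`r1_*`, `r2_*`), `frag_bound` (fragmentation-
#'   side boundary coordinate), `zp` (unset), and per-read truth columns
#'   (`true_locus`, `true_individual`, `true_hap`, `true_repeats`,
#'   `read_repeats`, `true_stutter`, `true_on_target`, `true_spanning`).
#' @export
generate_read_pairs <- function(truth, sim_panel, coverage,
                                stutter = stutter_model(),
                                frag = fragmentation_model(),
                                read_len = 150L, base_error = 0.001,
                                base_qual = 35L, seed = 1L) {
  stopifnot(inherits(truth, "str_truth"),
            inherits(sim_panel, "str_sim_panel"),
            inherits(stutter, "stutter_model"),
            inherits(frag, "fragmentation_model"))
  if (coverage <= 0) stop("coverage must be > 0")
  lay <- sim_panel$layout
  need <- 31L + lay$motif_len * sim_panel$panel$loci$min_repeats
  if (any(read_len < need))
    stop("read_len too short to span locus ",
         lay$str_name[which.max(need)], " (need >= ", max(need), ")")
  if (read_len > .SIM_CTX || sim_panel$r2_len > .SIM_CTX)
    stop("read lengths above ", .SIM_CTX, " are not supported")
  set.seed(seed)
  chrom_seq <- sim_panel$genome[[.SIM_CHROM]]
  r2_len <- sim_panel$r2_len
  qual1 <- strrep(rawToChar(as.raw(base_qual + 33L)), read_len)
  qual2 <- strrep(rawToChar(as.raw(base_qual + 33L)), r2_len)
  n <- as.integer(round(coverage))
  out <- vector("list", nrow(lay))

  for (i in seq_len(nrow(lay))) {
    S <- lay$start[i]; E <- lay$end[i]
    motif <- lay$motif[i]; mlen <- lay$motif_len[i]
    tr <- truth[truth$str_name == lay$str_name[i], ]
    if (nrow(tr) != 1L)
      stop("truth table does not match panel at locus ", lay$str_name[i])
    snp <- sim_panel$snps[i, ]

    hap <- sample(1:2, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    true_rep <- ifelse(hap == 1L, tr$hap1_repeats, tr$hap2_repeats)
    snp_base <- ifelse(hap == 1L, tr$hap1_snp, tr$hap2_snp)

    ev <- runif(n) < stutter$p_stutter
    sgn <- ifelse(runif(n) < stutter$p_deletion, -1L, 1L)
    mag <- 1L + rgeom(n, 1 - stutter$step_decay)
    read_rep <- pmax(1L, true_rep + ifelse(ev, sgn * mag, 0L))

    # fragmentation-side boundary (first base downstream of the break)
    rand_bound <- ifelse(strand == "+",
                         S - sample.int(read_len, n, replace = TRUE),
                         E + sample.int(read_len, n, replace = TRUE))
    if (frag$mode == "crispr") {
      on_t <- runif(n) < frag$on_target_prob
      cut <- ifelse(strand == "+", S - 25L, E + 26L)
      jit <- as.integer(round(rnorm(n, 0, frag$jitter_sd)))
      bound <- ifelse(on_t, cut + jit, rand_bound)
    } else {
      on_t <- rep(FALSE, n)
      bound <- rand_bound
    }

    # compose Read 1 from the haplotype sequence (tract length per read)
    left <- substr(chrom_seq, S - .SIM_CTX, S - 1L)
    right <- substr(chrom_seq, E + 1L, E + .SIM_CTX)
    r1 <- character(n)
    for (rr in unique(read_rep)) {
      idx <- which(read_rep == rr)
      full <- paste0(left, strrep(motif, rr), right)
      Lp <- rr * mlen
      rel_start <- ifelse(strand[idx] == "+",
                          bound[idx] - (S - .SIM_CTX) + 1L,
                          .SIM_CTX + Lp + (bound[idx] - 1L - E) - read_len + 1L)
      r1[idx] <- substr(rep(full, length(idx)), rel_start,
                        rel_start + read_len - 1L)
    }
    tract_len <- read_rep * mlen
    spanning <- ifelse(strand == "+",
                       bound <= S - 15L & bound + read_len - 1L >= S + tract_len + 14L,
                       bound - 1L >= S + tract_len + 14L & bound - read_len <= S - 15L)

    # Read 2 at the probe: plus covers [E+21, E+120] incl. SNP; minus
    # covers [S-120, S-21], all upstream reference sequence.
    r2_plus <- substr(chrom_seq, E + 21L, E + 20L + r2_len)
    r2_minus <- substr(chrom_seq, S - 20L - r2_len, S - 21L)
    r2 <- ifelse(strand == "+", r2_plus, r2_minus)
    snp_rel <- snp$pos - (E + 21L) + 1L
    plus_idx <- which(strand == "+")
    substr(r2[plus_idx], snp_rel, snp_rel) <- snp_base[plus_idx]
    r2_pos <- ifelse(strand == "+", E + 21L, S - 20L - r2_len)

    r1 <- .apply_base_errors(r1, base_error)
    r2 <- .apply_base_errors(r2, base_error)

    out[[i]] <- data.frame(
      pair_id = sprintf("%s:%s:%05d", tr$individual, lay$str_name[i],
                        seq_len(n)),
      r1_seq = r1, r1_qual = qual1,
      r1_chrom = lay$chrom[i],
      r1_pos = as.integer(ifelse(strand == "+", bound, bound - read_len)),
      r1_strand = strand, r1_mapq = 60L,
      r1_cigar = paste0(read_len, "M"),
      r2_seq = r2, r2_qual = qual2,
      r2_chrom = lay$chrom[i], r2_pos = as.integer(r2_pos),
      r2_strand = strand, r2_mapq = 60L,
      r2_cigar = paste0(r2_len, "M"),
      frag_bound = as.integer(bound),
      zp = NA_integer_,
      true_locus = lay$str_name[i],
      true_individual = tr$individual,
      true_hap = hap,
      true_repeats = as.integer(true_rep),
      read_repeats = as.integer(read_rep),
      true_stutter = as.integer(read_rep - true_rep),
      true_on_target = on_t,
      true_spanning = spanning,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "panel_sig") <- .object_sig(sim_panel$panel)
  attr(res, "r2_len") <- r2_len
  attr(res, "read_len") <- as.integer(read_len)
  class(res) <- c("str_reads", "data.frame")
  res
}

#' Mix read sets from several individuals
#'
#' Each output read is sampled from contributor `i` with probability
#' `fractions[i]`; per-read truth keeps the originating individual, so
#' the minor-component read share can be checked against the nominal
#' ratio.
#'
#' @param read_sets list of `str_reads` generated on the same panel.
#' @param fractions mixture fractions, summing to 1 (tolerance 1e-9).
#' @param n_reads output size; defaults to the total input size.
#' @param seed integer seed.
#' @return an `str_reads` data.frame (reads sampled with replacement when
#'   a contributor is oversubscribed).
#' @export
mix_read_sets <- function(read_sets, fractions, n_reads = NULL, seed = 1L) {
  stopifnot(length(read_sets) == length(fractions), length(read_sets) >= 1L)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  sigs <- vapply(read_sets, function(r) attr(r, "panel_sig") %||% NA_character_,
                 character(1))
  if (length(unique(sigs)) != 1L)
    stop("read sets were generated on different panels")
  set.seed(seed)
  n_out <- n_reads %||% sum(vapply(read_sets, nrow, integer(1)))
  counts <- as.vector(stats::rmultinom(1, n_out, fractions))
  picked <- vector("list", length(read_sets))
  for (i in seq_along(read_sets)) {
    if (counts[i] == 0L) next
    ni <- nrow(read_sets[[i]])
    idx <- sample.int(ni, counts[i], replace = counts[i] > ni)
    picked[[i]] <- read_sets[[i]][idx, , drop = FALSE]
  }
  res <- do.call(rbind, picked[!vapply(picked, is.null, logical(1))])
  res <- res[sample.int(nrow(res)), , drop = FALSE]
  res$pair_id <- sprintf("mix:%07d:%s", seq_len(nrow(res)), res$pair_id)
  rownames(res) <- NULL
  attr(res, "panel_sig") <- sigs[1]
  attr(res, "r2_len") <- attr(read_sets[[1]], "r2_len")
  attr(res, "read_len") <- attr(read_sets[[1]], "read_len")
  class(res) <- c("str_reads", "data.frame")
  res
}
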