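# Shared fixtures, built in code at test time.

# tiny deterministic panel + genome reused across files
fixture_sim_panel <- local({
  cache <- NULL
  function(n_loci = 5L, seed = 7L) {
    if (is.null(cache) || nrow(cache$panel$loci) != n_loci)
      cache <<- build_synthetic_panel(n_loci, seed = seed)
    cache
  }
})

# histogram literal: hist_of(`8` = 133, `11` = 114)
hist_of <- function(..., locus = "trfX") {
  v <- c(...)
  h <- data.frame(repeats = as.integer(names(v)), n_fwd = as.integer(v),
                  n_rev = 0L, n = as.integer(v))
  h <- h[order(h$repeats), ]
  rownames(h) <- NULL
  attr(h, "locus") <- locus
  class(h) <- c("allele_hist", "data.frame")
  h
}

# minimal hand-built panel: one locus "trfA" (motif GATA x 7 at 401..428)
# with one plus and one minus probe, on a 1000-base genome
fixture_manual_panel <- function() {
  set.seed(99)
  g <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
             collapse = "")
  S <- 401L
  tract <- strrep("GATA", 7)
  E <- S + nchar(tract) - 1L
  substr(g, S - 1L, S - 1L) <- "C"   # no motif continuation at boundaries
  g <- paste0(substr(g, 1, S - 1L), tract, substr(g, S + nchar(tract), 1000))
  p <- S + nchar(tract)
  substr(g, p, p) <- "C"
  loci <- data.frame(str_name = "trfA", motif = "GATA", chrom = "chrT",
                     start = S, end = E, min_repeats = 3L,
                     flank5 = substr(g, S - 15L, S - 1L),
                     flank3 = substr(g, E + 1L, E + 15L),
                     stringsAsFactors = FALSE)
  probes <- data.frame(probe_id = c(1L, 2L), chrom = "chrT",
                       expected_pos = c(E + 21L, S - 120L),
                       strand = c("+", "-"), str_name = "trfA",
                       probe_seq = c(substr(g, E + 21L, E + 60L),
                                     substr(g, S - 60L, S - 21L)),
                       stringsAsFactors = FALSE)
  bed5 <- data.frame(chrom = "chrT", start = S - 15L, end = S - 1L,
                     name = "trfA")
  bed3 <- data.frame(chrom = "chrT", start = E + 1L, end = E + 15L,
                     name = "trfA")
  nostr <- data.frame(chrom = "chrT", start = c(S - 150L, E + 6L),
                      end = c(S - 6L, E + 150L),
                      name = c("trfA_5p", "trfA_3p"))
  cuts <- data.frame(str_name = "trfA", chrom = "chrT",
                     cut_pos = c(S - 25L, E + 26L),
                     side = c("upstream", "downstream"),
                     stringsAsFactors = FALSE)
  list(panel = str_panel(loci, probes, bed5, bed3, nostr, cuts),
       genome = c(chrT = g), S = S, E = E)
}

# bare read-pair row(s) with only the fields the indexing layer needs
fake_r2 <- function(pos, chrom = "chrT", strand = "+", n = length(pos)) {
  data.frame(pair_id = sprintf("p%03d", seq_len(n)),
             r2_chrom = rep(chrom, length.out = n),
             r2_pos = as.integer(pos),
             r2_strand = rep(strand, length.out = n),
             zp = rep(NA_integer_, n),
             frag_bound = rep(NA_integer_, n), stringsAsFactors = FALSE)
}

expect_within <- function(x, center, tol) {
  expect_true(abs(x - center) <= tol,
              label = sprintf("%.5f within %.5f of %.5f", x, tol, center))
}
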