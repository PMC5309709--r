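# Repeat counting, allele histograms, threshold genotype calls,
# calibration, stutter fraction, dosage.

test_that("variable region extraction: worked example and failure tallies", {
  f5 <- "ACGTACGTACGTACG"
  f3 <- "TGCATGCATGCATGC"
  read <- paste0("GGGG", f5, strrep("GATA", 7), f3, "CCCC")
  ex <- extract_variable_region(read, f5, f3)
  expect_equal(nchar(ex$region), 28L)
  expect_equal(ex$region, strrep("GATA", 7))
  expect_equal(ex$reason, "ok")

  truncated <- paste0("GGGG", f5, strrep("GATA", 40))   # STR longer than read
  ex2 <- extract_variable_region(c(truncated, "AAAA"), f5, f3)
  expect_equal(ex2$reason, c("missing_3p", "missing_5p"))
  expect_true(all(is.na(ex2$region)))
})

test_that("a substituted flank is matched through its variant alternate", {
  f5 <- "ACGTACGTACGTACG"
  f3 <- "TGCATGCATGCATGC"
  f5_var <- f5
  substr(f5_var, 7, 7) <- "T"
  read <- paste0("GG", f5_var, strrep("GATA", 7), f3)
  # reference flank alone misses; adding the variant recovers the region
  expect_equal(extract_variable_region(read, f5, f3)$reason, "missing_5p")
  ex <- extract_variable_region(read, c(f5, f5_var), f3)
  expect_equal(ex$region, strrep("GATA", 7))
})

test_that("flank_variants enumerates substitution alternates from flank SNPs", {
  fx <- fixture_manual_panel()
  l <- fx$panel$loci
  snp_pos <- l$start - 10L   # inside the 5' flank interval
  snps <- data.frame(chrom = "chrT", pos = snp_pos,
                     ref = substr(fx$genome[["chrT"]], snp_pos, snp_pos),
                     alt = "A", stringsAsFactors = FALSE)
  if (snps$ref == "A") snps$alt <- "G"
  v <- flank_variants(fx$panel, snps)
  expect_length(v$trfA$flank5, 2L)
  expect_length(v$trfA$flank3, 1L)
  off <- snp_pos - (l$start - 15L) + 1L
  expect_equal(substr(v$trfA$flank5[2], off, off), snps$alt)
  # complex variants are excluded
  snps2 <- snps
  snps2$alt <- "AG"
  expect_length(flank_variants(fx$panel, snps2)$trfA$flank5, 1L)
})

test_that("repeat counting: division example, minimum-copy check, remainder", {
  expect_equal(count_motif_repeats(strrep("GATA", 7), "GATA", 3L)$repeats, 7L)
  r <- count_motif_repeats("GATAGA", "GATA", 3L)
  expect_true(is.na(r$repeats))
  expect_false(r$accepted)
  r27 <- count_motif_repeats(paste0(strrep("GATA", 6), "GAT"), "GATA", 3L)
  expect_equal(r27$repeats, 6L)        # floor division
  expect_true(r27$remainder)
})

test_that("histograms accumulate both probe strands and split support", {
  counted <- data.frame(locus = "trfA",
                        repeats = c(7L, 7L, 7L, 8L, NA, 7L),
                        strand = c("+", "+", "-", "-", "+", "-"))
  h <- build_allele_histogram(counted, "trfA")
  expect_equal(h$repeats, c(7L, 8L))
  expect_equal(h$n, c(4L, 1L))
  expect_equal(h$n_fwd, c(2L, 0L))
  expect_equal(h$n_rev, c(2L, 1L))
  expect_null(build_allele_histogram(counted, "trfB"))
})

test_that("genotype calls reproduce the published examples", {
  # 133 reads at 8 repeats, 114 at 11: distance +3 (>+1 class), passes
  cl <- call_str_genotype(hist_of(`8` = 133, `11` = 114))
  expect_equal(cl$zygosity, "het")
  expect_setequal(cl$alleles, c(8L, 11L))
  expect_equal(cl$major_allele, 8L)

  # distance -1 boundary: 0.36 >= 0.35 passes, 0.34 does not
  expect_equal(call_str_genotype(hist_of(`10` = 100, `9` = 36))$zygosity,
               "het")
  expect_equal(call_str_genotype(hist_of(`10` = 100, `9` = 34))$zygosity,
               "hom")

  # single-support histogram
  cl3 <- call_str_genotype(hist_of(`12` = 50))
  expect_equal(cl3$zygosity, "hom")
  expect_equal(cl3$alleles, 12L)
})

test_that("thresholds by allelic distance class behave at their boundaries", {
  th <- threshold_table()
  cases <- list(list(d = -1L, t = 0.35), list(d = 1L, t = 0.15),
                list(d = -2L, t = 0.45), list(d = 2L, t = 0.02),
                list(d = -4L, t = 0.45), list(d = 5L, t = 0.02))
  for (cs in cases) {
    major <- 10L
    n_major <- 1000L
    at <- ceiling(cs$t * n_major)
    h_pass <- hist_of(setNames(c(n_major, at), c(major, major + cs$d)))
    h_fail <- hist_of(setNames(c(n_major, at - 1L), c(major, major + cs$d)))
    expect_equal(call_str_genotype(h_pass, th)$zygosity, "het",
                 label = sprintf("distance %+d pass", cs$d))
    expect_equal(call_str_genotype(h_fail, th)$zygosity, "hom",
                 label = sprintf("distance %+d fail", cs$d))
  }
})

test_that("no-call below the read floor; scale invariance; monotonicity", {
  expect_null(call_str_genotype(hist_of(`9` = 2, `10` = 2)))
  # uniform scaling never changes the call
  set.seed(42)
  for (i in 1:25) {
    reps <- sort(sample(5:15, sample(2:4, 1)))
    counts <- sample(1:60, length(reps), replace = TRUE)
    h1 <- hist_of(setNames(counts, reps))
    h5 <- hist_of(setNames(counts * 5L, reps))
    c1 <- call_str_genotype(h1, min_total_reads = 1L)
    c5 <- call_str_genotype(h5, min_total_reads = 1L)
    expect_equal(c1$alleles, c5$alleles)
    expect_equal(c1$zygosity, c5$zygosity)
  }
  # raising a passing secondary never flips het -> hom
  for (extra in c(0L, 5L, 20L, 60L)) {
    h <- hist_of(`10` = 100, `9` = 36L + extra)
    expect_equal(call_str_genotype(h)$zygosity, "het")
  }
})

test_that("major-allele ties break to the shorter repeat and are flagged", {
  cl <- call_str_genotype(hist_of(`9` = 50, `12` = 50))
  expect_equal(cl$major_allele, 9L)
  expect_true("major_tie" %in% cl$flags)
})

test_that("stutter fraction arithmetic", {
  h0 <- hist_of(`10` = 100)
  expect_equal(stutter_fraction(h0, call_str_genotype(h0)), 0)
  h <- hist_of(`10` = 90, `9` = 5, `11` = 5)
  cl <- call_str_genotype(h)   # hom 10: 5/90 < 0.35 and < 0.15
  expect_equal(cl$zygosity, "hom")
  expect_equal(stutter_fraction(h, cl), 0.10)
})

test_that("simulated stutter mass lands off the true alleles at ~p", {
  sp <- build_synthetic_panel(1, seed = 9)
  tr <- draw_individual_genotypes(sp, allele_freqs =
    data.frame(repeats = 10L, freq = 1), seed = 1)
  rd <- generate_read_pairs(tr, sp, 20000, stutter_model(0.05, 0.8),
                            base_error = 0, seed = 4)
  g <- genotype_reads(tag_read_pairs(rd, sp$panel), sp$panel)
  h <- g$histograms[[1]]
  off_mass <- 1 - sum(h$n[h$repeats == 10L]) / sum(h$n)
  expect_within(off_mass, 0.05, 3 * sqrt(0.05 * 0.95 / sum(h$n)))
})

test_that("PCR-free cohorts show lower median stutter than PCR (direction)", {
  sp <- build_synthetic_panel(25, seed = 13)
  tr <- draw_individual_genotypes(sp, seed = 14)
  med_stutter <- function(p) {
    rd <- generate_read_pairs(tr, sp, 120, stutter_model(p), seed = 15)
    g <- genotype_reads(tag_read_pairs(rd, sp$panel), sp$panel)
    median(g$calls$stutter_fraction)
  }
  expect_gt(med_stutter(0.032), med_stutter(0.009))
})

test_that("dosage: published example, homozygotes, linearity", {
  mk_call <- function(alleles) structure(list(alleles = alleles),
                                         class = "str_call")
  # ref 18 bp, het 16 bp & 24 bp (dimer: 8 and 12 repeats) -> -2 + 6 = 4
  expect_equal(str_dosage(mk_call(c(8L, 12L)), 2L, 18L), 4L)
  expect_equal(str_dosage(mk_call(10L), 2L, 20L), 0L)      # ref homozygote
  expect_equal(str_dosage(mk_call(10L), 2L, 18L), 4L)      # hom counts twice
  # linearity: dosage = contribution(a1) + contribution(a2)
  set.seed(7)
  for (i in 1:20) {
    a <- sample(5:15, 2)
    mlen <- sample(2:5, 1)
    ref <- sample(10:40, 1)
    expect_equal(str_dosage(mk_call(a), mlen, ref),
                 (a[1] * mlen - ref) + (a[2] * mlen - ref))
  }
})

test_that("threshold calibration: separation, sweep oracle, simulation", {
  # perfectly separated: threshold = minimum case fraction
  cases <- data.frame(class = "-1", fraction = c(0.5, 0.6, 0.45))
  controls <- data.frame(class = "-1", fraction = c(0.10, 0.2, 0.05))
  cal <- suppressWarnings(calibrate_thresholds(cases, controls))
  expect_equal(unname(unclass(cal$thresholds)["-1"]), 0.45)

  # overlapping distributions equal an exhaustive brute-force sweep
  set.seed(11)
  cases2 <- data.frame(class = "+1", fraction = runif(200, 0.1, 0.8))
  controls2 <- data.frame(class = "+1", fraction = rbeta(200, 1, 6))
  cal2 <- suppressWarnings(calibrate_thresholds(cases2, controls2, 0.01))
  brute <- sort(unique(c(cases2$fraction, controls2$fraction)))
  feasible <- brute[vapply(brute, function(t)
    mean(controls2$fraction >= t) <= 0.01, logical(1))]
  expect_equal(unname(unclass(cal2$thresholds)["+1"]), min(feasible))

  # empty class warns and is omitted
  w <- testthat::capture_warnings(calibrate_thresholds(cases, controls))
  expect_true(any(grepl("omitted", w)))
})

test_that("calibration on simulator output lands near the shipped table", {
  # deletion-biased stutter at PCR-like rates: the -1 class dominates;
  # a usable threshold must sit below true-heterozygote balance (~1) and
  # above the largest homozygote stutter artifact fraction
  sp <- build_synthetic_panel(60, seed = 23)
  het <- draw_individual_genotypes(sp, allele_freqs =
    data.frame(repeats = c(9L, 10L), freq = c(.5, .5)), seed = 24)
  rd <- generate_read_pairs(het, sp, 150, stutter_model(0.032, 0.8),
                            seed = 25)
  g <- genotype_reads(tag_read_pairs(rd, sp$panel), sp$panel)
  frac_at <- function(h, rep_from, d) {
    i <- which(h$repeats == rep_from + d)
    j <- which.max(h$n)
    if (!length(i)) 0 else h$n[i] / max(h$n)
  }
  cases <- controls <- NULL
  for (nm in names(g$histograms)) {
    h <- g$histograms[[nm]]
    t <- het[het$str_name == nm, ]
    hi <- max(t$hap1_repeats, t$hap2_repeats)
    lo <- min(t$hap1_repeats, t$hap2_repeats)
    if (hi != lo) {          # true het at distance -1
      cases <- rbind(cases, data.frame(class = "-1",
                                       fraction = frac_at(h, hi, -1L)))
    } else {                 # hom: the -1 bin is pure stutter
      controls <- rbind(controls, data.frame(class = "-1",
                                             fraction = frac_at(h, hi, -1L)))
    }
  }
  cal <- suppressWarnings(calibrate_thresholds(cases, controls, 0.01))
  t1 <- unclass(cal$thresholds)["-1"]
  expect_gt(t1, 0.05)   # above stutter artifact levels
  expect_lt(t1, 0.9)    # below true-allele balance
})
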