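# CE offset concordance, trio reports, informative haplotypes, mixture
# quantification.

toy_loci <- data.frame(str_name = c("trfA", "trfB"), motif = c("GATA", "CA"),
                       chrom = "chrT", start = c(101L, 501L),
                       end = c(128L, 520L), stringsAsFactors = FALSE)

test_that("CE comparison: identity, median offsets, shift invariance", {
  seq_calls <- expand.grid(sample = paste0("s", 1:5),
                           locus = toy_loci$str_name,
                           stringsAsFactors = FALSE)
  seq_calls$allele1 <- c(7L, 8L, 7L, 9L, 7L, 10L, 11L, 10L, 10L, 12L)
  seq_calls$allele2 <- seq_calls$allele1 + c(0L, 1L, 2L, 0L, 1L,
                                             0L, 0L, 2L, 1L, 0L)
  mlen <- c(trfA = 4L, trfB = 2L)

  # identical annotation: concordance 1, offsets 0
  ce <- data.frame(sample = seq_calls$sample, locus = seq_calls$locus,
                   allele1_bp = seq_calls$allele1 * mlen[seq_calls$locus],
                   allele2_bp = seq_calls$allele2 * mlen[seq_calls$locus],
                   stringsAsFactors = FALSE)
  cmp <- ce_offset_concordance(seq_calls, ce, toy_loci)
  expect_equal(cmp$concordance, 1.0)
  expect_true(all(cmp$offsets$offset == 0))
  expect_equal(cmp$dosage_pairs$dosage_seq_bp, cmp$dosage_pairs$dosage_ce_bp)

  # a constant per-locus annotation shift is absorbed by the median offset
  for (k in c(-2L, 1L, 3L)) {
    ce_k <- ce
    shift <- ifelse(ce_k$locus == "trfA", k, -k)
    ce_k$allele1_bp <- ce_k$allele1_bp + shift * mlen[ce_k$locus]
    ce_k$allele2_bp <- ce_k$allele2_bp + shift * mlen[ce_k$locus]
    cmp_k <- ce_offset_concordance(seq_calls, ce_k, toy_loci)
    expect_equal(cmp_k$concordance, 1.0, label = paste("shift", k))
    expect_equal(cmp_k$offsets$offset[cmp_k$offsets$locus == "trfA"], -k)
  }

  # offsets {+1,+1,0,+1,+1} -> median +1 (majority-shift oracle)
  ce_m <- ce[ce$locus == "trfA", ]
  sq_m <- seq_calls[seq_calls$locus == "trfA", ]
  shift <- c(1L, 1L, 0L, 1L, 1L)
  sq_m$allele1 <- sq_m$allele1 + shift
  sq_m$allele2 <- sq_m$allele2 + shift
  cmp_m <- ce_offset_concordance(sq_m, ce_m, toy_loci)
  expect_equal(cmp_m$offsets$offset, 1)
  expect_equal(cmp_m$concordance, 4 / 5)   # the unshifted sample misses

  # loci absent from the CE table are skipped
  cmp_s <- ce_offset_concordance(seq_calls, ce[ce$locus == "trfA", ],
                                 toy_loci)
  expect_equal(nrow(cmp_s$offsets), 1L)
})

test_that("trio genotype/haplotype concordance: set-membership examples", {
  mk_member <- function(alleles1, alleles2, haps, phased_n = 50L) {
    calls <- data.frame(locus = "trfA", allele1 = alleles1,
                        allele2 = alleles2, total = 60L,
                        stringsAsFactors = FALSE)
    hdf <- data.frame(locus = "trfA", pos = 900L,
                      snp_base = vapply(strsplit(haps, "-"), `[`, "", 1),
                      repeats = as.integer(vapply(strsplit(haps, "-"),
                                                  `[`, "", 2)),
                      support = phased_n, stringsAsFactors = FALSE)
    ph <- hdf
    names(ph)[names(ph) == "support"] <- "n"
    list(calls = calls, haplotypes = hdf, phased = ph)
  }
  child <- mk_member(11L, 13L, c("A-11", "C-13"))
  father <- mk_member(11L, 12L, c("A-11", "A-12"))
  mother <- mk_member(13L, 9L, c("C-13", "G-9"))
  rep1 <- trio_concordance(child, father, mother)
  expect_equal(rep1$genotype_concordance, 100)
  expect_equal(rep1$haplotype_concordance, 100)

  father2 <- mk_member(8L, 9L, c("G-8", "G-9"))
  mother2 <- mk_member(13L, 13L, c("C-13", "C-13"))
  rep2 <- trio_concordance(child, father2, mother2)
  expect_equal(rep2$genotype_concordance, 0)    # 11 unexplained
  expect_equal(rep2$haplotype_concordance, 0)   # A-11 unexplained

  # homozygous child haplotype must be present in both parents
  child_hom <- mk_member(11L, 11L, "A-11")
  expect_equal(trio_concordance(child_hom, father, mother)$haplotype_concordance,
               0)   # mother lacks A-11
  mother3 <- mk_member(11L, 13L, c("A-11", "C-13"))
  expect_equal(trio_concordance(child_hom, father, mother3)$haplotype_concordance,
               100)

  # the 15% parent re-evaluation rule: a minor parental haplotype below
  # 15% of reads does not count as carried
  father_weak <- mk_member(11L, 12L, c("A-12", "A-11"))
  father_weak$phased$n <- c(90L, 10L)   # A-11 at 10% < 15%
  expect_equal(trio_concordance(child, father_weak, mother)$haplotype_concordance,
               0)
  father_ok <- father_weak
  father_ok$phased$n <- c(84L, 16L)     # 16% >= 15%
  expect_equal(trio_concordance(child, father_ok, mother)$haplotype_concordance,
               100)

  # coverage floor: under-covered sites do not qualify
  child_low <- child
  child_low$haplotypes$support <- 4L
  rep_low <- trio_concordance(child_low, father, mother)
  expect_equal(nrow(rep_low$haplotype), 0L)
})

test_that("informative haplotypes equal the brute-force set difference", {
  mk_h <- function(keys) {
    parts <- strsplit(keys, ":")
    data.frame(locus = vapply(parts, `[`, "", 1),
               snp_base = vapply(parts, `[`, "", 2),
               repeats = as.integer(vapply(parts, `[`, "", 3)),
               stringsAsFactors = FALSE)
  }
  minor <- mk_h(c("L1:A:11", "L1:C:13", "L2:G:8"))
  major <- mk_h(c("L1:A:11", "L1:A:11", "L2:G:9"))
  inf <- informative_haplotypes(minor, major)
  expect_equal(nrow(inf), 2L)
  expect_setequal(paste(inf$locus, inf$snp_base, inf$repeats),
                  c("L1 C 13", "L2 G 8"))
  # identical samples: empty set
  expect_equal(nrow(informative_haplotypes(minor, minor)), 0L)

  # six-component mixture against brute force
  set.seed(8)
  rand_h <- function(n) mk_h(sprintf("L%d:%s:%d", sample(1:6, n, TRUE),
                                     sample(c("A", "C"), n, TRUE),
                                     sample(8:12, n, TRUE)))
  minor6 <- rand_h(12)
  majors <- lapply(1:5, function(i) rand_h(10))
  inf6 <- informative_haplotypes(minor6, majors)
  key <- function(d) paste(d$locus, d$snp_base, d$repeats)
  brute <- minor6[!key(minor6) %in% unlist(lapply(majors, key)), ]
  expect_setequal(key(inf6), key(brute))
})

test_that("mixture quantification arithmetic and expected-fraction law", {
  ph <- data.frame(locus = "L1", pos = 900L,
                   snp_base = c("A", "C"), repeats = c(11L, 13L),
                   n = c(995L, 5L), stringsAsFactors = FALSE)
  inf <- data.frame(locus = "L1", pos = 900L, snp_base = "C",
                    repeats = 13L, zygosity = "het",
                    stringsAsFactors = FALSE)
  mq <- mixture_quantification(ph, inf, truth_ratio = 0.10)
  expect_equal(mq$observed_fraction, 0.005)
  expect_equal(mq$expected_fraction, 0.05)   # het minor at 10% -> 5%
  expect_true(mq$detected)

  # homozygous informative haplotype expects the full ratio
  mq_hom <- mixture_quantification(ph, within(inf, zygosity <- "hom"),
                                   truth_ratio = 0.10)
  expect_equal(mq_hom$expected_fraction, 0.10)

  # zero-coverage locus: undetectable, NA fraction
  inf2 <- rbind(inf, within(inf, locus <- "L2"))
  mq2 <- mixture_quantification(ph, inf2, truth_ratio = 0.10)
  expect_true(is.na(mq2$observed_fraction[2]))
  expect_false(mq2$detected[2])

  # detection floor: a singleton read does not count
  ph1 <- ph
  ph1$n <- c(999L, 1L)
  expect_false(mixture_quantification(ph1, inf)$detected)
})
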