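# Probe masking, pileup SNP calling, the filter cascade, read-level
# phasing and haplotype calls.

test_that("probe masking: forward, reverse, and short reads", {
  fwd <- mask_probe_bases(1001L, 150L, "+")
  expect_equal(c(fwd$use_start, fwd$use_end), c(1041L, 1150L))
  rev <- mask_probe_bases(1001L, 150L, "-")
  expect_equal(c(rev$use_start, rev$use_end), c(1001L, 1110L))
  expect_warning(short <- mask_probe_bases(1001L, 35L, "+"), "fully masked")
  expect_gt(short$use_start, short$use_end)
})

# helper: reads pile up over a 100-base window on a toy reference
toy_pileup_reads <- function(n_ref, n_alt, pos = 1L, qual_char = "D",
                             mapq = 60L, alt_at = 60L, alt_base = "T") {
  ref_seq <- strrep("A", 100)
  alt_seq <- ref_seq
  substr(alt_seq, alt_at, alt_at) <- alt_base
  data.frame(
    r2_chrom = "chrP", r2_pos = pos, r2_strand = "+",
    r2_seq = c(rep(ref_seq, n_ref), rep(alt_seq, n_alt)),
    r2_qual = strrep(qual_char, 100), r2_mapq = mapq,
    stringsAsFactors = FALSE)
}
toy_ref <- c(chrP = strrep("A", 200))
toy_iv <- data.frame(chrom = "chrP", start = 41L, end = 100L)

test_that("balanced high-quality pileup yields a heterozygous PASS call", {
  calls <- call_snps_pileup(toy_pileup_reads(5, 5), toy_iv, toy_ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 60L)
  expect_equal(calls$filter, "PASS")
  expect_equal(calls$genotype, "het")
  expect_equal(calls$alt_count, 5L)
  expect_equal(calls$ref, "A")
  expect_equal(calls$alt, "T")
})

test_that("coverage, pvar and quality-sum filters fire as published", {
  low_cov <- call_snps_pileup(toy_pileup_reads(0, 2), toy_iv, toy_ref)
  expect_match(low_cov$filter, "min_coverage")

  low_frac <- call_snps_pileup(toy_pileup_reads(97, 3), toy_iv, toy_ref)
  expect_match(low_frac$filter, "pvar")   # 0.03 < 0.05

  # one alt read: quality sums 35 < 60 and 60 < 90
  sums <- call_snps_pileup(toy_pileup_reads(10, 1, qual_char = "D"),
                           toy_iv, toy_ref, pvar = 0.05)
  expect_match(sums$filter, "mapping_qsum")
  expect_match(sums$filter, "allele_qsum")

  # low base quality removes the evidence entirely
  none <- call_snps_pileup(toy_pileup_reads(5, 5, qual_char = "+"),
                           toy_iv, toy_ref)   # Q10 < 15
  expect_equal(nrow(none), 0L)
  # low mapping quality likewise
  none2 <- call_snps_pileup(toy_pileup_reads(5, 5, mapq = 10L),
                            toy_iv, toy_ref)
  expect_equal(nrow(none2), 0L)
})

test_that("probe bases never influence variant discovery (masking invariance)", {
  rd <- toy_pileup_reads(5, 5)
  calls <- call_snps_pileup(rd, data.frame(chrom = "chrP", start = 1L,
                                           end = 100L), toy_ref)
  # scramble the masked probe region: calls must not change
  rd2 <- rd
  substr(rd2$r2_seq, 1L, 40L) <- strrep("G", 40)
  calls2 <- call_snps_pileup(rd2, data.frame(chrom = "chrP", start = 1L,
                                             end = 100L), toy_ref)
  expect_equal(calls2, calls)
})

test_that("filter_snps: thinning boundary, exclusion bed, PASS, alt quality", {
  mk <- function(pos, filter = "PASS", aq = 200, ao = 5) {
    data.frame(chrom = "chrP", pos = pos, ref = "A", alt = "T",
               coverage = 10L, ref_count = 5L, alt_count = ao,
               alt_qual_sum = aq, genotype = "het", ref_freq = .5,
               alt_freq = .5, filter = filter, stringsAsFactors = FALSE)
  }
  # 5 bp apart: both removed; 6 bp apart: both retained
  expect_equal(nrow(filter_snps(rbind(mk(100L), mk(105L)))), 0L)
  expect_equal(nrow(filter_snps(rbind(mk(100L), mk(106L)))), 2L)
  # a chain 100,105,110: all pairwise-close members go
  expect_equal(nrow(filter_snps(rbind(mk(100L), mk(105L), mk(110L)))), 0L)
  # exclusion intervals (repeat tracts) remove overlapping calls
  excl <- data.frame(chrom = "chrP", start = 95L, end = 102L)
  expect_equal(nrow(filter_snps(mk(100L), excl)), 0L)
  expect_equal(nrow(filter_snps(mk(103L), excl)), 1L)
  # non-PASS and low average alternate quality (QUAL/AO <= 8)
  expect_equal(nrow(filter_snps(mk(100L, filter = "pvar"))), 0L)
  expect_equal(nrow(filter_snps(mk(100L, aq = 40, ao = 5))), 0L)   # 8 !> 8
  expect_equal(nrow(filter_snps(mk(100L, aq = 41, ao = 5))), 1L)
})

test_that("read-level phasing links Read 2 base to Read 1 repeats", {
  counted <- data.frame(
    locus = "trfA", repeats = c(11L, 11L, 8L, NA, 11L),
    r2_chrom = "chrP", r2_pos = 1L, r2_strand = "+",
    r2_seq = c(paste0(strrep("A", 59), "C", strrep("A", 40)),
               paste0(strrep("A", 59), "C", strrep("A", 40)),
               paste0(strrep("A", 59), "G", strrep("A", 40)),
               paste0(strrep("A", 59), "C", strrep("A", 40)),
               paste0(strrep("A", 59), "T", strrep("A", 40))),  # third base
    r2_qual = strrep("D", 100), r2_mapq = 60L, stringsAsFactors = FALSE)
  snp <- data.frame(chrom = "chrP", pos = 60L, ref = "C", alt = "G",
                    ref_freq = 0.6, alt_freq = 0.4, stringsAsFactors = FALSE)
  ph <- link_reads_to_haplotypes(counted, snp, NULL)
  expect_equal(sort(ph$n), c(1L, 2L))
  expect_equal(ph$n[ph$snp_base == "C" & ph$repeats == 11L], 2L)
  expect_equal(ph$n[ph$snp_base == "G" & ph$repeats == 8L], 1L)
  # the NA-repeat pair and the third-base read are dropped
  expect_equal(sum(ph$n), 3L)

  # an allele whose called frequency is 0 is dropped
  snp0 <- snp
  snp0$ref_freq <- 0
  ph0 <- link_reads_to_haplotypes(counted, snp0, NULL)
  expect_equal(ph0$snp_base, "G")
})

test_that("haplotype calls follow the published rules", {
  # heterozygous SNP: each base takes its majority repeat
  ph <- data.frame(locus = "trfA",
                   snp_base = c("C", "G", "C"),
                   repeats = c(11L, 8L, 10L),
                   n = c(114L, 133L, 4L), stringsAsFactors = FALSE)
  hc <- call_haplotypes(ph, "het")
  expect_equal(hc$zygosity, "het")
  got <- hc$haplotypes[order(hc$haplotypes$snp_base), ]
  expect_equal(got$snp_base, c("C", "G"))
  expect_equal(got$repeats, c(11L, 8L))
  expect_equal(got$support, c(114L, 133L))

  # homozygous SNP, passing secondary (+2 class >+1: 40/60 >= 0.02)
  ph2 <- data.frame(locus = "trfA", snp_base = "A",
                    repeats = c(11L, 13L), n = c(60L, 40L),
                    stringsAsFactors = FALSE)
  hc2 <- call_haplotypes(ph2, "hom")
  expect_equal(hc2$zygosity, "het")
  expect_setequal(hc2$haplotypes$repeats, c(11L, 13L))
  expect_true(all(hc2$haplotypes$snp_base == "A"))

  # homozygous SNP, failing secondary (5/95 < 0.35 at -1)
  ph3 <- data.frame(locus = "trfA", snp_base = "A",
                    repeats = c(11L, 10L), n = c(95L, 5L),
                    stringsAsFactors = FALSE)
  hc3 <- call_haplotypes(ph3, "hom")
  expect_equal(hc3$zygosity, "hom")
  expect_equal(hc3$haplotypes$repeats, 11L)

  # heterozygous SNP with only one observed base: flagged incomplete
  hc4 <- call_haplotypes(ph3, "het")
  expect_true("incomplete" %in% hc4$flags)
})

test_that("haplotype alleles stay within genotype alleles on clean data", {
  sp <- fixture_sim_panel()
  tr <- draw_individual_genotypes(sp, seed = 2)
  rd <- generate_read_pairs(tr, sp, 120, stutter_model(0), base_error = 0,
                            seed = 3)
  g <- genotype_reads(tag_read_pairs(rd, sp$panel), sp$panel)
  snps <- call_snps_pileup(g$reads, sp$panel$nostr, sp$genome)
  h <- haplotype_reads(g, snps, sp$panel)
  for (i in seq_len(nrow(h$haplotypes))) {
    row <- h$haplotypes[i, ]
    cl <- g$calls[g$calls$locus == row$locus, ]
    expect_true(row$repeats %in% c(cl$allele1, cl$allele2))
  }
})

test_that("phased haplotypes recover simulated phase (>= 99% at 60x)", {
  sp <- build_synthetic_panel(40, seed = 31)
  tr <- draw_individual_genotypes(sp, seed = 32)
  rd <- generate_read_pairs(tr, sp, 60, stutter_model(0.03, 0.8),
                            seed = 33)
  g <- genotype_reads(tag_read_pairs(rd, sp$panel), sp$panel)
  snps <- call_snps_pileup(g$reads, sp$panel$nostr, sp$genome)
  h <- haplotype_reads(g, snps, sp$panel)
  checked <- 0L
  good <- 0L
  for (nm in unique(h$haplotypes$locus)) {
    t <- tr[tr$str_name == nm, ]
    truth_haps <- unique(c(paste(t$hap1_snp, t$hap1_repeats, sep = "-"),
                           paste(t$hap2_snp, t$hap2_repeats, sep = "-")))
    sub <- h$haplotypes[h$haplotypes$locus == nm, ]
    called <- paste(sub$snp_base, sub$repeats, sep = "-")
    checked <- checked + length(truth_haps)
    good <- good + sum(truth_haps %in% called)
  }
  expect_gte(good / checked, 0.99)
})
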