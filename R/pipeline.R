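## End-to-end pipeline with structured configuration and a run manifest
## recording per-stage read attrition.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its published default:
#' probe-match tolerance 2 b, fragmentation classification tolerance 4 b,
#' 15-base flanks, 40-base probe mask, the secondary-allele threshold
#' table, the SNP filter cascade (pvar 0.05, min coverage 3, min base
#' quality 15, min mapping quality 25, supporting mapping-quality sum 90,
#' supporting allele-quality sum 60, thin 6, average alternate quality
#' > 8), parent heterozygote fraction 0.15 and trio coverage floor 10.
#'
#' @param n_loci,coverage,read_len simulation shape.
#' @param stutter a [stutter_model()]; `frag` a [fragmentation_model()].
#' @param frag see above.
#' @param probe_tolerance,frag_tolerance indexing tolerances (bases).
#' @param thresholds a [threshold_table()].
#' @param min_total_reads genotype no-call floor.
#' @param pvar,min_coverage,min_base_quality,min_mapping_quality,
#'   min_supporting_mapping_qsum,min_supporting_allele_qsum,thin,
#'   min_avg_alt_qual SNP caller/filter parameters.
#' @param mask_n probe bases masked on Read 2.
#' @param parent_het_fraction,min_cov trio parameters.
#' @param seed master seed.
#' @param out_dir output directory (NULL: nothing written).
#' @return list of class `strseq_config`.
#' @export
strseq_config <- function(n_loci = 20L, coverage = 100L, read_len = 150L,
                          stutter = stutter_model(),
                          frag = fragmentation_model(),
                          probe_tolerance = 2L, frag_tolerance = 4L,
                          thresholds = threshold_table(),
                          min_total_reads = 5L,
                          pvar = 0.05, min_coverage = 3L,
                          min_base_quality = 15L, min_mapping_quality = 25L,
                          min_supporting_mapping_qsum = 90L,
                          min_supporting_allele_qsum = 60L,
                          thin = 6L, min_avg_alt_qual = 8,
                          mask_n = 40L,
                          parent_het_fraction = 0.15, min_cov = 10L,
                          seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "strseq_config")
}

#' Serialize / load a pipeline configuration
#'
#' Flat key=value text: nested models are flattened with a
#' `stutter.`/`frag.`/`thresholds.` prefix. `read_config(write_config(x))`
#' reproduces `x`.
#'
#' @param config an [strseq_config()].
#' @param path file path.
#' @return `path` (write) / the `strseq_config` (read).
#' @export
write_config <- function(config, path) {
  flat <- c()
  for (nm in names(config)) {
    v <- config[[nm]]
    if (inherits(v, c("stutter_model", "fragmentation_model"))) {
      for (k in names(unclass(v)))
        flat[paste(nm, k, sep = ".")] <- as.character(v[[k]])
    } else if (inherits(v, "str_thresholds")) {
      for (k in names(unclass(v)))
        flat[paste(nm, k, sep = ".")] <- as.character(unclass(v)[[k]])
    } else if (is.null(v)) {
      next
    } else {
      flat[nm] <- as.character(v)
    }
  }
  writeLines(paste0(names(flat), "=", flat), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  cfg <- strseq_config()
  num <- function(x) {
    y <- suppressWarnings(as.numeric(x))
    if (is.na(y)) x else if (y == as.integer(y)) as.integer(y) else y
  }
  st <- unclass(cfg$stutter); fr <- unclass(cfg$frag)
  th <- unclass(cfg$thresholds)
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (startsWith(k, "stutter.")) st[[sub("^stutter\\.", "", k)]] <- num(v)
    else if (startsWith(k, "frag.")) {
      f <- sub("^frag\\.", "", k)
      fr[[f]] <- if (f == "mode") v else num(v)
    }
    else if (startsWith(k, "thresholds."))
      th[[sub("^thresholds\\.", "", k)]] <- num(v)
    else if (k %in% names(cfg)) cfg[[k]] <- num(v)
  }
  cfg$stutter <- do.call(stutter_model, st[c("p_stutter", "p_deletion",
                                             "step_decay")])
  cfg$frag <- do.call(fragmentation_model, fr[c("mode", "jitter_sd",
                                                "on_target_prob")])
  cfg$thresholds <- threshold_table(th[["-1"]], th[["+1"]], th[["<-1"]],
                                    th[[">+1"]])
  cfg
}

#' Run the full simulated pipeline
#'
#' simulate -> index -> genotype -> haplotype, returning all stage
#' outputs and a manifest of per-stage read counts (pairs generated,
#' tagged, STR-spanning, genotyped loci) plus the headline QC fractions
#' (on-target fragmentation, STR-spanning read fraction). Outputs are a
#' pure function of the configuration.
#'
#' @param config an [strseq_config()].
#' @return list of class `strseq_run`: `manifest`, `sim_panel`, `truth`,
#'   `reads`, `tagged`, `frag_summary`, `genotypes`, `haplotypes`,
#'   `config`.
#' @export
run_pipeline <- function(config = strseq_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  sp <- stage("simulate_panel",
              build_synthetic_panel(config$n_loci, seed = config$seed))
  truth <- stage("simulate_truth",
                 draw_individual_genotypes(sp, seed = config$seed + 1L))
  reads <- stage("simulate_reads",
                 generate_read_pairs(truth, sp, config$coverage,
                                     config$stutter, config$frag,
                                     read_len = config$read_len,
                                     seed = config$seed + 2L))
  tagged <- stage("index",
                  tag_read_pairs(reads, sp$panel, config$probe_tolerance))
  fs <- stage("fragmentation",
              classify_fragmentation(tagged, sp$panel,
                                     config$frag_tolerance))
  geno <- stage("genotype",
                genotype_reads(tagged, sp$panel,
                               thresholds = config$thresholds,
                               min_total_reads = config$min_total_reads))
  snps <- stage("snp_call",
                call_snps_pileup(geno$reads, sp$panel$nostr, sp$genome,
                                 pvar = config$pvar,
                                 min_coverage = config$min_coverage,
                                 min_base_quality = config$min_base_quality,
                                 min_mapping_quality = config$min_mapping_quality,
                                 min_supporting_mapping_qsum =
                                   config$min_supporting_mapping_qsum,
                                 min_supporting_allele_qsum =
                                   config$min_supporting_allele_qsum,
                                 mask_n = config$mask_n))
  haps <- stage("haplotype",
                haplotype_reads(geno, snps, sp$panel,
                                thresholds = config$thresholds,
                                thin = config$thin,
                                min_avg_alt_qual = config$min_avg_alt_qual))
  n_span <- sum(!is.na(geno$reads$repeats))
  manifest <- list(
    tool_version = as.character(utils::packageVersion("strseq")),
    config_sig = .object_sig(config),
    n_pairs_in = nrow(reads),
    n_tagged = nrow(tagged),
    n_spanning = n_span,
    n_loci_genotyped = if (is.null(geno$calls)) 0L else nrow(geno$calls),
    on_target_fraction = fs$on_target_fraction,
    spanning_fraction = n_span / nrow(tagged),
    indexed_fraction = nrow(tagged) / nrow(reads))
  manifest$sig <- .object_sig(manifest[setdiff(names(manifest), "sig")])
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_panel_bundle(sp$panel, file.path(config$out_dir, "panel"))
    write_genome_fasta(sp, file.path(config$out_dir, "genome.fa"))
    write_truth(truth, file.path(config$out_dir, "truth.tsv"))
    write_reads_sam(tagged, file.path(config$out_dir, "tagged.sam"),
                    sp$genome)
    utils::write.table(geno$calls, file.path(config$out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(haps$haplotypes))
      utils::write.table(haps$haplotypes,
                         file.path(config$out_dir, "haplotypes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_snp_vcf(haps$snps, file.path(config$out_dir, "snps.vcf"))
  }
  structure(list(manifest = manifest, sim_panel = sp, truth = truth,
                 reads = reads, tagged = tagged, frag_summary = fs,
                 genotypes = geno, haplotypes = haps, config = config),
            class = "strseq_run")
}

#' @export
print.strseq_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("strseq run: %d pairs -> %d tagged (%.1f%%) -> ",
                     "%d spanning (%.1f%%) -> %d loci genotyped\n"),
              m$n_pairs_in, m$n_tagged, 100 * m$indexed_fraction,
              m$n_spanning, 100 * m$spanning_fraction,
              m$n_loci_genotyped))
  invisible(x)
}

#' Write SNP calls as a minimal VCF
#' @param snps a `snp_calls` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Coverage\">",
               "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternate observations\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate frequency\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.0f\t%s\tDP=%d;AO=%d;AF=%.4f",
                       snps$chrom, snps$pos, snps$ref, snps$alt,
                       snps$alt_qual_sum, snps$filter, snps$coverage,
                       snps$alt_count, snps$alt_freq), con)
  invisible(path)
}
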