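#' Construct an STR panel bundle
#'
#' A panel bundle collects the five metadata tables that describe a targeted
#' STR panel: the locus table (motif, tract coordinates, minimum repeat
#' count, 15-base flanking sequences), the 40-mer primer-probe table (one
#' expected Read 2 alignment position per probe), the 5' and 3' flank
#' interval sets, and the SNP-calling target intervals that exclude all
#' repeat tracts (plus 5 b padding). An optional guide-RNA cut-site table
#' supports fragmentation QC.
#'
#' @param loci data.frame with columns `str_name`, `motif`, `chrom`,
#'   `start`, `end`, `min_repeats`, `flank5`, `flank3`. Coordinates are
#'   1-based inclusive; `end - start + 1` is the reference tract length in
#'   base pairs.
#' @param probes data.frame with columns `probe_id`, `chrom`,
#'   `expected_pos`, `strand` (`"+"`/`"-"`), `str_name`, `probe_seq`
#'   (40 bases). `expected_pos` is the 1-based leftmost alignment position
#'   of a correctly primed Read 2.
#' @param flank5,flank3 data.frames (`chrom`, `start`, `end`, `name`) giving
#'   the genomic intervals of the 15-base flanks; `name` matches `str_name`.
#' @param nostr data.frame (`chrom`, `start`, `end`, `name`): target
#'   intervals for SNP calling, excluding every repeat tract +/- 5 b.
#' @param cut_sites optional data.frame (`str_name`, `chrom`, `cut_pos`,
#'   `side`): expected blunt double-strand-break boundaries, `side` in
#'   `upstream`/`downstream`. `cut_pos` is the 1-based coordinate of the
#'   first base on the downstream side of the cut.
#' @return An object of class `str_panel`.
#' @seealso [load_panel_bundle()], [validate_panel()]
#' @export
str_panel <- function(loci, probes, flank5, flank3, nostr, cut_sites = NULL) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  obj <- structure(
    list(loci = loci, probes = probes,
         flank5 = as.data.frame(flank5), flank3 = as.data.frame(flank3),
         nostr = as.data.frame(nostr),
         cut_sites = if (is.null(cut_sites)) NULL else as.data.frame(cut_sites)),
    class = "str_panel")
  bad <- validate_panel(obj)
  if (nrow(bad) > 0L) {
    stop("invalid panel bundle:\n",
         paste(sprintf("  [%s] %s", bad$id, bad$problem), collapse = "\n"))
  }
  obj
}

#' @export
print.str_panel <- function(x, ...) {
  cat(sprintf("str_panel: %d loci, %d probes%s\n",
              nrow(x$loci), nrow(x$probes),
              if (!is.null(x$cut_sites))
                sprintf(", %d gRNA cut sites", nrow(x$cut_sites)) else ""))
  invisible(x)
}

.LOCI_COLS  <- c("str_name", "motif", "chrom", "start", "end",
                 "min_repeats", "flank5", "flank3")
.PROBE_COLS <- c("probe_id", "chrom", "expected_pos", "strand",
                 "str_name", "probe_seq")
.BED_COLS   <- c("chrom", "start", "end", "name")
.CUT_COLS   <- c("str_name", "chrom", "cut_pos", "side")

#' Validate a panel bundle
#'
#' Checks every structural invariant of the bundle and reports violations
#' instead of stopping: motif length 1-6, flanks exactly 15 bases over
#' ACGT, tract start <= end, `min_repeats >= 1`, probe sequences exactly
#' 40 bases, probe strand `+`/`-`, unique probe ids, every probe resolving
#' to a loaded locus, every locus carrying at least one probe, flank
#' interval names matching locus names, and per-locus non-self-overlapping
#' interval sets.
#'
#' @param bundle a list with the `str_panel` structure (class not required,
#'   so a bundle can be checked before blessing).
#' @return data.frame with columns `id` (locus/probe identifier) and
#'   `problem`; zero rows when the bundle is well formed.
#' @export
validate_panel <- function(bundle) {
  viol <- list()
  add <- function(id, problem)
    viol[[length(viol) + 1L]] <<- data.frame(id = as.character(id),
                                             problem = problem)
  loci <- bundle$loci
  probes <- bundle$probes

  missing <- setdiff(.LOCI_COLS, names(loci))
  if (length(missing))
    add("loci", paste("missing columns:", paste(missing, collapse = ", ")))
  missing <- setdiff(.PROBE_COLS, names(probes))
  if (length(missing))
    add("probes", paste("missing columns:", paste(missing, collapse = ", ")))
  if (length(viol)) return(do.call(rbind, viol))

  is_dna <- function(s) grepl("^[ACGT]+$", s)
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    if (nchar(l$motif) < 1L || nchar(l$motif) > 6L || !is_dna(l$motif))
      add(l$str_name, sprintf("motif '%s' must be 1-6 bases over ACGT", l$motif))
    for (fl in c("flank5", "flank3")) {
      if (nchar(l[[fl]]) != 15L || !is_dna(l[[fl]]))
        add(l$str_name, sprintf("%s must be exactly 15 bases over ACGT (got %d)",
                                fl, nchar(l[[fl]])))
    }
    if (l$start > l$end)
      add(l$str_name, "tract start must be <= end")
    if (l$min_repeats < 1L)
      add(l$str_name, "min_repeats must be >= 1")
  }
  if (anyDuplicated(loci$str_name))
    add("loci", "duplicated str_name")
  if (anyDuplicated(probes$probe_id))
    add("probes", "duplicated probe_id")
  for (i in seq_len(nrow(probes))) {
    p <- probes[i, ]
    if (nchar(p$probe_seq) != 40L || !is_dna(p$probe_seq))
      add(p$probe_id, "probe_seq must be exactly 40 bases over ACGT")
    if (!p$strand %in% c("+", "-"))
      add(p$probe_id, sprintf("strand '%s' not in {+, -}", p$strand))
    if (!p$str_name %in% loci$str_name)
      add(p$probe_id, sprintf("probe references unknown STR '%s'", p$str_name))
  }
  orphans <- setdiff(loci$str_name, probes$str_name)
  for (o in orphans) add(o, "locus has no probe")

  for (bed in c("flank5", "flank3", "nostr")) {
    b <- bundle[[bed]]
    if (is.null(b) || !all(.BED_COLS %in% names(b))) {
      add(bed, "interval set missing or lacking chrom/start/end/name")
      next
    }
    if (bed != "nostr") {
      unknown <- setdiff(unique(b$name), loci$str_name)
      if (length(unknown))
        add(bed, paste("interval names not in locus table:",
                       paste(unknown, collapse = ", ")))
    }
    # per-locus self-overlap check
    for (nm in unique(b$name)) {
      bb <- b[b$name == nm, , drop = FALSE]
      if (nrow(bb) > 1L) {
        ir <- IRanges::IRanges(bb$start, bb$end)
        if (!isTRUE(all(IRanges::countOverlaps(ir, ir) == 1L)))
          add(nm, sprintf("%s intervals self-overlap", bed))
      }
    }
  }
  cs <- bundle$cut_sites
  if (!is.null(cs)) {
    if (!all(.CUT_COLS %in% names(cs))) {
      add("cut_sites", "missing chrom/str_name/cut_pos/side columns")
    } else {
      for (i in seq_len(nrow(cs))) {
        if (!cs$side[i] %in% c("upstream", "downstream"))
          add(cs$str_name[i], sprintf("cut side '%s' not in {upstream, downstream}",
                                      cs$side[i]))
        if (!cs$str_name[i] %in% loci$str_name)
          add(cs$str_name[i], "cut site references unknown STR")
      }
    }
  }
  if (length(viol) == 0L)
    data.frame(id = character(0), problem = character(0))
  else
    do.call(rbind, viol)
}

.read_tsv <- function(path, required, what) {
  if (!file.exists(path)) stop("missing required panel file: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(sprintf("%s (%s) lacks required columns: %s", what, path,
                 paste(missing, collapse = ", ")))
  extra <- setdiff(names(x), required)
  if (length(extra))
    warning(sprintf("%s: ignoring unknown columns: %s", what,
                    paste(extra, collapse = ", ")), call. = FALSE)
  x[required]
}

.read_bed4 <- function(path) {
  if (!file.exists(path)) stop("missing required panel file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             name = gr$name, stringsAsFactors = FALSE)
}

.write_bed4 <- function(df, path) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               name = df$name)
  rtracklayer::export(gr, path, format = "BED")
}

#' Load a panel bundle from its five metadata files
#'
#' @param dir directory holding `str_probes.txt`, `str_info.txt`,
#'   `5prflank.bed`, `3prflank.bed`, `noSTR_plus5b.bed` and (optionally)
#'   `cut_sites.txt`. Individual paths may be overridden.
#' @param probes_file,info_file,flank5_file,flank3_file,nostr_file,cut_file
#'   file paths; defaults are the canonical names under `dir`.
#' @return An `str_panel` (see [str_panel()]). A missing required file is
#'   fatal; a probe referencing an unknown STR, or a malformed flank, is
#'   fatal with the offending identifier in the message. Unknown columns
#'   are ignored with a warning.
#' @export
load_panel_bundle <- function(dir = ".",
                              probes_file = file.path(dir, "str_probes.txt"),
                              info_file   = file.path(dir, "str_info.txt"),
                              flank5_file = file.path(dir, "5prflank.bed"),
                              flank3_file = file.path(dir, "3prflank.bed"),
                              nostr_file  = file.path(dir, "noSTR_plus5b.bed"),
                              cut_file    = file.path(dir, "cut_sites.txt")) {
  loci   <- .read_tsv(info_file, .LOCI_COLS, "str_info")
  probes <- .read_tsv(probes_file, .PROBE_COLS, "str_probes")
  cuts <- if (file.exists(cut_file))
    .read_tsv(cut_file, .CUT_COLS, "cut_sites") else NULL
  str_panel(loci, probes,
            flank5 = .read_bed4(flank5_file),
            flank3 = .read_bed4(flank3_file),
            nostr  = .read_bed4(nostr_file),
            cut_sites = cuts)
}

#' Write a panel bundle to its canonical file set
#'
#' Inverse of [load_panel_bundle()]: writes `str_probes.txt`,
#' `str_info.txt`, the three BED files, and `cut_sites.txt` when cut sites
#' are present. `load_panel_bundle(write_panel_bundle(p, d))` reproduces
#' `p` exactly.
#'
#' @param panel an `str_panel`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel_bundle <- function(panel, dir) {
  stopifnot(inherits(panel, "str_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wr(panel$loci, "str_info.txt")
  wr(panel$probes, "str_probes.txt")
  .write_bed4(panel$flank5, file.path(dir, "5prflank.bed"))
  .write_bed4(panel$flank3, file.path(dir, "3prflank.bed"))
  .write_bed4(panel$nostr, file.path(dir, "noSTR_plus5b.bed"))
  if (!is.null(panel$cut_sites)) wr(panel$cut_sites, "cut_sites.txt")
  invisible(dir)
}

#' Reference tract length of each locus in base pairs
#' @param panel an `str_panel`.
#' @return named integer vector (by `str_name`).
#' @export
ref_tract_lengths <- function(panel) {
  setNames(panel$loci$end - panel$loci$start + 1L, panel$loci$str_name)
}
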