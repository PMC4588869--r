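#' Read a BED file of genomic intervals
#'
#' Accepts 3-6 column BED (0-based, half-open). Every line is validated
#' before parsing — a malformed line (too few fields, non-numeric or
#' inverted coordinates, or a zero-length `start == end` record, which
#' usually signals 1-based input) raises an error naming the line number.
#' Unsorted input is sorted on read with a notice. Parsing itself is
#' delegated to `rtracklayer`.
#'
#' @param path BED file path.
#' @return A `GRanges`; `name`, `score`, `strand` preserved when present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("%s line %d: expected >= 3 tab-separated fields", path, i))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("%s line %d: non-numeric coordinates", path, i))
    if (e == s)
      stop(sprintf(paste0("%s line %d: start == end (zero-length record; ",
                          "BED is 0-based half-open — is this 1-based input?)"),
                   path, i))
    if (e < s)
      stop(sprintf("%s line %d: end < start", path, i))
  }
  gr <- rtracklayer::import(path, format = "BED")
  ord <- order(as.factor(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr))
  if (is.unsorted(ord)) {
    message("unsorted BED input sorted on read: ", path)
    gr <- gr[ord]
  }
  gr
}

#' Write genomic intervals as BED
#'
#' Writes via `rtracklayer` in the 0-based half-open BED convention;
#' `name`, `score` and strand columns are emitted when present, so a
#' canonical 6-column record round-trips through [read_bed()] unchanged.
#'
#' @param regions A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(methods::is(regions, "GRanges"))
  rtracklayer::export(regions, path, format = "BED")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (one set per line: name, description, gene ids).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a table with a units header
#'
#' All user-facing tables carry a leading `# units:` comment so a table can
#' never be read without its units; [read_units_tsv()] checks it. Methylation
#' is written in percent (the internal representation is a proportion).
#'
#' @param df Data frame.
#' @param path Output path.
#' @param units Units string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_units_tsv <- function(df, path, units) {
  stopifnot(is.character(units), length(units) == 1, nzchar(units))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_units_tsv()]
#'
#' @param path Input path.
#' @return Data frame with the units string as attribute `units`.
#' @export
read_units_tsv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# units: ", first))
    stop(path, ": missing '# units:' header")
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "units") <- sub("^# units: ", "", first)
  df
}

#' Read a probe log2-ratio table
#'
#' TSV with BED-style coordinates (`chrom`, `start`, `end`, 0-based
#' half-open), a `probe_id` column, and one or more sample columns of log2
#' enrichment ratios.
#'
#' @param path TSV path.
#' @param sample_cols Names of the sample columns; defaults to every column
#'   after the coordinates.
#' @return List with `probes` (coordinate data frame) and `log2_ratio`
#'   (probes x samples matrix).
#' @export
read_probe_table <- function(path, sample_cols = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("probe table needs columns: ", paste(need, collapse = ", "))
  if (any(df$end <= df$start)) stop("probe table: end must exceed start")
  if (is.null(sample_cols)) sample_cols <- setdiff(names(df), need)
  if (length(sample_cols) == 0) stop("no sample columns found")
  mat <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!all(is.finite(mat))) stop("non-finite log2 ratios")
  rownames(mat) <- df$probe_id
  list(probes = df[, need], log2_ratio = mat)
}

#' Write an array cohort to disk
#'
#' Emits the methylation matrix as TSV (percent, samples in columns), the
#' windows as 6-column BED, the group assignment table, and a JSON sidecar
#' with the seed and full simulation configuration.
#'
#' @param cohort An `array_cohort`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_array_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "array_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meth <- data.frame(window_id = rownames(cohort$methylation),
                     round(100 * cohort$methylation, 6),
                     check.names = FALSE)
  write_units_tsv(meth, file.path(dir, "methylation.tsv"),
                  "percent methylation per 100-nt window")
  gr <- cohort$regions
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(gr)$window_id,
    score = as.integer(cohort$true_dmr_mask))
  write_bed(gr, file.path(dir, "regions.bed"))
  write_units_tsv(
    data.frame(sample = names(cohort$group_labels),
               group = unname(cohort$group_labels)),
    file.path(dir, "groups.tsv"), "ordinal group (1 = lowest phenotype)")
  jsonlite::write_json(
    list(seed = cohort$config$seed, config = unclass(cohort$config),
         clamped_fraction = cohort$clamped_fraction),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a validation cohort to disk
#'
#' One row per subject: CpG percentages, outcome, covariates; a JSON
#' sidecar records the seed and the planted truth.
#'
#' @param cohort A `validation_cohort`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_validation_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "validation_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(subject = rownames(cohort$cpg_methylation),
                    cohort$cpg_methylation,
                    outcome = unname(cohort$outcome),
                    cohort$covariates, check.names = FALSE)
  write_units_tsv(tab, file.path(dir, "subjects.tsv"),
                  "CpG columns percent methylation; outcome in test units")
  jsonlite::write_json(
    list(seed = cohort$config$seed, truth = cohort$truth),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
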