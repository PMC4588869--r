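#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the simulation parameters (or
#' paths to user-supplied inputs), the screen thresholds, the covariate
#' tiers, the seed, and the output directory. Can also be loaded from a
#' YAML file whose top-level keys mirror the arguments (scalar simulation
#' parameters under a `simulation:` block).
#'
#' @param outdir Output directory (created if absent).
#' @param seed Integer seed governing every random draw of the run.
#' @param simulation A [simulation_config()]; its own seed is overridden by
#'   `seed`.
#' @param thresholds A [dmr_thresholds()].
#' @param genesets Optional path to a GMT file for the gene-set stage; when
#'   `NULL`, the stage is skipped with a warning.
#' @param tiers Covariate tiers for the association stage.
#' @param probes,cpg_map,rois Optional paths (probe TSV, CpG BED, ROI BED)
#'   replacing the simulated array inputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("dmrscreen_run_"),
                            seed = 1L,
                            simulation = simulation_config(),
                            thresholds = dmr_thresholds(),
                            genesets = NULL,
                            tiers = c("sex", "sex_maternal"),
                            probes = NULL, cpg_map = NULL, rois = NULL) {
  simulation$seed <- as.integer(seed)
  validate_simulation_config(simulation)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulation = simulation, thresholds = thresholds,
                 genesets = genesets, tiers = tiers,
                 probes = probes, cpg_map = cpg_map, rois = rois),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [pipeline_config()] arguments, with
#'   simulation parameters under `simulation:` and thresholds under
#'   `thresholds:`.
#' @param outdir,seed Optional overrides of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  sim <- do.call(simulation_config, as.list(y$simulation %||% list()))
  th <- do.call(dmr_thresholds, as.list(y$thresholds %||% list()))
  pipeline_config(
    outdir = outdir %||% y$outdir %||% tempfile("dmrscreen_run_"),
    seed = as.integer(seed %||% y$seed %||% 1L),
    simulation = sim, thresholds = th,
    genesets = y$genesets, tiers = y$tiers %||% c("sex", "sex_maternal"),
    probes = y$probes, cpg_map = y$cpg_map, rois = y$rois)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full screen-to-association pipeline
#'
#' Executes estimate -> screen -> enrich -> associate on simulated (or
#' supplied) inputs and writes one TSV per stage plus a JSON run manifest
#' with the seed, package version, configuration and the MD5 checksum of
#' every output. A rerun with the same configuration and seed is
#' bitwise-identical. Stage failures abort with the stage name.
#'
#' @param config A [pipeline_config()] or a YAML path for
#'   [read_pipeline_config()].
#' @param stages Subset of stages to run (dependencies are always run
#'   first; `associate` is independent of the array stages).
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config,
                         stages = c("estimate", "screen", "enrich",
                                    "associate")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage_wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## inputs: simulate unless user paths are given
  scfg <- config$simulation
  use_sim <- is.null(config$probes)
  stage_wrap("simulate", {
    cohort <- simulate_array_cohort(scfg)
    if (use_sim) {
      cpgs <- simulate_cpg_map(cohort)
      signals <- simulate_probe_signals(cohort, cpgs)
      rois <- cohort_rois(cohort)
    } else {
      pt <- read_probe_table(config$probes)
      cpgs <- read_bed(config$cpg_map)
      rois_gr <- read_bed(config$rois)
      S4Vectors::mcols(rois_gr)$gene_id <- S4Vectors::mcols(rois_gr)$name
      rois <- rois_gr
      mass <- vapply(seq_len(nrow(pt$probes)), function(i)
        compute_coupling(pt$probes$start[i], pt$probes$end[i],
                         GenomicRanges::start(cpgs) - 1L)$mass, numeric(1))
      pt$probes$coupled_mass <- mass
      signals <- structure(list(probes = pt$probes,
                                log2_ratio = pt$log2_ratio,
                                link = probe_link()),
                           class = "probe_signals")
    }
    windows <- cohort$regions
    design <- group_design(names(cohort$group_labels),
                           cohort$group_labels)
  })

  est <- NULL
  if ("estimate" %in% stages ||
      any(c("screen", "enrich") %in% stages)) {
    stage_wrap("estimate", {
      est <- estimate_cohort_methylation(signals, windows,
                                         noise_sd = scfg$probe_noise_sd)
      meth_tab <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(windows)),
        start = GenomicRanges::start(windows) - 1L,
        end = GenomicRanges::end(windows),
        informative = est$informative,
        round(100 * est$methylation, 4),
        check.names = FALSE)
      f <- file.path(config$outdir, "region_methylation.tsv")
      write_units_tsv(meth_tab, f, "percent methylation per 100-nt window")
      outputs <- c(outputs, f)
    })
  }

  dmr <- NULL
  if (any(c("screen", "enrich") %in% stages)) {
    stage_wrap("screen", {
      dmr <- call_dmrs(est$methylation, design,
                       thresholds = config$thresholds,
                       informative = est$informative)
      tab <- as.data.frame(dmr)
      tab$chrom <- as.character(GenomicRanges::seqnames(windows))
      tab$start <- GenomicRanges::start(windows) - 1L
      tab$end <- GenomicRanges::end(windows)
      f <- file.path(config$outdir, "dmr_calls.tsv")
      write_units_tsv(
        tab, f, "methylation proportions; abs_diff proportion (0.2 = 20%)")
      outputs <- c(outputs, f)
    })
  }

  if ("enrich" %in% stages) {
    stage_wrap("enrich", {
      roi_tab <- call_dmrois(dmr, rois, windows, est$methylation, design)
      f <- file.path(config$outdir, "dmroi_calls.tsv")
      write_units_tsv(as.data.frame(roi_tab), f,
                      "counts and probabilities (unitless)")
      outputs <- c(outputs, f)
      if (is.null(config$genesets)) {
        warning("no gene-set file configured; gene-set stage skipped")
      } else {
        sets <- read_gmt(config$genesets)
        background <- unique(S4Vectors::mcols(rois)$gene_id)
        hits <- roi_tab$gene_id[roi_tab$is_dmroi]
        gs <- geneset_enrichment(hits, sets, background)
        f2 <- file.path(config$outdir, "geneset_enrichment.tsv")
        write_units_tsv(gs, f2, "counts and probabilities (unitless)")
        outputs <- c(outputs, f2)
      }
    })
  }

  if ("associate" %in% stages) {
    stage_wrap("associate", {
      vc <- simulate_validation_cohort(scfg)
      assoc <- associate_cohort(vc, tiers = config$tiers)
      f <- file.path(config$outdir, "associations.tsv")
      write_units_tsv(
        assoc, f, "beta = outcome units per SD methylation")
      outputs <- c(outputs, f)
    })
  }

  manifest <- list(
    tool = "dmrscreen",
    version = as.character(packageVersion("dmrscreen")),
    seed = config$seed,
    stages = stages,
    n_outputs = length(outputs),
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))),
    link = link_to_list(signals$link),
    thresholds = unclass(config$thresholds))
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
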