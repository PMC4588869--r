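#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohorts: the 24-sample array
#' screen across four ordinal phenotype groups, and the larger validation
#' cohort with correlated CpG percentages, covariates, and a planted
#' per-SD outcome effect.
#'
#' Defaults encode the study conditions the package's analyses assume:
#' 24 array samples in 4 ordinal groups of 6; planted monotone DMRs with a
#' 0.25 extreme-group methylation difference; a validation cohort of 175
#' subjects with 9 CpGs whose pairwise correlations span 0.31–0.85; and a
#' planted outcome effect of 3.2 outcome units per SD methylation.
#'
#' @param n_groups Number of ordinal phenotype groups.
#' @param group_sizes Samples per group, lowest phenotype first.
#' @param n_regions Number of 100-nt genomic windows on the synthetic array.
#' @param n_true_dmrs Number of windows with a planted group effect.
#' @param dmr_effect Methylation-proportion difference between the extreme
#'   groups at planted windows, in (0, 1).
#' @param monotone If `TRUE`, planted effects increase linearly across the
#'   ordinal groups (dose-response); otherwise only the extreme groups are
#'   shifted.
#' @param dmr_placement `"random"` scatters planted windows over the array;
#'   `"clustered"` packs them into consecutive windows of one promoter so the
#'   enrichment stage has a fully planted region of interest.
#' @param baseline_alpha,baseline_beta Shape parameters of the Beta baseline
#'   methylation distribution per region. The default Beta(2, 2) keeps
#'   baselines mid-range, where a +/-`dmr_effect`/2 shift stays inside
#'   `[0, 1]` (an enrichment array is biased to methylated CpG-rich regions,
#'   so extreme baselines are not the typical case).
#' @param noise_sd Per-sample methylation noise SD, proportion units.
#' @param probe_noise_sd SD of additive noise on probe log2 ratios.
#' @param cpgs_per_region Mean CpG count per 100-nt window (Poisson).
#' @param windows_per_roi Consecutive windows grouped into one synthetic
#'   promoter region of interest.
#' @param n_validation_subjects Validation cohort size.
#' @param n_cpgs CpGs assayed in the validation cohort.
#' @param cpg_corr_range Ordered pair: target min/max pairwise CpG
#'   correlation, reached through a one-factor Gaussian copula.
#' @param causal_cpg Index of the CpG that carries the planted outcome effect.
#' @param planted_beta Outcome units per SD of (normal-score transformed)
#'   methylation at the causal CpG.
#' @param covariate_effects Named numeric: coefficients for the `sex`
#'   indicator and the continuous `maternal` score in the outcome model.
#' @param confound_strength Correlation between the maternal score and the
#'   causal CpG's latent methylation; 0 gives an unconfounded design.
#' @param outcome_mean Outcome intercept (IQ-like scale).
#' @param outcome_noise_sd Residual SD of the outcome.
#' @param seed Integer RNG seed; all generators are deterministic given it.
#' @return A validated list of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_regions = 50, seed = 7)
#' cohort <- simulate_array_cohort(cfg)
#' dim(cohort$methylation)
#' @export
simulation_config <- function(n_groups = 4L,
                              group_sizes = c(6L, 6L, 6L, 6L),
                              n_regions = 500L,
                              n_true_dmrs = 10L,
                              dmr_effect = 0.25,
                              monotone = TRUE,
                              dmr_placement = c("random", "clustered"),
                              baseline_alpha = 2,
                              baseline_beta = 2,
                              noise_sd = 0.03,
                              probe_noise_sd = 0.1,
                              cpgs_per_region = 6,
                              windows_per_roi = 10L,
                              n_validation_subjects = 175L,
                              n_cpgs = 9L,
                              cpg_corr_range = c(0.31, 0.85),
                              causal_cpg = 2L,
                              planted_beta = 3.2,
                              covariate_effects = c(sex = 2, maternal = 0.25),
                              confound_strength = 0,
                              outcome_mean = 104,
                              outcome_noise_sd = 12.5,
                              seed = 1L) {
  cfg <- list(
    n_groups = as.integer(n_groups),
    group_sizes = as.integer(group_sizes),
    n_regions = as.integer(n_regions),
    n_true_dmrs = as.integer(n_true_dmrs),
    dmr_effect = dmr_effect,
    monotone = isTRUE(monotone),
    dmr_placement = match.arg(dmr_placement),
    baseline_alpha = baseline_alpha,
    baseline_beta = baseline_beta,
    noise_sd = noise_sd,
    probe_noise_sd = probe_noise_sd,
    cpgs_per_region = cpgs_per_region,
    windows_per_roi = as.integer(windows_per_roi),
    n_validation_subjects = as.integer(n_validation_subjects),
    n_cpgs = as.integer(n_cpgs),
    cpg_corr_range = as.numeric(cpg_corr_range),
    causal_cpg = as.integer(causal_cpg),
    planted_beta = planted_beta,
    covariate_effects = covariate_effects,
    confound_strength = confound_strength,
    outcome_mean = outcome_mean,
    outcome_noise_sd = outcome_noise_sd,
    seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (length(cfg$group_sizes) != cfg$n_groups)
    stop("group_sizes must have one entry per group")
  if (any(cfg$group_sizes < 1) || cfg$n_groups < 2)
    stop("all counts must be positive and n_groups >= 2")
  if (!(cfg$dmr_effect > 0 && cfg$dmr_effect < 1))
    stop("dmr_effect must lie in (0, 1)")
  if (cfg$n_regions < 1 || cfg$n_true_dmrs < 0 ||
      cfg$n_true_dmrs > cfg$n_regions)
    stop("n_true_dmrs must lie in [0, n_regions]")
  rng <- cfg$cpg_corr_range
  if (length(rng) != 2 || any(abs(rng) >= 1) || rng[1] > rng[2] ||
      rng[1] <= 0)
    stop("cpg_corr_range must be an ordered pair inside (0, 1)")
  if (cfg$n_cpgs < 2 || cfg$n_validation_subjects < 10)
    stop("validation cohort too small")
  if (cfg$causal_cpg < 1 || cfg$causal_cpg > cfg$n_cpgs)
    stop("causal_cpg out of range")
  stopifnot(cfg$noise_sd >= 0, cfg$probe_noise_sd >= 0,
            cfg$baseline_alpha > 0, cfg$baseline_beta > 0,
            cfg$outcome_noise_sd >= 0, cfg$windows_per_roi >= 1)
  invisible(cfg)
}

#' Simulate an array-stage cohort with planted DMRs
#'
#' Draws a per-region baseline methylation level from
#' `Beta(baseline_alpha, baseline_beta)`, adds per-sample Gaussian noise, and
#' at `n_true_dmrs` planted windows shifts the group means so the extreme
#' ordinal groups differ by exactly `dmr_effect` (centred on the baseline;
#' linear across groups when `monotone`). The shift direction
#' (hyper/hypomethylation in the high-phenotype group) is random per window.
#' Values are clamped to `[0, 1]` and the clamped fraction is reported;
#' configurations whose effect placement clamps more than 10% of draws are
#' rejected as unusable.
#'
#' @param config A [simulation_config()].
#' @return An object of class `array_cohort`: list with `methylation`
#'   (regions x samples matrix of proportions), `group_labels` (ordinal group
#'   per sample), `true_dmr_mask`, `regions` (a `GRanges` of non-overlapping
#'   100-nt windows with a `roi` gene id), `clamped_fraction`, and `config`.
#' @export
simulate_array_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  G <- config$n_groups
  n_samples <- sum(config$group_sizes)
  groups <- rep(seq_len(G), config$group_sizes)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  R <- config$n_regions

  baseline <- rbeta(R, config$baseline_alpha, config$baseline_beta)
  mask <- rep(FALSE, R)
  if (config$n_true_dmrs > 0) {
    if (config$dmr_placement == "clustered") {
      # pack planted windows into consecutive positions of one promoter
      w <- config$windows_per_roi
      n_rois <- max(1L, R %/% w)
      roi0 <- sample.int(n_rois, 1L)
      first <- (roi0 - 1L) * w + 1L
      idx <- first:min(first + config$n_true_dmrs - 1L, R)
      if (length(idx) < config$n_true_dmrs)
        stop("clustered placement needs n_true_dmrs <= windows_per_roi")
    } else {
      idx <- sample.int(R, config$n_true_dmrs)
    }
    mask[idx] <- TRUE
  }

  # centred group offsets: extreme-group difference equals dmr_effect
  if (config$monotone) {
    offs <- config$dmr_effect * ((seq_len(G) - 1) / (G - 1) - 0.5)
  } else {
    offs <- c(-config$dmr_effect / 2, rep(0, G - 2), config$dmr_effect / 2)
  }
  direction <- sample(c(-1, 1), R, replace = TRUE)

  mu <- matrix(baseline, nrow = R, ncol = n_samples)
  if (any(mask))
    mu[mask, ] <- mu[mask, , drop = FALSE] +
      direction[mask] %o% offs[groups]
  meth <- mu + matrix(rnorm(R * n_samples, sd = config$noise_sd),
                      nrow = R)
  clamped <- mean(meth < 0 | meth > 1)
  if (clamped > 0.10)
    stop(sprintf(
      "effect placement leaves [0,1] for %.1f%% of draws (> 10%%); ",
      100 * clamped),
      "adjust baseline_alpha/beta or dmr_effect")
  meth <- pmin(pmax(meth, 0), 1)
  dimnames(meth) <- list(sprintf("w%05d", seq_len(R)), sample_ids)

  starts <- 1000L + (seq_len(R) - 1L) * 100L
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = starts + 1L, width = 100L),
    window_id = rownames(meth),
    roi = sprintf("gene%04d", (seq_len(R) - 1L) %/% config$windows_per_roi + 1L))

  structure(list(methylation = meth,
                 group_labels = setNames(groups, sample_ids),
                 true_dmr_mask = setNames(mask, rownames(meth)),
                 regions = regions,
                 clamped_fraction = clamped,
                 config = config),
            class = "array_cohort")
}

#' @export
print.array_cohort <- function(x, ...) {
  cat(sprintf(
    "<array_cohort> %d regions x %d samples, %d groups, %d planted DMRs (%.2f%% clamped)\n",
    nrow(x$methylation), ncol(x$methylation),
    x$config$n_groups, sum(x$true_dmr_mask), 100 * x$clamped_fraction))
  invisible(x)
}

#' Simulate a CpG coordinate map for an array cohort
#'
#' CpG counts per 100-nt window are Poisson with mean `cpgs_per_region`;
#' positions are uniform within the window. A window may receive zero CpGs,
#' which downstream stages must flag as uninformative.
#'
#' @param cohort An `array_cohort`.
#' @param seed Optional seed; defaults to the cohort's seed offset by 1.
#' @return A `GRanges` of single-base CpG positions (0-based internally,
#'   1-based in the `GRanges`).
#' @export
simulate_cpg_map <- function(cohort, seed = NULL) {
  stopifnot(inherits(cohort, "array_cohort"))
  set.seed(if (is.null(seed)) cohort$config$seed + 1L else seed)
  counts <- rpois(length(cohort$regions), cohort$config$cpgs_per_region)
  starts <- GenomicRanges::start(cohort$regions)
  pos <- unlist(mapply(function(s, k) {
    if (k == 0) integer(0) else sort(s + sample.int(100L, k) - 1L)
  }, starts, counts, SIMPLIFY = FALSE))
  GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = as.integer(pos), width = 1L))
}

#' Forward-simulate probe log2 enrichment ratios
#'
#' One 60-mer probe is placed centrally in each 100-nt window. The expected
#' log2 ratio is the saturating [probe_link()] of (methylation x coupled
#' CpG mass), with the coupling mass computed from the CpG map by
#' [compute_coupling()]; Gaussian noise with SD `probe_noise_sd` is added.
#' Probes with zero coupled CpG mass are emitted but flagged uninformative —
#' their signal carries no methylation information.
#'
#' @param cohort An `array_cohort`.
#' @param cpg_map `GRanges` of CpG positions covering the cohort regions.
#' @param config A [simulation_config()]; defaults to the cohort's.
#' @param link A [probe_link()]; the exact link used is recorded in the
#'   output so the estimation stage can be tested against it.
#' @return An object of class `probe_signals`: list with `probes` (data frame
#'   of probe coordinates, window id, coupled mass, informative flag),
#'   `log2_ratio` (probes x samples matrix), and `link`.
#' @export
simulate_probe_signals <- function(cohort, cpg_map,
                                   config = cohort$config,
                                   link = probe_link()) {
  stopifnot(inherits(cohort, "array_cohort"))
  set.seed(config$seed + 2L)
  win_start <- GenomicRanges::start(cohort$regions) - 1L  # back to 0-based
  probe_start <- win_start + 20L
  probe_end <- probe_start + 60L
  cpg_pos <- GenomicRanges::start(cpg_map) - 1L
  mass <- vapply(seq_along(probe_start), function(i)
    compute_coupling(probe_start[i], probe_end[i], cpg_pos)$mass,
    numeric(1))

  mu <- link_eval(link, cohort$methylation * mass)   # recycles mass by row
  noise <- matrix(rnorm(length(mu), sd = config$probe_noise_sd),
                  nrow = nrow(mu))
  ratios <- mu + noise
  dimnames(ratios) <- dimnames(cohort$methylation)

  probes <- data.frame(
    probe_id = sprintf("p%05d", seq_along(probe_start)),
    chrom = "chr1",
    start = probe_start,
    end = probe_end,
    window_id = rownames(cohort$methylation),
    coupled_mass = mass,
    informative = mass > 0,
    stringsAsFactors = FALSE)

  structure(list(probes = probes, log2_ratio = ratios, link = link),
            class = "probe_signals")
}

#' Simulate a validation cohort with a planted per-SD outcome effect
#'
#' CpG percentages come from a one-factor Gaussian copula whose loadings are
#' geometrically spaced so pairwise latent correlations span
#' `cpg_corr_range`; marginals are skewed (Beta(2, 5) quantile transform,
#' scaled to percent) so the normal-score transform has real work to do. The
#' outcome is
#' `outcome_mean + planted_beta * z + covariate effects + noise`, where `z`
#' is the Fisher-Yates normal score of the causal CpG's realized
#' percentages — i.e. the planted effect is expressed per SD of transformed
#' methylation, matching how the association stage reports it. Setting
#' `confound_strength > 0` correlates the maternal score with the causal
#' CpG, creating classical confounding for sensitivity tests.
#'
#' @param config A [simulation_config()].
#' @return An object of class `validation_cohort`: list with
#'   `cpg_methylation` (subjects x CpGs, percent 0-100), `outcome`,
#'   `covariates` (data frame: sex, maternal, age, birthweight, smoking,
#'   bmi, parity), and `truth` (planted beta, causal CpG, covariate
#'   coefficients, copula loadings).
#' @export
simulate_validation_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed + 3L)
  n <- config$n_validation_subjects
  k <- config$n_cpgs
  lo <- config$cpg_corr_range[1]
  hi <- config$cpg_corr_range[2]

  # geometric loadings: product of the two smallest = lo, two largest = hi
  if (k > 2) {
    g <- (hi / lo)^(1 / (2 * k - 4))
    lam <- sqrt(lo / g) * g^(seq_len(k) - 1)
  } else {
    lam <- rep(sqrt(lo), k)
  }
  if (any(lam >= 1))
    stop("cpg_corr_range not achievable with a one-factor copula")

  f <- rnorm(n)
  z <- f %o% lam + matrix(rnorm(n * k), n, k) %*% diag(sqrt(1 - lam^2))
  pct <- 100 * stats::qbeta(pnorm(z), 2, 5)   # right-skewed marginals
  colnames(pct) <- sprintf("CpG%d", seq_len(k))
  rownames(pct) <- sprintf("subj%03d", seq_len(n))

  zc <- z[, config$causal_cpg]
  sex <- rbinom(n, 1, 0.5)
  cs <- config$confound_strength
  maternal <- 100 + 15 * (cs * zc + sqrt(1 - cs^2) * rnorm(n))
  covariates <- data.frame(
    sex = sex,
    maternal = maternal,
    age = rnorm(n, 4.4, 0.3),
    birthweight = rnorm(n, 3.5, 0.5),
    smoking = rbinom(n, 1, 0.2),
    bmi = rnorm(n, 24.5, 4),
    parity = rpois(n, 1),
    row.names = rownames(pct))

  score <- fisher_yates_scores(pct[, config$causal_cpg])$scores
  ce <- config$covariate_effects
  outcome <- config$outcome_mean +
    config$planted_beta * score +
    ce[["sex"]] * sex +
    ce[["maternal"]] * (maternal - 100) +
    rnorm(n, sd = config$outcome_noise_sd)

  structure(list(cpg_methylation = pct,
                 outcome = setNames(outcome, rownames(pct)),
                 covariates = covariates,
                 truth = list(planted_beta = config$planted_beta,
                              causal_cpg = config$causal_cpg,
                              covariate_effects = ce,
                              confound_strength = cs,
                              loadings = lam),
                 config = config),
            class = "validation_cohort")
}

#' @export
print.validation_cohort <- function(x, ...) {
  cat(sprintf(
    "<validation_cohort> %d subjects x %d CpGs, planted beta = %.3g per SD (CpG%d)\n",
    nrow(x$cpg_methylation), ncol(x$cpg_methylation),
    x$truth$planted_beta, x$truth$causal_cpg))
  invisible(x)
}

#' Promoter regions of interest for a synthetic cohort
#'
#' Groups each cohort's consecutive windows into the promoter they were
#' simulated under and returns strand-aware ROI spans with a nominal TSS at
#' 5.5 kb into the span (the design places promoters from -5.5 kb to +2.5 kb
#' of the TSS; the synthetic spans are shorter but keep the TSS interior).
#'
#' @param cohort An `array_cohort`.
#' @return A `GRanges` of ROIs with `gene_id` and `tss` metadata columns.
#' @export
cohort_rois <- function(cohort) {
  stopifnot(inherits(cohort, "array_cohort"))
  regions <- cohort$regions
  roi_ids <- S4Vectors::mcols(regions)$roi
  sp <- split(seq_along(regions), roi_ids)
  starts <- vapply(sp, function(i) min(GenomicRanges::start(regions[i])),
                   numeric(1))
  ends <- vapply(sp, function(i) max(GenomicRanges::end(regions[i])),
                 numeric(1))
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = starts, end = ends), strand = "+",
    gene_id = names(sp))
  S4Vectors::mcols(gr)$tss <- GenomicRanges::start(gr)
  sort(gr)
}
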