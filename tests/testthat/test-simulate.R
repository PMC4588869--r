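test_that("config validation rejects inconsistent designs", {
  expect_error(simulation_config(group_sizes = c(6, 6, 6)), "one entry")
  expect_error(simulation_config(dmr_effect = 1.2), "dmr_effect")
  expect_error(simulation_config(cpg_corr_range = c(0.9, 0.3)), "ordered")
  expect_error(simulation_config(n_true_dmrs = 600, n_regions = 500),
               "n_true_dmrs")
  expect_error(simulation_config(causal_cpg = 12), "causal_cpg")
})

test_that("array cohorts are deterministic given the seed", {
  cfg <- simulation_config(n_regions = 80, seed = 7)
  c1 <- simulate_array_cohort(cfg)
  c2 <- simulate_array_cohort(cfg)
  expect_identical(c1$methylation, c2$methylation)
  expect_identical(c1$true_dmr_mask, c2$true_dmr_mask)
  s1 <- simulate_probe_signals(c1, simulate_cpg_map(c1))
  s2 <- simulate_probe_signals(c2, simulate_cpg_map(c2))
  expect_identical(s1$log2_ratio, s2$log2_ratio)
  v1 <- simulate_validation_cohort(cfg)
  v2 <- simulate_validation_cohort(cfg)
  expect_identical(v1$cpg_methylation, v2$cpg_methylation)
  expect_identical(v1$outcome, v2$outcome)
})

test_that("null cohorts have no planted structure and are calibrated", {
  cfg <- simulation_config(n_regions = 1500, n_true_dmrs = 0, seed = 3)
  co <- simulate_array_cohort(cfg)
  expect_false(any(co$true_dmr_mask))
  g <- co$group_labels
  diff14 <- rowMeans(co$methylation[, g == 4]) -
    rowMeans(co$methylation[, g == 1])
  se <- sd(diff14) / sqrt(length(diff14))
  expect_lt(abs(mean(diff14)), 3 * se)
})

test_that("planted monotone effects hit the extreme-group difference", {
  # concentrated mid-range baseline + zero noise: no clamping, exact shift
  cfg <- simulation_config(n_regions = 60, n_true_dmrs = 10,
                           baseline_alpha = 80, baseline_beta = 80,
                           noise_sd = 0, seed = 11)
  co <- simulate_array_cohort(cfg)
  expect_equal(co$clamped_fraction, 0)
  g <- co$group_labels
  diff14 <- abs(rowMeans(co$methylation[, g == 4]) -
                  rowMeans(co$methylation[, g == 1]))
  expect_equal(unname(diff14[co$true_dmr_mask]),
               rep(cfg$dmr_effect, 10), tolerance = 1e-12)
  expect_equal(unname(diff14[!co$true_dmr_mask]),
               rep(0, sum(!co$true_dmr_mask)), tolerance = 1e-12)
  # monotone dose-response: group means ordered along the planted direction
  for (r in which(co$true_dmr_mask)) {
    gm <- vapply(1:4, function(k) mean(co$methylation[r, g == k]),
                 numeric(1))
    expect_true(all(diff(gm) > 0) || all(diff(gm) < 0))
  }
})

test_that("unusable effect placement is rejected via the clamping rule", {
  cfg <- simulation_config(n_regions = 300, baseline_alpha = 0.1,
                           baseline_beta = 0.1, noise_sd = 0.4, seed = 2)
  expect_error(simulate_array_cohort(cfg), "10%")
})

test_that("probe signals follow the recorded monotone link", {
  cfg <- simulation_config(n_regions = 40, n_true_dmrs = 0,
                           probe_noise_sd = 0, seed = 5)
  co <- simulate_array_cohort(cfg)
  cpgs <- simulate_cpg_map(co)
  sig <- simulate_probe_signals(co, cpgs)

  # zero methylation, zero noise: every ratio sits at the link floor
  co0 <- co
  co0$methylation[] <- 0
  sig0 <- simulate_probe_signals(co0, cpgs)
  expect_equal(unname(sig0$log2_ratio[, 1]),
               rep(sig0$link$floor, nrow(sig0$log2_ratio)),
               tolerance = 1e-12)

  # equal methylation, more coupled CpGs -> strictly larger ratio
  expect_gt(link_eval(sig$link, 0.5 * 8), link_eval(sig$link, 0.5 * 2))

  # analytic inversion recovers methylation exactly at zero noise
  mass <- sig$probes$coupled_mass
  ok <- sig$probes$informative
  rec <- link_invert(sig$link, sig$log2_ratio[ok, ]) / mass[ok]
  expect_lt(max(abs(rec - co$methylation[ok, ])), 1e-9)

  # zero-CpG probes are flagged uninformative
  expect_identical(sig$probes$informative, mass > 0)
})

test_that("validation cohorts span the requested CpG correlation range", {
  cfg <- simulation_config(n_validation_subjects = 200, seed = 17)
  vc <- simulate_validation_cohort(cfg)
  cors <- cor(vc$cpg_methylation)
  off <- cors[upper.tri(cors)]
  expect_lt(abs(min(off) - 0.31), 0.15)
  expect_lt(abs(max(off) - 0.85), 0.15)
  # skewed marginals: the normal-score transform has work to do
  skew <- apply(vc$cpg_methylation, 2, function(x)
    mean(((x - mean(x)) / sd(x))^3))
  expect_true(all(skew > 0.2))
  expect_true(all(apply(vc$cpg_methylation, 2, var) > 0))
})

test_that("a null planted effect gives a centred estimate over seeds", {
  betas <- vapply(1:120, function(s) {
    vc <- simulate_validation_cohort(
      simulation_config(planted_beta = 0, seed = s))
    sc <- fisher_yates_scores(vc$cpg_methylation[, vc$truth$causal_cpg])
    fit_association(vc$outcome, sc, vc$covariates, tier = "sex")$beta
  }, numeric(1))
  expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(length(betas)))
})

test_that("cohort writers emit units headers and seed sidecars", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_regions = 30, seed = 9)
  co <- simulate_array_cohort(cfg)
  write_array_cohort(co, dir)
  meth <- read_units_tsv(file.path(dir, "methylation.tsv"))
  expect_match(attr(meth, "units"), "percent")
  expect_equal(as.matrix(meth[, -1]) / 100, unname(co$methylation),
               tolerance = 1e-6, ignore_attr = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$seed, 9)
  vdir <- withr::local_tempdir()
  write_validation_cohort(simulate_validation_cohort(cfg), vdir)
  expect_true(file.exists(file.path(vdir, "subjects.tsv")))
  vmeta <- jsonlite::read_json(file.path(vdir, "metadata.json"))
  expect_equal(vmeta$truth$planted_beta, 3.2)
})
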