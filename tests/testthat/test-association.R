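test_that("normal scores satisfy the mean-0 / SD-1 contract, with ties", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:80, 1)
    x <- if (i %% 2 == 0) rnorm(n) else sample(round(rnorm(n), 1))
    sc <- fisher_yates_scores(x)
    expect_lt(abs(mean(sc$scores)), 1e-12)
    expect_lt(abs(sd(sc$scores) - 1), 1e-12)
    # rank monotone: identical order as the input (strict when untied)
    expect_equal(rank(sc$scores, ties.method = "average"),
                 rank(x, ties.method = "average"))
  }
})

test_that("normal scores: symmetry, missing values, degenerate input", {
  expect_equal(fisher_yates_scores(c(3, 1, 10))$scores[1], 0)
  x <- c(2, NA, 5, 1, 9)
  sc <- fisher_yates_scores(x)
  expect_true(is.na(sc$scores[2]))
  expect_equal(sc$n, 4)
  expect_lt(abs(mean(sc$scores, na.rm = TRUE)), 1e-12)
  expect_error(fisher_yates_scores(rep(2, 10)), "identical")
  expect_error(fisher_yates_scores(c(1, 2)), "at least 3")
  # untied input: strictly increasing with the data
  y <- c(5, 1, 3, 2, 4)
  expect_equal(cor(fisher_yates_scores(y)$scores, y,
                   method = "spearman"), 1)
})

test_that("scores track expected normal order statistics (Monte-Carlo)", {
  set.seed(101)
  n <- 5
  draws <- matrix(rnorm(1e6), ncol = n)   # 2e5 samples of size 5
  eos <- colMeans(t(apply(draws, 1, sort)))     # E[Z_(i)], i = 1..5
  sc <- fisher_yates_scores(1:5)$scores
  # same shape up to the exact re-standardization: compare normalized
  expect_lt(max(abs(sc / sd(sc) * sd(eos) - eos)), 0.02)
})

test_that("association fits recover an exact linear signal", {
  set.seed(2)
  n <- 60
  cov <- data.frame(sex = rbinom(n, 1, 0.5), maternal = rnorm(n, 100, 15))
  sc <- fisher_yates_scores(rgamma(n, 2))
  out <- 5 + 2.5 * sc$scores
  r <- fit_association(out, sc, cov, tier = "sex")
  expect_equal(r$beta, 2.5, tolerance = 1e-9)
  expect_lt(r$p, 1e-12)
  expect_lt(r$ucl - r$lcl, 1e-6)
  expect_equal(r$n, n)
})

test_that("association errors: collinearity, missing tier, tiny n", {
  set.seed(3)
  n <- 40
  sc <- fisher_yates_scores(rnorm(n))
  cov <- data.frame(sex = rbinom(n, 1, 0.5))
  cov$maternal <- 3 * cov$sex            # exactly collinear
  expect_error(
    fit_association(rnorm(n), sc, cov, tier = "sex_maternal"),
    "collinear.*maternal")
  expect_error(
    fit_association(rnorm(n), sc, cov[, "sex", drop = FALSE],
                    tier = "sex_maternal"),
    "maternal")
  expect_error(
    fit_association(rnorm(5)[c(1:5, rep(NA, 35))], sc, cov, tier = "sex"),
    "complete cases")
})

test_that("listwise deletion yields the per-row n of sparse tables", {
  set.seed(8)
  n <- 50
  x <- rnorm(n); x[c(3, 9)] <- NA
  sc <- fisher_yates_scores(x)
  cov <- data.frame(sex = rbinom(n, 1, 0.5), maternal = rnorm(n))
  cov$maternal[5] <- NA
  out <- rnorm(n); out[10] <- NA
  r <- fit_association(out, sc, cov, tier = "sex_maternal")
  expect_equal(r$n, n - 4)
})

test_that("planted effects are recovered across an effect grid", {
  for (b in c(0, 2, 3.2)) {
    betas <- vapply(1:60, function(s) {
      vc <- simulate_validation_cohort(
        simulation_config(planted_beta = b, seed = 1000 + s))
      sc <- fisher_yates_scores(vc$cpg_methylation[, vc$truth$causal_cpg])
      fit_association(vc$outcome, sc, vc$covariates,
                      tier = "sex_maternal")$beta
    }, numeric(1))
    se <- sd(betas) / sqrt(length(betas))
    expect_lt(abs(mean(betas) - b), 4 * se,
              label = sprintf("bias at beta=%g", b))
  }
})

test_that("adjusting for a true confounder moves the estimate down", {
  # maternal score correlated with both the causal CpG and the outcome:
  # the sex-only model inflates beta, the adjusted model reduces it
  deltas <- vapply(1:40, function(s) {
    vc <- simulate_validation_cohort(
      simulation_config(confound_strength = 0.6,
                        covariate_effects = c(sex = 2, maternal = 0.4),
                        seed = 500 + s))
    sc <- fisher_yates_scores(vc$cpg_methylation[, vc$truth$causal_cpg])
    un <- fit_association(vc$outcome, sc, vc$covariates, tier = "sex")$beta
    ad <- fit_association(vc$outcome, sc, vc$covariates,
                          tier = "sex_maternal")$beta
    un - ad
  }, numeric(1))
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.8)
})

test_that("variance explained: perfect fit, null limit, nestedness", {
  set.seed(4)
  x <- rnorm(100)
  expect_equal(variance_explained(2 * x - 1, data.frame(x))$r_squared, 1)
  big <- data.frame(a = rnorm(10000), b = rnorm(10000))
  expect_lte(variance_explained(rnorm(10000), big)$r_squared, 0.02)
  y <- rnorm(100); z <- rnorm(100)
  r1 <- variance_explained(y, data.frame(x))$r_squared
  r2 <- variance_explained(y, data.frame(x, z))$r_squared
  expect_gte(r2, r1)
})

test_that("cohort association tables mirror the CpG x tier layout", {
  vc <- simulate_validation_cohort(simulation_config(seed = 77))
  tab <- associate_cohort(vc, tiers = c("sex", "sex_maternal", "extended"))
  expect_equal(nrow(tab), 9 * 3)
  expect_true(all(tab$lcl <= tab$beta & tab$beta <= tab$ucl))
  expect_true(all(tab$n <= 175))
  # the planted CpG should carry the smallest adjusted p
  adj <- tab[tab$covariate_tier == "sex_maternal", ]
  expect_equal(adj$cpg_id[which.min(adj$p)], "CpG2")
})
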