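#' Fisher-Yates normal scores
#'
#' Rank-based inverse-normal transformation: values are ranked (ties
#' averaged), mapped through the Blom approximation to expected normal
#' order statistics, `qnorm((rank - 3/8) / (n + 1/4))`, and then
#' location-scale standardized so the scores have mean 0 and SD 1 exactly
#' (the Blom scores alone only approximate unit variance, and tie averaging
#' perturbs it further). Missing values propagate as missing and do not
#' enter `n`.
#'
#' The transform is strictly rank-monotone on untied inputs, so a
#' regression slope on the scores is an effect per SD of transformed
#' methylation by construction.
#'
#' @param values Numeric vector with at least 3 finite values, not all
#'   identical.
#' @return An object of class `normal_scores`: list with `scores` (same
#'   length as input, NA where input was NA), `rank_map` (mid-ranks),
#'   `tie_policy` (`"average"`), and `n` (finite count).
#' @examples
#' fisher_yates_scores(c(3, 1, 10))$scores   # middle value maps to 0
#' @export
fisher_yates_scores <- function(values) {
  ok <- is.finite(values)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 finite values")
  x <- values[ok]
  if (max(x) == min(x))
    stop("all values identical: normal-score transform undefined")
  r <- rank(x, ties.method = "average")
  s <- qnorm((r - 3 / 8) / (n + 1 / 4))
  s <- (s - mean(s)) / sd(s)
  scores <- rep(NA_real_, length(values))
  scores[ok] <- s
  rank_map <- rep(NA_real_, length(values))
  rank_map[ok] <- r
  structure(list(scores = scores, rank_map = rank_map,
                 tie_policy = "average", n = n),
            class = "normal_scores")
}

#' @export
print.normal_scores <- function(x, ...) {
  cat(sprintf("<normal_scores> n = %d, ties %s\n", x$n,
              if (anyDuplicated(stats::na.omit(x$rank_map))) "averaged"
              else "none"))
  invisible(x)
}

tier_columns <- function(tier) {
  switch(tier,
         sex = "sex",
         sex_maternal = c("sex", "maternal"),
         extended = c("sex", "maternal", "age", "birthweight", "smoking",
                      "bmi", "parity"),
         stop("unknown covariate tier: ", tier))
}

#' Covariate-adjusted association of one CpG with one outcome
#'
#' Ordinary least squares of the outcome on the normal-score transformed
#' methylation of one CpG plus the covariates of the requested tier
#' (`sex`; `sex_maternal` adds the continuous maternal score;
#' `extended` further adds age at assessment, birthweight, maternal
#' smoking, BMI and parity). Complete cases only (listwise deletion), so
#' `n` varies with missingness. Because the predictor has SD 1, the
#' reported coefficient is the outcome change per SD methylation; the 95%
#' confidence limits and two-sided p come from the t distribution.
#'
#' @param outcome Numeric outcome per subject.
#' @param scores A [fisher_yates_scores()] object (or a numeric vector of
#'   transformed values).
#' @param covariates Data frame of covariates, rows aligned with `outcome`.
#' @param tier One of `"sex"`, `"sex_maternal"`, `"extended"`.
#' @param cpg_id,outcome_id Labels carried into the result row.
#' @return One-row data frame of class `association_result`: `cpg_id`,
#'   `outcome_id`, `covariate_tier`, `n`, `beta`, `lcl`, `ucl`, `p`.
#' @export
fit_association <- function(outcome, scores, covariates,
                            tier = c("sex", "sex_maternal", "extended"),
                            cpg_id = "cpg", outcome_id = "outcome") {
  tier <- match.arg(tier)
  z <- if (inherits(scores, "normal_scores")) scores$scores else scores
  stopifnot(length(outcome) == length(z))
  cols <- tier_columns(tier)
  missing_cols <- setdiff(cols, names(covariates))
  if (length(missing_cols) > 0)
    stop("covariate tier '", tier, "' needs missing column(s): ",
         paste(missing_cols, collapse = ", "))
  covs <- covariates[, cols, drop = FALSE]
  dat <- data.frame(.outcome = outcome, .score = z, covs)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 10) stop("fewer than 10 complete cases")

  X <- model.matrix(~ ., data = dat[, -1, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  fit <- lm(.outcome ~ ., data = dat)
  est <- summary(fit)$coefficients[".score", ]
  df <- fit$df.residual
  tq <- qt(0.975, df)
  beta <- est[["Estimate"]]; se <- est[["Std. Error"]]
  p <- if (se == 0) if (beta == 0) 1 else 0 else 2 * pt(-abs(beta / se), df)
  structure(data.frame(cpg_id = cpg_id, outcome_id = outcome_id,
                       covariate_tier = tier, n = n, beta = beta,
                       lcl = beta - tq * se, ucl = beta + tq * se, p = p,
                       stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"))
}

#' Variance explained by a multivariate OLS model
#'
#' @param outcome Numeric outcome.
#' @param predictors Data frame (or matrix) of predictor columns.
#' @return List of class `model_summary`: `outcome_id`, `predictors`,
#'   `r_squared`, `n`.
#' @param outcome_id Label carried into the result.
#' @export
variance_explained <- function(outcome, predictors, outcome_id = "outcome") {
  predictors <- as.data.frame(predictors)
  stopifnot(length(outcome) == nrow(predictors))
  dat <- data.frame(.outcome = outcome, predictors)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < ncol(dat) + 1) stop("too few complete cases")
  fit <- lm(.outcome ~ ., data = dat)
  structure(list(outcome_id = outcome_id,
                 predictors = names(predictors),
                 r_squared = summary(fit)$r.squared,
                 n = nrow(dat)),
            class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("<model_summary> %s ~ %s: R^2 = %.3f (n = %d)\n",
              x$outcome_id, paste(x$predictors, collapse = " + "),
              x$r_squared, x$n))
  invisible(x)
}

#' Association table across all CpGs and covariate tiers
#'
#' Fits [fit_association()] for every CpG of a validation cohort at each
#' requested covariate tier, reproducing the one-row-per-CpG-and-tier
#' layout of a validation-cohort results table.
#'
#' @param cohort A `validation_cohort` (see [simulate_validation_cohort()]),
#'   or a list with `cpg_methylation`, `outcome`, `covariates`.
#' @param tiers Character vector of covariate tiers.
#' @param outcome_id Label for the outcome column.
#' @return Data frame, one row per CpG x tier, with `n`, `beta`, `lcl`,
#'   `ucl`, `p` and an informational BH column per tier.
#' @export
associate_cohort <- function(cohort, tiers = c("sex", "sex_maternal"),
                             outcome_id = "outcome") {
  pct <- cohort$cpg_methylation
  rows <- list()
  for (tier in tiers) {
    for (j in seq_len(ncol(pct))) {
      sc <- fisher_yates_scores(pct[, j])
      rows[[length(rows) + 1]] <- fit_association(
        cohort$outcome, sc, cohort$covariates, tier = tier,
        cpg_id = colnames(pct)[j], outcome_id = outcome_id)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::ave(out$p, out$covariate_tier,
                         FUN = function(p) p.adjust(p, method = "BH"))
  rownames(out) <- NULL
  out
}
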