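#' Ordinal group design
#'
#' Assigns every sample to one of `n_groups` ordinal phenotype categories
#' (1 = lowest phenotype, `n_groups` = highest). The screen requires at
#' least two samples per group.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param groups Integer group per sample, in `1..n_groups`.
#' @return An object of class `group_design`.
#' @export
group_design <- function(sample_ids, groups) {
  groups <- as.integer(groups)
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(groups) || anyNA(groups))
    stop("every sample must be assigned a group")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids")
  G <- max(groups)
  tab <- tabulate(groups, G)
  if (any(tab == 0))
    stop("missing group: ", paste(which(tab == 0), collapse = ", "))
  if (any(tab < 2))
    stop("each group needs >= 2 samples for testing")
  structure(list(sample_ids = sample_ids,
                 group_of = setNames(groups, sample_ids),
                 n_groups = G),
            class = "group_design")
}

#' DMR calling thresholds
#'
#' The four-part composite criterion's cut-offs. A window is a DMR when it
#' passes all four: (i) robust trend regression p <= `robust_p`; (ii) the
#' Mann-Whitney cascade — extreme groups 1 vs 4 p <= `mw_extreme_p` *and* at
#' least one adjacent pair (1v2, 2v3, 3v4) p <= `mw_adjacent_p`; (iii)
#' methylation odds ratio outside `[methor_low, methor_high]`; (iv) absolute
#' extreme-group methylation difference >= `abs_diff` (proportion units;
#' 0.20 = 20 percentage points). The default odds-ratio bounds are symmetric
#' (`methor_low = 1/methor_high`), which makes the direction of comparison
#' immaterial to calling.
#'
#' @param robust_p,mw_extreme_p,mw_adjacent_p P-value cut-offs in (0, 1).
#' @param methor_low,methor_high Odds-ratio bounds; must satisfy
#'   `methor_low == 1/methor_high` (within 1e-9).
#' @param abs_diff Minimum absolute methylation difference, in (0, 1).
#' @return An object of class `dmr_thresholds`.
#' @export
dmr_thresholds <- function(robust_p = 0.02, mw_extreme_p = 0.02,
                           mw_adjacent_p = 0.01,
                           methor_low = 1 / 1.5, methor_high = 1.5,
                           abs_diff = 0.20) {
  ps <- c(robust_p, mw_extreme_p, mw_adjacent_p)
  if (any(ps <= 0) || any(ps >= 1))
    stop("p-value thresholds must lie in (0, 1)")
  if (abs(methor_low - 1 / methor_high) > 1e-9)
    stop("methor_low must equal 1/methor_high")
  if (abs_diff <= 0 || abs_diff >= 1)
    stop("abs_diff must lie in (0, 1)")
  structure(list(robust_p = robust_p, mw_extreme_p = mw_extreme_p,
                 mw_adjacent_p = mw_adjacent_p, methor_low = methor_low,
                 methor_high = methor_high, abs_diff = abs_diff),
            class = "dmr_thresholds")
}

#' Heteroscedasticity-robust ordinal trend test
#'
#' Regresses per-sample methylation on the ordinal group score (1..G) by
#' least squares and tests the slope with heteroscedasticity-consistent
#' (HC3 sandwich) standard errors against a t reference with n - 2 degrees
#' of freedom; group-level variance differences are the norm for bounded
#' methylation proportions, hence the robust errors. A Huber M-estimator
#' (`method = "huber"`) is available as an alternative robustness notion.
#'
#' @param values Numeric methylation values, one per sample.
#' @param groups Ordinal group per sample (integer 1..G), or a
#'   [group_design()].
#' @param method `"hc3"` (default) or `"huber"`.
#' @return List with `p` (two-sided), `slope`, `se`, and `degenerate`
#'   (TRUE when the response has zero variance, in which case `p = 1`).
#' @export
robust_trend_test <- function(values, groups, method = c("hc3", "huber")) {
  method <- match.arg(method)
  if (inherits(groups, "group_design")) groups <- unname(groups$group_of)
  score <- as.numeric(groups)
  stopifnot(length(values) == length(score))
  ok <- is.finite(values) & is.finite(score)
  values <- values[ok]; score <- score[ok]
  n <- length(values)
  if (n < 8 || length(unique(score)) < 2)
    stop("need >= 8 samples across >= 2 groups")
  if (var(values) == 0)
    return(list(p = 1, slope = 0, se = NA_real_, degenerate = TRUE))

  if (method == "huber") {
    fit <- MASS::rlm(values ~ score, maxit = 100)
    s <- summary(fit)$coefficients
    slope <- s["score", "Value"]; se <- s["score", "Std. Error"]
  } else {
    fit <- lm(values ~ score)
    slope <- coef(fit)[["score"]]
    se <- sqrt(sandwich::vcovHC(fit, type = "HC3")["score", "score"])
  }
  if (!is.finite(se) || se == 0) {
    # exact linear fit: residuals vanish, evidence is unbounded
    p <- if (abs(slope) > 1e-14) 0 else 1
  } else {
    p <- 2 * pt(-abs(slope / se), df = n - 2)
  }
  list(p = p, slope = slope, se = se, degenerate = FALSE)
}

# exact null counts of the Mann-Whitney U statistic for sizes (m, n):
# counts[u + 1] = number of labelings with U = u, u in 0..m*n.
# Subset-sum dynamic programme over pooled ranks; cached per (m, n).
mw_null_counts <- function(m, n) {
  key <- paste0("mw", m, "_", n)
  hit <- .dmrscreen_cache[[key]]
  if (!is.null(hit)) return(hit)
  N <- m + n
  width <- m * N + 1                      # rank sums 0..m*N
  W <- matrix(0, nrow = m + 1, ncol = width)
  W[1, 1] <- 1
  for (t in seq_len(N)) {
    for (j in rev(seq_len(min(t, m)))) {
      idx <- seq_len(width - t)
      W[j + 1, idx + t] <- W[j + 1, idx + t] + W[j, idx]
    }
  }
  off <- m * (m + 1) / 2
  counts <- W[m + 1, (off + 1):(off + m * n + 1)]
  .dmrscreen_cache[[key]] <- counts
  counts
}

#' Mann-Whitney test with exact small-sample p-values
#'
#' Computes the Mann-Whitney U statistic for group `a` against group `b`.
#' For untied data with `n_a + n_b <= 20` the two-sided p-value is exact,
#' from the full null distribution of U over all labelings (twice the
#' smaller tail, capped at 1). With ties, or for larger samples, the
#' mid-rank normal approximation with tie-corrected variance is used
#' (without continuity correction, so identical groups give p = 1).
#'
#' @param a,b Numeric value vectors, both non-empty.
#' @return List with `U` (the statistic for `a`), `p` (two-sided), and
#'   `exact` (logical).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p   # exact: 0.1
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  m <- length(a); n <- length(b)
  if (m == 0 || n == 0)
    stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(pooled) > 0

  if (!ties && m + n <= 20) {
    counts <- mw_null_counts(m, n)
    total <- sum(counts)
    u <- as.integer(round(U))
    p_low <- sum(counts[seq_len(u + 1)]) / total
    p_high <- sum(counts[(u + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_low, p_high))
    return(list(U = U, p = p, exact = TRUE))
  }

  N <- m + n
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- m * n / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0)
    return(list(U = U, p = 1, exact = FALSE))
  z <- (U - m * n / 2) / sqrt(sigma2)
  list(U = U, p = 2 * pnorm(-abs(z)), exact = FALSE)
}

#' Methylation odds ratio between extreme groups
#'
#' `odds(mean_low) / odds(mean_high)` with `odds(m) = m / (1 - m)`, after
#' clamping both means to `[eps, 1 - eps]` so boundary methylation values
#' stay finite.
#'
#' @param mean_low,mean_high Group mean methylation proportions in `[0, 1]`
#'   (lowest and highest phenotype group).
#' @param eps Clamp width.
#' @return The odds ratio (positive scalar).
#' @examples
#' meth_or(0.5, 0.2)   # odds 1 / odds 0.25 = 4
#' @export
meth_or <- function(mean_low, mean_high, eps = 1e-6) {
  stopifnot(mean_low >= 0, mean_low <= 1, mean_high >= 0, mean_high <= 1)
  ml <- min(max(mean_low, eps), 1 - eps)
  mh <- min(max(mean_high, eps), 1 - eps)
  (ml / (1 - ml)) / (mh / (1 - mh))
}

#' Call DMRs with the four-part composite criterion
#'
#' Applies, per 100-nt window: the robust ordinal trend test, the
#' Mann-Whitney cascade (groups 1 vs G, plus each adjacent pair), the
#' methylation odds ratio, and the absolute extreme-group difference, and
#' combines them per [dmr_thresholds()]. Uninformative windows (e.g. zero
#' coupled CpG mass at estimation) and degenerate windows (zero variance)
#' are never called.
#'
#' No multiple-testing correction enters the call — the raw cut-offs act as
#' a deliberately stringent prioritisation filter; Benjamini-Hochberg
#' adjusted columns (`p_robust_bh`, `p_mw_extreme_bh`) are emitted for
#' information only.
#'
#' @param methylation Regions x samples matrix of methylation proportions.
#' @param design A [group_design()] matching the matrix columns.
#' @param thresholds A [dmr_thresholds()].
#' @param informative Optional logical per region; `FALSE` rows get `NA`
#'   statistics and `is_dmr = FALSE`.
#' @param method Robust-regression flavour, see [robust_trend_test()].
#' @return A data frame of class `dmr_results`, one row per region:
#'   `region`, all test statistics (`p_robust`, `p_mw_14`, `p_mw_12`,
#'   `p_mw_23`, `p_mw_34`, `methor`, `abs_diff`, group means), `is_dmr`,
#'   and BH columns. Thresholds are attached as an attribute.
#' @export
call_dmrs <- function(methylation, design, thresholds = dmr_thresholds(),
                      informative = NULL, method = "hc3") {
  stopifnot(is.matrix(methylation), inherits(design, "group_design"),
            inherits(thresholds, "dmr_thresholds"))
  if (ncol(methylation) != length(design$sample_ids))
    stop("methylation columns do not match the design samples")
  if (!is.null(colnames(methylation)) &&
      !identical(colnames(methylation), design$sample_ids))
    stop("methylation column names do not match the design sample ids")
  G <- design$n_groups
  if (G != 4)
    stop("the composite criterion is defined for exactly 4 ordinal groups")
  groups <- unname(design$group_of)
  idx <- lapply(seq_len(G), function(g) which(groups == g))
  R <- nrow(methylation)
  if (is.null(informative)) informative <- rep(TRUE, R)
  stopifnot(length(informative) == R)

  adj_pairs <- cbind(seq_len(G - 1), 2:G)
  res <- matrix(NA_real_, R, 7 + G,
                dimnames = list(NULL, c("p_robust", "p_mw_14", "p_mw_12",
                                        "p_mw_23", "p_mw_34", "methor",
                                        "abs_diff",
                                        sprintf("mean_g%d", seq_len(G)))))
  degenerate <- rep(FALSE, R)
  for (r in seq_len(R)) {
    if (!informative[r]) next
    x <- methylation[r, ]
    rt <- robust_trend_test(x, groups, method = method)
    degenerate[r] <- rt$degenerate
    gm <- vapply(idx, function(i) mean(x[i]), numeric(1))
    mw14 <- mann_whitney(x[idx[[1]]], x[idx[[G]]])$p
    mw_adj <- vapply(seq_len(G - 1), function(k)
      mann_whitney(x[idx[[adj_pairs[k, 1]]]], x[idx[[adj_pairs[k, 2]]]])$p,
      numeric(1))
    res[r, ] <- c(rt$p, mw14, mw_adj[1], mw_adj[2], mw_adj[3],
                  meth_or(gm[1], gm[G]), abs(gm[1] - gm[G]), gm)
  }

  th <- thresholds
  is_dmr <- informative & !degenerate &
    !is.na(res[, "p_robust"]) &
    res[, "p_robust"] <= th$robust_p &
    res[, "p_mw_14"] <= th$mw_extreme_p &
    (pmin(res[, "p_mw_12"], res[, "p_mw_23"], res[, "p_mw_34"]) <=
       th$mw_adjacent_p) &
    (res[, "methor"] <= th$methor_low | res[, "methor"] >= th$methor_high) &
    res[, "abs_diff"] >= th$abs_diff
  is_dmr[is.na(is_dmr)] <- FALSE

  out <- data.frame(
    region = if (is.null(rownames(methylation)))
      sprintf("w%05d", seq_len(R)) else rownames(methylation),
    res,
    informative = informative,
    degenerate = degenerate,
    is_dmr = is_dmr,
    stringsAsFactors = FALSE)
  out$p_robust_bh <- p.adjust(out$p_robust, method = "BH")
  out$p_mw_extreme_bh <- p.adjust(out$p_mw_14, method = "BH")
  attr(out, "thresholds") <- thresholds
  class(out) <- c("dmr_results", "data.frame")
  out
}
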