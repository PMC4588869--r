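#' CpG coupling weights for a probe
#'
#' A probe's enrichment signal responds to methylation at CpGs it can reach:
#' CpGs inside the probe couple fully (weight 1), CpGs in the flanking
#' sequence couple with a weight that decays linearly to 0 over `flank`
#' nucleotides from the probe edge, and CpGs beyond the flank do not couple.
#' The sum of weights is the probe's *coupled CpG mass*, the effective CpG
#' count driving its signal.
#'
#' Coordinates are 0-based half-open; a CpG position is the coordinate of
#' its C.
#'
#' @param probe_start,probe_end Probe coordinates (0-based half-open).
#' @param cpg_positions Integer vector of CpG coordinates on the same
#'   chromosome.
#' @param flank Flanking distance over which coupling decays (nt).
#' @return List with `weights` (one per CpG, in input order) and `mass`
#'   (their sum). An empty CpG list gives zero mass with an `uninformative`
#'   flag.
#' @examples
#' compute_coupling(100, 160, c(120, 130))$mass     # fully interior: 2
#' compute_coupling(100, 160, 210)$weights          # half-flank out: 0.5
#' @export
compute_coupling <- function(probe_start, probe_end, cpg_positions,
                             flank = 100) {
  stopifnot(probe_end > probe_start, flank > 0)
  if (length(cpg_positions) == 0)
    return(list(weights = numeric(0), mass = 0, uninformative = TRUE))
  p <- as.numeric(cpg_positions)
  d <- pmax(0, probe_start - p, p - probe_end)  # 0 inside the probe
  w <- pmax(0, 1 - d / flank)
  list(weights = w, mass = sum(w), uninformative = sum(w) == 0)
}

#' Estimate per-window methylation from probe log2 ratios
#'
#' The simplified Bayesian estimation step: for each 100-nt window, the
#' posterior over a methylation grid `m = 0, grid_step, ..., 1` is
#' proportional to the Gaussian likelihood of the observed log2 ratios of
#' the window's probes around `link(m * coupled mass)`, times a uniform
#' prior. The reported estimate is the posterior mode, which is what the
#' downstream screen consumes.
#'
#' Probes are attached to a window if they overlap it or its `flank`.
#' Windows whose probes all have zero coupled CpG mass carry no methylation
#' information: they get a flat posterior, a mode at the grid midpoint, and
#' `informative = FALSE` (the screen excludes them). Windows with no
#' overlapping probes are omitted with a warning.
#'
#' @param probes Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `log2_ratio`, and optionally `coupled_mass` (computed from
#'   `cpg_positions` when absent).
#' @param cpg_positions Integer vector of CpG coordinates (0-based), used
#'   when `coupled_mass` is not supplied.
#' @param windows `GRanges` of 100-nt windows to estimate. Defaults to a
#'   100-nt tiling of the probe span.
#' @param link The [probe_link()] relating methylated-CpG mass to expected
#'   log2 ratio (from simulation metadata or a fitted calibration).
#' @param grid_step Methylation grid resolution (proportion units).
#' @param noise_sd Gaussian observation noise SD on log2 ratios. When
#'   `NULL`, estimated as 1.4826 x the median absolute residual around each
#'   window's best-fitting grid value (a robust scale estimate that ignores
#'   the minority of probes any single window misfits).
#' @param flank Flanking distance for probe-window attachment (nt).
#' @return An object of class `region_estimates`: data frame with window
#'   coordinates, `methylation_mode`, `coupled_mass`, `informative`, plus a
#'   `posterior` matrix (grid x windows, columns normalized to sum 1) and
#'   the `grid` as attributes.
#' @export
estimate_region_methylation <- function(probes, cpg_positions = NULL,
                                        windows = NULL,
                                        link = probe_link(),
                                        grid_step = 0.01,
                                        noise_sd = NULL,
                                        flank = 100) {
  stopifnot(is.data.frame(probes),
            all(c("chrom", "start", "end", "log2_ratio") %in% names(probes)),
            all(probes$end > probes$start),
            all(is.finite(probes$log2_ratio)))
  if (is.null(probes$coupled_mass)) {
    if (is.null(cpg_positions))
      stop("supply either a coupled_mass column or cpg_positions")
    probes$coupled_mass <- vapply(seq_len(nrow(probes)), function(i)
      compute_coupling(probes$start[i], probes$end[i], cpg_positions,
                       flank = flank)$mass, numeric(1))
  }
  if (is.null(windows)) {
    lo <- 100 * (min(probes$start) %/% 100)
    hi <- 100 * ((max(probes$end) + 99) %/% 100)
    windows <- GenomicRanges::GRanges(
      probes$chrom[1],
      IRanges::IRanges(start = seq(lo, hi - 100, by = 100) + 1, width = 100))
  }
  stopifnot(all(GenomicRanges::width(windows) == 100))

  probe_gr <- GenomicRanges::GRanges(
    probes$chrom, IRanges::IRanges(start = probes$start + 1, end = probes$end))
  hits <- GenomicRanges::findOverlaps(windows, probe_gr)
  by_window <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  # windows with no probe of their own may borrow from their flank
  uncovered <- setdiff(seq_along(windows), as.integer(names(by_window)))
  if (length(uncovered) > 0) {
    fhits <- GenomicRanges::findOverlaps(windows[uncovered] + flank, probe_gr)
    fl <- split(S4Vectors::subjectHits(fhits), S4Vectors::queryHits(fhits))
    names(fl) <- as.character(uncovered[as.integer(names(fl))])
    by_window <- c(by_window, fl)
    by_window <- by_window[order(as.integer(names(by_window)))]
  }

  covered <- as.integer(names(by_window))
  if (length(covered) < length(windows))
    warning(sprintf("%d window(s) with no overlapping probes omitted",
                    length(windows) - length(covered)))

  grid <- seq(0, 1, by = grid_step)
  n_grid <- length(grid)

  loglik_window <- function(pr_idx, sd_use) {
    ll <- numeric(n_grid)
    for (j in pr_idx) {
      mu <- link_eval(link, grid * probes$coupled_mass[j])
      ll <- ll + dnorm(probes$log2_ratio[j], mean = mu, sd = sd_use,
                       log = TRUE)
    }
    ll
  }

  if (is.null(noise_sd)) {
    # robust residual scale around each window's best-fitting grid value
    res <- unlist(lapply(by_window, function(pr_idx) {
      pr_idx <- pr_idx[probes$coupled_mass[pr_idx] > 0]
      if (length(pr_idx) == 0) return(numeric(0))
      ll <- loglik_window(pr_idx, 1)
      m_hat <- grid[which.max(ll)]
      probes$log2_ratio[pr_idx] -
        link_eval(link, m_hat * probes$coupled_mass[pr_idx])
    }))
    noise_sd <- max(stats::median(abs(res)) * 1.4826, 1e-3)
  }
  sd_use <- max(noise_sd, 1e-6)

  post <- matrix(NA_real_, n_grid, length(covered))
  mode <- numeric(length(covered))
  mass_out <- numeric(length(covered))
  informative <- logical(length(covered))
  for (k in seq_along(covered)) {
    pr_idx <- by_window[[k]]
    mass_k <- sum(probes$coupled_mass[pr_idx])
    mass_out[k] <- mass_k
    if (mass_k == 0) {
      post[, k] <- 1 / n_grid
      mode[k] <- grid[ceiling(n_grid / 2)]   # grid midpoint, flagged
      informative[k] <- FALSE
      next
    }
    ll <- loglik_window(pr_idx, sd_use)
    w <- exp(ll - max(ll))
    post[, k] <- w / sum(w)
    mode[k] <- grid[which.max(post[, k])]
    informative[k] <- TRUE
  }

  win_used <- windows[covered]
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(win_used)),
    start = GenomicRanges::start(win_used) - 1L,
    end = GenomicRanges::end(win_used),
    methylation_mode = mode,
    coupled_mass = mass_out,
    informative = informative,
    stringsAsFactors = FALSE)
  attr(out, "posterior") <- post
  attr(out, "grid") <- grid
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("region_estimates", "data.frame")
  out
}

#' Estimate the full region x sample methylation matrix
#'
#' Applies [estimate_region_methylation()] to each sample of a simulated (or
#' imported) probe-signal set, using the link recorded with the signals.
#'
#' @param signals A `probe_signals` object (see [simulate_probe_signals()]).
#' @param windows `GRanges` of 100-nt windows matching the signal's probes.
#' @param ... Passed to [estimate_region_methylation()].
#' @return List with `methylation` (regions x samples matrix of posterior
#'   modes, proportions) and `informative` (logical per region).
#' @export
estimate_cohort_methylation <- function(signals, windows, ...) {
  stopifnot(inherits(signals, "probe_signals"))
  samples <- colnames(signals$log2_ratio)
  base <- signals$probes[c("chrom", "start", "end", "coupled_mass")]
  est <- lapply(samples, function(s) {
    pr <- base
    pr$log2_ratio <- signals$log2_ratio[, s]
    estimate_region_methylation(pr, windows = windows, link = signals$link,
                                ...)
  })
  meth <- vapply(est, function(e) e$methylation_mode,
                 numeric(nrow(est[[1]])))
  dimnames(meth) <- list(rownames(signals$log2_ratio), samples)
  list(methylation = meth, informative = est[[1]]$informative)
}
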