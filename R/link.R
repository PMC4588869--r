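#' Saturating probe response link
#'
#' The forward model tying methylation to probe log2 enrichment ratios. The
#' expected ratio for a probe is a saturating exponential of the probe's
#' *methylated CpG mass* `x = methylation * coupled CpG mass`:
#'
#' \deqn{r(x) = floor + amplitude (1 - e^{-rate \cdot x})}
#'
#' MBD capture pulls down fragments in proportion to the number of methylated
#' CpGs they carry, and the enrichment ratio saturates once a fragment is
#' captured with near certainty; a saturating exponential is the simplest
#' monotone link with that behaviour. The link is strictly increasing in `x`,
#' so it is analytically invertible, which the estimation stage exploits and
#' the tests use as an oracle.
#'
#' @param floor Log2 ratio at zero methylated-CpG mass (the unmethylated
#'   baseline after background subtraction).
#' @param amplitude Dynamic range of the log2 ratio above the floor.
#' @param rate Saturation rate per unit methylated-CpG mass.
#' @return An object of class `probe_link` with elements `floor`, `amplitude`,
#'   `rate`.
#' @seealso [link_eval()], [link_invert()]
#' @export
probe_link <- function(floor = -0.5, amplitude = 3, rate = 0.35) {
  stopifnot(is.finite(floor), amplitude > 0, rate > 0)
  structure(list(floor = floor, amplitude = amplitude, rate = rate),
            class = "probe_link")
}

#' Evaluate a probe link at a methylated-CpG mass
#'
#' @param link A [probe_link()] object.
#' @param x Methylated CpG mass (methylation proportion times coupled CpG
#'   mass), non-negative.
#' @return Expected log2 ratio(s).
#' @export
link_eval <- function(link, x) {
  stopifnot(inherits(link, "probe_link"))
  link$floor + link$amplitude * (1 - exp(-link$rate * x))
}

#' Invert a probe link
#'
#' Maps an observed log2 ratio back to the methylated-CpG mass that would
#' produce it noise-free. Ratios at or below the floor map to 0; ratios at or
#' above the saturation ceiling map to the largest finite mass representable
#' before the exponential underflows.
#'
#' @inheritParams link_eval
#' @param r Observed log2 ratio(s).
#' @return Methylated CpG mass(es), non-negative.
#' @export
link_invert <- function(link, r) {
  stopifnot(inherits(link, "probe_link"))
  f <- (r - link$floor) / link$amplitude
  f <- pmin(pmax(f, 0), 1 - 1e-12)
  -log1p(-f) / link$rate
}

#' @export
print.probe_link <- function(x, ...) {
  cat(sprintf(
    "<probe_link> r(x) = %.4g + %.4g * (1 - exp(-%.4g * x))\n",
    x$floor, x$amplitude, x$rate))
  invisible(x)
}

# serializable form for run manifests / sidecar metadata
link_to_list <- function(link) {
  list(type = "saturating_exponential", floor = link$floor,
       amplitude = link$amplitude, rate = link$rate)
}

link_from_list <- function(x) {
  stopifnot(identical(x$type, "saturating_exponential"))
  probe_link(floor = x$floor, amplitude = x$amplitude, rate = x$rate)
}
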