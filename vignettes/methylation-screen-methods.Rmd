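---
title: "Methods: from enrichment-array signals to DMROIs and outcome associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from enrichment-array signals to DMROIs and outcome associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrscreen)
```

# Overview

`dmrscreen` implements a two-stage epigenome-wide analysis design. A small
discovery screen (24 umbilical-cord DNA samples, methylation-enrichment
promoter tiling array) calls differentially methylated regions (DMRs) and
promoter-level regions of interest (DMROIs) across four ordinal phenotype
groups. A larger validation stage (~100–200 subjects, per-CpG percent
methylation from pyrosequencing-style assays) estimates covariate-adjusted
associations between CpG methylation and continuous neurodevelopmental
outcomes. Because no participant-level cohort is distributed with the
package, a seeded synthetic-data generator with planted truth stands in for
both stages; every statistical claim made by the test suite is a property
of the methods (calibration, power, recovery, exactness), not a
reproduction of any particular cohort's numbers.

# Signal model and estimation (`estimate_region_methylation`)

Methylation-enrichment arrays report, per probe, a background-subtracted
log2 ratio of captured versus input DNA. The capture efficiency of a
fragment grows with the number of methylated CpGs it carries, so the probe
signal is informative about methylation only jointly with the local CpG
density. The package models the expected ratio as a saturating exponential
of the *methylated CpG mass* \(x = m \cdot w\), where \(m\) is the
methylation proportion of the 100-nt window and \(w\) is the probe's
coupled CpG mass:

\[ r(x) = \mathrm{floor} + A\,(1 - e^{-\lambda x}), \qquad
   r_{\mathrm{obs}} \sim N(r(x), \sigma^2). \]

Coupling (`compute_coupling`) gives CpGs inside the probe weight 1 and
CpGs up to 100 nt beyond either probe edge a linearly decaying weight —
fragments hybridizing to the probe extend into the flanks, so flanking
CpGs contribute partially. Any strictly monotone link would serve; the
saturating exponential is the simplest one with a floor (unmethylated
baseline) and a ceiling (capture saturation), and it is analytically
invertible, which the round-trip tests exploit. The link parameters used
by a run are always recorded (signal metadata, run manifest) so estimates
can be audited against the forward model.

Estimation is a deliberately simplified version of the Bayesian
deconvolution used with such arrays: per 100-nt window, a uniform prior
over a methylation grid (step 0.01) is combined with the Gaussian
likelihood of the window's probe ratios, and the **posterior mode** is
reported — the downstream screen consumes only that mode. We do not model
cross-window coupling or nested sampling; with promoter tiling at one-two
probes per window, the per-window posterior is what the composite screen
actually uses, and the simplification is testable by construction
(forward-simulate, invert, compare). Probes are attached to the window
they overlap; the 100-nt flank is used only as a fallback for windows with
no probe of their own, because pooling flank probes of neighbouring
windows would mix distinct methylation levels.

Numerical choices: posteriors are normalized in log space (subtract the
max before exponentiating), so a near-zero observation SD degenerates
gracefully to a point mass instead of underflowing. The observation SD can
be supplied (e.g. the known simulation value); when it is not, it is
estimated as 1.4826 times the median absolute residual around each
window's best-fitting grid value — a robust scale estimate, meaningful
only when windows carry more than one probe. Windows with zero coupled
CpG mass are non-identifiable: they get a flat posterior, a mode at the
grid midpoint, an `informative = FALSE` flag, and are excluded from the
screen. Grid ties (flat stretches of posterior) resolve to the lowest
grid point, which only occurs in degenerate flat posteriors.

# The composite DMR screen (`call_dmrs`)

Samples are grouped into four ordinal phenotype categories (group 1
lowest). A 100-nt window is a DMR when **all four** criteria hold:

1. **Trend**: OLS regression of methylation on the ordinal group score
   with HC3 heteroscedasticity-consistent (sandwich) standard errors,
   two-sided \(p \le 0.02\). Bounded proportions make group-level variance
   differences the norm, hence the robust errors; with 24 samples the
   HC3 t-test holds its nominal level (measured 0.018 at nominal 0.02
   over 10,000 null regions). A Huber M-estimator is available as an
   alternative robustness notion (`method = "huber"`).
2. **Mann-Whitney cascade**: groups 1 vs 4 \(p \le 0.02\) *and* at least
   one adjacent pair (1v2, 2v3, 3v4) \(p \le 0.01\). For untied data with
   \(n \le 20\) pooled values the p-value is exact (full null distribution
   of U via a subset-sum dynamic programme; two-sided = twice the smaller
   tail, capped at 1). Ties fall back to the mid-rank normal approximation
   with tie-corrected variance and no continuity correction, so identical
   groups give exactly \(p = 1\). Tests are two-sided throughout — the
   screen is direction-agnostic by design.
3. **MethOR**: the odds ratio of group-mean methylation proportions,
   \(\mathrm{odds}(m_1)/\mathrm{odds}(m_4)\) with
   \(\mathrm{odds}(m) = m/(1-m)\), outside \([2/3, 1.5]\). The bounds are
   reciprocal, so which group sits in the numerator cannot change a call;
   means are clamped to \([10^{-6}, 1-10^{-6}]\) so boundary values stay
   finite.
4. **Effect size**: \(|\bar m_1 - \bar m_4| \ge 0.20\) (20 percentage
   points).

The screen applies these raw cut-offs with no multiple-testing
correction: the conjunction is a deliberately stringent prioritisation
filter (its realized null false-call rate is below 1% per window, measured
at 0 over 5,000 null regions), and BH-adjusted columns are emitted for
information only. Degenerate windows (zero variance) and uninformative
windows are never called. The screen requires exactly four groups — the
cascade's structure is not defined otherwise.

# ROI enrichment and DMROI calling (`call_dmrois`)

Promoter regions of interest (ROIs) span −5.5 kb to +2.5 kb around each
TSS on the array design. Windows map to ROIs by interval overlap, with
nearest-TSS tie-breaking when promoters overlap. Per ROI, a 2×2 table is
built from window-level trend significance (\(p < 0.01\)): \(a\)
significant inside, \(c\) non-significant inside, \(b, d\) the same counts
outside. The enrichment point probability is the hypergeometric mass

\[ P = \binom{a+b}{a}\binom{c+d}{c} \Big/ \binom{n}{a+c},
   \qquad n = a+b+c+d, \]

computed via `lchoose` in log space; calling uses the one-sided
(enrichment) upper tail \(\sum_{a' \ge a} P(a')\), i.e. the Fisher exact
tail. The counts outside the ROI close the margins so the table is a
proper 2×2 — the alternative reading (whole-array counts in \(b, d\))
would double-count the ROI and break \(n = a+b+c+d\).

An ROI is a **DMROI** when the tail \(p \le 0.01\), the Mann-Whitney test
between groups 1 and 4 on ROI-aggregate methylation gives \(p \le 0.02\),
and the ROI contains at least one composite DMR. The ROI aggregate is the
per-sample mean over informative member windows — the simplest
order-preserving summary; a window-level alternative is available by
feeding composite calls into the table (`use_composite = TRUE`).

Gene-set enrichment of DMROI genes (`geneset_enrichment`) is a standard
upper-tail hypergeometric test against the array-design background with BH
adjustment across sets. It deliberately replaces the proprietary pathway
suite used in this literature with a generic GMT interface; p-values from
a proprietary background are not comparable and are not a target.

# Association stage (`fisher_yates_scores`, `fit_association`)

Pyrosequencing percent-methylation distributions are typically skewed, so
CpG values are transformed to Fisher-Yates normal scores: mid-ranks
(ties averaged), Blom's approximation to expected normal order statistics
\(\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)\), then an exact location-scale
standardization to mean 0, SD 1. Blom scores alone have variance slightly
below 1 and tie-averaging perturbs both moments, which is why the final
standardization is exact rather than approximate; ties are handled
*before* standardization so the moment contract holds for tied data too.
Because the predictor has SD 1, the regression coefficient is directly
the outcome change per SD methylation.

Models are ordinary least squares, one CpG per model (mirroring how such
validation tables are reported), with covariate tiers: sex; sex + the
maternal score (maternal IQ or educational attainment); and an extended
tier adding age at assessment, birthweight, maternal smoking, BMI and
parity. Missing data are handled by listwise deletion, so `n` varies per
row exactly as in sparse cohort tables. Confidence limits and two-sided
p-values come from the t distribution; robust errors are not used here —
the robustness device belongs to the array screen, where group-level
heteroscedasticity is structural. No adjustment is made across the 9 CpGs
× outcomes (a BH column is emitted for information).

# The synthetic-data generator

`simulate_array_cohort` draws per-region baselines from Beta(2, 2) —
mid-range baselines, consistent with an array biased toward methylated
CpG-rich promoters, and leaving room for a ±0.125 shift inside \([0,1]\) —
and adds per-sample Gaussian noise (SD 0.03). Planted windows shift group
means so the extreme groups differ by exactly 0.25, linearly across groups
(dose-response) by default, with random hyper/hypo direction. Values are
clamped to \([0,1]\); the clamped fraction is reported and a configuration
that clamps more than 10% of draws is rejected as unusable. The discovery
design this emulates is 24 samples in 4 ordinal IQ bands; per-band counts
are not public, so the generator defaults to 6/6/6/6 (configurable). Planted windows can be
scattered or packed into one promoter (`dmr_placement = "clustered"`) to
exercise the enrichment stage with a fully planted ROI.

`simulate_validation_cohort` uses a one-factor Gaussian copula with
geometrically spaced loadings chosen so the smallest and largest pairwise
latent correlations match the requested span (default 0.31–0.85, the span
reported for the nine assayed CpGs); marginals are right-skewed
(Beta(2, 5) quantile transform scaled to percent) so the normal-score
transform is genuinely exercised. The outcome is linear in the normal
score of a designated causal CpG (default CpG2, planted effect 3.2 per
SD — the magnitude of the headline adjusted association this design
mirrors) plus sex and maternal-score effects and Gaussian noise. The
outcome noise SD defaults to 12.5, chosen once so that the default
multivariate model (causal CpG + maternal score + sex) explains ~15–16%
of outcome variance, matching the variance-explained regime such studies
report; this calibration is documented here and is not asserted by any
test. Setting `confound_strength > 0` correlates the maternal score with
the causal CpG to create classical confounding for sensitivity analyses.

What the generator does *not* emulate: array image artefacts, dye bias,
batch structure, bisulphite conversion error, genuine biological
covariance between neighbouring promoters, or SNP-disrupted CpGs.
Passing tests therefore demonstrate that the statistical machinery is
exact, calibrated and powered under the stated model — not that any
particular biological finding replicates.

# Problem sizes and reproducibility

The shipped tests and the acceptance script use: exhaustive 2×2
enumeration to \(n \le 12\); Mann-Whitney enumeration to 6 vs 6; 5,000
null regions for screen calibration; 200 replicates for screen power; 400
regions / 40 promoters for enrichment ranking; 500 seeds for effect
recovery and 1,000 for type-I error at \(n = 175\); 300 regions for the
estimation round trip. These sizes give Monte-Carlo standard errors well
inside the asserted tolerances. Every generator is deterministic given
its seed; `run_pipeline` reruns are bitwise-identical and record MD5
checksums, the seed, and the link parameters in `manifest.json`.

# Known limitations

* The estimation stage is per-window; long hypo/hypermethylated blocks
  spanning windows are estimated independently, unlike full Bayesian
  deconvolution with cross-window coupling.
* With one probe per window the observation SD is not identifiable from
  data and should be supplied.
* The screen's exact Mann-Whitney applies to untied data; estimated modes
  on a 0.01 grid often tie, in which case the tie-corrected approximation
  is used (a logged property, not an error).
* `call_dmrs` is specific to four ordinal groups by design.
* Gene-set results depend entirely on the user-supplied GMT and
  background; no curated pathway content is bundled.

# A worked default run

```{r, eval = FALSE}
cfg <- pipeline_config(
  outdir = "dmrscreen_out", seed = 1,
  simulation = simulation_config(n_regions = 500, n_true_dmrs = 8,
                                 dmr_placement = "clustered"),
  genesets = system.file("extdata", "example_sets.gmt",
                         package = "dmrscreen"))
man <- run_pipeline(cfg)
```

This writes `region_methylation.tsv`, `dmr_calls.tsv`, `dmroi_calls.tsv`,
`geneset_enrichment.tsv`, `associations.tsv` and `manifest.json` under
`dmrscreen_out/`; every table carries a `# units:` header (methylation is
percent in files, proportion in memory).
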