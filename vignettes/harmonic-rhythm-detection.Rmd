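---
title: "Detecting circadian and ultradian harmonic rhythms by model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circadian and ultradian harmonic rhythms by model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultrarhythm)
```

## The problem

Clock-controlled genes in a circadian organism need not oscillate at the
circadian period itself. When a transcript's period is an integer
fraction of the fundamental — half or a third — it is a *harmonic*
rhythm. In *Neurospora crassa*, whose intrinsic free-running period is
close to 22 hr, the interesting family is therefore 22 hr (circadian),
11 hr (second harmonic) and 22/3 ≈ 7.33 hr (third harmonic). Given a
gene × time expression matrix sampled every 2 hr over one circadian
cycle in the dark, the task is to assign every gene to exactly one of
these periods or to call it arrhythmic, with transcriptome-wide false
discovery rate (FDR) control, and then to quantify amplitude and phase,
ask whether the harmonic genes organize into two anti-phasic groups, and
compare genotypes in which the harmonic rhythms are perturbed.

## The model

For gene $i$ with expression $y_i(t)$ on the log2 scale, each candidate
period $T$ defines a cosinor regression

$$ y_i(t) = m_i + a_i \cos\!\frac{2\pi t}{T} + b_i \sin\!\frac{2\pi t}{T} + \varepsilon_t, $$

fit by ordinary least squares with explicit times (grids need not be
uniform). The derived quantities are the half-amplitude
$A = \sqrt{a^2 + b^2}$, the acrophase
$\varphi = \tfrac{T}{2\pi}\,\mathrm{atan2}(b, a) \bmod T$ (peak time in
hours in $[0, T)$), and the peak-to-peak fold amplitude $2^{2A}$
(peak-to-trough on the log2 scale is $2A$). The arrhythmic null is the
intercept-only fit.

**Model selection.** Per gene we fit the flat model ($k = 1$
parameter) and one cosinor per candidate period ($k = 3$) and select
the model minimizing

$$ \mathrm{BIC} = n \ln(\mathrm{RSS}/n) + k \ln n . $$

BIC is the default because its penalty is harsh at the $n \approx 12$
sample sizes of one-cycle designs, which suppresses spurious harmonic
picks; AICc is available via `criterion = "aicc"`. Ties are broken
toward the flat model first and then toward the longer period (fewer
observed cycles mean less aliasing risk). Each gene receives exactly
one period: a gene that is "best explained" by 7.33 hr is not also a
circadian call.

**Significance and FDR.** If a rhythmic model wins, significance is the
F test of the selected cosinor against flat with $(2, n-3)$ degrees of
freedom. Because the tested model was itself chosen as the best of
three near-orthogonal candidates, the raw post-selection p-value is
roughly three-fold anti-conservative under the null. The package
default therefore multiplies the selected model's p-value by the number
of candidate periods (a Bonferroni payment for the selection step);
`p_adjust_periods = "none"` gives the unadjusted variant. This choice
is what makes the nominal BH level hold empirically: in mixed
simulations (20% rhythmic, amplitude 1, noise 0.25) the mean
false-discovery proportion at the nominal 0.1 level is ≈ 0.08 with the
adjustment and ≈ 0.25 without it. Benjamini–Hochberg correction is
applied over the *full* expressed-gene universe, with flat-selected
genes entering at $p = 1$ — the conservative reading of a universe
that is not fully specified by the study design.

The time-label permutation null (`shuffle_null()`) is the empirical
complement to the parametric F test: it shuffles the assignment of time
labels to columns (one shared permutation per round, preserving the
inter-gene correlation structure — the stricter null; per-gene
independent shuffles via `shared = FALSE`) and reruns the entire
detection, yielding an add-one empirical p-value
$(1 + \#\{\text{perm} \ge k_{\mathrm{obs}}\})/(B+1)$ for the observed
number of calls at a period of interest.

## The synthetic-data generator

`simulate_transcriptome()` draws from the additive signal model the
analysis assumes:

$$ y_i(t) = m_i + \textstyle\sum_k A_{ik}\, e^{-\lambda t} \cos\!\frac{2\pi (t - \varphi_{ik})}{T_k} + \varepsilon_t, \qquad \varepsilon_t \sim \mathcal N(0, \sigma^2), $$

in log2 units. Defaults are pinned once to the wild-type study design
and not revisited:

* grid 0–22 h every 2 h (12 samples — one circadian cycle, three cycles
  of the third harmonic);
* 7,212 genes with fractions 0.17 / 0.015 / 0.064 rhythmic at
  22 / 11 / 7.33 hr. Class counts are `floor(fraction × n)` with the
  remainder arrhythmic, a deterministic rule that makes planted counts
  exactly reproducible;
* two anti-phasic phase groups per rhythmic class, the larger holding a
  392/460 share; group-center phases are exactly half a period apart
  and per-gene phases jitter $\mathcal N(0, 0.5\,\mathrm{h})$ around
  their center;
* log2 half-amplitudes lognormal with median 1 (4-fold
  peak-to-trough, consistent with an at-least-2-fold candidate rule and
  amplitudes comparable between harmonic and circadian genes), mesor
  $\mathcal N(8, 1.5)$ log2 a.u., noise $\sigma = 0.2$;
* optional shared exponential damping $e^{-\lambda t}$ for multi-day
  designs (`time_end = 46`, `damping_rate > 0`), modeling the strong
  damping seen after the first day in long time courses.

Genotype presets rewrite the truth table before synthesis. `dCSP1`
turns every third-harmonic gene into a *superimposed* gene — a
circadian component of equal amplitude (configurable via
`superimposed_ratio`) stacked on the retained harmonic, with circadian
phases again anti-phasic by group. `dMSN1` moves every third-harmonic
gene to the 11-hr period, keeping groups and phases. The original
class survives in `wt_class`, which is what recovery analyses compare
against.

The generator deliberately does **not** emulate: count-based sequencing
noise (values are Gaussian on the log scale, not negative binomial on
counts), library-size or batch effects, replicates (one sample per time
point, matching single-series designs), non-sinusoidal waveforms, or
per-gene damping rates. Passing recovery tests on these simulations
therefore demonstrates correctness of the estimation and calibration
machinery under the model's own assumptions — not robustness to the
full messiness of RNA-seq data.

## Phase groups and genotype comparisons

`cluster_antiphasic()` mean-subtracts profiles, uses the correlation
distance $d = 1 - r$ and average-linkage hierarchical clustering cut at
$k = 2$ (the two-group structure is imposed, not discovered; linkage is
configurable, Pearson is the declared correlation flavor). Groups are
relabeled so Group 1 is larger. `phase_group_difference()` compares
the groups' circular mean acrophases — resultant-vector means on the
common cycle — and reports the circular distance in hours and radians;
perfectly anti-phasic groups sit at $\pi$.

`subtract_component()` removes only the fitted cosine/sine part at a
given period, retaining the mesor, so an induced circadian rhythm can
be stripped to expose the residual harmonic; `residual_match()` is the
mean-subtracted Pearson correlation against a reference waveform. One
numerical caveat documented here because it is easy to mistake for a
bug: on the 12-point 0–22 h grid the circadian and third-harmonic
designs are *not exactly orthogonal* (both endpoints sample the same
circadian phase), so noiseless subtraction leaves ≈ 0.5% leakage
(r ≈ 0.995 instead of 1). On an endpoint-exclusive full cycle (0–20 h,
11 samples) the harmonics are exact discrete Fourier frequencies and
subtraction is exact. The same leakage shifts the local minima of
`period_scan()` on multi-component signals by a few tenths of an hour;
the scan is a histogramming device, not a precision period estimator.

For gene-set questions the package provides a competitive test
(`competitive_gene_set_test()`): are the cosinor F statistics at a
queried period larger inside a set than outside? The implementation is
a one-sided Wilcoxon rank-sum — exact via the Wilcoxon distribution for
small untied problems, a tie-corrected normal approximation otherwise,
with an optional camera-style variance inflation
$1 + (n_{\mathrm{set}}-1)\bar\rho$ for inter-gene correlation. This is
a deliberate, documented substitute for a full rotation-based
competitive test; it is calibrated (type-I ≤ 0.06 at nominal 0.05
under exchangeability) but does not reproduce any specific published
implementation. Degenerate all-tied inputs return $p = 1$.
`overlap_enrichment()` is the one-sided Fisher/hypergeometric
upper-tail test on a 2×2 membership table.

## Scoring and the baseline

`score_detection()` compares calls with planted truth: a true positive
is planted-rhythmic and called-rhythmic; period accuracy is judged over
true positives, with either component accepted for superimposed genes.
Zero calls report precision 1 with an explicit `no_calls` flag (a
documented convention avoiding 0/0). `benchmark_vs_baseline()` runs,
on identical simulated matrices, the multi-period model selection
against the standard single-period detector (cosinor F test at the
circadian period plus BH) — a stand-in for conventional one-period
rhythm detection, not a reimplementation of any specific published
tool. The baseline has no representation of the harmonics, which is
exactly where model selection gains recall; with only circadian genes
planted the two coincide by construction.

## Numerical choices

* RSS is floored at $10^{-300}$ inside the criterion so perfect
  noiseless fits stay finite and still dominate.
* Constant series are called flat outright (relative total-sum-of-squares
  guard) rather than letting $-\infty$ criteria tie.
* Aliased designs (e.g. $T$ equal to twice the sampling interval, where
  the sine column degenerates to rounding noise) are detected by the
  ratio of singular values of the design, not by pivoted-QR rank, which
  such tiny-but-independent columns fool; they raise an error naming
  the period, and `period_scan()` skips them with `NA`.
* Phases are wrapped into $[0, T)$ with a guard for the
  floating-point fold at the boundary.
* The third harmonic is $22/3$ exactly everywhere internally and is
  printed as 7.33; period matching uses a 0.005 h tolerance.
* All randomness flows from explicit integer seeds; a simulation is a
  pure function of its config.

## Problem sizes

The shipped tests exercise the pipeline at the sizes a laptop handles
comfortably while keeping the statistical claims meaningful: oracle
equivalence on 1,000 random series; FDR calibration on 50 replicates of
2,000 genes; anti-phase recovery on the full 7,212-gene wild-type
design; permutation calibration at 199 shuffles × 500 genes × 20 runs;
enrichment exactness on every 2×2 table with universe ≤ 60 and 2,000
null replicates of the competitive test. The whole suite runs in under
a minute.

## Known limitations

The F-test p-values are post-selection quantities; the Bonferroni
payment makes the BH calls conservative on average but is not a formal
selective-inference correction — the permutation null is the honest
calibration when it matters. Detection assumes a single dominant
period per gene; genuinely superimposed rhythms are assigned their
best single period (this is by design, and the subtraction workflow is
the tool for dissecting them). With only ~3.7 samples per third-harmonic
cycle, phase estimates at 7.33 hr carry substantially more variance
than circadian ones. Finally, all calibration statements are
statements about the generator's Gaussian additive world; real
count-derived expression with heteroskedastic noise will be somewhat
less well behaved.
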