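# ultrarhythm

Model-selection detection of circadian and ultradian **harmonic**
rhythms in expression time courses.

In circadian organisms, clock-controlled transcripts can oscillate not
only at the fundamental period but at integer fractions of it —
*harmonics*. For *Neurospora crassa*, with an intrinsic period near
22 hr, the family of interest is 22 hr (circadian), 11 hr (second
harmonic) and 22/3 ≈ 7.33 hr (third harmonic). `ultrarhythm` is for
chronobiologists and computational biologists who have a gene × time
expression matrix (typically 2-hr sampling over one circadian cycle)
and want each gene classified into exactly one of those periods or
called arrhythmic, with transcriptome-wide FDR control — plus the
downstream analyses such a study needs: amplitude/phase
quantification, a time-label permutation null, anti-phasic phase-group
clustering, cross-genotype comparisons, gene-set enrichment, a
synthetic-data generator and recovery scoring.

## The method

For each gene $y(t)$ (log2 scale) and each candidate period $T$, fit
the cosinor regression

$$ y(t) = m + a\cos\tfrac{2\pi t}{T} + b\sin\tfrac{2\pi t}{T} + \varepsilon $$

by least squares; the flat model $y(t) = m + \varepsilon$ is the
arrhythmic null. The gene's model is the one minimizing
$\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln n$ over {flat, 22, 11,
7.33}, so every gene gets **one** period. If a rhythmic model wins,
significance is the F test of that model against flat, multiplied by
the number of candidate periods to pay for the selection, followed by
Benjamini–Hochberg correction over all expressed genes (flat genes at
p = 1). Derived per-gene quantities: half-amplitude
$A = \sqrt{a^2+b^2}$, peak-to-peak fold amplitude $2^{2A}$, and
acrophase $\varphi = \tfrac{T}{2\pi}\mathrm{atan2}(b,a) \bmod T$.

See `vignettes/harmonic-rhythm-detection.Rmd` for the full model
account, defaults and limitations.

## Worked example

Simulate a wild-type-like transcriptome (2,000 genes, 12 samples every
2 hr, ~25% rhythmic with planted anti-phasic phase groups), detect
rhythms, score against the planted truth, and measure the phase split
of the third-harmonic genes:

```r
library(ultrarhythm)

cfg  <- sim_config(n_genes = 2000, seed = 7)
sim  <- simulate_transcriptome(cfg)
calls <- detect_transcriptome(sim$matrix, fdr = 0.1)
calls
#> rhythm_calls: 2000 genes, FDR <= 0.1
#>   total rhythmic: 547
#>   22 h: 345
#>   11 h: 53
#>   7.33 h: 149

score_detection(calls, sim$truth)
#> recovery_report: 2000 genes, 547 calls | precision 0.903, recall 0.992,
#>   period accuracy 1.000, FDP 0.097

res   <- calls$results
third <- res$gene_id[res$rhythmic & abs(res$selected_period - 22/3) < 0.01]
cl    <- cluster_antiphasic(sim$matrix, third)
cl
#> cluster_assignment (average linkage): Group 1 = 124, Group 2 = 25

phase_group_difference(cl, calls)$radians
#> [1] 3.110
```

Reading the numbers: at FDR 0.1 the detector calls 547 of 2,000 genes
rhythmic with an empirical false-discovery proportion of 0.097 (at or
under the nominal 0.1), every true positive is assigned its planted
period, and the third-harmonic genes split into a large and a small
phase group whose circular mean acrophases are 3.11 radians apart —
anti-phasic co-regulation (π would be exact anti-phase).

The same workflow is scriptable from a shell via the thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ultrarhythm.R", package = "ultrarhythm"))')" \
  simulate --seed 1 --out-matrix wt.tsv --out-truth wt_truth.json
Rscript .../ultrarhythm.R detect --matrix wt.tsv --periods 22,11,7.33 --fdr 0.1 --out wt_calls.tsv
```

Subcommands: `simulate`, `detect`, `cluster`, `null`, `compare`,
`benchmark`.

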