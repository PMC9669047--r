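---
title: "turnomix: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{turnomix: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models behind each turnomix component, the
parameters that matter and their defaults, the numerical conventions that
were pinned for reproducibility, and what the synthetic-data generator
does and does not emulate.

## mRNA stability from three RNA fractions

A 4-thiouridine (4sU) pulse of length $t$ labels nascent RNA. Separating a
sample into labelled (newly-synthesised, $L$), unlabelled (pre-existing,
$U$) and total ($T$) fractions gives, for a gene at steady state under
first-order decay with rate $\delta$ (1/h):

$$\theta \;=\; \frac{\text{labelled pool}}{\text{total pool}}
  \;=\; 1 - e^{-\delta t}, \qquad
  t_{1/2} \;=\; \frac{\ln 2}{\delta}.$$

The three fractions are sequenced as separate libraries, so after
median-of-ratios normalisation the labelled and unlabelled counts sit on
unknown scales relative to total. Because every molecule is either
labelled or not, the mixture identity $T_g = c_L L_g + c_U U_g$ holds per
gene for a per-sample pair of positive correction factors
(`estimateCorrectionFactors()`). The mean factors across samples then give
the labelled share as

$$\hat\theta_g = \frac{\bar c_L \bar L_g}
  {\bar c_L \bar L_g + \bar c_U \bar U_g},$$

where $\bar L_g,\bar U_g$ are group-mean normalised counts per
genotype-batch group (`estimateHalfLives()`). Using the *reconstructed*
total in the denominator rather than the observed $T$ guarantees
$\hat\theta\in(0,1)$ whenever both components are positive; rows with
$\theta \le 0$, $\theta \ge 1$ or a reconstructed total below `minCount`
(default 10 normalised counts) are flagged invalid with a reason code.
Group-mean counts are used before forming $\theta$ (rather than averaging
per-replicate $\theta$s) for variance reduction.

### Why the correction-factor fit is not plain least squares

The obvious estimator — per-sample ordinary least squares of $T$ on
$(L, U)$ without intercept — is severely attenuated on real(istic) counts:
$L$ and $U$ are themselves negative-binomially noisy and almost collinear
across genes (both scale with abundance), a textbook errors-in-variables
setting. At dispersion 0.05 the bias reaches 50–80% of the coefficient
value regardless of sequencing depth, because the dispersion noise floor
does not average away within a library. The default estimator therefore
solves the weighted moment equations

$$\hat c = (Z^\top W X)^{-1} Z^\top W \, T$$

with design $X = (L_j, U_j)$ from the sample being fitted and both the
instruments $Z$ (leave-one-out mean of the other samples' $L, U$) and the
weights $W = 1/\max(\bar T_{-j}, \text{floor})^2$ taken from the *other*
samples, whose counting noise is independent. On noiseless data the
identity is exact, and the estimator reproduces the factors exactly; under
negative-binomial noise at depth $10^6$ it recovers them to a few percent.
Plain OLS remains available as `method = "ols"`. Eligibility is restricted
to genes with normalised total $\ge 10$ to suppress zero-inflation
leverage.

### Batch-standardised stability change

With two experimental batches showing very different spreads of the
stability estimates, the per-gene log2 fold change in half-life
$d_{b,g} = \log_2(t_{1/2,\mathrm{dKO}} / t_{1/2,\mathrm{control}})$ is
divided by its within-batch standard deviation before averaging:

$$\text{score}_g = \frac{1}{|B_g|}\sum_{b\in B_g} \frac{d_{b,g}}{s_b},$$

over the batches $B_g$ in which the gene is valid in both genotypes
(`standardizedStabilityChange()`). Within each batch the standardised
values have unit standard deviation by construction, and swapping the
genotype labels negates the score exactly.

## The expression-local z statistic

Count-based differences are heteroscedastic: the spread of per-gene
changes depends strongly on expression. `intensityDiff()` standardises
each gene's difference against the genes with the most similar mean
expression:

$$z_g = \frac{d_g - \mathrm{mean}\{d_{W(g)}\}}
             {\mathrm{sd}\{d_{W(g)}\}},$$

where $W(g)$ is the window of the $w$ genes nearest to $g$ in mean
expression, always including $g$ itself, with
$w = \min(G, \max(200, \lceil 0.01\,G\rceil))$ by default. Two-sided
standard-normal p-values and Benjamini–Hochberg FDRs are attached. In
pooled mode the windows are formed over the union of several contrasts'
(expression, difference) points, so the local standard deviations are
modelled jointly and the z-scores are comparable between contrasts.

Numerical conventions, pinned for determinism:

* window membership uses the composite key (|expression difference|,
  expression, gene id): ties in expression break lexicographically, and of
  two equally distant neighbours the lower-expression one enters first;
* a window whose differences are all identical yields $z = 0$ (the focal
  gene is in its own window, so it necessarily equals the window mean);
* windows below 3 genes are an error.

The window size and the inclusion of the focal gene are design choices —
validated by a null-calibration property (i.i.d. normal differences give
a p < 0.05 fraction within [0.04, 0.06] at $G = 10^4$) and by exact
agreement with a brute-force window oracle at small $G$, rather than by
matching any particular implementation bit-for-bit. For stability
significance the expression axis is the mean normalised count over the
total and newly-synthesised libraries, log2-transformed (with pseudocount
0.5) before windowing.

Per-assay differential tables (`assayDiff()`) use plain log2 ratios of
group-mean normalised counts with pseudocount 0.5; no shrinkage of fold
changes is performed (externally shrunken estimates can be supplied to
`zScoreFromLFC()`, which divides by the overall standard deviation
without centering).

## Regulatory modes

`selectDerepressed()` takes the union of genes with a positive change
passing, per measure: FDR < 0.1 (newly-synthesised), FDR < 0.001 (total),
stability z > 2, FDR < 0.05 (ribosome-protected). The thresholds differ
because the assays differ in sensitivity; each is set so that genes with
the most evidence in that assay contribute.

`clusterModes()` clusters the z-score profiles over the newly-synthesised,
stability and ribosome-protected measures only (total is carried for
reporting), using $1-$Pearson correlation as the distance and complete
linkage, cutting at $k = 5$ by default. Pearson is the default reading of
"correlation"; $k$ is exposed because nothing in the method fixes it.
Rows with a constant profile (undefined correlation) are excluded with a
warning. Rows are pre-sorted by gene id and clusters renumbered by their
lexicographically smallest member, so the partition and its labels are
independent of input order. Per-cluster medians get categorical labels:
`++` above 1.2, `+` above 0.4, `-` below −0.4, blank otherwise. The
z-scores are clustered as-is, with no additional row standardisation.

## CLIP target calling and summarisation

Crosslink sites are single-nucleotide, BED-style 0-based half-open
intervals; assignment to gene features is strand-aware, and a site
touching several features goes to a 3'UTR if any overlapping feature is
one, then by the fixed priority CDS > 5'UTR > intron > non-coding (only
the 3'UTR-first rule is methodologically meaningful; the rest is pinned
for determinism, ties at equal priority by smallest gene id).

Two consistency rules designate 3'UTR targets:

* **iCLIP** (grouped replicates, two antibodies): a gene is a target if
  each antibody group has at least one 3'UTR site with FDR < 0.05;
* **HITS-CLIP** (individual replicates): a gene is a target if an
  *identical* significant site — exact (chromosome, position, strand)
  equality — occurs in its 3'UTR in at least two replicates. A window
  variant (`tolerance`) is available but off by default.

Both rules are monotone: adding qualifying sites or raising the FDR
threshold can only grow the target set.

The per-gene summary score sums reads at 3'UTR sites with FDR < 0.25
(duplicate rows at one position are aggregated first; reads summed,
smallest FDR kept), then normalises by the 90th percentile of sums over
detected genes and takes log2 with no pseudocount; undetected genes have
no score. Percentiles use linear interpolation between order statistics
(R type 7), pinned because the quantile convention changes scores at the
second decimal.

ARE motif scanning counts possibly overlapping occurrences of UAUUUAUU
(T/U-normalised, so DNA FASTA works unchanged). Conservation smoothing is
a centred 7-nt moving average whose window shrinks at the sequence edges.

## Matched-control enrichment

To ask whether a gene set is enriched for CLIP targets or ARE motifs
without confounding by expression or 3'UTR length,
`buildMatchedControls()` draws, per focal gene and control set: (1)
candidates (excluding focal genes and genes already used in this set)
with < 25% 3'UTR-length difference — relative to the focal gene's length,
the natural reading, pinned — or the 1000 length-closest if the band is
smaller; (2) of these, the 100 closest in log2 FPKM; (3) one uniform
draw. One hundred sets give the control median and 5th/95th percentile
band against which the observed count is normalised
(`enrichmentVsControls()`). Controls may recur across sets but not within
one. Ties at the pool cutoffs break by gene id. Note that in small
universes (a few thousand genes) the 1000-gene fallback dominates and
length matching loosens; with ≥ 5000 genes the strict 25% band is the
common path. The expression vector is an explicit input so each CLIP
dataset can be matched against expression from its own stimulation
condition.

`compareRateLimiting()` contrasts z-scores of genes annotated (by
literature curation, consumed as a flag vector) as rate-limiting versus
not, with an equal-variance two-sided t-test per assay and BH correction
across assays.

## Isotopologue correction and metabolite tables

For ¹³C tracing, the measured ion counts at mass shifts M+0…M+k mix the
true tracer-label distribution with natural heavy isotopes.
`naturalAbundanceMatrix()` builds $C[i,j]$ = probability that a molecule
with $j$ tracer labels appears at shift $i$, by convolving the per-atom
heavy-isotope distributions (C, H, N, O, Si, S; frequencies pinned in
`isotopeAbundances()`) of all non-tracer atoms of the measured fragment
and, by default, natural ¹³C at the $n-j$ unlabelled tracer positions
(full correction; disable with `natural13CAtTracer = FALSE` for
sensitivity analysis). `correctMID()` solves $y = Cm$ by non-negative
least squares (Lawson–Hanson, on the unit-sum spectrum since the solver
tolerance is absolute) and renormalises — preferred over matrix inversion,
which can produce negative isotopologues on noisy data. Fractional
labelling is $\sum_j j\,m_j / n$; the labelled/unlabelled partition of
the total relative ion count is total × FL and its complement (the
complement convention is one of two defensible readings; both components
are returned so the other is a subtraction away).

LC–MS tables are normalised to the per-sample internal standard and
optionally total ion content, with provenance recorded; per-metabolite
genotype comparisons use fold changes of means and equal-variance t-tests,
and metabolite pair ratios (e.g. α-ketoglutarate : succinate) are formed
per sample, not as ratios of means. Heatmap-style scaling uses row-wise
log2 deviation from the row mean.

## The synthetic-data generator

Every input the pipeline consumes can be generated with known ground
truth under a single seed (`simulateBundle()`), so the whole analysis is
testable offline. The generator emulates:

* **Kinetics** — per-gene synthesis rate α (log-normal, arbitrary scale),
  decay rate δ (log-normal with median half-life 4 h, log-SD 0.8,
  spanning roughly 1–16 h), translation efficiency (log-normal), and
  negative-binomial dispersion 0.05, a standard bulk RNA-seq noise level.
  Steady state is assumed throughout — abundance is α/δ and the labelled
  share $1-e^{-\delta t}$ — deliberately matching the estimator's model
  so recovery tests are exact; no time-course ODE is simulated.
* **Effects** — direct targets (default 5% of genes) gain 2× stability
  (δ × 0.5) and 2× translation efficiency in the knockout; indirect genes
  gain 2× synthesis. The magnitudes are free generator parameters, chosen
  as plausible round numbers: the emulated study reports no effect-size
  distributions.
* **Design** — two batches with independent per-gene log-normal abundance
  factors (SD 0.2 on the log2 scale), one replicate per genotype and
  batch for the fractions and a 2+3 replicate split for ribosome
  profiling, mirroring the emulated experiments. The labelling pulse is
  1 h. Per-fraction global scale factors emulate the unknown capture
  scales the correction factors recover; `depth` scales each library to
  an expected size.
* **CLIP** — 3'UTRs with log-normal lengths laid out on one chromosome,
  a TATTTATT motif planted wholly inside every bound (direct-target)
  gene's UTR (and scrubbed from unbound UTRs so motif presence tracks
  truth), crosslink sites at the planted motif with high reads and
  Beta(1, 50) FDRs, uniform-FDR background sites elsewhere. Site FDRs are
  emitted directly; the upstream permutation test that would produce them
  is out of scope.
* **Metabolomics** — a 52-metabolite LC–MS panel with planted knockout
  folds (glutamine 8×, matching a reported "over seven-fold" increase;
  α-ketoglutarate 3×; modest increases in pentose-phosphate,
  methionine-cycle and TCA intermediates), log-normal baselines,
  multiplicative noise of 0.15 log2 units per measurement (CV ≈ 11%, a
  realistic level for targeted LC–MS relative areas), six replicates per
  genotype, and internal-standard/TIC rows so the normalisation path is
  exercised. GC–MS spectra are built by convolving planted MIDs with the
  natural-abundance matrix of synthetic stand-in fragment formulas — real
  derivatised-fragment formulas are instrument-specific user inputs.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level artefacts (mapping, positional
bias), non-steady-state kinetics during the pulse (the estimator is known
to underestimate stability for genes far from steady state; no correction
is attempted), 4sU incorporation efficiency below 1 (exposed as
`purity` but 1 by default), correlated noise between fractions,
chromatographic peak shapes, and compound misidentification.

## Sizes used by the automated checks

The bundled checks run at sizes chosen to finish in a couple of minutes
on one core while leaving the conclusions stable: 2000 genes at $10^6$
reads per fraction library for half-life recovery (one pooled half-life
per gene on an all-null transcriptome, since a single true half-life is
the quantity compared); $10^4$ genes for the z-statistic null
calibration; 200 archetype genes for mode recovery; a 2000-gene universe
with 100 control sets for the enrichment calibration (200 null and 100
planted focal sets); and the default metabolomics panel. Re-running with
other seeds moves the stochastic quantities by amounts consistent with
their sampling noise.

## Known limitations

* Half-life estimates for very stable genes (θ near 0) are noise-limited;
  the invalid-row reason codes make the failure mode explicit rather than
  silent.
* The per-assay p-values come from the local-SD z statistic, not from a
  negative-binomial GLM; with few replicates they are calibrated under
  the null by construction of the window, but they do not model
  gene-specific dispersion.
* Enrichment confidence bands are resampling percentiles, not tests; with
  100 control sets the band itself has sampling noise of a few counts.
* The MID correction assumes the fragment formula is known exactly;
  errors in the formula propagate directly into the corrected
  distribution.
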