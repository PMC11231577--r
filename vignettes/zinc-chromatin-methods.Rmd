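---
title: "Methods: zinc perturbation, chromatin accessibility and motif enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zinc perturbation, chromatin accessibility and motif enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`zincatac` implements an analysis chain for asking how acute perturbations
of the labile nuclear Zn^2+^ pool (chelation with TPA, or ZnCl~2~
supplementation) reshape chromatin accessibility and transcription-factor
engagement. The chain runs from single-cell FRET-sensor calibration of
nuclear Zn^2+^, through ATAC-style differential accessibility and
rank-based motif enrichment stratified by promoter versus distal regions,
to candidate binding-site selection and ChIP-qPCR percent-input
quantification. Because the real sequencing and imaging inputs are
external deposits, the package ships seeded generators that emulate every
input's statistical structure; all tests are recovery- and property-based
against those generators.

# Nuclear Zn^2+^ quantification

The sensor reports a background-corrected FRET ratio
$R = (A - A_{bg}) / (D - D_{bg})$ per cell and timepoint. An in situ
calibration provides each cell's apo ratio $R_{min}$ (after chelation)
and saturated ratio $R_{max}$ (Zn^2+^/pyrithione). Concentration follows
the Hill-form inversion

$$[\mathrm{Zn}^{2+}] = K_d' \left( \frac{R - R_{min}}{R_{max} - R} \right)^{1/n}$$

with $K_d' = 5.3$ nM and $n = 0.29$ (the sensor's published constants,
the package defaults).

Choices a user should know about:

* **Plateau estimator.** Each phase ratio is the median of the last
  `plateau_window` (default 10) valid frames of the phase. The estimator
  is unstated in the source protocol; the median is robust to the
  transients that follow solution changes.
* **Censoring.** With `u = (R - R_min)/(R_max - R)`, estimates with
  `u <= eps_low` are reported `below_range`, where `eps_low` is derived
  from a concentration floor (default 1 pM, the sensor's stated
  quantification limit); ratios within `eps_high` (default 1%) of
  $R_{max}$ are `above_range` because the inversion diverges there.
  Censored cells carry no concentration, they are never imputed.
* **Per-cell calibration.** $R_{min}$/$R_{max}$ are extracted per cell,
  as in situ calibration is performed per experiment; cells missing a
  calibration phase, or with $R_{max} \le R_{min}$, are excluded with a
  recorded reason.

The trace generator emits channel intensities (not ratios) so background
correction is exercised end to end. Its chelation and saturation phases
hold the sensor exactly apo and exactly saturated: that is the assumption
the in situ calibration itself makes, and it is what makes the noiseless
round-trip exact (recovered concentrations match truth to $<10^{-9}$
relative). Rest and treatment phases follow the forward Hill model at
150 pM and 75 nM by default, the resting and post-ZnCl~2~ values the
study design targets.

# Interval algebra and annotation

Regions are 0-based half-open BED-style intervals. Merging coalesces
overlapping *and book-ended* intervals (half-open adjacency is contiguous
chromatin). Blacklist handling removes an overlapping region entirely
rather than trimming it. The probabilistic peak-combination step of the
published enrichment tool is replaced by plain union-merge: no formula for
it is available, and the downstream scan window is anchored on region
centers, so only boundary detail is affected.

The "-F 0.5"-style filter retains each ChIP peak whose total coverage by
transcribed regions is at least half *of the peak*. The tool convention
and the prose disagree on which side the fraction refers to; the prose
reading is the default and `fraction_of = "b"` switches to the other
convention.

Promoters are the 1,000 bp directly upstream of a TSS (strand-aware,
clipped at coordinate 0). A region overlapping any promoter is labeled
`promoter` even if it also overlaps a gene body (the promoter analysis
filter is applied first); otherwise gene-body overlap makes it `genic`,
else `nongenic`. The three labels partition any region set.

All set operations are verified against brute-force oracles (explicit
base-coverage unions, all-pairs overlap scans) on hundreds of randomized
instances.

# Motif scanning and exact p-values

Scanning is FIMO-style: log~2~ likelihood-ratio scores of the
position probability matrix against a 0-order background, both strands of
the ±1,500 bp window around each region center, hits reported at
$p \le 10^{-5}$. Implementation details:

* **Pseudocount** $10^{-4}$ is added to matrix entries (columns
  renormalized) before log-odds, so only `N` scores $-\infty$.
* **Background** defaults to the scanned genome's base frequencies; the
  source analysis does not state its background choice.
* **Exact p-values** come from discretizing per-column scores to
  `score_precision` (default 0.01) bits and convolving the column score
  distributions by dynamic programming. Scanning uses the same quantized
  matrix, so a reported score and its p-value are mutually consistent,
  and "p below cutoff" reduces to an integer score threshold. The
  quantization error of a window score is bounded by $W \cdot
  \delta / 2$ bits. Tables match exhaustive $4^W$ enumeration for
  $W \le 6$ in the tests, and the empirical false-positive rate on
  background sequence is bounded by the cutoff.
* **Clipping, ties.** Windows are clipped (not dropped) at chromosome
  ends; the best hit per region/motif is lowest p, then smallest
  |offset|, then + strand.

# Differential accessibility

The test is deliberately a *simplified* negative-binomial Wald test, not
a DESeq2 re-implementation (parity with DESeq2 is a non-goal; DESeq2's
shrinkage machinery is not reproduced). Counts are normalized with
median-of-ratios size factors rescaled to geometric mean 1; group means
$\hat\mu_c, \hat\mu_t$ give $\log_2 \mathrm{FC}$; a per-region dispersion
$\hat\alpha$ is estimated by method of moments pooled across both groups
(floored at $10^{-8}$); the delta method under
$\mathrm{Var}(y) = \mu + \alpha \mu^2$ gives the standard error.

Two departures from the most naive recipe, both forced by calibration:

* **t reference, not normal.** The Wald statistic with a plug-in moment
  dispersion is anticonservative against a normal reference at small
  replicate numbers (measured type-I error ≈ 0.083 at 5v5 for a nominal
  0.05). Referring it to Student's t with $n_c + n_t - 2$ degrees of
  freedom restores nominal error (≈ 0.048), which the acceptance
  calibration band requires.
* **Conditional pseudocount.** The 0.5 pseudocount enters the
  fold-change only when a group mean is zero (the region is then
  flagged). An always-on absolute pseudocount breaks exact invariance of
  the fold-change under depth rescaling, because geometric-mean-1 size
  factors change the overall scale of normalized counts.

Regions are ranked for enrichment by
$\mathrm{sign}(\log_2 \mathrm{FC}) \cdot (-\log_{10} p)$ (ties broken by
region id). Which exact statistic the published pipeline ranks by is not
stated; this signed significance is the declared choice and the ranking
function is a plain column any caller can replace.

**A normalization caveat the tests document.** When a large
one-directional fraction of regions is truly differential (the planted
default is 30% at $\log_2 \mathrm{FC} = 1$), median-of-ratios size
factors are themselves contaminated: treatment medians inflate and
control medians deflate, and the median estimated fold-change of the
affected regions drops to roughly 0.7. This is a property of
global-scaling normalization, not of this implementation; DESeq2 behaves
the same way. The generator's contract (counts really carry the planted
effect) is therefore tested under the recorded true depth factors, and
the fold-change-recovery acceptance check uses a 10% planted share, the
regime in which global scaling is trustworthy. Motif-enrichment recovery
is unaffected: the ranking, not the absolute fold-change, drives the
E-score.

# Motif enrichment (E-scores)

For a ranked list of $N$ regions with motif hits at ranks $r_1..r_H$,

$$E = 1 - 2\,\overline{\left(\frac{r_h - 0.5}{N}\right)} \in (-1, 1),$$

a rescaled Mann–Whitney statistic: positive when hits concentrate among
regions gaining accessibility under treatment. The published E-score
formula is not restated in the source; this statistic is a declared
stand-in — simple, exactly antisymmetric under ranking reversal (it is
computed from the integer rank sum, so antisymmetry is bitwise exact),
and permutation-testable. Numerical parity with the published tool is a
non-goal.

Significance is a two-sided permutation test with the +1 finite-sample
correction, $p = (1 + \#\{|E_{perm}| \ge |E_{obs}|\})/(B + 1)$; a normal
approximation with the exact null variance
$(N-H)(N+1)/(3HN^2)$ is reported alongside. P-values are BH-adjusted
across motifs within each stratum (`all`, `promoter`, `nongenic`).
Hits are binary per region/motif — no distance-to-center weighting and no
GC correction (unstated in the source; GC correction is out of scope).
Quartile barcodes split the stratum's ranked list into four contiguous
blocks (earlier blocks take the remainder) and count hits per block.

# ChIP-qPCR quantification

Technical-replicate Cts are averaged (undetermined wells excluded, never
imputed). Per target, condition and biological replicate, a standard
curve is fit to the input dilution series (1, 1:10, 1:100, 1:1,000)
against $\log_{10}$ relative quantity; slope, $R^2$ and efficiency
$10^{-1/\mathrm{slope}} - 1$ are reported, and a non-negative slope
rejects the plate. Quantities are dilution-relative, as the protocol's
curve is built from dilution factors, not copy numbers.

The percent-input equation in the protocol is typeset with its fraction
structure lost; the implemented arrangement is the standard per-eluate,
per-chromatin normalization consistent with the listed volumes:

$$\%IP = 100 \cdot \frac{q_{IP} \cdot V_{ChIP\ eluate} / V_{chromatin\ for\ ChIP}}
                        {q_{input} \cdot V_{input\ eluate} / V_{chromatin\ as\ input}}$$

Under this arrangement the curve intercept cancels, and the noiseless
synthetic plate (defaults: input = 10 µl of chromatin, 45 µl into the
ChIP, 200 µl eluates) inverts to exactly $100 \times$ the true bound
fraction. SNR divides +Ab by −Ab percent input (reference line 1.5);
fold enrichment divides each treated replicate's +Ab percent input by its
matched control replicate's, so the control condition is identically 1.
Outliers in enrichment ratios are flagged with Tukey's 1.5×IQR fences
(linear-interpolation quartiles) — the protocol names only an
"inter-quartile test", so the standard multiplier is used — and flagged
values are never dropped.

# The synthetic world

One `synth_config()` seed fans out deterministically to per-stage child
seeds, so every generator is independently reproducible and identical
configurations give byte-identical files. Defaults are the conditions the
analysis is designed around:

| parameter | default | note |
|---|---|---|
| genome | 4 Mbp, 41% GC | i.i.d. bases; one chromosome |
| regions | 2,000 × 500 bp | non-overlapping, uniformly placed |
| motifs | 21 PPMs, width 15, max column 0.97 | 1 planted + 20 decoys |
| planted share | 30% of regions | one instance, random offset/strand |
| counts | NB, µ = 200, α = 0.05, 5v5 | Var = µ + αµ², depth factors ~ logN(0, 0.15) |
| effect | $\log_2 \mathrm{FC} = 1$ | treatment mean of motif-bearing regions |
| FRET | 150 pM rest, 75 nM treatment | ratio noise SD 0.02, 50 cells |
| qPCR | slope −3.3219, noise 0.15 cycles | 6 biological × 2 technical replicates |

Width 15 for the planted motif ensures instances with up to two sampled
mismatches still clear the $10^{-5}$ scan threshold, so the planted-site
recovery target (≥95%) is attainable; at widths near 12–13 the two-
mismatch word-set's exact p-value straddles the cutoff.

What the generators deliberately do **not** model: read-level FASTQ
structure, Tn5 insertion and fragment-size bias, GC-dependent coverage,
overlapping/nested peaks, real gene architecture (the gene annotation is
plumbing for stratification), photobleaching, or qPCR efficiency drift.
A green recovery test therefore establishes that the analysis inverts its
own stated forward models at realistic noise — not that it reproduces the
study's numbers, which depend on external raw data (the deposited
accessions) and are explicitly out of desk-scale reach.

# Reproducibility

`run_all()` executes the whole chain on a configuration and writes every
output with an MD5 manifest; identical configurations reproduce identical
hashes. `scripts/acceptance.R --seed S --out path` runs the demo-scale
pipeline (600 regions, 8 motifs; statistical settings unchanged) from a
fresh seed and writes the result summary JSON. The demo scale exists only
to keep runtimes in minutes; the defaults above remain the canonical
world for the recovery experiments.
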