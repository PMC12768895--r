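---
title: "Copy-number analysis of plasma ctDNA from low-pass WGS: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number analysis of plasma ctDNA from low-pass WGS: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmacna)
```

## The problem

Pediatric neuroblastic tumors (neuroblastoma, ganglioneuroblastoma,
ganglioneuroma) shed cell-free DNA into plasma. Because neuroblastoma
genomes carry recurrent chromosomal copy-number aberrations (CNAs) — 17q,
7, 2p and 1q gains; 1p, 3p, 11q and 14q losses; focal MYCN amplification on
2p — the *aggregate CNA burden* visible in shallow (0.1–0.5×) whole-genome
sequencing of plasma DNA is itself a diagnostic signal. `plasmacna`
implements that analysis end to end: binned read counts are standardized
against a panel of healthy-control plasma profiles, segmented by circular
binary segmentation (CBS), summarized into a tumor DNA fraction (TFx), and
scored for homologous-recombination deficiency (HRD) and arm-level
aberrations; Wilcoxon and ROC/Youden machinery evaluates the resulting
classifier. A negative-binomial cohort simulator stands in for patient
data, which in studies of this kind is access-controlled.

## The model, stage by stage

### Binned coverage and the control-panel Z-score

The genome (22 hg19-like autosomes; sex chromosomes are excluded by default
because control panels mix sexes) is tiled into fixed 200-kb bins. For a
sample with per-bin read counts $r_b$, depth normalization sets
$x_b = r_b / \bar r$ so every sample has genome mean 1; the per-bin score
against $K$ controls is

$$Z_b = \frac{x_b - \mathrm{mean}_k(x_{b,k})}{\mathrm{stdev}_k(x_{b,k})},$$

with the $n-1$ SD denominator (a switch selects $n$). Depth normalization
before standardization is a deliberate choice: the raw-coverage version of
this formula is incoherent when samples differ in total read count. Bins
with zero baseline mean or SD are masked; kept bins whose SD falls below
5% of the genome-median SD have it floored there, so no bin can contribute
unbounded Z-scores. The log2 ratio
$\log_2(x_b / \mathrm{mean}_k(x_{b,k}))$ is carried alongside (zero
coverage clamped at $10^{-6}$ before the log).

### Circular binary segmentation

Per chromosome (or per arm, see below), CBS finds the circular arc
maximizing the absolute two-sample t-statistic between the arc and its
complement; the split is accepted when its permutation p-value — the
fraction of shuffles whose maximal statistic reaches the observed one,
with the $(1 + \#\{T_\pi \ge T\})/(1+B)$ convention — falls below
$\alpha = 0.05$, and the procedure recurses. Defaults: $B = 1000$
permutations, minimum two bins per side, lexicographic tie-breaking
(smallest $i$, then $j$) for determinism. Note that an arc and its
circular complement describe the same split with identical $|t|$; the tie
rule therefore reports the lexicographically first of the pair.
Permutation loops stop early once the exceedance count proves
$p \ge \alpha$; the accept/reject decision is unaffected and the reported
p-value is then based on the permutations actually run. A final undo pass
merges adjacent segments whose means differ by less than `undo_sd` (1.0)
pooled within-segment SDs. Zero-variance windows are guarded by an epsilon
in the pooled SD; constant vectors return no-split.

The segmentation statistic is the log2 ratio; per-segment mean Z is carried
for reporting, since the heatmap-style summaries of this field are drawn in
Z units while the TFx mixture works in ratio units.

**Per-arm segmentation in the pipeline.** The exported `cbs_segment()`
default treats each chromosome as one circular unit. The pipeline
(`segment_profile()`, `analyze_sample()`) instead segments each *arm*
independently: the centromere is an a-priori copy-number discontinuity,
the LGA score never counts centromere-crossing breaks anyway, and forcing
the boundary preserves arm-level signal that a whole-chromosome scan
dilutes at low tumor fraction (a 17q gain at $f = 0.05$ shifts its bins by
only $\log_2(1.025) \approx 0.036$).

### Tumor-fraction estimation

A bin with integer tumor copy state $c$ in a sample of tumor fraction $f$
has expected relative coverage $(fc + 2(1-f))/2$. Because depth
normalization rescales to genome mean 1, coverage is *compositional*: the
expected observed log2 ratio of a segment is
$\log_2\frac{fc+2(1-f)}{2} - \log_2 \bar\mu(f)$, where $\bar\mu(f)$ is the
bin-weighted genome-mean mixture. Ignoring this offset biases the estimate
low (a genome with a large gain pushes every diploid segment below zero).

`estimate_tfx()` grid-searches $f$ (step 0.0025 up to 0.6, so the 0.2%
reporting threshold is representable; coarser above). At each $f$ every
segment is assigned the state maximizing a Gaussian log-likelihood of its
mean ratio, with per-segment
$\sigma_s = \max(\hat\sigma_{\mathrm{bin}}/\sqrt{n_s}, 10^{-3})$ where
$\hat\sigma_{\mathrm{bin}}$ is the MAD of within-segment bin residuals
pooled over the genome — pooled, because the within-segment spread of a
segment carved around a noise extreme is biased small. The offset
$\log_2\bar\mu(f)$ is re-estimated by a three-step fixed-point iteration.
The state prior has three parts, all calibrated or argued a priori:

* a flat penalty $\lambda = 3.0$ per non-diploid segment;
* a genomic-span occupancy prior, $+\log(N/n_s)$ for $c \ne 2$: real tumor
  CNAs occupy chromosome arms or whole chromosomes, while segmentation
  artifacts are small — the prior encodes that asymmetry;
* a diploid-distance term $0.5\,|c-2|$. This breaks an exact aliasing:
  states $\{1,3\}$ at fraction $f$ produce the same expected ratios as
  $\{0,4\}$ at $f/2$, so without the term the smallest-$f$ tie rule
  systematically halves the estimate.

A uniform artifact component on $[-3, 3]$ log2 units with prior 0.05
bounds the influence any single spurious segment can exert on $f$.

**Why the calibration matters.** At the paper-scale depth (about 60
expected read pairs per 200-kb bin), CBS at $\alpha = 0.05$ produces on
the order of one to three false splits per null genome, and the resulting
small segments carry apparent evidence comparable to a true $f \approx
0.05$ arm event. With a flat penalty alone, no value of $\lambda$ both
zeroes flat genomes and preserves low-fraction sensitivity. With the
occupancy prior and artifact component in place, $\lambda$ was chosen as
the smallest value on a coarse grid for which all 25 null replicates
estimated exactly 0; the selected $\lambda = 3$ gives mean absolute
recovery error $\le 0.015$ at true $f \in \{0.05, 0.1, 0.2, 0.4\}$. A
residual noise floor is expected behavior for CNA-burden estimators at
this depth, which is why the downstream decision rule conjoins TFx with an
independent arm-level Z criterion.

Ploidy is fixed at 2 — there is no whole-genome-duplication search — and
ties in the grid score resolve toward the smaller fraction.

### HRD score (large genomic alterations)

The HRD score is the count of copy-level breaks between directly adjacent
same-arm segments, both spanning at least 10 Mb, with a mean-ratio step of
at least `delta_min = 0.1`. Segments under 3 Mb are first smoothed into
the closer-mean neighbor, so small interstitial fragments do not break the
adjacency of their large flanks. Centromere-crossing junctions never
count. The 0.1 step threshold is a fixed default chosen for determinism;
methods in this family often derive it from the data's step-size
distribution, and the parameter is exposed for that reason.

### Arm calls, decision rule, diagnostics

Arm-level calls Stouffer-combine the bin Z-scores,
$Z_{\mathrm{arm}} = \sum_b Z_b / \sqrt{n}$, and call a gain (loss) at
$Z_{\mathrm{arm}} \ge 3$ ($\le -3$); arms with fewer than 5 usable bins
are flagged and never called. In high-burden samples the compositional
recentering can push opposite-sign aggregate Z on unaffected arms; this is
inherent to depth-normalized coverage and documented rather than hidden.
The follow-up rule is a conjunction — TFx $\ge$ 0.2% AND at least one arm
$|Z| \ge 3$ — with the OR variant available behind a switch; the source
material lists both conditions jointly without stating the combinator, and
the conjunction is the clinically conservative reading. The same
conjunction protects healthy controls from the TFx noise floor.

Group comparisons use in-package Wilcoxon tests: rank-sum exact by
enumeration for $n_1+n_2 \le 12$ without ties, signed-rank exact for
$n \le 16$ tie-free (the threshold covers the 16-pair treatment-response
design), both falling back to normal approximations with tie and
continuity corrections. ROC AUC uses the Mann–Whitney rank identity (ties
count ½) with a stratified percentile bootstrap CI (2000 resamples,
seeded); the Youden cutoff is brute-forced over observed thresholds with
ties broken toward higher specificity, then the lower cutoff ("positive if
score ≥ cutoff").

## The simulator: what it emulates and what it does not

`simulate_cohort()` draws one lognormal per-bin bias vector (SD 0.1) per
cohort — systematic bin-level bias that the control baseline removes, GC
and mappability effects subsumed — and per-bin counts from a negative
binomial with mean $\mathrm{depth} \cdot \mathrm{bias}_b \cdot
(f c_b + 2(1-f))/2$ and size $2\cdot\mathrm{depth}$ (variance 1.5× mean at
the mean depth). Event presets encode the recurrent neuroblastoma
patterns; paired pre/post-chemotherapy specs reuse one event list at a
50-fold lower fraction. Controls are simulated at $f = 0$ exactly: the
TFx the estimator reports for them is its own noise floor, emerging
rather than injected.

Deliberately not modeled: read-level artifacts (the package consumes
counts or alignments, not FASTQs), GC correction as a separate effect,
subclonal mixtures, and inter-sample bias differences. A green
simulation test therefore establishes that the *statistical pipeline*
behaves as specified under the stated noise model — not that real plasma
libraries are free of platform effects the baseline cannot remove.

Tests run on a rescaled frame: 2-Mb bins at depth 600 (dispersion
$2\cdot$depth). Per-arm aggregate Z and segment-mean standard errors are
invariant under this joint rescaling, so the statistical difficulty
matches the stated 200-kb/depth-60 world while segmentation cost drops
two orders of magnitude.

## Numerical choices and degenerate inputs

* Permutation p-values are never zero ($(1+k)/(1+B)$) and permutation
  streams are seeded; the same seed reproduces a run bit for bit.
* Constant vectors, all-zero profiles, empty segment sets, single-class
  ROC labels and zero-denominator predictive values raise typed errors or
  return missing values as documented, never silent numbers.
* Midpoint-at-centromere bins belong to q; segment bp coordinates span
  surviving (unmasked) bins; SEG export is 1-based inclusive while
  everything internal is 0-based half-open.
* `implied_counts()` reconstructs integer confusion counts from printed
  rounded sensitivity/specificity and group sizes by nearest-integer
  inversion; with groups of ≤ 50 the inversion is unambiguous.

## Known limitations

* TFx has a depth-dependent noise floor (sub-percent at the scaled
  default; about 2–5% for single worst-case genomes when segmentation
  cascades) and a single-clone, diploid-ploidy model: high-ploidy genomes
  alias to lower fractions by construction.
* The HRD step threshold is fixed, not data-derived; scores on real data
  are sensitive to that choice.
* Arm calls in high-burden genomes can include compensatory opposite-sign
  calls (compositionality), so the call matrix is a screening readout,
  not a karyotype.
* The permutation CBS is quadratic per split; genome-scale runs at 200-kb
  resolution are minutes per sample on one core, which is why the bundled
  demos use the rescaled frame.
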