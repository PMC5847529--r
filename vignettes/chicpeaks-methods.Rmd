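---
title: "Methods: models, parameters, and design choices in chicpeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in chicpeaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the statistical model behind `chicpeaks`, the
meaning and default of every tunable parameter, what the bundled
simulator does and does not emulate, and the numerical decisions that the
function reference is too terse to justify.

## 1. Data model

A Capture Hi-C (CHi-C) experiment is represented by four tibbles:

- a **fragment map**: the in-silico restriction digest of the genome
  (`digest_sequence()`, `new_fragment_map()`), 0-based half-open
  coordinates, with captured fragments flagged by `mark_captured()`;
- **risk loci**: capture regions merged with their annotating SNPs by
  `define_loci()`;
- **pair counts**: per-replicate di-tag counts for fragment pairs, in
  canonical `frag_lo < frag_hi` order (`aggregate_pair_counts()`);
- **trans counts**: per-fragment, per-replicate totals of trans-chromosomal
  di-tags (`compute_trans_counts()`), the interactability measure.

`classify_ditags()` assigns each di-tag to exactly one class, tested in
this order: `same_fragment` (dropped, with a warning — these are
self-ligation artefacts), `off_target` (neither end captured),
`trans` (ends on different chromosomes; contributes only to trans
counts), `within_capture` (both ends captured, cis, within the distance
ceiling), `capture_to_cis` (one end captured, cis, within the ceiling),
and `out_of_range` (cis beyond the ceiling; discarded and deliberately
**not** counted as trans signal). Within-capture and capture-to-cis pairs
are modelled separately throughout because their count distributions
differ: both ends of a within-capture pair were enriched by the capture
step.

Assumptions worth stating explicitly: di-tags are exchangeable within a
replicate (no strand or orientation model); fragments are small relative
to the distances of interest, so the midpoint distance
`floor((start + end) / 2)` differences suffice; and replicates of one
cell line share the same underlying contact structure, differing only in
depth and noise.

## 2. Interactability filter

### Model

For captured fragment $i$ and replicate $r$, the trans-ligation total
$N_{T,ir}$ is bimodal across fragments: failed baits pile up near zero,
working baits form a broad overdispersed component. We model the working
component as a negative binomial observed only above a truncation point
$t$:

$$P(X = x \mid X \ge t) = \frac{f(x; \mu, \theta)}{1 - F(t - 1; \mu, \theta)},$$

with $f$, $F$ the NB($\mu$, size $\theta$) mass and distribution
functions. `fit_truncated_nb()` maximises this conditional likelihood
over $(\log \mu, \log \theta)$ with Nelder–Mead from three starts
(method-of-moments, and the same with $\mu$ doubled/halved), relative
tolerance $10^{-8}$. Working on log scale keeps the optimiser
unconstrained; multiple starts guard against the flat ridges the NB
likelihood has when $\theta$ is poorly identified.

The exclusion threshold is the 5% quantile of the **untruncated** fitted
NB. `interactability_threshold()` starts from `qnbinom(0.05, ...)` and
then walks the integer grid until the defining bracketing
$F(q - 1) < 0.05 \le F(q)$ holds exactly, because `qnbinom` can be off by
one at probabilities that sit on a mass point. A fragment is kept only if
$N_{T,ir} \ge$ threshold in **every** replicate (`filter_fragments()`):
a bait that failed in any library contributes unusable counts to the
summed response used downstream, so an AND rule is the conservative
choice.

### Truncation-point heuristic

`select_truncation_point()` histograms $\log(1 + N_T)$ with **binwidth
1** and smooths with a centred moving average of **window 3**. Local
maxima with smoothed height at least 10% of the global maximum are
candidate modes; if at least two survive, $t$ is the count at the
shallowest bin between the two tallest modes, accepted only if that
valley is at most 0.8 times the lower of the two mode heights. Otherwise
the distribution is declared unimodal (warning) and $t = 0$, i.e. no
truncation.

Rationale for the defaults: on the scales this filter meets
($N_T$ up to a few thousand), the $\log(1+x)$ histogram spans only ~8
bins of width 1. A wider smoothing window (e.g. 5) averages over more
than half the support, which can merge the two modes or drag the valley
into the signal component; window 3 is the smallest symmetric window
that still suppresses single-bin jitter. The 10% prominence and 0.8
valley-depth guards exist so that pure-noise or pure-signal inputs are
reported as unimodal instead of yielding an arbitrary cut. Both knobs
are exposed (`binwidth`, `window`) and a manual `t` can be forced via
`fit_interactability_filters(manual_t = ...)` when the heuristic is
wrong for an unusual library.

## 3. Background model and peak test

### Candidate space

`enumerate_candidate_pairs()` forms every (kept bait) × (cis fragment)
pair with midpoint distance in `[min_dist, max_dist]` — defaults
**10 kb** and **5 Mb** — including pairs with zero observed counts.
Including the zeros is essential: the background regression must see the
full candidate space, not just the sequenced pairs, or expectations are
biased upward. Below 10 kb counts are dominated by self-circle and
re-ligation artefacts rather than looping; above 5 Mb true signal is
vanishingly rare and the decay model would be extrapolating.

### Distance binning

Rather than fitting one global distance–decay curve, candidates are cut
into equal-count distance bins (`assign_distance_bins()`, defaults
`n_bins = 100`, `min_bin_pairs = 200`) and the model is fitted per bin.
Within a narrow distance slice the residual dependence on distance is
mild, so a log-linear term suffices; across bins the piecewise fits
track any smooth decay shape without committing to a power law globally.
Bin breaks are exact order statistics computed with integer arithmetic
(`ord[(seq_len(k - 1) * n) %/% k]`), not `quantile()`, because floating
point `type = 1` quantiles can land one element off and produce unequal
bins; ties in distance always share a bin, and bins that end up below
`min_bin_pairs` are merged with a neighbour so every regression has
enough residual degrees of freedom.

### Regression

Within a bin, for capture-to-cis pairs the summed-over-replicates count
$y$ is modelled as NB with log link:

$$\log \mu = \beta_0 + \beta_d \log d + \sum_r \beta_r \log N_{T,ir},$$

one interactability covariate per replicate (of the bait end). For
within-capture pairs both ends have interactability; the covariates are
the per-replicate **sum** $\log N_{T,ar} + \log N_{T,br}$ and **product**
$\log N_{T,ar} \cdot \log N_{T,br}$, which are symmetric under swapping
the two fragments — so the fit cannot depend on the arbitrary
`frag_lo`/`frag_hi` orientation (this invariance is tested).

Replicates are combined by **summing counts** in the response while
keeping **per-replicate covariates**: the sum is the sufficient statistic
if replicates share the structure, and the separate covariates let each
library's efficiency be weighted by the data instead of assuming equal
depth.

Estimation uses `MASS::glm.nb`. When it fails to converge (typical in
sparse, far-distance bins where the dispersion is unidentifiable) the
fit falls back to a Poisson GLM with a warning, encoded as NB with
size $10^8$; this is conservative in the direction that matters, since
for small means the Poisson tail is thinner than any NB tail only
negligibly, and the affected bins have expectations near zero anyway.
An all-zero bin short-circuits to $\hat\mu = 10^{-12}$, p-value 1.

### Test and error control

The peak p-value is the exact upper tail
$P(Y \ge y) = 1 - F(y - 1; \hat\mu, \hat\theta)$, computed via
`pnbinom(y - 1, ..., lower.tail = FALSE)` rather than `1 - pnbinom(...)`
to avoid cancellation in small tails; $y = 0$ gives $p = 1$ by
definition. Benjamini–Hochberg adjustment (`adjust_fdr()`, a thin wrapper
over `stats::p.adjust`) runs **within each locus × cell line × pair
class** family: loci are scientifically independent questions with very
different candidate counts, and pooling them would let a peak-rich locus
subsidise significance at a peak-poor one. A pair is significant iff
adjusted $p < \alpha$ (default **0.01**) and its distance lies in the
window.

## 4. Downstream analyses

- **Replicate QC** (`spearman_by_stratum()`): Spearman correlation of
  replicate counts in distance strata 0–500 kb, 500 kb–1 Mb, 1–1.5 Mb,
  >1.5 Mb, excluding pairs zero in both replicates. Spearman, not
  Pearson, because counts are heavy-tailed; stratified, because pooled
  correlations are dominated by the distance decay itself.
- **Cross-cell-line comparison**: exact-subset sharing counts
  (`peak_overlap_sets()`); a **permutation sharing test**
  (`permutation_sharing_test()`) that redraws each line's peak set as a
  uniform random subset of that line's *tested* universe, preserving set
  sizes, with $p = (1 + \#\{stat \ge obs\}) / (n_{perm} + 1)$ — the +1
  correction keeps $p > 0$ and valid; Jaccard distance with
  average-linkage clustering (`jaccard_dendrogram()`, Newick export via
  `ape` if available); Kruskal–Wallis and Mann–Whitney tests on
  per-locus peak counts (`locus_count_tests()`), exact Mann–Whitney
  p-values when both groups have $\le 8$ values.
- **Target genes** (`assign_target_genes()`): a gene is a direct putative
  target of a locus if its TSS fragment (TSS = `txStart` on +, `txEnd`
  on −) is an end of a significant peak anchored in the locus in at
  least `min_cell_lines = 2` cell lines, and the TSS lies within the
  locus hull ± 5 Mb. Requiring two lines trades sensitivity for
  robustness to single-library artefacts. `assign_adjacent_locus_targets()`
  extends assignments across loci joined by a within-capture peak.
  `nearest_gene()` implements the naive baseline (containing gene, else
  nearest TSS; for noncoding hits also the nearest coding gene) and
  `compare_chic_vs_nearest()` classifies each locus as
  `sole` / `one_of_several` / `other` / `uninformative`.
  `enrichment_hypergeometric()` uses `phyper(overlap - 1, ...)` for the
  standard off-by-one-correct upper tail.

## 5. The simulator

`simulate_chic()` exists to give every statistical claim in the test
suite a known ground truth; its defaults are the package's study
conditions and are **not** tuned to any particular outcome.

What it emulates:

- a restriction map with geometric fragment lengths (mean 4 kb, the
  6-cutter scale), default 4 chromosomes × 2.5 Mb;
- a capture design of 8 × 100 kb regions (~200 captured fragments,
  ~10^5 candidate pairs — small enough to run hundreds of times in a
  test budget, large enough for stable regression fits);
- failed baits: a `noise_fraction = 0.2` of baits whose trans counts are
  Poisson(3) and whose interactability factor is near zero;
- working baits: trans counts with mean ~300 driven by a shared
  Gamma(5, 5) fragment factor $G_i$, so a fragment's trans total and its
  cis background are correlated — the correlation the background model's
  covariates exist to absorb;
- background counts $y \sim \mathrm{NB}(\mu, 6)$ with
  $\mu = k \cdot s_r \cdot B_i B_j \cdot d^{-1} \cdot E_{ij}$
  (power-law decay, replicate scale factors 1.0 / 1.2);
- planted peaks: `E = 8` on 15 capture-to-cis and 5 within-capture pairs
  with adequate background mean, or an explicit `planted_pairs` tibble;
  presets `default`, `null` (nothing planted — FDR calibration), and
  `power` (sensitivity).

What it does **not** emulate: mappability and GC bias, copy-number
variation, restriction-site density variation along real chromosomes,
A/B compartment structure, read-level errors, or trans-chromosomal
*signal* (trans counts are pure ligation noise by construction). Results
on simulated data therefore validate the statistics, not the genomics.

## 6. Numerical choices, in one place

- Truncated-NB likelihood optimised over $(\log\mu, \log\theta)$,
  Nelder–Mead, three starts, `reltol = 1e-8`.
- Thresholds verified against the CDF bracketing by an explicit integer
  walk, never trusted from `qnbinom` alone.
- Tail p-values via `pnbinom(y - 1, lower.tail = FALSE)`; tested against
  brute-force mass summation to $10^{-10}$ absolute.
- Distance-bin breaks by exact integer order statistics; ties share a
  bin.
- `glm.nb` → Poisson fallback with warning; sentinel size $10^8$.
- All randomised procedures (`simulate_chic()`,
  `permutation_sharing_test()`) take a mandatory seed and use
  `withr::with_seed`, so no call disturbs the caller's RNG state and
  every result is reproducible bit-for-bit.

## 7. Limitations

- The background model conditions on one distance window and assumes the
  within-bin decay is log-linear; pathological capture designs with very
  few candidates per bin degrade to the merged-bin fit.
- The AND rule across replicates discards baits that a single bad
  library ruined, which loses power when many replicates are available;
  with two replicates (the intended design) the trade-off is right.
- The valley heuristic assumes at most two meaningful modes; libraries
  with intermediate-efficiency bait populations should set `manual_t`.
- FDR control is per locus × cell line × class family; global FDR over
  an entire study is not directly controlled.
- The permutation sharing test conditions on peak-set sizes and assumes
  exchangeability of pairs within each line's tested universe; strong
  shared distance structure between lines makes it anti-conservative in
  principle, though the calibration tests show no such effect at the
  simulated scales.
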