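---
title: "Methods: the fgrscreen biomarker-screening pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fgrscreen biomarker-screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgrscreen)
```

# Scope

`fgrscreen` implements the statistics of a CSF-proteome biomarker screen in
a rat model of mild fetal growth restriction (FGR) induced by chronic
intrauterine hypoperfusion: birth-weight threshold classification, a
per-protein Spearman/Storey-q screen against birth weight with dual-day
concordance and brain-expression filtering, Steel--Dwass and Wilcoxon
signed-rank comparisons, measurement-normalization rules, and behavioral
scoring. Everything upstream of the abundance tables (mass spectrometry,
peptide-to-protein rollup, image segmentation) and everything
interpretive is out of scope; the package consumes and produces tabular
data only.

# FGR classification

Clinical FGR cutoffs are quoted as birth-weight percentiles of a normal
population; `z_from_percentile()` is the standard normal quantile that
converts them to SD units (10th percentile $\leftrightarrow -1.28$ SD, 5th
$\leftrightarrow -1.64$, 3rd $\leftrightarrow -1.88$). The working
definition used throughout is a threshold $\mu_{\mathrm{ref}} - k\,
\sigma_{\mathrm{ref}}$ on the untreated reference group's birth weight,
with $k = 1.5$ by default; for the calibrated reference $7.01 \pm 0.55$ g
the threshold is $6.185$ g.

Two deliberate conventions:

* **Strict inequality.** A pup exactly at the threshold is *not* FGR
  ("below the threshold" is read strictly). Ties at the exact double-precision
  threshold are vanishingly rare for continuous weights, but the rule is
  fixed so classifications are reproducible.
* **Full-precision arithmetic.** The quantile and the threshold are kept in
  double precision; 2-decimal rounding (6.185 g printing as 6.18 g) is a
  display concern only.

# The proteome screen

For protein $g$ on postnatal day $d \in \{4, 5\}$, with abundance vector
$a_{g}$ and birth weights $w$ over the $n$ profiled pups:

$$\rho_{gd} = \mathrm{cor}\big(\mathrm{rank}(a_g), \mathrm{rank}(w)\big),$$

with average midranks for ties. The two-sided p-value refers
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ to Student's $t_{n-2}$. This
t-approximation is the default because it is what general scientific
Python/R stacks compute for Spearman tests at these sample sizes and it
reproduces the magnitudes of the per-candidate p-values from 2-decimal
rhos (e.g. $\rho = -0.81$, $n = 20 \Rightarrow p \approx 1.5\times10^{-5}$).
An exact permutation p (enumeration of all $n!$ rank permutations) is
available for $n \le 9$; at $n = 8$ the t-approximation agrees with the
exact law within $0.02$ everywhere the exact p is below $0.2$, and within
$0.025$ globally (the worst case sits near $p \approx 0.93$, far from any
decision boundary). $|\rho| = 1$ returns the smallest representable double
(t path) or $2/n!$ (exact path).

**Storey q-values.** With p-values sorted ascending,
$q_{(i)} = \min_{j \ge i}\, \pi_0\, m\, p_{(j)} / j$, capped at 1. $\pi_0$
is estimated by the smoother method: $\pi_0(\lambda) = \#\{p >
\lambda\}/(m(1-\lambda))$ on the grid $\lambda = 0.05, \dots, 0.95$, fitted
with a 3-df cubic smoothing spline and evaluated at the largest $\lambda$,
clamped to $[1/m,\, 1]$. A `fixed` mode with $\pi_0 = 1$ is offered, in
which q-values coincide *exactly* with Benjamini--Hochberg adjusted
p-values (a property the test suite asserts against `p.adjust`). Fewer
than 10 p-values falls back to the fixed value with a warning. Q-values
are computed within each day's full screened protein set, so each day's
significance calls are self-contained.

**Selection.** A protein is significant on a day iff $p < 0.05$ and
$q < 0.1$; candidates are proteins significant on both days with the same
nonzero sign of $\rho$ (a zero correlation has no direction and cannot be
concordant); proteins screened on only one day are excluded from
concordance. Missing abundances are handled per protein with complete
pairs; proteins with $n < 4$ complete pairs are flagged and excluded from
the q-value pool.

**Brain-expression filter.** "Highly expressed in brain cells" is
operationalized as: at least one annotation at level Medium or higher in a
*neuronal*, *glial* or *Purkinje* cell class, in any of the four annotated
regions (cerebral cortex, hippocampus, caudate, cerebellum). The rule is
configuration, not code: `min_level` and `cell_classes` are arguments.
This rule reproduces the 15 $\to$ 6 split of the packaged candidate
annotation table (`inst/extdata/table1_annotations.tsv`); note that the
per-protein assignment of region $\times$ cell-type entries in that
fixture is a best-effort transcription (the source presentation does not
unambiguously delimit columns), exact in the property that drives the
filter — which proteins carry a $\ge$ Medium neuronal/glial/Purkinje
annotation. Candidates lacking any annotation record are excluded but
reported in a `needs_review` list rather than silently dropped.

# Nonparametric comparisons

**Steel--Dwass.** For each unordered pair of groups, observations of the
two groups are pooled and midranked; with rank sum $W$ of the second
group, $E[W] = n_b(N+1)/2$ and the ties-corrected
$\mathrm{Var}(W) = \frac{n_a n_b}{N(N-1)}\left(\sum r^2 -
\frac{N(N+1)^2}{4}\right)$, the standardized $t = (W - E[W]) /
\sqrt{\mathrm{Var}(W)}$ is referred via $\sqrt{2}\,|t|$ to the studentized
range $Q_{k,\infty}$ (`stats::ptukey` with infinite df). Family-wise
control is internal; no further adjustment is applied. Choices:

* Asymptotic (infinite-df) reference, the standard for rank statistics;
  at $n = 15$/group the family-wise type-I error at nominal 0.05 is within
  $[0.03, 0.07]$ over 2{,}000 null simulations (asserted in the suite). At
  $n = 4$/group the pairwise statistic is heavily discrete (about 29
  support points), and the continuous p falls inside the atom of the exact
  permutation law at the observed value — between $P(\max > q_{obs})$ and
  $P(\max \ge q_{obs})$ over all $34{,}650$ relabelings — rather than
  within a fixed small distance of the inclusive exact p. Exactness at
  such sizes would require the permutation distribution itself.
* Zero pooled variance (all values tied) yields $t = 0$, $p = 1$ instead
  of an error, so degenerate simulated inputs cannot crash a pipeline.
* For $k = 2$ the procedure reduces algebraically to the two-sided
  normal-approximation rank-sum test (asserted in the suite).

**Wilcoxon signed-rank.** Zero differences are dropped with a message;
$n \le 25$ untied differences use the exact distribution, otherwise the
normal approximation with ties-corrected variance and continuity
correction (at $n = 30$ the approximation sits within $0.01$ of exact
enumeration). The study design this serves compares body-weight *gain*
between two groups; how pairs were formed there is not specified, so both
the signed-rank (paired) and the $k = 2$ Steel--Dwass (unpaired) paths
are exposed and the choice is left to the analyst.

# Normalization rules

* `albumin_normalize()`: band density / albumin density (endogenous
  control), requiring a positive control.
* `relative_to_reference()`: division by the arithmetic mean of the
  reference ratios, making the reference mean exactly 1. Two conventions
  are supported in `normalize_timecourse()` because study designs differ:
  *global* (sham at the earliest day $= 1$, one anchor per analyte) and
  *per-day* (sham $= 1$ at every time point). The convention is selected
  per dataset.
* `fluorescence_rescale()`: the affine map sending background to 1 and the
  panel maximum to 100. Out-of-range values are clamped to the anchors
  with a reported count (per-image maxima can exceed the panel-wide
  display maximum); the background/maximum anchors are per panel by
  default.

# Behavioral scoring

* **Climb-up score** (negative geotaxis): 5/4/3/2/1 points for latencies
  in $[0,15)/[15,30)/[30,45)/[45,60)/[60,\infty)$ s; 0 for no reaction or
  a fall. The printed bin edges overlap at 15, 30, 45, 60 s;
  left-closed/right-open bins are adopted, so a 15 s latency scores 4.
* **Spontaneous alternation**: number of consecutive-entry triads visiting
  three distinct arms, divided by (entries $-$ 1), times 100. The printed
  denominator is (entries $-$ 1) even though the maximum number of triads
  is (entries $-$ 2) — so a perfect alternator scores
  $100\,(n-2)/(n-1) < 100$. The rule is implemented as printed; a
  `denominator = "entries_minus_2"` option provides the conventional
  index, default off.
* **Recognition index**: novel / (novel + familiar) exploration time;
  undefined (error) when both are zero.
* **Rota-rod learning**: trial-2 minus trial-1 latency, capped at the
  300 s protocol limit with a warning.

# The synthetic-data module

The generators exist so every downstream stage is testable without the
deposited data. They emulate the *statistical structure* of the study, not
its biology.

**Cohort.** Birth weights are normal per group: control $7.01 \pm 0.55$ g,
sham $6.87 \pm 0.74$ g, hypoperfusion $5.727 \pm 0.74$ g. The
hypoperfusion mean is not reported by the study design this emulates; it
is back-calculated so that $P(W < 6.18\,\mathrm{g}) = 0.73$ at
$\sigma = 0.74$, matching the reported 73% below-threshold fraction
(the printed fraction pins the mean: $6.18 - \Phi^{-1}(0.73)\cdot 0.74
\approx 5.727$). Pups are assigned round-robin to dams of 10; litter
effects default to zero variance (the emulated analysis does not model
litter clustering).

**Proteome.** $m = 601$ proteins, $n = 10$ sham $+ 10$ hypoperfusion pups
per day. Log-abundance of a null protein is baseline
$\mathcal{N}(13, 1)$ plus $\mathcal{N}(0, \sigma_\varepsilon^2)$ noise
($\sigma_\varepsilon = 0.3$; log-normal because reporter intensities are
positive and right-skewed). A planted responder adds
$\delta_g\, \beta\, z(w)$ on the log scale, where $z(w)$ is the
within-day birth-weight z-score (so the effect is scale-free),
$\delta_g = \pm 1$, and $\beta$ is calibrated from the target Spearman
magnitude $\rho_s$ via the bivariate-normal identity $\rho_s =
\frac{6}{\pi}\arcsin(r/2)$, $\beta = \sigma_\varepsilon\, r /
\sqrt{1-r^2}$. Default target $|\rho_s| = 0.8$ with $m_1 = 15$
responders. Day-5 pups are independent of day-4 pups by default (the
emulated design does not state whether the same pups were profiled twice;
`shared_pups = TRUE` covers the other reading). Each responder keeps its
direction on day 5 with probability `concordance_prob` (default 1).

What the generator does *not* emulate: MS missing-value mechanisms,
protein-protein correlation, batch/plex effects, and non-normal weight
distributions. Passing the recovery tests therefore shows the screen's
statistics behave as designed under the assumed structure — not that the
screen is robust to the full messiness of real TMT data.

**Time course and behavior.** Densitometry time courses put the sham arm
at relative level 1, the FGR-vehicle arm at `elevation` (default 2.0),
and the MSC-treated arm at $1 + (\mathrm{elevation}-1)(1 -
\mathrm{attenuation})$ from day 5 on (treatment at day 4; default
attenuation 0.7), with mean-one multiplicative log-normal noise
($\sigma = 0.3$, $n = 15$/arm) so arm means sit exactly at their targets.
Behavioral deficits (longer geotaxis latency, shorter rota-rod latency
with no trial-2 gain, lower alternation bias) scale with a single
`deficit` knob in $[0,1]$; `deficit = 0` makes arms exchangeable. Y-maze
sequences come from a completion-biased walk whose bias 1 limit is a
perfect rotation, attaining the alternation index's upper bound
$100\,(n-2)/(n-1)$.

**Reproducibility.** Every generator draws from its own RNG stream derived
from the master seed by a fixed offset, so identical (seed, config) give
bit-identical outputs and adding one generator to a script never perturbs
another's draws.

# Problem sizes and numerical choices

The suite checks, among others: generator calibration at $n = 10^4$
weights (below-threshold fraction within $\pm 1.5$ points of 73%); null
p-value uniformity at $m = 5{,}000$ proteins (fraction $< 0.05$ in
$[0.04, 0.06]$); planted-responder recovery over 50 replicate screens at
the default configuration (mean recovery $\ge 70\%$, mean realized FDR
$\le 10\%$); Steel--Dwass family-wise error over 2{,}000 null simulations
of three $n = 15$ groups; and exact-oracle comparisons (all $34{,}650$
relabelings for three groups of 4; all $8!$ rank permutations at
$n = 8$; signed-rank enumeration at $n = 20$ and $30$). These sizes keep
each property statistically meaningful while the whole suite runs in
well under a minute.

Tie-breaks and degenerate inputs are all explicit: midranks everywhere;
strict `<` at the FGR threshold; $\rho = 0$ non-concordant; zero-variance
rank statistics give $p = 1$; all-zero signed-rank differences give
$p = 1$ with a warning; constant vectors are an error for correlation;
empty references an error for normalization.

# Known limitations

* The screen is mass-univariate; no multivariate or regression-based
  selection, and no modeling of correlated proteins.
* The Steel--Dwass reference is asymptotic; at group sizes of 4--5 its
  p-values carry the discreteness error quantified above.
* The packaged candidate-annotation fixture is a transcription with the
  column-assignment caveat noted earlier; its six-protein filter outcome
  is exact, individual region-level entries may not be.
* The alternation index follows the printed (entries $-$ 1) denominator;
  comparisons to literature using the conventional denominator need the
  config flag.
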