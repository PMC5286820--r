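---
title: "Methods: root skewing morphometrics and candidate-gene screening"
author: "rootskew package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: root skewing morphometrics and candidate-gene screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootskew)
```

# The problem

Arabidopsis roots grown on tilted agar plates *skew* (their steady-state
growth direction deviates from the gravity vector) and *wave* (they
undulate laterally along the growth axis). The two behaviours are
separable by the environment: on plates tilted backward (growth-plate
angle $A_{gp} = 45°$) many ecotypes both skew and wave; tilted forward
($A_{gp} = 135°$) they skew with minimal waving; vertical plates
($A_{gp} = 90°$) are the non-skewing, non-waving control. Ecotypes also
differ: WS (Wassilewskija) skews strongly, Col-0 (Columbia) waves but
barely skews.

This package implements the two quantitative tracks of that experimental
design:

1. **Morphometrics** — per-root shape statistics from traced coordinates,
   with the group-level summary (means, 95% confidence intervals, two-way
   Type-II ANOVA, Scheffé post hoc with compact letters).
2. **Candidate-gene screening** — a seven-contrast differential-expression
   comparison across the 2 ecotype × 3 angle design, a six-category
   pattern classification of between-ecotype differences, an
   inherent-difference filter, and a Venn-intersection step that yields
   the *highly probable skew gene candidates* (HPSGC).

A seeded synthetic-data module generates root traces and expression
matrices with planted ground truth, so every stage is verifiable without
external data.

# Root morphometrics

For a trace of ordered points $p_1, \dots, p_n$ (mm, $y$ increasing with
gravity), with arc length $L = \sum_i \lVert p_{i+1} - p_i \rVert$:

* **HGI** (horizontal growth index) $= (x_n - x_1)/L$. For a straight
  root at angle $\theta$ from vertical, $\mathrm{HGI} = \sin\theta$; it is
  signed (+x to the viewer's right on the plate face). A per-trace
  `view_flipped` flag negates $x$ for images taken through the media,
  where the apparent axis is mirrored. Group summaries report both signed
  and absolute HGI: published skew magnitudes are unsigned, but the sign
  carries biological information (skew direction is chiral).
* **VGI** $= (y_n - y_1)/L$, the vertical analogue.
* **STR** (straightness) $=$ chord length $\lVert p_n - p_1 \rVert / L$,
  1 iff the trace is collinear in order.
* **WD** (wave density) $=$ wave count $/ L$, waves per mm.

## The wave-counting rule

"Waves per millimetre" does not prescribe a counting algorithm, so the
package defines one and exposes its two knobs (`waveConfig()`):

1. compute the signed perpendicular deviation $d_i$ of every point from
   the start-to-tip chord;
2. smooth $d$ with a centred moving average over a window of
   `window_frac` of the points (default 5%, minimum 3, forced odd);
3. find local extrema of the smoothed profile, keep those with
   $|d| \ge$ `amplitude_mm` (default 0.1 mm), and collapse consecutive
   same-sign extrema (a split crest is one crest);
4. a full wave is one crest plus one trough:
   `wave_count = floor(alternating extrema / 2)`.

This matches the visual definition (a noiseless sinusoid of $k$ full
periods has $2k$ alternating extrema and counts $k$ waves), is invariant
to uniform rescaling of both axes when the threshold is scaled along, and
is robust to tracing jitter because sub-threshold wiggles are ignored.
The defaults were chosen once from the geometry of the assay — typical
wave amplitudes are around 0.5 mm, tracing error well under 0.1 mm — and
are configurable rather than load-bearing.

## Group statistics

Per-cell summaries use the Student-t interval
$\bar y \pm t_{0.975,\,n-1}\, s/\sqrt n$ — appropriate at the small
per-cell $n$ of plate assays; a cell with $n = 1$ reports its mean with
no interval, an empty cell reports $n = 0$.

`anovaTypeII()` fits `metric ~ ecotype * angle_gp` and reports Type-II
sums of squares (each main effect adjusted for the other, the interaction
from the full model), which are the appropriate decomposition when cell
counts are unequal, as they are in practice when some roots cannot be
traced. The fit is delegated to `car::Anova` on a base `lm`; the test
suite verifies it against an explicit projection oracle on seeded random
balanced and unbalanced designs, and verifies that it differs from
sequential (Type-I) sums of squares where it should.

`scheffePosthoc()` compares all pairs of groups with Scheffé's method:
for pair $(i, j)$,
$$F_{ij} = \frac{(\bar y_i - \bar y_j)^2}{\mathrm{MSE}\,(1/n_i + 1/n_j)},
\qquad p_{ij} = P\!\left(F_{k-1,\,df_e} \ge F_{ij}/(k-1)\right),$$
with MSE and $df_e$ from the full two-way model (falling back to a
one-way error term when only one factor has two or more observed
levels). Scheffé protects all contrasts simultaneously, which suits an
exploratory morphometric screen. The grouping follows the interaction
rule used in the original figure logic and automated by
`metricSummary()`: when the ecotype × angle interaction has $p < 0.05$
the six cell means are compared; otherwise marginal means are.

Letters come from an insert-and-absorb compact letter display. To make
the output deterministic, groups are processed in descending mean order
and columns that become subsets of another column are absorbed
immediately; ties in the letter assignment therefore cannot depend on
input order.

# Differential expression

The pipeline consumes an already normalized log2 expression matrix bound
to the factorial design (an `ExpressionStudy`, a thin
`SummarizedExperiment`). Array summarization from raw probe intensities
is out of scope; `quantileNormalize()` is provided as a light-weight
option for matrices that did not go through a summarization pipeline
(every column is mapped to the mean of the column-wise order statistics,
ties receiving the average of the quantiles they span).

## Moderated t

`contrastStats()` computes, per gene, the two-group statistics with an
empirical-Bayes variance moderation written from the model (a DE package
is deliberately not called here; `limma` is used only as an independent
cross-check in the test suite). With pooled within-group variance $s^2$
on $d = n_1 + n_2 - 2$ df, the gene variances are modelled as draws from
a scaled inverse-chi-square prior with parameters $(d_0, s_0^2)$,
estimated by moment matching on $e = \log s^2 - \psi(d/2) + \log(d/2)$:

$$\mathrm{Var}[e] = \psi'(d/2) + \psi'(d_0/2), \qquad
\mathrm{E}[e] = \log s_0^2 - \psi(d_0/2) + \log(d_0/2),$$

solved with a Newton iteration for the inverse trigamma. When the
observed dispersion of $e$ does not exceed what chi-square sampling alone
implies, $d_0 = \infty$ and $s_0^2$ is the mean sample variance (a
point-mass prior). The moderated statistic is

$$\tilde t = \frac{\Delta\bar y}{\tilde s \sqrt{1/n_1 + 1/n_2}}, \quad
\tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d},$$

on $d_0 + d$ df (normal when $d_0 = \infty$); p-values are two-sided
throughout, and q-values are Benjamini–Hochberg (via `stats::p.adjust`,
verified against a hand step-up oracle). Genes with zero residual
variance and no shrinkage are called by convention: $p = 1$ when the
mean difference is zero, $p = 0$ otherwise.

Significance is strict on both axes: $|\log_2 FC| > 1$ **and**
$p < 0.05$, with an additional flag for $q < 0.05$. A gene at exactly
$\log_2 FC = 1$ is not called.

## The seven-contrast comparison matrix

`comparisonMatrix()` fits the contrasts as pairwise two-group
comparisons, mirroring the arrow structure of the design: within each
ecotype, 45° vs 90° and 135° vs 90° (the vertical plate is the control);
between ecotypes at each angle, Col-0 vs WS with WS as reference
(log2FC = Col-0 − WS, so a negative value means WS expresses more). A
single six-group model with shared variance would be a defensible
alternative; pairwise contrasts were chosen because each published
comparison is a simple two-group arrow, and the moderated variance
already borrows strength across genes. No mean–variance trend is fitted.

# Pattern classification and candidate sets

Between-ecotype genes are classified by their significance pattern over
(45°, 90°, 135°):

| pattern | category | reading |
|---|---|---|
| (0,1,0) | I | control-only difference |
| (1,1,0) | II | 45° and 90°, same direction |
| (0,1,1) | III | 90° and 135°, same direction |
| (1,0,0) | IV | tilted-back only |
| (1,0,1) | V | both tilted angles, same direction |
| (0,0,1) | VI | tilted-forward only |

Before classification, the **inherent-difference filter** removes genes
that differ at all three angles by near-equal magnitude — constitutive
ecotype differences rather than angle responses. "Near the same
magnitude, within ±1 on the log2 scale" is interpreted as a pairwise
span: $\max FC - \min FC \le 1$ log2 unit, with sign agreement required
(automatic when each $|FC| > 1$ and the span is ≤ 1). The wider reading
(span ≤ 2) sits behind the same `span` argument. Genes significant at
all three angles that escape the filter, and two-angle patterns with
discordant directions ("in the same way" fails), are set aside as
`OTHER` and excluded from candidates — conservative, since no category
is defined for them. Within-ecotype shared genes deliberately do *not*
require sign agreement: a gene may flip direction between 45° and 135°
(the asparagine synthetase ASN1 does exactly this) and remain a valid
angle-responsive candidate.

The candidate algebra is then:

* **physiology track** = union of the within-WS DE sets at 45° and 135°;
* **genotype track** = Categories IV ∪ V ∪ VI;
* **overlap** = their intersection;
* **HPSGC** = overlap genes whose evidence involves 135° *on both
  sides*: in the WS 135°-vs-90° DE set **and** in Category V or VI
  (between-ecotype significance at 135°). The published account states
  this rule pictorially (bold connecting lines at the 135° angle); the
  conjunction above is its formalization, and on the reference-scale
  fixture it reproduces the 16 → 11 narrowing exactly.

Every report carries per-gene provenance (which contrasts and category
admitted each overlap gene, and whether each side of the anchor held).

# Synthetic data with planted truth

## Traces

`simulateTraces()` samples each root along a straight direction tilted
by the planted skew angle from vertical, adds a sinusoidal lateral
component with the planted integer number of full periods, and jitters
both coordinates. The default per-cell phenotypes encode the study
conditions this package models: WS skews 20° on tilted plates and 0° on
vertical ones, Col-0 at most 2–3°; both ecotypes wave (4 periods) at
45° and barely (1 period) elsewhere; vertical-plate roots are longest
and Col-0 roots shorter than WS; 43 roots per cell (a typical per-cell
sample size for this assay), amplitude 0.5 mm, tracing noise 0.05 mm.

The jitter is *locally correlated* (white noise passed through a short
moving average, rescaled to the requested sd) rather than independent
per point. Independent jitter at 200 points per trace would inflate the
measured arc length by 15–25% and bias HGI and STR downward — an
artifact of the noise model, not of tracing, which errs smoothly. With
correlated jitter the round trip recovers planted wave counts exactly
and HGI within 0.05 of $\sin(\text{skew angle})$.

## Expression

`simulateExpression()` draws
$y_{gs} = \mu_g + \delta_{g}(s) + \varepsilon_{gs}$ with per-gene
baselines uniform on log2 6–12, Gaussian residuals with $\sigma = 0.25$
(microarray-typical on the log2 scale), effect size $e = 2.0$ log2
units, and 3 replicates per cell — the design and noise level of the
study this models (3 chips per condition; planted effects at the
magnitude of the reported fold changes). Planted classes mirror the
pipeline stages: `INHERENT` shifts Col-0 equally at all angles;
`CAT_I..CAT_VI` shift Col-0 at the angle sets defining each category;
`HPSGC_LIKE` shifts WS at 135° only, which simultaneously makes the gene
DE within WS (135° vs 90°) and Category VI between ecotypes — the HPSGC
signature. At these settings the expected moderated $|t|$ for a planted
gene is $e/(\sigma\sqrt{2/3}) \approx 9.8$, so near-complete recovery
with near-zero null contamination is the *expected* behaviour, and the
test suite asserts it (≥ 95% category and HPSGC recovery, ≤ 1% null
contamination).

Two generator choices deserve a note:

* The `WS_ANGLE_45`/`WS_ANGLE_135` classes shift **both** ecotypes at
  the tilted angle. A WS-only shift would be statistically
  indistinguishable from `HPSGC_LIKE` (it induces the same
  between-ecotype difference), collapsing two planted classes into one;
  shifting both ecotypes makes the class purely angle-responsive, so it
  exercises the physiology track without leaking into the genotype
  track.
* Residuals are homoscedastic by default (the moment fit then correctly
  drives $d_0 \to \infty$); `variance_mixture = TRUE` draws gene
  variances from a scaled inverse-chi-square mixture so that shrinkage
  is exercised with a finite prior.

Generators are pure functions of (config, seed); the same seed gives
bit-identical output, and truth tables are emitted alongside the data.

## The reference-scale fixture

`referenceSkewFixture()` is a fully synthetic, deterministic membership
fixture that encodes the printed set structure of the GSE83242 skewing
analysis — within-WS sets of 66 and 40 genes sharing 14; Col-0 sets of
22 and 6 sharing 4; categories I–VI of sizes 61/24/43/38/26/64 with
their up/down splits; 16 overlap genes; the 11 HPSGC under their real
gene identifiers and reported log2 fold changes. The supplementary
gene lists themselves are not shipped; all non-anchor members are `SYN*`
placeholders, and the per-gene statistics are synthetic values
consistent with the encoded significance patterns. Running the actual
classification and intersection code on this fixture demonstrates that
the *algebra* reproduces the published counts (92, 128, 16, 11, 50
down in Category VI); it does not re-derive those counts from raw
arrays, which requires the deposited data.

# Problem sizes and runtime choices

The test suite and the acceptance script run the generators at 2000
genes × 18 samples (the full default), 20-instance oracle sweeps for
each statistic, and trace sets of a few hundred roots — sizes chosen so
the whole verification cycle completes in well under a minute on one
CPU while keeping every planted class populated enough for stable rates
(20–40 genes per class; binomial sd of a 95% recovery rate at n = 120
is about 2%).

# Known limitations

* Probe-level summarization (RMA/MAS5), probe→gene collapsing, batch
  correction and annotation are out of scope; inputs are gene-level
  log2 matrices.
* The synthetic generator plants gene-wise independent effects with
  Gaussian noise and no gene–gene correlation; passing its recovery
  tests shows the pipeline's logic is correct under its own model, not
  that real arrays at n = 3 have this power.
* The morphometric track consumes traces; it does not segment images or
  quantify lateral roots.
* Scheffé letters summarize pairwise decisions at a fixed α; with many
  near-ties the compact display can be conservative.
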