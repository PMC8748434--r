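---
title: "Methods: chromatin architecture dynamics from binned Hi-C maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin architecture dynamics from binned Hi-C maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicdynamics)
```

# Scope

`hicdynamics` analyzes how three-dimensional chromatin architecture changes
across developmental stages — the motivating system is granulosa cells
profiled at three follicle stages (SWF, F1, POF) — from binned
intrachromosomal Hi-C contact matrices. It covers the layers of organization
usually read out of such data, from global to local: overall structural
order (Von Neumann entropy), A/B compartments and their cross-stage
switches, topologically associating domains (TADs) with boundary dynamics
and domain scores, promoter–enhancer interactions (PEIs) with a per-gene
regulatory potential score (RPS), super-/regular-/poised-enhancer classes
from H3K27ac, and chromatin loops filtered for convergent CTCF motifs.
Everything upstream of a binned matrix (alignment, pair filtering,
duplicate removal) is out of scope.

Because full-depth datasets (billions of contacts) are not reproducible at
desk scale, the package ships a synthetic contact-map generator with
planted, recoverable architecture; every analysis step is validated by
recovering what was planted.

# Data model and normalization

A `contact_map` is a symmetric dense matrix over fixed-width, 0-based,
half-open bins (`bin_id = floor(start/resolution)`); 20 kb is used for
compartments and TADs, 5 kb for PEIs and loops. Input is plain-text COO
triplets plus a BED4 bin table; lower-triangle records are folded and
duplicates summed, so a matrix written with both triangles reads back
identically.

Balancing (`kr_balance`) finds a diagonal scaling `D M D` equalizing row
sums, in the Knight–Ruiz/Sinkhorn family for symmetric non-negative
matrices. Two numerical choices:

* **Target marginal.** Rows are scaled to the *mean pre-balancing
  marginal*, not to 1. This preserves the total count scale so that
  balanced entries remain interpretable as counts in the Poisson-style
  significance tests downstream.
* **Masking.** Zero-marginal rows are masked before iteration; a config
  option additionally masks the sparsest fraction of rows
  (`mask_quantile`), since near-empty rows destabilize the scaling.
  Convergence is declared when the maximum relative row-sum deviation
  falls below `tol = 1e-10` (audited directly in the tests at 1e-8).

The distance-decay expectation is the per-diagonal mean over unmasked
pairs, including genuinely zero cells; the observed/expected (O/E)
transform divides each cell by it, so every diagonal stratum of an O/E map
averages to exactly 1. Where a significance test needs a smooth
expectation (PEI and loop calling), the decay curve is spline-smoothed in
log–log space.

# Von Neumann entropy

The entropy is computed from the Pearson correlation matrix `C` of the O/E
map (positive semidefinite by construction; tiny negative eigenvalues from
floating point are clipped at zero). With eigenvalues scaled to sum to 1,

$$\mathrm{VNE} = -\sum_i p_i \ln p_i \,/\, \ln n$$

normalized by `ln(n)` so that independent bins give 1 (maximal disorder)
and a rank-one correlation gives 0. Several definitions of a contact-map entropy circulate in the
literature; this spectral-entropy definition was chosen because it is scale invariant, bounded in [0, 1], and produces values in
the 0.7–0.9 range on realistically structured maps — the default
simulation yields ≈ 0.88. Missing O/E cells are treated as the neutral
value 1 before correlating, and constant bins are masked.

# Compartments and switches

PC1 is the leading eigenvector of the same O/E correlation matrix,
computed per chromosome. Its sign is arbitrary, so it is oriented by the
Spearman correlation with a per-bin gene-density track (GC content is an
equivalent choice); bins with positive PC1 are labeled A, the rest B. A
PC1 of exactly 0 is assigned B (conservative; measure-zero case).
Chromosomes with fewer than 20 usable bins are skipped.

Switch classification requires exactly three stages: each bin analyzable
in all of them gets a three-letter pattern (e.g. `AAB`), runs are merged
into segments, and patterns are grouped as stable (`AAA`, `BBB`),
unidirectional (`AAB`, `ABB`, `BAA`, `BBA`) or transient (`ABA`, `BAB`).
Segment lengths sum to the analyzable genome by construction.

# TAD calling

The caller is hybrid: directionality index
(DI) segmented by a hidden Markov model, then insulation-score (IS)
subdivision of oversized domains.

**DI.** For each bin with a full ±10-bin (±200 kb at 20 kb) window, with
`A`/`B` the summed balanced contacts to the upstream/downstream window and
`E = (A+B)/2`:
`DI = sign(B−A) · ((A−E)²/E + (B−E)²/E)`, 0 when `A = B = 0`.

**HMM.** Three hidden states (upstream-biased, unbiased,
downstream-biased) with Gaussian emissions, fitted by EM and decoded by
the most probable path. Design choices within the HMM segmentation:

* Emissions are fitted to a variance-stabilized DI,
  `sign(DI)·log(1+|DI|)`. The raw DI is extremely heavy-tailed (most mass
  near zero, chi-square-style tails in the hundreds), and Gaussian EM on
  the raw scale converges to degenerate solutions in which one wide state
  absorbs both tails. The transform is monotone and sign-preserving, so
  state semantics are untouched.
* Initialization is deterministic (tercile means, sticky 0.95/0.025
  transitions), making the fit a pure function of the track.
* A domain spans from the first bin of a downstream-biased run to the last
  bin of the following upstream-biased run(s).
* Domains narrower than the DI window are merged into an adjacent domain,
  dropping whichever boundary shows the weaker DI sign-jump — a ±w window
  cannot support a domain narrower than w.

**IS subdivision.** `IS(b)` is the mean contact in the 10×10 square
bridging bin `b`, normalized as log2 ratio to the chromosomal mean.
DI domains larger than 1 Mb (a conventional threshold for "large") are
split at
interior local minima with two-sided prominence ≥ 0.1 (log2 units); both
parameters are exposed.

**Boundary dynamics.** Boundaries of two stages are matched at a ±1 bin
tolerance (one bin at 20 kb, the default). For candidates found in
only one stage, the permutation test computes the Spearman correlation of
the two stages' 21-bin DI profiles at the boundary and compares it against
1,000 correlations of 20 randomly scattered bins; a boundary whose
concordance does not exceed the null's 95th percentile is called
stage-specific. This cutoff is liberal by construction — under a null
where both profiles are random the flag rate is ≈ 95%, equivalently the
complementary "conserved" call has ≈ 5% error — which the calibration
tests document. The random selections are scattered without replacement
(contiguous selections are an alternative; scattered is the default).

**Consensus and domain scores.** Boundaries recurring (within tolerance)
in at least half of all stage × replicate samples define consensus TADs; a
consensus TAD is an A-TAD when more than 70% of its analyzable bins are in
compartment A, otherwise a B-TAD (a strict mode demands >70% B for B-TAD
and returns "mixed" between). The domain score of a consensus TAD is the
fraction of all intrachromosomal contacts with both ends inside it, so
disjoint TADs sum to ≤ 1. Differential domain scores between stages use a
two-sample t test across replicates — Welch by default for robustness with
2–3 replicates, pooled available — flagging `p < 0.05` with the sign of
the mean difference.

# Promoter–enhancer interactions and RPS

Hierarchical promoter-background callers (PSYCHIC-style) fit a domain
tree; here the background is a per-window distance-decay count model,
which preserves the quantities that matter downstream (FDR < 0.01,
≥ 15 kb, the intensity formula) with far simpler machinery. Within each sliding window (20 Mb, 10 Mb step), every
promoter bin is tested against each candidate bin at ≥ 15 kb: the mean is
the window's smoothed decay, the p-value a Poisson upper tail (computed
via the gamma identity so balanced non-integer counts interpolate
smoothly), and Benjamini–Hochberg correction runs over all
promoter–candidate tests. Calls in overlapping windows are deduplicated by
best q. Intensity is `log10(observed − expected)`, floored at 0 when the
excess is ≤ 1 (the log would otherwise be negative or undefined).

RPS is the per-gene sum of intensities over its significant PEIs (0 for no
PEIs; adding a PEI can never decrease it). Differential RPS between stages
flags genes with both `|log2FC| > 1.5` and `|ΔRPS| > 3`, with a
pseudocount ε = 0.1 in the fold change to handle zeros. Profiles of
dynamic genes are clustered by k-means (k = 6 for RPS, k = 4 for temporal
expression) on row-z-scored matrices with a fixed seed and 25 restarts.

Negative-binomial counts are available in the config as an alternative to
Poisson for both callers.

# Enhancer classes, loops, CTCF convergence

H3K27ac peaks within 12.5 kb are stitched; stitched regions are ranked by
total signal, both axes are scaled to the unit square, and the inflection
point is where a slope-1 tangent touches the rank–signal curve (the point
furthest below the diagonal). Regions above it are super-enhancers, the
rest regular enhancers; with fewer than three stitched regions the
inflection is undefined and everything is RE (with a warning). Regions
contacting distal promoters but overlapping no peak are poised enhancers,
so every candidate region receives exactly one class.

Loops are called at 5 kb in the 20 kb–2 Mb range against the
spline-smoothed decay with the same Poisson/BH machinery (`q < 0.05`),
scored by observed/expected strength, and capped at the strongest 15,000.
A loop is convergent when a `+` motif lies within one bin of its left
anchor and a `−` motif within one bin of its right anchor; otherwise
divergent, tandem, or absent by the motif inventory. The promoter-skipping
fraction counts enhancers none of whose interacting promoters is their
nearest promoter (distance ties count as nearest).

# The synthetic generator

`build_expected_map` composes, multiplicatively on a power-law decay
`(1+d)^−α`:

* a checkerboard compartment factor `1±c`,
* an intra-TAD factor `1+t`,
* corner peaks `1+l` at loop anchors (±1 bin),
* promoter-anchored cells `1+p`.

Replicates are independent Poisson draws scaled to a target depth
(gamma-Poisson overdispersion optional — replicate variance is what makes
the differential domain-score t test meaningful). Stage differences are
explicit toggles: one compartment block flipped in stage 3, one TAD
boundary deleted in stage 2, a subset of loops and PEIs restricted to
single stages. Companion tracks couple gene expression to compartment
membership and planted regulatory potential
(`base · exp(β_A·[A] + β_R·z(RPS) + noise)`, defaults β_A = 1, β_R = 0.5,
lognormal noise sd 0.3 — effect sizes a sequencing study would call
moderate), give super-enhancers ≥ 5 stitchable member peaks with high
signal, regular enhancers one moderate peak, poised enhancers none, and
place convergent CTCF motifs at loop anchors with tandem and scattered
decoys elsewhere.

Default scale: one chromosome of 1,000 bins × 20 kb (20 Mb), depth 2×10⁶
contacts, 2 replicates × 3 stages for the compartment/TAD layer, plus a
1,000-bin × 5 kb layer over the first 5 Mb of the same chromosome for
PEIs and loops, pooled across replicates as is conventional for
interaction calling at fine resolution. This runs in seconds; genes live on the fine layer so
each carries both a compartment label (from the coarse truth) and an RPS
truth.

Two generator design points deserve emphasis:

* **Compartment blocks are unions of whole TADs.** A/B transitions
  insulate — placing a compartment edge mid-TAD would plant a genuine
  boundary-like feature the truth does not list, unfairly penalizing a
  correct caller. Real genomes show the same alignment.
* **Decoy CTCF pairs are kept clear of other motifs**, so their
  non-convergence is unambiguous rather than dependent on a scattered
  motif landing nearby.

What the generator does *not* emulate: restriction-fragment geometry,
mappability and GC biases, translocations, inter-chromosomal contacts,
sub-compartments, copy-number variation, and single-cell heterogeneity.
Passing recovery tests therefore demonstrates the correctness of the
computations on idealized planted signal, not performance on real
libraries with systematic biases.

# Numerical and degenerate-case policy

* Poisson tails use `P(X ≥ o) = P(Gamma(o, 1) ≤ λ)`, exact at integers
  and a smooth interpolation for balanced counts; `o = 0` gives p = 1.
* Differential domain scores with zero variance in both groups: equal
  means give p = 1; unequal means are flagged with a degenerate-variance
  warning.
* A flat DI track yields a single unbiased state and no domains; an
  all-constant correlation raises an error rather than NaN entropies.
* Boundary candidates within a DI window of the track edge are excluded
  from the permutation test with a warning.
* All randomness (EM init, k-means, permutations, sampling) derives from
  explicit seeds; a repeated run with the same configuration is
  byte-identical, which the tests verify by hashing artifact tables.

# Problem sizes used in validation

The test-suite and acceptance runs use the default study above
(recovering compartment labels at ≥ 95%, boundaries at F1 ≥ 0.8 with ±1
bin, planted PEIs and loops at ≥ 90% recall), 400-bin pure-decay maps for
the null calibration of the PEI and loop callers, five 1,000-bin no-change
studies (≥ 200 consensus TADs total) for the differential domain-score
null, and 100–120 random-track pairs for the permutation-test calibration.
These sizes make the whole validation reproducible on a laptop in a few
minutes while keeping every statistical check adequately powered.

# Known limitations

* Single-chromosome simulation; per-chromosome PCA and genome-wide
  aggregation are implemented but exercised on one chromosome.
* The PEI background is a distance-decay Poisson model, not PSYCHIC's
  domain-tree hierarchy; calls near strong TAD corners can differ.
* The Fit-Hi-C spline binning is simplified to one smoothed decay curve.
* "TAD intactness"-style summaries are not implemented; no standard
  definition exists.
* The permutation test inherits the liberal "specific" definition
  discussed above; treat specific-boundary lists as candidates, not
  confirmations.
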