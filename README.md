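# hicdynamics

Chromatin architecture dynamics from binned Hi-C contact maps.

## The problem

During development, the three-dimensional folding of the genome reorganizes
at every scale: the balance of active (A) and inactive (B) compartments
shifts, topologically associating domains (TADs) gain or lose boundaries and
internal contact strength, and promoter–enhancer contacts rewire gene
regulation. Studies of this kind — the motivating system is granulosa cells
across three chicken follicle stages (SWF, F1, POF) — read all of these
layers out of binned intrachromosomal contact matrices at 20 kb
(compartments, TADs) and 5 kb (interactions, loops).

`hicdynamics` is for analysts who have such binned matrices plus standard
annotations (TSS positions, CTCF motifs with strand, H3K27ac peaks,
expression tables) and want the full multi-stage analysis as tested,
reusable R functions. Because the underlying datasets (~10⁹ contacts) are
not reproducible at desk scale, the package also ships a synthetic
contact-map generator with planted architecture, and validates every step by
recovering what was planted.

## What it computes

* **Balancing and expectation** — Knight–Ruiz-style diagonal scaling
  (`kr_balance`, row sums equalized to 1e-8 relative), per-diagonal
  distance-decay expectation, observed/expected transform.
* **Von Neumann entropy** — for O/E correlation matrix *C* with
  trace-normalized eigenvalues *p&#7522;*:
  VNE = −Σ *p&#7522;* ln *p&#7522;* / ln *n* ∈ [0, 1]; higher = more
  disordered architecture.
* **Compartments** — PC1 of the O/E correlation matrix, sign-oriented by
  gene density; A where PC1 > 0; three-stage switch patterns (AAB, ABA, …)
  classified unidirectional/transient/stable.
* **TADs** — directionality index
  DI = sign(B−A)·((A−E)²/E + (B−E)²/E) over ±10 bins, segmented by a
  3-state Gaussian HMM, oversized domains subdivided at insulation-score
  minima; boundary overlap between stages, a 1,000-permutation test for
  stage-specific boundaries, consensus TADs (≥ 50% support), A-TAD/B-TAD
  classes (> 70% rule), domain scores
  D = intra-TAD contacts / all intrachromosomal contacts, and differential
  D-score t tests.
* **Promoter–enhancer interactions** — windowed Poisson tests against
  smoothed decay, BH-corrected (FDR < 0.01, distance ≥ 15 kb); per-gene
  regulatory potential RPS = Σ log₁₀(observed − expected); differential
  RPS (|log₂FC| > 1.5 and |ΔRPS| > 3) with k-means profile clustering.
* **Enhancers and loops** — ROSE-style 12.5 kb stitching with a slope-1
  inflection separating super- from regular enhancers, poised enhancers
  from peak-free contacted regions; loop calling in 20 kb–2 Mb
  (q < 0.05, top 15,000 by strength) with convergent-CTCF annotation and
  the promoter-skipping fraction.
* **Orchestration** — `run_config()` / `run_pipeline()` run the whole
  three-stage analysis deterministically; `recovery_report()` scores every
  planted-recovery property; the numbered scripts under `analysis/` walk
  the same workflow step by step and write tables under `results/`.

## Worked example

```r
library(hicdynamics)

cfg   <- sim_config(n_bins = 300, depth = 6e5, seed = 3)   # 6 Mb toy chromosome
truth <- build_truth(cfg)
E     <- build_expected_map(truth, cfg, stage = 1)
map   <- sample_replicate(E, cfg, seed = 14)
bal   <- kr_balance(map)
bal
#> contact_map: chrS, 300 bins @ 20000 bp, total 6.005e+05, balanced, 0 masked

von_neumann_entropy(bal, stage = "SWF", replicate = 1)
#>   stage replicate       vne
#> 1   SWF         1 0.8037364

prof <- compute_pc1(bal, truth$gene_density, stage = "SWF")
mean(prof$label == truth$compartment_labels$SWF)
#> [1] 1

tads <- call_tads(bal, seed = 1)
tads
#> tad_set: 12 domains, 13 boundaries over 300 bins
truth$tad_boundaries$SWF
#>  [1]  15  50  71  87 100 135 152 172 189 218 237 269 286
tads$boundaries
#>  [1]  15  50  71  87 100 135 152 172 189 218 237 269 286
```

The entropy (0.80) sits in the range typical of structured chromatin; the
compartment labels match the planted checkerboard exactly; and the caller
recovers all 13 planted boundaries at this depth with none spurious.

The full three-stage workflow is one call —
`run_pipeline(run_config(seed = 1))` — or, step by step with narrative
output and result tables:

```sh
Rscript analysis/01_simulate.R            # plant & export the study
Rscript analysis/02_entropy_compartments.R
Rscript analysis/03_tads.R
Rscript analysis/04_interactions.R
Rscript analysis/05_report.R              # recovery vs planted truth
```

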