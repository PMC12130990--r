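---
title: "Merging nuclei predictions from two segmentation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging nuclei predictions from two segmentation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleimerge)
```

## The integration model

Two pretrained nuclei segmentation models applied to the same H&E slide
produce overlapping but non-identical detection sets, in different cell-type
vocabularies. The integration treats one set (M₁) as a fixed reference
indexed by centroid position, and streams the other set (M₂) through a
nearest-neighbour matching loop:

* a pair within the Euclidean distance threshold `D` whose types agree is
  *the same nucleus seen twice* — it is collapsed into one record (centroid
  midpoint, probability `max(p₁, p₂)`, geometry from the M₂ member, type =
  the more specific of the two labels);
* a pair within `D` whose types disagree is a *classification conflict* —
  the higher-probability nucleus is retained (M₂ on ties), and when both
  probabilities exceed the equivocal threshold the disagreement is recorded
  for manual review;
* everything else is a *single-model detection* and is retained unchanged.

The working assumption is that centroids of the same physical nucleus, as
localised by two models, fall within `D` of each other, while distinct
nuclei (whose centers are separated by at least a nucleus diameter at 40×)
essentially never do. Matching uses centroids only; contours and boxes are
carried through but never influence a decision, so partially overlapping
segmentation masks neither help nor hurt.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `distance_threshold` | 10 | px (0.263 µm/px at 40×) | inclusive bound `d ≤ D` for "same nucleus" |
| `equivocal_prob_threshold` | 0.75 | probability | conflicts with *both* `p` strictly above it are flagged |
| `index_backend` | `exact` | — | k-d tree; `approximate` = random-projection forest |
| `n_trees` / `search_k` | 100 / −1 | — | forest size / candidate budget (−1 ⇒ `n_trees`) |
| `matching_strategy` | `literal` | — | guard behaviour for contended neighbours (below) |

The defaults reproduce the constants of the motivating pipeline (D = 10 was
chosen there by profiling centroid distances of overlapping nuclei; 0.75 is
the published equivocal cut-off). Both bounds are directional by design:
`d ≤ D` is inclusive, the equivocal test is strict, and a conflict tie
`p₂ = p₁` keeps the M₂ nucleus.

## The type schema

Vocabulary harmonisation is a tree rooted at `cell`, in which child labels
are always consistent with their parents:

```
cell ── epithelial ── neoplastic epithelial | non-neoplastic epithelial
     ── inflammatory ── lymphocyte | neutrophil | macrophage
     ── connective
     ── dead
```

Every node has a *match level* — the ancestor at which cross-model equality
is tested; by default its depth-1 ancestor. A MoNuSAC "lymphocyte" and a
PanNuke "inflammatory" therefore match (both resolve to `inflammatory`),
and the merged record keeps the more specific node, `lymphocyte`. This
most-specific output rule is this package's design choice: it is the only
rule under which a merged set can simultaneously report inflammatory
subtypes (which only the MoNuSAC vocabulary carries) and connective/dead
cells (which only PanNuke carries). For user schemas where two *sibling*
leaves share a match level, neither being an ancestor of the other, the M₂
node is kept, mirroring the merge rule that the merged type comes from M₂.
The conflict/equivocal test compares labels at match level, not raw
strings; raw labels appear verbatim in the equivocal report. Schemas are
user-overridable YAML files (`load_schema()`), so additional models only
require a mapping, not code.

## Matching strategies and degenerate inputs

The printed form of the algorithm never guards against two M₂ nuclei
matching the same M₁ nucleus. To preserve the no-duplicate-output
invariant, `literal` (default) adds a first-consumption-wins guard: a later
M₂ nucleus whose nearest neighbour is already consumed is handled as if out
of range. `one_to_one` instead re-queries for the nearest *unconsumed* M₁
neighbour (by exhaustive scan — the index is static, and dynamic deletion
from a k-d tree buys nothing at these sizes). An M₁ nucleus that *loses* a
conflict is deliberately not consumed — it remains available and, if never
matched, is retained at the end, exactly as the match-flag bookkeeping of
the printed algorithm implies.

Merged-pair monotonicity in `D` (every pair merged under `D` also merged
under `D′ > D`) holds only when neighbours are uncontended: under
contention, a larger `D` can let an earlier M₂ nucleus consume the partner
a later one would have taken. The test suite checks the property in the
spaced regime where it is well defined.

Numerical corner cases are resolved deterministically: equidistant
neighbours break ties toward the smallest index (both backends, including
coincident points); coincident centroids within one set are legal — the
algorithm reads centroids only and never deduplicates inside a set; an
empty index returns a no-neighbour sentinel rather than an error; an empty
merge result yields proportion tables flagged `undefined` rather than
silent `NaN`s. After every merge the implementation asserts its
bookkeeping identities (`merged + conflict_m1 + conflict_m2 + unmatched_m2
= |M₂|`; `unmatched_m1 = |M₁| − consumed`; no source id duplicated), so a
violation fails fast rather than corrupting downstream counts.

## Index backends

The exact backend is a k-d tree over the M₁ centroids and is the default:
merging is then fully deterministic and byte-reproducible, and an
independent exhaustive-scan implementation (`brute_force_merge()`) must
agree with it field-for-field — the test suite enforces this equivalence on
hundreds of random instances. The approximate backend is a seeded
random-projection forest in the style of Annoy (two-point hyperplane
splits, one priority queue across all trees, exact re-ranking of the
`search_k` candidates); with the default 100 trees its nearest-neighbour
agreement with the exact backend is ≥ 99% on fields of 10,000 nuclei, and
is checked as part of the suite. It exists because the original pipeline
used an approximate index as an engineering accelerant; nothing in the
statistics depends on it.

## The synthetic generator

`synthetic_config()` describes ground truth and two degradation profiles.
Truth is a hard-core point field (uniform dart throwing with a minimum
separation of 30 px, circular stand-in contours) with exact per-category
counts; the default composition is a normal-prostate-like mixture of 2,000
nuclei — 50% epithelial (mostly non-neoplastic), 43% connective, 6%
inflammatory (mostly lymphocytes), 1% dead. The default profiles encode the
documented model asymmetries: the MoNuSAC-like profile maps both epithelial
subtypes to plain "epithelial", labels inflammatory subtypes, and detects
connective/dead cells with probability 0; the PanNuke-like profile covers
everything but detects inflammatory cells with probability 0.25 (vs 0.9
elsewhere). Centroid jitter is isotropic Gaussian with sd 1 px — small
relative to `D`, as co-detections of one nucleus must be — and probability
scores are Beta(8, 2), right-skewed as confident model scores are.

What the generator does *not* emulate: real nucleus shapes and mask
overlap, spatially clustered tissue architecture, density-dependent
detection failure, or correlated errors between the two models. Passing
tests therefore demonstrate that the merging logic, bookkeeping and
reporting are correct under the stated noise model — not that any
particular biological accuracy is achieved on real slides.

With the separation ≫ jitter, expected merge statistics are computable by
construction (a truth nucleus detected by both models with concordant
labels must merge; nothing else may), which is what `generate_pair()`
returns and the end-to-end tests assert. The headline recovery property —
the integrated composition is closer to the truth (total-variation distance
over the depth-1 categories) than either single model's on ≥ 95% of seeds —
is checked over 100 seeds at the default conditions.

## Validation statistics

`lin_ccc()` is Lin's 1989 concordance estimator with biased (1/n) moments,
`2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²)`, with a Fisher-z confidence interval
using Lin's asymptotic variance. Which CCC variant or CI method produced
the published intervals is not stated anywhere; this package documents its
choice rather than reverse-engineering one, and reference estimates are
treated as plain numerics (pathologist deciles enter as percentages, with
no ordinal machinery). `two_sample_t()` delegates to `stats::t.test()`
(Welch by default) and resolves the zero-variance corner cases that
`t.test()` refuses, by documented convention: identical constant samples
give `t = 0, p = 1`; constant samples with different means give an infinite
`t` flagged degenerate.

## Problem sizes

The shipped tests run random-instance oracle equivalence up to 1,000 nuclei
per side (200 instances), recovery at the default 2,000-nucleus field over
100 seeds, and approximate-vs-exact agreement on 10,000 points — sizes at
which every property of interest is already exercised while the whole suite
stays interactive (a few minutes). `scripts/acceptance.R` simulates a
30-slide cohort (per-slide composition drawn from a Dirichlet around the
default mixture, concentration 50, so cohort-level concordance statistics
have between-slide variance to measure) and writes the resulting summary
quantities as JSON. Real-slide workloads (10⁵–10⁶ nuclei) pose no
algorithmic difficulty — the index query is logarithmic and the loop linear
— but are dominated by I/O.

## Known limitations

* Pairwise only: merging more than two models requires chaining merges,
  with a schema whose match levels remain meaningful at every step.
* Matching ignores contour overlap entirely; two models that systematically
  split/merge touching nuclei differently will not be reconciled by a
  centroid threshold.
* The distance threshold is in pixels; slides scanned at a different
  resolution need `distance_threshold` rescaled by hand.
* `one_to_one` is order-dependent (M₂ file order); a globally optimal
  assignment (e.g. Hungarian matching) is out of scope.
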