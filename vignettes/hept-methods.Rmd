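---
title: "Methods: the tensor-extended HITS model behind HEPT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tensor-extended HITS model behind HEPT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HEPT)
```

## The problem and the model

Essential proteins tend to be network hubs, but degree alone is a weak
predictor on noisy, incomplete PPI data. HEPT's premise is that several
independent relationships between proteins — sharing interaction neighbors,
sharing domain types, sharing functional annotation — each carry part of the
essentiality signal, and that these relationships should *not* be collapsed
into a single aggregate network: different relation types can matter to
different degrees, and that degree of importance is itself something the
model should estimate.

The data structure is therefore a three-way tensor T: one n × n symmetric
slice per relation type, entries in [0, 1]. The ranking model is a
HITS-style mutual-reinforcement system with three score vectors —
authority VA (the ranking score), hub VH, and edge-type importance VE —
encoding three assumptions: a protein is authoritative if high-hub proteins
point at it through important relation types; a protein is a good hub if it
points at authoritative proteins through important relation types; and a
relation type is important if it frequently connects high-hub proteins to
high-authority proteins. The authority update additionally mixes, with
weight `1 − alpha`, a restart distribution D concentrated on proteins that
are conserved across many organisms and located in large (well-populated)
compartments — two classic essentiality covariates that are *not* functions
of the network and therefore anchor the walk against topology noise.

Because every slice is built from a shared-item count, a pair of proteins
with no shared neighbor, domain or GO term has weight zero in the
corresponding slice. Slices are constructed only over candidate pairs found
by inverted-index joins (sparse cross-products), never over all n² pairs;
this is mathematically identical and is what makes networks of several
thousand proteins practical.

## Relation weights

* **Co-neighbor.** `|N_i ∩ N_j|² / ((|N_i|−1)(|N_j|−1))`, zero unless both
  proteins have at least two neighbors. The ratio can exceed 1 (two
  degree-2 proteins sharing both neighbors give 4); we clip at 1 so every
  tensor entry stays interpretable as a probability-like weight, and log
  how many entries were clipped. Clipping is configurable off
  (`clipCoNeighbor = FALSE`) for sensitivity analyses.
* **Co-domain.** Per-protein domain scores sum `1/NP_d` over the protein's
  domains (`NP_d` = indexed proteins carrying domain d), so rare domains
  and domain-rich proteins score high; scores are min–max normalized over
  all n proteins. The pair weight is the product of the two scores, gated
  on sharing at least one domain type. If all raw scores coincide (e.g. no
  annotations at all) min–max is undefined and we set every score to 0
  with a warning — the slice then carries no signal rather than an
  arbitrary constant.
* **Co-annotation.** `|F_i ∩ F_j| / sqrt(|F_i||F_j|)` over filtered GO term
  sets — a cosine-style overlap, in [0, 1] by Cauchy–Schwarz. GO terms
  annotating fewer than `goMin = 10` or more than `goMax = 200` proteins
  are discarded first: very rare terms are too specific to create reliable
  pair signal, near-universal terms connect everything. The filter is
  applied after restricting annotations to network proteins (the frequency
  that matters is frequency among ranked proteins); `goFilterFirst = TRUE`
  applies it to the raw table instead.

Relations are computed for *any* protein pair sharing the relevant item,
not only for pairs that directly interact — the co-domain and co-annotation
slices deliberately add edges the PPI network lacks. The conservative
variant (`restrictToPpi = TRUE`) masks all slices by the adjacency pattern.
Diagonal entries are excluded from every slice: the input network carries
no self-interactions, and a self-edge would siphon probability mass in the
fiber normalizations.

## Transition normalization and the iteration

Mode-wise normalization turns T into three transfer tensors: each authority
fiber (fixed j, k; running i), each hub fiber (fixed i, k) and each
edge-type fiber (fixed i, j; running k) is divided by its sum; all-zero
fibers become uniform, 1/n or 1/m. The uniform fibers are never
materialized: their contribution to each contraction is added analytically
(for a slice with z empty columns the authority contraction gains
`(1/n) · VE_k · Σ_{j empty} VH(j)`, and the edge-type update gains
`(1/m) · (ΣVA ΣVH − Σ_{(i,j) with some relation} VA_i VH_j)`). A dense
n × n × 3 tensor at n ≈ 5000 would hold 75M entries per mode; the implicit
form is exact, and its equality with an explicit dense materialization is a
unit test (`denseTransitionTensor()` exists for exactly such checks on
small n). Since every slice is symmetric, the hub transition tensor is the
transpose of the authority one and shares its storage.

One iteration performs, in order: the VA update (restart plus contraction
against the *previous* VH and VE), the VH update against the *fresh* VA,
and the VE update against both fresh vectors. Numerical choices, all made
where the design was genuinely open:

* **Per-iteration L1 normalization** of VA, VH and VE (default on,
  `normalizeState = FALSE` to disable). Classical HITS requires
  renormalization to prevent geometric growth or decay; here it is also
  what keeps the restart mixture coherent — VA is a convex combination of
  the probability vector D and a contraction term only if VH and VE remain
  distributions.
* **Stopping rule**: the iteration stops when
  `‖ΔVA‖₁ + ‖ΔVH‖₁ + ‖ΔVE‖₁ < epsilon`. The L1 norm matches the
  probability-vector semantics of the normalized state. Defaults
  `epsilon = 1e-8`, `maxIter = 1000`; hitting the cap returns the state
  with `converged = FALSE` and a warning rather than an error.
* **Restart weight** `alpha = 0.3`, the value at which prediction accuracy
  peaks on the yeast DIP benchmark; `alpha = 0` reduces VA to D in one
  step, `alpha = 1` removes the restart entirely. The restart applies only
  to the authority update — VH and VE are purely structural.
* **Jump vector normalization**: D is L1-normalized (disable with
  `normalizeD = FALSE`); an all-zero raw product vector (no orthology or
  localization signal anywhere) falls back to uniform with a warning, so
  the restart term never degenerates. Proteins missing from the orthology
  table get `NI = 0`; proteins without localization get `S = 0`; such
  proteins are reachable only through the tensor term.
* **Tie-breaking**: final rankings order equal VA scores by ascending
  protein identifier (byte order), making output deterministic and
  reproducible across platforms.
* **Degenerate inputs**: an all-zero tensor is valid — every fiber is
  uniform, and with `alpha = 1` the uniform state is the exact fixed point
  (a unit test); empty annotation tables yield all-zero slices rather than
  errors.

## The synthetic data generator

`syntheticBundle()` generates the six input files the method consumes, with
a planted essential set, and is the package's test bed. It emulates the
statistical structure the model assumes: a preferential-attachment
(scale-free) topology in which planted essentials attract attachment at a
`bias`-scaled rate; domain and GO annotations whose per-protein counts are
`bias`-scaled for essentials and drawn preferentially from small enriched
term pools (so essentials share them); binomial ortholog species counts
(out of 100 reference organisms, base rate 0.08) with a `bias`-scaled
success probability; and compartment assignments whose sizes decay across
the vocabulary, with essentials favoring the largest compartment at a
`bias`-scaled rate. Defaults: 200 proteins, 20 essentials, bias 5, 3 edges
per arriving node, 60 domains, 40 GO terms, 8 compartments. At `bias = 1`
every feature distribution is identical for essential and non-essential
proteins, giving an exact null in which recovery can only be at chance —
the property the null-model test checks with a binomial test. Each data
type draws from its own seeded stream, so changing one vocabulary size
does not perturb the others.

What the generator does *not* emulate: false-positive/false-negative
interaction noise with realistic spoke/matrix bias, the true yeast degree
distribution, GO term hierarchy (terms are drawn independently, not
propagated up an ontology), correlated multi-compartment localization, or
paralogy structure in the ortholog counts. Passing the recovery tests
therefore shows the pipeline extracts a planted multi-source signal
correctly — not that it attains any particular accuracy on real organisms.

## Problem sizes used by the test suite

Dense brute-force oracles (triple-loop tensor construction, normalization
and contraction) are compared entry-for-entry at n ≤ 30; fiber
stochasticity is checked exhaustively over 50 random tensors at n ≤ 30
including all-zero-fiber and all-zero-slice cases; the single-slice
degeneracy is checked against a dense personalized-HITS matrix
implementation for 10 iterations; recovery experiments run at n = 200 with
20 planted essentials (10 signal seeds, 20 null seeds), and the
bias-monotonicity sweep at bias ∈ {1, 2, 5, 10} × 10 seeds. These sizes
keep the full suite under a minute while exercising every branch of the
normalization.

## Known limitations

* The co-domain slice treats domain content as a bag of types; domain
  architecture (order, copy number) and domain–domain interaction evidence
  are ignored.
* GO overlap is set-based; no semantic-similarity measure (Resnik, Lin,
  Wang) is offered, and annotation evidence codes are not filtered when
  reading GAF input.
* The iteration is a plain power method; no acceleration is attempted.
  Convergence is fast in practice (tens of iterations at the defaults) but
  is not theoretically guaranteed for `normalizeState = FALSE`.
* Identifier matching across the six inputs is exact-string and
  case-sensitive; no ID mapping is performed, so inputs must share a
  namespace.
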