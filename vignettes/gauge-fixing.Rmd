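---
title: "Gauge fixing for one-hot sequence-function models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gauge fixing for one-hot sequence-function models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqgauge)
```

## The model class

seqgauge works with linear one-hot models of sequence-function
relationships. A sequence `s` of length `L` over an alphabet of `α`
characters is embedded as a binary feature vector `x(s)`, and the model
is `f(s; θ) = θ · x(s)`. Features are indexed by *augmented sequences*:
length-`L` strings over the alphabet plus the wildcard `*`, read as match
patterns. The all-order model activates all `(α+1)^L` patterns; additive
and pairwise models activate the patterns of order ≤ 1 or ≤ 2; a
*hierarchical* model is any zero-pattern-closed subset (if a feature is
inactive, every refinement of it is inactive too). The embedding
factorizes across positions, `x(s) = ⊗_l (1, e_{s_l})`, which is what
makes the gauge family below tractable.

Because summing an order-`K` feature over the characters at one of its
positions reproduces an order-`K−1` feature, the columns of the design
matrix `X` are linearly dependent and the model has gauge freedoms: the
null space `G` of `X`. An additive model has `L` of them, a pairwise
model `L + C(L,2)(2α−1)`, the all-order model `(α+1)^L − α^L`. The
package computes an orthonormal basis of `G` from the Gram matrix `XᵀX`
over the full factorial, whose entries have a closed product form
(`α` per doubly-starred position, 0 for clashing characters, 1
otherwise), so no sequence enumeration is needed even for long additive
models.

## The parametric gauge family

A gauge is a subspace `Θ` meeting each gauge orbit `{θ + g : g ∈ G}`
exactly once. The family implemented here is indexed by a penalization
strength `λ ∈ [0, ∞]` and a factorized distribution
`p(s) = ∏_l p_{l,s_l}`. Per position, the gauge space is the direct sum
of `span{(λ, 1, …, 1)}` and the `p_l`-orthogonal complement of the
constant within the character block; the full space is the tensor product
over positions. The corresponding projection matrix is the Kronecker
product of `(α+1)×(α+1)` blocks that depend only on `η = λ/(1+λ)` and
`p_l`: row `*` is `(η, p_{c}η)`, row `c` is `(1−η, δ_{cc′} − p_{c′}η)`.
Both this Kronecker route and a direct elementwise evaluation of the
product formula are implemented and cross-checked; every entry of the
projector is a polynomial of degree `L` in `η`, which is why
`eta_sweep()` trajectories are exact degree-`L` polynomials.

`λ` is always handled through `η`; `λ = ∞` is the symbolic point `η = 1`
and never a floating-point infinity. For `0 < λ < ∞` and strictly
positive `p` the same gauge arises from constrained optimization: it
minimizes `θᵀΛθ` on the orbit with the diagonal penalizer
`Λ_{s′s′} = p(s′)λ^{o(s′)}`. `penalization_matrix()` refuses the limit
cases (`λ ∈ {0, ∞}` or zero probabilities) because no finite penalizer
realizes them; the projection route stays well defined there, and
`wildtype_limit_check()` verifies empirically that smoothing a
zero-containing `p` toward uniform (`(1−ε)p + ε/α`) yields projections
converging to the direct `η = 1` projection — the limit is checked
numerically rather than via an explicit penalizer series, which the
constrained-optimization formulation does not supply.

Arbitrary linear gauges are supported through `linear_gauge()`: either a
spanning basis (projected along `G` via `B(XB)⁺X`) or a
positive-definite penalizer (via `Λ^{-1/2}(XΛ^{-1/2})⁺X`).

## Hierarchical gauges without the all-order space

At `η = 1` the gauge-fixed coefficients are conditional means and their
differences: the constant is `⟨f⟩_p`, an additive coefficient is
`⟨f | c at l⟩_p − ⟨f⟩_p`, and in general a coefficient is the
inclusion-exclusion sum of conditional means over subsets of its fixed
positions. `conditional_mean()` evaluates these in closed form — each
active feature contributes its coefficient times a product of per-position
probabilities or match indicators — so `project_hierarchical()` runs on
additive, pairwise, nearest-neighbor, and other hierarchical models
without constructing `(α+1)^L` features (the 2481-parameter pairwise
model over a 20-letter alphabet projects in about a second). Downward
closure of the active set guarantees every inclusion-exclusion term is
itself an active feature; the all-order `η = 1` Kronecker projector
serves as the oracle for this construction in the test suite.

Conditioning on a character with `p`-probability zero is well defined:
fixing a position overrides `p` there. This is what makes indicator
distributions (wild-type gauge) and region distributions (generalized
wild-type gauges) ordinary members of the family.

Consequences used throughout the package:

* **Marginalization** — each parameter group sums to zero under
  `p`-weights over the character at any of its positions
  (`marginalization_residual()` reports the worst violation, relative to
  the parameter scale).
* **Orthogonality / variance decomposition** — landscape components with
  different star patterns are `p`-orthogonal, so
  `var_p[f] = Σ_k var_p[f_k]` with
  `var_p[f_k] = Σ_{o(s′)=k} p(s′) θ_{s′}²`. The constant component is
  assigned variance 0 by convention. With zeros in `p` the decomposition
  refers to the supported region only. `variance_decomposition()` fails
  loudly on out-of-gauge input unless `auto_project = TRUE` — silent
  reinterpretation of a parameter vector in the wrong gauge is the kind
  of bug this package exists to prevent.
* **Truncation optimality** — dropping orders above `k` from a
  hierarchical-gauge model yields the `p`-weighted least-squares
  approximation among order-`k` models (on the support of `p`). This is
  how local additive approximations for regions of sequence space are
  produced: project into the region's hierarchical gauge, then
  `truncate_to_order(·, 1)`.

The *maximum gauge* (constant anchored at the best sequence, additive
parameters all ≤ 0) lies outside the linear family — its constraint set
is nonlinear — and is provided for additive models only, where it is a
deterministic per-position shift. Subtracting each position's maximum
makes every maximal character exactly zero, so no tie-breaking is needed;
where several characters tie they all end at zero.

## The synthetic-landscape generator

No external datasets ship with the package; `simulate_landscape()`
produces the study systems:

* `random_all_order` emulates a random activity landscape on short
  sequences: i.i.d. standard-normal activities (scale `activity = 1`),
  stored in the trivial gauge. The binary `L = 3` instance used in the
  examples and acceptance checks has 8 activities and 27 parameters.
* `region_structured_pairwise` emulates an empirical pairwise landscape
  containing a few disjoint high-activity regions, anchored at the last
  two positions: i.i.d. background effects (additive sd 0.5, pairwise sd
  0.2) plus planted positive effects — +3 on each region's anchor
  character, +2 on the anchor-pair interaction for regions that restrict
  both anchors, and +1.5 region-specific pairwise preferences linking
  the anchor to each free position so that the best local additive
  description genuinely differs between regions. These magnitudes were
  chosen once to give regions that stand a few standard deviations above
  background, comparable to the strong-epistasis regimes reported for
  protein interaction domains. The default instance is a 4-letter
  alphabet at `L = 4` (256 sequences, 113 parameters), which keeps
  100-replicate comparisons fast while preserving the qualitative
  region structure; a 20-letter alphabet changes the sizes, not the
  logic.
* `additive` is the trivial control: constant 0 plus i.i.d. additive
  effects.

Noise, when requested, is additive i.i.d. Gaussian on the activity
table. The generator does not emulate sequencing-count noise,
missing-variant patterns, or the nonlinearities of enrichment assays —
so a passing test suite demonstrates the gauge algebra and the
projection/truncation logic, not robustness to real measurement error.
Every simulation takes a mandatory seed and restores the caller's RNG
state.

`fit_least_squares()` is deliberately plain: minimum-norm least squares
via the SVD pseudoinverse (which lands in the Euclidean gauge), or ridge
on the identity for `ridge > 0`. It exists so the
simulate → fit → project pipeline can be exercised end to end, not as a
contribution in itself.

## Numerical choices

* Feature order: tensor-product mixed-radix order, `*` first at each
  position, position 1 most significant. The literature fixes no
  canonical order; this one makes the projector an exact Kronecker
  product with no permutation. Sequences are ordered lexicographically
  in the declared alphabet order, and positions are 1-based in all
  user-facing labels.
* Null spaces and pseudoinverses use a relative singular-value cutoff of
  `1e-10` (Gram-eigenvalue cutoff `1e-10` for `gauge_freedom_basis()`);
  the spectra of these binary designs are integer-separated at the
  supported sizes, so the cutoff is not delicate.
* `linear_gauge()` refuses penalizers with condition number above
  `1e12`, and basis gauges whose largest principal-angle cosine against
  `G` exceeds `1 − 1e-14` (transversality would be numerically
  meaningless beyond that).
* Dense enumeration is capped at `10^6` sequences and `10^5` features;
  operations with closed forms (gauge-freedom dimensions, conditional
  means, hierarchical projections, variance decompositions) never
  enumerate sequence space.
* TSV round-trips write numeric values at 17 significant digits and
  re-parse them with base R's strtod-exact reader, so parameter tables
  round-trip bit-exactly.

## Problem sizes in the checks

The test suite and the acceptance script run entirely on desk-scale
instances: binary to 4-letter alphabets with `L ≤ 4` for anything that
builds dense projectors (`M ≤ 256`), the 20-letter pairwise spec
(`M = 2481`) for closed-form hierarchical operations, and 100 simulation
replicates for the region-truncation comparison. These sizes were chosen
so each property is exercised at more than one `(α, L)` combination
while the whole suite completes in well under a minute of compute per
module.

## Known limitations

* Only factorized distributions `p` are supported; the gauge family is
  defined in terms of per-position factors, and non-factorizable
  distributions fall outside it.
* The maximum gauge is not available for models with interactions.
* `fit_least_squares()` forms dense design matrices; it is not meant for
  data far beyond `10^5` rows or `10^4` features.
* Linear models only: linear-nonlinear (global-epistasis) links,
  diffeomorphic parameter freedoms, and uncertainty-driven sloppy modes
  are out of scope.
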