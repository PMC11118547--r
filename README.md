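# seqgauge

Gauge fixing for one-hot models of sequence–function relationships.

## The problem

Quantitative models of sequence–function relationships — DNA binding
energies, protein fitness landscapes, enhancer activities — are usually
built from one-hot features: indicators for specific characters (or
character combinations) at specific positions. These models carry **gauge
freedoms**: directions in parameter space along which parameters can be
changed without altering a single model prediction. For a linear model
`f(s; θ) = θ · x(s)` with design matrix `X`, the gauge freedoms are the
null space `G = {g : Xg = 0}`. Until these degrees of freedom are removed
by imposing constraints (a *gauge*), individual parameter values have no
meaning — the same landscape can be written with wildly different
coefficients.

seqgauge is a toolkit for choosing, applying, and exploiting gauges, aimed
at anyone fitting additive, pairwise, higher-order, or all-order
interaction models to sequence–activity data.

## The core machinery

Features of the all-order model are indexed by *augmented sequences*
`s′`: length-`L` strings over the alphabet plus a wildcard `*`, acting as
match patterns. seqgauge implements a two-parameter family of linear
gauges `Θ^{λ,p}`, where `λ ∈ [0, ∞]` sets how strongly high-order features
are penalized and `p` is a factorized position-specific distribution
`p(s) = ∏_l p_{l,s_l}`. The family is a tensor product of single-position
gauge spaces, so its M×M projection matrix is an exact Kronecker product
of `(α+1)×(α+1)` blocks in `η = λ/(1+λ)`:

- `λ = 0` — **trivial gauge**: parameters are the raw activities;
- `λ = α`, uniform `p` — **Euclidean gauge**: the minimum-L2
  representative, equal to the orthogonal projection `X⁺X θ`;
- `λ = 1` — **equitable gauge**: each parameter penalized by the fraction
  of sequences it touches;
- `λ → ∞` — **hierarchical gauges**: ANOVA-like gauges whose coefficients
  are p-weighted conditional means and differences. Uniform `p` gives the
  **zero-sum gauge**, an indicator `p` gives the **wild-type gauge**, and
  region-restricted `p` gives **generalized wild-type gauges**.

For `0 < λ < ∞` and positive `p` the gauge is equivalently the minimizer
of `θᵀΛθ` on the gauge orbit, with diagonal penalizer
`Λ_{s′s′} = p(s′) λ^{o(s′)}`; arbitrary positive-definite penalizers are
supported through `P = Λ^{-1/2}(XΛ^{-1/2})⁺X`.

Hierarchical gauges are computed by closed-form conditional means
(inclusion–exclusion, no all-order enumeration), so they apply directly to
additive, pairwise, nearest-neighbor, and other *hierarchical* models.
They make the landscape variance split exactly by interaction order, and
truncating a hierarchical-gauge model at order `k` yields the p-weighted
least-squares approximation of that order — the basis for extracting local
additive models valid within regions of sequence space.

## Worked example

```r
library(seqgauge)

# a random landscape on binary sequences of length 3 (8 activities)
sim <- simulate_landscape("01", 3, "random_all_order", seed = 20240512)
sim$data
#> # A tibble: 8 × 2
#>   sequence activity
#>   <chr>       <dbl>
#> 1 000        -0.788
#> 2 001         2.26
#> 3 010         0.654
#> 4 011         0.395
#> 5 100         0.926
#> 6 101        -0.810
#> 7 110         1.21
#> 8 111         2.75

# fix the zero-sum gauge: the constant is the mean activity, and
# parameter groups sum to zero over characters at each position
theta_zs <- fix_gauge(sim$theta, "zero_sum")
theta_zs
#> # A param_vec: M = 27 features (alphabet {01}, L = 3, all_order)
#> # A tibble: 27 × 3
#>   feature order    value
#> 1 ***         0  0.825
#> 2 **0         1 -0.324
#> 3 **1         1  0.324
#> ...
```

`***` is the constant feature: 0.825 is the mean of the 8 activities.
`**0`/`**1` are the two additive effects at position 3, equal and
opposite as the zero-sum constraint demands.

```r
variance_decomposition(theta_zs, uniform_dist(sim$spec))
#> # A tibble: 4 × 3
#>   order variance fraction
#> 1     0    0        0
#> 2     1    0.326    0.228
#> 3     2    0.425    0.297
#> 4     3    0.677    0.474
```

47% of this landscape's variance sits in third-order epistasis — a random
landscape is dominated by its highest-order interactions. In the
wild-type gauge anchored at `000`, the constant becomes that sequence's
activity and every parameter touching `000` is zeroed:

```r
head(tidy(fix_gauge(sim$theta, "wild_type", wt = "000")), 4)
#>   feature order  value
#> 1 ***         0 -0.788
#> 2 **0         1  0
#> 3 **1         1  3.05
#> 4 *0*         1  0
```

so `**1 = 3.05` reads directly as the effect of mutating position 3 from
0 to 1 on the wild-type background. `eta_sweep()` traces all 27
parameters across the whole gauge family (each trajectory is an exact
cubic in `η`), and `autoplot()` methods draw the sweep, variance table,
and parameter vectors.

A shell interface mirrors the main verbs
(`simulate | fit | project | decompose | truncate | freedoms | orbit-check`):

```sh
Rscript inst/cli/gauge.R freedoms --alphabet 01 --length 3 --order 2
#> gauge freedoms: 12
```

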