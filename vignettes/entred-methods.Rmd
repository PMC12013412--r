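---
title: "Methods: relative-entropy functional redundancy and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative-entropy functional redundancy and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entred)
```

## The model

A sample is a community of `n` species with relative abundances
`a ∈ (0, 1]ⁿ`, `Σaᵢ = 1`. For one function `F` (typically the secretion
of a metabolite, quantified per species by constraint-based community
modelling), each species has a non-negative quantitative output `fᵢ`,
and `f̃ᵢ = fᵢ / Σfᵢ` is its functional share. The package's measures are
all Kullback–Leibler divergences of `f̃` against a baseline:

| measure | definition | range | zero iff |
|---|---|---|---|
| sample taxon-based FR | `H(f̃) − log n` | `[−log n, 0]` | equal positive shares over all `n` species |
| reference taxon-based FR | `H(f̃) − log m` | `[−log m, 0]` | all `m` reference species present, equal shares |
| abundance-based FR | `−Σ_{f̃ᵢ>0} f̃ᵢ log(f̃ᵢ/aᵢ)` | `≤ 0` | `f̃ = a` elementwise |
| interdependency `I` | `Σ_J f̃ⱼ log(f̃ⱼ/ãⱼ)`, `ãⱼ = aⱼ/Σ_J aⱼ` | `≥ 0` | `fⱼ ∝ aⱼ` on the producer set `J` |

Natural logarithms throughout, so everything is in nats; the log base is
an argument of nothing — keeping one convention package-wide avoids an
entire class of unit bugs, and the documented anchor values
(e.g. −log(100) ≈ −4.6052) all assume base e.

Two useful closed forms, both enforced by property tests:

* uniform abundances make the sample and abundance measures coincide
  exactly;
* `fⱼ ∝ aⱼ` on `J` makes the abundance measure equal `log Σ_J aⱼ` — a
  function of the producers' total abundance only, which is precisely why
  deviations of `I` from zero can be read as interdependency: whatever
  part of `f̃` abundance cannot explain, something between species must.

The reference measure uses a *fixed* `m` per function, supplied
explicitly. A reference derived from a corpus (the union of species ever
seen producing the function) is supported for exploratory use but labelled
`derived`, because it underestimates `m` and therefore overestimates the
reference FR.

## Interdependency: what `I` does and does not say

`I` compares the producer-restricted share vector with the
producer-renormalised abundance vector. `I = 0` for a single producer by
construction (`k = 1` gives two one-point distributions), so `I` is only
informative when several species produce the function. The per-sample
aggregate is the median across functions — robust to the strongly skewed
`I` distributions that flux tables produce; for even counts the mean of
the central pair is used (the ordinary convention; nothing downstream
depends on the tie-break).

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `zero_tol` | 1e-12 | share/flux | below this a share is an exact zero: the index sets run over strictly positive shares and log underflow must not manufacture −Inf from solver noise |
| `tolerance` (uptake) | 1e-9 | mmol·gDW⁻¹·h⁻¹ | LP solvers emit ±1e-13-scale jitter; a flux below −1e-9 is treated as genuine uptake (pair missing), above it as noise (clipped to 0) |
| `min_species` | 25 | species | samples with fewer species give unstable community models; "fewer than 25" is read strictly, so richness 25 is retained |
| `min_nonmissing` | 0.8 | fraction | functions are kept only with *strictly more* than 80 % non-missing pairs; whether exactly 80.0 % should pass is not decidable from the convention's wording, so the strict reading was chosen and the threshold left configurable |

Missingness is two-tier by design: *expected* degeneracies (no producers,
an uptake) travel as `NA` with a `missing_reason`, because they are data,
not bugs; *structural* problems (a producer absent from the reference,
misaligned species sets, duplicate keys) raise errors, because silently
repairing them would hide upstream corruption.

## The community-level contrast

`community_fr()` implements `FR = D − Q` with `D` Simpson's diversity and
`Q` Rao's quadratic entropy over Gower trait dissimilarities
`d = √(1 − s)` (equal trait weights; quantitative traits range-normalised;
binary traits matched symmetrically, so two non-producers count as
similar). `keystone_series()` makes the conceptual gap concrete: one
producer among `n` uniformly abundant species, encoded as a single binary
producer trait (the minimal trait structure consistent with a
single-function comparison — the exact encoding behind the published
picture is not specified anywhere, but any encoding separating producer
from non-producers gives the same qualitative shape). The closed form is
`FR(n) = (n−1)(n−2)/n²`: zero at `n ∈ {1, 2}`, strictly increasing from
`n = 3`, converging to 1 — while every single-trait measure falls to its
minimum or stays there. `FR = D − Q` measures the redundancy of the
community's *trait composition*, not the retention of any one function.

## The synthetic-data generator

`simulate_unknown()` states a simple world: per iteration one
concentration parameter `α` is drawn (50/50 from {1, 5} by default — `α=1`
is the uniform distribution over the simplex and yields uneven
communities, `α=5` more even ones), then shares and abundances are drawn
*independently* from symmetric Dirichlet(α) over 100 species. The wording
of the underlying design does not fix the dependence structure between
`f̃` and `a`; independence is the weakest assumption, it is switchable in
code by construction (draw your own vectors and call
`reclassify_unknown()` directly), and none of the tested conclusions
depend on it. Species are then reclassified as "unknown" cumulatively, 10
at a time up to 80, by a uniformly random removal order; both vectors are
renormalised over the classified remainder. The reference measure keeps
`m = 100` fixed — unknown species remain members of the reference — which
is exactly what produces its systematic underestimation; the sample
measure recomputes `n` on the shortened vector.

What the generator emulates: compositionality, uneven vs even regimes,
and the information loss of unclassified taxa. What it does not emulate:
phylogenetic correlation between abundance and function, sparse flux
tables (every species produces a little under a Dirichlet), uptake, or
measurement error in the abundances themselves. A green simulation test
therefore establishes the *bias structure* of the estimators under random
information loss, not their behaviour on real metagenomes.

Scale: the package default is 1000 iterations (the stated world); the
acceptance test runs 200 iterations under a fixed seed to stay inside the
test-time budget, which is ample for the three qualitative assertions
(sign of the reference bias, |mean| < 2·SE for the other two, α=1 spread
exceeding α=5).

## Numerical choices

* KL sums run only over strictly positive `p`-entries (`0·log 0 = 0`);
  a positive `p` against a zero `q` raises a typed
  `entred_support_violation` condition rather than returning `Inf`.
* Shares below `zero_tol` are clipped and the producer-restricted vector
  re-closed before the `I` divergence, so a 1e-15 share cannot dominate a
  divergence through its log.
* Dirichlet draws use normalised `rgamma` variates — the textbook
  construction — under R's global RNG, so a single `set.seed()` makes
  every run byte-reproducible.
* Probability-vector validation tolerates |Σp − 1| ≤ 1e-6 on input and
  renormalises community abundances exactly; preprocessing is idempotent.

## Known limitations

* All measures are built on *relative* abundances and shares; absolute
  variants are out of scope.
* `I` conflates all sources of share/abundance decoupling (cross-feeding,
  condition-specific regulation, model artefacts) into one number.
* The affine case `fᵢ = b·aᵢ + d` with `d ≠ 0` does not give an exact
  zero of the abundance measure (KL is zero only under proportionality or
  uniform abundances); the implementation follows the divergence
  literally and documents the zero condition for the proportional case.
* `γ`, the theoretical functional maximum, is carried on profiles but
  used by nothing; it is retained for schema completeness only.
* The toy fixture's numeric abundances and fluxes are this package's own
  choices; only its geometry (5 sample species, 4 producers, `m = 7`) is
  canonical.
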