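---
title: "Energy landscapes of microbial assemblage dynamics: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy landscapes of microbial assemblage dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mela)
```

## The modelling chain

`mela` turns longitudinal genus-level 16S profiles into a statement about
community stability in three model layers. Each layer has assumptions worth
making explicit before trusting the output.

### 1. Assemblages via latent Dirichlet allocation

The genus table is modelled generatively: every read in sample $n$ picks a
latent *assemblage* $i$ from the sample mixture $\theta_n \sim
\mathrm{Dirichlet}(\beta)$ and then a genus from the assemblage composition
$\phi_i \sim \mathrm{Dirichlet}(\alpha)$. Assemblages are therefore groups of
genera that *co-occur across samples*, not phylogenetic or functional guilds;
any functional reading must come from their dominant genera
(`dominant_genera`, `shared_genus_network`).

Assumptions inherited from LDA: reads are exchangeable within a sample (no
read-level structure), the number of assemblages $I$ is fixed a priori, and
sample mixtures are independent given the priors — time ordering is *not*
modelled at this layer. $I = 9$ is the package default, chosen for the same
reason the approach generally uses a small $I$: $2^I$ pattern enumeration
downstream and interpretability. There is no automatic selection of $I$.

Fitting is batch variational Bayes (the same algorithm family as
scikit-learn's `LatentDirichletAllocation`, which is the reference
implementation for this kind of analysis; no LDA implementation is available
in the R dependency stack, so the package carries its own). The variational
objective is intractable to state exactly in closed form at the point
estimates we track, so `fit_diagnostics$objective_trace` records the data
log-likelihood under the current point estimates $\hat\theta\hat\phi$; the
stopping rule is a relative change below `tol` (default `1e-6`, `max_iter`
200 sweeps). Two practical consequences:

* **Determinism.** The topic initialisation is seeded (`seed`), so identical
  inputs and seed give bit-identical $\phi$. Across *different* seeds the
  optimum is the same in well-separated problems but labels permute;
  assemblages are therefore re-ordered by descending top-genus weight after
  fitting, which stabilises labels for reporting but is cosmetic, not an
  identifiability fix.
* **Equivariance is statistical.** Permuting genus columns permutes the
  fitted $\phi$ only up to the (seeded, position-tied) initialisation; tests
  check agreement to ~0.01, not bit-exactness.

Priors default to symmetric $\alpha = \beta = 1/I$ (the common default of the
reference implementation); neither value is dictated by the method and both
are exposed. LDA needs counts: relative-abundance tables must pass through
`to_counts(depth = 10000)`, which rescales rows and repairs rounding by
largest remainder so row totals are exact.

The model is fitted on **one sample per participant** (`first_samples`) and
then applied with $\phi$ frozen (`infer_abundances`) to all retained samples.
Freezing avoids letting the heavily autocorrelated within-participant series
dominate the assemblage definitions; the transform-with-fixed-$\phi$ route is
implemented rather than a joint refit.

### 2. Occurrence states

Within one class, assemblage $i$ is activated in sample $n$ ($\sigma_i^n =
+1$) iff $\theta_{ni}$ strictly exceeds the upper 25th percentile of
$\{\theta_i\}$ over the class' samples. The percentile is implemented as the
order statistic of rank $\lceil 0.75N \rceil$ with **no interpolation**, so
for distinct values exactly $\lfloor N/4 \rfloor$ samples activate — with the
design's $N = 260$ per class, exactly 65 (25%). Ties at the threshold fall to
$-1$ (strict inequality); a fully constant column therefore activates
nothing. Because the rule is rank-based it is invariant under any strictly
increasing transform of a column. Thresholds are computed within one class
only; pooling across classes would let class composition leak into the
binarization.

The 25% cut is a declared operating point, not an estimate: it guarantees
every assemblage is "rare but present" in activated form, which keeps the
empirical moments away from the $\pm 1$ boundary where the next layer's
maximum-likelihood problem diverges.

### 3. Pairwise maximum-entropy model and its landscape

Per class, the distribution over $\pm 1$ patterns with maximal entropy
subject to matching $\langle\sigma_i\rangle$ and
$\langle\sigma_i\sigma_j\rangle$ is the Ising form with fields $h$ and
symmetric zero-diagonal couplings $g$ ($kT \equiv 1$; temperature is absorbed
into the parameters). Fitting is maximum likelihood by moment-matching
ascent from $h = 0, g = 0$, with model moments computed **exactly** by
enumerating all $2^I$ patterns — no sampling, no pseudolikelihood. The
likelihood is concave, so the fitted point is the unique MLE whenever the
empirical moments lie in the interior of the realisable set; with 260
samples this can fail only if some assemblage or pair is perfectly locked,
which the quartile rule prevents for singles and makes rare for pairs
(non-convergence is reported, never hidden).

**Step-size control.** The plain fixed-$\varepsilon$ iteration (default
$\varepsilon = 0.1$) converges but can be very slow on ill-conditioned
moment sets: on this package's own 260-sample, $I = 9$ fixtures it needs
roughly 250k iterations to push the largest moment gap below the `1e-5`
tolerance. `fit_maxent(adapt = TRUE)` (the default) keeps the update
*direction* — exactly the empirical-minus-model moment gap — but halves the
step whenever it would decrease the likelihood and lets it regrow (× 1.1,
capped at $100\varepsilon$) afterwards. Because a step is only accepted when
the likelihood does not decrease, the monotone log-likelihood trace holds by
construction; `adapt = FALSE` recovers the textbook fixed-step update. The
trace itself is computed through the exponential-family identity
$\frac{1}{N}\sum_n \log P(\sigma^n) = h\cdot\langle\sigma\rangle_{emp} +
\sum_{i<j} g_{ij}\langle\sigma_i\sigma_j\rangle_{emp} - \log Z$, so it is the
exact data log-likelihood at every iteration.

The landscape assigns every pattern its energy and a steepest-descent link to
its minimal single-flip neighbour when that neighbour is *strictly* lower.
Patterns with no strictly lower neighbour are local minimal patterns; on an
exactly flat plateau every pattern is its own minimum (the strict rule
guarantees descent paths terminate). Ties among equally minimal lower
neighbours resolve to the lowest pattern id, making the whole construction
deterministic. A pattern of length $I$ has $I$ single-flip neighbours — at
$I = 9$, nine of them. Pattern ids follow
$\mathrm{id} = 1 + \sum_{i:\sigma_i=+1} 2^{i-1}$, which reproduces the
field's P-# labels (P-#33 $\leftrightarrow$ assemblage #6 only;
P-#137 $\leftrightarrow$ assemblages #4 and #8). Landscapes are invariant
under adding a constant to all energies, so only energy *differences* are
interpretable. Enumeration is guarded at $I \le 20$; the method is
exact-by-enumeration by design and is not meant for large $I$.

## The synthetic cohort: what it emulates, what it does not

`simulate_cohort` generates cohorts with the package's default design
arithmetic for an IBD time-series cohort:
by default 65 CD + 38 UC + 27 non-IBD participants with a full series of 10
visits (130 participants / 1300 samples surviving the first-10 filter; 26
participants per class × 10 visits = 780 samples entering the per-class
fits), plus 20 short participants (deterministic cycle of 1–9 visits) so the
filter is exercised. Per sample, genus counts are Dirichlet-multinomial:
participant-level mixture $m \sim \mathrm{Dirichlet}(0.5)$ — the low
concentration produces the strong assemblage-abundance imbalance seen in
real data — per-visit $\theta \sim \mathrm{Dirichlet}(50\,m)$, giving
within-participant correlation with visit-to-visit wobble (the 50 is a
realism choice, stated once here), and reads drawn assemblage-then-genus
from a planted block-structured $\phi^*$ (`planted_phi`: 90% of each
assemblage's mass on its own genus block, geometrically decaying).

What it does **not** emulate: phylogenetic correlation between genera,
sequencing noise beyond multinomial sampling, compositional artefacts of
real pipelines, class-specific community differences (all classes share
$\phi^*$ and priors by default), or any true underlying attractor dynamics.
A green end-to-end test therefore establishes that the machinery — filters,
fits, binarization, landscape — is correct and deterministic, *not* that the
method recovers true ecological attractors; parameter-recovery claims are
tested separately against the exact Boltzmann sampler
(`sample_boltzmann_patterns`), where ground truth exists.

## Numerical and design choices

* `balanced_subset` draws participants by seeded uniform sampling without
  replacement — there is no canonical rule for *which* 26 participants per
  class enter the per-class fits, so the package makes the draw explicit and
  reproducible through the recorded seed.
* "First ten successive" samples are the ten smallest visit indices; calendar
  gaps are ignored (no date rule is defined).
* The class label set defaults to CD/UC/nonIBD and is configurable.
* Kruskal–Wallis class comparison reports raw p-values (no multiplicity
  correction, matching the practice it mirrors); a fully tied column returns
  statistic 0, p = 1 rather than NaN.
* `to_counts` rounds half-to-even then repairs totals by largest remainder,
  so `(1/3, 2/3)` at depth 10 becomes `(3, 7)`.
* Energy TSVs print energies with `%.17g`, so re-reading reproduces the
  doubles bit-exactly; GraphML omits self-loops and flags LMPs by attribute.
* Defaults: $\varepsilon = 0.1$, moment-gap tolerance `1e-5`, `max_iter`
  50000 in `fit_maxent` (200000 in `run_config`, where the slow-converging
  real-shaped fixtures live).

## Known limitations

* LDA assemblages ignore time order; the landscape adds a dynamical reading
  (descent = plausible transition) that the fitted model itself does not
  license — it is a stationary distribution, not a kinetic model. Barrier
  heights, transition rates and disconnectivity graphs are out of scope.
* The number of LMPs is sensitive to sampling noise in the moments at
  $N = 260$; small basins (a handful of patterns) should be read with
  caution.
* Binarization discards within-quartile abundance variation by design.
* Exact enumeration caps $I$ at 20 in principle and ~15 in practice.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_cohort(cohort_spec(depth = 2000, seed = 5))
cfg <- run_config(out_dir = tempfile(), depth = 2000)
res <- run_pipeline(cfg, counts_table = sim$table,
                    metadata_table = sim$metadata)
landscape_summary(res$landscapes$CD)
plot(res$landscapes$CD)
```
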