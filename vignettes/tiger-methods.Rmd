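---
title: "Sign-constrained Bayesian matrix factorization for TF activity inference"
author: "tiger package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sign-constrained Bayesian matrix factorization for TF activity inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiger)
```

## The model

Transcription factor (TF) activity is latent: a TF's mRNA level is a poor
surrogate for how strongly it is driving its targets. `tiger` treats each
sample's expression profile as a noisy linear readout of hidden TF
activities routed through a signed regulatory network,

$$X_n = W Z_n + \epsilon, \qquad \epsilon \sim N(0, \sigma_\epsilon^2 I),$$

where $X$ is the $g \times n$ gene-wise z-scored expression matrix, $W$ is
the $g \times h$ weighted adjacency matrix of the TF→gene network and
$Z_n \ge 0$ is the vector of TF activities in sample $n$. The priors are

* **Edge weights.** $W_{ij} \sim N(0, \alpha_{ij})$ with
  $\alpha_{ij} \sim IG(a_\alpha, b_\alpha)$, but only where the curated
  prior network $W^0$ has an edge; $W_{ij} = 0$ wherever $W^0_{ij} = 0$.
  The Gaussian–inverse-gamma pair gives per-edge adaptive shrinkage: edges
  the data do not support collapse toward zero, which is what lets the
  posterior network be context specific. The model can only re-weight and
  re-sign edges present in the prior; it cannot invent new ones.
* **Activities.** $Z_n \sim MVN^+(0, \sigma_Z^2 I)$, a half-normal. The
  non-negativity is not cosmetic: together with the signed prior it breaks
  the $W \to -W$, $Z \to -Z$ symmetry of any bilinear factorization and
  fixes the meaning of an edge sign (activation increases a target when the
  TF is active).
* **Noise.** $\sigma_\epsilon^2 \sim IG(a_\sigma, b_\sigma)$.

Defaults are $a_\alpha = b_\alpha = a_\sigma = b_\sigma = 1$ and
$\sigma_Z^2 = 100$ (`tigerHyper()`), weakly informative on the z-score
scale of the input.

## Vetting prior edge signs

Curated edge signs are often wrong in a new biological context. Before
fitting, each prior edge is compared against the *shrinkage partial
correlation* between the TF's own expression and the target's expression
(`shrinkagePartialCorrelation`): the correlation matrix across genes is
shrunk toward the identity with the analytic Schäfer–Strimmer intensity
$\lambda^\ast$ and partial correlations are read off its inverse, which
stays well defined when genes outnumber samples.

`assignConstraints` then gives each edge one of four prior families:

| prior sign | partial correlation | family |
|---|---|---|
| 0 | any | `ZERO` (weight fixed at 0) |
| ±1 | same sign, $|\rho| >$ threshold | `POS/NEG_HALF_NORMAL` (hard) |
| ±1 | opposite sign | `FREE_NORMAL` (sign learned) |
| ±1 | zero, below threshold, or TF unmeasured | `FREE_NORMAL` |

A hard half-normal constraint pins the sign of a well-supported edge; a
disagreeing or unsupported edge keeps a full normal so the data decide its
final sign. The evidence threshold defaults to 0 — any nonzero agreement
counts, with an exactly-zero partial correlation breaking ties toward the
less constrained family. The conditioning set is all genes of the aligned
matrix, capped to the union of prior-network genes above 2000 genes for
tractability; the choice of conditioning set is a package decision, since
reasonable alternatives (per-pair conditioning) exist.

Note an asymmetry worth knowing about: flipping every prior sign does not
swap the two half-normal families — it turns agreement into disagreement,
so previously hard edges become free and previously disagreeing edges
become hard with the family matching the data's sign. The constraint step
is what makes the model robust to sign-corrupted priors.

## Inference

All constrained quantities (half-normal weight magnitudes, activities,
variances) are log-transformed to the real line; free-sign weights keep the
identity transform. On that space:

* **VI (default).** A fully factorized Gaussian variational family is
  optimized by stochastic gradient ascent on the ELBO with reparameterized
  single-draw gradients and Adam updates (learning rate 0.01). The
  single-sample ELBO estimate is noisy, so convergence is judged on an
  exponentially smoothed trace (smoothing constant 0.002, recorded every
  100 steps): the fit stops when the relative change stays below
  `elbo_tol` ($10^{-4}$) for 10 consecutive checks, or at `max_iter`
  (50,000) steps. Posterior means and standard deviations are recovered on
  the constrained scale by Monte-Carlo averaging of at least 200 draws from
  the fitted variational distribution, so half-normal edges have posterior
  means of the constrained sign by construction.
* **MCMC.** A Hamiltonian Monte Carlo sampler (20 leapfrog steps,
  dual-averaged step size targeting 0.8 acceptance, diagonal mass adapted
  during warmup) targets the *same* transformed posterior. Mean-field VI is
  fast but underestimates posterior spread; HMC is the reference on small
  instances, and the test suite requires the two estimators' posterior mean
  networks to correlate at 0.95 or better there.

**Initialization.** Optimization is seeded deterministically: constrained
weight magnitudes start at 0.1, free weights at 0, variational standard
deviations at 0.1, and activities at a per-sample non-negative least
squares solve. The NNLS design matrix is the *evidence-informed* sign
matrix — the half-normal constraint sign where one was assigned, otherwise
the sign of the partial correlation, otherwise the prior sign. Using the
raw prior signs instead is tempting but fragile: when most prior signs are
wrong, a bilinear model started from the wrong orientation can settle into
a sign-inverted mode (mean-field VI is mode-seeking and will not escape
it). The evidence-informed start uses only quantities the constraint step
already computed and keeps the starting basin aligned with the data.
Seeded jitter (sd 0.01) breaks residual ties; every source of randomness
flows from `tigerControl(seed=)`, so a fit is exactly reproducible.

**Identifiability and scale.** The likelihood only constrains the product
$W Z$, so the scale split between weights and activities is fixed by
convention: $\sigma_Z^2$ is held at its prior value and the canonical
network output is the L1-normalized regulon, $\sum_j |W_{ij}| = 1$ per TF
(`normalizeRegulons`) — the same normalization under which regulon quality
scores are defined. The reconstruction $W Z$ is invariant under that
renormalization applied jointly to $W$ and $Z$. $\Sigma_Z$ is diagonal by
design; correlated-activity extensions are out of scope.

**Degenerate inputs.** There is no minimum regulon size; a TF whose edges
are all free with zero partial correlations still fits. A diverging ELBO
(final below initial) raises an error suggesting a smaller learning rate
rather than returning a silently bad fit.

## Reading the output

Raw activities are non-negative and their scale is entangled with each
TF's regulon scale, so they are not comparable across TFs.
`standardizeTFA` z-scores each TF across samples first, and `rankTFA`
ranks within samples with average ranks on ties. The ranking direction is
a flag because the two use cases differ: knockout evaluation puts the
*lowest* activity at rank 1 (a knocked-out TF should be least active),
tissue characterization puts the *highest* first. Gene-level regulation is
summarized by the in-degree, the sum of absolute incoming edge weights
(`geneInDegree`).

Evaluation statistics: `regulonQS` (L1-normalized inner product of
absolute weights with external evidence rank percentiles, so uniform prior
weights score the evidence mean), `rbo` (extrapolated rank-biased overlap;
persistence defaults to 0.98, a strong top-weighting appropriate when the
question is whether driver TFs surface at the top — the value is exposed
because no canonical choice exists), `edgeSignAccuracy` (an estimated sign
of exactly zero counts as incorrect, a conservative convention), and
`knockoutMetrics` (success = rank ≤ 10). `baselineSignedMean` provides a
deliberately simple sign-aware regulon-mean comparator for simulations; it
is not a reimplementation of any published enrichment method.

## What the simulator emulates — and what it does not

`syntheticScenario`/`generateTruth` run the generative equations forward:
sparse signed $W$ (per-TF targets drawn with probability `density`,
half-normal magnitudes, signs by `pos_fraction`), half-normal activities,
Gaussian noise, then gene-wise z-scoring. Two design points matter:

* **TF expression proxies.** The constraint step needs the TF's own
  expression. Each TF's encoding gene carries a structural self-edge of
  weight `tf_self_weight` (default 1), so TF expression is a noisy copy of
  the TF's activity *through the generative equation itself* — at zero
  noise, $X = WZ$ holds exactly. Self-edges are excluded from the prior,
  the gold-standard signs and the corruption machinery.
* **Prior corruption.** `corruptPrior` flips exactly
  `round(flip_frac * E)` signs, deletes `round(fn_frac * E)` distinct
  further edges and adds `round(fp_frac * E)` spurious edges with random
  signs — exact counts keep tests deterministic, and a 30% flip gives a
  prior sign accuracy of 0.70 by construction.

Scenario defaults (g = 200, h = 20, n = 60, density 0.1, unit weight and
activity scales, noise sd 0.2) are sized like a small curated-regulon
study: regulons of ~20 targets, three samples per TF, noise at a fifth of
the signal scale. The test suite and the acceptance script use these
conditions, plus a g = 300, h = 50 knockout panel and a g = 12, h = 3
instance where HMC is cheap enough to serve as the VI reference.

The simulator deliberately does **not** emulate single-cell dropout or
count sparsity, TF–TF interactions, nonlinear (saturating) regulation, or
correlated activities — all listed as future extensions of the model
family. Passing tests therefore show that the estimator recovers the
model's own generative process under realistic corruption, not that it is
robust to every failure mode of real expression data; the evaluation
statistics are the tools for checking behaviour on real inputs.

## Known limitations

* The posterior support is the prior's support: missing true edges cannot
  be recovered (add candidate edges to the prior if recall matters).
* Mean-field VI underestimates uncertainty; `W_sd`/`Z_sd` from a VI fit
  are optimistic. Use `method = "MCMC"` when calibrated uncertainty on a
  small problem is needed.
* Partial-correlation vetting needs the TF's gene measured in the
  expression matrix; otherwise all of its edges stay free, which weakens
  (but does not break) sign correction for that TF.
* Very small regulons carry little information and their activities are
  dominated by the prior.
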