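---
title: "Energy rank alignment for simulated directed evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy rank alignment for simulated directed evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erade)
library(dplyr)
```

## The problem

Directed evolution (DE) optimizes a protein by iterating rounds of
mutagenesis and selection against an experimental fitness readout. When a
small set of residue positions is chosen for combinatorial mutation, the
search space is $|A|^n$ variants ($A$ the residue alphabet, $n$ the mutated
positions) but each round assays only on the order of $N \approx 100$
variants. `erade` simulates a campaign design in which a generative sequence
policy proposes each round's batch and is *aligned* to the accumulating
fitness observations between rounds, so that probability mass moves toward
high-fitness variants while retaining enough entropy to keep exploring.

In the setting this package targets, the policy in production would be a
large protein language model sampled by masking the mutated positions and
unmasking them simultaneously, which makes the drawn residues conditionally
independent given the fixed sequence context. The campaign algorithm,
however, interacts with the policy only through four capabilities:
log-likelihoods, constrained sampling, a frozen reference snapshot, and a
gradient step. `erade` therefore provides two tabular policies exposing
exactly that contract:

* a **factorized policy** — one categorical distribution per mutated
  position; the variant pseudo-likelihood is the product of per-position
  probabilities, mirroring the simultaneous-unmasking scheme;
* a **joint policy** — an explicit log-probability table over an enumerated
  variant space, needed because the alignment optimum is in general not
  factorized.

An adapter wrapping a real language model in the same four functions would
drop into the campaign loop unchanged.

## The alignment objective

Assayed variants are scored on the unit interval: raw fitness is divided by
the landscape maximum (so the best variant scores exactly 1) and each
variant's *energy* is $U(y) = -\log f_y$ in nats. All $\binom{N}{2}$ pairs of
assayed variants become preference pairs. The policy's preference probability
for a pair $(y, y')$ is

$$p_\theta(y \succ y') = \sigma\!\left(\log \pi_\theta(y) - \log
\pi_\theta(y')\right),$$

and it is trained to match an entropy-regularized Gibbs–Boltzmann target

$$p_\gamma(y \succ y') = \sigma\!\left(\tfrac{\beta}{1+\gamma}\left(U(y') -
U(y)\right) + c_\gamma \left(\log \pi_{\mathrm{ref}}(y) - \log
\pi_{\mathrm{ref}}(y')\right)\right)$$

by minimizing the mean Bernoulli KL divergence
$D(p_\gamma \,\|\, p_\theta)$ over pairs. $\beta$ (inverse temperature)
controls how sharply the target concentrates on low-energy variants;
$\gamma$ regularizes toward the frozen reference policy
$\pi_{\mathrm{ref}}$.

With $c_\gamma = \gamma/(1+\gamma)$ (the package default,
`logratio_coefficient_mode = "self_consistent"`), the objective has an exact
closed-form minimizer over an enumerable variant space:

$$\pi^*(y) \propto \pi_{\mathrm{ref}}(y)^{\gamma/(1+\gamma)}
\exp\!\left(-\tfrac{\beta}{1+\gamma} U(y)\right) =
\pi_{\mathrm{ref}}(y)^{\gamma/(1+\gamma)} f_y^{\beta/(1+\gamma)}.$$

Substituting $\pi^*$ into $p_\theta$ reproduces $p_\gamma$ identically —
this fixed point is the package's strongest self-check and is verified to
$10^{-9}$ in the tests. An alternative coefficient $c_\gamma = \gamma/\beta$
is retained behind `logratio_coefficient_mode = "as_printed"`; it changes
only the exponent on $\pi_{\mathrm{ref}}$ in the corresponding optimum. The
two modes coincide exactly when $\beta = 1 + \gamma$ and differ otherwise;
the self-consistent mode is the one under which the Gibbs–Boltzmann form
above is stationary for every $(\beta, \gamma)$, which is why it is the
default.

Limits worth knowing: $\gamma = 0$ gives the pure Boltzmann distribution
$e^{-\beta U}/Z$ on scaled fitness; $\gamma \to \infty$ pins the policy to
the reference; $\beta \to \infty$ at $\gamma = 0$ concentrates on the global
optimum. Increasing $\beta$ at fixed $\gamma$ never decreases the expected
scaled fitness under $\pi^*$.

A rank-only **DPO baseline** is included: it uses the same pairs but only
their ordering,
$-\log \sigma(\beta_{\mathrm{dpo}} [\Delta_\theta(w) - \Delta_\theta(l)])$
with $\Delta_\theta = \log \pi_\theta - \log \pi_{\mathrm{ref}}$ and $w$ the
fitter variant. Energy ties carry no rank signal and are skipped (counted in
the fit object).

## The trainer

Both tabular policies are parameterized by logits whose pairwise
log-likelihood differences are *linear* in the parameters (the softmax
normalizers cancel), so the ERA and DPO losses are convex and plain
full-batch gradient descent suffices; optional minibatching reshuffles pairs
each epoch under the configured seed. Defaults are $\beta = 1$,
$\gamma = 0.1$, learning rate $0.1$, 25 epochs. On desk-scale problems the
tabular loss keeps decreasing well past those defaults; where an experiment
needs a converged policy (e.g. the campaign study below) we use learning
rate 1 and 200 epochs, by which the loss trace is flat to ~$10^{-3}$
relative change. Training aborts with a diagnostic on a non-finite loss.

Degenerate inputs: a pair set needs at least one (non-tied, for DPO) pair;
training with 0 epochs is an explicit no-op so a campaign can be run
"untrained" as a control; the closed-form optimum requires a complete,
enumerable landscape (cap $10^6$ variants).

## The campaign loop

`run_campaign()` executes, per replicate:

1. sample `round_size` *previously unseen* variants from the current policy
   (round 1 uses the untrained reference), look up their fitness in the
   landscape table — the simulated assay;
2. rebuild the exhaustive preference-pair set over **all** variants assayed
   so far, with energies from benchmark scaling and log-ratios from the
   reference snapshot taken before any training (re-anchoring each round is
   available behind `reanchor_reference`, but the default keeps the original
   anchor because the target distribution is defined against it);
3. train the policy on those pairs and recompute every assayed variant's
   log-likelihood under the updated policy;
4. after the last training round, optionally sample one final batch from the
   aligned policy without training (stochastic sampling with exclusion, not
   a greedy argmax — the final batch is a draw from the aligned
   distribution).

Defaults mirror the standard benchmark protocol: 4 training rounds of 96
plus a final 96, i.e. 480 evaluations; 96 variants yield 4,560 pairs.
Replicate and round seeds are derived deterministically from the master
seed and logged in the result, so a campaign is byte-reproducible. If the
admissible pool runs out, the replicate stops early and is flagged rather
than erroring. Two benchmark metrics summarize a result: the mean (± SE)
over replicates of the best scaled fitness found, and the fraction of
replicates whose assayed set contains the global optimum.

Sampling uniqueness uses rejection sampling with a proposal budget of
$1000\,n$ for variant spaces too large to enumerate — the code path an
un-enumerable model adapter needs — but below the enumeration cap the
admissible set is enumerated and sampled exactly, which keeps edge cases
("every variant but one excluded") exact rather than probabilistic.

## The synthetic landscapes

No external dataset is required: `generate_synthetic_landscape()` builds
complete landscapes from a latent score with independent Gaussian additive
effects (per position), pairwise couplings (the ruggedness dial), optional
three-way interactions, and measurement noise, mapped to non-negative
fitness through one of three links. The exponential link
$e^{s - \max s}$ (default) makes the *energy* additive in the latent
effects; the linear link (affine onto $[0.1, 1]$) makes the *fitness* itself
additive and is the one under which the additive limit shows exactly zero
roughness, zero epistatic squares, a single local optimum, and full optimum
accessibility. The logistic link gives saturating activities. Under the
exponential link an additive score produces multiplicative fitness effects:
squares can show magnitude epistasis but never a sign flip, which the tests
assert.

What these landscapes emulate: tunable ruggedness and epistasis over a
residue alphabet with a known global optimum, at sizes where every
brute-force oracle (path enumeration, exhaustive square classification,
full distribution enumeration) runs in seconds. What they do not emulate:
the correlated, structure-driven effect patterns of real proteins, assay
noise heteroscedasticity, or a realistic prior — so passing campaign tests
here demonstrates the machinery and its statistical behavior, not expected
wet-lab performance. Planted-optimum landscapes
(`make_planted_optimum_landscape()`) and biased reference policies
(`make_biased_reference_policy()`, interpolating uniform to near point
mass) complete the fixture set.

## Landscape diagnostics

The analysis module reimplements standard fitness-landscape statistics over
the complete variant graph (Hamming-1 edges), all on scaled fitness:

* **local optima ratio** — fraction of variants with no strictly fitter
  single-mutation neighbor (non-strict, so plateaus count as optima);
* **roughness-slope ratio** — RMS residual of the best additive one-hot
  least-squares fit divided by the mean absolute fitted effect; 0 for
  additive landscapes, undefined (error) for flat ones;
* **neutrality index** — fraction of neighbor pairs within `delta`
  (default $10^{-3}$ scaled-fitness units) of each other;
* **global optimum accessibility** — fraction of non-optimal variants with
  a strictly increasing mutational path to the optimum set, computed by
  reverse traversal from the optimum and verified against forward path
  enumeration;
* **epistasis classification** — every background × position-pair ×
  substitution-pair square classified as additive / magnitude / sign /
  reciprocal-sign from the interaction gap and the two effect-sign
  comparisons, with a gap tolerance (default $10^{-9}$). A marginal effect
  within tolerance of zero is treated as sign-consistent with either sign,
  so ties do not generate spurious sign-epistasis calls.

These operational definitions follow the standard literature; published
values computed with other toolchains need not be bit-identical because
neutrality tolerances and path conventions vary.

## Policy diagnostics

`distribution_summary()` reports entropy, KL to uniform (in nats — the two
always sum to $\ln M$, an identity the tests check for arbitrary policies),
top-$k$ coverage, and redundancy (duplicate fraction in a seeded batch of
1000 samples drawn with repeats — the policy's natural collision rate).
`loglik_fitness_correlation()` gives the Pearson correlation of
log-likelihood with raw activity over the enumerated landscape;
`probability_mass_fold_change()` the post/pre ratio of mass above activity
thresholds (`NA` where the before-mass is zero);
`weighted_position_frequency_matrix()` the likelihood-weighted MSA over the
mutant space; `residue_count_change()` the percent change in per-position
residue counts between sampled batches, flagging newly appeared residues.

## A worked example

A small end-to-end run: a rugged 3-position × 8-letter landscape (512
variants), a moderately mode-seeking prior, and ten 64-sample campaigns
(4 × 16) against ten matched-budget uniform-random baselines.

```{r campaign}
l <- scale_landscape(generate_synthetic_landscape(synthetic_spec(
  n_positions = 3, alphabet_size = 8, additive_scale = 1,
  pairwise_scale = 1, seed = 42)))
prior <- make_biased_reference_policy(l, bias = 0.25, seed = 7)

cfg <- campaign_config(round_size = 16, n_training_rounds = 3,
                       era = era_config(epochs = 200, learning_rate = 1),
                       seed = 5)
res <- run_campaign(l, cfg, n_replicates = 10, initial_policy = prior)
average_maximum_fitness(res)
fraction_reaching_optimum(res, l)
```

```{r baseline}
rand_best <- vapply(1:10, function(r) {
  draws <- sample_variants(uniform_policy(l), 64, seed = 1000 + r)
  max(l$tbl$scaled[match(draws, l$tbl$combo)])
}, numeric(1))
mean(rand_best)
```

```{r correlation}
before <- loglik_fitness_correlation(prior, l)
after <- vapply(res$policies, loglik_fitness_correlation, numeric(1), l = l)
c(before = before, improved = sum(after > before))
```

```{r plots, fig.width = 6, fig.height = 3.5}
autoplot(res)
autoplot(weighted_position_frequency_matrix(res$policies[[1]], l))
```

The prior's bias of 0.25 and the 64-of-512 budget were fixed as the study
condition for this vignette and the test suite: the budget is an eighth of
the landscape so the comparison against uniform sampling is informative,
and the biased prior stands in for an informative but
activity-uncorrelated generative prior (a uniform prior would make the
"before" correlation undefined).

## Numerical choices and limitations

* **Fitness floor.** $U = -\log f$ is undefined for dead variants; scaled
  fitness is floored at $\varepsilon = 10^{-6}$ (configurable), giving
  zero-activity sequences a finite energy of $6 \ln 10 \approx 13.8$ nats.
* **Scaling reference.** Benchmark mode divides by the full-landscape
  maximum (appropriate when a combinatorially complete dataset is the
  simulated assay); `reference_max` switches to an online convention for
  campaigns where the global maximum is unknown.
* **Pair orientation.** Pairs are stored fitter-variant-first; all losses
  are orientation-invariant, so this is purely cosmetic.
* **Tie handling.** DPO skips energy-tied pairs (logged count) rather than
  randomizing them; the epistasis classifier treats zero effects as
  sign-neutral.
* **Problem sizes.** Tests and the acceptance script use landscapes of
  9–8,000 variants, pair sets up to $\binom{480}{2}$, and 10-replicate
  campaigns; every oracle comparison (path enumeration, exhaustive squares,
  Monte-Carlo frequency checks) is exact or seeded.
* **Out of scope.** Fine-tuning an actual language model (the policies here
  are tabular stand-ins satisfying the same contract), structure or
  stability conditioning, insertion/deletion moves, non-canonical residues,
  and imputation of incomplete landscapes.
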