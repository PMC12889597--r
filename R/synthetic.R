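# Synthetic combinatorial landscapes with tunable epistasis, plus the small
# planted-optimum landscapes and biased reference policies used as fixtures.
# These emulate the rugged multi-site experimental landscapes a campaign
# navigates: additive per-position effects, pairwise couplings (the source of
# sign and reciprocal-sign epistasis), an optional higher-order interaction
# term, and measurement noise, mapped to non-negative fitness.

#' Specification for a synthetic combinatorial landscape
#'
#' The latent additive/epistatic score of a variant is
#' \deqn{s(v) = \sum_i a_i(v_i) + \sum_{i<j} J_{ij}(v_i, v_j) +
#'   \sum_{i<j<k} T_{ijk}(v_i, v_j, v_k) + \epsilon_v,}
#' with independent Gaussian effect tables \eqn{a_i \sim N(0,
#' \mathrm{additive\_scale}^2)}, couplings \eqn{J_{ij} \sim N(0,
#' \mathrm{pairwise\_scale}^2)}, three-way interactions \eqn{T_{ijk} \sim N(0,
#' \mathrm{higher\_order\_scale}^2)}, and noise \eqn{\epsilon_v \sim N(0,
#' \mathrm{noise\_sd}^2)}. Fitness is `exp(s - max(s))` (default link, so the
#' maximum raw fitness is exactly 1), `plogis(s)` (logistic link), or an
#' affine map of `s` onto `[0.1, 1]` (linear link). Only the linear link
#' preserves additivity of the latent score on the fitness scale itself: a
#' zero-coupling, zero-noise spec is then purely additive (zero roughness, no
#' epistatic squares), whereas under the exponential link the per-position
#' effects act multiplicatively on fitness, giving magnitude -- but never
#' sign -- epistasis.
#'
#' @param n_positions Number of mutated positions (>= 2).
#' @param alphabet_size Residues per position (2--20; the first
#'   `alphabet_size` canonical amino acids are used).
#' @param additive_scale,pairwise_scale,higher_order_scale Non-negative
#'   standard deviations of the effect tables. `pairwise_scale` plays the role
#'   of the coupling strength that tunes ruggedness.
#' @param noise_sd Non-negative measurement-noise standard deviation.
#' @param seed Integer seed; the same spec and seed always regenerate an
#'   identical landscape.
#' @param link `"exponential"`, `"logistic"`, or `"linear"` map from latent
#'   score to non-negative fitness.
#'
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_positions = 3, alphabet_size = 8,
                           additive_scale = 1, pairwise_scale = 0,
                           higher_order_scale = 0, noise_sd = 0,
                           seed = 1,
                           link = c("exponential", "logistic", "linear")) {
  link <- match.arg(link)
  if (n_positions < 2) abort("`n_positions` must be >= 2")
  if (alphabet_size < 2 || alphabet_size > 20) {
    abort("`alphabet_size` must be between 2 and 20")
  }
  for (nm in c("additive_scale", "pairwise_scale", "higher_order_scale",
               "noise_sd")) {
    stopifnot_scalar_number(get(nm), nm, min = 0)
  }
  structure(
    list(n_positions = as.integer(n_positions),
         alphabet_size = as.integer(alphabet_size),
         additive_scale = additive_scale, pairwise_scale = pairwise_scale,
         higher_order_scale = higher_order_scale, noise_sd = noise_sd,
         seed = as.integer(seed), link = link),
    class = "synthetic_spec"
  )
}

#' Generate a complete synthetic fitness landscape
#'
#' Enumerates all `alphabet_size^n_positions` variants and computes their
#' fitness from the latent score model described in [synthetic_spec()]. With
#' `pairwise_scale = 0`, `higher_order_scale = 0`, `noise_sd = 0`, and the
#' linear link the landscape is purely additive: it has a single peak, zero
#' roughness, and no epistatic squares.
#'
#' @param spec A [synthetic_spec()].
#' @param max_size Safety cap on the number of variants (default `1e6`).
#' @return A [fitness_landscape()] whose parent sequence is a poly-alanine
#'   stand-in of length `n_positions` with positions `1..n_positions` mutated.
#' @export
generate_synthetic_landscape <- function(spec, max_size = 1e6) {
  stopifnot(inherits(spec, "synthetic_spec"))
  a <- spec$alphabet_size
  p <- spec$n_positions
  m <- a^p
  if (m > max_size) {
    abort(sprintf("landscape size %g exceeds the cap of %g variants",
                  m, max_size))
  }
  alphabet <- aa_alphabet()[seq_len(a)]
  combos <- enumerate_combos(alphabet, p)
  ri <- match(residue_matrix(combos), alphabet)
  dim(ri) <- c(m, p)

  score <- local_seed(spec$seed, {
    s <- numeric(m)
    for (i in seq_len(p)) {
      eff <- rnorm(a, sd = spec$additive_scale)
      s <- s + eff[ri[, i]]
    }
    if (p >= 2 && spec$pairwise_scale > 0) {
      for (i in seq_len(p - 1)) {
        for (j in (i + 1):p) {
          J <- matrix(rnorm(a * a, sd = spec$pairwise_scale), a, a)
          s <- s + J[cbind(ri[, i], ri[, j])]
        }
      }
    }
    if (p >= 3 && spec$higher_order_scale > 0) {
      for (i in seq_len(p - 2)) {
        for (j in (i + 1):(p - 1)) {
          for (k in (j + 1):p) {
            Tv <- array(rnorm(a^3, sd = spec$higher_order_scale), c(a, a, a))
            s <- s + Tv[cbind(ri[, i], ri[, j], ri[, k])]
          }
        }
      }
    }
    if (spec$noise_sd > 0) s <- s + rnorm(m, sd = spec$noise_sd)
    s
  })

  fitness <- switch(spec$link,
    exponential = exp(score - max(score)),
    logistic = plogis(score),
    linear = {
      rng <- max(score) - min(score)
      if (rng == 0) rep(1, m) else
        0.1 + 0.9 * (score - min(score)) / rng
    }
  )
  fitness_landscape(
    tibble::tibble(combo = combos, fitness = fitness),
    positions = seq_len(p),
    parent = paste(rep("A", p), collapse = ""),
    alphabet = alphabet,
    name = sprintf("synthetic_p%d_a%d_seed%d", p, a, spec$seed)
  )
}

#' Landscape with a planted global optimum
#'
#' Draws background fitness uniformly on `(0, 1 - gap)` and sets one
#' seed-chosen variant to fitness 1, so after scaling the unique global
#' optimum exceeds the runner-up by at least `gap`. Useful for testing whether
#' a campaign locates a known peak.
#'
#' @param n_positions,alphabet_size Landscape dimensions.
#' @param gap Scaled-fitness margin of the planted optimum over all other
#'   variants (in `(0, 1)`).
#' @param seed Integer seed.
#' @return A [fitness_landscape()] with attribute `"optimum"` holding the
#'   planted combo.
#' @export
make_planted_optimum_landscape <- function(n_positions = 3, alphabet_size = 4,
                                           gap = 0.2, seed = 1) {
  if (gap <= 0 || gap >= 1) abort("`gap` must be in (0, 1)")
  alphabet <- aa_alphabet()[seq_len(alphabet_size)]
  combos <- enumerate_combos(alphabet, n_positions)
  m <- length(combos)
  fit <- local_seed(seed, {
    f <- runif(m, min = 0, max = 1 - gap)
    opt <- sample.int(m, 1)
    f[opt] <- 1
    attr(f, "opt") <- opt
    f
  })
  opt <- attr(fit, "opt")
  l <- fitness_landscape(
    tibble::tibble(combo = combos, fitness = as.numeric(fit)),
    positions = seq_len(n_positions),
    parent = paste(rep("A", n_positions), collapse = ""),
    alphabet = alphabet,
    name = sprintf("planted_p%d_a%d_seed%d", n_positions, alphabet_size, seed)
  )
  attr(l, "optimum") <- combos[opt]
  l
}

#' Biased factorized reference policy
#'
#' Interpolates between a uniform policy (`bias = 0`) and a near point mass on
#' a seed-chosen variant (`bias = 1`) by scaling a one-hot logit bump of
#' height `logit_scale` at that variant's residues. Emulates priors ranging
#' from spread-out to strongly mode-seeking.
#'
#' @param l A `fitness_landscape` providing positions and alphabet.
#' @param bias Interpolation weight in `[0, 1]`.
#' @param seed Integer seed choosing the favored variant.
#' @param logit_scale Logit bump height at `bias = 1` (default 12).
#' @return A [factorized_policy()] with attribute `"favored"` holding the
#'   favored combo.
#' @export
make_biased_reference_policy <- function(l, bias = 0.5, seed = 1,
                                         logit_scale = 12) {
  stopifnot(inherits(l, "fitness_landscape"))
  if (bias < 0 || bias > 1) abort("`bias` must be in [0, 1]")
  a <- length(l$alphabet)
  p <- length(l$positions)
  target <- local_seed(seed, sample(l$tbl$combo, 1))
  ti <- combo_index(target, l$alphabet)
  td <- match(residue_matrix(target)[1, ], l$alphabet)
  logits <- matrix(0, nrow = p, ncol = a,
                   dimnames = list(NULL, l$alphabet))
  logits[cbind(seq_len(p), td)] <- bias * logit_scale
  pol <- factorized_policy(logits, alphabet = l$alphabet,
                           positions = l$positions)
  attr(pol, "favored") <- target
  pol
}

#' Deterministic fixture suite
#'
#' Regenerates, from one master seed, a named set of small
#' landscape/reference-policy pairs with a manifest of properties each pair is
#' expected to satisfy (recomputable with the analysis functions): a purely
#' additive landscape, a rugged pairwise-coupled landscape, and a
#' planted-optimum landscape with a mode-seeking prior.
#'
#' @param master_seed Integer master seed.
#' @return Named list of fixtures, each a list with elements `landscape`,
#'   `policy`, and `manifest`.
#' @export
fixture_suite <- function(master_seed = 1) {
  seeds <- derive_seeds(master_seed, 6)
  additive <- generate_synthetic_landscape(
    synthetic_spec(n_positions = 3, alphabet_size = 4,
                   pairwise_scale = 0, noise_sd = 0, seed = seeds[1],
                   link = "linear")
  )
  rugged <- generate_synthetic_landscape(
    synthetic_spec(n_positions = 3, alphabet_size = 4,
                   pairwise_scale = 1.5, noise_sd = 0, seed = seeds[2])
  )
  planted <- make_planted_optimum_landscape(3, 4, gap = 0.2, seed = seeds[3])
  list(
    additive = list(
      landscape = additive,
      policy = make_biased_reference_policy(additive, bias = 0,
                                            seed = seeds[4]),
      manifest = list(entropy = 3 * log(4), local_optima_ratio = 1 / 64,
                      epistatic_squares = 0, roughness = 0,
                      global_optimum_accessibility = 1)
    ),
    rugged = list(
      landscape = rugged,
      policy = make_biased_reference_policy(rugged, bias = 0.5,
                                            seed = seeds[5]),
      manifest = list(min_local_optima_ratio = 1 / 64,
                      epistatic_squares_positive = TRUE)
    ),
    planted = list(
      landscape = planted,
      policy = make_biased_reference_policy(planted, bias = 1,
                                            seed = seeds[6]),
      manifest = list(optimum = attr(planted, "optimum"),
                      runner_up_max = 0.8, top5_coverage_min = 0.99)
    )
  )
}
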