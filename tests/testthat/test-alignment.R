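test_that("pair construction yields N(N-1)/2 canonical pairs", {
  l <- scale_landscape(generate_synthetic_landscape(
    synthetic_spec(n_positions = 3, alphabet_size = 20, seed = 1)))
  ref <- snapshot_reference(uniform_policy(l))

  recs96 <- l$tbl[1:96, c("combo", "energy")]
  pairs <- build_preference_pairs(recs96, ref)
  expect_equal(nrow(pairs), 4560)
  # canonical orientation: lower energy (fitter variant) first
  expect_true(all(pairs$U_y <= pairs$U_yprime))

  expect_equal(nrow(build_preference_pairs(recs96[1, ], ref)), 0)

  p3 <- build_preference_pairs(recs96[1:3, ], ref)
  expect_equal(nrow(p3), 3)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(p3$combo_y, p3$combo_yprime),
                  key(c("AAA", "AAA", "CAA"), c("CAA", "DAA", "DAA")))

  expect_error(
    build_preference_pairs(rbind(recs96[1, ], recs96[1, ]), ref),
    "duplicate")
})

test_that("parametric preference probability is a sigmoid of the log ratio", {
  ref <- uniform_policy(alphabet = c("A", "C", "D"), positions = 1:2)
  pairs <- tibble::tibble(combo_y = "AA", combo_yprime = "CC",
                          U_y = 0, U_yprime = 1, ref_logratio = 0)
  expect_equal(parametric_preference_probability(pairs, ref), 0.5)

  # per-variant probabilities in ratio 3:1 -> sigma(log 3) = 3/4
  jp <- joint_policy(c("AA", "CC"), log(c(3, 1)), alphabet = c("A", "C"),
                     positions = 1:2)
  expect_equal(parametric_preference_probability(pairs, jp), 0.75)
  rev_pairs <- pairs
  rev_pairs$combo_y <- "CC"; rev_pairs$combo_yprime <- "AA"
  expect_equal(parametric_preference_probability(pairs, jp) +
                 parametric_preference_probability(rev_pairs, jp), 1)
})

test_that("target preference probability implements the regularized target", {
  pair0 <- tibble::tibble(combo_y = "A", combo_yprime = "C",
                          U_y = 1, U_yprime = 1, ref_logratio = 0)
  expect_equal(target_preference_probability(pair0, era_config()), 0.5)

  pair <- tibble::tibble(combo_y = "A", combo_yprime = "C",
                         U_y = 0, U_yprime = log(2), ref_logratio = 0.7)
  cfg <- era_config(beta = 1, gamma = 0)
  expect_equal(target_preference_probability(pair, cfg), 2 / 3)

  # gamma -> Inf: the target defers to the reference's own preference
  cfg_inf <- era_config(beta = 1, gamma = 1e12)
  expect_equal(target_preference_probability(pair_inf <- pair, cfg_inf),
               plogis(0.7), tolerance = 1e-9)

  # as-printed mode scales the reference ratio by gamma / beta
  cfg_ap <- era_config(beta = 2, gamma = 1,
                       logratio_coefficient_mode = "as_printed")
  expect_equal(target_preference_probability(pair, cfg_ap),
               plogis(2 / 2 * (log(2) - 0) + 1 / 2 * 0.7))
})

test_that("per-pair ERA divergence is the Bernoulli KL", {
  # p_gamma = 0.5, p_theta = 0.75
  pair <- tibble::tibble(combo_y = "AA", combo_yprime = "CC",
                         U_y = 1, U_yprime = 1, ref_logratio = 0)
  jp <- joint_policy(c("AA", "CC"), log(c(3, 1)), alphabet = c("A", "C"),
                     positions = 1:2)
  expect_equal(era_pair_divergence(pair, jp, era_config()),
               0.5 * log(4 / 3), tolerance = 1e-12)
  # identical distributions -> zero
  expect_equal(era_pair_divergence(pair, uniform_policy(
    alphabet = c("A", "C"), positions = 1:2), era_config()), 0)

  # non-negativity over random pairs and policies
  set.seed(31)
  l <- random_scaled_landscape(2, 4, seed = 31)
  p <- factorized_policy(matrix(rnorm(8), 2, 4), alphabet = l$alphabet,
                         positions = l$positions)
  ref <- factorized_policy(matrix(rnorm(8), 2, 4), alphabet = l$alphabet,
                           positions = l$positions)
  idx <- cbind(sample.int(16, 2000, TRUE), sample.int(16, 2000, TRUE))
  idx <- idx[idx[, 1] != idx[, 2], ]
  lp <- pseudo_log_likelihood(ref, l$tbl$combo)
  pairs <- tibble::tibble(
    combo_y = l$tbl$combo[idx[, 1]], combo_yprime = l$tbl$combo[idx[, 2]],
    U_y = l$tbl$energy[idx[, 1]], U_yprime = l$tbl$energy[idx[, 2]],
    ref_logratio = lp[idx[, 1]] - lp[idx[, 2]]
  )
  expect_true(all(era_pair_divergence(pairs, p, era_config()) >= 0))

  # mean loss is invariant to pair orientation
  flipped <- tibble::tibble(
    combo_y = pairs$combo_yprime, combo_yprime = pairs$combo_y,
    U_y = pairs$U_yprime, U_yprime = pairs$U_y,
    ref_logratio = -pairs$ref_logratio
  )
  expect_equal(mean(era_pair_divergence(pairs, p, era_config())),
               mean(era_pair_divergence(flipped, p, era_config())),
               tolerance = 1e-12)
})

test_that("DPO loss follows the rank-only contract and skips ties", {
  pair <- tibble::tibble(combo_y = "AA", combo_yprime = "CC",
                         U_y = 0, U_yprime = 1, ref_logratio = 0.3)
  # policy equal to reference: -log sigma(0) = log 2 regardless of beta
  jp <- joint_policy(c("AA", "CC"), c(0.3, 0), alphabet = c("A", "C"),
                     positions = 1:2)
  expect_equal(as.numeric(dpo_pair_loss(pair, jp, beta_dpo = 0.7)), log(2))

  # advantage log 3 at beta_dpo = 1 -> -log(3/4)
  jadv <- joint_policy(c("AA", "CC"), c(0.3 + log(3), 0),
                       alphabet = c("A", "C"), positions = 1:2)
  expect_equal(as.numeric(dpo_pair_loss(pair, jadv, beta_dpo = 1)),
               -log(0.75), tolerance = 1e-12)

  tied <- pair
  tied$U_yprime <- 0
  out <- dpo_pair_loss(dplyr::bind_rows(pair, tied), jp)
  expect_length(out, 1)
  expect_equal(attr(out, "n_skipped"), 1)
})

test_that("closed-form optimum recovers the Boltzmann and reference limits", {
  l <- random_scaled_landscape(2, 3, seed = 40)
  ref <- snapshot_reference(make_biased_reference_policy(l, 0.4, seed = 2))

  # two variants, uniform ref, beta=1, gamma=0, U=(0, ln 2) -> (2/3, 1/3)
  two <- scale_landscape(tiny_landscape(c("A", "C"), c(2, 1),
                                        alphabet = c("A", "C")))
  pstar <- closed_form_optimal_policy(two, uniform_policy(two),
                                      era_config(beta = 1, gamma = 0))
  expect_equal(enumerate_distribution(pstar, two)$prob, c(2 / 3, 1 / 3),
               tolerance = 1e-12)

  p0 <- closed_form_optimal_policy(l, ref, era_config(beta = 1.7, gamma = 0))
  boltz <- exp(-1.7 * l$tbl$energy)
  boltz <- boltz / sum(boltz)
  expect_equal(enumerate_distribution(p0, l, renormalize = TRUE)$prob, boltz,
               tolerance = 1e-9)

  pinf <- closed_form_optimal_policy(l, ref, era_config(gamma = 1e12))
  expect_lt(policy_total_variation(pinf, ref, l), 1e-9)
})

test_that("expected fitness under the optimum is monotone in beta", {
  for (seed in c(7, 8)) {
    l <- random_scaled_landscape(2, 4, seed = seed)
    ref <- snapshot_reference(make_biased_reference_policy(l, 0.3,
                                                           seed = seed))
    ef <- vapply(c(0.5, 1, 2, 4, 8), function(b) {
      d <- enumerate_distribution(
        closed_form_optimal_policy(l, ref, era_config(beta = b, gamma = 0.2)),
        l, renormalize = TRUE)
      sum(d$prob * l$tbl$scaled)
    }, numeric(1))
    expect_true(all(diff(ef) >= -1e-12))
  }
})

test_that("training from the optimum stays there; gamma pins to reference", {
  l <- random_scaled_landscape(2, 3, seed = 50)
  ref <- snapshot_reference(uniform_policy(l))
  cfg <- era_config(beta = 1, gamma = 0.1, epochs = 50, learning_rate = 0.5)
  pairs <- build_preference_pairs(l$tbl[, c("combo", "energy")], ref)

  pstar <- closed_form_optimal_policy(l, ref, cfg)
  fit <- train_policy(pstar, pairs, cfg)
  expect_lt(fit$loss_trace$loss[1], 1e-12)
  expect_lt(policy_total_variation(fit$policy, pstar, l), 1e-6)

  cfg_big <- era_config(beta = 1, gamma = 1e6, epochs = 200,
                        learning_rate = 0.5)
  fit_big <- train_policy(uniform_policy(l), pairs, cfg_big)
  expect_lt(policy_total_variation(fit_big$policy, ref, l), 1e-2)
})

test_that("trained policies converge to the closed-form optimum", {
  l <- random_scaled_landscape(2, 3, seed = 60)
  ref <- snapshot_reference(uniform_policy(l))
  cfg <- era_config(beta = 1, gamma = 0.1, epochs = 500, learning_rate = 0.5)
  pairs <- build_preference_pairs(l$tbl[, c("combo", "energy")], ref)
  pstar <- closed_form_optimal_policy(l, ref, cfg)

  jfit <- train_policy(
    joint_policy(l$tbl$combo, rep(0, 9), l$alphabet, l$positions),
    pairs, cfg)
  expect_lt(policy_kl(pstar, jfit$policy, l), 1e-3)

  # additive energies + factorized reference: the optimum factorizes and the
  # factorized trainer reaches it too
  la <- random_scaled_landscape(2, 3, seed = 61, rugged = FALSE)
  pa <- build_preference_pairs(la$tbl[, c("combo", "energy")],
                               snapshot_reference(uniform_policy(la)))
  ffit <- train_policy(uniform_policy(la), pa, cfg)
  pstar_a <- closed_form_optimal_policy(la, uniform_policy(la), cfg)
  expect_lt(policy_kl(pstar_a, ffit$policy, la), 1e-3)

  expect_equal(glance(jfit)$epochs, 500)
  expect_equal(nrow(tidy(jfit)), 500)
})

test_that("minibatched training also reduces the loss deterministically", {
  l <- random_scaled_landscape(2, 3, seed = 70)
  ref <- snapshot_reference(uniform_policy(l))
  cfg <- era_config(epochs = 30, learning_rate = 0.5, pair_batch_size = 10,
                    seed = 3)
  pairs <- build_preference_pairs(l$tbl[, c("combo", "energy")], ref)
  f1 <- train_policy(uniform_policy(l), pairs, cfg)
  f2 <- train_policy(uniform_policy(l), pairs, cfg)
  expect_identical(f1$policy$logits, f2$policy$logits)
  expect_lt(f1$final_loss, f1$loss_trace$loss[1])
})

test_that("pair dataset TSV export round-trips", {
  l <- random_scaled_landscape(2, 3, seed = 80)
  ref <- snapshot_reference(uniform_policy(l))
  pairs <- build_preference_pairs(l$tbl[1:4, c("combo", "energy")], ref)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs_tsv(pairs, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(pairs))
})
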