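test_that("epistasis squares classify per the four-delta rule", {
  expect_equal(as.character(classify_epistasis_square(0, 1, 1, 2)$class),
               "additive")
  m <- classify_epistasis_square(0, 1, 1, 3)
  expect_equal(as.character(m$class), "magnitude")
  expect_equal(m$interaction_sign, "positive")
  expect_equal(as.character(classify_epistasis_square(0, 1, 1, 0.5)$class),
               "reciprocal_sign")
  expect_equal(as.character(classify_epistasis_square(0, -1, 1, 2)$class),
               "sign")
  # zero marginal effect with nonzero gap counts as magnitude, not sign
  expect_equal(as.character(classify_epistasis_square(0, 0, 1, 2)$class),
               "magnitude")
})

test_that("classification is invariant to square symmetries", {
  set.seed(17)
  for (i in 1:200) {
    w <- rnorm(4)
    base <- as.character(classify_epistasis_square(w[1], w[2], w[3],
                                                   w[4])$class)
    # swap the two positions: exchanges the single mutants
    expect_equal(as.character(classify_epistasis_square(w[1], w[3], w[2],
                                                        w[4])$class), base)
    # relabel which substitution is "first" at each position
    expect_equal(as.character(classify_epistasis_square(w[2], w[1], w[4],
                                                        w[3])$class), base)
    expect_equal(as.character(classify_epistasis_square(w[4], w[3], w[2],
                                                        w[1])$class), base)
  }
})

test_that("classifier agrees with the exhaustive-delta oracle", {
  set.seed(23)
  w <- matrix(rnorm(4 * 2000), ncol = 4)
  # mix in squares with exact ties to exercise the tolerance edges
  w[1:200, 2] <- w[1:200, 1]
  got <- as.character(classify_epistasis_square(w[, 1], w[, 2], w[, 3],
                                                w[, 4])$class)
  want <- vapply(seq_len(nrow(w)),
                 function(i) oracle_classify(w[i, 1], w[i, 2], w[i, 3],
                                             w[i, 4]),
                 character(1))
  expect_identical(got, want)
})

test_that("prevalences cover all squares once and sum to one", {
  sl <- random_scaled_landscape(3, 4, seed = 77)
  epi <- epistasis_prevalence(sl)
  # C(3,2) position pairs x C(4,2)^2 substitution pairs x 4 backgrounds
  expect_equal(epi$n_squares, 3 * 36 * 4)
  expect_true(epi$any_epistasis)
  expect_equal(epi$magnitude + epi$sign + epi$reciprocal_sign, 1,
               tolerance = 1e-12)

  # a single-square landscape matches the square classifier directly
  one <- scale_landscape(tiny_landscape(c("AA", "CA", "AC", "CC"),
                                        c(1, 2, 2, 1.5),
                                        alphabet = c("A", "C")))
  epi1 <- epistasis_prevalence(one)
  expect_equal(epi1$n_squares, 1)
  cl <- classify_epistasis_square(1, 2, 2, 1.5)$class
  expect_equal(epi1$reciprocal_sign,
               as.numeric(cl == "reciprocal_sign"))

  flat_add <- additive_scaled_landscape(2, 3, seed = 3)
  epi0 <- epistasis_prevalence(flat_add)
  expect_false(epi0$any_epistasis)
  expect_equal(c(epi0$magnitude, epi0$sign, epi0$reciprocal_sign),
               c(0, 0, 0))
})

test_that("local optima ratio matches a brute-force neighbor scan", {
  const <- scale_landscape(tiny_landscape(c("AA", "AC", "CA", "CC"),
                                          rep(2, 4),
                                          alphabet = c("A", "C")))
  expect_equal(local_optima_ratio(const), 1)

  add <- additive_scaled_landscape(3, 4, seed = 12)
  expect_equal(local_optima_ratio(add), 1 / 64)

  nk <- random_scaled_landscape(3, 4, seed = 13)
  f <- setNames(nk$tbl$scaled, nk$tbl$combo)
  oracle <- mean(vapply(nk$tbl$combo, function(v) {
    all(f[oracle_neighbors(v, nk)] <= f[[v]])
  }, logical(1)))
  expect_equal(local_optima_ratio(nk), oracle)
})

test_that("roughness-slope ratio matches the closed-form least squares", {
  two <- scale_landscape(tiny_landscape(c("AA", "CA", "AC", "CC"),
                                        c(1, 2, 2, 4),
                                        alphabet = c("A", "C")))
  expect_equal(roughness_slope_ratio(two), 1 / 6, tolerance = 1e-9)

  add <- additive_scaled_landscape(3, 4, seed = 14)
  expect_lt(roughness_slope_ratio(add), 1e-8)

  flat <- scale_landscape(tiny_landscape(c("AA", "AC", "CA", "CC"),
                                         rep(1, 4), alphabet = c("A", "C")))
  expect_error(roughness_slope_ratio(flat), "flat")
})

test_that("neutrality index matches brute-force edge enumeration", {
  flat <- scale_landscape(tiny_landscape(c("AA", "AC", "CA", "CC"),
                                         rep(1, 4), alphabet = c("A", "C")))
  expect_equal(neutrality_index(flat, delta = 1e-3), 1)

  nk <- random_scaled_landscape(3, 4, seed = 15)
  delta <- 0.05
  f <- setNames(nk$tbl$scaled, nk$tbl$combo)
  combos <- nk$tbl$combo
  neutral <- 0; total <- 0
  for (i in seq_along(combos)) {
    for (u in oracle_neighbors(combos[i], nk)) {
      if (u > combos[i]) {  # each unordered edge once
        total <- total + 1
        if (abs(f[[u]] - f[[combos[i]]]) <= delta) neutral <- neutral + 1
      }
    }
  }
  expect_equal(neutrality_index(nk, delta = delta), neutral / total)
  expect_equal(neutrality_index(nk, delta = 0), 0)
})

test_that("global optimum accessibility equals forward path enumeration", {
  add <- additive_scaled_landscape(3, 4, seed = 16)
  expect_equal(global_optimum_accessibility(add), 1)

  # two-peak toy: the second peak's basin is cut off by a strict valley
  two_peak <- scale_landscape(tiny_landscape(
    c("AA", "CA", "AC", "CC"), c(1.0, 0.2, 0.3, 0.9),
    alphabet = c("A", "C")))
  expect_lt(global_optimum_accessibility(two_peak), 1)
  expect_equal(global_optimum_accessibility(two_peak),
               oracle_goa(two_peak))

  one <- scale_landscape(tiny_landscape("A", 1, alphabet = "A"))
  expect_equal(global_optimum_accessibility(one), 1)

  for (dims in list(c(2, 2), c(3, 2), c(2, 3), c(3, 3), c(3, 4))) {
    sl <- random_scaled_landscape(dims[1], dims[2], seed = sum(dims))
    expect_equal(global_optimum_accessibility(sl), oracle_goa(sl))
  }
})

test_that("stronger couplings do not reduce reciprocal-sign prevalence", {
  prev <- function(pair_scale, seed) {
    sl <- scale_landscape(generate_synthetic_landscape(synthetic_spec(
      n_positions = 3, alphabet_size = 4, additive_scale = 1,
      pairwise_scale = pair_scale, seed = seed)))
    epistasis_prevalence(sl)$reciprocal_sign
  }
  seeds <- 1:20
  weak <- vapply(seeds, function(s) prev(0.4, s), numeric(1))
  strong <- vapply(seeds, function(s) prev(2.5, s), numeric(1))
  expect_gte(mean(strong), mean(weak))
})

test_that("the full landscape report assembles every metric", {
  sl <- random_scaled_landscape(3, 4, seed = 18)
  rep_ <- analyze_landscape(sl)
  expect_equal(rep_$lor, local_optima_ratio(sl))
  expect_equal(rep_$goa, global_optimum_accessibility(sl))
  expect_equal(rep_$rs_ratio, roughness_slope_ratio(sl))
  expect_true(rep_$lor >= 0 && rep_$lor <= 1)
  expect_true(rep_$neutrality >= 0 && rep_$neutrality <= 1)
  expect_equal(rep_$magnitude + rep_$sign + rep_$reciprocal_sign, 1,
               tolerance = 1e-12)
})
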