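# Shared fixture builders and independent brute-force oracles. Oracles here
# deliberately avoid the package's vectorized code paths: they loop over
# variants, enumerate paths recursively, and evaluate formulas directly.

tiny_landscape <- function(combos, fitness, alphabet = NULL, name = "tiny") {
  if (is.null(alphabet)) {
    alphabet <- sort(unique(unlist(strsplit(combos, ""))))
  }
  p <- nchar(combos[1])
  fitness_landscape(
    data.frame(combo = combos, fitness = fitness),
    positions = seq_len(p),
    parent = paste(rep("A", p), collapse = ""),
    alphabet = alphabet, name = name
  )
}

# complete landscape over the first `a` amino acids at `p` positions with
# explicitly supplied fitness (in enumeration order)
complete_landscape <- function(p, a, fitness, name = "complete") {
  alphabet <- aa_alphabet()[seq_len(a)]
  grid <- expand.grid(rep(list(alphabet), p), stringsAsFactors = FALSE)
  combos <- do.call(paste0, grid)
  tiny_landscape(combos, fitness, alphabet = alphabet, name = name)
}

hamming <- function(x, y) {
  sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
}

# brute-force Hamming-1 neighborhood by filtering the whole table
oracle_neighbors <- function(v, l) {
  combos <- l$tbl$combo
  combos[vapply(combos, function(u) hamming(u, v) == 1, logical(1))]
}

# per-variant product probability, looping positions explicitly
oracle_factorized_prob <- function(p, combo) {
  res <- strsplit(combo, "")[[1]]
  out <- 1
  for (i in seq_along(res)) {
    w <- exp(p$logits[i, ])
    out <- out * w[[res[i]]] / sum(w)
  }
  out
}

# independent epistasis classification from the four deltas
oracle_classify <- function(w00, w10, w01, w11, tol = 1e-9) {
  gap <- (w11 + w00) - (w10 + w01)
  if (abs(gap) <= tol) return("additive")
  sgn <- function(x) if (x > tol) 1 else if (x < -tol) -1 else 0
  flip1 <- sgn(w10 - w00) * sgn(w11 - w01) == -1
  flip2 <- sgn(w01 - w00) * sgn(w11 - w10) == -1
  if (flip1 && flip2) "reciprocal_sign" else if (flip1 || flip2) "sign" else
    "magnitude"
}

# forward path search: can `v` reach any global optimum by strictly
# fitness-increasing single mutations? (depth-first over increasing edges)
oracle_can_reach_optimum <- function(v, l) {
  f <- setNames(l$tbl$scaled, l$tbl$combo)
  opt <- names(f)[f == max(f)]
  seen <- character(0)
  dfs <- function(u) {
    if (u %in% opt) return(TRUE)
    seen <<- c(seen, u)
    ups <- setdiff(oracle_neighbors(u, l), seen)
    ups <- ups[f[ups] > f[u]]
    for (w in ups) if (dfs(w)) return(TRUE)
    FALSE
  }
  dfs(v)
}

oracle_goa <- function(l) {
  f <- setNames(l$tbl$scaled, l$tbl$combo)
  opt <- names(f)[f == max(f)]
  non_opt <- setdiff(names(f), opt)
  if (length(non_opt) == 0) return(1)
  mean(vapply(non_opt, oracle_can_reach_optimum, logical(1), l = l))
}

random_scaled_landscape <- function(p, a, seed, rugged = TRUE,
                                    link = "exponential") {
  scale_landscape(generate_synthetic_landscape(synthetic_spec(
    n_positions = p, alphabet_size = a, additive_scale = 1,
    pairwise_scale = if (rugged) 1 else 0, noise_sd = 0, seed = seed,
    link = link
  )))
}

# additive on the fitness scale itself (linear link, no couplings)
additive_scaled_landscape <- function(p, a, seed) {
  random_scaled_landscape(p, a, seed, rugged = FALSE, link = "linear")
}
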