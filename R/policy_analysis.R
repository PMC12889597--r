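# Distributional diagnostics of a policy over a landscape: mode-seeking
# statistics (entropy, KL to uniform, top-k coverage, sampling redundancy),
# correlation of log-likelihood with experimental activity, the change in
# probability mass assigned to high-activity variants after alignment, the
# likelihood-weighted position frequency matrix (a weighted MSA over the
# mutant space), and residue-count changes between sampled batches.

#' Mode-seeking summary of a policy's distribution
#'
#' Over the enumerated (renormalized) distribution `pi` on the landscape's
#' `M` variants: entropy `-sum pi log pi` (nats), KL to the uniform
#' distribution `sum pi log(pi M)` (nats; the two always add to `log M`),
#' top-`k` coverage (probability mass of the `k` likeliest variants), and
#' redundancy -- the duplicate fraction `(batch - #unique)/batch` in a seeded
#' batch of samples drawn with repeats allowed, the policy's natural
#' collision rate.
#'
#' @param p An `era_policy`.
#' @param l A `fitness_landscape` (enumerable).
#' @param k Top-k size (default 5); must not exceed the landscape size.
#' @param batch Redundancy batch size (default 1000).
#' @param seed Seed for the redundancy sample.
#' @return One-row tibble: `entropy`, `kl_uniform`, `top_k_coverage`,
#'   `redundancy`, `k`, `batch`, `n_variants`.
#' @export
distribution_summary <- function(p, l, k = 5, batch = 1000, seed = 1) {
  stopifnot(inherits(p, "era_policy"), inherits(l, "fitness_landscape"))
  m <- n_variants(l)
  if (k > m) abort(sprintf("`k` (%d) exceeds the landscape size (%d)", k, m))
  d <- enumerate_distribution(p, l, renormalize = TRUE)
  entropy <- -sum(ifelse(d$prob > 0, d$prob * d$log_prob, 0))
  kl_uniform <- log(m) - entropy
  topk <- sum(sort(d$prob, decreasing = TRUE)[seq_len(k)])
  draws <- sample_variants(p, batch,
                           sampling_constraints(allow_repeats = TRUE),
                           seed = seed)
  redundancy <- (batch - length(unique(draws))) / batch
  tibble::tibble(entropy = entropy, kl_uniform = kl_uniform,
                 top_k_coverage = topk, redundancy = redundancy,
                 k = as.integer(k), batch = as.integer(batch),
                 n_variants = m)
}

#' Correlation of policy log-likelihood with experimental activity
#'
#' Pearson correlation, over all enumerated variants, of the policy's
#' pseudo-log-likelihood with the raw experimental fitness (or the scaled
#' fitness when `use_scaled = TRUE`).
#'
#' @param p An `era_policy`.
#' @param l A `fitness_landscape` (>= 2 variants).
#' @param use_scaled Correlate against scaled rather than raw fitness.
#' @return Pearson r in `[-1, 1]`. Errors when either series is constant.
#' @export
loglik_fitness_correlation <- function(p, l, use_scaled = FALSE) {
  stopifnot(inherits(p, "era_policy"), inherits(l, "fitness_landscape"))
  if (n_variants(l) < 2) abort("need at least two variants")
  y <- if (use_scaled) {
    if (!inherits(l, "scaled_landscape")) abort("landscape is not scaled")
    l$tbl$scaled
  } else {
    l$tbl$fitness
  }
  x <- pseudo_log_likelihood(p, l$tbl$combo)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined: a series is constant")
  }
  cor(x, y)
}

#' Fold change in probability mass above activity thresholds
#'
#' For each threshold `t`, the ratio of the probability mass the `after`
#' policy assigns to variants with fitness strictly above `t` to the mass the
#' `before` policy assigns to the same set. A threshold where the before-mass
#' is zero yields `NA` (undefined) rather than an error.
#'
#' @param before,after Policies (e.g. pre- and post-alignment).
#' @param l A `fitness_landscape`; thresholds refer to its raw `fitness`
#'   column unless `use_scaled = TRUE`.
#' @param thresholds Numeric vector of activity thresholds.
#' @param use_scaled Threshold on scaled fitness instead.
#' @return Tibble: `threshold`, `mass_before`, `mass_after`, `fold_change`.
#' @export
probability_mass_fold_change <- function(before, after, l, thresholds,
                                         use_scaled = FALSE) {
  stopifnot(inherits(l, "fitness_landscape"))
  y <- if (use_scaled) l$tbl$scaled else l$tbl$fitness
  db <- enumerate_distribution(before, l, renormalize = TRUE)
  da <- enumerate_distribution(after, l, renormalize = TRUE)
  purrr::map_dfr(thresholds, function(t) {
    sel <- y > t
    mb <- sum(db$prob[sel])
    ma <- sum(da$prob[sel])
    tibble::tibble(threshold = t, mass_before = mb, mass_after = ma,
                   fold_change = if (mb > 0) ma / mb else NA_real_)
  })
}

#' Likelihood-weighted position frequency matrix
#'
#' The weighted multiple sequence alignment over the mutant space: the entry
#' for residue `a` at position `i` is the total policy probability of
#' variants carrying `a` at `i`. Each position's column sums to 1.
#'
#' @param p An `era_policy`.
#' @param l A `fitness_landscape` (enumerable).
#' @return Tibble of class `era_pfm` with columns `position` (the 1-based
#'   residue index in the parent), `residue`, `frequency`.
#' @export
weighted_position_frequency_matrix <- function(p, l) {
  stopifnot(inherits(p, "era_policy"), inherits(l, "fitness_landscape"))
  d <- enumerate_distribution(p, l, renormalize = TRUE)
  rm_ <- residue_matrix(d$combo)
  out <- purrr::map_dfr(seq_along(l$positions), function(i) {
    w <- vapply(split(d$prob, factor(rm_[, i], levels = l$alphabet)), sum,
                numeric(1))
    tibble::tibble(position = l$positions[i], residue = l$alphabet,
                   frequency = unname(w))
  })
  class(out) <- c("era_pfm", class(out))
  attr(out, "alphabet") <- l$alphabet
  out
}

#' Position frequency matrix as a residue-by-position matrix
#'
#' @param pfm An `era_pfm` from [weighted_position_frequency_matrix()].
#' @return Numeric matrix, rows = residues in alphabet order, columns =
#'   positions.
#' @export
pfm_matrix <- function(pfm) {
  stopifnot(inherits(pfm, "era_pfm"))
  wide <- tidyr::pivot_wider(tibble::as_tibble(pfm), names_from = "position",
                             values_from = "frequency")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$residue
  m
}

#' Write a position frequency matrix to TSV
#'
#' Rows are residues in alphabet order, columns the mutated positions.
#'
#' @param pfm An `era_pfm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm_tsv <- function(pfm, path) {
  m <- pfm_matrix(pfm)
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(residue = rownames(m)), out)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Per-position residue count change between two sampled batches
#'
#' Percent change in the count of each residue generated at each position,
#' `100 * (after - before) / max(before, 1)`. Residues absent before but
#' present after are flagged as newly appeared (their percent change equals
#' 100 times the raw new count under the same formula).
#'
#' @param samples_before,samples_after Non-empty character vectors of combos
#'   (e.g. batches sampled before and after alignment).
#' @param positions Optional 1-based position labels (defaults to sequence
#'   order).
#' @param alphabet Residue universe for the tally (default: residues observed
#'   in either batch, per position).
#' @return Tibble: `position`, `residue`, `count_before`, `count_after`,
#'   `pct_change`, `newly_appeared`.
#' @export
residue_count_change <- function(samples_before, samples_after,
                                 positions = NULL, alphabet = NULL) {
  if (length(samples_before) == 0 || length(samples_after) == 0) {
    abort("both sample lists must be non-empty")
  }
  bm <- residue_matrix(samples_before)
  am <- residue_matrix(samples_after)
  if (ncol(bm) != ncol(am)) abort("sample combos have mismatched lengths")
  p <- ncol(bm)
  if (is.null(positions)) positions <- seq_len(p)
  purrr::map_dfr(seq_len(p), function(i) {
    res <- if (is.null(alphabet)) sort(unique(c(bm[, i], am[, i]))) else
      alphabet
    cb <- vapply(res, function(a) sum(bm[, i] == a), numeric(1),
                 USE.NAMES = FALSE)
    ca <- vapply(res, function(a) sum(am[, i] == a), numeric(1),
                 USE.NAMES = FALSE)
    tibble::tibble(
      position = positions[i], residue = res,
      count_before = cb, count_after = ca,
      pct_change = 100 * (ca - cb) / pmax(cb, 1),
      newly_appeared = cb == 0 & ca > 0
    )
  })
}
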