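# The simulated directed-evolution campaign: at each round, sample a batch of
# previously unseen variants from the current policy, look up their assayed
# fitness, rebuild the exhaustive preference-pair dataset over every variant
# assayed so far (energies from benchmark scaling, log-ratios from the frozen
# reference), train the policy, and recompute the log-likelihoods of all
# prior variants under the updated policy. After the training rounds an
# optional final batch is sampled from the aligned policy without further
# training.

#' Campaign configuration
#'
#' Defaults mirror the benchmark protocol: four training rounds of 96
#' variants plus a final sampled batch of 96, for 480 evaluations total.
#'
#' @param round_size Variants sampled (and assayed) per round (>= 2).
#' @param n_training_rounds Rounds that include a training step.
#' @param final_sample Sample one additional batch from the final policy
#'   without training (default `TRUE`).
#' @param era An [era_config()].
#' @param objective `"era"` or `"dpo"`.
#' @param seed Master seed; replicate and round seeds are derived from it.
#' @param allow_repeats Permit re-assaying variants (the concession the DPO
#'   baseline needs under mode collapse); default `FALSE`.
#' @param reanchor_reference Re-snapshot the reference policy at the start of
#'   every round instead of keeping the pre-training anchor (default
#'   `FALSE`).
#' @param beta_dpo DPO inverse temperature.
#' @return A list of class `campaign_config`.
#' @export
campaign_config <- function(round_size = 96, n_training_rounds = 4,
                            final_sample = TRUE, era = era_config(),
                            objective = c("era", "dpo"), seed = 1,
                            allow_repeats = FALSE,
                            reanchor_reference = FALSE, beta_dpo = 0.1) {
  objective <- match.arg(objective)
  if (round_size < 2) abort("`round_size` must be >= 2")
  if (n_training_rounds < 1) abort("`n_training_rounds` must be >= 1")
  structure(
    list(round_size = as.integer(round_size),
         n_training_rounds = as.integer(n_training_rounds),
         final_sample = isTRUE(final_sample), era = era,
         objective = objective, seed = as.integer(seed),
         allow_repeats = isTRUE(allow_repeats),
         reanchor_reference = isTRUE(reanchor_reference),
         beta_dpo = beta_dpo),
    class = "campaign_config"
  )
}

# assay lookup against the scaled landscape
assay_variants <- function(l, combos) {
  idx <- match(combos, l$tbl$combo)
  if (anyNA(idx)) {
    abort(sprintf("variant(s) not present in the landscape: %s",
                  paste(combos[is.na(idx)], collapse = ", ")))
  }
  tibble::tibble(
    combo = combos,
    raw_fitness = l$tbl$fitness[idx],
    scaled_fitness = l$tbl$scaled[idx],
    energy = l$tbl$energy[idx]
  )
}

#' Run one campaign round
#'
#' Samples `cfg$round_size` admissible variants from `p`, assays them against
#' the landscape, rebuilds preference pairs over all variants assayed so far
#' (prior records plus this batch), trains per the configured objective, and
#' recomputes every record's log-likelihood under the post-training policy.
#'
#' @param p Policy to sample from and train.
#' @param ref Reference snapshot anchoring the alignment target.
#' @param l A `scaled_landscape`.
#' @param prior_records Tibble of records from earlier rounds (may have 0
#'   rows); columns as in the round log.
#' @param cfg A [campaign_config()].
#' @param round_seed Integer seed for this round's sampling.
#' @param round_index Round number recorded in the log.
#' @param train Set `FALSE` for the final, untrained sampling batch.
#' @return List with `records` (all records to date, log-likelihood columns
#'   refreshed), `policy` (trained), `fit` (the `era_fit`, or `NULL`).
#' @export
run_round <- function(p, ref, l, prior_records, cfg, round_seed,
                      round_index = 1L, train = TRUE) {
  stopifnot(inherits(l, "scaled_landscape"))
  excl <- if (cfg$allow_repeats || nrow(prior_records) == 0) character() else
    prior_records$combo
  constraints <- sampling_constraints(excluded = excl,
                                      allow_repeats = cfg$allow_repeats)
  drawn <- sample_variants(p, cfg$round_size, constraints, seed = round_seed)
  batch <- assay_variants(l, drawn)
  batch$round <- round_index
  batch$loglik_at_sampling <- pseudo_log_likelihood(p, batch$combo)
  batch$loglik_after_training <- batch$loglik_at_sampling
  records <- dplyr::bind_rows(prior_records, batch)

  fit <- NULL
  if (train && cfg$era$epochs > 0) {
    train_set <- dplyr::distinct(records, .data$combo, .keep_all = TRUE)
    pairs <- build_preference_pairs(
      train_set[, c("combo", "energy")],
      if (cfg$reanchor_reference) snapshot_reference(p) else ref
    )
    fit <- train_policy(p, pairs, cfg$era, objective = cfg$objective,
                        beta_dpo = cfg$beta_dpo)
    p <- fit$policy
    records$loglik_after_training <- pseudo_log_likelihood(p, records$combo)
  }
  list(records = records, policy = p, fit = fit)
}

#' Run a directed-evolution campaign
#'
#' Executes `n_replicates` independent seeded campaigns: an untrained
#' reference policy samples the first batch, each training round aligns the
#' policy to all fitness observations so far, and (optionally) a final batch
#' is sampled from the aligned policy. If the admissible pool is exhausted a
#' replicate stops early and is flagged.
#'
#' @param l A `scaled_landscape` (the simulated assay).
#' @param cfg A [campaign_config()].
#' @param n_replicates Number of independent replicates.
#' @param initial_policy Starting policy; default a uniform factorized policy
#'   over the landscape's positions and alphabet.
#' @return An object of class `campaign_result`: list with `records` (tibble
#'   `replicate`, `round`, `combo`, `raw_fitness`, `scaled_fitness`,
#'   `energy`, `loglik_at_sampling`, `loglik_after_training`), `replicates`
#'   (tibble `replicate`, `seed`, `best_combo`, `best_scaled_fitness`,
#'   `n_evaluated`, `truncated`), `policies` (final policy per replicate),
#'   `config`, `landscape_name`.
#'
#' @examples
#' l <- scale_landscape(generate_synthetic_landscape(synthetic_spec(
#'   n_positions = 2, alphabet_size = 4, pairwise_scale = 1, seed = 7)))
#' cfg <- campaign_config(round_size = 3, n_training_rounds = 2,
#'                        era = era_config(epochs = 5), seed = 11)
#' res <- run_campaign(l, cfg, n_replicates = 2)
#' average_maximum_fitness(res)
#' @export
run_campaign <- function(l, cfg = campaign_config(), n_replicates = 1,
                         initial_policy = NULL) {
  stopifnot(inherits(l, "scaled_landscape"),
            inherits(cfg, "campaign_config"))
  if (is.null(initial_policy)) initial_policy <- uniform_policy(l)
  rep_seeds <- derive_seeds(cfg$seed, n_replicates)
  n_rounds <- cfg$n_training_rounds + as.integer(cfg$final_sample)

  all_records <- vector("list", n_replicates)
  summaries <- vector("list", n_replicates)
  policies <- vector("list", n_replicates)

  for (r in seq_len(n_replicates)) {
    round_seeds <- derive_seeds(rep_seeds[r], n_rounds)
    p <- initial_policy
    ref <- snapshot_reference(initial_policy)
    records <- tibble::tibble()
    truncated <- FALSE
    for (k in seq_len(n_rounds)) {
      is_final <- cfg$final_sample && k == n_rounds
      step <- tryCatch(
        run_round(p, ref, l, records, cfg, round_seeds[k],
                  round_index = k, train = !is_final),
        error = function(e) e
      )
      if (inherits(step, "error")) {
        if (grepl("admissible", conditionMessage(step))) {
          truncated <- TRUE
          break
        }
        stop(step)
      }
      records <- step$records
      p <- step$policy
    }
    has_rows <- nrow(records) > 0
    best <- if (has_rows) which.max(records$scaled_fitness) else NA_integer_
    if (has_rows) records$replicate <- r
    all_records[[r]] <- records
    policies[[r]] <- p
    summaries[[r]] <- tibble::tibble(
      replicate = r, seed = rep_seeds[r],
      best_combo = if (has_rows) records$combo[best] else NA_character_,
      best_scaled_fitness = if (has_rows) records$scaled_fitness[best] else
        NA_real_,
      n_evaluated = nrow(records), truncated = truncated
    )
  }

  records <- dplyr::bind_rows(all_records[vapply(all_records, nrow,
                                                 integer(1)) > 0])
  if (nrow(records) > 0) {
    records <- records[, c("replicate", "round", "combo", "raw_fitness",
                           "scaled_fitness", "energy", "loglik_at_sampling",
                           "loglik_after_training")]
  }
  structure(
    list(records = records, replicates = dplyr::bind_rows(summaries),
         policies = policies, config = cfg, landscape_name = l$name),
    class = "campaign_result"
  )
}

#' @export
print.campaign_result <- function(x, ...) {
  cat(sprintf(
    "<campaign_result> %s: %d replicate(s), %d evaluations each (max)\n",
    x$landscape_name, nrow(x$replicates), max(x$replicates$n_evaluated)))
  print(x$replicates)
  invisible(x)
}

#' Write the per-round campaign log to TSV
#'
#' @param r A `campaign_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_campaign_tsv <- function(r, path) {
  stopifnot(inherits(r, "campaign_result"))
  readr::write_tsv(r$records, path)
  invisible(path)
}

#' Average maximum fitness across replicates
#'
#' Mean over replicates of each replicate's best scaled fitness, with the
#' standard error of that mean (reported as 0, with `se_defined = FALSE`, for
#' a single replicate).
#'
#' @param r A `campaign_result`.
#' @return One-row tibble: `estimate`, `std_error`, `n_replicates`,
#'   `se_defined`.
#' @export
average_maximum_fitness <- function(r) {
  stopifnot(inherits(r, "campaign_result"))
  best <- r$replicates$best_scaled_fitness
  if (length(best) == 0) abort("empty campaign result")
  se_defined <- length(best) > 1
  tibble::tibble(
    estimate = mean(best),
    std_error = if (se_defined) stats::sd(best) / sqrt(length(best)) else 0,
    n_replicates = length(best),
    se_defined = se_defined
  )
}

#' Fraction of replicates reaching the global optimum
#'
#' @param r A `campaign_result`.
#' @param l The `scaled_landscape` the campaign ran on; the optimum set is
#'   every variant attaining the maximum scaled fitness (ties included).
#' @return Scalar fraction in `[0, 1]`.
#' @export
fraction_reaching_optimum <- function(r, l) {
  stopifnot(inherits(r, "campaign_result"),
            inherits(l, "scaled_landscape"))
  opt <- l$tbl$combo[l$tbl$scaled == max(l$tbl$scaled)]
  hits <- vapply(split(r$records$combo, r$records$replicate),
                 function(cs) any(cs %in% opt), logical(1))
  mean(hits)
}
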