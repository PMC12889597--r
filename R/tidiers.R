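# broom-style tidiers for fitted objects and campaign results.

#' Tidy an ERA fit
#'
#' @param x An `era_fit` from [train_policy()].
#' @param ... Unused.
#' @return The per-epoch loss trace as a tibble (`epoch`, `loss`).
#' @export
tidy.era_fit <- function(x, ...) {
  x$loss_trace
}

#' One-row summary of an ERA fit
#'
#' @param x An `era_fit`.
#' @param ... Unused.
#' @return Tibble: `objective`, `n_pairs`, `n_skipped`, `epochs`, `beta`,
#'   `gamma`, `learning_rate`, `initial_loss`, `final_loss`.
#' @export
glance.era_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    n_pairs = x$n_pairs,
    n_skipped = x$n_skipped,
    epochs = nrow(x$loss_trace),
    beta = x$config$beta,
    gamma = x$config$gamma,
    learning_rate = x$config$learning_rate,
    initial_loss = if (nrow(x$loss_trace) > 0) x$loss_trace$loss[1] else
      x$final_loss,
    final_loss = x$final_loss
  )
}

#' Tidy a campaign result
#'
#' @param x A `campaign_result` from [run_campaign()].
#' @param ... Unused.
#' @return The per-variant round log: `replicate`, `round`, `combo`,
#'   `raw_fitness`, `scaled_fitness`, `energy`, `loglik_at_sampling`,
#'   `loglik_after_training`.
#' @export
tidy.campaign_result <- function(x, ...) {
  x$records
}

#' One-row-per-replicate summary of a campaign
#'
#' @param x A `campaign_result`.
#' @param ... Unused.
#' @return Tibble: `replicate`, `seed`, `best_combo`, `best_scaled_fitness`,
#'   `n_evaluated`, `truncated`.
#' @export
glance.campaign_result <- function(x, ...) {
  x$replicates
}

#' Tidy a factorized or joint policy
#'
#' @param x An `era_policy`.
#' @param ... Unused.
#' @return For a factorized policy, a tibble `position`, `residue`, `logit`,
#'   `prob`; for a joint policy, a tibble `combo`, `log_prob`, `prob`.
#' @export
tidy.era_policy <- function(x, ...) {
  if (inherits(x, "factorized_policy")) {
    lp <- position_log_probs(x)
    tidyr::expand_grid(position = x$positions, residue = x$alphabet) |>
      dplyr::mutate(
        logit = as.vector(t(x$logits)),
        prob = as.vector(t(exp(lp)))
      )
  } else {
    lp <- x$logits - logsumexp(x$logits)
    tibble::tibble(combo = x$combos, log_prob = lp, prob = exp(lp))
  }
}

#' @export
tidy.factorized_policy <- tidy.era_policy

#' @export
tidy.joint_policy <- tidy.era_policy
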