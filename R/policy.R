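# Tabular sequence policies over the mutated positions. A factorized policy
# mirrors the simultaneous-unmasking scheme of a masked language model: the
# residues drawn at the masked positions are conditionally independent given
# the fixed parent context, so the joint pseudo-likelihood of a variant is the
# product of per-position probabilities. A joint policy stores an explicit
# log-probability table over an enumerated variant space; the closed-form
# alignment optimum generally does not factorize, so both are needed. Either
# form exposes the full policy contract the trainer and campaign loop use:
# log-likelihoods, constrained sampling, a reference snapshot, and a gradient
# step. An adapter around a real protein language model satisfying the same
# contract could be dropped in.

#' Factorized policy over mutated positions
#'
#' One logit vector per mutated position over the alphabet; per-position
#' probabilities are the softmax of the logits and the variant
#' pseudo-likelihood is their product.
#'
#' @param logits Numeric matrix, `length(positions)` rows by
#'   `length(alphabet)` columns.
#' @param alphabet Ordered character vector of residue symbols.
#' @param positions 1-based mutated residue indices (metadata only).
#' @param name Optional identifier.
#' @return An object of class `c("factorized_policy", "era_policy")`.
#' @examples
#' p <- uniform_policy(alphabet = c("A", "C", "D"), positions = 1:2)
#' pseudo_log_likelihood(p, "AC")  # = 2 * log(1/3)
#' @export
factorized_policy <- function(logits, alphabet, positions,
                              name = "factorized") {
  logits <- as.matrix(logits)
  if (ncol(logits) != length(alphabet)) {
    abort("`logits` must have one column per alphabet symbol")
  }
  if (nrow(logits) != length(positions)) {
    abort("`logits` must have one row per mutated position")
  }
  if (!all(is.finite(logits))) abort("`logits` must be finite")
  colnames(logits) <- alphabet
  structure(
    list(logits = logits, alphabet = alphabet,
         positions = as.integer(positions), name = name),
    class = c("factorized_policy", "era_policy")
  )
}

#' Joint policy over an enumerated variant space
#'
#' Stores unnormalized log-weights for every variant of a (small, complete)
#' landscape; probabilities are recovered by log-sum-exp normalization over
#' the stored support.
#'
#' @param combos Character vector of variant combos (the support).
#' @param logits Numeric vector of unnormalized log-weights, same length.
#' @param alphabet,positions Metadata matching the landscape.
#' @param name Optional identifier.
#' @return An object of class `c("joint_policy", "era_policy")`.
#' @export
joint_policy <- function(combos, logits, alphabet, positions,
                         name = "joint") {
  if (length(combos) != length(logits)) {
    abort("`combos` and `logits` must have the same length")
  }
  if (anyDuplicated(combos)) abort("`combos` must be distinct")
  if (!all(is.finite(logits))) abort("`logits` must be finite")
  structure(
    list(combos = combos, logits = as.numeric(logits), alphabet = alphabet,
         positions = as.integer(positions), name = name),
    class = c("joint_policy", "era_policy")
  )
}

#' Uniform factorized policy
#'
#' @param l Optional `fitness_landscape` supplying alphabet and positions.
#' @param alphabet,positions Used when `l` is not given.
#' @return A [factorized_policy()] with all-zero logits.
#' @export
uniform_policy <- function(l = NULL, alphabet = NULL, positions = NULL) {
  if (!is.null(l)) {
    stopifnot(inherits(l, "fitness_landscape"))
    alphabet <- l$alphabet
    positions <- l$positions
  }
  factorized_policy(
    matrix(0, nrow = length(positions), ncol = length(alphabet)),
    alphabet = alphabet, positions = positions, name = "uniform"
  )
}

#' @export
print.era_policy <- function(x, ...) {
  kind <- class(x)[1]
  cat(sprintf("<%s> %s: %d positions, alphabet size %d\n", kind, x$name,
              length(x$positions), length(x$alphabet)))
  if (isTRUE(attr(x, "snapshot"))) cat("  (reference snapshot)\n")
  invisible(x)
}

# per-position log-probability matrix (softmax of logits, rows = positions)
position_log_probs <- function(p) {
  t(apply(p$logits, 1, function(row) row - logsumexp(row)))
}

#' Pseudo-log-likelihood of variants under a policy
#'
#' For a factorized policy this is the simultaneous-unmasking
#' pseudo-likelihood: the sum over mutated positions of the per-position
#' log-probability of the variant's residue. For a joint policy it is a
#' normalized table lookup.
#'
#' @param p An `era_policy`.
#' @param v Character vector of combo strings.
#' @return Numeric vector of log-probabilities (nats).
#' @export
pseudo_log_likelihood <- function(p, v) {
  UseMethod("pseudo_log_likelihood")
}

#' @export
pseudo_log_likelihood.factorized_policy <- function(p, v) {
  if (length(v) == 0) return(numeric(0))
  rm_ <- residue_matrix(v)
  if (ncol(rm_) != nrow(p$logits)) {
    abort("variant length does not match the policy's positions")
  }
  ri <- match(rm_, p$alphabet)
  if (anyNA(ri)) {
    abort(sprintf("residue symbol(s) outside the alphabet: %s",
                  paste(unique(rm_[is.na(ri)]), collapse = ", ")))
  }
  dim(ri) <- dim(rm_)
  lp <- position_log_probs(p)
  out <- numeric(length(v))
  for (i in seq_len(ncol(ri))) out <- out + lp[i, ri[, i]]
  unname(out)
}

#' @export
pseudo_log_likelihood.joint_policy <- function(p, v) {
  if (length(v) == 0) return(numeric(0))
  rm_ <- residue_matrix(v)
  bad <- setdiff(unique(as.vector(rm_)), p$alphabet)
  if (length(bad) > 0) {
    abort(sprintf("residue symbol(s) outside the alphabet: %s",
                  paste(bad, collapse = ", ")))
  }
  idx <- match(v, p$combos)
  lz <- logsumexp(p$logits)
  out <- rep(-Inf, length(v))  # zero probability off the stored support
  out[!is.na(idx)] <- p$logits[idx[!is.na(idx)]] - lz
  out
}

#' Enumerate a policy's distribution over a landscape
#'
#' Evaluates the policy probability of every variant in the landscape table.
#' Over a complete landscape a factorized policy's probabilities sum to 1 by
#' construction. Over an incomplete landscape the values are the unnormalized
#' joint probabilities unless `renormalize = TRUE`; the attribute
#' `"renormalized"` records which was returned.
#'
#' @param p An `era_policy`.
#' @param l A `fitness_landscape`.
#' @param renormalize Normalize probabilities over the landscape's variants.
#' @param max_size Enumeration cap (default `1e6` variants).
#' @return Tibble with columns `combo`, `log_prob`, `prob`, carrying
#'   attribute `"renormalized"`.
#' @export
enumerate_distribution <- function(p, l, renormalize = FALSE,
                                   max_size = 1e6) {
  stopifnot(inherits(p, "era_policy"), inherits(l, "fitness_landscape"))
  if (nrow(l$tbl) > max_size) {
    abort(sprintf("landscape size %d exceeds the enumeration cap of %g",
                  nrow(l$tbl), max_size))
  }
  lp <- pseudo_log_likelihood(p, l$tbl$combo)
  if (renormalize) lp <- lp - logsumexp(lp)
  out <- tibble::tibble(combo = l$tbl$combo, log_prob = lp, prob = exp(lp))
  attr(out, "renormalized") <- renormalize
  out
}

#' Sampling constraints
#'
#' @param excluded Combos that may not be returned (e.g. variants assayed in
#'   earlier rounds).
#' @param fixed Named character vector mapping position index (as it appears
#'   in the policy's `positions`) to a required residue.
#' @param max_hamming Optional list `list(radius =, reference =)` restricting
#'   samples to within `radius` substitutions of at least one reference
#'   combo.
#' @param allow_repeats Permit duplicate draws (and draws from `excluded` is
#'   still forbidden); default `FALSE` returns mutually distinct variants.
#' @return A list of class `sampling_constraints`.
#' @export
sampling_constraints <- function(excluded = character(), fixed = NULL,
                                 max_hamming = NULL, allow_repeats = FALSE) {
  if (!is.null(max_hamming)) {
    if (!is.list(max_hamming) ||
        !all(c("radius", "reference") %in% names(max_hamming)) ||
        max_hamming$radius < 0) {
      abort("`max_hamming` must be list(radius >= 0, reference = combos)")
    }
  }
  structure(
    list(excluded = toupper(as.character(excluded)), fixed = fixed,
         max_hamming = max_hamming, allow_repeats = isTRUE(allow_repeats)),
    class = "sampling_constraints"
  )
}

# logical filter: which combos satisfy the non-exclusion constraints
satisfies_constraints <- function(combos, constraints, positions) {
  ok <- rep.int(TRUE, length(combos))
  if (!is.null(constraints$fixed) && length(constraints$fixed) > 0) {
    rm_ <- residue_matrix(combos)
    for (nm in names(constraints$fixed)) {
      slot <- match(as.integer(nm), positions)
      if (is.na(slot)) abort(sprintf("fixed position %s not mutated", nm))
      ok <- ok & rm_[, slot] == constraints$fixed[[nm]]
    }
  }
  if (!is.null(constraints$max_hamming)) {
    d <- min_hamming_to_set(combos, constraints$max_hamming$reference)
    ok <- ok & d <= constraints$max_hamming$radius
  }
  ok
}

#' Sample variants from a policy under constraints
#'
#' Draws `n` variants from the policy's distribution -- independent
#' per-position categorical draws for a factorized policy, a categorical draw
#' over the support for a joint policy -- subject to the constraints. Unless
#' `allow_repeats`, results are mutually distinct and disjoint from the
#' excluded set. Deterministic under `seed`.
#'
#' When the variant space is small enough to enumerate (at most
#' `enumerate_cap` variants), the admissible set is enumerated and sampled
#' exactly, so the number of admissible variants is checked up front. For
#' larger spaces, rejection sampling with a proposal budget of `1000 * n` is
#' used, matching how an adapter that cannot enumerate would sample.
#'
#' @param p An `era_policy`.
#' @param n Number of variants to draw (>= 1).
#' @param constraints A [sampling_constraints()].
#' @param seed Integer seed.
#' @param enumerate_cap Largest variant space enumerated exactly.
#' @return Character vector of `n` combos.
#' @export
sample_variants <- function(p, n, constraints = sampling_constraints(),
                            seed = 1, enumerate_cap = 262144) {
  stopifnot(inherits(p, "era_policy"))
  if (n < 1) abort("`n` must be >= 1")
  n <- as.integer(n)

  if (inherits(p, "joint_policy")) {
    support <- p$combos
    lw <- p$logits
  } else {
    a <- length(p$alphabet)
    np <- nrow(p$logits)
    if (a^np <= enumerate_cap) {
      support <- enumerate_combos(p$alphabet, np)
      lw <- pseudo_log_likelihood(p, support)
    } else {
      support <- NULL
    }
  }

  if (!is.null(support)) {
    keep <- satisfies_constraints(support, constraints, p$positions) &
      !(support %in% constraints$excluded)
    adm <- support[keep]
    w <- exp(lw[keep] - logsumexp(lw[keep]))
    need <- if (constraints$allow_repeats) 1L else n
    if (length(adm) < need) {
      abort(sprintf(
        "only %d admissible variant(s) remain but %d were requested (shortfall %d)",
        length(adm), n, n - length(adm)))
    }
    return(local_seed(seed, {
      if (length(adm) == 1) {
        rep.int(adm, if (constraints$allow_repeats) n else 1L)
      } else {
        sample(adm, n, replace = constraints$allow_repeats, prob = w)
      }
    }))
  }

  # rejection path for spaces too large to enumerate
  local_seed(seed, {
    lp <- position_log_probs(p)
    probs <- exp(lp)
    budget <- 1000L * n
    proposed <- 0L
    out <- character(0)
    while (length(out) < n && proposed < budget) {
      batch <- min(budget - proposed, max(4L * n, 64L))
      draws <- vapply(seq_len(batch), function(k) {
        paste(vapply(seq_len(nrow(probs)), function(i) {
          sample(p$alphabet, 1, prob = probs[i, ])
        }, character(1)), collapse = "")
      }, character(1))
      proposed <- proposed + batch
      keep <- satisfies_constraints(draws, constraints, p$positions) &
        !(draws %in% constraints$excluded)
      draws <- draws[keep]
      if (!constraints$allow_repeats) {
        draws <- setdiff(draws, out)
        draws <- unique(draws)
      }
      out <- c(out, draws)
    }
    if (length(out) < n) {
      abort(paste0(
        "rejection budget exhausted before drawing the requested variants; ",
        "review the constraints or the policy's entropy"))
    }
    out[seq_len(n)]
  })
}

#' Snapshot a policy as an immutable reference
#'
#' Returns a deep copy to serve as the frozen reference distribution that the
#' alignment target is anchored to; later training of the original policy
#' never alters the snapshot's log-likelihoods. Idempotent.
#'
#' @param p An `era_policy`.
#' @return The snapshot policy (attribute `"snapshot"` set).
#' @export
snapshot_reference <- function(p) {
  stopifnot(inherits(p, "era_policy"))
  attr(p, "snapshot") <- TRUE
  p
}

#' Write a policy to JSON
#'
#' @param p An `era_policy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_policy_json <- function(p, path) {
  stopifnot(inherits(p, "era_policy"))
  obj <- list(type = class(p)[1], name = p$name, alphabet = p$alphabet,
              positions = p$positions)
  if (inherits(p, "factorized_policy")) {
    obj$logits <- lapply(seq_len(nrow(p$logits)),
                         function(i) unname(p$logits[i, ]))
  } else {
    obj$combos <- p$combos
    obj$logits <- p$logits
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a policy from JSON
#'
#' Validates dimensions and that the stored logits define normalizable
#' per-position (or joint) distributions.
#'
#' @param path JSON path written by [write_policy_json()].
#' @return An `era_policy`.
#' @export
read_policy_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "factorized_policy")) {
    logits <- if (is.matrix(obj$logits)) obj$logits else
      do.call(rbind, as.list(obj$logits))
    p <- factorized_policy(logits, alphabet = obj$alphabet,
                           positions = obj$positions, name = obj$name)
    pp <- exp(position_log_probs(p))
    if (any(abs(rowSums(pp) - 1) > 1e-9)) {
      abort("stored per-position probabilities do not normalize")
    }
    p
  } else if (identical(obj$type, "joint_policy")) {
    joint_policy(obj$combos, obj$logits, alphabet = obj$alphabet,
                 positions = obj$positions, name = obj$name)
  } else {
    abort(sprintf("unknown policy type: %s", obj$type))
  }
}
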