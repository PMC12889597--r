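# Internal helpers shared across modules: seed handling, log-space numerics,
# and the integer encoding of residue combinations used by the vectorized
# landscape diagnostics.

#' The twenty canonical amino acids
#'
#' One-letter symbols in alphabetical order; the default alphabet for
#' combinatorial landscapes and policies.
#'
#' @format Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic sub-seeds (replicates, rounds) from a master seed; all
# strictly below 2^31 so they remain valid R integers.
derive_seeds <- function(master_seed, n) {
  local_seed(master_seed, sample.int(2147483646L, n))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# combos -> n x p character matrix of residues
residue_matrix <- function(combos) {
  if (length(combos) == 0) {
    return(matrix(character(), nrow = 0, ncol = 0))
  }
  out <- matrix(unlist(strsplit(combos, "", fixed = TRUE), use.names = FALSE),
                nrow = length(combos), byrow = TRUE)
  rownames(out) <- NULL
  out
}

# combos -> 1-based integer index with position 1 varying fastest
combo_index <- function(combos, alphabet) {
  rm_ <- residue_matrix(combos)
  p <- ncol(rm_)
  ri <- match(rm_, alphabet)
  if (anyNA(ri)) {
    bad <- unique(rm_[is.na(ri)])
    abort(sprintf("residue symbol(s) outside the alphabet: %s",
                  paste(bad, collapse = ", ")))
  }
  dim(ri) <- dim(rm_)
  a <- length(alphabet)
  as.integer(1 + (ri - 1) %*% a^(0:(p - 1)))
}

# all alphabet^p combos, ordered so position 1 varies fastest (matches
# combo_index)
enumerate_combos <- function(alphabet, n_positions) {
  grid <- expand.grid(rep(list(alphabet), n_positions),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  do.call(paste0, grid)
}

# minimum Hamming distance from each combo to a reference set
min_hamming_to_set <- function(combos, reference) {
  cm <- residue_matrix(combos)
  rm_ <- residue_matrix(reference)
  out <- rep.int(ncol(cm), length(combos))
  for (j in seq_len(nrow(rm_))) {
    d <- rowSums(cm != matrix(rm_[j, ], nrow = nrow(cm), ncol = ncol(cm),
                              byrow = TRUE))
    out <- pmin(out, d)
  }
  out
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s", name, min))
  }
  invisible(x)
}
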