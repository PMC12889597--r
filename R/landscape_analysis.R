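# Ruggedness, navigability, and epistasis diagnostics of a scaled landscape.
# All metrics operate on scaled fitness. A "square" is the elementary unit of
# pairwise epistasis: a genetic background, two distinct positions, and one
# substitution at each, giving four variants with fitnesses w00 (background),
# w10 and w01 (single mutants), and w11 (double mutant).

# fitness array indexed by residue, one dimension per position
landscape_array <- function(l, column = "scaled") {
  if (!is_complete_landscape(l)) {
    abort("this diagnostic requires a complete combinatorial landscape")
  }
  a <- length(l$alphabet)
  p <- length(l$positions)
  f <- numeric(a^p)
  f[combo_index(l$tbl$combo, l$alphabet)] <- l$tbl[[column]]
  array(f, dim = rep(a, p))
}

#' Classify pairwise epistasis of a square
#'
#' With the epistatic gap `g = w11 - w10 - w01 + w00` and single-mutation
#' effects `d1 = w10 - w00`, `d1' = w11 - w01` (first substitution, without /
#' with the second) and `d2 = w01 - w00`, `d2' = w11 - w10`: a square with
#' `|g| <= tol` is additive; otherwise it shows magnitude epistasis if
#' neither effect changes sign across backgrounds, sign epistasis if exactly
#' one does, and reciprocal sign epistasis if both do. An effect within
#' `tol` of zero is treated as sign-consistent with either sign, so squares
#' with a zero marginal effect but a nonzero gap classify as magnitude.
#' All arguments are vectorized.
#'
#' @param w00,w10,w01,w11 Fitness of the background, the two single mutants,
#'   and the double mutant.
#' @param tol Non-negative tolerance on the gap and on effect signs
#'   (default `1e-9`).
#' @return Tibble with columns `class` (factor: additive, magnitude, sign,
#'   reciprocal_sign), `interaction_sign` (`"positive"`, `"negative"`, or
#'   `"none"` for additive squares), and `gap`.
#'
#' @examples
#' classify_epistasis_square(0, 1, 1, 2)    # additive
#' classify_epistasis_square(0, 1, 1, 0.5)  # reciprocal sign
#' @export
classify_epistasis_square <- function(w00, w10, w01, w11, tol = 1e-9) {
  stopifnot_scalar_number(tol, "tol", min = 0)
  gap <- w11 - w10 - w01 + w00
  d1 <- w10 - w00
  d1p <- w11 - w01
  d2 <- w01 - w00
  d2p <- w11 - w10
  flip <- function(x, y) (x > tol & y < -tol) | (x < -tol & y > tol)
  f1 <- flip(d1, d1p)
  f2 <- flip(d2, d2p)
  cls <- ifelse(abs(gap) <= tol, "additive",
         ifelse(f1 & f2, "reciprocal_sign",
         ifelse(f1 | f2, "sign", "magnitude")))
  tibble::tibble(
    class = factor(cls, levels = c("additive", "magnitude", "sign",
                                   "reciprocal_sign")),
    interaction_sign = ifelse(cls == "additive", "none",
                              ifelse(gap > 0, "positive", "negative")),
    gap = gap
  )
}

# enumerate every square of a complete landscape once and classify it;
# returns a count per class
count_epistasis_classes <- function(l, tol = 1e-9) {
  arr <- landscape_array(l)
  a <- length(l$alphabet)
  p <- length(l$positions)
  if (p < 2) abort("epistasis needs at least two mutated positions")
  counts <- c(additive = 0, magnitude = 0, sign = 0, reciprocal_sign = 0)
  subs <- which(upper.tri(matrix(0, a, a)), arr.ind = TRUE)  # r1 < r2
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      # bring positions i and j to the front; remaining dims are backgrounds
      perm <- c(i, j, setdiff(seq_len(p), c(i, j)))
      B <- aperm(arr, perm)
      dim(B) <- c(a, a, a^(p - 2))
      for (s1 in seq_len(nrow(subs))) {
        r1 <- subs[s1, 1]; r2 <- subs[s1, 2]
        for (s2 in seq_len(nrow(subs))) {
          q1 <- subs[s2, 1]; q2 <- subs[s2, 2]
          cl <- classify_epistasis_square(
            B[r1, q1, ], B[r2, q1, ], B[r1, q2, ], B[r2, q2, ], tol = tol
          )$class
          tab <- table(cl)
          counts <- counts + as.numeric(tab[names(counts)])
        }
      }
    }
  }
  counts
}

#' Prevalence of epistasis classes over a complete landscape
#'
#' Enumerates every square (all position pairs, all unordered substitution
#' pairs at each, all backgrounds; each square counted once) and reports the
#' fraction of epistatic (non-additive) squares falling in each class.
#'
#' @param l A `scaled_landscape` (complete).
#' @param tol Gap/sign tolerance passed to [classify_epistasis_square()].
#' @return One-row tibble: `magnitude`, `sign`, `reciprocal_sign` (fractions
#'   of epistatic squares, summing to 1 when any exist), `n_squares`,
#'   `n_epistatic`, `any_epistasis`. With no epistatic squares the fractions
#'   are 0 and `any_epistasis` is `FALSE`.
#' @export
epistasis_prevalence <- function(l, tol = 1e-9) {
  stopifnot(inherits(l, "scaled_landscape"))
  counts <- count_epistasis_classes(l, tol = tol)
  n_epi <- sum(counts[c("magnitude", "sign", "reciprocal_sign")])
  frac <- if (n_epi > 0) {
    counts[c("magnitude", "sign", "reciprocal_sign")] / n_epi
  } else {
    c(magnitude = 0, sign = 0, reciprocal_sign = 0)
  }
  tibble::tibble(
    magnitude = unname(frac["magnitude"]),
    sign = unname(frac["sign"]),
    reciprocal_sign = unname(frac["reciprocal_sign"]),
    n_squares = unname(sum(counts)),
    n_epistatic = unname(n_epi),
    any_epistasis = n_epi > 0
  )
}

#' Local optima ratio
#'
#' Fraction of variants with no strictly fitter single-mutation neighbor.
#' The definition is non-strict, so every variant of a flat plateau counts as
#' a local optimum.
#'
#' @param l A `scaled_landscape` (complete).
#' @return Scalar in `(0, 1]`.
#' @export
local_optima_ratio <- function(l) {
  stopifnot(inherits(l, "scaled_landscape"))
  arr <- landscape_array(l)
  a <- dim(arr)[1]
  p <- length(dim(arr))
  is_opt <- array(TRUE, dim = dim(arr))
  for (i in seq_len(p)) {
    perm <- c(i, setdiff(seq_len(p), i))
    B <- aperm(arr, perm)
    dim(B) <- c(a, a^(p - 1))
    fiber_max <- apply(B, 2, max)
    opt_i <- B == rep(fiber_max, each = a)
    dim(opt_i) <- rep(a, p)
    is_opt <- is_opt & aperm(opt_i, order(perm))
  }
  mean(is_opt)
}

#' Roughness-slope ratio
#'
#' Fits the best additive model (intercept plus one effect per non-reference
#' residue per position, ordinary least squares over all variants) to scaled
#' fitness. Roughness is the root-mean-square residual; slope is the mean
#' absolute fitted additive effect; the ratio measures deviation from
#' additivity (0 for a purely additive landscape).
#'
#' @param l A `scaled_landscape` (complete or not; every table row is used).
#' @return Non-negative scalar. Errors on a flat landscape (zero slope).
#' @export
roughness_slope_ratio <- function(l) {
  stopifnot(inherits(l, "scaled_landscape"))
  rm_ <- residue_matrix(l$tbl$combo)
  keep <- vapply(seq_len(ncol(rm_)),
                 function(i) length(unique(rm_[, i])) > 1, logical(1))
  if (!any(keep)) {
    abort("no position varies; the additive model is not fittable")
  }
  df <- as.data.frame(rm_[, keep, drop = FALSE], stringsAsFactors = TRUE)
  names(df) <- paste0("pos", which(keep))
  df$.y <- l$tbl$scaled
  fit <- lm(.y ~ ., data = df)
  roughness <- sqrt(mean(residuals(fit)^2))
  slope <- mean(abs(coef(fit)[-1]), na.rm = TRUE)
  if (!is.finite(slope) || slope < 1e-12) {
    abort("flat landscape: mean additive effect is zero, ratio undefined")
  }
  roughness / slope
}

#' Neutrality index
#'
#' Fraction of single-mutation neighbor pairs whose scaled-fitness difference
#' is at most `delta` in absolute value.
#'
#' @param l A `scaled_landscape` (complete).
#' @param delta Neutrality band on scaled fitness (default `1e-3`).
#' @return Scalar in `[0, 1]`.
#' @export
neutrality_index <- function(l, delta = 1e-3) {
  stopifnot(inherits(l, "scaled_landscape"))
  stopifnot_scalar_number(delta, "delta", min = 0)
  arr <- landscape_array(l)
  a <- dim(arr)[1]
  p <- length(dim(arr))
  neutral <- 0
  total <- 0
  subs <- which(upper.tri(matrix(0, a, a)), arr.ind = TRUE)
  for (i in seq_len(p)) {
    perm <- c(i, setdiff(seq_len(p), i))
    B <- aperm(arr, perm)
    dim(B) <- c(a, a^(p - 1))
    for (s in seq_len(nrow(subs))) {
      d <- abs(B[subs[s, 1], ] - B[subs[s, 2], ])
      neutral <- neutral + sum(d <= delta)
      total <- total + length(d)
    }
  }
  neutral / total
}

# 0-based neighbor indices of a 0-based variant index in a complete landscape
neighbor_indices0 <- function(idx0, a, p) {
  pow <- a^(0:(p - 1))
  digits <- (idx0 %/% pow) %% a
  unlist(lapply(seq_len(p), function(i) {
    r <- setdiff(0:(a - 1), digits[i])
    idx0 + (r - digits[i]) * pow[i]
  }), use.names = FALSE)
}

#' Global optimum accessibility
#'
#' Fraction of non-optimal variants from which the global optimum can be
#' reached by a strictly fitness-increasing path of single mutations.
#' Computed by a reverse breadth-first traversal from the optimum set (all
#' variants tied at the maximum scaled fitness) over strictly decreasing
#' edges. A landscape of one variant is vacuously fully accessible.
#'
#' @param l A `scaled_landscape` (complete).
#' @return Scalar in `[0, 1]`.
#' @export
global_optimum_accessibility <- function(l) {
  stopifnot(inherits(l, "scaled_landscape"))
  arr <- landscape_array(l)
  f <- as.vector(arr)
  a <- dim(arr)[1]
  p <- length(dim(arr))
  m <- length(f)
  if (m == 1) return(1)
  opt <- which(f == max(f))
  reach <- logical(m)
  reach[opt] <- TRUE
  queue <- opt
  head_ <- 1L
  while (head_ <= length(queue)) {
    v <- queue[head_]
    head_ <- head_ + 1L
    nb <- neighbor_indices0(v - 1L, a, p) + 1L
    worse <- nb[f[nb] < f[v] & !reach[nb]]
    reach[worse] <- TRUE
    queue <- c(queue, worse)
  }
  non_opt <- setdiff(seq_len(m), opt)
  if (length(non_opt) == 0) return(1)
  mean(reach[non_opt])
}

#' Full landscape diagnostic report
#'
#' Runs every ruggedness/navigability metric and the epistasis prevalences
#' over a complete scaled landscape.
#'
#' @param l A `scaled_landscape`.
#' @param tol Epistasis gap tolerance.
#' @param delta Neutrality band.
#' @return One-row tibble: `name`, `n_variants`, `lor`, `rs_ratio`,
#'   `neutrality`, `goa`, `magnitude`, `sign`, `reciprocal_sign`,
#'   `any_epistasis`.
#' @export
analyze_landscape <- function(l, tol = 1e-9, delta = 1e-3) {
  stopifnot(inherits(l, "scaled_landscape"))
  epi <- epistasis_prevalence(l, tol = tol)
  tibble::tibble(
    name = l$name,
    n_variants = n_variants(l),
    lor = local_optima_ratio(l),
    rs_ratio = roughness_slope_ratio(l),
    neutrality = neutrality_index(l, delta = delta),
    goa = global_optimum_accessibility(l),
    magnitude = epi$magnitude,
    sign = epi$sign,
    reciprocal_sign = epi$reciprocal_sign,
    any_epistasis = epi$any_epistasis
  )
}
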