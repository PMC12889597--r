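# Combinatorial multi-site fitness landscapes: construction, validation,
# CSV round-trip, fitness scaling to the unit interval, and the Hamming-1
# neighborhood used throughout the diagnostics.

#' Construct a combinatorial fitness landscape
#'
#' A fitness landscape maps every assayed variant -- an ordered combination of
#' residues at a fixed set of mutated positions in a parent sequence -- to a
#' non-negative experimental fitness. The variant table is stored as a tibble
#' with columns `combo` (one uppercase letter per mutated position, in
#' ascending position order) and `fitness`.
#'
#' @param table Data frame with columns `combo` (character) and `fitness`
#'   (non-negative numeric). One row per variant; duplicate combos are an
#'   error.
#' @param positions Integer vector of 1-based residue indices into `parent`,
#'   strictly increasing.
#' @param parent Parent amino-acid sequence (single uppercase string).
#' @param alphabet Ordered character vector of allowed residue symbols;
#'   defaults to the 20 canonical amino acids.
#' @param name Identifier carried through reports and plots.
#'
#' @return An object of class `fitness_landscape`: a list with elements
#'   `tbl` (tibble `combo`, `fitness`), `positions`, `parent`, `alphabet`,
#'   `name`.
#'
#' @examples
#' l <- fitness_landscape(
#'   data.frame(combo = c("AA", "AC", "CA", "CC"), fitness = c(1, 2, 2, 4)),
#'   positions = c(5, 9),
#'   parent = "MKLVAQRTWDE",
#'   alphabet = c("A", "C")
#' )
#' n_variants(l)
#' @export
fitness_landscape <- function(table, positions, parent,
                              alphabet = aa_alphabet(), name = "landscape") {
  if (!is.data.frame(table) || !all(c("combo", "fitness") %in% names(table))) {
    abort("`table` must be a data frame with columns `combo` and `fitness`")
  }
  tbl <- tibble::tibble(combo = toupper(as.character(table$combo)),
                        fitness = as.numeric(table$fitness))
  positions <- as.integer(positions)
  parent <- toupper(parent)
  if (length(positions) < 1 || any(diff(positions) <= 0)) {
    abort("`positions` must be strictly increasing")
  }
  if (any(positions < 1) || any(positions > nchar(parent))) {
    abort("`positions` must index into the parent sequence")
  }
  if (anyDuplicated(alphabet)) abort("`alphabet` has duplicate symbols")
  dup <- tbl$combo[duplicated(tbl$combo)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate combo(s) in landscape table: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  if (any(nchar(tbl$combo) != length(positions))) {
    abort("every combo must have one residue per mutated position")
  }
  if (nrow(tbl) > 0) {
    syms <- unique(unlist(strsplit(tbl$combo, "", fixed = TRUE)))
    bad <- setdiff(syms, alphabet)
    if (length(bad) > 0) {
      abort(sprintf("combo residue(s) outside the alphabet: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  if (anyNA(tbl$fitness) || any(tbl$fitness < 0)) {
    abort("raw fitness must be non-negative and non-missing")
  }
  structure(
    list(tbl = tbl, positions = positions, parent = parent,
         alphabet = alphabet, name = name),
    class = "fitness_landscape"
  )
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("<%s> %s: %d variants, %d positions (%s), alphabet size %d\n",
              paste(class(x), collapse = "/"), x$name, nrow(x$tbl),
              length(x$positions), paste(x$positions, collapse = ","),
              length(x$alphabet)))
  if (!is.null(x$floor)) {
    cat(sprintf("  scaled to [%g, 1]; energy = -log(scaled fitness)\n",
                x$floor))
  }
  print(head(x$tbl, 5))
  invisible(x)
}

#' Variants of a landscape
#'
#' @param l A `fitness_landscape`.
#' @return Character vector of combo strings.
#' @export
variants <- function(l) {
  stopifnot(inherits(l, "fitness_landscape"))
  l$tbl$combo
}

#' Number of variants in a landscape
#'
#' @param l A `fitness_landscape`.
#' @return Integer count.
#' @export
n_variants <- function(l) {
  stopifnot(inherits(l, "fitness_landscape"))
  nrow(l$tbl)
}

# TRUE when the table covers alphabet^positions exactly
is_complete_landscape <- function(l) {
  a <- length(l$alphabet)
  p <- length(l$positions)
  m <- nrow(l$tbl)
  if (m != a^p) return(FALSE)
  !anyDuplicated(combo_index(l$tbl$combo, l$alphabet))
}

#' Read a landscape variant table from CSV
#'
#' Expects the two-column dialect `combo,fitness` with a header row, one
#' variant per row. Combos are uppercased on read; duplicates, symbols outside
#' the alphabet, and negative fitness raise errors.
#'
#' @param path CSV file path.
#' @inheritParams fitness_landscape
#' @return A [fitness_landscape()].
#' @export
read_landscape_csv <- function(path, positions, parent,
                               alphabet = aa_alphabet(),
                               name = tools::file_path_sans_ext(basename(path))) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    combo = readr::col_character(),
    fitness = readr::col_double()
  ))
  fitness_landscape(tbl, positions = positions, parent = parent,
                    alphabet = alphabet, name = name)
}

#' Write a landscape variant table to CSV
#'
#' Emits the same `combo,fitness` dialect that [read_landscape_csv()] reads,
#' so a write/read round trip reproduces the table exactly.
#'
#' @param l A `fitness_landscape`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(l, path) {
  stopifnot(inherits(l, "fitness_landscape"))
  readr::write_csv(l$tbl[, c("combo", "fitness")], path)
  invisible(path)
}

#' Scale fitness to the unit interval and attach variant energies
#'
#' Divides raw fitness by the landscape maximum so the fittest variant scores
#' exactly 1, floors the result at `floor` so inactive variants keep a finite
#' energy, and defines the energy of each variant as the negative log scaled
#' fitness (nats). The fittest variant therefore sits at energy 0.
#'
#' @param l A `fitness_landscape` with at least one positive fitness.
#' @param floor Small positive floor applied to scaled fitness before the log;
#'   default `1e-6`.
#' @param reference_max Optional scaling reference. The default (`NULL`) uses
#'   the full-landscape maximum, the benchmark convention when the complete
#'   landscape has been assayed; pass the largest fitness observed so far for
#'   an online campaign where the global maximum is unknown.
#' @return A `scaled_landscape` (also a `fitness_landscape`) whose table
#'   gains columns `scaled` in `[floor, 1]` and `energy = -log(scaled)`.
#'
#' @examples
#' l <- fitness_landscape(
#'   data.frame(combo = c("A", "C"), fitness = c(2, 1)),
#'   positions = 1, parent = "A", alphabet = c("A", "C")
#' )
#' scale_landscape(l)$tbl
#' @export
scale_landscape <- function(l, floor = 1e-6, reference_max = NULL) {
  stopifnot(inherits(l, "fitness_landscape"))
  stopifnot_scalar_number(floor, "floor", min = 0)
  if (floor <= 0 || floor > 1) abort("`floor` must be in (0, 1]")
  ref <- if (is.null(reference_max)) max(l$tbl$fitness) else reference_max
  if (!is.finite(ref) || ref <= 0) {
    abort("cannot scale: no positive fitness to use as reference")
  }
  tbl <- l$tbl
  tbl$scaled <- pmin(pmax(tbl$fitness / ref, floor), 1)
  tbl$energy <- -log(tbl$scaled)
  out <- l
  out$tbl <- tbl
  out$floor <- floor
  class(out) <- c("scaled_landscape", "fitness_landscape")
  out
}

#' Single-mutation neighbors of a variant
#'
#' All variants present in the landscape table at Hamming distance exactly 1
#' from `v` (one position changed, all others equal).
#'
#' @param v Combo string of a variant present in the landscape.
#' @param l A `fitness_landscape`.
#' @return Character vector of neighbor combos (possibly empty).
#' @export
single_mutation_neighbors <- function(v, l) {
  stopifnot(inherits(l, "fitness_landscape"))
  v <- toupper(v)
  if (!v %in% l$tbl$combo) {
    abort(sprintf("variant %s is not in the landscape", v))
  }
  res <- strsplit(v, "", fixed = TRUE)[[1]]
  cands <- unlist(lapply(seq_along(res), function(i) {
    subs <- setdiff(l$alphabet, res[i])
    vapply(subs, function(s) {
      r <- res
      r[i] <- s
      paste(r, collapse = "")
    }, character(1))
  }), use.names = FALSE)
  intersect(cands, l$tbl$combo)
}

# full-length mutant sequences for a set of combos
apply_variants <- function(l, combos) {
  rm_ <- residue_matrix(combos)
  vapply(seq_along(combos), function(k) {
    s <- strsplit(l$parent, "", fixed = TRUE)[[1]]
    s[l$positions] <- rm_[k, ]
    paste(s, collapse = "")
  }, character(1))
}

#' Export full-length mutant sequences as FASTA
#'
#' Applies each variant's residues to the parent sequence at the mutated
#' positions and writes one FASTA record per variant, with the combo string as
#' the record id.
#'
#' @param l A `fitness_landscape`.
#' @param path Output FASTA path.
#' @param combos Variants to export; defaults to the full table.
#' @return `path`, invisibly.
#' @export
write_variants_fasta <- function(l, path, combos = variants(l)) {
  stopifnot(inherits(l, "fitness_landscape"))
  seqs <- apply_variants(l, combos)
  seqinr::write.fasta(as.list(seqs), names = combos, file.out = path,
                      as.string = TRUE)
  invisible(path)
}
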