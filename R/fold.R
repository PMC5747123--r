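#' Parameters of the simplified folding engine
#'
#' The engine scores a nested structure as the sum of its pair weights plus a
#' bonus for every stacked pair (a pair `(i, j)` whose inner neighbour
#' `(i+1, j-1)` is also paired); the reported energy is the negated weight.
#' Boltzmann factors are `exp(weight / kT)`.  This is deliberately a light
#' stand-in for a full nearest-neighbour model: it produces ensembles with the
#' statistical features the aligner needs (helix cooperativity via the stack
#' bonus, canonical pairing, hairpin-size constraint) without any external
#' dependency.  A thermodynamic engine can be plugged in by supplying
#' externally computed dot plots to the aligner instead.
#'
#' @param w_gc,w_au,w_gu weights of G-C, A-U and G-U pairs.
#' @param stack_bonus extra weight per stacked pair.
#' @param kT Boltzmann scale.
#' @param min_hairpin minimum unpaired residues in a hairpin loop.
#' @param p_min probability floor: ensemble entries below it are dropped from
#'   dot plots (the fold-envelope heuristic as a probability threshold).
#' @return an object of class `fold_params`.
#' @export
fold_params <- function(w_gc = 3, w_au = 2, w_gu = 1, stack_bonus = 1,
                        kT = 1, min_hairpin = 3, p_min = 0.001) {
  stopifnot(w_gc > 0, w_au > 0, w_gu > 0, stack_bonus >= 0, kT > 0,
            min_hairpin >= 3, p_min >= 0, p_min <= 1)
  structure(list(w_gc = w_gc, w_au = w_au, w_gu = w_gu,
                 stack_bonus = stack_bonus, kT = kT,
                 min_hairpin = as.integer(min_hairpin), p_min = p_min),
            class = "fold_params")
}

#' Base-pair probabilities from the equilibrium ensemble
#'
#' McCaskill-style inside/outside recursions over the simplified energy model:
#' `p[i, j]` is the Boltzmann probability that residues i and j pair, summed
#' over all nested structures.  Entries below `params$p_min` are dropped.
#'
#' @param seq RNA sequence (string; T accepted and mapped to U).
#' @param params a [fold_params()].
#' @return a [dot_plot()].
#' @export
partition_fold <- function(seq, params = fold_params()) {
  seq <- normalize_rna(seq)
  enc <- encode_seq(seq)
  P <- c_partition_fold(enc, params$w_gc, params$w_au, params$w_gu,
                        params$stack_bonus, params$kT, params$min_hairpin)
  dotplot_from_matrix(P, p_min = params$p_min)
}

#' Maximum-weight structure of a single sequence
#'
#' Nussinov-style dynamic program under the simplified model.  Ties are broken
#' deterministically toward the lexicographically smallest pair list (prefer
#' pairing the leftmost residue, with its smallest admissible partner).
#'
#' @inheritParams partition_fold
#' @return list with elements `structure` (dot-bracket), `energy`
#'   (non-positive; the negated structure weight) and `pairs`.
#' @export
mfe_fold <- function(seq, params = fold_params()) {
  seq <- normalize_rna(seq)
  enc <- encode_seq(seq)
  W <- c_pair_weight_matrix(enc, params$w_gc, params$w_au, params$w_gu)
  res <- c_mfe_fold(W, params$stack_bonus, params$min_hairpin)
  list(structure = pairs_dotbracket(res$pairs, nchar(seq)),
       energy = res$energy, pairs = res$pairs)
}

#' Maximum-weight consensus structure of an alignment
#'
#' Runs the same dynamic program over alignment columns.  A column pair
#' `(i, j)` is admissible when at least a fraction `rho` of the rows carry
#' complementary residues (G-C, A-U or G-U, gaps never complementary) at those
#' columns; its weight is the mean over all rows, rows without a complementary
#' combination contributing 0.
#'
#' @param alignment character vector of equal-length gapped rows (gap = `-`).
#' @param params a [fold_params()].
#' @param rho minimum fraction of rows that must support a column pair.
#' @return as [mfe_fold()], on column coordinates.
#' @export
mfe_fold_consensus <- function(alignment, params = fold_params(), rho = 0.5) {
  if (length(alignment) < 2) stop("need at least two alignment rows")
  if (length(unique(nchar(alignment))) != 1) {
    stop("ragged alignment: rows differ in length")
  }
  rows <- toupper(gsub("T", "U", alignment, fixed = TRUE))
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  n <- ncol(mat); k <- nrow(mat)
  code <- matrix(match(mat, c("A", "C", "G", "U")) - 1L, nrow = k)
  code[is.na(code)] <- -1L  # gaps and ambiguity codes never pair
  W <- matrix(0, n, n)
  wt <- function(a, b) {
    w <- numeric(length(a))
    w[(a == 2L & b == 1L) | (a == 1L & b == 2L)] <- params$w_gc
    w[(a == 0L & b == 3L) | (a == 3L & b == 0L)] <- params$w_au
    w[(a == 2L & b == 3L) | (a == 3L & b == 2L)] <- params$w_gu
    w
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      w_rows <- wt(code[, i], code[, j])
      frac <- mean(w_rows > 0)
      if (frac > 0 && frac >= rho) W[i, j] <- sum(w_rows) / k
    }
  }
  res <- c_mfe_fold(W, params$stack_bonus, params$min_hairpin)
  list(structure = pairs_dotbracket(res$pairs, n),
       energy = res$energy, pairs = res$pairs)
}
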