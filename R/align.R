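#' Alignment parameters
#'
#' Defaults are the tuned runtime parameters of the method: `theta = 0.5`
#' (weight of sequence identity vs unpaired-probability similarity in the
#' base-wise score), `kappa = 0.3` (weight of the sequence-level score vs the
#' dot-plot score in the final similarity), `gap_open = 1`, `gap_ext = 0.05`.
#' `temp` is the sampling-diversity temperature of the alignment partition
#' function (scores saturate around 1000 samples at `temp = 0.25`);
#' `n_samples = 0` disables stochastic backtracking, which is the recommended
#' speed/accuracy trade-off for large all-vs-all runs.
#'
#' @param theta weight in \[0, 1\] of sequence similarity vs similarity of
#'   unpaired probabilities.
#' @param kappa weight in \[0, 1\] of the sequence score vs the dot-plot score.
#' @param gap_open,gap_ext affine gap penalties; a gap of length L costs
#'   `gap_open + (L - 1) * gap_ext`.
#' @param temp sampling temperature (> 0).
#' @param n_samples number of stochastic backtracks (>= 0).
#' @param seed optional RNG seed for sampling.
#' @param free_end_gaps if `TRUE`, terminal gap runs cost nothing
#'   (semi-global alignment).
#' @param mismatch_score sequence-identity score of mismatched residues.
#' @param band_width optional alignment-envelope band: only cells with
#'   `|i * m/n - j| <= band_width` are explored (`NULL` = full matrix).
#' @return an object of class `align_params`.
#' @export
align_params <- function(theta = 0.5, kappa = 0.3, gap_open = 1,
                         gap_ext = 0.05, temp = 0.25, n_samples = 0,
                         seed = NULL, free_end_gaps = FALSE,
                         mismatch_score = 0, band_width = NULL) {
  stopifnot(theta >= 0, theta <= 1, kappa >= 0, kappa <= 1,
            gap_open >= 0, gap_ext >= 0, temp > 0, n_samples >= 0,
            mismatch_score >= 0, mismatch_score <= 1)
  structure(list(theta = theta, kappa = kappa, gap_open = gap_open,
                 gap_ext = gap_ext, temp = temp,
                 n_samples = as.integer(n_samples), seed = seed,
                 free_end_gaps = isTRUE(free_end_gaps),
                 mismatch_score = mismatch_score, band_width = band_width),
            class = "align_params")
}

#' Base-wise similarity score
#'
#' `sigma = theta * m(a, b) + (1 - theta) * (1 - |qa - qb|)` where
#' `m(a, b)` is 1 for identical residues and `mismatch_score` otherwise, and
#' `qa`, `qb` are the residues' unpaired probabilities.  Vectorised.
#'
#' @param a,b residues (single characters).
#' @param qa,qb unpaired probabilities in \[0, 1\].
#' @param params an [align_params()].
#' @return similarity in \[0, 1\].
#' @export
basewise_similarity <- function(a, qa, b, qb, params = align_params()) {
  m <- ifelse(a == b, 1, params$mismatch_score)
  params$theta * m + (1 - params$theta) * (1 - abs(qa - qb))
}

# full sigma matrix for two sequences; band constraint applied as -Inf
sigma_matrix <- function(x, qx, y, qy, params) {
  cx <- strsplit(x, "", fixed = TRUE)[[1]]
  cy <- strsplit(y, "", fixed = TRUE)[[1]]
  m <- outer(cx, cy, "==") * 1
  m[m == 0] <- params$mismatch_score
  sig <- params$theta * m + (1 - params$theta) * (1 - abs(outer(qx, qy, "-")))
  if (!is.null(params$band_width)) {
    n <- length(cx); mm <- length(cy)
    centre <- outer(seq_len(n) * mm / n, seq_len(mm), function(ci, j) abs(ci - j))
    sig[centre > params$band_width] <- -Inf
  }
  sig
}

events_to_path <- function(events, x_len, y_len) {
  op <- c("match", "gap_y", "gap_x")[events + 1L]
  i <- rep(NA_integer_, length(op)); j <- rep(NA_integer_, length(op))
  ii <- 0L; jj <- 0L
  for (k in seq_along(op)) {
    if (op[k] != "gap_x") { ii <- ii + 1L; i[k] <- ii }
    if (op[k] != "gap_y") { jj <- jj + 1L; j[k] <- jj }
  }
  stopifnot(ii == x_len, jj == y_len)
  tibble::tibble(op = op, i = i, j = j)
}

# raw affine-gap score of a path under sigma (terminal runs free when asked)
path_raw_score <- function(path, sigma, params) {
  op <- path$op
  s <- sum(sigma[cbind(path$i[op == "match"], path$j[op == "match"])])
  gap <- op != "match"
  if (!any(gap)) return(s)
  runs <- rle(op)
  drop_first <- params$free_end_gaps && runs$values[1] != "match"
  drop_last <- params$free_end_gaps && runs$values[length(runs$values)] != "match"
  keep <- which(runs$values != "match")
  if (drop_first) keep <- setdiff(keep, 1L)
  if (drop_last) keep <- setdiff(keep, length(runs$values))
  # gap runs of the two types interrupt each other: each maximal
  # single-type run is charged one opening
  for (k in keep) {
    s <- s - (params$gap_open + (runs$lengths[k] - 1) * params$gap_ext)
  }
  s
}

#' Optimal probabilistic string alignment
#'
#' Gotoh affine-gap maximisation of the summed base-wise similarity, the
#' "step 1" path of the aligner.  Ties are broken deterministically
#' (match > gap in Y > gap in X).
#'
#' @param x,y RNA sequences (strings).
#' @param dp_x,dp_y their [dot_plot()]s (used for unpaired profiles).
#' @param params an [align_params()].
#' @return list with `path` (tibble of `op`, `i`, `j`) and `score` (raw).
#' @export
string_align_optimal <- function(x, dp_x, y, dp_y, params = align_params()) {
  if (!nchar(x) || !nchar(y)) stop("empty sequence")
  sig <- sigma_matrix(x, unpaired_profile(dp_x), y, unpaired_profile(dp_y),
                      params)
  res <- c_align_optimal(sig, params$gap_open, params$gap_ext,
                         params$free_end_gaps)
  list(path = events_to_path(res$events, nchar(x), nchar(y)),
       score = res$score)
}

#' Partition function over string alignments
#'
#' Same recursions as [string_align_optimal()] with max replaced by
#' log-sum-exp over Boltzmann weights `exp(score / temp)`, yielding the
#' log-partition value over all global (or semi-global) alignment paths and
#' the three DP layers needed for stochastic backtracking.
#'
#' @inheritParams string_align_optimal
#' @return an object of class `partition_matrices`: list with `logZ`, layers
#'   `M`, `X`, `Y`, and the inputs needed to sample.
#' @export
string_align_partition <- function(x, dp_x, y, dp_y, params = align_params()) {
  if (!nchar(x) || !nchar(y)) stop("empty sequence")
  sig <- sigma_matrix(x, unpaired_profile(dp_x), y, unpaired_profile(dp_y),
                      params)
  res <- c_align_partition(sig, params$gap_open, params$gap_ext, params$temp,
                           params$free_end_gaps)
  structure(list(logZ = res$logZ, M = res$M, X = res$X, Y = res$Y,
                 sigma = sig, x_len = nchar(x), y_len = nchar(y),
                 params = params),
            class = "partition_matrices")
}

#' @export
print.partition_matrices <- function(x, ...) {
  cat("<partition_matrices>", x$x_len, "x", x$y_len,
      "logZ =", format(x$logZ), "\n")
  invisible(x)
}

#' Stochastic backtracking of alignment paths
#'
#' Draws `s` independent alignment paths, each with probability
#' `exp(score / temp) / Z`, by tracing the partition matrices backwards with
#' probabilistic layer choices.  Reproducible under a fixed seed.
#'
#' @param pm a [string_align_partition()] result.
#' @param s number of paths (`0` returns an empty list).
#' @param seed optional seed.
#' @param raw return bare event-code vectors (0 match, 1 gap in Y, 2 gap in
#'   X) instead of path tibbles; cheaper for very large `s`.
#' @return list of path tibbles (or event vectors with `raw = TRUE`).
#' @export
sample_paths <- function(pm, s, seed = NULL, raw = FALSE) {
  stopifnot(inherits(pm, "partition_matrices"), s >= 0)
  if (s == 0) return(list())
  p <- pm$params
  ev <- with_seed_if(seed,
    c_align_sample(pm$sigma, p$gap_open, p$gap_ext, p$temp, p$free_end_gaps,
                   as.integer(s)))
  if (raw) return(ev)
  lapply(ev, events_to_path, x_len = pm$x_len, y_len = pm$y_len)
}

#' Dot-plot superposition score of an alignment path
#'
#' Sums, over every two residue positions of X matched to two positions of Y,
#' the product of the corresponding base-pair probabilities:
#' `sum over matched (i, j), (i', j') with i < i' of pX(i, i') * pY(j, j')`.
#' This rewards paths that superimpose probable base pairs of the two
#' ensembles.
#'
#' @param path alignment path tibble.
#' @param dp_x,dp_y [dot_plot()]s of the two sequences.
#' @return non-negative raw score.
#' @export
dotplot_path_score <- function(path, dp_x, dp_y) {
  m <- path$op == "match"
  if (!any(m)) return(0)
  c_dotplot_path_score(path$i[m], path$j[m],
                       as.matrix(dp_x), as.matrix(dp_y))
}

dotplot_self_score <- function(dp) sum(dp$p^2)

#' Combined normalised similarity of an alignment path
#'
#' The sequence term is the raw affine-gap path score divided by
#' `sqrt(|X| * |Y|)` (so a self-alignment scores exactly 1); the dot-plot term
#' is [dotplot_path_score()] divided by the geometric mean of the two
#' self-superposition scores `sum(p^2)`.  The final similarity is
#' `clamp(kappa * seq + (1 - kappa) * dotplot, 0, 1)`.
#'
#' @inheritParams dotplot_path_score
#' @param x,y sequences.
#' @param params an [align_params()].
#' @return list with `seq_score_norm`, `dotplot_score_norm`, `score`.
#' @export
combined_score <- function(path, x, dp_x, y, dp_y, params = align_params()) {
  sig <- sigma_matrix(x, unpaired_profile(dp_x), y, unpaired_profile(dp_y),
                      params)
  seq_norm <- path_raw_score(path, sig, params) /
    sqrt(nchar(x) * nchar(y))
  self_x <- dotplot_self_score(dp_x)
  self_y <- dotplot_self_score(dp_y)
  dp_norm <- if (self_x > 0 && self_y > 0) {
    dotplot_path_score(path, dp_x, dp_y) / sqrt(self_x * self_y)
  } else {
    0
  }
  list(seq_score_norm = seq_norm, dotplot_score_norm = dp_norm,
       score = clamp01(params$kappa * seq_norm + (1 - params$kappa) * dp_norm))
}

#' Pairwise sequence identity along an alignment path
#'
#' 100 times the number of identical match columns over the number of columns
#' in which at least one sequence contributes a residue (i.e. all columns).
#' Full precision is kept; round only for display.
#'
#' @inheritParams combined_score
#' @return percentage.
#' @export
pid <- function(path, x, y) {
  cx <- strsplit(x, "", fixed = TRUE)[[1]]
  cy <- strsplit(y, "", fixed = TRUE)[[1]]
  m <- path$op == "match"
  ident <- sum(cx[path$i[m]] == cy[path$j[m]])
  100 * ident / nrow(path)
}

#' Ensemble-guided pairwise alignment
#'
#' The full two-step aligner.  Step 1 computes the optimal probabilistic
#' string alignment; step 2 (optional, `n_samples > 0`) draws suboptimal
#' paths from the alignment partition function and rescores every candidate
#' by the combined sequence + dot-plot similarity, returning the best.  With
#' `n_samples = 0` the optimal string path is scored directly — the
#' recommended mode for large all-vs-all runs.
#'
#' Scores are symmetric: the pair is canonically ordered by id before
#' alignment so `align_pair(x, y)` and `align_pair(y, x)` agree to 1e-9.
#'
#' @param x,y RNA sequences (strings).
#' @param dp_x,dp_y optional [dot_plot()]s; computed with [partition_fold()]
#'   at `fold_p` when missing.
#' @param params an [align_params()].
#' @param id_x,id_y sequence identifiers (used for canonical ordering).
#' @param fold_p [fold_params()] used when dot plots must be computed.
#' @return an object of class `dot_alignment`: the winning path plus
#'   `seq_score_norm`, `dotplot_score_norm`, `score`, `pid`,
#'   `n_samples_used`.
#' @export
align_pair <- function(x, y, dp_x = NULL, dp_y = NULL,
                       params = align_params(), id_x = "x", id_y = "y",
                       fold_p = fold_params()) {
  x <- normalize_rna(x); y <- normalize_rna(y)
  if (is.null(dp_x)) dp_x <- partition_fold(x, fold_p)
  if (is.null(dp_y)) dp_y <- partition_fold(y, fold_p)
  swapped <- id_y < id_x || (id_y == id_x && y < x)
  if (swapped) {
    tmp <- x; x <- y; y <- tmp
    tmpd <- dp_x; dp_x <- dp_y; dp_y <- tmpd
    tmpi <- id_x; id_x <- id_y; id_y <- tmpi
  }
  opt <- string_align_optimal(x, dp_x, y, dp_y, params)
  candidates <- list(opt$path)
  if (params$n_samples > 0) {
    pm <- string_align_partition(x, dp_x, y, dp_y, params)
    candidates <- c(candidates,
                    sample_paths(pm, params$n_samples, params$seed))
  }
  scores <- lapply(candidates, combined_score, x = x, dp_x = dp_x, y = y,
                   dp_y = dp_y, params = params)
  vals <- vapply(scores, `[[`, numeric(1), "score")
  best <- which.max(vals)  # ties resolve to the earliest: optimal path first
  path <- candidates[[best]]
  sc <- scores[[best]]
  out <- list(path = path, seq_score_norm = sc$seq_score_norm,
              dotplot_score_norm = sc$dotplot_score_norm, score = sc$score,
              pid = pid(path, x, y),
              n_samples_used = length(candidates) - 1L,
              id_x = id_x, id_y = id_y, x = x, y = y, swapped = swapped)
  class(out) <- "dot_alignment"
  out
}

#' @export
print.dot_alignment <- function(x, ...) {
  g <- aligned_strings(x)
  cat("<dot_alignment> ", x$id_x, " vs ", x$id_y, "\n", sep = "")
  cat("  score ", sprintf("%.4f", x$score),
      " (seq ", sprintf("%.4f", x$seq_score_norm),
      ", dotplot ", sprintf("%.4f", x$dotplot_score_norm), ")",
      "  PID ", sprintf("%.0f%%", x$pid), "\n", sep = "")
  cat("  ", g[1], "\n  ", g[2], "\n", sep = "")
  invisible(x)
}

#' Gapped strings of an alignment
#'
#' @param aln a `dot_alignment`.
#' @return character vector of the two gapped rows (in the canonical order
#'   used internally; `names()` carry the ids).
#' @export
aligned_strings <- function(aln) {
  cx <- strsplit(aln$x, "", fixed = TRUE)[[1]]
  cy <- strsplit(aln$y, "", fixed = TRUE)[[1]]
  gx <- ifelse(is.na(aln$path$i), "-", cx[aln$path$i])
  gy <- ifelse(is.na(aln$path$j), "-", cy[aln$path$j])
  stats::setNames(c(paste(gx, collapse = ""), paste(gy, collapse = "")),
                  c(aln$id_x, aln$id_y))
}

#' @export
tidy.dot_alignment <- function(x, ...) x$path

#' @export
glance.dot_alignment <- function(x, ...) {
  tibble::tibble(id_x = x$id_x, id_y = x$id_y, score = x$score,
                 seq_score_norm = x$seq_score_norm,
                 dotplot_score_norm = x$dotplot_score_norm, pid = x$pid,
                 n_samples_used = x$n_samples_used)
}
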