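#' Base-pair probability dot plot
#'
#' Sparse symmetric matrix of base-pair probabilities `p[i, j]` for one RNA
#' sequence, the ensemble representation consumed by the aligner.  Only the
#' upper triangle (`i < j`) is stored; entries below the probability floor
#' `p_min` are absent.
#'
#' @param length sequence length (positive integer).
#' @param i,j 1-based paired positions with `i < j`.
#' @param p base-pair probabilities in \[0, 1\].
#' @param p_min probability floor used when the plot was built.
#' @return an object of class `dot_plot`.
#' @export
dot_plot <- function(length, i = integer(), j = integer(), p = numeric(),
                     p_min = 0) {
  length <- as.integer(length)
  stopifnot(length >= 1, length(i) == length(j), length(i) == length(p))
  i <- as.integer(i); j <- as.integer(j); p <- as.numeric(p)
  if (any(i < 1 | j > length | i >= j)) {
    stop("dot plot indices must satisfy 1 <= i < j <= length")
  }
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  row_mass <- rowsum_pairs(length, i, j, p)
  if (any(row_mass > 1 + 1e-9)) {
    stop("per-base pair probability mass exceeds 1")
  }
  ord <- order(i, j)
  structure(
    list(length = length, i = i[ord], j = j[ord], p = p[ord],
         p_min = p_min),
    class = "dot_plot"
  )
}

rowsum_pairs <- function(n, i, j, p) {
  m <- numeric(n)
  if (length(i)) {
    ti <- tapply(p, i, sum); tj <- tapply(p, j, sum)
    m[as.integer(names(ti))] <- m[as.integer(names(ti))] + ti
    m[as.integer(names(tj))] <- m[as.integer(names(tj))] + tj
  }
  m
}

#' @export
print.dot_plot <- function(x, ...) {
  cat("<dot_plot> length", x$length, "with", length(x$i),
      "base pairs (p_min =", format(x$p_min), ")\n")
  invisible(x)
}

#' @method as.matrix dot_plot
#' @export
as.matrix.dot_plot <- function(x, ...) {
  m <- matrix(0, x$length, x$length)
  if (length(x$i)) {
    m[cbind(x$i, x$j)] <- x$p
    m[cbind(x$j, x$i)] <- x$p
  }
  m
}

# dense matrix -> dot_plot, applying the probability floor
dotplot_from_matrix <- function(m, p_min = 0) {
  n <- nrow(m)
  idx <- which(upper.tri(m) & m >= p_min & m > 0, arr.ind = TRUE)
  dot_plot(n, idx[, 1], idx[, 2], m[idx], p_min = p_min)
}

#' Unpaired-probability profile of a dot plot
#'
#' `q[i] = 1 - sum_j p[i, j]`, clamped into \[0, 1\].  This per-base profile
#' is what the base-wise similarity score compares between two sequences.
#'
#' @param dp a [dot_plot()].
#' @return numeric vector of length `dp$length`.
#' @export
unpaired_profile <- function(dp) {
  stopifnot(inherits(dp, "dot_plot"))
  clamp01(1 - rowsum_pairs(dp$length, dp$i, dp$j, dp$p))
}

#' Read a PostScript-dialect dot plot
#'
#' Parses the widely used PostScript dot-plot dialect in which ensemble
#' entries are lines `"i j v ubox"` with `v = sqrt(p)`; probabilities are
#' recovered by squaring.  `lbox` (single-structure) entries are ignored.
#'
#' @param path file path or connection.
#' @param length sequence length; if `NULL`, taken from a
#'   `/sequence` block if present, else from the largest index seen.
#' @param p_min floor recorded on the returned object.
#' @return a [dot_plot()].
#' @export
read_dotplot_ps <- function(path, length = NULL, p_min = 0) {
  lines <- readLines(path)
  if (is.null(length)) {
    seq_start <- grep("^/sequence", lines)
    if (length(seq_start) == 1) {
      chunk <- character()
      for (k in seq(seq_start + 1, base::length(lines))) {
        if (grepl("def", lines[k], fixed = TRUE)) break
        chunk <- c(chunk, gsub("[^A-Za-z]", "", lines[k]))
      }
      n_seq <- nchar(paste(chunk, collapse = ""))
      if (n_seq > 0) length <- n_seq
    }
  }
  ub <- grep("ubox\\s*$", lines)
  i <- integer(0); j <- integer(0); p <- numeric(0)
  for (k in ub) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (base::length(f) != 4) {
      stop("malformed dot plot line ", k, ": '", lines[k], "'")
    }
    ii <- suppressWarnings(as.integer(f[1]))
    jj <- suppressWarnings(as.integer(f[2]))
    vv <- suppressWarnings(as.numeric(f[3]))
    if (is.na(ii) || is.na(jj) || is.na(vv)) {
      stop("malformed dot plot line ", k, ": '", lines[k], "'")
    }
    i <- c(i, min(ii, jj)); j <- c(j, max(ii, jj)); p <- c(p, vv^2)
  }
  if (is.null(length)) length <- if (base::length(j)) max(j) else 1L
  dot_plot(length, i, j, pmin(1, p), p_min = p_min)
}

#' Write a dot plot in the PostScript dialect
#'
#' Emits a minimal file whose `ubox` entries store `sqrt(p)`, readable by
#' [read_dotplot_ps()] (round-trip lossless to 1e-12).
#'
#' @param dp a [dot_plot()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dotplot_ps <- function(dp, path) {
  stopifnot(inherits(dp, "dot_plot"))
  hdr <- c("%!PS-Adobe-3.0 EPSF-3.0",
           sprintf("%% dot plot, length %d", dp$length),
           "/DotplotData {")
  body <- sprintf("%d %d %.12g ubox", dp$i, dp$j, sqrt(dp$p))
  writeLines(c(hdr, body, "} def"), path)
  invisible(path)
}

#' Read/write dot plots as plain TSV
#'
#' Lossless plain-text interchange: a header line `# length <n> p_min <f>`
#' followed by `i<TAB>j<TAB>p` rows.
#'
#' @param path file path.
#' @return [read_dotplot_tsv()] returns a [dot_plot()].
#' @export
read_dotplot_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# length ", lines[1])) {
    stop("missing '# length' header in dot plot TSV")
  }
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  n <- as.integer(hdr[3])
  p_min <- if (length(hdr) >= 5) as.numeric(hdr[5]) else 0
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) return(dot_plot(n, p_min = p_min))
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  i <- as.integer(f[, 1]); j <- as.integer(f[, 2]); p <- as.numeric(f[, 3])
  if (anyNA(i) || anyNA(j) || anyNA(p)) stop("malformed dot plot TSV row")
  if (any(j > n)) stop("dot plot TSV index out of range")
  dot_plot(n, i, j, p, p_min = p_min)
}

#' @param dp a [dot_plot()].
#' @rdname read_dotplot_tsv
#' @export
write_dotplot_tsv <- function(dp, path) {
  stopifnot(inherits(dp, "dot_plot"))
  lines <- c(sprintf("# length %d p_min %.12g", dp$length, dp$p_min),
             sprintf("%d\t%d\t%.17g", dp$i, dp$j, dp$p))
  writeLines(lines, path)
  invisible(path)
}

#' @export
tidy.dot_plot <- function(x, ...) {
  tibble::tibble(i = x$i, j = x$j, p = x$p)
}
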