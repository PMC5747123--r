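#' Read a Stockholm alignment
#'
#' Minimal single-block or interleaved Stockholm reader.  The `#=GC SS_cons`
#' line, when present, is simplified from WUSS to plain dot-bracket: all
#' bracket families (`<>`, `()`, `[]`, `{}`) map to `()`, pseudoknot letters
#' and unpaired annotation characters (`-_,:.~`) map to `.` — i.e. the
#' structure is stripped of pseudoknots.
#'
#' @param path file path.
#' @return list with `alignment` (tibble `id`, `aln`) and `ss_cons`
#'   (dot-bracket string or `NULL`).
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1])) {
    stop("missing '# STOCKHOLM' header")
  }
  rows <- list()
  ss <- character(0)
  for (ln in lines[-1]) {
    if (grepl("^//", ln) || !nzchar(trimws(ln))) next
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      ss <- c(ss, f[length(f)])
    } else if (grepl("^#", ln)) {
      next
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) != 2) stop("malformed sequence line: '", ln, "'")
      rows[[f[1]]] <- paste0(rows[[f[1]]] %||% "", f[2])
    }
  }
  ss_cons <- if (length(ss)) wuss_to_dotbracket(paste(ss, collapse = ""))
             else NULL
  aln <- tibble::tibble(id = names(rows),
                        aln = unlist(rows, use.names = FALSE))
  if (nrow(aln) && length(unique(nchar(aln$aln))) != 1) {
    stop("ragged alignment in Stockholm file")
  }
  list(alignment = aln, ss_cons = ss_cons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simplify WUSS consensus annotation to dot-bracket
#'
#' @param wuss WUSS string.
#' @return dot-bracket string of the same length.
#' @export
wuss_to_dotbracket <- function(wuss) {
  chars <- strsplit(wuss, "", fixed = TRUE)[[1]]
  open <- chars %in% c("<", "(", "[", "{")
  close <- chars %in% c(">", ")", "]", "}")
  out <- rep(".", length(chars))
  out[open] <- "("
  out[close] <- ")"
  paste(out, collapse = "")
}

#' Write a Stockholm alignment
#'
#' @param alignment tibble with `id`, `aln`.
#' @param path output path.
#' @param ss_cons optional consensus structure line.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(alignment, path, ss_cons = NULL) {
  width <- max(nchar(alignment$id), nchar("#=GC SS_cons"))
  body <- sprintf(paste0("%-", width, "s %s"), alignment$id, alignment$aln)
  if (!is.null(ss_cons)) {
    body <- c(body, sprintf(paste0("%-", width, "s %s"),
                            "#=GC SS_cons", ss_cons))
  }
  writeLines(c("# STOCKHOLM 1.0", body, "//"), path)
  invisible(path)
}
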