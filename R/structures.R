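#' Parse a dot-bracket secondary structure into a pair table
#'
#' Only nested (pseudoknot-free) structures are supported.  Validates bracket
#' balance and the minimum hairpin size.
#'
#' @param db dot-bracket string using `(`, `)` and `.`.
#' @param min_hairpin smallest allowed number of unpaired residues enclosed by
#'   a pair; set to 0 to skip the check (e.g. for consensus columns).
#' @return integer matrix with columns `i`, `j` (1-based, `i < j`).
#' @export
dotbracket_pairs <- function(db, min_hairpin = 3) {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("(", ")", "."))) {
    stop("structure may only contain '(', ')' and '.'")
  }
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (!length(stack)) stop("unbalanced structure: unmatched ')' at ", k)
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (k - i - 1 < min_hairpin) {
        stop("hairpin loop smaller than ", min_hairpin, " at pair (",
             i, ",", k, ")")
      }
      pairs <- rbind(pairs, c(i, k))
    }
  }
  if (length(stack)) stop("unbalanced structure: unmatched '('")
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Build a dot-bracket string from a pair table
#'
#' @param pairs two-column matrix of 1-based pair positions.
#' @param n sequence length.
#' @return dot-bracket string.
#' @export
pairs_dotbracket <- function(pairs, n) {
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}
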