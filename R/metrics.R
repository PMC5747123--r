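#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; if any factor
#' under the root is zero the MCC is reported as 0.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return value in \[-1, 1\].
#' @export
mcc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fp + tn + fn == 0) stop("MCC undefined for all-zero counts")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Structural conservation index of an alignment
#'
#' `SCI = MFE_consensus / mean(MFE_single)`: the consensus folding energy of
#' the alignment divided by the average folding energy of its de-gapped rows,
#' folded independently under the same engine.  Values near 1 indicate that
#' the alignment supports a common structure as stable as the individual
#' ones; values near 0 indicate no conserved structure.  Comparable only
#' within one folding engine.
#'
#' @param alignment character vector of equal-length gapped rows.
#' @param params a [fold_params()].
#' @param rho consensus column-pair support threshold (see
#'   [mfe_fold_consensus()]).
#' @return the SCI (0 when the mean single energy is 0).
#' @export
sci <- function(alignment, params = fold_params(), rho = 0.5) {
  if (length(alignment) < 2) stop("need at least two alignment rows")
  cons <- mfe_fold_consensus(alignment, params, rho)$energy
  singles <- vapply(gsub("-", "", alignment, fixed = TRUE), function(s) {
    mfe_fold(s, params)$energy
  }, numeric(1))
  ms <- mean(singles)
  if (ms == 0) return(0)
  cons / ms
}

#' SCI ratio of predicted vs reference alignment
#'
#' `delta_sci = sci_predicted / sci_reference`.
#'
#' @param sci_pred,sci_ref structural conservation indices.
#' @return ratio.
#' @export
delta_sci <- function(sci_pred, sci_ref) {
  if (sci_ref == 0) stop("delta SCI undefined for zero reference SCI")
  sci_pred / sci_ref
}

#' Distance between two secondary structures
#'
#' `mode = "bp"`: size of the symmetric difference of the two pair sets
#' (structures must have equal length).  `mode = "tree"`: Zhang–Shasha tree
#' edit distance with unit costs between the rooted ordered forests whose
#' internal nodes are base pairs and whose leaves are unpaired residues.
#'
#' @param s1,s2 dot-bracket strings.
#' @param mode `"bp"` or `"tree"`.
#' @return non-negative distance.
#' @export
structure_distance <- function(s1, s2, mode = c("bp", "tree")) {
  mode <- match.arg(mode)
  if (mode == "bp") {
    if (nchar(s1) != nchar(s2)) {
      stop("bp mode requires equal-length structures")
    }
    p1 <- dotbracket_pairs(s1, min_hairpin = 0)
    p2 <- dotbracket_pairs(s2, min_hairpin = 0)
    k1 <- paste(p1[, 1], p1[, 2]); k2 <- paste(p2[, 1], p2[, 2])
    length(setdiff(k1, k2)) + length(setdiff(k2, k1))
  } else {
    tree_edit_distance(structure_forest(s1), structure_forest(s2))
  }
}

# rooted ordered forest of a structure: node labels "P" (pair) / "U"
# (unpaired leaf); encoded in postorder as required by Zhang-Shasha
structure_forest <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  # recursive descent; returns list of trees, each list(label, children)
  parse_forest <- function(lo, hi) {
    out <- list()
    k <- lo
    while (k <= hi) {
      if (chars[k] == ".") {
        out[[length(out) + 1]] <- list(label = "U", children = list())
        k <- k + 1
      } else if (chars[k] == "(") {
        depth <- 0
        m <- k
        repeat {
          if (chars[m] == "(") depth <- depth + 1
          if (chars[m] == ")") depth <- depth - 1
          if (depth == 0) break
          m <- m + 1
          if (m > hi) stop("unbalanced structure")
        }
        out[[length(out) + 1]] <-
          list(label = "P", children = parse_forest(k + 1, m - 1))
        k <- m + 1
      } else {
        stop("unbalanced structure: unexpected ')'")
      }
    }
    out
  }
  if (!nchar(db)) return(list())
  # validate balance up front for a clear error
  dotbracket_pairs(db, min_hairpin = 0)
  parse_forest(1, length(chars))
}

# Zhang-Shasha ordered tree/forest edit distance, unit costs.
# Forests are handled by attaching a virtual root with relabel cost 0.
tree_edit_distance <- function(f1, f2) {
  t1 <- list(label = "R", children = f1)
  t2 <- list(label = "R", children = f2)
  post <- function(tree) {
    labels <- character(0); lml <- integer(0)
    walk <- function(node) {
      first_leaf <- NA_integer_
      for (ch in node$children) {
        fl <- walk(ch)
        if (is.na(first_leaf)) first_leaf <- fl
      }
      labels[length(labels) + 1] <<- node$label
      idx <- length(labels)
      if (is.na(first_leaf)) first_leaf <- idx
      lml[idx] <<- first_leaf
      first_leaf
    }
    walk(tree)
    keyroots <- which(vapply(seq_along(labels), function(k) {
      !any(lml[seq_along(lml) > k] == lml[k])
    }, logical(1)))
    list(labels = labels, lml = lml, keyroots = keyroots)
  }
  a <- post(t1); b <- post(t2)
  n <- length(a$labels); m <- length(b$labels)
  td <- matrix(0, n, m)
  cost <- function(la, lb) if (la == lb) 0 else 1
  for (ki in a$keyroots) {
    for (kj in b$keyroots) {
      li <- a$lml[ki]; lj <- b$lml[kj]
      fd <- matrix(0, ki - li + 2, kj - lj + 2)
      for (x in seq(2, ki - li + 2)) fd[x, 1] <- fd[x - 1, 1] + 1
      for (y in seq(2, kj - lj + 2)) fd[1, y] <- fd[1, y - 1] + 1
      for (x in seq(2, ki - li + 2)) {
        i1 <- li + x - 2
        for (y in seq(2, kj - lj + 2)) {
          j1 <- lj + y - 2
          if (a$lml[i1] == li && b$lml[j1] == lj) {
            fd[x, y] <- min(fd[x - 1, y] + 1, fd[x, y - 1] + 1,
                            fd[x - 1, y - 1] +
                              cost(a$labels[i1], b$labels[j1]))
            td[i1, j1] <- fd[x, y]
          } else {
            fd[x, y] <- min(fd[x - 1, y] + 1, fd[x, y - 1] + 1,
                            fd[a$lml[i1] - li + 1, b$lml[j1] - lj + 1] +
                              td[i1, j1])
          }
        }
      }
    }
  }
  td[n, m]
}

#' Rank-based ROC AUC of a similarity matrix against binary labels
#'
#' Uses each unordered off-diagonal pair once (the upper triangle) and the
#' Mann–Whitney statistic with ties given half credit.
#'
#' @param S symmetric similarity matrix.
#' @param L binary label matrix of the same shape (1 = same family).
#' @return AUC in \[0, 1\].
#' @export
roc_auc_matrix <- function(S, L) {
  stopifnot(all(dim(S) == dim(L)))
  ut <- upper.tri(S)
  roc_auc(S[ut], L[ut])
}

#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @rdname roc_auc_matrix
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: labels are all one class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary same-family label matrix
#'
#' @param labels character vector of family labels, one per item.
#' @return 0/1 matrix with unit diagonal.
#' @export
binary_label_matrix <- function(labels) {
  m <- outer(labels, labels, "==") * 1L
  dimnames(m) <- list(names(labels), names(labels))
  m
}

#' Cluster-level confusion counts
#'
#' Scores an extracted clustering against known family labels where control
#' items carry the label `control`.  Per cluster: a unique dominant real
#' family contributes its member count to TP and the remaining members
#' (other families and clustered controls) to FP; a cluster with tied
#' dominant families, or dominated by controls, contributes 1 FP (the
#' cluster itself) — or all its members when `fp_counts_members = TRUE`.
#' FN counts family-labelled items left unclustered; TN counts controls left
#' unclustered.
#'
#' @param clusters list of character vectors of item ids (a `cluster_set`
#'   works directly).
#' @param labels named character vector mapping every item id to its family
#'   or to `control_label`.
#' @param control_label label marking negative controls.
#' @param fp_counts_members charge all members of a degenerate cluster as FP
#'   instead of 1 per cluster.
#' @return tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
cluster_confusion <- function(clusters, labels, control_label = "control",
                              fp_counts_members = FALSE) {
  if (inherits(clusters, "cluster_set")) clusters <- clusters$clusters
  items <- names(labels)
  clustered <- unlist(clusters, use.names = FALSE)
  if (!all(clustered %in% items)) {
    stop("unlabelled item(s): ",
         paste(setdiff(clustered, items), collapse = ", "))
  }
  tp <- 0L; fp <- 0L
  for (cl in clusters) {
    labs <- labels[cl]
    fam <- labs[labs != control_label]
    n_ctrl <- sum(labs == control_label)
    if (length(fam)) {
      cnt <- sort(table(fam), decreasing = TRUE)
      max_fam <- cnt[1]
      tie <- sum(cnt == max_fam) > 1
    } else {
      max_fam <- 0L; tie <- FALSE
    }
    if (n_ctrl > max_fam || tie || max_fam == 0) {
      fp <- fp + if (fp_counts_members) length(cl) else 1L
    } else {
      tp <- tp + as.integer(max_fam)
      fp <- fp + length(cl) - as.integer(max_fam)
    }
  }
  un <- setdiff(items, clustered)
  fn <- sum(labels[un] != control_label)
  tn <- sum(labels[un] == control_label)
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Clustering performance metrics from confusion counts
#'
#' Sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, false
#' positive rate `1 - specificity`, precision `TP/(TP+FP)` and accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`.  Metrics with a zero denominator are `NA`.
#'
#' @param counts tibble or list with `tp`, `fp`, `tn`, `fn`.
#' @return one-row tibble of the five metrics.
#' @export
cluster_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  spec <- safe(tn, tn + fp)
  tibble::tibble(
    sensitivity = safe(tp, tp + fn),
    specificity = spec,
    fpr = if (is.na(spec)) NA_real_ else 1 - spec,
    precision = safe(tp, tp + fp),
    accuracy = safe(tp + tn, tp + tn + fp + fn)
  )
}
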