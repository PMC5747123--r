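# Independent brute-force oracles used across the suite.  These deliberately
# re-derive every quantity from first principles (exhaustive enumeration,
# naive recursions) and share no code with the package internals they check.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# pair weight table mirroring the simplified energy model, derived from the
# model definition (not from package code)
oracle_pair_weight <- function(a, b, fp) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(fp$w_gc)
  if (key %in% c("AU", "UA")) return(fp$w_au)
  if (key %in% c("GU", "UG")) return(fp$w_gu)
  0
}

# enumerate every nested structure (as a pair matrix) over a sequence,
# honouring canonical pairing and the hairpin constraint
oracle_enum_structures <- function(seq, fp) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    W[i, j] <- oracle_pair_weight(chars[i], chars[j], fp)
  }
  res <- list()
  rec <- function(pairs, last_i, last_j) {
    res[[length(res) + 1]] <<- pairs
    used <- as.vector(pairs)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j - i - 1 < fp$min_hairpin) next
      if (i %in% used || j %in% used) next
      if (W[i, j] == 0) next
      if (i < last_i || (i == last_i && j <= last_j)) next
      crossing <- FALSE
      if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
        a <- pairs[k, 1]; b <- pairs[k, 2]
        if ((i < a && a < j && j < b) || (a < i && i < b && b < j)) {
          crossing <- TRUE; break
        }
      }
      if (!crossing) rec(rbind(pairs, c(i, j)), i, j)
    }
  }
  rec(matrix(integer(0), ncol = 2), 0, 0)
  list(structures = res, W = W)
}

oracle_structure_weight <- function(pairs, W, stack_bonus) {
  if (!nrow(pairs)) return(0)
  w <- sum(W[pairs])
  key <- paste(pairs[, 1], pairs[, 2])
  w + stack_bonus * sum(paste(pairs[, 1] + 1, pairs[, 2] - 1) %in% key)
}

# exact base-pair probabilities by full enumeration (n <= 12)
oracle_pair_probs <- function(seq, fp) {
  n <- nchar(seq)
  en <- oracle_enum_structures(seq, fp)
  wts <- vapply(en$structures, oracle_structure_weight, numeric(1),
                W = en$W, stack_bonus = fp$stack_bonus)
  bz <- exp(wts / fp$kT)
  P <- matrix(0, n, n)
  for (k in seq_along(en$structures)) {
    p <- en$structures[[k]]
    if (nrow(p)) P[p] <- P[p] + bz[k]
  }
  P <- P / sum(bz)
  P + t(P)
}

oracle_best_weight <- function(seq, fp) {
  en <- oracle_enum_structures(seq, fp)
  max(vapply(en$structures, oracle_structure_weight, numeric(1),
             W = en$W, stack_bonus = fp$stack_bonus))
}

# ---- alignment path oracles ------------------------------------------------

# all global alignment event sequences (0 = match, 1 = gap in Y consuming x,
# 2 = gap in X consuming y)
oracle_enum_paths <- function(n, m) {
  res <- list()
  rec <- function(i, j, ev) {
    if (i == n && j == m) { res[[length(res) + 1]] <<- ev; return() }
    if (i < n && j < m) rec(i + 1, j + 1, c(ev, 0L))
    if (i < n) rec(i + 1, j, c(ev, 1L))
    if (j < m) rec(i, j + 1, c(ev, 2L))
  }
  rec(0L, 0L, integer(0))
  res
}

# affine-gap score of one event sequence; with free ends the leading and
# trailing single-type gap runs cost nothing
oracle_path_score <- function(ev, sigma, go, ge, free_end = FALSE) {
  i <- 0; j <- 0; s <- 0
  for (k in seq_along(ev)) {
    if (ev[k] == 0L) { i <- i + 1; j <- j + 1; s <- s + sigma[i, j] }
    else if (ev[k] == 1L) i <- i + 1 else j <- j + 1
  }
  runs <- rle(ev)
  idx <- which(runs$values != 0L)
  if (free_end && length(runs$values)) {
    if (runs$values[1] != 0L) idx <- setdiff(idx, 1)
    if (runs$values[length(runs$values)] != 0L) {
      idx <- setdiff(idx, length(runs$values))
    }
  }
  for (k in idx) s <- s - go - (runs$lengths[k] - 1) * ge
  s
}

# semi-global path space: drop paths whose terminal gap runs mix both types
oracle_mixed_terminal <- function(ev) {
  runs <- rle(ev != 0L)
  lead <- if (runs$values[1]) seq_len(runs$lengths[1]) else integer(0)
  tl <- if (runs$values[length(runs$values)]) {
    seq(length(ev) - runs$lengths[length(runs$values)] + 1, length(ev))
  } else {
    integer(0)
  }
  (length(unique(ev[lead])) > 1) || (length(unique(ev[tl])) > 1)
}

# base-wise similarity recomputed from its definition
oracle_sigma <- function(x, qx, y, qy, theta, mismatch = 0) {
  cx <- strsplit(x, "", fixed = TRUE)[[1]]
  cy <- strsplit(y, "", fixed = TRUE)[[1]]
  m <- outer(cx, cy, function(a, b) ifelse(a == b, 1, mismatch))
  theta * m + (1 - theta) * (1 - abs(outer(qx, qy, "-")))
}

# O(k^2) double loop over matched columns, straight from the definition
oracle_dotplot_score <- function(path, mx, my) {
  mcols <- which(path$op == "match")
  s <- 0
  if (length(mcols) < 2) return(0)
  for (a in seq_len(length(mcols) - 1)) {
    for (b in seq(a + 1, length(mcols))) {
      s <- s + mx[path$i[mcols[a]], path$i[mcols[b]]] *
        my[path$j[mcols[a]], path$j[mcols[b]]]
    }
  }
  s
}

# ---- clustering oracles ----------------------------------------------------

# textbook DBSCAN on a distance matrix; minPts counts the point itself
oracle_dbscan <- function(D, eps, min_pts) {
  n <- nrow(D)
  core <- vapply(seq_len(n), function(i) sum(D[i, ] <= eps) >= min_pts,
                 logical(1))
  lab <- rep(0L, n); cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cur <- cur + 1L
    queue <- i; lab[i] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      if (!core[p]) next
      for (q in which(D[p, ] <= eps)) {
        if (lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  list(labels = lab, core = core)
}

# random distance matrix with planted clumps, for OPTICS fuzz tests
random_clumped_dist <- function(n, k = sample(2:4, 1)) {
  centers <- matrix(stats::runif(2 * k, 0, 10), ncol = 2)
  assign <- sample(seq_len(k), n, replace = TRUE)
  pts <- matrix(stats::rnorm(2 * n, sd = 0.3), ncol = 2) + centers[assign, ]
  D <- as.matrix(stats::dist(pts))
  D / max(D)
}

# naive recursive ordered-forest edit distance (unit costs); exponential but
# exact on small inputs.  Forests are lists of list(label, children).
oracle_forest_dist <- function(f1, f2) {
  sz <- function(f) {
    if (!length(f)) return(0)
    sum(vapply(f, function(t) 1 + sz(t$children), numeric(1)))
  }
  memo <- new.env()
  keyof <- function(f) paste(deparse(f), collapse = "")
  fd <- function(f1, f2) {
    if (!length(f1)) return(sz(f2))
    if (!length(f2)) return(sz(f1))
    key <- paste(keyof(f1), "|", keyof(f2))
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- f1[[length(f1)]]; w <- f2[[length(f2)]]
    # delete v: promote its children
    f1_del <- c(f1[-length(f1)], v$children)
    f2_del <- c(f2[-length(f2)], w$children)
    d <- min(fd(f1_del, f2) + 1,
             fd(f1, f2_del) + 1,
             fd(v$children, w$children) +
               fd(f1[-length(f1)], f2[-length(f2)]) +
               (if (v$label == w$label) 0 else 1))
    memo[[key]] <- d
    d
  }
  fd(f1, f2)
}

# all permutations of a tiny sequence preserving dinucleotide counts and the
# terminal residues (for shuffle-uniformity checks)
oracle_valid_shuffles <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v)) {
      rest <- perms(v[-k])
      for (r in rest) out[[length(out) + 1]] <- c(v[k], r)
    }
    out
  }
  dinu <- function(ch) sort(paste0(ch[-length(ch)], ch[-1]))
  target <- dinu(chars)
  cand <- perms(chars[-c(1, n)])
  res <- character(0)
  for (p in cand) {
    full <- c(chars[1], p, chars[n])
    if (identical(dinu(full), target)) {
      res <- c(res, paste(full, collapse = ""))
    }
  }
  unique(res)
}
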