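#' OPTICS clustering parameters
#'
#' Defaults follow the tuned clustering regime: the whole normalised distance
#' range as radius (`eps = 1`), a minimum of four points per cluster
#' (`min_pts = 4`) and a steepness threshold `xi = 0.006`, extracting only the
#' most specific (leaf) clusters.
#'
#' @param eps radius cap on reachability computation.
#' @param min_pts minimum number of points of a cluster / density scale
#'   (counts the point itself).
#' @param xi steepness threshold in (0, 1).
#' @param minimum_only return only leaf clusters (no nested parents).
#' @return an object of class `cluster_params`.
#' @export
cluster_params <- function(eps = 1, min_pts = 4, xi = 0.006,
                           minimum_only = TRUE) {
  stopifnot(eps > 0, min_pts >= 2, xi > 0, xi < 1)
  structure(list(eps = eps, min_pts = as.integer(min_pts), xi = xi,
                 minimum_only = isTRUE(minimum_only)),
            class = "cluster_params")
}

#' All-vs-all pairwise similarity matrix
#'
#' Runs [align_pair()] over every unordered pair.  Embarrassingly parallel:
#' the result is identical for any `n_jobs` (each pair's sampling stream, when
#' `params$n_samples > 0`, is seeded from the pair ids and the base seed).
#'
#' @param seqs tibble with columns `id` and `seq`; ids must be unique.
#' @param dotplots optional named list of [dot_plot()]s keyed by id; computed
#'   when missing.
#' @param params an [align_params()].
#' @param n_jobs number of worker processes (forked; 1 = serial).
#' @param fold_p [fold_params()] for missing dot plots.
#' @return symmetric `score_matrix` with unit diagonal and ids as dimnames.
#' @export
all_vs_all <- function(seqs, dotplots = NULL, params = align_params(),
                       n_jobs = 1, fold_p = fold_params()) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  ids <- seqs$id
  if (anyDuplicated(ids)) stop("duplicate sequence id(s)")
  n <- length(ids)
  if (is.null(dotplots)) {
    dotplots <- lapply(seqs$seq, partition_fold, params = fold_p)
    names(dotplots) <- ids
  }
  stopifnot(length(dotplots) == n)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  score_one <- function(k) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    p <- params
    if (p$n_samples > 0) {
      base <- if (is.null(p$seed)) 0L else as.integer(p$seed)
      p$seed <- (base + 7919L * a + 104729L * b) %% 2147483647L
    }
    align_pair(seqs$seq[a], seqs$seq[b], dotplots[[a]], dotplots[[b]],
               params = p, id_x = ids[a], id_y = ids[b])$score
  }
  ks <- seq_len(nrow(pairs))
  vals <- if (n_jobs > 1) {
    unlist(parallel::mclapply(ks, score_one, mc.cores = n_jobs))
  } else {
    vapply(ks, score_one, numeric(1))
  }
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  S[pairs] <- vals
  S <- S + t(S)
  diag(S) <- 1
  class(S) <- c("score_matrix", class(S))
  S
}

#' Convert a similarity matrix to a dissimilarity matrix
#'
#' Inverts and rescales the off-diagonal similarities so the largest becomes
#' distance 0 and the smallest distance 1; the diagonal is forced to 0.
#'
#' @param S symmetric similarity matrix.
#' @param no_rescale if `TRUE`, use `1 - s` without min/max rescaling (the
#'   fallback for degenerate inputs).
#' @return symmetric `dissimilarity_matrix` in \[0, 1\].
#' @export
to_dissimilarity <- function(S, no_rescale = FALSE) {
  S <- unclass(S)
  off <- S[upper.tri(S) | lower.tri(S)]
  if (no_rescale) {
    D <- 1 - S
  } else {
    lo <- min(off); hi <- max(off)
    if (hi == lo) {
      stop("degenerate score matrix (all off-diagonal scores equal); ",
           "use no_rescale = TRUE for the raw 1 - s transform")
    }
    D <- (hi - S) / (hi - lo)
  }
  diag(D) <- 0
  class(D) <- c("dissimilarity_matrix", class(D))
  D
}

#' OPTICS ordering on a precomputed dissimilarity matrix
#'
#' Standard OPTICS with the core distance of a point defined as the distance
#' to its `min_pts`-th nearest neighbour (the point itself included, matching
#' DBSCAN's `|N_eps(p)| >= min_pts`), `eps` as radius cap, a deterministic
#' start at the lowest-index unprocessed point and priority ties broken by
#' index.
#'
#' @param D symmetric dissimilarity matrix (zero diagonal).
#' @param params a [cluster_params()].
#' @return an object of class `reachability`: `order` (visit order, indices),
#'   `reachability` (in visit order; `Inf` for the start of each density
#'   component), `coredist`, `predecessor` (in visit order), `ids`.
#' @export
optics_order <- function(D, params = cluster_params()) {
  D <- unclass(D)
  n <- nrow(D)
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  eps <- params$eps; min_pts <- params$min_pts
  cd <- vapply(seq_len(n), function(i) {
    s <- sort(D[i, ], partial = min(min_pts, n))[min(min_pts, n)]
    if (min_pts > n || s > eps) Inf else s
  }, numeric(1))
  processed <- logical(n)
  visit <- integer(0)
  reach_of <- rep(Inf, n)      # by item index
  pred_of <- rep(NA_integer_, n)
  seeds <- rep(Inf, n)         # tentative reachability; Inf = not queued
  in_seeds <- logical(n)
  update <- function(p) {
    if (!is.finite(cd[p])) return()
    nb <- which(!processed & D[p, ] <= eps)
    newr <- pmax(cd[p], D[p, nb])
    better <- newr < seeds[nb]
    if (any(better)) {
      seeds[nb[better]] <<- newr[better]
      pred_of[nb[better]] <<- p
      in_seeds[nb[better]] <<- TRUE
    }
  }
  for (start in seq_len(n)) {
    if (processed[start]) next
    processed[start] <- TRUE
    visit <- c(visit, start)
    update(start)
    repeat {
      cand <- which(in_seeds & !processed)
      if (!length(cand)) break
      o <- cand[which.min(seeds[cand])]  # which.min: ties -> lowest index
      processed[o] <- TRUE
      in_seeds[o] <- FALSE
      reach_of[o] <- seeds[o]
      visit <- c(visit, o)
      update(o)
    }
  }
  structure(list(order = visit,
                 reachability = reach_of[visit],
                 coredist = cd[visit],
                 predecessor = pred_of[visit],
                 ids = ids[visit],
                 params = params),
            class = "reachability")
}

#' @export
print.reachability <- function(x, ...) {
  fin <- is.finite(x$reachability)
  cat("<reachability> ", length(x$order), " points, ",
      sum(!fin), " infinite; finite range [",
      if (any(fin)) sprintf("%.3f, %.3f", min(x$reachability[fin]),
                            max(x$reachability[fin])) else "",
      "]\n", sep = "")
  invisible(x)
}

#' @export
tidy.reachability <- function(x, ...) {
  tibble::tibble(position = seq_along(x$order), item = x$order,
                 id = x$ids, reachability = x$reachability,
                 coredist = x$coredist)
}

#' Extract DBSCAN-equivalent clusters by thresholding reachability
#'
#' Scanning the OPTICS ordering with a threshold `eps'` reproduces the
#' clustering DBSCAN would produce at `(eps', min_pts)` (border points are
#' attached to the cluster that reached them first).
#'
#' @param r a [optics_order()] result.
#' @param eps_cluster threshold on reachability.
#' @return integer vector of cluster labels in item order (0 = noise).
#' @export
extract_dbscan <- function(r, eps_cluster) {
  n <- length(r$order)
  lab_visit <- integer(n)
  cur <- 0L
  for (k in seq_len(n)) {
    if (r$reachability[k] > eps_cluster) {
      if (is.finite(r$coredist[k]) && r$coredist[k] <= eps_cluster) {
        cur <- cur + 1L
        lab_visit[k] <- cur
      } else {
        lab_visit[k] <- 0L
      }
    } else {
      lab_visit[k] <- cur
    }
  }
  out <- integer(n)
  out[r$order] <- lab_visit
  out
}

#' Xi-steepness cluster extraction
#'
#' Extracts clusters as reachability valleys bounded by xi-steep down and
#' xi-steep up areas, following the original steep-area algorithm, with
#' predecessor correction applied to trailing points (as modern
#' implementations do).  Clusters smaller than `min_pts` and the trivial
#' cluster spanning the whole ordering are discarded; with `minimum_only`
#' only leaf (most specific) clusters are returned.
#'
#' @param r a [optics_order()] result.
#' @param params a [cluster_params()] (`xi`, `min_pts`, `minimum_only`).
#' @return an object of class `cluster_set`: list of character-id clusters
#'   plus the noise set.
#' @export
extract_xi <- function(r, params = r$params) {
  n <- length(r$order)
  reach <- c(r$reachability, Inf)  # implicit infinite point past the end
  ixi <- 1 - params$xi
  sd_pt <- function(k) reach[k] * ixi >= reach[k + 1]
  su_pt <- function(k) reach[k] <= reach[k + 1] * ixi
  # maximal steep area starting at `start`; allows up to min_pts consecutive
  # non-steep points while monotonicity holds
  extend_area <- function(start, steep, mono) {
    end <- start; idx <- start; non_steep <- 0
    while (idx < n) {
      nxt <- idx + 1
      if (!mono(nxt)) break
      if (steep(nxt)) {
        end <- nxt; non_steep <- 0
      } else {
        non_steep <- non_steep + 1
        if (non_steep > params$min_pts) break
      }
      idx <- nxt
    }
    end
  }
  sdas <- list()   # pending steep-down areas: start, end, maximum, mib
  ivs <- list()    # extracted cluster index intervals
  index <- 1
  mib <- 0
  filter_sdas <- function(sdas, mib) {
    keep <- list()
    for (d in sdas) {
      if (d$maximum * ixi >= mib || (is.infinite(d$maximum) &&
                                     is.infinite(mib))) {
        d$mib <- max(d$mib, mib)
        keep[[length(keep) + 1]] <- d
      }
    }
    keep
  }
  while (index <= n) {
    mib <- max(mib, reach[index])
    if (sd_pt(index)) {
      sdas <- filter_sdas(sdas, mib)
      end <- extend_area(index,
                         steep = sd_pt,
                         mono = function(k) reach[k + 1] <= reach[k])
      sdas[[length(sdas) + 1]] <-
        list(start = index, end = end, maximum = reach[index], mib = 0)
      index <- end + 1
      mib <- if (index <= n) reach[index] else 0
    } else if (su_pt(index)) {
      sdas <- filter_sdas(sdas, mib)
      u_start <- index
      u_end <- extend_area(index,
                           steep = su_pt,
                           mono = function(k) reach[k + 1] >= reach[k])
      esucc <- reach[u_end + 1]
      for (d in sdas) {
        # the maximum between the areas must be deep relative to both sides
        if (d$mib > min(d$maximum, esucc) * ixi) next
        if (d$maximum * ixi >= esucc && !is.infinite(esucc)) {
          # the down start towers over the up end: move the start right,
          # to the last point still above the up end's level
          cs <- d$start
          while (cs < d$end && reach[cs + 1] > esucc) cs <- cs + 1
          ce <- u_end
        } else if (esucc * ixi >= d$maximum) {
          # the up end towers over the down start: pull the end left
          cs <- d$start
          ce <- u_end
          while (ce > u_start && reach[ce] > d$maximum) ce <- ce - 1
        } else {
          cs <- d$start
          ce <- u_end
        }
        # predecessor correction: trailing points reached from outside the
        # cluster are peeled off
        repeat {
          if (ce <= cs) break
          members <- r$order[cs:ce]
          pr <- r$predecessor[ce]
          if (!is.na(pr) && pr %in% members[-length(members)]) break
          ce <- ce - 1
        }
        if (ce - cs + 1 < params$min_pts) next
        if (cs <= 1 && ce >= n) next  # trivial root covering everything
        ivs[[length(ivs) + 1]] <- list(start = cs, end = ce)
      }
      index <- u_end + 1
      mib <- if (index <= n) reach[index] else 0
    } else {
      index <- index + 1
    }
  }
  if (params$minimum_only && length(ivs) > 1) {
    keep <- vapply(seq_along(ivs), function(a) {
      ca <- ivs[[a]]
      !any(vapply(seq_along(ivs), function(b) {
        if (a == b) return(FALSE)
        cb <- ivs[[b]]
        cb$start >= ca$start && cb$end <= ca$end &&
          (cb$end - cb$start < ca$end - ca$start)
      }, logical(1)))
    }, logical(1))
    ivs <- ivs[keep]
  }
  key <- vapply(ivs, function(cl) paste(cl$start, cl$end), character(1))
  ivs <- ivs[!duplicated(key)]
  member_sets <- lapply(ivs, function(cl) r$ids[cl$start:cl$end])
  noise <- setdiff(r$ids, unlist(member_sets))
  structure(list(clusters = member_sets, noise = noise, intervals = ivs),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> ", length(x$clusters), " clusters, ",
      length(x$noise), " noise points\n", sep = "")
  for (k in seq_along(x$clusters)) {
    cat("  [", k, "] n=", length(x$clusters[[k]]), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.cluster_set <- function(x, ...) {
  if (!length(x$clusters)) {
    return(tibble::tibble(id = x$noise, cluster = 0L))
  }
  dplyr::bind_rows(
    purrr::imap(x$clusters,
                ~ tibble::tibble(id = .x, cluster = .y)),
    tibble::tibble(id = x$noise, cluster = 0L)
  )
}

#' @export
glance.cluster_set <- function(x, ...) {
  tibble::tibble(n_clusters = length(x$clusters),
                 n_clustered = length(unlist(x$clusters)),
                 n_noise = length(x$noise))
}
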