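#' Random nested secondary structure
#'
#' Draws a random pseudoknot-free structure with stems of 3–8 pairs, hairpin
#' loops of at least 3 residues and a total paired fraction between 40 and
#' 70 % — the regime typical of structured ncRNA families.  Deterministic
#' under `seed`.
#'
#' @param length structure length (>= 10).
#' @param seed optional RNG seed.
#' @param paired_range acceptable (lo, hi) paired fraction.
#' @param max_tries rejection-sampling bound.
#' @return dot-bracket string.
#' @export
random_structure <- function(length, seed = NULL,
                             paired_range = c(0.4, 0.7), max_tries = 200) {
  stopifnot(length >= 10)
  with_seed_if(seed, {
    for (t in seq_len(max_tries)) {
      db <- strsplit(grow_region(length, depth = 0), "")[[1]]
      frac <- mean(db != ".")
      if (frac >= paired_range[1] && frac <= paired_range[2]) {
        return(paste(db, collapse = ""))
      }
    }
    stop("could not draw a structure with paired fraction in [",
         paired_range[1], ", ", paired_range[2], "] at length ", length)
  })
}

# recursive generator: either an unpaired run, or pad-stem-loop-pad
grow_region <- function(len, depth) {
  if (len < 11 || (depth > 0 && stats::runif(1) < 0.15)) {
    return(strrep(".", len))
  }
  stem <- sample(3:8, 1)
  stem <- min(stem, (len - 3) %/% 2)
  if (stem < 3) return(strrep(".", len))
  room <- len - 2 * stem
  pad_l <- sample(0:min(3, room - 3), 1)
  pad_r <- sample(0:min(3, room - 3 - pad_l), 1)
  inner_len <- room - pad_l - pad_r
  # multiloop: occasionally split the interior into two stems side by side
  inner <- if (inner_len >= 24 && stats::runif(1) < 0.5) {
    cut <- sample(11:(inner_len - 11), 1)
    paste0(grow_region(cut, depth + 1), grow_region(inner_len - cut, depth + 1))
  } else {
    grow_region(inner_len, depth + 1)
  }
  paste0(strrep(".", pad_l), strrep("(", stem), inner, strrep(")", stem),
         strrep(".", pad_r))
}

#' Specification of a synthetic structure family
#'
#' Describes one family for [sample_family()]: a shared consensus structure,
#' a number of members and a target band of pairwise sequence identity.
#' Defaults mirror the benchmark design this generator emulates: families of
#' 70–170 nt sampled at controlled identity.
#'
#' @param consensus dot-bracket consensus; drawn by [random_structure()]
#'   when `NULL`.
#' @param n_members members per family (>= 2).
#' @param pid_range target pairwise identity band, percentages.
#' @param length_range length bounds used when drawing a consensus.
#' @param gu_fraction probability of a G-U pair at paired sites.
#' @param seed optional RNG seed.
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(consensus = NULL, n_members = 8,
                        pid_range = c(55, 95), length_range = c(70, 170),
                        gu_fraction = 0.1, seed = NULL) {
  stopifnot(n_members >= 2, pid_range[1] >= 0, pid_range[2] <= 100,
            pid_range[1] <= pid_range[2], gu_fraction >= 0, gu_fraction <= 1)
  structure(list(consensus = consensus, n_members = as.integer(n_members),
                 pid_range = pid_range, length_range = length_range,
                 gu_fraction = gu_fraction, seed = seed),
            class = "family_spec")
}

draw_pair <- function(gu_fraction) {
  if (stats::runif(1) < gu_fraction) {
    if (stats::runif(1) < 0.5) c("G", "U") else c("U", "G")
  } else {
    switch(sample(4, 1), c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"))
  }
}

#' Sample a structure-constrained sequence family
#'
#' Generates an ancestral sequence compatible with the consensus (paired
#' sites complementary, G-U pairs at `gu_fraction`) and derives each member
#' by compensatory substitution: at paired sites the whole pair is redrawn
#' (structure preserved as a pair, both partners rewritten), at loop sites
#' residues mutate freely.  Members are redrawn until every pairwise identity
#' falls inside `pid_range`.  Compensatory change at paired sites is what
#' decouples sequence identity from structural homology — the statistical
#' property of curated RNA families this generator emulates.
#'
#' @param spec a [family_spec()].
#' @param max_tries rejection bound on whole-family draws.
#' @return tibble with columns `id`, `seq`; the consensus structure is
#'   attached as attribute `consensus`.
#' @export
sample_family <- function(spec, max_tries = 400) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed_if(spec$seed, {
    consensus <- spec$consensus
    if (is.null(consensus)) {
      len <- sample(spec$length_range[1]:spec$length_range[2], 1)
      consensus <- random_structure(len)
    }
    pairs <- dotbracket_pairs(consensus)
    n <- nchar(consensus)
    paired_pos <- c(pairs[, 1], pairs[, 2])
    loop_pos <- setdiff(seq_len(n), paired_pos)
    ancestor <- character(n)
    for (k in seq_len(nrow(pairs))) {
      pr <- draw_pair(spec$gu_fraction)
      ancestor[pairs[k, 1]] <- pr[1]
      ancestor[pairs[k, 2]] <- pr[2]
    }
    ancestor[loop_pos] <- sample(c("A", "C", "G", "U"), length(loop_pos),
                                 replace = TRUE)
    lo <- spec$pid_range[1]; hi <- spec$pid_range[2]
    target <- (lo + hi) / 200
    # per-member site mutation probability so that two members' expected
    # identity lands mid-band: P(site identical) ~ (1 - mu)^2 for loops
    mu0 <- 1 - sqrt(target)
    mutate_member <- function(mu) {
      s <- ancestor
      for (k in seq_len(nrow(pairs))) {
        if (stats::runif(1) < mu) {
          pr <- draw_pair(spec$gu_fraction)
          s[pairs[k, 1]] <- pr[1]
          s[pairs[k, 2]] <- pr[2]
        }
      }
      flip <- loop_pos[stats::runif(length(loop_pos)) < mu]
      if (length(flip)) {
        s[flip] <- vapply(s[flip], function(b) {
          sample(setdiff(c("A", "C", "G", "U"), b), 1)
        }, character(1))
      }
      paste(s, collapse = "")
    }
    for (t in seq_len(max_tries)) {
      mu <- mu0 * stats::runif(1, 0.7, 1.3)
      members <- vapply(seq_len(spec$n_members), function(k) mutate_member(mu),
                        character(1))
      if (spec$pid_range[1] == 100) members <- rep(members[1], spec$n_members)
      pids <- utils::combn(members, 2, function(p) seq_identity(p[1], p[2]))
      if (all(pids >= lo & pids <= hi)) {
        out <- tibble::tibble(id = sprintf("m%02d", seq_along(members)),
                              seq = members)
        attr(out, "consensus") <- consensus
        return(out)
      }
    }
    stop("could not reach pairwise identity range [", lo, ", ", hi,
         "] within ", max_tries, " attempts")
  })
}

#' Dinucleotide-preserving shuffle
#'
#' Eulerian-walk shuffle (Altschul–Erickson): returns a random permutation of
#' the sequence that preserves the exact multiset of all 16 dinucleotide
#' counts (hence also mononucleotide counts) and the first and last residues.
#' The random arborescence is drawn by loop-erased random walks, which makes
#' the sampled shuffles uniform over all valid Eulerian arrangements.
#'
#' @param seq sequence (string, length >= 3).
#' @param seed optional RNG seed.
#' @return shuffled sequence string.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 3) stop("sequence too short to shuffle (need >= 3)")
  with_seed_if(seed, {
    verts <- unique(chars)
    if (length(verts) == 1) return(seq)
    from <- chars[-n]; to <- chars[-1]
    last <- chars[n]
    # multigraph successor lists
    succ <- split(to, factor(from, levels = verts))
    # Wilson: loop-erased random walks toward `last` give each non-terminal
    # vertex a tree out-edge; walk steps follow edge multiplicities
    in_tree <- stats::setNames(verts == last, verts)
    tree_next <- stats::setNames(rep(NA_character_, length(verts)), verts)
    for (v in verts) {
      if (in_tree[[v]]) next
      path <- character(0)
      nxt <- list()
      u <- v
      while (!in_tree[[u]]) {
        step <- sample(succ[[u]], 1)
        nxt[[u]] <- step       # loop erasure: keep only the latest choice
        path <- union(path, u)
        u <- step
      }
      # retrace the loop-erased path and freeze it into the tree
      u <- v
      while (!in_tree[[u]]) {
        in_tree[[u]] <- TRUE
        tree_next[[u]] <- nxt[[u]]
        u <- nxt[[u]]
      }
    }
    # arrange successor lists: random order, tree edge last
    arranged <- lapply(verts, function(v) {
      s <- succ[[v]]
      if (!is.na(tree_next[[v]])) {
        drop <- match(tree_next[[v]], s)
        s <- s[-drop]
      }
      s <- if (length(s)) sample(s, length(s)) else character(0)
      c(s, if (!is.na(tree_next[[v]])) tree_next[[v]])
    })
    names(arranged) <- verts
    used <- stats::setNames(integer(length(verts)), verts)
    out <- character(n)
    out[1] <- chars[1]
    u <- chars[1]
    for (k in 2:n) {
      used[[u]] <- used[[u]] + 1L
      w <- arranged[[u]][used[[u]]]
      out[k] <- w
      u <- w
    }
    paste(out, collapse = "")
  })
}

#' Build a labelled synthetic benchmark
#'
#' Families of structure-constrained sequences with distinct random consensus
#' structures, plus one dinucleotide-shuffled control per member (the 1:1
#' positive/negative design of the clustering benchmark, at any scale).
#'
#' @param n_families number of families.
#' @param members members per family.
#' @param pid_range pairwise-identity band (percent).
#' @param seed RNG seed for the whole dataset.
#' @param length_range family length bounds.
#' @param gu_fraction G-U probability at paired sites.
#' @param out_dir if given, writes `benchmark.fa` and `labels.tsv` there.
#' @return tibble with columns `id`, `seq`, `label` (family id or
#'   `"control"`); consensus structures attached as attribute `consensus`.
#' @export
make_benchmark <- function(n_families = 5, members = 8,
                           pid_range = c(55, 95), seed = NULL,
                           length_range = c(70, 170), gu_fraction = 0.1,
                           out_dir = NULL) {
  with_seed_if(seed, {
    fams <- list()
    consensi <- character(n_families)
    for (f in seq_len(n_families)) {
      fam <- sample_family(family_spec(n_members = members,
                                       pid_range = pid_range,
                                       length_range = length_range,
                                       gu_fraction = gu_fraction))
      consensi[f] <- attr(fam, "consensus")
      fams[[f]] <- tibble::tibble(
        id = sprintf("fam%02d_%s", f, fam$id),
        seq = fam$seq,
        label = sprintf("fam%02d", f))
    }
    pos <- dplyr::bind_rows(fams)
    ctrl <- tibble::tibble(
      id = paste0("shuf_", pos$id),
      seq = vapply(pos$seq, dinucleotide_shuffle, character(1)),
      label = "control")
    out <- dplyr::bind_rows(pos, ctrl)
    attr(out, "consensus") <- consensi
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(out, file.path(out_dir, "benchmark.fa"))
      readr::write_tsv(dplyr::select(out, "id", "label"),
                       file.path(out_dir, "labels.tsv"))
    }
    out
  })
}

#' Count dinucleotides
#'
#' @param seq sequence string.
#' @return named integer vector of the 16 (or observed) dinucleotide counts.
#' @export
dinucleotide_counts <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2) return(integer(0))
  table(paste0(chars[-n], chars[-1]))
}
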