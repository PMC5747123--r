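#' Read a narrowPeak-like BED file of CLIP peaks
#'
#' Columns follow the ENCODE narrowPeak convention: chrom, start, end
#' (0-based half-open), name, score, strand, signalValue (fold enrichment
#' over input), pValue (-log10), qValue, peak.  Trailing columns may be
#' absent.
#'
#' @param path file path.
#' @return tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `fold_enrichment`, `neg_log10_p` (plus `neg_log10_q`, `peak`
#'   when present).
#' @export
read_narrowpeak <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "fold_enrichment", "neg_log10_p", "neg_log10_q", "peak")
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  names(raw) <- cols[seq_len(ncol(raw))]
  for (nm in intersect(c("start", "end", "fold_enrichment", "neg_log10_p"),
                       names(raw))) {
    if (!is.numeric(raw[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[nm]]))))
      stop("non-numeric '", nm, "' at line ", bad[1])
    }
  }
  tibble::as_tibble(raw)
}

#' Write intervals back to BED/narrowPeak text
#'
#' @param peaks tibble as returned by [read_narrowpeak()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter CLIP peaks by enrichment and significance
#'
#' Keeps peaks with fold enrichment at least `min_fold` (inclusive) and
#' P value at most `max_p` (inclusive; the narrowPeak column stores
#' -log10 P).  With `fold_is_log2` the signal column is interpreted as log2
#' enrichment, so the threshold becomes `log2(min_fold)`.
#'
#' @param peaks tibble of peaks.
#' @param min_fold minimum enrichment over background (linear scale).
#' @param max_p maximum P value.
#' @param fold_is_log2 signal column is log2 enrichment.
#' @return filtered tibble.
#' @export
filter_peaks <- function(peaks, min_fold = 8, max_p = 1e-4,
                         fold_is_log2 = FALSE) {
  thr <- if (fold_is_log2) log2(min_fold) else min_fold
  dplyr::filter(peaks,
                .data$fold_enrichment >= thr,
                10^(-.data$neg_log10_p) <= max_p)
}

#' Merge peaks overlapping by more than a minimum length
#'
#' Same-chromosome, same-strand peaks whose overlap exceeds `min_overlap`
#' nucleotides (strictly) are unioned transitively; a merged record spans the
#' union and keeps the maximum fold enrichment and the maximum -log10 P of
#' its constituents.  Applying the operation twice is a no-op.
#'
#' @param peaks tibble of peaks.
#' @param min_overlap overlap (nt) that must be exceeded for a merge.
#' @return tibble of merged peaks, sorted by (chrom, strand, start).
#' @export
merge_overlapping <- function(peaks, min_overlap = 50) {
  if (!nrow(peaks)) return(peaks)
  peaks <- dplyr::arrange(peaks, .data$chrom, .data$strand, .data$start)
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end),
    strand = peaks$strand)
  hits <- GenomicRanges::findOverlaps(gr, gr,
                                      minoverlap = min_overlap + 1)
  # transitive closure via union-find over the overlap graph
  parent <- seq_len(nrow(peaks))
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (k in seq_along(hits)) {
    a <- find(S4Vectors::queryHits(hits)[k])
    b <- find(S4Vectors::subjectHits(hits)[k])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(nrow(peaks)), find, integer(1))
  peaks |>
    dplyr::mutate(.component = comp) |>
    dplyr::group_by(.data$.component) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      name = dplyr::first(.data$name),
      score = max(.data$score),
      strand = dplyr::first(.data$strand),
      fold_enrichment = max(.data$fold_enrichment),
      neg_log10_p = max(.data$neg_log10_p),
      .groups = "drop") |>
    dplyr::select(-".component") |>
    dplyr::arrange(.data$chrom, .data$strand, .data$start)
}

#' Keep peaks with a same-strand overlap with any region
#'
#' At least one nucleotide of same-chromosome, same-strand overlap is
#' required (coordinates are half-open, so touching intervals do not count).
#'
#' @param peaks tibble of peaks.
#' @param regions tibble of regions with `chrom`, `start`, `end`, `strand`.
#' @return the overlapping subset of `peaks`.
#' @export
intersect_same_strand <- function(peaks, regions) {
  if (!nrow(peaks) || !nrow(regions)) return(peaks[0, ])
  gp <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end),
    strand = peaks$strand)
  gre <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end),
    strand = regions$strand)
  hits <- GenomicRanges::findOverlaps(gp, gre, ignore.strand = FALSE)
  peaks[sort(unique(S4Vectors::queryHits(hits))), ]
}
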