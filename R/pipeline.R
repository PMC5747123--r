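#' Pipeline configuration
#'
#' Bundles all stage parameters plus input/output paths into one serialisable
#' object; [write_config()]/[read_config()] round-trip it through JSON.
#'
#' @param input path to a FASTA file (or `NULL` when a sequence tibble is
#'   passed to [run_pipeline()] directly).
#' @param out_dir output directory for the pipeline artifacts.
#' @param labels optional path to a two-column TSV (`id`, `label`) enabling
#'   the confusion-metrics report (`control` marks negatives).
#' @param align an [align_params()].
#' @param cluster a [cluster_params()].
#' @param fold a [fold_params()].
#' @param n_jobs worker processes for the all-vs-all stage.
#' @param seed seed forwarded to the sampling stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, out_dir = "dotclust_out",
                            labels = NULL, align = align_params(),
                            cluster = cluster_params(), fold = fold_params(),
                            n_jobs = 1, seed = 1) {
  structure(list(input = input, out_dir = out_dir, labels = labels,
                 align = align, cluster = cluster, fold = fold,
                 n_jobs = n_jobs, seed = seed),
            class = "pipeline_config")
}

#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @rdname pipeline_config
#' @export
write_config <- function(config, path) {
  plain <- lapply(unclass(config), function(x) {
    if (inherits(x, c("align_params", "cluster_params", "fold_params"))) {
      unclass(x)
    } else {
      x
    }
  })
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config(
    input = raw$input, out_dir = raw$out_dir, labels = raw$labels,
    align = do.call(align_params, raw$align),
    cluster = do.call(cluster_params, raw$cluster),
    fold = do.call(fold_params, raw$fold),
    n_jobs = raw$n_jobs, seed = raw$seed)
  cfg
}

#' Run the full motif-clustering pipeline
#'
#' fold -> all-vs-all alignment -> dissimilarity -> OPTICS -> xi extraction
#' (-> confusion metrics when labels are available).  All artifacts are
#' written with fixed file names under `config$out_dir`:
#' `scores.tsv`, `dissimilarity.tsv`, `reachability.tsv`, `clusters.json`,
#' `metrics.tsv` (labels only), `run.log`.  A rerun with an identical config
#' and seed is bit-identical for the TSV/JSON outputs; with `n_samples = 0`
#' the whole run is deterministic regardless of `n_jobs`.
#'
#' @param config a [pipeline_config()].
#' @param seqs optional sequence tibble (`id`, `seq`(, `label`)) overriding
#'   `config$input`.
#' @return list with `scores`, `dissimilarity`, `reachability`, `clusters`,
#'   and (with labels) `confusion` and `metrics`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), seqs = NULL) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  logmsg <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)  # truncate
  logmsg("dotclust pipeline")
  logmsg("config: ", jsonlite::toJSON(lapply(unclass(config), unclass),
                                      auto_unbox = TRUE, null = "null"))
  if (is.null(seqs)) {
    if (is.null(config$input)) stop("[input] no sequences given")
    seqs <- stage("input", read_fasta(config$input))
  }
  labels <- NULL
  if (!is.null(config$labels)) {
    lab <- stage("labels", readr::read_tsv(config$labels,
                                           show_col_types = FALSE))
    labels <- stats::setNames(lab$label, lab$id)
  } else if ("label" %in% names(seqs)) {
    labels <- stats::setNames(seqs$label, seqs$id)
  }
  logmsg("sequences: ", nrow(seqs))

  ap <- config$align
  if (ap$n_samples > 0 && is.null(ap$seed)) ap$seed <- config$seed
  dps <- stage("fold", lapply(seqs$seq, partition_fold, params = config$fold))
  names(dps) <- seqs$id
  logmsg("fold: done")
  S <- stage("align", all_vs_all(seqs, dps, ap, n_jobs = config$n_jobs,
                                 fold_p = config$fold))
  logmsg("align: all-vs-all done")
  D <- stage("dissimilarity", to_dissimilarity(S))
  r <- stage("optics", optics_order(D, config$cluster))
  cl <- stage("extract", extract_xi(r, config$cluster))
  logmsg("cluster: ", length(cl$clusters), " clusters")

  write_matrix_tsv(S, file.path(config$out_dir, "scores.tsv"))
  write_matrix_tsv(D, file.path(config$out_dir, "dissimilarity.tsv"))
  rt <- tidy(r)
  rt$reachability <- ifelse(is.finite(rt$reachability),
                            format(rt$reachability, digits = 10), "inf")
  readr::write_tsv(rt, file.path(config$out_dir, "reachability.tsv"))
  jsonlite::write_json(
    list(clusters = lapply(cl$clusters, as.list), noise = as.list(cl$noise)),
    file.path(config$out_dir, "clusters.json"),
    auto_unbox = TRUE, pretty = TRUE)
  out <- list(scores = S, dissimilarity = D, reachability = r, clusters = cl)
  if (!is.null(labels)) {
    conf <- stage("metrics", cluster_confusion(cl, labels))
    met <- cluster_metrics(conf)
    readr::write_tsv(dplyr::bind_cols(conf, met),
                     file.path(config$out_dir, "metrics.tsv"))
    out$confusion <- conf
    out$metrics <- met
    logmsg("metrics: sensitivity ", round(met$sensitivity, 3),
           " specificity ", round(met$specificity, 3))
  }
  logmsg("done")
  invisible(out)
}

# headered symmetric-matrix TSV (ids as first column and header row)
write_matrix_tsv <- function(m, path) {
  m <- unclass(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by the pipeline
#'
#' @param path TSV path with an `id` first column.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
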