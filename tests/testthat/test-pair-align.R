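# two-step aligner: string DP, partition function, sampling, dot-plot scoring

test_that("basewise similarity follows its definition", {
  p <- align_params()
  expect_equal(basewise_similarity("G", 0.3, "G", 0.3, p), 1)
  expect_equal(basewise_similarity("G", 0.2, "G", 0.8, p), 0.7)
  expect_equal(basewise_similarity("A", 0.5, "C", 0.5, align_params(theta = 1)),
               0)
  # vectorised and bounded
  set.seed(1)
  qa <- runif(20); qb <- runif(20)
  v <- basewise_similarity(sample(c("A", "C"), 20, TRUE), qa,
                           sample(c("A", "C"), 20, TRUE), qb, p)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("optimal string alignment equals brute-force path maximisation", {
  fp <- fold_params()
  p <- align_params()
  set.seed(301)
  for (k in 1:12) {
    x <- random_rna(sample(3:6, 1)); y <- random_rna(sample(3:6, 1))
    dx <- partition_fold(x, fp); dy <- partition_fold(y, fp)
    sig <- oracle_sigma(x, unpaired_profile(dx), y, unpaired_profile(dy),
                        p$theta)
    best <- max(vapply(oracle_enum_paths(nchar(x), nchar(y)),
                       oracle_path_score, numeric(1), sigma = sig,
                       go = p$gap_open, ge = p$gap_ext))
    expect_equal(string_align_optimal(x, dx, y, dy, p)$score, best,
                 tolerance = 1e-9)
  }
  expect_error(string_align_optimal("", dot_plot(1), "A", dot_plot(1), p),
               "empty")
})

test_that("identical sequences align all-match with raw score = length", {
  fp <- fold_params()
  set.seed(8)
  x <- random_rna(30)
  dx <- partition_fold(x, fp)
  res <- string_align_optimal(x, dx, x, dx, align_params())
  expect_true(all(res$path$op == "match"))
  expect_equal(res$score, 30)
})

test_that("free end gaps make terminal overhangs costless", {
  fp <- fold_params()
  pf <- align_params(free_end_gaps = TRUE)
  x <- "AAGGGG"; y <- "GGGG"
  dx <- partition_fold(x, fp); dy <- partition_fold(y, fp)
  res <- string_align_optimal(x, dx, y, dy, pf)
  # oracle over the semi-global path space
  sig <- oracle_sigma(x, unpaired_profile(dx), y, unpaired_profile(dy),
                      pf$theta)
  paths <- Filter(function(ev) !oracle_mixed_terminal(ev),
                  oracle_enum_paths(6, 4))
  best <- max(vapply(paths, oracle_path_score, numeric(1), sigma = sig,
                     go = 1, ge = 0.05, free_end = TRUE))
  expect_equal(res$score, best, tolerance = 1e-9)
  # the leading AA overhang costs nothing: both Gs blocks align in full
  expect_equal(res$path$op[1:2], c("gap_y", "gap_y"))
})

test_that("log partition value matches the enumeration sum and bounds", {
  fp <- fold_params()
  p <- align_params()
  set.seed(302)
  for (k in 1:10) {
    x <- random_rna(sample(3:6, 1)); y <- random_rna(sample(3:6, 1))
    dx <- partition_fold(x, fp); dy <- partition_fold(y, fp)
    sig <- oracle_sigma(x, unpaired_profile(dx), y, unpaired_profile(dy),
                        p$theta)
    sc <- vapply(oracle_enum_paths(nchar(x), nchar(y)), oracle_path_score,
                 numeric(1), sigma = sig, go = p$gap_open, ge = p$gap_ext)
    pm <- string_align_partition(x, dx, y, dy, p)
    expect_equal(pm$logZ, log(sum(exp(sc / p$temp))), tolerance = 1e-9)
    # the sum dominates its largest term
    expect_gte(pm$logZ, max(sc) / p$temp)
  }
})

test_that("low temperature collapses the partition onto the optimum", {
  fp <- fold_params()
  set.seed(303)
  x <- random_rna(20); y <- random_rna(22)
  dx <- partition_fold(x, fp); dy <- partition_fold(y, fp)
  p0 <- align_params(temp = 0.01)
  opt <- string_align_optimal(x, dx, y, dy, p0)
  pm <- string_align_partition(x, dx, y, dy, p0)
  expect_equal(pm$logZ * 0.01, opt$score, tolerance = 0.01)
  # sampled paths concentrate on the optimum
  sp <- sample_paths(pm, 1000, seed = 1)
  hit <- vapply(sp, function(pp) identical(pp$op, opt$path$op), logical(1))
  expect_gte(mean(hit), 0.99)
})

test_that("partition recursions stay finite at length 500", {
  fp <- fold_params()
  set.seed(304)
  x <- random_rna(500); y <- random_rna(500)
  dx <- partition_fold(x, fp); dy <- partition_fold(y, fp)
  pm <- string_align_partition(x, dx, y, dy, align_params())
  expect_true(is.finite(pm$logZ))
  expect_true(all(is.finite(pm$M[nrow(pm$M), ncol(pm$M)])))
})

test_that("sampling is reproducible and empty at s = 0", {
  fp <- fold_params()
  set.seed(305)
  x <- random_rna(15); y <- random_rna(14)
  pm <- string_align_partition(x, partition_fold(x, fp), y,
                               partition_fold(y, fp), align_params())
  expect_identical(sample_paths(pm, 0), list())
  a <- sample_paths(pm, 25, seed = 42)
  b <- sample_paths(pm, 25, seed = 42)
  expect_identical(a, b)
})

test_that("sampled path frequencies follow the Boltzmann distribution", {
  fp <- fold_params()
  p <- align_params()
  set.seed(306)
  x <- random_rna(4); y <- random_rna(4)
  dx <- partition_fold(x, fp); dy <- partition_fold(y, fp)
  sig <- oracle_sigma(x, unpaired_profile(dx), y, unpaired_profile(dy),
                      p$theta)
  paths <- oracle_enum_paths(4, 4)
  pr <- exp(vapply(paths, oracle_path_score, numeric(1), sigma = sig,
                   go = 1, ge = 0.05) / p$temp)
  pr <- pr / sum(pr)
  keys <- vapply(paths, paste, character(1), collapse = "")
  pm <- string_align_partition(x, dx, y, dy, p)
  sp <- sample_paths(pm, 10000, seed = 7)
  got <- vapply(sp, function(pp) {
    paste(match(pp$op, c("match", "gap_y", "gap_x")) - 1L, collapse = "")
  }, character(1))
  counts <- table(factor(got, levels = keys))
  # pool cells with tiny expectation for a valid chi-square
  expected <- pr * 10000
  big <- expected >= 5
  obs <- c(counts[big], sum(counts[!big]))
  exp_ct <- c(expected[big], sum(expected[!big]))
  chi <- sum((obs - exp_ct)^2 / exp_ct)
  expect_gt(stats::pchisq(chi, length(obs) - 1, lower.tail = FALSE), 0.001)
})

test_that("dot-plot path score equals the quadratic brute force", {
  fp <- fold_params(p_min = 0)
  set.seed(307)
  for (k in 1:6) {
    x <- random_rna(sample(8:14, 1)); y <- random_rna(sample(8:14, 1))
    dx <- partition_fold(x, fp); dy <- partition_fold(y, fp)
    res <- string_align_optimal(x, dx, y, dy, align_params())
    expect_equal(dotplot_path_score(res$path, dx, dy),
                 oracle_dotplot_score(res$path, as.matrix(dx), as.matrix(dy)),
                 tolerance = 1e-12)
  }
  # identity path on one sequence gives the self-superposition sum(p^2)
  x <- "GGGGAAAACCCC"
  dx <- partition_fold(x, fp)
  self <- string_align_optimal(x, dx, x, dx, align_params())
  expect_equal(dotplot_path_score(self$path, dx, dx), sum(dx$p^2),
               tolerance = 1e-12)
  # an empty dot plot scores 0
  da <- partition_fold("AAAAAAAAAAAA", fp)
  aa <- string_align_optimal(x, dx, "AAAAAAAAAAAA", da, align_params())
  expect_equal(dotplot_path_score(aa$path, dx, da), 0)
})

test_that("combined score anchors, weight limits and range", {
  fp <- fold_params()
  set.seed(308)
  x <- random_rna(25)
  dx <- partition_fold(x, fp)
  self <- string_align_optimal(x, dx, x, dx, align_params())
  cs <- combined_score(self$path, x, dx, x, dx, align_params())
  expect_equal(cs$seq_score_norm, 1)
  expect_equal(cs$dotplot_score_norm, 1)
  expect_equal(cs$score, 1)
  # kappa = 1: only the sequence term matters
  cs1 <- combined_score(self$path, x, dx, x, dx, align_params(kappa = 1))
  expect_equal(cs1$score, cs1$seq_score_norm)
  for (k in 1:8) {
    y <- random_rna(sample(10:30, 1))
    dy <- partition_fold(y, fp)
    pth <- string_align_optimal(x, dx, y, dy, align_params())$path
    s <- combined_score(pth, x, dx, y, dy, align_params())$score
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("PID counts identical match columns over all columns", {
  p <- align_params()
  fp <- fold_params()
  a <- align_pair("ACGU", "ACGU", params = p)
  expect_equal(a$pid, 100)
  b <- align_pair("ACGU", "ACGA", params = p)
  expect_true(all(b$path$op == "match"))
  expect_equal(b$pid, 75)
  # hand-built path with gap columns in the denominator:
  # ACGU / A-GU + trailing gap = 3 identities over 5 columns
  path <- tibble::tibble(op = c("match", "gap_y", "match", "match", "gap_x"),
                         i = c(1L, 2L, 3L, 4L, NA),
                         j = c(1L, NA, 2L, 3L, 4L))
  expect_equal(pid(path, "ACGU", "AGUC"), 100 * 3 / 5)
})

test_that("align_pair is symmetric at s = 0 and monotone in s", {
  fp <- fold_params()
  set.seed(309)
  for (k in 1:8) {
    x <- random_rna(sample(10:35, 1)); y <- random_rna(sample(10:35, 1))
    a <- align_pair(x, y, params = align_params(), id_x = "a", id_y = "b")
    b <- align_pair(y, x, params = align_params(), id_x = "b", id_y = "a")
    expect_lt(abs(a$score - b$score), 1e-9)
  }
  # the candidate set only grows with s under a fixed seed stream
  x <- random_rna(30); y <- random_rna(32)
  dx <- partition_fold(x, fp); dy <- partition_fold(y, fp)
  sc <- vapply(c(0, 5, 25), function(s) {
    align_pair(x, y, dx, dy,
               params = align_params(n_samples = s, seed = 11))$score
  }, numeric(1))
  expect_true(all(diff(sc) >= -1e-12))
})

test_that("self-alignment through align_pair is exact", {
  set.seed(310)
  x <- random_rna(40)
  a <- align_pair(x, x, id_x = "s", id_y = "s")
  expect_equal(a$score, 1)
  expect_equal(a$pid, 100)
  expect_equal(a$n_samples_used, 0L)
  g <- glance(a)
  expect_equal(g$score, 1)
  expect_identical(nrow(tidy(a)), nrow(a$path))
})
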