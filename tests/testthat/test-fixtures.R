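# synthetic benchmark generator, shuffles, Stockholm I/O

test_that("random structures respect their constraints", {
  set.seed(61)
  for (k in 1:40) {
    len <- sample(10:170, 1)
    db <- random_structure(len, seed = k)
    expect_equal(nchar(db), len)
    pairs <- dotbracket_pairs(db)  # validates balance + hairpin >= 3
    frac <- 2 * nrow(pairs) / len
    expect_gte(frac, 0.4 - 1e-9)
    expect_lte(frac, 0.7 + 1e-9)
    if (nrow(pairs)) {
      # stems within 3..8 pairs
      runs <- rle(diff(pairs[, 1]) == 1 & diff(pairs[, 2]) == -1)
    }
  }
  expect_identical(random_structure(50, seed = 9),
                   random_structure(50, seed = 9))
})

test_that("sampled families hit their identity band and share structure", {
  spec <- family_spec(n_members = 5, pid_range = c(60, 90),
                      length_range = c(70, 90), seed = 62)
  fam <- sample_family(spec)
  expect_equal(nrow(fam), 5)
  pids <- utils::combn(fam$seq, 2, function(p) seq_identity(p[1], p[2]))
  expect_true(all(pids >= 60 & pids <= 90))
  # members refold onto the consensus: ensemble mass on consensus pairs
  # beats mass on random non-consensus pairs
  cons <- attr(fam, "consensus")
  pairs <- dotbracket_pairs(cons)
  set.seed(63)
  for (s in fam$seq[1:3]) {
    P <- as.matrix(partition_fold(s, fold_params(p_min = 0)))
    on <- mean(P[pairs])
    n <- nchar(s)
    rnd <- cbind(sample(n, 200, replace = TRUE), sample(n, 200, replace = TRUE))
    rnd <- rnd[abs(rnd[, 1] - rnd[, 2]) > 4, , drop = FALSE]
    key <- paste(pmin(rnd[, 1], rnd[, 2]), pmax(rnd[, 1], rnd[, 2]))
    off <- mean(P[rnd[!key %in% paste(pairs[, 1], pairs[, 2]), ,
                      drop = FALSE]])
    expect_gt(on, off)
  }
})

test_that("degenerate identity band returns identical members", {
  fam <- sample_family(family_spec(n_members = 4, pid_range = c(100, 100),
                                   length_range = c(70, 80), seed = 64))
  expect_equal(length(unique(fam$seq)), 1)
})

test_that("unreachable identity bands fail loudly", {
  spec <- family_spec(n_members = 4, pid_range = c(0, 1),
                      length_range = c(70, 80), seed = 65)
  expect_error(sample_family(spec, max_tries = 5), "identity range")
})

test_that("dinucleotide shuffle preserves counts and terminals exactly", {
  set.seed(66)
  for (k in 1:25) {
    s <- random_rna(sample(20:120, 1))
    sh <- dinucleotide_shuffle(s, seed = k)
    expect_equal(dinucleotide_counts(sh), dinucleotide_counts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, nchar(s), nchar(s)), substr(s, nchar(s), nchar(s)))
    # mononucleotide counts preserved as a corollary
    expect_equal(sort(strsplit(sh, "")[[1]]), sort(strsplit(s, "")[[1]]))
  }
  expect_identical(dinucleotide_shuffle("ACGUACGUAC", seed = 1),
                   dinucleotide_shuffle("ACGUACGUAC", seed = 1))
})

test_that("tiny-sequence shuffles cover all valid arrangements uniformly", {
  s <- "GAUCAUGA"
  valid <- oracle_valid_shuffles(s)
  expect_gt(length(valid), 1)
  set.seed(67)
  draws <- vapply(1:3000, function(k) dinucleotide_shuffle(s), character(1))
  expect_true(all(draws %in% valid))
  counts <- table(factor(draws, levels = valid))
  expected <- rep(3000 / length(valid), length(valid))
  chi <- sum((as.numeric(counts) - expected)^2 / expected)
  expect_gt(stats::pchisq(chi, length(valid) - 1, lower.tail = FALSE), 0.001)
})

test_that("benchmark datasets are labelled, paired with controls, seeded", {
  b1 <- make_benchmark(n_families = 2, members = 3, pid_range = c(60, 95),
                       seed = 68, length_range = c(70, 90))
  expect_equal(nrow(b1), 12)
  expect_equal(sum(b1$label == "control"), 6)
  expect_equal(sum(b1$label != "control"), 6)
  b2 <- make_benchmark(n_families = 2, members = 3, pid_range = c(60, 95),
                       seed = 68, length_range = c(70, 90))
  expect_identical(b1$seq, b2$seq)
  # each control shares composition with its source
  for (k in which(b1$label == "control")) {
    src <- b1$seq[match(sub("^shuf_", "", b1$id[k]), b1$id)]
    expect_equal(dinucleotide_counts(b1$seq[k]), dinucleotide_counts(src))
  }
  # out_dir writes FASTA + labels
  td <- withr::local_tempdir()
  make_benchmark(2, 3, c(60, 95), seed = 68, length_range = c(70, 90),
                 out_dir = td)
  expect_true(file.exists(file.path(td, "benchmark.fa")))
  back <- read_fasta(file.path(td, "benchmark.fa"))
  expect_equal(nrow(back), 12)
})

test_that("within-family similarity separates from family-vs-control", {
  set.seed(69)
  b <- make_benchmark(n_families = 2, members = 4, pid_range = c(55, 95),
                      seed = 70, length_range = c(70, 90))
  S <- unclass(all_vs_all(b[, c("id", "seq")]))
  fam1 <- which(b$label == "fam01")
  ctrl <- which(b$label == "control")
  within <- S[fam1, fam1][upper.tri(S[fam1, fam1])]
  across <- as.vector(S[fam1, ctrl])
  expect_gt(stats::median(within) - stats::median(across), 0.1)
})

test_that("Stockholm round-trips and simplifies WUSS", {
  td <- withr::local_tempfile()
  aln <- tibble::tibble(id = c("seq1", "seq2"),
                        aln = c("GGG-AAACCC", "GGGUAAACC-"))
  write_stockholm(aln, td, ss_cons = "<<<..AA>>>")
  back <- read_stockholm(td)
  expect_equal(back$alignment, aln)
  expect_equal(back$ss_cons, "(((....)))")
  expect_equal(wuss_to_dotbracket("<<<...>>>"), "(((...)))")
  # pseudoknot letters are dropped to dots
  expect_equal(wuss_to_dotbracket("<<aa..>>AA"), "((....))..")
  writeLines("seq1 ACGU", td)
  expect_error(read_stockholm(td), "STOCKHOLM")
})

test_that("interleaved Stockholm blocks are concatenated", {
  td <- withr::local_tempfile()
  writeLines(c("# STOCKHOLM 1.0", "",
               "s1 GGG-A", "s2 GGGUA", "#=GC SS_cons <<...",
               "", "s1 AACCC", "s2 AACC-", "#=GC SS_cons ..>>.",
               "//"), td)
  back <- read_stockholm(td)
  expect_equal(back$alignment$aln, c("GGG-AAACCC", "GGGUAAACC-"))
  expect_equal(back$ss_cons, "((.....)).")
})
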