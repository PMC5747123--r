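# alignment- and cluster-quality metrics

test_that("MCC formula, degenerate cases and swap symmetry", {
  expect_equal(mcc(1, 0, 1, 0), 1)
  expect_equal(mcc(1, 1, 1, 1), 0)
  expect_equal(mcc(3, 1, 2, 0), 6 / sqrt(72))
  expect_equal(mcc(0, 0, 5, 0), 0)  # zero factor under the root
  expect_error(mcc(0, 0, 0, 0), "undefined")
  set.seed(1)
  for (k in 1:20) {
    v <- sample(0:10, 4, replace = TRUE)
    if (sum(v) == 0) next
    m1 <- mcc(v[1], v[2], v[3], v[4])
    expect_gte(m1, -1); expect_lte(m1, 1)
    # swapping the positive and negative classes leaves MCC unchanged
    expect_equal(m1, mcc(v[3], v[4], v[1], v[2]))
  }
})

test_that("SCI is 1 for copies of one sequence and low for unrelated rows", {
  fp <- fold_params()
  s <- "GGGGCAAAAGCCCCAUAAGGGAAACCCUU"
  expect_equal(sci(rep(s, 3), fp), 1)
  set.seed(21)
  rows <- vapply(1:4, function(k) random_rna(60), character(1))
  v <- sci(rows, fp, rho = 1)
  expect_lt(v, 0.35)
  expect_error(sci(c("AC-G", "ACG"), fp), "ragged")
})

test_that("a conserved family has higher SCI than its shuffled rows", {
  set.seed(22)
  fam <- sample_family(family_spec(n_members = 4, pid_range = c(70, 95),
                                   length_range = c(70, 90), seed = 3))
  fp <- fold_params()
  sci_fam <- sci(fam$seq, fp)
  shuf <- vapply(fam$seq, dinucleotide_shuffle, character(1))
  expect_gt(sci_fam, sci(unname(shuf), fp))
})

test_that("delta SCI is the plain ratio", {
  expect_equal(delta_sci(1, 1), 1)
  expect_equal(delta_sci(0, 0.7), 0)
  expect_equal(delta_sci(0.8, 0.5), 1.6)
  expect_error(delta_sci(0.5, 0), "undefined")
})

test_that("base-pair distance is the symmetric difference and a metric", {
  expect_equal(structure_distance("((...))", "((...))", "bp"), 0)
  expect_equal(structure_distance("((...))", "(.....)", "bp"), 1)
  expect_error(structure_distance("(...)", "(....)", "bp"), "equal-length")
  expect_error(structure_distance("((...)", "((...)", "bp"), "unbalanced")
  # identity, symmetry, triangle inequality on fuzzed triples
  set.seed(23)
  structs <- vapply(1:6, function(k) random_structure(30), character(1))
  for (k in 1:15) {
    tri <- sample(structs, 3, replace = TRUE)
    d12 <- structure_distance(tri[1], tri[2], "bp")
    d21 <- structure_distance(tri[2], tri[1], "bp")
    d13 <- structure_distance(tri[1], tri[3], "bp")
    d23 <- structure_distance(tri[2], tri[3], "bp")
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23)
    expect_equal(structure_distance(tri[1], tri[1], "bp"), 0)
  }
})

test_that("tree edit distance matches the naive forest recursion", {
  expect_equal(structure_distance("((...))", "((...))", "tree"), 0)
  cases <- list(
    c("(...)", "....."),
    c("((...))", "(.....)"),
    c("(...).", ".(...)"),
    c("(...)(...)", "((...))..."),
    c("..(...)", "(....).")
  )
  for (cs in cases) {
    f1 <- dotclust:::structure_forest(cs[1])
    f2 <- dotclust:::structure_forest(cs[2])
    expect_equal(structure_distance(cs[1], cs[2], "tree"),
                 oracle_forest_dist(f1, f2),
                 label = paste(cs[1], "vs", cs[2]))
  }
})

test_that("ROC AUC: anchors, worked case and complement identity", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # pair-counting oracle: 1 concordant, 1 discordant of 2 pairs
  expect_equal(roc_auc(c(0.9, 0.8, 0.4), c(1, 0, 1)), 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "one class")
  set.seed(24)
  s <- runif(30); l <- rbinom(30, 1, 0.4)
  expect_equal(roc_auc(s, l) + roc_auc(1 - s, l), 1)
})

test_that("matrix AUC separates a two-family score matrix", {
  labels <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  L <- binary_label_matrix(labels)
  expect_true(isSymmetric(L))
  expect_equal(diag(L), setNames(rep(1L, 6), names(labels)))
  S <- matrix(0.2, 6, 6, dimnames = list(names(labels), names(labels)))
  S[1:3, 1:3] <- 0.9; S[4:6, 4:6] <- 0.9; diag(S) <- 1
  expect_equal(roc_auc_matrix(S, L), 1)
})

test_that("cluster confusion follows the dominance bookkeeping", {
  labels <- c(x1 = "A", x2 = "A", x3 = "A", x4 = "B", x5 = "A",
              x6 = "control")
  cc <- cluster_confusion(list(c("x1", "x2", "x3", "x4")), labels)
  expect_equal(as.list(cc), list(tp = 3L, fp = 1L, tn = 1L, fn = 1L))
  # tied dominant families: one FP for the cluster itself
  labels2 <- c(y1 = "A", y2 = "A", y3 = "B", y4 = "B")
  cc2 <- cluster_confusion(list(c("y1", "y2", "y3", "y4")), labels2)
  expect_equal(cc2$fp, 1L)
  expect_equal(cc2$tp, 0L)
  # ... or every member, under the alternative reading
  cc2b <- cluster_confusion(list(c("y1", "y2", "y3", "y4")), labels2,
                            fp_counts_members = TRUE)
  expect_equal(cc2b$fp, 4L)
  # control-dominated cluster
  labels3 <- c(z1 = "control", z2 = "control", z3 = "A")
  cc3 <- cluster_confusion(list(c("z1", "z2", "z3")), labels3)
  expect_equal(cc3$fp, 1L)
  # nothing clustered: all controls are true negatives
  labels4 <- c(w1 = "control", w2 = "control")
  cc4 <- cluster_confusion(list(), labels4)
  expect_equal(as.list(cc4), list(tp = 0L, fp = 0L, tn = 2L, fn = 0L))
  expect_error(cluster_confusion(list("nope"), labels4), "unlabelled")
})

test_that("cluster metrics formulas and perfect-clustering anchor", {
  m <- cluster_metrics(list(tp = 3, fp = 1, tn = 1, fn = 1))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$fpr, 0.5)
  expect_equal(m$precision, 0.75)
  expect_equal(m$accuracy, 4 / 6)
  perfect <- cluster_metrics(list(tp = 10, fp = 0, tn = 10, fn = 0))
  expect_true(all(unlist(perfect[c("sensitivity", "specificity",
                                   "precision", "accuracy")]) == 1))
  expect_equal(perfect$fpr, 0)
  nodata <- cluster_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0))
  expect_true(is.na(nodata$sensitivity))
})

test_that("confusion + metrics agree with a hand-verified sheet", {
  # two clusters {A,A,A,B}, {B,B,B,B,control}; unclustered: A, control x3
  labels <- c(a1 = "A", a2 = "A", a3 = "A", a4 = "A",
              b1 = "B", b2 = "B", b3 = "B", b4 = "B", b5 = "B",
              c1 = "control", c2 = "control", c3 = "control",
              c4 = "control")
  cl <- list(c("a1", "a2", "a3", "b5"), c("b1", "b2", "b3", "b4", "c1"))
  cc <- cluster_confusion(cl, labels)
  # hand count: TP = 3 + 4; FP = 1 + 1; FN = a4; TN = c2..c4
  expect_equal(as.list(cc), list(tp = 7L, fp = 2L, tn = 3L, fn = 1L))
  m <- cluster_metrics(cc)
  expect_equal(m$sensitivity, 7 / 8)
  expect_equal(m$specificity, 3 / 5)
  expect_equal(m$accuracy, 10 / 13)
})
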