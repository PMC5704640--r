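# Build a small two-class fixture: 6 genes, 4 samples per class, two
# planted reversals ((g1,g2) and (g3,g4)), and (g5,g6) unstable in A.
make_reversal_fixture <- function() {
  a <- cbind(s1 = c(1, 10, 2, 30, 5, 6),
             s2 = c(1, 12, 2, 33, 7, 6),
             s3 = c(2, 11, 3, 31, 5, 6),
             s4 = c(1, 11, 2, 32, 8, 6))
  b <- cbind(t1 = c(10, 1, 30, 2, 5, 6),
             t2 = c(12, 1, 31, 3, 5, 7),
             t3 = c(11, 2, 32, 2, 6, 7),
             t4 = c(13, 1, 33, 2, 5, 8))
  rownames(a) <- rownames(b) <- paste0("g", 1:6)
  list(a = a, b = b)
}

test_that("reversal discovery matches the exhaustive oracle", {
  fx <- make_reversal_fixture()
  got <- find_reversal_pairs(fx$a, fx$b)
  want <- oracle_reversal_pairs(fx$a, fx$b)
  expect_setequal(pair_key(got), pair_key(want))
  expect_true(all(c("g1 g2", "g3 g4") %in% pair_key(got)))
  expect_false("g5 g6" %in% pair_key(got))
  ord <- match(pair_key(want), pair_key(got))
  expect_equal(got$direction_a[ord], want$direction_a)
  expect_equal(got$mean_rank_diff_a[ord], want$mean_rank_diff_a)
  expect_equal(got$mean_rank_diff_b[ord], want$mean_rank_diff_b)

  # concordant classes yield nothing
  expect_equal(nrow(find_reversal_pairs(fx$a, fx$a + 1)), 0)

  # random matrices agree with the oracle too
  for (seed in 1:4) {
    a <- random_expr(12, 3, seed)
    b <- random_expr(12, 3, seed + 50)
    for (f in c(1, 0.66)) {
      got <- find_reversal_pairs(a, b, f = f, strict = FALSE)
      want <- oracle_reversal_pairs(a, b, f = f, strict = FALSE)
      expect_setequal(pair_key(got), pair_key(want))
    }
  }
})

test_that("reversal degree is the geometric mean of class rank diffs", {
  expect_equal(reversal_degree(100, 400), 200)
  expect_equal(reversal_degree(0, 123), 0)
  expect_equal(reversal_degree(77, 77), 77)
  expect_equal(reversal_degree(c(1, 4), c(9, 4)), c(3, 4))
  expect_error(reversal_degree(-1, 4), "non-negative")
  # symmetric under class swap
  fx <- make_reversal_fixture()
  ab <- find_reversal_pairs(fx$a, fx$b)
  ba <- find_reversal_pairs(fx$b, fx$a)
  expect_equal(ab$degree, ba$degree)
  expect_equal(pair_key(ab), pair_key(ba))
  expect_equal(ab$direction_a, -ba$direction_a)
})

test_that("majority vote classifies, drops unmeasured pairs, flags ties", {
  pairs <- data.frame(gene_i = c("g1", "g3", "g5"),
                      gene_j = c("g2", "g4", "g6"),
                      direction_a = c(1L, 1L, 1L),
                      mean_rank_diff_a = c(3, 2, 1),
                      mean_rank_diff_b = c(3, 2, 1),
                      degree = c(3, 2, 1), stringsAsFactors = FALSE)
  sig <- reo_signature(pairs, "pos", "neg", positive = "a", k = "all")

  m <- cbind(all_pos = c(6, 1, 5, 2, 4, 3),
             two_of_three = c(6, 1, 5, 2, 3, 4),
             all_neg = c(1, 6, 2, 5, 3, 4))
  rownames(m) <- paste0("g", 1:6)
  lab <- classify_samples(m, sig)
  expect_equal(lab$label, c("pos", "pos", "neg"))
  expect_equal(lab$votes_positive, c(3, 2, 0))

  # a pair with both genes zero is unmeasurable; one zero still votes
  m2 <- cbind(s = c(6, 1, 0, 0, 0, 3))
  rownames(m2) <- paste0("g", 1:6)
  lab2 <- classify_samples(m2, sig)
  expect_equal(lab2$votes_evaluated, 2)
  expect_equal(lab2$votes_positive, 1)    # g1>g2 pos, g5<g6 neg
  expect_equal(lab2$label, "unclassified")

  # genes absent from the platform drop their pairs
  m3 <- m[1:4, , drop = FALSE]
  lab3 <- classify_samples(m3, sig)
  expect_equal(unique(lab3$votes_evaluated), 2)

  expect_error(classify_samples(m2, sig, min_evaluated = 3),
               "measurable")

  # label depends only on the multiset of votes, not pair order
  perm <- reo_signature(pairs[c(3, 1, 2), ], "pos", "neg",
                        positive = "a", k = "all")
  expect_equal(classify_samples(m, perm)$label, lab$label)
})

test_that("sensitivity and specificity follow the confusion formulas", {
  labels <- c(rep("pos", 10), rep("pos", 2), rep("neg", 8))
  truth <- c(rep("pos", 10), rep("neg", 10))
  out <- evaluate_classification(labels, truth, "pos")
  expect_equal(c(out$TP, out$TN, out$FP, out$FN), c(10, 8, 2, 0))
  expect_equal(out$sensitivity, 1.0)
  expect_equal(out$specificity, 0.8)

  perfect <- evaluate_classification(truth, truth, "pos")
  expect_equal(c(perfect$sensitivity, perfect$specificity), c(1, 1))

  degenerate <- evaluate_classification(rep("pos", 20), truth, "pos")
  expect_equal(c(degenerate$sensitivity, degenerate$specificity), c(1, 0))

  # unclassified counts as wrong for its true class
  u <- suppressWarnings(
    evaluate_classification(c("unclassified", "pos"), c("pos", "pos"),
                            "pos"))
  expect_equal(u$sensitivity, 0.5)
  expect_warning(evaluate_classification("pos", "pos", "pos"),
                 "specificity undefined")
})

test_that("selection returns the smallest k with the best geometric mean", {
  # P1 = (gA, gB) separates training perfectly: k = 1 wins immediately
  pairs <- data.frame(gene_i = c("gA", "gC"), gene_j = c("gB", "gD"),
                      direction_a = c(1L, 1L),
                      mean_rank_diff_a = c(5, 4),
                      mean_rank_diff_b = c(5, 4),
                      degree = c(5, 4), stringsAsFactors = FALSE)
  pos <- cbind(p1 = c(gA = 2, gB = 1, gC = 2, gD = 1),
               p2 = c(gA = 3, gB = 1, gC = 4, gD = 1))
  neg <- cbind(n1 = c(gA = 1, gB = 2, gC = 1, gD = 2),
               n2 = c(gA = 1, gB = 4, gC = 1, gD = 3))
  sig <- select_signature(pairs, pos, neg, positive = "a")
  expect_equal(sig$k, 1)
  expect_equal(sig$k_path$gmean[1], 1)

  # top pair errs on one positive sample; k = 3 fixes it by majority
  pairs3 <- data.frame(gene_i = c("g1", "g3", "g5"),
                       gene_j = c("g2", "g4", "g6"),
                       direction_a = c(1L, 1L, 1L),
                       mean_rank_diff_a = c(5, 4, 3),
                       mean_rank_diff_b = c(5, 4, 3),
                       degree = c(5, 4, 3), stringsAsFactors = FALSE)
  mk <- function(p1, p2, p3, id) {
    v <- c(if (p1) c(2, 1) else c(1, 2),
           if (p2) c(2, 1) else c(1, 2),
           if (p3) c(2, 1) else c(1, 2))
    names(v) <- paste0("g", 1:6)
    m <- matrix(v, ncol = 1, dimnames = list(paste0("g", 1:6), id))
    m
  }
  pos3 <- cbind(mk(TRUE, TRUE, TRUE, "p1"), mk(FALSE, TRUE, TRUE, "p2"))
  neg3 <- cbind(mk(FALSE, FALSE, FALSE, "n1"), mk(FALSE, FALSE, FALSE, "n2"))
  sig3 <- select_signature(pairs3, pos3, neg3, positive = "a")
  expect_equal(sig3$k, 3)
  expect_equal(sig3$k_path$gmean, c(sqrt(0.5), 1))

  expect_error(select_signature(pairs3[0, ], pos3, neg3), "candidate")
})

test_that("rank-difference filtering removes the union of class bottoms", {
  pairs <- data.frame(
    gene_i = sprintf("a%02d", 1:10), gene_j = sprintf("b%02d", 1:10),
    direction_a = 1L,
    mean_rank_diff_a = c(1, 10, 9, 8, 7, 6, 5, 4, 3, 2),
    mean_rank_diff_b = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
    stringsAsFactors = FALSE)
  pairs$degree <- reversal_degree(pairs$mean_rank_diff_a,
                                  pairs$mean_rank_diff_b)
  # same pair smallest in both classes -> union is a singleton, 9 remain
  sig <- reo_signature(pairs, "pos", "neg", positive = "a", k = "all")
  expect_equal(filter_signature_rank_diff(sig, 0.1)$k, 9)
  expect_identical(filter_signature_rank_diff(sig, 0), sig)

  # disjoint bottoms -> 8 remain
  pairs2 <- pairs
  pairs2$mean_rank_diff_a <- c(10, 1, 9, 8, 7, 6, 5, 4, 3, 2)
  sig2 <- reo_signature(pairs2, "pos", "neg", positive = "a", k = "all")
  expect_equal(filter_signature_rank_diff(sig2, 0.1)$k, 8)

  expect_error(filter_signature_rank_diff(sig, 0.99), "smaller fraction")
})

test_that("classification is invariant under monotone transforms", {
  fx <- make_reversal_fixture()
  cand <- find_reversal_pairs(fx$a, fx$b)
  sig <- reo_signature(cand, "B", "A", positive = "b", k = "all")
  m <- cbind(fx$a[, 1:2], fx$b[, 1:2])
  colnames(m) <- c("a1", "a2", "b1", "b2")
  base <- classify_samples(m, sig)
  for (seed in 1:5) {
    f <- random_monotone(seed)
    m_t <- apply(m, 2, f)
    rownames(m_t) <- rownames(m)
    expect_identical(classify_samples(m_t, sig), base)
  }
  expect_equal(base$label, c("A", "A", "B", "B"))
})

test_that("signature files round-trip and the packaged fixture classifies", {
  fx <- make_reversal_fixture()
  sig <- reo_signature(find_reversal_pairs(fx$a, fx$b), "B", "A",
                       positive = "b", k = "all")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_file(sig, path)
  back <- read_signature_file(path)
  expect_equal(back$pairs$gene_i, sig$pairs$gene_i)
  expect_equal(back$pairs$direction_positive,
               sig$pairs$direction_positive)
  expect_equal(back$positive_class, "B")

  fixture <- read_signature_file(
    system.file("extdata", "lymphoma_breast_signature.tsv",
                package = "reosig"))
  expect_equal(fixture$k, 3)
  expect_equal(fixture$positive_class, "lymphoma")
  # a sample with the breast-cancer orderings votes 0/3 positive
  breast <- c(MMP3 = 9, RGS13 = 2, EPCAM = 8, CD37 = 3, STAP1 = 1)
  lymph <- c(MMP3 = 2, RGS13 = 9, EPCAM = 3, CD37 = 8, STAP1 = 7)
  m <- cbind(breast_s = breast, lymph_s = lymph)
  lab <- classify_samples(m, fixture)
  expect_equal(lab$label, c("breast_cancer", "lymphoma"))
  expect_equal(lab$votes_positive, c(0, 3))
})
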