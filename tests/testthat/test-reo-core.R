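test_that("rank profiles use ascending average ranks", {
  expect_equal(unname(rank_profile(c(a = 5, b = 1, c = 3, d = 3))),
               c(4, 1, 2.5, 2.5))
  expect_equal(unname(rank_profile(c(x = 1, y = 2, z = 7))), 1:3)
  expect_equal(unname(rank_profile(c(a = 2, b = 2, c = 2, d = 2))),
               rep(2.5, 4))
  expect_error(rank_profile(c(a = 1, b = NA)), "NA")
})

test_that("replicate-identity stable pairs keep concordant strict orderings", {
  all3 <- stable_pairs_replicates(c(a = 1, b = 2, c = 3),
                                  c(a = 10, b = 20, c = 30))
  expect_equal(all3$n_pairs, 3)
  expect_equal(all3$pairs$direction, rep(-1L, 3))  # gene_j always higher

  none <- stable_pairs_replicates(c(a = 1, b = 2), c(a = 2, b = 1))
  expect_equal(none$n_pairs, 0)

  # adjacent swap drops exactly the swapped pair
  two <- stable_pairs_replicates(c(a = 1, b = 2, c = 3),
                                 c(a = 1, b = 3, c = 2))
  expect_equal(two$n_pairs, 2)
  expect_equal(pair_key(two$pairs), c("a b", "a c"))

  # a tie in one replicate excludes the pair
  tied <- stable_pairs_replicates(c(a = 1, b = 2), c(a = 5, b = 5))
  expect_equal(tied$n_pairs, 0)
})

test_that("frequency rule distinguishes strict > f from >= f", {
  # unanimity across 10 samples passes f = 0.99 strict
  m <- sapply(1:10, function(s) c(g1 = 2 + s / 100, g2 = 1))
  colnames(m) <- paste0("s", 1:10)
  expect_equal(stable_pairs_frequency(m, f = 0.99)$n_pairs, 1)

  # 68 of 69 samples (0.9855) fails the strict 0.99 rule
  m69 <- sapply(1:69, function(s) if (s <= 68) c(g1 = 2, g2 = 1)
                else c(g1 = 1, g2 = 2))
  colnames(m69) <- paste0("s", 1:69)
  expect_equal(stable_pairs_frequency(m69, f = 0.99, strict = TRUE)$n_pairs,
               0)
  # ... but 69/69 would pass; and f = 1 strict = FALSE is unanimity
  expect_equal(stable_pairs_frequency(m69, f = 1, strict = FALSE)$n_pairs,
               0)
  m69[, 69] <- c(2, 1)
  expect_equal(stable_pairs_frequency(m69, f = 1, strict = FALSE)$n_pairs,
               1)

  expect_error(stable_pairs_frequency(m, f = 0.4), "0.5")
})

test_that("consistency score counts maintained orderings", {
  v <- c(a = 1, b = 2, c = 3, d = 4)
  ref <- stable_pairs_replicates(v, v)   # all 6 pairs
  expect_equal(ref$n_pairs, 6)
  expect_equal(consistency_score(ref, v)$score, 1)

  # reversing one adjacent pair breaks exactly 1 of 6
  q <- c(a = 1, b = 2, c = 4, d = 3)
  expect_equal(consistency_score(ref, q)$score, 5 / 6)

  # full reversal breaks everything
  expect_equal(consistency_score(ref, c(a = 4, b = 3, c = 2, d = 1))$score,
               0)

  # ties: discordant keeps them in n, drop removes them
  qt <- c(a = 1, b = 2, c = 3, d = 3)
  disc <- consistency_score(ref, qt)
  expect_equal(disc$n, 6); expect_equal(disc$k, 5)
  drop <- consistency_score(ref, qt, tie_policy = "drop")
  expect_equal(drop$n, 5); expect_equal(drop$k, 5)

  expect_error(consistency_score(ref, c(a = 1, b = 2, c = 3)),
               "intersect_genes")
})

test_that("small-rank-difference exclusion removes floor(x*n) closest pairs", {
  # 5 genes, ranks 1..5: pair (a,b) has the smallest diff among stable set
  v1 <- c(a = 10, b = 11, c = 40, d = 80, e = 200)
  v2 <- c(a = 11, b = 12, c = 45, d = 90, e = 150)
  ref <- stable_pairs_replicates(v1, v2)
  expect_equal(ref$n_pairs, 10)

  expect_identical(exclude_small_rank_diff(ref, 0), ref)

  ex <- exclude_small_rank_diff(ref, 0.1)   # floor(0.1 * 10) = 1
  expect_equal(ex$n_pairs, 9)
  expect_false("a b" %in% pair_key(ex$pairs))

  # flipping only the closest pair: exclusion restores a perfect score
  q <- c(a = 11, b = 10.5, c = 40, d = 80, e = 200)
  s0 <- consistency_score(ref, q)$score
  s1 <- consistency_score(ref, q, exclude_fraction = 0.1)$score
  expect_equal(s0, 9 / 10)
  expect_equal(s1, 1)
  expect_gte(s1, s0)
})

test_that("implicit and materialized references agree exactly", {
  for (seed in 1:6) {
    m <- random_expr(30, 2, seed)
    q <- random_expr(30, 1, seed + 100)[, 1]
    mat <- stable_pairs_replicates(m[, 1], m[, 2], materialize = TRUE)
    imp <- stable_pairs_replicates(m[, 1], m[, 2], materialize = FALSE)
    expect_equal(imp$n_pairs, mat$n_pairs)
    for (x in c(0, 0.1, 0.25)) {
      for (tp in c("discordant", "drop")) {
        a <- consistency_score(mat, q, tie_policy = tp,
                               exclude_fraction = x)
        b <- consistency_score(imp, q, tie_policy = tp,
                               exclude_fraction = x)
        expect_identical(c(a$n, a$k), c(b$n, b$k))
      }
    }
  }
})

test_that("exclusion tie-breaks deterministically at the cutoff", {
  # four genes evenly spaced: all adjacent pairs share rank diff 1
  v <- c(a = 1, b = 2, c = 3, d = 4)
  ref <- stable_pairs_replicates(v, v)
  ex <- exclude_small_rank_diff(ref, 0.4)  # drop 2 of the 3 diff-1 pairs
  expect_equal(ex$n_pairs, 4)
  # lexicographic order drops (a,b) then (b,c)
  expect_false(any(c("a b", "b c") %in% pair_key(ex$pairs)))
  expect_true("c d" %in% pair_key(ex$pairs))

  imp <- stable_pairs_replicates(v, v, materialize = FALSE)
  q <- c(a = 2, b = 1, c = 4, d = 3)
  a <- consistency_score(ref, q, exclude_fraction = 0.4)
  b <- consistency_score(imp, q, exclude_fraction = 0.4)
  expect_identical(c(a$n, a$k), c(b$n, b$k))
})

test_that("scores are invariant under strictly increasing transforms", {
  m <- random_expr(40, 2, 9)
  q <- random_expr(40, 1, 10)[, 1]
  ref <- stable_pairs_replicates(m[, 1], m[, 2])
  base <- consistency_score(ref, q, exclude_fraction = 0.1)
  for (seed in 1:5) {
    f <- random_monotone(seed)
    ref_t <- stable_pairs_replicates(f(m[, 1]), f(m[, 2]))
    expect_identical(ref_t$pairs, ref$pairs)
    tr <- consistency_score(ref_t, f(q), exclude_fraction = 0.1)
    expect_identical(c(tr$n, tr$k), c(base$n, base$k))
  }
})
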