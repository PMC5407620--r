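test_that("identical and disjoint path sets bound the overlap factor", {
  ident <- make_paths(matrix(rep(c("a", "b", "c"), each = 3), nrow = 3))
  for (i in 1:3) {
    of <- path_overlap_factor(ident, i)
    expect_equal(of$cardinality, 2)
    expect_setequal(of$set, setdiff(1:3, i))
    expect_setequal(edge_overlap_factor(ident, i, 1), setdiff(1:3, i))
  }

  disj <- make_paths(rbind(c("a", "b", "c"), c("d", "e", "f"),
                           c("g", "h", "i")))
  for (i in 1:3) {
    expect_equal(path_overlap_factor(disj, i)$cardinality, 0)
    expect_length(edge_overlap_factor(disj, i, 2), 0)
  }
})

test_that("edge equality requires the same transition index", {
  # path 2 uses the pair (a,b) but at transition 2, so it does not match
  ps <- make_paths(rbind(c("a", "b", "c"),
                         c("x", "a", "b")))
  expect_length(edge_overlap_factor(ps, 1, 1), 0)
  expect_length(edge_overlap_factor(ps, 2, 2), 0)

  # unordered pair: b-a matches a-b at the same transition
  ps2 <- make_paths(rbind(c("a", "b", "c"),
                          c("b", "a", "x")))
  expect_equal(edge_overlap_factor(ps2, 1, 1), 2L)
})

test_that("hand-built paths match the exhaustive pairwise comparison oracle", {
  m <- rbind(c("a", "b", "c", "d"),
             c("a", "b", "x", "d"),
             c("q", "b", "c", "d"),
             c("a", "b", "c", "e"),
             c("z", "y", "x", "w"))
  ps <- make_paths(m)
  for (i in 1:5) {
    want <- integer(0)
    for (mm in setdiff(1:5, i)) {
      for (j in 1:3) {
        same <- setequal(m[i, j:(j + 1)], m[mm, j:(j + 1)]) &&
          identical(sort(m[i, j:(j + 1)]), sort(m[mm, j:(j + 1)]))
        if (same) want <- union(want, mm)
      }
    }
    expect_setequal(path_overlap_factor(ps, i)$set, want)
  }
})

test_that("overlap sets are symmetric, bounded, and grow by one per duplicate", {
  for (seed in 1:4) {
    ps <- random_path_set(25, t = 4, n_nodes = 5, seed = seed)
    rep <- overlap_summary(ps)
    n <- length(ps)
    for (i in seq_len(n)) {
      expect_true(all(rep$sets[[i]] != i))
      expect_gte(rep$overlap_factors[i], 0)
      expect_lte(rep$overlap_factors[i], n - 1)
      for (m in rep$sets[[i]]) expect_true(i %in% rep$sets[[m]])
    }
  }
  # duplicating path i increases |O(P_i)| by exactly 1
  ps <- random_path_set(10, seed = 9)
  base <- path_overlap_factor(ps, 3)$cardinality
  dup <- make_paths(rbind(ps$processes, ps$processes[3, ]))
  expect_equal(path_overlap_factor(dup, 3)$cardinality, base + 1)
})

test_that("overlap summary means equal the per-path loop", {
  ps <- random_path_set(30, t = 5, n_nodes = 4, seed = 2)
  rep <- overlap_summary(ps)
  cards <- vapply(seq_len(30), function(i) path_overlap_factor(ps, i)$cardinality, 0L)
  expect_equal(rep$overlap_factors, cards)
  expect_equal(rep$mean_overlap_factor, mean(cards))

  id4 <- make_paths(matrix(rep(c("a", "b", "c"), each = 4), nrow = 4))
  expect_equal(overlap_summary(id4)$mean_overlap_factor, 3)
})

test_that("resampled null reproduces degenerate pools exactly", {
  ident <- make_paths(matrix(rep(c("a", "b", "c"), each = 30), nrow = 30))
  rs <- resampled_null(ident, set_size = 10, n_reps = 20, seed = 1)
  expect_true(all(rs$mean_overlap_factor == 9))

  disj <- make_paths(t(sapply(1:30, function(i)
    paste0(letters[(i %% 26) + 1], 1:4, "_", i))))
  rs2 <- resampled_null(disj, set_size = 10, n_reps = 20, seed = 1)
  expect_true(all(rs2$mean_overlap_factor == 0))

  expect_error(resampled_null(ident, set_size = 50, n_reps = 5), "smaller")

  # two seeds: distinct draws, concordant distributions
  pool <- random_path_set(200, t = 4, n_nodes = 6, seed = 3)
  a <- resampled_null(pool, set_size = 50, n_reps = 60, seed = 1)
  b <- resampled_null(pool, set_size = 50, n_reps = 60, seed = 2)
  expect_false(identical(a$mean_overlap_factor, b$mean_overlap_factor))
  expect_gt(suppressWarnings(
    ks.test(a$mean_overlap_factor, b$mean_overlap_factor)$p.value), 0.01)
})

test_that("distribution comparison matches the rank-sum formula and flags ties", {
  a <- random_path_set(20, t = 4, n_nodes = 4, seed = 5)
  b <- random_path_set(20, t = 4, n_nodes = 8, seed = 6)
  cmp <- compare_overlap_distributions(a, b)
  oa <- overlap_summary(a)$overlap_factors
  ob <- overlap_summary(b)$overlap_factors
  # direct rank-sum computation of the U statistic
  r <- rank(c(oa, ob))
  u <- sum(r[seq_along(oa)]) - length(oa) * (length(oa) + 1) / 2
  expect_equal(cmp$overlap_u, u)

  same <- compare_overlap_distributions(a, a)
  expect_gt(same$overlap_pvalue, 0.9)

  id1 <- make_paths(matrix(rep(c("a", "b"), each = 3), nrow = 3))
  tied <- compare_overlap_distributions(id1, id1)
  expect_true(tied$ties)
})

test_that("coverage search finds the converging clusters", {
  ident <- make_paths(matrix(rep(c("a", "b", "c"), each = 6), nrow = 6))
  b1 <- best_covering(ident, k = 1)
  expect_equal(b1$fraction, 1.0)
  expect_equal(nrow(b1$indices), 6)   # all tied

  # two disjoint converging clusters: the optimal pair spans both
  cl1 <- matrix(rep(c("a", "b", "c"), each = 4), nrow = 4)
  cl2 <- matrix(rep(c("x", "y", "z"), each = 3), nrow = 3)
  both <- make_paths(rbind(cl1, cl2))
  b2 <- best_covering(both, k = 2)
  expect_equal(b2$covered, 7)
  expect_equal(b2$fraction, 1.0)
  for (r in seq_len(nrow(b2$indices))) {
    expect_true(min(b2$indices[r, ]) <= 4 && max(b2$indices[r, ]) >= 5)
  }

  # pair coverage never below single coverage
  ps <- random_path_set(40, t = 4, n_nodes = 5, seed = 7)
  expect_lte(best_covering(ps, 1)$covered, best_covering(ps, 2)$covered)

  expect_error(best_covering(ps, k = 2, max_paths = 10), "max_paths")
})

test_that("bundle thickness equals the edge overlap cardinality", {
  ps <- random_path_set(15, t = 4, n_nodes = 4, seed = 8)
  bd <- path_bundle_data(ps)
  expect_equal(sum(bd$nodes$n_paths), 15 * 4)
  for (r in sample(nrow(bd$edges), 10)) {
    e <- bd$edges[r, ]
    a <- ps$processes[, e$transition]
    b <- ps$processes[, e$transition + 1]
    i <- which((a == e$from & b == e$to) | (a == e$to & b == e$from))[1]
    expect_equal(e$thickness,
                 length(edge_overlap_factor(ps, i, e$transition)))
  }

  single <- make_paths(matrix(c("a", "b", "c"), nrow = 1))
  expect_true(all(path_bundle_data(single)$edges$thickness == 0))

  id5 <- make_paths(matrix(rep(c("a", "b", "c"), each = 5), nrow = 5))
  expect_true(all(path_bundle_data(id5)$edges$thickness == 4))
})
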