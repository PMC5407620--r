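test_that("gene ranking is by descending |FC| with alphabetical tie-break", {
  mat <- cbind("Day 1" = c(a = -3, b = 2, c = 0.5))
  r <- rank_genes(mat, "Day 1")
  expect_equal(r$genes, c("a", "b", "c"))
  expect_equal(r$weights, c(-3, 2, 0.5))

  mat2 <- cbind("Day 1" = c(z = 1.5, a = -1.5, m = 0.2))
  expect_equal(rank_genes(mat2, 1)$genes, c("a", "z", "m"))

  set.seed(42)
  v <- rnorm(100)
  mat3 <- cbind("Day 1" = v)
  rownames(mat3) <- sprintf("g%03d", 1:100)
  got <- rank_genes(mat3, 1)$genes
  want <- rownames(mat3)[order(-abs(v), rownames(mat3))]
  expect_equal(got, want)

  expect_error(rank_genes(mat, "Day 9"), "unknown time point")
})

test_that("running sum matches direct summation and terminates at zero", {
  mat <- cbind("Day 1" = c(a = 1, b = 1, c = 1, d = 1))
  r <- rank_genes(mat, 1)
  expect_equal(running_sum(r, c("a", "b")), c(0.5, 1.0, 0.5, 0.0))
  expect_equal(running_sum(r, c("c", "d")), c(-0.5, -1.0, -0.5, 0.0))

  set.seed(7)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    v <- rnorm(n) * sample(c(0.2, 1, 5), 1)
    m <- cbind("Day 1" = v)
    rownames(m) <- sprintf("g%03d", seq_len(n))
    rk <- rank_genes(m, 1)
    set <- sample(rk$genes, sample(2:(n - 2), 1))
    rs <- running_sum(rk, set)
    expect_equal(rs, naive_running_sum(rk$genes, rk$weights, set),
                 tolerance = 1e-12)
    expect_equal(rs[n], 0, tolerance = 1e-9)
  }

  expect_error(running_sum(r, c("zz")), "no member")
  expect_error(running_sum(r, c("a", "b", "c", "d")), "whole ranked list")
})

test_that("enrichment score is the running-sum maximum plus minimum", {
  # perfect top enrichment scores 1, perfect bottom -1
  mat <- cbind("Day 1" = rep(1, 10))
  rownames(mat) <- sprintf("g%02d", 1:10)
  r <- rank_genes(mat, 1)
  expect_equal(enrichment_score(r, sprintf("g%02d", 1:3)), 1)
  expect_equal(enrichment_score(r, sprintf("g%02d", 8:10)), -1)

  # worked example: N = 5, |r| = (5,4,3,2,1), hits at ranks 1, 3, 5
  m2 <- cbind("Day 1" = c(a = 5, b = 4, c = 3, d = 2, e = 1))
  r2 <- rank_genes(m2, 1)
  expect_equal(running_sum(r2, c("a", "c", "e")),
               c(5 / 9, 5 / 9 - 0.5, 8 / 9 - 0.5, 8 / 9 - 1, 0),
               tolerance = 1e-12)
  expect_equal(enrichment_score(r2, c("a", "c", "e")), 5 / 9 + 8 / 9 - 1,
               tolerance = 1e-12)
})

test_that("enrichment score equals the naive double-loop oracle on random instances", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(15:80, 1)
    v <- rnorm(n) * runif(1, 0.1, 4)
    m <- cbind("Day 1" = v)
    rownames(m) <- sprintf("g%03d", seq_len(n))
    rk <- rank_genes(m, 1)
    set <- sample(rk$genes, sample(2:(n - 3), 1))
    expect_equal(enrichment_score(rk, set),
                 naive_es(rk$genes, rk$weights, set), tolerance = 1e-12)
  }
})

test_that("enrichment score is invariant to positive rescaling of fold changes", {
  set.seed(3)
  v <- rnorm(40)
  m <- cbind("Day 1" = v)
  rownames(m) <- sprintf("g%03d", 1:40)
  rk <- rank_genes(m, 1)
  set <- sample(rownames(m), 8)
  e1 <- enrichment_score(rk, set)
  for (c in c(0.01, 3, 250)) {
    mc <- m * c
    expect_equal(enrichment_score(rank_genes(mc, 1), set), e1,
                 tolerance = 1e-12)
  }
})

test_that("permutation null is reproducible and centered under equal weights", {
  mat <- cbind("Day 1" = rep(1, 1000))
  rownames(mat) <- sprintf("g%04d", 1:1000)
  r <- rank_genes(mat, 1)
  a <- permutation_null(r, set_size = 50, n_perm = 300, seed = 99)
  b <- permutation_null(r, set_size = 50, n_perm = 300, seed = 99)
  expect_identical(a, b)
  # equal weights make the max+min statistic symmetric around 0
  expect_lt(abs(mean(a)), 0.05)
  expect_length(permutation_null(r, 10, n_perm = 1, seed = 1), 1)
  expect_error(permutation_null(r, 10, n_perm = 0), "n_perm")
})

test_that("normalization and p-value follow the sign-matched-portion rule", {
  res <- normalize_and_pvalue(0.5, c(0.25, 0.25, -0.3))
  expect_equal(res$nes, 2.0)
  expect_equal(res$pvalue, 0)

  # ties count via 'or equal'
  expect_equal(normalize_and_pvalue(0.4, rep(0.4, 10))$pvalue, 1)

  # zero es is degenerate by convention
  expect_equal(normalize_and_pvalue(0, c(0.1, -0.2))$nes, 0)

  # negative es uses the negative portion and the lower tail
  rn <- normalize_and_pvalue(-0.5, c(-0.25, 0.3, -0.75))
  expect_equal(rn$nes, -0.5 / 0.5)
  expect_equal(rn$pvalue, 1 / 3)

  # empty sign-matched portion: nes undefined, p floored at 1/n_perm
  rd <- normalize_and_pvalue(0.5, c(-0.1, -0.2, -0.3, -0.4))
  expect_true(is.na(rd$nes))
  expect_equal(rd$pvalue, 0.25)
  expect_true(rd$degenerate)
})

test_that("the enrichment grid has the right shape and planted signal wins its column", {
  sc <- small_scenario(seed = 21)
  expect_equal(dim(sc$nm$nes), c(length(sc$lib), 5L))
  expect_equal(sc$nm$processes, names(sc$lib$sets))
  # the planted process attains the column-maximum nes at its own time point
  for (j in seq_len(5)) {
    expect_equal(sc$nm$processes[which.max(sc$nm$nes[, j])], sc$sl$planted[j])
  }
  # higher nes associates with lower p-value among positive-es results
  pos <- !is.na(sc$nm$es) & sc$nm$es > 0
  ct <- suppressWarnings(
    cor.test(sc$nm$nes[pos], sc$nm$pvalue[pos], method = "spearman"))
  expect_lt(ct$estimate, 0)
  # higher nes associates with higher mean |FC| of the set's genes
  mfc <- vapply(names(sc$lib$sets), function(p) {
    mean(abs(sc$mat[intersect(sc$lib$sets[[p]], rownames(sc$mat)), 1]))
  }, 0.0)
  expect_gt(cor(mfc, sc$nm$nes[, 1], method = "spearman", use = "complete.obs"), 0)
})

test_that("long-format export carries one row per grid cell", {
  sc <- small_scenario(seed = 5, n_genes = 300, n_processes = 12,
                       n_timepoints = 3, n_perm = 50)
  long <- nes_long(sc$nm)
  expect_equal(nrow(long), length(sc$lib) * 3L)
  i <- sample(nrow(long), 1)
  expect_equal(long$nes[i], sc$nm$nes[long$process[i], long$timepoint[i]])
})
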