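test_that("cross-dataset path evaluation aligns the last k positions", {
  grid <- matrix(as.numeric(1:30), 3, 10,
                 dimnames = list(c("a", "b", "c"), paste("Day", 1:10)))
  nm <- fake_nes(grid)
  path <- rep(c("a", "b"), 5)
  # full-width evaluation reproduces path_mean_nes exactly
  expect_equal(path_nes_in_dataset(path, nm), path_mean_nes(path, nm))

  # k = 3: path positions 8..10 against dataset time points 1..3
  nm3 <- fake_nes(grid[, 1:3])
  expect_equal(path_nes_in_dataset(path, nm3),
               mean(grid[cbind(match(path[8:10], rownames(grid)), 1:3)]))

  # absent process: excluded with a warning
  nm_missing <- fake_nes(grid[c("a", "c"), 1:2])
  expect_warning(v <- path_nes_in_dataset(c("a", "b"), nm_missing), "absent")
  expect_equal(v, grid["a", 1])
})

test_that("precision arithmetic matches the reported percentages", {
  p1 <- precision_from_counts(1, 10)
  expect_equal(p1$precision, 100 / 11)
  expect_equal(p1$percent, 9)
  expect_equal(precision_from_counts(1, 0)$percent, 100)
  expect_equal(precision_from_counts(0, 5)$precision, 0)
  expect_error(precision_from_counts(0, 0), "at least 1")
})

test_that("exceedance probability is the exceedance fraction", {
  expect_equal(round(exceedance_probability(10, 194), 3), 0.052)
  expect_equal(exceedance_probability(0, 7), 0)
  expect_equal(exceedance_probability(7, 7), 1)
  expect_error(exceedance_probability(8, 7), "n_exceed")
  expect_error(exceedance_probability(1, 0), "positive integer")
})

test_that("process baseline counts exceedances conservatively (ties count against)", {
  set.seed(12)
  grid <- matrix(rnorm(40), 4, 10,
                 dimnames = list(paste0("p", 1:4), paste("Day", 1:10)))
  grid["p2", 3] <- 100   # globally maximal source value
  nm <- fake_nes(grid)
  decoys <- lapply(1:3, function(i)
    fake_nes(matrix(rnorm(40), 4, 10, dimnames = dimnames(grid))))
  rep <- process_precision_baseline("p2", nm, "Day 3", decoys)
  expect_equal(rep$n_exceed, 0)
  expect_equal(rep$percent, 100)
  expect_equal(rep$n_total, 9 + 3 * 10)

  # a tie with the source value counts as a false positive
  grid2 <- grid
  grid2["p2", 5] <- 100
  rep2 <- process_precision_baseline("p2", fake_nes(grid2), "Day 3", decoys)
  expect_equal(rep2$n_exceed, 1)
  expect_equal(rep2$percent, 50)

  # identically distributed decoys leave the source near rank-uniformity
  set.seed(99)
  fracs <- replicate(40, {
    g <- matrix(rnorm(20), 2, 10,
                dimnames = list(c("p1", "p2"), paste("Day", 1:10)))
    r <- process_precision_baseline(
      "p1", fake_nes(g), 1,
      list(fake_nes(matrix(rnorm(20), 2, 10, dimnames = dimnames(g)))))
    r$exceedance_probability
  })
  expect_gt(mean(fracs), 0.3)
  expect_lt(mean(fracs), 0.7)
})

test_that("path-level precision separates the source from decoy datasets", {
  sc <- small_scenario(seed = 23)
  g1 <- systematic_paths(sc$nm, sc$net, branch = 1)
  path <- g1$processes[1, ]
  decoys <- lapply(1:4, function(i) {
    fcd <- make_fc_matrix(sc$spec, sc$sl$library, seed = 100 + i,
                          planted = character(0))
    nes_matrix(drop_never_perturbed(fcd$matrix), sc$lib, n_perm = 60,
               seed = 100 + i)
  })
  pr <- path_precision(path, sc$nm, decoys)
  expect_equal(pr$n_exceed, 0)
  expect_equal(pr$percent, 100)
  expect_equal(pr$exceedance_probability, 0)
  expect_equal(pr$source_value, g1$mean_nes)
})

test_that("gene-process graphs flag connector genes from the planted chain", {
  sc <- small_scenario(seed = 29)
  path <- sc$sl$planted
  gp <- gene_process_graph(path, sc$lib, sc$mat)
  # every planted connector gene links consecutive processes above the cutoff
  for (r in seq_len(nrow(sc$sl$connectors))) {
    cg <- sc$sl$connectors$gene[r]
    if (cg %in% rownames(sc$mat)) expect_true(cg %in% gp$connectors)
  }
  expect_true(all(gp$multi_connectors %in% gp$connectors))
  expect_true(igraph::is_bipartite(gp$graph))
  # table rows respect the cutoff
  expect_true(all(abs(gp$table$fold_change) > 1))

  # gene ordering in the library does not change the edge set
  lib2 <- geneset_library(lapply(sc$lib$sets, rev), sc$lib$descriptions)
  gp2 <- gene_process_graph(path, lib2, sc$mat)
  expect_setequal(apply(igraph::as_edgelist(gp$graph), 1, paste, collapse = "|"),
                  apply(igraph::as_edgelist(gp2$graph), 1, paste, collapse = "|"))

  # a process with nothing above the cutoff keeps its node and warns
  tiny_lib <- geneset_library(list(A = c("g1", "g2"), B = c("g2", "g3")))
  m <- matrix(c(2, 2, 0.1, 0.1, 0.1, 0.2), 3, 2,
              dimnames = list(c("G1", "G2", "G3"), c("Day 1", "Day 2")))
  expect_warning(gpe <- gene_process_graph(c("A", "B"), tiny_lib, m), "no gene")
  expect_true("B@2" %in% igraph::V(gpe$graph)$name)

  prefix <- withr::local_tempfile()
  write_gene_process_graph(gp, prefix)
  expect_true(file.size(paste0(prefix, ".graphml")) > 0)
  expect_gt(nrow(read.delim(paste0(prefix, ".tsv"))), 0)
})
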