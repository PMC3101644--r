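test_that("simulate_model_tree produces labelled Yule trees", {
  tr <- simulate_model_tree(10, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), sort(paste0("T", 1:10)))
  expect_equal(tr$Nnode, 9L)             # rooted binary
  expect_error(simulate_model_tree(3), "n")
  # determinism and variability
  expect_identical(write_newick(simulate_model_tree(10, seed = 5)),
                   write_newick(simulate_model_tree(10, seed = 5)))
  tops <- vapply(1:20, function(s)
    paste(bipartition_set(simulate_model_tree(10, seed = s)), collapse = ";"),
    character(1))
  expect_gt(length(unique(tops)), 1)
})

test_that("deviation_sd = 0 gives an ultrametric tree of the set height", {
  tr <- simulate_model_tree(12, deviation_sd = 0, seed = 3, height = 2)
  depth <- ape::node.depth.edgelength(tr)[1:12]
  expect_true(all(abs(depth - 2) < 1e-9))
  trd <- simulate_model_tree(12, deviation_sd = 0.5, seed = 3, height = 2)
  depthd <- ape::node.depth.edgelength(trd)[1:12]
  expect_gt(diff(range(depthd)), 1e-6)
})

test_that("gene leaf sets are clades minus subclades with >= min_leaves", {
  tr <- simulate_model_tree(16, seed = 2)
  ls0 <- assign_gene_leafsets(tr, 5, loss_rate = 0, gain_node = 17L, seed = 1)
  for (g in 1:5) expect_setequal(ls0[[g]], tr$tip.label)   # root gain, no loss
  ls <- assign_gene_leafsets(tr, 20, loss_rate = 0.5, min_leaves = 4, seed = 9)
  gains <- attr(ls, "gain_nodes"); losses <- attr(ls, "loss_nodes")
  desc <- phangorn::Descendants(tr, seq_len(16 + tr$Nnode), "tips")
  for (g in seq_along(ls)) {
    expect_gte(length(ls[[g]]), 4)
    clade <- tr$tip.label[desc[[gains[g]]]]
    lost <- tr$tip.label[unique(unlist(desc[losses[[g]]]))]
    expect_setequal(ls[[g]], setdiff(clade, lost))
  }
  expect_error(assign_gene_leafsets(tr, 1, min_leaves = 17), "min_leaves")
})

test_that("gene gains follow branch lengths (binomial law)", {
  tr <- simulate_model_tree(8, seed = 4)
  ls <- assign_gene_leafsets(tr, 1000, loss_rate = 0, min_leaves = 1,
                             root_gain_prob = 0, seed = 11)
  gains <- attr(ls, "gain_nodes")
  # the child below the longest edge
  long_edge <- which.max(tr$edge.length)
  node <- tr$edge[long_edge, 2]
  p <- tr$edge.length[long_edge] / sum(tr$edge.length)
  phat <- mean(gains == node)
  se <- sqrt(p * (1 - p) / 1000)
  expect_lt(abs(phat - p), 3 * se + 1e-12)
})

test_that("evolve_sequences respects the model limits", {
  tr <- simulate_model_tree(6, seed = 5)
  m <- gtr_preset()
  tr0 <- tr; tr0$edge.length <- rep(0, nrow(tr0$edge))
  aln0 <- evolve_sequences(tr0, m, 200, seed = 1)
  expect_true(all(apply(aln0, 2, function(col) length(unique(col)) == 1)))
  # high invariable proportion: nearly all sites constant
  mi <- gtr_model(rep(1, 6), rep(0.25, 4), alpha = 100, p_inv = 0.99)
  alni <- evolve_sequences(tr, mi, 5000, seed = 2)
  const <- mean(apply(alni, 2, function(col) length(unique(col)) == 1))
  expect_gt(const, 0.95)
  # long single branch converges to stationary frequencies
  m2 <- gtr_model(c(1, 2, 1, 1, 2, 1), c(0.4, 0.3, 0.2, 0.1))
  t2 <- read_newick("(a:8,b:8);")
  aln2 <- evolve_sequences(t2, m2, 50000, seed = 3)
  freq <- table(factor(aln2["a", ], levels = c("A", "C", "G", "T"))) / 50000
  expect_true(all(abs(as.numeric(freq) - c(0.4, 0.3, 0.2, 0.1)) < 0.015))
  expect_error(gtr_model(rep(1, 6), c(0.5, 0.5, 0.5, 0.5)), "sum")
})

test_that("the built-in estimator is consistent on generous data", {
  ok <- 0
  for (s in 1:10) {
    t0 <- simulate_model_tree(8, deviation_sd = 0.2, seed = 700 + s)
    aln <- evolve_sequences(t0, gtr_preset(), 5000, seed = 800 + s)
    est <- estimate_source_tree(list(g = aln))
    expect_setequal(est$tip.label, t0$tip.label)
    er <- error_rates(est, unroot_tree(t0))
    if (er[["fn"]] == 0) ok <- ok + 1
  }
  expect_gte(ok, 8)
  expect_error(estimate_source_tree(list(g = matrix("A", 3, 10,
    dimnames = list(c("a", "b", "c"), NULL)))), "4 taxa")
})

test_that("build_profile is deterministic and tree-consistent", {
  cond <- model_condition(12, 1.0, "mixed", estimator = "true", sites = 50)
  b1 <- build_profile(cond, seed = 6)
  b2 <- build_profile(cond, seed = 6)
  expect_identical(b1$profile$manifest, b2$profile$manifest)
  expect_identical(write_newick(b1$model_tree), write_newick(b2$model_tree))
  for (tr in b1$profile$trees) {
    expect_true(all(tr$tip.label %in% b1$model_tree$tip.label))
    t0r <- unroot_tree(restrict(b1$model_tree, tr$tip.label))
    expect_equal(error_rates(unroot_tree(tr), t0r)[["fn"]], 0)
  }
  expect_equal(sum(b1$profile$tags == "scaffold"), 1)
})

test_that("all-scaffold profiles contain only scaffolds of the right size", {
  cond <- model_condition(16, 0.5, "all-scaffold", estimator = "true",
                          sites = 50)
  b <- build_profile(cond, seed = 7)
  expect_true(all(b$profile$tags == "scaffold"))
  for (ds in b$datasets) expect_lte(length(ds$taxa), 8)
  expect_error(model_condition(16, 0.1, "mixed"), "scaffold")
})

test_that("fasta files round trip", {
  aln <- matrix(sample(c("A", "C", "G", "T"), 40, TRUE), 4, 10,
                dimnames = list(c("t1", "t2", "t3", "t4"), NULL))
  f <- tempfile(fileext = ".fasta")
  write_fasta(aln, f)
  back <- read_fasta(f)
  expect_equal(back[rownames(aln), ], aln, ignore_attr = TRUE)
})
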