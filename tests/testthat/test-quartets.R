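test_that("quartet_set canonicalises, aggregates and prints", {
  qs <- quartet_set(c("a,b|c,d", "a,b|c,d", "a,c|b,d"), c(1, 2, 1))
  expect_equal(nrow(qs), 2)
  expect_equal(qs$weight[qs$topology == "a,b|c,d"], 3)
  expect_setequal(attr(qs, "taxa"), letters[1:4])
  expect_output(print(qs), "quartet_set")
})

test_that("quartet_diameter counts edges on the longest pairwise path", {
  tr <- ape::unroot(read_newick("((a,b),(c,d));"))
  expect_equal(quartet_diameter(tr, letters[1:4]), 3L)
  cat8 <- read_newick("((a,b),(c,(d,(e,(f,(g,h))))));")
  expect_equal(quartet_diameter(ape::unroot(cat8), c("a", "b", "g", "h")), 7L)
  expect_error(quartet_diameter(tr, c("a", "b", "c", "zz")), "zz")
  t0 <- rand_topo(9, 11)
  D <- oracle_topo_dist(t0)
  for (k in 1:20) {
    q <- with_seed(k, sample(t0$tip.label, 4))
    expect_equal(quartet_diameter(t0, q), max(D[q, q]))
  }
})

test_that("all_quartets has C(n,4) entries on binary trees and matches the oracle", {
  t5 <- rand_topo(5, 2)
  expect_equal(nrow(all_quartets(t5)), choose(5, 4))
  st <- star_tree(letters[1:4])
  aq <- all_quartets(st)
  expect_equal(nrow(aq), 0)
  expect_equal(attr(aq, "n_unresolved"), 1L)
  for (s in 1:3) {
    t8 <- rand_topo(8, 400 + s)
    qs <- all_quartets(t8)
    expect_equal(nrow(qs), choose(8, 4))
    for (i in seq_len(nrow(qs))) {
      labs <- sort(unique(strsplit(qs$topology[i], "[,|]")[[1]]))
      expect_equal(qs$topology[i], oracle_induced_quartet(t8, labs))
    }
  }
})

test_that("tsq_trees implements the short-quartet construction with ties", {
  tr <- read_newick("((a,b),(c,d));")
  expect_equal(tsq_trees(tr)$topology, "a,b|c,d")
  # cherry edge of ((a,b),(c,d),(e,f)): ties give 4 TSQs around that edge
  t3 <- read_newick("((a,b),(c,d),(e,f));")
  tsq <- tsq_trees(t3)$topology
  expect_true(all(c("a,b|c,e", "a,b|c,f", "a,b|d,e", "a,b|d,f") %in% tsq))
  # subset of all quartets; topologies agree with the source tree
  for (s in 1:5) {
    t0 <- rand_topo(10, 500 + s)
    tsq0 <- tsq_trees(t0)$topology
    expect_true(all(tsq0 %in% all_quartets(t0)$topology))
  }
})

test_that("every internal edge lies on the internal path of one of its TSQs", {
  separates <- function(key, qtop) {
    sides <- strsplit(strsplit(key, "|", fixed = TRUE)[[1]], ",")
    prs <- strsplit(strsplit(qtop, "|", fixed = TRUE)[[1]], ",")
    (all(prs[[1]] %in% sides[[1]]) && all(prs[[2]] %in% sides[[2]])) ||
      (all(prs[[1]] %in% sides[[2]]) && all(prs[[2]] %in% sides[[1]]))
  }
  for (s in 1:30) {
    t0 <- rand_topo(10, 600 + s)
    tsq <- tsq_trees(t0)$topology
    for (key in bipartition_set(t0))
      expect_true(any(vapply(tsq, separates, logical(1), key = key)))
  }
})

test_that("sampled encodings keep the TSQs and sample from all_quartets", {
  cat12 <- ape::unroot(with_seed(1, ape::rtree(12)))
  cat12$edge.length <- NULL
  tsq <- tsq_trees(cat12)$topology
  for (s in 1:5) for (rule in c("geo", "exp")) {
    enc <- sampled_encoding(cat12, rule, seed = s)
    expect_true(all(tsq %in% enc$topology))
    expect_true(all(enc$topology %in% all_quartets(cat12)$topology))
    expect_true(all(enc$weight == 1))
  }
  # deterministic under seed
  e1 <- sampled_encoding(cat12, "exp", seed = 99)
  e2 <- sampled_encoding(cat12, "exp", seed = 99)
  expect_identical(e1$topology, e2$topology)
})

test_that("encode_profile combines weighted multisets", {
  t0 <- rand_topo(6, 3)
  two <- encode_profile(list(t0, t0), "all")
  expect_true(all(two$weight == 2))
  expect_equal(attr(two, "n_quartets"), 2 * choose(6, 4))
  one <- encode_profile(list(t0), "all")
  expect_identical(one$topology, all_quartets(t0)$topology)
  # disjoint taxa: counts add, no shared quartets
  tb <- rand_topo(5, 4); tb$tip.label <- paste0("z", seq_len(5))
  both <- encode_profile(list(t0, tb), "all")
  expect_equal(sum(both$weight), choose(6, 4) + choose(5, 4))
  expect_true(all(both$weight == 1))
  # union mode deduplicates
  uni <- encode_profile(list(t0, t0), "all", combine = "union")
  expect_true(all(uni$weight == 1))
})

test_that("quartet files round trip byte-stably", {
  qs <- quartet_set(c("a,b|c,d", "a,c|b,e", "b,d|c,e"), c(2, 1, 3))
  f <- withr::local_tempfile()
  write_quartets(qs, f)
  back <- read_quartets(f)
  expect_equal(as.data.frame(back), as.data.frame(qs))
  f2 <- withr::local_tempfile()
  write_quartets(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # weight-less lines read as weight 1
  f3 <- withr::local_tempfile()
  writeLines(c("a,b|c,d", "a,c|b,e\t4"), f3)
  q3 <- read_quartets(f3)
  expect_equal(q3$weight[q3$topology == "a,b|c,d"], 1)
  expect_equal(q3$weight[q3$topology == "a,c|b,e"], 4)
})
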