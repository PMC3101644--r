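test_that("newick round trip preserves topology, labels and lengths", {
  tr <- read_newick("((a,b),(c,d));")
  expect_equal(sort(tr$tip.label), c("a", "b", "c", "d"))
  expect_equal(bipartition_set(ape::unroot(tr)), "a,b|c,d",
               ignore_attr = TRUE)
  for (s in 1:20) {
    t0 <- with_seed(s, ape::rtree(sample(4:12, 1)))
    t1 <- read_newick(write_newick(t0))
    expect_true(topo_equal(t0, t1))
    expect_equal(sort(t1$tip.label), sort(t0$tip.label))
  }
})

test_that("malformed newick and bad labels are rejected with positions", {
  expect_error(read_newick("((a,b,(c);"), "unclosed|position")
  expect_error(read_newick("(a,b))c;"), "unmatched.*position")
  expect_error(read_newick("((a,b),(c,d))"), ";")
  expect_error(read_newick("((a,b),(a,c));"), "duplicate")
})

test_that("bipartition_set enumerates internal edges", {
  expect_equal(bipartition_set(read_newick("((a,b),(c,d));")), "a,b|c,d",
               ignore_attr = TRUE)
  expect_length(bipartition_set(star_tree(letters[1:5])), 0)
  cat6 <- read_newick("(((((a,b),c),d),e),f);")
  expect_setequal(bipartition_set(cat6),
                  c("a,b|c,d,e,f", "a,b,c|d,e,f", "a,b,c,d|e,f"))
  for (n in c(5, 8, 13)) {
    tr <- rand_topo(n, n)
    expect_length(bipartition_set(tr), n - 3)
  }
})

test_that("restrict matches the bipartition-restriction oracle", {
  tr <- read_newick("((a,b),(c,d),(e,f));")
  expect_true(topo_equal(restrict(tr, c("a", "c", "e")),
                         star_tree(c("a", "c", "e"))))
  expect_error(restrict(tr, c("a", "b", "zz")), "zz")
  for (s in 1:10) {
    t0 <- rand_topo(10, 100 + s)
    expect_true(topo_equal(restrict(t0, t0$tip.label), t0))
    for (k in 1:5) {
      sub <- with_seed(s * 10 + k, sort(sample(t0$tip.label, sample(4:8, 1))))
      got <- bipartition_set(restrict(t0, sub))
      want <- unique(unlist(lapply(bipartition_set(t0), function(key) {
        sides <- strsplit(strsplit(key, "|", fixed = TRUE)[[1]], ",")
        a <- intersect(sides[[1]], sub); b <- intersect(sides[[2]], sub)
        if (length(a) >= 2 && length(b) >= 2) make_key(a, b)
      })))
      expect_setequal(got, want)
    }
  }
})

test_that("restrict is idempotent", {
  t0 <- rand_topo(12, 7)
  sub <- sort(t0$tip.label[1:7])
  r1 <- restrict(t0, sub)
  expect_true(topo_equal(restrict(r1, sub), r1))
})

test_that("induced_quartet agrees with the restriction oracle", {
  tr <- read_newick("((a,b),(c,d));")
  expect_equal(induced_quartet(tr, c("a", "b", "c", "d")), "a,b|c,d")
  expect_true(is.na(induced_quartet(star_tree(letters[1:4]), letters[1:4])))
  expect_error(induced_quartet(tr, c("a", "b", "c", "zz")), "zz")
  t6 <- rand_topo(6, 42)
  for (q in utils::combn(t6$tip.label, 4, simplify = FALSE))
    expect_equal(induced_quartet(t6, q), oracle_induced_quartet(t6, q))
})

test_that("topo_dist_matrix matches graph search", {
  tr <- read_newick("((a,b),(c,d));")
  D <- topo_dist_matrix(ape::unroot(tr))
  expect_equal(D["a", "b"], 2L)
  expect_equal(D["a", "c"], 3L)
  for (s in 1:5) {
    t0 <- rand_topo(10, 200 + s)
    expect_equal(topo_dist_matrix(t0), oracle_topo_dist(t0))
  }
})

test_that("midpoint_root halves the longest weighted path", {
  tr <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
  r <- midpoint_root(tr)
  depth <- ape::node.depth.edgelength(r)[seq_along(r$tip.label)]
  expect_equal(max(depth), 2)
  expect_equal(sort(depth, decreasing = TRUE)[1:2], c(2, 2))
  # long pendant edge: midpoint lies on it
  tr2 <- read_newick("((a:10,b:1):1,(c:1,d:1):1);")
  r2 <- midpoint_root(tr2)
  d2 <- ape::node.depth.edgelength(r2)[seq_along(r2$tip.label)]
  names(d2) <- r2$tip.label
  expect_equal(unname(d2["a"]), 6.5)   # (10+1+1+1)/2
  expect_equal(max(d2[c("b", "c", "d")]), 6.5)
  expect_error(midpoint_root(rand_topo(5, 1)), "length")
})

test_that("greedy_consensus keeps majority splits and stays compatible", {
  t0 <- rand_topo(8, 9)
  expect_true(topo_equal(greedy_consensus(list(t0, t0, t0)), t0))
  tA <- read_newick("((a,b),(c,(d,e)));")
  tB <- read_newick("((a,b),(d,(c,e)));")
  tC <- read_newick("((a,c),(b,(d,e)));")
  cons <- greedy_consensus(lapply(list(tA, tB, tA), unroot_tree))
  expect_true("a,b|c,d,e" %in% bipartition_set(cons))
  # pairwise compatibility of the output
  mix <- greedy_consensus(lapply(list(tA, tB, tC), unroot_tree))
  bps <- bipartition_set(mix)
  taxa <- sort(tA$tip.label)
  for (i in seq_along(bps)) for (j in seq_len(i - 1)) {
    a1 <- strsplit(strsplit(bps[i], "|", fixed = TRUE)[[1]], ",")
    a2 <- strsplit(strsplit(bps[j], "|", fixed = TRUE)[[1]], ",")
    compatible <- any(vapply(a1, function(x) any(vapply(a2, function(y)
      length(intersect(x, y)) == 0, logical(1))), logical(1)))
    expect_true(compatible)
  }
  expect_error(greedy_consensus(list(tA, star_tree(letters[1:4]))), "leaf")
})

test_that("greedy consensus contains every split in more than half the trees", {
  trees <- lapply(1:5, function(s) rand_topo(7, 300 + s))
  tally <- table(unlist(lapply(trees, bipartition_set)))
  majority <- names(tally)[tally > length(trees) / 2]
  cons <- bipartition_set(greedy_consensus(trees))
  expect_true(all(majority %in% cons))
})

test_that("unroot_tree collapses a degree-2 root and topo_equal works", {
  r <- read_newick("((a,b),(c,d));")
  u <- unroot_tree(r)
  expect_equal(u$Nnode, 2L)
  expect_true(topo_equal(u, r))
  expect_false(topo_equal(read_newick("((a,b),(c,d));"),
                          read_newick("((a,c),(b,d));")))
})
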