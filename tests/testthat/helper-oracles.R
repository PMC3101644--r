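# Independent oracles used across the suite. These deliberately avoid the
# package's own primitives wherever an external route exists.

# Canonical split key, re-derived: sides sorted, side containing the
# overall smallest label first.
make_key <- function(side_a, side_b) {
  side_a <- sort(side_a); side_b <- sort(side_b)
  if (side_a[1] > side_b[1]) { tmp <- side_a; side_a <- side_b; side_b <- tmp }
  paste0(paste(side_a, collapse = ","), "|", paste(side_b, collapse = ","))
}

# Induced quartet by restriction: keep the four tips and read the single
# split of the restricted tree (NA when the restriction is a star).
oracle_induced_quartet <- function(tree, labels) {
  sub <- ape::unroot(ape::keep.tip(tree, labels))
  bp <- bipartition_set(sub)
  if (length(bp) != 1) NA_character_ else bp[[1]]
}

# Topological distances by breadth-first search on the tree graph.
oracle_topo_dist <- function(tree) {
  g <- igraph::graph_from_edgelist(matrix(as.character(tree$edge), ncol = 2),
                                   directed = FALSE)
  d <- igraph::distances(g)
  tips <- as.character(seq_along(tree$tip.label))
  m <- d[tips, tips]
  rownames(m) <- colnames(m) <- tree$tip.label
  ord <- order(rownames(m))
  m <- m[ord, ord]
  storage.mode(m) <- "integer"
  m
}

# Fitch length by exhaustive enumeration of every internal-node (and
# '?'-leaf) state assignment; feasible up to ~6 taxa.
oracle_fitch <- function(tree, mat) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label); nn <- tree$Nnode
  total <- 0L
  for (j in seq_len(ncol(mat))) {
    states <- mat[tree$tip.label, j]
    free_tips <- which(states == "?")
    fixed <- suppressWarnings(as.integer(states))
    nfree <- nn + length(free_tips)
    best <- Inf
    for (mask in 0:(2^nfree - 1)) {
      bits <- as.integer(intToBits(mask))[seq_len(nfree)]
      lab <- integer(nt + nn)
      lab[seq_len(nt)] <- fixed
      if (length(free_tips)) lab[free_tips] <- bits[seq_along(free_tips)]
      lab[nt + seq_len(nn)] <- bits[length(free_tips) + seq_len(nn)]
      best <- min(best, sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]]))
    }
    total <- total + best
  }
  total
}

# Closed-form Spearman for tie-free vectors.
oracle_spearman <- function(x, y) {
  n <- length(x)
  1 - 6 * sum((rank(x) - rank(y))^2) / (n * (n^2 - 1))
}

# A random binary unrooted topology (no branch lengths).
rand_topo <- function(n, seed) {
  tr <- with_seed(seed, ape::rtree(n))
  tr$edge.length <- NULL
  ape::unroot(tr)
}
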