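# Quartet encodings of source trees: all induced quartets, the
# topologically-short-quartet (TSQ) construction, and the diameter-based
# random sampling rules ("geo": keep a quartet with probability d^-3;
# "exp": with probability 1.5^-d, d the quartet's topological diameter),
# each combined with the TSQ trees.

#' Construct a weighted quartet set
#'
#' A quartet set maps resolved four-leaf splits `"a,b|c,d"` (canonical form:
#' sides sorted, side with the overall smallest label first) to positive
#' weights, over a universe of taxa. Conflicting topologies on the same four
#' labels may coexist; they are distinct entries.
#'
#' @param topologies Character vector of canonical quartet keys.
#' @param weights Positive numeric weights (recycled; default 1). Entries
#'   with equal keys are aggregated by summing weights.
#' @param taxa Character vector, the taxon universe (defaults to the labels
#'   appearing in `topologies`).
#' @return An object of class `quartet_set`: a data frame with columns
#'   `topology` and `weight`, attribute `taxa`.
#' @export
quartet_set <- function(topologies = character(0), weights = 1, taxa = NULL) {
  weights <- rep_len(weights, length(topologies))
  if (length(topologies)) {
    agg <- rowsum(weights, topologies)
    topologies <- rownames(agg)
    weights <- as.numeric(agg)
  } else {
    weights <- numeric(0)
  }
  if (is.null(taxa))
    taxa <- sort(unique(unlist(strsplit(topologies, "[,|]"))))
  qs <- data.frame(topology = topologies, weight = weights,
                   stringsAsFactors = FALSE)
  qs <- qs[order(qs$topology), , drop = FALSE]
  rownames(qs) <- NULL
  structure(qs, taxa = sort(taxa), class = c("quartet_set", "data.frame"))
}

#' @export
print.quartet_set <- function(x, ...) {
  cat(sprintf("quartet_set: %d topologies on %d taxa (total weight %g)\n",
              nrow(x), length(attr(x, "taxa")), sum(x$weight)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# Split canonical quartet keys into a 4-column label matrix (pair 1 = cols
# 1:2, pair 2 = cols 3:4).
quartet_labels <- function(keys) {
  parts <- strsplit(keys, "[,|]")
  matrix(unlist(parts), ncol = 4, byrow = TRUE)
}

#' Topological diameter of a quartet within a tree
#'
#' The maximum of the six pairwise edge-count distances among the four
#' leaves, measured in the source tree.
#'
#' @param tree A `phylo` object.
#' @param labels Four distinct leaf labels.
#' @return Integer `>= 3` for leaves of a tree with at least 4 leaves.
#' @export
quartet_diameter <- function(tree, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 4) stopf("need four distinct labels")
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing))
    stopf("labels not in tree: %s", paste(missing, collapse = ", "))
  D <- topo_dist_matrix(tree)
  max(D[labels, labels])
}

# Enumerate all 4-subsets of the tree's (label-sorted) leaves with their
# displayed pairing and diameter, fully vectorised. Returns a list with the
# label matrix of resolved quartets (columns a,b,c,d; a<b, c<d, a<c), their
# keys, diameters, and the count of unresolved subsets.
enumerate_quartets <- function(tree) {
  D <- topo_dist_matrix(tree)
  labs <- rownames(D)
  n <- length(labs)
  if (n < 4) stopf("need at least 4 leaves")
  idx <- utils::combn(n, 4)
  i1 <- idx[1, ]; i2 <- idx[2, ]; i3 <- idx[3, ]; i4 <- idx[4, ]
  d12 <- D[cbind(i1, i2)]; d34 <- D[cbind(i3, i4)]
  d13 <- D[cbind(i1, i3)]; d24 <- D[cbind(i2, i4)]
  d14 <- D[cbind(i1, i4)]; d23 <- D[cbind(i2, i3)]
  s1 <- d12 + d34; s2 <- d13 + d24; s3 <- d14 + d23
  diam <- pmax(d12, d34, d13, d24, d14, d23)
  m <- pmin(s1, s2, s3)
  resolved <- (s1 == m) + (s2 == m) + (s3 == m) == 1L
  which1 <- resolved & s1 == m
  which2 <- resolved & s2 == m
  which3 <- resolved & s3 == m
  a <- b <- cc <- d <- character(sum(resolved))
  la <- labs[i1]; lb <- labs[i2]; lc <- labs[i3]; ld <- labs[i4]
  out_a <- c(la[which1], la[which2], la[which3])
  out_b <- c(lb[which1], lc[which2], ld[which3])
  out_c <- c(lc[which1], lb[which2], lb[which3])
  out_d <- c(ld[which1], ld[which2], lc[which3])
  # paste0 recycles the literal separators to length 1 when all inputs are
  # zero-length, so guard the no-resolved-quartets case explicitly
  keys <- if (length(out_a) == 0) character(0) else
    paste0(out_a, ",", out_b, "|", out_c, ",", out_d)
  diams <- c(diam[which1], diam[which2], diam[which3])
  ord <- order(keys)
  list(keys = keys[ord], diam = diams[ord],
       n_unresolved = sum(!resolved), taxa = labs)
}

#' All induced quartets of a tree
#'
#' One entry per resolved 4-subset of the leaves; a binary tree on n leaves
#' yields exactly `choose(n, 4)` quartets. Unresolved 4-subsets of
#' multifurcating trees are omitted; their count is recorded in attribute
#' `n_unresolved`.
#'
#' @param tree A `phylo` object with at least 4 leaves.
#' @return A `quartet_set`, all weights 1.
#' @export
all_quartets <- function(tree) {
  eq <- enumerate_quartets(tree)
  qs <- quartet_set(eq$keys, 1, taxa = eq$taxa)
  attr(qs, "n_unresolved") <- eq$n_unresolved
  qs
}

#' Topologically short quartet (TSQ) trees of a tree
#'
#' For each internal edge, each of the subtrees hanging off the edge's two
#' endpoints contributes its topologically nearest leaf (all of them on
#' ties); the TSQs of the edge are all one-leaf-per-subtree combinations,
#' pairing the two same-side subtrees against the two on the other side.
#' The result is the deduplicated union over internal edges, weight 1. At a
#' polytomy the (three or more) subtrees on that side are taken pairwise.
#'
#' @param tree A `phylo` object with at least 4 leaves.
#' @return A `quartet_set`.
#' @export
tsq_trees <- function(tree) {
  if (length(tree$tip.label) < 4) stopf("need at least 4 leaves")
  tr <- unroot_tree(tree)
  ntip <- length(tr$tip.label)
  Dn <- ape::dist.nodes(compute_unit_lengths(tr))
  internal <- tr$edge[, 1] > ntip & tr$edge[, 2] > ntip
  keys <- character(0)
  for (row in which(internal)) {
    u <- tr$edge[row, 1]; v <- tr$edge[row, 2]
    groups_u <- edge_side_groups(tr, u, v, Dn, ntip)
    groups_v <- edge_side_groups(tr, v, u, Dn, ntip)
    if (length(groups_u) < 2 || length(groups_v) < 2) next
    pu <- utils::combn(length(groups_u), 2)
    pv <- utils::combn(length(groups_v), 2)
    for (cu in seq_len(ncol(pu))) for (cv in seq_len(ncol(pv))) {
      g1 <- groups_u[[pu[1, cu]]]; g2 <- groups_u[[pu[2, cu]]]
      g3 <- groups_v[[pv[1, cv]]]; g4 <- groups_v[[pv[2, cv]]]
      combos <- expand.grid(a = g1, b = g2, c = g3, d = g4,
                            stringsAsFactors = FALSE)
      keys <- c(keys, apply(combos, 1, function(r)
        canonical_quartet(c(r[1], r[2]), c(r[3], r[4]))))
    }
  }
  quartet_set(unique(keys), 1, taxa = sort(tr$tip.label))
}

# Nearest-leaf groups of the subtrees hanging off endpoint `end` of the
# internal edge (end, other): one group per incident subtree, each holding
# the leaves at minimum edge-count distance from `end` within that subtree
# (ties kept). Subtree membership of leaf x: its path to `end` passes
# through neighbour w, i.e. Dn[x, w] < Dn[x, end].
edge_side_groups <- function(tr, end, other, Dn, ntip) {
  nb <- c(tr$edge[tr$edge[, 1] == end, 2], tr$edge[tr$edge[, 2] == end, 1])
  nb <- setdiff(nb, other)
  lapply(nb, function(w) {
    if (w <= ntip) return(tr$tip.label[w])
    tips <- which(Dn[seq_len(ntip), w] < Dn[seq_len(ntip), end])
    dist_to_end <- Dn[tips, end]
    tr$tip.label[tips[dist_to_end == min(dist_to_end)]]
  })
}

canonical_quartet <- function(pair1, pair2) {
  pair1 <- sort(unlist(pair1, use.names = FALSE))
  pair2 <- sort(unlist(pair2, use.names = FALSE))
  if (pair2[1] < pair1[1]) { tmp <- pair1; pair1 <- pair2; pair2 <- tmp }
  paste0(pair1[1], ",", pair1[2], "|", pair2[1], ",", pair2[2])
}

compute_unit_lengths <- function(tr) {
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

#' Diameter-based random quartet encoding (plus TSQ trees)
#'
#' Every 4-subset is kept by an independent Bernoulli draw whose success
#' probability depends on the quartet's topological diameter d in the source
#' tree: `d^-3` under the `"geo"` rule or `1.5^-d` under the `"exp"` rule.
#' The TSQ trees are always added, so the encoding never loses the short
#' quartets around any edge.
#'
#' @param tree A binary `phylo` object with at least 4 leaves.
#' @param rule `"geo"` or `"exp"`.
#' @param seed Integer seed making the draw reproducible (optional).
#' @return A `quartet_set`, weight 1 per retained topology.
#' @export
sampled_encoding <- function(tree, rule = c("geo", "exp"), seed = NULL) {
  rule <- match.arg(rule)
  eq <- enumerate_quartets(tree)
  p <- if (rule == "geo") eq$diam^(-3) else 1.5^(-eq$diam)
  keep <- with_seed(seed, stats::runif(length(p)) < p)
  keys <- eq$keys[keep]
  tsq <- tsq_trees(tree)
  quartet_set(unique(c(keys, tsq$topology)), 1, taxa = eq$taxa)
}

#' Encode a source-tree profile as a combined weighted quartet set
#'
#' Each source tree is encoded under the chosen strategy and the per-tree
#' sets are combined as a weighted multiset: the weight of a topology is the
#' number of source trees contributing it. Conflicting topologies on the
#' same four labels are all retained.
#'
#' @param profile A [source_tree_profile()] or a plain list of `phylo`
#'   objects.
#' @param strategy `"all"`, `"geo+tsq"` or `"exp+tsq"`.
#' @param seed Integer seed for the sampling strategies (optional).
#' @param combine `"weighted"` (default) sums per-tree contributions;
#'   `"union"` deduplicates to weight 1.
#' @return A `quartet_set` over the union of the source trees' taxa, with
#'   attribute `n_quartets` (total weight, the size of the combined
#'   collection).
#' @export
encode_profile <- function(profile, strategy = c("all", "geo+tsq", "exp+tsq"),
                           seed = NULL, combine = c("weighted", "union")) {
  strategy <- match.arg(strategy)
  combine <- match.arg(combine)
  trees <- if (inherits(profile, "source_tree_profile")) profile$trees
           else profile
  if (!length(trees)) stopf("profile is empty")
  per_tree <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (length(tr$tip.label) < 4) return(NULL)
    s <- derive_seed(seed %||% 0, i)
    switch(strategy,
           "all" = all_quartets(tr),
           "geo+tsq" = sampled_encoding(tr, "geo", seed = s),
           "exp+tsq" = sampled_encoding(tr, "exp", seed = s))
  })
  per_tree <- per_tree[!vapply(per_tree, is.null, logical(1))]
  taxa <- sort(unique(unlist(lapply(trees, leaf_set))))
  keys <- unlist(lapply(per_tree, function(q) q$topology))
  if (combine == "union") keys <- unique(keys)
  qs <- quartet_set(keys, 1, taxa = taxa)
  attr(qs, "n_quartets") <- sum(qs$weight)
  qs
}

#' Read / write weighted quartet files
#'
#' Plain text, one record per line: `a,b|c,d<TAB>weight`; a missing weight
#' field means weight 1. The writer emits canonical topologies in sorted
#' line order, so files are byte-stable.
#'
#' @param path File path.
#' @return `read_quartets()` returns a `quartet_set`.
#' @export
read_quartets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[[`, character(1), 1)
  w <- vapply(parts, function(p)
    if (length(p) >= 2) as.numeric(p[2]) else 1, numeric(1))
  labs <- quartet_labels(keys)
  keys <- vapply(seq_len(nrow(labs)), function(i)
    canonical_quartet(labs[i, 1:2], labs[i, 3:4]), character(1))
  quartet_set(keys, w)
}

#' @param quartets A `quartet_set`.
#' @rdname read_quartets
#' @export
write_quartets <- function(quartets, path) {
  lines <- sprintf("%s\t%g", quartets$topology, quartets$weight)
  writeLines(sort(lines), path)
  invisible(path)
}
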