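# Bipartitions, restriction, induced quartets, topological distances,
# midpoint rooting and greedy consensus: the core operations every other
# module is built on. Trees are ape "phylo" objects and are compared as
# unrooted objects throughout (rooting is only used to feed rooted-input
# consumers).

# -- canonical split / quartet keys ------------------------------------------

# A bipartition A|B is keyed as "a1,a2|b1,b2" with each side sorted and the
# side containing the lexicographically smallest label first. Keys are the
# unit of all set arithmetic on splits.
split_key <- function(sideA, sideB) {
  sideA <- sort(sideA)
  sideB <- sort(sideB)
  if (sideB[1] < sideA[1]) {
    tmp <- sideA; sideA <- sideB; sideB <- tmp
  }
  paste0(paste(sideA, collapse = ","), "|", paste(sideB, collapse = ","))
}

split_sides <- function(key) {
  halves <- strsplit(key, "|", fixed = TRUE)[[1]]
  lapply(strsplit(halves, ",", fixed = TRUE), identity)
}

#' Set of non-trivial bipartitions of a tree
#'
#' One bipartition per internal edge, each encoded as a canonical key string
#' `"a1,a2|b1,b2"` (sides sorted, side with the smallest label first). Rooted
#' trees are treated as their unrooted versions, so a binary tree with n
#' leaves yields n - 3 bipartitions; a star tree yields none.
#'
#' @param tree A `phylo` object.
#' @return Sorted character vector of canonical bipartition keys with
#'   attribute `taxa` (the sorted leaf set).
#' @export
bipartition_set <- function(tree) {
  validate_tree(tree)
  taxa <- sort(tree$tip.label)
  keys <- character(0)
  if (length(taxa) >= 4) {
    tr <- unroot_tree(tree)
    pp <- ape::prop.part(tr)
    if (length(pp) > 1) {
      tips <- tr$tip.label
      keys <- vapply(pp[-1], function(idx) {
        side <- tips[idx]
        split_key(side, setdiff(tips, side))
      }, character(1))
      keys <- sort(unique(keys))
    }
  }
  structure(keys, taxa = taxa)
}

#' Restrict a tree to a subset of its leaves
#'
#' Returns the subtree induced on `subset`, with degree-2 nodes suppressed
#' (branch lengths summed across suppressed nodes when present).
#'
#' @param tree A `phylo` object.
#' @param subset Character vector of leaf labels, a subset of
#'   `leaf_set(tree)` with at least 2 elements.
#' @return A `phylo` object on `subset`.
#' @export
restrict <- function(tree, subset) {
  subset <- unique(subset)
  missing <- setdiff(subset, tree$tip.label)
  if (length(missing))
    stopf("labels not in tree: %s", paste(missing, collapse = ", "))
  if (length(subset) < 2) stopf("subset must contain at least 2 leaves")
  if (length(subset) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, subset)
}

#' Quartet topology induced by a tree on four leaves
#'
#' Determines the split `ab|cd` displayed by the tree on four of its leaves,
#' using the four-point condition on topological (edge-count) distances: the
#' displayed pairing is the one with the strictly smallest sum of
#' within-pair distances. Returns `NA` when the restriction is a star
#' (unresolved).
#'
#' @param tree A `phylo` object.
#' @param labels Four distinct leaf labels.
#' @return Canonical quartet key `"a,b|c,d"`, or `NA_character_` if
#'   unresolved.
#' @export
induced_quartet <- function(tree, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 4) stopf("need four distinct labels")
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing))
    stopf("labels not in tree: %s", paste(missing, collapse = ", "))
  D <- topo_dist_matrix(tree)
  l <- sort(labels)
  s1 <- D[l[1], l[2]] + D[l[3], l[4]]  # 12|34
  s2 <- D[l[1], l[3]] + D[l[2], l[4]]  # 13|24
  s3 <- D[l[1], l[4]] + D[l[2], l[3]]  # 14|23
  quartet_from_sums(l, s1, s2, s3)
}

# Shared by induced_quartet and the vectorised encoders: the pairing with the
# strictly smallest distance sum is the displayed split.
quartet_from_sums <- function(l, s1, s2, s3) {
  m <- min(s1, s2, s3)
  if (sum(c(s1, s2, s3) == m) > 1) return(NA_character_)
  if (s1 == m) paste0(l[1], ",", l[2], "|", l[3], ",", l[4])
  else if (s2 == m) paste0(l[1], ",", l[3], "|", l[2], ",", l[4])
  else paste0(l[1], ",", l[4], "|", l[2], ",", l[3])
}

#' Pairwise topological (edge-count) leaf distances
#'
#' @param tree A `phylo` object with at least 2 leaves.
#' @return Symmetric integer matrix of path lengths in edges, rows/columns
#'   ordered by sorted leaf label, zero diagonal.
#' @export
topo_dist_matrix <- function(tree) {
  if (length(tree$tip.label) < 2) stopf("need at least 2 leaves")
  tr <- unroot_tree(tree)
  tr$edge.length <- rep(1, nrow(tr$edge))
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  D <- D[ord, ord, drop = FALSE]
  storage.mode(D) <- "integer"
  D
}

#' Root a tree at the midpoint of its longest leaf-to-leaf path
#'
#' The root is placed at the point halving the longest weighted leaf-to-leaf
#' path; when that point falls exactly on a node the root attaches there.
#' When two or more longest paths tie, the path between the
#' lexicographically smallest leaf pair is used, so the result is
#' deterministic.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A rooted `phylo` object.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length))
    stopf(paste("midpoint rooting needs branch lengths;",
                "set tree$edge.length <- rep(1, nrow(tree$edge))",
                "explicitly to use unit lengths"))
  tr <- unroot_tree(tree)
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  D <- D[ord, ord]
  dmax <- max(D)
  hits <- which(D == dmax, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  pairs <- cbind(rownames(D)[hits[, 1]], colnames(D)[hits[, 2]])
  pairs <- t(apply(pairs, 1, sort))
  sel <- order(pairs[, 1], pairs[, 2])[1]
  a <- pairs[sel, 1]; b <- pairs[sel, 2]
  ia <- match(a, tr$tip.label); ib <- match(b, tr$tip.label)
  np <- ape::nodepath(tr, from = ia, to = ib)
  elen <- vapply(seq_len(length(np) - 1), function(k) {
    row <- which((tr$edge[, 1] == np[k] & tr$edge[, 2] == np[k + 1]) |
                 (tr$edge[, 2] == np[k] & tr$edge[, 1] == np[k + 1]))
    tr$edge.length[row]
  }, numeric(1))
  half <- dmax / 2
  cum <- cumsum(elen)
  k <- which(cum >= half - 1e-12)[1]
  before <- if (k == 1) 0 else cum[k - 1]
  offset <- half - before            # distance from np[k] into edge k
  tol <- 1e-9 * max(dmax, 1)
  if (offset <= tol || abs(offset - elen[k]) <= tol) {
    node <- if (offset <= tol) np[k] else np[k + 1]
    if (node <= length(tr$tip.label)) stopf("degenerate midpoint at a leaf")
    return(ape::root(tr, node = node, resolve.root = FALSE))
  }
  u <- np[k]; v <- np[k + 1]
  row <- which((tr$edge[, 1] == u & tr$edge[, 2] == v) |
               (tr$edge[, 2] == u & tr$edge[, 1] == v))
  child <- tr$edge[row, 2]
  # phytools::reroot measures `position` from the rootward (parent) end of
  # the edge above `node`; `offset` is measured from np[k].
  pos <- if (child == u) elen[k] - offset else offset
  phytools::reroot(tr, node.number = child, position = pos)
}

#' Greedy consensus of a set of trees on one leaf set
#'
#' Bipartitions are ranked by frequency (ties broken by canonical key, then
#' first appearance) and added greedily when compatible with those already
#' accepted. The result refines the majority consensus: it contains every
#' bipartition present in more than half the input trees.
#'
#' @param trees A list of `phylo` objects with identical leaf sets.
#' @return A `phylo` object (possibly multifurcating, unrooted semantics).
#' @export
greedy_consensus <- function(trees) {
  if (!length(trees)) stopf("need at least one tree")
  taxa <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), taxa))
      stopf("all trees must share one leaf set")
  all_keys <- unlist(lapply(trees, bipartition_set))
  if (!length(all_keys)) return(star_tree(taxa))
  tab <- table(all_keys)
  keys <- names(tab)
  first <- match(keys, all_keys)
  ord <- order(-as.integer(tab), keys, first)
  keys <- keys[ord]
  ref <- taxa[1]
  clusters <- lapply(keys, function(k) {
    sides <- split_sides(k)
    if (ref %in% sides[[1]]) sides[[2]] else sides[[1]]
  })
  accepted <- list()
  for (cl in clusters) {
    ok <- all(vapply(accepted, function(acc) clusters_compatible(acc, cl),
                     logical(1)))
    if (ok) accepted[[length(accepted) + 1]] <- cl
  }
  tree_from_clusters(accepted, taxa)
}

# Two clusters (both excluding a common reference leaf) are compatible iff
# they are nested or disjoint.
clusters_compatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0 || i == length(a) || i == length(b)
}

star_tree <- function(taxa) {
  ape::read.tree(text = paste0("(", paste(sort(taxa), collapse = ","), ");"))
}

# Build the (unique) tree displaying a laminar family of clusters; clusters
# must exclude taxa[1] and be pairwise compatible.
tree_from_clusters <- function(clusters, taxa) {
  if (!length(clusters)) return(star_tree(taxa))
  build <- function(members, cls) {
    maximal <- rep(TRUE, length(cls))
    for (i in seq_along(cls)) for (j in seq_along(cls)) {
      if (i != j && all(cls[[i]] %in% cls[[j]]) &&
          length(cls[[i]]) < length(cls[[j]])) { maximal[i] <- FALSE; break }
    }
    frags <- character(0)
    covered <- character(0)
    for (i in which(maximal)) {
      inner <- cls[vapply(cls, function(x)
        all(x %in% cls[[i]]) && length(x) < length(cls[[i]]), logical(1))]
      frags <- c(frags, build(cls[[i]], inner))
      covered <- c(covered, cls[[i]])
    }
    loose <- setdiff(members, covered)
    frags <- c(frags, sort(loose))
    if (length(frags) == 1) frags else
      paste0("(", paste(sort(frags), collapse = ","), ")")
  }
  txt <- paste0(build(taxa, clusters), ";")
  ape::read.tree(text = txt)
}

#' Test two trees for equality as unrooted topologies
#'
#' @param t1,t2 `phylo` objects.
#' @return `TRUE` iff the leaf sets coincide and the bipartition sets are
#'   identical.
#' @export
topo_equal <- function(t1, t2) {
  identical(sort(t1$tip.label), sort(t2$tip.label)) &&
    identical(as.character(bipartition_set(t1)),
              as.character(bipartition_set(t2)))
}
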