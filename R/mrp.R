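# Matrix representation with parsimony: partial binary encoding of the
# source trees, Fitch length with missing data, a parsimony ratchet search
# returning all best-found trees, and the greedy consensus of that set
# (gMRP).

#' Encode a source-tree profile as partial binary characters
#'
#' One column per internal edge of each source tree: taxa on one side 0,
#' the other side 1 (the side containing the lexicographically smallest
#' leaf of that tree gets 0), and `?` for taxa absent from that tree. The
#' column count is the sum of the per-tree internal edge counts.
#'
#' @param profile A [source_tree_profile()] or list of `phylo` objects.
#' @return Character matrix (taxa x columns) over `0`, `1`, `?` of class
#'   `mrp_matrix`, rows sorted by taxon label, with attribute `provenance`
#'   (data frame: source-tree index and bipartition key per column) and
#'   `uncovered` (taxa appearing in no source tree's columns).
#' @export
mrp_encode <- function(profile) {
  trees <- if (inherits(profile, "source_tree_profile")) profile$trees
           else profile
  if (!length(trees)) stopf("profile is empty")
  taxa <- sort(unique(unlist(lapply(trees, leaf_set))))
  cols <- list(); prov_tree <- integer(0); prov_split <- character(0)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (length(tr$tip.label) < 4) {
      message(sprintf("source tree %d has < 4 leaves; contributes no columns",
                      i))
      next
    }
    splits <- bipartition_set(tr)
    anchor <- min(tr$tip.label)
    for (key in splits) {
      sides <- split_sides(key)
      zero_side <- if (anchor %in% sides[[1]]) sides[[1]] else sides[[2]]
      one_side <- setdiff(tr$tip.label, zero_side)
      col <- rep("?", length(taxa)); names(col) <- taxa
      col[zero_side] <- "0"; col[one_side] <- "1"
      cols[[length(cols) + 1]] <- col
      prov_tree <- c(prov_tree, i); prov_split <- c(prov_split, key)
    }
  }
  m <- if (length(cols)) do.call(cbind, cols)
       else matrix(character(0), nrow = length(taxa), ncol = 0,
                   dimnames = list(taxa, NULL))
  rownames(m) <- taxa
  covered <- taxa[rowSums(m != "?") > 0]
  structure(m, provenance = data.frame(tree = prov_tree, split = prov_split,
                                       stringsAsFactors = FALSE),
            uncovered = setdiff(taxa, covered),
            class = c("mrp_matrix", class(m)))
}

mrp_to_phydat <- function(matrix) {
  if (ncol(matrix) == 0) return(NULL)
  phangorn::phyDat(unclass(matrix), type = "USER", levels = c("0", "1"),
                   ambiguity = "?")
}

#' Fitch parsimony length of a tree on a character matrix
#'
#' Sum over columns of the minimum number of state changes, with `?`
#' treated as a free assignment.
#'
#' @param tree A `phylo` object whose leaves include the matrix taxa.
#' @param matrix An [mrp_encode()] matrix (or any taxa x columns character
#'   matrix over `0`, `1`, `?`).
#' @return Integer parsimony length.
#' @export
fitch_length <- function(tree, matrix) {
  extra <- setdiff(rownames(matrix), tree$tip.label)
  if (length(extra))
    stopf("matrix taxa not in tree: %s", paste(extra, collapse = ", "))
  if (ncol(matrix) == 0) return(0L)
  absent <- setdiff(tree$tip.label, rownames(matrix))
  if (length(absent)) {
    pad <- matrix("?", length(absent), ncol(matrix),
                  dimnames = list(absent, NULL))
    matrix <- rbind(unclass(matrix), pad)
  }
  pd <- mrp_to_phydat(matrix)
  as.integer(phangorn::fitch(tree, pd))
}

#' Parsimony ratchet search
#'
#' Per start: a random-addition starting tree refined by
#' nearest-neighbor-interchange hill climbing, then ratchet iterations that
#' alternate (i) a search under a matrix with a random fraction of columns
#' upweighted x2 and (ii) a search under the original weights, keeping the
#' best tree found. Returns all distinct topologies attaining the best
#' score found across starts.
#'
#' @param matrix An [mrp_encode()] matrix with at least 4 taxa.
#' @param iterations Ratchet iterations per start.
#' @param perturbation Fraction of columns upweighted in each ratchet
#'   perturbation.
#' @param starts Independent random-addition starts.
#' @param seed Integer seed (optional).
#' @param rearrangements `"NNI"` or `"SPR"` (passed to the hill climber).
#' @param max_trees Cap on the number of distinct best trees kept.
#' @return List of unrooted `phylo` trees, attribute `score` (the best
#'   Fitch length found) and `capped` (logical).
#' @export
ratchet_search <- function(matrix, iterations = 25, perturbation = 0.25,
                           starts = 5, seed = NULL, rearrangements = "NNI",
                           max_trees = 100) {
  taxa <- rownames(matrix)
  if (length(taxa) < 4) stopf("need >= 4 taxa")
  if (ncol(matrix) == 0) {
    out <- list(star_tree(taxa))
    attr(out, "score") <- 0L; attr(out, "capped") <- FALSE
    return(out)
  }
  pd <- mrp_to_phydat(matrix)
  w0 <- attr(pd, "weight")
  with_seed(seed, {
    best_score <- Inf
    best <- list(); best_keys <- character(0)
    note <- function(tr) {
      s <- as.integer(phangorn::fitch(tr, pd))
      if (s > best_score) return(s)
      key <- paste(bipartition_set(tr), collapse = ";")
      if (s < best_score) {
        best_score <<- s; best <<- list(unroot_tree(tr)); best_keys <<- key
      } else if (!(key %in% best_keys) && length(best) < max_trees) {
        best[[length(best) + 1]] <<- unroot_tree(tr)
        best_keys <<- c(best_keys, key)
      }
      s
    }
    climb <- function(tr, data) {
      suppressMessages(phangorn::optim.parsimony(
        tr, data, method = "fitch", rearrangements = rearrangements,
        trace = 0))
    }
    for (st in seq_len(starts)) {
      cur <- phangorn::random.addition(pd)
      cur <- climb(cur, pd)
      cur_score <- note(cur)
      for (it in seq_len(iterations)) {
        wp <- w0 + stats::rbinom(length(w0), w0, perturbation)
        pdw <- pd; attr(pdw, "weight") <- wp
        pert <- climb(cur, pdw)
        cand <- climb(pert, pd)
        s <- note(cand)
        if (s <= cur_score) { cur <- cand; cur_score <- s }
      }
    }
    attr(best, "score") <- best_score
    attr(best, "capped") <- length(best) >= max_trees
    best
  })
}

#' gMRP supertree: greedy consensus of the ratchet's best trees
#'
#' The full matrix-representation-with-parsimony pathway: encode the
#' profile as partial binary characters, search with the parsimony ratchet,
#' and return the greedy consensus of all best-scoring trees found.
#'
#' @param profile A [source_tree_profile()] or list of `phylo` objects.
#' @param seed Integer seed.
#' @inheritParams ratchet_search
#' @return An unrooted `phylo` supertree on the union of source-tree taxa,
#'   with attribute `score` (best Fitch length).
#' @export
gmrp <- function(profile, iterations = 25, perturbation = 0.25, starts = 5,
                 seed = NULL, rearrangements = "NNI", max_trees = 100) {
  m <- mrp_encode(profile)
  best <- ratchet_search(m, iterations = iterations,
                         perturbation = perturbation, starts = starts,
                         seed = seed, rearrangements = rearrangements,
                         max_trees = max_trees)
  out <- greedy_consensus(best)
  attr(out, "score") <- attr(best, "score")
  out
}

#' Write an MRP matrix as relaxed PHYLIP or a NEXUS data block
#'
#' @param matrix An [mrp_encode()] matrix.
#' @param path Output path.
#' @param format `"phylip"` (relaxed: name, space, characters) or
#'   `"nexus"`.
#' @export
write_mrp_matrix <- function(matrix, path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  taxa <- rownames(matrix)
  rows <- apply(unclass(matrix), 1, paste, collapse = "")
  if (format == "phylip") {
    writeLines(c(sprintf("%d %d", nrow(matrix), ncol(matrix)),
                 sprintf("%s  %s", taxa, rows)), path)
  } else {
    writeLines(c("#NEXUS", "BEGIN DATA;",
                 sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                         nrow(matrix), ncol(matrix)),
                 "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
                 "  MATRIX",
                 sprintf("    %s  %s", taxa, rows),
                 "  ;", "END;"), path)
  }
  invisible(path)
}
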