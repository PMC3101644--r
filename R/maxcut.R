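# Max-cut style quartet amalgamation: a divide-and-conquer heuristic for
# Maximum Quartet Consistency. At each level the taxon set is split by a
# seeded randomized hill-climbing cut scored directly on the quartets:
# a quartet ab|cd counts +w when the cut separates {a,b} from {c,d}
# (satisfied), -lambda*w when the cut splits it 2+2 the wrong way
# (violated, unreachable afterwards), and 0 when it straddles 3+1 or lies
# inside a side (deferred). Quartets with three taxa in a side are
# projected onto that side with the fourth taxon replaced by the side's
# attachment dummy, so the recursion can place the side's subtree; wrongly
# split 2+2 quartets are dropped and counted.

#' Amalgamate a weighted quartet set into a supertree
#'
#' Problems (and recursive subproblems) with at most `exact_limit` labels
#' are solved exactly: every unrooted binary tree on the labels is
#' enumerated and the one displaying the largest satisfied quartet weight
#' is returned (first in enumeration order on ties, so the result is
#' deterministic). Larger sets are split by the best cut found by hill
#' climbing from single-taxon seeds plus `restarts` random starts (both
#' sides are kept at size at least two, since a pendant cut carries no
#' quartet information). Quartets entirely within a side are retained;
#' quartets with three taxa in a side keep those three with the outside
#' taxon replaced by the side's attachment dummy; quartets split 2+2
#' against their pairing are dropped at that level and counted. The output
#' leaf set always equals `taxa`; an empty quartet set yields a star tree.
#'
#' @param quartets A [quartet_set()].
#' @param taxa Taxon universe (defaults to the quartet set's); must cover
#'   all quartet labels and have `>= 3` elements.
#' @param lambda Penalty weight for violated (wrongly split) quartets. The
#'   large default makes the objective near-lexicographic: cuts violating
#'   less quartet weight always win, and satisfied weight breaks ties.
#'   On a consistent quartet set a violation-free cut exists at every
#'   level, so this preserves exact recovery.
#' @param restarts Random hill-climb restarts per cut (added to the
#'   deterministic single-taxon starts).
#' @param seed Integer seed.
#' @param exact_limit Label-set size up to which subproblems are solved by
#'   exhaustive tree enumeration (at most 9; enumeration grows as the
#'   double factorial `(2k-5)!!`).
#' @return An unrooted `phylo` tree on `taxa` with attribute `n_dropped`
#'   (total weight of quartets discarded across all levels: wrongly split
#'   at a cut, or left unsatisfied by an exact subsolution).
#' @export
maxcut_amalgamate <- function(quartets, taxa = NULL, lambda = 1000,
                              restarts = 10, seed = NULL, exact_limit = 7) {
  if (exact_limit > 9) stopf("exact_limit must be <= 9")
  taxa <- sort(taxa %||% attr(quartets, "taxa"))
  if (length(taxa) < 3) stopf("need at least 3 taxa")
  if (nrow(quartets)) {
    qlab <- quartet_labels(quartets$topology)
    missing <- setdiff(unique(as.vector(qlab)), taxa)
    if (length(missing))
      stopf("quartet labels not in taxa: %s", paste(missing, collapse = ", "))
    qm0 <- matrix(match(qlab, taxa), ncol = 4)
  } else {
    qm0 <- matrix(integer(0), ncol = 4)
  }
  w0 <- quartets$weight
  env <- new.env()
  env$labels <- taxa            # grows with dummy/supernode tokens
  env$dropped <- 0
  new_id <- function() {
    env$labels <- c(env$labels, sprintf("..s%d..", length(env$labels) + 1))
    length(env$labels)
  }
  # Fragment for the taxa in `ids` minus the attachment dummy `dum`,
  # written as a rooted newick fragment whose root is the attachment point.
  solve_frag <- function(ids, dum, qm, w) {
    reals <- setdiff(ids, dum)
    if (length(reals) == 1) return(env$labels[reals])
    if (length(ids) <= 3 || nrow(qm) == 0)
      return(paste0("(", paste(sort(env$labels[reals]), collapse = ","), ")"))
    if (length(ids) <= exact_limit) {
      t_best <- exact_best_tree(env$labels[ids],
                                matrix(env$labels[qm], ncol = 4), w)
      env$dropped <- env$dropped + attr(t_best, "unsat")
      return(frag_minus_leaf(t_best, env$labels[dum]))
    }
    loc <- matrix(match(qm, ids), ncol = 4)
    x <- best_cut(loc, w, length(ids), lambda, restarts)
    if (x[match(dum, ids)]) x <- !x     # B = the side without the dummy
    A <- ids[!x]; B <- ids[x]
    inB <- matrix(qm %in% B, ncol = 4)
    cntB <- rowSums(inB)
    sat <- cntB == 2 & (inB[, 1] == inB[, 2])   # pairs separated correctly
    env$dropped <- env$dropped + sum(w[cntB == 2 & !sat])
    dB <- new_id(); sB <- new_id()
    selB <- cntB >= 3
    qmB <- qm[selB, , drop = FALSE]
    qmB[!(qmB %in% B)] <- dB
    selA <- cntB <= 1
    qmA <- qm[selA, , drop = FALSE]
    qmA[matrix(qmA %in% B, ncol = 4)] <- sB
    fragB <- solve_frag(c(B, dB), dB, qmB, w[selB])
    fragA <- solve_frag(c(A, sB), dum, qmA, w[selA])
    sub_token(fragA, env$labels[sB], fragB)
  }
  tree <- with_seed(seed, {
    if (length(taxa) >= 4 && length(taxa) <= exact_limit && nrow(qm0) > 0) {
      t_best <- exact_best_tree(taxa, matrix(taxa[qm0], ncol = 4), w0)
      env$dropped <- attr(t_best, "unsat")
      t_best
    } else {
      top <- new_id() # virtual attachment so the top level reuses solve_frag
      txt <- paste0(solve_frag(c(seq_along(taxa), top), top, qm0, w0), ";")
      ape::read.tree(text = txt)
    }
  })
  tree <- unroot_tree(tree)
  attr(tree, "n_dropped") <- env$dropped
  tree
}

# Exact small-case solver: per label-set size k, cache every unrooted
# binary tree on k generic tips together with the quartet topology each
# tree displays for every 4-subset (pairing index 1/2/3 relative to the
# sorted subset).
.exact_cache <- new.env(parent = emptyenv())

exact_tables <- function(k) {
  key <- as.character(k)
  tab <- .exact_cache[[key]]
  if (!is.null(tab)) return(tab)
  tips <- sprintf("x%02d", seq_len(k))   # zero-padded so sorting is stable
  trees <- phangorn::allTrees(k, tip.label = tips)
  subs <- utils::combn(seq_len(k), 4L)
  i <- subs[1, ]; j <- subs[2, ]; a <- subs[3, ]; b <- subs[4, ]
  disp <- matrix(0L, length(trees), ncol(subs))
  for (ti in seq_along(trees)) {
    D <- topo_dist_matrix(trees[[ti]])
    s1 <- D[cbind(i, j)] + D[cbind(a, b)]
    s2 <- D[cbind(i, a)] + D[cbind(j, b)]
    s3 <- D[cbind(i, b)] + D[cbind(j, a)]
    disp[ti, ] <- max.col(-cbind(s1, s2, s3), ties.method = "first")
  }
  tab <- list(trees = trees,
              keys = apply(subs, 2, paste, collapse = ","), disp = disp)
  .exact_cache[[key]] <- tab
  tab
}

# Maximum-satisfaction tree on `labs` (4..9 labels) by enumeration.
# `qlab` is the quartet label matrix (pairing = columns (1,2)|(3,4)),
# `w` the weights. Deterministic: first enumerated maximiser on ties.
exact_best_tree <- function(labs, qlab, w) {
  slabs <- sort(labs)
  k <- length(slabs)
  tab <- exact_tables(k)
  loc <- matrix(match(qlab, slabs), ncol = 4)
  srt <- t(apply(loc, 1, sort))
  sidx <- match(apply(srt, 1, paste, collapse = ","), tab$keys)
  in_p1 <- srt[, 1] == loc[, 1] | srt[, 1] == loc[, 2]
  partner <- ifelse(in_p1, loc[, 1] + loc[, 2], loc[, 3] + loc[, 4]) -
    srt[, 1]
  p <- 1L * (partner == srt[, 2]) + 2L * (partner == srt[, 3]) +
    3L * (partner == srt[, 4])
  m <- tab$disp[, sidx, drop = FALSE] ==
    matrix(p, nrow(tab$disp), length(p), byrow = TRUE)
  sat <- as.numeric(m %*% w)
  best <- which.max(sat)
  t_best <- tab$trees[[best]]
  t_best$tip.label <- slabs[match(t_best$tip.label,
                                  sprintf("x%02d", seq_len(k)))]
  attr(t_best, "unsat") <- sum(w) - sat[best]
  t_best
}

# Newick fragment of `tree` rooted where the leaf `leaf` attaches, with
# that leaf removed (the fragment's root is the attachment point).
frag_minus_leaf <- function(tree, leaf) {
  t2 <- ape::root(tree, outgroup = leaf, resolve.root = TRUE)
  s <- sub(";$", "", ape::write.tree(t2))
  s <- substr(s, 2, nchar(s) - 1)
  cs <- strsplit(s, "")[[1]]
  depth <- 0L; cuts <- integer(0)
  for (ii in seq_along(cs)) {
    if (cs[ii] == "(") depth <- depth + 1L
    else if (cs[ii] == ")") depth <- depth - 1L
    else if (cs[ii] == "," && depth == 0L) cuts <- c(cuts, ii)
  }
  parts <- substring(s, c(1L, cuts + 1L), c(cuts - 1L, nchar(s)))
  keep <- parts[parts != leaf]
  if (length(keep) == 1) keep
  else paste0("(", paste(keep, collapse = ","), ")")
}

# Replace a leaf token in a newick fragment by a sub-fragment. Tokens are
# always delimited by ( , ) so a boundary-aware substitution is safe.
sub_token <- function(frag, token, replacement) {
  if (identical(frag, token)) return(replacement)
  gsub(paste0("([(,])\\Q", token, "\\E([,)])"),
       paste0("\\1", replacement, "\\2"),
       frag, perl = TRUE)
}

# Quartet-scored cut contribution of assignment x (logical side membership)
# restricted to rows `rows`: +w satisfied, -lambda*w violated, 0 deferred.
cut_rows_score <- function(qm, w, x, rows, lambda) {
  if (!length(rows)) return(0)
  xa <- x[qm[rows, 1]]; xb <- x[qm[rows, 2]]
  xc <- x[qm[rows, 3]]; xd <- x[qm[rows, 4]]
  two <- (xa + xb + xc + xd) == 2L
  sat <- two & xa == xb
  viol <- two & !sat
  sum(w[rows][sat]) - lambda * sum(w[rows][viol])
}

# Hill-climbing cut on the quartet objective (n >= 4). Starts: every
# single-taxon seed plus `restarts` random assignments, each grown/kept so
# both sides hold >= 2 vertices. First-improvement sweeps over vertices in
# index order until no flip improves. Deterministic given the RNG state.
best_cut <- function(qm, w, n, lambda, restarts = 10) {
  rows_by_vertex <- lapply(seq_len(n), function(v)
    which(qm[, 1] == v | qm[, 2] == v | qm[, 3] == v | qm[, 4] == v))
  climb <- function(x) {
    while (min(sum(x), sum(!x)) < 2) {
      big <- sum(x) >= sum(!x)
      cand <- which(x == big)
      gains <- vapply(cand, function(v) {
        x2 <- x; x2[v] <- !x2[v]
        cut_rows_score(qm, w, x2, rows_by_vertex[[v]], lambda) -
          cut_rows_score(qm, w, x, rows_by_vertex[[v]], lambda)
      }, numeric(1))
      v <- cand[which.max(gains)]
      x[v] <- !x[v]
    }
    repeat {
      improved <- FALSE
      for (v in seq_len(n)) {
        side_n <- if (x[v]) sum(x) else sum(!x)
        if (side_n <= 2) next
        rows <- rows_by_vertex[[v]]
        old <- cut_rows_score(qm, w, x, rows, lambda)
        x[v] <- !x[v]
        new <- cut_rows_score(qm, w, x, rows, lambda)
        if (new > old + 1e-9) improved <- TRUE else x[v] <- !x[v]
      }
      if (!improved) break
    }
    x
  }
  best_val <- -Inf; best_x <- NULL
  starts <- lapply(seq_len(n), function(v) {
    x <- rep(FALSE, n); x[v] <- TRUE; x
  })
  for (r in seq_len(restarts))
    starts[[n + r]] <- stats::runif(n) < 0.5
  for (x0 in starts) {
    x <- climb(x0)
    val <- cut_rows_score(qm, w, x, seq_along(w), lambda)
    if (val > best_val) { best_val <- val; best_x <- x }
  }
  best_x
}

#' Weighted quartet satisfaction of a tree
#'
#' The total weight (and fraction) of quartets in a set whose topology is
#' displayed by the tree.
#'
#' @param tree A `phylo` object containing all quartet labels as leaves.
#' @param quartets A [quartet_set()].
#' @return List with elements `satisfied` (weight displayed), `total`
#'   (total weight) and `fraction`.
#' @export
quartet_satisfaction <- function(tree, quartets) {
  if (!nrow(quartets))
    return(list(satisfied = 0, total = 0, fraction = NA_real_))
  D <- topo_dist_matrix(tree)
  labs <- quartet_labels(quartets$topology)
  l <- t(apply(labs, 1, sort))
  pairsum <- function(i, j, k, m)
    D[cbind(l[, i], l[, j])] + D[cbind(l[, k], l[, m])]
  s1 <- pairsum(1, 2, 3, 4); s2 <- pairsum(1, 3, 2, 4)
  s3 <- pairsum(1, 4, 2, 3)
  mn <- pmin(s1, s2, s3)
  resolved <- (s1 == mn) + (s2 == mn) + (s3 == mn) == 1L
  shown <- ifelse(!resolved, NA_character_,
    ifelse(s1 == mn, paste0(l[, 1], ",", l[, 2], "|", l[, 3], ",", l[, 4]),
    ifelse(s2 == mn, paste0(l[, 1], ",", l[, 3], "|", l[, 2], ",", l[, 4]),
                     paste0(l[, 1], ",", l[, 4], "|", l[, 2], ",", l[, 3]))))
  ok <- !is.na(shown) & shown == quartets$topology
  list(satisfied = sum(quartets$weight[ok]), total = sum(quartets$weight),
       fraction = sum(quartets$weight[ok]) / sum(quartets$weight))
}
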