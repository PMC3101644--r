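# Supertree-profile simulator: pure-birth model trees deviated from the
# molecular clock, gene presence by a gain/loss (birth-death) process on the
# model tree, GTR+Gamma+I sequence evolution, clade-based and scaffold
# dataset assembly at controlled scaffold density, and the built-in
# distance-based source-tree estimator.

#' GTR+Gamma+I substitution model
#'
#' @param rates Six non-negative exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT.
#' @param base_freqs Four stationary frequencies (A, C, G, T) summing to 1.
#' @param alpha Gamma shape for among-site rate variation (`> 0`).
#' @param p_inv Proportion of invariable sites in `[0, 1)`.
#' @return An object of class `gtr_model`. The rate matrix is rescaled so
#'   the expected substitution rate at stationarity is 1, i.e. branch
#'   lengths are in expected substitutions per variable site.
#' @export
gtr_model <- function(rates, base_freqs, alpha = 1, p_inv = 0) {
  if (length(rates) != 6 || any(rates < 0))
    stopf("rates must be 6 non-negative values (AC, AG, AT, CG, CT, GT)")
  if (length(base_freqs) != 4 || abs(sum(base_freqs) - 1) > 1e-9)
    stopf("base_freqs must be 4 frequencies summing to 1")
  if (alpha <= 0) stopf("alpha must be positive")
  if (p_inv < 0 || p_inv >= 1) stopf("p_inv must be in [0, 1)")
  # symmetric exchangeability matrix, pair order AC, AG, AT, CG, CT, GT
  R <- matrix(0, 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) { R[pairs[k, 1], pairs[k, 2]] <- rates[k]
                   R[pairs[k, 2], pairs[k, 1]] <- rates[k] }
  Q <- R * rep(base_freqs, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))
  Q <- Q / mu
  structure(list(Q = Q, rates = rates, base_freqs = base_freqs,
                 alpha = alpha, p_inv = p_inv),
            class = "gtr_model")
}

#' Named GTR parameter presets
#'
#' Ready-made parameter sets for simulation. These are package defaults in
#' the spirit of matrices estimated from real alignments, not reproductions
#' of any published matrix.
#'
#' @param name `"default"` (moderately unequal frequencies, transition bias,
#'   alpha 0.7, 20% invariable sites) or `"jc-like"` (all rates and
#'   frequencies equal, no rate variation).
#' @return A `gtr_model`.
#' @export
gtr_preset <- function(name = c("default", "jc-like")) {
  name <- match.arg(name)
  switch(name,
    "default" = gtr_model(rates = c(1.1, 3.3, 0.9, 0.95, 3.7, 1.0),
                          base_freqs = c(0.30, 0.21, 0.24, 0.25),
                          alpha = 0.7, p_inv = 0.2),
    "jc-like" = gtr_model(rates = rep(1, 6), base_freqs = rep(0.25, 4),
                          alpha = 100, p_inv = 0))
}

#' Simulate a model tree under a pure-birth process
#'
#' A rooted binary Yule tree with leaves `T1..Tn`, optionally rescaled to a
#' target root-to-tip height and then deviated from ultrametricity by
#' multiplying every branch length by an independent lognormal factor with
#' log-mean 0 and log-sd `deviation_sd` (0 keeps the tree ultrametric).
#'
#' @param n Number of leaves (`>= 4`).
#' @param birth_rate Speciation rate of the pure-birth process.
#' @param deviation_sd Log-sd of the lognormal branch-length deviation.
#' @param seed Integer seed (optional).
#' @param height Target maximum root-to-leaf path length before deviation
#'   (expected substitutions/site); `NULL` keeps the Yule time scale.
#' @return A rooted binary `phylo` object with `n` leaves.
#' @export
simulate_model_tree <- function(n, birth_rate = 1, deviation_sd = 0,
                                seed = NULL, height = NULL) {
  if (n < 4) stopf("need n >= 4 taxa")
  if (deviation_sd < 0) stopf("deviation_sd must be >= 0")
  with_seed(seed, {
    tr <- ape::rphylo(n, birth = birth_rate, death = 0)
    tr$tip.label <- paste0("T", seq_len(n))
    if (!is.null(height)) {
      depths <- ape::node.depth.edgelength(tr)
      tr$edge.length <- tr$edge.length * height / max(depths)
    }
    if (deviation_sd > 0)
      tr$edge.length <- tr$edge.length *
        stats::rlnorm(length(tr$edge.length), 0, deviation_sd)
    tr
  })
}

#' Assign gene presence patterns by a gain/loss process
#'
#' Each gene is gained once, either on the root (probability
#' `root_gain_prob`) or on an edge sampled proportionally to branch length,
#' and then lost independently on the edges of the gained subtree (Poisson
#' with mean `loss_rate` x branch length; an edge with at least one loss
#' prunes everything below it). The gene's leaf set is therefore always a
#' clade minus a union of sub-clades. Genes with fewer than `min_leaves`
#' leaves are redrawn.
#'
#' @param tree Rooted `phylo` with branch lengths (the model tree).
#' @param n_genes Number of genes.
#' @param loss_rate Loss events per unit branch length.
#' @param min_leaves Minimum leaves per gene (`<=` number of taxa).
#' @param root_gain_prob Probability that a gene is gained at the root
#'   (present in the whole tree before losses).
#' @param seed Integer seed (optional).
#' @param gain_node Force the gain node for every gene (used mostly in
#'   testing); `NULL` samples it.
#' @return List of character vectors (leaf sets), with attributes
#'   `gain_nodes` and `loss_nodes` recording the realised events.
#' @export
assign_gene_leafsets <- function(tree, n_genes, loss_rate = 0.3,
                                 min_leaves = 4, root_gain_prob = 0.5,
                                 seed = NULL, gain_node = NULL) {
  ntip <- length(tree$tip.label)
  if (min_leaves > ntip)
    stopf("min_leaves (%d) exceeds the number of taxa (%d)", min_leaves, ntip)
  if (is.null(tree$edge.length)) stopf("model tree needs branch lengths")
  root <- ntip + 1L
  desc <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), "tips")
  with_seed(seed, {
    leafsets <- vector("list", n_genes)
    gains <- integer(n_genes)
    losses <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      for (try in seq_len(1000)) {
        gnode <- if (!is.null(gain_node)) gain_node
                 else if (stats::runif(1) < root_gain_prob) root
                 else tree$edge[sample.int(nrow(tree$edge), 1,
                                           prob = tree$edge.length), 2]
        clade_tips <- desc[[gnode]]
        sub_edges <- which(edge_below(tree, gnode))
        k <- stats::rpois(length(sub_edges),
                          loss_rate * tree$edge.length[sub_edges])
        lost_children <- tree$edge[sub_edges[k > 0], 2]
        lost_tips <- unique(unlist(desc[lost_children]))
        leaves <- setdiff(clade_tips, lost_tips)
        if (length(leaves) >= min_leaves) {
          leafsets[[g]] <- sort(tree$tip.label[leaves])
          gains[g] <- gnode
          losses[[g]] <- lost_children
          break
        }
      }
      if (is.null(leafsets[[g]]))
        stopf("could not draw a gene with >= %d leaves; lower loss_rate",
              min_leaves)
    }
    structure(leafsets, gain_nodes = gains, loss_nodes = losses)
  })
}

# Logical index over edges: is the edge inside the clade rooted at `node`
# (i.e. both endpoints at or below it, excluding the edge above `node`)?
edge_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  below <- unlist(phangorn::Descendants(tree, node, "all"))
  tree$edge[, 2] %in% below
}

#' Evolve sequences along a tree under GTR+Gamma+I
#'
#' The root sequence is drawn from the stationary frequencies; each site
#' gets rate 0 with probability `p_inv` and otherwise an independent
#' mean-one Gamma(`alpha`) draw; substitutions follow the GTR transition
#' probabilities of rate x branch length. No indels are simulated, so the
#' true alignment is the simulated matrix itself.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param model A [gtr_model()].
#' @param length Number of sites (`>= 1`).
#' @param seed Integer seed (optional).
#' @return Character matrix (taxa x sites) over A, C, G, T with the tree's
#'   tip labels as row names.
#' @export
evolve_sequences <- function(tree, model, length, seed = NULL) {
  if (!inherits(model, "gtr_model")) stopf("model must be a gtr_model")
  if (length < 1) stopf("length must be >= 1")
  if (is.null(tree$edge.length)) stopf("tree needs branch lengths")
  S <- as.integer(length)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  pi <- model$base_freqs
  # reversible Q diagonalised through its symmetrised form
  B <- diag(sqrt(pi)) %*% model$Q %*% diag(1 / sqrt(pi))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / sqrt(pi)) %*% eig$vectors
  Vinv <- t(eig$vectors) %*% diag(sqrt(pi))
  lam <- eig$values
  with_seed(seed, {
    rate <- ifelse(stats::runif(S) < model$p_inv, 0,
                   stats::rgamma(S, shape = model$alpha, rate = model$alpha))
    seqs <- matrix(0L, nnode, S)
    root <- ntip + 1L
    seqs[root, ] <- sample.int(4, S, replace = TRUE, prob = pi)
    edge_ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(edge_ord$edge))) {
      par <- edge_ord$edge[e, 1]; chi <- edge_ord$edge[e, 2]
      len <- edge_ord$edge.length[e]
      E <- exp(outer(len * rate, lam))          # S x 4
      child <- integer(S)
      pstates <- seqs[par, ]
      for (i in 1:4) {
        sel <- which(pstates == i)
        if (!length(sel)) next
        W <- U[i, ] * Vinv                       # 4(k) x 4(j)
        P <- E[sel, , drop = FALSE] %*% W        # |sel| x 4
        P[P < 0] <- 0
        P <- P / rowSums(P)
        u <- stats::runif(length(sel))
        cs1 <- P[, 1]; cs2 <- cs1 + P[, 2]; cs3 <- cs2 + P[, 3]
        child[sel] <- 1L + (u > cs1) + (u > cs2) + (u > cs3)
      }
      seqs[chi, ] <- child
    }
    out <- matrix(c("A", "C", "G", "T")[seqs[seq_len(ntip), ]], ntip, S)
    rownames(out) <- tree$tip.label
    out
  })
}

#' Estimate a source tree from gene alignments
#'
#' The built-in estimator concatenates the dataset's gene alignments
#' (missing genes padded with gaps), computes maximum-likelihood-corrected
#' pairwise distances (TN93, pairwise deletion) and runs neighbor joining.
#' Saturated (undefined) corrected distances fall back to uncorrected
#' p-distances with a warning. A hook is provided for an external
#' maximum-likelihood program.
#'
#' @param alignments Named list of character matrices (taxa x sites).
#' @param method `"nj"` (built-in) or `"external"`.
#' @param ml_command For `method = "external"`: a command line receiving a
#'   FASTA path as `{fasta}` and printing a newick tree on stdout.
#' @return Unrooted binary `phylo` on the taxa present in the alignments.
#' @export
estimate_source_tree <- function(alignments, method = c("nj", "external"),
                                 ml_command = NULL) {
  method <- match.arg(method)
  taxa <- sort(unique(unlist(lapply(alignments, rownames))))
  if (length(taxa) < 4) stopf("need >= 4 taxa with data")
  concat <- do.call(cbind, lapply(alignments, function(a) {
    m <- matrix("-", length(taxa), ncol(a), dimnames = list(taxa, NULL))
    m[rownames(a), ] <- a
    m
  }))
  if (method == "external") {
    if (is.null(ml_command)) stopf("ml_command required for external method")
    fa <- tempfile(fileext = ".fasta")
    write_fasta(concat, fa)
    out <- system(sub("{fasta}", fa, ml_command, fixed = TRUE), intern = TRUE)
    return(unroot_tree(read_newick(paste(out, collapse = ""))))
  }
  dna <- ape::as.DNAbin(tolower(concat))
  D <- ape::dist.dna(dna, model = "TN93", pairwise.deletion = TRUE)
  Dm <- as.matrix(D)
  bad <- !is.finite(Dm)
  if (any(bad)) {
    warning("saturated corrected distances; falling back to p-distance for ",
            sum(bad & upper.tri(bad)), " pair(s)")
    Praw <- as.matrix(ape::dist.dna(dna, model = "raw",
                                    pairwise.deletion = TRUE))
    Dm[bad] <- Praw[bad]
    still <- !is.finite(Dm)
    if (any(still)) Dm[still] <- max(Dm[is.finite(Dm)], 0.75) * 1.5
  }
  tr <- ape::nj(stats::as.dist(Dm))
  # NJ can emit slightly negative branch lengths; clamp to zero (the
  # downstream use is purely topological).
  tr$edge.length[tr$edge.length < 0] <- 0
  unroot_tree(tr)
}

#' Write a character alignment matrix as FASTA
#'
#' @param alignment Character matrix (taxa x sites) with row names.
#' @param path Output path.
#' @export
write_fasta <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment)))
    writeLines(c(paste0(">", rownames(alignment)[i]),
                 paste(alignment[i, ], collapse = "")), con)
  invisible(path)
}

#' Read a FASTA file into a character matrix
#' @param path FASTA file path.
#' @return Character matrix (taxa x sites).
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  mat <- toupper(as.character(as.matrix(dna)))
  mat
}
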