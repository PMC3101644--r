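# Model conditions, dataset assembly (scaffold + clade-based), and the
# orchestration that turns a condition + seed into a source-tree profile.

#' Define a simulation model condition
#'
#' A model condition fixes everything about one cell of the benchmarking
#' design: taxon count, scaffold density, profile type, replicate count and
#' the generative parameters of the simulator.
#'
#' @param n Taxon count (`>= 8` recommended; `>= 4` required).
#' @param scaffold_density Fraction `p` of all taxa sampled into each
#'   scaffold dataset, in `(0, 1]`.
#' @param profile_type `"mixed"` (one scaffold dataset plus several
#'   clade-based datasets) or `"all-scaffold"` (scaffold datasets only).
#' @param replicates Number of replicate profiles (`>= 1`).
#' @param n_clade_datasets Number of clade-based datasets per mixed profile.
#' @param n_scaffold_datasets Number of scaffolds per all-scaffold profile.
#' @param clade_size_range Two integers: admissible clade sizes (leaves).
#' @param genes_per_clade,genes_per_scaffold Genes per dataset (3 and 4 by
#'   default).
#' @param sites Sites per gene alignment.
#' @param birth_rate,deviation_sd,tree_height Model-tree parameters, see
#'   [simulate_model_tree()].
#' @param loss_rate,root_gain_prob,min_gene_leaves Gene gain/loss process,
#'   see [assign_gene_leafsets()].
#' @param model A [gtr_model()]; default [gtr_preset()]`("default")`.
#' @param estimator `"nj"` (built-in), `"true"` (skip estimation and use the
#'   true restriction of the model tree) or `"external"`.
#' @param ml_command Command template for `estimator = "external"`.
#' @return An object of class `model_condition`.
#' @export
model_condition <- function(n, scaffold_density, profile_type = c("mixed",
                            "all-scaffold"), replicates = 1,
                            n_clade_datasets = max(4L, round(n / 8)),
                            n_scaffold_datasets = n_clade_datasets + 1L,
                            clade_size_range = c(5L, ceiling(n / 2)),
                            genes_per_clade = 3L, genes_per_scaffold = 4L,
                            sites = 500L, birth_rate = 1, deviation_sd = 0.3,
                            tree_height = 1, loss_rate = 0.3,
                            root_gain_prob = 0.5, min_gene_leaves = 4L,
                            model = gtr_preset(), estimator = c("nj", "true",
                            "external"), ml_command = NULL) {
  profile_type <- match.arg(profile_type)
  estimator <- match.arg(estimator)
  if (n < 4) stopf("n must be >= 4")
  if (scaffold_density <= 0 || scaffold_density > 1)
    stopf("scaffold_density must be in (0, 1]")
  if (replicates < 1) stopf("replicates must be >= 1")
  if (round(scaffold_density * n) < 4)
    stopf("scaffold density %.2f on %d taxa gives a scaffold of < 4 taxa",
          scaffold_density, n)
  structure(list(n = as.integer(n), scaffold_density = scaffold_density,
                 profile_type = profile_type,
                 replicates = as.integer(replicates),
                 n_clade_datasets = as.integer(n_clade_datasets),
                 n_scaffold_datasets = as.integer(n_scaffold_datasets),
                 clade_size_range = as.integer(clade_size_range),
                 genes_per_clade = as.integer(genes_per_clade),
                 genes_per_scaffold = as.integer(genes_per_scaffold),
                 sites = as.integer(sites), birth_rate = birth_rate,
                 deviation_sd = deviation_sd, tree_height = tree_height,
                 loss_rate = loss_rate, root_gain_prob = root_gain_prob,
                 min_gene_leaves = as.integer(min_gene_leaves),
                 model = model, estimator = estimator,
                 ml_command = ml_command),
            class = "model_condition")
}

condition_id <- function(condition) {
  sprintf("n%d_%s_d%d", condition$n,
          sub("-", "", condition$profile_type),
          round(condition$scaffold_density * 100))
}

#' Assemble simulated datasets for one profile
#'
#' Builds the scaffold dataset(s) (a uniform random sample of
#' `round(p * n)` taxa with `genes_per_scaffold` genes) and, for mixed
#' profiles, the clade-based datasets (the leaves of a randomly chosen
#' rooted subtree whose size falls in `clade_size_range`, with
#' `genes_per_clade` genes gained within the clade). Each dataset keeps
#' only the taxa possessing at least one of its genes.
#'
#' @param model_tree Rooted model tree (`phylo`).
#' @param condition A [model_condition()].
#' @param seed Integer seed.
#' @return List of datasets, each a list with elements `taxa`, `genes`
#'   (named list of character alignment matrices), `gene_leafsets` and
#'   `tag` (`"scaffold"` or `"clade"`).
#' @export
assemble_datasets <- function(model_tree, condition, seed = NULL) {
  n <- length(model_tree$tip.label)
  p <- condition$scaffold_density
  n_scaffold_taxa <- round(p * n)
  if (n_scaffold_taxa < 4)
    stopf("scaffold of %d taxa is too small to carry a tree", n_scaffold_taxa)
  n_scaffolds <- if (condition$profile_type == "mixed") 1L
                 else condition$n_scaffold_datasets
  datasets <- list()
  ds_idx <- 0L
  make_genes <- function(subtree, n_genes, s) {
    leafsets <- assign_gene_leafsets(subtree, n_genes,
                                     loss_rate = condition$loss_rate,
                                     min_leaves = condition$min_gene_leaves,
                                     root_gain_prob = condition$root_gain_prob,
                                     seed = derive_seed(s, 1))
    genes <- lapply(seq_along(leafsets), function(g) {
      gt <- if (length(leafsets[[g]]) == length(subtree$tip.label)) subtree
            else ape::keep.tip(subtree, leafsets[[g]])
      evolve_sequences(gt, condition$model, condition$sites,
                       seed = derive_seed(s, 1 + g))
    })
    names(genes) <- paste0("gene", seq_along(genes))
    list(genes = genes, leafsets = leafsets)
  }
  for (i in seq_len(n_scaffolds)) {
    ds_idx <- ds_idx + 1L
    s <- derive_seed(seed %||% 0, 100 + ds_idx)
    taxa <- with_seed(s, sort(sample(model_tree$tip.label, n_scaffold_taxa)))
    gg <- make_genes(model_tree, condition$genes_per_scaffold,
                     derive_seed(s, 2))
    keep <- intersect(taxa, unique(unlist(gg$leafsets)))
    genes <- lapply(gg$genes, function(a) {
      rows <- intersect(rownames(a), keep)
      a[rows, , drop = FALSE]
    })
    datasets[[ds_idx]] <- list(taxa = sort(keep), genes = genes,
                               gene_leafsets = gg$leafsets, tag = "scaffold")
  }
  if (condition$profile_type == "mixed") {
    ntip <- n
    clade_sizes <- lengths(phangorn::Descendants(
      model_tree, ntip + seq_len(model_tree$Nnode), "tips"))
    lo <- max(4L, condition$clade_size_range[1])
    hi <- min(ntip - 1L, condition$clade_size_range[2])
    eligible <- ntip + which(clade_sizes >= lo & clade_sizes <= hi)
    if (!length(eligible))
      eligible <- ntip + which(clade_sizes >= 4 & clade_sizes < ntip)
    for (i in seq_len(condition$n_clade_datasets)) {
      ds_idx <- ds_idx + 1L
      s <- derive_seed(seed %||% 0, 100 + ds_idx)
      node <- with_seed(s, eligible[sample.int(length(eligible), 1)])
      subtree <- ape::extract.clade(model_tree, node)
      gg <- make_genes(subtree, condition$genes_per_clade, derive_seed(s, 2))
      keep <- unique(unlist(gg$leafsets))
      genes <- lapply(gg$genes, function(a) a)
      datasets[[ds_idx]] <- list(taxa = sort(keep), genes = genes,
                                 gene_leafsets = gg$leafsets, tag = "clade")
    }
  }
  datasets
}

#' Construct a source-tree profile
#'
#' @param trees List of `phylo` source trees.
#' @param tags Character vector (`"scaffold"`/`"clade"`), recycled.
#' @param model_tree Optional true (model) tree; every source-tree leaf set
#'   must be a subset of its leaves.
#' @param condition Optional [model_condition()].
#' @param manifest Optional manifest list (seeds, dataset composition).
#' @return An object of class `source_tree_profile`.
#' @export
source_tree_profile <- function(trees, tags = "scaffold", model_tree = NULL,
                                condition = NULL, manifest = NULL) {
  if (!length(trees)) stopf("profile needs at least one source tree")
  tags <- rep_len(tags, length(trees))
  if (!is.null(model_tree)) {
    for (tr in trees) {
      extra <- setdiff(tr$tip.label, model_tree$tip.label)
      if (length(extra))
        stopf("source-tree leaves not in the model tree: %s",
              paste(extra, collapse = ", "))
    }
  }
  structure(list(trees = trees, tags = tags, model_tree = model_tree,
                 condition = condition, manifest = manifest),
            class = "source_tree_profile")
}

#' @export
print.source_tree_profile <- function(x, ...) {
  cat(sprintf("source_tree_profile: %d trees (%d scaffold, %d clade) on %d taxa\n",
              length(x$trees), sum(x$tags == "scaffold"),
              sum(x$tags == "clade"), length(profile_taxa(x))))
  invisible(x)
}

#' Union of all source-tree taxa in a profile
#' @param profile A `source_tree_profile`.
#' @return Sorted character vector.
#' @export
profile_taxa <- function(profile) {
  sort(unique(unlist(lapply(profile$trees, leaf_set))))
}

#' Internal-edge counts of the source trees
#'
#' The per-tree number of non-trivial bipartitions, the normalising
#' constants of the sum-distances.
#'
#' @param profile A `source_tree_profile`.
#' @return Integer vector, one entry per source tree.
#' @export
internal_edge_counts <- function(profile) {
  vapply(profile$trees, function(t) length(bipartition_set(t)), integer(1))
}

#' Build a complete simulated profile from a model condition
#'
#' Runs the full generative pipeline: model tree, dataset assembly,
#' sequence evolution and source-tree estimation, all deterministically
#' derived from `(condition, seed)`. With `estimator = "true"` in the
#' condition, estimation is skipped and each source tree is the true
#' restriction of the model tree to the dataset's taxa (clean-recovery
#' mode).
#'
#' @param condition A [model_condition()].
#' @param seed Integer master seed.
#' @return List with elements `model_tree` (`phylo`) and `profile`
#'   (`source_tree_profile`, carrying a manifest of per-step seeds).
#' @export
build_profile <- function(condition, seed = NULL) {
  seed <- seed %||% 0
  s_tree <- derive_seed(seed, 1)
  s_data <- derive_seed(seed, 2)
  t0 <- simulate_model_tree(condition$n, condition$birth_rate,
                            condition$deviation_sd, seed = s_tree,
                            height = condition$tree_height)
  datasets <- assemble_datasets(t0, condition, seed = s_data)
  trees <- list(); tags <- character(0); kept <- list()
  for (ds in datasets) {
    if (length(ds$taxa) < 4) next
    tr <- switch(condition$estimator,
      "true" = unroot_tree(restrict(t0, ds$taxa)),
      "nj" = estimate_source_tree(ds$genes),
      "external" = estimate_source_tree(ds$genes, method = "external",
                                        ml_command = condition$ml_command))
    trees[[length(trees) + 1]] <- tr
    tags <- c(tags, ds$tag)
    kept[[length(kept) + 1]] <- ds
  }
  if (!length(trees)) stopf("no dataset retained >= 4 taxa")
  manifest <- list(
    condition = condition_id(condition), seed = seed,
    step_seeds = list(model_tree = s_tree, datasets = s_data),
    estimator = condition$estimator,
    datasets = lapply(kept, function(ds)
      list(tag = ds$tag, n_taxa = length(ds$taxa), taxa = ds$taxa,
           n_genes = length(ds$genes),
           gene_sizes = vapply(ds$gene_leafsets, length, integer(1)))))
  profile <- source_tree_profile(trees, tags, model_tree = t0,
                                 condition = condition, manifest = manifest)
  list(model_tree = t0, profile = profile, datasets = kept)
}
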