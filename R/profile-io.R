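# On-disk layout of a simulated profile: one directory per replicate with
# a JSON manifest, the model tree, the source trees (one newick per line
# file) and the per-dataset gene alignments as FASTA.

#' Write a simulated profile to a directory
#'
#' Layout: `manifest.json` (condition id, seeds, per-dataset composition,
#' source-tree tags), `model_tree.nwk`, `source_trees.nwk` (one newick per
#' line, in profile order) and `alignments/ds<i>_<gene>.fasta` for every
#' simulated gene (omitted when the profile carries no datasets, e.g. in
#' true-source-tree mode the alignments are still written if present).
#'
#' @param built A [build_profile()] result (or a list with elements
#'   `model_tree`, `profile` and optionally `datasets`).
#' @param dir Output directory (created; must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param overwrite Replace an existing profile directory.
#' @return `dir`, invisibly.
#' @export
write_profile_dir <- function(built, dir, overwrite = FALSE) {
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stopf("%s already holds a profile (use overwrite = TRUE)", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  profile <- built$profile
  manifest <- profile$manifest %||% list()
  manifest$tags <- profile$tags
  manifest$n_trees <- length(profile$trees)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (!is.null(built$model_tree))
    write_newick_file(built$model_tree, file.path(dir, "model_tree.nwk"))
  write_newick_file(profile$trees, file.path(dir, "source_trees.nwk"))
  if (length(built$datasets)) {
    adir <- file.path(dir, "alignments")
    dir.create(adir, showWarnings = FALSE)
    for (i in seq_along(built$datasets)) {
      genes <- built$datasets[[i]]$genes
      for (g in names(genes))
        write_fasta(genes[[g]], file.path(adir, sprintf("ds%03d_%s.fasta",
                                                        i, g)))
    }
  }
  invisible(dir)
}

#' Read a profile directory back into a source-tree profile
#'
#' @param dir A directory written by [write_profile_dir()].
#' @return A [source_tree_profile()] with the model tree and manifest
#'   attached; alignments are not re-read (they are reproducible from the
#'   manifest seeds).
#' @export
read_profile_dir <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path))
    stopf("no manifest.json in %s", dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  trees <- read_newick_file(file.path(dir, "source_trees.nwk"))
  model_path <- file.path(dir, "model_tree.nwk")
  model_tree <- if (file.exists(model_path))
    read_newick_file(model_path)[[1]] else NULL
  tags <- manifest$tags %||% "scaffold"
  source_tree_profile(trees, tags = tags, model_tree = model_tree,
                      manifest = manifest)
}
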