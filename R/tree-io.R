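#' Read a tree from a newick string
#'
#' Thin validating wrapper around [ape::read.tree()]. Trees are plain `phylo`
#' objects throughout the package: leaf-labelled, rooted or unrooted, possibly
#' multifurcating, with optional non-negative branch lengths.
#'
#' @param text A single newick string (must end with `;`). Labels may not
#'   contain whitespace, parentheses, commas or colons.
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- read_newick("((a,b),(c,d));")
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  bad <- which(depth < 0)
  if (length(bad))
    stopf("malformed newick: unmatched ')' at position %d", bad[1])
  if (length(depth) && depth[length(depth)] != 0)
    stopf("malformed newick: %d unclosed '(' (first opened at position %d)",
          depth[length(depth)], which(chars == "(")[1])
  if (!grepl(";\\s*$", text))
    stopf("malformed newick: missing terminating ';' at position %d",
          nchar(text))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stopf("malformed newick: %s",
                                           conditionMessage(e)))
  if (is.null(tr)) stopf("malformed newick: could not parse tree")
  validate_tree(tr)
  tr
}

#' Write a tree as a newick string
#'
#' @param tree A `phylo` object.
#' @param digits Number of digits used for branch lengths.
#' @return A newick string terminated by `;`.
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Read / write multi-tree newick files (one tree per line)
#'
#' @param path File path.
#' @return `read_newick_file()` returns a list of `phylo` objects.
#' @export
read_newick_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, read_newick)
}

#' @param trees A list of `phylo` objects.
#' @rdname read_newick_file
#' @export
write_newick_file <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(path)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a phylo object")
  lab <- tree$tip.label
  if (any(!nzchar(lab))) stopf("empty leaf labels are not allowed")
  dup <- lab[duplicated(lab)]
  if (length(dup))
    stopf("duplicate leaf labels: %s", paste(unique(dup), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stopf("negative branch lengths are not allowed")
  invisible(tree)
}

# Collapse a degree-2 root so trees compare as unrooted objects.
unroot_tree <- function(tree) {
  if (ape::is.rooted(tree) && tree$Nnode > 1) ape::unroot(tree) else tree
}

#' Leaf labels of a tree
#' @param tree A `phylo` object.
#' @return Character vector of leaf labels.
#' @export
leaf_set <- function(tree) tree$tip.label
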