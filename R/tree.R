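#' Newick serialization of a single-linkage tree
#'
#' Branch lengths follow the ultrametric dendrogram convention: each
#' internal node sits at its merge height, leaves at height 0, so a
#' child's branch length is the parent's merge height minus the child's
#' own merge height (the full merge height for a leaf child).
#'
#' @param tree An `hclust` object, e.g. from [single_linkage()].
#' @param digits Significant digits for branch lengths (default 10).
#' @return A single Newick string terminated by ";".
#' @export
as_newick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "hclust"))
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  node_str <- function(k) {
    # k < 0: leaf index; k > 0: row of the merge matrix
    if (k < 0) {
      list(str = gsub("[(),:; \t]", "_", tree$labels[-k]), height = 0)
    } else {
      h <- tree$height[k]
      left <- node_str(tree$merge[k, 1L])
      right <- node_str(tree$merge[k, 2L])
      str <- paste0("(", left$str, ":", fmt(h - left$height), ",",
                    right$str, ":", fmt(h - right$height), ")")
      list(str = str, height = h)
    }
  }
  paste0(node_str(nrow(tree$merge))$str, ";")
}

#' Write a tree to a Newick file
#'
#' @param tree An `hclust` object.
#' @param path Output path.
#' @param digits Significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 10L) {
  writeLines(as_newick(tree, digits = digits), path)
  invisible(path)
}
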