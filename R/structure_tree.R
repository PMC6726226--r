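#' Brain structure hierarchy
#'
#' A structure tree records the parent/child hierarchy of brain structures
#' (parents contain children) and the identity of the cortex root node.
#' Cortex and per-area masks are derived from an annotation volume by
#' collecting a node together with all of its descendants.
#'
#' @param nodes A data.frame with columns `id` (unique positive integers),
#'   `name` (character) and `parent_id` (integer, `NA` for the root).
#' @param cortex_root_id Id of the node whose descendants are cortical areas.
#' @return An object of class `structure_tree`.
#' @export
structure_tree <- function(nodes, cortex_root_id) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "name", "parent_id") %in% names(nodes)))
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyDuplicated(nodes$id)) stop("duplicate structure ids")
  if (any(nodes$id <= 0L)) stop("structure ids must be positive (0 is background)")
  known <- c(NA_integer_, nodes$id)
  if (!all(nodes$parent_id %in% known)) stop("parent_id refers to unknown node")
  # acyclicity: every node must reach a root by walking parents
  parent <- stats::setNames(nodes$parent_id, nodes$id)
  for (id in nodes$id) {
    seen <- integer(0)
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) stop("structure tree contains a cycle at id ", cur)
      seen <- c(seen, cur)
      cur <- parent[[as.character(cur)]]
    }
  }
  cortex_root_id <- as.integer(cortex_root_id)
  if (!cortex_root_id %in% nodes$id)
    stop("cortex_root_id ", cortex_root_id, " not present in tree")
  structure(list(nodes = nodes, cortex_root_id = cortex_root_id),
            class = "structure_tree")
}

#' @export
print.structure_tree <- function(x, ...) {
  cat("<structure_tree> ", nrow(x$nodes), " nodes, cortex root id ",
      x$cortex_root_id, "\n", sep = "")
  invisible(x)
}

#' Ids of a node and all its descendants
#'
#' @param tree A [structure_tree()].
#' @param id Node id.
#' @return Integer vector of ids (the node itself first).
#' @export
tree_descendants <- function(tree, id) {
  id <- as.integer(id)
  if (!id %in% tree$nodes$id) stop("unknown structure id: ", id)
  out <- id
  frontier <- id
  while (length(frontier)) {
    kids <- tree$nodes$id[tree$nodes$parent_id %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Leaf areas under the cortex root
#' @param tree A [structure_tree()].
#' @return Integer vector of ids of cortex descendants with no children.
#' @export
cortical_leaf_areas <- function(tree) {
  desc <- setdiff(tree_descendants(tree, tree$cortex_root_id),
                  tree$cortex_root_id)
  parents <- tree$nodes$parent_id[!is.na(tree$nodes$parent_id)]
  desc[!desc %in% parents]
}

#' Read / write a structure tree as CSV (columns id, name, parent_id)
#' @param tree A [structure_tree()].
#' @param path CSV file path.
#' @return `read_structure_tree` returns a [structure_tree()]; the writer
#'   returns `path` invisibly.
#' @export
write_structure_tree <- function(tree, path) {
  df <- tree$nodes
  df$cortex_root <- as.integer(df$id == tree$cortex_root_id)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_structure_tree
#' @export
read_structure_tree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  root <- df$id[df$cortex_root == 1L]
  structure_tree(df[c("id", "name", "parent_id")], cortex_root_id = root)
}
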