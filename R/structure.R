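#' Build a structure node
#'
#' A structure node describes one element position in the reference XML
#' document layout (a hierarchical concept graph): an XML local name plus the
#' namespace IRI it lives in.  Nodes are assembled into a tree with
#' [structure_tree()]; search concepts are later bound to nodes by id.
#'
#' @param id Node identifier (unique within the tree).  Defaults to
#'   `local_name`.
#' @param local_name XML element local name (tag name without prefix).
#' @param namespace Namespace IRI; `""` means "no namespace".
#' @param children List of child nodes built with `structure_node()`.
#' @return A list of class `sox_structure_node` (nested form; flattened by
#'   [structure_tree()]).
#' @export
structure_node <- function(local_name, namespace = "", id = local_name,
                           children = list()) {
  stopifnot(is.character(local_name), length(local_name) == 1L)
  out <- list(id = as.character(id), local_name = local_name,
              namespace = as.character(namespace), children = children)
  class(out) <- "sox_structure_node"
  out
}

#' Build a structure tree from a nested root node
#'
#' Flattens a nested [structure_node()] description into the internal tree
#' representation: a named list of nodes each holding its parent id and an
#' ordered character vector of child ids.
#'
#' @param root A `sox_structure_node` (possibly with nested children).
#' @return A list of class `sox_structure` with elements `nodes` (named list)
#'   and `root` (root node id).
#' @export
structure_tree <- function(root) {
  nodes <- list()
  add <- function(nd, parent) {
    id <- nd$id
    kids <- vapply(nd$children, function(ch) ch$id, character(1))
    if (!is.null(nodes[[id]])) {
      stop("duplicate structure node id: ", id, call. = FALSE)
    }
    nodes[[id]] <<- list(id = id, local_name = nd$local_name,
                         namespace = nd$namespace, parent = parent,
                         children = kids)
    for (ch in nd$children) add(ch, id)
  }
  add(root, NA_character_)
  out <- list(nodes = nodes, root = root$id)
  class(out) <- "sox_structure"
  out
}

#' @export
print.sox_structure <- function(x, ...) {
  cat("<sox_structure> ", length(x$nodes), " nodes, root '", x$root, "'\n",
      sep = "")
  rec <- function(id, depth) {
    nd <- x$nodes[[id]]
    ns <- if (nzchar(nd$namespace)) paste0(" {", nd$namespace, "}") else ""
    cat(strrep("  ", depth), nd$local_name, ns, "\n", sep = "")
    for (ch in nd$children) rec(ch, depth + 1L)
  }
  rec(x$root, 0L)
  invisible(x)
}

# Preorder ids of a structure tree.  Order is deterministic: children in
# declaration order.
structure_preorder <- function(tree) {
  out <- character(0)
  # iterative walk so corrupt trees (cycles) cannot recurse forever
  stack <- tree$root
  seen <- character(0)
  while (length(stack)) {
    id <- stack[[1L]]
    stack <- stack[-1L]
    if (id %in% seen) next
    seen <- c(seen, id)
    out <- c(out, id)
    nd <- tree$nodes[[id]]
    if (!is.null(nd)) stack <- c(nd$children, stack)
  }
  out
}

#' Resolve the location path of a structure node
#'
#' Walks parent links from the node up to the root and returns the ordered
#' root-to-node sequence of `(namespace, local_name)` steps, the raw material
#' for an XPath location path.
#'
#' @param model A [sox_model()] (or a bare `sox_structure`).
#' @param node A node id, or a node list taken from the tree.
#' @return A data.frame with columns `namespace` and `local_name`, one row per
#'   step, first row the root.
#' @export
resolve_path <- function(model, node) {
  tree <- if (inherits(model, "sox_structure")) model else model$structure
  id <- if (is.character(node)) node else node$id
  if (is.null(tree$nodes[[id]])) {
    stop("structure node not in tree: ", id, call. = FALSE)
  }
  ids <- character(0)
  cur <- id
  guard <- 0L
  while (!is.na(cur)) {
    ids <- c(cur, ids)
    cur <- tree$nodes[[cur]]$parent
    guard <- guard + 1L
    if (guard > length(tree$nodes) + 1L) {
      stop("structure parent links contain a cycle at node: ", id,
           call. = FALSE)
    }
  }
  if (ids[1L] != tree$root) {
    stop("structure node not reachable from root: ", id, call. = FALSE)
  }
  data.frame(
    namespace = vapply(ids, function(i) tree$nodes[[i]]$namespace, ""),
    local_name = vapply(ids, function(i) tree$nodes[[i]]$local_name, ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Deterministic namespace prefix map of a structure tree
#'
#' Assigns prefixes `ns1`, `ns2`, ... to the distinct non-empty namespace IRIs
#' of the tree in preorder of first appearance.  The same map is used by the
#' compiler (emitting prefixed XPath steps) and by the engine (registering
#' prefixes for evaluation), so compiled queries are portable as-is.
#'
#' @param tree A `sox_structure`.
#' @return Named character vector, names are prefixes, values namespace IRIs.
#' @export
prefix_map <- function(tree) {
  uris <- character(0)
  for (id in structure_preorder(tree)) {
    ns <- tree$nodes[[id]]$namespace
    if (nzchar(ns) && !(ns %in% uris)) uris <- c(uris, ns)
  }
  if (!length(uris)) return(stats::setNames(character(0), character(0)))
  stats::setNames(uris, paste0("ns", seq_along(uris)))
}
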