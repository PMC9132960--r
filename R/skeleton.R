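#' Neuron skeleton trees
#'
#' A `skeleton_tree` is a rooted tree of 3D nodes, the unit of tracing,
#' warping and traceable-length evaluation. Node coordinates are held in
#' nanometres throughout the package. The node table is an ordinary tibble
#' with columns `id`, `x`, `y`, `z`, `radius` and `parent_id` (`NA` for the
#' root), so all the usual data-frame verbs apply.
#'
#' @param nodes A data frame with columns `id` (integer, unique), `x`, `y`,
#'   `z` (finite, nm), optionally `radius` (nm, default 0) and `parent_id`
#'   (integer, `NA` marks the root).
#' @param name Name of the tree (cell id).
#' @return A `skeleton_tree` object: a list with elements `name` and `nodes`.
#' @examples
#' tr <- skeleton_tree(data.frame(
#'   id = 1:3, x = c(0, 0, 0), y = c(0, 1000, 2000), z = 0,
#'   parent_id = c(NA, 1, 2)
#' ), name = "cell_a")
#' tree_cable_length(tr)
#' @export
skeleton_tree <- function(nodes, name = "") {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("id", "x", "y", "z", "parent_id") %in% names(nodes)))
  if (!"radius" %in% names(nodes)) nodes$radius <- 0
  nodes <- nodes[, c("id", "x", "y", "z", "radius", "parent_id")]
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  validate_skeleton_nodes(nodes)
  structure(list(name = as.character(name), nodes = nodes),
            class = "skeleton_tree")
}

validate_skeleton_nodes <- function(nodes) {
  if (anyDuplicated(nodes$id) > 0) {
    dup <- nodes$id[duplicated(nodes$id)][1]
    stop("duplicate node id: ", dup, call. = FALSE)
  }
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")])))) {
    stop("non-finite node coordinates", call. = FALSE)
  }
  root <- which(is.na(nodes$parent_id))
  if (length(root) != 1) {
    stop("tree must have exactly one root, found ", length(root),
         call. = FALSE)
  }
  pid <- nodes$parent_id[!is.na(nodes$parent_id)]
  missing <- setdiff(pid, nodes$id)
  if (length(missing) > 0) {
    stop("dangling parent reference: parent id ", missing[1],
         " does not exist", call. = FALSE)
  }
  # connectivity + acyclicity: BFS from the root must reach every node
  n <- nrow(nodes)
  pidx <- match(nodes$parent_id, nodes$id)       # NA at the root
  visited <- logical(n)
  frontier <- root
  visited[root] <- TRUE
  while (length(frontier) > 0) {
    frontier <- which(!visited & pidx %in% frontier)
    visited[frontier] <- TRUE
  }
  if (!all(visited)) {
    stop("cycle or disconnected component in skeleton (node id ",
         nodes$id[which(!visited)[1]], ")", call. = FALSE)
  }
  invisible(nodes)
}

#' @export
print.skeleton_tree <- function(x, ...) {
  cat("<skeleton_tree> '", x$name, "': ", nrow(x$nodes), " nodes, ",
      format(tree_cable_length(x) / 1000, digits = 5), " um cable\n",
      sep = "")
  invisible(x)
}

root_id <- function(tree) tree$nodes$id[is.na(tree$nodes$parent_id)]

node_xyz <- function(tree) as.matrix(tree$nodes[, c("x", "y", "z")])

#' Total cable length of a skeleton tree
#'
#' Sum of parent-child Euclidean edge lengths, in nm.
#' @param tree A `skeleton_tree`.
#' @return Length in nm.
#' @export
tree_cable_length <- function(tree) {
  nd <- tree$nodes
  child <- nd[!is.na(nd$parent_id), ]
  if (nrow(child) == 0) return(0)
  idx <- match(child$parent_id, nd$id)
  sum(sqrt((child$x - nd$x[idx])^2 +
           (child$y - nd$y[idx])^2 +
           (child$z - nd$z[idx])^2))
}

#' Extract the unique root-to-tip polyline
#'
#' Walks from `tip_id` up to the root and returns the node positions in
#' root-to-tip order. Intended for unbranched-dendrite analyses: the walk
#' itself is always unique, so no ambiguity check beyond tip existence is
#' needed.
#'
#' @param tree A `skeleton_tree`.
#' @param tip_id Node id of the tip.
#' @return Numeric matrix (n x 3) of positions in nm.
#' @export
root_to_tip_path <- function(tree, tip_id) {
  nd <- tree$nodes
  if (!tip_id %in% nd$id) stop("tip id ", tip_id, " not found", call. = FALSE)
  idx <- match(tip_id, nd$id)
  path <- idx
  while (!is.na(nd$parent_id[idx])) {
    idx <- match(nd$parent_id[idx], nd$id)
    path <- c(idx, path)
  }
  m <- as.matrix(nd[path, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Split a skeleton into branchlets
#'
#' Branchlets are maximal unbranched runs between the root, branch points
#' and leaves; every edge belongs to exactly one branchlet, so branchlet
#' lengths sum to the tree's cable length. Each branchlet inherits a
#' dendrite type from the label of its distal run.
#'
#' @param tree A `skeleton_tree`.
#' @param type_labels Named character vector mapping node id to dendrite
#'   type (e.g. `"trunk"`, `"apical_oblique"`). Every node must be labelled.
#' @return Tibble with columns `cell_id`, `branchlet_id`, `dendrite_type`,
#'   `length_nm`, `n_points` and a list-column `polyline` of n x 3 matrices
#'   ordered proximal to distal.
#' @export
split_branchlets <- function(tree, type_labels) {
  nd <- tree$nodes
  lbl <- type_labels[as.character(nd$id)]
  if (anyNA(lbl)) {
    stop("missing dendrite type label for node ",
         nd$id[which(is.na(lbl))[1]], call. = FALSE)
  }
  kids <- split(nd$id[!is.na(nd$parent_id)], nd$parent_id[!is.na(nd$parent_id)])
  n_children <- function(id) length(kids[[as.character(id)]])
  rt <- root_id(tree)
  # breakpoints: root, branch points (>1 child) and leaves delimit runs
  out <- list()
  starts <- c(rt, nd$id[vapply(nd$id, n_children, 1L) > 1])
  starts <- unique(starts)
  bi <- 0L
  for (s in starts) {
    for (child in kids[[as.character(s)]]) {
      run <- c(s, child)
      cur <- child
      while (n_children(cur) == 1) {
        cur <- kids[[as.character(cur)]]
        run <- c(run, cur)
      }
      bi <- bi + 1L
      m <- as.matrix(nd[match(run, nd$id), c("x", "y", "z")])
      dimnames(m) <- list(NULL, c("x", "y", "z"))
      out[[bi]] <- tibble::tibble(
        cell_id = tree$name,
        branchlet_id = sprintf("%s_b%03d", tree$name, bi),
        dendrite_type = unname(lbl[as.character(cur)]),
        length_nm = path_length(m),
        n_points = nrow(m),
        polyline = list(m)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Export a branchlet table to CSV
#'
#' Writes the scalar columns (`cell_id`, `branchlet_id`, `dendrite_type`,
#' `length_nm`, `n_points`), dropping the polyline geometry.
#' @param branchlets Tibble from [split_branchlets()].
#' @param path Output file.
#' @export
write_branchlet_csv <- function(branchlets, path) {
  utils::write.csv(
    branchlets[, c("cell_id", "branchlet_id", "dendrite_type",
                   "length_nm", "n_points")],
    path, row.names = FALSE)
  invisible(path)
}
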