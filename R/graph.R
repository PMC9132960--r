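#' Dataset graphs
#'
#' A dataset graph holds named coordinate spaces as nodes and transforms
#' as directed edges. Registering an invertible transform also registers
#' its inverse edge (exact for scale-offset/affine; a swapped-landmark
#' approximation for thin-plate splines). Points and whole skeletons can
#' then be moved between any connected pair of spaces.
#'
#' @param transforms List of `corr_transform` edges to register.
#' @param auto_inverse Register inverse edges where invertible
#'   (default `TRUE`).
#' @return A `dataset_graph`.
#' @examples
#' lm <- landmark_set(diag(3) * 1000, diag(3) * 2000 + 10, "A", "B")
#' g <- dataset_graph(list(fit_scale_offset(lm)))
#' graph_spaces(g)
#' @export
dataset_graph <- function(transforms = list(), auto_inverse = TRUE) {
  g <- structure(list(edges = list()), class = "dataset_graph")
  for (tr in transforms) g <- add_edge(g, tr, auto_inverse = auto_inverse)
  g
}

#' Add a transform edge to a dataset graph
#' @param graph A `dataset_graph`.
#' @param transform A `corr_transform`.
#' @param auto_inverse Also register the inverse edge when one exists.
#' @export
add_edge <- function(graph, transform, auto_inverse = TRUE) {
  key <- paste0(transform$source_space, "->", transform$target_space)
  graph$edges[[key]] <- transform
  if (auto_inverse) {
    inv <- invert_transform(transform)
    if (!is.null(inv)) {
      ikey <- paste0(inv$source_space, "->", inv$target_space)
      if (is.null(graph$edges[[ikey]])) graph$edges[[ikey]] <- inv
    }
  }
  graph
}

#' Spaces registered in a dataset graph
#' @param graph A `dataset_graph`.
#' @return Sorted character vector of space names.
#' @export
graph_spaces <- function(graph) {
  sort(unique(unlist(lapply(graph$edges,
                            function(e) c(e$source_space, e$target_space)))))
}

#' @export
print.dataset_graph <- function(x, ...) {
  cat("<dataset_graph> ", length(graph_spaces(x)), " spaces, ",
      length(x$edges), " edges\n", sep = "")
  for (k in names(x$edges)) cat("  ", k, " (", x$edges[[k]]$kind, ")\n",
                                sep = "")
  invisible(x)
}

#' Compose the transform along the shortest path between two spaces
#'
#' Breadth-first search over edges; shortest path by edge count with ties
#' broken lexicographically by space name, so routing is deterministic.
#' The result is a lazy composite applied left-to-right.
#'
#' @param graph A `dataset_graph`.
#' @param src,dst Space names.
#' @return A `corr_transform` (kind `composite`, or `identity` when
#'   `src == dst`).
#' @export
compose_path <- function(graph, src, dst) {
  spaces <- graph_spaces(graph)
  if (!src %in% spaces || !dst %in% spaces) {
    stop("space not in graph: ", if (!src %in% spaces) src else dst,
         call. = FALSE)
  }
  if (src == dst) return(identity_transform(src, dst))
  adj <- split(
    vapply(graph$edges, function(e) e$target_space, character(1)),
    vapply(graph$edges, function(e) e$source_space, character(1)))
  adj <- lapply(adj, function(v) sort(unname(v)))
  prev <- stats::setNames(rep(NA_character_, length(spaces)), spaces)
  seen <- stats::setNames(rep(FALSE, length(spaces)), spaces)
  seen[src] <- TRUE
  queue <- src
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (!seen[nb]) {
        seen[nb] <- TRUE
        prev[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    if (seen[dst]) break
  }
  if (!seen[dst]) stop("no path from ", src, " to ", dst, call. = FALSE)
  path <- dst
  while (path[1] != src) path <- c(prev[[path[1]]], path)
  chain <- lapply(seq_len(length(path) - 1), function(i) {
    graph$edges[[paste0(path[i], "->", path[i + 1])]]
  })
  new_transform("composite", list(chain = chain, path = path), src, dst)
}

#' Warp a skeleton between dataset spaces
#'
#' Moves all node positions through [compose_path()]; topology, ids and
#' radii are unchanged.
#'
#' @param graph A `dataset_graph`.
#' @param tree A `skeleton_tree`.
#' @param src,dst Space names.
#' @return The warped `skeleton_tree`.
#' @export
warp_skeleton <- function(graph, tree, src, dst) {
  tr <- compose_path(graph, src, dst)
  pts <- apply_transform(tr, node_xyz(tree))
  out <- tree
  out$nodes$x <- pts[, 1]
  out$nodes$y <- pts[, 2]
  out$nodes$z <- pts[, 3]
  out
}
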