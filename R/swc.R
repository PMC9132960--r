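#' Read neuron skeletons from an SWC file
#'
#' SWC is the standard plain-text skeleton exchange format: seven columns
#' (id, type, x, y, z, radius, parent), `#` comments, parent `-1` marking a
#' root. One `skeleton_tree` is returned per connected component.
#' Coordinates are converted to nanometres on read; most SWC files are in
#' micrometres, the default.
#'
#' @param path SWC file path.
#' @param unit Unit of the coordinates in the file: `"um"` (default,
#'   scaled x1000) or `"nm"`.
#' @param name Base name for the trees; components get `_1`, `_2`, ...
#'   suffixes when there are several.
#' @return A list of `skeleton_tree` objects (often length 1).
#' @seealso [write_swc()]
#' @export
read_swc <- function(path, unit = c("um", "nm"), name = NULL) {
  unit <- match.arg(unit)
  scale <- if (unit == "um") 1000 else 1
  if (is.null(name)) name <- sub("\\.swc$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) stop("no node rows in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad) > 0) {
    stop("SWC format error at line ", rows[bad[1]],
         ": expected 7 columns", call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    stop("SWC format error at line ",
         rows[which(apply(is.na(m), 1, any))[1]], ": non-numeric field",
         call. = FALSE)
  }
  nodes <- tibble::tibble(
    id = as.integer(m[, 1]),
    type = as.integer(m[, 2]),
    x = m[, 3] * scale, y = m[, 4] * scale, z = m[, 5] * scale,
    radius = m[, 6] * scale,
    parent_id = ifelse(m[, 7] < 0, NA_integer_, as.integer(m[, 7]))
  )
  if (anyDuplicated(nodes$id) > 0) {
    line <- rows[which(duplicated(nodes$id))[1]]
    stop("SWC format error at line ", line, ": duplicate node id",
         call. = FALSE)
  }
  dangling <- !is.na(nodes$parent_id) & !(nodes$parent_id %in% nodes$id)
  if (any(dangling)) {
    stop("SWC format error at line ", rows[which(dangling)[1]],
         ": parent id ", nodes$parent_id[which(dangling)[1]],
         " does not exist", call. = FALSE)
  }
  comp <- swc_components(nodes)
  trees <- lapply(seq_along(comp), function(i) {
    nm <- if (length(comp) == 1) name else paste0(name, "_", i)
    sub <- nodes[nodes$id %in% comp[[i]], ]
    tr <- skeleton_tree(sub[, c("id", "x", "y", "z", "radius", "parent_id")],
                        name = nm)
    attr(tr, "swc_type") <- stats::setNames(sub$type, sub$id)
    tr
  })
  trees
}

# connected components by walking each node to its root
swc_components <- function(nodes) {
  parent <- stats::setNames(nodes$parent_id, nodes$id)
  root_of <- vapply(nodes$id, function(i) {
    cur <- i
    repeat {
      p <- parent[[as.character(cur)]]
      if (is.na(p)) return(cur)
      cur <- p
    }
  }, integer(1))
  unname(split(nodes$id, root_of))
}

#' Write skeleton trees to an SWC file
#'
#' Inverse of [read_swc()] for the declared fields: a round trip
#' reproduces the node table exactly (ids, coordinates, radii, topology).
#' Output is bit-stable for identical input.
#'
#' @param trees A `skeleton_tree` or list of them.
#' @param path Output file.
#' @param unit Unit to write coordinates in (`"um"` default).
#' @export
write_swc <- function(trees, path, unit = c("um", "nm")) {
  unit <- match.arg(unit)
  scale <- if (unit == "um") 1e-3 else 1
  if (inherits(trees, "skeleton_tree")) trees <- list(trees)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# SWC export (corrbridge)",
               paste0("# units ", unit),
               "# id type x y z radius parent"), con)
  for (tr in trees) {
    types <- attr(tr, "swc_type")
    nd <- tr$nodes
    ty <- if (is.null(types)) rep(0L, nrow(nd)) else
      as.integer(types[as.character(nd$id)])
    writeLines(sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                       nd$id, ty, nd$x * scale, nd$y * scale, nd$z * scale,
                       nd$radius * scale,
                       ifelse(is.na(nd$parent_id), -1L, nd$parent_id)), con)
  }
  invisible(path)
}
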