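#' Traceable-length evaluation parameters
#'
#' Defaults follow the published protocol: 320 nm resampling, a 12 um
#' "lost" threshold for olfactory-bulb dendrites (use 6 um for the
#' hippocampal setting) and a 35 um "linked" threshold marking the end of
#' the soma-to-dendrite linkage region.
#'
#' @param spacing Resampling interval, nm.
#' @param lost_threshold Distance above which a tracing is lost, nm.
#' @param link_threshold Arc length a tracing must reach to count as
#'   linked, nm.
#' @return A list of class `eval_params`.
#' @export
eval_params <- function(spacing = 320, lost_threshold = 12000,
                        link_threshold = 35000) {
  stopifnot(spacing > 0, lost_threshold > spacing, link_threshold > 0)
  structure(list(spacing = spacing, lost_threshold = lost_threshold,
                 link_threshold = link_threshold), class = "eval_params")
}

#' Distance profile of a test tracing against a reference
#'
#' For every point of the resampled test path, the Euclidean distance to
#' the nearest point of the resampled reference path, as a function of
#' arc position along the test path. Exact nearest neighbour (block-wise
#' full distance computation).
#'
#' @param test,reference `resampled_path` objects (or n x 3 matrices; a
#'   matrix is taken with cumulative polyline arc positions) in the same
#'   coordinate space.
#' @return A `distance_profile` tibble with columns `arc_nm`, `dist_nm`.
#' @export
distance_profile <- function(test, reference) {
  tm <- as_xyz_matrix(test)
  rm_ <- as_xyz_matrix(reference)
  if (nrow(tm) == 0 || nrow(rm_) == 0) stop("empty path", call. = FALSE)
  arcs <- if (inherits(test, "resampled_path")) test$arc_nm else
    c(0, cumsum(sqrt(rowSums(diff(tm)^2))))
  d <- nearest_dist(tm, rm_)
  out <- tibble::tibble(arc_nm = arcs, dist_nm = d)
  class(out) <- c("distance_profile", class(out))
  out
}

nearest_dist <- function(a, b, block = 2048L) {
  nb2 <- rowSums(b^2)
  out <- numeric(nrow(a))
  for (i0 in seq(1, nrow(a), by = block)) {
    i1 <- min(i0 + block - 1L, nrow(a))
    ab <- a[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(ab^2), nb2, "+") - 2 * tcrossprod(ab, b)
    out[i0:i1] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Traceable length from a distance profile
#'
#' A tracing is lost at the first profile point whose distance to the
#' reference exceeds `lost_threshold`; the traceable length is the arc
#' position of that point, or the full test arc length when the threshold
#' is never exceeded. A `min_run` larger than 1 requires that many
#' consecutive above-threshold samples before declaring loss (the
#' definition itself uses a single sample, the default).
#'
#' @param profile A `distance_profile`.
#' @param params An [eval_params()] list.
#' @param min_run Consecutive above-threshold samples required (default 1).
#' @return One-row tibble: `traceable_length_nm`, `lost`,
#'   `lost_position_nm`, `total_length_nm`.
#' @export
traceable_length <- function(profile, params = eval_params(), min_run = 1L) {
  stopifnot(nrow(profile) >= 1)
  above <- profile$dist_nm > params$lost_threshold
  idx <- NA_integer_
  if (min_run <= 1L) {
    hits <- which(above)
    if (length(hits) > 0) idx <- hits[1]
  } else {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    k <- which(r$values & r$lengths >= min_run)
    if (length(k) > 0) idx <- ends[k[1]] - r$lengths[k[1]] + 1L
  }
  total <- profile$arc_nm[nrow(profile)]
  if (is.na(idx)) {
    tibble::tibble(traceable_length_nm = total, lost = FALSE,
                   lost_position_nm = NA_real_, total_length_nm = total)
  } else {
    pos <- profile$arc_nm[idx]
    tibble::tibble(traceable_length_nm = pos, lost = TRUE,
                   lost_position_nm = pos, total_length_nm = total)
  }
}

#' Classify a trace-evaluation result
#'
#' Splits tracings into `linked_kept` (never lost, long enough to be
#' linked), `linked_lost` (lost beyond the linkage region),
#' `lost_at_linkage` (lost within it) and `too_short` (never lost but the
#' whole tracing is shorter than the link threshold).
#'
#' @param result One-row tibble from [traceable_length()].
#' @param params An [eval_params()] list.
#' @return `result` with a `status` factor column appended.
#' @export
classify_trace <- function(result, params = eval_params()) {
  lt <- params$link_threshold
  status <- dplyr::case_when(
    result$lost & result$lost_position_nm < lt ~ "lost_at_linkage",
    result$lost ~ "linked_lost",
    result$total_length_nm >= lt ~ "linked_kept",
    TRUE ~ "too_short"
  )
  result$status <- factor(status, levels = trace_statuses())
  result
}

trace_statuses <- function() {
  c("linked_kept", "linked_lost", "lost_at_linkage", "too_short")
}

#' Evaluate one test tracing against a reference tracing
#'
#' Convenience wrapper: resamples both root-to-tip polylines at
#' `params$spacing`, builds the distance profile, computes the traceable
#' length and classifies it.
#'
#' @param test,reference Polylines (n x 3 nm matrices), `resampled_path`s
#'   or `skeleton_tree`s (trees are taken root-to-furthest-leaf).
#' @param params An [eval_params()] list.
#' @param cell_id,tracer_id Optional identifiers carried into the result.
#' @return One-row tibble as [classify_trace()], plus id columns.
#' @export
evaluate_tracing <- function(test, reference, params = eval_params(),
                             cell_id = NA_character_,
                             tracer_id = NA_character_) {
  as_path <- function(p) {
    if (inherits(p, "skeleton_tree")) p <- tree_main_path(p)
    if (!inherits(p, "resampled_path")) p <- resample_path(p, params$spacing)
    p
  }
  tp <- as_path(test)
  rp <- as_path(reference)
  res <- classify_trace(traceable_length(distance_profile(tp, rp), params),
                        params)
  dplyr::bind_cols(tibble::tibble(cell_id = cell_id, tracer_id = tracer_id),
                   res)
}

# root-to-tip polyline towards the arc-wise furthest leaf
tree_main_path <- function(tree) {
  nd <- tree$nodes
  leaves <- setdiff(nd$id, nd$parent_id[!is.na(nd$parent_id)])
  paths <- lapply(leaves, function(l) root_to_tip_path(tree, l))
  paths[[which.max(vapply(paths, path_length, numeric(1)))]]
}

#' Select the consensus tracing
#'
#' The longest (by cable length) of the correctly traced trees; ties go
#' to the earliest in input order. Correctness flags are inputs — in the
#' original workflow they come from manual curation.
#'
#' @param trees List of `skeleton_tree`s.
#' @param correct_flags Logical vector, one per tree.
#' @return The selected `skeleton_tree`.
#' @export
select_consensus <- function(trees, correct_flags) {
  stopifnot(length(trees) == length(correct_flags))
  ok <- which(correct_flags)
  if (length(ok) == 0) stop("no correctly traced trees", call. = FALSE)
  lens <- vapply(trees[ok], tree_cable_length, numeric(1))
  trees[[ok[which.max(lens)]]]
}

#' Cohort summary of trace evaluations
#'
#' Per-tracer mean traceable lengths, the cross-tracer mean with its SEM,
#' pooled median/quartiles with Tukey whiskers (most extreme points within
#' 1.5 x IQR of the quartiles) and counts per status.
#'
#' @param results Tibble of per-dendrite rows as produced by
#'   [evaluate_tracing()] (needs `tracer_id`, `traceable_length_nm`,
#'   `status`).
#' @param exclude_statuses Character vector of statuses to drop before
#'   summarising (e.g. `"lost_at_linkage"`).
#' @return A list of class `cohort_summary`: `overall` (one-row tibble),
#'   `per_tracer`, `status_counts`.
#' @export
cohort_summary <- function(results, exclude_statuses = character()) {
  counts <- dplyr::count(results, .data$status, .drop = FALSE)
  kept <- results[!(as.character(results$status) %in% exclude_statuses), ]
  if (nrow(kept) == 0) stop("no results left after exclusion", call. = FALSE)
  per_tracer <- dplyr::summarise(
    dplyr::group_by(kept, .data$tracer_id),
    n = dplyr::n(),
    mean_nm = mean(.data$traceable_length_nm), .groups = "drop")
  tm <- per_tracer$mean_nm
  x <- kept$traceable_length_nm
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- x[x >= q[1] - 1.5 * iqr]
  hi <- x[x <= q[3] + 1.5 * iqr]
  overall <- tibble::tibble(
    n = nrow(kept),
    cross_tracer_mean_nm = mean(tm),
    cross_tracer_sem_nm = if (length(tm) > 1)
      stats::sd(tm) / sqrt(length(tm)) else NA_real_,
    median_nm = q[2], q1_nm = q[1], q3_nm = q[3],
    whisker_low_nm = min(lo), whisker_high_nm = max(hi))
  structure(list(overall = overall, per_tracer = per_tracer,
                 status_counts = counts),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  o <- x$overall
  cat("<cohort_summary> n =", o$n, "\n")
  cat(sprintf("  traceable length: %.1f +/- %.1f um (cross-tracer mean +/- SEM)\n",
              o$cross_tracer_mean_nm / 1000, o$cross_tracer_sem_nm / 1000))
  cat(sprintf("  pooled median [Q1, Q3]: %.1f [%.1f, %.1f] um\n",
              o$median_nm / 1000, o$q1_nm / 1000, o$q3_nm / 1000))
  cat("  status counts: ",
      paste(x$status_counts$status, x$status_counts$n, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write trace-evaluation results to CSV
#'
#' Columns: cell_id, tracer_id, traceable_length_um, lost,
#' lost_position_um, status.
#' @param results Tibble of [evaluate_tracing()] rows.
#' @param path Output file.
#' @export
write_trace_eval_csv <- function(results, path) {
  out <- tibble::tibble(
    cell_id = results$cell_id,
    tracer_id = results$tracer_id,
    traceable_length_um = results$traceable_length_nm / 1000,
    lost = results$lost,
    lost_position_um = results$lost_position_nm / 1000,
    status = as.character(results$status))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
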