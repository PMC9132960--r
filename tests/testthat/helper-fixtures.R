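# in-code fixtures shared across test files

# random skeleton tree built as a chain with optional binary branching;
# returns the tree and the number of branch points added
random_binary_tree <- function(n_branch, seed, step = 1000) {
  set.seed(seed)
  nodes <- data.frame(id = 1:2, x = c(0, 0), y = c(0, step), z = 0,
                      parent_id = c(NA, 1))
  leaves <- 2L
  nid <- 2L
  for (b in seq_len(n_branch)) {
    leaf <- if (length(leaves) == 1) leaves else sample(leaves, 1)
    for (k in 1:2) {
      nid <- nid + 1L
      nodes <- rbind(nodes, data.frame(
        id = nid, x = nodes$x[leaf] + stats::rnorm(1, 0, step),
        y = nodes$y[leaf] + step, z = stats::rnorm(1, 0, step),
        parent_id = nodes$id[leaf]))
      leaves <- c(leaves, nid)
    }
    leaves <- setdiff(leaves, nodes$id[leaf])
  }
  skeleton_tree(nodes, name = "rand")
}

# helix polyline: smooth curve with known arc length
helix_polyline <- function(n = 200, radius = 5000, pitch = 2000,
                           turns = 3) {
  t <- seq(0, 2 * pi * turns, length.out = n)
  cbind(radius * cos(t), radius * sin(t), pitch * t / (2 * pi))
}

helix_true_length <- function(radius = 5000, pitch = 2000, turns = 3) {
  2 * pi * turns * sqrt(radius^2 + (pitch / (2 * pi))^2)
}

# brute-force nearest-neighbour distances, deliberately naive
brute_nearest <- function(a, b) {
  bt <- t(b)
  vapply(seq_len(nrow(a)), function(i) {
    sqrt(min(colSums((bt - a[i, ])^2)))
  }, numeric(1))
}

# evaluate every trace of a generated cohort against its truth tree
eval_cohort <- function(coh, params = eval_params()) {
  truth_names <- vapply(coh$truth, function(t) t$name, character(1))
  dplyr::bind_rows(lapply(seq_len(nrow(coh$traces)), function(i) {
    evaluate_tracing(coh$traces$tree[[i]],
                     coh$truth[[match(coh$traces$cell_id[i], truth_names)]],
                     params = params,
                     cell_id = coh$traces$cell_id[i],
                     tracer_id = coh$traces$tracer_id[i])
  }))
}

# tiny spine annotation with known counts
toy_annotation <- function() {
  br <- tibble::tibble(
    cell_id = c("c1", "c1"), branchlet_id = c("b1", "b2"),
    dendrite_type = c("apical_oblique", "apical_oblique"),
    length_nm = c(30000, 20000))
  sp <- tibble::tibble(
    cell_id = "c1",
    branchlet_id = rep(c("b1", "b2"), c(6, 4)),
    attachment_arc_nm = c(seq(2000, 27000, length.out = 6),
                          seq(1000, 19000, length.out = 4)),
    has_sa = rep(c(TRUE, FALSE), 5),
    n_heads = 1L)
  spine_annotation(br, sp)
}
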