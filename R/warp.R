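#' Landmark sets
#'
#' Paired landmarks linking two named dataset coordinate systems, in nm.
#'
#' @param source Numeric matrix (n x 3), positions in the source space (nm).
#' @param target Numeric matrix (n x 3), corresponding positions in the
#'   target space (nm).
#' @param source_space,target_space Names of the two spaces.
#' @return A `landmark_set`.
#' @export
landmark_set <- function(source, target, source_space, target_space) {
  source <- as_xyz_matrix(source)
  target <- as_xyz_matrix(target)
  stopifnot(nrow(source) == nrow(target), nrow(source) >= 1)
  if (anyDuplicated(source) > 0) {
    stop("duplicated source landmarks", call. = FALSE)
  }
  structure(list(source = source, target = target,
                 source_space = source_space, target_space = target_space),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", x$source_space, " -> ", x$target_space, ": ",
      nrow(x$source), " pairs\n", sep = "")
  invisible(x)
}

#' Read / write landmark files
#'
#' JSON schema: `source_space`, `target_space`, `unit` (always `"nm"`) and
#' `pairs`, an n x 6 array of source xyz followed by target xyz.
#' @param path JSON file.
#' @return [read_landmarks()] returns a `landmark_set`.
#' @rdname landmark_io
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(j$unit, "nm"))
  p <- matrix(as.numeric(j$pairs), ncol = 6)
  landmark_set(p[, 1:3, drop = FALSE], p[, 4:6, drop = FALSE],
               j$source_space, j$target_space)
}

#' @param landmarks A `landmark_set`.
#' @rdname landmark_io
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(
    list(source_space = landmarks$source_space,
         target_space = landmarks$target_space,
         unit = "nm",
         pairs = cbind(landmarks$source, landmarks$target)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

new_transform <- function(kind, params, source_space, target_space) {
  structure(list(kind = kind, params = params,
                 source_space = source_space, target_space = target_space),
            class = "corr_transform")
}

#' @export
print.corr_transform <- function(x, ...) {
  cat("<transform:", x$kind, "> ", x$source_space, " -> ", x$target_space,
      "\n", sep = "")
  invisible(x)
}

#' Identity transform between two spaces
#' @param source_space,target_space Space names.
#' @export
identity_transform <- function(source_space = "a", target_space = source_space) {
  new_transform("identity", list(), source_space, target_space)
}

#' Fit a per-axis scale-offset transform
#'
#' Independent least-squares scale and offset on each axis:
#' `y_i = s_i * x_i + o_i`.
#'
#' @param landmarks A `landmark_set` with at least 2 pairs.
#' @return A `corr_transform` of kind `scale_offset`.
#' @export
fit_scale_offset <- function(landmarks) {
  s <- landmarks$source; t <- landmarks$target
  if (nrow(s) < 2) stop("need >= 2 pairs", call. = FALSE)
  scale <- numeric(3); offset <- numeric(3)
  for (a in 1:3) {
    v <- stats::var(s[, a])
    if (v < .Machine$double.eps * max(1, mean(s[, a])^2)) {
      stop("degenerate landmarks: zero variance on axis ", a, call. = FALSE)
    }
    scale[a] <- stats::cov(s[, a], t[, a]) / v
    offset[a] <- mean(t[, a]) - scale[a] * mean(s[, a])
  }
  new_transform("scale_offset", list(scale = scale, offset = offset),
                landmarks$source_space, landmarks$target_space)
}

#' Fit an affine transform
#'
#' Least-squares 3 x 4 affine matrix mapping source to target landmarks.
#' Requires at least 4 non-coplanar source points.
#'
#' @param landmarks A `landmark_set`.
#' @return A `corr_transform` of kind `affine` with `params$A` (3 x 3)
#'   and `params$b` (3-vector, nm).
#' @export
fit_affine <- function(landmarks) {
  s <- landmarks$source; t <- landmarks$target
  check_noncoplanar(s)
  X <- cbind(s, 1)
  B <- qr.solve(X, t)        # 4 x 3
  new_transform("affine", list(A = t(B[1:3, , drop = FALSE]), b = B[4, ]),
                landmarks$source_space, landmarks$target_space)
}

check_noncoplanar <- function(s) {
  if (nrow(s) < 4) stop("need >= 4 landmark pairs", call. = FALSE)
  c0 <- sweep(s, 2, colMeans(s))
  sv <- svd(c0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    stop("rank error: source landmarks are coplanar or collinear",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a 3D thin-plate spline transform
#'
#' Biharmonic 3D TPS with kernel `U(r) = r` and an affine part. At zero
#' regularisation the spline interpolates its defining landmarks exactly;
#' positive `regularisation` trades interpolation for smoothness
#' (coefficient added to the kernel matrix diagonal).
#'
#' @param landmarks A `landmark_set` with >= 4 non-coplanar pairs.
#' @param regularisation Non-negative smoothing scalar (nm units; 0 =
#'   exact interpolation, the default).
#' @return A `corr_transform` of kind `thin_plate_spline`.
#' @export
fit_tps <- function(landmarks, regularisation = 0) {
  s <- landmarks$source; y <- landmarks$target
  check_noncoplanar(s)
  stopifnot(regularisation >= 0)
  n <- nrow(s)
  K <- tps_kernel(s, s) + diag(regularisation, n)
  P <- cbind(1, s)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(y, matrix(0, 4, 3))
  coefs <- solve(L, rhs)
  new_transform("thin_plate_spline",
                list(control = s, W = coefs[1:n, , drop = FALSE],
                     A = coefs[(n + 1):(n + 4), , drop = FALSE],
                     regularisation = regularisation),
                landmarks$source_space, landmarks$target_space)
}

tps_kernel <- function(a, b) {
  # |a_i - b_j| pairwise; U(r) = r for the 3D biharmonic spline
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Apply a transform to points
#'
#' Elementwise, order-preserving mapping of 3D points through any
#' transform, including lazy composites from [compose_path()].
#'
#' @param transform A `corr_transform`.
#' @param points Numeric matrix (n x 3) in nm.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  p <- as_xyz_matrix(points)
  stopifnot(all(is.finite(p)))
  out <- switch(
    transform$kind,
    identity = p,
    scale_offset = sweep(sweep(p, 2, transform$params$scale, "*"),
                         2, transform$params$offset, "+"),
    affine = tcrossprod(p, transform$params$A) +
      matrix(transform$params$b, nrow(p), 3, byrow = TRUE),
    thin_plate_spline = {
      pr <- transform$params
      cbind(1, p) %*% pr$A + tps_kernel(p, pr$control) %*% pr$W
    },
    composite = {
      for (tr in transform$params$chain) p <- apply_transform(tr, p)
      p
    },
    stop("unknown transform kind: ", transform$kind, call. = FALSE)
  )
  colnames(out) <- c("x", "y", "z")
  out
}

#' Invert a transform
#'
#' Scale-offset and affine transforms invert exactly. Thin-plate splines
#' have no closed-form inverse; the returned inverse is a TPS fitted to
#' the swapped landmark pairs and is approximate (round-trip error is
#' reported by [dataset_graph()] per edge).
#'
#' @param transform A `corr_transform`.
#' @return The inverse `corr_transform`, or `NULL` when no inverse is
#'   defined.
#' @export
invert_transform <- function(transform) {
  sw <- function(kind, params) new_transform(kind, params,
                                             transform$target_space,
                                             transform$source_space)
  switch(
    transform$kind,
    identity = sw("identity", list()),
    scale_offset = sw("scale_offset",
                      list(scale = 1 / transform$params$scale,
                           offset = -transform$params$offset /
                             transform$params$scale)),
    affine = {
      Ai <- solve(transform$params$A)
      sw("affine", list(A = Ai, b = -as.vector(Ai %*% transform$params$b)))
    },
    thin_plate_spline = {
      lm <- landmark_set(
        apply_transform(transform, transform$params$control),
        transform$params$control,
        transform$target_space, transform$source_space)
      fit_tps(lm, transform$params$regularisation)
    },
    NULL
  )
}
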