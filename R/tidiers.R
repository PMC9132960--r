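#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a depth regression
#'
#' One row per model term with estimate, standard error, t statistic and
#' two-sided p-value.
#' @param x A `depth_regression`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy depth_regression
#' @export
tidy.depth_regression <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = unname(co[, 1]),
                 std.error = unname(co[, 2]),
                 statistic = unname(co[, 3]),
                 p.value = unname(co[, 4]))
}

#' Glance at a depth regression
#'
#' One-row model summary: R^2, slope p-value, residual sigma, n.
#' @param x A `depth_regression`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance depth_regression
#' @export
glance.depth_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared,
                 sigma = s$sigma,
                 p.value = s$coefficients[2, 4],
                 nobs = nrow(x$data),
                 dendrite_type = x$dendrite_type,
                 response = x$response)
}

#' Tidy a transform
#'
#' Flat coefficient table of a fitted transform (scale/offset per axis,
#' affine matrix entries, or TPS affine part plus kernel weight norms).
#' @param x A `corr_transform`.
#' @param ... Unused.
#' @return A tibble with `term` and `value`.
#' @method tidy corr_transform
#' @export
tidy.corr_transform <- function(x, ...) {
  p <- x$params
  ax <- c("x", "y", "z")
  switch(
    x$kind,
    scale_offset = tibble::tibble(
      term = c(paste0("scale_", ax), paste0("offset_", ax)),
      value = c(p$scale, p$offset)),
    affine = tibble::tibble(
      term = c(paste0("A_", outer(ax, ax, paste0)), paste0("b_", ax)),
      value = c(p$A, p$b)),
    thin_plate_spline = tibble::tibble(
      term = c(paste0("affine_", c("1", ax), rep(paste0("_", ax),
                                                 each = 4)),
               "kernel_weight_rms"),
      value = c(p$A, sqrt(mean(p$W^2)))),
    tibble::tibble(term = character(), value = numeric()))
}
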