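#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a distance profile
#'
#' Distance to the reference tracing as a function of arc position, with
#' the lost threshold as a dashed line.
#' @param object A `distance_profile`.
#' @param params [eval_params()] providing the threshold line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot distance_profile
#' @export
autoplot.distance_profile <- function(object, params = eval_params(), ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$arc_nm / 1000,
                                       y = .data$dist_nm / 1000)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = params$lost_threshold / 1000,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "arc position (µm)",
                  y = "distance to reference (µm)") +
    ggplot2::theme_minimal()
}

#' Plot an FSC curve with criterion thresholds
#'
#' @param object An `fsc_curve`.
#' @param criteria Criterion names to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fsc_curve
#' @export
autoplot.fsc_curve <- function(object,
                               criteria = c("half_bit", "fixed_1_7"),
                               ...) {
  cc <- object[object$shell >= 1, ]
  thr <- dplyr::bind_rows(lapply(criteria, function(cr) {
    tibble::tibble(freq = cc$freq, value = criterion_threshold(cc$n, cr),
                   criterion = cr)
  }))
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$freq, y = .data$fsc)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_line(data = thr,
                       ggplot2::aes(y = .data$value,
                                    colour = .data$criterion),
                       linetype = "dashed") +
    ggplot2::labs(x = "spatial frequency (cycles/voxel)", y = "FSC",
                  colour = "criterion") +
    ggplot2::theme_minimal()
}

#' Box-style cohort plot of traceable lengths
#'
#' One box per tracer (Tukey whiskers, matching [cohort_summary()]'s
#' convention) over the jittered per-dendrite values.
#' @param results Tibble of [evaluate_tracing()] rows.
#' @return A ggplot.
#' @export
plot_traceable_lengths <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$tracer_id,
                               y = .data$traceable_length_nm / 1000)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "traceable length (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a depth regression with its 95% confidence band
#'
#' @param object A `depth_regression`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot depth_regression
#' @export
autoplot.depth_regression <- function(object, ...) {
  band <- depth_regression_band(object)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$depth_um, y = .data$.y)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$depth_um, y = .data$fit,
                                      ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.2) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(x = .data$depth_um, y = .data$fit)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "soma depth (µm)",
                  y = paste(object$response, "(per µm)")) +
    ggplot2::theme_minimal()
}
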