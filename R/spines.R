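#' Spine annotations
#'
#' Tabular representation of a spine-annotation dataset: one tibble of
#' branchlets (shaft segments) and one of spines attached to them.
#' Branched spines occupy a single row (`n_heads = 2`) and so count once
#' in every statistic, including spine-apparatus counts when both heads
#' carry a cistern.
#'
#' @param branchlets Tibble with `cell_id`, `branchlet_id`,
#'   `dendrite_type` (`"trunk"` or `"apical_oblique"`), `length_nm`.
#' @param spines Tibble with `cell_id`, `branchlet_id`,
#'   `attachment_arc_nm` (position along the shaft), `has_sa` (logical),
#'   optionally `n_heads` (1 or 2, default 1).
#' @return A `spine_annotation` list.
#' @export
spine_annotation <- function(branchlets, spines) {
  branchlets <- tibble::as_tibble(branchlets)
  spines <- tibble::as_tibble(spines)
  stopifnot(all(c("cell_id", "branchlet_id", "dendrite_type",
                  "length_nm") %in% names(branchlets)),
            all(c("cell_id", "branchlet_id", "attachment_arc_nm",
                  "has_sa") %in% names(spines)))
  if (!"n_heads" %in% names(spines)) spines$n_heads <- 1L
  len <- stats::setNames(branchlets$length_nm, branchlets$branchlet_id)
  bad <- spines$attachment_arc_nm < 0 |
    spines$attachment_arc_nm > len[spines$branchlet_id]
  if (any(bad)) stop("spine attachment outside [0, branchlet length]",
                     call. = FALSE)
  spines <- dplyr::arrange(spines, .data$cell_id, .data$branchlet_id,
                           .data$attachment_arc_nm)
  structure(list(branchlets = branchlets, spines = spines),
            class = "spine_annotation")
}

#' @export
print.spine_annotation <- function(x, ...) {
  cat("<spine_annotation> ", length(unique(x$branchlets$cell_id)),
      " cells, ", nrow(x$branchlets), " branchlets, ", nrow(x$spines),
      " spines (", sum(x$spines$has_sa), " with spine apparatus)\n",
      sep = "")
  invisible(x)
}

#' Read / write spine annotations as JSON
#'
#' Schema: `{cells: [{cell_id, branchlets: [{branchlet_id, dendrite_type,
#' length_nm, spines: [{attachment_arc_nm, has_sa, n_heads}]}]}]}`.
#' @param path JSON file.
#' @rdname spine_io
#' @export
read_spine_json <- function(path) {
  j <- jsonlite::read_json(path)
  br <- list(); sp <- list()
  for (cell in j$cells) {
    for (b in cell$branchlets) {
      br[[length(br) + 1]] <- tibble::tibble(
        cell_id = cell$cell_id, branchlet_id = b$branchlet_id,
        dendrite_type = b$dendrite_type, length_nm = b$length_nm)
      for (s in b$spines) {
        sp[[length(sp) + 1]] <- tibble::tibble(
          cell_id = cell$cell_id, branchlet_id = b$branchlet_id,
          attachment_arc_nm = s$attachment_arc_nm,
          has_sa = isTRUE(s$has_sa),
          n_heads = if (is.null(s$n_heads)) 1L else as.integer(s$n_heads))
      }
    }
  }
  spine_annotation(dplyr::bind_rows(br), dplyr::bind_rows(sp))
}

#' @param annotation A `spine_annotation`.
#' @rdname spine_io
#' @export
write_spine_json <- function(annotation, path) {
  cells <- lapply(split(annotation$branchlets,
                        annotation$branchlets$cell_id), function(bdf) {
    list(cell_id = bdf$cell_id[1],
         branchlets = lapply(seq_len(nrow(bdf)), function(i) {
           sp <- annotation$spines[
             annotation$spines$branchlet_id == bdf$branchlet_id[i], ]
           list(branchlet_id = bdf$branchlet_id[i],
                dendrite_type = bdf$dendrite_type[i],
                length_nm = bdf$length_nm[i],
                spines = lapply(seq_len(nrow(sp)), function(k) {
                  list(attachment_arc_nm = sp$attachment_arc_nm[k],
                       has_sa = sp$has_sa[k], n_heads = sp$n_heads[k])
                }))
         }))
  })
  jsonlite::write_json(list(cells = unname(cells)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fit the pyramidal-layer line to soma positions
#'
#' Line through the somata in the x,y plane. The default fit is total
#' least squares (first principal axis through the centroid), which makes
#' the perpendicular depth axis-invariant; `method = "y_on_x"` gives the
#' ordinary regression line instead. The side of the line counting as
#' "deep" is set by an explicit orientation hint vector: depths are
#' positive in the half-plane the hint points into.
#'
#' @param somata_xy n x 2 matrix of soma x,y coordinates (nm); z is
#'   ignored by construction.
#' @param deep_hint Length-2 vector pointing towards the deep side.
#' @param method `"tls"` (default) or `"y_on_x"`.
#' @return A `depth_model`: list with `centroid`, `direction` (unit),
#'   `normal` (unit, pointing deep).
#' @export
fit_soma_layer_line <- function(somata_xy, deep_hint = c(0, 1),
                                method = c("tls", "y_on_x")) {
  method <- match.arg(method)
  m <- as.matrix(somata_xy)[, 1:2, drop = FALSE]
  stopifnot(nrow(m) >= 2)
  ctr <- colMeans(m)
  cm <- sweep(m, 2, ctr)
  if (all(abs(cm) < 1e-12)) stop("all somata identical", call. = FALSE)
  if (method == "tls") {
    direction <- svd(cm)$v[, 1]
  } else {
    b <- stats::coef(stats::lm(cm[, 2] ~ cm[, 1] - 1))
    direction <- c(1, b) / sqrt(1 + b^2)
  }
  normal <- c(-direction[2], direction[1])
  if (sum(normal * deep_hint) < 0) normal <- -normal
  structure(list(centroid = ctr, direction = direction, normal = normal),
            class = "depth_model")
}

#' Signed soma depth
#'
#' Perpendicular distance from the pyramidal-layer line in the x,y plane,
#' positive on the deep side (z ignored).
#'
#' @param soma_xy n x 2 (or length-2) soma coordinates, nm.
#' @param model A `depth_model`.
#' @return Signed depths in nm.
#' @export
soma_depth <- function(soma_xy, model) {
  m <- matrix(as.matrix(soma_xy), ncol = length(model$centroid))
  if (ncol(m) > 2) m <- m[, 1:2, drop = FALSE]
  as.numeric(sweep(m, 2, model$centroid) %*% model$normal)
}

#' Spine and spine-apparatus density table
#'
#' Counts and shaft lengths pooled per cell and dendrite type; densities
#' are counts per micrometre of pooled shaft. A branched spine is one row
#' of the annotation and therefore contributes 1 regardless of how many
#' heads carry a spine apparatus. When soma positions and a depth model
#' are supplied, the signed soma depth is joined per cell.
#'
#' @param annotation A `spine_annotation`.
#' @param somata Optional tibble with `cell_id`, `x`, `y` (nm).
#' @param depth_model Optional `depth_model` from
#'   [fit_soma_layer_line()].
#' @return Tibble: `cell_id`, `dendrite_type`, `n_spines`, `n_sa`,
#'   `shaft_length_nm`, `spine_density_per_um`, `sa_density_per_um`,
#'   and `soma_depth_nm` when computable.
#' @export
density_table <- function(annotation, somata = NULL, depth_model = NULL) {
  shaft <- dplyr::summarise(
    dplyr::group_by(annotation$branchlets, .data$cell_id,
                    .data$dendrite_type),
    shaft_length_nm = sum(.data$length_nm), .groups = "drop")
  if (any(shaft$shaft_length_nm <= 0)) {
    stop("zero shaft length", call. = FALSE)
  }
  sp <- dplyr::left_join(
    annotation$spines,
    annotation$branchlets[, c("branchlet_id", "dendrite_type")],
    by = "branchlet_id")
  counts <- dplyr::summarise(
    dplyr::group_by(sp, .data$cell_id, .data$dendrite_type),
    n_spines = dplyr::n(), n_sa = sum(.data$has_sa), .groups = "drop")
  out <- dplyr::left_join(shaft, counts,
                          by = c("cell_id", "dendrite_type"))
  out$n_spines[is.na(out$n_spines)] <- 0L
  out$n_sa[is.na(out$n_sa)] <- 0L
  out$spine_density_per_um <- out$n_spines / (out$shaft_length_nm / 1000)
  out$sa_density_per_um <- out$n_sa / (out$shaft_length_nm / 1000)
  if (!is.null(somata) && !is.null(depth_model)) {
    somata <- tibble::as_tibble(somata)
    somata$soma_depth_nm <- soma_depth(as.matrix(somata[, c("x", "y")]),
                                       depth_model)
    out <- dplyr::left_join(out, somata[, c("cell_id", "soma_depth_nm")],
                            by = "cell_id")
  }
  out[, c("cell_id", "dendrite_type", "n_spines", "n_sa",
          "shaft_length_nm", "spine_density_per_um", "sa_density_per_um",
          intersect("soma_depth_nm", names(out)))]
}

#' Inter-spine gaps along each branchlet
#'
#' Successive differences of sorted attachment positions within each
#' branchlet, in micrometres. Gaps never span branchlets; branchlets with
#' fewer than two qualifying spines contribute nothing. Set
#' `sa_only = TRUE` for inter-spine-apparatus gaps (the SA-flagged
#' subset).
#'
#' @param annotation A `spine_annotation`.
#' @param sa_only Use only spines with a spine apparatus.
#' @return Tibble: `cell_id`, `branchlet_id`, `gap_um`.
#' @export
inter_spine_distances <- function(annotation, sa_only = FALSE) {
  sp <- annotation$spines
  if (sa_only) sp <- sp[sp$has_sa, ]
  dplyr::reframe(
    dplyr::group_by(sp, .data$cell_id, .data$branchlet_id),
    gap_um = diff(sort(.data$attachment_arc_nm)) / 1000)
}

#' Maximum-likelihood exponential rate for inter-spine gaps
#'
#' Under a homogeneous Poisson process the gaps are exponential with
#' density `f(x) = lambda exp(-lambda x)`; the MLE of the rate is the
#' reciprocal mean gap.
#'
#' @param gaps Positive gaps in micrometres.
#' @return Rate `lambda_hat` per micrometre.
#' @export
fit_exponential <- function(gaps) {
  gaps <- as.numeric(gaps)
  if (length(gaps) < 1 || any(gaps <= 0)) {
    stop("need positive gaps", call. = FALSE)
  }
  1 / mean(gaps)
}

ks_D_exp <- function(x, rate) {
  x <- sort(x)
  n <- length(x)
  cdf <- 1 - exp(-rate * x)
  max(max(seq_len(n) / n - cdf), max(cdf - (seq_len(n) - 1) / n))
}

#' One-sample Kolmogorov-Smirnov test against a fitted exponential
#'
#' Tests whether gaps are compatible with the exponential null implied by
#' a homogeneous Poisson process. `calibration = "naive"` computes the
#' p-value from the standard one-sample KS distribution with the fitted
#' rate plugged in; because the rate is estimated from the same data this
#' is conservative (type-I error below nominal). The default
#' `"parametric_bootstrap"` refits the rate on each of `B` exponential
#' resamples and uses the bootstrap distribution of D, which restores
#' nominal calibration.
#'
#' @param gaps Positive gaps, micrometres (>= 5 values).
#' @param rate Optional externally fitted rate; default refits on `gaps`.
#'   Supplying the all-spines rate reproduces the protocol of testing
#'   spine-apparatus gaps against the same fitted exponential.
#' @param calibration `"parametric_bootstrap"` (default) or `"naive"`.
#' @param B Bootstrap resamples (default 999).
#' @return One-row `exp_fit` tibble: `n`, `lambda_hat`, `mean_gap_um`,
#'   `ks_D`, `ks_p`, `method`.
#' @export
ks_test_exponential <- function(gaps, rate = NULL,
                                calibration = c("parametric_bootstrap",
                                                "naive"),
                                B = 999) {
  calibration <- match.arg(calibration)
  gaps <- as.numeric(gaps)
  if (length(gaps) < 5) stop("need at least 5 gaps", call. = FALSE)
  if (any(gaps <= 0)) stop("need positive gaps", call. = FALSE)
  refit <- is.null(rate)
  if (refit) rate <- fit_exponential(gaps)
  D <- ks_D_exp(gaps, rate)
  n <- length(gaps)
  if (calibration == "naive") {
    p <- suppressWarnings(
      stats::ks.test(gaps, "pexp", rate = rate)$p.value)
  } else {
    exceed <- 0L
    for (b in seq_len(B)) {
      xb <- stats::rexp(n, rate)
      rb <- if (refit) 1 / mean(xb) else rate
      if (ks_D_exp(xb, rb) >= D) exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (B + 1)
  }
  out <- tibble::tibble(n = n, lambda_hat = rate, mean_gap_um = mean(gaps),
                        ks_D = D, ks_p = p, method = calibration)
  class(out) <- c("exp_fit", class(out))
  out
}

#' Maximum inter-spine gap per branchlet
#'
#' One row per branchlet with at least two spines: branchlet length and
#' the largest gap (both micrometres). The maximum gap is geometrically
#' bounded by the branchlet length.
#'
#' @param annotation A `spine_annotation`.
#' @param sa_only Restrict to spine-apparatus spines.
#' @return Tibble: `cell_id`, `branchlet_id`, `length_um`, `max_gap_um`.
#' @export
max_gap_vs_length <- function(annotation, sa_only = FALSE) {
  gaps <- inter_spine_distances(annotation, sa_only = sa_only)
  mx <- dplyr::summarise(
    dplyr::group_by(gaps, .data$cell_id, .data$branchlet_id),
    max_gap_um = max(.data$gap_um), .groups = "drop")
  dplyr::left_join(
    mx,
    dplyr::mutate(annotation$branchlets[, c("branchlet_id", "length_nm")],
                  length_um = .data$length_nm / 1000,
                  length_nm = NULL),
    by = "branchlet_id")[, c("cell_id", "branchlet_id", "length_um",
                             "max_gap_um")]
}

#' Regress spine(-apparatus) density on soma depth
#'
#' Ordinary least squares of per-cell density against signed soma depth
#' for one dendrite type, with the two-sided t-test on the slope and the
#' pointwise 95% confidence band of the mean response.
#'
#' @param records [density_table()] output including `soma_depth_nm`.
#' @param dendrite_type Which type to regress (`"trunk"` or
#'   `"apical_oblique"`).
#' @param response Density column, default `"sa_density_per_um"`.
#' @return A `depth_regression` object wrapping the `lm` fit; supports
#'   [generics::tidy()], [generics::glance()] and `predict()`.
#' @export
regress_density_vs_depth <- function(records,
                                     dendrite_type = "apical_oblique",
                                     response = "sa_density_per_um") {
  df <- records[records$dendrite_type == dendrite_type, ]
  if (nrow(df) < 3) stop("need >= 3 records of type ", dendrite_type,
                         call. = FALSE)
  df$depth_um <- df$soma_depth_nm / 1000
  if (stats::var(df$depth_um) == 0) stop("zero depth variance",
                                         call. = FALSE)
  df$.y <- df[[response]]
  fit <- stats::lm(.y ~ depth_um, data = df)
  structure(list(fit = fit, data = df, dendrite_type = dendrite_type,
                 response = response),
            class = "depth_regression")
}

#' @export
print.depth_regression <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  cat("<depth_regression> ", x$response, " ~ soma depth (",
      x$dendrite_type, ", n = ", nrow(x$data), ")\n", sep = "")
  cat(sprintf("  slope %.4g per um depth, p = %.3g\n",
              co[2, 1], co[2, 4]))
  invisible(x)
}

#' Confidence band of a depth regression
#'
#' Pointwise 95% interval for the mean response, symmetric about the
#' fitted line.
#' @param x A `depth_regression`.
#' @param depth_um Depths (um) to evaluate; default spans the data.
#' @return Tibble: `depth_um`, `fit`, `lwr`, `upr`.
#' @export
depth_regression_band <- function(x, depth_um = NULL) {
  if (is.null(depth_um)) {
    depth_um <- seq(min(x$data$depth_um), max(x$data$depth_um),
                    length.out = 100)
  }
  pr <- stats::predict(x$fit, newdata = data.frame(depth_um = depth_um),
                       interval = "confidence", level = 0.95)
  tibble::tibble(depth_um = depth_um, fit = pr[, "fit"],
                 lwr = pr[, "lwr"], upr = pr[, "upr"])
}
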