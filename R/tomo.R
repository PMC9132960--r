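#' Flat-field / dark-current normalisation of projections
#'
#' `p_norm = (p - d) / (f - d)` elementwise. `projections` may be a 2D
#' matrix or a 3D array (angle, row, col); dark and flat are matched
#' in-plane.
#'
#' @param projections 2D matrix or 3D array of raw projections.
#' @param dark,flat Detector dark-current and flat-field images
#'   (matrices, or scalars for synthetic work).
#' @return Normalised projections, same shape as the input.
#' @export
normalise_projections <- function(projections, dark, flat) {
  denom <- flat - dark
  if (any(denom <= 0)) {
    bad <- if (is.matrix(denom)) {
      paste(which(denom <= 0, arr.ind = TRUE)[1, ], collapse = ",")
    } else {
      as.character(which(denom <= 0)[1])
    }
    stop("flat - dark not positive at pixel ", bad, call. = FALSE)
  }
  if (length(dim(projections)) == 3 && length(denom) > 1) {
    out <- projections
    for (i in seq_len(dim(projections)[1])) {
      out[i, , ] <- (projections[i, , ] - dark) / denom
    }
    out
  } else {
    (projections - dark) / denom
  }
}

#' Paganin phase-retrieval parameters
#'
#' The single-distance filter needs the X-ray energy, the
#' sample-to-detector propagation distance, the detector pixel size and
#' the ratio of the refractive index decrement to its absorption part.
#' Defaults follow the synchrotron microtomography configuration the
#' package targets (22 keV, 52 mm, 325 nm, delta/beta = 1). Absolute
#' `delta` and `beta` may be supplied instead of the ratio (e.g.
#' delta = 2e-6, beta = 6e-7 for a monochromatic beamline setting, giving
#' a ratio of 10/3).
#'
#' @param energy_kev X-ray energy, keV.
#' @param dist_mm Propagation distance, mm.
#' @param pixel_nm Detector pixel size, nm.
#' @param delta_beta Ratio delta/beta; ignored when `delta` and `beta`
#'   are both given.
#' @param delta,beta Optional absolute refractive-index parts.
#' @return A `phase_params` list (includes the wavelength in nm).
#' @export
phase_params <- function(energy_kev = 22, dist_mm = 52, pixel_nm = 325,
                         delta_beta = 1, delta = NULL, beta = NULL) {
  if (!is.null(delta) && !is.null(beta)) delta_beta <- delta / beta
  stopifnot(energy_kev > 0, dist_mm > 0, pixel_nm > 0, delta_beta >= 0)
  wavelength_nm <- 1.23984193 / energy_kev   # hc = 1239.84 eV nm
  structure(list(energy_kev = energy_kev, dist_mm = dist_mm,
                 pixel_nm = pixel_nm, delta_beta = delta_beta,
                 wavelength_nm = wavelength_nm), class = "phase_params")
}

#' Paganin single-distance phase retrieval
#'
#' Low-pass filters a normalised projection in Fourier space with
#' `1 / (1 + pi * lambda * z * (delta/beta) * (u^2 + v^2))` (u, v in
#' cycles per unit length) and takes `-log` of the result, yielding a
#' thickness-proportional map under the homogeneous-object assumption.
#' The filter gain is exactly 1 at DC and strictly below 1 at every other
#' frequency. With `delta_beta = 0` the output is the pure absorption
#' signal `-log(p_norm)`.
#'
#' @param p_norm Normalised 2D projection (positive; values that come out
#'   non-positive before the log are clipped at `eps`, with the clip
#'   count reported as attribute `n_clipped`).
#' @param params A [phase_params()] list.
#' @param output `"thickness"` (default, `-log` applied) or
#'   `"intensity"` (the filtered image itself).
#' @param eps Clipping floor for the log step.
#' @return Filtered 2D matrix.
#' @export
paganin_filter <- function(p_norm, params = phase_params(),
                           output = c("thickness", "intensity"),
                           eps = 1e-8) {
  output <- match.arg(output)
  stopifnot(is.matrix(p_norm), all(is.finite(p_norm)))
  d <- dim(p_norm)
  freq2 <- function(n) {
    k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n
    (k / (n * params$pixel_nm))^2       # cycles^2 per nm^2
  }
  u2 <- outer(freq2(d[1]), freq2(d[2]), "+")
  z_nm <- params$dist_mm * 1e6
  H <- 1 / (1 + pi * params$wavelength_nm * z_nm * params$delta_beta * u2)
  filt <- Re(stats::fft(stats::fft(p_norm) * H, inverse = TRUE)) /
    prod(d)
  if (output == "intensity") return(filt)
  n_clipped <- sum(filt <= 0)
  if (n_clipped > 0) {
    warning(n_clipped, " non-positive values clipped before log",
            call. = FALSE)
    filt[filt <= 0] <- eps
  }
  out <- -log(filt)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Parallel-beam forward projection (Radon transform)
#'
#' Line integrals of a square phantom by rotated bilinear sampling, used
#' as the oracle for reconstruction. Detector bins coincide with image
#' columns; angle 0 integrates along rows.
#'
#' @param phantom Square 2D matrix.
#' @param angles_deg Projection angles in degrees over \[0, 180).
#' @return Sinogram matrix (length(angles) x n).
#' @export
forward_project <- function(phantom, angles_deg) {
  n <- nrow(phantom)
  stopifnot(ncol(phantom) == n)
  ctr <- (n + 1) / 2
  g <- seq_len(n) - ctr
  sino <- matrix(0, length(angles_deg), n)
  for (k in seq_along(angles_deg)) {
    th <- angles_deg[k] * pi / 180
    # sample the phantom on the rotated grid (t = detector, s = ray)
    xs <- outer(g * cos(th), -g * sin(th), "+")    # t rows, s cols
    ys <- outer(g * sin(th), g * cos(th), "+")
    sino[k, ] <- rowSums(bilinear_lookup(phantom, xs + ctr, ys + ctr))
  }
  sino
}

bilinear_lookup <- function(img, xi, yi) {
  n <- nrow(img); m <- ncol(img)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  val <- function(ix, iy) {
    ok <- ix >= 1 & ix <= n & iy >= 1 & iy <= m
    out <- numeric(length(ix))
    out[ok] <- img[cbind(ix[ok], iy[ok])]
    out
  }
  v <- val(x0, y0) * (1 - fx) * (1 - fy) +
    val(x0 + 1, y0) * fx * (1 - fy) +
    val(x0, y0 + 1) * (1 - fx) * fy +
    val(x0 + 1, y0 + 1) * fx * fy
  matrix(v, nrow(xi), ncol(xi))
}

#' Filtered back-projection with a Ram-Lak filter
#'
#' Each sinogram row is zero-padded by a factor of sqrt(2) (edge
#' replication optional), ramp-filtered in frequency, and back-projected
#' with bilinear interpolation; the result is scaled by `pi / n_angles`.
#'
#' @param sinogram Matrix (n_angles x n_detector).
#' @param angles_deg Angles matching the sinogram rows, degrees.
#' @param padding `"zero"` (default) or `"edge"`.
#' @return A `recon_slice`: n x n matrix with attribute `pixel_nm`
#'   when supplied.
#' @param pixel_nm Optional pixel size to attach to the slice.
#' @export
fbp_reconstruct <- function(sinogram, angles_deg,
                            padding = c("zero", "edge"), pixel_nm = NULL) {
  padding <- match.arg(padding)
  stopifnot(nrow(sinogram) == length(angles_deg))
  if (length(angles_deg) < 2) stop("need at least 2 angles", call. = FALSE)
  n <- ncol(sinogram)
  npad <- 2L * ceiling(n * sqrt(2) / 2)          # even, >= sqrt(2) n
  pre <- (npad - n) %/% 2
  # Ram-Lak kernel built in real space (unit detector spacing):
  # h(0) = 1/4, h(k odd) = -1/(pi k)^2, h(k even) = 0. Its transform is
  # the band-limited ramp |f| without the DC bias a naive frequency-
  # domain ramp introduces.
  k <- 0:(npad - 1); k[k > npad / 2] <- k[k > npad / 2] - npad
  h <- ifelse(k == 0, 0.25, ifelse(k %% 2 != 0, -1 / (pi * k)^2, 0))
  ramp <- Re(stats::fft(h))
  filt <- matrix(0, nrow(sinogram), n)
  for (i in seq_len(nrow(sinogram))) {
    row <- numeric(npad)
    row[pre + seq_len(n)] <- sinogram[i, ]
    if (padding == "edge") {
      row[seq_len(pre)] <- sinogram[i, 1]
      row[(pre + n + 1):npad] <- sinogram[i, n]
    }
    fr <- Re(stats::fft(stats::fft(row) * ramp, inverse = TRUE)) / npad
    filt[i, ] <- fr[pre + seq_len(n)]
  }
  ctr <- (n + 1) / 2
  g <- seq_len(n) - ctr
  xg <- matrix(g, n, n)        # row coordinate
  yg <- matrix(g, n, n, byrow = TRUE)
  rec <- matrix(0, n, n)
  for (i in seq_along(angles_deg)) {
    th <- angles_deg[i] * pi / 180
    t <- xg * cos(th) + yg * sin(th) + ctr
    t0 <- floor(t); ft <- t - t0
    ok0 <- t0 >= 1 & t0 <= n
    ok1 <- t0 + 1 >= 1 & t0 + 1 <= n
    v <- matrix(0, n, n)
    v[ok0] <- filt[i, t0[ok0]] * (1 - ft[ok0])
    v[ok1] <- v[ok1] + filt[i, t0[ok1] + 1] * ft[ok1]
    rec <- rec + v
  }
  rec <- rec * pi / length(angles_deg)
  if (!is.null(pixel_nm)) attr(rec, "pixel_nm") <- pixel_nm
  class(rec) <- c("recon_slice", class(rec))
  rec
}

#' Ring-removal / centre-finding stubs
#'
#' The reconstruction pipeline the package mirrors applies sinogram
#' ring-removal and automatic centre-finding between phase retrieval and
#' back-projection; those algorithms are out of scope here, so this stage
#' passes data through unchanged. Kept so pipeline code can call the full
#' stage sequence.
#'
#' @param sinogram Sinogram matrix.
#' @return The input, unchanged.
#' @export
remove_rings <- function(sinogram) sinogram

#' Write / read a 2D slice or image as 32-bit TIFF
#'
#' Thin wrappers over the tiff package (a suggested dependency) for
#' floating-point slices.
#' @param slice Numeric matrix.
#' @param path TIFF file.
#' @rdname slice_io
#' @export
write_slice_tiff <- function(slice, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O", call. = FALSE)
  }
  tiff::writeTIFF(unclass(slice), path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname slice_io
#' @export
read_slice_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O", call. = FALSE)
  }
  tiff::readTIFF(path)
}
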