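#' Volume pairs for split-half resolution estimation
#'
#' @param half_a,half_b 3D numeric arrays of identical shape with finite
#'   values.
#' @param voxel_size Isotropic voxel size in nm.
#' @return A `volume_pair`.
#' @export
volume_pair <- function(half_a, half_b, voxel_size) {
  stopifnot(length(dim(half_a)) == 3, identical(dim(half_a), dim(half_b)),
            all(is.finite(half_a)), all(is.finite(half_b)), voxel_size > 0)
  structure(list(half_a = half_a, half_b = half_b, voxel_size = voxel_size),
            class = "volume_pair")
}

#' Split an EM volume into odd/even-slice halves
#'
#' Emulates the split-half construction used for serial block-face EM:
#' the two half volumes are the odd and even slices along the first axis,
#' each then 2 x 2 mean-pooled in-plane, which doubles the voxel size
#' (isotropic again when the slice pitch is twice the pixel size).
#'
#' @param volume 3D array (slice, row, col).
#' @param voxel_size In-plane pixel size of the input, nm.
#' @return A `volume_pair` with `voxel_size` doubled.
#' @export
split_half_em <- function(volume, voxel_size) {
  d <- dim(volume)
  stopifnot(length(d) == 3)
  if (d[1] < 2) stop("need at least 2 slices to split", call. = FALSE)
  odd <- volume[seq(1, d[1], by = 2), , , drop = FALSE]
  even <- volume[seq(2, d[1], by = 2), , , drop = FALSE]
  n <- min(dim(odd)[1], dim(even)[1])
  volume_pair(pool2x2(odd[seq_len(n), , , drop = FALSE]),
              pool2x2(even[seq_len(n), , , drop = FALSE]),
              voxel_size * 2)
}

pool2x2 <- function(v) {
  d <- dim(v)
  r <- (d[2] %/% 2) * 2
  c_ <- (d[3] %/% 2) * 2
  v <- v[, seq_len(r), seq_len(c_), drop = FALSE]
  (v[, seq(1, r, 2), seq(1, c_, 2), drop = FALSE] +
   v[, seq(2, r, 2), seq(1, c_, 2), drop = FALSE] +
   v[, seq(1, r, 2), seq(2, c_, 2), drop = FALSE] +
   v[, seq(2, r, 2), seq(2, c_, 2), drop = FALSE]) / 4
}

# per-axis normalised frequency coordinates and integer shell index
# (rounded radius in units of the reference axis length)
shell_index <- function(d) {
  fax <- lapply(d, function(n) {
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n
    k / n                                 # cycles per voxel
  })
  nref <- max(d)
  r <- sqrt(outer(outer(fax[[1]]^2, fax[[2]]^2, "+"), fax[[3]]^2, "+"))
  round(r * nref)                          # integer shell id
}

#' Compute the Fourier Shell Correlation of a volume pair
#'
#' Per-shell normalised cross-correlation of the two half volumes:
#' `FSC(r) = Re(sum F_a F_b*) / sqrt(sum |F_a|^2 sum |F_b|^2)` over
#' integer-radius shells one frequency voxel wide (rounded radius).
#' Shell 0 is the DC term alone; analysis shells start at 1. Non-cubic
#' volumes are handled by normalising frequencies per axis before radius
#' binning.
#'
#' @param pair A `volume_pair`.
#' @return An `fsc_curve` tibble: `shell`, `freq` (cycles/voxel), `fsc`,
#'   `n` (voxels per shell), with the voxel size as an attribute.
#' @export
compute_fsc <- function(pair) {
  a <- pair$half_a; b <- pair$half_b
  if (all(a == 0) || all(b == 0)) {
    stop("all-zero volume: FSC normalisation undefined", call. = FALSE)
  }
  d <- dim(a)
  Fa <- stats::fft(a)
  Fb <- stats::fft(b)
  sh <- shell_index(d)
  smax <- floor(max(d) / 2)
  keep <- sh <= smax
  f <- factor(sh[keep], levels = 0:smax)
  num <- tapply(Re(Fa[keep] * Conj(Fb[keep])), f, sum)
  pa <- tapply(abs(Fa[keep])^2, f, sum)
  pb <- tapply(abs(Fb[keep])^2, f, sum)
  n_i <- as.integer(table(f))
  denom <- sqrt(pa * pb)
  fsc <- ifelse(denom > 0, num / denom, NA_real_)
  out <- tibble::tibble(shell = 0:smax,
                        freq = (0:smax) / max(d),
                        fsc = as.numeric(fsc),
                        n = n_i)
  attr(out, "voxel_size") <- pair$voxel_size
  class(out) <- c("fsc_curve", class(out))
  out
}

#' Per-shell thresholds for the standard FSC resolution criteria
#'
#' Information-based 1-bit and half-bit curves, the 3-sigma noise
#' threshold and the fixed 1/7 line, as functions of the voxel count
#' `n` in each shell. Two 3-sigma variants exist in the criterion
#' literature; `three_sigma_plus_one` (with `+ 1` in the denominator) is
#' the default family member, `three_sigma` the bare `3 / sqrt(n/2)`.
#'
#' @param n Integer vector of per-shell voxel counts (>= 1).
#' @param criterion One of `"one_bit"`, `"half_bit"`, `"three_sigma"`,
#'   `"fixed_1_7"`.
#' @param sigma_plus_one For the 3-sigma criterion, include `+ 1` in the
#'   denominator (default `TRUE`).
#' @return Numeric vector of thresholds, one per shell.
#' @export
criterion_threshold <- function(n,
                                criterion = c("one_bit", "half_bit",
                                              "three_sigma", "fixed_1_7"),
                                sigma_plus_one = TRUE) {
  criterion <- match.arg(criterion)
  if (any(n < 1)) stop("shell counts must be >= 1", call. = FALSE)
  rn <- sqrt(n)
  switch(criterion,
    one_bit = (0.5 + 2.4142 / rn) / (1.5 + 1.4142 / rn),
    half_bit = (0.2071 + 1.9102 / rn) / (1.2071 + 0.9102 / rn),
    three_sigma = if (sigma_plus_one) 3 / (sqrt(n / 2) + 1)
                  else 3 / sqrt(n / 2),
    fixed_1_7 = rep(1 / 7, length(n)))
}

#' Read resolution off an FSC curve
#'
#' The crossing is the first analysis shell (DC excluded) where the FSC
#' falls below the criterion threshold, refined by linear interpolation
#' between the adjacent shells; resolution = voxel size / crossing
#' frequency. When the curve never crosses below the threshold within
#' Nyquist, the estimate is flagged `beyond_nyquist` with `NA` values.
#'
#' @param curve An `fsc_curve`.
#' @param criterion Criterion name (see [criterion_threshold()]).
#' @param voxel_size Voxel size in nm; defaults to the curve's attribute.
#' @param sigma_plus_one Passed to [criterion_threshold()].
#' @return One-row tibble: `criterion`, `crossing_freq` (cycles/voxel),
#'   `resolution_nm`, `beyond_nyquist`.
#' @export
resolution_from_curve <- function(curve, criterion = "fixed_1_7",
                                  voxel_size = attr(curve, "voxel_size"),
                                  sigma_plus_one = TRUE) {
  cc <- curve[curve$shell >= 1 & !is.na(curve$fsc), ]
  thr <- criterion_threshold(cc$n, criterion, sigma_plus_one)
  below <- cc$fsc < thr
  if (!any(below)) {
    return(tibble::tibble(criterion = criterion, crossing_freq = NA_real_,
                          resolution_nm = NA_real_, beyond_nyquist = TRUE))
  }
  i <- which(below)[1]
  if (i == 1) {
    f <- cc$freq[1]
  } else {
    # linear interpolation of fsc - threshold between shells i-1 and i
    g0 <- cc$fsc[i - 1] - thr[i - 1]
    g1 <- cc$fsc[i] - thr[i]
    w <- g0 / (g0 - g1)
    f <- cc$freq[i - 1] + w * (cc$freq[i] - cc$freq[i - 1])
  }
  tibble::tibble(criterion = criterion, crossing_freq = f,
                 resolution_nm = if (is.null(voxel_size)) NA_real_
                                 else voxel_size / f,
                 beyond_nyquist = FALSE)
}

#' Average FSC curves over ROI pairs
#'
#' Pointwise mean of the correlation with shell counts summed; all curves
#' must share the same shell grid.
#'
#' @param curves List of `fsc_curve`s.
#' @return An `fsc_curve`.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  sh <- curves[[1]]$shell
  for (cu in curves) {
    if (!identical(cu$shell, sh)) stop("mismatched shell grids",
                                       call. = FALSE)
  }
  out <- curves[[1]]
  out$fsc <- rowMeans(sapply(curves, function(cu) cu$fsc))
  out$n <- as.integer(rowSums(sapply(curves, function(cu) cu$n)))
  out
}

#' Normalise FSC curves assuming null high-frequency correlation
#'
#' Some reconstruction pipelines share filtering between the two half
#' volumes, leaving an artifactual correlation floor. This rescale
#' assumes correlations in a high-frequency band (default
#' `[1/(3 px), 1/(2 px)]`, i.e. 1/3 to 1/2 cycles per voxel) are truly
#' null: the band mean `m` of the *averaged* curve is estimated and every
#' curve is rescaled as `fsc' = (fsc - m) / (1 - m)`, fixing `fsc = 1`
#' and mapping the band mean to 0. `mode = "subtract"` only subtracts `m`.
#'
#' @param curves List of `fsc_curve`s on one shell grid.
#' @param band Frequency band (cycles/voxel) assumed uncorrelated.
#' @param mode `"rescale"` (default) or `"subtract"`.
#' @return List of normalised `fsc_curve`s.
#' @export
normalise_high_freq <- function(curves, band = c(1 / 3, 1 / 2),
                                mode = c("rescale", "subtract")) {
  mode <- match.arg(mode)
  avg <- average_curves(curves)
  in_band <- avg$freq >= band[1] & avg$freq <= band[2] & !is.na(avg$fsc)
  if (!any(in_band)) stop("band outside curve range", call. = FALSE)
  m <- mean(avg$fsc[in_band])
  if (m >= 1) stop("band mean >= 1: cannot normalise", call. = FALSE)
  lapply(curves, function(cu) {
    cu$fsc <- if (mode == "rescale") (cu$fsc - m) / (1 - m) else cu$fsc - m
    cu
  })
}

#' Radially averaged power spectral density of a 2D image
#'
#' Mean squared FFT magnitude in integer-radius bins, DC excluded. The
#' frequency axis is the radial bin index divided by half the FFT size,
#' so Nyquist sits at 1.
#'
#' @param image 2D numeric matrix.
#' @return Tibble with `freq` (fraction of Nyquist) and `power`.
#' @export
radial_psd <- function(image) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  d <- dim(image)
  P <- abs(stats::fft(image))^2
  fax <- lapply(d, function(n) {
    k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n; k / n
  })
  nref <- max(d)
  r <- round(sqrt(outer(fax[[1]]^2, fax[[2]]^2, "+")) * nref)
  smax <- floor(nref / 2)
  keep <- r >= 1 & r <= smax
  f <- factor(r[keep], levels = 1:smax)
  pw <- tapply(P[keep], f, mean)
  pw[is.na(pw)] <- 0
  tibble::tibble(freq = (1:smax) / (nref / 2), power = as.numeric(pw))
}

#' Export an FSC curve with criterion thresholds to CSV
#'
#' Columns: shell, freq_cyc_per_voxel, fsc, n, and one threshold column
#' per requested criterion.
#' @param curve An `fsc_curve`.
#' @param path Output file.
#' @param criteria Criterion names to tabulate.
#' @export
write_fsc_csv <- function(curve, path,
                          criteria = c("one_bit", "half_bit",
                                       "three_sigma", "fixed_1_7")) {
  out <- data.frame(shell = curve$shell, freq_cyc_per_voxel = curve$freq,
                    fsc = curve$fsc, n = curve$n)
  for (cr in criteria) out[[cr]] <- criterion_threshold(curve$n, cr)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read an FSC curve written by [write_fsc_csv()]
#' @param path CSV file.
#' @param voxel_size Optional voxel size (nm) to attach.
#' @return An `fsc_curve`.
#' @export
read_fsc_csv <- function(path, voxel_size = NULL) {
  df <- utils::read.csv(path)
  out <- tibble::tibble(shell = as.integer(df$shell),
                        freq = df$freq_cyc_per_voxel,
                        fsc = df$fsc, n = as.integer(df$n))
  attr(out, "voxel_size") <- voxel_size
  class(out) <- c("fsc_curve", class(out))
  out
}
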