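#' Seeded synthetic-data generators
#'
#' Every generator takes an integer `seed` and is bit-reproducible under
#' it. A single study-level seed can be fanned out into independent
#' per-generator substreams with [substream_seed()], so tests of one
#' module never perturb another's draws.
#'
#' @param seed Integer master seed.
#' @param label Character label of the substream.
#' @return An integer seed derived deterministically from `seed` and
#'   `label`, below 2^31.
#' @export
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

# persistent random walk in 3D: nearly straight path of given length,
# step-wise angular diffusion controlled by tortuosity (rad per sqrt(um))
random_walk_path <- function(full_length_nm, step_nm = 1000,
                             tortuosity = 0.02) {
  n <- ceiling(full_length_nm / step_nm)
  dir <- c(0, 1, 0)
  pts <- matrix(0, n + 1, 3)
  for (i in seq_len(n)) {
    perturb <- stats::rnorm(3, 0, tortuosity * sqrt(step_nm / 1000))
    dir <- dir + perturb
    dir <- dir / sqrt(sum(dir^2))
    pts[i + 1, ] <- pts[i, ] + dir * step_nm
  }
  colnames(pts) <- c("x", "y", "z")
  pts
}

# smooth random displacement along a path: sum of a few random-phase
# sinusoids in arc length per axis; amplitude sigma_nm RMS per axis
smooth_jitter <- function(arc_nm, sigma_nm, corr_nm = 20000, n_modes = 4) {
  out <- matrix(0, length(arc_nm), 3)
  for (a in 1:3) {
    for (k in seq_len(n_modes)) {
      wl <- corr_nm * stats::runif(1, 0.8, 3)
      ph <- stats::runif(1, 0, 2 * pi)
      out[, a] <- out[, a] + sin(2 * pi * arc_nm / wl + ph)
    }
  }
  out * sigma_nm / sqrt(n_modes / 2)
}

polyline_tree <- function(pts, name) {
  n <- nrow(pts)
  skeleton_tree(tibble::tibble(
    id = seq_len(n), x = pts[, 1], y = pts[, 2], z = pts[, 3],
    parent_id = c(NA_integer_, seq_len(n - 1))), name = name)
}

#' Generate a synthetic dendrite-tracing cohort
#'
#' Emulates the error structure of manual apical-dendrite tracing
#' evaluated against a ground-truth tracing. Truth dendrites are
#' persistent random walks of the designed length (nearly straight, as
#' mitral-cell apical dendrites crossing the external plexiform layer
#' are). Each tracer copy receives smooth low-frequency positional jitter
#' and, independently per dendrite:
#' with probability `q` a *linkage failure* — a sustained wrong-turn
#' departure at an arc position uniform in `[0, linkage_window]`, placed
#' so the resulting loss position falls inside the ~40 um linkage region
#' and below the 35 um link threshold; otherwise, with probability `q2`,
#' a late departure uniform beyond the linkage window.
#'
#' @param n_cells Number of dendrites.
#' @param full_length_um Designed truth length (default 200, an
#'   EPL-crossing apical dendrite).
#' @param tortuosity Angular diffusion of the truth walk.
#' @param q Linkage-failure probability.
#' @param q2 Late-departure probability among non-linkage-failed cells.
#' @param jitter_sigma_nm RMS smooth tracer jitter per axis (default 500).
#' @param linkage_window_um Range of linkage-failure departure points
#'   (default 20).
#' @param n_tracers Tracer copies per dendrite.
#' @param seed Integer seed.
#' @return List with `truth` (list of `skeleton_tree`) and `traces`
#'   (tibble: `cell_id`, `tracer_id`, `tree` list-column, `departure_nm`,
#'   `failure_mode`).
#' @export
gen_dendrite_cohort <- function(n_cells = 50, full_length_um = 200,
                                tortuosity = 0.02, q = 0.25, q2 = 0.05,
                                jitter_sigma_nm = 500,
                                linkage_window_um = 20,
                                n_tracers = 3, seed = 1) {
  with_seed(substream_seed(seed, "dendrite_cohort"), {
    full_nm <- full_length_um * 1000
    truth <- lapply(seq_len(n_cells), function(i) {
      polyline_tree(random_walk_path(full_nm, tortuosity = tortuosity),
                    sprintf("cell_%03d", i))
    })
    rows <- list()
    for (i in seq_len(n_cells)) {
      tm <- node_xyz(truth[[i]])
      arcs <- c(0, cumsum(sqrt(rowSums(diff(tm)^2))))
      for (tr in seq_len(n_tracers)) {
        u <- stats::runif(1)
        if (u < q) {
          mode <- "linkage"
          dep <- stats::runif(1, 0, linkage_window_um * 1000)
        } else if (u < q + (1 - q) * q2) {
          mode <- "late"
          dep <- stats::runif(1, linkage_window_um * 1000, full_nm * 0.9)
        } else {
          mode <- "none"
          dep <- NA_real_
        }
        pts <- tm + smooth_jitter(arcs, jitter_sigma_nm)
        if (!is.na(dep)) {
          keep <- arcs <= dep
          base <- pts[keep, , drop = FALSE]
          k <- nrow(base)
          tangent <- tm[min(k + 1, nrow(tm)), ] - tm[max(k - 1, 1), ]
          tangent <- tangent / sqrt(sum(tangent^2))
          # sustained perpendicular wrong turn, long enough to be
          # unambiguously beyond any lost threshold
          perp <- c(tangent[2], -tangent[1], 0)
          if (sum(abs(perp)) < 1e-9) perp <- c(1, 0, 0)
          perp <- perp / sqrt(sum(perp^2))
          ext_len <- 60000
          ext <- outer(seq(1000, ext_len, by = 1000), perp) +
            matrix(base[k, ], ext_len / 1000, 3, byrow = TRUE)
          pts <- rbind(base, ext)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          cell_id = truth[[i]]$name,
          tracer_id = sprintf("tracer_%d", tr),
          tree = list(polyline_tree(pts, truth[[i]]$name)),
          departure_nm = dep, failure_mode = mode)
      }
    }
    list(truth = truth, traces = dplyr::bind_rows(rows))
  })
}

#' Generate a split-half volume pair with known shared signal
#'
#' Both halves share a band-limited Gaussian random field (hard spherical
#' cutoff in Fourier space) plus independent white Gaussian noise, so the
#' expected FSC is `snr / (snr + 1)` below the cutoff and 0 above it,
#' where `snr` is the per-Fourier-coefficient signal-to-noise power
#' ratio.
#'
#' @param shape Cube side in voxels (default 64).
#' @param cutoff Band limit in cycles/voxel (<= 0.5).
#' @param snr Per-shell signal-to-noise power ratio below the cutoff;
#'   `Inf` gives noise-free halves.
#' @param voxel_size Voxel size, nm.
#' @param seed Integer seed.
#' @return A `volume_pair`.
#' @export
gen_fsc_pair <- function(shape = 64, cutoff = 0.25, snr = 1,
                         voxel_size = 50, seed = 1) {
  stopifnot(cutoff <= 0.5)
  with_seed(substream_seed(seed, "fsc_pair"), {
    d <- rep(shape, 3)
    white <- array(stats::rnorm(prod(d)), d)
    sh <- shell_index(d)
    mask <- array(sh <= round(cutoff * shape), d)
    signal <- Re(stats::fft(stats::fft(white) * mask, inverse = TRUE)) /
      prod(d)
    # in-band Fourier coefficients of `signal` carry the power of unit
    # white noise, so white noise of sd 1/sqrt(snr) gives the target
    # per-coefficient signal-to-noise power ratio in every in-band shell
    noise_sd <- if (is.infinite(snr)) 0 else 1 / sqrt(snr)
    a <- signal + array(stats::rnorm(prod(d), 0, noise_sd), d)
    b <- signal + array(stats::rnorm(prod(d), 0, noise_sd), d)
    volume_pair(a, b, voxel_size)
  })
}

#' Generate spiny dendrite annotations with depth-dependent apparatus
#'
#' Somata are placed on a known layer line with designed signed depths.
#' Spine attachment positions follow a homogeneous Poisson process of
#' rate `lambda` per micrometre along each branchlet; each spine carries
#' a spine apparatus with probability `p0 + beta * depth_um` of its
#' cell's soma. Defaults mirror the scale of the CA1 study cohort:
#' 7 cells, ~2 mm total shaft, rate 1.5/um, overall apparatus fraction
#' around 0.14.
#'
#' @param n_cells Number of cells.
#' @param branchlets_per_cell Branchlets per cell (split between trunk
#'   and apical_oblique).
#' @param branchlet_length_um Mean branchlet length (exponential-ish
#'   variation around it).
#' @param lambda Spine rate per micrometre.
#' @param p0 Baseline spine-apparatus probability at depth 0.
#' @param beta Change in SA probability per micrometre of depth.
#' @param depth_range_um Somata depths are drawn uniform in this range.
#' @param seed Integer seed.
#' @return List: `annotation` (a `spine_annotation`), `somata` tibble
#'   (`cell_id`, `x`, `y`, `depth_um` designed depth), `depth_model`
#'   (the designed layer line).
#' @export
gen_spiny_cells <- function(n_cells = 7, branchlets_per_cell = 10,
                            branchlet_length_um = 28, lambda = 1.5,
                            p0 = 0.14, beta = 0.002,
                            depth_range_um = c(-20, 20), seed = 1) {
  stopifnot(lambda > 0)
  pr <- p0 + beta * depth_range_um
  if (any(pr < 0 | pr > 1)) stop("SA probability out of [0,1] over range",
                                 call. = FALSE)
  with_seed(substream_seed(seed, "spiny_cells"), {
    # layer line: through origin along x, deep side +y
    depths <- stats::runif(n_cells, depth_range_um[1], depth_range_um[2])
    somata <- tibble::tibble(
      cell_id = sprintf("ca1_%02d", seq_len(n_cells)),
      x = stats::runif(n_cells, 0, 2e5),
      y = depths * 1000,
      depth_um = depths)
    br <- list(); sp <- list()
    for (i in seq_len(n_cells)) {
      p_sa <- p0 + beta * depths[i]
      for (b in seq_len(branchlets_per_cell)) {
        len_nm <- 1000 * branchlet_length_um *
          stats::runif(1, 0.5, 1.5)
        bid <- sprintf("%s_b%02d", somata$cell_id[i], b)
        dty <- if (b <= ceiling(branchlets_per_cell * 0.3)) "trunk" else
          "apical_oblique"
        br[[length(br) + 1]] <- tibble::tibble(
          cell_id = somata$cell_id[i], branchlet_id = bid,
          dendrite_type = dty, length_nm = len_nm)
        k <- stats::rpois(1, lambda * len_nm / 1000)
        if (k > 0) {
          sp[[length(sp) + 1]] <- tibble::tibble(
            cell_id = somata$cell_id[i], branchlet_id = bid,
            attachment_arc_nm = sort(stats::runif(k, 0, len_nm)),
            has_sa = stats::runif(k) < p_sa,
            n_heads = 1L)
        }
      }
    }
    dm <- structure(list(centroid = c(0, 0), direction = c(1, 0),
                         normal = c(0, 1)), class = "depth_model")
    list(annotation = spine_annotation(dplyr::bind_rows(br),
                                       dplyr::bind_rows(sp)),
         somata = somata, depth_model = dm)
  })
}

#' Generate landmarks under a known affine + smooth deformation
#'
#' Targets are `affine(source) + displacement`, with a smooth
#' low-frequency sinusoidal displacement field of given amplitude. A
#' held-out regular grid with exact ground-truth targets is returned for
#' measuring warp recovery.
#'
#' @param n_landmarks Number of landmark pairs.
#' @param A 3 x 3 affine matrix (default identity).
#' @param b Offset 3-vector, nm.
#' @param warp_amplitude_nm Amplitude of the nonlinear field (0 = pure
#'   affine).
#' @param extent_nm Cube side of the source domain.
#' @param n_grid Held-out grid resolution per axis.
#' @param seed Integer seed.
#' @return List: `landmarks` (`landmark_set` A -> B), `grid_source`,
#'   `grid_target` (matrices with exact truth).
#' @export
gen_landmark_deformation <- function(n_landmarks = 60, A = diag(3),
                                     b = c(0, 0, 0),
                                     warp_amplitude_nm = 0,
                                     extent_nm = 1e5, n_grid = 5,
                                     seed = 1) {
  stopifnot(n_landmarks >= 4)
  with_seed(substream_seed(seed, "landmarks"), {
    disp_field <- make_disp_field(warp_amplitude_nm, extent_nm)
    src <- matrix(stats::runif(3 * n_landmarks, 0, extent_nm),
                  ncol = 3)
    tgt <- tcrossprod(src, A) +
      matrix(b, n_landmarks, 3, byrow = TRUE) + disp_field(src)
    g <- seq(0.15, 0.85, length.out = n_grid) * extent_nm
    grid <- as.matrix(expand.grid(x = g, y = g, z = g))
    gt <- tcrossprod(grid, A) + matrix(b, nrow(grid), 3, byrow = TRUE) +
      disp_field(grid)
    list(landmarks = landmark_set(src, tgt, "A", "B"),
         grid_source = grid, grid_target = gt)
  })
}

make_disp_field <- function(amp, extent) {
  if (amp == 0) return(function(p) 0)
  # gentle mesoscale distortion: at most half a period across the domain,
  # as in embedding/shrinkage warps between imaging modalities
  ph <- stats::runif(9, 0, 2 * pi)
  freq <- stats::runif(9, 0.2, 0.5) / extent
  function(p) {
    out <- matrix(0, nrow(p), 3)
    idx <- 1
    for (a in 1:3) {
      for (ax in 1:3) {
        out[, a] <- out[, a] +
          sin(2 * pi * freq[idx] * p[, ax] + ph[idx])
        idx <- idx + 1
      }
    }
    out * amp / 3
  }
}

#' Generate 2D test phantoms
#'
#' Deterministic analytic phantoms with known support for tomography
#' round-trip tests: a centred disc, a simple head-like nest of ellipses,
#' or seeded soft blobs.
#'
#' @param kind `"disc"`, `"shepp_logan_like"` or `"soft_tissue_blobs"`.
#' @param size Image side in pixels (>= 32).
#' @param amplitude Value inside the disc / base ellipse.
#' @param radius_frac Disc radius as a fraction of the image side.
#' @param seed Seed (used by `soft_tissue_blobs` only).
#' @return List: `image` (size x size matrix), `support` (logical mask).
#' @export
gen_phantom <- function(kind = c("disc", "shepp_logan_like",
                                 "soft_tissue_blobs"),
                        size = 128, amplitude = 1, radius_frac = 0.35,
                        seed = 1) {
  kind <- match.arg(kind)
  stopifnot(size >= 32)
  ctr <- (size + 1) / 2
  g <- seq_len(size) - ctr
  xg <- matrix(g, size, size)
  yg <- matrix(g, size, size, byrow = TRUE)
  half <- size / 2
  if (kind == "disc") {
    mask <- xg^2 + yg^2 <= (radius_frac * size)^2
    img <- amplitude * mask
    return(list(image = img, support = mask))
  }
  if (kind == "shepp_logan_like") {
    inside <- function(cx, cy, a, b_, phi) {
      xr <- (xg - cx) * cos(phi) + (yg - cy) * sin(phi)
      yr <- -(xg - cx) * sin(phi) + (yg - cy) * cos(phi)
      (xr / a)^2 + (yr / b_)^2 <= 1
    }
    img <- amplitude * inside(0, 0, 0.42 * size, 0.31 * size, 0)
    img <- img - 0.6 * amplitude * inside(0, 0, 0.37 * size,
                                          0.27 * size, 0)
    img <- img + 0.4 * amplitude * inside(0.12 * size, 0.05 * size,
                                          0.08 * size, 0.05 * size, 0.5)
    img <- img + 0.4 * amplitude * inside(-0.12 * size, -0.05 * size,
                                          0.06 * size, 0.09 * size, -0.4)
    return(list(image = img,
                support = inside(0, 0, 0.42 * size, 0.31 * size, 0)))
  }
  with_seed(substream_seed(seed, "phantom_blobs"), {
    img <- matrix(0, size, size)
    for (i in 1:6) {
      cx <- stats::runif(1, -0.3, 0.3) * size
      cy <- stats::runif(1, -0.3, 0.3) * size
      sg <- stats::runif(1, 0.04, 0.1) * size
      w <- stats::runif(1, 0.3, 1) * amplitude
      img <- img + w * exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * sg^2))
    }
    list(image = img, support = img > 0.05 * amplitude)
  })
}
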