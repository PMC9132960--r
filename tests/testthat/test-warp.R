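affine_pairs <- function(A, b, n = 12, seed = 5, sigma = 0) {
  set.seed(seed)
  src <- matrix(stats::runif(3 * n, 0, 1e5), ncol = 3)
  tgt <- tcrossprod(src, A) + matrix(b, n, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * n, 0, sigma), ncol = 3)
  landmark_set(src, tgt, "A", "B")
}

test_that("scale-offset fitting recovers exact and noisy parameters", {
  lm0 <- affine_pairs(diag(c(2, 2, 2)), c(10, 0, 0))
  tr <- fit_scale_offset(lm0)
  expect_equal(tr$params$scale, c(2, 2, 2), tolerance = 1e-9)
  expect_equal(tr$params$offset, c(10, 0, 0), tolerance = 1e-6)

  idt <- fit_scale_offset(affine_pairs(diag(3), c(0, 0, 0)))
  expect_equal(idt$params$scale, c(1, 1, 1), tolerance = 1e-9)

  # noisy fit equals the per-axis normal-equations closed form
  lmn <- affine_pairs(diag(c(1.5, 0.8, 1.1)), c(5, -3, 2), n = 50,
                      seed = 9, sigma = 5)
  tr <- fit_scale_offset(lmn)
  for (a in 1:3) {
    X <- cbind(lmn$source[, a], 1)
    beta <- solve(t(X) %*% X, t(X) %*% lmn$target[, a])
    expect_equal(tr$params$scale[a], beta[1], tolerance = 1e-9)
    expect_equal(tr$params$offset[a], beta[2], tolerance = 1e-6)
  }

  degenerate <- landmark_set(cbind(rep(1, 5), 1:5, 1:5),
                             cbind(rep(2, 5), 1:5, 1:5), "A", "B")
  expect_error(fit_scale_offset(degenerate), "degenerate")
})

test_that("affine fitting recovers rotation+shear and flags rank defects", {
  A <- matrix(c(0.9, 0.2, 0, -0.2, 0.9, 0.1, 0.05, 0, 1.1), 3, 3)
  lm0 <- affine_pairs(A, c(100, -50, 20))
  tr <- fit_affine(lm0)
  expect_lt(max(abs(tr$params$A - A)), 1e-9)
  expect_lt(max(abs(tr$params$b - c(100, -50, 20))), 1e-6)

  coplanar <- landmark_set(cbind(stats::runif(6), stats::runif(6), 0),
                           matrix(stats::runif(18), ncol = 3), "A", "B")
  expect_error(fit_affine(coplanar), "rank|coplanar")

  # least-squares residual equals the normal-equations oracle
  lmn <- affine_pairs(A, c(1, 2, 3), n = 40, seed = 3, sigma = 10)
  tr <- fit_affine(lmn)
  X <- cbind(lmn$source, 1)
  B_or <- solve(t(X) %*% X, t(X) %*% lmn$target)
  fitted_or <- X %*% B_or
  res_fit <- apply_transform(tr, lmn$source) - lmn$target
  expect_equal(sum(res_fit^2), sum((fitted_or - lmn$target)^2),
               tolerance = 1e-9)
})

test_that("TPS interpolates landmarks and degrades to affine", {
  A <- matrix(c(1.1, 0.1, 0, 0, 0.9, 0.05, 0.02, 0, 1.05), 3, 3)
  lm0 <- affine_pairs(A, c(5, 6, 7), n = 10, seed = 2)
  tps <- fit_tps(lm0)
  res <- apply_transform(tps, lm0$source) - lm0$target
  expect_lt(max(abs(res)), 1)                   # < 1 nm interpolation

  # affine-consistent landmarks: agrees with fit_affine on a test grid
  aff <- fit_affine(lm0)
  set.seed(1)
  grid <- matrix(stats::runif(60, 1e4, 9e4), ncol = 3)
  expect_lt(max(abs(apply_transform(tps, grid) -
                    apply_transform(aff, grid))), 1)
})

test_that("TPS recovers a smooth deformation on held-out points", {
  amp <- 2000
  gl <- gen_landmark_deformation(n_landmarks = 60, A = diag(3) * 1.05,
                                 b = c(100, 200, 300),
                                 warp_amplitude_nm = amp, seed = 4)
  tps <- fit_tps(gl$landmarks)
  pred <- apply_transform(tps, gl$grid_source)
  rms <- sqrt(mean(rowSums((pred - gl$grid_target)^2)))
  expect_lt(rms, 0.05 * amp)
})

test_that("transforms apply elementwise and invert", {
  idt <- identity_transform("A")
  p <- matrix(stats::runif(30, 0, 100), ncol = 3)
  expect_equal(apply_transform(idt, p), p, ignore_attr = TRUE)

  A <- matrix(c(0.9, 0.2, 0, -0.2, 0.9, 0.1, 0.05, 0, 1.1), 3, 3)
  aff <- fit_affine(affine_pairs(A, c(1, 2, 3)))
  rt <- apply_transform(invert_transform(aff), apply_transform(aff, p))
  expect_lt(max(abs(rt - p)), 1e-9)

  # TPS approximate inverse: round trip well under 0.5% of the bbox diag
  gl <- gen_landmark_deformation(n_landmarks = 60,
                                 warp_amplitude_nm = 2000, seed = 4)
  tps <- fit_tps(gl$landmarks)
  inner <- gl$grid_source
  rt2 <- apply_transform(invert_transform(tps),
                         apply_transform(tps, inner))
  diag_len <- sqrt(sum((apply(inner, 2, max) - apply(inner, 2, min))^2))
  expect_lt(max(sqrt(rowSums((rt2 - inner)^2))), 0.005 * diag_len)
})

test_that("graph composition matches direct fits and handles errors", {
  set.seed(9)
  src <- matrix(stats::runif(45, 0, 1e5), ncol = 3)
  A1 <- diag(3) * 1.2; b1 <- c(10, 20, 30)
  A2 <- matrix(c(0.9, 0.1, 0, -0.1, 0.9, 0, 0, 0, 1.1), 3, 3)
  b2 <- c(-5, 0, 5)
  mid <- tcrossprod(src, A1) + matrix(b1, 15, 3, byrow = TRUE)
  dst <- tcrossprod(mid, A2) + matrix(b2, 15, 3, byrow = TRUE)
  g <- dataset_graph(list(fit_affine(landmark_set(src, mid, "A", "B")),
                          fit_affine(landmark_set(mid, dst, "B", "C"))))

  comp <- compose_path(g, "A", "C")
  direct <- fit_affine(landmark_set(src, dst, "A", "C"))
  grid <- matrix(stats::runif(300, 0, 1e5), ncol = 3)
  expect_lt(max(abs(apply_transform(comp, grid) -
                    apply_transform(direct, grid))), 1e-6)

  expect_equal(compose_path(g, "A", "A")$kind, "identity")
  expect_error(compose_path(g, "A", "Z"), "not in graph")
  g2 <- dataset_graph(list(fit_affine(landmark_set(src, mid, "A", "B")),
                           fit_affine(landmark_set(mid, dst, "X", "Y"))))
  expect_error(compose_path(g2, "A", "Y"), "no path")

  # associativity over the auto-registered inverse chain
  back <- compose_path(g, "C", "A")
  rt <- apply_transform(back, apply_transform(comp, grid))
  expect_lt(max(abs(rt - grid)), 1e-6)
})

test_that("skeleton warping preserves topology and maps positions", {
  tr <- random_binary_tree(3, seed = 11)
  # rigid translation edge fitted from consistent landmarks
  set.seed(12)
  src <- matrix(stats::runif(15, 0, 1e4), ncol = 3)
  tshift <- c(500, -200, 100)
  lmt <- landmark_set(src, src + matrix(tshift, 5, 3, byrow = TRUE),
                      "A", "B")
  g <- dataset_graph(list(fit_affine(lmt)))
  w <- warp_skeleton(g, tr, "A", "B")
  expect_identical(w$nodes$id, tr$nodes$id)
  expect_identical(w$nodes$parent_id, tr$nodes$parent_id)
  expect_equal(w$nodes$x, tr$nodes$x + tshift[1], tolerance = 1e-6)
  expect_equal(w$nodes$y, tr$nodes$y + tshift[2], tolerance = 1e-6)

  # identity path returns the tree unchanged
  w0 <- warp_skeleton(g, tr, "A", "A")
  expect_equal(w0$nodes, tr$nodes, tolerance = 1e-12)

  # warp + unwarp round trip
  back <- warp_skeleton(g, w, "B", "A")
  expect_equal(back$nodes$x, tr$nodes$x, tolerance = 1e-6)
})

test_that("landmark JSON round trip is lossless", {
  lm0 <- affine_pairs(diag(3), c(1, 2, 3), n = 7, seed = 13, sigma = 50)
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm0, path)
  back <- read_landmarks(path)
  expect_equal(back$source, lm0$source)
  expect_equal(back$target, lm0$target)
  expect_identical(back$source_space, "A")
  expect_identical(back$target_space, "B")
})
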