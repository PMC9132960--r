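test_that("annotation construction validates attachment positions", {
  ann <- toy_annotation()
  expect_s3_class(ann, "spine_annotation")
  br <- ann$branchlets
  sp <- ann$spines
  sp$attachment_arc_nm[1] <- 40000      # beyond the 30 um branchlet
  expect_error(spine_annotation(br, sp), "outside")
})

test_that("density table pools counts per cell and dendrite type", {
  ann <- toy_annotation()               # 6+4 spines, 30+20 um shaft
  dt <- density_table(ann)
  expect_equal(nrow(dt), 1)
  expect_equal(dt$n_spines, 10)
  expect_equal(dt$spine_density_per_um, 10 / 50)
  expect_equal(dt$n_sa, 5)
  expect_equal(dt$sa_density_per_um, 5 / 50)

  # 10 spines, 2 with apparatus, 50 um shaft: 0.2 and 0.04 per um
  sp <- ann$spines
  sp$has_sa <- rep(c(TRUE, FALSE), c(2, 8))
  dt2 <- density_table(spine_annotation(ann$branchlets, sp))
  expect_equal(dt2$spine_density_per_um, 0.2)
  expect_equal(dt2$sa_density_per_um, 0.04)

  # a branched spine is one row, so it counts once however many heads
  sp$n_heads[1] <- 2L
  dt3 <- density_table(spine_annotation(ann$branchlets, sp))
  expect_equal(dt3$n_spines, 10)
  expect_equal(dt3$n_sa, 2)

  bad <- ann$branchlets; bad$length_nm <- 0    # whole cell with no shaft
  sp0 <- ann$spines[0, ]
  expect_error(density_table(spine_annotation(bad, sp0)), "zero shaft")
})

test_that("inter-spine gaps telescope within branchlets", {
  br <- tibble::tibble(cell_id = "c", branchlet_id = "b",
                       dendrite_type = "trunk", length_nm = 10000)
  sp <- tibble::tibble(cell_id = "c", branchlet_id = "b",
                       attachment_arc_nm = c(0, 2000, 5000),
                       has_sa = FALSE, n_heads = 1L)
  g <- inter_spine_distances(spine_annotation(br, sp))
  expect_equal(g$gap_um, c(2, 3))

  # single spine contributes nothing
  g1 <- inter_spine_distances(spine_annotation(br, sp[1, ]))
  expect_equal(nrow(g1), 0)

  # n spines -> n-1 gaps summing to the arc span; never across branchlets
  ann <- toy_annotation()
  g2 <- inter_spine_distances(ann)
  expect_equal(nrow(g2), (6 - 1) + (4 - 1))
  span_b1 <- diff(range(
    ann$spines$attachment_arc_nm[ann$spines$branchlet_id == "b1"])) / 1000
  expect_equal(sum(g2$gap_um[g2$branchlet_id == "b1"]), span_b1)

  # SA-only gaps use the flagged subset
  gsa <- inter_spine_distances(ann, sa_only = TRUE)
  expect_equal(nrow(gsa), sum(ann$spines$has_sa) - 2)  # 3+2 spines -> 2+1
})

test_that("exponential MLE is the reciprocal mean gap", {
  expect_equal(fit_exponential(c(1, 2, 3)), 1 / 2)
  expect_equal(fit_exponential(rep(4, 10)), 0.25)
  expect_error(fit_exponential(c(1, -1)), "positive")
  set.seed(6)
  x <- stats::rexp(1e4, 0.3)
  expect_lt(abs(fit_exponential(x) - 0.3), 3 * 0.3 / sqrt(1e4))
})

test_that("KS statistic matches a 3-point hand computation and ks.test", {
  # gaps at the quantiles i/(n+1) of Exp(rate = 2): F values 1/4, 2/4, 3/4,
  # so D = max_i max(i/3 - i/4, i/4 - (i-1)/3) = 1/4 by hand
  rate <- 2
  gaps <- stats::qexp((1:3) / 4, rate)
  expect_equal(corrbridge:::ks_D_exp(gaps, rate), 0.25)
  # our D and naive p equal ks.test's on random data
  set.seed(9)
  x <- stats::rexp(50, 1.3)
  ours <- ks_test_exponential(x, rate = 1.3, calibration = "naive")
  ref <- suppressWarnings(stats::ks.test(x, "pexp", rate = 1.3))
  expect_equal(ours$ks_D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$ks_p, ref$p.value, tolerance = 1e-12)
})

test_that("bootstrap KS rejects regular spacing and keeps the null", {
  set.seed(10)
  reg <- rep(0.5, 200) + stats::runif(200, -0.05, 0.05)
  r <- ks_test_exponential(reg, B = 999)
  expect_lt(r$ks_p, 0.01)

  ok <- ks_test_exponential(stats::rexp(200, 1.5), B = 199)
  expect_gt(ok$ks_p, 0.01)
  expect_error(ks_test_exponential(c(1, 2, 3)), "at least 5")
})

test_that("max gap per branchlet is bounded by branchlet length", {
  ann <- toy_annotation()
  mg <- max_gap_vs_length(ann)
  expect_equal(nrow(mg), 2)
  expect_true(all(mg$max_gap_um <= mg$length_um))

  g <- gen_spiny_cells(n_cells = 3, seed = 12)
  mg2 <- max_gap_vs_length(g$annotation)
  expect_true(all(mg2$max_gap_um <= mg2$length_um))
})

test_that("soma layer line and signed depth behave geometrically", {
  # collinear points give the exact line; depth is perpendicular distance
  pts <- cbind(seq(0, 10000, 1000), 0)
  m <- fit_soma_layer_line(pts, deep_hint = c(0, 1))
  expect_equal(abs(m$direction), c(1, 0), tolerance = 1e-12)
  expect_equal(soma_depth(c(5000, 3000), m), 3000)
  expect_equal(soma_depth(c(2000, 0), m), 0)
  # hint flip flips the sign
  m2 <- fit_soma_layer_line(pts, deep_hint = c(0, -1))
  expect_equal(soma_depth(c(5000, 3000), m2), -3000)

  # rotated collinear set recovered exactly
  th <- 0.4
  rot <- cbind(cos(th) * pts[, 1], sin(th) * pts[, 1])
  m3 <- fit_soma_layer_line(rot, deep_hint = c(-sin(th), cos(th)))
  expect_lt(max(abs(soma_depth(rot, m3))), 1e-6)

  # TLS direction equals the leading eigenvector of the covariance
  set.seed(15)
  xy <- cbind(stats::runif(100, 0, 1e5), stats::rnorm(100, 0, 2000))
  m4 <- fit_soma_layer_line(xy)
  ev <- eigen(stats::cov(xy))$vectors[, 1]
  expect_lt(abs(abs(sum(m4$direction * ev)) - 1), 1e-9)

  expect_error(fit_soma_layer_line(matrix(1, 5, 2)), "identical")
})

test_that("depth regression matches the normal-equations hand oracle", {
  depths <- c(-15, -9, -4, 0, 5, 10, 16)
  dens <- c(0.10, 0.12, 0.11, 0.15, 0.14, 0.18, 0.17)
  rec <- tibble::tibble(cell_id = paste0("c", 1:7),
                        dendrite_type = "trunk",
                        n_spines = 100, n_sa = 10, shaft_length_nm = 1e6,
                        spine_density_per_um = 0.5,
                        sa_density_per_um = dens,
                        soma_depth_nm = depths * 1000)
  fit <- regress_density_vs_depth(rec, "trunk")
  X <- cbind(1, depths)
  beta <- solve(t(X) %*% X, t(X) %*% dens)
  td <- tidy(fit)
  expect_equal(td$estimate, as.numeric(beta), tolerance = 1e-12)
  resid <- dens - X %*% beta
  s2 <- sum(resid^2) / 5
  se_slope <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  tstat <- beta[2] / se_slope
  expect_equal(td$p.value[2], 2 * stats::pt(-abs(tstat), df = 5),
               tolerance = 1e-12)

  # confidence band is symmetric about the fit
  band <- depth_regression_band(fit)
  expect_equal(band$fit - band$lwr, band$upr - band$fit, tolerance = 1e-9)

  # degenerate cases
  rec0 <- rec; rec0$soma_depth_nm <- 0
  expect_error(regress_density_vs_depth(rec0, "trunk"), "depth variance")
  expect_error(regress_density_vs_depth(rec[1:2, ], "trunk"), ">= 3")

  # near-perfectly linear data: exact slope, p at the precision floor
  recl <- rec
  recl$sa_density_per_um <- 0.1 + 0.002 * depths +
    1e-9 * c(1, -1, 1, -1, 1, -1, 1)
  tdl <- tidy(regress_density_vs_depth(recl, "trunk"))
  expect_equal(tdl$estimate[2], 0.002, tolerance = 1e-6)
  expect_lt(tdl$p.value[2], 1e-12)
})

test_that("spine JSON round trip preserves the annotation", {
  ann <- toy_annotation()
  path <- withr::local_tempfile(fileext = ".json")
  write_spine_json(ann, path)
  back <- read_spine_json(path)
  expect_equal(back$branchlets, ann$branchlets)
  expect_equal(back$spines, ann$spines)
})
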