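test_that("boundary tracing of a disc recovers its area and rejects bad masks", {
  img <- make_disc_mask(50)
  tr <- trace_outline(img)
  area <- abs(sum(tr$x * c(tr$y[-1], tr$y[1]) - c(tr$x[-1], tr$x[1]) * tr$y) / 2)
  expect_lt(abs(area - pi * 50^2) / (pi * 50^2), 0.02)
  expect_gte(nrow(tr), 32)
  # counterclockwise with y up
  expect_gt(sum(tr$x * c(tr$y[-1], tr$y[1]) - c(tr$x[-1], tr$x[1]) * tr$y) / 2, 0)

  # two components are rejected with the component count in the message
  img2 <- cbind(img, matrix(0L, nrow(img), 5), img)
  expect_error(trace_outline(img2), "found 2", class = "introshell_parameter_error")
  expect_error(trace_outline(matrix(0L, 10, 10)), "found 0",
               class = "introshell_parameter_error")

  # a tiny blob has too short a boundary
  img3 <- matrix(0L, 5, 5); img3[2:4, 2:4] <- 1L
  expect_error(trace_outline(img3), class = "introshell_parameter_error")
})

test_that("traced contours agree with an independent image-analysis library", {
  skip_if_not_installed("EBImage")
  img <- make_disc_mask(30)
  tr <- trace_outline(img)
  # EBImage: transpose because it stores x as first dimension
  oc <- EBImage::ocontour(EBImage::bwlabel(t(img)))[[1]]
  expect_equal(nrow(tr), nrow(oc), tolerance = 0.05)
  # same pixel set up to the 0/1-based offset
  mine <- paste(tr$x, tr$y)
  theirs <- paste(oc[, 1], oc[, 2])
  expect_gt(mean(mine %in% theirs), 0.95)
})

test_that("preprocessing centres, resamples to uniform arc length, and orients", {
  o <- simulate_outline(1.6, 200, noise_sd = 0.03, seed = 4)
  pre <- preprocess_outline(o, 300)
  expect_equal(nrow(pre), 300)
  expect_lt(abs(mean(pre$x)), 1e-9)
  expect_lt(abs(mean(pre$y)), 1e-9)
  # perimeter preserved within 1% at 300 points
  per0 <- sum(sqrt(diff(c(o$x, o$x[1]))^2 + diff(c(o$y, o$y[1]))^2))
  per1 <- sum(sqrt(diff(c(pre$x, pre$x[1]))^2 + diff(c(pre$y, pre$y[1]))^2))
  expect_lt(abs(per1 - per0) / per0, 0.01)
  # uniform spacing
  seg <- sqrt(diff(pre$x)^2 + diff(pre$y)^2)
  expect_lt(stats::sd(seg) / mean(seg), 0.01)
  # clockwise input comes out counterclockwise
  ocw <- o[rev(seq_len(nrow(o))), ]
  pre2 <- preprocess_outline(ocw, 300)
  a <- sum(pre2$x * c(pre2$y[-1], pre2$y[1]) - c(pre2$x[-1], pre2$x[1]) * pre2$y) / 2
  expect_gt(a, 0)
  expect_error(preprocess_outline(tibble::tibble(x = rep(1, 40), y = rep(2, 40))),
               class = "introshell_parameter_error")
})

test_that("an exact ellipse is exactly harmonic 1 under uniform parametrization", {
  e <- efa_decompose(make_ellipse(2, 1, 360), 20, parametrization = "uniform")
  hp <- harmonic_power(e)
  expect_lt(1 - hp$share[1], 1e-10)
  expect_equal(abs(e$an[1]), 2, tolerance = 1e-3)
  expect_equal(abs(e$dn[1]), 1, tolerance = 1e-3)
  # circle: harmonic-1 x and y amplitudes both equal the radius
  ec <- efa_decompose(make_ellipse(3, 3, 360), 5, parametrization = "uniform")
  expect_equal(ec$an[1]^2 + ec$bn[1]^2, 9, tolerance = 1e-3)
  expect_equal(ec$cn[1]^2 + ec$dn[1]^2, 9, tolerance = 1e-3)
  expect_error(efa_decompose(make_ellipse(2, 1, 100), 60),
               class = "introshell_parameter_error")
})

test_that("a square outline has odd-harmonic power matching dense numerical Fourier", {
  # square traversed at uniform speed: piecewise-linear x(t), y(t)
  side <- seq(0, 1, length.out = 101)[-101]
  sq <- tibble::tibble(
    x = c(side, rep(1, 100), rev(side), rep(0, 100)),
    y = c(rep(0, 100), side, rep(1, 100), rev(side)))
  e <- efa_decompose(sq, 8)
  hp <- harmonic_power(e)
  even <- hp$power[c(2, 4, 6, 8)]
  # zero analytically; the one-sample phase offset of the discrete square
  # leaves O((1/K)^2) leakage
  expect_lt(sum(even) / sum(hp$power), 1e-4)
  # dense numerical Fourier oracle for the power(3)/power(1) ratio
  K <- 20000
  t <- (seq_len(K) - 1) / K
  xt <- stats::approx(seq(0, 1, length.out = 401),
                      c(sq$x, sq$x[1]), t, ties = "ordered")$y
  yt <- stats::approx(seq(0, 1, length.out = 401),
                      c(sq$y, sq$y[1]), t, ties = "ordered")$y
  pw <- function(n) {
    (mean(xt * cos(2 * pi * n * t)) * 2)^2 + (mean(xt * sin(2 * pi * n * t)) * 2)^2 +
      (mean(yt * cos(2 * pi * n * t)) * 2)^2 + (mean(yt * sin(2 * pi * n * t)) * 2)^2
  }
  expect_equal(hp$power[3] / hp$power[1], pw(3) / pw(1), tolerance = 0.01)
})

test_that("normalized coefficients are invariant to rotation, scale and start point", {
  o <- preprocess_outline(simulate_outline(1.7, 300, noise_sd = 0.05, seed = 3), 300)
  ref <- efa_normalize(efa_decompose(o, 12))
  expect_gt(ref$an[1], 0)
  expect_equal(ref$bn[1], 0, tolerance = 1e-12)
  expect_equal(ref$cn[1], 0, tolerance = 1e-12)

  # rotation by 37 degrees
  o_rot <- rotate_outline(o, 37 * pi / 180)
  expect_lt(max(abs(efa_vector(efa_normalize(efa_decompose(o_rot, 12))) -
                    efa_vector(ref))), 1e-6)
  # isotropic scaling by 2.5 (plus translation, absorbed by the offsets)
  o_sc <- tibble::tibble(x = 2.5 * o$x + 3, y = 2.5 * o$y - 1)
  expect_lt(max(abs(efa_vector(efa_normalize(efa_decompose(o_sc, 12))) -
                    efa_vector(ref))), 1e-6)
  # starting point shifted by 40% of the perimeter
  o_sh <- shift_outline(o, 120)
  expect_lt(max(abs(efa_vector(efa_normalize(efa_decompose(o_sh, 12))) -
                    efa_vector(ref))), 1e-6)
  # all three at once
  o_all <- shift_outline(tibble::tibble(x = 0.7 * o_rot$x + 2,
                                        y = 0.7 * o_rot$y + 5), 77)
  expect_lt(max(abs(efa_vector(efa_normalize(efa_decompose(o_all, 12))) -
                    efa_vector(ref))), 1e-6)

  degenerate <- structure(list(an = 0, bn = 0, cn = 0, dn = 0, A0 = 0, C0 = 0,
                               n_harmonics = 1, normalized = FALSE, scale = NA),
                          class = "efa")
  expect_error(efa_normalize(degenerate), class = "introshell_parameter_error")
})

test_that("harmonic truncation picks the smallest count exceeding the threshold", {
  # constructed spectrum whose cumulative share crosses 0.95 at harmonic 7
  pw <- c(0.40, 0.15, 0.12, 0.10, 0.08, 0.07, 0.05, 0.02, 0.01)
  e <- structure(list(an = sqrt(2 * pw), bn = rep(0, 9), cn = rep(0, 9),
                      dn = rep(0, 9), A0 = 0, C0 = 0, n_harmonics = 9,
                      normalized = TRUE, scale = 1),
                 class = "efa")
  expect_equal(choose_harmonics(e, 0.95), 7)
  expect_equal(choose_harmonics(harmonic_power(e), 0.95), 7)
  # a pure ellipse needs one harmonic at any threshold below 1
  ell <- efa_decompose(make_ellipse(2, 1, 200), 10, parametrization = "uniform")
  expect_equal(choose_harmonics(ell, 0.999), 1)
  expect_error(choose_harmonics(e, 1.0), class = "introshell_parameter_error")
  expect_error(choose_harmonics(e, 0), class = "introshell_parameter_error")
})

test_that("round-trip error decreases with harmonic count and vanishes for ellipses", {
  o <- preprocess_outline(simulate_outline(1.8, 300, noise_sd = 0.04, seed = 8), 300)
  errs <- vapply(c(3, 7, 12, 20), function(n) efa_roundtrip_error(o, n), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[4], 0.005)

  # closed-form first-harmonic coefficients of the ellipse reproduce it
  # exactly; decomposing its samples recovers them to discretization accuracy
  ell <- make_ellipse(2, 1, 240)
  e1 <- structure(list(an = 2, bn = 0, cn = 0, dn = 1, A0 = 0, C0 = 0,
                       n_harmonics = 1, normalized = FALSE, scale = NA),
                  class = "efa")
  rec <- efa_reconstruct(e1, 240)
  expect_lt(sqrt(mean((rec$x - ell$x)^2 + (rec$y - ell$y)^2)), 1e-9)
  est <- efa_decompose(ell, 1, parametrization = "uniform")
  expect_equal(c(est$an, est$bn, est$cn, est$dn), c(2, 0, 0, 1),
               tolerance = 1e-3)

  # appending zero high harmonics leaves the reconstruction unchanged
  e2 <- e1
  e2$an <- c(e2$an, 0); e2$bn <- c(e2$bn, 0)
  e2$cn <- c(e2$cn, 0); e2$dn <- c(e2$dn, 0)
  e2$n_harmonics <- 2
  expect_equal(efa_reconstruct(e2, 240), rec, tolerance = 1e-12)
})

test_that("shape PCA separates elongation classes and respects PCA identities", {
  mk <- function(el, n, seed0) purrr::map(seq_len(n), function(i)
    efa_normalize(efa_decompose(preprocess_outline(
      simulate_outline(el, 200, noise_sd = 0.01, seed = seed0 + i), 200), 10)))
  e_round <- mk(1.2, 15, 100)
  e_slim <- mk(2.0, 15, 200)
  tab <- efa_coef_table(c(e_round, e_slim))
  pca <- shape_pca(tab)
  grp <- rep(c("round", "slim"), each = 15)
  s1 <- pca$scores$PC1
  # zero overlap between the clusters on PC1
  expect_true(max(s1[grp == "round"]) < min(s1[grp == "slim"]) ||
                min(s1[grp == "round"]) > max(s1[grp == "slim"]))
  # variance shares: in [0,1], non-increasing, summing to 1
  expect_true(all(pca$variance_share >= 0 & pca$variance_share <= 1))
  expect_true(all(diff(pca$variance_share) <= 1e-12))
  expect_equal(sum(pca$variance_share), 1, tolerance = 1e-12)
  # duplicated individuals get identical scores
  tab2 <- dplyr::bind_rows(tab, tab[1, ])
  pca2 <- shape_pca(tab2)
  expect_equal(unlist(pca2$scores[1, -1]), unlist(pca2$scores[31, -1]),
               tolerance = 1e-10)
  expect_error(shape_pca(tab[1:2, ]), class = "introshell_parameter_error")
})

test_that("Wilks lambda is 1 under identical means and matches ANOVA for 1 response", {
  set.seed(9)
  y <- matrix(stats::rnorm(90), 30, 3)
  # identical group means by construction: mirrored copies
  y2 <- rbind(y, y)
  g <- rep(c("a", "b"), each = 30)
  res <- manova_wilks(y2, g)
  expect_equal(res$wilks_lambda, 1, tolerance = 1e-10)
  expect_equal(res$approx_f, 0, tolerance = 1e-8)

  # 2-group, 1-response: approx F equals the one-way ANOVA F exactly
  y1 <- matrix(stats::rnorm(40, mean = rep(c(0, 1), each = 20)), ncol = 1)
  g1 <- rep(c("a", "b"), each = 20)
  res1 <- manova_wilks(y1, g1)
  aov_f <- summary(stats::aov(y1[, 1] ~ g1))[[1]]$`F value`[1]
  expect_equal(res1$approx_f, aov_f, tolerance = 1e-10)

  # continuous covariate mode
  xc <- stats::rnorm(30)
  resc <- manova_wilks(y + cbind(xc, 0 * xc, 0 * xc), xc)
  expect_lt(resc$wilks_lambda, 1)
  expect_equal(resc$df1, 3)

  expect_error(manova_wilks(y, rep("a", 30)), class = "introshell_parameter_error")
  expect_error(manova_wilks(y, c(1, 2)), class = "introshell_parameter_error")
})

test_that("pairwise MANOVA iterates group pairs with optional Bonferroni column", {
  set.seed(4)
  y <- matrix(stats::rnorm(120), 40, 3)
  y[31:40, 1] <- y[31:40, 1] + 4
  g <- rep(c("a", "b", "c", "d"), each = 10)
  pw <- pairwise_manova(y, g)
  expect_equal(nrow(pw), 6)
  expect_true(all(pw$p_bonferroni >= pw$p_value))
  # the shifted group differs from every other
  dpairs <- pw[pw$group1 == "d" | pw$group2 == "d", ]
  expect_true(all(dpairs$p_value < 0.01))
})

test_that("mean shapes average coefficients and track the elongation gradient", {
  norm_efa <- function(el, seed) {
    efa_normalize(efa_decompose(preprocess_outline(
      simulate_outline(el, 200, noise_sd = 0.02, seed = seed), 200), 10))
  }
  # single-member group reproduces that member's reconstruction
  e <- norm_efa(1.5, 2)
  tab <- efa_coef_table(list(e), ids = "solo")
  ms <- mean_shape(tab, "g1", n_points = 120)
  expect_equal(ms[, c("x", "y")], efa_reconstruct(e, 120), tolerance = 1e-12)

  # mirror-symmetric deviations around a base shape cancel in the mean
  base <- as.vector(rbind(e$an, e$bn, e$cn, e$dn))  # interleaved table order
  dev <- stats::rnorm(length(base), 0, 0.01)
  m2 <- rbind(base + dev, base - dev)
  colnames(m2) <- setdiff(names(tab), "individual_id")
  tab2 <- tibble::as_tibble(m2)
  ms2 <- mean_shape(tab2, c("m", "m"), n_points = 120)
  expect_equal(ms2[, c("x", "y")], efa_reconstruct(e, 120), tolerance = 1e-9)

  # depth gradient: simulated elongation decreasing with depth shows up as a
  # monotone decrease of the mean-shape aspect ratio
  els <- c(2.0, 1.8, 1.6, 1.4)  # 1 m .. 7 m
  groups <- rep(c("1", "3", "5", "7"), each = 8)
  efas <- purrr::flatten(purrr::map(seq_along(els), function(d)
    purrr::map(1:8, function(i) norm_efa(els[d], seed = d * 50 + i))))
  tab3 <- efa_coef_table(efas)
  ms3 <- mean_shape(tab3, groups)
  ratios <- purrr::map_dbl(c("1", "3", "5", "7"), function(gl) {
    oo <- ms3[ms3$group == gl, ]
    outline_elongation(oo)
  })
  expect_true(all(diff(ratios) < 0))
  expect_error(mean_shape(tab3, groups[-1]), class = "introshell_parameter_error")
})
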