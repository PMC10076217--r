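test_that("retina alignment is rigid, zeroes the optic nerve, and mirrors left retinas", {
  set.seed(51)
  cells <- data.frame(x_um = rnorm(30, 100, 200), y_um = rnorm(30, -50, 200))
  on_xy <- c(120, -30)
  al <- align_retina(cells, optic_nerve_xy = on_xy, ventral_direction = 0.8,
                     side = "right")
  # optic nerve maps to the origin
  on_row <- align_retina(data.frame(x_um = on_xy[1], y_um = on_xy[2]),
                         optic_nerve_xy = on_xy, ventral_direction = 0.8)
  expect_equal(unlist(on_row[1, c("x_um", "y_um")]), c(x_um = 0, y_um = 0),
               tolerance = 1e-12)
  # pairwise distances preserved
  d0 <- stats::dist(cells)
  d1 <- stats::dist(al[, c("x_um", "y_um")])
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  # the ventral direction maps onto +y
  vent <- align_retina(data.frame(x_um = on_xy[1] + cos(0.8),
                                  y_um = on_xy[2] + sin(0.8)),
                       optic_nerve_xy = on_xy, ventral_direction = 0.8)
  expect_equal(unlist(vent[1, c("x_um", "y_um")]), c(x_um = 0, y_um = 1),
               tolerance = 1e-12)
  # mirroring twice restores the original
  l1 <- align_retina(cells, side = "left")
  l2 <- align_retina(l1, side = "left")
  expect_equal(l2$x_um, cells$x_um, tolerance = 1e-12)
})

test_that("ON-centre flipping unifies polarity and preserves metrics", {
  tab <- data.frame(polarity = c("ON", "OFF"), g1_amp = c(0.8, -0.9),
                    g2_amp = c(-0.2, 0.25),
                    relative_surround = c(0.5, 0.6),
                    vertical_asymmetry = c(0.1, -0.2))
  out <- flip_on_center_rfs(tab)$table
  expect_true(all(out$g1_amp <= 0))
  expect_true(all(out$g2_amp >= 0))
  expect_equal(out$relative_surround, tab$relative_surround)
  expect_equal(out$vertical_asymmetry, tab$vertical_asymmetry)
  expect_equal(out$polarity_flipped, c(TRUE, FALSE))
})

test_that("2D binning enforces the minimum count and matches a group-by", {
  set.seed(52)
  tab <- data.frame(x_um = runif(50, -400, 400), y_um = runif(50, -400, 400),
                    m = rnorm(50))
  bm <- bin_metric_2d(tab, "m", bin_um = 200, min_count = 5)
  # brute-force group-by
  for (i in seq_len(nrow(bm))) {
    inb <- tab$x_um >= bm$x_center[i] - 100 & tab$x_um < bm$x_center[i] + 100 &
      tab$y_um >= bm$y_center[i] - 100 & tab$y_um < bm$y_center[i] + 100
    expect_equal(bm$n[i], sum(inb))
    if (bm$n[i] >= 5) expect_equal(bm$mean[i], mean(tab$m[inb]), tolerance = 1e-9)
    else expect_true(is.na(bm$mean[i]))
  }
  # four cells in one isolated bin are excluded
  tab4 <- data.frame(x_um = rep(1000, 4), y_um = rep(1000, 4), m = 1:4)
  bm4 <- bin_metric_2d(tab4, "m", bin_um = 100, min_count = 5)
  expect_true(all(is.na(bm4$mean)))
})

test_that("1D binning uses six equal bins over the group range", {
  tab <- data.frame(x_um = 0, y_um = seq(-300, 300, length.out = 60))
  tab$m <- tab$y_um * 2
  b <- bin_metric_1d(tab, "m", n_bins = 6)
  expect_equal(nrow(b), 6L)
  # metric = 2y -> bin means equal bin-wise coordinate means
  edges <- seq(-300, 300, length.out = 7)
  idx <- pmin(pmax(findInterval(tab$y_um, edges, rightmost.closed = TRUE), 1), 6)
  hand <- vapply(1:6, function(k) mean(tab$m[idx == k]), numeric(1))
  expect_equal(b$mean, hand, tolerance = 1e-9)

  single <- bin_metric_1d(tab, "m", n_bins = 1)
  expect_equal(single$mean, mean(tab$m))

  tab$m2 <- 5
  expect_true(all(bin_metric_1d(tab, "m2")$mean == 5))
})

test_that("the KS statistic matches exhaustive ECDF evaluation", {
  same <- c(0.1, 0.4, 0.9)
  expect_equal(ks_dorsoventral(same, same)$statistic, 0)
  expect_equal(ks_dorsoventral(c(1, 2, 3), c(10, 11, 12))$statistic, 1)
  ks <- ks_dorsoventral(c(1, 2, 3), c(1.5, 2.5, 3.5))
  expect_equal(ks$statistic, 1 / 3, tolerance = 1e-12)
  expect_error(ks_dorsoventral(1, c(1, 2)), ">= 2")
})

test_that("regression weights recover exact linear structure", {
  set.seed(53)
  tab <- data.frame(x_um = rnorm(40, 0, 300), y_um = rnorm(40, 0, 300))
  tab$m_const <- 7
  w0 <- regression_weights(tab, "m_const")
  expect_equal(w0$beta_elevation, 0, tolerance = 1e-10)
  expect_equal(w0$beta_azimuth, 0, tolerance = 1e-10)

  tab$m_lin <- 2 * as.vector(scale(tab$y_um))
  w1 <- regression_weights(tab, "m_lin")
  expect_equal(w1$beta_elevation, 2, tolerance = 1e-9)
  expect_equal(w1$beta_azimuth, 0, tolerance = 1e-9)
})

test_that("GMM clustering recovers separable families deterministically", {
  fam <- synth_temporal_families(100, k = 3, seed = 7)
  cl <- cluster_temporal_rfs(fam$profiles, pca_dims = 10, k_grid = 1:8)
  expect_equal(cl$chosen_k, 3L)
  expect_gte(mclust::adjustedRandIndex(cl$membership, fam$labels), 0.9)
  expect_true(all(abs(rowSums(cl$responsibilities) - 1) < 1e-8))
  cl2 <- cluster_temporal_rfs(fam$profiles, pca_dims = 10, k_grid = 1:8)
  expect_identical(cl$membership, cl2$membership)
  expect_error(cluster_temporal_rfs(fam$profiles[1:5, ], k_grid = 1:6),
               "sample count")
})

test_that("the tiling index matches its closed forms and converges", {
  disjoint <- data.frame(m_x = c(0, 300, 600), m_y = 0,
                         sigma_x = 30, sigma_y = 30, theta = 0)
  expect_equal(tiling_index(disjoint), 1, tolerance = 1e-6)

  identical4 <- data.frame(m_x = rep(0, 4), m_y = 0,
                           sigma_x = 40, sigma_y = 40, theta = 0)
  expect_equal(tiling_index(identical4), 0.25, tolerance = 1e-6)

  # two unit shapes overlapping by half: union = 1.5 areas -> TI = 0.75
  # construct via circles whose lens-shaped overlap is 50% of one circle:
  # centre distance d with overlap area = pi r^2 / 2 solves
  # 2 r^2 acos(d/2r) - d/2 sqrt(4r^2 - d^2) = pi r^2 / 2 -> d ~ 0.8079 r
  r <- 100; dctr <- 0.807946 * r
  half <- data.frame(m_x = c(0, dctr), m_y = 0, sigma_x = r / 2,
                     sigma_y = r / 2, theta = 0)   # 2 s.d. contour radius r
  expect_equal(tiling_index(half, pitch_um = 1), 0.75, tolerance = 0.01)

  # raster convergence: halving the pitch changes TI by < 1%
  t2 <- tiling_index(half, pitch_um = 2)
  t1 <- tiling_index(half, pitch_um = 1)
  expect_lt(abs(t2 - t1) / t1, 0.01)
  expect_error(tiling_index(data.frame(m_x = 0, m_y = 0, sigma_x = 0,
                                       sigma_y = 1, theta = 0)), "zero-area")
})

test_that("saccade detection finds known events and rejects small ones", {
  drift <- simulate_eye_trace(120, saccade_rate_hz = 0, seed = 54)
  expect_equal(nrow(detect_saccades(drift)), 0L)

  ey <- simulate_eye_trace(900, saccade_rate_hz = 0.2, seed = 55)
  det <- detect_saccades(ey)
  truth <- ey$true_saccades
  matched <- vapply(truth$time, function(t0)
    any(abs(det$time - t0) < 0.6), logical(1))
  expect_gte(mean(matched), 0.95)               # recall
  false_pos <- vapply(det$time, function(t0)
    !any(abs(truth$time - t0) < 0.6), logical(1))
  expect_lte(mean(false_pos), 0.05)

  # a 2 degree jump is rejected by the amplitude threshold
  small <- simulate_eye_trace(60, saccade_rate_hz = 0, seed = 56)
  idx <- small$time >= 30
  small$azimuth[idx] <- small$azimuth[idx] + 2
  expect_equal(nrow(detect_saccades(small)), 0L)
})

test_that("saccade orientation tuning follows the doubled-angle formulas", {
  collinear <- data.frame(amplitude = c(5, 3, 8),
                          direction_deg = c(30, 210, 30))
  st <- saccade_orientation_tuning(collinear)
  expect_equal(st$tuning, 1, tolerance = 1e-12)
  expect_equal(st$preferred_orientation_deg, 30, tolerance = 1e-9)

  four <- data.frame(amplitude = rep(2, 4),
                     direction_deg = c(0, 45, 90, 135))
  expect_equal(saccade_orientation_tuning(four)$tuning, 0, tolerance = 1e-12)

  set.seed(57)
  rnd <- data.frame(amplitude = runif(25, 1, 10),
                    direction_deg = runif(25, 0, 360))
  st2 <- saccade_orientation_tuning(rnd)
  z <- sum(rnd$amplitude * exp(2i * rnd$direction_deg * pi / 180))
  expect_equal(st2$tuning, Mod(z) / sum(rnd$amplitude), tolerance = 1e-12)
  expect_equal(st2$preferred_orientation_deg,
               ((Arg(z) / 2) * 180 / pi) %% 180, tolerance = 1e-9)
  expect_error(saccade_orientation_tuning(data.frame(amplitude = 0,
                                                     direction_deg = 10)),
               "positive")
})

test_that("RF matrices rotate with the retina", {
  m <- matrix(0, 11, 11); m[3, 6] <- 1   # a blob above the centre
  r90 <- rotate_rf_matrix(m, pi / 2)
  # row = y increasing downward, so +90 degrees carries "up" to "right"
  expect_equal(which(r90 == 1, arr.ind = TRUE)[1, ],
               c(row = 6, col = 9))
  back <- rotate_rf_matrix(r90, -pi / 2)
  expect_equal(back, m)
})

test_that("a banded surround asymmetry is localized by 2D binning", {
  set.seed(58)
  banded <- list(
    surround_gain = function(y) rep(0.6, length(y)),
    center_sigma_um = function(y) rep(45, length(y)),
    surround_offset_um = function(y) ifelse(y >= 0 & y <= 250, 50, 0))
  cells <- make_population(800, extent_um = c(1000, 1000),
                           gradient_spec = banded, seed = 59)
  truth <- true_population_metrics(cells)
  tab <- data.frame(x_um = truth$x_um, y_um = truth$y_um,
                    asym = truth$true_vertical_asymmetry +
                      rnorm(800, sd = 0.05))
  bm <- bin_metric_2d(tab, "asym", bin_um = 250, min_count = 5,
                      extent_um = 500)
  peak <- bm[which.max(abs(bm$mean)), ]
  expect_true(peak$y_center >= 0 && peak$y_center <= 250)
})
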