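test_that("rf2d extraction takes windowed medians and excludes weak pixels", {
  # hand medians on a 3x3x5 array with window +-1 around t_var
  set.seed(41)
  v <- array(rnorm(3 * 3 * 5, sd = 0.01), dim = c(3, 3, 5))
  v[2, 2, ] <- c(0, 1, 5, 2, 0)
  rf <- st_rf(v, latency = seq(0.025, 0.125, 0.025), um_per_px = 10)
  rd <- extract_rf2d(rf, half_window = 1L, corr_threshold = 0)
  expect_equal(rd$t_var, 3L)
  for (r in 1:3) for (c in 1:3)
    expect_equal(rd$values[r, c], stats::median(v[r, c, 2:4]), tolerance = 1e-12)

  # window of one sample equals the t_var slice
  rd0 <- extract_rf2d(rf, half_window = 0L, corr_threshold = 0)
  expect_equal(rd0$values, v[, , 3], tolerance = 1e-12)

  # a pixel whose time course is uncorrelated noise gets masked out
  set.seed(42)
  n_lat <- 40
  v2 <- array(0, dim = c(5, 5, n_lat))
  sig <- sin(seq(0, 3 * pi, length.out = n_lat))
  for (r in 2:4) for (c in 2:4) v2[r, c, ] <- sig * 1.6
  v2[3, 3, ] <- 2 * sig
  v2[1, 1, ] <- rnorm(n_lat, sd = 0.5)      # uncorrelated, low variance
  rf2 <- st_rf(v2 + array(rnorm(length(v2), sd = 0.01), dim = dim(v2)),
               latency = seq(0.025, by = 0.025, length.out = n_lat),
               um_per_px = 10)
  rd2 <- extract_rf2d(rf2, half_window = 2L, corr_threshold = 0.25)
  expect_false(rd2$mask[1, 1])
  expect_true(rd2$mask[3, 3])
  expect_equal(rd2$values[1, 1], 0)
})

test_that("RF type classification follows the ratio and distance rules", {
  # single blob: weaker extremum is noise -> ratio << 0.75 -> overlapping
  blob <- render_dog_rf2d(A2 = 0, noise_sd = 0)
  blob$values <- blob$values + 1e-6 * (row(blob$values) %% 2)
  g1 <- fit_center_gaussian(blob)
  expect_equal(classify_rf_type(blob, g1), "overlapping")

  # two equal, distant extrema -> separated
  two <- render_dog_rf2d(A1 = -1, s1x = 25, s1y = 25,
                         A2 = 1, m2x = 150, m2y = 0, s2x = 25, s2y = 25)
  g1b <- fit_center_gaussian(two)
  expect_equal(classify_rf_type(two, g1b), "separated")

  # ratio exactly 0.75 at distance > d -> separated (strict <); built by
  # hand so the extrema ratio is exact
  m <- matrix(0, 21, 21)
  m[11, 4] <- -1; m[11, 18] <- 0.75
  handmade <- structure(list(values = m, mask = matrix(TRUE, 21, 21),
                             um_per_px = 10, p_var = c(row = 11, col = 4),
                             t_var = 1L, cell_id = NA), class = "rf2d")
  g1c <- list(A = -1, m_x = -70, m_y = 0, sigma_x = 15, sigma_y = 15,
              theta = 0, r2 = 1, ok = TRUE)
  expect_equal(classify_rf_type(handmade, g1c), "separated")
})

test_that("stage-1 Gaussian fit recovers rendered parameters", {
  truth <- list(A = -1.2, mx = 30, my = -20, sx = 55, sy = 35, th = 0.5)
  rd <- render_dog_rf2d(nr = 61, nc = 61, A1 = truth$A, m_x = truth$mx,
                        m_y = truth$my, s1x = truth$sx, s1y = truth$sy,
                        th1 = truth$th, A2 = 0)
  g1 <- fit_center_gaussian(rd)
  expect_true(g1$ok)
  expect_lt(abs(g1$A - truth$A) / abs(truth$A), 0.01)
  expect_lt(abs(g1$m_x - truth$mx), 1)
  expect_lt(abs(g1$m_y - truth$my), 1)
  expect_lt(abs(g1$sigma_x - truth$sx) / truth$sx, 0.01)
  expect_lt(abs(g1$sigma_y - truth$sy) / truth$sy, 0.01)
  expect_lt(abs(g1$theta - truth$th), 0.02)
  expect_equal(sign(g1$A), -1)

  # refitting the model surface is a fixed point
  surf <- matrix(panorf:::eval_gaussian2d(
    g1, panorf:::rf2d_coords(rd$values, rd$um_per_px)$x,
    panorf:::rf2d_coords(rd$values, rd$um_per_px)$y), nrow(rd$values))
  rd2 <- rd; rd2$values <- surf
  g1b <- fit_center_gaussian(rd2)
  expect_lt(abs(g1b$sigma_x - g1$sigma_x) / g1$sigma_x, 1e-3)
})

test_that("two-stage DoG fit recovers the surround parameters", {
  rd <- render_dog_rf2d(nr = 61, nc = 61, A1 = -1, s1x = 40, s1y = 40,
                        A2 = 0.22, m2x = 8, m2y = 12, s2x = 80, s2y = 90,
                        th2 = 0.2)
  fit <- fit_dog(rd, refine = TRUE)
  expect_true(fit$ok)
  expect_equal(fit$rf_type, "overlapping")
  expect_equal(sign(fit$g1$A), -sign(fit$g2$A))
  # the DoG decomposition valley is shallow; a single noiseless fit lands
  # near the generating surround (medians over many RFs are ~3%, see the
  # render-and-refit benchmark; individual fits can sit farther along the
  # amplitude/width trade-off)
  expect_lt(abs(fit$g2$A - 0.22) / 0.22, 0.15)
  expect_lt(sqrt((fit$g2$m_x - 8)^2 + (fit$g2$m_y - 12)^2), 20)
  st <- sort(c(fit$g2$sigma_x, fit$g2$sigma_y))
  expect_lt(abs(st[1] - 80) / 80, 0.1)
  expect_lt(abs(st[2] - 90) / 90, 0.1)
  expect_gt(fit$r2, 0.99)
  expect_gte(fit$r2, fit$stage1_r2)
})

test_that("the overlap constraint keeps the surround near the centre", {
  set.seed(43)
  n_violation <- 0
  for (rep in 1:25) {
    rd <- render_dog_rf2d(nr = 41, nc = 41, A1 = -1,
                          s1x = runif(1, 30, 50), s1y = runif(1, 30, 50),
                          A2 = runif(1, 0.1, 0.3),
                          m2x = runif(1, -15, 15), m2y = runif(1, -15, 15),
                          s2x = runif(1, 60, 110), s2y = runif(1, 60, 110),
                          noise_sd = 0.03)
    g1 <- fit_center_gaussian(rd)
    fit <- fit_dog(rd, g1 = g1, rf_type = "overlapping")
    if (!fit$ok) next
    dist12 <- sqrt((fit$g2$m_x - fit$g1$m_x)^2 + (fit$g2$m_y - fit$g1$m_y)^2)
    if (dist12 > fit$constraint_d && !fit$penalty_active) n_violation <- n_violation + 1
  }
  expect_equal(n_violation, 0)
})

test_that("R^2 matches its closed forms", {
  rf <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(compute_r2(rf, rf), 1)
  expect_equal(compute_r2(rf, matrix(mean(rf), 2, 2)), 0)
  expect_equal(compute_r2(rf, matrix(c(1, 2, 3, 5), 2)), 0.8)
  expect_error(compute_r2(matrix(1, 2, 2), matrix(0, 2, 2)), "constant")
})

test_that("summary metrics follow the pixel-set definitions", {
  # vertically symmetric DoG -> zero asymmetry; exact to numerical
  # precision with the generating parameters, up to fit error otherwise
  rd <- render_dog_rf2d(nr = 61, nc = 61, A1 = -1, s1x = 40, s1y = 40,
                        A2 = 0.2, s2x = 85, s2y = 85)
  exact <- structure(list(
    g1 = list(A = -1, m_x = 0, m_y = 0, sigma_x = 40, sigma_y = 40, theta = 0),
    g2 = list(A = 0.2, m_x = 0, m_y = 0, sigma_x = 85, sigma_y = 85, theta = 0),
    rf_type = "overlapping", r2 = 1, constraint_d = 80,
    penalty_active = FALSE, ok = TRUE), class = "dog_fit")
  expect_lt(abs(summarize_rf(exact, rd)$vertical_asymmetry), 1e-12)
  fit <- fit_dog(rd)
  sm <- summarize_rf(fit, rd)
  expect_lt(abs(sm$vertical_asymmetry), 1e-3)
  expect_equal(sm$polarity, "OFF")

  # hand-rasterized ellipse membership on a coarse DoG
  rd2 <- render_dog_rf2d(nr = 11, nc = 11, um_per_px = 20, A1 = -1,
                         s1x = 30, s1y = 30, A2 = 0.3, s2x = 60, s2y = 60,
                         m2y = 15)
  fit2 <- fit_dog(rd2)
  sets <- rf_pixel_sets(fit2, rd2)
  co <- panorf:::rf2d_coords(rd2$values, 20)
  for (i in seq_along(co$x)) {
    u1 <- cos(fit2$g1$theta) * (co$x[i] - fit2$g1$m_x) +
      sin(fit2$g1$theta) * (co$y[i] - fit2$g1$m_y)
    v1 <- -sin(fit2$g1$theta) * (co$x[i] - fit2$g1$m_x) +
      cos(fit2$g1$theta) * (co$y[i] - fit2$g1$m_y)
    in_c <- (u1 / fit2$g1$sigma_x)^2 + (v1 / fit2$g1$sigma_y)^2 <= 4
    expect_equal(as.vector(sets$center)[i], in_c)
  }
  expect_false(any(sets$center & sets$surround))

  # a pure centre fit has zero relative surround
  sm2 <- summarize_rf(fit2, rd2)
  expect_gt(sm2$relative_surround, 0)
  fit0 <- fit2; fit0$g2$A <- 0
  rd0 <- rd2
  rd0$values <- matrix(panorf:::eval_gaussian2d(fit0$g1, co$x, co$y), 11)
  sm0 <- summarize_rf(fit0, rd0)
  expect_lt(sm0$relative_surround, 0.15)
})

test_that("sign flips leave summary metrics unchanged", {
  rd <- render_dog_rf2d(nr = 41, nc = 41, A1 = -1, s1x = 40, s1y = 40,
                        A2 = 0.22, m2y = 20, s2x = 80, s2y = 80,
                        noise_sd = 0.02)
  f1 <- fit_dog(rd)
  rd_flip <- rd; rd_flip$values <- -rd$values
  f2 <- fit_dog(rd_flip)
  s1 <- summarize_rf(f1, rd)
  s2 <- summarize_rf(f2, rd_flip)
  expect_equal(sign(f1$g1$A), -sign(f2$g1$A))
  expect_equal(s1$relative_surround, s2$relative_surround, tolerance = 0.02)
  expect_equal(s1$vertical_asymmetry, s2$vertical_asymmetry, tolerance = 0.05)
  expect_equal(s1$center_size_mm2, s2$center_size_mm2, tolerance = 0.1)
})

test_that("radial profiles match a brute-force distance scan", {
  rd <- render_dog_rf2d(nr = 21, nc = 21, A1 = 1, s1x = 40, s1y = 40, A2 = 0)
  prof <- radial_profile(rd, ring_width_px = 2)
  # rings of an isotropic centred Gaussian decrease
  vals <- prof$mean_value[!is.na(prof$mean_value)]
  expect_true(all(diff(vals[1:5]) < 0))
  # membership against an exhaustive scan
  d <- sqrt(outer((1:21 - 11)^2, (1:21 - 11)^2, `+`))
  for (k in 1:4) {
    ring <- d >= (k - 1) * 2 & d < k * 2
    expect_equal(prof$mean_value[k], mean(rd$values[ring]), tolerance = 1e-12)
    expect_equal(prof$n_px[k], sum(ring))
  }
  # constant image gives a constant profile
  rdc <- rd; rdc$values[] <- 3
  pc <- radial_profile(rdc, ring_width_px = 2)
  expect_true(all(abs(pc$mean_value[!is.na(pc$mean_value)] - 3) < 1e-12))
})

test_that("temporal dynamics are per-set means across latency", {
  set.seed(44)
  v <- array(rnorm(3 * 3 * 4), dim = c(3, 3, 4))
  rf <- st_rf(v, latency = seq(0.025, 0.1, 0.025), um_per_px = 10)
  cen <- matrix(FALSE, 3, 3); cen[2, 2] <- TRUE
  sur <- matrix(FALSE, 3, 3); sur[1, ] <- TRUE
  dyn <- temporal_dynamics(rf, cen, sur)
  expect_equal(dyn$center, v[2, 2, ])
  hand <- vapply(1:4, function(t) mean(v[1, , t]), numeric(1))
  expect_equal(dyn$surround, hand)
  expect_error(temporal_dynamics(rf, matrix(FALSE, 3, 3), sur), "empty")
})

test_that("1D DoG fit recovers parameters within its box constraints", {
  x <- seq(-25, 25, by = 0.5)
  truth <- c(ac = 1, as = 0.3, lc = 2, ls = 4, sc = 4, ss = 9)
  prof <- truth["ac"] * exp(-(x - truth["lc"])^2 / (2 * truth["sc"]^2)) -
    truth["as"] * exp(-(x - truth["ls"])^2 / (2 * truth["ss"]^2))
  fit <- fit_dog_1d(prof, x)
  expect_true(fit$ok)
  expect_lt(abs(fit$amp_center - truth["ac"]) / truth["ac"], 0.05)
  expect_lt(abs(fit$amp_surround - truth["as"]) / truth["as"], 0.05)
  expect_lt(abs(fit$sigma_center - truth["sc"]) / truth["sc"], 0.05)
  expect_lt(abs(fit$sigma_surround - truth["ss"]) / truth["ss"], 0.05)
  # all six printed box constraints hold
  p <- c(fit$amp_center, fit$amp_surround, fit$loc_center, fit$loc_surround,
         fit$sigma_center, fit$sigma_surround)
  expect_true(all(p >= fit$bounds$lower - 1e-9))
  expect_true(all(p <= fit$bounds$upper + 1e-9))

  # pure centre Gaussian -> surround amplitude at its lower bound 0
  pure <- exp(-x^2 / (2 * 16))
  f0 <- fit_dog_1d(pure, x)
  expect_lt(f0$amp_surround, 1e-4)
})

test_that("random noisy 1D fits always respect the printed bounds", {
  set.seed(45)
  x <- seq(-25, 25, by = 1)
  for (rep in 1:20) {
    prof <- runif(1, 0.5, 2) * exp(-(x - runif(1, -5, 5))^2 / (2 * runif(1, 2, 6)^2)) -
      runif(1, 0, 0.5) * exp(-(x - runif(1, -8, 8))^2 / (2 * runif(1, 8, 15)^2)) +
      rnorm(length(x), sd = 0.05)
    if (max(prof) <= 0) next
    fit <- fit_dog_1d(prof, x)
    if (!fit$ok) next
    p <- c(fit$amp_center, fit$amp_surround, fit$loc_center, fit$loc_surround,
           fit$sigma_center, fit$sigma_surround)
    expect_true(all(p >= fit$bounds$lower - 1e-9))
  }
})
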