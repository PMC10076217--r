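test_that("dF/F detrending matches a per-window sort oracle", {
  const <- rep(3, 400)
  expect_equal(compute_dff(const, sample_hz = 10), rep(0, 400),
               ignore_attr = TRUE)

  set.seed(21)
  f <- 5 + abs(cumsum(rnorm(400, sd = 0.1)))
  d1 <- compute_dff(f, sample_hz = 10, window_s = 4, percentile = 8)
  # oracle: direct quantile of each centred window
  half <- 20L
  base <- vapply(seq_along(f), function(i)
    stats::quantile(f[max(1, i - half):min(length(f), i + half)], 0.08,
                    names = FALSE), numeric(1))
  expect_equal(as.vector(d1), (f - base) / base, tolerance = 1e-12)

  # ratio invariance
  d2 <- compute_dff(2 * f, sample_hz = 10, window_s = 4, percentile = 8)
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-12)
  expect_error(compute_dff(f[1:10], sample_hz = 10, window_s = 20), "window")
})

test_that("the calcium-triggered average equals a four-deep brute-force loop", {
  stim <- make_stimulus(8, field_um = c(60, 60), seed = 22)   # 6x6 checkers
  set.seed(23)
  n <- 3; S <- 70
  traces <- matrix(stats::rexp(n * S), n)
  lat <- seq(-0.1, 0.3, by = 0.025)
  rfs <- estimate_rf(traces, stim, sample_hz = 10, latencies = lat)
  fr <- render_stimulus(stim)
  h <- stim$h_px
  for (i in 1:n) {
    for (li in seq_along(lat)) {
      for (px in list(c(1, 1), c(3, 5), c(6, 6))) {
        acc <- 0
        for (s in 1:S) {
          fidx <- floor((s / 10 - lat[li]) * 6) + 1
          if (fidx >= 1 && fidx <= stim$n_frames) {
            sval <- fr[fidx, (px[2] - 1) * h + px[1]]
            acc <- acc + sval * traces[i, s] - sval * mean(traces[, s])
          }
        }
        expect_equal(rfs[[i]]$values[px[1], px[2], li], acc, tolerance = 1e-10)
      }
    }
  }
})

test_that("degenerate traces produce the expected degenerate RFs", {
  stim <- make_stimulus(6, field_um = c(60, 60), seed = 24)
  traces <- rbind(rep(0, 50), stats::rexp(50))
  rfs <- estimate_rf(traces, stim, sample_hz = 10,
                     latencies = seq(0, 0.2, by = 0.025), pop_term = "none")
  expect_true(all(rfs[[1]]$values == 0))

  # identical traces cancel against the population mean
  tr <- matrix(rep(stats::rexp(50), 3), 3, byrow = TRUE)
  rfs2 <- estimate_rf(tr, stim, sample_hz = 10,
                      latencies = seq(0, 0.2, by = 0.025), pop_term = "mean")
  for (i in 1:3) expect_lt(max(abs(rfs2[[i]]$values)), 1e-10)
})

test_that("normalization, affine invariance and idempotence hold", {
  set.seed(25)
  v <- array(rnorm(5 * 5 * 8), dim = c(5, 5, 8))
  rf <- st_rf(v, latency = seq(-0.075, 0.1, by = 0.025), um_per_px = 10)
  nrm <- normalize_rf(rf)
  expect_equal(max(abs(nrm$values)), 1, tolerance = 1e-12)
  pre <- nrm$latency < 0
  expect_lt(abs(mean(nrm$values[, , pre])), 1e-6)

  shifted <- rf; shifted$values <- 2.5 * rf$values + 7
  nrm2 <- normalize_rf(shifted)
  expect_equal(nrm2$values, nrm$values, tolerance = 1e-9)
  expect_equal(normalize_rf(nrm)$values, nrm$values, tolerance = 1e-9)

  rf_nopre <- st_rf(v, latency = seq(0.025, 0.2, by = 0.025), um_per_px = 10)
  expect_error(normalize_rf(rf_nopre), "tau < 0")
})

test_that("locate finds the variance peaks, matching a double loop", {
  v <- array(0, dim = c(6, 7, 9))
  v[4, 2, ] <- c(0, 0, 1, 5, -3, 0, 0, 0, 0)
  rf <- st_rf(v, latency = seq(-0.05, 0.15, by = 0.025), um_per_px = 10)
  loc <- locate_rf(rf)
  expect_equal(unname(loc$p_var), c(4, 2))
  expect_equal(loc$t_var, 4L)

  set.seed(26)
  v2 <- array(rnorm(8 * 8 * 10), dim = c(8, 8, 10))
  rf2 <- st_rf(v2, latency = seq(0.025, 0.25, by = 0.025), um_per_px = 10)
  loc2 <- locate_rf(rf2)
  vars <- matrix(NA_real_, 8, 8)
  for (r in 1:8) for (c in 1:8) vars[r, c] <- stats::var(v2[r, c, ])
  expect_equal(unname(loc2$p_var),
               c((which.max(vars) - 1) %% 8 + 1, (which.max(vars) - 1) %/% 8 + 1))
  tvars <- vapply(1:10, function(t) stats::var(as.vector(v2[, , t])), numeric(1))
  expect_equal(loc2$t_var, which.max(tvars))
  expect_error(locate_rf(st_rf(array(1, dim = c(3, 3, 4)),
                               seq(0, 0.075, 0.025), 10)), "constant")
})

test_that("cropping pads, masks and recentres consistently", {
  set.seed(27)
  v <- array(rnorm(20 * 20 * 5), dim = c(20, 20, 5))
  v[10, 12, ] <- v[10, 12, ] + c(0, 6, 8, 4, 0)
  rf <- st_rf(v, latency = seq(-0.025, 0.075, by = 0.025), um_per_px = 10)
  loc <- locate_rf(rf)
  cr <- crop_rf(rf, loc$p_var, edge_um = 100)    # 11 px window
  expect_equal(dim(cr$values), c(11L, 11L, 5L))
  expect_true(all(cr$mask))
  expect_equal(cr$values[6, 6, ], v[10, 12, ])
  # crop then locate: P_var maps to the crop centre
  loc2 <- locate_rf(cr)
  expect_equal(unname(loc2$p_var), c(6, 6))

  # corner crop gets a padded mask
  cr2 <- crop_rf(rf, c(2, 2), edge_um = 100)
  expect_false(all(cr2$mask))
  expect_true(all(apply(cr2$values, 3, function(m) all(m[!cr2$mask] == 0))))
})

test_that("RF SNR follows its dB definition and moment check", {
  v <- array(0.1, dim = c(21, 21, 4))
  rf <- st_rf(v, latency = seq(0, 0.075, 0.025), um_per_px = 50)
  # peak equals rms noise -> 0 dB
  expect_equal(compute_rf_snr(rf, c(11, 11), exclusion_radius_um = 300), 0)

  # known noise sd in the far region
  set.seed(28)
  v2 <- array(rnorm(41 * 41 * 6, sd = 0.1), dim = c(41, 41, 6))
  v2[21, 21, 3] <- 1
  rf2 <- st_rf(v2, latency = seq(0, 0.125, 0.025), um_per_px = 25)
  snr <- compute_rf_snr(rf2, c(21, 21), exclusion_radius_um = 500)
  noise_power_implied <- 1 / 10^(snr / 10)
  expect_lt(abs(noise_power_implied - 0.01) / 0.01, 0.1)

  # zero far region is capped and flagged
  v3 <- array(0, dim = c(21, 21, 2)); v3[11, 11, ] <- 1
  rf3 <- st_rf(v3, latency = c(0, 0.025), um_per_px = 50)
  capped <- compute_rf_snr(rf3, c(11, 11), exclusion_radius_um = 300)
  expect_true(isTRUE(attr(capped, "capped")))
})

test_that("the SNR filter is strict and reports counts", {
  rfs <- as.list(1:4)
  flt <- filter_rfs(rfs, snr_db = c(20, 15, 14.9, 15.0001), threshold_db = 15)
  expect_equal(flt$keep, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(flt$report$kept, 2L)
  all15 <- filter_rfs(rfs, snr_db = rep(15, 4))
  expect_equal(all15$report$kept, 0L)
})

test_that("zero-noise mapping recovers the rendered ground-truth RFs", {
  stim <- make_stimulus(150, field_um = c(500, 500), seed = 29)
  cells <- make_population(4, extent_um = c(150, 150), seed = 30)
  rec <- simulate_responses(cells, stim, noise_level = 0, seed = 31)
  # population term off: with only 4 neurons the mean-response subtraction
  # removes 1/4 of each cell's own average and injects its neighbours';
  # at recording scale the term is benign (opposite polarities cancel)
  mapped <- map_recording(rec, crop_um = 300, exclusion_radius_um = 160,
                          pop_term = "none")
  for (i in seq_along(cells)) {
    crop <- mapped$rfs[[i]]
    loc <- locate_rf(crop)
    slice <- crop$values[, , loc$t_var]
    rftrue <- render_cell_rf(cells[[i]], stim)
    dense <- numeric(stim$h_px * stim$w_px)
    dense[rftrue$idx] <- rftrue$w
    dense <- matrix(dense, stim$h_px)
    # cut the same crop from the dense truth
    r0 <- crop$origin_px[1]; c0 <- crop$origin_px[2]
    rows <- r0:(r0 + nrow(slice) - 1); cols <- c0:(c0 + ncol(slice) - 1)
    ok <- rows >= 1 & rows <= stim$h_px
    okc <- cols >= 1 & cols <= stim$w_px
    # the reverse-correlation estimate recovers the truth blurred by the
    # stimulus spatial autocorrelation: with shifts uniform over one
    # checker period the autocorrelation is a separable triangle of one
    # checker width
    tri <- pmax(0, 1 - abs(-(stim$ck_px - 1):(stim$ck_px - 1)) / stim$ck_px)
    tri <- tri / sum(tri)
    blur <- function(m) {
      m1 <- apply(m, 2, function(col) stats::filter(col, tri, circular = TRUE))
      t(apply(m1, 1, function(row) stats::filter(row, tri, circular = TRUE)))
    }
    dense_b <- blur(dense)
    tr_crop <- dense_b[rows[ok], cols[okc]]
    r <- stats::cor(as.vector(slice[ok, okc]), as.vector(tr_crop))
    expect_gt(abs(r), 0.95)
    r_raw <- stats::cor(as.vector(slice[ok, okc]),
                        as.vector(dense[rows[ok], cols[okc]]))
    expect_gt(abs(r_raw), 0.9)
  }
})

test_that("shifting checkers beat static checkers at centre-size estimation", {
  cells <- make_population(12, extent_um = c(200, 200), seed = 61)
  truth <- vapply(cells, `[[`, numeric(1), "center_sigma_um")
  err <- function(shifting) {
    stim <- make_stimulus(200, field_um = c(600, 600), shifting = shifting,
                          seed = 62)
    rec <- simulate_responses(cells, stim, seed = 63)
    mapped <- map_recording(rec, crop_um = 400, exclusion_radius_um = 200,
                            pop_term = "none")
    sig <- vapply(seq_along(cells), function(i) {
      rd <- extract_rf2d(mapped$rfs[[i]])
      g1 <- tryCatch(fit_center_gaussian(rd), error = function(e) NULL)
      if (is.null(g1) || !g1$ok) return(NA_real_)
      sqrt(g1$sigma_x * g1$sigma_y)
    }, numeric(1))
    mean(abs(sig - truth), na.rm = TRUE)
  }
  expect_lt(err(TRUE), err(FALSE))
})
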