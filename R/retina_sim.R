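#' Shifting white-noise checkerboard stimulus
#'
#' Binary checkerboard (contrast values -1/+1) rendered on a pixel grid and
#' updated at 6 Hz; after every frame the whole grid is shifted by random
#' multiples of the shift quantum in x and y, which raises the spatial
#' resolution of reverse-correlation receptive-field estimates beyond the
#' checker size.  The working grid is 10 um per pixel, so the default
#' 100 um checkers are 10 px and the 10 um shift quantum is exactly 1 px.
#'
#' @param duration_s stimulus duration in seconds.
#' @param field_um c(width, height) of the rendered field in um.
#' @param checker_um checker edge (default 100).
#' @param shift_quantum_um shift quantum (default 10); offsets are drawn
#'   uniformly over multiples of this spanning one checker period,
#'   independently per axis per frame.
#' @param um_per_px working pixel size (default 10, must divide checker_um
#'   and be divided by into shift_quantum_um exactly).
#' @param update_hz frame rate (default 6).
#' @param shifting set FALSE for the static-checker control (all offsets 0).
#' @param seed integer seed.
#' @return object of class `shifting_noise_stimulus` with fields `checkers`
#'   (T x nCkRow x nCkCol array of -1/+1), `shifts` (T x 2 matrix of pixel
#'   offsets, columns dy, dx), geometry metadata, and `n_frames`.
#' @export
make_stimulus <- function(duration_s, field_um = c(1200, 1200),
                          checker_um = 100, shift_quantum_um = 10,
                          um_per_px = 10, update_hz = 6,
                          shifting = TRUE, seed = NULL) {
  if (duration_s <= 0) stop("duration must be positive")
  if (checker_um %% um_per_px != 0 || shift_quantum_um %% um_per_px != 0)
    stop("grid resolution must divide the checker size and shift quantum")
  if (!is.null(seed)) set.seed(seed)
  w_px <- as.integer(round(field_um[1] / um_per_px))
  h_px <- as.integer(round(field_um[2] / um_per_px))
  ck_px <- as.integer(checker_um / um_per_px)
  sq_px <- as.integer(shift_quantum_um / um_per_px)
  n_frames <- as.integer(round(duration_s * update_hz))
  nck_r <- h_px %/% ck_px + 2L            # one spare row/col to cover shifts
  nck_c <- w_px %/% ck_px + 2L
  checkers <- array(sample(c(-1, 1), n_frames * nck_r * nck_c, replace = TRUE),
                    dim = c(n_frames, nck_r, nck_c))
  n_offsets <- ck_px %/% sq_px
  shifts <- if (shifting) {
    matrix(sample.int(n_offsets, 2L * n_frames, replace = TRUE) - 1L,
           ncol = 2L) * sq_px
  } else matrix(0L, n_frames, 2L)
  colnames(shifts) <- c("dy", "dx")
  structure(list(checkers = checkers, shifts = shifts,
                 n_frames = n_frames, h_px = h_px, w_px = w_px,
                 ck_px = ck_px, um_per_px = um_per_px,
                 checker_um = checker_um, shift_quantum_um = shift_quantum_um,
                 update_hz = update_hz, duration_s = duration_s,
                 shifting = shifting, seed = seed),
            class = "shifting_noise_stimulus")
}

#' Render one stimulus frame as an h_px x w_px matrix
#' @param stim a `shifting_noise_stimulus`.
#' @param t frame index (1-based).
#' @export
stimulus_frame <- function(stim, t) {
  ck <- stim$checkers[t, , ]
  dy <- stim$shifts[t, 1L]; dx <- stim$shifts[t, 2L]
  rows <- ((seq_len(stim$h_px) - 1L + dy) %/% stim$ck_px) + 1L
  cols <- ((seq_len(stim$w_px) - 1L + dx) %/% stim$ck_px) + 1L
  ck[rows, cols, drop = FALSE]
}

#' Render all frames into a T x (h_px * w_px) matrix
#'
#' Pixels are vectorized column-major (pixel index = (col-1) * h_px + row).
#' Frame rendering is cached per distinct (dy, dx) offset via an index map.
#'
#' @param stim a `shifting_noise_stimulus`.
#' @return numeric matrix of -1/+1 values.
#' @export
render_stimulus <- function(stim) {
  h <- stim$h_px; w <- stim$w_px; ck <- stim$ck_px
  nck_r <- dim(stim$checkers)[2]
  maps <- list()
  out <- matrix(0, stim$n_frames, h * w)
  for (t in seq_len(stim$n_frames)) {
    dy <- stim$shifts[t, 1L]; dx <- stim$shifts[t, 2L]
    key <- paste0(dy, "_", dx)
    map <- maps[[key]]
    if (is.null(map)) {
      rows <- ((seq_len(h) - 1L + dy) %/% ck) + 1L
      cols <- ((seq_len(w) - 1L + dx) %/% ck) + 1L
      map <- maps[[key]] <- as.vector(outer(rows, (cols - 1L) * nck_r, `+`))
    }
    out[t, ] <- stim$checkers[t, , ][map]
  }
  out
}

#' Ground-truth RGC population with dorsoventral receptive-field gradients
#'
#' Cells are scattered uniformly over a rectangle of retina centred on the
#' field; the optic nerve head is the origin and +y is ventral.  Each cell
#' carries a ground-truth difference-of-Gaussians spatial RF whose relative
#' surround strength, centre size and vertical surround offset vary along
#' the dorsoventral (y) axis according to `gradient_spec`, emulating the
#' retina-wide trends the measurement pipeline is meant to recover, plus a
#' biphasic temporal kernel and a trace noise level.
#'
#' @param n_cells number of cells.
#' @param extent_um c(width, height) of the cell sheet in um, centred on 0.
#' @param gradient_spec list of functions of y (um, +y ventral):
#'   `surround_gain(y)` (true relative surround strength),
#'   `center_sigma_um(y)`, `surround_offset_um(y)` (vertical displacement of
#'   the surround Gaussian, positive = ventral).  Pass
#'   [flat_gradient_spec()] for a null (gradient-free) population.
#' @param on_fraction probability that a cell is ON-polarity.
#' @param noise_level trace noise s.d. as a fraction of each cell's
#'   zero-noise response s.d.
#' @param surround_sigma_factor surround sigma as multiple of centre sigma.
#' @param seed integer seed.
#' @return list of `ground_truth_cell` objects (class `rgc_population`).
#' @export
make_population <- function(n_cells, extent_um = c(700, 700),
                            gradient_spec = default_gradient_spec(),
                            on_fraction = 0.5, noise_level = 0.2,
                            surround_sigma_factor = 2,
                            seed = NULL) {
  if (any(extent_um <= 0)) stop("empty extent")
  if (!is.null(seed)) set.seed(seed)
  xs <- stats::runif(n_cells, -extent_um[1] / 2, extent_um[1] / 2)
  ys <- stats::runif(n_cells, -extent_um[2] / 2, extent_um[2] / 2)
  pol <- ifelse(stats::runif(n_cells) < on_fraction, 1, -1)
  t1 <- stats::runif(n_cells, 0.06, 0.09)
  cells <- lapply(seq_len(n_cells), function(i) {
    structure(list(
      cell_id = i,
      x_um = xs[i], y_um = ys[i],
      polarity = if (pol[i] > 0) "ON" else "OFF",
      surround_gain = gradient_spec$surround_gain(ys[i]),
      center_sigma_um = gradient_spec$center_sigma_um(ys[i]),
      surround_sigma_um = surround_sigma_factor * gradient_spec$center_sigma_um(ys[i]),
      surround_offset_um = gradient_spec$surround_offset_um(ys[i]),
      tau1 = t1[i], tau2 = 2 * t1[i],
      noise_level = noise_level
    ), class = "ground_truth_cell")
  })
  class(cells) <- c("rgc_population", class(cells))
  cells
}

## centre weight sign: ON cells weight bright (+1) positively, OFF cells
## weight dark, i.e. centre weight -1
polarity_sign <- function(cell) if (identical(cell$polarity, "ON")) 1 else -1

#' Default dorsoventral gradient specification
#'
#' Linear trends over the default +-350 um extent: relative surround
#' strength rising from 0.45 (dorsal) to 0.85 (ventral), centre sigma
#' falling 55 to 35 um, surround vertical offset rising from -50 to +50 um.
#' These emulate, at the scale of the simulated patch of retina, gradual
#' dorsoventral gradients of surround strength, centre size and surround
#' asymmetry; the effect sizes are set so that, given the information the
#' 100-um shifting-checker stimulus carries about the weak surround, a
#' desk-scale recording has adequate power to recover the per-cell trends.
#'
#' @param extent_um vertical extent the linear ramps span.
#' @export
default_gradient_spec <- function(extent_um = 700) {
  h <- extent_um / 2
  list(
    surround_gain = function(y) 0.45 + 0.40 * (y + h) / (2 * h),
    center_sigma_um = function(y) 55 - 20 * (y + h) / (2 * h),
    surround_offset_um = function(y) -50 + 100 * (y + h) / (2 * h)
  )
}

#' Gradient-free specification for null-control populations
#' @export
flat_gradient_spec <- function() {
  list(surround_gain = function(y) rep(0.5, length(y)),
       center_sigma_um = function(y) rep(45, length(y)),
       surround_offset_um = function(y) rep(0, length(y)))
}

## rotated 2D Gaussian over pixel-centre coordinates (um)
gauss2d_eval <- function(x, y, A, mx, my, sx, sy, theta = 0) {
  u <- cos(theta) * (x - mx) + sin(theta) * (y - my)
  v <- -sin(theta) * (x - mx) + cos(theta) * (y - my)
  A * exp(-0.5 * (u^2 / sx^2 + v^2 / sy^2))
}

#' Render a cell's true spatial receptive field on the stimulus pixel grid
#'
#' Centre Gaussian of amplitude +-1 (sign = polarity) plus an opposite-sign
#' surround Gaussian, displaced vertically by the cell's surround offset and
#' scaled so that the true relative surround strength (|sum surround| /
#' |sum centre|) equals the cell's `surround_gain`.
#'
#' @param cell a `ground_truth_cell`.
#' @param stim a `shifting_noise_stimulus` (geometry reference; the retinal
#'   field is centred on the stimulus field).
#' @return list with `idx` (pixel indices of the footprint, column-major on
#'   the stimulus grid), `w` (weights), and the dense `matrix` accessor via
#'   attributes `h_px`, `w_px`.
#' @export
render_cell_rf <- function(cell, stim) {
  upp <- stim$um_per_px
  h <- stim$h_px; w <- stim$w_px
  ## pixel-centre coordinates, origin at field centre
  cx0 <- (w + 1) / 2; cy0 <- (h + 1) / 2
  px_x <- (cell$x_um / upp) + cx0
  px_y <- (cell$y_um / upp) + cy0
  sx_c <- cell$center_sigma_um / upp
  sx_s <- cell$surround_sigma_um / upp
  off <- cell$surround_offset_um / upp
  half <- ceiling(3.5 * sx_s + abs(off))
  rows <- max(1, floor(px_y - half)):min(h, ceiling(px_y + half))
  cols <- max(1, floor(px_x - half)):min(w, ceiling(px_x + half))
  if (length(rows) == 0 || length(cols) == 0) stop("RF outside stimulus")
  g <- expand.grid(row = rows, col = cols)
  s <- polarity_sign(cell)
  cen <- gauss2d_eval(g$col, g$row, s, px_x, px_y, sx_c, sx_c)
  sur_raw <- gauss2d_eval(g$col, g$row, 1, px_x, px_y + off, sx_s, sx_s)
  amp_s <- -s * cell$surround_gain * sum(abs(cen)) / sum(sur_raw)
  wgt <- cen + amp_s * sur_raw
  idx <- (g$col - 1L) * h + g$row
  list(idx = idx, w = wgt, rows = range(rows), cols = range(cols),
       h_px = h, w_px = w)
}

#' Biphasic temporal kernel sampled on a fine latency grid
#'
#' k(tau) = (tau/t1)^2 exp(-tau/t1) - 0.35 (tau/t2)^2 exp(-tau/t2),
#' normalized to peak 1.
#'
#' @param tau latencies (s).
#' @param tau1 time-to-peak scale of the driving lobe.
#' @param tau2 scale of the rebound lobe.
#' @export
temporal_kernel <- function(tau, tau1 = 0.07, tau2 = 2 * tau1) {
  k <- (tau / tau1)^2 * exp(-tau / tau1) - 0.35 * (tau / tau2)^2 * exp(-tau / tau2)
  k[tau < 0] <- 0
  k / max(abs(k))
}

#' Simulate deconvolved-like responses to a shifting-noise stimulus
#'
#' Forward model: space-time separable linear filtering of the stimulus by
#' each cell's true spatial RF and temporal kernel (stimulus evaluated by
#' zero-order hold at `t - tau`), half-wave rectification, then additive
#' truncated-Gaussian noise standing in for deconvolution residuals, so the
#' returned traces are non-negative like deconvolved calcium event rates.
#'
#' @param cells an `rgc_population`.
#' @param stim a `shifting_noise_stimulus`.
#' @param imaging_hz trace sampling rate (default 10).
#' @param kernel_len_s temporal kernel support (default 0.4 s at 0.025 s
#'   resolution).
#' @param noise_level overrides the cells' noise level if not NULL.
#' @param seed integer seed for the noise.
#' @param frames optional pre-rendered stimulus matrix from
#'   [render_stimulus()] (rendered internally when NULL).
#' @return object of class `simulated_recording`: list with `traces`
#'   (n_cells x n_samples), `sample_hz`, `cells`, `stim`, `seed`.
#' @export
simulate_responses <- function(cells, stim, imaging_hz = 10,
                               kernel_len_s = 0.4, noise_level = NULL,
                               seed = NULL, frames = NULL) {
  if (is.null(frames)) frames <- render_stimulus(stim)
  n_samp <- as.integer(floor(stim$duration_s * imaging_hz))
  t_samp <- seq_len(n_samp) / imaging_hz
  taus <- seq(0.025, kernel_len_s, by = 0.025)
  ## frame shown at time u is the last frame before u
  lag_idx <- outer(t_samp, taus, function(ts, tau)
    floor((ts - tau) * stim$update_hz) + 1L)
  valid <- lag_idx >= 1L & lag_idx <= stim$n_frames
  lag_idx[!valid] <- 1L
  traces <- matrix(0, length(cells), n_samp)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    rf <- render_cell_rf(cell, stim)
    drive_f <- as.vector(frames[, rf$idx, drop = FALSE] %*% rf$w)  # per frame
    k <- temporal_kernel(taus, cell$tau1, cell$tau2)
    g <- matrix(drive_f[lag_idx], nrow = n_samp)
    g[!valid] <- 0
    lin <- as.vector(g %*% k)
    rate <- pmax(lin, 0)
    nl <- if (is.null(noise_level)) cell$noise_level else noise_level
    if (nl > 0) {
      sdr <- stats::sd(rate)
      rate <- pmax(rate + stats::rnorm(n_samp, sd = nl * ifelse(sdr > 0, sdr, 1)), 0)
    }
    traces[i, ] <- rate
  }
  structure(list(traces = traces, sample_hz = imaging_hz,
                 cells = cells, stim = stim, seed = seed),
            class = "simulated_recording")
}

#' Simulate an eye-position trace with known saccades
#'
#' Slow drift (smoothed random walk) plus step-like saccades with known
#' times, amplitudes and directions; directions concentrate around a
#' preferred orientation (on the doubled-angle circle, so opposite
#' directions are equivalent).  The median position is re-zeroed in both
#' coordinates, so positions are relative to the median eye position.
#'
#' @param duration_s trace length (s).
#' @param sample_hz sampling rate (default 50).
#' @param saccade_rate_hz mean saccade rate (default 0.2).
#' @param preferred_orientation_deg orientation about which saccade
#'   directions concentrate.
#' @param orientation_kappa von Mises concentration on the doubled angle
#'   (large = tightly oriented; 0 = isotropic).
#' @param amplitude_range_deg saccade amplitudes drawn uniformly here.
#' @param drift_sd_deg s.d. of the smoothed drift component.
#' @param seed integer seed.
#' @return object of class `eye_trace`: data.frame-like list with `time`,
#'   `azimuth`, `elevation` and `true_saccades` (data.frame time,
#'   amplitude, direction_deg).
#' @export
simulate_eye_trace <- function(duration_s, sample_hz = 50,
                               saccade_rate_hz = 0.2,
                               preferred_orientation_deg = 0,
                               orientation_kappa = 8,
                               amplitude_range_deg = c(4, 15),
                               drift_sd_deg = 0.3, seed = NULL) {
  if (saccade_rate_hz < 0) stop("rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s * sample_hz))
  tm <- seq_len(n) / sample_hz
  drift <- function() {
    w <- cumsum(stats::rnorm(n, sd = drift_sd_deg / sqrt(sample_hz)))
    stats::filter(w, rep(1 / 25, 25), sides = 2, circular = TRUE)
  }
  az <- as.numeric(drift()); el <- as.numeric(drift())
  n_sacc <- stats::rpois(1, saccade_rate_hz * duration_s)
  sacc <- data.frame(time = numeric(0), amplitude = numeric(0),
                     direction_deg = numeric(0))
  if (n_sacc > 0) {
    times <- sort(stats::runif(n_sacc, 2, duration_s - 2))
    keep <- c(TRUE, diff(times) > 1.0)
    times <- times[keep]
    amp <- stats::runif(length(times), amplitude_range_deg[1], amplitude_range_deg[2])
    ## doubled-angle von Mises orientation, random direction along it
    th2 <- circular_vonmises(length(times), 2 * preferred_orientation_deg * pi / 180,
                             orientation_kappa)
    ori <- th2 / 2
    flip <- sample(c(0, pi), length(times), replace = TRUE)
    dir <- ori + flip
    for (k in seq_along(times)) {
      idx <- which(tm >= times[k])
      az[idx] <- az[idx] + amp[k] * cos(dir[k])
      el[idx] <- el[idx] + amp[k] * sin(dir[k])
    }
    sacc <- data.frame(time = times, amplitude = amp,
                       direction_deg = (dir * 180 / pi) %% 360)
  }
  az <- az - stats::median(az); el <- el - stats::median(el)
  structure(list(time = tm, azimuth = az, elevation = el,
                 sample_hz = sample_hz, true_saccades = sacc, seed = seed),
            class = "eye_trace")
}

## von Mises sampler (Best-Fisher); kappa = 0 falls back to uniform
circular_vonmises <- function(n, mu, kappa) {
  if (kappa <= 0) return(stats::runif(n, 0, 2 * pi))
  out <- numeric(n)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (u[2] < c_ * (2 - c_) || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out %% (2 * pi)
}

#' Ground-truth summary metrics of a cell's spatial receptive field
#'
#' Computes, from the true DoG parameters and the same two-standard-
#' deviation ellipse construction used by the measurement pipeline, the
#' cell's true relative surround strength, centre size and vertical surround
#' asymmetry ((u - l)/(u + l), u = side of the centre towards smaller y =
#' dorsal).
#'
#' @param cell a `ground_truth_cell`.
#' @param um_per_px raster resolution for the pixel sums (default 10).
#' @return data.frame row with the true metrics.
#' @export
true_cell_metrics <- function(cell, um_per_px = 10) {
  s <- polarity_sign(cell)
  half <- ceiling((2 * cell$surround_sigma_um + abs(cell$surround_offset_um)) /
                    um_per_px) + 2L
  g <- expand.grid(col = -half:half, row = -half:half)
  x <- g$col * um_per_px; y <- g$row * um_per_px
  cen_v <- gauss2d_eval(x, y, s, 0, 0, cell$center_sigma_um, cell$center_sigma_um)
  sur_raw <- gauss2d_eval(x, y, 1, 0, cell$surround_offset_um,
                          cell$surround_sigma_um, cell$surround_sigma_um)
  amp_s <- -s * cell$surround_gain * sum(abs(cen_v)) / sum(sur_raw)
  rf <- cen_v + amp_s * sur_raw
  in_cen <- (x^2 + y^2) / cell$center_sigma_um^2 <= 4
  in_sur <- (x^2 + (y - cell$surround_offset_um)^2) / cell$surround_sigma_um^2 <= 4 &
    !in_cen
  cen_sum <- sum(rf[in_cen]); sur_sum <- sum(rf[in_sur])
  u <- abs(sum(rf[in_sur & y < 0]))
  l <- abs(sum(rf[in_sur & y > 0]))
  data.frame(
    cell_id = cell$cell_id, x_um = cell$x_um, y_um = cell$y_um,
    polarity = cell$polarity,
    true_surround_gain = cell$surround_gain,
    true_center_sigma_um = cell$center_sigma_um,
    true_surround_offset_um = cell$surround_offset_um,
    true_relative_surround = abs(sur_sum) / abs(cen_sum),
    true_center_size_mm2 = sum(in_cen) * (um_per_px / 1000)^2,
    true_vertical_asymmetry = if (u + l > 0) (u - l) / (u + l) else 0
  )
}

#' Ground-truth metric table for a whole population
#' @param cells an `rgc_population`.
#' @param um_per_px raster resolution.
#' @export
true_population_metrics <- function(cells, um_per_px = 10) {
  do.call(rbind, lapply(cells, true_cell_metrics, um_per_px = um_per_px))
}
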