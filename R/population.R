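#' Population-level analysis of receptive-field metrics
#'
#' Alignment to a common retinal frame, 1D/2D binning of RF metrics,
#' dorsoventral trend statistics (two-sample Kolmogorov-Smirnov tests and
#' linear-regression weights on elevation and azimuth), clustering of
#' temporal RFs with a diagonal-covariance Gaussian mixture selected by a
#' BIC elbow, the mosaic tiling index, and saccade statistics.
#'
#' @name population_analysis
NULL

#' Align a cell table to the common retinal frame
#'
#' Translates the optic nerve head to the origin, rotates so the stated
#' ventral direction maps onto +y, and mirrors left retinas in x so +x is
#' nasal for all retinas.  The transform is rigid (up to the mirror), so
#' pairwise distances are preserved.
#'
#' @param cells data.frame with columns `x_um`, `y_um` (raw coordinates).
#' @param optic_nerve_xy c(x, y) of the optic nerve head in raw coordinates.
#' @param ventral_direction angle (radians) of the ventral direction in the
#'   raw frame.
#' @param side "left" or "right"; left retinas are mirrored in x.
#' @return the table with `x_um`, `y_um` replaced by aligned coordinates and
#'   a `mirrored` attribute.
#' @export
align_retina <- function(cells, optic_nerve_xy = c(0, 0),
                         ventral_direction = pi / 2,
                         side = c("right", "left")) {
  side <- match.arg(side)
  if (length(optic_nerve_xy) != 2 || any(!is.finite(optic_nerve_xy)))
    stop("missing optic nerve position")
  x <- cells$x_um - optic_nerve_xy[1]
  y <- cells$y_um - optic_nerve_xy[2]
  rot <- pi / 2 - ventral_direction
  xr <- cos(rot) * x - sin(rot) * y
  yr <- sin(rot) * x + cos(rot) * y
  if (side == "left") xr <- -xr
  cells$x_um <- xr
  cells$y_um <- yr
  attr(cells, "mirrored") <- side == "left"
  attr(cells, "rotation") <- rot
  cells
}

#' Rotate a spatial RF crop with its retina
#'
#' Nearest-neighbour remap of a 2D RF matrix by the alignment rotation (and
#' optional mirror), so pooled average RFs stay consistent with the aligned
#' coordinates.
#'
#' @param m matrix.
#' @param rotation angle in radians (as stored by [align_retina()]).
#' @param mirror mirror in x after rotation.
#' @export
rotate_rf_matrix <- function(m, rotation, mirror = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  out <- matrix(0, nr, nc)
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  dx <- g$col - cx; dy <- g$row - cy
  if (mirror) dx <- -dx
  sx <- cos(-rotation) * dx - sin(-rotation) * dy + cx
  sy <- sin(-rotation) * dx + cos(-rotation) * dy + cy
  si <- round(sy); sj <- round(sx)
  ok <- si >= 1 & si <= nr & sj >= 1 & sj <= nc
  out[cbind(g$row[ok], g$col[ok])] <- m[cbind(si[ok], sj[ok])]
  out
}

#' Unify RF polarity by flipping ON-centre RFs in sign
#'
#' After the flip all centres are negative and all surrounds positive, so
#' RFs can be pooled across polarities; the summary metrics are
#' sign-symmetric and unchanged.
#'
#' @param table per-cell table with `polarity`, `g1_amp`, `g2_amp`.
#' @param rf2ds optional list of `rf2d` objects to flip alongside.
#' @return list with the updated `table` and `rf2ds`.
#' @export
flip_on_center_rfs <- function(table, rf2ds = NULL) {
  is_on <- !is.na(table$polarity) & table$polarity == "ON"
  if (!is.null(table$g1_amp)) table$g1_amp[is_on] <- -abs(table$g1_amp[is_on])
  if (!is.null(table$g2_amp)) table$g2_amp[is_on] <- abs(table$g2_amp[is_on])
  table$polarity_flipped <- is_on
  if (!is.null(rf2ds)) {
    for (i in which(is_on)) rf2ds[[i]]$values <- -rf2ds[[i]]$values
  }
  list(table = table, rf2ds = rf2ds)
}

#' Bin a metric on a 2D retinal grid
#'
#' Square bins over the given extent; bins holding fewer than `min_count`
#' cells carry no value.
#'
#' @param table aligned cell table.
#' @param metric column name.
#' @param bin_um bin edge length.
#' @param min_count minimum cells per analysed bin (default 5).
#' @param extent_um half-extent of the grid (default 1500, i.e. -1500 to
#'   1500 um in both axes).
#' @return data.frame x_center, y_center, mean, n (mean NA below count).
#' @export
bin_metric_2d <- function(table, metric, bin_um = 100, min_count = 5,
                          extent_um = 1500) {
  if (bin_um <= 0) stop("bin size must be positive")
  edges <- seq(-extent_um, extent_um, by = bin_um)
  ix <- cut(table$x_um, edges, labels = FALSE, include.lowest = TRUE)
  iy <- cut(table$y_um, edges, labels = FALSE, include.lowest = TRUE)
  ok <- !is.na(ix) & !is.na(iy) & is.finite(table[[metric]])
  key <- paste(ix[ok], iy[ok])
  vals <- split(table[[metric]][ok], key)
  ids <- strsplit(names(vals), " ")
  out <- data.frame(
    x_center = edges[as.integer(vapply(ids, `[`, "", 1))] + bin_um / 2,
    y_center = edges[as.integer(vapply(ids, `[`, "", 2))] + bin_um / 2,
    mean = vapply(vals, mean, numeric(1)),
    n = vapply(vals, length, integer(1))
  )
  out$mean[out$n < min_count] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Bin a metric along one retinal axis
#'
#' The coordinate range of the group is divided into `n_bins` equal bins;
#' each bin's mean metric is reported at the bin centre.
#'
#' @param table aligned cell table.
#' @param metric column name.
#' @param axis "y" (dorsoventral, default) or "x" (nasotemporal).
#' @param n_bins number of bins (default 6).
#' @return data.frame bin_center, mean, n.
#' @export
bin_metric_1d <- function(table, metric, axis = c("y", "x"), n_bins = 6) {
  axis <- match.arg(axis)
  coord <- if (axis == "y") table$y_um else table$x_um
  ok <- is.finite(coord) & is.finite(table[[metric]])
  coord <- coord[ok]; val <- table[[metric]][ok]
  if (length(coord) < 1) stop("no cells to bin")
  rng <- range(coord)
  if (diff(rng) == 0) stop("degenerate coordinate range")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(coord, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  data.frame(
    bin_center = (edges[-1] + edges[-length(edges)]) / 2,
    mean = vapply(seq_len(n_bins), function(b)
      if (any(idx == b)) mean(val[idx == b]) else NA_real_, numeric(1)),
    n = vapply(seq_len(n_bins), function(b) sum(idx == b), integer(1))
  )
}

#' Two-sample Kolmogorov-Smirnov test between ventral and dorsal samples
#'
#' @param ventral,dorsal numeric samples (each of length >= 2).
#' @return list with `statistic` (D), `p_value`.
#' @export
ks_dorsoventral <- function(ventral, dorsal) {
  ventral <- ventral[is.finite(ventral)]
  dorsal <- dorsal[is.finite(dorsal)]
  if (length(ventral) < 2 || length(dorsal) < 2) stop("need >= 2 values per sample")
  kt <- suppressWarnings(stats::ks.test(ventral, dorsal))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Linear-regression weights of a metric on elevation and azimuth
#'
#' Ordinary least squares of the metric on the standardized dorsoventral
#' (elevation proxy) and nasotemporal (azimuth proxy) coordinates, fitted
#' jointly; standardization makes the two weights comparable.
#'
#' @param table aligned cell table.
#' @param metric column name.
#' @return list with `beta_elevation`, `beta_azimuth`.
#' @export
regression_weights <- function(table, metric) {
  ok <- is.finite(table[[metric]]) & is.finite(table$x_um) & is.finite(table$y_um)
  if (sum(ok) < 3) stop("need >= 3 cells")
  y_std <- as.vector(scale(table$y_um[ok]))
  x_std <- as.vector(scale(table$x_um[ok]))
  if (any(!is.finite(y_std)) || any(!is.finite(x_std)))
    stop("degenerate positions")
  fit <- stats::lm(table[[metric]][ok] ~ y_std + x_std)
  co <- stats::coef(fit)
  list(beta_elevation = unname(co["y_std"]), beta_azimuth = unname(co["x_std"]))
}

#' Cluster temporal RFs with a diagonal-covariance Gaussian mixture
#'
#' Profiles are PCA-reduced (default 10 components) and Gaussian mixtures
#' with diagonal covariances are fitted for each candidate number of
#' clusters; the number of clusters is chosen at the elbow of the BIC curve
#' (argmax of the discrete second difference of BIC(k), with BIC in its
#' lower-is-better form -2 loglik + npar log n), overridable via
#' `k_override`.  Model fitting uses deterministic hierarchical
#' initialization, so results are reproducible.
#'
#' @param profiles n x t matrix (one normalized temporal profile per row).
#' @param pca_dims PCA dimensionality (default 10).
#' @param k_grid candidate cluster counts (default 1:15).
#' @param k_override force this k instead of the elbow choice.
#' @return list of class `gmm_result`: `chosen_k`, `bic` (data.frame k,
#'   bic), `membership`, `responsibilities`, `pca_dims`.
#' @export
cluster_temporal_rfs <- function(profiles, pca_dims = 10, k_grid = 1:15,
                                 k_override = NULL) {
  if (max(k_grid) >= nrow(profiles)) stop("k exceeds the sample count")
  pca_dims <- min(pca_dims, ncol(profiles), nrow(profiles) - 1)
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE,
                      rank. = pca_dims)
  z <- pc$x
  fits <- vector("list", length(k_grid))
  bics <- rep(NA_real_, length(k_grid))
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller frame
  for (i in seq_along(k_grid)) {
    fit <- tryCatch(
      mclust::Mclust(z, G = k_grid[i], modelNames = "VVI", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) next
    fits[[i]] <- fit
    bics[i] <- -2 * fit$loglik + fit$df * log(nrow(z))
  }
  ok <- which(is.finite(bics))
  if (length(ok) < 3) stop("too few successful mixture fits for an elbow")
  chosen_k <- if (!is.null(k_override)) k_override else {
    interior <- ok[ok > min(ok) & ok < max(ok)]
    curv <- vapply(interior, function(i) {
      lo <- max(ok[ok < i]); hi <- min(ok[ok > i])
      bics[lo] - 2 * bics[i] + bics[hi]
    }, numeric(1))
    k_grid[interior[which.max(curv)]]
  }
  best <- fits[[match(chosen_k, k_grid)]]
  structure(list(chosen_k = chosen_k,
                 bic = data.frame(k = k_grid, bic = bics),
                 membership = best$classification,
                 responsibilities = best$z,
                 pca_dims = pca_dims),
            class = "gmm_result")
}

#' Tiling index of a set of receptive-field ellipses
#'
#' TI = Area(union of ellipses) / sum of individual areas, computed by
#' rasterization; 1 for a perfect non-overlapping mosaic, 1/K for K
#' coincident ellipses.
#'
#' @param ellipses data.frame with columns m_x, m_y, sigma_x, sigma_y,
#'   theta (ellipse = `n_sd` standard-deviation contour).
#' @param n_sd contour level in standard deviations (default 2, matching
#'   the centre-pixel definition).
#' @param pitch_um raster pitch (default 2 um).
#' @return tiling index in (0, 1].
#' @export
tiling_index <- function(ellipses, n_sd = 2, pitch_um = 2) {
  if (nrow(ellipses) < 1) stop("need at least one ellipse")
  if (any(ellipses$sigma_x <= 0 | ellipses$sigma_y <= 0))
    stop("zero-area ellipse")
  rx <- n_sd * pmax(ellipses$sigma_x, ellipses$sigma_y)
  x_rng <- range(ellipses$m_x - rx, ellipses$m_x + rx)
  y_rng <- range(ellipses$m_y - rx, ellipses$m_y + rx)
  xs <- seq(x_rng[1], x_rng[2], by = pitch_um)
  ys <- seq(y_rng[1], y_rng[2], by = pitch_um)
  g <- expand.grid(x = xs, y = ys)
  union_mask <- rep(FALSE, nrow(g))
  area_sum <- 0
  for (i in seq_len(nrow(ellipses))) {
    par <- list(m_x = ellipses$m_x[i], m_y = ellipses$m_y[i],
                sigma_x = ellipses$sigma_x[i], sigma_y = ellipses$sigma_y[i],
                theta = if (!is.null(ellipses$theta)) ellipses$theta[i] else 0)
    inside <- ellipse_membership(par, g$x, g$y, n_sd = n_sd)
    union_mask <- union_mask | inside
    area_sum <- area_sum + sum(inside)
  }
  if (area_sum == 0) stop("zero-area rasterization; reduce pitch")
  sum(union_mask) / area_sum
}

#' Detect saccades on an eye-position trace
#'
#' Median-filters the azimuth/elevation trace, finds runs where speed
#' exceeds the minimal saccadic speed, and keeps events whose pre-to-post
#' displacement reaches the minimal amplitude and that are separated by the
#' minimal interval.
#'
#' @param eye an `eye_trace`.
#' @param median_window_s median filter window (default 0.7 s).
#' @param min_speed_dps minimal saccadic speed (default 45 deg/s).
#' @param min_amp_deg minimal amplitude (default 3 deg).
#' @param min_interval_s minimal interval between saccades (default 0.25 s).
#' @return data.frame time, amplitude, direction_deg.
#' @export
detect_saccades <- function(eye, median_window_s = 0.7, min_speed_dps = 45,
                            min_amp_deg = 3, min_interval_s = 0.25) {
  fs <- eye$sample_hz
  if (fs < 2 * min_speed_dps / min_amp_deg)
    stop("sampling rate too low for the speed threshold")
  k <- as.integer(round(median_window_s * fs))
  if (k %% 2 == 0) k <- k + 1L
  az <- stats::runmed(eye$azimuth, k)
  el <- stats::runmed(eye$elevation, k)
  sp <- c(0, sqrt(diff(az)^2 + diff(el)^2) * fs)
  fast <- sp > min_speed_dps
  if (!any(fast)) return(data.frame(time = numeric(0), amplitude = numeric(0),
                                    direction_deg = numeric(0)))
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- data.frame(start = starts[r$values], end = ends[r$values])
  pre_n <- as.integer(round(0.1 * fs))
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    i0 <- max(1L, ev$start[i] - pre_n)
    i1 <- min(length(az), ev$end[i] + pre_n)
    dx <- az[i1] - az[i0]; dy <- el[i1] - el[i0]
    amp <- sqrt(dx^2 + dy^2)
    data.frame(time = eye$time[ev$start[i]], amplitude = amp,
               direction_deg = (atan2(dy, dx) * 180 / pi) %% 360)
  })
  out <- do.call(rbind, rows)
  out <- out[out$amplitude >= min_amp_deg, , drop = FALSE]
  if (nrow(out) > 1) {
    keep <- rep(TRUE, nrow(out))
    last_t <- out$time[1]
    for (i in 2:nrow(out)) {
      if (out$time[i] - last_t < min_interval_s) keep[i] <- FALSE
      else last_t <- out$time[i]
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Saccadic orientation tuning statistics
#'
#' Amplitude-weighted circular statistics on doubled angles:
#' preferred orientation = (1/2) arg(sum_t r_t exp(2 i alpha_t)) and tuning
#' strength rbar = |sum_t r_t exp(2 i alpha_t)| / sum_t r_t, so opposite
#' directions along one axis reinforce.
#'
#' @param saccades data.frame with `amplitude` and `direction_deg`.
#' @return list with `preferred_orientation_deg` (in [0, 180)) and
#'   `tuning` (rbar in [0, 1]).
#' @export
saccade_orientation_tuning <- function(saccades) {
  r <- saccades$amplitude
  if (length(r) < 1 || sum(r) <= 0) stop("need saccades with positive amplitude")
  a <- saccades$direction_deg * pi / 180
  zc <- sum(r * exp(2i * a))
  list(preferred_orientation_deg = ((Arg(zc) / 2) * 180 / pi) %% 180,
       tuning = Mod(zc) / sum(r))
}
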