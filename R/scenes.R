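#' Synthetic panoramic scenes with elevation-dependent power
#'
#' Surrogate panoramas emulate the dominant statistical structure of the
#' mouse visual environment: spatially correlated (approximately 1/f
#' amplitude spectrum) intensity fluctuations whose local luminance and
#' contrast increase with elevation, with an abrupt multiplicative drop of
#' stimulus power below a simulated horizon.  Rows index elevation with row 1
#' at the top of the visual field; a linear row-to-degree mapping is stored
#' with each image.
#'
#' @param texture "leaves" (default) for a dead-leaves texture of occluding
#'   random discs, which carries both the approximately 1/f^2 power spectrum
#'   and the sparse edge/occlusion structure of natural scenes, or
#'   "power_law" for a Gaussian random field with power-law spectrum (same
#'   second-order statistics, no sparseness).  A weak power-law field is
#'   always mixed in so no region is exactly constant.
#' @param spectral_exponent exponent of the spatial power law of the texture
#'   (power ~ 1/f^exponent; the default 2 corresponds to a 1/f amplitude
#'   spectrum).
#' @param luminance_gradient function mapping elevation (degrees) to mean
#'   intensity (arbitrary linear light units, non-negative).
#' @param contrast_gradient function mapping elevation (degrees) to the
#'   intensity standard deviation.
#' @param horizon_step multiplicative factor in (0, 1] applied to both
#'   gradients below 0 degrees elevation; values < 1 create the sudden power
#'   drop at the horizon.
#' @param image_shape integer vector c(rows, cols).
#' @param elev_range numeric c(top, bottom) elevation in degrees covered by
#'   the image rows (top > bottom).
#' @param channel one of "UV", "green", "joint".
#' @param channel_correlation correlation between the UV and green textures;
#'   "joint" averages the two fields pixel-wise.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   images.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(texture = c("leaves", "power_law"),
                         spectral_exponent = 2,
                         luminance_gradient = default_luminance_gradient,
                         contrast_gradient = default_contrast_gradient,
                         horizon_step = 0.45,
                         image_shape = c(90L, 180L),
                         elev_range = c(45, -45),
                         channel = c("UV", "green", "joint"),
                         channel_correlation = 0.8,
                         seed = NULL) {
  channel <- match.arg(channel)
  texture <- match.arg(texture)
  if (any(image_shape <= 0)) stop("image_shape must be positive")
  if (horizon_step <= 0 || horizon_step > 1) stop("horizon_step must lie in (0, 1]")
  if (elev_range[1] <= elev_range[2]) stop("elev_range must be c(top, bottom) with top > bottom")
  structure(list(
    texture = texture,
    spectral_exponent = spectral_exponent,
    luminance_gradient = luminance_gradient,
    contrast_gradient = contrast_gradient,
    horizon_step = horizon_step,
    image_shape = as.integer(image_shape),
    elev_range = elev_range,
    channel = channel,
    channel_correlation = channel_correlation,
    seed = seed
  ), class = "scene_params")
}

#' @rdname scene_params
#' @param e elevation in degrees.
#' @export
default_luminance_gradient <- function(e) pmax(0, 4 + 0.03 * e)

#' @rdname scene_params
#' @export
default_contrast_gradient <- function(e) pmax(0.2, 1 + 0.008 * e)

#' Construct a panoramic image object
#'
#' @param intensity matrix (rows = elevation, row 1 = top of visual field).
#' @param elev_range numeric c(top, bottom) degrees.
#' @param channel spectral channel tag.
#' @return object of class `panoramic_image`.
#' @export
panoramic_image <- function(intensity, elev_range = c(45, -45),
                            channel = "UV") {
  stopifnot(is.matrix(intensity), all(is.finite(intensity)), all(intensity >= 0))
  structure(list(intensity = intensity, elev_range = elev_range,
                 channel = channel), class = "panoramic_image")
}

#' Elevation (degrees) of each image row
#'
#' Row centres are mapped linearly from the top to the bottom of the stated
#' elevation range.
#' @param img a `panoramic_image`.
#' @export
row_elevations <- function(img) {
  n <- nrow(img$intensity)
  top <- img$elev_range[1]; bot <- img$elev_range[2]
  top - (seq_len(n) - 0.5) * (top - bot) / n
}

## dead-leaves texture: occluding random discs, radius density ~ r^-3,
## i.i.d. Gaussian disc intensities; zero mean, unit sd
dead_leaves_field <- function(nr, nc, rmin = 2, rmax = 25,
                              n_discs = ceiling(0.17 * nr * nc)) {
  img <- matrix(stats::rnorm(1), nr, nc)
  u <- stats::runif(n_discs)
  rs <- sqrt(1 / ((1 - u) / rmin^2 + u / rmax^2))
  cx <- stats::runif(n_discs, 1, nc)
  cy <- stats::runif(n_discs, 1, nr)
  vals <- stats::rnorm(n_discs)
  for (k in seq_len(n_discs)) {
    ylo <- max(1, floor(cy[k] - rs[k])); yhi <- min(nr, ceiling(cy[k] + rs[k]))
    xlo <- max(1, floor(cx[k] - rs[k])); xhi <- min(nc, ceiling(cx[k] + rs[k]))
    if (ylo > yhi || xlo > xhi) next
    sy <- ylo:yhi; sx <- xlo:xhi
    m <- outer((sy - cy[k])^2, (sx - cx[k])^2, `+`) <= rs[k]^2
    blk <- img[sy, sx]; blk[m] <- vals[k]; img[sy, sx] <- blk
  }
  (img - mean(img)) / stats::sd(as.vector(img))
}

## correlated noise field with power-law spatial spectrum, zero mean, unit sd
power_law_field <- function(nr, nc, exponent) {
  white <- matrix(stats::rnorm(nr * nc), nr, nc)
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  if (nr == 1) fy <- 0
  if (nc == 1) fx <- 0
  f <- sqrt(outer(fy^2, fx^2, `+`))
  amp <- f^(-exponent / 2)
  amp[1, 1] <- 0
  field <- Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / (nr * nc)
  s <- stats::sd(as.vector(field))
  if (s == 0) field else (field - mean(field)) / s
}

#' Generate a surrogate panoramic image
#'
#' The image is a spatially correlated random texture modulated row-wise by
#' the luminance and contrast gradients; below 0 degrees elevation both are
#' additionally multiplied by `horizon_step`, producing a sudden drop in
#' stimulus power at the simulated horizon.  Negative intensities arising
#' from the correlated-noise tails are clipped at zero.
#'
#' @param params a `scene_params` object.
#' @param seed optional seed overriding `params$seed`.
#' @return a `panoramic_image`.
#' @export
generate_panorama <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "scene_params"))
  if (!is.null(seed)) set.seed(seed)
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  elev <- params$elev_range[1] -
    (seq_len(nr) - 0.5) * (params$elev_range[1] - params$elev_range[2]) / nr
  step <- ifelse(elev < 0, params$horizon_step, 1)
  lum <- params$luminance_gradient(elev) * step
  ctr <- params$contrast_gradient(elev) * step
  if (any(lum < 0) || any(ctr < 0)) stop("gradients must be non-negative")
  base_field <- function() {
    if (params$texture == "leaves") {
      f <- dead_leaves_field(nr, nc) + 0.15 * power_law_field(nr, nc, params$spectral_exponent)
      (f - mean(f)) / stats::sd(as.vector(f))
    } else {
      power_law_field(nr, nc, params$spectral_exponent)
    }
  }
  field <- base_field()
  if (params$channel %in% c("green", "joint")) {
    rho <- params$channel_correlation
    other <- base_field()
    green <- rho * field + sqrt(1 - rho^2) * other
    field <- switch(params$channel,
                    green = green,
                    joint = (field + green) / 2)
  }
  img <- lum + ctr * field
  img <- pmax(img, 0)
  panoramic_image(img, elev_range = params$elev_range, channel = params$channel)
}

#' Concatenate an upper- and a lower-visual-field image at a horizon seam
#'
#' Stacks the upper image on top of the lower one, mirroring the construction
#' of horizon-straddling stimuli from independently drawn upper- and
#' lower-field images.
#'
#' @param upper,lower `panoramic_image` objects with equal widths and channel.
#' @return a `panoramic_image` whose elevation range spans both inputs, with
#'   the seam at the boundary between the two elevation ranges.
#' @export
simulate_horizon_concat <- function(upper, lower) {
  stopifnot(inherits(upper, "panoramic_image"), inherits(lower, "panoramic_image"))
  if (ncol(upper$intensity) != ncol(lower$intensity))
    stop("images must have equal widths")
  if (!identical(upper$channel, lower$channel))
    stop("images must share the spectral channel")
  panoramic_image(rbind(upper$intensity, lower$intensity),
                  elev_range = c(upper$elev_range[1], lower$elev_range[2]),
                  channel = upper$channel)
}

#' Per-row luminance, power and SNR of a set of panoramas
#'
#' For each row (elevation), the mean intensity estimates local luminance and
#' the intensity variance (population form, pooled over all images and
#' columns) estimates local stimulus power/contrast.  The SNR is the ratio of
#' stimulus power to a constant noise power.
#'
#' @param images list of `panoramic_image` objects of identical shape.
#' @param noise_power positive scalar noise power.
#' @return object of class `elevation_profile`: a data.frame with columns
#'   `elevation`, `mean_intensity`, `mean_power`, `snr`.
#' @export
compute_power_profile <- function(images, noise_power = 1) {
  if (length(images) < 1) stop("need at least one image")
  if (noise_power <= 0) stop("noise_power must be > 0")
  dims <- vapply(images, function(im) dim(im$intensity), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all images must share the same shape")
  stack <- vapply(images, function(im) im$intensity,
                  matrix(0, dims[1, 1], dims[2, 1]))        # nr x nc x nimg
  n <- dims[2, 1] * length(images)
  m <- apply(stack, 1, mean)
  pow <- apply(stack, 1, function(v) mean((v - mean(v))^2))
  out <- data.frame(elevation = row_elevations(images[[1]]),
                    mean_intensity = m, mean_power = pow,
                    snr = pow / noise_power)
  class(out) <- c("elevation_profile", class(out))
  out
}

#' Vertical SNR asymmetry of a stimulus window
#'
#' For a window of `window_height` rows centred on row `y`, computes
#' asym(y) = (m_up - m_down) / (m_up + m_down), where m_up and m_down are the
#' sums of the SNR profile above and below the window midline.  For
#' even-height windows the midline falls between the two central rows so both
#' halves contain the same number of rows; for odd heights the central row
#' contributes half its SNR to each side.
#'
#' @param profile an `elevation_profile`.
#' @param window_height window height in rows.
#' @param y centre row index.
#' @return scalar in [-1, 1]; positive values mean more SNR above the midline
#'   (higher elevation).
#' @export
compute_snr_asymmetry <- function(profile, window_height, y) {
  snr <- profile$snr
  h <- as.integer(window_height)
  r1 <- y - (h - 1L) %/% 2L
  r2 <- r1 + h - 1L
  if (r1 < 1L || r2 > length(snr)) stop("window does not fit inside profile")
  w <- snr[r1:r2]
  if (h %% 2L == 0L) {
    m_up <- sum(w[seq_len(h %/% 2L)])
    m_down <- sum(w[(h %/% 2L + 1L):h])
  } else {
    mid <- (h + 1L) %/% 2L
    m_up <- sum(w[seq_len(mid - 1L)]) + w[mid] / 2
    m_down <- sum(w[(mid + 1L):h]) + w[mid] / 2
  }
  tot <- m_up + m_down
  if (tot <= 0) stop("zero total SNR in window; asymmetry undefined")
  (m_up - m_down) / tot
}

#' Asymmetry of the SNR profile as a function of elevation
#'
#' Evaluates [compute_snr_asymmetry()] at every centre row where the window
#' fits, the sliding-window analogue of mapping vertical SNR asymmetry across
#' the visual field.
#'
#' @inheritParams compute_snr_asymmetry
#' @return data.frame with columns `row`, `elevation`, `asym`.
#' @export
snr_asymmetry_profile <- function(profile, window_height) {
  h <- as.integer(window_height)
  lo <- 1L + (h - 1L) %/% 2L
  hi <- nrow(profile) - (h - (h - 1L) %/% 2L - 1L)
  rows <- lo:hi
  data.frame(row = rows,
             elevation = profile$elevation[rows],
             asym = vapply(rows, function(y)
               compute_snr_asymmetry(profile, h, y), numeric(1)))
}
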