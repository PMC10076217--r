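# Small fixtures shared across tests; everything is generated in code.

flat_scene_params <- function(shape = c(40, 80)) {
  scene_params(horizon_step = 1,
               luminance_gradient = function(e) rep(4, length(e)),
               contrast_gradient = function(e) rep(1, length(e)),
               image_shape = shape)
}

tiny_images <- function(n = 6, shape = c(40, 80), seed0 = 100) {
  p <- flat_scene_params(shape)
  lapply(seq_len(n), function(i) generate_panorama(p, seed = seed0 + i))
}

# brute-force per-row mean/variance over a list of panoramic images
brute_power_profile <- function(images, noise_power) {
  nr <- nrow(images[[1]]$intensity)
  mean_p <- numeric(nr); var_p <- numeric(nr)
  for (r in seq_len(nr)) {
    vals <- c()
    for (im in images) vals <- c(vals, im$intensity[r, ])
    mean_p[r] <- mean(vals)
    var_p[r] <- mean((vals - mean(vals))^2)
  }
  data.frame(mean_intensity = mean_p, mean_power = var_p,
             snr = var_p / noise_power)
}

# render a noiseless DoG rf2d on a pixel grid (um coordinates, crop centre 0)
render_dog_rf2d <- function(nr = 41, nc = 41, um_per_px = 10,
                            A1 = -1, m_x = 0, m_y = 0, s1x = 40, s1y = 40,
                            th1 = 0, A2 = 0.18, m2x = 0, m2y = 0,
                            s2x = 90, s2y = 90, th2 = 0, noise_sd = 0) {
  x <- rep((seq_len(nc) - (nc + 1) / 2) * um_per_px, each = nr)
  y <- rep((seq_len(nr) - (nr + 1) / 2) * um_per_px, times = nc)
  v <- panorf:::gauss2d_eval(x, y, A1, m_x, m_y, s1x, s1y, th1) +
    panorf:::gauss2d_eval(x, y, A2, m2x, m2y, s2x, s2y, th2)
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), sd = noise_sd)
  structure(list(values = matrix(v, nr, nc),
                 mask = matrix(TRUE, nr, nc),
                 um_per_px = um_per_px,
                 p_var = c(row = (nr + 1) %/% 2, col = (nc + 1) %/% 2),
                 t_var = 1L, cell_id = NA),
            class = "rf2d")
}
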