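#' Efficient-coding receptive-field optimization
#'
#' Model responses are r_t = phi' s_t for noisy stimulus patches s_t.  The
#' filter phi minimizes
#'
#'   L(phi) = < |r_t| >_t + lambda * sum_i phi_i^2 d(i)
#'
#' subject to ||phi|| = 1, where d(i) is the squared pixel distance between
#' pixel i and the pixel holding the peak absolute filter value, and lambda
#' sets the strength of the spatial-locality constraint.  Minimizing the mean
#' absolute response maximizes response sparsity; the locality term keeps the
#' filter compact (without it the optimum is an oriented, Gabor-like filter).
#'
#' @name efficient_coding
NULL

#' Squared pixel distances to a peak pixel
#'
#' @param edge patch edge in pixels.
#' @param peak_index flat (column-major) index of the peak pixel.
#' @return numeric vector d with d[peak_index] = 0 and
#'   d[i] = (delta row)^2 + (delta col)^2.
#' @export
locality_weights <- function(edge, peak_index) {
  edge <- as.integer(edge)
  if (peak_index < 1 || peak_index > edge^2) stop("peak_index outside grid")
  r <- (seq_len(edge^2) - 1L) %% edge + 1L
  c <- (seq_len(edge^2) - 1L) %/% edge + 1L
  pr <- (peak_index - 1L) %% edge + 1L
  pc <- (peak_index - 1L) %/% edge + 1L
  (r - pr)^2 + (c - pc)^2
}

#' Cost function of the efficient-coding model
#'
#' The locality weights are computed from the current peak-|phi| pixel (ties
#' broken by lowest flat index).  |r| is smoothed as sqrt(r^2 + eps) to avoid
#' the subgradient at zero.
#'
#' @param phi filter vector of length edge^2.
#' @param ens a normalized `patch_ensemble`.
#' @param lam locality strength lambda.
#' @param eps smoothing constant for |r|.
#' @return scalar cost L.
#' @export
rf_cost <- function(phi, ens, lam, eps = 1e-8) {
  if (nrow(ens$patches) == 0) stop("empty ensemble")
  r <- ens$patches %*% phi
  d <- locality_weights(ens$edge, which.max(abs(phi)))
  mean(sqrt(r^2 + eps)) + lam * sum(phi^2 * d)
}

#' Optimize a receptive field under the efficient-coding cost
#'
#' Full-batch projected gradient descent with a fixed step size, matching
#' the procedure whose trajectory the theory characterizes: the optimization
#' path from the noisy centered initialization is part of the model, since
#' under strong input noise the activity gradient flattens and the filter
#' retains a broad, diffuse profile within the fixed iteration budget.
#'
#' Optimization runs in the coordinate system of a PCA reduction of the
#' stimulus ensemble (the data, not the filter, are reduced): the filter is
#' constrained to the span of the leading components, its pixel
#' representation is reconstructed every step to evaluate the locality term
#' (anchored at the current peak-|phi| pixel, ties broken by lowest flat
#' index), the gradient is projected onto the tangent space of the unit
#' sphere, and the norm constraint is enforced by renormalization after each
#' step.
#'
#' The filter is initialized with Gaussian noise of variance 0.1 with the
#' central pixel set to -1; because projection onto the component basis can
#' move the peak off the central pixel, the initialization is adjusted so
#' that the reconstructed filter has exactly -1 at the central pixel before
#' renormalization, which keeps the emerging receptive field centered in the
#' patch.
#'
#' @param ens a normalized (optionally noise-corrupted) `patch_ensemble`.
#' @param lam locality strength (default 0.05).
#' @param pca a `pca_projection`; per the sweep protocol this is fitted on
#'   noiseless data (SNR sweep) or per asymmetry level (asymmetry sweep).
#' @param step fixed gradient step size (default 0.02).
#' @param max_iter iteration budget (default 3000).
#' @param tol relative cost-change tolerance; the converged flag is set when
#'   the smoothed cost changes by less than this over the final iterations.
#' @param eps smoothing constant for |r| (sqrt(r^2 + eps)).
#' @param warn emit an R warning when the budget ends before convergence
#'   (the `converged` flag records it either way).
#' @param seed integer seed for the initialization.
#' @return object of class `model_rf` with fields `phi` (unit norm), `lam`,
#'   `edge`, `init_cost`, `final_cost`, `cost_trace` (every 10th iteration),
#'   `converged`, `peak_index`, `seed`.  Non-convergence within the budget
#'   is reported via `converged = FALSE`, never silently.
#' @export
optimize_rf <- function(ens, lam = 0.05, pca = NULL,
                        step = 0.02, max_iter = 3000L, tol = 1e-6,
                        eps = 1e-8, warn = TRUE, seed = NULL) {
  stopifnot(ens$normalized)
  p <- ens$edge^2
  if (is.null(pca)) pca <- fit_pca(ens, k = min(128L, p, nrow(ens$patches)))
  C <- pca$components                      # k x p, orthonormal rows
  mu <- pca$center
  Z <- pca_project(pca, ens$patches)       # n x k
  n <- nrow(Z)
  Cmu <- as.vector(C %*% mu)
  edge <- ens$edge
  cp <- center_pixel(edge)
  dcache <- new.env(parent = emptyenv())
  dist2 <- function(peak) {
    key <- as.character(peak)
    d <- dcache[[key]]
    if (is.null(d)) d <- dcache[[key]] <- locality_weights(edge, peak)
    d
  }

  if (!is.null(seed)) set.seed(seed)
  phi0 <- stats::rnorm(p, sd = sqrt(0.1))
  phi0[cp] <- -1
  a <- as.vector(C %*% phi0)
  ## re-impose the -1 central value on the reconstructed (subspace) filter
  delta_a <- as.vector(C[, cp])
  q <- sum(delta_a^2)
  if (q > 1e-12) {
    cur <- sum(crossprod(C, a)[cp])
    a <- a + delta_a * (-1 - cur) / q
  }
  a <- a / sqrt(sum(a^2))

  cost_of <- function(a) {
    phi <- as.vector(crossprod(C, a))
    r <- as.vector(Z %*% a) + sum(phi * mu)
    mean(sqrt(r^2 + eps)) + lam * sum(phi^2 * dist2(which.max(abs(phi))))
  }
  init_cost <- cost_of(a)
  trace <- numeric(0)
  last <- init_cost
  for (it in seq_len(max_iter)) {
    phi <- as.vector(crossprod(C, a))
    r <- as.vector(Z %*% a) + sum(phi * mu)
    w <- r / sqrt(r^2 + eps)
    d <- dist2(which.max(abs(phi)))
    if (it %% 10L == 1L)
      trace <- c(trace, mean(sqrt(r^2 + eps)) + lam * sum(phi^2 * d))
    g <- as.vector(crossprod(Z, w)) / n + Cmu * mean(w) +
      2 * lam * as.vector(C %*% (d * phi))
    g <- g - a * sum(g * a)
    a <- a - step * g
    a <- a / sqrt(sum(a^2))
  }
  final_cost <- cost_of(a)
  nt <- length(trace)
  tail_drop <- if (nt >= 10) abs(trace[nt - 9L] - final_cost) else Inf
  converged <- is.finite(tail_drop) && tail_drop <= tol * max(abs(final_cost), 1e-12) * 100
  if (!converged && warn)
    warning("optimize_rf: cost still changing at the end of the iteration budget")
  phi <- as.vector(crossprod(C, a))
  phi <- phi / sqrt(sum(phi^2))
  structure(list(phi = phi, a = a, lam = lam, edge = edge,
                 init_cost = init_cost, final_cost = final_cost,
                 cost_trace = trace,
                 converged = converged,
                 peak_index = which.max(abs(phi)), seed = seed),
            class = "model_rf")
}

## flat index of the central pixel of an edge x edge grid (column-major)
center_pixel <- function(edge) {
  mid <- (edge + 1L) %/% 2L
  (mid - 1L) * edge + mid
}

#' Radius of the smallest centred circle containing 90\% of filter energy
#'
#' Energy is phi_i^2; the circle is centred on the patch centre (filters are
#' centred there by the initialization).
#'
#' @param phi filter vector.
#' @param edge patch edge.
#' @param frac energy fraction (default 0.9).
#' @return radius in pixels.
#' @export
radius90 <- function(phi, edge, frac = 0.9) {
  d <- sqrt(locality_weights(edge, center_pixel(edge)))
  e <- phi^2
  o <- order(d)
  cum <- cumsum(e[o]) / sum(e)
  d[o][which(cum >= frac)[1]]
}

#' Centre/surround metrics of a model receptive field
#'
#' Within the circle of radius `radius` (pixels) around the patch centre,
#' centre pixels are those with phi < 0 and surround pixels those with
#' phi >= 0.  Surround strength is sum of |phi| over surround pixels, centre
#' strength the analogue over centre pixels, relative surround their ratio,
#' and centre size the count of centre pixels.  Vertical asymmetry applies
#' (u - l) / (u + l) to the positive entries above and below the circle's
#' centre row (u = upper = smaller row index = higher elevation).
#'
#' @param phi filter vector (or a `model_rf`).
#' @param edge patch edge (ignored when `phi` is a `model_rf`).
#' @param radius circle radius in pixels; per the sweep protocol this is the
#'   mean of per-filter [radius90()] values across all noise levels.
#' @return list of class `model_rf_metrics`.
#' @export
characterize_model_rf <- function(phi, edge = NULL, radius) {
  if (inherits(phi, "model_rf")) { edge <- phi$edge; phi <- phi$phi }
  if (all(phi == 0)) stop("all-zero filter")
  inside <- sqrt(locality_weights(edge, center_pixel(edge))) <= radius
  v <- phi[inside]
  surround_strength <- sum(abs(v[v >= 0]))
  center_strength <- sum(abs(v[v < 0]))
  rows <- ((seq_len(edge^2) - 1L) %% edge + 1L)[inside]
  crow <- (edge + 1L) / 2
  pos <- v >= 0 & v > 0
  u <- sum(v[pos & rows < crow])
  l <- sum(v[pos & rows > crow])
  structure(list(
    radius = radius,
    surround_strength = surround_strength,
    center_strength = center_strength,
    relative_surround = if (center_strength > 0) surround_strength / center_strength else 0,
    center_size = sum(v < 0),
    vertical_asymmetry = if (u + l > 0) (u - l) / (u + l) else 0
  ), class = "model_rf_metrics")
}

#' Optimize receptive fields across an SNR or SNR-asymmetry sweep
#'
#' For `mode = "snr"` the noise variance sigma2 takes each value in `levels`
#' (with `bottom_scale = 1`) and the PCA basis is fitted once on the
#' noiseless normalized patches.  For `mode = "asym"` the bottom-half scaling
#' factor takes each value in `levels` at fixed `sigma2`, and the PCA basis
#' is fitted separately per asymmetry level (on the scaled, noiseless data).
#' Metric computation uses one shared circle radius: the mean of per-filter
#' 90\%-energy radii across all levels and seeds of the sweep.
#'
#' @param raw an unnormalized `patch_ensemble`.
#' @param mode "snr" or "asym".
#' @param levels sigma2 grid ("snr", default 1, 4, 16, 64) or bottom_scale
#'   grid ("asym", default 1, 0.8, 0.6, 0.4).
#' @param lam locality strength.
#' @param seeds integer vector; one optimization per level per seed.
#' @param sigma2 fixed noise variance for the asymmetry sweep (default 0.5,
#'   a moderate level at which antagonistic surrounds are fully formed).
#' @param k_pca number of PCA components.
#' @param ... passed to [optimize_rf()].
#' @return list with `table` (one row per level per seed, with metrics),
#'   `rfs` (list of `model_rf`), `radius` (shared metric radius).
#' @export
run_rf_sweep <- function(raw, mode = c("snr", "asym"), levels = NULL,
                         lam = 0.05, seeds = 1:3, sigma2 = 0.5,
                         k_pca = 128L, ...) {
  mode <- match.arg(mode)
  if (is.null(levels))
    levels <- if (mode == "snr") c(1, 4, 16, 64) else c(1, 0.8, 0.6, 0.4)
  if (length(levels) < 1) stop("empty level grid")
  edge <- raw$edge
  k_pca <- min(k_pca, edge^2, nrow(raw$patches))
  rfs <- list(); rows <- list(); i <- 0L
  if (mode == "snr") {
    clean <- normalize_patches(raw)
    pca <- fit_pca(clean, k = k_pca)
  }
  for (lev in levels) {
    if (mode == "asym") {
      scaled <- corrupt_patches(raw, noise_spec(0, bottom_scale = lev),
                                order = "normalize_first")
      pca <- fit_pca(scaled, k = k_pca)
    }
    for (sd_ in seeds) {
      i <- i + 1L
      ns <- if (mode == "snr") noise_spec(lev, 1, seed = sd_ * 1000L + i)
            else noise_spec(sigma2, lev, seed = sd_ * 1000L + i)
      ord <- if (mode == "snr") "noise_first" else "normalize_first"
      ens <- corrupt_patches(raw, ns, order = ord)
      rf <- optimize_rf(ens, lam = lam, pca = pca, seed = sd_, warn = FALSE, ...)
      rf$noise <- ns
      rfs[[i]] <- rf
      rows[[i]] <- data.frame(mode = mode, level = lev, seed = sd_, lam = lam,
                              final_cost = rf$final_cost,
                              converged = rf$converged,
                              radius90 = radius90(rf$phi, edge))
    }
  }
  tab <- do.call(rbind, rows)
  rad <- mean(tab$radius90)
  mets <- lapply(rfs, function(rf) characterize_model_rf(rf, radius = rad))
  tab$surround_strength <- vapply(mets, `[[`, numeric(1), "surround_strength")
  tab$center_strength <- vapply(mets, `[[`, numeric(1), "center_strength")
  tab$relative_surround <- vapply(mets, `[[`, numeric(1), "relative_surround")
  tab$center_size <- vapply(mets, `[[`, numeric(1), "center_size")
  tab$vertical_asymmetry <- vapply(mets, `[[`, numeric(1), "vertical_asymmetry")
  list(table = tab, rfs = rfs, radius = rad)
}
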