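#' Patch ensembles for receptive-field optimization
#'
#' A patch ensemble holds N flattened square image patches (one per row).
#' Patches are vectorized column-major from the edge x edge pixel grid, so
#' pixel (row r, col c) maps to index (c - 1) * edge + r; row index increases
#' downward in the visual field.
#'
#' @param patches N x edge^2 numeric matrix.
#' @param edge patch edge length in pixels.
#' @param normalized logical; TRUE when each patch has zero mean and unit
#'   (population) variance.
#' @param channel spectral channel tag.
#' @param positions optional data.frame logging the source image / row / col
#'   of each patch.
#' @return object of class `patch_ensemble`.
#' @export
patch_ensemble <- function(patches, edge, normalized = FALSE,
                           channel = "UV", positions = NULL) {
  stopifnot(is.matrix(patches), ncol(patches) == edge^2)
  structure(list(patches = patches, edge = as.integer(edge),
                 normalized = normalized, channel = channel,
                 positions = positions), class = "patch_ensemble")
}

#' Sample square patches uniformly from a set of panoramas
#'
#' Source image and window position are drawn uniformly over all admissible
#' top-left positions, so the elevation distribution of sampled patches is
#' uniform.
#'
#' @param images list of `panoramic_image` objects.
#' @param n number of patches.
#' @param edge patch edge in pixels (default 27).
#' @param seed integer seed.
#' @return a `patch_ensemble` (unnormalized) with a `positions` log.
#' @export
sample_patches <- function(images, n, edge = 27L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  edge <- as.integer(edge)
  dims <- vapply(images, function(im) dim(im$intensity), integer(2))
  if (any(dims[1, ] < edge) || any(dims[2, ] < edge))
    stop("patch edge larger than an image")
  if (n == 0) {
    return(patch_ensemble(matrix(0, 0, edge^2), edge,
                          channel = images[[1]]$channel,
                          positions = data.frame(image = integer(0),
                                                 row = integer(0),
                                                 col = integer(0))))
  }
  img_id <- sample.int(length(images), n, replace = TRUE)
  rows <- integer(n); cols <- integer(n)
  out <- matrix(0, n, edge^2)
  for (k in seq_len(n)) {
    im <- images[[img_id[k]]]$intensity
    r0 <- sample.int(nrow(im) - edge + 1L, 1L)
    c0 <- sample.int(ncol(im) - edge + 1L, 1L)
    rows[k] <- r0; cols[k] <- c0
    out[k, ] <- as.vector(im[r0:(r0 + edge - 1L), c0:(c0 + edge - 1L)])
  }
  patch_ensemble(out, edge, channel = images[[1]]$channel,
                 positions = data.frame(image = img_id, row = rows, col = cols))
}

#' Normalize each patch to zero mean and unit variance
#'
#' Uses the population variance (divisor N), so the four-pixel patch
#' (0, 0, 2, 2) maps to (-1, -1, 1, 1).
#'
#' @param ens a `patch_ensemble`.
#' @param on_constant what to do with zero-variance patches: "error" or
#'   "drop".
#' @return a normalized `patch_ensemble`.
#' @export
normalize_patches <- function(ens, on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  x <- ens$patches
  mu <- rowMeans(x)
  xc <- x - mu
  sdev <- sqrt(rowMeans(xc^2))
  bad <- sdev == 0
  if (any(bad)) {
    if (on_constant == "error") stop("constant patch cannot be normalized")
    xc <- xc[!bad, , drop = FALSE]
    sdev <- sdev[!bad]
    ens$positions <- ens$positions[!bad, , drop = FALSE]
  }
  ens$patches <- xc / sdev
  ens$normalized <- TRUE
  ens
}

#' Noise specification for simulated photoreceptor output
#'
#' @param sigma2 additive Gaussian noise variance (>= 0).
#' @param bottom_scale factor in (0, 1] multiplying the bottom half of each
#'   patch before normalization; values < 1 create vertically asymmetric SNR.
#' @param seed integer seed for the noise draw.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(sigma2 = 0, bottom_scale = 1, seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (bottom_scale <= 0 || bottom_scale > 1) stop("bottom_scale must lie in (0, 1]")
  structure(list(sigma2 = sigma2, bottom_scale = bottom_scale, seed = seed),
            class = "noise_spec")
}

#' Scale, normalize and corrupt patches
#'
#' Applies the vertical SNR manipulation and the photoreceptor noise model.
#' The bottom half of each patch grid is first multiplied by `bottom_scale`
#' (scaling always precedes normalization).  The order of the remaining two
#' steps follows the protocol of the sweep being simulated:
#'
#' * `order = "noise_first"` (SNR sweep): Gaussian noise of variance
#'   `sigma2` (on the scale of the raw, ensemble-standardized patches) is
#'   added to the scaled patches, and each noisy patch is then normalized to
#'   zero mean and unit variance, i.e. the patches are normalized with the
#'   noise included.  Raising `sigma2` therefore shrinks the signal content
#'   of a unit-variance stimulus.
#' * `order = "normalize_first"` (asymmetry sweep): each scaled patch is
#'   normalized first and noise of constant variance `sigma2` is added
#'   afterwards.
#'
#' Before either path, raw patches are standardized by the ensemble-pooled
#' root-mean-square contrast so that `sigma2 = 1` always means noise power
#' equal to the mean signal power.
#'
#' @param ens an unnormalized `patch_ensemble` (required when
#'   `bottom_scale < 1` or `order = "noise_first"`); an already-normalized
#'   ensemble is accepted for `order = "normalize_first"` with
#'   `bottom_scale == 1`.
#' @param noise a `noise_spec`.
#' @param order noise/normalization order, see above.
#' @return a normalized (plus additive noise when `order =
#'   "normalize_first"`), noise-corrupted `patch_ensemble`.
#' @export
corrupt_patches <- function(ens, noise,
                            order = c("noise_first", "normalize_first")) {
  stopifnot(inherits(ens, "patch_ensemble"), inherits(noise, "noise_spec"))
  order <- match.arg(order)
  if (ens$normalized && (noise$bottom_scale < 1 || order == "noise_first"))
    stop("this corruption protocol requires unnormalized patches")
  edge <- ens$edge
  if (!ens$normalized) {
    xc <- ens$patches - rowMeans(ens$patches)
    pooled <- sqrt(mean(xc^2))
    if (pooled > 0) ens$patches <- ens$patches / pooled
  }
  if (noise$bottom_scale < 1) {
    bottom_rows <- (edge %/% 2L + 1L):edge
    idx <- as.vector(outer(bottom_rows, (seq_len(edge) - 1L) * edge, `+`))
    ens$patches[, idx] <- ens$patches[, idx] * noise$bottom_scale
  }
  if (!is.null(noise$seed)) set.seed(noise$seed)
  if (order == "noise_first") {
    if (noise$sigma2 > 0)
      ens$patches <- ens$patches +
        matrix(stats::rnorm(length(ens$patches), sd = sqrt(noise$sigma2)),
               nrow(ens$patches))
    ens$normalized <- FALSE
    ens <- normalize_patches(ens)
  } else {
    if (!ens$normalized) ens <- normalize_patches(ens)
    if (noise$sigma2 > 0)
      ens$patches <- ens$patches +
        matrix(stats::rnorm(length(ens$patches), sd = sqrt(noise$sigma2)),
               nrow(ens$patches))
  }
  ens
}

#' Principal-component projection of a patch ensemble
#'
#' Plain (unwhitened) PCA of the centred patch matrix; the data, not the
#' filter, are reduced in dimension during optimization.
#'
#' @param ens a `patch_ensemble`.
#' @param k number of components (default 128).
#' @return object of class `pca_projection` with fields `components`
#'   (k x edge^2, orthonormal rows), `center`, `sdev`.
#' @export
fit_pca <- function(ens, k = 128L) {
  x <- ens$patches
  k <- as.integer(k)
  if (k > ncol(x)) stop("k exceeds patch dimension")
  if (nrow(x) < k) stop("need at least k patches")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  structure(list(components = t(pc$rotation[, seq_len(k), drop = FALSE]),
                 center = pc$center,
                 sdev = pc$sdev[seq_len(k)],
                 n_components = k),
            class = "pca_projection")
}

#' Project patches into PCA coordinates
#' @param pca a `pca_projection`.
#' @param x patch matrix (N x edge^2).
#' @return N x k score matrix.
#' @export
pca_project <- function(pca, x) {
  sweep(x, 2L, pca$center) %*% t(pca$components)
}

#' Reconstruct patches from PCA coordinates
#' @param pca a `pca_projection`.
#' @param z N x k score matrix.
#' @return N x edge^2 reconstruction.
#' @export
pca_backproject <- function(pca, z) {
  sweep(z %*% pca$components, 2L, pca$center, `+`)
}
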