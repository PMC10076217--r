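#' Receptive-field estimation from shifting white-noise responses
#'
#' The spatiotemporal RF of neuron i at latency tau is the calcium-triggered
#' average
#'
#'   RF(i,x,y,tau) = sum_t s(x,y,t - tau) r(i,t)
#'                   - sum_t s(x,y,t - tau) rbar(t)
#'
#' where r(i,t) are deconvolved responses, s is the binary stimulus
#' (zero-order hold: the frame shown is the last frame before t - tau), and
#' the second, population term couples the stimulus with the mean response
#' over neurons, subtracting the residual stimulus distribution and slow
#' signal drifts common to all neurons of a recording.
#'
#' @name rf_mapping
NULL

#' Construct a spatiotemporal RF container
#'
#' @param values h x w x n_lat array.
#' @param latency latency grid (s).
#' @param um_per_px pixel size.
#' @param mask logical h x w matrix; FALSE marks padded/invalid pixels.
#' @param cell_id optional id.
#' @export
st_rf <- function(values, latency, um_per_px, mask = NULL, cell_id = NA) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(latency))
  if (is.null(mask)) mask <- matrix(TRUE, dim(values)[1], dim(values)[2])
  structure(list(values = values, latency = latency, um_per_px = um_per_px,
                 mask = mask, cell_id = cell_id, normalized = FALSE),
            class = "st_rf")
}

#' Detrend fluorescence traces to dF/F with a sliding-percentile baseline
#'
#' The baseline at each time point is the given percentile of the
#' fluorescence in a sliding window centred on that point (clipped at the
#' trace edges); dF/F = (F - baseline) / baseline.
#'
#' @param f numeric vector or matrix (traces in rows).
#' @param sample_hz sampling rate.
#' @param window_s window length (default 20 s).
#' @param percentile baseline percentile (default 8).
#' @return dF/F of the same shape; positions with non-positive baseline are
#'   NA and flagged via the "degenerate" attribute.
#' @export
compute_dff <- function(f, sample_hz, window_s = 20, percentile = 8) {
  one <- function(v) {
    n <- length(v)
    half <- max(1L, as.integer(round(window_s * sample_hz / 2)))
    if (2 * half + 1 > n) stop("window longer than trace")
    base <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      stats::quantile(v[lo:hi], percentile / 100, names = FALSE, type = 7)
    }, numeric(1))
    out <- (v - base) / base
    out[base <= 0] <- NA_real_
    out
  }
  if (is.matrix(f)) {
    res <- t(apply(f, 1, one))
  } else res <- one(f)
  attr(res, "degenerate") <- any(is.na(res))
  res
}

#' Estimate spatiotemporal RFs by calcium-triggered averaging
#'
#' @param traces n_neurons x n_samples matrix of non-negative deconvolved
#'   responses.
#' @param stim a `shifting_noise_stimulus`.
#' @param sample_hz trace sampling rate.
#' @param latencies latency grid in seconds (default -0.5 to 1.5 s in
#'   0.025 s steps).
#' @param pop_term population term: "mean" (default; stimulus triggered on
#'   the mean response over neurons, including neuron i), "sum" (raw sum
#'   over neurons) or "none".
#' @param frames optional pre-rendered stimulus matrix.
#' @return list of `st_rf` objects (unnormalized), one per neuron.
#' @export
estimate_rf <- function(traces, stim, sample_hz,
                        latencies = seq(-0.5, 1.5, by = 0.025),
                        pop_term = c("mean", "sum", "none"),
                        frames = NULL) {
  pop_term <- match.arg(pop_term)
  if (!is.matrix(traces)) traces <- matrix(traces, nrow = 1)
  n <- nrow(traces); S <- ncol(traces)
  t_samp <- seq_len(S) / sample_hz
  max_lag_frames <- stim$n_frames
  if (max(abs(latencies)) >= stim$duration_s)
    stop("latency grid exceeds the recording span")
  if (is.null(frames)) frames <- render_stimulus(stim)
  p <- ncol(frames)
  rfs <- array(0, dim = c(p, n, length(latencies)))
  pop <- switch(pop_term,
                mean = colMeans(traces),
                sum = colSums(traces),
                none = NULL)
  for (li in seq_along(latencies)) {
    f_idx <- floor((t_samp - latencies[li]) * stim$update_hz) + 1L
    ok <- f_idx >= 1L & f_idx <= max_lag_frames
    if (!any(ok)) next
    fi <- f_idx[ok]
    ## accumulate trace weight per frame
    w <- rowsum(t(traces[, ok, drop = FALSE]), group = fi)    # uf x n
    uf <- as.integer(rownames(w))
    wfull <- matrix(0, stim$n_frames, n)
    wfull[uf, ] <- w
    if (!is.null(pop)) {
      wp <- numeric(stim$n_frames)
      wp[uf] <- rowsum(pop[ok], group = fi)
      wfull <- wfull - wp                # recycles column-wise
    }
    rfs[, , li] <- crossprod(frames, wfull)                   # p x n
  }
  lapply(seq_len(n), function(i) {
    st_rf(array(rfs[, i, ], dim = c(stim$h_px, stim$w_px, length(latencies))),
          latency = latencies, um_per_px = stim$um_per_px, cell_id = i)
  })
}

#' Normalize an RF to the [-1, 1] convention
#'
#' Subtracts the mean of the RF over latencies tau < 0 (acausal baseline)
#' and divides by the maximum absolute value of the entire RF, so the
#' result is invariant to positive affine rescaling of the input.
#'
#' @param rf an `st_rf` whose latency grid contains tau < 0 samples.
#' @export
normalize_rf <- function(rf) {
  pre <- rf$latency < 0
  if (!any(pre)) stop("latency grid has no tau < 0 samples")
  base <- mean(rf$values[, , pre, drop = FALSE][rep(rf$mask, sum(pre))])
  v <- rf$values - base
  m <- max(abs(v[rep(rf$mask, length(rf$latency))]))
  if (m == 0) stop("all-zero RF cannot be normalized")
  rf$values <- v / m
  rf$normalized <- TRUE
  rf
}

#' Locate an RF in space and time by variance
#'
#' P_var is the pixel with the largest variance of its time course; T_var
#' the latency with the largest spatial variance.  Ties break at the lowest
#' flat (column-major) index.
#'
#' @param rf an `st_rf`.
#' @return list with `p_var` (c(row, col)), `t_var` (latency index),
#'   `t_var_s` (latency in seconds).
#' @export
locate_rf <- function(rf) {
  d <- dim(rf$values)
  flat <- matrix(rf$values, d[1] * d[2], d[3])
  flat[!rf$mask, ] <- NA
  pv <- apply(flat, 1, function(v) if (all(is.na(v))) -Inf else stats::var(v))
  if (all(!is.finite(pv)) || max(pv, na.rm = TRUE) == 0)
    stop("constant RF has no variance peak")
  p_flat <- which.max(pv)
  tv <- apply(flat, 2, function(v) stats::var(v, na.rm = TRUE))
  t_var <- which.max(tv)
  list(p_var = c(row = (p_flat - 1L) %% d[1] + 1L,
                 col = (p_flat - 1L) %/% d[1] + 1L),
       t_var = t_var, t_var_s = rf$latency[t_var])
}

#' Crop an RF to a square window centred on P_var
#'
#' Out-of-field regions are zero-padded and masked; masked pixels are
#' excluded from downstream statistics.
#'
#' @param rf an `st_rf`.
#' @param p_var centre pixel c(row, col).
#' @param edge_um crop edge (default 1000 um = 1 mm).
#' @export
crop_rf <- function(rf, p_var, edge_um = 1000) {
  d <- dim(rf$values)
  half <- as.integer(round(edge_um / rf$um_per_px / 2))
  rows <- (p_var[1] - half):(p_var[1] + half)
  cols <- (p_var[2] - half):(p_var[2] + half)
  nr <- length(rows); nc <- length(cols)
  out <- array(0, dim = c(nr, nc, d[3]))
  mask <- matrix(FALSE, nr, nc)
  rok <- rows >= 1 & rows <= d[1]
  cok <- cols >= 1 & cols <= d[2]
  out[rok, cok, ] <- rf$values[rows[rok], cols[cok], , drop = FALSE]
  mask[rok, cok] <- rf$mask[rows[rok], cols[cok]]
  res <- st_rf(out, rf$latency, rf$um_per_px, mask = mask, cell_id = rf$cell_id)
  res$normalized <- rf$normalized
  res$origin_px <- c(row = rows[1], col = cols[1])
  res
}

#' Peak-to-noise SNR of an RF in decibels
#'
#' snr_db = 10 log10(peak^2 / noise power); the peak is the maximum |value|
#' of the RF and the noise power is the mean squared value over all pixels
#' farther than `exclusion_radius_um` from P_var, across all latencies.
#'
#' @param rf an `st_rf`.
#' @param p_var centre pixel c(row, col).
#' @param exclusion_radius_um far-region threshold (default 500 um).
#' @param cap value returned (with a "capped" attribute) when the far
#'   region is exactly zero.
#' @export
compute_rf_snr <- function(rf, p_var, exclusion_radius_um = 500, cap = 200) {
  d <- dim(rf$values)
  rr <- (seq_len(d[1]) - p_var[1])
  cc <- (seq_len(d[2]) - p_var[2])
  dist_um <- sqrt(outer(rr^2, cc^2, `+`)) * rf$um_per_px
  far <- dist_um > exclusion_radius_um & rf$mask
  if (!any(far)) stop("no pixels beyond the exclusion radius")
  varr <- matrix(rf$values, d[1] * d[2], d[3])
  noise_power <- mean(varr[as.vector(far), ]^2)
  peak <- max(abs(rf$values[rep(rf$mask, d[3])]))
  if (noise_power == 0) {
    out <- cap
    attr(out, "capped") <- TRUE
    return(out)
  }
  10 * log10(peak^2 / noise_power)
}

#' Filter RFs by SNR threshold
#'
#' Retains RFs with SNR strictly above the threshold.
#'
#' @param rfs list of `st_rf` objects.
#' @param snr_db numeric vector of their SNRs.
#' @param threshold_db threshold (default 15 dB).
#' @return list with `kept` (the surviving subset), `keep` (logical
#'   vector), `report` (counts).
#' @export
filter_rfs <- function(rfs, snr_db, threshold_db = 15) {
  keep <- snr_db > threshold_db
  list(kept = rfs[keep], keep = keep,
       report = data.frame(total = length(rfs), kept = sum(keep),
                           threshold_db = threshold_db))
}

#' Map a simulated recording end to end
#'
#' Estimates RFs in neuron chunks (bounded memory), normalizes, locates,
#' scores and crops them, and applies the SNR filter.
#'
#' @param rec a `simulated_recording`.
#' @param latencies latency grid (default -0.2 to 0.6 s; spans the
#'   simulator's kernel support plus an acausal baseline).
#' @param crop_um crop edge.
#' @param threshold_db SNR threshold.
#' @param chunk neurons per chunk.
#' @param pop_term passed to [estimate_rf()].
#' @param exclusion_radius_um far-region threshold for the SNR estimate;
#'   keep it below half the field size so a far region exists.
#' @return list with `rfs` (cropped, normalized `st_rf`s for all neurons),
#'   `quality` (data.frame cell_id, p_var, t_var_s, snr_db, kept).
#' @export
map_recording <- function(rec, latencies = seq(-0.2, 0.6, by = 0.025),
                          crop_um = 600, threshold_db = 15, chunk = 50L,
                          pop_term = "mean", exclusion_radius_um = 500) {
  frames <- render_stimulus(rec$stim)
  n <- nrow(rec$traces)
  ## the population term must reflect the whole recording, not the chunk
  pop <- colMeans(rec$traces)
  out <- vector("list", n)
  qual <- vector("list", n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(n, lo + chunk - 1L)
    sub <- rec$traces[lo:hi, , drop = FALSE]
    ## estimate with explicit population reference: subtract via pop_term
    ## by temporarily appending the population-mean as weights
    rfs <- estimate_rf_with_pop(sub, rec$stim, rec$sample_hz, latencies,
                                pop = if (identical(pop_term, "none")) NULL else
                                  if (identical(pop_term, "sum")) pop * n else pop,
                                frames = frames)
    for (j in seq_along(rfs)) {
      i <- lo + j - 1L
      rf <- rfs[[j]]
      rf$cell_id <- i
      rf <- normalize_rf(rf)
      loc <- locate_rf(rf)
      snr <- compute_rf_snr(rf, loc$p_var, exclusion_radius_um = exclusion_radius_um)
      crop <- crop_rf(rf, loc$p_var, edge_um = crop_um)
      crop$snr_db <- as.numeric(snr)
      crop$p_var_field <- loc$p_var
      out[[i]] <- crop
      qual[[i]] <- data.frame(cell_id = i,
                              p_row = loc$p_var[1], p_col = loc$p_var[2],
                              t_var_s = loc$t_var_s,
                              snr_db = as.numeric(snr))
    }
  }
  quality <- do.call(rbind, qual)
  quality$kept <- quality$snr_db > threshold_db
  list(rfs = out, quality = quality)
}

## internal: estimate_rf against an externally supplied population trace
estimate_rf_with_pop <- function(traces, stim, sample_hz, latencies, pop,
                                 frames) {
  n <- nrow(traces); S <- ncol(traces)
  t_samp <- seq_len(S) / sample_hz
  p <- ncol(frames)
  rfs <- array(0, dim = c(p, n, length(latencies)))
  for (li in seq_along(latencies)) {
    f_idx <- floor((t_samp - latencies[li]) * stim$update_hz) + 1L
    ok <- f_idx >= 1L & f_idx <= stim$n_frames
    if (!any(ok)) next
    fi <- f_idx[ok]
    w <- rowsum(t(traces[, ok, drop = FALSE]), group = fi)
    uf <- as.integer(rownames(w))
    wfull <- matrix(0, stim$n_frames, n)
    wfull[uf, ] <- w
    if (!is.null(pop)) {
      wp <- numeric(stim$n_frames)
      wp[uf] <- rowsum(pop[ok], group = fi)
      wfull <- wfull - wp
    }
    rfs[, , li] <- crossprod(frames, wfull)
  }
  lapply(seq_len(n), function(i) {
    st_rf(array(rfs[, i, ], dim = c(stim$h_px, stim$w_px, length(latencies))),
          latency = latencies, um_per_px = stim$um_per_px, cell_id = i)
  })
}
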