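# Spatial Gaussian smoothing and zero-phase Butterworth band-pass filtering.
#
# No signal-processing package ships with this stack, so the band-pass is
# designed here from the analog Butterworth prototype (lowpass-to-bandpass
# transform, bilinear mapping with prewarping) and applied forward-backward
# with odd-symmetric padding and steady-state initial conditions.

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Spatially smooth a volume with a Gaussian kernel
#'
#' Frame-wise separable convolution with an isotropic-in-mm Gaussian;
#' anisotropic voxels get a per-axis sigma of
#' `fwhm / (voxel_size * 2 sqrt(2 ln 2))`. Reflective boundaries conserve
#' total intensity. `fwhm_mm = 0` is the identity.
#'
#' @param vol a [volume4d].
#' @param fwhm_mm kernel full width at half maximum in mm.
#' @return a smoothed [volume4d].
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "volume4d"))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("`fwhm_mm` must be a nonnegative number")
  if (fwhm_mm == 0) return(vol)
  sigma <- fwhm_mm / (vol$voxel_size_mm * 2 * sqrt(2 * log(2)))
  d <- dim(vol$data)
  out <- smooth4d_cpp(as.numeric(vol$data), as.integer(d),
                      gaussian_kernel_1d(sigma[1]),
                      gaussian_kernel_1d(sigma[2]),
                      gaussian_kernel_1d(sigma[3]))
  volume4d(array(out, d), vol$voxel_size_mm, vol$tr_s, vol$affine)
}

# --- Butterworth band-pass design --------------------------------------------

# Real polynomial coefficients from complex roots (descending powers,
# leading 1).
poly_from_roots <- function(r) {
  p <- 1
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  re <- Re(p)
  stopifnot(max(abs(Im(p))) < 1e-8)
  re
}

#' Design a digital band-pass Butterworth filter
#'
#' Analog Butterworth prototype of order `order/2`, lowpass-to-bandpass
#' transformed (which doubles the pole count to `order`), bilinearly mapped
#' with edge prewarping. Gain is normalized to 1 at the geometric band
#' centre.
#'
#' @param low_hz,high_hz band edges in Hz, 0 < low < high < Nyquist.
#' @param fs sampling rate in Hz.
#' @param order total band-pass order (even; default 4, i.e. a 2nd-order
#'   prototype per edge).
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(low_hz, high_hz, fs, order = 4L) {
  if (order < 2L || order %% 2L != 0L) stop("`order` must be a positive even integer")
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2))
    stop("band edges must satisfy 0 < low < high < Nyquist")
  n <- order / 2L
  # analog prototype poles (Butterworth, unit cutoff)
  k <- seq_len(n)
  theta <- pi * (2 * k - 1) / (2 * n) + pi / 2
  p_proto <- complex(modulus = 1, argument = theta)
  # prewarped analog band edges
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # lowpass -> bandpass: each prototype pole p maps to two poles
  pb <- bw * p_proto / 2
  disc <- sqrt(pb^2 - w0^2 + 0i)
  poles_a <- c(pb + disc, pb - disc)
  # bilinear transform
  fs2 <- 2 * fs
  poles_z <- (fs2 + poles_a) / (fs2 - poles_a)
  zeros_z <- c(rep(1, n), rep(-1, n))
  b <- poly_from_roots(zeros_z)
  a <- poly_from_roots(poles_z)
  # unit gain at the digital image of the analog band centre
  wc <- 2 * atan(w0 / fs2)
  z <- exp(1i * wc)
  h <- sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1))
  list(b = b / abs(h), a = a)
}

#' One-pass frequency response of a digital filter
#' @param filt list with `b`, `a` as from [butter_bandpass].
#' @param f_hz frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return complex response at each frequency.
#' @export
freq_response <- function(filt, f_hz, fs) {
  vapply(f_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    sum(filt$b * z^(seq_along(filt$b) - 1)) /
      sum(filt$a * z^(seq_along(filt$a) - 1))
  }, complex(1))
}

# IIR filtering of each column of x (direct form II transposed), vectorized
# across columns. zi: initial state scaled per column (matrix) or NULL.
iir_filter_cols <- function(b, a, x, zi = NULL) {
  nord <- length(a) - 1L
  nt <- nrow(x); nc <- ncol(x)
  z <- if (is.null(zi)) matrix(0, nord, nc) else zi
  y <- matrix(0, nt, nc)
  for (t in seq_len(nt)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    for (s in seq_len(nord)) {
      znext <- if (s < nord) z[s + 1, ] else 0
      z[s, ] <- b[s + 1] * xt + znext - a[s + 1] * yt
    }
    y[t, ] <- yt
  }
  y
}

# Steady-state initial state per unit input (lfilter_zi analog).
filter_zi <- function(b, a) {
  nord <- length(a) - 1L
  A <- matrix(0, nord, nord)
  A[, 1] <- -a[-1]
  if (nord > 1L) A[seq_len(nord - 1L), 2:nord] <- diag(nord - 1L)
  B <- b[-1] - a[-1] * b[1]
  solve(diag(nord) - A, B)
}

# Zero-phase forward-backward filtering of columns with odd-symmetric padding.
filtfilt_cols <- function(b, a, x) {
  nt <- nrow(x)
  nord <- length(a) - 1L
  pad <- min(nt - 1L, max(3L * nord, 12L))
  top <- 2 * matrix(x[1, ], pad, ncol(x), byrow = TRUE) -
    x[seq(pad + 1, 2), , drop = FALSE]
  bot <- 2 * matrix(x[nt, ], pad, ncol(x), byrow = TRUE) -
    x[seq(nt - 1, nt - pad), , drop = FALSE]
  ext <- rbind(top, x, bot)
  zi <- filter_zi(b, a)
  y <- iir_filter_cols(b, a, ext, zi = outer(zi, ext[1, ]))
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y <- iir_filter_cols(b, a, y, zi = outer(zi, y[1, ]))
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y[seq(pad + 1, pad + nt), , drop = FALSE]
}

#' Temporal band-pass filter a 4D volume
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass to every
#' voxel time course; the per-voxel mean is removed before filtering and
#' restored afterwards, so DC is preserved as the mean and all other
#' out-of-band fluctuation is suppressed. Effective attenuation is the
#' squared one-pass magnitude response.
#'
#' @param vol a [volume4d] (TR defines the sampling rate).
#' @param low_hz,high_hz passband edges in Hz (defaults 0.01 and 0.1).
#' @param order total band-pass order (default 4).
#' @param zero_phase apply forward-backward (default) or single-pass.
#' @return a filtered [volume4d].
#' @export
bandpass <- function(vol, low_hz = 0.01, high_hz = 0.1, order = 4L,
                     zero_phase = TRUE) {
  stopifnot(inherits(vol, "volume4d"))
  nt <- n_frames(vol)
  if (nt < 3L * order)
    stop(sprintf("time series too short: need at least %d frames, have %d",
                 3L * order, nt))
  fs <- 1 / vol$tr_s
  filt <- butter_bandpass(low_hz, high_hz, fs, order)
  x <- vol_to_matrix(vol)
  mu <- colMeans(x)
  x <- sweep(x, 2, mu)
  y <- if (zero_phase) filtfilt_cols(filt$b, filt$a, x)
       else iir_filter_cols(filt$b, filt$a, x,
                            zi = outer(filter_zi(filt$b, filt$a), x[1, ]))
  y <- sweep(y, 2, mu, "+")
  matrix_to_vol(y, vol)
}

#' Band-pass filter the columns of a plain matrix
#'
#' Same filter as [bandpass] for non-image time series (e.g. IC time
#' courses).
#'
#' @param x T x K numeric matrix.
#' @param tr_s sampling interval in seconds.
#' @param low_hz,high_hz,order as in [bandpass].
#' @return filtered matrix of the same shape.
#' @export
bandpass_matrix <- function(x, tr_s, low_hz = 0.01, high_hz = 0.1,
                            order = 4L) {
  filt <- butter_bandpass(low_hz, high_hz, 1 / tr_s, order)
  mu <- colMeans(x)
  sweep(filtfilt_cols(filt$b, filt$a, sweep(x, 2, mu)), 2, mu, "+")
}
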