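# Spatial and temporal signal-to-noise quality-control maps.

#' Spatial and temporal SNR maps
#'
#' sSNR is computed voxelwise from the 10th frame (1-based) as the frame
#' value divided by the standard deviation of the out-of-brain noise pool:
#' two 5 x 5 voxel squares at the left and right top corners of every slice.
#' tSNR is each voxel's temporal mean divided by its temporal standard
#' deviation; voxels with constant time courses are flagged infinite and
#' excluded from the within-brain mean.
#'
#' @param vol a raw [volume4d] with at least 10 frames.
#' @param brain logical 3D brain mask.
#' @param cube corner square edge length in voxels (default 5).
#' @param frame frame used for sSNR (default 10, 1-based).
#' @return object of class `snr_maps`: `ssnr`, `tsnr` (3D arrays),
#'   `mean_ssnr`, `mean_tsnr` (means over brain voxels), `noise_sd`,
#'   `n_noise_voxels`.
#' @export
snr_maps <- function(vol, brain, cube = 5L, frame = 10L) {
  stopifnot(inherits(vol, "volume4d"))
  d <- dim(vol$data)
  if (d[4] < frame) stop("need at least ", frame, " frames")
  if (d[1] < 2L * cube || d[2] < cube)
    stop("grid too small for ", cube, "x", cube, " corner noise squares")
  f <- array(vol$data[, , , frame], d[1:3])
  corners <- array(FALSE, d[1:3])
  ytop <- seq(d[2] - cube + 1L, d[2])
  corners[seq_len(cube), ytop, ] <- TRUE                   # left top
  corners[seq(d[1] - cube + 1L, d[1]), ytop, ] <- TRUE     # right top
  noise <- f[corners]
  noise_sd <- stats::sd(noise)
  if (!is.finite(noise_sd) || noise_sd == 0)
    stop("corner noise pool has zero standard deviation")
  ssnr <- f / noise_sd

  X <- vol_to_matrix(vol)          # T x V
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  tsnr_vec <- ifelse(sdv == 0, Inf, mu / sdv)
  tsnr <- array(tsnr_vec, d[1:3])

  bidx <- as.logical(brain)
  tvals <- tsnr[bidx]
  structure(list(ssnr = ssnr, tsnr = tsnr,
                 mean_ssnr = mean(ssnr[bidx]),
                 mean_tsnr = mean(tvals[is.finite(tvals)]),
                 n_flagged_infinite = sum(!is.finite(tvals)),
                 noise_sd = noise_sd, n_noise_voxels = sum(corners)),
            class = "snr_maps")
}

#' @export
print.snr_maps <- function(x, ...) {
  cat(sprintf("<snr_maps> mean sSNR %.2f, mean tSNR %.2f (noise sd %.3g, %d noise voxels)\n",
              x$mean_ssnr, x$mean_tsnr, x$noise_sd, x$n_noise_voxels))
  invisible(x)
}
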