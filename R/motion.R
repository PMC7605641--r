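# Motion estimation, framewise displacement, scrubbing, motion correction.

#' Framewise displacement from rigid motion parameters
#'
#' FD for frame i sums the absolute consecutive differences of the three
#' translations plus `r_mm` times the absolute consecutive differences of the
#' three rotation angles (small-angle arc length at radius `r_mm`,
#' approximately the cortex-to-head-centre distance in the rat). The
#' per-frame parameters are each frame's rigid transform to the first frame;
#' FD of the first frame is 0 by convention.
#'
#' @param trace a `motion_trace`, a list of [rigid_transform]s, or a T x 6
#'   numeric matrix (tx, ty, tz in mm; ax, ay, az in radians).
#' @param r_mm rotation radius in mm (default 5).
#' @return numeric vector of nonnegative FD values (length T).
#' @export
compute_fd <- function(trace, r_mm = 5) {
  p <- motion_params(trace)
  if (any(!is.finite(p))) stop("motion parameters must be finite")
  nt <- nrow(p)
  if (nt < 1L) stop("need at least one frame")
  if (nt == 1L) return(0)
  dp <- abs(diff(p))
  fd <- rowSums(dp[, 1:3, drop = FALSE]) +
    r_mm * rowSums(dp[, 4:6, drop = FALSE])
  c(0, fd)
}

motion_params <- function(trace) {
  if (inherits(trace, "motion_trace")) return(trace$params)
  if (is.matrix(trace)) {
    stopifnot(ncol(trace) == 6L)
    return(trace)
  }
  if (is.list(trace) && all(vapply(trace, inherits, logical(1),
                                   "rigid_transform")))
    return(do.call(rbind, lapply(trace, rigid_params)))
  stop("cannot interpret motion trace")
}

motion_trace <- function(params, fd_mm, r_mm, transforms = NULL) {
  structure(list(params = params, fd_mm = fd_mm, r_mm = r_mm,
                 transforms = transforms),
            class = "motion_trace")
}

#' Estimate frame-to-first rigid motion of a 4D scan
#'
#' Registers every frame to the first frame (intensity MSE, multi-resolution,
#' optionally within a mask) and derives the FD series. Each frame's
#' optimization is warm-started from the previous frame's estimate.
#'
#' @param vol a [volume4d].
#' @param mask optional logical 3D array (typically the dilated brain mask).
#' @param r_mm FD rotation radius in mm.
#' @param levels,max_iter registration controls, see [estimate_rigid].
#' @param est_fwhm_mm Gaussian pre-smoothing applied to the estimation
#'   copies only (the returned transforms refer to the raw frames);
#'   suppresses noise and interpolation ripple in the metric.
#' @return a `motion_trace`: `params` (T x 6), `fd_mm`, `transforms`.
#' @export
estimate_motion_trace <- function(vol, mask = NULL, r_mm = 5, levels = 2L,
                                  max_iter = 100L, est_fwhm_mm = 2,
                                  reltol = 1e-8) {
  nt <- n_frames(vol)
  if (est_fwhm_mm > 0) vol <- gaussian_smooth(vol, est_fwhm_mm)
  ref <- get_frame(vol, 1L)
  center <- world_centroid(ref, vol$affine)
  transforms <- vector("list", nt)
  transforms[[1]] <- rigid_transform(center = center)
  prev <- transforms[[1]]
  for (i in seq_len(nt)[-1]) {
    transforms[[i]] <- tryCatch({
      # fast trilinear solve, then a short cubic polish: the cubic metric
      # halves the rotation bias but costs 8x per evaluation
      coarse <- estimate_rigid(get_frame(vol, i), ref, affine = vol$affine,
                               mask = mask, center = center, levels = 1L,
                               init = prev, max_iter = max_iter,
                               reltol = 1e-6, metric_interp = "trilinear")
      estimate_rigid(get_frame(vol, i), ref, affine = vol$affine,
                     mask = mask, center = center, levels = 1L,
                     init = coarse, max_iter = 30L, reltol = reltol,
                     metric_interp = "cubic")
    }, error = function(e) stop("registration failed on frame ", i, ": ",
                                conditionMessage(e)))
    prev <- transforms[[i]]
  }
  params <- do.call(rbind, lapply(transforms, rigid_params))
  colnames(params) <- c("tx", "ty", "tz", "ax", "ay", "az")
  motion_trace(params, compute_fd(params, r_mm), r_mm, transforms)
}

#' Scrub high-motion frames
#'
#' Drops (i) the first `n_drop_first` frames (magnetization steady state),
#' (ii) every frame with FD above `fd_thresh_mm`, and (iii) the temporal
#' neighbours of each exceedance (both sides by default). A scan keeping
#' less than `min_keep_fraction` of its frames is flagged excluded.
#'
#' @param vol a [volume4d].
#' @param fd numeric FD series, one value per frame of `vol`.
#' @param fd_thresh_mm FD threshold in mm (default 0.2).
#' @param n_drop_first number of leading frames always dropped (default 10).
#' @param min_keep_fraction minimum kept fraction below which the scan is
#'   excluded (default 0.9).
#' @param neighbors which neighbours of an exceedance to drop:
#'   "both", "before", "after" or "none".
#' @return list with `vol` (retained frames), `decision` (fields `keep`,
#'   `n_dropped_first`, `scrubbed_fraction`, `scan_excluded`).
#' @export
scrub <- function(vol, fd, fd_thresh_mm = 0.2, n_drop_first = 10L,
                  min_keep_fraction = 0.9,
                  neighbors = c("both", "before", "after", "none")) {
  neighbors <- match.arg(neighbors)
  nt <- n_frames(vol)
  if (length(fd) != nt)
    stop(sprintf("FD length %d != frame count %d", length(fd), nt))
  drop <- rep(FALSE, nt)
  drop[seq_len(min(n_drop_first, nt))] <- TRUE
  exceed <- which(fd > fd_thresh_mm)
  drop[exceed] <- TRUE
  if (neighbors %in% c("both", "before"))
    drop[pmax(exceed - 1L, 1L)] <- TRUE
  if (neighbors %in% c("both", "after"))
    drop[pmin(exceed + 1L, nt)] <- TRUE
  keep <- !drop
  if (!any(keep)) stop("scrubbing dropped every frame")
  kept_fraction <- mean(keep)
  decision <- list(keep = keep,
                   n_dropped_first = as.integer(min(n_drop_first, nt)),
                   scrubbed_fraction = 1 - kept_fraction,
                   scan_excluded = kept_fraction < min_keep_fraction)
  out <- volume4d(vol$data[, , , keep, drop = FALSE], vol$voxel_size_mm,
                  vol$tr_s, vol$affine)
  list(vol = out, decision = decision)
}

#' Motion-correct a 4D scan
#'
#' Resamples every frame into the first frame's space through its rigid
#' frame-to-first transform, estimated within a dilated brain mask (or taken
#' from a previously estimated trace). The recorded per-frame parameters are
#' the six motion regressors used downstream.
#'
#' @param vol a [volume4d].
#' @param dilated_mask logical 3D array windowing the registration metric.
#' @param trace optional precomputed `motion_trace` for these frames (e.g.
#'   estimated on the raw scan and subset to retained frames); when given,
#'   no re-estimation is done.
#' @param r_mm,levels,max_iter see [estimate_motion_trace].
#' @return list with `vol` (corrected) and `trace` (`motion_trace`).
#' @export
motion_correct <- function(vol, dilated_mask = NULL, trace = NULL, r_mm = 5,
                           levels = 2L, max_iter = 200L) {
  if (n_frames(vol) < 2L) stop("need at least two frames")
  if (is.null(trace))
    trace <- estimate_motion_trace(vol, mask = dilated_mask, r_mm = r_mm,
                                   levels = levels, max_iter = max_iter)
  if (nrow(trace$params) != n_frames(vol))
    stop("motion trace length does not match frame count")
  out <- vol$data
  for (i in seq_len(n_frames(vol))[-1]) {
    out[, , , i] <- apply_rigid(get_frame(vol, i), trace$transforms[[i]],
                                affine = vol$affine)
  }
  list(vol = volume4d(out, vol$voxel_size_mm, vol$tr_s, vol$affine),
       trace = trace)
}

subset_trace <- function(trace, keep) {
  motion_trace(trace$params[keep, , drop = FALSE],
               compute_fd(trace$params[keep, , drop = FALSE], trace$r_mm),
               trace$r_mm,
               if (!is.null(trace$transforms)) trace$transforms[keep])
}

#' Write motion parameters as a 6-column text file
#' @param trace a `motion_trace`.
#' @param path destination path.
#' @return invisibly, `path`.
#' @export
write_motion_params <- function(trace, path) {
  utils::write.table(trace$params, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
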