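#' Rigid-body transform
#'
#' Six-parameter rigid transform in world (mm) coordinates: rotations about
#' the x, y, z axes (radians, applied as Rz Ry Rx about a rotation centre)
#' followed by a translation.
#'
#' @param tx,ty,tz translations in mm.
#' @param ax,ay,az rotations in radians about the x, y and z axes.
#' @param center length-3 world-space rotation centre (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(tx = 0, ty = 0, tz = 0, ax = 0, ay = 0, az = 0,
                            center = c(0, 0, 0)) {
  par <- c(tx, ty, tz, ax, ay, az)
  if (any(!is.finite(par))) stop("rigid parameters must be finite")
  structure(list(tx = tx, ty = ty, tz = tz, ax = ax, ay = ay, az = az,
                 center = as.numeric(center)),
            class = "rigid_transform")
}

rigid_params <- function(t) c(t$tx, t$ty, t$tz, t$ax, t$ay, t$az)

rotation_matrix <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax)
  cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' World-space 4x4 matrix of a rigid transform
#' @param t a [rigid_transform].
#' @return 4x4 matrix mapping world points p to R (p - c) + c + t.
#' @export
rigid_matrix <- function(t) {
  R <- rotation_matrix(t$ax, t$ay, t$az)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t$center - R %*% t$center + c(t$tx, t$ty, t$tz)
  M
}

#' Invert a rigid transform
#' @param t a [rigid_transform].
#' @return the inverse [rigid_transform] (same rotation centre).
#' @export
invert_rigid <- function(t) {
  rigid_from_matrix(rigid_inverse_matrix(rigid_matrix(t)),
                    center = t$center)
}

# Analytic inverse of a rigid 4x4 matrix: [R t]^-1 = [R' -R't].
rigid_inverse_matrix <- function(M) {
  R <- M[1:3, 1:3]
  out <- diag(4)
  out[1:3, 1:3] <- t(R)
  out[1:3, 4] <- -t(R) %*% M[1:3, 4]
  out
}

# Recover a rigid_transform (ZYX Euler angles) from a 4x4 world matrix.
rigid_from_matrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  ay <- -asin(max(-1, min(1, R[3, 1])))
  ax <- atan2(R[3, 2], R[3, 3])
  az <- atan2(R[2, 1], R[1, 1])
  trans <- M[1:3, 4] - (center - R %*% center)
  rigid_transform(trans[1], trans[2], trans[3], ax, ay, az, center)
}

#' Apply a rigid transform to a 3D image
#'
#' Resamples the image under the inverse mapping with trilinear
#' interpolation, so the returned image is the input moved by `t`.
#' Out-of-field voxels are set to `fill`.
#'
#' @param img numeric 3D array.
#' @param t a [rigid_transform].
#' @param affine 4x4 voxel-to-world matrix of the grid.
#' @param fill value for voxels sampled outside the field of view.
#' @param interp "trilinear" (the pipeline default) or "cubic"
#'   (Catmull-Rom; used e.g. by the phantom generator where resampling
#'   artifacts must stay below the planted motion signal).
#' @return numeric 3D array on the same grid.
#' @export
apply_rigid <- function(img, t, affine = NULL, fill = 0,
                        interp = c("trilinear", "cubic")) {
  interp <- match.arg(interp)
  d <- dim(img)
  stopifnot(length(d) == 3L)
  if (is.null(affine)) affine <- default_affine(c(1, 1, 1), d)
  Tw <- rigid_matrix(t)
  M <- solve(affine) %*% rigid_inverse_matrix(Tw) %*% affine
  out <- resample_affine_cpp(as.numeric(img), as.integer(d),
                             M[1:3, , drop = FALSE], fill,
                             cubic = interp == "cubic")
  array(out, dim = d)
}

world_centroid <- function(img, affine) {
  d <- dim(img)
  w <- pmax(as.numeric(img), 0)
  s <- sum(w)
  if (s <= 0) return((affine %*% c((d - 1) / 2, 1))[1:3])
  ix <- rep.int(seq_len(d[1]) - 1, times = d[2] * d[3])
  iy <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  v <- c(sum(w * ix), sum(w * iy), sum(w * iz)) / s
  (affine %*% c(v, 1))[1:3]
}

downsample_block <- function(img, f) {
  if (f == 1L) return(img)
  d <- dim(img)
  nd <- pmax(d %/% f, 1L)
  img <- img[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f),
             drop = FALSE]
  a <- array(img, c(f, nd[1], f, nd[2], f, nd[3]))
  out <- apply(a, c(2, 4, 6), mean)
  array(out, nd)
}

level_affine <- function(affine, f) {
  S <- diag(4)
  diag(S)[1:3] <- f
  S[1:3, 4] <- (f - 1) / 2
  affine %*% S
}

#' Estimate the rigid transform aligning two 3D images
#'
#' Intensity-based registration: multi-resolution minimization of the mean
#' squared error over the six rigid parameters, optionally restricted to a
#' mask, with centre-of-mass initialization. The returned transform `t`
#' satisfies `apply_rigid(moving, t) ~ fixed`.
#'
#' @param moving,fixed numeric 3D arrays on the same grid.
#' @param affine 4x4 voxel-to-world matrix shared by both images.
#' @param mask optional logical 3D array restricting the metric (evaluated
#'   on the fixed image's grid).
#' @param center rotation centre in world mm; default: the fixed image's
#'   intensity centroid.
#' @param levels number of resolution levels (downsampling factors
#'   2^(levels-1), ..., 2, 1; coarse levels with fewer than 8 voxels per
#'   axis are skipped).
#' @param init optional initial [rigid_transform].
#' @param max_iter per-level iteration cap for the optimizer.
#' @param max_translation_mm,max_rotation_rad search bounds around the
#'   initialization (restrained-head acquisitions move little; bounds also
#'   exclude symmetry aliases).
#' @return a [rigid_transform]; attribute `mse` holds the final objective.
#' @export
estimate_rigid <- function(moving, fixed, affine = NULL, mask = NULL,
                           center = NULL, levels = 3L, init = NULL,
                           max_iter = 200L, max_translation_mm = 10,
                           max_rotation_rad = 0.5, reltol = 1e-10,
                           metric_interp = c("cubic", "trilinear")) {
  metric_interp <- match.arg(metric_interp)
  use_cubic <- metric_interp == "cubic"
  d <- dim(moving)
  stopifnot_same_grid(d, dim(fixed), "moving/fixed pair")
  if (is.null(affine)) affine <- default_affine(c(1, 1, 1), d)
  if (is.null(center)) center <- world_centroid(fixed, affine)

  par <- if (is.null(init)) {
    cm_mov <- world_centroid(moving, affine)
    cm_fix <- world_centroid(fixed, affine)
    c(cm_fix - cm_mov, 0, 0, 0)
  } else rigid_params(init)

  factors <- 2^(seq(levels - 1L, 0L))
  factors <- factors[pmin(d[1], d[2], d[3]) / factors >= 5 | factors == 1]
  last_val <- NA_real_
  bound <- c(rep(max_translation_mm, 3), rep(max_rotation_rad, 3))
  par0 <- par
  for (f in factors) {
    mov_l <- downsample_block(moving, f)
    fix_l <- downsample_block(fixed, f)
    msk_l <- if (is.null(mask)) logical(0)
             else as.vector(downsample_block(mask * 1, f) > 0.5)
    aff_l <- level_affine(affine, f)
    aff_inv <- solve(aff_l)
    dl <- as.integer(dim(mov_l))
    # The metric lives on a half-voxel-offset grid: the fixed image is
    # interpolated once, and the moving image is interpolated at every
    # probe, so no transform enjoys artifact-free on-grid sampling (a
    # trilinear/cubic resampling bias would otherwise pin the optimum at
    # grid-aligned transforms).
    Mh <- cbind(diag(3), rep(0.5, 3))
    fix_h <- resample_affine_cpp(as.numeric(fix_l), dl, Mh, 0, cubic = TRUE)
    mov_n <- as.numeric(mov_l)
    # the half-offset grid loses the last face slab along each axis
    in_h <- array(TRUE, dl)
    in_h[dl[1], , ] <- FALSE; in_h[, dl[2], ] <- FALSE; in_h[, , dl[3]] <- FALSE
    msk_l <- if (length(msk_l)) msk_l & as.vector(in_h) else as.vector(in_h)
    obj <- function(p) {
      if (any(!is.finite(p))) return(1e12)
      # smooth penalty outside the search bounds keeps the optimizer away
      # from symmetry aliases and degenerate far-field plateaus
      over <- pmax(abs(p - par0) - bound, 0)
      Tw <- rigid_matrix(rigid_transform(p[1], p[2], p[3], p[4], p[5], p[6],
                                         center))
      M <- (aff_inv %*% rigid_inverse_matrix(Tw) %*% aff_l)[1:3, ,
                                                            drop = FALSE]
      M[, 4] <- M[, 4] + M[, 1:3] %*% rep(0.5, 3)
      v <- mse_affine_cpp(mov_n, fix_h, dl, M, msk_l, cubic = use_cubic)
      if (is.na(v)) v <- 1e12
      v + 1e6 * sum(over^2)
    }
    fit <- stats::optim(par, obj, method = "BFGS",
                        control = list(maxit = max_iter, reltol = reltol,
                                       parscale = c(1, 1, 1, .02, .02, .02)))
    par <- fit$par
    last_val <- fit$value
    if (fit$convergence > 1)
      stop(sprintf(paste0("rigid registration failed to converge ",
                          "(code %d); best parameters: %s, objective %.3g"),
                   fit$convergence, paste(signif(par, 4), collapse = ", "),
                   fit$value))
  }
  out <- rigid_transform(par[1], par[2], par[3], par[4], par[5], par[6],
                         center)
  attr(out, "mse") <- last_val
  out
}
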