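# Per-scan spatial ICA: PCA whitening followed by symmetric fixed-point ICA
# (logcosh contrast). Implemented here because no ICA package ships with
# this stack; deterministic under a fixed seed.

# X: n x p (samples x variables). Returns k independent components over
# samples (S: n x k) and the whitening/unmixing pieces. Runs up to
# `restarts` deterministic re-initializations (seed, seed+1000, ...) and
# keeps the tightest fixed point; see fast_ica_once for the oscillation
# handling.
fast_ica_sym <- function(X, k, seed = 1L, max_iter = 500L, tol = 1e-5,
                         restarts = 3L) {
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- fast_ica_once(X, k, seed = seed + (r - 1L) * 1000L,
                         max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$delta < best$delta) best <- fit
    if (best$converged) break
  }
  if (!best$converged && best$delta > 0.05)
    stop(sprintf(
      "fixed-point ICA did not converge in %d runs (best delta %.3g)",
      restarts, best$delta))
  best
}

fast_ica_once <- function(X, k, seed = 1L, max_iter = 500L, tol = 1e-5) {
  n <- nrow(X); p <- ncol(X)
  if (k > min(n, p)) stop("k must not exceed either data dimension")
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values[seq_len(k)], .Machine$double.eps)
  K <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(1 / sqrt(ev), k)
  Z <- Xc %*% K                       # n x k, whitened
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  sym_decorrelate <- function(W) {
    e <- eigen(crossprod(W), symmetric = TRUE)
    W %*% e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
      t(e$vectors)
  }
  W <- sym_decorrelate(W)
  it <- 0L; delta <- Inf
  best_delta <- Inf; best_W <- W
  while (it < max_iter) {
    it <- it + 1L
    U <- Z %*% W                      # n x k
    G <- tanh(U)
    gprime <- colMeans(1 - G^2)
    W_new <- crossprod(Z, G) / n - sweep(W, 2, gprime, "*")
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(1 - abs(colSums(W_new * W))))
    W <- W_new
    if (delta < best_delta) {
      best_delta <- delta
      best_W <- W
    }
    if (delta < tol) break
  }
  converged <- delta < tol
  if (!converged) {
    # Surplus near-Gaussian components oscillate without settling; their
    # rotation is undefined and does not affect the non-Gaussian sources.
    # Keep the closest-to-fixed-point iterate; fast_ica_sym decides
    # whether it is acceptable.
    W <- best_W
  }
  list(S = Z %*% W, K = K, W = W, iterations = it, converged = converged,
       delta = if (converged) delta else best_delta)
}

#' Per-scan spatial ICA
#'
#' Decomposes a scan into `k` spatially independent components over brain
#' voxels: data ~ timecourses %*% maps. Maps are z-scored over brain voxels
#' and sign-fixed so each map's skewness is positive; time courses are
#' obtained by regressing the maps against every frame
#' (see [ic_timecourses]). Deterministic under a fixed seed.
#'
#' @param vol a [volume4d] (typically smoothed at FWHM 0.7 mm beforehand).
#' @param brain logical 3D brain mask.
#' @param k number of components (50 for real scans; lower for phantoms).
#' @param seed integer seed for the fixed-point initialization.
#' @param max_iter iteration cap.
#' @return an object of class `ica_decomposition`: `maps` (k x V),
#'   `timecourses` (T x k), `k`, `brain`, `seed`, `iterations`.
#' @export
spatial_ica <- function(vol, brain, k = 50L, seed = 1L, max_iter = 500L) {
  stopifnot(inherits(vol, "volume4d"))
  stopifnot_same_grid(dim(brain), dim(vol$data)[1:3], "brain mask")
  X <- vol_to_matrix(vol, brain)      # T x V
  nt <- nrow(X)
  if (k >= nt) stop("k must be smaller than the number of frames")
  fit <- fast_ica_sym(t(X), k, seed = seed, max_iter = max_iter)  # V x k
  maps <- t(fit$S)                    # k x V
  maps <- maps - rowMeans(maps)
  maps <- maps / sqrt(rowMeans(maps^2))
  skew <- rowMeans(maps^3)
  flip <- ifelse(skew < 0, -1, 1)
  maps <- maps * flip
  tc <- ic_timecourses(maps, vol, brain)
  structure(list(maps = maps, timecourses = tc, k = as.integer(k),
                 brain = brain, seed = as.integer(seed),
                 iterations = fit$iterations),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components, %d frames, %d brain voxels\n",
              x$k, nrow(x$timecourses), ncol(x$maps)))
  invisible(x)
}

#' IC time courses by spatial regression
#'
#' For each frame, the K coefficients of the least-squares fit of the
#' frame's brain voxels onto the K spatial maps (plus an intercept). With
#' orthonormal maps this reduces to per-map inner products.
#'
#' @param maps K x V matrix of spatial maps over brain voxels.
#' @param vol a [volume4d].
#' @param brain logical 3D brain mask with V `TRUE` voxels.
#' @return T x K matrix of component time courses.
#' @export
ic_timecourses <- function(maps, vol, brain) {
  X <- vol_to_matrix(vol, brain)      # T x V
  if (ncol(X) != ncol(maps))
    stop("maps do not cover the brain voxel set")
  A <- cbind(1, t(maps))              # V x (K+1)
  qa <- qr(A)
  if (qa$rank < ncol(A))
    stop("rank-deficient map matrix; cannot regress time courses")
  coef <- qr.coef(qa, t(X))           # (K+1) x T
  t(coef[-1, , drop = FALSE])
}

#' Write IC maps as a 4D NIfTI image
#' @param decomp an `ica_decomposition`.
#' @param vol the source [volume4d] (for grid and affine).
#' @param path destination NIfTI path.
#' @return invisibly, `path`.
#' @export
write_ic_maps <- function(decomp, vol, path) {
  v <- matrix_to_vol(decomp$maps, vol, decomp$brain)
  write_volume(v, path)
}
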