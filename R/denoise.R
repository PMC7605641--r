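# Monte-Carlo CompCor nuisance selection and soft (shared-variance
# preserving) noise removal.

#' Null distribution of the first-PC variance-explained fraction
#'
#' Simulates `n_mc` iid standard-normal T x V datasets (columns standardized
#' exactly as the real data are) and records the fraction of total variance
#' carried by the first principal component of each. This is the reference
#' distribution the CompCor p-values are read from; computing it once and
#' passing it to [compcor] amortizes the cost across scans with the same
#' data size.
#'
#' @param nt,nv data dimensions (frames, voxels).
#' @param n_mc number of Monte-Carlo datasets (default 1000).
#' @param seed integer seed.
#' @return numeric vector of `n_mc` first-PC variance-explained fractions.
#' @export
compcor_null <- function(nt, nv, n_mc = 1000L, seed = 1L) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  out <- vapply(seq_len(n_mc), function(i) {
    x <- matrix(stats::rnorm(nt * nv), nt, nv)
    x <- scale_cols(x)
    first_pc_ve(x)
  }, numeric(1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  out
}

scale_cols <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  s <- sqrt(colSums(x^2) / (nrow(x) - 1))
  s[s == 0] <- 1
  sweep(x, 2, s, "/")
}

# Largest-eigenvalue fraction of trace, via the smaller Gram matrix and a
# few power iterations (the null only needs lambda_1 / trace).
first_pc_ve <- function(x) {
  small_t <- nrow(x) <= ncol(x)
  G <- if (small_t) tcrossprod(x) else crossprod(x)
  tr <- sum(diag(G))
  if (tr <= 0) return(0)
  v <- rep(1 / sqrt(nrow(G)), nrow(G))
  lam <- 0
  for (i in 1:50) {
    w <- G %*% v
    lam_new <- sqrt(sum(w^2))
    v <- as.numeric(w / lam_new)
    if (abs(lam_new - lam) < 1e-10 * lam_new) break
    lam <- lam_new
  }
  lam_new / tr
}

#' Monte-Carlo CompCor
#'
#' Principal components of the variance-normalized WM + CSF voxel time
#' courses, selected by comparing each component's variance-explained
#' fraction with the null distribution of the first PC of equally sized iid
#' normal data: p = (number of null datasets whose first-PC fraction exceeds
#' this PC's fraction) / n_mc, selecting components with p < alpha in
#' variance order.
#'
#' @param vol a [volume4d].
#' @param wm,csf logical 3D masks.
#' @param n_mc number of Monte-Carlo null datasets (default 1000).
#' @param alpha selection threshold on the Monte-Carlo p-value.
#' @param seed integer seed for the null simulation.
#' @param null_ve optional precomputed null from [compcor_null].
#' @param max_components cap on returned components.
#' @return list with `components` (T x C), `p` (length C), `ve`
#'   (variance-explained fractions of all candidates), `n_candidates`.
#' @export
compcor <- function(vol, wm, csf, n_mc = 1000L, alpha = 0.05, seed = 1L,
                    null_ve = NULL, max_components = Inf) {
  stopifnot(inherits(vol, "volume4d"))
  mask <- wm | csf
  nv <- sum(mask)
  if (nv < 2L) stop("need at least 2 WM/CSF voxels")
  X <- scale_cols(vol_to_matrix(vol, mask))
  nt <- nrow(X)
  sv <- svd(X, nu = min(nt, nv), nv = 0)
  ve <- sv$d^2 / sum(sv$d^2)
  if (is.null(null_ve)) null_ve <- compcor_null(nt, nv, n_mc, seed)
  p <- vapply(ve, function(v) mean(null_ve > v), numeric(1))
  sel <- which(p < alpha)
  if (length(sel)) sel <- sel[seq_len(min(length(sel), max_components))]
  list(components = sv$u[, sel, drop = FALSE], p = p[sel], ve = ve,
       p_all = p, n_candidates = length(ve))
}

#' Assemble a nuisance regressor set
#'
#' Six rigid motion parameters plus Monte-Carlo-selected CompCor components,
#' aligned on the retained-frame axis.
#'
#' @param trace a `motion_trace` for the retained frames (or T x 6 matrix).
#' @param compcor_fit result of [compcor] on the same frames (or NULL).
#' @return list with `motion` (T x 6), `compcor` (T x C), `compcor_p`,
#'   `n_candidates`; class `nuisance_set`.
#' @export
nuisance_set <- function(trace, compcor_fit = NULL) {
  motion <- motion_params(trace)
  cc <- if (is.null(compcor_fit)) matrix(0, nrow(motion), 0)
        else compcor_fit$components
  if (nrow(cc) && nrow(cc) != nrow(motion))
    stop("motion and CompCor regressors have different frame counts")
  stopifnot(all(is.finite(motion)), all(is.finite(cc)))
  structure(list(motion = motion, compcor = cc,
                 compcor_p = if (is.null(compcor_fit)) numeric(0)
                             else compcor_fit$p,
                 n_candidates = if (is.null(compcor_fit)) 0L
                                else compcor_fit$n_candidates),
            class = "nuisance_set")
}

nuisance_matrix <- function(nuisance) {
  if (is.null(nuisance)) return(NULL)
  if (inherits(nuisance, "nuisance_set"))
    return(cbind(nuisance$motion, nuisance$compcor))
  as.matrix(nuisance)
}

# Residualize the columns of Y against design N (always with intercept;
# N = NULL demeans only).
residualize <- function(Y, N = NULL) {
  X <- if (is.null(N) || ncol(N) == 0) matrix(1, nrow(Y), 1) else cbind(1, N)
  qx <- qr(X)
  Y - qr.fitted(qx, Y)
}

#' Soft removal of noise ICs
#'
#' Removes only the nuisance-unique contribution of the noise components,
#' preserving variance they share with signal components. Motion and CompCor
#' regressors are first regressed out of both the IC time courses and every
#' voxel time course (giving `ICA_m` and `Y_m`); the joint least-squares
#' weights `beta = pinv(ICA_m) Y_m` over all K components are computed, and
#' the noise components' fitted part `ICA_m[, noise] beta[noise, ]` is
#' subtracted from `Y_m`. Intended for the unsmoothed normalized data.
#'
#' @param vol a [volume4d] on the retained-frame axis.
#' @param decomp an `ica_decomposition` whose time courses align with `vol`.
#' @param labels data.frame from [classify_ics] (`is_noise` column), or a
#'   logical vector per IC.
#' @param nuisance a `nuisance_set`, a T x Q matrix, or NULL.
#' @return a cleaned [volume4d].
#' @export
soft_clean <- function(vol, decomp, labels, nuisance = NULL) {
  stopifnot(inherits(vol, "volume4d"))
  is_noise <- if (is.data.frame(labels)) labels$is_noise else as.logical(labels)
  if (length(is_noise) != decomp$k)
    stop("labels do not match the number of ICs")
  tc <- decomp$timecourses
  if (nrow(tc) != n_frames(vol))
    stop("IC time courses and volume have different frame counts")
  Y <- vol_to_matrix(vol)
  N <- nuisance_matrix(nuisance)
  if (!is.null(N) && nrow(N) != nrow(Y))
    stop("nuisance regressors and volume have different frame counts")
  ICA_m <- residualize(tc, N)
  Y_m <- residualize(Y, N)
  if (!any(is_noise)) return(matrix_to_vol(Y_m, vol))
  qx <- qr(ICA_m)
  if (qx$rank < ncol(ICA_m))
    stop("regressed IC time courses are rank deficient")
  beta <- qr.coef(qx, Y_m)                 # K x V
  Y_clean <- Y_m - ICA_m[, is_noise, drop = FALSE] %*%
    beta[is_noise, , drop = FALSE]
  matrix_to_vol(Y_clean, vol)
}

#' Hard regression of noise ICs and nuisance regressors
#'
#' The conventional alternative to [soft_clean]: residualizes every voxel
#' against the noise IC time courses and the nuisance columns jointly,
#' removing shared variance as well. Used for method comparison.
#'
#' @inheritParams soft_clean
#' @return a cleaned [volume4d].
#' @export
hard_clean <- function(vol, decomp, labels, nuisance = NULL) {
  is_noise <- if (is.data.frame(labels)) labels$is_noise else as.logical(labels)
  Y <- vol_to_matrix(vol)
  N <- cbind(nuisance_matrix(nuisance),
             decomp$timecourses[, is_noise, drop = FALSE])
  matrix_to_vol(residualize(Y, N), vol)
}
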