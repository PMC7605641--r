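# Group spatial ICA (temporal concatenation with two-level PCA reduction)
# and Ward clustering of components into modules.

#' Group spatial ICA
#'
#' Each scan's voxel time courses are demeaned and reduced to `reduce_k`
#' temporal principal components; the reduced scans are concatenated along
#' the (reduced) time axis, reduced again to `k` components, and unmixed
#' with the same fixed-point ICA as [spatial_ica]. Per-scan component time
#' courses are recovered by spatial regression of the group maps against
#' each scan's frames.
#'
#' @param scans list of preprocessed [volume4d] on a common grid.
#' @param brain logical 3D brain mask.
#' @param k number of group components (30 for real data).
#' @param seed integer seed.
#' @param reduce_k per-scan reduction dimension (default
#'   `min(ceiling(1.5 k), T - 1)`).
#' @return object of class `group_ica`: `maps` (k x V, z-scored over brain
#'   voxels, positive skewness), `timecourses` (list of T x k per scan),
#'   `k`, `brain`, `seed`.
#' @export
group_ica <- function(scans, brain, k = 30L, seed = 1L, reduce_k = NULL) {
  stopifnot(length(scans) >= 2L)
  nts <- vapply(scans, n_frames, integer(1))
  if (is.null(reduce_k)) reduce_k <- min(ceiling(1.5 * k), min(nts) - 1L)
  if (k > reduce_k * length(scans))
    stop("k exceeds the concatenated reduced dimension")
  if (reduce_k < k)
    stop("per-scan reduction dimension is smaller than k")
  reduced <- lapply(scans, function(v) {
    X <- vol_to_matrix(v, brain)               # T x V
    X <- X - rowMeans(X)                       # remove per-frame offset
    X <- sweep(X, 2, colMeans(X))              # demean voxel time courses
    sv <- svd(X, nu = reduce_k, nv = 0)
    t(sv$u[, seq_len(reduce_k), drop = FALSE]) %*% X   # reduce_k x V
  })
  R <- do.call(rbind, reduced)
  fit <- fast_ica_sym(t(R), k, seed = seed)    # V x k sources
  maps <- t(fit$S)
  maps <- maps - rowMeans(maps)
  maps <- maps / sqrt(rowMeans(maps^2))
  maps <- maps * ifelse(rowMeans(maps^3) < 0, -1, 1)
  tcs <- lapply(scans, function(v) ic_timecourses(maps, v, brain))
  structure(list(maps = maps, timecourses = tcs, k = as.integer(k),
                 brain = brain, seed = as.integer(seed)),
            class = "group_ica")
}

#' @export
print.group_ica <- function(x, ...) {
  cat(sprintf("<group_ica> %d components over %d scans\n", x$k,
              length(x$timecourses)))
  invisible(x)
}

#' Between-component connectivity and Ward modules
#'
#' Per scan, Fisher-z Pearson correlations between component time courses;
#' group t matrix and max-t permutation significance via the same machinery
#' as ROI FC; Ward linkage (on the distance `max(t) - t`, diagonal
#' excluded) groups components into modules at a configurable cut.
#'
#' @param timecourses list of T x K matrices (one per scan), e.g. from
#'   [group_ica].
#' @param subjects character vector, subject of each scan.
#' @param n_perm,alpha,seed permutation controls, see [permutation_fwer].
#' @param n_modules number of modules to cut the dendrogram into (NULL to
#'   skip cutting).
#' @param cut_height alternative dendrogram cut height.
#' @return list with `group` (a `group_fc_result` with `sig`), `hclust`,
#'   `modules` (integer vector per component or NULL), `distance`.
#' @export
ic_modules <- function(timecourses, subjects, n_perm = 1000L, alpha = 0.05,
                       seed = 1L, n_modules = NULL, cut_height = NULL) {
  stopifnot(length(timecourses) >= 1L)
  k <- ncol(timecourses[[1]])
  if (k < 2L) stop("need at least 2 components")
  fc <- lapply(seq_along(timecourses), function(i) {
    tc <- timecourses[[i]]
    sds <- apply(tc, 2, stats::sd)
    if (any(sds == 0))
      warning("scan ", i, ": constant component time course(s) flagged: ",
              paste(which(sds == 0), collapse = ", "))
    scan_fc(t(tc), scan_id = paste0("scan", i),
            subject_id = as.character(subjects[i]))
  })
  grp <- permutation_fwer(fc, subjects = as.character(subjects),
                          n_perm = n_perm, alpha = alpha, seed = seed)
  D <- max(grp$t[upper.tri(grp$t)]) - grp$t
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  modules <- NULL
  if (!is.null(n_modules)) modules <- stats::cutree(hc, k = n_modules)
  else if (!is.null(cut_height)) modules <- stats::cutree(hc, h = cut_height)
  list(group = grp, hclust = hc, modules = modules, distance = D)
}
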