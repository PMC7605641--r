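# Group-level FC inference: random-intercept mixed model (or its exact
# one-scan-per-subject reduction), and max-statistic permutation control of
# the familywise error rate.

T_CAP <- 1e6

# Stack a list of fc_matrix objects into entries x scans, with subjects.
stack_fc <- function(fc, subjects = NULL) {
  stopifnot(length(fc) >= 1L)
  n <- nrow(fc[[1]]$z)
  Z <- vapply(fc, function(f) {
    stopifnot(nrow(f$z) == n)
    upper_tri_vec(f$z)
  }, numeric(n * (n - 1) / 2))
  Z <- matrix(Z, ncol = length(fc))
  if (is.null(subjects))
    subjects <- vapply(fc, function(f) as.character(f$subject_id),
                       character(1))
  if (anyNA(subjects)) stop("subject mapping required")
  list(Z = Z, subjects = as.character(subjects), n_roi = n,
       roi_ids = fc[[1]]$roi_ids)
}

# One-sample t on the rows of a matrix (entries x units); returns t and a
# flag for capped (zero-variance) entries. Missing values (flagged
# degenerate inputs) are dropped row-wise.
row_t <- function(X) {
  n_eff <- rowSums(!is.na(X))
  m <- rowMeans(X, na.rm = TRUE)
  s <- sqrt(pmax(rowSums((X - m)^2, na.rm = TRUE) / pmax(n_eff - 1, 1), 0))
  se <- s / sqrt(pmax(n_eff, 1))
  capped <- se == 0 & m != 0 & n_eff > 1
  t <- ifelse(n_eff < 2 | !is.finite(m), 0,
              ifelse(se == 0, ifelse(m == 0, 0, sign(m) * T_CAP), m / se))
  list(t = t, capped = capped, df = ncol(X) - 1)
}

subject_means <- function(Z, subjects) {
  us <- unique(subjects)
  M <- vapply(us, function(s)
    rowMeans(Z[, subjects == s, drop = FALSE], na.rm = TRUE),
    numeric(nrow(Z)))
  matrix(M, nrow = nrow(Z), dimnames = list(NULL, us))
}

entry_t_lmm <- function(z, subjects) {
  fit <- lme4::lmer(z ~ 1 + (1 | subj),
                    data = data.frame(z = z, subj = subjects),
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore", calc.derivs = FALSE))
  cf <- summary(fit)$coefficients
  cf[1, "t value"]
}

#' Group-level FC t matrix
#'
#' Per-entry intercept t statistic of a random-intercept-per-subject linear
#' mixed model fitted to the per-scan Fisher-z values. With one scan per
#' subject this reduces exactly to the classical one-sample t across
#' subjects, which is also the deterministic fallback (one-sample t on
#' subject means) used when the variance components cannot be estimated or
#' when `method = "subject_mean"` is requested (e.g. inside permutations).
#' Entries with zero variance are capped at +/- 1e6 and flagged.
#'
#' @param fc list of `fc_matrix` objects.
#' @param subjects character vector, subject of each scan (default: taken
#'   from the `fc_matrix` objects).
#' @param method "auto" (mixed model when any subject has repeated scans,
#'   classical t otherwise), "lmm", or "subject_mean".
#' @return object of class `group_fc_result`: `t` (N x N symmetric, zero
#'   diagonal), `capped` (logical matrix), `df`, `n_scans`, `n_subjects`,
#'   `method`.
#' @export
group_fc <- function(fc, subjects = NULL,
                     method = c("auto", "lmm", "subject_mean")) {
  method <- match.arg(method)
  st <- stack_fc(fc, subjects)
  if (length(unique(st$subjects)) < 2L) stop("need at least 2 subjects")
  one_scan_each <- !any(duplicated(st$subjects))
  if (method == "auto")
    method <- if (one_scan_each) "subject_mean" else "lmm"
  M <- subject_means(st$Z, st$subjects)
  base <- row_t(M)
  t_vec <- base$t
  used <- method
  if (method == "lmm" && !one_scan_each) {
    t_lmm <- rep(NA_real_, nrow(st$Z))
    for (e in seq_len(nrow(st$Z))) {
      t_lmm[e] <- tryCatch(entry_t_lmm(st$Z[e, ], st$subjects),
                           error = function(err) NA_real_)
    }
    failed <- is.na(t_lmm)
    if (any(failed))
      message(sum(failed), " entries fell back to the subject-mean t")
    t_vec <- ifelse(failed, base$t, t_lmm)
  } else if (method == "lmm") {
    used <- "subject_mean"   # exact reduction: one scan per subject
  }
  structure(list(t = vec_to_sym(t_vec, st$n_roi),
                 capped = vec_to_sym(base$capped, st$n_roi) > 0,
                 df = base$df, n_scans = ncol(st$Z),
                 n_subjects = ncol(M), roi_ids = st$roi_ids,
                 method = used),
            class = "group_fc_result")
}

#' @export
print.group_fc_result <- function(x, ...) {
  cat(sprintf("<group_fc_result> %d ROIs, %d scans / %d subjects (%s)\n",
              nrow(x$t), x$n_scans, x$n_subjects, x$method))
  if (!is.null(x$t_crit))
    cat(sprintf("  max-t FWER: t_crit %.3f, density %.2f%% (%d permutations)\n",
                x$t_crit, 100 * x$density, x$n_perm))
  invisible(x)
}

#' Max-t permutation FWER control for group FC
#'
#' For each permutation, ROI labels are independently shuffled within each
#' scan's FC matrix, the group t matrix is recomputed and its maximum entry
#' recorded; an observed entry is significant when its familywise-adjusted
#' permutation p-value, (1 + #\{max-t >= t\}) / (1 + n_perm), is at most
#' `alpha` (equivalently, the t value exceeds the corresponding upper
#' percentile of the max-t null).
#'
#' @inheritParams group_fc
#' @param n_perm number of permutations (default 1000; below 100 a warning
#'   is issued).
#' @param alpha familywise error level (default 0.05).
#' @param seed integer seed for the permutations.
#' @param method group statistic inside permutations; the deterministic
#'   subject-mean t by default (exact when each subject contributes one
#'   scan).
#' @return `group_fc_result` with additional fields `sig` (logical N x N),
#'   `t_crit`, `p_fwer` (N x N), `max_t_null`, `n_perm`, `density`.
#' @export
permutation_fwer <- function(fc, subjects = NULL, n_perm = 1000L,
                             alpha = 0.05, seed = 1L,
                             method = "subject_mean") {
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse null")
  res <- group_fc(fc, subjects, method = method)
  st <- stack_fc(fc, subjects)
  n <- st$n_roi
  ut <- upper.tri(matrix(0, n, n))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  zs <- lapply(fc, function(f) f$z)
  max_t <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    Zp <- vapply(zs, function(z) {
      pm <- sample.int(n)
      z[pm, pm][ut]
    }, numeric(sum(ut)))
    Zp <- matrix(Zp, ncol = length(zs))
    M <- subject_means(Zp, st$subjects)
    max_t[p] <- max(row_t(M)$t)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  t_vec <- res$t[ut]
  p_fwer <- vapply(t_vec, function(t) (1 + sum(max_t >= t)) / (1 + n_perm),
                   numeric(1))
  sig_vec <- p_fwer <= alpha
  res$sig <- vec_to_sym(sig_vec, n) > 0
  res$p_fwer <- vec_to_sym(p_fwer, n, diag_value = 1)
  res$t_crit <- as.numeric(stats::quantile(max_t, 1 - min(alpha, 1)))
  res$max_t_null <- max_t
  res$n_perm <- as.integer(n_perm)
  res$alpha <- alpha
  res$density <- mean(sig_vec)
  res
}

#' Group seed-based connectivity map
#'
#' Per scan, the Fisher-z correlation of every brain voxel with the mean
#' time course of a small seed box (the convention is a 3 x 3 x 2 voxel
#' cube); the per-voxel group t statistic is then computed with the same
#' subject-mean machinery as [group_fc].
#'
#' @param scans list of preprocessed [volume4d].
#' @param seed_box 3 x 2 matrix of voxel index ranges (rows x, y, z; columns
#'   from, to), or a list with `center` (length-3) and `size` (length-3,
#'   default c(3, 3, 2)).
#' @param brain logical 3D brain mask.
#' @param subjects character vector, one subject per scan.
#' @return list with `t` (3D array, NA outside brain), `df`, `n_scans`,
#'   `seed_voxels` (logical 3D array).
#' @export
seed_map <- function(scans, seed_box, brain, subjects) {
  d <- dim(scans[[1]]$data)[1:3]
  seed <- array(FALSE, d)
  if (is.list(seed_box) && !is.null(seed_box$center)) {
    sz <- if (is.null(seed_box$size)) c(3L, 3L, 2L) else seed_box$size
    lo <- pmax(seed_box$center - (sz - 1L) %/% 2L, 1L)
    hi <- pmin(lo + sz - 1L, d)
    seed[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  } else {
    sb <- as.matrix(seed_box)
    seed[sb[1, 1]:sb[1, 2], sb[2, 1]:sb[2, 2], sb[3, 1]:sb[3, 2]] <- TRUE
  }
  if (!any(seed & brain)) stop("seed box lies outside the brain mask")
  seed <- seed & brain
  cap <- 1 - 1e-7
  Z <- vapply(scans, function(v) {
    X <- vol_to_matrix(v, brain)
    stc <- rowMeans(vol_to_matrix(v, seed))
    r <- suppressWarnings(as.numeric(stats::cor(stc, X)))
    r[!is.finite(r)] <- 0
    atanh(pmin(pmax(r, -cap), cap))
  }, numeric(sum(brain)))
  Z <- matrix(Z, ncol = length(scans))
  M <- subject_means(Z, as.character(subjects))
  tt <- row_t(M)
  tmap <- array(NA_real_, d)
  tmap[brain] <- tt$t
  list(t = tmap, df = tt$df, n_scans = length(scans), seed_voxels = seed)
}
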