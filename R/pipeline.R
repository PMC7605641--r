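# Pipeline orchestration: configuration, the 9-step per-scan preprocessing
# chain, group analyses, and the nuisance-regression comparison harness.

#' Pipeline configuration
#'
#' All thresholds and parameters of the preprocessing and analysis stages.
#' Every default is the published operating point of the awake-rat pipeline:
#' FD threshold 0.2 mm with r = 5 mm and the first 10 frames dropped, 90%
#' retention rule, 50 per-scan ICs, 0.7 mm pre-ICA and 1.0 mm post-clean
#' smoothing, 0.01-0.1 Hz 4th-order Butterworth band-pass, 1000-sample
#' Monte-Carlo CompCor at alpha 0.05, 540-frame truncation, 30 group ICs,
#' 1000 permutations at FWER 0.05.
#'
#' @param ... overrides of any default field.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fd_thresh_mm = 0.2, r_mm = 5, n_drop_first = 10L,
    min_keep_fraction = 0.9,
    ica_k = 50L, pre_ica_fwhm_mm = 0.7, post_fwhm_mm = 1.0,
    band_low_hz = 0.01, band_high_hz = 0.1, band_order = 4L,
    compcor_n_mc = 1000L, compcor_alpha = 0.05,
    group_ica_k = 30L, n_perm = 1000L, fwer_alpha = 0.05,
    truncate_frames = 540L, seed = 1L,
    registration_levels = 2L, z_thresh = 2)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  structure(cfg, class = "pipeline_config")
}

#' Preprocess one scan through the 9-step chain
#'
#' Steps (template alignment is assumed done, or delegated to
#' `align_hook`): (1) FD-based scrubbing of raw frames, (2-3) alignment +
#' dilated-mask crop hook, (4) rigid motion correction of retained frames,
#' (5) normalization hook, (6) 0.7 mm smoothing + per-scan spatial ICA with
#' feature-based noise labelling, (7) soft cleaning of the unsmoothed data
#' with motion + Monte-Carlo CompCor regressors, (8) 1.0 mm smoothing,
#' (9) 0.01-0.1 Hz band-pass. Returns the cleaned volume and the full
#' provenance (FD, scrub decision, motion trace, IC features/labels,
#' CompCor p-values, step log).
#'
#' @param vol raw [volume4d], assumed template-space.
#' @param masks a [mask_set] on the data grid.
#' @param config a [pipeline_config].
#' @param ica_k override of the IC count (e.g. for small phantoms).
#' @param compcor_null precomputed [compcor_null] distribution (optional).
#' @param motion_trace optional precomputed raw-frame `motion_trace`
#'   (e.g. the phantom's ground truth schedule is *not* allowed here;
#'   this is for caching a previous estimate).
#' @param align_hook optional function(volume4d) -> volume4d applied before
#'   motion estimation (external registration step; identity by default).
#' @return list: `vol` (cleaned), `scrub`, `trace`, `fd_raw`, `ica`,
#'   `features`, `labels`, `compcor_p`, `excluded`, `steps` (log
#'   data.frame).
#' @export
preprocess_scan <- function(vol, masks, config = pipeline_config(),
                            ica_k = NULL, compcor_null = NULL,
                            motion_trace = NULL, align_hook = NULL,
                            keep_mc = FALSE) {
  steps <- list()
  log_step <- function(name, frames_in, frames_out)
    steps[[length(steps) + 1L]] <<-
      data.frame(step = name, frames_in = frames_in, frames_out = frames_out)
  nt0 <- n_frames(vol)

  if (!is.null(align_hook)) vol <- align_hook(vol)
  log_step("align", nt0, n_frames(vol))

  if (is.null(motion_trace))
    motion_trace <- estimate_motion_trace(vol, mask = masks$dilated_brain,
                                          r_mm = config$r_mm,
                                          levels = config$registration_levels)
  fd_raw <- motion_trace$fd_mm
  sc <- scrub(vol, fd_raw, fd_thresh_mm = config$fd_thresh_mm,
              n_drop_first = config$n_drop_first,
              min_keep_fraction = config$min_keep_fraction)
  log_step("scrub", nt0, n_frames(sc$vol))
  if (sc$decision$scan_excluded) {
    return(list(vol = NULL, scrub = sc$decision, fd_raw = fd_raw,
                excluded = TRUE, steps = do.call(rbind, steps)))
  }
  kept_trace <- subset_trace(motion_trace, sc$decision$keep)

  mc <- motion_correct(sc$vol, masks$dilated_brain, trace = kept_trace)
  log_step("motion_correct", n_frames(sc$vol), n_frames(mc$vol))

  k <- if (is.null(ica_k)) config$ica_k else ica_k
  smoothed <- gaussian_smooth(mc$vol, config$pre_ica_fwhm_mm)
  decomp <- spatial_ica(smoothed, masks$brain, k = k, seed = config$seed)
  feats <- extract_features(decomp, masks, vol$tr_s,
                            z_thresh = config$z_thresh)
  labels <- classify_ics(feats)
  log_step("ica_classify", n_frames(mc$vol), n_frames(mc$vol))

  cc <- compcor(mc$vol, masks$wm, masks$csf, n_mc = config$compcor_n_mc,
                alpha = config$compcor_alpha, seed = config$seed,
                null_ve = compcor_null)
  nuis <- nuisance_set(kept_trace, cc)
  # soft cleaning operates on the unsmoothed motion-corrected data, with the
  # IC time courses re-estimated on those frames via spatial regression
  decomp_unsm <- decomp
  decomp_unsm$timecourses <- ic_timecourses(decomp$maps, mc$vol, masks$brain)
  cleaned <- soft_clean(mc$vol, decomp_unsm, labels, nuis)
  log_step("soft_clean", n_frames(mc$vol), n_frames(cleaned))

  cleaned <- gaussian_smooth(cleaned, config$post_fwhm_mm)
  log_step("smooth", n_frames(cleaned), n_frames(cleaned))
  cleaned <- bandpass(cleaned, config$band_low_hz, config$band_high_hz,
                      config$band_order)
  log_step("bandpass", n_frames(cleaned), n_frames(cleaned))

  out <- list(vol = cleaned, scrub = sc$decision, trace = kept_trace,
              fd_raw = fd_raw, ica = decomp, features = feats,
              labels = labels, compcor_p = cc$p, nuisance = nuis,
              excluded = FALSE, steps = do.call(rbind, steps))
  if (keep_mc) attr(out, "mc_vol") <- mc$vol
  out
}

#' Preprocess a phantom group in memory
#'
#' Runs [preprocess_scan] on every scan of a [make_group] result, sharing
#' one Monte-Carlo CompCor null across scans of equal size. Excluded scans
#' are dropped and reported.
#'
#' @param group result of [make_group].
#' @param config a [pipeline_config].
#' @param ica_k per-scan IC count override.
#' @return list: `preproc` (per retained scan), `subjects`, `excluded`
#'   (scan ids).
#' @export
preprocess_group <- function(group, config = pipeline_config(),
                             ica_k = NULL, keep_mc = FALSE) {
  masks <- group$truths[[1]]$masks
  nv <- sum(masks$wm | masks$csf)
  null_ve <- compcor_null(n_frames(group$scans[[1]]), nv,
                          n_mc = config$compcor_n_mc, seed = config$seed)
  out <- list(); subjects <- character(0); excluded <- character(0)
  for (i in seq_along(group$scans)) {
    pp <- preprocess_scan(group$scans[[i]], masks, config, ica_k = ica_k,
                          compcor_null = null_ve, keep_mc = keep_mc)
    if (pp$excluded) {
      excluded <- c(excluded, group$scan_ids[i])
      next
    }
    out[[length(out) + 1L]] <- pp
    subjects <- c(subjects, group$subjects[i])
  }
  list(preproc = out, subjects = subjects, excluded = excluded,
       masks = masks, atlas = group$truths[[1]]$atlas)
}

#' ROI FC analysis of preprocessed scans
#'
#' Truncates to a common length, extracts ROI time courses, forms per-scan
#' Fisher-z matrices, and runs the max-t permutation group analysis.
#'
#' @param vols list of preprocessed [volume4d].
#' @param subjects character vector, subject per scan.
#' @param atlas a [roi_atlas].
#' @param config a [pipeline_config].
#' @param truncate truncate to `config$truncate_frames` first (default
#'   TRUE when all scans are long enough).
#' @return list: `fc` (per-scan `fc_matrix`), `group`
#'   (`group_fc_result` with significance), `subjects`.
#' @export
analyze_fc <- function(vols, subjects, atlas, config = pipeline_config(),
                       truncate = NULL) {
  if (is.null(truncate))
    truncate <- all(vapply(vols, n_frames, integer(1)) >=
                      config$truncate_frames)
  if (truncate) {
    vols <- truncate_to_common_length(vols, config$truncate_frames)
    subjects <- subjects[attr(vols, "source")]
  }
  fc <- lapply(seq_along(vols), function(i) {
    tc <- roi_timecourses(vols[[i]], atlas)
    scan_fc(tc, scan_id = paste0("scan", i), subject_id = subjects[i])
  })
  grp <- permutation_fwer(fc, subjects = subjects, n_perm = config$n_perm,
                          alpha = config$fwer_alpha, seed = config$seed)
  list(fc = fc, group = grp, subjects = subjects)
}

#' Compare nuisance-regression variants
#'
#' Reprocesses the same motion-corrected scans under five cleaning variants
#' -- WM/CSF mean-signal regression, CompCor, ICA soft cleaning alone, ICA
#' cleaning + WM/CSF regression, ICA cleaning + CompCor (the main pipeline)
#' -- followed by identical smoothing/filtering, and returns the group FC
#' matrix of each, on the same ROI ordering.
#'
#' @param preproc_group result of [preprocess_group] (needs the stored ICA,
#'   labels and nuisance of each scan); the variants re-clean from the
#'   motion-corrected data retained inside each record.
#' @param group the originating [make_group] result (for raw scans).
#' @param config a [pipeline_config].
#' @return named list of `group_fc_result`, one per variant.
#' @export
compare_nuisance <- function(preproc_group, group,
                             config = pipeline_config()) {
  masks <- preproc_group$masks
  atlas <- preproc_group$atlas
  variants <- c("wmcsf", "compcor", "ica", "ica_wmcsf", "ica_compcor")
  res <- list()
  for (v in variants) {
    vols <- lapply(preproc_group$preproc, function(pp)
      clean_variant(pp, masks, v, config))
    fcres <- analyze_fc(vols, preproc_group$subjects, atlas, config)
    res[[v]] <- fcres$group
  }
  res
}

# Rebuild the motion-corrected volume for a preprocessed record and apply
# one cleaning variant + smoothing + band-pass.
clean_variant <- function(pp, masks, variant, config) {
  # reconstruct Y_m input: the unsmoothed motion-corrected data are not
  # stored; re-derive from the soft-clean inputs kept on the record
  mcvol <- attr(pp, "mc_vol")
  if (is.null(mcvol)) stop("record lacks cached motion-corrected data; ",
                           "run preprocess_group(keep_mc = TRUE)")
  wmcsf_tc <- function(v) {
    m <- masks$wm | masks$csf
    matrix(rowMeans(vol_to_matrix(v, m)), ncol = 1)
  }
  motion <- pp$trace$params
  nuis <- switch(variant,
    wmcsf = cbind(motion, wmcsf_tc(mcvol)),
    compcor = cbind(motion, pp$nuisance$compcor),
    ica = motion,
    ica_wmcsf = cbind(motion, wmcsf_tc(mcvol)),
    ica_compcor = cbind(motion, pp$nuisance$compcor))
  use_ica <- variant %in% c("ica", "ica_wmcsf", "ica_compcor")
  decomp <- pp$ica
  decomp$timecourses <- ic_timecourses(decomp$maps, mcvol, masks$brain)
  cleaned <- if (use_ica) soft_clean(mcvol, decomp, pp$labels, nuis)
             else matrix_to_vol(residualize(vol_to_matrix(mcvol), nuis),
                                mcvol)
  cleaned <- gaussian_smooth(cleaned, config$post_fwhm_mm)
  bandpass(cleaned, config$band_low_hz, config$band_high_hz,
           config$band_order)
}
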