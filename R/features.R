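# Feature extraction and noise/signal classification of ICs, following the
# rat adaptation of the HCP hand-classification guidelines: three
# "applicable" feature families (tissue overlap of the supra-threshold map,
# sudden time-course jumps, degenerate frequency content) and optional
# "confident" detectors (susceptibility zones, acquisition banding). An IC
# is noise if any confident feature fires or at least two applicable
# families fire.

#' Per-IC features for noise classification
#'
#' Spatial features are fractions of supra-threshold voxels (|z| above
#' `z_thresh`) falling in grey matter, WM/CSF, and the brain-boundary shell.
#' Temporal features come from the standardized time course: the maximal
#' absolute first difference (jump score) and periodogram band fractions
#' (0.01-0.1 Hz; above 0.2 Hz) plus spectral flatness (geometric over
#' arithmetic mean power).
#'
#' @param decomp an `ica_decomposition` from [spatial_ica].
#' @param masks a [mask_set] on the data grid.
#' @param tr_s repetition time in seconds.
#' @param z_thresh map threshold (default 2).
#' @param edge_width brain-boundary shell depth in voxels.
#' @return data.frame with one row per IC: `ic`, `gm_overlap`,
#'   `wm_csf_overlap`, `edge_fraction`, `jump_score`, `low_band_fraction`,
#'   `high_band_fraction`, `spectral_flatness`, `n_supra`.
#' @export
extract_features <- function(decomp, masks, tr_s, z_thresh = 2,
                             edge_width = 1L) {
  stopifnot(inherits(decomp, "ica_decomposition"),
            inherits(masks, "mask_set"))
  brain_idx <- which(decomp$brain)
  edge <- edge_mask(masks, edge_width)[brain_idx]
  wmcsf <- (masks$wm | masks$csf)[brain_idx]
  gm <- gm_mask(masks)[brain_idx] & !edge
  k <- decomp$k
  out <- vector("list", k)
  for (i in seq_len(k)) {
    supra <- abs(decomp$maps[i, ]) > z_thresh
    n_supra <- sum(supra)
    if (n_supra == 0L) {
      warning(sprintf("IC %d has no supra-threshold voxels at |z| > %g",
                      i, z_thresh))
      ov <- c(0, 0, 0)
    } else {
      ov <- c(mean(gm[supra]), mean(wmcsf[supra]), mean(edge[supra]))
    }
    tc <- decomp$timecourses[, i]
    zt <- as.numeric(scale(tc))
    jump <- if (length(zt) > 1) max(abs(diff(zt))) else 0
    sp <- tc_band_power(zt, tr_s)
    out[[i]] <- data.frame(
      ic = i, gm_overlap = ov[1], wm_csf_overlap = ov[2],
      edge_fraction = ov[3], jump_score = jump,
      low_band_fraction = sp["low"], high_band_fraction = sp["high"],
      spectral_flatness = sp["flatness"], n_supra = n_supra)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Periodogram band fractions of a (standardized) time course.
tc_band_power <- function(zt, tr_s, low_band = c(0.01, 0.1),
                          high_cut = 0.2) {
  nt <- length(zt)
  sp <- Mod(stats::fft(zt))^2
  nf <- floor(nt / 2)
  freqs <- seq_len(nf) / (nt * tr_s)
  p <- sp[2:(nf + 1)]
  total <- sum(p)
  if (total <= 0) return(c(low = 0, high = 0, flatness = 1))
  low <- sum(p[freqs >= low_band[1] & freqs <= low_band[2]]) / total
  high <- sum(p[freqs > high_cut]) / total
  flat <- exp(mean(log(pmax(p, 1e-300)))) / mean(p)
  c(low = low, high = high, flatness = flat)
}

#' Default thresholds for the noise-classification rule
#'
#' The published procedure was manual; these quantitative defaults make it
#' automatic and auditable. An applicable "spatial" feature fires when the
#' supra-threshold map is predominately in WM/CSF or at brain boundaries
#' (`wm_csf_overlap + edge_fraction > 0.5` and `gm_overlap < 0.5`);
#' "jumps" fires at jump score > 6; "spectrum" fires when the passband
#' fraction is below 0.5, the high-frequency fraction above 0.5, or spectral
#' flatness above 0.8.
#'
#' @param spatial_dominance,gm_max,jump_max,low_band_min,high_band_max,flatness_max
#'   rule thresholds.
#' @return named list of thresholds.
#' @export
classification_rule <- function(spatial_dominance = 0.5, gm_max = 0.5,
                                jump_max = 6, low_band_min = 0.5,
                                high_band_max = 0.5, flatness_max = 0.8) {
  list(spatial_dominance = spatial_dominance, gm_max = gm_max,
       jump_max = jump_max, low_band_min = low_band_min,
       high_band_max = high_band_max, flatness_max = flatness_max)
}

#' Classify ICs as signal or noise
#'
#' Applies the rat-adapted rule: an IC is a noise component if it has at
#' least one fired "confident" feature or at least two of the three
#' "applicable" features (spatial WM/CSF/edge dominance; sudden time-course
#' jumps; flat / very-low / high-frequency-dominated spectrum).
#'
#' @param features data.frame from [extract_features].
#' @param rule thresholds from [classification_rule].
#' @param confident optional logical matrix or data.frame (ICs x detectors)
#'   of fired confident features (susceptibility zones, acquisition
#'   banding); disabled (all FALSE) by default.
#' @return data.frame with one row per IC: `ic`, `is_noise`,
#'   `fired_applicable` and `fired_confident` (comma-separated audit
#'   strings), plus the individual feature firings.
#' @export
classify_ics <- function(features, rule = classification_rule(),
                         confident = NULL) {
  stopifnot(all(is.finite(as.matrix(features[, c(
    "gm_overlap", "wm_csf_overlap", "edge_fraction", "jump_score",
    "low_band_fraction", "high_band_fraction", "spectral_flatness")]))))
  spatial <- (features$wm_csf_overlap + features$edge_fraction) >
    rule$spatial_dominance & features$gm_overlap < rule$gm_max
  jumps <- features$jump_score > rule$jump_max
  spectrum <- features$low_band_fraction < rule$low_band_min |
    features$high_band_fraction > rule$high_band_max |
    features$spectral_flatness > rule$flatness_max
  n_ic <- nrow(features)
  if (is.null(confident)) {
    conf <- matrix(FALSE, n_ic, 0)
  } else {
    conf <- as.matrix(confident)
    stopifnot(nrow(conf) == n_ic)
  }
  n_conf <- if (ncol(conf)) rowSums(conf) else rep(0L, n_ic)
  n_appl <- spatial + jumps + spectrum
  fired_appl <- vapply(seq_len(n_ic), function(i)
    paste(c("spatial", "jumps", "spectrum")[c(spatial[i], jumps[i],
                                              spectrum[i])],
          collapse = ","), character(1))
  fired_conf <- vapply(seq_len(n_ic), function(i) {
    nm <- colnames(conf)
    if (is.null(nm)) nm <- paste0("confident", seq_len(ncol(conf)))
    paste(nm[conf[i, ]], collapse = ",")
  }, character(1))
  data.frame(ic = features$ic,
             is_noise = n_conf >= 1L | n_appl >= 2L,
             fired_applicable = fired_appl,
             fired_confident = fired_conf,
             spatial = spatial, jumps = jumps, spectrum = spectrum,
             stringsAsFactors = FALSE)
}

#' Slice-banding confident detector
#'
#' Flags ICs whose supra-threshold map energy alternates along the slice
#' axis: a single high slice-frequency (upper half of the profile spectrum,
#' as produced by interleaved-acquisition artefacts) carries more than
#' `energy_min` of the per-slice |z| profile's spectral energy.
#'
#' @param decomp an `ica_decomposition`.
#' @param z_thresh map threshold.
#' @param energy_min dominant-frequency energy fraction required to fire.
#' @return logical vector, one element per IC.
#' @export
detect_slice_banding <- function(decomp, z_thresh = 2, energy_min = 0.6) {
  d <- dim(decomp$brain)
  brain_idx <- which(decomp$brain)
  slice_of <- ((brain_idx - 1L) %/% (d[1] * d[2])) + 1L
  vapply(seq_len(decomp$k), function(i) {
    # signed supra-threshold values: alternating-sign banding survives,
    # single-signed blobs collapse to low slice frequencies
    w <- decomp$maps[i, ] * (abs(decomp$maps[i, ]) > z_thresh)
    prof <- vapply(seq_len(d[3]), function(s) sum(w[slice_of == s]),
                   numeric(1))
    if (all(prof == 0) || d[3] < 4) return(FALSE)
    prof <- prof - mean(prof)
    p <- Mod(stats::fft(prof))^2
    nf <- floor(d[3] / 2)
    p <- p[2:(nf + 1)]
    if (sum(p) == 0) return(FALSE)
    upper <- p[seq(ceiling(nf / 2), nf)]
    max(upper) / sum(p) > energy_min
  }, logical(1))
}
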