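# Synthetic phantom generator with full ground truth: an ellipsoidal brain
# with GM/WM/CSF compartments, planted band-limited network signals
# organized into modules, planted artefact components that violate the
# signal-IC feature profile, injected rigid motion, and thermal noise.
# Defaults emulate the desk-scale version of the acquisition geometry
# (64x64x20 EPI at TR 1 s, halved to 32x32x10).

#' Phantom specification
#'
#' The stated world for all synthetic tests. Networks are sets of spherical
#' GM blobs sharing a band-limited (0.01-0.1 Hz) time course; networks are
#' grouped into modules whose members share a common module time course with
#' weight `module_coupling`. Artefacts are built-in spatial/temporal
#' patterns chosen to fire the noise-classification features: `edge_spikes`
#' (brain-boundary ring with a spiking time course), `wm_highfreq` (WM blob
#' with >0.2 Hz content), `csf_flat` (ventricle with white-noise time
#' course). Motion is an iid parameter jitter plus optional sustained
#' displacement steps at spike frames.
#'
#' @param grid spatial dimensions (default 32 x 32 x 10).
#' @param nt number of frames (default 300).
#' @param voxel_size_mm voxel size (default 0.5 x 0.5 x 1 mm).
#' @param tr_s repetition time in seconds (default 1).
#' @param n_networks number of planted networks (default 4).
#' @param rois_per_network spherical blobs per network (default 2).
#' @param n_modules number of modules the networks are split into.
#' @param module_coupling weight of the shared module time course in each
#'   network time course (0 = independent networks).
#' @param network_amp network signal amplitude (baseline GM is 100).
#' @param artefacts character vector of built-in artefact names (subset of
#'   "edge_spikes", "wm_highfreq", "csf_flat").
#' @param artefact_amp artefact amplitude.
#' @param motion_jitter_mm,motion_jitter_rad iid per-frame motion jitter.
#' @param motion_spike_frames frames at which a sustained displacement step
#'   occurs.
#' @param motion_spike_mm step size in mm.
#' @param noise_sigma thermal noise standard deviation.
#' @param extra_rois additional no-network ROIs planted in GM.
#' @param roi_radius_mm blob radius in mm.
#' @param seed integer master seed; everything derives from it.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(32L, 32L, 10L), nt = 300L,
                         voxel_size_mm = c(0.5, 0.5, 1), tr_s = 1,
                         n_networks = 4L, rois_per_network = 2L,
                         n_modules = 2L, module_coupling = 0.8,
                         network_amp = 3,
                         artefacts = c("edge_spikes", "wm_highfreq",
                                       "csf_flat"),
                         artefact_amp = 5,
                         motion_jitter_mm = 0.01,
                         motion_jitter_rad = 0.001,
                         motion_spike_frames = integer(0),
                         motion_spike_mm = 0.5,
                         noise_sigma = 2, extra_rois = 2L,
                         roi_radius_mm = 1.1, seed = 1L) {
  if (length(artefacts))
    artefacts <- match.arg(artefacts, several.ok = TRUE)
  structure(as.list(environment()), class = "phantom_spec")
}

substream <- function(seed, i) as.integer((seed %% 100003L) * 7919L + i)

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  force(expr)
}

ellipsoid_mask <- function(grid, center_frac, semi_frac) {
  cx <- (grid - 1) * center_frac
  ax <- pmax(grid * semi_frac, 0.5)
  x <- (seq_len(grid[1]) - 1 - cx[1]) / ax[1]
  y <- (seq_len(grid[2]) - 1 - cx[2]) / ax[2]
  z <- (seq_len(grid[3]) - 1 - cx[3]) / ax[3]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= 1
}

phantom_anatomy <- function(spec) {
  g <- spec$grid
  brain <- ellipsoid_mask(g, c(.5, .5, .5), c(.38, .32, .42))
  # off-centre compartments and fixed texture bumps break the rotational
  # symmetry of the ellipsoid so that all six rigid parameters are
  # identifiable by intensity registration (real brains are asymmetric too)
  wm <- ellipsoid_mask(g, c(.46, .54, .50), c(.18, .20, .24))
  csf <- ellipsoid_mask(g, c(.56, .44, .50), c(.07, .08, .12))
  wm <- wm & !csf & brain
  csf <- csf & brain
  base <- array(0, g)
  base[brain] <- 100
  base[wm] <- 80
  base[csf] <- 120
  bump_at <- function(frac, sigma_vox, amp) {
    cx <- (g - 1) * frac
    x <- (seq_len(g[1]) - 1 - cx[1])^2
    y <- (seq_len(g[2]) - 1 - cx[2])^2
    z <- ((seq_len(g[3]) - 1 - cx[3]) * g[1] / g[3])^2
    amp * exp(-outer(outer(x, y, "+"), z, "+") / (2 * sigma_vox^2))
  }
  texture <- bump_at(c(.34, .42, .45), 2.0, 25) +
    bump_at(c(.63, .57, .55), 2.5, -20) +
    bump_at(c(.44, .66, .50), 2.0, 18) +
    bump_at(c(.57, .33, .60), 1.8, -15)
  base <- base + texture * brain
  # smooth the anatomy so intensity-based registration has gradients
  bv <- volume4d(array(base, c(g, 1L)), spec$voxel_size_mm, spec$tr_s)
  base <- array(gaussian_smooth(bv, 2 * min(spec$voxel_size_mm))$data, g)
  list(base = base, masks = mask_set(brain, wm, csf, dilate = 2L))
}

#' Band-limited Gaussian time course
#'
#' White Gaussian noise restricted to a frequency band by Fourier masking,
#' standardized to zero mean and unit variance. These survive the pipeline's
#' band-pass filter by construction.
#'
#' @param nt number of samples.
#' @param tr_s sampling interval in seconds.
#' @param band passband in Hz.
#' @param seed integer seed.
#' @return numeric vector of length `nt`.
#' @export
bandlimited_tc <- function(nt, tr_s, band = c(0.01, 0.1), seed = 1L) {
  with_seed(seed, {
    x <- stats::rnorm(nt)
    X <- stats::fft(x)
    freqs <- c(0, seq_len(nt - 1)) / (nt * tr_s)
    freqs <- pmin(freqs, 1 / tr_s - freqs)   # two-sided
    keep <- freqs >= band[1] & freqs <= band[2]
    X[!keep] <- 0
    y <- Re(stats::fft(X, inverse = TRUE)) / nt
    as.numeric(scale(y))
  })
}

artefact_tc <- function(kind, nt, tr_s, seed) {
  with_seed(seed, switch(kind,
    edge_spikes = {
      tc <- 0.5 * stats::rnorm(nt)
      # spike rate ~1/60 frames, matching the few-percent scrub fractions
      # seen in practice, rather than a fixed count
      n_spk <- max(1L, min(5L, nt %/% 60L))
      at <- sort(sample.int(max(nt - 2L, 1L), n_spk)) + 1L
      tc[at] <- tc[at] + 8 * sample(c(-1, 1), n_spk, replace = TRUE)
      tc
    },
    wm_highfreq = {
      f <- 0.3 * min(1, (1 / tr_s) / 2 / 0.35)  # keep below Nyquist
      sin(2 * pi * f * seq_len(nt) * tr_s) + 0.2 * stats::rnorm(nt)
    },
    csf_flat = stats::rnorm(nt),
    stop("unknown artefact kind: ", kind)))
}

artefact_map <- function(kind, anat, spec) {
  masks <- anat$masks
  switch(kind,
    edge_spikes = edge_mask(masks) * 1,
    wm_highfreq = masks$wm * 1,
    csf_flat = masks$csf * 1,
    stop("unknown artefact kind: ", kind))
}

place_roi_centers <- function(spec, anat, n, seed) {
  g <- spec$grid
  vz <- spec$voxel_size_mm
  inner <- array(erode3d_cpp(anat$masks$brain, g,
                             if (min(g) >= 10L) 2L else 1L), g)
  forbid <- array(dilate3d_cpp(anat$masks$wm | anat$masks$csf, g, 1L), g)
  cand <- which(inner & !forbid & gm_mask(anat$masks), arr.ind = TRUE)
  if (nrow(cand) < n) stop("phantom grid too small to place ROIs")
  with_seed(seed, {
    # place with generous separation, relaxing down to the no-overlap
    # floor on crowded grids
    for (min_sep in seq(2 * spec$roi_radius_mm + min(vz),
                        2 * spec$roi_radius_mm, length.out = 4)) {
      centers <- matrix(NA_real_, 0, 3)
      ord <- sample.int(nrow(cand))
      for (i in ord) {
        p <- cand[i, ] * vz
        if (nrow(centers) == 0 ||
            min(sqrt(rowSums(sweep(centers, 2, p)^2))) >= min_sep) {
          centers <- rbind(centers, p)
          if (nrow(centers) == n) break
        }
      }
      if (nrow(centers) == n) break
    }
    if (nrow(centers) < n)
      stop("could not place ", n, " non-overlapping ROIs on this grid")
    sweep(centers, 2, vz, "/")   # back to voxel units
  })
}

sphere_mask <- function(grid, center_vox, radius_mm, voxel_size_mm) {
  x <- (seq_len(grid[1]) - center_vox[1]) * voxel_size_mm[1]
  y <- (seq_len(grid[2]) - center_vox[2]) * voxel_size_mm[2]
  z <- (seq_len(grid[3]) - center_vox[3]) * voxel_size_mm[3]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= radius_mm^2
}

#' Generate a synthetic scan with ground truth
#'
#' Builds the phantom: baseline anatomy + sum of network signals + sum of
#' artefacts, each frame rigidly displaced according to the motion schedule
#' (the stored ground-truth parameters are the frame-to-first transforms, so
#' motion estimation should recover them directly), plus iid Gaussian noise.
#' Identical spec and seed give bit-identical output.
#'
#' @param spec a [phantom_spec].
#' @param scan_seed optional seed overriding `spec$seed` (used by
#'   [make_group] for per-scan substreams).
#' @param network_amp_scale optional per-network amplitude multipliers
#'   (subject random effects).
#' @return list with `vol` (raw [volume4d]) and `truth` (list: `masks`,
#'   `atlas`, `network_maps`, `network_tcs`, `module_of_network`,
#'   `artefact_maps`, `artefact_tcs`, `artefact_kinds`, `motion_params`,
#'   `fd_mm`, `sc`, `roi_network`).
#' @export
make_phantom <- function(spec = phantom_spec(), scan_seed = NULL,
                         network_amp_scale = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  seed0 <- if (is.null(scan_seed)) spec$seed else scan_seed
  anat <- phantom_anatomy(spec)
  g <- spec$grid; nt <- spec$nt
  vz <- spec$voxel_size_mm

  # ROI layout is derived from the master spec seed (shared across a group)
  n_roi <- spec$n_networks * spec$rois_per_network + spec$extra_rois
  centers <- place_roi_centers(spec, anat, n_roi, substream(spec$seed, 1L))
  labels <- array(0L, g)
  roi_network <- integer(n_roi)
  for (i in seq_len(n_roi)) {
    sph <- sphere_mask(g, centers[i, ], spec$roi_radius_mm, vz) &
      anat$masks$brain
    labels[sph] <- i
    roi_network[i] <- if (i <= spec$n_networks * spec$rois_per_network)
      ((i - 1L) %/% spec$rois_per_network) + 1L else 0L
  }
  affine <- default_affine(vz, g)
  atlas <- roi_atlas(labels,
                     data.frame(label = seq_len(n_roi),
                                name = sprintf("ROI%02d", seq_len(n_roi)),
                                system = ifelse(roi_network > 0,
                                                sprintf("network%d",
                                                        roi_network),
                                                "none")),
                     affine = affine)

  # network time courses: module-shared + unique parts
  module_of <- ((seq_len(spec$n_networks) - 1L) %%
                  max(spec$n_modules, 1L)) + 1L
  mod_tc <- vapply(seq_len(max(spec$n_modules, 1L)), function(m)
    bandlimited_tc(nt, spec$tr_s, seed = substream(seed0, 100L + m)),
    numeric(nt))
  w <- spec$module_coupling
  net_tcs <- vapply(seq_len(spec$n_networks), function(i) {
    uniq <- bandlimited_tc(nt, spec$tr_s, seed = substream(seed0, 200L + i))
    w * mod_tc[, module_of[i]] + sqrt(max(0, 1 - w^2)) * uniq
  }, numeric(nt))
  amp <- rep(spec$network_amp, spec$n_networks)
  if (!is.null(network_amp_scale)) amp <- amp * network_amp_scale
  net_maps <- lapply(seq_len(spec$n_networks), function(i)
    (array(labels %in% which(roi_network == i), g)) * 1)

  art_kinds <- spec$artefacts
  art_maps <- lapply(art_kinds, artefact_map, anat = anat, spec = spec)
  art_tcs <- vapply(seq_along(art_kinds), function(i)
    artefact_tc(art_kinds[i], nt, spec$tr_s, substream(seed0, 300L + i)),
    numeric(nt))
  art_tcs <- matrix(art_tcs, nrow = nt)

  # motion schedule: ground truth is the frame-to-first parameter series
  P <- matrix(0, nt, 6)
  if (spec$motion_jitter_mm > 0 || spec$motion_jitter_rad > 0) {
    P <- with_seed(substream(seed0, 400L), {
      cbind(matrix(stats::rnorm(3 * nt, 0, spec$motion_jitter_mm), nt, 3),
            matrix(stats::rnorm(3 * nt, 0, spec$motion_jitter_rad), nt, 3))
    })
  }
  for (f in spec$motion_spike_frames)
    P[seq(f, nt), 1] <- P[seq(f, nt), 1] + spec$motion_spike_mm
  P[1, ] <- 0
  colnames(P) <- c("tx", "ty", "tz", "ax", "ay", "az")

  center_w <- world_centroid(anat$base, affine)
  data <- array(0, c(g, nt))
  any_motion <- any(P != 0)
  for (t in seq_len(nt)) {
    frame <- anat$base
    for (i in seq_len(spec$n_networks))
      frame <- frame + amp[i] * net_tcs[t, i] * net_maps[[i]]
    if (length(art_kinds))
      for (i in seq_along(art_kinds))
        frame <- frame + spec$artefact_amp * art_tcs[t, i] * art_maps[[i]]
    if (any_motion && any(P[t, ] != 0)) {
      # stored params are frame->first; the frame is displaced by the inverse
      tf <- invert_rigid(rigid_transform(P[t, 1], P[t, 2], P[t, 3],
                                         P[t, 4], P[t, 5], P[t, 6],
                                         center = center_w))
      frame <- apply_rigid(frame, tf, affine = affine, interp = "cubic")
    }
    data[, , , t] <- frame
  }
  if (spec$noise_sigma > 0) {
    data <- data + with_seed(substream(seed0, 500L),
      array(stats::rnorm(length(data), 0, spec$noise_sigma), dim(data)))
  }

  n_net_roi <- spec$n_networks * spec$rois_per_network
  sc <- matrix(0L, n_roi, n_roi)
  for (i in seq_len(n_net_roi))
    for (j in seq_len(n_net_roi))
      if (i != j && roi_network[i] == roi_network[j]) sc[i, j] <- 1L

  truth <- list(masks = anat$masks, atlas = atlas, baseline = anat$base,
                network_maps = net_maps, network_tcs = net_tcs,
                network_amp = amp, module_of_network = module_of,
                artefact_maps = art_maps, artefact_tcs = art_tcs,
                artefact_kinds = art_kinds, motion_params = P,
                fd_mm = compute_fd(P, r_mm = 5), sc = sc,
                roi_network = roi_network)
  list(vol = volume4d(data, vz, spec$tr_s, affine), truth = truth)
}

#' Generate a multi-subject phantom group
#'
#' All subjects share the network layout and module structure; each subject
#' draws a random multiplicative amplitude effect per network (log-normal
#' with sd `subject_sigma`), exercising the random-intercept group model.
#' Scans within a subject share the subject effect but draw independent time
#' courses, motion and noise. Optionally writes a BIDS-like dataset tree
#' (images, sidecars, masks, atlas CSV, truth JSON).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param scans_per_subject scans per subject.
#' @param spec a [phantom_spec]; its `seed` drives everything.
#' @param subject_sigma subject random-effect sd on log network amplitude
#'   (0 makes all subjects' true FC identical).
#' @param dir optional directory to write the dataset to.
#' @return list with `scans` (list of [volume4d]), `truths` (per scan),
#'   `subjects` (character vector per scan), `scan_ids`, `spec`, and
#'   `dir` when written.
#' @export
make_group <- function(n_subjects, scans_per_subject = 1L,
                       spec = phantom_spec(), subject_sigma = 0.2,
                       dir = NULL) {
  stopifnot(n_subjects >= 2L)
  scans <- list(); truths <- list()
  subjects <- character(0); scan_ids <- character(0)
  for (s in seq_len(n_subjects)) {
    eff <- with_seed(substream(spec$seed, 9000L + s),
                     exp(stats::rnorm(spec$n_networks, 0, subject_sigma)))
    for (r in seq_len(scans_per_subject)) {
      ph <- make_phantom(spec,
                         scan_seed = substream(spec$seed,
                                               1000L + s * 20L + r),
                         network_amp_scale = eff)
      scans[[length(scans) + 1L]] <- ph$vol
      truths[[length(truths) + 1L]] <- ph$truth
      subjects <- c(subjects, sprintf("sub-%02d", s))
      scan_ids <- c(scan_ids, sprintf("sub-%02d_run-%02d_bold", s, r))
    }
  }
  out <- list(scans = scans, truths = truths, subjects = subjects,
              scan_ids = scan_ids, spec = spec)
  if (!is.null(dir)) {
    write_group_dataset(out, dir)
    out$dir <- dir
  }
  out
}

write_group_dataset <- function(group, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t1 <- group$truths[[1]]
  mdir <- file.path(dir, "masks")
  dir.create(mdir, showWarnings = FALSE)
  aff <- group$scans[[1]]$affine
  vz <- group$scans[[1]]$voxel_size_mm
  for (nm in c("brain", "wm", "csf", "dilated_brain")) {
    write_volume(volume4d(array(t1$masks[[nm]] * 1,
                                c(dim(t1$masks[[nm]]), 1L)), vz, 1, aff),
                 file.path(mdir, paste0(nm, ".nii.gz")))
  }
  write_volume(volume4d(array(t1$atlas$labels * 1.0,
                              c(dim(t1$atlas$labels), 1L)), vz, 1, aff),
               file.path(mdir, "atlas.nii.gz"))
  utils::write.csv(t1$atlas$table, file.path(mdir, "atlas.csv"),
                   row.names = FALSE)
  utils::write.csv(t1$sc, file.path(mdir, "sc.csv"), row.names = FALSE)
  for (i in seq_along(group$scans)) {
    sub <- group$subjects[i]
    fdir <- file.path(dir, sub, "func")
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(fdir, paste0(group$scan_ids[i], ".nii.gz"))
    write_volume(group$scans[[i]], p)
    rec <- scan_record(group$scan_ids[i], sub, n_frames(group$scans[[i]]), p)
    write_sidecar(rec, group$truths[[i]]$fd_mm,
                  qc = list(true_motion = "phantom"))
  }
  jsonlite::write_json(list(generator = "ratfc phantom",
                            seed = group$spec$seed,
                            n_scans = length(group$scans)),
                       file.path(dir, "dataset.json"), auto_unbox = TRUE)
  invisible(dir)
}
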