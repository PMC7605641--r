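# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# Smooth analytic image: sum of wide Gaussian blobs evaluated at world
# coordinates, optionally under a rigid world map (exact, no resampling).
blob_image <- function(d, affine, centers, sigmas, amps, world_map = NULL) {
  g <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                             z = 0:(d[3] - 1)))
  w <- t(affine[1:3, 1:3] %*% t(g) + affine[1:3, 4])
  if (!is.null(world_map))
    w <- t(world_map[1:3, 1:3] %*% t(w) + world_map[1:3, 4])
  v <- 0
  for (i in seq_len(nrow(centers)))
    v <- v + amps[i] * exp(-rowSums(sweep(w, 2, centers[i, ])^2) /
                             (2 * sigmas[i]^2))
  array(v, d)
}

# Standard smooth 32^3 registration fixture.
smooth_fixture <- function(seed = 5, d = c(32L, 32L, 32L)) {
  set.seed(seed)
  centers <- matrix(stats::runif(12, -8, 8), 4, 3)
  sigmas <- c(6, 4, 5, 3)
  amps <- c(100, 60, 80, 50)
  affine <- diag(4)
  affine[1:3, 4] <- -(d - 1) / 2
  list(img = blob_image(d, affine, centers, sigmas, amps),
       affine = affine, d = d, centers = centers, sigmas = sigmas,
       amps = amps)
}

# The fixture image such that estimate_rigid(moved, img) recovers `tr`:
# moved(x) = img(T x), evaluated analytically (no resampling).
smooth_fixture_moved <- function(fx, tr) {
  blob_image(fx$d, fx$affine, fx$centers, fx$sigmas, fx$amps,
             world_map = rigid_matrix(tr))
}

# fc_matrix straight from a symmetric z matrix.
fc_from_z <- function(z, subject, scan = subject) {
  diag(z) <- 0
  structure(list(z = z, roi_ids = as.character(seq_len(nrow(z))),
                 scan_id = scan, subject_id = subject),
            class = "fc_matrix")
}

# Random-noise fc_matrix from ROI time courses.
fc_noise_scan <- function(n_roi, nt, subject) {
  tc <- matrix(stats::rnorm(n_roi * nt), n_roi, nt)
  suppressWarnings(scan_fc(tc, scan_id = subject, subject_id = subject))
}

# One-sample t, written independently of the package internals.
classical_t <- function(x) mean(x) / (stats::sd(x) / sqrt(length(x)))

# Brute-force Lance-Williams Ward (ward.D2 convention: recurrence on
# squared distances, heights reported on the distance scale).
ward_linkage_bruteforce <- function(D) {
  n <- nrow(D)
  S <- D^2
  active <- seq_len(n)
  sizes <- rep(1L, n)
  id <- -seq_len(n)            # hclust convention: negatives are leaves
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); bv <- Inf
    for (i in seq_along(active)[-length(active)])
      for (j in seq(i + 1L, length(active))) {
        v <- S[active[i], active[j]]
        if (v < bv) { bv <- v; best <- c(i, j) }
      }
    i <- best[1]; j <- best[2]
    ai <- active[i]; aj <- active[j]
    height[step] <- sqrt(bv)
    merge[step, ] <- sort(c(id[ai], id[aj]))
    ni <- sizes[ai]; nj <- sizes[aj]
    for (m in seq_along(active)) {
      am <- active[m]
      if (am == ai || am == aj) next
      nk <- sizes[am]
      v <- ((ni + nk) * S[ai, am] + (nj + nk) * S[aj, am] -
              nk * S[ai, aj]) / (ni + nj + nk)
      S[ai, am] <- S[am, ai] <- v
    }
    sizes[ai] <- ni + nj
    id[ai] <- step
    active <- active[-j]
  }
  list(merge = merge, height = height)
}
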