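# Rigid transforms, registration, framewise displacement, scrubbing,
# motion correction.

test_that("rigid transforms compose, invert and round-trip", {
  tr <- rigid_transform(1.2, -0.4, 0.3, 0.05, -0.02, 0.08,
                        center = c(1, 2, -1))
  M <- rigid_matrix(tr) %*% rigid_matrix(invert_rigid(tr))
  expect_lt(max(abs(M - diag(4))), 1e-12)
  expect_error(rigid_transform(Inf), "finite")
  # Euler extraction is consistent
  tr2 <- ratfc:::rigid_from_matrix(rigid_matrix(tr), center = tr$center)
  expect_equal(ratfc:::rigid_params(tr2), ratfc:::rigid_params(tr),
               tolerance = 1e-10)
})

test_that("apply_rigid: identity, exact integer shifts, round-trip", {
  fx <- smooth_fixture()
  out <- apply_rigid(fx$img, rigid_transform(), affine = fx$affine)
  expect_equal(out, fx$img, tolerance = 1e-12)
  # integer-voxel translation is interpolation-free
  sh <- apply_rigid(fx$img, rigid_transform(tx = 2), affine = fx$affine)
  expect_equal(sh[3:32, , ], fx$img[1:30, , ], tolerance = 1e-12)
  # t then t^-1 recovers interior voxels within interpolation tolerance
  smooth_img <- blob_image(fx$d, fx$affine,
                           matrix(c(0, 0, 0, 5, -4, 3), 2, 3, byrow = TRUE),
                           sigmas = c(9, 7), amps = c(100, 60))
  tr <- rigid_transform(0.7, -0.3, 0.4, 0.04, 0.02, -0.05)
  back <- apply_rigid(apply_rigid(smooth_img, tr, affine = fx$affine),
                      invert_rigid(tr), affine = fx$affine)
  core <- 9:24
  rel <- max(abs((back - smooth_img)[core, core, core])) /
    diff(range(smooth_img[core, core, core]))
  expect_lt(rel, 0.02)
})

test_that("estimate_rigid recovers identity and planted transforms", {
  fx <- smooth_fixture()
  est0 <- estimate_rigid(fx$img, fx$img, affine = fx$affine, levels = 2)
  expect_lt(max(abs(ratfc:::rigid_params(est0))), 1e-3)
  set.seed(42)
  for (i in 1:5) {
    p <- c(runif(3, -2, 2), runif(3, -0.1, 0.1))
    cen <- ratfc:::world_centroid(fx$img, fx$affine)
    tru <- rigid_transform(p[1], p[2], p[3], p[4], p[5], p[6], center = cen)
    moved <- smooth_fixture_moved(fx, tru)
    est <- estimate_rigid(moved, fx$img, affine = fx$affine, levels = 3)
    err <- abs(ratfc:::rigid_params(est) - p)
    expect_lt(max(err[1:3]), 0.1)
    expect_lt(max(err[4:6]), 0.005)
  }
})

test_that("compute_fd follows the printed formula", {
  # forced by the formula: |dx|+|dy|+|dz| + r(|da|+|db|+|dg|)
  p <- matrix(0, 3, 6)
  p[2, ] <- c(0.01, 0.02, 0.03, 0.004, 0.002, 0.002)
  p[3, ] <- p[2, ]
  fd <- compute_fd(p, r_mm = 5)
  expect_equal(fd, c(0, 0.06 + 5 * 0.008, 0))
  # constant transforms -> all zero
  pc <- matrix(rep(c(1, 2, 3, .1, .2, .3), each = 10), 10, 6)
  expect_equal(compute_fd(pc), rep(0, 10))
  expect_error(compute_fd(matrix(NA_real_, 2, 6)), "finite")
})

test_that("FD invariances: offset, reversal, nonnegativity", {
  set.seed(3)
  for (rep in 1:20) {
    p <- matrix(rnorm(60, 0, 0.1), 10, 6)
    fd <- compute_fd(p)
    expect_true(all(fd >= 0))
    # adding a constant transform to every frame leaves FD unchanged
    off <- matrix(rep(rnorm(6), each = 10), 10, 6)
    expect_equal(compute_fd(p + off), fd)
    # reversed order: reversed FD, shifted by one
    fd_rev <- compute_fd(p[10:1, ])
    expect_equal(fd_rev[-1], rev(fd[-1]))
  }
})

test_that("scrub implements the first-10, neighbour, and 90% rules", {
  v <- volume4d(array(rnorm(2 * 2 * 2 * 600), c(2, 2, 2, 600)))
  # no exceedances: frames 11..600 kept
  s <- scrub(v, rep(0.1, 600))
  expect_equal(which(s$decision$keep), 11:600)
  expect_equal(n_frames(s$vol), 590L)
  expect_false(s$decision$scan_excluded)
  # single exceedance at frame 100 drops 99, 100, 101 as well
  fd <- rep(0.1, 600); fd[100] <- 0.25
  s2 <- scrub(v, fd)
  expect_equal(which(!s2$decision$keep), sort(c(1:10, 99, 100, 101)))
  # one-sided neighbour options
  s2b <- scrub(v, fd, neighbors = "before")
  expect_equal(which(!s2b$decision$keep), sort(c(1:10, 99, 100)))
  s2a <- scrub(v, fd, neighbors = "after")
  expect_equal(which(!s2a$decision$keep), sort(c(1:10, 100, 101)))
  # 80 spread-out exceedances -> kept fraction < 0.9 -> excluded
  fd3 <- rep(0.1, 600); fd3[seq(15, by = 7, length.out = 80)] <- 0.3
  s3 <- scrub(v, fd3)
  expect_true(s3$decision$scan_excluded)
  expect_lt(1 - s3$decision$scrubbed_fraction, 0.9)
  # all frames dropped is an error
  expect_error(scrub(v, rep(1, 600), n_drop_first = 600), "every frame")
  expect_error(scrub(v, rep(0.1, 10)), "length")
})

test_that("scrubbing is idempotent", {
  set.seed(4)
  v <- volume4d(array(rnorm(2 * 2 * 2 * 200), c(2, 2, 2, 200)))
  fd <- abs(rnorm(200, 0.08, 0.06))
  s1 <- scrub(v, fd)
  fd2 <- fd[s1$decision$keep]
  s2 <- scrub(s1$vol, fd2, n_drop_first = 0)
  expect_equal(n_frames(s2$vol), n_frames(s1$vol))
  expect_true(all(s2$decision$keep))
})

test_that("motion-free phantom yields near-zero parameters and r > 0.999", {
  sp <- phantom_spec(nt = 12L,
                     motion_jitter_mm = 0, motion_jitter_rad = 0,
                     artefacts = character(0), noise_sigma = 0.5)
  ph <- make_phantom(sp)
  mc <- motion_correct(ph$vol, ph$truth$masks$dilated_brain)
  expect_lt(max(abs(mc$trace$params[, 1:3])), 0.02)
  expect_lt(max(abs(mc$trace$params[, 4:6])), 0.005)
  X <- ratfc:::vol_to_matrix(ph$vol, ph$truth$masks$brain)
  Y <- ratfc:::vol_to_matrix(mc$vol, ph$truth$masks$brain)
  expect_gt(cor(as.numeric(X), as.numeric(Y)), 0.999)
})

test_that("FD of an integer-shift motion phantom matches the schedule", {
  sp <- phantom_spec(nt = 40L,
                     artefacts = character(0), n_networks = 0L,
                     rois_per_network = 0L, extra_rois = 3L,
                     noise_sigma = 0.5, motion_jitter_mm = 0,
                     motion_jitter_rad = 0)
  ph <- make_phantom(sp)
  aff <- ph$vol$affine
  cen <- ratfc:::world_centroid(ph$truth$baseline, aff)
  set.seed(11)
  P <- matrix(0, 40, 6)
  P[, 1] <- sample(-1:1, 40, TRUE) * sp$voxel_size_mm[1]
  P[, 2] <- sample(-1:1, 40, TRUE) * sp$voxel_size_mm[2]
  P[1, ] <- 0
  dat <- ph$vol$data
  for (t in 2:40) {
    tf <- invert_rigid(rigid_transform(P[t, 1], P[t, 2], 0, center = cen))
    dat[, , , t] <- apply_rigid(get_frame(ph$vol, t), tf, affine = aff)
  }
  v <- volume4d(dat, sp$voxel_size_mm, 1, aff)
  tr <- estimate_motion_trace(v, mask = ph$truth$masks$dilated_brain)
  expect_lt(max(abs(tr$fd_mm - compute_fd(P))), 0.02)
})

test_that("injected jitter is recovered and correction tightens the scan", {
  sp <- phantom_spec(nt = 40L,
                     artefacts = character(0),
                     motion_jitter_mm = 0.05, motion_jitter_rad = 0.004,
                     motion_spike_frames = 20L)
  ph <- make_phantom(sp)
  mc <- motion_correct(ph$vol, ph$truth$masks$dilated_brain)
  for (j in 1:3)
    expect_gt(cor(mc$trace$params[, j], ph$truth$motion_params[, j]), 0.95)
  expect_gt(cor(mc$trace$fd_mm, ph$truth$fd_mm), 0.95)
  # corrected frames realign: within-brain temporal std shrinks
  sdv <- function(v) mean(apply(ratfc:::vol_to_matrix(v, ph$truth$masks$brain),
                                2, sd))
  expect_lt(sdv(mc$vol), sdv(ph$vol))
  # mean FD lands in the sidecar
  rec <- ratfc:::scan_record("s", "sub", 40L, tempfile(fileext = ".nii"))
  p <- write_sidecar(rec, mc$trace$fd_mm, path = tempfile(fileext = ".json"))
  expect_equal(read_sidecar(p)$mean_fd_mm, mean(mc$trace$fd_mm))
})

test_that("motion parameter text files round-trip", {
  p <- matrix(rnorm(30), 5, 6)
  tr <- ratfc:::motion_trace(p, compute_fd(p), 5)
  f <- tempfile()
  write_motion_params(tr, f)
  expect_equal(unname(as.matrix(read.table(f))), p, tolerance = 1e-12)
  unlink(f)
})
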