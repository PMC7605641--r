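# Per-scan spatial ICA, time-course regression, features, classification.

make_ica_phantom <- function(seed = 1, coupling = 0, noise = 0.5,
                             artefacts = character(0)) {
  sp <- phantom_spec(motion_jitter_mm = 0, motion_jitter_rad = 0,
                     module_coupling = coupling, artefacts = artefacts,
                     noise_sigma = noise, seed = seed)
  make_phantom(sp)
}

test_that("spatial ICA recovers disjoint planted networks", {
  ph <- make_ica_phantom()
  masks <- ph$truth$masks
  sm <- gaussian_smooth(ph$vol, 0.7)
  dec <- spatial_ica(sm, masks$brain, k = 6, seed = 1)
  bidx <- which(masks$brain)
  M <- sapply(ph$truth$network_maps, function(m)
    apply(dec$maps, 1, function(icm) abs(cor(icm, m[bidx]))))
  best <- apply(M, 2, which.max)
  expect_true(all(apply(M, 2, max) > 0.9))
  expect_equal(length(unique(best)), 4L)
  # time courses track the planted ones
  for (i in 1:4)
    expect_gt(abs(cor(dec$timecourses[, best[i]],
                      ph$truth$network_tcs[, i])), 0.95)
  # maps are z-scored with positive skewness
  expect_equal(rowMeans(dec$maps), rep(0, 6), tolerance = 1e-10)
  expect_equal(rowMeans(dec$maps^2), rep(1, 6), tolerance = 1e-10)
  expect_true(all(rowMeans(dec$maps^3) >= 0))
})

test_that("spatial ICA is deterministic and validates k", {
  ph <- make_ica_phantom(seed = 2)
  sm <- gaussian_smooth(ph$vol, 0.7)
  d1 <- spatial_ica(sm, ph$truth$masks$brain, k = 5, seed = 3)
  d2 <- spatial_ica(sm, ph$truth$masks$brain, k = 5, seed = 3)
  expect_identical(d1$maps, d2$maps)
  expect_identical(d1$timecourses, d2$timecourses)
  expect_error(spatial_ica(sm, ph$truth$masks$brain, k = 300, seed = 1),
               "smaller")
})

test_that("ic_timecourses solves the frame-wise least squares exactly", {
  set.seed(4)
  V <- 200; K <- 3; nt <- 40
  # orthogonal maps via QR
  maps <- t(qr.Q(qr(matrix(rnorm(V * K), V, K))))
  tc <- matrix(rnorm(nt * K), nt, K)
  X <- tc %*% maps                  # frames x voxels
  mask <- array(TRUE, c(V, 1, 1))
  vol <- volume4d(array(t(X), c(V, 1, 1, nt)))
  est <- ic_timecourses(maps, vol, mask)
  expect_equal(est, tc, tolerance = 1e-8)
  # orthonormal maps: equals projection (inner products)
  expect_equal(est, X %*% t(maps), tolerance = 1e-8)
  # adding an image orthogonal to the maps (and the intercept) to every
  # frame changes nothing
  null_dir <- qr.Q(qr(cbind(1, t(maps), rnorm(V))))[, K + 2]
  X2 <- X + matrix(5 * null_dir, nt, V, byrow = TRUE)
  vol2 <- volume4d(array(t(X2), c(V, 1, 1, nt)))
  expect_equal(ic_timecourses(maps, vol2, mask), tc, tolerance = 1e-8)
  # rank-deficient maps error
  maps_bad <- rbind(maps, maps[1, ])
  expect_error(ic_timecourses(maps_bad, vol, mask), "rank")
})

test_that("features capture edge overlap, band power, and jumps", {
  ph <- make_ica_phantom(seed = 5)
  masks <- ph$truth$masks
  brain <- masks$brain
  V <- sum(brain)
  # hand-built decomposition: supra voxels sit exactly on the edge shell
  # (map 1) and in a GM blob (map 2); sub-threshold background elsewhere
  set.seed(55)
  edge <- edge_mask(masks)[brain]
  m1 <- 0.3 * rnorm(V); m1[edge] <- 4
  gm <- gm_mask(masks)[brain] & !edge
  blob <- ph$truth$network_maps[[1]][brain] > 0
  m2 <- 0.3 * rnorm(V); m2[blob & gm] <- 4
  nt <- 200
  tc1 <- rnorm(nt); tc1[100] <- tc1[100] + 10
  tc2 <- sin(2 * pi * 0.05 * seq_len(nt))
  dec <- structure(list(maps = rbind(m1, m2),
                        timecourses = cbind(tc1, tc2), k = 2L,
                        brain = brain, seed = 1L),
                   class = "ica_decomposition")
  f <- extract_features(dec, masks, tr_s = 1)
  expect_gt(f$edge_fraction[1], 0.8)
  expect_gt(f$jump_score[1], 5)
  expect_gt(f$low_band_fraction[2], 0.9)
  expect_lt(f$high_band_fraction[2], 0.05)
  expect_gt(f$gm_overlap[2], 0.8)
  # empty supra-threshold map warns and zeroes the overlaps
  dec0 <- dec; dec0$maps[1, ] <- 0.1 * dec0$maps[1, ]
  expect_warning(f0 <- extract_features(dec0, masks, 1), "supra")
  expect_equal(f0$edge_fraction[1], 0)
})

test_that("the noise rule needs one confident or two applicable features", {
  base <- data.frame(ic = 1:4,
                     gm_overlap = c(0.9, 0.1, 0.1, 0.9),
                     wm_csf_overlap = c(0.05, 0.7, 0.7, 0.0),
                     edge_fraction = c(0.0, 0.2, 0.1, 0.05),
                     jump_score = c(3, 8, 3, 3),
                     low_band_fraction = c(0.8, 0.6, 0.7, 0.7),
                     high_band_fraction = c(0.1, 0.2, 0.2, 0.1),
                     spectral_flatness = c(0.3, 0.4, 0.5, 0.4))
  lab <- classify_ics(base)
  # 1: zero features -> signal; 2: spatial+jumps -> noise;
  # 3: spatial only -> signal; 4: clean -> signal
  expect_equal(lab$is_noise, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(lab$fired_applicable[2], "spatial,jumps")
  # one confident feature alone flips to noise
  conf <- matrix(c(FALSE, FALSE, TRUE, FALSE), 4, 1,
                 dimnames = list(NULL, "banding"))
  lab2 <- classify_ics(base, confident = conf)
  expect_true(lab2$is_noise[3])
  expect_equal(lab2$fired_confident[3], "banding")
})

test_that("classification is monotone in confident features", {
  set.seed(6)
  for (i in 1:30) {
    f <- data.frame(ic = 1, gm_overlap = runif(1), wm_csf_overlap = runif(1),
                    edge_fraction = runif(1), jump_score = runif(1, 0, 10),
                    low_band_fraction = runif(1),
                    high_band_fraction = runif(1),
                    spectral_flatness = runif(1))
    without <- classify_ics(f)$is_noise
    with_conf <- classify_ics(f, confident = matrix(TRUE, 1, 1))$is_noise
    expect_true(with_conf >= without)   # adding confident never flips to signal
  }
})

test_that("slice banding detector fires on alternating-slice maps", {
  ph <- make_ica_phantom(seed = 7)
  brain <- ph$truth$masks$brain
  d <- dim(brain)
  slice_of <- rep(seq_len(d[3]), each = d[1] * d[2])
  band <- array(ifelse(slice_of %% 2 == 0, 1, -1), d)
  m <- band[brain]; m <- (m - mean(m)) / sd(m) * 3
  set.seed(8)
  m2 <- rnorm(sum(brain)) * 3
  dec <- structure(list(maps = rbind(m, m2),
                        timecourses = matrix(rnorm(40), 20, 2), k = 2L,
                        brain = brain, seed = 1L),
                   class = "ica_decomposition")
  det <- detect_slice_banding(dec)
  expect_true(det[1])
  expect_false(det[2])
})
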