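# Group spatial ICA, between-component modules, Ward clustering, SNR maps.

make_group_scans <- function(n_scans = 8, n_networks = 5, seed = 20) {
  # shared spatial layout, independent per-scan time courses
  sp <- phantom_spec(motion_jitter_mm = 0, motion_jitter_rad = 0,
                     module_coupling = 0, artefacts = character(0),
                     n_networks = n_networks, rois_per_network = 2L,
                     extra_rois = 0L, noise_sigma = 1, nt = 200L,
                     seed = seed)
  scans <- list(); truths <- list()
  for (s in seq_len(n_scans)) {
    ph <- make_phantom(sp, scan_seed = 500 + s)
    scans[[s]] <- ph$vol
    truths[[s]] <- ph$truth
  }
  list(scans = scans, truths = truths)
}

test_that("group ICA recovers the shared networks across scans", {
  gs <- make_group_scans()
  brain <- gs$truths[[1]]$masks$brain
  gica <- group_ica(gs$scans, brain, k = 8, seed = 1)
  bidx <- which(brain)
  M <- sapply(gs$truths[[1]]$network_maps, function(m)
    apply(gica$maps, 1, function(icm) abs(cor(icm, m[bidx]))))
  expect_true(all(apply(M, 2, max) > 0.85))
  best <- apply(M, 2, which.max)
  expect_equal(length(unique(best)), 5L)
  # per-scan time courses track each scan's own planted time course
  tc_cor <- sapply(seq_along(gs$scans), function(s)
    sapply(1:5, function(i)
      abs(cor(gica$timecourses[[s]][, best[i]],
              gs$truths[[s]]$network_tcs[, i]))))
  expect_gt(min(tc_cor), 0.8)
  # determinism
  gica2 <- group_ica(gs$scans, brain, k = 8, seed = 1)
  expect_identical(gica$maps, gica2$maps)
  expect_error(group_ica(gs$scans[1], brain, k = 4), "2")
})

test_that("between-IC modules recover planted block structure", {
  set.seed(21)
  nscan <- 12; k <- 6; T <- 150
  # two blocks of components with strong within-block coupling
  tcs <- lapply(seq_len(nscan), function(s) {
    b1 <- rnorm(T); b2 <- rnorm(T)
    base <- cbind(b1, b1, b1, b2, b2, b2) * 1.2 +
      matrix(rnorm(T * k), T, k)
    base
  })
  res <- ic_modules(tcs, subjects = paste0("s", seq_len(nscan)),
                    n_perm = 200, seed = 2, n_modules = 2)
  expect_equal(length(unique(res$modules[1:3])), 1L)
  expect_equal(length(unique(res$modules[4:6])), 1L)
  expect_false(res$modules[1] == res$modules[4])
  # within-block connections significant, between-block not
  expect_true(all(res$group$sig[1, 2:3]))
  expect_false(any(res$group$sig[1:3, 4:6]))
  # a single coupled block stays one module at any cut above the max merge
  tcs1 <- lapply(seq_len(nscan), function(s) {
    b <- rnorm(T)
    matrix(b, T, 4) + 0.5 * matrix(rnorm(T * 4), T, 4)
  })
  res1 <- ic_modules(tcs1, subjects = paste0("s", seq_len(nscan)),
                     n_perm = 100, seed = 3)
  above_max <- max(res1$hclust$height) + 1
  expect_equal(unname(unique(cutree(res1$hclust, h = above_max))), 1L)
  # constant component is flagged
  tcs_bad <- tcs
  tcs_bad[[1]][, 2] <- 1
  w <- capture_warnings(ic_modules(tcs_bad,
                                   subjects = paste0("s", seq_len(nscan)),
                                   n_perm = 100, seed = 4))
  expect_true(any(grepl("constant", w)))
})

test_that("Ward linkage matches a brute-force Lance-Williams oracle", {
  set.seed(22)
  for (rep in 1:10) {
    n <- 6
    x <- matrix(rnorm(2 * n), n, 2)
    D <- as.matrix(dist(x))
    hc <- hclust(as.dist(D), method = "ward.D2")
    bf <- ward_linkage_bruteforce(D)
    expect_equal(hc$height, bf$height, tolerance = 1e-12)
    pairs <- function(m) t(apply(m, 1, sort))
    expect_equal(pairs(unclass(hc$merge)), pairs(bf$merge))
  }
})

test_that("SNR maps follow their definitions", {
  d <- c(12L, 12L, 3L)
  nt <- 12L
  set.seed(23)
  arr <- array(0, c(d, nt))
  brain <- array(FALSE, d); brain[4:9, 4:9, ] <- TRUE
  # out-of-brain corners: noise sd 10; brain voxel value 100 at frame 10
  arr[] <- rnorm(prod(d) * nt, 0, 10)
  for (t in seq_len(nt)) arr[, , , t][brain] <- 100 + rnorm(sum(brain), 0, 5)
  v <- volume4d(arr)
  sn <- snr_maps(v, brain, cube = 5L)
  expect_equal(sn$n_noise_voxels, 2 * 25 * d[3])
  # sSNR of a brain voxel ~ value / corner sd
  i <- c(5, 5, 2)
  expect_equal(sn$ssnr[i[1], i[2], i[3]],
               arr[i[1], i[2], i[3], 10] / sn$noise_sd)
  # tSNR ~ mean/sd over time, here ~ 100/5
  expect_equal(sn$mean_tsnr, 20, tolerance = 3)
  # constant voxel is flagged infinite and excluded from the mean
  arr2 <- arr; arr2[5, 5, 1, ] <- 77
  sn2 <- snr_maps(volume4d(arr2), brain)
  expect_true(is.infinite(sn2$tsnr[5, 5, 1]))
  expect_equal(sn2$n_flagged_infinite, 1L)
  expect_true(is.finite(sn2$mean_tsnr))
  # degenerate noise pool errors
  arr3 <- arr; arr3[1:5, 8:12, , ] <- 0; arr3[8:12, 8:12, , ] <- 0
  expect_error(snr_maps(volume4d(arr3), brain), "zero standard deviation")
  expect_error(snr_maps(volume4d(arr[, , , 1:5, drop = FALSE]), brain),
               "at least 10")
})
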