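# Group t statistics, permutation FWER, seed maps, FC characterization.

test_that("group_fc reduces to the classical one-sample t and caps zero variance", {
  set.seed(1)
  nsub <- 10; nroi <- 5
  fc <- lapply(seq_len(nsub), function(s) {
    z <- matrix(rnorm(nroi^2), nroi); z <- (z + t(z)) / 2
    fc_from_z(z, paste0("s", s))
  })
  g <- group_fc(fc)
  Z <- sapply(fc, function(f) upper_z <- f$z[upper.tri(f$z)])
  t_oracle <- apply(Z, 1, classical_t)
  expect_equal(g$t[upper.tri(g$t)], t_oracle, tolerance = 1e-12)
  expect_equal(g$t, t(g$t))
  expect_equal(diag(g$t), rep(0, nroi))
  # permuting scan order changes nothing
  g2 <- group_fc(fc[sample(nsub)])
  expect_equal(g2$t, g$t)
  # identical value at an entry: capped t with flag
  fc_c <- lapply(fc, function(f) { f$z[1, 2] <- f$z[2, 1] <- 0.4; f })
  gc <- group_fc(fc_c)
  expect_equal(gc$t[1, 2], 1e6)
  expect_true(gc$capped[1, 2])
  expect_error(group_fc(fc[1]), "2 subjects")
})

test_that("the mixed model handles repeated scans and falls back cleanly", {
  set.seed(2)
  nroi <- 4
  subs <- rep(paste0("s", 1:6), each = 2)
  fc <- lapply(seq_along(subs), function(i) {
    z <- matrix(rnorm(nroi^2, 0.2), nroi); z <- (z + t(z)) / 2
    fc_from_z(z, subs[i], scan = paste0("scan", i))
  })
  g <- group_fc(fc, method = "lmm")
  expect_equal(g$method, "lmm")
  expect_true(all(is.finite(g$t[upper.tri(g$t)])))
  # subject-mean route gives similar but not identical statistics
  gs <- group_fc(fc, method = "subject_mean")
  expect_gt(cor(g$t[upper.tri(g$t)], gs$t[upper.tri(gs$t)]), 0.9)
})

test_that("permutation FWER: alpha 1 rejects everywhere, monotone in alpha", {
  set.seed(3)
  fc <- lapply(1:8, function(s) fc_noise_scan(6, 60, paste0("s", s)))
  r1 <- permutation_fwer(fc, n_perm = 200, alpha = 1, seed = 5)
  expect_true(all(r1$sig[upper.tri(r1$sig)]))
  r05 <- permutation_fwer(fc, n_perm = 200, alpha = 0.05, seed = 5)
  r01 <- permutation_fwer(fc, n_perm = 200, alpha = 0.01, seed = 5)
  expect_true(all(r01$sig[upper.tri(r01$sig)] <= r05$sig[upper.tri(r05$sig)]))
  expect_warning(permutation_fwer(fc, n_perm = 50, seed = 1), "coarse")
  # p_fwer is a valid permutation p-value matrix
  expect_true(all(r05$p_fwer >= 1 / 201 - 1e-12))
})

test_that("a planted connection is detected while the null stays controlled", {
  set.seed(4)
  nsub <- 20; nroi <- 8; T <- 100
  fc <- lapply(seq_len(nsub), function(s) {
    tc <- matrix(rnorm(nroi * T), nroi, T)
    shared <- rnorm(T)
    tc[1, ] <- tc[1, ] + 2 * shared
    tc[2, ] <- tc[2, ] + 2 * shared
    suppressWarnings(scan_fc(tc, subject_id = paste0("s", s)))
  })
  res <- permutation_fwer(fc, n_perm = 200, seed = 6)
  expect_true(res$sig[1, 2])
  expect_lt(res$density, 0.2)
})

test_that("seed maps light up the planted network", {
  sp <- phantom_spec(motion_jitter_mm = 0, motion_jitter_rad = 0,
                     module_coupling = 0, artefacts = character(0),
                     noise_sigma = 1, nt = 200L)
  set.seed(7)
  scans <- lapply(1:6, function(s) make_phantom(sp, scan_seed = 100 + s)$vol)
  truth <- make_phantom(sp, scan_seed = 101)$truth
  brain <- truth$masks$brain
  net1 <- truth$network_maps[[1]] > 0
  # seed cube centred on a network-1 voxel
  cen <- round(colMeans(which(net1 & truth$atlas$labels == 1, arr.ind = TRUE)))
  sm <- seed_map(scans, list(center = cen, size = c(3, 3, 2)), brain,
                 subjects = paste0("s", 1:6))
  expect_equal(sm$n_scans, 6L)
  # seed voxels sit at the top of the map (self-correlation)
  expect_gt(mean(sm$t[sm$seed_voxels]),
            quantile(sm$t[brain], 0.95, na.rm = TRUE))
  # supra-threshold voxels overlap the network map (Dice)
  thr <- qt(1 - 0.001, df = sm$df)
  sig <- !is.na(sm$t) & sm$t > thr
  other <- net1 & !sm$seed_voxels
  dice <- 2 * sum(sig & other) / (sum(sig) + sum(other))
  expect_gt(dice, 0.5)
  # seed outside the brain errors
  expect_error(seed_map(scans, list(center = c(1, 1, 1)), brain,
                        subjects = paste0("s", 1:6)), "outside")
})

test_that("fc_vs_distance matches construction and a permutation oracle", {
  set.seed(8)
  n <- 12
  cen <- matrix(runif(3 * n, 0, 2), n, 3)
  D <- as.matrix(dist(cen))
  fc_exp <- exp(-D); diag(fc_exp) <- 0
  r1 <- fc_vs_distance(fc_exp, D)
  expect_lt(r1$r, -0.9)
  # N = 3 hand computation
  D3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  F3 <- matrix(c(0, .5, .1, .5, 0, .2, .1, .2, 0), 3)
  r3 <- fc_vs_distance(F3, D3)
  expect_equal(r3$r, cor(c(1, 2, 3), c(.5, .1, .2)), tolerance = 1e-12)
  # random FC: p from the t approximation tracks a permutation oracle
  fcr <- matrix(rnorm(n^2), n); fcr <- fcr + t(fcr); diag(fcr) <- 0
  rr <- fc_vs_distance(fcr, D)
  x <- D[upper.tri(D)]; y <- fcr[upper.tri(fcr)]
  perm_p <- mean(replicate(2000, abs(cor(x, sample(y))) >= abs(rr$r)))
  expect_lt(abs(perm_p - rr$p), 0.05)
  expect_error(fc_vs_distance(fcr, D * 0), "zero variance")
})

test_that("jaccard_fc_sc computes the index and a sane permutation p", {
  a <- matrix(0, 6, 6)
  a[1, 2] <- a[2, 1] <- a[3, 4] <- a[4, 3] <- 1
  expect_equal(jaccard_fc_sc(a, a, n_perm = 50, seed = 1)$jaccard, 1)
  b <- matrix(0, 6, 6); b[5, 6] <- b[6, 5] <- 1
  expect_equal(jaccard_fc_sc(a, b, n_perm = 50, seed = 1)$jaccard, 0)
  # 2 shared edges, 4 in the union -> 0.5
  c_ <- a; c_[1, 3] <- c_[3, 1] <- 1
  d_ <- a; d_[2, 5] <- d_[5, 2] <- 1
  expect_equal(jaccard_fc_sc(c_, d_, n_perm = 50, seed = 1)$jaccard, 0.5)
  expect_error(jaccard_fc_sc(matrix(0, 4, 4), matrix(0, 4, 4)), "empty")
  # degree-preserving null keeps degrees
  set.seed(9)
  g <- matrix(0, 8, 8)
  for (i in 1:7) { g[i, i + 1] <- g[i + 1, i] <- 1 }
  g[1, 5] <- g[5, 1] <- 1
  v <- ratfc:::rewire_degree_preserving(g)
  m <- matrix(0, 8, 8); m[upper.tri(m)] <- v; m <- m + t(m)
  expect_equal(rowSums(m), rowSums(g))
})

test_that("reproducibility separates shared from independent FC structure", {
  set.seed(10)
  nroi <- 12; nsub <- 12
  base <- matrix(rnorm(nroi^2), nroi); base <- base + t(base)
  shared_fc <- lapply(1:nsub, function(s)
    fc_from_z(base + 0.3 * (function(m) m + t(m))(matrix(rnorm(nroi^2), nroi)),
              paste0("s", s)))
  r_sh <- reproducibility(shared_fc, mode = "split_half", seed = 1)
  expect_gt(r_sh$r, 0.9)
  indep_fc <- lapply(1:nsub, function(s)
    fc_from_z((function(m) m + t(m))(matrix(rnorm(nroi^2), nroi)),
              paste0("s", s)))
  r_in <- reproducibility(indep_fc, mode = "split_half", seed = 1)
  expect_lt(abs(r_in$r), 0.4)
  loo <- reproducibility(shared_fc, mode = "leave_one_out")
  expect_length(loo$r, nsub)
  expect_gt(loo$r_mean, 0.8)
  # distance regression with zero coupling barely changes r
  cenm <- matrix(runif(3 * nroi, 0, 10), nroi, 3)
  D <- as.matrix(dist(cenm))
  r_d <- reproducibility(shared_fc, mode = "split_half", distances = D,
                         seed = 1)
  expect_equal(r_d$r, r_sh$r, tolerance = 1e-2)
  expect_error(reproducibility(shared_fc[1:3], mode = "split_half"),
               "4 subjects")
})

test_that("specificity categories follow the two-threshold rule", {
  expect_equal(specificity_classify(0.3, 0.05), "specific")
  expect_equal(specificity_classify(0.3, 0.3), "unspecific")
  expect_equal(specificity_classify(0.0, 0.0), "none")
  expect_equal(specificity_classify(0.05, 0.3), "spurious")
  # vectorized with a custom threshold
  expect_equal(specificity_classify(c(0.2, 0.0), c(0.0, 0.2), thresh = 0.1),
               c("specific", "spurious"))
  # scan-level wrapper with a planted specific pair
  set.seed(11)
  fc <- lapply(1:20, function(s) {
    T <- 200
    tc <- matrix(rnorm(3 * T), 3, T)
    shared <- rnorm(T)
    tc[1, ] <- tc[1, ] + shared
    tc[2, ] <- tc[2, ] + shared
    suppressWarnings(scan_fc(tc, scan_id = paste0("sc", s),
                             subject_id = paste0("s", s)))
  })
  tab <- specificity_table(fc, seed_roi = 1, specific_roi = 2,
                           nonspecific_roi = 3)
  expect_gte(mean(tab$category == "specific"), 0.9)
})
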