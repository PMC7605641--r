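# Monte-Carlo CompCor and soft cleaning.

wmcsf_masks <- function(d = c(10L, 10L, 2L)) {
  wm <- array(FALSE, d); wm[, , 1] <- TRUE
  csf <- array(FALSE, d); csf[, , 2] <- TRUE
  list(wm = wm, csf = csf)
}

noise_vol <- function(nt, d = c(10L, 10L, 2L), extra = NULL) {
  x <- matrix(rnorm(nt * prod(d)), nt, prod(d))
  if (!is.null(extra)) x <- x + extra
  volume4d(array(t(x), c(d, nt)))
}

test_that("compcor selects nothing at alpha 0 and needs 2+ voxels", {
  set.seed(1)
  m <- wmcsf_masks()
  v <- noise_vol(60)
  nul <- compcor_null(60, 200, n_mc = 100, seed = 1)
  cc <- compcor(v, m$wm, m$csf, alpha = 0, null_ve = nul)
  expect_equal(ncol(cc$components), 0L)
  tiny <- array(FALSE, c(10, 10, 2)); tiny[1, 1, 1] <- TRUE
  none <- array(FALSE, c(10, 10, 2))
  expect_error(compcor(v, tiny, none), "at least 2")
})

test_that("compcor finds a planted dominant component", {
  set.seed(2)
  m <- wmcsf_masks()
  nul <- compcor_null(120, 200, n_mc = 200, seed = 3)
  tc <- as.numeric(scale(rnorm(120)))
  v <- noise_vol(120, extra = tc %*% t(rep(1, 200)))
  cc <- compcor(v, m$wm, m$csf, null_ve = nul)
  expect_gte(ncol(cc$components), 1L)
  expect_gt(abs(cor(cc$components[, 1], tc)), 0.95)
  expect_true(all(cc$p < 0.05))
  expect_gt(cc$ve[1], 0.3)
})

test_that("compcor p-values are super-uniform beyond the first PC on null data", {
  set.seed(4)
  nul <- compcor_null(60, 40, n_mc = 300, seed = 5)
  m <- list(wm = array(c(TRUE, rep(FALSE, 39)), c(40, 1, 1)))
  p2 <- replicate(200, {
    x <- ratfc:::scale_cols(matrix(rnorm(60 * 40), 60, 40))
    sv <- svd(x, nu = 0, nv = 0)
    ve <- sv$d^2 / sum(sv$d^2)
    mean(nul > ve[2])
  })
  # PC2's variance-explained sits well inside the first-PC null
  expect_lte(mean(p2 < 0.05), 0.05)
  expect_gt(mean(p2), 0.5)
})

test_that("soft cleaning preserves signal and removes only unique noise", {
  set.seed(6)
  V <- 150; nt <- 80
  sig_map <- rnorm(V); noise_map <- rnorm(V)
  sig_tc <- as.numeric(scale(rnorm(nt)))
  noise_tc_raw <- rnorm(nt)
  # orthogonalize noise tc against signal tc
  noise_tc <- as.numeric(scale(residuals(lm(noise_tc_raw ~ sig_tc))))
  Y <- sig_tc %*% t(sig_map) + noise_tc %*% t(noise_map)
  vol <- volume4d(array(t(Y), c(V, 1, 1, nt)))
  brain <- array(TRUE, c(V, 1, 1))
  dec <- structure(list(maps = rbind(sig_map, noise_map),
                        timecourses = cbind(sig_tc, noise_tc), k = 2L,
                        brain = brain, seed = 1L),
                   class = "ica_decomposition")
  # no ICs labeled noise: output is exactly the (demeaned) input
  out0 <- soft_clean(vol, dec, c(FALSE, FALSE))
  Ym <- ratfc:::residualize(ratfc:::vol_to_matrix(vol))
  expect_equal(ratfc:::vol_to_matrix(out0), Ym, tolerance = 1e-12)
  # cleaning the noise IC leaves the pure signal part
  out1 <- soft_clean(vol, dec, c(FALSE, TRUE))
  X1 <- ratfc:::vol_to_matrix(out1)
  pure <- sig_tc %*% t(sig_map)
  cors <- sapply(which(abs(sig_map) > 0.5), function(j)
    cor(X1[, j], pure[, j]))
  expect_gt(min(cors), 0.99)
  # orthogonal time courses: soft equals hard regression of the noise IC
  hard <- hard_clean(vol, dec, c(FALSE, TRUE))
  expect_lt(max(abs(X1 - ratfc:::vol_to_matrix(hard))), 1e-8)
})

test_that("soft cleaning residuals are orthogonal to nuisance columns", {
  set.seed(7)
  V <- 100; nt <- 60
  Y <- matrix(rnorm(nt * V), nt, V)
  vol <- volume4d(array(t(Y), c(V, 1, 1, nt)))
  brain <- array(TRUE, c(V, 1, 1))
  tc <- matrix(rnorm(nt * 3), nt, 3)
  maps <- matrix(rnorm(3 * V), 3, V)
  dec <- structure(list(maps = maps, timecourses = tc, k = 3L,
                        brain = brain, seed = 1L),
                   class = "ica_decomposition")
  N <- matrix(rnorm(nt * 4), nt, 4)
  out <- soft_clean(vol, dec, c(TRUE, FALSE, TRUE), nuisance = N)
  X <- ratfc:::vol_to_matrix(out)
  Xn <- scale(X)
  for (q in 1:4)
    expect_lt(max(abs(crossprod(scale(N[, q]), Xn) / (nt - 1))), 1e-6)
})

test_that("soft cleaning removes no more variance than hard cleaning", {
  set.seed(8)
  V <- 80; nt <- 70
  tc <- matrix(rnorm(nt * 4), nt, 4)
  maps <- matrix(rnorm(4 * V), 4, V)
  Y <- tc %*% maps + matrix(rnorm(nt * V), nt, V)
  vol <- volume4d(array(t(Y), c(V, 1, 1, nt)))
  brain <- array(TRUE, c(V, 1, 1))
  dec <- structure(list(maps = maps, timecourses = tc, k = 4L,
                        brain = brain, seed = 1L),
                   class = "ica_decomposition")
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  N <- matrix(rnorm(nt * 2), nt, 2)
  soft <- ratfc:::vol_to_matrix(soft_clean(vol, dec, labels, N))
  hard <- ratfc:::vol_to_matrix(hard_clean(vol, dec, labels, N))
  Ym <- ratfc:::residualize(Y, N)
  v_soft <- colSums(Ym^2) - colSums((Ym - soft)^2)
  # removed variance: soft <= hard, per voxel
  removed_soft <- colSums(Ym^2) - colSums(soft^2)
  removed_hard <- colSums(Ym^2) - colSums(hard^2)
  expect_true(all(removed_soft <= removed_hard + 1e-8))
})

test_that("nuisance sets validate alignment and finiteness", {
  p <- matrix(rnorm(60), 10, 6)
  tr <- ratfc:::motion_trace(p, compute_fd(p), 5)
  ns <- nuisance_set(tr)
  expect_equal(ncol(ns$compcor), 0L)
  cc <- list(components = matrix(rnorm(8), 4, 2), p = c(0.01, 0.02),
             n_candidates = 4L)
  expect_error(nuisance_set(tr, cc), "frame counts")
})
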