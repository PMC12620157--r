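# SENSE operators, CG, navigator phases, TV prox, slab combination

test_that("sense forward/adjoint pass the dot-product test", {
  proto <- small_protocol()
  masks <- small_masks()
  ph <- small_phantom()
  phases <- small_phases()
  nv <- nrow(proto$samples)
  S <- random_complex_array(c(32, 32, 6, nv), seed = 10)
  Y <- random_complex_array(c(32, 32, 6, 8, nv), seed = 11)
  AS <- sense_forward(S, ph$coil_sens, phases, masks)
  AtY <- sense_adjoint(Y, ph$coil_sens, phases, masks)
  ip1 <- sum(Conj(AS) * Y)
  ip2 <- sum(Conj(S) * AtY)
  expect_lt(abs(ip1 - ip2) / (sqrt(sum(abs(S)^2)) * sqrt(sum(abs(Y)^2))),
            1e-10)
  # entries outside the mask are exactly zero
  for (v in seq_len(nv)) {
    off <- array(rep(!masks[[v]]$grid, each = 32), c(32, 32, 6, 8))
    expect_true(all(AS[, , , , v][off] == 0))
  }
  # sample count = mask count x n_coils (per x readout column)
  expect_equal(sum(AS[, , , , 1] != 0),
               sum(masks[[1]]$grid) * 8 * 32)
})

test_that("unit-coil full-mask operator is the plain centered FT", {
  proto <- small_protocol()
  m1 <- generate_caipi_masks(proto, sampling_config(1, 1, seed = 1))
  nv <- nrow(proto$samples)
  coils1 <- array(1 + 0i, c(32, 32, 6, 1))
  ph0 <- array(0, c(32, 32, m1[[1]]$n_shots, nv))
  img <- random_complex_array(c(32, 32, 6, nv), seed = 12)
  K <- sense_forward(img, coils1, ph0, m1)
  # forward equals the centered unitary FT over (y, z)
  k1 <- slabkq:::ft_yz(img[, , , 1])
  expect_lt(max(abs(K[, , , 1, 1] - k1)), 1e-12)
  # A^H A = identity
  back <- sense_adjoint(K, coils1, ph0, m1)
  expect_lt(max(abs(back - img)), 1e-12)
  expect_true(all(sense_adjoint(K * 0, coils1, ph0, m1) == 0))
})

test_that("CG residuals are non-increasing and reach tolerance", {
  ph <- small_phantom()
  masks <- small_masks()
  phases <- small_phases()
  coils <- ph$coil_sens
  m1 <- masks[[1]]; phv <- phases[, , , 1]
  AtA <- function(x) slabkq:::.adjoint_vol(
    slabkq:::.forward_vol(x, coils, phv, m1), coils, phv, m1) + 0.3 * x
  b <- random_complex_array(c(32, 32, 6), seed = 13)
  sol <- slabkq:::cg_solve(AtA, b, tol = 1e-8, max_iters = 100)
  expect_true(all(diff(sol$trace) < 1e-12))
  expect_lt(sol$relres, 1e-8)
  # residual identity at the returned iterate
  expect_equal(sqrt(sum(abs(b - AtA(sol$x))^2) / sum(abs(b)^2)), sol$relres,
               tolerance = 1e-6)
})

test_that("navigator phase estimation recovers simulated shot phases", {
  proto <- small_protocol()
  masks <- small_masks()
  phases <- small_phases()
  ph <- small_phantom()
  # fully sampled single-coil navigator: exact recovery (noiseless)
  ph1 <- build_phantom(c(32, 32, 6), n_coils = 1, seed = 3)
  acq1 <- simulate_acquisition(ph1, proto, masks, phases, snr = Inf,
                               seed = 6, nav_ry = 1)
  est1 <- cg_sense_navigator(acq1$navigator)
  fg <- ph$foreground[, , acq1$navigator$zmid]
  errs <- sapply(seq_len(dim(est1)[4]), function(v)
    sapply(seq_len(dim(est1)[3]), function(s)
      phase_rmse(est1[, , s, v], phases[, , s, v], fg)))
  expect_lt(max(errs), 0.02)
  # zero simulated phase -> estimate is (numerically) zero
  acq0 <- simulate_acquisition(ph1, proto, masks, phases * 0, snr = Inf,
                               seed = 6, nav_ry = 1)
  est0 <- cg_sense_navigator(acq0$navigator)
  expect_lt(max(abs(est0)), 0.02)
})

test_that("undersampled multi-coil navigator at SNR 20 stays accurate", {
  # oracle simulation experiment; the bound is the measured performance of
  # the b1000 shell in this stated world (see the methods vignette)
  proto <- small_protocol(n_dirs = 4)
  masks <- small_masks(n_dirs = 4)
  phases <- small_phases(n_dirs = 4)
  ph <- small_phantom()
  acq <- simulate_acquisition(ph, proto, masks, phases, snr = 20, seed = 7,
                              nav_ry = 3)
  est <- suppressWarnings(cg_sense_navigator(acq$navigator))
  fg <- ph$foreground[, , acq$navigator$zmid]
  b1000 <- which(proto$samples$b == 1000)
  errs <- sapply(b1000, function(v)
    sapply(seq_len(dim(est)[3]), function(s)
      phase_rmse(est[, , s, v], phases[, , s, v], fg)))
  expect_lt(mean(errs), 0.2)
})

test_that("tv_prox contracts total variation and preserves phase", {
  x <- random_complex_array(c(16, 16, 4), seed = 14)
  expect_identical(tv_prox(x, 0), x)
  # constant magnitude image is unchanged
  const <- array(2 + 0i, c(16, 16, 4))
  expect_lt(max(abs(tv_prox(const, 0.5, 20) - const)), 1e-10)
  y <- tv_prox(x, 0.2, 20)
  expect_lt(slabkq:::tv_norm(abs(y)), slabkq:::tv_norm(abs(x)))
  # phase preserved where magnitude survives
  keep <- abs(y) > 1e-6 & abs(x) > 1e-6
  expect_lt(max(abs(Arg(y[keep] / x[keep]))), 1e-10)
})

test_that("toy reconstruction matches a dense normal-equations solve", {
  proto <- build_protocol(c(1000, 2000, 6000), 1, Ny = 8, seed = 1)
  proto$FOVz <- 4; proto$n_kz <- 4L
  masks <- generate_caipi_masks(proto, sampling_config(2, 1, seed = 3))
  shape <- c(8, 8, 4)
  coils <- simulate_coils(2, shape, seed = 2)
  phases <- simulate_shot_phases(proto, masks, shape, severity = 0.5,
                                 seed = 4)
  nvox <- prod(shape)
  img <- random_complex_array(c(shape, 3), seed = 15)
  Y <- sense_forward(img, coils, phases, masks)
  r <- qmodel_reconstruct(Y, masks, coils, phases,
                          cfg = recon_config(lambda1 = 0, lambda2 = 0,
                                             cg_tol = 1e-12,
                                             cg_max_iters = 1000))
  for (v in 1:3) {
    A <- matrix(0i, nvox * 2, nvox)
    e <- array(0i, shape)
    for (j in seq_len(nvox)) {
      e[] <- 0i; e[j] <- 1
      A[, j] <- c(sense_forward(e, coils,
                                array(phases[, , , v], dim(phases)[1:3]),
                                masks[v]))
    }
    AH <- t(Conj(A))
    dense <- solve(AH %*% A, AH %*% c(Y[, , , , v]))
    expect_lt(nrmse(r$S[, , , v], array(dense, shape)), 1e-8)
  }
  # noiseless consistent data: residual below cg_tol
  res <- sense_forward(r$S, coils, phases, masks) - Y
  expect_lt(sqrt(sum(abs(res)^2) / sum(abs(Y)^2)), 1e-9)
})

test_that("missing DAE model with lambda2 > 0 errors", {
  proto <- small_protocol()
  masks <- small_masks()
  phases <- small_phases()
  ph <- small_phantom()
  nv <- nrow(proto$samples)
  Y <- random_complex_array(c(32, 32, 6, 8, nv), seed = 16)
  expect_error(qmodel_reconstruct(Y, masks, ph$coil_sens, phases,
                                  cfg = recon_config(lambda2 = 0.5)),
               "DAE")
})

test_that("combine_slabs is exact for trivial and overlapping tilings", {
  vol <- array(stats::runif(16 * 16 * 6), c(16, 16, 6))
  # single slab: identity
  expect_equal(combine_slabs(list(vol), list(rep(1, 6)), 1), vol)
  # two abutting rectangular slabs: concatenation
  v1 <- vol[, , 1:3]; v2 <- vol[, , 4:6]
  got <- combine_slabs(list(v1, v2), list(rep(1, 3), rep(1, 3)), c(1, 4))
  expect_equal(got, vol)
  # overlapping raised-cosine profiles on a constant object: no banding
  prof <- slabkq:::slab_profile_weights(8)
  const <- array(3, c(4, 4, 8))
  got <- combine_slabs(list(const, const, const),
                       list(prof, prof, prof), c(1, 5, 9))
  expect_lt(max(abs(got - 3)), 1e-10)
  expect_error(combine_slabs(list(v1, v2), list(rep(1, 3), rep(1, 3)),
                             c(1, 6)), "gap")
})
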