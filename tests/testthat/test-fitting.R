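# spherical means, rotational invariants, compartment/DTI/DKI fits, ROI stats

cc <- compartment_params(0.6, 2.27, 1.8, 0.6, fw = 0.05)

# a B-tensor-varied (QTI-style) protocol: 3 b-shells x 3 encoding shapes
mde_protocol <- function() fixture("mde_protocol", function()
  build_protocol(rep(c(1000, 2000, 6000), 3), 21,
                 betas = rep(c(1, 0.7, 0), each = 3), seed = 1))

test_that("spherical means match the closed-form powder average", {
  p <- full_protocol()
  grid <- sphere_grid(2000)
  odf <- watson_odf(c(0, 1, 0), 5, grid)
  sig <- synthesize_signal(p, cc, odf, S0 = 2.5)
  sm <- spherical_mean(matrix(sig, 1), p, b0 = 2.5)
  expect_equal(nrow(sm$groups), 3)
  pa <- powder_average(sm$groups$b, sm$groups$beta, cc)
  # angular truncation of 22 directions limits agreement at b6000
  expect_lt(max(abs(sm$means[1, ] - pa)), 5e-4)
  # isotropic voxel: every direction equals the mean
  sig_iso <- synthesize_signal(p, compartment_params(0, 1.2, 0.7, 0.7),
                               isotropic_odf(grid))
  smi <- spherical_mean(matrix(sig_iso, 1), p, b0 = 1)
  idx <- which(p$samples$b == 2000)
  expect_equal(unname(sig_iso[idx[1]]), smi$means[1, 2], tolerance = 1e-12)
  expect_error(spherical_mean(matrix(sig, 1), p), "b0")
})

test_that("shell invariants follow the Funk-Hecke factorization", {
  dirs <- uniform_hemisphere_dirs(60, seed = 5)
  tab <- data.frame(b = 2000, gx = dirs[, 1], gy = dirs[, 2],
                    gz = dirs[, 3], beta = 1, shell_id = 1)
  odf <- watson_odf(c(0.3, -0.5, 0.9) / sqrt(1.15), 8, sphere_grid(2000))
  sig <- synthesize_signal(tab, cc, odf)
  inv <- shell_invariants(sig, dirs, lmax = 6)
  p2 <- slabkq:::odf_p2(odf)
  bb <- 2
  k0 <- powder_average(2000, 1, cc)
  k2 <- cc$fa * slabkq:::kernel_proj_l(0, bb * cc$Da, 2) +
    cc$fe * slabkq:::kernel_proj_l(bb * cc$De_perp,
                                   bb * (cc$De_par - cc$De_perp), 2)
  expect_equal(unname(inv[1, "l0"]), k0, tolerance = 1e-4)
  expect_equal(unname(inv[1, "l2"]), abs(p2 * k2), tolerance = 1e-3)
  # SH basis orthonormality on the quadrature grid
  g <- sphere_grid(4000)
  B <- real_sh_basis(g$dirs, 4)
  G <- crossprod(B * g$weights * 4 * pi, B)
  expect_lt(max(abs(G - diag(ncol(B)))), 1e-6)
})

test_that("noiseless single-voxel fit recovers the CC parameters", {
  mde <- mde_protocol()
  sig <- synthesize_signal(mde, cc, isotropic_odf(sphere_grid(2000)))
  fit <- fit_compartments(matrix(sig, 1), mde, b0 = 1,
                          fit_cfg = fit_config(n_starts = 8, use_l2 = FALSE,
                                               n_polish = 3,
                                               polish_restarts = 4))
  truth <- c(0.6, 2.27, 1.8, 0.6, 0.05)
  expect_lt(max(abs(fit$params[1, 1:5] - truth) / truth), 1e-3)
  expect_false(fit$branch_flag[1])
})

test_that("free-water voxels are flagged as CSF-degenerate", {
  mde <- mde_protocol()
  csf <- compartment_params(0, 2, 1, 1, fw = 1)
  sig <- synthesize_signal(mde, csf, isotropic_odf(sphere_grid(500)))
  fit <- fit_compartments(matrix(sig, 1), mde, b0 = 1,
                          fit_cfg = fit_config(n_starts = 6, use_l2 = FALSE,
                                               n_polish = 2))
  expect_true(fit$csf_flag[1])
  # all-background input gives an empty result
  empty <- fit_compartments(matrix(0, 3, nrow(mde$samples)), mde, b0 = rep(1, 3))
  expect_equal(nrow(empty$params), 0)
})

test_that("DTI fit is exact on single-tensor voxels and rotation invariant", {
  p <- full_protocol()
  sub <- p$samples[p$samples$b <= 2000, ]
  G <- as.matrix(sub[, c("gx", "gy", "gz")])
  # isotropic Gaussian voxel D = 0.7
  sig <- exp(-sub$b / 1000 * 0.7)
  f <- fit_dti(matrix(sig, 1), sub, b0 = 1)
  expect_equal(f$MD[1], 0.7, tolerance = 1e-8)
  expect_equal(f$FA[1], 0, tolerance = 1e-6)
  # eigenvalues (1.7, 0.3, 0.3): closed-form FA / MD
  D <- diag(c(1.7, 0.3, 0.3))
  sig2 <- exp(-sub$b / 1000 * rowSums((G %*% D) * G))
  f2 <- fit_dti(matrix(sig2, 1), sub, b0 = 1)
  expect_equal(f2$MD[1], 23 / 30, tolerance = 1e-8)
  # closed form: FA = sqrt(1.5 * sum((ev - mean)^2) / sum(ev^2)) = 0.79904
  ev <- c(1.7, 0.3, 0.3)
  expect_equal(f2$FA[1], sqrt(1.5 * sum((ev - mean(ev))^2) / sum(ev^2)),
               tolerance = 1e-8)
  expect_equal(sort(f2$evals[1, ]), c(0.3, 0.3, 1.7), tolerance = 1e-8)
  # rotating directions and tensor together leaves FA unchanged
  th <- 0.7; R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
                        c(0, 0, 1))
  GR <- G %*% t(R); DR <- R %*% D %*% t(R)
  subR <- sub; subR[, c("gx", "gy", "gz")] <- GR
  sig3 <- exp(-sub$b / 1000 * rowSums((G %*% DR) * G))  # same projections
  f3 <- fit_dti(matrix(exp(-subR$b / 1000 *
                             rowSums((GR %*% DR) * GR)), 1), subR, b0 = 1)
  expect_equal(f3$FA[1], f2$FA[1], tolerance = 1e-10)
  expect_warning(fit_dti(matrix(c(-1, sig2[-1]), 1), sub, b0 = 1),
                 "clipped")
})

test_that("DKI: monoexponential MK = 0; two-Gaussian mixture = 1/3", {
  # small-b shells keep the cumulant truncation bias within the tolerance
  p <- build_protocol(c(100, 200), c(30, 30), seed = 4)
  sub <- p$samples
  sig_mono <- exp(-sub$b / 1000 * 1.1)
  f <- fit_dki(matrix(sig_mono, 1), sub, b0 = 1)
  expect_lt(abs(f$MK[1]), 1e-6)
  expect_true(all(f$MK >= 0))
  # equal mixture of isotropic D = 1 and D = 2: K = 3 Var / mean^2 = 1/3
  sig_mix <- 0.5 * exp(-sub$b / 1000) + 0.5 * exp(-2 * sub$b / 1000)
  f2 <- fit_dki(matrix(sig_mix, 1), sub, b0 = 1)
  expect_equal(f2$MK[1], 1 / 3, tolerance = 0.02 / 3)
  expect_error(fit_dki(matrix(sig_mono, 1),
                       sub[sub$b == 100, ], b0 = 1), "shells")
})

test_that("ROI statistics and the COV identity", {
  lab <- array(c(1, 1, 1, 2, 2, 2, 0, 0), c(2, 2, 2))
  vals <- array(c(2, 2, 2, 1, 2, 3, 9, 9), c(2, 2, 2))
  st <- roi_statistics(list(Da = vals), lab)
  r1 <- st[st$roi == 1, ]
  expect_equal(r1$mean, 2); expect_equal(r1$sd, 0); expect_equal(r1$cov, 0)
  r2 <- st[st$roi == 2, ]
  expect_equal(r2$mean, 2); expect_equal(r2$sd, 1); expect_equal(r2$cov, 50)
  # COV x mean / 100 = SD exactly
  expect_equal(r2$cov * r2$mean / 100, r2$sd)
  # empty ROI flagged
  st3 <- roi_statistics(list(Da = vals), lab, roi_ids = c(1, 7))
  expect_true(st3$empty[st3$roi == 7])
  # across-realization aggregation
  maps <- list(vals, vals + 1, vals - 1)
  acr <- roi_cov_across(maps, lab, 2)
  expect_equal(acr$mean, 2)
  expect_equal(acr$sd, 1)
})
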