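# digital phantom, coils, shot phases, acquisition simulation

test_that("phantom construction is deterministic and carries CC values", {
  ph <- small_phantom()
  ph2 <- build_phantom(c(32, 32, 6), n_coils = 8, seed = 3)
  expect_identical(ph$S0, ph2$S0)
  expect_identical(ph$label_map, ph2$label_map)
  cc <- ph$params[[which(ph$label_names == "cc")]]
  expect_equal(cc$fa, 0.60)
  expect_equal(cc$Da, 2.27)
  csf <- ph$params[[which(ph$label_names == "csf")]]
  expect_equal(csf$fw, 1)
  # CSF signal at b1000 is exp(-b Dw) x S0
  sig <- synthesize_signal(small_protocol(), csf,
                           ph$odfs[[which(ph$label_names == "csf")]])
  b1 <- which(small_protocol()$samples$b == 1000)
  expect_equal(sig[b1], rep(exp(-3.0), length(b1)), tolerance = 1e-9)
  expect_error(build_phantom(c(8, 8, 2)), "at least")
})

test_that("coil maps are smooth with unit root-sum-of-squares", {
  sens <- small_phantom()$coil_sens
  rss <- sqrt(rowSums(abs(sens)^2, dims = 3))
  expect_true(all(rss > 0.99 & rss < 1.01))
  # spatial smoothness of magnitudes
  mag <- abs(sens)
  dif <- max(abs(mag[-1, , , ] - mag[-32, , , ]),
             abs(mag[, -1, , ] - mag[, -32, , ]))
  expect_lt(dif, 0.2)
  # single coil: constant unit magnitude
  s1 <- simulate_coils(1, c(16, 16, 4), seed = 1)
  expect_lt(max(abs(abs(s1) - 1)), 1e-12)
})

test_that("shot phases scale with sqrt(b/1000) and are independent", {
  proto <- small_protocol()
  masks <- small_masks()
  # severity 0 -> all zero
  ph0 <- simulate_shot_phases(proto, masks, c(32, 32, 6), severity = 0,
                              seed = 1)
  expect_true(all(ph0 == 0))
  # Monte-Carlo scaling: sd at b6000 ~ sqrt(6) x sd at b1000
  proto2 <- build_protocol(c(1000, 6000), c(500, 500), Ny = 32, seed = 1)
  proto2$FOVz <- 6; proto2$n_kz <- 6L
  masks2 <- generate_caipi_masks(proto2, sampling_config(3, "6/2", seed = 2))
  phs <- simulate_shot_phases(proto2, masks2, c(8, 8, 6), severity = 0.5,
                              seed = 9)
  sds <- apply(phs, 4, stats::sd)
  r <- mean(sds[proto2$samples$b == 6000]) / mean(sds[proto2$samples$b == 1000])
  expect_equal(r, sqrt(6), tolerance = 0.1)
  # shots of one volume are independent draws
  cors <- sapply(1:100, function(v)
    stats::cor(c(phs[, , 1, v]), c(phs[, , 2, v])))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("noiseless unit-coil acquisition inverts exactly", {
  proto <- small_protocol()
  m1 <- generate_caipi_masks(proto, sampling_config(1, 1, seed = 1))
  ph1 <- build_phantom(c(32, 32, 6), n_coils = 1, seed = 3)
  ph1$coil_sens[] <- 1 + 0i
  nv <- nrow(proto$samples)
  ph0 <- array(0, c(32, 32, m1[[1]]$n_shots, nv))
  acq <- simulate_acquisition(ph1, proto, m1, ph0, snr = Inf, seed = 1)
  back <- sense_adjoint(acq$kspace, ph1$coil_sens, ph0, m1)
  expect_lt(nrmse(abs(back), acq$truth), 1e-10)
})

test_that("acquisition respects masks and the requested SNR", {
  proto <- small_protocol()
  masks <- small_masks()
  ph <- small_phantom()
  phases <- small_phases()
  acq <- simulate_acquisition(ph, proto, masks, phases, snr = 20, seed = 8)
  for (v in seq_along(masks)) {
    off <- array(rep(!masks[[v]]$grid, each = 32), c(32, 32, 6, 8))
    expect_true(all(acq$kspace[, , , , v][off] == 0))
  }
  expect_error(simulate_acquisition(ph, proto, masks[1:3], phases, snr = 20),
               "mismatch")
  # measured image-domain noise matches sigma over repeated realizations
  m1 <- generate_caipi_masks(proto, sampling_config(1, 1, seed = 1))
  nv <- nrow(proto$samples)
  ph0 <- array(0, c(32, 32, m1[[1]]$n_shots, nv))
  sds <- sapply(1:20, function(i) {
    a <- simulate_acquisition(ph, proto, m1, ph0, snr = 20, seed = 100 + i)
    noise <- sense_adjoint(a$kspace, ph$coil_sens, ph0, m1)[, , , 1] -
      sense_adjoint(simulate_acquisition(ph, proto, m1, ph0, snr = Inf,
                                         seed = 1)$kspace,
                    ph$coil_sens, ph0, m1)[, , , 1]
    stats::sd(c(Re(noise), Im(noise)))
  })
  a <- simulate_acquisition(ph, proto, m1, ph0, snr = 20, seed = 1)
  # per-component noise sd after coil combination ~ sigma / sqrt(2)
  expect_equal(mean(sds), a$sigma / sqrt(2), tolerance = 0.05)
})

test_that("background magnitudes after RSS follow the chi distribution", {
  proto <- small_protocol()
  m1 <- generate_caipi_masks(proto, sampling_config(1, 1, seed = 1))
  ph <- small_phantom()
  nv <- nrow(proto$samples)
  ph0 <- array(0, c(32, 32, m1[[1]]$n_shots, nv))
  acq <- simulate_acquisition(ph, proto, m1, ph0, snr = 20, seed = 9)
  # RSS combination of the per-coil zero-filled reconstructions
  imgs <- array(0i, c(32, 32, 6, 8))
  for (cc in 1:8) imgs[, , , cc] <- slabkq:::ift_yz(acq$kspace[, , , cc, 1])
  rss <- sqrt(rowSums(abs(imgs)^2, dims = 3))
  bgv <- rss[!ph$foreground & array(TRUE, c(32, 32, 6))]
  bgv <- bgv[seq_len(min(10000, length(bgv)))]
  # chi with 2 * n_coils dof, scale sigma / sqrt(2) per component
  pchi <- function(q, k, s) stats::pgamma((q / s)^2 / 2, k / 2)
  ks <- stats::ks.test(bgv, function(q) pchi(q, 16, acq$sigma / sqrt(2)))
  expect_gt(ks$p.value, 0.01)
})
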