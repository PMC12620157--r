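# Digital multi-slab head phantom: tissue parameter maps, ODFs, coil
# sensitivities, slab profiles, per-shot motion phases, and the simulated
# multi-channel undersampled k-space plus 2D navigators.

# raised-cosine-edged slab excitation profile sampled at nz voxel centers:
# flat over the nominal slab, rolling off inside the oversampled FOVz
slab_profile_weights <- function(nz, slab_fraction = 0.7) {
  u <- abs(2 * (seq_len(nz) - 0.5) / nz - 1)        # 0 center .. ~1 edge
  inner <- slab_fraction - 0.2
  outer <- min(0.98, slab_fraction + 0.25)
  w <- numeric(nz)
  w[u <= inner] <- 1
  ramp <- u > inner & u < outer
  w[ramp] <- 0.5 * (1 + cos(pi * (u[ramp] - inner) / (outer - inner)))
  w
}

#' Simulate smooth complex coil sensitivity maps
#'
#' Gaussian magnitude profiles centered on points around the FOV with a
#' low-order polynomial phase, normalized to unit root-sum-of-squares
#' everywhere (so in particular in the object foreground).
#'
#' @param n_coils number of receive channels
#' @param shape c(nx, ny, nz)
#' @param seed RNG seed
#' @return complex array (nx, ny, nz, n_coils)
#' @export
simulate_coils <- function(n_coils, shape, seed = 1) {
  stopifnot(n_coils >= 1, length(shape) == 3)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  x <- 2 * (seq_len(nx) - 0.5) / nx - 1
  y <- 2 * (seq_len(ny) - 0.5) / ny - 1
  z <- if (nz > 1) 2 * (seq_len(nz) - 0.5) / nz - 1 else 0
  X <- array(x, c(nx, ny, nz))
  Y <- array(rep(y, each = nx), c(nx, ny, nz))
  Z <- array(rep(z, each = nx * ny), c(nx, ny, nz))
  sens <- array(0i, c(nx, ny, nz, n_coils))
  with_seed(seed, {
    for (cc in seq_len(n_coils)) {
      th <- 2 * pi * (cc - 1) / n_coils + stats::rnorm(1, sd = 0.1)
      x0 <- 1.3 * cos(th); y0 <- 1.3 * sin(th)
      mag <- exp(-((X - x0)^2 + (Y - y0)^2) / (2 * 0.8^2)) *
        (1 + 0.1 * stats::rnorm(1) * Z)
      ph <- stats::rnorm(1, sd = 1) + 0.5 * stats::rnorm(1) * X +
        0.5 * stats::rnorm(1) * Y + 0.3 * stats::rnorm(1) * Z +
        0.3 * stats::rnorm(1) * X * Y
      sens[, , , cc] <- mag * exp(1i * ph)
    }
  })
  rss <- sqrt(rowSums(abs(sens)^2, dims = 3))
  sens / as.vector(rss)
}

# per-label tissue table: CC-like bundle carries the corpus-callosum values
# used as simulation inputs (Da = 2.27 um^2/ms, fa = 0.60)
phantom_tissue_table <- function() {
  list(
    csf = list(params = compartment_params(0, 2.0, 1.0, 1.0, fw = 1),
               kappa = 0, mu = c(0, 0, 1), S0 = 1.2),
    cc = list(params = compartment_params(0.60, 2.27, 1.8, 0.6, fw = 0.05),
              kappa = 8, mu = c(1, 0, 0), S0 = 1),
    cst = list(params = compartment_params(0.68, 2.25, 1.9, 0.7, fw = 0.02),
               kappa = 6, mu = c(0, 1, 0), S0 = 1),
    wm = list(params = compartment_params(0.63, 2.12, 1.9, 0.8, fw = 0.05),
              kappa = 4, mu = c(1, 1, 0) / sqrt(2), S0 = 1),
    gm = list(params = compartment_params(0.25, 1.7, 1.2, 0.9, fw = 0.10),
              kappa = 1, mu = c(0, 0, 1), S0 = 1)
  )
}

#' Build the digital multi-slab head phantom
#'
#' Concentric geometric regions emulate a CSF ventricle (fw = 1), a
#' corpus-callosum-like bundle carrying the CC literature values
#' (fa = 0.60, Da = 2.27 um^2/ms), a second WM bundle, generic WM and a GM
#' rim. Tissue parameters are piecewise constant per label; S0 carries a
#' smooth seeded +-2% texture so distinct seeds give distinct realizations.
#'
#' @param shape c(nx, ny, nz) with each >= c(16, 16, 4)
#' @param n_coils receive channels for the stored sensitivity maps
#' @param seed RNG seed (coils use seed + 1)
#' @param grid spherical quadrature grid for the per-region ODFs
#' @param odf_kind "watson" (default; per-region concentrations) or
#'   "isotropic" (fully dispersed fibers, e.g. for pipeline-closure checks
#'   where powder averages over finite direction sets are exact)
#' @return object of class `slabkq_phantom` with label_map, per-label
#'   `params` and `odfs`, S0, coil_sens, slab_profile, foreground
#' @export
build_phantom <- function(shape = c(32, 32, 6), n_coils = 8, seed = 1,
                          grid = sphere_grid(1000),
                          odf_kind = c("watson", "isotropic")) {
  odf_kind <- match.arg(odf_kind)
  if (length(shape) != 3 || shape[1] < 16 || shape[2] < 16 || shape[3] < 4)
    stop("phantom shape must be at least (16, 16, 4)")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  x <- 2 * (seq_len(nx) - 0.5) / nx - 1
  y <- 2 * (seq_len(ny) - 0.5) / ny - 1
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  r <- sqrt((X / 0.92)^2 + (Y / 0.95)^2)
  lab2d <- matrix(0L, nx, ny)
  lab2d[r <= 1] <- 4L                                   # generic WM
  lab2d[r > 0.78 & r <= 1] <- 5L                        # GM rim
  lab2d[sqrt((X / 0.16)^2 + ((Y + 0.05) / 0.22)^2) <= 1] <- 1L   # CSF
  cc <- abs(Y - 0.38) < 0.14 & abs(X) < 0.55 & lab2d == 4L
  lab2d[cc] <- 2L                                       # CC-like bundle
  cst <- abs(X + 0.42) < 0.13 & abs(Y + 0.15) < 0.38 & lab2d == 4L
  lab2d[cst] <- 3L                                      # CST-like bundle
  label_map <- array(rep(lab2d, nz), c(nx, ny, nz))
  tis <- phantom_tissue_table()
  odfs <- if (odf_kind == "watson")
    lapply(tis, function(t) watson_odf(t$mu, t$kappa, grid))
  else lapply(tis, function(t) isotropic_odf(grid))
  S0 <- array(0, shape)
  for (l in seq_along(tis)) S0[label_map == l] <- tis[[l]]$S0
  tex <- with_seed(seed, {
    f <- array(stats::rnorm(prod(shape), sd = 1), shape)
    k <- stats::dnorm(seq(-2, 2, length.out = 5)); k <- k / sum(k)
    for (d in 1:2) f <- apply_mat_dim(f, smooth_band(shape[d], k), d)
    Re(f)
  })
  S0 <- S0 * (1 + 0.02 * tex / max(abs(tex)))
  structure(list(
    shape = shape, label_map = label_map,
    params = lapply(tis, `[[`, "params"), odfs = odfs,
    label_names = names(tis), S0 = S0,
    coil_sens = simulate_coils(n_coils, shape, seed = seed + 1),
    slab_profile = slab_profile_weights(nz),
    foreground = label_map > 0
  ), class = "slabkq_phantom")
}

# banded smoothing matrix (circular) used for the S0 texture
smooth_band <- function(n, kernel) {
  hw <- (length(kernel) - 1) / 2
  M <- matrix(0, n, n)
  for (j in seq_along(kernel))
    M[cbind(seq_len(n), (seq_len(n) + j - hw - 2) %% n + 1)] <- kernel[j]
  M
}

#' Simulate per-shot motion-induced phase maps
#'
#' Each (volume, shot) receives a smooth second-order 2D polynomial phase
#' c0 + c1 x + c2 y + c3 xy + c4 x^2 + c5 y^2 with coefficients drawn from
#' Normal(0, severity^2 * b/1000). Non-diffusion-weighted (b = 0) shots get
#' exactly zero phase.
#'
#' @param protocol a [build_protocol()] object
#' @param masks output of [generate_caipi_masks()] (defines the shot count)
#' @param shape c(nx, ny, ...) image grid
#' @param severity phase scale in radians at b = 1000 s/mm^2
#' @param seed RNG seed
#' @return array (nx, ny, n_shots, n_volumes), radians
#' @export
simulate_shot_phases <- function(protocol, masks, shape, severity = 0.5,
                                 seed = 1) {
  stopifnot(severity >= 0)
  nx <- shape[1]; ny <- shape[2]
  ns <- masks[[1]]$n_shots
  nv <- nrow(protocol$samples)
  x <- 2 * (seq_len(nx) - 0.5) / nx - 1
  y <- 2 * (seq_len(ny) - 0.5) / ny - 1
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  basis <- list(1 + 0 * X, X, Y, X * Y, X^2, Y^2)
  ph <- array(0, c(nx, ny, ns, nv))
  with_seed(seed, {
    for (v in seq_len(nv)) {
      sdv <- severity * sqrt(protocol$samples$b[v] / 1000)
      for (s in seq_len(ns)) {
        if (sdv == 0) next
        co <- stats::rnorm(6, sd = sdv)
        ph[, , s, v] <- Reduce(`+`, Map(`*`, co, basis))
      }
    }
  })
  ph
}

#' Simulate the accelerated multi-coil acquisition
#'
#' Per volume the phantom signal image (synthesized from the compartment
#' model, scaled by S0 and the slab profile) is shot-phased, coil-weighted,
#' Fourier-transformed over (y, z) per shot, restricted to the shot's sampled
#' (ky, kz) points and corrupted with complex Gaussian noise of standard
#' deviation sigma = mean foreground b0 magnitude / snr. A low-resolution 2D
#' navigator carrying the same shot phase is produced per (volume, shot),
#' ky-undersampled by `nav_ry`.
#'
#' @param phantom a [build_phantom()] object
#' @param protocol a [build_protocol()] object
#' @param masks per-volume masks from [generate_caipi_masks()]
#' @param phases array from [simulate_shot_phases()]
#' @param snr foreground b0 SNR (Inf for noiseless)
#' @param seed noise seed
#' @param nav_ry navigator ky reduction factor
#' @return list with `kspace` (nx, ny, nz, n_coils, n_vol; zero outside each
#'   volume's mask), `navigator`, `truth` (noise-free magnitude volumes),
#'   `b0` image, `sigma`, `foreground`
#' @export
simulate_acquisition <- function(phantom, protocol, masks, phases,
                                 snr = Inf, seed = 1, nav_ry = 3) {
  nv <- nrow(protocol$samples)
  if (length(masks) != nv) stop("mask/protocol volume-count mismatch")
  shp <- phantom$shape
  nx <- shp[1]; ny <- shp[2]; nz <- shp[3]
  nc <- dim(phantom$coil_sens)[4]
  sig_by_label <- vapply(seq_along(phantom$params), function(l)
    synthesize_signal(protocol, phantom$params[[l]], phantom$odfs[[l]]),
    numeric(nv))
  M <- array(0, c(nx, ny, nz, nv))
  base <- phantom$S0 * rep(phantom$slab_profile, each = nx * ny)
  lab <- phantom$label_map
  for (l in seq_along(phantom$params)) {
    idx <- which(lab == l)
    if (!length(idx)) next
    for (v in seq_len(nv))
      M[idx + (v - 1) * nx * ny * nz] <- base[idx] * sig_by_label[v, l]
  }
  b0 <- base
  Y <- sense_forward(M, phantom$coil_sens, phases, masks)
  sigma <- 0
  if (is.finite(snr)) {
    sigma <- mean(b0[phantom$foreground]) / snr
    with_seed(seed, {
      for (v in seq_len(nv)) {
        g <- masks[[v]]$grid
        for (cc in seq_len(nc)) {
          for (xx in seq_len(nx))
            Y[xx, , , cc, v] <- Y[xx, , , cc, v] +
              matrix(crnorm(length(g), sd = sigma), ny, nz) * g
        }
      }
    })
  }
  # navigator: mid-slice image with the same shot phase, 1D-SENSE sampling
  zmid <- ceiling(nz / 2)
  ns <- masks[[1]]$n_shots
  coils2d <- phantom$coil_sens[, , zmid, , drop = FALSE]
  dim(coils2d) <- c(nx, ny, nc)
  navk <- array(0i, c(nx, ny, nc, ns, nv))
  nav_rows <- lapply(seq_len(ns), function(s)
    seq(((s - 1) %% nav_ry) + 1, ny, by = nav_ry))
  with_seed(seed + 1, {
    for (v in seq_len(nv)) {
      img <- M[, , zmid, v]
      for (s in seq_len(ns)) {
        ph <- exp(1i * phases[, , s, v])
        K <- ft_y(array(as.complex(img * ph) * as.vector(coils2d),
                        c(nx, ny, nc)))
        rows <- nav_rows[[s]]
        sel <- array(FALSE, c(nx, ny, nc)); sel[, rows, ] <- TRUE
        K[!sel] <- 0i
        if (sigma > 0)
          K[sel] <- K[sel] + crnorm(sum(sel), sd = sigma)
        navk[, , , s, v] <- K
      }
    }
  })
  list(kspace = Y, sigma = sigma,
       navigator = list(k = navk, ry = nav_ry, rows = nav_rows,
                        coils = coils2d, zmid = zmid),
       truth = M, b0 = b0, foreground = phantom$foreground)
}
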