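# Acquisition protocols: multi-shell q-space designs, slab geometry, scan-time
# arithmetic and randomized 2D-CAIPI ky-kz sampling masks.

#' Approximately uniform directions on the hemisphere
#'
#' Electrostatic-repulsion layout with antipodal symmetry: points repel both
#' each other and each other's antipodes, so the set is well spread under the
#' angular metric acos(|u.v|). Deterministic for a given seed.
#'
#' @param n number of directions
#' @param seed RNG seed
#' @param n_iter repulsion iterations
#' @return n x 3 matrix of unit row vectors (z >= 0 hemisphere)
#' @export
uniform_hemisphere_dirs <- function(n, seed = 1, n_iter = 300) {
  stopifnot(n >= 1)
  if (n == 1L) return(matrix(c(0, 0, 1), 1, 3))
  key <- sprintf("dirs_%d_%d_%d", n, seed, n_iter)
  got <- .slabkq_cache[[key]]
  if (!is.null(got)) return(got)
  P <- with_seed(seed, {
    P <- matrix(stats::rnorm(3 * n), n, 3)
    P <- P / sqrt(rowSums(P^2))
    step <- 0.1 / n
    for (it in seq_len(n_iter)) {
      Fr <- matrix(0, n, 3)
      for (i in seq_len(n)) {
        d1 <- sweep(P[-i, , drop = FALSE], 2, P[i, ], "-")   # from +p_j
        d2 <- sweep(-P[-i, , drop = FALSE], 2, P[i, ], "-")  # from -p_j
        r1 <- pmax(sqrt(rowSums(d1^2)), 1e-6)
        r2 <- pmax(sqrt(rowSums(d2^2)), 1e-6)
        Fr[i, ] <- -colSums(d1 / r1^3) - colSums(d2 / r2^3)
      }
      P <- P + step * Fr
      P <- P / sqrt(rowSums(P^2))
    }
    P
  })
  flip <- P[, 3] < 0
  P[flip, ] <- -P[flip, ]
  .slabkq_cache[[key]] <- P
  P
}

# minimal pairwise angle (antipodally identified), used by tests
min_pairwise_angle <- function(dirs) {
  G <- abs(tcrossprod(dirs))
  diag(G) <- 0
  acos(pmin(1, max(G)))
}

#' Slab FOVz from thickness and oversampling
#'
#' slab_thickness * (1 + oversampling), rounded up to an integer multiple of
#' the slice thickness (e.g. 14 mm * 1.4 = 19.6 -> 20 mm at 1 mm slices).
#'
#' @param slab_thickness mm
#' @param oversampling dimensionless fraction (e.g. 0.4)
#' @param slice_thickness mm
#' @export
slab_fovz <- function(slab_thickness, oversampling, slice_thickness = 1) {
  ceiling(slab_thickness * (1 + oversampling) / slice_thickness) *
    slice_thickness
}

#' Build a multi-shell acquisition protocol
#'
#' Defines the full q-space design (per-volume b-value, unit direction and
#' encoding shape beta) together with slab geometry and timing. Directions on
#' each shell come from a seeded electrostatic-repulsion layout on the
#' hemisphere. The default geometry is an axial multi-slab acquisition: 14 mm
#' slabs extended by 40% oversampling to a 20 mm FOVz at 1 mm slices
#' (20 kz planes), TR = 2 s, 8 slabs (112 mm coverage).
#'
#' @param shell_bvalues distinct b-values in s/mm^2, one per shell
#' @param n_dirs_per_shell directions per shell (scalar or per-shell vector)
#' @param betas encoding shape in [0, 1] per shell (1 = linear); recycled
#' @param TR repetition time, seconds
#' @param slice_thickness mm
#' @param slab_thickness mm
#' @param oversampling slab oversampling fraction
#' @param FOVz mm; default derived from slab geometry via [slab_fovz()]
#' @param n_slabs number of slabs tiling the head along z
#' @param Ny in-plane phase-encode count
#' @param n_nondw_fully_sampled number of fully sampled non-DW volumes
#' @param seed seed for the direction layout
#' @return object of class `slabkq_protocol`; `$samples` is a data frame with
#'   columns b, gx, gy, gz, beta, shell_id
#' @export
build_protocol <- function(shell_bvalues, n_dirs_per_shell, betas = 1,
                           TR = 2, slice_thickness = 1, slab_thickness = 14,
                           oversampling = 0.4, FOVz = NULL, n_slabs = 8,
                           Ny = 210, n_nondw_fully_sampled = 1, seed = 1) {
  if (any(shell_bvalues < 0))
    stop("shell b-values must be distinct and >= 0")
  if (any(n_dirs_per_shell < 1)) stop("n_dirs_per_shell must be >= 1")
  if (TR <= 0 || slice_thickness <= 0 || slab_thickness <= 0)
    stop("invalid protocol: non-positive TR or geometry")
  ns <- length(shell_bvalues)
  n_dirs <- rep_len(n_dirs_per_shell, ns)
  betas <- rep_len(betas, ns)
  # shells are (b, beta) pairs: b may repeat across encoding shapes
  if (anyDuplicated(paste(shell_bvalues, betas)))
    stop("shell b-values must be distinct and >= 0 (per encoding shape)")
  if (any(betas < 0 | betas > 1)) stop("beta must lie in [0, 1]")
  if (is.null(FOVz))
    FOVz <- slab_fovz(slab_thickness, oversampling, slice_thickness)
  if (FOVz <= 0) stop("invalid protocol: non-positive FOVz")
  samples <- do.call(rbind, lapply(seq_len(ns), function(s) {
    g <- uniform_hemisphere_dirs(n_dirs[s], seed = seed + s)
    data.frame(b = shell_bvalues[s], gx = g[, 1], gy = g[, 2], gz = g[, 3],
               beta = betas[s], shell_id = s)
  }))
  structure(list(
    samples = samples,
    TR = TR, FOVz = FOVz, slice_thickness = slice_thickness,
    n_kz = as.integer(round(FOVz / slice_thickness)),
    n_slabs = as.integer(n_slabs), slab_thickness = slab_thickness,
    oversampling_fraction = oversampling, Ny = as.integer(Ny),
    n_nondw_fully_sampled = as.integer(n_nondw_fully_sampled)
  ), class = "slabkq_protocol")
}

#' @export
print.slabkq_protocol <- function(x, ...) {
  sh <- unique(x$samples[c("b", "beta", "shell_id")])
  cat(sprintf("slabkq protocol: %d volumes, %d shells, TR=%gs, FOVz=%gmm (%d kz), %d slabs\n",
              nrow(x$samples), nrow(sh), x$TR, x$FOVz, x$n_kz, x$n_slabs))
  for (i in seq_len(nrow(sh)))
    cat(sprintf("  shell %d: b=%g s/mm^2, beta=%g, %d dirs\n", sh$shell_id[i],
                sh$b[i], sh$beta[i], sum(x$samples$shell_id == sh$shell_id[i])))
  invisible(x)
}

# parse a sampling reduction given as number, "num/den" string or c(num, den)
parse_rz <- function(rz) {
  if (is.character(rz)) {
    parts <- as.numeric(strsplit(rz, "/", fixed = TRUE)[[1]])
    if (length(parts) == 1) return(parts)
    return(parts[1] / parts[2])
  }
  if (length(rz) == 2) return(rz[1] / rz[2])
  as.numeric(rz)
}

#' Sampling configuration for 2D-CAIPI undersampling
#'
#' @param ry in-plane (ky) reduction factor, integer >= 1
#' @param rz kz reduction; rational values should be given as a string
#'   ("20/6") or a length-2 vector c(20, 6) so the shot count is exact
#' @param seed seed for the per-volume randomized offsets
#' @param caipi_shift kz-plane-rank dependent ky offset increment
#' @export
sampling_config <- function(ry = 3, rz = "20/6", seed = 1, caipi_shift = 1) {
  ry <- as.integer(ry)
  if (ry < 1) stop("ry must be >= 1")
  structure(list(ry = ry, rz = parse_rz(rz), seed = as.integer(seed),
                 caipi_shift = as.integer(caipi_shift)),
            class = "slabkq_sampling_config")
}

n_kz_shots <- function(n_kz, rz) {
  if (rz > n_kz) stop("Rz exceeds the number of kz planes")
  as.integer(ceiling(n_kz / rz - 1e-9))
}

#' Generate randomized 2D-CAIPI sampling masks, one per DW volume
#'
#' Each mask samples ceiling(n_kz / Rz) kz planes forming an even partition of
#' the kz axis with a per-volume random circular offset; within the plane of
#' rank j the sampled ky indices form an arithmetic progression of step Ry
#' with offset (base + caipi_shift * j) mod Ry, the base randomized per
#' volume. Deterministic given `cfg$seed`.
#'
#' @param protocol a [build_protocol()] object
#' @param cfg a [sampling_config()]
#' @return list of masks; each has `grid` (logical Ny x n_kz), `planes`
#'   (1-based sampled kz planes in shot order) and `shot_of_kz` (integer per
#'   kz plane, NA if unsampled)
#' @export
generate_caipi_masks <- function(protocol, cfg) {
  n_kz <- protocol$n_kz
  Ny <- protocol$Ny
  ns <- n_kz_shots(n_kz, cfg$rz)
  n_vol <- nrow(protocol$samples)
  with_seed(cfg$seed, {
    lapply(seq_len(n_vol), function(v) {
      off_kz <- sample.int(n_kz, 1) - 1L
      base_ky <- sample.int(cfg$ry, 1) - 1L
      planes0 <- (off_kz + round((seq_len(ns) - 1) * n_kz / ns)) %% n_kz
      grid <- matrix(FALSE, Ny, n_kz)
      shot_of_kz <- rep(NA_integer_, n_kz)
      for (j in seq_len(ns)) {
        o <- (base_ky + cfg$caipi_shift * (j - 1L)) %% cfg$ry
        ky <- seq(o + 1L, Ny, by = cfg$ry)
        grid[ky, planes0[j] + 1L] <- TRUE
        shot_of_kz[planes0[j] + 1L] <- j
      }
      structure(list(grid = grid, planes = planes0 + 1L,
                     shot_of_kz = shot_of_kz, ry = cfg$ry, n_shots = ns),
                class = "slabkq_mask")
    })
  })
}

#' Volume acquisition time (seconds)
#'
#' Time to sample one diffusion volume: kz shots times TR.
#' @inheritParams generate_caipi_masks
#' @export
volume_acquisition_time <- function(protocol, cfg) {
  n_kz_shots(protocol$n_kz, cfg$rz) * protocol$TR
}

#' Total scheduled scan time (seconds)
#'
#' n_DW volumes at the accelerated VAT plus the fully sampled non-DW volumes
#' at n_kz shots each.
#' @inheritParams generate_caipi_masks
#' @export
total_scan_time <- function(protocol, cfg) {
  nrow(protocol$samples) * volume_acquisition_time(protocol, cfg) +
    protocol$n_nondw_fully_sampled * protocol$n_kz * protocol$TR
}

#' Net undersampling factor of one mask
#'
#' (Ny x n_kz) / number of sampled (ky, kz) points.
#' @param mask an element of [generate_caipi_masks()]
#' @export
net_undersampling_factor <- function(mask) {
  n <- sum(mask$grid)
  if (n == 0) stop("empty sampling mask")
  length(mask$grid) / n
}

#' Nominal slab coverage along z (mm)
#'
#' Contiguous non-overlapping coverage: n_slabs x slab_thickness.
#' @param protocol a [build_protocol()] object
#' @export
slab_coverage <- function(protocol) {
  if (protocol$n_slabs < 1) stop("n_slabs must be >= 1")
  protocol$n_slabs * protocol$slab_thickness
}

#' Write / read FSL-dialect gradient tables
#'
#' Writes `<basename>.bval`, `<basename>.bvec` (3 rows) and a single-column
#' `<basename>.beta` file with one encoding-shape value per volume.
#'
#' @param protocol a [build_protocol()] object
#' @param basename path prefix
#' @return `basename`, invisibly
#' @export
write_gradient_table <- function(protocol, basename) {
  s <- protocol$samples
  writeLines(paste(format(s$b, trim = TRUE), collapse = " "),
             paste0(basename, ".bval"))
  bv <- rbind(s$gx, s$gy, s$gz)
  writeLines(apply(bv, 1, function(r)
    paste(format(r, digits = 10, trim = TRUE), collapse = " ")),
    paste0(basename, ".bvec"))
  writeLines(format(s$beta, trim = TRUE), paste0(basename, ".beta"))
  invisible(basename)
}

#' @rdname write_gradient_table
#' @export
read_gradient_table <- function(basename) {
  b <- scan(paste0(basename, ".bval"), quiet = TRUE)
  bv <- matrix(scan(paste0(basename, ".bvec"), quiet = TRUE),
               nrow = 3, byrow = TRUE)
  beta_file <- paste0(basename, ".beta")
  beta <- if (file.exists(beta_file)) scan(beta_file, quiet = TRUE)
          else rep(1, length(b))
  data.frame(b = b, gx = bv[1, ], gy = bv[2, ], gz = bv[3, ], beta = beta)
}
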