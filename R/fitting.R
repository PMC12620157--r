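# Compartment-model estimation from reconstructed multi-shell data via
# per-shell rotational invariants (spherical mean + optional l=2), DTI/DKI
# validation fits, and ROI statistics.

as_voxel_matrix <- function(volumes) {
  d <- dim(volumes)
  if (is.null(d) || length(d) == 2) return(as.matrix(volumes))
  nv <- d[length(d)]
  matrix(volumes, ncol = nv)
}

#' Spherical (powder) means per (b, beta) shell group
#'
#' Signals are b0-normalized and averaged over directions within each
#' distinct (b, beta) group with b > 0.
#'
#' @param volumes array (nx, ny, nz, n_vol) or matrix (n_vox x n_vol)
#' @param protocol matching [build_protocol()] object
#' @param b0 per-voxel non-DW reference; if missing, the mean of the
#'   protocol's b = 0 volumes is used (error if none)
#' @return list with `groups` (data frame b, beta) and `means`
#'   (n_vox x n_group)
#' @export
spherical_mean <- function(volumes, protocol, b0 = NULL) {
  X <- as_voxel_matrix(volumes)
  s <- protocol$samples
  if (is.null(b0)) {
    iz <- which(s$b == 0)
    if (!length(iz)) stop("missing b0: supply `b0` or include b = 0 volumes")
    b0 <- rowMeans(X[, iz, drop = FALSE])
  }
  b0 <- pmax(as.vector(b0), 1e-12)
  groups <- unique(s[s$b > 0, c("b", "beta")])
  rownames(groups) <- NULL
  means <- sapply(seq_len(nrow(groups)), function(g) {
    idx <- which(s$b == groups$b[g] & s$beta == groups$beta[g])
    rowMeans(X[, idx, drop = FALSE]) / b0
  })
  list(groups = groups, means = matrix(means, nrow = nrow(X)))
}

#' Fitting configuration for the compartment model
#'
#' @param n_starts multistart count (fixed Latin hypercube)
#' @param use_l2 include the l = 2 rotational invariant (needed for
#'   identifiability of single-beta protocols)
#' @param lmax SH order of the data-side invariant fit
#' @param Dw fixed free-water diffusivity, um^2/ms
#' @param Dmax diffusivity upper bound
#' @param seed seed for the multistart design
#' @param n_polish number of best multistart candidates refined with tight
#'   restarted solves
#' @param polish_restarts restarts per polished candidate
#' @export
fit_config <- function(n_starts = 10, use_l2 = TRUE, lmax = 4, Dw = 3.0,
                       Dmax = 3.2, seed = 101, n_polish = 3,
                       polish_restarts = 3) {
  structure(list(n_starts = as.integer(n_starts), use_l2 = use_l2,
                 lmax = as.integer(lmax), Dw = Dw, Dmax = Dmax,
                 seed = as.integer(seed), n_polish = as.integer(n_polish),
                 polish_restarts = as.integer(polish_restarts)),
            class = "slabkq_fit_config")
}

# fixed Latin-hypercube multistart on the bounded box; theta order:
# fa, Da, De_par, De_perp, fw, p2
fit_starts <- function(cfg) {
  k <- cfg$n_starts
  lo <- c(0.05, 0.3, 0.3, 0.1, 0.0, 0.05)
  hi <- c(0.9, cfg$Dmax - 0.1, cfg$Dmax - 0.1, 1.8, 0.5, 0.95)
  with_seed(cfg$seed, {
    U <- sapply(1:6, function(j) (sample.int(k) - stats::runif(k)) / k)
    sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+")
  })
}

# model-side invariants for one (b, beta) design; theta as above
model_invariants <- function(theta, b, beta, Dw, want_l2) {
  fa <- theta[1]; Da <- theta[2]; Dep <- theta[3]; Deq <- theta[4]
  fw <- theta[5]; p2 <- theta[6]
  fe <- 1 - fa - fw
  bb <- b / 1000
  s0 <- fa * exp(-bb * Da * (1 - beta) / 3) * mean_exp_t2(bb * Da * beta) +
    fe * exp(-bb * Deq - bb * (Dep - Deq) * (1 - beta) / 3) *
      mean_exp_t2(bb * (Dep - Deq) * beta) +
    fw * exp(-bb * Dw)
  if (!want_l2) return(list(s0 = s0, s2 = NULL))
  k2a <- kernel_proj_l(bb * Da * (1 - beta) / 3, bb * Da * beta, 2)
  k2e <- kernel_proj_l(bb * Deq + bb * (Dep - Deq) * (1 - beta) / 3,
                       bb * (Dep - Deq) * beta, 2)
  list(s0 = s0, s2 = abs(p2 * (fa * k2a + fe * k2e)))
}

fit_voxel <- function(s0_obs, s2_obs, b, beta, cfg, starts) {
  want_l2 <- !is.null(s2_obs) && any(is.finite(s2_obs))
  s2_use <- if (want_l2) which(is.finite(s2_obs)) else integer(0)
  objfn <- function(theta) {
    pen <- 1e3 * (max(0, theta[1] + theta[5] - 1)^2 +
                    max(0, theta[4] - theta[3])^2)
    m <- model_invariants(theta, b, beta, cfg$Dw, want_l2)
    r <- sum((m$s0 - s0_obs)^2)
    if (want_l2) r <- r + sum((m$s2[s2_use] - s2_obs[s2_use])^2)
    r + pen
  }
  lo <- c(0, 0, 0, 0, 0, 0)
  hi <- c(1, cfg$Dmax, cfg$Dmax, cfg$Dmax, 1, 1)
  run_lbfgsb <- function(th0, factr, maxit, ndeps = 1e-6) tryCatch(
    stats::optim(th0, objfn, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = maxit, factr = factr, pgtol = 0,
                                ndeps = rep(ndeps, 6))),
    error = function(e) list(par = th0, value = objfn(th0),
                             convergence = 99L))
  # stage 1: coarse multistart
  sols <- apply(starts, 1, function(th0) {
    fit <- run_lbfgsb(th0, 1e7, 200)
    c(fit$par, fit$value, fit$convergence)
  })
  # stage 2: polish the best candidates with restarted tight solves (the
  # invariant surface has long flat valleys; restarting resets the L-BFGS
  # curvature memory)
  ord1 <- order(sols[7, ])
  for (j in ord1[seq_len(min(cfg$n_polish, ncol(sols)))]) {
    fit <- list(par = sols[1:6, j], value = sols[7, j], convergence = 0L)
    for (r in seq_len(cfg$polish_restarts)) fit <- run_lbfgsb(fit$par, 1e1, 1500)
    sols[, j] <- c(fit$par, fit$value, fit$convergence)
  }
  vals <- sols[7, ]
  ord <- order(vals, sols[2, ])            # residual, then lowest Da
  best <- sols[, ord[1]]
  # branch flag: a near-equal-residual solution on the other Da vs De_par side
  branch <- FALSE
  side <- sign(best[2] - best[3])
  for (j in ord[-1]) {
    if (vals[j] > max(vals[ord[1]] * 1.01, vals[ord[1]] + 1e-12)) break
    if (sign(sols[2, j] - sols[3, j]) != side &&
        abs(sols[2, j] - best[2]) > 0.05) { branch <- TRUE; break }
  }
  list(theta = best[1:6], residual = sqrt(best[7]),
       converged = best[8] == 0, branch_flag = branch)
}

#' Fit the three-compartment model per voxel
#'
#' Computes per-shell rotational invariants (spherical mean, plus the l = 2
#' invariant for every (b, beta) group with at least 6 directions) and solves
#' a bounded nonlinear least-squares problem per voxel with Latin-hypercube
#' multistarts. Single-beta (linear-encoding) protocols are identifiable only
#' up to the known flat valley of the standard model; protocols with >= 2
#' encoding shapes (B-tensor variation) are well-posed. Voxels
#' where a near-equal-residual solution exists on the other branch of the
#' known Da vs De_par degeneracy are flagged. CSF-degenerate voxels
#' (fw ~ 1) are flagged too, since Da is unidentifiable there.
#'
#' @param volumes array (nx, ny, nz, n_vol) or matrix (n_vox x n_vol)
#' @param protocol matching [build_protocol()] object (needs >= 3 shells or
#'   >= 2 beta values)
#' @param fit_cfg a [fit_config()]
#' @param b0 per-voxel non-DW reference (see [spherical_mean()])
#' @param mask optional logical voxel mask; background (all-zero) voxels are
#'   skipped automatically
#' @return list of class `slabkq_fit` with per-voxel parameter matrix
#'   `params` (columns fa, Da, De_par, De_perp, fw, p2), `residual`,
#'   `converged`, `branch_flag`, `csf_flag`, and the voxel `dim`
#' @export
fit_compartments <- function(volumes, protocol, fit_cfg = fit_config(),
                             b0 = NULL, mask = NULL) {
  X <- as_voxel_matrix(volumes)
  s <- protocol$samples
  groups <- unique(s[s$b > 0, c("b", "beta")])
  if (nrow(groups) < 3)
    stop("need >= 3 shells (or >= 2 beta values) for identifiability")
  use_l2 <- fit_cfg$use_l2
  if (is.null(b0)) {
    iz <- which(s$b == 0)
    b0 <- if (length(iz)) rowMeans(abs(X[, iz, drop = FALSE])) else rep(1, nrow(X))
  }
  b0 <- pmax(as.vector(b0), 1e-12)
  keep <- if (is.null(mask)) rowSums(abs(X)) > 1e-10 else as.vector(mask)
  if (!any(keep)) {
    return(structure(list(params = matrix(numeric(0), 0, 6),
                          residual = numeric(0), converged = logical(0),
                          branch_flag = logical(0), csf_flag = logical(0),
                          voxels = integer(0), dim = dim(volumes)),
                     class = "slabkq_fit"))
  }
  sm <- spherical_mean(X, protocol, b0 = b0)
  s2_all <- NULL
  if (use_l2) {
    # per-group l = 2 invariant wherever the group has enough directions
    s2_all <- sapply(seq_len(nrow(groups)), function(g) {
      idx <- which(s$b == groups$b[g] & s$beta == groups$beta[g])
      if (length(idx) < 6) return(rep(NA_real_, nrow(X)))
      dirs <- as.matrix(s[idx, c("gx", "gy", "gz")])
      inv <- shell_invariants(X[, idx, drop = FALSE] / b0, dirs,
                              lmax = fit_cfg$lmax)
      if ("l2" %in% colnames(inv)) inv[, "l2"] else rep(NA_real_, nrow(X))
    })
    s2_all <- matrix(s2_all, nrow = nrow(X))
    if (all(!is.finite(s2_all))) s2_all <- NULL
  }
  starts <- fit_starts(fit_cfg)
  vox <- which(keep)
  n <- length(vox)
  params <- matrix(NA_real_, n, 6,
                   dimnames = list(NULL, c("fa", "Da", "De_par", "De_perp",
                                           "fw", "p2")))
  residual <- numeric(n); converged <- logical(n); branch <- logical(n)
  for (i in seq_len(n)) {
    v <- vox[i]
    r <- fit_voxel(sm$means[v, ],
                   if (!is.null(s2_all)) s2_all[v, ] else NULL,
                   groups$b, groups$beta, fit_cfg, starts)
    params[i, ] <- r$theta
    residual[i] <- r$residual
    converged[i] <- r$converged
    branch[i] <- r$branch_flag
  }
  structure(list(params = params, residual = residual, converged = converged,
                 branch_flag = branch, csf_flag = params[, "fw"] > 0.95,
                 voxels = vox, dim = dim(volumes)),
            class = "slabkq_fit")
}

#' Extract a parameter map from a fit
#'
#' @param fit a `slabkq_fit`
#' @param name one of fa, Da, De_par, De_perp, fw, p2
#' @return array shaped like the fitted volume's spatial grid
#' @export
fit_map <- function(fit, name) {
  d <- fit$dim
  spat <- if (length(d) >= 3) d[1:3] else c(nrow = prod(d[-length(d)]), 1, 1)
  out <- array(NA_real_, spat)
  out[fit$voxels] <- fit$params[, name]
  out
}

# ---- DTI / DKI --------------------------------------------------------------

dti_design <- function(b, G) {
  bb <- b / 1000
  cbind(1, -bb * G[, 1]^2, -bb * G[, 2]^2, -bb * G[, 3]^2,
        -2 * bb * G[, 1] * G[, 2], -2 * bb * G[, 1] * G[, 3],
        -2 * bb * G[, 2] * G[, 3])
}

tensor_eigvals <- function(beta) {
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  eigen(D, symmetric = TRUE, only.values = TRUE)$values
}

fa_from_eig <- function(ev) {
  md <- mean(ev)
  num <- sum((ev - md)^2)
  den <- sum(ev^2)
  if (den <= 0) return(0)
  sqrt(1.5 * num / den)
}

#' Diffusion tensor (DTI) fit: FA and MD maps
#'
#' Weighted linear least squares on log-signals (weights = squared fitted
#' signals, one reweighting pass) for the six tensor elements plus log S0;
#' FA and MD follow from the eigenvalues. Only beta = 1 volumes are valid
#' input; non-positive signals are clipped to eps with a warning.
#'
#' @param volumes array or voxel matrix of the beta = 1 subset (may include
#'   b = 0 volumes)
#' @param protocol protocol describing exactly those volumes
#' @param b0 optional reference appended as a b = 0 measurement
#' @return list with `FA`, `MD` (um^2/ms) and eigenvalue matrix `evals`
#' @export
fit_dti <- function(volumes, protocol, b0 = NULL) {
  s <- if (inherits(protocol, "slabkq_protocol")) protocol$samples else protocol
  if (any(s$beta != 1)) {
    s <- s[s$beta == 1, , drop = FALSE]
  }
  X <- as_voxel_matrix(volumes)
  if (!is.null(b0)) {
    X <- cbind(as.vector(b0), X)
    s <- rbind(data.frame(b = 0, gx = 0, gy = 0, gz = 1, beta = 1,
                          shell_id = 0L), s[, c("b", "gx", "gy", "gz",
                                                "beta", "shell_id")])
  }
  if (sum(s$b > 0) < 6) stop("need >= 6 diffusion-weighted directions")
  if (any(X <= 0)) {
    warning("non-positive signals clipped to eps before log")
    X[X <= 0] <- 1e-10
  }
  A <- dti_design(s$b, as.matrix(s[, c("gx", "gy", "gz")]))
  L <- log(X)
  beta_ols <- t(qr.solve(A, t(L)))
  n <- nrow(X)
  FA <- numeric(n); MD <- numeric(n)
  evals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    w <- exp(A %*% beta_ols[i, ])^2          # WLLS weights
    Aw <- A * as.vector(w)
    bta <- solve(crossprod(A, Aw), crossprod(Aw, L[i, ]))
    ev <- tensor_eigvals(as.vector(bta))
    evals[i, ] <- ev
    MD[i] <- mean(ev)
    FA[i] <- fa_from_eig(ev)
  }
  list(FA = FA, MD = MD, evals = evals)
}

dki_design <- function(b, G) {
  bb <- b / 1000
  g1 <- G[, 1]; g2 <- G[, 2]; g3 <- G[, 3]
  D_part <- cbind(g1^2, g2^2, g3^2, 2 * g1 * g2, 2 * g1 * g3, 2 * g2 * g3)
  W_part <- cbind(g1^4, g2^4, g3^4,
                  4 * g1^3 * g2, 4 * g1^3 * g3, 4 * g2^3 * g1,
                  4 * g2^3 * g3, 4 * g3^3 * g1, 4 * g3^3 * g2,
                  6 * g1^2 * g2^2, 6 * g1^2 * g3^2, 6 * g2^2 * g3^2,
                  12 * g1^2 * g2 * g3, 12 * g2^2 * g1 * g3,
                  12 * g3^2 * g1 * g2)
  cbind(1, -bb * D_part, (bb^2 / 6) * W_part)
}

#' Diffusion kurtosis (DKI) fit: mean kurtosis map
#'
#' Linear least squares of log S = log S0 - b D_app + b^2 (D_app^2 K_app)/6
#' through the kurtosis-tensor design matrix (22 parameters; needs >= 2
#' nonzero shells of beta = 1 data). The directional apparent kurtosis
#' K_app(n) = W_app(n) / D_app(n)^2 is clamped to [0, 10] and averaged over
#' 256 uniform directions to give MK.
#'
#' @inheritParams fit_dti
#' @param n_mk_dirs directions for the MK average
#' @return list with `MK`, plus tensors `D` (6 cols) and `W` (15 cols)
#' @export
fit_dki <- function(volumes, protocol, b0 = NULL, n_mk_dirs = 256) {
  s <- if (inherits(protocol, "slabkq_protocol")) protocol$samples else protocol
  s <- s[s$beta == 1, , drop = FALSE]
  X <- as_voxel_matrix(volumes)
  if (!is.null(b0)) {
    X <- cbind(as.vector(b0), X)
    s <- rbind(data.frame(b = 0, gx = 0, gy = 0, gz = 1, beta = 1,
                          shell_id = 0L),
               s[, c("b", "gx", "gy", "gz", "beta", "shell_id")])
  }
  if (length(unique(s$b[s$b > 0])) < 2)
    stop("DKI needs >= 2 nonzero shells")
  if (any(X <= 0)) {
    warning("non-positive signals clipped to eps before log")
    X[X <= 0] <- 1e-10
  }
  A <- dki_design(s$b, as.matrix(s[, c("gx", "gy", "gz")]))
  cf <- t(qr.solve(A, t(log(X))))           # n_vox x 22
  dirs <- uniform_hemisphere_dirs(n_mk_dirs, seed = 7)
  # directional projections: D_app(n) and (D_app^2 K_app)(n)
  Dproj <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
                 2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
                 2 * dirs[, 2] * dirs[, 3])
  g1 <- dirs[, 1]; g2 <- dirs[, 2]; g3 <- dirs[, 3]
  Wproj <- cbind(g1^4, g2^4, g3^4,
                 4 * g1^3 * g2, 4 * g1^3 * g3, 4 * g2^3 * g1,
                 4 * g2^3 * g3, 4 * g3^3 * g1, 4 * g3^3 * g2,
                 6 * g1^2 * g2^2, 6 * g1^2 * g3^2, 6 * g2^2 * g3^2,
                 12 * g1^2 * g2 * g3, 12 * g2^2 * g1 * g3,
                 12 * g3^2 * g1 * g2)
  Dmat <- cf[, 2:7, drop = FALSE] %*% t(Dproj)       # n_vox x n_dirs
  Wmat <- cf[, 8:22, drop = FALSE] %*% t(Wproj)
  Kapp <- Wmat / pmax(Dmat, 1e-12)^2
  Kapp <- pmin(pmax(Kapp, 0), 10)
  list(MK = rowMeans(Kapp), D = cf[, 2:7, drop = FALSE],
       W = cf[, 8:22, drop = FALSE])
}

# ---- ROI statistics ---------------------------------------------------------

#' Per-ROI mean, SD and coefficient of variation
#'
#' @param param_maps named list of arrays (or a single array)
#' @param label_map integer ROI labels, same spatial shape
#' @param roi_ids labels to evaluate (default: all nonzero labels)
#' @return data frame with roi, parameter, n, mean, sd, cov (percent);
#'   empty ROIs are flagged and excluded from the values
#' @export
roi_statistics <- function(param_maps, label_map, roi_ids = NULL) {
  if (!is.list(param_maps)) param_maps <- list(value = param_maps)
  if (is.null(roi_ids)) roi_ids <- sort(setdiff(unique(as.vector(label_map)), 0))
  out <- do.call(rbind, lapply(names(param_maps), function(nm) {
    do.call(rbind, lapply(roi_ids, function(r) {
      v <- param_maps[[nm]][label_map == r]
      v <- v[is.finite(v)]
      if (!length(v))
        return(data.frame(roi = r, parameter = nm, n = 0L, mean = NA_real_,
                          sd = NA_real_, cov = NA_real_, empty = TRUE))
      m <- mean(v); sdev <- stats::sd(v)
      data.frame(roi = r, parameter = nm, n = length(v), mean = m, sd = sdev,
                 cov = if (m != 0) 100 * sdev / m else NA_real_,
                 empty = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Across-realization ROI variability
#'
#' Aggregates the per-realization ROI means (one "subject" per phantom
#' realization) and reports their mean, SD and COV.
#'
#' @param maps list (one per realization) of parameter arrays
#' @param label_map shared ROI labels
#' @param roi_id single ROI label
#' @export
roi_cov_across <- function(maps, label_map, roi_id) {
  means <- vapply(maps, function(m) mean(m[label_map == roi_id],
                                         na.rm = TRUE), numeric(1))
  m <- mean(means); sdev <- stats::sd(means)
  data.frame(roi = roi_id, n_realizations = length(maps), mean = m,
             sd = sdev, cov = 100 * sdev / m)
}
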