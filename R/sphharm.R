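# Real spherical harmonics and per-shell rotational invariants.
#
# Conventions: orthonormal real SH on the sphere. For an axially symmetric
# kernel K(b, t), t = cos(angle), and an ODF with Legendre moments
# p_l = E[P_l(mu . n)] (p_0 = 1, delta ODF -> p_l = 1), the Funk-Hecke
# theorem gives per-shell signal invariants
#   s_l(b) = p_l * Ktilde_l(b),  Ktilde_l(b) = int_0^1 K(b, t) P_l(t) dt,
# where the data-side invariant is s_l = sqrt(sum_m S_lm^2 / (4 pi (2l+1)))
# from a least-squares SH fit of the shell samples (s_0 is the spherical
# mean).

# associated Legendre P_l^m(z), forward column recursion (no phase issues for
# the invariants, which sum squares)
assoc_legendre <- function(z, l, m) {
  pmm <- rep(1, length(z))
  if (m > 0) {
    somz2 <- sqrt(pmax(0, 1 - z^2))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- -pmm * fact * somz2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- z * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in (m + 2):l) {
    pll <- (z * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pmmp1
}

#' Real spherical harmonic design matrix
#'
#' Orthonormal real SH evaluated at unit directions, even orders only
#' (antipodally symmetric signals).
#'
#' @param dirs n x 3 unit vectors
#' @param lmax maximum (even) order
#' @return n x n_coef matrix; attribute `l` gives the order of each column
#' @export
real_sh_basis <- function(dirs, lmax = 4) {
  ls <- seq(0, lmax, by = 2)
  z <- dirs[, 3]
  phi <- atan2(dirs[, 2], dirs[, 1])
  cols <- list(); lcol <- integer(0)
  for (l in ls) {
    for (m in -l:l) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      P <- assoc_legendre(z, l, am)
      y <- if (m == 0) N * P
           else if (m > 0) sqrt(2) * N * P * cos(am * phi)
           else sqrt(2) * N * P * sin(am * phi)
      cols[[length(cols) + 1]] <- y
      lcol <- c(lcol, l)
    }
  }
  B <- do.call(cbind, cols)
  attr(B, "l") <- lcol
  B
}

#' Per-shell rotational invariants from sampled signals
#'
#' Least-squares SH fit per shell followed by the order-wise invariant
#' s_l = sqrt(sum_m c_lm^2 / (4 pi (2l + 1))). s_0 equals the spherical mean.
#'
#' @param signals matrix (n_vox x n_dir) or vector of shell samples
#' @param dirs n_dir x 3 unit directions of the shell
#' @param lmax maximum even SH order for the fit (needs (lmax+1)(lmax+2)/2
#'   <= n_dir); higher orders are fitted to absorb leakage even when only
#'   s_0, s_2 are used downstream
#' @return matrix n_vox x length(ls) with columns l = 0, 2, ..., lmax
#' @export
shell_invariants <- function(signals, dirs, lmax = 4) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  n_coef_needed <- (lmax + 1) * (lmax + 2) / 2
  while (lmax > 0 && n_coef_needed > ncol(signals)) {
    lmax <- lmax - 2
    n_coef_needed <- (lmax + 1) * (lmax + 2) / 2
  }
  B <- real_sh_basis(dirs, lmax)
  lcol <- attr(B, "l")
  coef <- t(qr.solve(B, t(signals)))        # n_vox x n_coef
  ls <- seq(0, lmax, by = 2)
  out <- sapply(ls, function(l) {
    idx <- which(lcol == l)
    sqrt(rowSums(coef[, idx, drop = FALSE]^2) / (4 * pi * (2 * l + 1)))
  })
  out <- matrix(out, nrow = nrow(signals))
  colnames(out) <- paste0("l", ls)
  out
}

# Ktilde_l(b, beta) = int_0^1 K(b, t) P_l(t) dt for one axially symmetric
# exponential compartment exp(-p - q t^2); vectorized over (p, q).
kernel_proj_l <- function(p, q, l) {
  gl <- .slabkq_cache[["gl64"]]
  if (is.null(gl)) {
    gl <- gauss_legendre(64)
    gl$t <- (gl$nodes + 1) / 2
    gl$w <- gl$weights / 2
    .slabkq_cache[["gl64"]] <- gl
  }
  t2 <- gl$t^2
  Pl <- switch(as.character(l),
               "0" = rep(1, 64),
               "2" = (3 * t2 - 1) / 2,
               "4" = (35 * t2^2 - 30 * t2 + 3) / 8,
               stop("unsupported order"))
  ew <- exp(-outer(q, t2))            # n x 64
  exp(-p) * as.vector(ew %*% (gl$w * Pl))
}
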