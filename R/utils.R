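# Shared numerics: special functions, quadrature, centered DFTs, RNG scoping.

# Error function via the normal CDF (base R has no erf).
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Gauss-Legendre quadrature nodes and weights on [-1, 1]
#'
#' Golub-Welsch: nodes are the eigenvalues of the symmetric Jacobi matrix,
#' weights follow from the first eigenvector components.
#'
#' @param n number of nodes (>= 1)
#' @return list with `nodes` and `weights` (weights sum to 2)
#' @keywords internal
gauss_legendre <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = 2))
  k <- seq_len(n - 1)
  off <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- off
  J[cbind(k + 1, k)] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1, idx]^2)
}

# cache for DFT matrices and direction sets
.slabkq_cache <- new.env(parent = emptyenv())

#' Centered unitary DFT matrix
#'
#' DC sits at index floor(N/2) (0-based), i.e. the fftshift convention used
#' throughout the package. The matrix is symmetric and unitary, so the
#' adjoint/inverse is its elementwise conjugate.
#'
#' @param n transform length
#' @keywords internal
dft_matrix <- function(n) {
  key <- paste0("F", n)
  got <- .slabkq_cache[[key]]
  if (!is.null(got)) return(got)
  c0 <- floor(n / 2)
  idx <- seq_len(n) - 1 - c0
  F <- exp(-2i * pi * outer(idx, idx) / n) / sqrt(n)
  .slabkq_cache[[key]] <- F
  F
}

# Multiply matrix M (p x d[k]) along dimension k of array `arr`.
apply_mat_dim <- function(arr, M, k) {
  d <- dim(arr)
  nd <- length(d)
  if (k != 1L) {
    perm <- c(k, seq_len(nd)[-k])
    arr <- aperm(arr, perm)
  }
  dp <- dim(arr)
  out <- M %*% matrix(arr, nrow = dp[1])
  dim(out) <- c(nrow(M), dp[-1])
  if (k != 1L) {
    inv <- order(c(k, seq_len(nd)[-k]))
    out <- aperm(out, inv)
  }
  out
}

# Centered unitary FT along dims 2 (y) and 3 (z) of an (x, y, z, ...) array.
ft_yz <- function(arr) {
  d <- dim(arr)
  arr <- apply_mat_dim(arr, dft_matrix(d[2]), 2L)
  apply_mat_dim(arr, dft_matrix(d[3]), 3L)
}

ift_yz <- function(arr) {
  d <- dim(arr)
  arr <- apply_mat_dim(arr, Conj(dft_matrix(d[2])), 2L)
  apply_mat_dim(arr, Conj(dft_matrix(d[3])), 3L)
}

# Centered unitary FT along dim 2 only (navigator: ky undersampling).
ft_y <- function(arr) apply_mat_dim(arr, dft_matrix(dim(arr)[2]), 2L)
ift_y <- function(arr) apply_mat_dim(arr, Conj(dft_matrix(dim(arr)[2])), 2L)

#' Normalized root-mean-square error
#'
#' @param x estimate
#' @param ref reference (normalization)
#' @export
nrmse <- function(x, ref) {
  sqrt(sum(abs(x - ref)^2) / sum(abs(ref)^2))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# complex white noise with per-sample std `sd` (sd/sqrt(2) per component)
crnorm <- function(n, sd = 1) {
  complex(real = stats::rnorm(n, sd = sd / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sd / sqrt(2)))
}
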