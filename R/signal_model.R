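# Three-compartment diffusion signal model with B-tensor encoding shapes:
# intra-axonal stick + extra-axonal axially symmetric tensor + free water,
# convolved with an orientation distribution function (ODF).
#
# b-values are supplied in s/mm^2 and converted internally to ms/um^2 so that
# diffusivities expressed in um^2/ms multiply directly.

#' Tissue compartment parameters
#'
#' @param fa intra-axonal signal fraction in [0, 1]
#' @param Da intra-axonal diffusivity, um^2/ms, in [0, 3.2]
#' @param De_par extra-axonal parallel diffusivity, um^2/ms
#' @param De_perp extra-axonal perpendicular diffusivity (<= De_par)
#' @param fw free-water fraction in [0, 1] with fa + fw <= 1
#' @param Dw free-water diffusivity; fixed default 3.0 um^2/ms (body
#'   temperature)
#' @return object of class `compartment_params`
#' @export
compartment_params <- function(fa, Da, De_par, De_perp, fw = 0, Dw = 3.0) {
  if (fa < 0 || fa > 1 || fw < 0 || fw > 1 || fa + fw > 1 + 1e-12)
    stop("fractions must satisfy fa, fw in [0,1] and fa + fw <= 1")
  if (Da < 0 || Da > 3.2 || De_par < 0 || De_par > 3.2 ||
      De_perp < 0 || De_perp > De_par + 1e-12)
    stop("diffusivities must satisfy 0 <= De_perp <= De_par <= 3.2, 0 <= Da <= 3.2")
  structure(list(fa = fa, Da = Da, De_par = De_par, De_perp = De_perp,
                 fw = fw, Dw = Dw, fe = 1 - fa - fw),
            class = "compartment_params")
}

#' Compartment kernel response
#'
#' Signal fraction of the three-compartment kernel for diffusion weighting b,
#' encoding shape beta and squared cosine cos2 between the encoding axis and
#' the fiber axis:
#' K = fa exp(-b Da s) + fe exp(-b De_perp - b (De_par - De_perp) s)
#'   + fw exp(-b Dw),  with s = beta (cos2 - 1/3) + 1/3.
#' beta = 1 reduces to the linear (single-diffusion-encoding) kernel.
#'
#' @param b b-value(s), s/mm^2
#' @param beta encoding shape(s) in [0, 1]
#' @param cos2 squared cosine(s) in [0, 1]
#' @param params a [compartment_params()] object
#' @return signal fraction(s) in [0, 1]; arguments recycle elementwise
#' @export
kernel_response <- function(b, beta, cos2, params) {
  stopifnot(inherits(params, "compartment_params"))
  if (any(cos2 < -1e-12 | cos2 > 1 + 1e-12)) stop("cos2 must lie in [0, 1]")
  if (any(b < 0)) stop("b must be >= 0")
  bb <- b / 1000  # ms/um^2
  s <- beta * (cos2 - 1 / 3) + 1 / 3
  params$fa * exp(-bb * params$Da * s) +
    params$fe * exp(-bb * params$De_perp -
                    bb * (params$De_par - params$De_perp) * s) +
    params$fw * exp(-bb * params$Dw)
}

#' Spherical quadrature grid
#'
#' Deterministic antipodally symmetric product grid: Gauss-Legendre nodes in
#' cos(theta) times a uniform (even-count) azimuthal grid. Weights sum to 1,
#' i.e. they integrate f over the unit sphere normalized by 4*pi.
#'
#' @param n_nodes approximate total node count (default 1000)
#' @return list with `dirs` (n x 3) and `weights`
#' @export
sphere_grid <- function(n_nodes = 1000) {
  n_t <- max(3L, round(sqrt(n_nodes / 1.6)))
  if (n_t %% 2 == 0) n_t <- n_t + 1L        # odd: symmetric incl. equator
  n_phi <- 2L * max(2L, ceiling(n_nodes / (2 * n_t)))
  gl <- gauss_legendre(n_t)
  t <- gl$nodes
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  st <- sqrt(pmax(0, 1 - t^2))
  dirs <- cbind(as.vector(outer(st, cos(phi))),
                as.vector(outer(st, sin(phi))),
                rep(t, n_phi))
  weights <- rep(gl$weights / (2 * n_phi), n_phi)
  list(dirs = dirs, weights = weights)
}

#' Watson orientation distribution
#'
#' Weights proportional to exp(kappa (mu . n)^2) on a spherical quadrature
#' grid, normalized to sum to 1. kappa = 0 gives the isotropic ODF.
#'
#' @param mu unit mean direction
#' @param kappa concentration >= 0
#' @param grid a [sphere_grid()] (default 1000 nodes)
#' @return object of class `odf_model` with `dirs`, `weights`, `kind`
#' @export
watson_odf <- function(mu, kappa, grid = sphere_grid(1000)) {
  if (kappa < 0) stop("kappa must be >= 0 (bipolar Watson not supported)")
  mu <- mu / sqrt(sum(mu^2))
  c2 <- as.vector(grid$dirs %*% mu)^2
  w <- grid$weights * exp(kappa * (c2 - max(c2)))  # stable for large kappa
  structure(list(kind = "watson", mu = mu, kappa = kappa,
                 dirs = grid$dirs, weights = w / sum(w)),
            class = "odf_model")
}

#' @rdname watson_odf
#' @export
isotropic_odf <- function(grid = sphere_grid(1000)) {
  structure(list(kind = "discrete", mu = c(0, 0, 1), kappa = 0,
                 dirs = grid$dirs, weights = grid$weights / sum(grid$weights)),
            class = "odf_model")
}

#' Discrete ODF from explicit nodes and weights
#' @param dirs n x 3 unit vectors
#' @param weights nonnegative, normalized internally
#' @rdname watson_odf
#' @export
discrete_odf <- function(dirs, weights) {
  if (any(weights < 0)) stop("ODF weights must be nonnegative")
  s <- sum(weights)
  if (abs(s) < 1e-12) stop("ODF weights sum to zero")
  structure(list(kind = "discrete", mu = c(0, 0, 1), kappa = NA_real_,
                 dirs = dirs, weights = weights / s),
            class = "odf_model")
}

# ODF Legendre moments: p_l = E[P_l(mu . n)] (p2 in [0,1] for Watson)
odf_p2 <- function(odf) {
  c2 <- as.vector(odf$dirs %*% odf$mu)^2
  sum(odf$weights * (3 * c2 - 1) / 2)
}

#' Synthesize per-volume diffusion signals
#'
#' S(q) = S0 * sum_n w(n) K(b_q, beta_q, (g_q . n)^2), the quadrature form of
#' the ODF-convolved compartment kernel. A b = 0 volume returns exactly S0.
#'
#' @param protocol a [build_protocol()] object (or data frame with columns
#'   b, gx, gy, gz, beta)
#' @param params a [compartment_params()]
#' @param odf an `odf_model`
#' @param S0 non-diffusion-weighted signal
#' @return numeric vector, one signal per protocol volume
#' @export
synthesize_signal <- function(protocol, params, odf, S0 = 1) {
  s <- if (inherits(protocol, "slabkq_protocol")) protocol$samples else protocol
  if (abs(sum(odf$weights) - 1) > 1e-6) stop("ODF weights must sum to 1")
  G <- as.matrix(s[, c("gx", "gy", "gz")])
  C2 <- (G %*% t(odf$dirs))^2           # n_vol x n_nodes
  bb <- s$b / 1000
  sh <- sweep(C2 - 1 / 3, 1, s$beta, "*") + 1 / 3
  K <- params$fa * exp(-bb * params$Da * sh) +
    params$fe * exp(-bb * params$De_perp -
                    bb * (params$De_par - params$De_perp) * sh) +
    params$fw * exp(-bb * params$Dw)
  S0 * as.vector(K %*% odf$weights)
}

# mean over the sphere of exp(-a t^2), t = cos(theta):
# sqrt(pi / (4 a)) erf(sqrt(a)) for a > 0, with a series near 0 and a
# quadrature fallback for a < 0 (only reachable from unconstrained fits).
mean_exp_t2 <- function(a) {
  out <- numeric(length(a))
  small <- abs(a) < 1e-6
  out[small] <- 1 - a[small] / 3 + a[small]^2 / 10
  pos <- !small & a > 0
  out[pos] <- sqrt(pi / (4 * a[pos])) * erf(sqrt(a[pos]))
  neg <- !small & a < 0
  if (any(neg)) {
    gl <- gauss_legendre(48)
    t2 <- ((gl$nodes + 1) / 2)^2
    out[neg] <- vapply(a[neg], function(ai)
      sum(gl$weights / 2 * exp(-ai * t2)), numeric(1))
  }
  out
}

#' Closed-form powder average of the compartment kernel
#'
#' Orientation average over the sphere, per compartment:
#' an axially symmetric term with exponent -b D_perp' - b Delta
#' (beta (t^2 - 1/3) + 1/3) averages to
#' exp(-b D_perp' - b Delta (1 - beta)/3) sqrt(pi/(4x)) erf(sqrt(x)) with
#' x = b Delta beta; beta = 0 collapses to the orientation-free
#' exp(-b (D_perp' + Delta/3)).
#'
#' @inheritParams kernel_response
#' @return powder-averaged signal fraction(s); b and beta recycle
#' @export
powder_average <- function(b, beta, params) {
  stopifnot(inherits(params, "compartment_params"))
  bb <- b / 1000
  n <- max(length(bb), length(beta))
  bb <- rep_len(bb, n); beta <- rep_len(beta, n)
  intra <- exp(-bb * params$Da * (1 - beta) / 3) *
    mean_exp_t2(bb * params$Da * beta)
  delta <- params$De_par - params$De_perp
  extra <- exp(-bb * params$De_perp - bb * delta * (1 - beta) / 3) *
    mean_exp_t2(bb * delta * beta)
  params$fa * intra + params$fe * extra + params$fw * exp(-bb * params$Dw)
}
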