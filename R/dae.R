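# Compact fully connected denoising autoencoder used as the plug-and-play
# q-space prior: three hidden representations (encoder-hidden, bottleneck,
# decoder-hidden), tanh activations, linear output, trained with Adam on a
# weighted MSE that up-weights the highest-b shell.

#' Per-volume loss weights emphasizing the maximal-b shell
#'
#' Volumes on the maximal-b shell receive `high_b_weight`, all others 1.
#'
#' @param protocol a [build_protocol()] object
#' @param high_b_weight weight for the highest shell (literature default
#'   1.5)
#' @return positive numeric vector, one weight per volume
#' @export
shell_weight_vector <- function(protocol, high_b_weight = 1.5) {
  b <- protocol$samples$b
  w <- rep(1, length(b))
  w[b == max(b)] <- high_b_weight
  w
}

#' Simulated training set on the compartment-model signal manifold
#'
#' Parameters are drawn uniformly from `param_ranges`, ODFs are Watson with
#' random mean direction and concentration, clean signals come from
#' [synthesize_signal()] (b0-normalized by construction, S0 = 1), and noisy
#' signals add i.i.d. Gaussian perturbations at an SNR drawn uniformly from
#' `snr_range`.
#'
#' @param protocol a [build_protocol()] object
#' @param param_ranges named list of c(min, max) for fa, Da, De_par, De_perp,
#'   fw, kappa; defaults span healthy-brain values
#' @param n_train number of samples
#' @param snr_range c(min, max) SNR; c(Inf, Inf) gives noiseless pairs
#' @param seed RNG seed
#' @param grid spherical quadrature grid
#' @return list with `clean`, `noisy` (n_train x n_q), `params`, `protocol`
#'   metadata
#' @export
make_training_set <- function(protocol,
                              param_ranges = list(
                                fa = c(0.05, 0.85), Da = c(1.2, 3.0),
                                De_par = c(0.8, 2.8), De_perp = c(0.2, 1.5),
                                fw = c(0, 0.6), kappa = c(0, 32)),
                              n_train = 10000, snr_range = c(10, 50),
                              seed = 1, grid = sphere_grid(600)) {
  for (r in param_ranges)
    if (length(r) != 2 || r[2] < r[1]) stop("invalid parameter range")
  nq <- nrow(protocol$samples)
  with_seed(seed, {
    ru <- function(nm) stats::runif(n_train, param_ranges[[nm]][1],
                                    param_ranges[[nm]][2])
    fa <- ru("fa"); Da <- ru("Da"); De_par <- ru("De_par")
    De_perp <- pmin(ru("De_perp"), De_par)
    fw <- pmin(ru("fw"), 1 - fa)
    kappa <- ru("kappa")
    mu <- matrix(stats::rnorm(3 * n_train), n_train, 3)
    mu <- mu / sqrt(rowSums(mu^2))
    clean <- matrix(0, n_train, nq)
    for (i in seq_len(n_train)) {
      p <- compartment_params(fa[i], Da[i], De_par[i], De_perp[i], fw[i])
      clean[i, ] <- synthesize_signal(protocol, p,
                                      watson_odf(mu[i, ], kappa[i], grid))
    }
    noisy <- if (all(is.infinite(snr_range))) clean else {
      snr <- stats::runif(n_train, snr_range[1], snr_range[2])
      clean + matrix(stats::rnorm(n_train * nq), n_train, nq) /
        ifelse(is.finite(snr), snr, Inf)
    }
    list(clean = clean, noisy = noisy,
         params = data.frame(fa = fa, Da = Da, De_par = De_par,
                             De_perp = De_perp, fw = fw, kappa = kappa),
         n_q = nq, seed = seed)
  })
}

# weighted MSE: mean over samples of sum_q w_q e_q^2 / sum_q w_q
weighted_mse <- function(pred, target, w) {
  sw <- sum(w)
  mean((((pred - target)^2) %*% w) / sw)
}

dae_forward <- function(model, X) {
  H1 <- tanh(sweep(X %*% model$W1, 2, model$b1, "+"))
  H2 <- tanh(sweep(H1 %*% model$W2, 2, model$b2, "+"))
  H3 <- tanh(sweep(H2 %*% model$W3, 2, model$b3, "+"))
  list(H1 = H1, H2 = H2, H3 = H3,
       out = sweep(H3 %*% model$W4, 2, model$b4, "+"))
}

#' Train the q-space denoising autoencoder
#'
#' Architecture n_q -> hidden -> bottleneck -> hidden -> n_q (tanh hidden
#' units, linear output), minimizing the shell-weighted MSE
#' sum_i sum_q w_q (Q(noisy_i)_q - clean_i_q)^2 / sum_q w_q with Adam on
#' minibatches. A held-out split tracks validation loss; the best validation
#' parameters are returned. Deterministic for a given seed.
#'
#' @param training_set a [make_training_set()] list
#' @param weights per-volume loss weights (see [shell_weight_vector()])
#' @param epochs training epochs
#' @param lr Adam learning rate
#' @param seed RNG seed (initialization, shuffling)
#' @param hidden,bottleneck layer widths
#' @param batch_size minibatch size
#' @param val_frac held-out fraction
#' @param shells optional integer shell id per volume for per-shell
#'   validation losses
#' @return object of class `dae_model`
#' @export
train_dae <- function(training_set, weights = NULL, epochs = 150, lr = 1e-3,
                      seed = 1, hidden = 64, bottleneck = 32,
                      batch_size = 64, val_frac = 0.1, shells = NULL) {
  Xc <- training_set$clean
  Xn <- training_set$noisy
  n <- nrow(Xc); nq <- ncol(Xc)
  if (n < 2) stop("training set is empty or too small")
  if (is.null(weights)) weights <- rep(1, nq)
  if (length(weights) != nq || any(weights <= 0))
    stop("weights must be positive, one per volume")
  with_seed(seed, {
    idx <- sample.int(n)
    n_val <- max(1L, round(val_frac * n))
    val <- idx[seq_len(n_val)]
    trn <- idx[-seq_len(n_val)]
    init <- function(p, q) matrix(stats::rnorm(p * q, sd = sqrt(2 / (p + q))),
                                  p, q)
    model <- list(W1 = init(nq, hidden), b1 = numeric(hidden),
                  W2 = init(hidden, bottleneck), b2 = numeric(bottleneck),
                  W3 = init(bottleneck, hidden), b3 = numeric(hidden),
                  W4 = init(hidden, nq), b4 = numeric(nq))
    adam <- lapply(model, function(p) list(m = p * 0, v = p * 0))
    t_step <- 0
    sw <- sum(weights)
    best <- list(val = Inf, model = model)
    for (ep in seq_len(epochs)) {
      ord <- sample(trn)
      for (start in seq(1, length(ord), by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1, length(ord))]
        X <- Xn[bi, , drop = FALSE]; Tg <- Xc[bi, , drop = FALSE]
        f <- dae_forward(model, X)
        nb <- length(bi)
        dOut <- 2 * (f$out - Tg) *
          matrix(weights / sw, nb, nq, byrow = TRUE) / nb
        if (any(!is.finite(dOut))) stop("DAE training diverged (NaN loss)")
        gW4 <- crossprod(f$H3, dOut); gb4 <- colSums(dOut)
        dH3 <- (dOut %*% t(model$W4)) * (1 - f$H3^2)
        gW3 <- crossprod(f$H2, dH3); gb3 <- colSums(dH3)
        dH2 <- (dH3 %*% t(model$W3)) * (1 - f$H2^2)
        gW2 <- crossprod(f$H1, dH2); gb2 <- colSums(dH2)
        dH1 <- (dH2 %*% t(model$W2)) * (1 - f$H1^2)
        gW1 <- crossprod(X, dH1); gb1 <- colSums(dH1)
        grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                      W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
        t_step <- t_step + 1
        for (nm in names(model)) {
          adam[[nm]]$m <- 0.9 * adam[[nm]]$m + 0.1 * grads[[nm]]
          adam[[nm]]$v <- 0.999 * adam[[nm]]$v + 0.001 * grads[[nm]]^2
          mhat <- adam[[nm]]$m / (1 - 0.9^t_step)
          vhat <- adam[[nm]]$v / (1 - 0.999^t_step)
          model[[nm]] <- model[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
      }
      pv <- dae_forward(model, Xn[val, , drop = FALSE])$out
      vloss <- weighted_mse(pv, Xc[val, , drop = FALSE], weights)
      if (vloss < best$val) best <- list(val = vloss, model = model)
    }
    model <- best$model
    pv <- dae_forward(model, Xn[val, , drop = FALSE])$out
    err2 <- (pv - Xc[val, , drop = FALSE])^2
    shell_losses <- if (!is.null(shells)) {
      vapply(sort(unique(shells)), function(s)
        mean(err2[, shells == s, drop = FALSE]), numeric(1))
    } else NULL
    structure(c(model, list(
      n_q = nq, shell_weights = weights, activation = "tanh",
      layer_sizes = c(nq, hidden, bottleneck, hidden, nq),
      val_loss = best$val, shell_val_losses = shell_losses,
      val_idx = val,
      training_meta = list(seed = seed, epochs = epochs, lr = lr,
                           batch_size = batch_size))),
      class = "dae_model")
  })
}

#' Apply the trained denoiser to q-space signal vectors
#'
#' Signals are b0-normalized (divided by `s0`), passed through the network
#' per voxel and rescaled by the same factor, so the normalization convention
#' is never changed by the denoiser.
#'
#' @param model a [train_dae()] model
#' @param signals matrix (n_vox x n_q) or vector of length n_q
#' @param s0 optional per-voxel b0 reference used for normalization
#' @return denoised signals, same shape as the input
#' @export
denoise <- function(model, signals, s0 = NULL) {
  vec <- is.vector(signals)
  if (vec) signals <- matrix(signals, nrow = 1)
  if (ncol(signals) != model$n_q)
    stop(sprintf("signal width %d does not match model width %d",
                 ncol(signals), model$n_q))
  scale <- if (is.null(s0)) rep(1, nrow(signals)) else {
    if (length(s0) == 1) rep(s0, nrow(signals)) else s0
  }
  scale <- pmax(scale, 1e-12)
  out <- dae_forward(model, signals / scale)$out * scale
  if (vec) out <- as.vector(out)
  out
}

#' Serialize / load a DAE model as portable text (JSON)
#'
#' @param model a `dae_model`
#' @param path output file
#' @export
write_dae <- function(model, path) {
  obj <- lapply(unclass(model), function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.vector(x)) else x
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dae
#' @export
read_dae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("W1", "W2", "W3", "W4"))
    obj[[nm]] <- matrix(obj[[nm]]$data, obj[[nm]]$dim[1], obj[[nm]]$dim[2])
  structure(obj, class = "dae_model")
}
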