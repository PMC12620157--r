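# Shared fixtures, built lazily and cached for the session.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# the reference 3-shell, 66-direction acquisition (full geometry, Ny = 210)
full_protocol <- function() fixture("full_protocol", function()
  build_protocol(c(1000, 2000, 6000), 22, seed = 1))

# small slab protocol on the 32x32x6 grid used by operator/recon tests
small_protocol <- function(n_dirs = 2) fixture(
  paste0("small_protocol_", n_dirs), function() {
    p <- build_protocol(c(1000, 2000, 6000), n_dirs, Ny = 32, seed = 1)
    p$FOVz <- 6; p$n_kz <- 6L
    p
  })

small_phantom <- function() fixture("small_phantom", function()
  build_phantom(c(32, 32, 6), n_coils = 8, seed = 3))

small_masks <- function(n_dirs = 2) fixture(
  paste0("small_masks_", n_dirs), function()
    generate_caipi_masks(small_protocol(n_dirs), sampling_config(3, "6/2", seed = 2)))

small_phases <- function(n_dirs = 2) fixture(
  paste0("small_phases_", n_dirs), function()
    simulate_shot_phases(small_protocol(n_dirs), small_masks(n_dirs),
                         c(32, 32, 6), severity = 0.5, seed = 4))

# a trained DAE on the full 66-volume protocol (shared across tests)
trained_dae <- function() fixture("trained_dae", function() {
  ts <- make_training_set(full_protocol(), n_train = 3000, seed = 11)
  train_dae(ts, shell_weight_vector(full_protocol(), 1.5), epochs = 120,
            seed = 21, shells = full_protocol()$samples$shell_id)
})

# circular RMSE between phase maps over a mask, offset-invariant
phase_rmse <- function(est, truth, mask) {
  d <- Arg(exp(1i * (est - truth)))
  off <- Arg(mean(exp(1i * d[mask])))
  d <- Arg(exp(1i * (d - off)))
  sqrt(mean(d[mask]^2))
}

random_complex_array <- function(dims, seed = 1) {
  n <- prod(dims)
  slabkq:::with_seed(seed, array(complex(real = stats::rnorm(n),
                                         imaginary = stats::rnorm(n)), dims))
}
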