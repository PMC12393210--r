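# Shared small fixtures, built once per test run.

# 16^3 grid over the standard 400 mm FOV (25 mm voxels)
tg16 <- function() empty_grid(16, 400)

# deterministic complex test volume
random_volume <- function(grid, seed = 7) {
  withr::local_seed(seed)
  n <- prod(grid$shape)
  naquant:::with_values(grid, array(
    complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)),
    dim = grid$shape))
}

# small DA-3DPR trajectory for oracle-scale problems
small_traj <- function(n_proj = 50, n_samp = 16, res = 25)
  da3dpr_trajectory(n_proj, n_samp, kmax = 1 / (2 * res),
                    readout_duration = 5)

# coil fields with all-ones receive channels (keeps the forward model
# but removes receive shading), used to isolate other effects
flat_rx <- function(fields) {
  fields$rx_sens <- lapply(fields$rx_sens, function(g)
    naquant:::with_values(g, array(1 + 0i, dim(g$values))))
  fields
}

# memoized full-protocol trajectory (10000 x 256) for PSF tests
.cache <- new.env(parent = emptyenv())
table2_traj <- function() {
  if (is.null(.cache$traj))
    .cache$traj <- da3dpr_trajectory(10000, 256, kmax = 1 / (2 * 5),
                                     readout_duration = 5, n_center = 2)
  .cache$traj
}
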