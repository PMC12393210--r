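test_that("apodization windows evaluate to their defining values", {
  expect_equal(hamming_window(0, 0.1), 1.00)
  expect_equal(hamming_window(0.1, 0.1), 0.08)
  expect_equal(hamming_window(0.05, 0.1), 0.54)
  expect_error(hamming_window(0.11, 0.1), "k must lie")
  expect_equal(gauss_window(0, 20), 1)
  expect_equal(gauss_window(0.3, 0), rep(1, 1))   # sigma -> 0: identity
  # k-space multiplier equals the analytic Gaussian transform
  expect_equal(gauss_window(0.02, 20), exp(-2 * pi^2 * 400 * 4e-4))
})

test_that("gauss filtering produces the stated image-space blur", {
  # impulse at the center, reconstructed with the gaussian window:
  # the blob's sample SD must equal sigma_image within 2%. kmax is chosen
  # so the window has decayed to ~0 at the edge of the sampled ball
  # (otherwise the sharp cutoff adds the trajectory's own PSF width), and
  # the protocol's dense radial sampling (256) is kept: a window this
  # concentrated at low k needs fine low-k quadrature.
  traj <- da3dpr_trajectory(1000, 256, kmax = 1 / (2 * 12.5),
                            readout_duration = 5)
  ks <- structure(list(
    samples = array(1 + 0i, c(traj$n_samples_total, 1000, 1)),
    traj = traj,
    params = acq_params(n_projections = 1000, n_samples = 256,
                        nominal_resolution = 12.5, fov = 400)),
    class = "kspace_data")
  rec <- adjoint_recon(ks, recon_settings("gauss", gauss_sigma = 40,
                                          zerofill = 2))
  img <- Mod(rec$channels[[1]]$values)
  n <- rec$channels[[1]]$shape[1]
  x <- grid_axis(rec$channels[[1]], 1)
  prof <- img[, n / 2 + 1, n / 2 + 1]
  sd_est <- sqrt(sum(prof * x^2) / sum(prof))
  expect_equal(sd_est, 40, tolerance = 0.02)
})

test_that("adjoint reconstruction matches the conjugate-phase oracle", {
  g <- tg16()
  traj <- small_traj(50, 16)
  kco <- trajectory_coords(traj)
  withr::local_seed(21)
  m <- nrow(kco)
  samp <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  ks <- structure(list(
    samples = array(samp, c(traj$n_samples_total, 50, 1)),
    traj = traj,
    params = acq_params(n_projections = 50, n_samples = 16,
                        nominal_resolution = 25, fov = 400)),
    class = "kspace_data")
  rec <- adjoint_recon(ks, recon_settings("none", zerofill = 1))
  w <- rep(traj$dcf, 50) / sum(rep(traj$dcf, 50))
  r <- grid_coords(g)
  ref <- array(as.vector(exp(2i * pi * (r %*% t(kco))) %*% (samp * w)),
               dim = g$shape)
  expect_lt(sqrt(sum(Mod(rec$channels[[1]]$values - ref)^2) /
                   sum(Mod(ref)^2)), 1e-5)
})

test_that("all-zero data give an all-zero image; dims are validated", {
  traj <- small_traj(10, 8)
  ks <- structure(list(
    samples = array(0i, c(traj$n_samples_total, 10, 2)),
    traj = traj,
    params = acq_params(n_projections = 10, n_samples = 8,
                        nominal_resolution = 25, fov = 400)),
    class = "kspace_data")
  rec <- adjoint_recon(ks, recon_settings("none"))
  expect_equal(max(Mod(rec$image$values)), 0)
  ks$samples <- ks$samples[, 1:5, , drop = FALSE]
  expect_error(adjoint_recon(ks), "match the trajectory")
})

test_that("uniform unit k-space data reconstruct to unit central value", {
  traj <- da3dpr_trajectory(2000, 64, kmax = 1 / (2 * 25),
                            readout_duration = 5, n_center = 2)
  ks <- structure(list(
    samples = array(1 + 0i, c(traj$n_samples_total, 2000, 1)),
    traj = traj,
    params = acq_params(n_projections = 2000, n_samples = 64,
                        nominal_resolution = 25, fov = 400)),
    class = "kspace_data")
  rec <- adjoint_recon(ks, recon_settings("none", zerofill = 2))
  n <- rec$channels[[1]]$shape[1]
  center <- Mod(rec$channels[[1]]$values[n / 2 + 1, n / 2 + 1, n / 2 + 1])
  expect_equal(center, 1, tolerance = 0.02)
})

test_that("point source round trip peaks at the source voxel", {
  g <- empty_grid(32, 400)
  co <- grid_coords(g)
  i <- which(co[, 1] == 50 & co[, 2] == -37.5 & co[, 3] == 12.5)
  conc <- array(0, g$shape); conc[i] <- 100
  t1 <- array(NA_real_, g$shape); t1[i] <- 55
  t2 <- array(NA_real_, g$shape); t2[i] <- 1e9
  maps <- structure(list(concentration = naquant:::with_values(g, conc),
                         t1 = naquant:::with_values(g, t1),
                         t2star = naquant:::with_values(g, t2)),
                    class = "tissue_maps")
  fields <- flat_rx(generate_coil_fields(g, 0, seed = 1))
  p <- acq_params(n_projections = 1500, n_samples = 32,
                  nominal_resolution = 25, fov = 400)
  traj <- trajectory_for(p)
  ks <- simulate_kspace(maps, fields, traj, p)
  # zerofill 2 puts the 16^3-nominal reconstruction on the 32^3 simulation
  # grid, so the peak index is directly comparable
  rec <- adjoint_recon(ks, recon_settings("none", zerofill = 2))
  img <- Mod(rec$channels[[1]]$values)
  expect_equal(which.max(img), i)
})

test_that("SOS combination follows the Pythagorean contract", {
  g <- tg16()
  mk <- function(v) naquant:::with_values(g, array(v, g$shape))
  expect_equal(sos_combine(list(mk(-3 + 4i)))$values,
               array(5, g$shape))
  expect_equal(sos_combine(list(mk(2i), mk(2), mk(-2), mk(2i)))$values,
               array(4, g$shape))
  expect_equal(sos_combine(list(mk(3), mk(4i), mk(0), mk(0)))$values,
               array(5, g$shape))
  # invariance under per-channel global phase
  chans <- list(mk(1 + 2i), mk(3 - 1i))
  rot <- list(mk((1 + 2i) * exp(1i * 0.7)), mk((3 - 1i) * exp(-1i * 1.2)))
  expect_equal(sos_combine(chans)$values, sos_combine(rot)$values)
  expect_error(sos_combine(list(mk(1), naquant:::with_values(
    empty_grid(8, 400), array(1, c(8, 8, 8))))), "same grid")
})

test_that("apodization strictly reduces high-frequency energy", {
  g <- empty_grid(32, 400)
  maps <- generate_phantom(phantom_spec(), g)
  fields <- flat_rx(generate_coil_fields(g, 0, seed = 1))
  p <- acq_params(n_projections = 600, n_samples = 32,
                  nominal_resolution = 25, fov = 400)
  traj <- trajectory_for(p)
  ks <- simulate_kspace(maps, fields, traj, p)
  hi_energy <- function(settings) {
    img <- adjoint_recon(ks, settings)$channels[[1]]$values
    K <- naquant:::shift3(stats::fft(naquant:::shift3(img)))
    n <- dim(K)[1]
    f <- (seq_len(n) - 1 - n / 2)
    r2 <- outer(outer(f^2, f^2, `+`), f^2, `+`)
    sum(Mod(K[r2 > (n / 4)^2])^2)
  }
  e_none <- hi_energy(recon_settings("none", zerofill = 1))
  e_ham <- hi_energy(recon_settings("hamming", zerofill = 1))
  expect_lt(e_ham, e_none)
})
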