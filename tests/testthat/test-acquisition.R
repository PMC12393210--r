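test_that("FLASH signal has the right limits and protocol value", {
  # full relaxation: S -> rho * sin(alpha)
  expect_equal(flash_signal(10, 55, 1e6, 61), 10 * sin(61 * pi / 180))
  # 90 degrees: S = rho * (1 - E1)
  expect_equal(flash_signal(10, 50, 100, 90), 10 * (1 - exp(-2)))
  # protocol saturation factor: S / (rho sin a) = 0.965 at T1 55 / TR 150
  expect_equal(flash_signal(35, 55, 150, 61) / (35 * sin(61 * pi / 180)),
               0.965, tolerance = 5e-4)
  expect_error(flash_signal(1, -5, 150, 61), "t1")
})

test_that("RF calibration arithmetic reproduces the protocol numbers", {
  expect_equal(pulse_voltage(1267, 61, 1.8), 239, tolerance = 0.5 / 239)
  expect_equal(pulse_voltage(1000, 180, 1), 1000)   # definition of Uref
  expect_equal(pulse_voltage(1304, 61, 1.8), 245.6, tolerance = 1e-3)
  expect_error(pulse_voltage(1267, 61, 0), "tau")
  expect_equal(round(pulse_power(239), 2), 1.14)   # printed precision
  expect_equal(pulse_power(0), 0)
  expect_equal(round(pulse_power(245.6), 2), 1.21)
  expect_error(pulse_power(-1), "voltage")
  expect_error(pulse_power(239, 0), "impedance")
})

test_that("acquisition timing matches the protocol table", {
  expect_equal(acquisition_time(acq_params()), 1500)          # 25:00
  pair <- b1_map_params()
  expect_equal(acquisition_time(pair), 1020 * 0.274)          # ~4:39
  expect_equal(acquisition_time(acq_params(n_projections = 0)), 0)
})

test_that("simulated k-space matches a direct forward model", {
  g <- tg16()
  spec <- phantom_spec()
  maps <- generate_phantom(spec, g)
  fields <- generate_coil_fields(g, 0.3, seed = 5)
  traj <- small_traj(30, 12)
  p <- acq_params(n_projections = 30, n_samples = 12,
                  nominal_resolution = 25, fov = 400)
  ks <- simulate_kspace(maps, fields, traj, p)
  expect_equal(dim(ks$samples), c(traj$n_samples_total, 30, 4))

  # direct oracle for channel 2
  amp <- fields$rx_sens[[2]]$values *
    flash_signal(ifelse(is.na(maps$t1$values), 0, maps$concentration$values),
                 ifelse(is.na(maps$t1$values), 1, maps$t1$values),
                 p$tr, p$nominal_fa * fields$tx_scale$values)
  t2 <- maps$t2star$values
  kco <- trajectory_coords(traj)
  ref <- 0
  for (gvl in unique(t2[!is.na(t2) & amp != 0])) {
    a <- amp; a[is.na(t2) | t2 != gvl] <- 0
    s <- exp(-2i * pi * (kco %*% t(grid_coords(g)))) %*% as.complex(a)
    ref <- ref + as.vector(s) *
      rep(exp(-(p$te + traj$times) / gvl), times = 30)
  }
  expect_lt(sqrt(sum(Mod(as.vector(ks$samples[, , 2]) - ref)^2) /
                   sum(Mod(ref)^2)), 1e-5)
})

test_that("forward model is linear and zero for empty objects", {
  g <- tg16()
  spec <- phantom_spec()
  maps <- generate_phantom(spec, g)
  fields <- generate_coil_fields(g, 0.2, seed = 2)
  traj <- small_traj(10, 8)
  p <- acq_params(n_projections = 10, n_samples = 8,
                  nominal_resolution = 25, fov = 400)

  empty <- generate_phantom(
    phantom_spec(body_concentration = 0, bed_concentration = 0,
                 vial_concentrations = c(0, 0, 0, 0)), g)
  expect_equal(max(Mod(simulate_kspace(empty, fields, traj, p)$samples)), 0)

  doubled <- maps
  doubled$concentration$values <- 2 * maps$concentration$values
  s1 <- simulate_kspace(maps, fields, traj, p)$samples
  s2 <- simulate_kspace(doubled, fields, traj, p)$samples
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
})

test_that("a point source gives constant magnitude and linear phase", {
  g <- tg16()
  co <- grid_coords(g)
  i <- which(co[, 1] == 25 & co[, 2] == -50 & co[, 3] == 0)
  conc <- array(0, g$shape); conc[i] <- 40
  t1 <- array(NA_real_, g$shape); t1[i] <- 55
  t2 <- array(NA_real_, g$shape); t2[i] <- 1e9   # no decay
  maps <- structure(list(
    concentration = naquant:::with_values(g, conc),
    t1 = naquant:::with_values(g, t1),
    t2star = naquant:::with_values(g, t2)), class = "tissue_maps")
  fields <- flat_rx(generate_coil_fields(g, 0, seed = 1))
  traj <- small_traj(12, 10)
  p <- acq_params(n_projections = 12, n_samples = 10,
                  nominal_resolution = 25, fov = 400, te = 0)
  s <- simulate_kspace(maps, fields, traj, p)$samples[, , 1]
  a0 <- 40 * flash_signal(1, 55, p$tr, p$nominal_fa)
  expect_equal(Mod(as.vector(s)), rep(a0, length(s)), tolerance = 1e-6)
  kco <- trajectory_coords(traj)
  expected_phase <- -2 * pi * as.vector(kco %*% co[i, ])
  dphi <- Arg(as.vector(s)) - expected_phase
  expect_lt(max(abs(exp(1i * dphi) - 1)), 1e-6)
})

test_that("noise is seeded and reproducible", {
  g <- tg16()
  maps <- generate_phantom(phantom_spec(), g)
  fields <- generate_coil_fields(g, 0.2, seed = 2)
  traj <- small_traj(10, 8)
  p1 <- acq_params(n_projections = 10, n_samples = 8,
                   nominal_resolution = 25, fov = 400,
                   noise_sd = 5, seed = 99)
  s1 <- simulate_kspace(maps, fields, traj, p1)$samples
  s2 <- simulate_kspace(maps, fields, traj, p1)$samples
  expect_identical(s1, s2)
  p2 <- p1; p2$seed <- 100
  expect_false(identical(simulate_kspace(maps, fields, traj, p2)$samples, s1))
})

test_that("dual-flip-angle pair has the expected signal ratio", {
  g <- tg16()
  spec <- phantom_spec()
  maps <- generate_phantom(spec, g)
  # full relaxation: make T1 negligible relative to both TRs
  maps$t1$values[!is.na(maps$t1$values)] <- 0.1
  fields <- flat_rx(generate_coil_fields(g, 0, seed = 1))
  traj <- small_traj(20, 10)
  pair <- b1_map_params(n_projections = 20, n_samples = 10,
                        nominal_resolution = 25, fov = 400)
  both <- simulate_dual_fa(maps, fields, traj, pair)
  # k = 0 samples: ratio sums to sin(90)/sin(45) = sqrt(2)
  r <- Mod(both$fa90$samples[1, 1, 1]) / Mod(both$fa45$samples[1, 1, 1])
  expect_equal(r, sqrt(2), tolerance = 1e-3)

  # tx = 0.8: ratio sin(72)/sin(36) = 2 cos(36)
  f8 <- fields
  f8$tx_scale$values[] <- 0.8
  both8 <- simulate_dual_fa(maps, f8, traj, pair)
  r8 <- Mod(both8$fa90$samples[1, 1, 1]) / Mod(both8$fa45$samples[1, 1, 1])
  expect_equal(r8, 2 * cos(36 * pi / 180), tolerance = 1e-3)
})
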