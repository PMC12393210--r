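mkgrid <- function(v, g = tg16()) naquant:::with_values(g, array(v, g$shape))

test_that("dual-flip-angle mapping inverts the signal ratio", {
  g <- tg16()
  # nominal field: S90/S45 = sqrt(2) -> 45 degrees, rel_b1 = 1
  s45 <- mkgrid(1)
  s90 <- mkgrid(sqrt(2))
  fm <- dual_fa_map(s45, s90)
  expect_equal(fm$alpha$values, array(45, g$shape))
  expect_equal(fm$rel_b1$values, array(1, g$shape))

  # ratio sin(72)/sin(36) -> rel_b1 = 0.8
  fm8 <- dual_fa_map(mkgrid(sin(36 * pi / 180)),
                     mkgrid(sin(72 * pi / 180)))
  expect_equal(fm8$rel_b1$values, array(0.8, g$shape), tolerance = 1e-12)

  # S90 > 2*S45 (arccos domain) and low-signal voxels are flagged, not 0
  s90b <- s90; s90b$values[1, 1, 1] <- 3
  s45b <- s45; s45b$values[2, 1, 1] <- 1e-6
  fmb <- dual_fa_map(s45b, s90b)
  expect_true(is.na(fmb$alpha$values[1, 1, 1]))
  expect_true(is.na(fmb$alpha$values[2, 1, 1]))
  expect_false(fmb$defined$values[1, 1, 1])
  expect_error(dual_fa_map(mkgrid(1), mkgrid(5)), "no voxel")
  expect_error(dual_fa_map(s45, s90, nominal_pair = c(45, 80)), "2\\*alpha")
})

test_that("dual-FA mapping recovers a known 0.8 transmit scale to 1e-3", {
  # end-to-end: simulate, reconstruct, map (noiseless, full relaxation)
  g <- empty_grid(32, 400)
  maps <- generate_phantom(phantom_spec(), g)
  maps$t1$values[!is.na(maps$t1$values)] <- 0.1   # TR >> T1
  fields <- flat_rx(generate_coil_fields(g, 0, seed = 1))
  fields$tx_scale$values[] <- 0.8
  pair <- b1_map_params(n_projections = 600, n_samples = 32,
                        nominal_resolution = 25, fov = 400)
  traj <- trajectory_for(pair$fa45)
  both <- simulate_dual_fa(maps, fields, traj, pair)
  rs <- recon_settings("gauss", gauss_sigma = 25, zerofill = 2)
  img45 <- adjoint_recon(both$fa45, rs)$image
  img90 <- adjoint_recon(both$fa90, rs)$image
  fm <- dual_fa_map(img45, img90)
  # evaluate deep inside the body, away from filter edge effects
  voi <- phantom_voi(g, phantom_spec(), erosion_mm = 50)
  rb <- fm$rel_b1$values[voi$values > 0]
  expect_lt(max(abs(rb - 0.8)), 1e-3)
})

test_that("T1 correction factors match the protocol", {
  expect_equal(round(t1_correction_factor(55, 150, 61), 3), 0.965)
  expect_equal(round(t1_correction_factor(34, 150, 61), 3), 0.994)
  expect_equal(t1_correction_factor(55, 1e9, 61), 1)
  expect_error(t1_correction_factor(-1, 150, 61), "> 0")
})

test_that("apply_corrections composes the correction chain", {
  g <- tg16()
  img <- mkgrid(10)
  # rel_b1 = 1, rx = 1, TR >> T1: corrected = image / sin(nominal)
  fm <- dual_fa_map(mkgrid(1), mkgrid(sqrt(2)))
  rx <- mkgrid(1)
  mask <- naquant:::with_values(g, array(TRUE, g$shape))
  t1 <- mkgrid(1e-9)
  out <- apply_corrections(img, fm, rx, t1, nominal_fa = 61, tr = 150,
                           norm_mask = mask)
  expect_equal(out$values, array(10 / sin(61 * pi / 180), g$shape))

  # linearity in the input image
  out2 <- apply_corrections(mkgrid(30), fm, rx, t1, nominal_fa = 61,
                            tr = 150, norm_mask = mask)
  expect_equal(out2$values, 3 * out$values)

  # receive normalization: scaling rx_sos leaves the output unchanged
  out3 <- apply_corrections(img, fm, mkgrid(7), t1, nominal_fa = 61,
                            tr = 150, norm_mask = mask)
  expect_equal(out3$values, out$values)

  # undefined flip-angle voxels propagate NA
  s45 <- mkgrid(1); s45$values[3, 3, 3] <- 1e-9
  fmb <- dual_fa_map(s45, mkgrid(sqrt(2)))
  outb <- apply_corrections(img, fmb, nominal_fa = 61, tr = 150)
  expect_true(is.na(outb$values[3, 3, 3]))
  expect_error(apply_corrections(img, fm, rx, t1, norm_mask = NULL),
               "norm_mask")
})

test_that("calibration recovers exact linear signal maps", {
  g <- empty_grid(64, 400)
  spec <- phantom_spec()
  masks <- vial_voi_masks(g, spec, erosion_mm = 5)
  kappa <- 0.04   # mM per signal unit
  maps <- generate_phantom(spec, g)
  signal <- naquant:::with_values(g, maps$concentration$values / kappa)
  fit <- calibrate(signal, masks, spec$vial_concentrations)
  expect_equal(fit$slope, kappa, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)

  # permutation invariance
  perm <- c(3, 1, 4, 2)
  fitp <- calibrate(signal, masks[perm], spec$vial_concentrations[perm])
  expect_equal(fitp$slope, fit$slope)
  expect_equal(fitp$intercept, fit$intercept)

  expect_error(calibrate(signal, masks, c(35, 35, 35, 35)), "distinct")
  expect_error(calibrate(signal, masks[1:2], c(20, 30, 40)), "one concentration")

  # applying the fit back to the vial means reproduces the concentrations
  conc <- to_concentration(signal, fit)
  for (v in 1:4)
    expect_equal(mean(conc$values[masks[[v]]$values > 0]),
                 spec$vial_concentrations[v], tolerance = 1e-9)
  # zero signal maps to the intercept
  expect_equal(to_concentration(mkgrid(0, g), fit)$values[1, 1, 1],
               fit$intercept)
})

test_that("calibration fits serialize to JSON sidecars", {
  g <- empty_grid(64, 400)
  spec <- phantom_spec()
  masks <- vial_voi_masks(g, spec, erosion_mm = 5)
  maps <- generate_phantom(spec, g)
  fit <- calibrate(naquant:::with_values(g, maps$concentration$values * 25),
                   masks, spec$vial_concentrations)
  p <- withr::local_tempfile(fileext = ".json")
  write_calibration(fit, p)
  got <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(got$slope, fit$slope, tolerance = 1e-12)
  expect_equal(got$r_squared, fit$r_squared, tolerance = 1e-12)
})
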