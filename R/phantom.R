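#' Digital phantom specification
#'
#' Describes the physical validation setup: a homogeneous NaCl-filled
#' canister ("body"), four oval reference vials of known concentration in a
#' drawer below it, and the agarose bed the vials are embedded in.
#'
#' Geometry (mm, all solids centered on the z axis unless offset):
#' * body: a cuboid 170 wide (x) x 270 long (z) x 160 high (y) flanked in x
#'   by two elliptical cylinders (axis along z, length 270) with horizontal
#'   semi-axis 75 (width 150) and vertical semi-axis 80 (height 160);
#' * vials: each an oval prism -- two cylinders of diameter 38 and length
#'   152 whose axes (along z) are 22 mm apart, joined by a 22 mm-wide
#'   cuboid (a "stadium" cross-section 60 x 38 mm); four vials side by
#'   side along x, symmetric about x = 0;
#' * bed: a cuboid of 35 mM NaCl/agarose surrounding the vials in the
#'   drawer (total drawer structure height 52 mm below the body).
#'
#' The vials' absolute x/y placement inside the drawer is a reproducibility
#' choice of this package (fixed below, identical across sessions); only
#' the fixed, repeatable positioning matters for reusable VOI masks.
#'
#' Relaxation defaults: T1 = 55 ms and T2* = 30 ms for NaCl liquid
#' compartments (body, vials), T1 = 34 ms and T2* = 15 ms for the
#' tissue-like agarose bed.
#'
#' @param body_concentration mM, canister fill (default 35).
#' @param vial_concentrations four mM values (default 20/30/40/50, the
#'   phantom-session set; the in-vivo session uses 20/60/100/140).
#' @param bed_concentration mM of the agarose bed (default 35).
#' @param t1_liquid,t1_bed T1 in ms.
#' @param t2star_liquid,t2star_bed T2* in ms (mono-exponential).
#' @param body_center,vial_y,vial_x,bed geometry overrides (mm).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_concentration = 35,
                         vial_concentrations = c(20, 30, 40, 50),
                         bed_concentration = 35,
                         t1_liquid = 55, t1_bed = 34,
                         t2star_liquid = 30, t2star_bed = 15,
                         body_center = c(0, -8, 0),
                         vial_y = -114,
                         vial_x = c(-105, -35, 35, 105),
                         bed = list(x = 140, y = c(-140, -88), z = 80)) {
  if (length(vial_concentrations) != 4)
    stop("exactly four vial concentrations are required")
  if (any(c(body_concentration, vial_concentrations, bed_concentration) < 0))
    stop("concentrations must be >= 0")
  if (any(c(t1_liquid, t1_bed, t2star_liquid, t2star_bed) <= 0))
    stop("relaxation times must be > 0")
  structure(
    list(body_concentration = body_concentration,
         vial_concentrations = vial_concentrations,
         bed_concentration = bed_concentration,
         t1_liquid = t1_liquid, t1_bed = t1_bed,
         t2star_liquid = t2star_liquid, t2star_bed = t2star_bed,
         body_center = body_center, vial_y = vial_y, vial_x = vial_x,
         bed = bed,
         body_cuboid_halfwidth = 85, body_length = 270,
         body_halfheight = 80, body_ellipse_a = 75,
         vial_cyl_radius = 19, vial_cyl_sep = 22, vial_length = 152),
    class = "phantom_spec")
}

# signed inside-margin (mm, > 0 inside) of the body solid
body_margin <- function(spec, x, y, z) {
  xc <- x - spec$body_center[1]
  yc <- y - spec$body_center[2]
  zc <- z - spec$body_center[3]
  mz <- spec$body_length / 2 - abs(zc)
  # cuboid part
  mcub <- pmin(spec$body_cuboid_halfwidth - abs(xc),
               spec$body_halfheight - abs(yc))
  # elliptical cylinders at x = +-85: 1 - (dx/a)^2 - (y/b)^2 scaled to ~mm
  dx <- abs(xc) - spec$body_cuboid_halfwidth
  e <- 1 - (dx / spec$body_ellipse_a)^2 - (yc / spec$body_halfheight)^2
  mell <- e * min(spec$body_ellipse_a, spec$body_halfheight) / 2
  pmin(pmax(mcub, mell), mz)
}

# signed inside-margin (mm) of vial v; stadium cross-section in (x, y)
vial_margin <- function(spec, v, x, y, z) {
  hx <- spec$vial_cyl_sep / 2
  dx <- pmax(abs(x - spec$vial_x[v]) - hx, 0)
  dy <- y - spec$vial_y
  pmin(spec$vial_cyl_radius - sqrt(dx^2 + dy^2),
       spec$vial_length / 2 - abs(z))
}

bed_margin <- function(spec, x, y, z) {
  pmin(spec$bed$x - abs(x),
       y - spec$bed$y[1], spec$bed$y[2] - y,
       spec$bed$z - abs(z))
}

#' Generate phantom tissue maps on a grid
#'
#' Assigns each voxel (tested at its center, no partial-volume
#' anti-aliasing) the concentration, T1 and T2* of the innermost
#' compartment containing it: vials take precedence over the bed, the bed
#' and body over air. Voxels outside every solid are zero concentration
#' with `NA` relaxation times.
#'
#' @param spec a [phantom_spec].
#' @param grid a [volume_grid] covering the (400 mm)^3 FOV.
#' @return list of class `tissue_maps`: `concentration`, `t1`, `t2star`
#'   ([volume_grid]s) plus `compartment` (integer codes: 0 air, 1 body,
#'   2 bed, 3..6 vials 1-4).
#' @export
generate_phantom <- function(spec, grid) {
  co <- grid_coords(grid)
  x <- co[, 1]; y <- co[, 2]; z <- co[, 3]
  half_fov <- grid$fov / 2
  check_fits <- function(name, xmax, ymax, zmax) {
    if (xmax > half_fov[1] + grid$origin[1] || ymax > half_fov[2] ||
        zmax > half_fov[3])
      stop(sprintf("phantom geometry: solid '%s' exceeds the field of view",
                   name))
  }
  check_fits("body",
             spec$body_cuboid_halfwidth + spec$body_ellipse_a +
               abs(spec$body_center[1]),
             spec$body_halfheight + abs(spec$body_center[2]),
             spec$body_length / 2 + abs(spec$body_center[3]))
  check_fits("bed", spec$bed$x, max(abs(unlist(spec$bed$y))), spec$bed$z)
  check_fits("vials",
             max(abs(spec$vial_x)) + spec$vial_cyl_sep / 2 +
               spec$vial_cyl_radius,
             abs(spec$vial_y) + spec$vial_cyl_radius, spec$vial_length / 2)

  comp <- integer(length(x))
  comp[body_margin(spec, x, y, z) > 0] <- 1L
  comp[bed_margin(spec, x, y, z) > 0] <- 2L
  for (v in 1:4) comp[vial_margin(spec, v, x, y, z) > 0] <- 2L + v

  conc <- numeric(length(x))
  t1 <- rep(NA_real_, length(x))
  t2 <- rep(NA_real_, length(x))
  conc[comp == 1L] <- spec$body_concentration
  t1[comp == 1L] <- spec$t1_liquid; t2[comp == 1L] <- spec$t2star_liquid
  conc[comp == 2L] <- spec$bed_concentration
  t1[comp == 2L] <- spec$t1_bed; t2[comp == 2L] <- spec$t2star_bed
  for (v in 1:4) {
    sel <- comp == 2L + v
    conc[sel] <- spec$vial_concentrations[v]
    t1[sel] <- spec$t1_liquid; t2[sel] <- spec$t2star_liquid
  }
  structure(
    list(concentration = with_values(grid, conc),
         t1 = with_values(grid, t1),
         t2star = with_values(grid, t2),
         compartment = with_values(grid, comp),
         spec = spec),
    class = "tissue_maps")
}

#' Synthetic transmit and receive coil fields
#'
#' Stand-ins for the measured transmit (B1+) and electromagnetically
#' simulated 4-channel receive (B1-) fields of the birdcage coil. The
#' transmit scale is a smooth random second-order polynomial of position,
#' affinely rescaled so that its min/max over the support region are
#' exactly 1 and `1 + tx_variation` (so the peak-to-peak relative
#' variation across the support equals `tx_variation`). The receive
#' channels are smooth complex Lorentzian-like sensitivities peaked near
#' four positions around the bore (azimuths 45/135/225/315 degrees at
#' 230 mm radius) with a mild linear phase. The support region is a fixed
#' box (|x| <= 165, -140 <= y <= 80, |z| <= 140 mm) covering the phantom
#' and drawer; it is returned so that callers evaluate and normalize
#' fields over the same region. Deterministic given `seed`.
#'
#' @param grid a [volume_grid].
#' @param tx_variation peak-to-peak relative transmit variation in [0, 1).
#' @param seed integer seed.
#' @return list of class `coil_fields`: `tx_scale` ([volume_grid], >= 1 on
#'   the support), `rx_sens` (list of 4 complex [volume_grid]s), `support`
#'   (logical [volume_grid]).
#' @export
generate_coil_fields <- function(grid, tx_variation, seed = 1L) {
  if (!(tx_variation >= 0 && tx_variation < 1))
    stop("tx_variation must lie in [0, 1)")
  co <- grid_coords(grid)
  u <- sweep(co, 2, grid$fov / 2, "/")   # normalized coordinates in [-1, 1]
  support <- abs(co[, 1]) <= 165 & co[, 2] >= -140 & co[, 2] <= 80 &
    abs(co[, 3]) <= 140

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  # smooth low-order polynomial: quadratic form with random coefficients
  cf <- stats::rnorm(9, sd = 1)
  f <- cf[1] * u[, 1] + cf[2] * u[, 2] + cf[3] * u[, 3] +
    cf[4] * u[, 1]^2 + cf[5] * u[, 2]^2 + cf[6] * u[, 3]^2 +
    cf[7] * u[, 1] * u[, 2] + cf[8] * u[, 2] * u[, 3] +
    cf[9] * u[, 1] * u[, 3]
  rng <- range(f[support])
  tx <- if (tx_variation == 0 || diff(rng) < 1e-12) {
    rep(1, nrow(co))
  } else {
    # exact [1, 1 + tx_variation] over the support; clamped outside of it
    # (air region, physically irrelevant) to keep the field positive
    pmin(pmax(1 + tx_variation * (f - rng[1]) / diff(rng), 0.05), 3)
  }

  # receive channels: loops around the bore at fixed azimuths
  az <- (c(45, 135, 225, 315) + stats::runif(4, -5, 5)) * pi / 180
  rad <- 230
  width <- 260
  rx <- lapply(1:4, function(c4) {
    p <- c(rad * cos(az[c4]), rad * sin(az[c4]), stats::runif(1, -40, 40))
    d2 <- (co[, 1] - p[1])^2 + (co[, 2] - p[2])^2 + (co[, 3] - p[3])^2
    mag <- 1 / (1 + d2 / width^2)
    phase <- 2 * pi * (co %*% stats::rnorm(3, sd = 2e-4))
    with_values(grid, mag * exp(1i * as.vector(phase)))
  })
  structure(
    list(tx_scale = with_values(grid, tx), rx_sens = rx,
         support = with_values(grid, array(support, grid$shape)),
         tx_variation = tx_variation, seed = as.integer(seed)),
    class = "coil_fields")
}

#' Sum-of-squares combination of the receive sensitivities
#'
#' @param fields a `coil_fields` object.
#' @return a real [volume_grid] of `sqrt(sum_c |B1-_c|^2)`.
#' @export
rx_sos_field <- function(fields) {
  acc <- Reduce(`+`, lapply(fields$rx_sens, function(g) Mod(g$values)^2))
  with_values(fields$rx_sens[[1]], sqrt(acc))
}

#' Reference-vial VOI masks
#'
#' Fixed, reusable volume-of-interest masks in the central part of each
#' reference vial (position-fixed because the vial drawer is always at the
#' same place). Candidate voxels are those whose centers lie inside the
#' vial with at least `erosion_mm` margin to the vial wall (partial-volume
#' guard); of those, the `target_voxels` most central voxels (largest
#' margin, ties broken in array order) are kept, making the mask size
#' deterministic. The default target reproduces the reference protocol's
#' 93.5 mL per-vial mask -- 5984 voxels at the (2.5 mm)^3 reconstructed
#' voxel -- scaled to the voxel volume of `grid`.
#'
#' @param grid the reconstructed-image [volume_grid].
#' @param spec a [phantom_spec].
#' @param erosion_mm minimum margin to the vial wall (default 5).
#' @param target_voxels voxels per mask; default
#'   `round(93500 / voxel_size^3)`.
#' @return list of 4 logical [volume_grid] masks.
#' @export
vial_voi_masks <- function(grid, spec, erosion_mm = 5,
                           target_voxels = round(93.5e3 / grid$voxel_size^3)) {
  co <- grid_coords(grid)
  lapply(1:4, function(v) {
    m <- vial_margin(spec, v, co[, 1], co[, 2], co[, 3])
    cand <- which(m >= erosion_mm)
    if (length(cand) == 0)
      stop(sprintf("vial %d: erosion of %.3g mm leaves an empty mask",
                   v, erosion_mm))
    if (length(cand) < target_voxels)
      stop(sprintf(
        "vial %d: only %d voxels have >= %.3g mm margin (need %d)",
        v, length(cand), erosion_mm, target_voxels))
    keep <- cand[order(-m[cand], cand)[seq_len(target_voxels)]]
    mask <- logical(nrow(co))
    mask[keep] <- TRUE
    with_values(grid, array(mask, grid$shape))
  })
}

#' Whole-phantom VOI mask
#'
#' All voxels inside the canister body with at least `erosion_mm` margin to
#' its wall, excluding the outermost (partially volumed) voxels as in the
#' reference evaluation.
#'
#' @param grid image [volume_grid].
#' @param spec a [phantom_spec].
#' @param erosion_mm margin in mm.
#' @return logical [volume_grid].
#' @export
phantom_voi <- function(grid, spec, erosion_mm) {
  co <- grid_coords(grid)
  m <- body_margin(spec, co[, 1], co[, 2], co[, 3])
  mask <- m >= erosion_mm
  if (!any(mask)) stop("phantom VOI: erosion leaves an empty mask")
  with_values(grid, array(mask, grid$shape))
}

#' Mask volume in milliliters
#'
#' @param n_voxels voxel count (>= 0).
#' @param voxel_size isotropic voxel edge in mm (> 0).
#' @return volume in mL (`n_voxels * voxel_size^3 / 1000`).
#' @export
mask_volume <- function(n_voxels, voxel_size) {
  if (any(n_voxels < 0)) stop("n_voxels must be >= 0")
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0")
  n_voxels * voxel_size^3 / 1000
}
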