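#' Acquisition parameters
#'
#' Parameter block for one sodium acquisition. Defaults are the reference
#' quantitative-image protocol: TE 1 ms, TR 150 ms, nominal flip angle 61
#' degrees, 1.8 ms pulse, 5 ms readout, 10000 projections, 256 radial
#' samples (+2 k-space center points), 5 mm nominal resolution, 400 mm
#' FOV. The B1+ mapping protocol uses TE 1.65 ms, alternating TR 106/168
#' ms with nominal flip angles 45/90 degrees, 1020 projections and 20 mm
#' nominal resolution (see [b1_map_params()]).
#'
#' @param te echo time, ms.
#' @param tr repetition time, ms (scalar; the alternating dual-flip-angle
#'   scheme is represented as two parameter blocks).
#' @param nominal_fa nominal flip angle, degrees, in (0, 180].
#' @param pulse_duration ms.
#' @param readout_duration ms.
#' @param n_projections,n_samples,n_center trajectory dimensions.
#' @param nominal_resolution mm (sets `kmax = 1/(2*resolution)`).
#' @param fov mm.
#' @param noise_sd standard deviation of the complex Gaussian sample noise
#'   (per real/imaginary component, in k-space signal units).
#' @param seed integer noise seed.
#' @param reference_voltage V, voltage of a 1 ms rectangular pulse
#'   inverting the equilibrium magnetization.
#' @param ramp_fraction readout gradient-ramp fraction (see [da_readout()]).
#' @return object of class `acq_params`.
#' @export
acq_params <- function(te = 1, tr = 150, nominal_fa = 61,
                       pulse_duration = 1.8, readout_duration = 5,
                       n_projections = 10000, n_samples = 256,
                       n_center = 2, nominal_resolution = 5, fov = 400,
                       noise_sd = 0, seed = 1L,
                       reference_voltage = 1267,
                       ramp_fraction = 0.1) {
  if (te < 0 || tr <= te) stop("need te >= 0 and tr > te")
  if (!(nominal_fa > 0 && nominal_fa <= 180))
    stop("nominal_fa must lie in (0, 180]")
  structure(as.list(environment()), class = "acq_params")
}

#' B1+ mapping parameter pair
#'
#' The alternating-excitation dual-flip-angle protocol: nominal 45 degrees
#' at TR 106 ms and nominal 90 degrees at TR 168 ms, TE 1.65 ms, 3 ms
#' pulse, 3.33 ms readout, 1020 projections, 20 mm nominal resolution.
#'
#' @param n_projections,n_samples,nominal_resolution,noise_sd,seed,fov
#'   overrides for reduced-scale runs.
#' @return list with elements `fa45` and `fa90` (two [acq_params()]).
#' @export
b1_map_params <- function(n_projections = 1020, n_samples = 256,
                          nominal_resolution = 20, noise_sd = 0,
                          seed = 1L, fov = 400) {
  list(
    fa45 = acq_params(te = 1.65, tr = 106, nominal_fa = 45,
                      pulse_duration = 3, readout_duration = 3.33,
                      n_projections = n_projections, n_samples = n_samples,
                      nominal_resolution = nominal_resolution, fov = fov,
                      noise_sd = noise_sd, seed = seed),
    fa90 = acq_params(te = 1.65, tr = 168, nominal_fa = 90,
                      pulse_duration = 3, readout_duration = 3.33,
                      n_projections = n_projections, n_samples = n_samples,
                      nominal_resolution = nominal_resolution, fov = fov,
                      noise_sd = noise_sd, seed = seed + 1L))
}

#' Trajectory implied by an acquisition parameter block
#' @param params an [acq_params()].
#' @param ... passed on to [da3dpr_trajectory()].
#' @export
trajectory_for <- function(params, ...) {
  da3dpr_trajectory(params$n_projections, params$n_samples,
                    kmax = 1 / (2 * params$nominal_resolution),
                    readout_duration = params$readout_duration,
                    ramp_fraction = params$ramp_fraction,
                    n_center = params$n_center, ...)
}

#' FLASH steady-state signal
#'
#' Spoiled gradient-echo steady-state signal
#' `S = rho * sin(a) * (1 - E1) / (1 - E1 * cos(a))` with
#' `E1 = exp(-TR/T1)`; `rho` is the spin density (concentration) and `a`
#' the local flip angle.
#'
#' @param concentration mM (or any density unit).
#' @param t1 ms (> 0).
#' @param tr ms.
#' @param alpha_local local flip angle, degrees.
#' @export
flash_signal <- function(concentration, t1, tr, alpha_local) {
  if (any(t1 <= 0, na.rm = TRUE)) stop("t1 must be > 0")
  a <- alpha_local * pi / 180
  e1 <- exp(-tr / t1)
  concentration * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Simulate multi-channel radial k-space data
#'
#' Forward model of the FLASH steady state sampled along the DA-3DPR
#' readout: the sample of channel `c`, spoke `p`, readout time `t` is
#' `sum_j rx_c(j) * flash(rho_j, T1_j, TR, fa * tx(j)) *`
#' `exp(-(TE + t)/T2*_j) * exp(-2 pi i k(p,t) . r_j)` plus complex
#' Gaussian noise. The voxel sum is evaluated with the gridding NUFFT; the
#' time-dependent T2* decay is handled exactly by transforming each group
#' of voxels sharing a T2* value separately and applying the per-sample
#' decay afterwards (tissue maps here are compartmental, so the number of
#' distinct T2* values is small; an error is raised above 32 groups).
#'
#' @param maps a `tissue_maps` object (see [generate_phantom()]).
#' @param fields a `coil_fields` object on the same grid.
#' @param traj an `na_trajectory`.
#' @param params an [acq_params()].
#' @return object of class `kspace_data`: `samples` (complex array
#'   `n_samples_total x n_projections x n_channels`), `traj`, `params`.
#' @export
simulate_kspace <- function(maps, fields, traj, params) {
  grid <- maps$concentration
  stopifnot_same_grid(grid, fields$tx_scale, "tissue maps and coil fields")
  kco <- trajectory_coords(traj)
  ns <- traj$n_samples_total
  np <- traj$n_projections
  nch <- length(fields$rx_sens)

  alpha_local <- params$nominal_fa * fields$tx_scale$values
  t1 <- maps$t1$values
  base <- maps$concentration$values
  amp0 <- ifelse(base > 0 & !is.na(t1),
                 flash_signal(ifelse(is.na(t1), 0, base),
                              ifelse(is.na(t1), 1, t1),
                              params$tr, alpha_local),
                 0)

  t2v <- maps$t2star$values
  groups <- sort(unique(t2v[base > 0 & !is.na(t2v)]))
  if (length(groups) > 32)
    stop("more than 32 distinct T2* values; quantize the T2* map first")
  samples <- array(0i, dim = c(ns, np, nch))
  for (ch in seq_len(nch)) {
    acc <- complex(ns * np)
    for (g in groups) {
      sel <- (t2v == g) & !is.na(t2v) & base > 0
      if (!any(sel)) next
      amp <- amp0 * fields$rx_sens[[ch]]$values
      amp[!sel] <- 0
      s <- nufft_forward(with_values(grid, amp), kco)
      dec <- exp(-(params$te + traj$times) / g)   # per radial sample
      acc <- acc + s * rep(dec, times = np)
    }
    samples[, , ch] <- acc
  }
  if (params$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(params$seed))
    nv <- length(samples)
    samples <- samples + params$noise_sd *
      (array(stats::rnorm(nv), dim = dim(samples)) +
         1i * array(stats::rnorm(nv), dim = dim(samples)))
  }
  structure(list(samples = samples, traj = traj, params = params,
                 grid = grid[c("shape", "voxel_size", "fov", "origin")]),
            class = "kspace_data")
}

#' Simulate the alternating dual-flip-angle acquisition pair
#'
#' Runs [simulate_kspace()] twice on the same trajectory with the
#' dual-flip-angle protocol (nominal 45 degrees at its TR and nominal 90
#' degrees at its TR); local flip angles are `45 * tx` and `90 * tx`. Each
#' acquisition is treated as an independent FLASH steady state at its own
#' TR (the alternating TRs of the protocol are chosen such that residual
#' saturation nearly cancels in the ratio).
#'
#' @param maps,fields as in [simulate_kspace()].
#' @param traj trajectory of the B1+ mapping protocol.
#' @param pair a [b1_map_params()] list.
#' @return list with `fa45` and `fa90` `kspace_data` objects.
#' @export
simulate_dual_fa <- function(maps, fields, traj, pair) {
  list(fa45 = simulate_kspace(maps, fields, traj, pair$fa45),
       fa90 = simulate_kspace(maps, fields, traj, pair$fa90))
}

#' Rectangular-pulse voltage for a target flip angle
#'
#' For rectangular pulses the flip angle is proportional to voltage times
#' duration, so the voltage needed for flip angle `alpha` with pulse
#' length `tau` is `u_ref * (alpha / 180) * (1 ms / tau)`, where `u_ref`
#' is the reference voltage (180-degree inversion with a 1 ms pulse).
#'
#' @param u_ref reference voltage, V.
#' @param alpha flip angle, degrees.
#' @param tau pulse duration, ms (> 0).
#' @return pulse voltage in V.
#' @export
pulse_voltage <- function(u_ref, alpha, tau) {
  if (any(tau <= 0)) stop("tau must be > 0")
  u_ref * (alpha / 180) * (1 / tau)
}

#' RF pulse power
#'
#' Power delivered during the pulse, treating the stated voltage as an RMS
#' voltage across the system impedance: `P = U^2 / Z`.
#'
#' @param voltage V (>= 0).
#' @param impedance Ohm (> 0), default 50.
#' @return power in kW.
#' @export
pulse_power <- function(voltage, impedance = 50) {
  if (any(voltage < 0)) stop("voltage must be >= 0")
  if (any(impedance <= 0)) stop("impedance must be > 0")
  voltage^2 / impedance / 1000
}

#' Total acquisition time
#'
#' `n_projections * TR` for a single-TR sequence; for the alternating
#' dual-TR B1+ protocol, `n_projections * (TR_a + TR_b)`.
#'
#' @param params an [acq_params()] or a [b1_map_params()] pair.
#' @return seconds.
#' @export
acquisition_time <- function(params) {
  if (inherits(params, "acq_params"))
    return(params$n_projections * params$tr / 1000)
  if (is.list(params) && all(c("fa45", "fa90") %in% names(params)))
    return(params$fa45$n_projections *
             (params$fa45$tr + params$fa90$tr) / 1000)
  stop("unsupported parameter object")
}
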