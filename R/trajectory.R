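#' Golden-angle directions on the unit sphere
#'
#' Spoke directions for 3D projection imaging following the 3D golden-means
#' scheme: projection `i` has z-component `2*frac(i*m1) - 1` and azimuth
#' `2*pi*frac(i*m2)`, with the 3D golden means `m1 = 0.4656...` and
#' `m2 = 0.6823...` (the two components of the eigenvector-based 3D
#' generalization of the golden ratio). Successive spokes fill the full
#' sphere quasi-uniformly, so any contiguous subset of projections is an
#' approximately uniform sampling.
#'
#' @param n_projections number of spokes (>= 1).
#' @return `n_projections x 3` matrix of unit vectors.
#' @export
golden_angle_directions <- function(n_projections) {
  if (!is.numeric(n_projections) || n_projections < 1)
    stop("n_projections must be >= 1")
  n_projections <- as.integer(n_projections)
  # 3D golden means m1 = 1/psi^2, m2 = 1/psi with psi the real root of
  # x^3 = x^2 + 1 (psi = 1.46557...); the pair (frac(i*m1), frac(i*m2)) is
  # jointly 2D-equidistributed, unlike e.g. 1D golden-ratio pairs
  r <- polyroot(c(-1, 0, -1, 1))
  r <- Re(r[abs(Im(r)) < 1e-9][1])
  m1 <- 1 / r^2            # 0.4655712...
  m2 <- 1 / r              # 0.6823278...
  i <- seq_len(n_projections)
  z <- 2 * ((i * m1) %% 1) - 1
  az <- 2 * pi * ((i * m2) %% 1)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(x = s * cos(az), y = s * sin(az), z = z)
}

#' Density-adapted radial readout curve
#'
#' Radial k-space position versus time for a density-adapted center-out
#' projection readout. During the gradient ramp (`t` in `[0, t0]`,
#' `t0 = ramp_fraction * T`) `k(t)` grows linearly to `k0`; afterwards the
#' readout is slowed so that the sampled spherical shells have constant
#' volume per unit time: `k(t) = (k0^3 + 3 k0^2 g0 (t - t0))^(1/3)` with
#' `g0 = k0 / t0` (slope-continuous at `t0`). `k0` is chosen so that
#' `k(T) = kmax`, which gives the closed form
#' `k0/kmax = (u / (3 - 2u))^(1/3)` with `u = ramp_fraction`.
#' Samples are uniform in time on `[0, T]`.
#'
#' @param n_samples radial samples along the spoke (>= 2).
#' @param kmax maximum k-space radius in cycles/mm (`1 / (2 * resolution)`).
#' @param readout_duration readout length T in ms.
#' @param ramp_fraction fraction `u` of the readout spent on the linear
#'   ramp, in (0, 1). Default 0.1; the PSF width is insensitive to this
#'   choice over `u` in 0.05..0.2 (see the evaluation module).
#' @return list with `radii` (cycles/mm, increasing, last = kmax), `times`
#'   (ms from readout start) and `k0` (cycles/mm).
#' @export
da_readout <- function(n_samples, kmax, readout_duration, ramp_fraction = 0.1) {
  if (!(ramp_fraction > 0 && ramp_fraction < 1))
    stop("ramp_fraction must lie in (0, 1)")
  if (n_samples < 2) stop("n_samples must be >= 2")
  u <- ramp_fraction
  t_total <- readout_duration
  t0 <- u * t_total
  k0 <- kmax * (u / (3 - 2 * u))^(1 / 3)
  g0 <- k0 / t0
  t <- seq(0, t_total, length.out = n_samples)
  k <- ifelse(t <= t0, g0 * t, (k0^3 + 3 * k0^2 * g0 * (t - t0))^(1 / 3))
  k[n_samples] <- kmax   # guard against last-ulp rounding
  list(radii = k, times = t, k0 = k0)
}

#' Density compensation weights for a radial trajectory
#'
#' Per-sample weights proportional to the spherical-shell volume each
#' sample represents: `dcf_j = k_j^2 * dk_j`, with `dk` by central
#' differences along the spoke (one-sided at the ends). The k = 0 sample(s)
#' would get zero weight from this rule, so the center is regularized with
#' half of the first shell's volume, `(1/2) * (dk_0 / 2)^3 / 3` in the
#' `k^2 dk` convention, split evenly across repeated center points. The
#' returned weights are scaled so that, summed over all spokes, they
#' approximate the k-space ball volume `(4/3) * pi * kmax^3`; the adjoint
#' reconstruction divides by the total weight so that uniform unit k-space
#' data reconstructs to a unit central value.
#'
#' In the density-adapted portion of the readout `k^2 dk/dt` is constant by
#' construction, so the weights there are constant up to discretization.
#'
#' @param radii per-sample k radius along one spoke (nondecreasing).
#' @param n_projections number of spokes the weights will be shared by.
#' @return numeric vector of nonnegative weights (per sample of one spoke).
#' @export
density_compensation <- function(radii, n_projections) {
  n <- length(radii)
  if (n < 2) stop("need at least 2 radial samples")
  if (any(diff(radii) < -1e-12)) stop("radii must be nondecreasing")
  dk <- numeric(n)
  dk[1] <- radii[2] - radii[1]
  dk[n] <- radii[n] - radii[n - 1]
  if (n > 2) dk[2:(n - 1)] <- (radii[3:n] - radii[1:(n - 2)]) / 2
  w <- radii^2 * dk
  center <- which(radii == 0)
  if (length(center) > 0) {
    # first positive step after the duplicated center points
    pos <- which(radii > 0)
    dk0 <- if (length(pos) > 0) radii[pos[1]] - 0 else dk[1]
    w[center] <- 0.5 * (dk0 / 2)^3 / 3 / length(center)
  }
  # scale k^2 dk (per steradian-ish) to shell volume shared across spokes
  w * 4 * pi / n_projections
}

#' DA-3DPR sampling trajectory
#'
#' Assembles the full golden-angle density-adapted 3D projection
#' reconstruction (DA-3DPR) trajectory: spoke directions, the shared radial
#' sample positions and timing, and density-compensation weights.
#' `n_center` extra k-space center points (2 in the reference protocol,
#' intended for retrospective respiratory sorting, which is out of scope
#' here) are stored as leading k = 0 samples with the center weight split
#' between them.
#'
#' @param n_projections number of spokes.
#' @param n_samples radial samples along each spoke (excluding the extra
#'   center points).
#' @param kmax maximum k radius, cycles/mm; `kmax = 1/(2*resolution)`.
#' @param readout_duration ms.
#' @param ramp_fraction see [da_readout()].
#' @param n_center additional k-space center samples per spoke (default 2).
#' @return object of class `na_trajectory` with fields `directions`
#'   (n_projections x 3), `radii`, `times`, `dcf` (per-sample, shared by
#'   all spokes), `kmax`, `n_projections`, `n_samples_total`.
#' @export
da3dpr_trajectory <- function(n_projections, n_samples, kmax,
                              readout_duration, ramp_fraction = 0.1,
                              n_center = 2) {
  ro <- da_readout(n_samples, kmax, readout_duration, ramp_fraction)
  radii <- ro$radii
  times <- ro$times
  if (n_center > 1) {
    radii <- c(rep(0, n_center - 1), radii)
    times <- c(rep(0, n_center - 1), times)
  }
  dcf <- density_compensation(radii, n_projections)
  structure(
    list(directions = golden_angle_directions(n_projections),
         radii = radii, times = times, dcf = dcf, kmax = kmax,
         k0 = ro$k0, ramp_fraction = ramp_fraction,
         readout_duration = readout_duration,
         n_projections = as.integer(n_projections),
         n_samples_total = length(radii)),
    class = "na_trajectory")
}

#' @export
print.na_trajectory <- function(x, ...) {
  cat(sprintf(
    "<na_trajectory: %d spokes x %d samples, kmax %.4g /mm (nominal %.3g mm)>\n",
    x$n_projections, x$n_samples_total, x$kmax, 1 / (2 * x$kmax)))
  invisible(x)
}

#' All k-space sample coordinates of a trajectory
#'
#' @param traj an `na_trajectory`.
#' @return `(n_samples_total * n_projections) x 3` matrix of k-space
#'   positions (cycles/mm); sample index varies fastest.
#' @export
trajectory_coords <- function(traj) {
  cbind(as.vector(outer(traj$radii, traj$directions[, 1])),
        as.vector(outer(traj$radii, traj$directions[, 2])),
        as.vector(outer(traj$radii, traj$directions[, 3])))
}

#' Export a trajectory as plain-text tables
#'
#' Writes `<stem>_directions.tsv` (one unit vector per spoke) and
#' `<stem>_readout.tsv` (per-sample radius, time and density-compensation
#' weight).
#' @param traj an `na_trajectory`.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
export_trajectory <- function(traj, stem) {
  pd <- paste0(stem, "_directions.tsv")
  pr <- paste0(stem, "_readout.tsv")
  utils::write.table(
    data.frame(x = traj$directions[, 1], y = traj$directions[, 2],
               z = traj$directions[, 3]),
    pd, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(k = traj$radii, t_ms = traj$times, dcf = traj$dcf),
    pr, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(pd, pr))
}
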