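#' Dual-flip-angle B1+ map
#'
#' Computes the local flip angle of the nominal-45-degree acquisition from
#' the magnitude-image ratio of the alternating pair:
#' `alpha_45 = arccos(S90 / (2 * S45))` per voxel (from
#' `S(2a)/S(a) = 2 cos(a)` for fully relaxed spin-density signals), and
#' the relative transmit field `rel_b1 = alpha_45 / 45`. Voxels where the
#' ratio falls outside the arccos domain or where `S45` is below a support
#' threshold are flagged undefined (`NA`), never imputed.
#'
#' @param img45,img90 magnitude [volume_grid]s reconstructed identically
#'   from the two acquisitions.
#' @param nominal_pair the nominal flip-angle pair, degrees (default
#'   c(45, 90)).
#' @param support_frac voxels with `S45` below this fraction of the 99th
#'   percentile of `S45` are undefined (default 0.05).
#' @return object of class `flip_angle_map`: `alpha` (degrees,
#'   [volume_grid] with `NA` where undefined), `rel_b1`, `defined`
#'   (logical [volume_grid]).
#' @export
dual_fa_map <- function(img45, img90, nominal_pair = c(45, 90),
                        support_frac = 0.05) {
  stopifnot_same_grid(img45, img90, "dual-flip-angle images")
  if (abs(nominal_pair[2] - 2 * nominal_pair[1]) > 1e-9)
    stop("dual_fa_map requires a (alpha, 2*alpha) nominal pair")
  s45 <- img45$values
  s90 <- img90$values
  thresh <- support_frac * stats::quantile(s45, 0.99, names = FALSE)
  ratio <- s90 / (2 * s45)
  ok <- is.finite(ratio) & ratio > 0 & ratio < 1 & s45 >= thresh
  if (!any(ok))
    stop("dual_fa_map: no voxel yields a defined flip angle")
  alpha <- array(NA_real_, dim = img45$shape)
  alpha[ok] <- acos(ratio[ok]) * 180 / pi
  structure(
    list(alpha = with_values(img45, alpha),
         rel_b1 = with_values(img45, alpha / nominal_pair[1]),
         defined = with_values(img45, array(ok, img45$shape)),
         nominal = nominal_pair[1]),
    class = "flip_angle_map")
}

#' FLASH T1 correction factor
#'
#' Steady-state saturation factor `(1 - E1) / (1 - E1 * cos(alpha))` with
#' `E1 = exp(-TR/T1)`; the corrected signal is the measured signal divided
#' by this factor. At TR = 150 ms and nominal 61 degrees this gives 0.965
#' for the 55 ms NaCl compartments and 0.994 for kidney-like T1 = 34 ms.
#'
#' @param t1 ms (> 0).
#' @param tr ms (> 0).
#' @param alpha flip angle, degrees.
#' @export
t1_correction_factor <- function(t1, tr, alpha) {
  if (any(t1 <= 0, na.rm = TRUE) || any(tr <= 0)) stop("t1 and tr must be > 0")
  e1 <- exp(-tr / t1)
  (1 - e1) / (1 - e1 * cos(alpha * pi / 180))
}

#' Apply the T1 / B1+ / B1- correction chain
#'
#' `corrected = image / (sin(nominal_fa * rel_b1) * rx_norm * t1_factor)`:
#' the transmit correction divides by the sine of the local flip angle,
#' the receive field enters linearly (after normalization to mean 1 over
#' `norm_mask`, by default the union of the vial VOIs -- absolute receive
#' scale cancels in the calibration), and the T1 factor is the FLASH
#' saturation factor evaluated with the *nominal* flip angle and the
#' declared per-compartment T1 map (voxels without a declared T1 get
#' factor 1). Each component is optional: pass `NULL` to skip it (used to
#' compare the uncorrected / B1+-corrected / fully corrected chains).
#' Undefined flip-angle voxels propagate as `NA`.
#'
#' @param image magnitude [volume_grid].
#' @param fa_map a [dual_fa_map()] result, or `NULL`.
#' @param rx_sos the sum-of-squares receive field [volume_grid] (see
#'   [rx_sos_field()]), or `NULL`.
#' @param t1_map [volume_grid] of per-compartment T1 (ms, `NA` where
#'   undeclared), or `NULL`.
#' @param nominal_fa quantitative-sequence nominal flip angle, degrees.
#' @param tr quantitative-sequence TR, ms.
#' @param norm_mask logical [volume_grid] over which `rx_sos` is
#'   normalized to mean 1 (required when `rx_sos` is given).
#' @param local_fa_in_t1 if `TRUE`, use the local flip angle inside the
#'   FLASH factor instead of the nominal one (default `FALSE`, matching
#'   the fixed per-compartment correction of the reference protocol).
#' @return corrected [volume_grid] (`NA` where undefined).
#' @export
apply_corrections <- function(image, fa_map = NULL, rx_sos = NULL,
                              t1_map = NULL, nominal_fa = 61, tr = 150,
                              norm_mask = NULL, local_fa_in_t1 = FALSE) {
  corr <- image$values
  denom <- array(1, dim = image$shape)
  alpha_eff <- array(nominal_fa, dim = image$shape)
  if (!is.null(fa_map)) {
    stopifnot_same_grid(image, fa_map$rel_b1, "image and flip-angle map")
    alpha_eff <- nominal_fa * fa_map$rel_b1$values
    denom <- denom * sin(alpha_eff * pi / 180)
  }
  if (!is.null(rx_sos)) {
    stopifnot_same_grid(image, rx_sos, "image and receive field")
    if (is.null(norm_mask))
      stop("apply_corrections: norm_mask is required with rx_sos")
    stopifnot_same_grid(image, norm_mask, "image and normalization mask")
    m <- norm_mask$values > 0
    rx <- rx_sos$values / mean(rx_sos$values[m])
    bad <- sum(rx == 0 & is.finite(corr))
    if (any(rx[m] == 0))
      stop(sprintf("apply_corrections: receive field is zero in %d voxels inside the support", bad))
    denom <- denom * rx
  }
  if (!is.null(t1_map)) {
    stopifnot_same_grid(image, t1_map, "image and T1 map")
    af <- if (local_fa_in_t1) alpha_eff else nominal_fa
    f <- array(1, dim = image$shape)
    has <- !is.na(t1_map$values)
    e1 <- exp(-tr / t1_map$values[has])
    a <- (if (local_fa_in_t1) af[has] else af) * pi / 180
    f[has] <- (1 - e1) / (1 - e1 * cos(a))
    denom <- denom * f
  }
  with_values(image, corr / denom)
}

#' Reference-vial calibration fit
#'
#' Ordinary least-squares regression of the known vial concentrations on
#' the mean corrected signal per vial VOI (free intercept, which absorbs
#' the noise floor of the magnitude images): `conc = slope * signal +
#' intercept`.
#'
#' @param corrected corrected signal [volume_grid].
#' @param vial_masks list of logical [volume_grid] VOI masks.
#' @param concentrations known vial concentrations, mM (>= 2 distinct).
#' @return object of class `calibration_fit`: `slope` (mM per signal
#'   unit), `intercept` (mM), `r_squared`, `vial_means`,
#'   `vial_concentrations`.
#' @export
calibrate <- function(corrected, vial_masks, concentrations) {
  if (length(vial_masks) != length(concentrations))
    stop("one concentration per mask is required")
  if (length(unique(concentrations)) < 2)
    stop("calibration needs at least 2 distinct vial concentrations")
  means <- vapply(vial_masks, function(m) {
    stopifnot_same_grid(corrected, m, "image and vial mask")
    v <- corrected$values[m$values > 0]
    if (length(v) == 0) stop("calibrate: empty vial mask")
    mean(v, na.rm = TRUE)
  }, numeric(1))
  fit <- stats::lm(concentrations ~ means)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((concentrations - mean(concentrations))^2)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = 1 - ss_res / ss_tot,
         vial_means = means,
         vial_concentrations = concentrations),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit: conc = %.4g * signal + %.4g mM, R^2 = %.4f>\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Convert corrected signal to apparent sodium concentration
#'
#' Applies the calibration line voxelwise:
#' `aSC = slope * signal + intercept` (mM). Over tissue this is the
#' apparent tissue sodium concentration (aTSC).
#'
#' @param corrected corrected signal [volume_grid].
#' @param fit a [calibrate()] result.
#' @return concentration [volume_grid] (mM).
#' @export
to_concentration <- function(corrected, fit) {
  with_values(corrected, fit$slope * corrected$values + fit$intercept)
}

#' Write a calibration fit as a JSON sidecar
#' @param fit a `calibration_fit`.
#' @param path output path.
#' @export
write_calibration <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
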