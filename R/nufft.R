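#' @useDynLib naquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# --- non-uniform FFT by Kaiser-Bessel gridding -------------------------------
#
# Conventions: forward transform  s_j = sum_i rho_i exp(-2*pi*i k_j . r_i)
# over voxel centers r_i of a volume_grid; adjoint is the conjugate
# transpose. Oversampling factor 2, kernel width 8, Kaiser-Bessel shape
# parameter from the standard minimum-aliasing-error formula; this meets
# the < 1e-5 relative-error contract against direct summation.

.kb_width <- 8L
.kb_os <- 2L

kb_beta <- function(width = .kb_width, os = .kb_os) {
  pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)
}

# circular half-shift of all three axes (even n: fftshift == ifftshift)
shift3 <- function(a) {
  n <- dim(a)[1]
  i <- c((n / 2 + 1):n, 1:(n / 2))
  a[i, i, i]
}

# continuous Fourier transform of the KB kernel at f cycles/sample
kb_hat <- function(f, width = .kb_width, beta = kb_beta()) {
  arg <- beta^2 - (pi * width * f)^2
  out <- numeric(length(f))
  p <- arg > 0
  out[p] <- width * sinh(sqrt(arg[p])) / sqrt(arg[p])
  out[!p] <- width * sinc0(sqrt(-arg[!p]))
  out
}

sinc0 <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)

# deapodization values for the central N entries of an oversampled n-grid
deapod_axis <- function(n_img, n_os) {
  xt <- (seq_len(n_img) - 1 - n_img / 2)   # integer offsets from center
  kb_hat(xt / n_os)
}

#' Forward non-uniform Fourier transform (image to k-space samples)
#'
#' Evaluates `s_j = sum_i rho_i exp(-2 pi i k_j . r_i)` over the voxel
#' centers of `grid` at arbitrary k-space positions, via Kaiser-Bessel
#' gridding (oversampling 2, width-8 kernel) with exact deapodization.
#'
#' @param grid a [volume_grid] (real or complex values).
#' @param kcoords `m x 3` matrix of k-space positions in cycles/mm.
#' @return complex vector of length `m`.
#' @export
nufft_forward <- function(grid, kcoords) {
  N <- grid$shape[1]
  n <- .kb_os * N
  d <- deapod_axis(N, n)
  A <- grid$values / (d %o% d %o% d)
  pad <- array(0i, dim = c(n, n, n))
  off <- n / 2 - N / 2
  pad[off + 1:N, off + 1:N, off + 1:N] <- A
  K <- shift3(stats::fft(shift3(pad)))
  g <- kcoords * (n * grid$voxel_size)      # continuous grid units
  s <- kb_interp3(K, g + n / 2, .kb_width, kb_beta())
  if (any(grid$origin != 0)) {
    ph <- kcoords %*% grid$origin
    s <- s * exp(-2i * pi * as.vector(ph))
  }
  s
}

#' Adjoint non-uniform Fourier transform (k-space samples to image)
#'
#' Evaluates `I_i = sum_j v_j exp(+2 pi i k_j . r_i)` on the voxel centers
#' of `out_grid` (the exact conjugate transpose of [nufft_forward()]).
#' Density-compensation and apodization weights are expected to be folded
#' into `values` by the caller.
#'
#' @param values complex sample values (length m).
#' @param kcoords `m x 3` k-space positions in cycles/mm.
#' @param out_grid a [volume_grid] defining the output geometry.
#' @return complex 3D array on `out_grid`'s geometry.
#' @export
nufft_adjoint <- function(values, kcoords, out_grid) {
  N <- out_grid$shape[1]
  n <- .kb_os * N
  v <- as.complex(values)
  if (any(out_grid$origin != 0)) {
    ph <- kcoords %*% out_grid$origin
    v <- v * exp(2i * pi * as.vector(ph))
  }
  g <- kcoords * (n * out_grid$voxel_size)
  G <- kb_spread3(v, g + n / 2, n, .kb_width, kb_beta())
  Im <- shift3(stats::fft(shift3(G), inverse = TRUE))
  off <- n / 2 - N / 2
  Im <- Im[off + 1:N, off + 1:N, off + 1:N]
  d <- deapod_axis(N, n)
  Im / (d %o% d %o% d)
}

#' Direct non-uniform DFT (reference implementation)
#'
#' Brute-force evaluation of the forward (`sign = -1`) or adjoint
#' (`sign = +1`) sum. Quadratic cost; used for small problems and
#' validation.
#'
#' @param amps complex amplitudes at source points.
#' @param source `n x 3` source positions (mm for image side, cycles/mm for
#'   k side).
#' @param target `m x 3` target positions (the conjugate domain).
#' @param sign -1 for image-to-k, +1 for k-to-image.
#' @export
ndft_direct <- function(amps, source, target, sign = -1) {
  ndft_sum(as.complex(amps), as.matrix(source), as.matrix(target),
           as.numeric(sign))
}
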