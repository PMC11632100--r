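# Bluestein chirped z-transform (zoom DFT) core.
#
# The zoom transform evaluates, for uniform input samples x_n = x0 + n*dx and
# uniform output samples k_m = k0 + m*dk,
#
#     F_m = sum_n f_n * exp(1i * sgn * k_m * x_n),
#
# i.e. a semidiscrete Fourier sum on an arbitrary, arbitrarily fine output
# window. Bluestein's identity n*m = (n^2 + m^2 - (m-n)^2)/2 converts the
# coupled exponent into a linear convolution, evaluated with three FFTs.
# This is what lets the diffraction integrals below be sampled on zoomed
# detector windows at no extra cost.

# transform each column of the N x K matrix `a` (axis n -> axis m)
czt_cols <- function(a, x0, dx, k0, dk, m_out, sgn = 1) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1L)
  n_in <- nrow(a); k_cols <- ncol(a)
  w <- sgn * dk * dx
  nn <- seq_len(n_in) - 1
  mm <- seq_len(m_out) - 1

  an_fac <- exp(1i * (sgn * k0 * dx * nn + w * nn^2 / 2))
  a2 <- a * an_fac  # recycles down columns

  L <- stats::nextn(n_in + m_out - 1L, 2L)
  jj <- c(mm, -(rev(seq_len(n_in - 1L))))             # j = 0..M-1, then -(N-1)..-1
  b <- complex(length.out = L)
  b[(jj %% L) + 1L] <- exp(-1i * w * jj^2 / 2)
  B <- stats::fft(b)

  apad <- matrix(0 + 0i, L, k_cols)
  apad[seq_len(n_in), ] <- a2
  conv <- stats::mvfft(stats::mvfft(apad) * B, inverse = TRUE) / L
  res <- conv[seq_len(m_out), , drop = FALSE]

  pre <- exp(1i * (sgn * k0 * x0 + sgn * dk * x0 * mm + w * mm^2 / 2))
  res * pre
}

# separable 2-D zoom transform of matrix `f` (ny x nx):
#   F[my, mx] = sum f[ny, nx] exp(1i*sgn*(kx_mx * x_nx + ky_my * y_ny))
zoom_dft2 <- function(f, x0, dx, y0, dy, kx0, dkx, mx, ky0, dky, my, sgn = 1) {
  tmp <- czt_cols(f, y0, dy, ky0, dky, my, sgn)            # transform y axis
  out <- czt_cols(t(tmp), x0, dx, kx0, dkx, mx, sgn)       # transform x axis
  t(out)
}

fftshift_idx <- function(p) ((seq_len(p) - 1L + ceiling(p / 2)) %% p) + 1L
ifftshift_idx <- function(p) ((seq_len(p) - 1L + floor(p / 2)) %% p) + 1L

fftshift2 <- function(m) m[fftshift_idx(nrow(m)), fftshift_idx(ncol(m)), drop = FALSE]
ifftshift2 <- function(m) m[ifftshift_idx(nrow(m)), ifftshift_idx(ncol(m)), drop = FALSE]

fft2 <- function(m, inverse = FALSE) {
  r <- stats::fft(m, inverse = inverse)
  if (inverse) r / length(m) else r
}
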