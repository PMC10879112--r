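# Internal Fourier helpers shared by the simulator and the reconstructor.
# All spatial frequencies are handled in cycles/nm internally; user-facing
# functions convert to cycles/um.

# DFT sample frequencies for an n-point grid with sample spacing d
# (same ordering as stats::fft output: 0, +, ..., -, so bin k maps to
# frequency fft_freq(n, d)[k + 1]).
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# |frequency| on a 2D FFT grid, optionally centred at (-kx, -ky), i.e. the
# radial coordinate |nu + k| used for shifted-band OTF supports.
freq_radius <- function(nr, nc, d, kx = 0, ky = 0) {
  fy <- fft_freq(nr, d) + ky
  fx <- fft_freq(nc, d) + kx
  sqrt(outer(fy^2, rep(1, nc)) + outer(rep(1, nr), fx^2))
}

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Swap quadrants so that the zero-frequency (or centre) pixel moves to the
# array centre; inverse = TRUE undoes it.
fftshift2 <- function(x, inverse = FALSE) {
  nr <- nrow(x)
  nc <- ncol(x)
  sr <- if (inverse) ceiling(nr / 2) else floor(nr / 2)
  sc <- if (inverse) ceiling(nc / 2) else floor(nc / 2)
  idx_r <- c(seq_len(nr)[-seq_len(sr)], seq_len(sr))
  idx_c <- c(seq_len(nc)[-seq_len(sc)], seq_len(sc))
  x[idx_r, idx_c, drop = FALSE]
}

# Crop (n_out < n_in) or zero-pad (n_out > n_in) a 2D FFT spectrum while
# keeping physical frequencies aligned; both fields of view must be equal,
# so the frequency bin spacing is unchanged.  Amplitudes are rescaled so
# that real-space values (not sums) are preserved.
fourier_resize <- function(spec, out_shape) {
  nr_in <- nrow(spec)
  nc_in <- ncol(spec)
  nr_out <- out_shape[1]
  nc_out <- out_shape[2]
  out <- matrix(0i, nr_out, nc_out)
  hr <- min(floor((nr_in - 1) / 2), floor((nr_out - 1) / 2))
  hc <- min(floor((nc_in - 1) / 2), floor((nc_out - 1) / 2))
  rows_in <- c(seq_len(hr + 1), nr_in - seq_len(hr) + 1)
  rows_out <- c(seq_len(hr + 1), nr_out - seq_len(hr) + 1)
  cols_in <- c(seq_len(hc + 1), nc_in - seq_len(hc) + 1)
  cols_out <- c(seq_len(hc + 1), nc_out - seq_len(hc) + 1)
  out[rows_out, cols_out] <- spec[rows_in, cols_in]
  out * (nr_out * nc_out) / (nr_in * nc_in)
}

# Evaluate the 2D DFT of `img` at one arbitrary (sub-bin) frequency
# (kx, ky) in cycles/nm, pixel pitch `d` in nm.  Separable plane-wave dot
# product; cheap enough to call inside an optimizer.
dft_at <- function(img, kx, ky, d) {
  y <- (seq_len(nrow(img)) - 1) * d
  x <- (seq_len(ncol(img)) - 1) * d
  wy <- exp(-2i * pi * ky * y)
  wx <- exp(-2i * pi * kx * x)
  as.complex(crossprod(wy, img %*% wx))
}

# Gaussian transfer function exp(-2 pi^2 sigma^2 nu^2): Fourier transform of
# a normalized spatial Gaussian with standard deviation sigma (nm).
gaussian_transfer <- function(nr, nc, d, sigma) {
  nu2 <- freq_radius(nr, nc, d)^2
  exp(-2 * pi^2 * sigma^2 * nu2)
}

# Run an expression with a private RNG stream (restores .Random.seed).
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
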