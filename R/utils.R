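# Internal numerics shared across modules.

# Separable Gaussian smoothing (kernel truncated at 3 sigma, edge-replicated
# padding). Equivalent to a direct Gaussian convolution but runs via
# stats::filter, which is much faster than FFT filtering for the kernel
# sizes used here.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  pad_rows <- function(x) {
    rbind(x[rep(1L, h), , drop = FALSE], x,
          x[rep(nrow(x), h), , drop = FALSE])
  }
  smooth_cols <- function(x) {
    y <- stats::filter(pad_rows(x), k, sides = 2)
    y[(h + 1):(h + nrow(x)), , drop = FALSE]
  }
  t(smooth_cols(t(smooth_cols(m))))
}
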