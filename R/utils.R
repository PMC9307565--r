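#' @keywords internal
"_PACKAGE"

# Abort with a classed condition so callers can test on error class.
rh_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "radharm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

rh_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "radharm_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Population standard deviation (divide by n, not n - 1).
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Gaussian-smoothed 2D field via separable banded convolution matrices.
# Kernel is renormalised at the borders (no padding artefacts).
gauss_smooth2d <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / sigma)^2)
    k[d > 3 * sigma + 1] <- 0
    k / rowSums(k)
  }
  band(nrow(mat)) %*% mat %*% t(band(ncol(mat)))
}
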