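#' Wrap angles to the half-open interval [-pi, pi)
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to `[-pi, pi)`.
#' @export
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

## Composite trapezoidal rule on an equispaced periodic grid: for a smooth
## 2*pi-periodic integrand this is spectrally accurate, which is why the
## package standardizes on it for all ring quadratures.
periodic_trapz <- function(values, spacing) {
  sum(values) * spacing
}

## Trapezoid on a (possibly non-periodic) equispaced grid including both ends.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Circular resultant length
#'
#' Modulus of the mean of `exp(1i * beta)`; 0 for a uniform sample, 1 for a
#' point mass.
#'
#' @param beta numeric vector of angles.
#' @return resultant length in `[0, 1]`.
#' @export
circular_resultant <- function(beta) {
  Mod(mean(exp(1i * beta)))
}

#' Circular mean
#'
#' @param beta numeric vector of angles.
#' @return circular mean in `[-pi, pi)`.
#' @export
circular_mean <- function(beta) {
  wrap_angle(Arg(mean(exp(1i * beta))))
}

#' Total-variation distance between two discrete distributions
#'
#' @param p,q probability vectors over the same bins.
#' @return `sum(abs(p - q)) / 2`.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  sum(abs(p - q)) / 2
}

## Equal-width histogram of wrapped phases; returns bin probabilities.
phase_bin_probs <- function(beta, bins = 36L) {
  beta <- wrap_angle(beta)
  edges <- seq(-pi, pi, length.out = bins + 1L)
  idx <- findInterval(beta, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > bins] <- bins
  tabulate(idx, nbins = bins) / length(beta)
}

## Probability mass of a density function within each of `bins` equal bins on
## [-pi, pi), by midpoint quadrature with `sub` points per bin.
density_bin_probs <- function(pdf_fun, bins = 36L, sub = 32L) {
  edges <- seq(-pi, pi, length.out = bins + 1L)
  w <- (2 * pi / bins) / sub
  vapply(seq_len(bins), function(b) {
    mids <- edges[b] + (seq_len(sub) - 0.5) * w
    sum(pdf_fun(mids)) * w
  }, numeric(1))
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
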