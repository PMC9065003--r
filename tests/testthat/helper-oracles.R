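# Independent oracles, deliberately coded without the package's internals.

# piecewise-linear interpolation through (xs, ys) evaluated at x, by the
# explicit two-point line formula segment by segment
oracle_piecewise_linear <- function(xs, ys, x) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (x[i] <= xs[1]) {
      seg <- 1
    } else {
      seg <- max(which(xs <= x[i]))
      if (seg == length(xs)) seg <- length(xs) - 1
    }
    slope <- (ys[seg + 1] - ys[seg]) / (xs[seg + 1] - xs[seg])
    out[i] <- ys[seg] + slope * (x[i] - xs[seg])
  }
  out
}

# baseline by brute force: scan every interior point for the local-minimum
# rule, then interpolate between anchors with the oracle above
oracle_baseline <- function(shift, intensity) {
  n <- length(intensity)
  anchors <- 1L
  for (i in 2:(n - 1)) {
    if (intensity[i] < intensity[i - 1] && intensity[i] <= intensity[i + 1]) {
      anchors <- c(anchors, i)
    }
  }
  anchors <- c(anchors, n)
  oracle_piecewise_linear(shift[anchors], intensity[anchors], shift)
}

# type-7 sample quantile written out from the definition
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  q <- xs[lo]
  if (lo < length(xs)) q <- q + (h - lo) * (xs[lo + 1] - xs[lo])
  q
}

# random synthetic spectrum: a few Gaussian peaks on a linear background
random_peaky_spectrum <- function(n_points = 300, id = "rnd") {
  shift <- seq(400, 400 + n_points - 1)
  y <- runif(1, 0, 5) + runif(1, 0, 0.01) * (shift - 400)
  for (k in seq_len(sample(2:5, 1))) {
    y <- y + runif(1, 0.5, 3) *
      exp(-4 * log(2) * (shift - runif(1, 450, 650))^2 / runif(1, 10, 40)^2)
  }
  raman_spectrum(shift, y + rnorm(n_points, 0, 0.05), id = id)
}

gauss_curve <- function(nu, h, cc, w) h * exp(-4 * log(2) * (nu - cc)^2 / w^2)
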