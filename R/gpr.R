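# Exact Gaussian process regression with a constant basis (mean) function
# and a choice of stationary kernels. The workhorse is the rational
# quadratic kernel
#     k_RQ(r) = sigma_f^2 * (1 + r^2 / (2 alpha l^2))^(-alpha),
# r = |x - x'| the Euclidean distance; a scale mixture of
# squared-exponential kernels that converges to one as alpha -> Inf.
# sigma_f (signal sd) and sigma_n (noise sd) complete the model and are
# optimized jointly with l and alpha by maximizing the log marginal
# likelihood; the constant basis coefficient beta is profiled out by
# generalized least squares at every evaluation.

KERNEL_TAGS <- c("rq", "se", "matern52", "exp")

kernel_from_dist <- function(D, tag, l, alpha = 1) {
  switch(tag,
    rq = (1 + D^2 / (2 * alpha * l^2))^(-alpha),
    se = exp(-D^2 / (2 * l^2)),
    matern52 = {
      s <- sqrt(5) * D / l
      (1 + s + s^2 / 3) * exp(-s)
    },
    exp = exp(-D / l),
    stop_ramansalt("parameter", "unknown kernel tag '", tag, "'"))
}

#' Rational quadratic kernel value between two inputs
#'
#' `sigma_f^2 * (1 + r^2/(2 alpha l^2))^(-alpha)` with `r` the Euclidean
#' distance between `x` and `x_prime`. The value lies in `(0, sigma_f^2]`
#' and equals `sigma_f^2` at `r = 0`; as `alpha -> Inf` it converges to the
#' squared-exponential kernel `sigma_f^2 exp(-r^2/(2 l^2))`.
#'
#' @param x,x_prime Numeric input vectors of equal length.
#' @param l Characteristic length scale, > 0 (input distance units).
#' @param alpha Scale-mixture parameter, > 0, dimensionless.
#' @param sigma_f Signal standard deviation, > 0 (output units).
#' @return Scalar covariance value.
#' @export
rq_kernel <- function(x, x_prime, l = 1, alpha = 1, sigma_f = 1) {
  if (length(x) != length(x_prime)) {
    stop_ramansalt("input", "x and x_prime must have the same dimension")
  }
  if (l <= 0 || alpha <= 0 || sigma_f <= 0) {
    stop_ramansalt("parameter", "l, alpha and sigma_f must be positive")
  }
  r2 <- sum((x - x_prime)^2)
  sigma_f^2 * (1 + r2 / (2 * alpha * l^2))^(-alpha)
}

#' Kernel Gram matrix for a set of inputs
#'
#' @param X Numeric matrix, one input per row.
#' @param kernel One of `"rq"`, `"se"`, `"matern52"`, `"exp"`.
#' @param l,alpha,sigma_f Kernel hyperparameters (alpha used by rq only).
#' @return n x n covariance matrix.
#' @export
kernel_gram <- function(X, kernel = "rq", l = 1, alpha = 1, sigma_f = 1) {
  kernel <- match.arg(kernel, KERNEL_TAGS)
  D <- self_dist(as.matrix(X))
  sigma_f^2 * kernel_from_dist(D, kernel, l, alpha)
}

# pairwise Euclidean distances between rows of A and rows of B
euclid_dist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# self-distances with an exactly-zero diagonal
self_dist <- function(X) {
  D <- euclid_dist(X, X)
  diag(D) <- 0
  D
}

# Cholesky with progressive jitter; returns list(L, jitter)
chol_jitter <- function(K) {
  md <- mean(diag(K))
  for (j in c(0, 1e-12, 1e-10, 1e-8, 1e-6) * md) {
    L <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
  }
  stop_ramansalt("fit", "covariance matrix is not positive definite")
}

# negative log marginal likelihood with beta profiled out; par on log scale
gpr_nll <- function(logpar, D, y, tag) {
  p <- exp(logpar)
  l <- p[["l"]]; sf <- p[["sigma_f"]]; sn <- p[["sigma_n"]]
  a <- if (tag == "rq") p[["alpha"]] else 1
  n <- length(y)
  K <- sf^2 * kernel_from_dist(D, tag, l, a) + diag(sn^2, n)
  ch <- tryCatch(chol_jitter(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  L <- ch$L
  Kinv_y <- backsolve(L, forwardsolve(t(L), y))
  Kinv_1 <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  beta <- sum(Kinv_y) / sum(Kinv_1)           # GLS with H = 1_n
  resid <- y - beta
  Kinv_r <- Kinv_y - beta * Kinv_1
  val <- 0.5 * sum(resid * Kinv_r) + sum(log(diag(L))) +
    0.5 * n * log(2 * pi)
  if (!is.finite(val)) 1e10 else val
}

#' Fit an exact Gaussian process regression model
#'
#' Maximizes the log marginal likelihood of an exact GP with constant mean
#' `beta * 1_n` (beta profiled out by generalized least squares) and
#' covariance `K + sigma_n^2 I` over `(l, alpha, sigma_f, sigma_n)` on the
#' log scale, with multiple restarts from jittered initial values.
#' Initialization: `l` = median pairwise training distance, `alpha` = 1,
#' `sigma_f` = sd(y), `sigma_n` = sd(y)/10.
#'
#' @param X Numeric matrix of training inputs (rows = preprocessed
#'   spectra, or any features).
#' @param y Numeric targets (NaCl concentration, mM).
#' @param kernel `"rq"` (default), `"se"`, `"matern52"` or `"exp"`.
#' @param optimize If FALSE, keep the supplied `params` fixed.
#' @param params Optional named list `l`, `alpha`, `sigma_f`, `sigma_n`
#'   (initial values when optimizing, fixed values otherwise).
#' @param restarts Number of optimization restarts (default 3).
#' @param sigma_n_floor Lower bound for the noise sd (default 1e-8).
#' @param seed Integer seed controlling restart jitter.
#' @param max_n Exact-GP training-size budget (default 3000); larger
#'   training sets are refused with a suggestion to subsample, because
#'   exact inference is cubic in n.
#' @return A `gpr_model` (also `salt_model`) with elements `kernel`,
#'   `params` (l, alpha, sigma_f, sigma_n), `beta` (mM), `X`, `y`,
#'   `alpha_vec` (weights `K^{-1}(y - beta)`), `L` (Cholesky factor),
#'   `jitter`, `nll`, `seed`.
#' @export
fit_gpr <- function(X, y, kernel = "rq", optimize = TRUE, params = NULL,
                    restarts = 3L, sigma_n_floor = 1e-8, seed = 1L,
                    max_n = 3000L) {
  kernel <- match.arg(kernel, KERNEL_TAGS)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y) || n < 2L) {
    stop_ramansalt("input", "need matching X rows and y with n >= 2")
  }
  if (n > max_n) {
    stop_ramansalt("input", "n = ", n, " exceeds the exact-GP budget (",
                   max_n, "); subsample the training set (stratified by ",
                   "concentration) before fitting")
  }
  D <- self_dist(X)
  l0 <- stats::median(D[upper.tri(D)])
  if (!is.finite(l0) || l0 <= 0) l0 <- 1
  sy <- stats::sd(y)
  if (!is.finite(sy) || sy == 0) sy <- 1
  init <- list(l = l0, alpha = 1, sigma_f = sy, sigma_n = sy / 10)
  if (!is.null(params)) init[names(params)] <- params

  pick <- c("l", "alpha", "sigma_f", "sigma_n")
  logpar <- log(pmax(unlist(init[pick]), 1e-12))
  if (optimize) {
    lower <- c(l = log(l0) - 8, alpha = -8, sigma_f = log(sy) - 8,
               sigma_n = log(max(sigma_n_floor, 1e-12)))
    upper <- c(l = log(l0) + 8, alpha = 12, sigma_f = log(sy) + 6,
               sigma_n = log(sy) + 4)
    best <- NULL
    set.seed(as.integer(seed))
    starts <- list(logpar)
    for (r in seq_len(max(restarts - 1L, 0L))) {
      starts[[r + 1L]] <- logpar + stats::rnorm(4, 0, 0.5)
    }
    for (st in starts) {
      st <- pmin(pmax(st, lower), upper)
      opt <- tryCatch(
        stats::optim(st, gpr_nll, D = D, y = y, tag = kernel,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e9 &&
          (is.null(best) || opt$value < best$value)) best <- opt
    }
    if (is.null(best)) {
      stop_ramansalt("fit", "marginal likelihood non-finite at all restarts")
    }
    logpar <- best$par
    nll <- best$value
  } else {
    nll <- gpr_nll(logpar, D, y, kernel)
  }
  p <- exp(logpar)
  l <- p[["l"]]; sf <- p[["sigma_f"]]
  sn <- max(p[["sigma_n"]], sigma_n_floor)
  a <- if (kernel == "rq") p[["alpha"]] else 1
  K <- sf^2 * kernel_from_dist(D, kernel, l, a) + diag(sn^2, n)
  ch <- chol_jitter(K)
  L <- ch$L
  Kinv_y <- backsolve(L, forwardsolve(t(L), y))
  Kinv_1 <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  beta <- sum(Kinv_y) / sum(Kinv_1)
  alpha_vec <- Kinv_y - beta * Kinv_1
  structure(list(kernel = kernel,
                 params = list(l = l, alpha = a, sigma_f = sf, sigma_n = sn),
                 beta = beta, X = X, y = y, alpha_vec = alpha_vec, L = L,
                 jitter = ch$jitter, nll = nll, seed = seed),
            class = c("gpr_model", "salt_model"))
}

#' Posterior predictions from a fitted GP
#'
#' Posterior mean `beta + k_*^T (K + sigma_n^2 I)^{-1} (y - beta 1)` and
#' the latent-function posterior sd. Far from all training points the
#' mean reverts to `beta` and the sd to `sigma_f` (stationary-kernel
#' limit). Deterministic given the model.
#'
#' @param object A `gpr_model`.
#' @param X_new Matrix of new inputs (training input dimension).
#' @param se Return predictive sd alongside the mean.
#' @param ... Unused.
#' @return Numeric vector of mean predictions (mM), or if `se = TRUE` a
#'   list with `mean` and `sd`.
#' @export
predict.gpr_model <- function(object, X_new, se = FALSE, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(object$X)) {
    stop_ramansalt("input", "X_new has ", ncol(X_new),
                   " columns, training inputs have ", ncol(object$X))
  }
  p <- object$params
  Dx <- euclid_dist(X_new, object$X)
  Ks <- p$sigma_f^2 * kernel_from_dist(Dx, object$kernel, p$l, p$alpha)
  mu <- object$beta + as.numeric(Ks %*% object$alpha_vec)
  if (!se) return(mu)
  v <- forwardsolve(t(object$L), t(Ks))
  var <- pmax(p$sigma_f^2 - colSums(v^2), 0)
  list(mean = mu, sd = sqrt(var))
}

#' @export
print.gpr_model <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<gpr_model kernel=%s: n=%d, l=%.4g, alpha=%.4g, ",
                     "sigma_f=%.4g, sigma_n=%.4g, beta=%.4g mM>\n"),
              x$kernel, length(x$y), p$l, p$alpha, p$sigma_f, p$sigma_n,
              x$beta))
  invisible(x)
}
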