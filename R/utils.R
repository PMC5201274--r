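#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm dnorm rnorm runif rbinom quantile optimize
#'   nlminb pchisq cor var sd complete.cases setNames cov aggregate plogis lm
#'   coef vcov qlogis
#' @importFrom utils head tail write.csv read.csv
NULL

# Derive a 32-bit substream seed from a master seed and a stage label.
# Deterministic, stage-separated, and stable across platforms.
substream_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  chars <- utf8ToInt(paste0(stage, ":"))
  h <- as.numeric(master_seed) %% 2147483647
  for (ch in chars) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(master_seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(master_seed, stage))
  expr
}

# Lower-triangular (excluding diagonal) vectorization of a symmetric matrix.
vech_lower <- function(m) m[lower.tri(m)]

# Index pairs (i, j), i > j, in the order used by vech_lower().
lower_pairs <- function(p) {
  idx <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

# Nearest positive semi-definite repair by eigenvalue clipping.
# Returns the input unchanged when it is already PSD (within tol).
nearest_psd <- function(m, tol = 1e-10) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -tol * max(abs(e$values), 1)) {
    return(m)
  }
  v <- pmax(e$values, tol * max(abs(e$values), 1))
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

# Draws from N(mu, sigma) using an eigendecomposition square root, so a
# PSD (possibly singular) sigma is acceptable. Rows are draws.
rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% rt, 2, mu, "+")
}

# Vectorized standard bivariate normal CDF P(Z1 <= h, Z2 <= k; rho), via
# Gauss-Legendre quadrature on the correlation path:
#   Phi2(h, k, rho) = Phi(h) Phi(k) +
#     (1/2pi) int_0^rho exp(-(h^2 - 2 t h k + k^2) / (2 (1 - t^2)))
#                      / sqrt(1 - t^2) dt.
# Accurate to ~1e-10 for |rho| <= 0.999 with 48 nodes; h, k may be +-Inf.
pbinorm <- function(h, k, rho) {
  n <- max(length(h), length(k))
  h <- rep_len(h, n)
  k <- rep_len(k, n)
  stopifnot(length(rho) == 1L, abs(rho) < 1)
  base <- pnorm(h) * pnorm(k)
  if (rho == 0) {
    return(base)
  }
  gl <- gauss_legendre_48
  t_nodes <- rho / 2 * gl$nodes + rho / 2
  w <- rho / 2 * gl$weights
  hf <- ifelse(is.finite(h), h, sign(h) * 1e6)
  kf <- ifelse(is.finite(k), k, sign(k) * 1e6)
  acc <- numeric(n)
  for (j in seq_along(t_nodes)) {
    tt <- t_nodes[j]
    om <- 1 - tt^2
    acc <- acc + w[j] * exp(-(hf^2 - 2 * tt * hf * kf + kf^2) / (2 * om)) /
      sqrt(om)
  }
  out <- base + acc / (2 * pi)
  # degenerate margins dominate the quadrature term
  out[h < -1e5 | k < -1e5] <- 0
  big_h <- h > 1e5
  big_k <- k > 1e5
  out[big_h] <- pnorm(k[big_h])
  out[big_k] <- pnorm(h[big_k])
  out[big_h & big_k] <- 1
  pmin(pmax(out, 0), 1)
}

gl48 <- local({
  # nodes/weights for Gauss-Legendre on [-1, 1], computed by Newton iteration
  # on Legendre polynomials (Golub-Welsch is overkill for fixed n)
  n <- 48L
  i <- seq_len(n %/% 2)
  x0 <- cos(pi * (i - 0.25) / (n + 0.5))
  for (iter in 1:100) {
    p0 <- rep(1, length(x0))
    p1 <- x0
    for (k in 2:n) {
      p2 <- ((2 * k - 1) * x0 * p1 - (k - 1) * p0) / k
      p0 <- p1
      p1 <- p2
    }
    dp <- n * (x0 * p1 - p0) / (x0^2 - 1)
    x1 <- x0 - p1 / dp
    if (max(abs(x1 - x0)) < 1e-15) {
      x0 <- x1
      break
    }
    x0 <- x1
  }
  p0 <- rep(1, length(x0))
  p1 <- x0
  for (k in 2:n) {
    p2 <- ((2 * k - 1) * x0 * p1 - (k - 1) * p0) / k
    p0 <- p1
    p1 <- p2
  }
  dp <- n * (x0 * p1 - p0) / (x0^2 - 1)
  w <- 2 / ((1 - x0^2) * dp^2)
  list(
    nodes = c(-x0, rev(x0)),
    weights = c(w, rev(w))
  )
})
gauss_legendre_48 <- gl48

`%||%` <- function(a, b) if (is.null(a)) b else a
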