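#' Polychoric/polyserial correlation matrix with thresholds
#'
#' Estimates the latent-response correlation matrix of a mixed block of
#' ordinal/binary and continuous columns by pairwise two-step maximum
#' likelihood: thresholds of each ordinal column from its univariate margin
#' (cumulative normal quantiles), then each pairwise correlation by
#' maximizing the bivariate likelihood with thresholds held fixed
#' (polychoric/tetrachoric for two ordinal columns, polyserial for a mixed
#' pair, Pearson for two continuous columns). Pairwise-present observations
#' are used under `missing = "pairwise"`. Continuous columns are
#' standardized, so the result is a full correlation matrix.
#'
#' Pairwise asymptotic variances of the estimates -- used as inverse DWLS
#' weights downstream -- are obtained from the curvature of the pairwise
#' log-likelihood at the estimate (for Pearson pairs, the usual
#' \eqn{(1-\rho^2)^2/n} approximation).
#'
#' @param data data.frame or matrix of the analyzed columns.
#' @param ordinal logical vector (or character vector of column names)
#'   marking ordinal columns; by default, integer-valued columns with at
#'   most 10 distinct observed values.
#' @param missing `"pairwise"` or `"complete"`.
#' @param bound correlations are constrained to `[-bound, bound]`;
#'   boundary estimates (e.g. a perfectly concordant binary pair) are
#'   clipped there with a warning.
#' @return A list of class `clp_polycor`: `rho` (correlation matrix),
#'   `thresholds` (named list, `numeric(0)` for continuous columns),
#'   `avar` (matrix of asymptotic variances of the pairwise estimates),
#'   `n_pairwise` (matrix of pairwise sample sizes), `ordinal`.
#' @examples
#' set.seed(1)
#' x <- rnorm(500); y <- 0.5 * x + sqrt(0.75) * rnorm(500)
#' d <- data.frame(a = as.integer(x > 0), b = as.integer(y > 0))
#' pc <- polychoric_matrix(d)
#' pc$rho[1, 2] # close to 0.5
#' @export
polychoric_matrix <- function(data, ordinal = NULL,
                              missing = c("pairwise", "complete"),
                              bound = 0.999) {
  missing <- match.arg(missing)
  data <- as.data.frame(data)
  p <- ncol(data)
  nm <- names(data)
  if (missing == "complete") {
    data <- data[complete.cases(data), , drop = FALSE]
  }
  if (is.null(ordinal)) {
    ordinal <- vapply(data, function(x) {
      v <- unique(x[!is.na(x)])
      length(v) <= 10 && all(v == round(v))
    }, logical(1))
  } else if (is.character(ordinal)) {
    ordinal <- nm %in% ordinal
  }
  names(ordinal) <- nm

  thresholds <- setNames(vector("list", p), nm)
  levels_of <- setNames(vector("list", p), nm)
  cols <- vector("list", p)
  for (j in seq_len(p)) {
    x <- data[[j]]
    if (ordinal[j]) {
      obs <- x[!is.na(x)]
      lev <- sort(unique(obs))
      if (length(lev) < 2) {
        stop("column ", nm[j], " has a single observed category")
      }
      # empty intermediate categories are absent from lev, i.e. adjacent
      # categories are collapsed onto the observed ones
      props <- cumsum(tabulate(match(obs, lev),
                               length(lev))) / length(obs)
      thresholds[[j]] <- qnorm(head(props, -1))
      levels_of[[j]] <- lev
      cols[[j]] <- match(x, lev)
    } else {
      mu <- mean(x, na.rm = TRUE)
      s <- sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        stop("column ", nm[j], " is constant")
      }
      thresholds[[j]] <- numeric(0)
      cols[[j]] <- (x - mu) / s
    }
  }

  rho <- diag(p)
  avar <- matrix(0, p, p)
  n_pw <- matrix(NA_integer_, p, p)
  dimnames(rho) <- dimnames(avar) <- dimnames(n_pw) <- list(nm, nm)
  diag(n_pw) <- colSums(!is.na(data))

  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      ok <- !is.na(cols[[i]]) & !is.na(cols[[j]])
      n_ok <- sum(ok)
      n_pw[i, j] <- n_pw[j, i] <- n_ok
      if (n_ok < 3) stop("empty pairwise overlap: ", nm[i], ", ", nm[j])
      est <- pairwise_latent_cor(
        cols[[i]][ok], cols[[j]][ok],
        thresholds[[i]], thresholds[[j]],
        ordinal[i], ordinal[j], bound = bound,
        pair = paste(nm[i], nm[j], sep = "-")
      )
      rho[i, j] <- rho[j, i] <- est$rho
      avar[i, j] <- avar[j, i] <- est$avar
    }
  }
  structure(
    list(rho = rho, thresholds = thresholds, avar = avar,
         n_pairwise = n_pw, ordinal = ordinal),
    class = "clp_polycor"
  )
}

# One pairwise latent correlation: polychoric, polyserial, or Pearson.
# x, y are category indices (ordinal) or standardized values (continuous).
pairwise_latent_cor <- function(x, y, tx, ty, ord_x, ord_y,
                                bound = 0.999, pair = "") {
  if (!ord_x && !ord_y) {
    r <- cor(x, y)
    r <- min(max(r, -bound), bound)
    return(list(rho = r, avar = (1 - r^2)^2 / length(x)))
  }
  if (ord_x && !ord_y) {
    return(pairwise_latent_cor(y, x, ty, tx, FALSE, TRUE, bound, pair))
  }

  if (!ord_x && ord_y) {
    cuts <- c(-Inf, ty, Inf)
    negll <- function(r) {
      s <- sqrt(1 - r^2)
      up <- pnorm((cuts[y + 1L] - r * x) / s)
      lo <- pnorm((cuts[y] - r * x) / s)
      -sum(log(pmax(up - lo, 1e-300)))
    }
  } else {
    kx <- length(tx) + 1L
    ky <- length(ty) + 1L
    tab <- matrix(0, kx, ky)
    counts <- table(factor(x, levels = seq_len(kx)),
                    factor(y, levels = seq_len(ky)))
    tab[] <- as.numeric(counts)
    cx <- c(-Inf, tx, Inf)
    cy <- c(-Inf, ty, Inf)
    grid_h <- rep(cx, times = ky + 1L)
    grid_k <- rep(cy, each = kx + 1L)
    nz <- which(tab > 0)
    negll <- function(r) {
      cdf <- matrix(pbinorm(grid_h, grid_k, r), kx + 1L, ky + 1L)
      pr <- cdf[-1, -1] - cdf[-(kx + 1L), -1] -
        cdf[-1, -(ky + 1L)] + cdf[-(kx + 1L), -(ky + 1L)]
      -sum(tab[nz] * log(pmax(pr[nz], 1e-300)))
    }
  }

  opt <- optimize(negll, c(-bound, bound), tol = 1e-7)
  r <- opt$minimum
  if (abs(r) > bound - 1e-3) {
    r <- sign(r) * bound
    warning("latent correlation at boundary for pair ", pair,
            "; clipped to ", signif(r, 4), call. = FALSE)
  }
  h <- 1e-3
  curv <- (negll(min(r + h, bound)) - 2 * negll(r) +
             negll(max(r - h, -bound))) / h^2
  avar <- if (is.finite(curv) && curv > 0) 1 / curv else (1 - r^2)^2 /
    length(x)
  list(rho = r, avar = avar)
}
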