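#' Fit a cross-lagged structural equation model
#'
#' Estimates a [clpm_spec()] model on a wide panel. Two estimation routes
#' are provided. `estimator = "wls"`: two-stage categorical-faithful
#' estimation -- thresholds and a polychoric/polyserial correlation matrix
#' from pairwise-present data, then diagonally weighted least squares
#' (weights = inverse asymptotic variances of the pairwise estimates) for
#' the structural parameters. `estimator = "ml"`: normal-theory maximum
#' likelihood treating variables as continuous, on complete cases or, with
#' `missing = "fiml"`, by full-information maximum likelihood over all
#' observed cells.
#'
#' Optimization uses a quasi-Newton method (`nlminb`) with up to three
#' jittered restarts on failure; convergence requires a relative objective
#' change below 1e-9 (reported along with the gradient norm otherwise).
#'
#' @param spec a [clpm_spec()].
#' @param data wide data.frame containing every `<item>_<wave>` column the
#'   spec refers to.
#' @param se compute standard errors (and the standardized solution's
#'   delta-method covariance); disable for speed in simulations.
#' @param control optional list: `iter.max`, `rel.tol`, `restarts`.
#' @return An object of class `clp_fit`: `estimates`, `vcov`, `chi_square`,
#'   `df`, `chi_square_null`, `df_null`, `cfi`, `rmsea`, `standardized`,
#'   `std_vcov` (structural block), `p_values` (structural Wald tests),
#'   `n_used`, `converged`, `estimator`, plus the compiled model and sample
#'   moments.
#' @export
fit_sem <- function(spec, data, se = TRUE, control = list()) {
  stopifnot(inherits(spec, "clp_model"))
  cmp <- compile_model(spec)
  miss_cols <- setdiff(cmp$ov, names(data))
  if (length(miss_cols)) {
    stop("data lacks columns: ", paste(head(miss_cols, 5), collapse = ", "))
  }
  X <- data[, cmp$ov, drop = FALSE]

  if (spec$estimator == "wls") {
    fit <- fit_dwls(cmp, X, se = se, control = control)
  } else if (spec$missing == "fiml") {
    fit <- fit_fiml(cmp, X, se = se, control = control)
  } else {
    fit <- fit_ml_complete(cmp, X, se = se, control = control)
  }

  if (fit$df > 0) {
    fi <- fit_indices(fit$chi_square, fit$df, fit$chi_square_null,
                      fit$df_null, fit$n_used)
    fit$cfi <- fi[["cfi"]]
    fit$rmsea <- fi[["rmsea"]]
  } else {
    # saturated model: perfect fit by convention
    fit$cfi <- 1
    fit$rmsea <- 0
  }

  std <- standardize_solution(cmp, fit$estimates)
  fit$standardized <- std
  struct <- names(cmp$par_group)[cmp$par_group == "structural"]
  if (se && length(struct) && !is.null(fit$vcov)) {
    J <- fd_jacobian(function(th) {
      standardize_solution(cmp, setNames(th, names(fit$estimates)))[
        paste0("std_", struct)]
    }, fit$estimates)
    fit$std_vcov <- J %*% fit$vcov %*% t(J)
    dimnames(fit$std_vcov) <- list(paste0("std_", struct),
                                   paste0("std_", struct))
    se_raw <- sqrt(pmax(diag(fit$vcov), 0))
    z <- fit$estimates[struct] / se_raw[struct]
    fit$p_values <- setNames(2 * pnorm(-abs(z)), struct)
  }
  fit$spec <- spec
  fit$compiled <- cmp
  class(fit) <- "clp_fit"
  fit
}

run_optimizer <- function(obj, start, lower, control = list()) {
  iter_max <- control$iter.max %||% 1000L
  rel_tol <- control$rel.tol %||% 1e-9
  restarts <- control$restarts %||% 3L
  ctl <- list(iter.max = iter_max, eval.max = 10L * iter_max,
              rel.tol = rel_tol)
  best <- NULL
  cur <- start
  for (r in 0:restarts) {
    opt <- tryCatch(
      nlminb(cur, obj, lower = lower, control = ctl),
      error = function(e) NULL
    )
    if (!is.null(opt) && is.finite(opt$objective)) {
      if (is.null(best) || opt$objective < best$objective) best <- opt
      if (opt$convergence == 0) break
    }
    # jittered restart (seeded by the restart index for determinism)
    jit <- with_substream(1L, paste0("fit-restart-", r),
                          rnorm(length(start), 0, 0.05))
    cur <- pmax(start + jit, lower + 1e-4)
  }
  if (is.null(best)) stop("optimizer failed to produce a finite objective")
  gr <- fd_gradient(obj, best$par)
  converged <- best$convergence == 0 || sqrt(sum(gr^2)) < 1e-4
  if (!converged) {
    warning(sprintf(
      "non-convergence: gradient norm %.3g after %d iterations",
      sqrt(sum(gr^2)), best$iterations
    ), call. = FALSE)
  }
  list(par = best$par, objective = best$objective, converged = converged,
       iterations = best$iterations, grad_norm = sqrt(sum(gr^2)))
}

fd_gradient <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x
    xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

fd_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    xp <- x
    xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

fd_hessian <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  fp <- fm <- numeric(k)
  for (i in seq_len(k)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h; xm[i] <- x[i] - h
    fp[i] <- f(xp); fm[i] <- f(xm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        xpp <- x; xpp[i] <- x[i] + h; xpp[j] <- x[j] + h
        xmm <- x; xmm[i] <- x[i] - h; xmm[j] <- x[j] - h
        H[i, j] <- H[j, i] <-
          (f(xpp) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + f(xmm)) /
          (2 * h^2)
      }
    }
  }
  H
}

# ---- DWLS route ----------------------------------------------------------

fit_dwls <- function(cmp, X, se = TRUE, control = list()) {
  spec <- cmp$spec
  pc <- polychoric_matrix(
    X, ordinal = cmp$ov_ordinal,
    missing = if (spec$missing == "pairwise") "pairwise" else "complete"
  )
  s_vec <- vech_lower(pc$rho)
  w <- 1 / pmax(vech_lower(pc$avar), 1e-12)
  p <- cmp$p

  obj <- function(theta) {
    sig <- tryCatch(implied_observed(cmp, theta), error = function(e) NULL)
    if (is.null(sig) || anyNA(sig)) return(1e10)
    sum(w * (s_vec - vech_lower(sig))^2)
  }
  opt <- run_optimizer(obj, cmp$start, cmp$lower, control)
  theta <- setNames(opt$par, cmp$par_names)

  n_mom <- p * (p - 1) / 2
  k <- length(theta)
  n_used <- stats::median(pc$n_pairwise[lower.tri(pc$n_pairwise)])

  vc <- NULL
  if (se) {
    D <- fd_jacobian(function(th) vech_lower(implied_observed(cmp, th)),
                     theta)
    # naive DWLS covariance; the asymptotic covariance of the polychoric
    # vector is approximated as diagonal (its pairwise avars)
    vc <- tryCatch(solve(crossprod(D, w * D)), error = function(e) {
      warning("singular information; pseudo-inverse used", call. = FALSE)
      ginv_sym(crossprod(D, w * D))
    })
    dimnames(vc) <- list(cmp$par_names, cmp$par_names)
  }

  list(
    estimates = theta, vcov = vc,
    chi_square = opt$objective, df = n_mom - k,
    chi_square_null = sum(w * s_vec^2), df_null = n_mom,
    n_used = n_used, converged = opt$converged,
    optimizer = opt[c("iterations", "grad_norm")],
    estimator = "wls",
    sample_moments = pc, implied = implied_observed(cmp, theta)
  )
}

ginv_sym <- function(m, tol = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  pos <- e$values > tol * max(e$values)
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

# ---- complete-data normal-theory ML --------------------------------------

fit_ml_complete <- function(cmp, X, se = TRUE, control = list()) {
  Xc <- as.matrix(X[complete.cases(X), , drop = FALSE])
  n <- nrow(Xc)
  p <- cmp$p
  if (n <= p) stop("too few complete cases (", n, ") for ", p, " variables")
  S <- cov(Xc)
  ldS <- determinant(S, logarithm = TRUE)$modulus

  obj <- function(theta) {
    sig <- tryCatch(implied_observed(cmp, theta), error = function(e) NULL)
    if (is.null(sig) || anyNA(sig)) return(1e10)
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ld <- 2 * sum(log(diag(ch)))
    tr <- sum(diag(chol2inv(ch) %*% S))
    as.numeric(ld + tr - ldS - p)
  }
  opt <- run_optimizer(obj, cmp$start, cmp$lower, control)
  theta <- setNames(opt$par, cmp$par_names)
  k <- length(theta)

  vc <- NULL
  if (se) {
    H <- fd_hessian(obj, theta)
    vc <- tryCatch(2 / (n - 1) * solve(H), error = function(e) {
      warning("singular Hessian; pseudo-inverse used", call. = FALSE)
      2 / (n - 1) * ginv_sym(H)
    })
    dimnames(vc) <- list(cmp$par_names, cmp$par_names)
  }

  f_null <- sum(log(diag(S))) - ldS
  list(
    estimates = theta, vcov = vc,
    chi_square = (n - 1) * opt$objective, df = p * (p + 1) / 2 - k,
    chi_square_null = (n - 1) * f_null, df_null = p * (p + 1) / 2 - p,
    n_used = n, converged = opt$converged,
    optimizer = opt[c("iterations", "grad_norm")],
    estimator = "ml",
    sample_moments = S, implied = implied_observed(cmp, theta)
  )
}

# ---- full-information ML -------------------------------------------------

fit_fiml <- function(cmp, X, se = TRUE, control = list()) {
  Xm <- as.matrix(X)
  keep <- rowSums(!is.na(Xm)) > 0
  Xm <- Xm[keep, , drop = FALSE]
  n <- nrow(Xm)
  p <- cmp$p

  pat <- apply(!is.na(Xm), 1, function(z) paste(as.integer(z),
                                                collapse = ""))
  groups <- split(seq_len(n), pat)

  mu_names <- paste0("mu_", cmp$ov)
  start <- c(cmp$start, setNames(colMeans(Xm, na.rm = TRUE), mu_names))
  lower <- c(cmp$lower, setNames(rep(-Inf, p), mu_names))
  k_str <- length(cmp$start)

  neg2ll <- function(theta_all) {
    theta <- theta_all[seq_len(k_str)]
    mu <- theta_all[k_str + seq_len(p)]
    sig <- tryCatch(implied_observed(cmp, theta), error = function(e) NULL)
    if (is.null(sig) || anyNA(sig)) return(1e10)
    tot <- 0
    for (g in groups) {
      obs <- which(!is.na(Xm[g[1], ]))
      sg <- sig[obs, obs, drop = FALSE]
      ch <- tryCatch(chol(sg), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      z <- sweep(Xm[g, obs, drop = FALSE], 2, mu[obs], "-")
      q <- backsolve(ch, t(z), transpose = TRUE)
      tot <- tot + length(g) * (length(obs) * log(2 * pi) +
                                  2 * sum(log(diag(ch)))) + sum(q^2)
    }
    tot
  }
  opt <- run_optimizer(neg2ll, start, lower, control)
  theta_all <- setNames(opt$par, names(start))
  theta <- theta_all[seq_len(k_str)]

  vc <- NULL
  if (se) {
    H <- fd_hessian(neg2ll, theta_all)
    vc_all <- tryCatch(2 * solve(H), error = function(e) {
      warning("singular Hessian; pseudo-inverse used", call. = FALSE)
      2 * ginv_sym(H)
    })
    vc <- vc_all[seq_len(k_str), seq_len(k_str), drop = FALSE]
    dimnames(vc) <- list(cmp$par_names, cmp$par_names)
  }

  sat <- mvn_em(Xm)
  chisq <- opt$objective - sat$neg2ll
  k <- length(start)
  n_mom <- p * (p + 1) / 2 + p

  # independence baseline: per-variable observed-cell ML
  ll0 <- 0
  for (j in seq_len(p)) {
    xj <- Xm[!is.na(Xm[, j]), j]
    s2 <- mean((xj - mean(xj))^2)
    ll0 <- ll0 + sum(dnorm(xj, mean(xj), sqrt(s2), log = TRUE))
  }
  chisq_null <- (-2 * ll0) - sat$neg2ll

  list(
    estimates = theta, vcov = vc,
    chi_square = max(chisq, 0), df = n_mom - k,
    chi_square_null = max(chisq_null, 0), df_null = n_mom - 2 * p,
    n_used = n, converged = opt$converged,
    optimizer = opt[c("iterations", "grad_norm")],
    estimator = "ml-fiml", means = theta_all[k_str + seq_len(p)],
    implied = implied_observed(cmp, theta)
  )
}

# Saturated Gaussian log-likelihood under missing data via EM.
mvn_em <- function(Xm, max_iter = 500, tol = 1e-8) {
  n <- nrow(Xm)
  p <- ncol(Xm)
  mu <- colMeans(Xm, na.rm = TRUE)
  S <- cov(Xm, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  S <- nearest_psd(S, tol = 1e-8) + diag(1e-6, p)

  pat <- apply(!is.na(Xm), 1, function(z) paste(as.integer(z),
                                                collapse = ""))
  groups <- split(seq_len(n), pat)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    sum_x <- numeric(p)
    sum_xx <- matrix(0, p, p)
    ll <- 0
    for (g in groups) {
      obs <- which(!is.na(Xm[g[1], ]))
      mis <- setdiff(seq_len(p), obs)
      xo <- Xm[g, obs, drop = FALSE]
      So <- S[obs, obs, drop = FALSE]
      ch <- chol(So)
      z <- sweep(xo, 2, mu[obs], "-")
      q <- backsolve(ch, t(z), transpose = TRUE)
      ll <- ll - 0.5 * (length(g) * (length(obs) * log(2 * pi) +
                                       2 * sum(log(diag(ch)))) + sum(q^2))
      xs <- matrix(0, length(g), p)
      xs[, obs] <- xo
      if (length(mis)) {
        B <- solve(So, S[obs, mis, drop = FALSE])
        xm_hat <- sweep(z %*% B, 2, mu[mis], "+")
        xs[, mis] <- xm_hat
        cond_cov <- S[mis, mis, drop = FALSE] -
          t(S[obs, mis, drop = FALSE]) %*% B
        sum_xx[mis, mis] <- sum_xx[mis, mis] + length(g) * cond_cov
      }
      sum_x <- sum_x + colSums(xs)
      sum_xx <- sum_xx + crossprod(xs)
    }
    mu <- sum_x / n
    S <- sum_xx / n - tcrossprod(mu)
    S <- (S + t(S)) / 2 + diag(1e-10, p)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = S, loglik = ll, neg2ll = -2 * ll)
}

# ---- fit indices, standardization, nested tests --------------------------

#' Comparative fit index and RMSEA from chi-square statistics
#'
#' Standard definitions:
#' `CFI = 1 - max(chisq_m - df_m, 0) / max(chisq_m - df_m, chisq_0 - df_0, 0)`
#' and `RMSEA = sqrt(max(chisq_m - df_m, 0) / (df_m * (n - 1)))`.
#'
#' @param chi_sq_model,df_model model chi-square and degrees of freedom.
#' @param chi_sq_null,df_null baseline (independence) model values.
#' @param n sample size.
#' @return Named numeric vector `c(cfi = , rmsea = )`.
#' @examples
#' fit_indices(150, 100, 1100, 120, 1000)
#' @export
fit_indices <- function(chi_sq_model, df_model, chi_sq_null, df_null, n) {
  if (df_model <= 0) stop("df_model must be positive")
  if (n <= 1) stop("n must exceed 1")
  num <- max(chi_sq_model - df_model, 0)
  den <- max(chi_sq_model - df_model, chi_sq_null - df_null, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rmsea <- sqrt(max(chi_sq_model - df_model, 0) / (df_model * (n - 1)))
  c(cfi = cfi, rmsea = rmsea)
}

# Standardized solution: each directed coefficient rescaled by the
# model-implied SDs of its source and target nodes; covariance parameters
# rescaled to correlations.
standardize_solution <- function(cmp, theta) {
  sigma <- implied_covariance(cmp, theta)
  sdv <- sqrt(pmax(diag(sigma), 1e-12))
  pt <- cmp$partable
  free_rows <- which(pt$free)
  out <- c()
  seen <- character()
  for (k in free_rows) {
    lab <- pt$label[k]
    if (lab %in% seen) next
    seen <- c(seen, lab)
    i <- cmp$idx[pt$row[k]]
    j <- cmp$idx[pt$col[k]]
    val <- theta[[lab]]
    std <- if (pt$mat[k] == "A") {
      val * sdv[j] / sdv[i]
    } else if (i != j) {
      val / (sdv[i] * sdv[j])
    } else {
      val / sigma[i, i]
    }
    out[paste0("std_", lab)] <- std
  }
  out
}

#' Standardized structural coefficients of a fitted model
#'
#' Returns the structural coefficients rescaled by the model-implied
#' standard deviations of source and target constructs (binary mediators on
#' their latent-response scale), the form used for the product-of-
#' coefficients effect calculus.
#'
#' @param fit a [fit_sem()] result.
#' @return Named numeric vector (`std_b_*`).
#' @export
standardized_coefficients <- function(fit) {
  stopifnot(inherits(fit, "clp_fit"))
  struct <- names(fit$compiled$par_group)[
    fit$compiled$par_group == "structural"]
  fit$standardized[paste0("std_", struct)]
}

#' Chi-square difference test for nested models
#'
#' Compares a constrained model (e.g. structural paths equal over time)
#' against the free model by the chi-square difference statistic.
#'
#' @param fit_free,fit_constrained [fit_sem()] results on the same data,
#'   the constrained model nested in the free one.
#' @return List with `delta_chi_sq`, `delta_df`, `p_value`.
#' @export
nested_test <- function(fit_free, fit_constrained) {
  d_df <- fit_constrained$df - fit_free$df
  if (d_df < 0) {
    stop("models are not nested: the constrained model has fewer df")
  }
  d_chi <- fit_constrained$chi_square - fit_free$chi_square
  p <- if (d_df > 0) pchisq(max(d_chi, 0), d_df, lower.tail = FALSE) else
    NA_real_
  list(delta_chi_sq = d_chi, delta_df = d_df, p_value = p)
}

#' @export
print.clp_fit <- function(x, ...) {
  cat("<clp_fit>", x$estimator, "estimation,", length(x$estimates),
      "free parameters, n =", x$n_used, "\n")
  cat(sprintf("  chi-square %.3f on %d df;  CFI %.4f  RMSEA %.4f\n",
              x$chi_square, x$df, x$cfi, x$rmsea))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' Write a fitted model to disk
#'
#' Exports a [fit_sem()] result as JSON (estimates, fit statistics,
#' convergence diagnostics) plus a flat CSV of parameter/SE/p rows.
#'
#' @param fit a `clp_fit`.
#' @param stem output path stem; writes `<stem>.json` and `<stem>.csv`.
#' @return Invisibly, the two paths.
#' @export
write_fit <- function(fit, stem) {
  stopifnot(inherits(fit, "clp_fit"))
  json <- paste0(stem, ".json")
  csv <- paste0(stem, ".csv")
  jsonlite::write_json(
    list(
      estimator = fit$estimator,
      n_used = fit$n_used,
      chi_square = fit$chi_square, df = fit$df,
      chi_square_null = fit$chi_square_null, df_null = fit$df_null,
      cfi = fit$cfi, rmsea = fit$rmsea,
      converged = fit$converged,
      optimizer = fit$optimizer,
      estimates = as.list(fit$estimates),
      standardized = as.list(fit$standardized)
    ),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write.csv(parameter_table(fit), csv, row.names = FALSE)
  invisible(c(json = json, csv = csv))
}

#' Export a fitted model as parameter/SE/p rows
#'
#' @param fit a [fit_sem()] result.
#' @return A data.frame with one row per free parameter: estimate, standard
#'   error, z, p (structural rows), and the standardized value.
#' @export
parameter_table <- function(fit) {
  est <- fit$estimates
  se <- if (!is.null(fit$vcov)) sqrt(pmax(diag(fit$vcov), 0)) else
    rep(NA_real_, length(est))
  std <- fit$standardized[paste0("std_", names(est))]
  z <- est / se
  data.frame(
    parameter = names(est),
    group = unname(fit$compiled$par_group[names(est)]),
    estimate = unname(est),
    se = unname(se),
    z = unname(z),
    p = unname(2 * pnorm(-abs(z))),
    std = unname(std),
    row.names = NULL
  )
}
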