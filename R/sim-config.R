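#' Simulation configuration for a synthetic multi-wave panel
#'
#' Defines the generating model for a synthetic occupational-health cohort:
#' a lag-1 linear system over three standardized latent constructs -- an
#' exposure work characteristic (X, demands or support), a mediator behavior
#' propensity (M) and depressive symptoms (Y) -- plus independent
#' autoregressive propensities for the remaining health behaviors and the
#' other work scale. Ordinal questionnaire items and binary behavior
#' indicators are deterministic threshold functions of normal latent
#' responses (probit link), which matches the polychoric/weighted
#' least-squares estimation route used downstream.
#'
#' Each latent construct is kept at unit marginal variance at every wave:
#' innovation variances are derived as \eqn{1 - \mathrm{diag}(B \Sigma B')},
#' so thresholds are interpretable as standard-normal quantiles at all waves
#' and binary prevalences are (approximately) wave-constant. Wave-1 latents
#' are drawn from the correlation fixed point implied by the lag-1 system
#' unless `wave1_cor` overrides it.
#'
#' @param n_subjects number of subjects (positive integer).
#' @param n_waves number of waves (default 4, mapping to the survey years
#'   2008/2010/2012/2014).
#' @param ar named numeric, lag-1 autoregressive coefficients for the three
#'   system constructs `c(X=, M=, Y=)`.
#' @param crosslag cross-lagged coefficients among X, M, Y: either a single
#'   3x3 matrix (rows = target, cols = source; diagonal ignored) applied to
#'   every transition, or a list of length `n_waves - 1` of such matrices.
#' @param exposure which work scale plays the exposure role, `"support"`
#'   (default) or `"demands"`; the other scale is generated as an
#'   independent autoregressive construct.
#' @param mediator which behavior is driven by the M propensity of the
#'   system: one of `"smoking"`, `"alcohol"`, `"diet"`, `"inactivity"`.
#' @param loadings named list of item loadings per construct
#'   (`demands`, `support`, `depressive`), each within (0, 1).
#' @param thresholds named list of strictly increasing item cutpoints on the
#'   standard-normal latent response scale: `demands`/`support` items have 3
#'   cutpoints (4 ordered categories coded 1-4), `depressive` items 4
#'   cutpoints (5 categories coded 0-4).
#' @param behavior_thresholds named numeric of length 4: the latent cutpoint
#'   of each binary behavior; prevalence is `1 - pnorm(threshold)`. Defaults
#'   are calibrated so baseline prevalences are 8.3\% (smoking), 5.2\%
#'   (excessive alcohol), 6.8\% (unhealthy diet) and 16.1\% (inactivity).
#' @param behavior_ar lag-1 autocorrelation of the non-mediator behavior
#'   propensities and the non-exposure work construct.
#' @param residual_cor lag-invariant cross-wave correlation of item-specific
#'   errors, a scalar in [0, 1) (applies to all ordinal items).
#' @param covariate_effects optional named list with numeric vectors `X`,
#'   `M`, `Y`: effects of centered baseline covariates
#'   (age10, female, single, edu) on the wave-1 latent means.
#' @param missingness list with `mechanism` in `c("none","MCAR","MAR")`,
#'   `rate` in [0,1], and for MAR `strength` (log-odds shift per SD of the
#'   wave-1 depressive sum score).
#' @param emit_raw_items if `TRUE`, also emit raw behavior questionnaire
#'   items (smoking status, weekly alcohol units + binge flag or CAGE items,
#'   diet category, exercise frequency) consistent with the binary
#'   indicators, so the scoring rules can be round-tripped.
#' @param allow_nonstationary declare that the lag-1 system is deliberately
#'   explosive; otherwise coefficients implying a non-positive innovation
#'   variance are an error.
#' @param seed master seed; all stages draw from deterministic substreams.
#'
#' @return An object of class `clp_sim_config`.
#' @seealso [generate_panel()], [apply_missingness()], [true_effects()]
#' @export
sim_config <- function(n_subjects,
                       n_waves = 4,
                       ar = c(X = 0.60, M = 0.60, Y = 0.55),
                       crosslag = NULL,
                       exposure = c("support", "demands"),
                       mediator = c("alcohol", "smoking", "diet", "inactivity"),
                       loadings = NULL,
                       thresholds = NULL,
                       behavior_thresholds = NULL,
                       behavior_ar = 0.6,
                       residual_cor = 0.2,
                       covariate_effects = NULL,
                       missingness = list(mechanism = "none", rate = 0),
                       emit_raw_items = FALSE,
                       allow_nonstationary = FALSE,
                       seed = 1L) {
  exposure <- match.arg(exposure)
  mediator <- match.arg(mediator)
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1) {
    stop("n_subjects must be a positive count")
  }
  n_subjects <- as.integer(n_subjects)
  n_waves <- as.integer(n_waves)
  if (n_waves < 2) stop("n_waves must be at least 2")

  stopifnot(all(c("X", "M", "Y") %in% names(ar)))
  ar <- ar[c("X", "M", "Y")]

  B_list <- build_transition_matrices(ar, crosslag, n_waves)

  loadings <- modify_defaults(default_loadings(), loadings)
  thresholds <- modify_defaults(default_item_thresholds(), thresholds)
  for (sc in names(thresholds)) {
    for (i in seq_along(thresholds[[sc]])) {
      cuts <- thresholds[[sc]][[i]]
      if (any(diff(cuts) <= 0)) {
        stop("item thresholds must be strictly increasing (", sc, ")")
      }
    }
  }
  n_cuts <- list(demands = 3L, support = 3L, depressive = 4L)
  for (sc in names(n_cuts)) {
    if (length(loadings[[sc]]) != length(thresholds[[sc]])) {
      stop("loadings and thresholds disagree on item count for ", sc)
    }
    if (any(vapply(thresholds[[sc]], length, 1L) != n_cuts[[sc]])) {
      stop(sc, " items need ", n_cuts[[sc]], " cutpoints")
    }
  }

  behavior_thresholds <- modify_defaults(
    default_behavior_thresholds(), behavior_thresholds,
    as_list = FALSE
  )
  if (!is.numeric(residual_cor) || residual_cor < 0 || residual_cor >= 1) {
    stop("residual_cor must lie in [0, 1)")
  }

  missingness <- modify_defaults(
    list(mechanism = "none", rate = 0, strength = 1), missingness
  )
  if (!missingness$mechanism %in% c("none", "MCAR", "MAR")) {
    stop("unknown missingness mechanism: ", missingness$mechanism)
  }
  if (missingness$rate < 0 || missingness$rate > 1) {
    stop("missingness rate must lie in [0, 1]")
  }

  cov_default <- list(
    X = c(age10 = 0, female = 0, single = 0, edu = 0),
    M = c(age10 = 0, female = 0, single = 0, edu = 0),
    Y = c(age10 = 0, female = 0, single = 0, edu = 0)
  )
  covariate_effects <- modify_defaults(cov_default, covariate_effects)

  cfg <- structure(
    list(
      n_subjects = n_subjects,
      n_waves = n_waves,
      ar = ar,
      B_list = B_list,
      exposure = exposure,
      mediator = mediator,
      loadings = loadings,
      thresholds = thresholds,
      behavior_thresholds = behavior_thresholds,
      behavior_ar = behavior_ar,
      residual_cor = residual_cor,
      covariate_effects = covariate_effects,
      missingness = missingness,
      emit_raw_items = emit_raw_items,
      allow_nonstationary = allow_nonstationary,
      seed = as.integer(seed)
    ),
    class = "clp_sim_config"
  )
  # innovation variances must stay positive along the recursion
  sig <- latent_wave_covariances(cfg)
  if (!allow_nonstationary && any(unlist(lapply(sig$psi, diag)) <= 0)) {
    stop(
      "lag-1 coefficients imply non-positive innovation variance; ",
      "declare allow_nonstationary or reduce the coefficients"
    )
  }
  cfg
}

build_transition_matrices <- function(ar, crosslag, n_waves) {
  cn <- c("X", "M", "Y")
  base <- diag(ar)
  dimnames(base) <- list(cn, cn)
  n_tr <- n_waves - 1L
  if (is.null(crosslag)) {
    return(rep(list(base), n_tr))
  }
  as_full <- function(cl) {
    cl <- as.matrix(cl)
    stopifnot(identical(dim(cl), c(3L, 3L)))
    dimnames(cl) <- list(cn, cn)
    b <- cl
    diag(b) <- ar
    b
  }
  if (is.list(crosslag)) {
    if (length(crosslag) != n_tr) {
      stop("crosslag list must have n_waves - 1 elements")
    }
    lapply(crosslag, as_full)
  } else {
    rep(list(as_full(crosslag)), n_tr)
  }
}

default_loadings <- function() {
  list(
    demands = c(0.70, 0.75, 0.65, 0.70),
    support = c(0.75, 0.80, 0.70, 0.72, 0.68),
    depressive = c(0.80, 0.78, 0.75, 0.70, 0.72, 0.76)
  )
}

# Cutpoints calibrated so composite means match baseline descriptives:
# demands item mean 2.6 (scale 1-4), support 3.1 (1-4),
# depressive item mean 0.9 (0-4, so the 6-item sum averages 5.4).
default_item_thresholds <- function() {
  dem <- qnorm(c(0.12, 0.45, 0.83))
  sup <- qnorm(c(0.05, 0.20, 0.65))
  dep <- qnorm(c(0.55, 0.75, 0.85, 0.95))
  list(
    demands = rep(list(dem), 4),
    support = rep(list(sup), 5),
    depressive = rep(list(dep), 6)
  )
}

# Baseline prevalences: smoking 8.3%, excessive alcohol 5.2%,
# unhealthy diet 6.8%, physical inactivity 16.1%.
default_behavior_thresholds <- function() {
  c(
    smoking = qnorm(1 - 0.083),
    alcohol = qnorm(1 - 0.052),
    diet = qnorm(1 - 0.068),
    inactivity = qnorm(1 - 0.161)
  )
}

modify_defaults <- function(defaults, user, as_list = TRUE) {
  if (is.null(user)) {
    return(defaults)
  }
  if (!as_list) {
    defaults[names(user)] <- user
    return(defaults)
  }
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  defaults
}

# Per-wave latent covariance bookkeeping for the standardized lag-1 system:
# Sigma_1 is the correlation fixed point of Sigma -> B Sigma B' + Psi(Sigma)
# with Psi diagonal chosen to keep unit variances; psi[[t]] is the
# innovation covariance used at transition t.
latent_wave_covariances <- function(cfg) {
  B_list <- cfg$B_list
  sigma <- diag(3)
  # fixed point under the first transition matrix
  for (i in 1:200) {
    nxt <- B_list[[1]] %*% sigma %*% t(B_list[[1]])
    diag_psi <- 1 - diag(nxt)
    nxt <- nxt + diag(diag_psi)
    if (max(abs(nxt - sigma)) < 1e-12) {
      sigma <- nxt
      break
    }
    sigma <- nxt
  }
  sigmas <- vector("list", cfg$n_waves)
  psi <- vector("list", cfg$n_waves - 1L)
  sigmas[[1]] <- sigma
  for (t in seq_len(cfg$n_waves - 1L)) {
    prop <- B_list[[t]] %*% sigmas[[t]] %*% t(B_list[[t]])
    psi[[t]] <- diag(1 - diag(prop))
    sigmas[[t + 1]] <- prop + psi[[t]]
  }
  list(sigma = sigmas, psi = psi)
}

#' @export
print.clp_sim_config <- function(x, ...) {
  cat("<clp_sim_config>\n")
  cat("  subjects:", x$n_subjects, " waves:", x$n_waves, "\n")
  cat("  exposure:", x$exposure, " mediator:", x$mediator, "\n")
  cat("  AR:", paste(sprintf("%s=%.2f", names(x$ar), x$ar), collapse = " "), "\n")
  cl <- x$B_list[[1]]
  diag(cl) <- 0
  if (any(cl != 0)) {
    nz <- which(cl != 0, arr.ind = TRUE)
    cat("  cross-lags (transition 1):",
        paste(sprintf(
          "%s->%s=%.2f", colnames(cl)[nz[, 2]], rownames(cl)[nz[, 1]],
          cl[nz]
        ), collapse = " "), "\n")
  } else {
    cat("  cross-lags: none\n")
  }
  cat("  missingness:", x$missingness$mechanism,
      "rate", x$missingness$rate, "\n")
  invisible(x)
}
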