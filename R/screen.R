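#' Fit a bivariate cross-lagged screening model
#'
#' Fits the two-construct autoregressive cross-lagged model for one pair
#' (e.g. support-alcohol, alcohol-depressive): lag-1 stability paths for
#' both constructs and cross-lagged paths in both directions, free per
#' transition, with within-wave covariances and (for the latent engine)
#' cross-wave item-error covariances. Reports wave-specific standardized
#' estimates and two-sided significance at `alpha` for both directions;
#' reverse-direction paths are always reported but never used for gating.
#'
#' @param data wide panel containing the pair's columns (items and/or
#'   derived indicators; see [derive_variables()]).
#' @param pair named list of two construct definitions in `A`, `B` order,
#'   each as in [clpm_spec()] (for the latent engine), or for
#'   `engine = "composite"` simply the two column stems, e.g.
#'   `c("support", "alcohol")`.
#' @param engine `"sem"`: latent/ordinal model via [fit_sem()];
#'   `"composite"`: observed-score path model via [fit_path_model()]
#'   (composite scores and indicators treated as continuous -- the rapid
#'   screening engine).
#' @param estimator passed to [clpm_spec()] for the sem engine.
#' @param covariates optional baseline covariate columns (adjustment).
#' @param n_waves number of waves.
#' @param alpha per-path two-sided significance level (default 0.05, no
#'   multiplicity correction -- deliberately liberal screening).
#' @return An object of class `clp_screen`: `pair` (construct names),
#'   `table` (transition, direction, beta (standardized), se, p, sig),
#'   `any_ab`, `any_ba` (any significant path per direction), and the
#'   underlying fit.
#' @export
fit_bivariate <- function(data, pair, engine = c("sem", "composite"),
                          estimator = "wls", covariates = NULL,
                          n_waves = 4, alpha = 0.05) {
  engine <- match.arg(engine)
  if (engine == "composite") {
    stems <- if (is.list(pair)) names(pair) else pair
    stopifnot(length(stems) == 2)
    fit <- fit_path_model(data, constructs = stems, n_waves = n_waves,
                          edges = "full", covariates = covariates,
                          standardize = TRUE)
    est <- fit$estimates
    se <- sqrt(diag(fit$vcov))
    keep <- grepl("^b_", names(est))
    info <- lapply(names(est)[keep], parse_edge_name)
    tab <- data.frame(
      transition = vapply(info, function(z) z$t, 1L),
      from = vapply(info, function(z) z$src, ""),
      to = vapply(info, function(z) z$tgt, ""),
      beta = unname(est[keep]),
      se = unname(se[keep])
    )
  } else {
    stopifnot(is.list(pair), length(pair) == 2, !is.null(names(pair)))
    stems <- names(pair)
    spec <- clpm_spec(pair, n_waves = n_waves, structural = "full",
                      constraints = "free", estimator = estimator,
                      covariates = covariates)
    fit <- fit_sem(spec, data)
    struct <- names(fit$p_values)
    info <- lapply(struct, parse_edge_name)
    tab <- data.frame(
      transition = vapply(info, function(z) z$t, 1L),
      from = vapply(info, function(z) z$src, ""),
      to = vapply(info, function(z) z$tgt, ""),
      beta = unname(fit$standardized[paste0("std_", struct)]),
      se = unname(sqrt(pmax(diag(fit$vcov)[struct], 0)))
    )
  }
  tab <- tab[tab$from != tab$to, , drop = FALSE] # cross-lags only
  tab$direction <- paste0(tab$from, "->", tab$to)
  z <- tab$beta / tab$se
  if (engine == "sem") {
    # Wald tests on the raw coefficients (same z up to standardization)
    raw <- paste0("b_", tab$from, ".", tab$to, "_t", tab$transition)
    z <- fit$estimates[raw] /
      sqrt(pmax(diag(fit$vcov)[raw], .Machine$double.eps))
  }
  tab$p <- 2 * pnorm(-abs(z))
  tab$sig <- tab$p < alpha
  tab <- tab[order(tab$direction, tab$transition),
             c("transition", "direction", "beta", "se", "p", "sig")]
  rownames(tab) <- NULL

  ab <- paste0(stems[1], "->", stems[2])
  structure(
    list(
      pair = stems, table = tab, alpha = alpha,
      any_ab = any(tab$sig[tab$direction == ab]),
      any_ba = any(tab$sig[tab$direction != ab]),
      n_significant = c(
        ab = sum(tab$sig[tab$direction == ab]),
        ba = sum(tab$sig[tab$direction != ab])
      ),
      engine = engine, fit = fit
    ),
    class = "clp_screen"
  )
}

#' @export
print.clp_screen <- function(x, ...) {
  cat("<clp_screen>", paste(x$pair, collapse = " <-> "),
      sprintf("(%s engine)\n", x$engine))
  print(x$table, digits = 3)
  cat(sprintf("  significant paths: %s->%s: %d of %d; reverse: %d of %d\n",
              x$pair[1], x$pair[2], x$n_significant[["ab"]],
              sum(x$table$direction == paste0(x$pair[1], "->", x$pair[2])),
              x$n_significant[["ba"]],
              sum(x$table$direction != paste0(x$pair[1], "->", x$pair[2]))))
  invisible(x)
}

#' Gating rule for fitting a mediation model
#'
#' A mediation model is fitted for a behavior only when the bivariate
#' screens show at least one significant cross-lagged path from the
#' exposure to the behavior *and* at least one from the behavior to the
#' outcome. Reverse-direction paths never enter the decision. The decision
#' is a pure function of the two screens' significance flags.
#'
#' @param screen_xm `clp_screen` for (exposure, mediator).
#' @param screen_my `clp_screen` for (mediator, outcome).
#' @return List of class `clp_gate`: `open` (logical),
#'   `exposure_to_mediator_any_significant`,
#'   `mediator_to_outcome_any_significant`, and the counts.
#' @export
gate_mediation <- function(screen_xm, screen_my) {
  if (!inherits(screen_xm, "clp_screen") ||
        !inherits(screen_my, "clp_screen")) {
    stop("both screens are required for the gate")
  }
  xm <- screen_xm$any_ab
  my <- screen_my$any_ab
  structure(
    list(
      open = xm && my,
      exposure_to_mediator_any_significant = xm,
      mediator_to_outcome_any_significant = my,
      n_significant = c(exposure_mediator = screen_xm$n_significant[["ab"]],
                        mediator_outcome = screen_my$n_significant[["ab"]])
    ),
    class = "clp_gate"
  )
}

#' @export
print.clp_gate <- function(x, ...) {
  cat("<clp_gate>", if (x$open) "OPEN: mediation model to be fitted"
      else "CLOSED: no mediation model fitted", "\n")
  cat("  exposure->mediator significant paths:",
      x$n_significant[["exposure_mediator"]], "\n")
  cat("  mediator->outcome significant paths:",
      x$n_significant[["mediator_outcome"]], "\n")
  invisible(x)
}

#' Screening table shaped like the bivariate-model figure annotations
#'
#' One row per (transition, direction) with the standardized coefficient,
#' its standard error, p-value and a significance star.
#'
#' @param screens list of `clp_screen` objects.
#' @return data.frame with columns pair, transition, direction, beta, se,
#'   p, star.
#' @export
screening_table <- function(screens) {
  rows <- lapply(screens, function(s) {
    cbind(pair = paste(s$pair, collapse = "-"), s$table,
          star = ifelse(s$table$sig, "*", ""))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("pair", "transition", "direction", "beta", "se", "p", "star")]
}
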