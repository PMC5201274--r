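#' Fit a three-construct autoregressive mediation model
#'
#' Fits the exposure-mediator-outcome cross-lagged system over all waves
#' and decomposes the overall effect of the exposure at wave 1 on the
#' outcome at the last wave into total, direct and indirect parts by the
#' product-of-coefficients method, with Monte Carlo simulation confidence
#' intervals.
#'
#' The fitted model contains autoregressive paths, cross-lagged paths in
#' both directions and within-wave covariances; only the forward lag-1
#' edges (exposure -> {exposure, mediator, outcome}, mediator ->
#' {mediator, outcome}, outcome -> outcome) enter the path products, as in
#' the graphical convention where reverse arrows are estimated but excluded
#' from the effect calculus. Standardized coefficients are used throughout
#' (recommended with dichotomous mediators); Monte Carlo draws are taken
#' over the structural coefficients only, on the standardized scale via
#' their delta-method covariance, with measurement parameters held fixed.
#'
#' @param data wide panel with the constructs' columns.
#' @param constructs named list of three construct definitions in
#'   (exposure, mediator, outcome) order -- see [clpm_spec()] -- or, for
#'   `engine = "composite"`, a character vector of three column stems.
#' @param engine `"sem"` (latent/ordinal) or `"composite"`
#'   (observed-score path model).
#' @param estimator passed to [clpm_spec()] for the sem engine.
#' @param covariates optional baseline covariate columns.
#' @param n_waves number of waves.
#' @param n_draws Monte Carlo draws for the intervals (default 20000).
#' @param level interval level (default 0.95).
#' @param seed seed for the Monte Carlo draws.
#' @return A `clp_mediation` object: the `clp_effects` decomposition
#'   (`$effects`), the underlying fit (`$fit`), the structural graph
#'   (`$graph`) and a per-path breakdown (`$path_table`).
#' @export
fit_mediation <- function(data, constructs,
                          engine = c("sem", "composite"),
                          estimator = "wls", covariates = NULL,
                          n_waves = 4, n_draws = 20000, level = 0.95,
                          seed = 1L) {
  engine <- match.arg(engine)
  if (engine == "composite") {
    stems <- if (is.list(constructs)) names(constructs) else constructs
    stopifnot(length(stems) == 3)
    fit <- fit_path_model(data, constructs = stems, n_waves = n_waves,
                          edges = "forward", covariates = covariates,
                          standardize = TRUE)
    graph <- fit$graph
    mc_fit <- fit
  } else {
    stopifnot(is.list(constructs), length(constructs) == 3)
    stems <- names(constructs)
    spec <- clpm_spec(constructs, n_waves = n_waves, structural = "full",
                      constraints = "free", estimator = estimator,
                      covariates = covariates)
    fit <- fit_sem(spec, data)
    gp <- forward_graph_from_fit(fit, stems)
    graph <- gp$graph
    mc_fit <- gp$mc_fit
  }
  eff <- monte_carlo_ci(mc_fit, graph, n_draws = n_draws, level = level,
                        seed = seed, mediator = stems[2])
  paths <- eff$paths
  pt <- data.frame(
    path = c(paths$labels$indirect, paths$labels$direct),
    kind = c(rep("indirect", length(paths$indirect)),
             rep("direct", length(paths$direct))),
    product = c(eff$path_products$indirect, eff$path_products$direct)
  )
  pt$share_of_kind <- ifelse(
    pt$kind == "indirect",
    pt$product / sum(eff$path_products$indirect),
    pt$product / sum(eff$path_products$direct)
  )
  structure(
    list(effects = eff, fit = fit, graph = graph, path_table = pt,
         constructs = stems, engine = engine),
    class = "clp_mediation"
  )
}

# Builds the forward-edge structural graph of a fitted latent model on the
# standardized scale, plus the estimate/covariance pair the Monte Carlo
# draws are taken from.
forward_graph_from_fit <- function(fit, stems) {
  n_waves <- fit$spec$n_waves
  ord <- setNames(seq_along(stems), stems)
  struct <- names(fit$compiled$par_group)[
    fit$compiled$par_group == "structural"]
  B_list <- vector("list", n_waves - 1L)
  P_list <- vector("list", n_waves - 1L)
  used <- character()
  for (t in seq_len(n_waves - 1L)) {
    B <- matrix(0, 3, 3, dimnames = list(stems, stems))
    P <- matrix(NA_character_, 3, 3, dimnames = list(stems, stems))
    for (nm in struct) {
      info <- parse_edge_name(nm)
      if (info$t != t || ord[info$src] > ord[info$tgt]) next
      std_nm <- paste0("std_", nm)
      B[info$tgt, info$src] <- fit$standardized[[std_nm]]
      P[info$tgt, info$src] <- std_nm
      used <- c(used, std_nm)
    }
    B_list[[t]] <- B
    P_list[[t]] <- P
  }
  graph <- structural_graph(B_list, constructs = stems,
                            par_list = P_list)
  est <- fit$standardized[paste0("std_", struct)]
  V <- fit$std_vcov
  if (is.null(V)) stop("fit carries no standardized covariance; ",
                       "refit with se = TRUE")
  list(graph = graph,
       mc_fit = list(estimates = est, vcov = V))
}

#' @export
print.clp_mediation <- function(x, ...) {
  cat("<clp_mediation>", paste(x$constructs, collapse = " -> "),
      sprintf("(%s engine)\n", x$engine))
  print(x$effects)
  invisible(x)
}

#' Mediation summary table (one row per mediator model)
#'
#' Collects effect decompositions into the familiar three-column layout:
#' total, direct and indirect effect with percentile confidence intervals
#' and significance markers, plus the proportion mediated.
#'
#' @param decompositions named list of `clp_mediation` or `clp_effects`
#'   objects (names label the rows, e.g. `"support-alcohol-depressive"`).
#' @return data.frame of class `clp_mediation_table` with attribute
#'   `status` = `"ok"`, or -- for an empty list, as when every gate closed
#'   -- an empty table with the same header and `status` = `"gate-closed"`.
#' @export
mediation_report <- function(decompositions) {
  cols <- c("model", "total", "total_lower", "total_upper", "total_sig",
            "direct", "direct_lower", "direct_upper", "direct_sig",
            "indirect", "indirect_lower", "indirect_upper",
            "indirect_sig", "proportion_mediated", "n_draws")
  if (!length(decompositions)) {
    out <- as.data.frame(setNames(
      c(list(character()), rep(list(numeric()), 13), list(integer())),
      cols
    ))
    attr(out, "status") <- "gate-closed"
    class(out) <- c("clp_mediation_table", "data.frame")
    return(out)
  }
  rows <- lapply(names(decompositions), function(nm) {
    d <- decompositions[[nm]]
    eff <- if (inherits(d, "clp_mediation")) d$effects else d
    data.frame(
      model = nm,
      total = eff$total,
      total_lower = eff$ci["total", "lower"],
      total_upper = eff$ci["total", "upper"],
      total_sig = unname(eff$significant[["total"]]),
      direct = eff$direct,
      direct_lower = eff$ci["direct", "lower"],
      direct_upper = eff$ci["direct", "upper"],
      direct_sig = unname(eff$significant[["direct"]]),
      indirect = eff$indirect,
      indirect_lower = eff$ci["indirect", "lower"],
      indirect_upper = eff$ci["indirect", "upper"],
      indirect_sig = unname(eff$significant[["indirect"]]),
      proportion_mediated = eff$proportion_mediated,
      n_draws = eff$n_draws
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "status") <- "ok"
  class(out) <- c("clp_mediation_table", "data.frame")
  out
}

#' @export
print.clp_mediation_table <- function(x, ...) {
  if (!nrow(x)) {
    cat("No mediation model fitted (gate closed for every mediator).\n")
    return(invisible(x))
  }
  fmt <- function(e, lo, hi, s) {
    sprintf("%.5f (%.5f to %.5f)%s", e, lo, hi, ifelse(s, " *", ""))
  }
  df <- data.frame(
    Model = x$model,
    `Total effect (95% CI)` = fmt(x$total, x$total_lower, x$total_upper,
                                  x$total_sig),
    `Direct effect (95% CI)` = fmt(x$direct, x$direct_lower,
                                   x$direct_upper, x$direct_sig),
    `Indirect effect (95% CI)` = fmt(x$indirect, x$indirect_lower,
                                     x$indirect_upper, x$indirect_sig),
    check.names = FALSE
  )
  print(df, right = FALSE, row.names = FALSE)
  invisible(x)
}
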