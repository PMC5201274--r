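#' Structural graph of a cross-lagged panel system
#'
#' Represents the structural part of a fitted (or generating) cross-lagged
#' model as a directed acyclic graph on (construct, wave) nodes with lag-1
#' edges carrying standardized coefficients. Edge coefficients may be tied
#' to named entries of an estimate vector so that Monte Carlo draws can be
#' propagated through the graph.
#'
#' @param B_list list of per-transition coefficient matrices (rows = target
#'   construct, columns = source construct), length `n_waves - 1`. Entries
#'   equal to zero with no parameter label are omitted from the graph.
#' @param constructs construct names; defaults to the row names of the first
#'   matrix, or `c("X", "M", "Y")`.
#' @param par_list optional list parallel to `B_list` of character matrices
#'   giving, for each retained edge, the name of the coefficient in the
#'   estimate vector (`NA` for fixed edges).
#' @return An object of class `clp_graph` with elements `edges` (data.frame:
#'   `from`, `from_wave`, `to`, `to_wave`, `coef`, `par`) and `n_waves`.
#' @examples
#' B <- matrix(c(.6, .3, 0, 0, .5, .4, 0, 0, .5), 3, 3, byrow = TRUE,
#'             dimnames = list(c("X", "M", "Y"), c("X", "M", "Y")))
#' g <- structural_graph(list(B, B, B))
#' enumerate_paths(g)
#' @export
structural_graph <- function(B_list, constructs = NULL, par_list = NULL) {
  stopifnot(is.list(B_list), length(B_list) >= 1)
  if (is.null(constructs)) {
    constructs <- rownames(B_list[[1]]) %||% c("X", "M", "Y")
  }
  n_waves <- length(B_list) + 1L
  rows <- list()
  for (t in seq_along(B_list)) {
    B <- as.matrix(B_list[[t]])
    P <- if (!is.null(par_list)) par_list[[t]] else
      matrix(NA_character_, nrow(B), ncol(B))
    for (i in seq_len(nrow(B))) {
      for (j in seq_len(ncol(B))) {
        if (B[i, j] != 0 || !is.na(P[i, j])) {
          rows[[length(rows) + 1L]] <- data.frame(
            from = constructs[j], from_wave = t,
            to = constructs[i], to_wave = t + 1L,
            coef = B[i, j], par = P[i, j],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(), from_wave = integer(),
               to = character(), to_wave = integer(),
               coef = numeric(), par = character())
  structure(
    list(edges = edges, constructs = constructs, n_waves = n_waves),
    class = "clp_graph"
  )
}

#' Enumerate wave-spanning paths from exposure to outcome
#'
#' Exhaustively lists all forward directed paths from the exposure construct
#' at the first wave to the outcome construct at the last wave. A path is
#' classified as *indirect* if it visits the mediator construct at least
#' once, and *direct* otherwise -- the classification used by the
#' product-of-coefficients method.
#'
#' @param graph a [structural_graph()].
#' @param source,sink node labels `"construct@wave"`; default `X` at wave 1
#'   and `Y` at the last wave.
#' @param mediator construct name whose visit makes a path indirect.
#' @return A list with `indirect` and `direct`, each a list of integer
#'   vectors of row indices into `graph$edges`, plus `labels` giving each
#'   path as a human-readable string.
#' @export
enumerate_paths <- function(graph, source = NULL, sink = NULL,
                            mediator = "M") {
  stopifnot(inherits(graph, "clp_graph"))
  xcon <- graph$constructs[1]
  ycon <- graph$constructs[length(graph$constructs)]
  source <- source %||% paste0(xcon, "@1")
  sink <- sink %||% paste0(ycon, "@", graph$n_waves)
  parse_node <- function(s) {
    parts <- strsplit(s, "@", fixed = TRUE)[[1]]
    list(con = parts[1], wave = as.integer(parts[2]))
  }
  src <- parse_node(source)
  snk <- parse_node(sink)
  if (!src$con %in% graph$constructs || !snk$con %in% graph$constructs) {
    stop("source or sink construct absent from the graph")
  }
  if (src$wave >= snk$wave) stop("source must precede sink")

  e <- graph$edges
  paths <- list()
  walk <- function(con, wave, trail) {
    if (wave == snk$wave) {
      if (con == snk$con) paths[[length(paths) + 1L]] <<- trail
      return(invisible())
    }
    nxt <- which(e$from == con & e$from_wave == wave)
    for (k in nxt) walk(e$to[k], e$to_wave[k], c(trail, k))
  }
  walk(src$con, src$wave, integer())

  visits_mediator <- vapply(paths, function(tr) {
    any(e$to[tr] == mediator) || src$con == mediator
  }, logical(1))
  label <- vapply(paths, function(tr) {
    nodes <- c(paste0(e$from[tr[1]], e$from_wave[tr[1]]),
               paste0(e$to[tr], e$to_wave[tr]))
    paste(nodes, collapse = " -> ")
  }, character(1))
  list(
    indirect = paths[visits_mediator],
    direct = paths[!visits_mediator],
    labels = list(indirect = label[visits_mediator],
                  direct = label[!visits_mediator])
  )
}

#' Total, direct and indirect effects by product of coefficients
#'
#' Computes the overall total, direct and indirect standardized effects of
#' the exposure at the first wave on the outcome at the last wave: the
#' indirect effect sums, over every forward path passing through the
#' mediator at least once, the product of the standardized coefficients
#' along the path; the direct effect sums the products over all remaining
#' forward paths; the total is their sum. The proportion mediated is
#' `indirect / total`, flagged non-interpretable when the total is
#' numerically zero.
#'
#' @param graph a [structural_graph()] whose edge coefficients are
#'   standardized estimates (or generating values).
#' @param paths optionally, the output of [enumerate_paths()] (recomputed
#'   otherwise).
#' @param mediator construct defining indirectness, default `"M"`.
#' @return An object of class `clp_effects` with elements `total`, `direct`,
#'   `indirect` (point estimates), `proportion_mediated`, `paths`, and
#'   per-path products in `path_products`.
#' @export
effect_decomposition <- function(graph, paths = NULL, mediator = "M") {
  stopifnot(inherits(graph, "clp_graph"))
  paths <- paths %||% enumerate_paths(graph, mediator = mediator)
  coefs <- graph$edges$coef
  if (anyNA(coefs)) stop("missing coefficient on a structural edge")
  prods <- function(pl) vapply(pl, function(tr) prod(coefs[tr]), numeric(1))
  ip <- prods(paths$indirect)
  dp <- prods(paths$direct)
  indirect <- sum(ip)
  direct <- sum(dp)
  total <- direct + indirect
  structure(
    list(
      total = total, direct = direct, indirect = indirect,
      proportion_mediated = if (abs(total) > 10 * .Machine$double.eps) {
        indirect / total
      } else {
        NA_real_
      },
      paths = paths,
      path_products = list(indirect = ip, direct = dp),
      ci = NULL, n_draws = 0L, level = NA_real_, seed = NA_integer_
    ),
    class = "clp_effects"
  )
}

#' Monte Carlo simulation confidence intervals for mediation effects
#'
#' Draws coefficient vectors from a multivariate normal distribution
#' centered at the structural estimates with their estimated covariance,
#' recomputes the total, direct and indirect effects for every draw by the
#' product-of-coefficients path calculus, and reports percentile intervals.
#' The identity `total = direct + indirect` holds in every draw. An effect
#' is flagged significant when its interval excludes zero.
#'
#' @param fit either a fitted model (class `clp_fit` or `clp_path_fit`) or a
#'   list with named `estimates` and `vcov` covering every edge parameter of
#'   the graph.
#' @param graph a [structural_graph()] whose `par` column names coefficients
#'   in `fit$estimates`; edges with `par = NA` are held fixed at their
#'   coefficient value.
#' @param n_draws number of Monte Carlo draws (default 20000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; results are deterministic given it.
#' @param mediator construct defining indirectness.
#' @return A `clp_effects` object with `ci` (rows `total`, `direct`,
#'   `indirect`; columns `lower`, `upper`), `significant` flags,
#'   `proportion_mediated` (flagged uninterpretable unless the total's
#'   interval excludes zero), `n_draws`, `level` and `seed`.
#' @export
monte_carlo_ci <- function(fit, graph, n_draws = 20000, level = 0.95,
                           seed = 1L, mediator = "M") {
  stopifnot(inherits(graph, "clp_graph"))
  est <- fit$estimates
  V <- fit$vcov
  pars <- unique(stats::na.omit(graph$edges$par))
  missing_pars <- setdiff(pars, names(est))
  if (length(missing_pars)) {
    stop("estimates missing for edge parameters: ",
         paste(missing_pars, collapse = ", "))
  }
  V <- as.matrix(V)[pars, pars, drop = FALSE]
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    warning("coefficient covariance not PSD; nearest-PSD repair applied")
    V <- nearest_psd(V)
  }

  paths <- enumerate_paths(graph, mediator = mediator)
  point <- effect_decomposition(graph, paths, mediator = mediator)

  draws <- with_substream(seed, "mc-ci", rmvn(n_draws, est[pars], V))
  colnames(draws) <- pars

  # per-edge coefficient columns (fixed edges replicated as constants)
  e <- graph$edges
  edge_col <- function(k) {
    if (is.na(e$par[k])) rep(e$coef[k], n_draws) else draws[, e$par[k]]
  }
  path_sum <- function(pl) {
    if (!length(pl)) return(rep(0, n_draws))
    acc <- rep(0, n_draws)
    for (tr in pl) {
      prod_k <- edge_col(tr[1])
      for (k in tr[-1]) prod_k <- prod_k * edge_col(k)
      acc <- acc + prod_k
    }
    acc
  }
  ind_d <- path_sum(paths$indirect)
  dir_d <- path_sum(paths$direct)
  tot_d <- ind_d + dir_d

  alpha <- (1 - level) / 2
  qs <- function(x) unname(quantile(x, c(alpha, 1 - alpha)))
  ci <- rbind(total = qs(tot_d), direct = qs(dir_d), indirect = qs(ind_d))
  colnames(ci) <- c("lower", "upper")
  sig <- ci[, "lower"] > 0 | ci[, "upper"] < 0

  point$ci <- ci
  point$significant <- sig
  point$n_draws <- as.integer(n_draws)
  point$level <- level
  point$seed <- as.integer(seed)
  point$proportion_interpretable <-
    sig[["total"]] && abs(point$total) > 10 * .Machine$double.eps
  point
}

#' @export
print.clp_effects <- function(x, ...) {
  cat("<clp_effects> product-of-coefficients decomposition\n")
  fmt <- function(nm) {
    v <- x[[nm]]
    if (!is.null(x$ci)) {
      sprintf("  %-9s %+.5f  [%+.5f, %+.5f]%s", nm, v,
              x$ci[nm, "lower"], x$ci[nm, "upper"],
              if (isTRUE(x$significant[[nm]])) " *" else "")
    } else {
      sprintf("  %-9s %+.5f", nm, v)
    }
  }
  cat(fmt("total"), fmt("direct"), fmt("indirect"), sep = "\n")
  if (!is.na(x$proportion_mediated)) {
    cat(sprintf("  proportion mediated: %.4f%s\n", x$proportion_mediated,
                if (isFALSE(x$proportion_interpretable)) {
                  " (not interpretable)"
                } else {
                  ""
                }))
  } else {
    cat("  proportion mediated: undefined (total ~ 0)\n")
  }
  if (x$n_draws > 0) {
    cat(sprintf("  %d Monte Carlo draws, %.0f%% percentile intervals\n",
                x$n_draws, 100 * x$level))
  }
  invisible(x)
}

#' Exact generating effects of a simulation configuration
#'
#' Computes the exact overall total, direct and indirect effects of the
#' exposure at wave 1 on depressive symptoms at the last wave implied by the
#' generating lag-1 coefficient matrices, using the same path calculus as
#' the estimation side ([effect_decomposition()]). Because the generating
#' system is standardized (unit latent variance at each wave), the
#' generating coefficients are already standardized coefficients. Serves as
#' ground truth for parameter- and effect-recovery studies.
#'
#' @param config a [sim_config()].
#' @return A `clp_effects` object (point estimates only; no intervals).
#' @export
true_effects <- function(config) {
  stopifnot(inherits(config, "clp_sim_config"))
  g <- structural_graph(config$B_list, constructs = c("X", "M", "Y"))
  effect_decomposition(g)
}
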