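#' Fit an observed-variable cross-lagged path model by equation-wise OLS
#'
#' For a recursive lag-1 panel system on observed scores, the normal-theory
#' maximum-likelihood estimates factorize into one regression per
#' construct-wave: each wave-`t+1` variable regressed on its wave-`t`
#' predictors. This gives exact estimates and an exact block-diagonal
#' coefficient covariance at a fraction of the cost of the general SEM
#' optimizer, and is the engine used for replicated simulations (interval
#' coverage, null calibration) and rapid screening on composite scores.
#'
#' @param data data.frame with columns `<construct>_<wave>`.
#' @param constructs character vector of construct names in causal order
#'   (default `c("X", "M", "Y")`).
#' @param n_waves number of waves (default inferred from columns).
#' @param edges which lag-1 edges to estimate: `"forward"` (default; each
#'   construct regressed on itself and on the constructs preceding it in
#'   `constructs`, the edge set whose paths enter the effect calculus) or
#'   `"full"` (every construct on every construct, the bivariate screening
#'   layout).
#' @param covariates optional baseline covariate columns, appended to every
#'   equation's design matrix.
#' @param standardize z-score every construct column before fitting, so
#'   coefficients are on the standardized-observed scale (used when mixing
#'   composite scores, counts and binary indicators); default `FALSE`
#'   (simulated panels are standardized by construction).
#' @return An object of class `clp_path_fit`: `estimates` (named
#'   `b_<src>.<tgt>_t<t>`), `vcov` (block diagonal across equations),
#'   `graph` (a [structural_graph()] carrying the estimates), `n_used`,
#'   `sigma2` (per-equation residual variances).
#' @export
fit_path_model <- function(data, constructs = c("X", "M", "Y"),
                           n_waves = NULL, edges = c("forward", "full"),
                           covariates = NULL, standardize = FALSE) {
  edges <- match.arg(edges)
  if (is.null(n_waves)) {
    w <- grep(paste0("^", constructs[1], "_[0-9]+$"), names(data),
              value = TRUE)
    n_waves <- max(as.integer(sub(".*_", "", w)))
  }
  if (standardize) {
    for (cc in constructs) {
      for (w in seq_len(n_waves)) {
        cl <- paste0(cc, "_", w)
        data[[cl]] <- as.numeric(scale(data[[cl]]))
      }
    }
  }
  K <- length(constructs)
  ord <- setNames(seq_len(K), constructs)

  est <- c()
  vcs <- list()
  sig2 <- c()
  n_used <- Inf
  for (t in seq_len(n_waves - 1L)) {
    for (tgt in constructs) {
      srcs <- if (edges == "full") constructs else
        constructs[ord <= ord[tgt]]
      xcols <- paste0(srcs, "_", t)
      ycol <- paste0(tgt, "_", t + 1L)
      dd <- data[, c(ycol, xcols, covariates), drop = FALSE]
      dd <- dd[complete.cases(dd), , drop = FALSE]
      n_used <- min(n_used, nrow(dd))
      fm <- lm(
        stats::reformulate(c(xcols, covariates), response = ycol),
        data = dd
      )
      nm <- paste0("b_", srcs, ".", tgt, "_t", t)
      b <- coef(fm)[xcols]
      v <- vcov(fm)[xcols, xcols, drop = FALSE]
      names(b) <- nm
      dimnames(v) <- list(nm, nm)
      est <- c(est, b)
      vcs[[length(vcs) + 1L]] <- v
      sig2[paste0(tgt, "_t", t)] <- summary(fm)$sigma^2
    }
  }
  V <- matrix(0, length(est), length(est),
              dimnames = list(names(est), names(est)))
  at <- 1L
  for (v in vcs) {
    k <- nrow(v)
    V[at:(at + k - 1L), at:(at + k - 1L)] <- v
    at <- at + k
  }

  B_list <- vector("list", n_waves - 1L)
  P_list <- vector("list", n_waves - 1L)
  for (t in seq_len(n_waves - 1L)) {
    B <- matrix(0, K, K, dimnames = list(constructs, constructs))
    P <- matrix(NA_character_, K, K, dimnames = list(constructs,
                                                     constructs))
    for (nmk in names(est)) {
      info <- parse_edge_name(nmk)
      if (info$t != t) next
      B[info$tgt, info$src] <- est[[nmk]]
      P[info$tgt, info$src] <- nmk
    }
    B_list[[t]] <- B
    P_list[[t]] <- P
  }
  graph <- structural_graph(B_list, constructs = constructs,
                            par_list = P_list)

  structure(
    list(estimates = est, vcov = V, graph = graph, n_used = n_used,
         sigma2 = sig2, constructs = constructs, n_waves = n_waves,
         edges = edges),
    class = "clp_path_fit"
  )
}

parse_edge_name <- function(nm) {
  m <- regmatches(nm, regexec("^b_([^.]+)\\.(.+)_t([0-9]+)$", nm))[[1]]
  list(src = m[2], tgt = m[3], t = as.integer(m[4]))
}

#' @export
print.clp_path_fit <- function(x, ...) {
  cat("<clp_path_fit>", length(x$estimates), "lag-1 coefficients,",
      x$n_waves, "waves, n =", x$n_used, "\n")
  invisible(x)
}

#' Simulate an observed-variable X/M/Y cross-lagged panel
#'
#' Generates the observed-score analogue of the latent system: a
#' standardized lag-1 vector autoregression on (X, M, Y) observed directly,
#' the design used for replicated interval-coverage and null-calibration
#' studies where measurement structure is not at issue.
#'
#' @param n subjects.
#' @param B either a single transition matrix (rows = target, cols =
#'   source, in X, M, Y order) or a list per transition.
#' @param n_waves waves (default 4).
#' @param seed integer seed.
#' @return data.frame with columns `X_w`, `M_w`, `Y_w`.
#' @export
simulate_path_panel <- function(n, B, n_waves = 4, seed = 1L) {
  cn <- c("X", "M", "Y")
  if (!is.list(B)) B <- rep(list(B), n_waves - 1L)
  B <- lapply(B, function(b) {
    b <- as.matrix(b)
    dimnames(b) <- list(cn, cn)
    b
  })
  cfg_like <- list(B_list = B, n_waves = n_waves)
  sig <- latent_wave_covariances(structure(cfg_like,
                                           class = "clp_sim_config"))
  if (any(unlist(lapply(sig$psi, diag)) <= 0)) {
    stop("transition coefficients imply non-positive innovation variance")
  }
  with_substream(seed, "path-panel", {
    eta <- rmvn(n, rep(0, 3), sig$sigma[[1]])
    out <- list(X_1 = eta[, 1], M_1 = eta[, 2], Y_1 = eta[, 3])
    for (t in seq_len(n_waves - 1L)) {
      eta <- eta %*% t(B[[t]]) + rmvn(n, rep(0, 3), sig$psi[[t]])
      out[[paste0("X_", t + 1L)]] <- eta[, 1]
      out[[paste0("M_", t + 1L)]] <- eta[, 2]
      out[[paste0("Y_", t + 1L)]] <- eta[, 3]
    }
    as.data.frame(out)
  })
}
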