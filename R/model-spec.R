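#' Specify a latent autoregressive cross-lagged model
#'
#' Builds a declarative model specification for a multi-wave cross-lagged
#' structural equation model. Each construct is measured either by a set of
#' ordinal questionnaire items (a latent variable per wave, first loading
#' fixed to 1 for identification) or by a single observed variable whose
#' latent response enters the structural model directly (the usual
#' treatment of a dichotomous behavior indicator). The structural part
#' consists of lag-1 autoregressive paths and cross-lagged paths between
#' constructs, free per transition or constrained equal over time;
#' within-wave construct covariances (wave-1 covariances and innovation
#' covariances at later waves) are free, and same-item error covariances
#' across waves absorb consistent item-specific variance.
#'
#' Ordinal variables follow the latent response formulation with the delta
#' parameterization: the total implied variance of each ordinal latent
#' response is fixed at 1, its residual variance being derived rather than
#' free.
#'
#' @param constructs named list, in causal order, of measurement
#'   definitions: either `list(items = c("sup1", ...), ordinal = TRUE)` or
#'   `list(observed = "alcohol", ordinal = TRUE)`. Data columns are
#'   `<item>_<wave>`.
#' @param n_waves number of waves.
#' @param structural `"full"`: cross-lagged paths in both directions between
#'   every construct pair (plus autoregressive paths); `"forward"`: only
#'   pairs respecting the list order of `constructs`.
#' @param constraints `"free"`: time-specific structural paths;
#'   `"equal"`: each path constrained equal over transitions (used for the
#'   nested comparison of time-constant against time-varying paths).
#' @param equal_loadings constrain item loadings equal over waves (the
#'   default; separate per-wave loadings relax measurement invariance).
#' @param error_cov `"item"`: one lag-invariant error covariance per item
#'   across all wave pairs; `"none"`.
#' @param estimator `"wls"` (diagonally weighted least squares on the
#'   polychoric/polyserial correlation matrix) or `"ml"` (normal-theory
#'   maximum likelihood treating variables as continuous).
#' @param missing `"pairwise"` (wls), `"complete"`, or `"fiml"`
#'   (full-information ML; ml route only).
#' @param covariates optional character vector of baseline covariate
#'   columns, entering the wave-1 constructs only.
#' @return An object of class `clp_model`.
#' @seealso [fit_sem()]
#' @export
clpm_spec <- function(constructs, n_waves = 4,
                      structural = c("full", "forward"),
                      constraints = c("free", "equal"),
                      equal_loadings = TRUE,
                      error_cov = c("item", "none"),
                      estimator = c("wls", "ml"),
                      missing = NULL,
                      covariates = NULL) {
  structural <- match.arg(structural)
  constraints <- match.arg(constraints)
  error_cov <- match.arg(error_cov)
  estimator <- match.arg(estimator)
  missing <- missing %||% if (estimator == "wls") "pairwise" else "complete"
  stopifnot(missing %in% c("pairwise", "complete", "fiml"))
  if (estimator == "wls" && missing == "fiml") {
    stop("fiml is available on the ml route only; ",
         "use missing = 'pairwise' with wls")
  }
  if (is.null(names(constructs)) || any(names(constructs) == "")) {
    stop("constructs must be a named list")
  }
  for (cn in names(constructs)) {
    cc <- constructs[[cn]]
    if (is.null(cc$items) && is.null(cc$observed)) {
      stop("construct ", cn, " needs items or an observed variable")
    }
    if (!is.null(cc$items) && length(cc$items) < 1) {
      stop("construct ", cn, " has an empty item list")
    }
  }

  structure(
    list(
      constructs = constructs,
      n_waves = as.integer(n_waves),
      structural = structural,
      constraints = constraints,
      equal_loadings = equal_loadings,
      error_cov = error_cov,
      estimator = estimator,
      missing = missing,
      covariates = covariates
    ),
    class = "clp_model"
  )
}

#' Serialize a model specification as YAML
#' @param spec a [clpm_spec()].
#' @param path file path.
#' @export
write_model_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @export
print.clp_model <- function(x, ...) {
  cat("<clp_model>", length(x$constructs), "constructs x", x$n_waves,
      "waves\n")
  for (cn in names(x$constructs)) {
    cc <- x$constructs[[cn]]
    meas <- if (!is.null(cc$items)) {
      paste0(length(cc$items), " items")
    } else {
      paste0("observed (", cc$observed, ")")
    }
    cat(sprintf("  %-12s %s%s\n", cn, meas,
                if (isTRUE(cc$ordinal)) " [ordinal]" else ""))
  }
  cat("  structural:", x$structural, "paths,", x$constraints,
      "over time;", "estimator:", x$estimator,
      paste0("(missing: ", x$missing, ")"), "\n")
  invisible(x)
}

# ---- compilation to RAM index structures ---------------------------------

# Translates a clp_model into flat index arrays for fast evaluation of the
# model-implied covariance: matrices A (directed paths), S (covariances),
# node bookkeeping and the free-parameter table. Nodes are ordered observed
# first, then latent.
compile_model <- function(spec) {
  n_waves <- spec$n_waves
  cons <- names(spec$constructs)

  ov <- character()
  ov_ordinal <- logical()
  lv <- character()
  node_of <- list() # construct x wave -> node name

  for (cn in cons) {
    cc <- spec$constructs[[cn]]
    if (!is.null(cc$items)) {
      for (w in seq_len(n_waves)) {
        ov <- c(ov, paste0(cc$items, "_", w))
        ov_ordinal <- c(ov_ordinal,
                        rep(isTRUE(cc$ordinal), length(cc$items)))
      }
      lv <- c(lv, paste0(cn, ".", seq_len(n_waves)))
      node_of[[cn]] <- paste0(cn, ".", seq_len(n_waves))
    } else {
      vnames <- paste0(cc$observed, "_", seq_len(n_waves))
      ov <- c(ov, vnames)
      ov_ordinal <- c(ov_ordinal, rep(isTRUE(cc$ordinal), n_waves))
      node_of[[cn]] <- vnames
    }
  }
  if (!is.null(spec$covariates)) {
    ov <- c(ov, spec$covariates)
    ov_ordinal <- c(ov_ordinal, rep(FALSE, length(spec$covariates)))
  }
  ov_u <- unique(ov)
  if (length(ov_u) != length(ov)) stop("duplicated observed variables")
  names(ov_ordinal) <- ov

  nodes <- c(ov, lv)
  m <- length(nodes)
  p <- length(ov)
  idx <- setNames(seq_len(m), nodes)

  pt <- list() # rows of the parameter table
  add <- function(mat, row, col, free, value, label, group, lower = -Inf) {
    pt[[length(pt) + 1L]] <<- data.frame(
      mat = mat, row = row, col = col, free = free, value = value,
      label = label, group = group, lower = lower,
      stringsAsFactors = FALSE
    )
  }

  # measurement: loadings and item error structure
  for (cn in cons) {
    cc <- spec$constructs[[cn]]
    if (is.null(cc$items)) next
    for (w in seq_len(n_waves)) {
      lvn <- paste0(cn, ".", w)
      for (i in seq_along(cc$items)) {
        ovn <- paste0(cc$items[i], "_", w)
        if (i == 1L) {
          add("A", ovn, lvn, FALSE, 1, NA_character_, "loading")
        } else {
          lab <- if (spec$equal_loadings) {
            paste0("lam_", cn, "_", cc$items[i])
          } else {
            paste0("lam_", cn, "_", cc$items[i], "_w", w)
          }
          add("A", ovn, lvn, TRUE, 0.7, lab, "loading")
        }
      }
    }
    # cross-wave same-item error covariances (lag-invariant by label)
    if (spec$error_cov == "item") {
      for (i in seq_along(cc$items)) {
        lab <- paste0("ecov_", cc$items[i])
        for (w1 in seq_len(n_waves - 1L)) {
          for (w2 in (w1 + 1L):n_waves) {
            add("S", paste0(cc$items[i], "_", w1),
                paste0(cc$items[i], "_", w2),
                TRUE, 0.05, lab, "error_cov")
          }
        }
      }
    }
  }

  # structural lag-1 edges
  pairs <- expand.grid(src = cons, tgt = cons, stringsAsFactors = FALSE)
  if (spec$structural == "forward") {
    ord <- setNames(seq_along(cons), cons)
    pairs <- pairs[ord[pairs$src] <= ord[pairs$tgt], , drop = FALSE]
  }
  for (t in seq_len(n_waves - 1L)) {
    for (k in seq_len(nrow(pairs))) {
      src <- pairs$src[k]
      tgt <- pairs$tgt[k]
      lab <- if (spec$constraints == "equal") {
        paste0("b_", src, ".", tgt)
      } else {
        paste0("b_", src, ".", tgt, "_t", t)
      }
      start <- if (src == tgt) 0.3 else 0
      add("A", node_of[[tgt]][t + 1L], node_of[[src]][t],
          TRUE, start, lab, "structural")
    }
  }

  # construct variances and within-wave covariances; on the wls route the
  # analysis runs on the correlation metric, so no observed variable may
  # carry a free variance (its total variance is derived to 1)
  is_ordinal_node <- function(nd) {
    nd %in% ov && (ov_ordinal[[nd]] || spec$estimator == "wls")
  }
  for (ci in seq_along(cons)) {
    nd1 <- node_of[[cons[ci]]][1]
    if (!is_ordinal_node(nd1)) {
      add("S", nd1, nd1, TRUE, 1, paste0("var_", cons[ci], "_w1"),
          "lv_var", lower = 1e-6)
    }
    for (w in 2:n_waves) {
      ndw <- node_of[[cons[ci]]][w]
      if (!is_ordinal_node(ndw)) {
        add("S", ndw, ndw, TRUE, 0.7, paste0("ivar_", cons[ci], "_w", w),
            "lv_var", lower = 1e-6)
      }
    }
    if (ci < length(cons)) {
      for (cj in (ci + 1L):length(cons)) {
        for (w in seq_len(n_waves)) {
          grp <- if (w == 1L) "w1_cov" else "innov_cov"
          add("S", node_of[[cons[ci]]][w], node_of[[cons[cj]]][w],
              TRUE, 0, paste0("cov_", cons[ci], ".", cons[cj], "_w", w),
              grp)
        }
      }
    }
  }

  # item residual variances (continuous ml only; ordinal and wls-route
  # variances are derived)
  for (v in ov) {
    structural_node <- v %in% unlist(node_of)
    if (ov_ordinal[[v]] || structural_node ||
          spec$estimator == "wls" ||
          v %in% (spec$covariates %||% character())) {
      next
    }
    add("S", v, v, TRUE, 0.4, paste0("evar_", v), "resid", lower = 1e-6)
  }

  # baseline covariates: saturated among themselves, edges to wave-1 nodes
  if (!is.null(spec$covariates)) {
    cv <- spec$covariates
    for (i in seq_along(cv)) {
      if (spec$estimator == "ml") {
        add("S", cv[i], cv[i], TRUE, 1, paste0("var_", cv[i]), "cov_var",
            lower = 1e-6)
      }
      if (i < length(cv)) {
        for (j in (i + 1L):length(cv)) {
          add("S", cv[i], cv[j], TRUE, 0, paste0("cov_", cv[i], ".", cv[j]),
              "cov_cov")
        }
      }
      for (cn in cons) {
        add("A", node_of[[cn]][1], cv[i], TRUE, 0,
            paste0("g_", cv[i], ".", cn), "covariate")
      }
    }
  }

  pt <- do.call(rbind, pt)

  # wls analyses on the correlation metric: every observed total variance
  # is 1, continuous variables being standardized in stage 1
  derived <- if (spec$estimator == "wls") {
    setNames(rep(TRUE, p), ov)
  } else {
    setNames(ov_ordinal, ov)
  }
  # variables with a free residual/variance entry are not derived
  has_free_diag <- unique(pt$row[pt$mat == "S" & pt$row == pt$col])
  derived[names(derived) %in% has_free_diag] <- FALSE

  # free parameters: shared labels share one parameter
  free_rows <- which(pt$free)
  labels <- pt$label[free_rows]
  par_names <- unique(labels)
  par_id <- match(labels, par_names)
  start <- setNames(numeric(length(par_names)), par_names)
  lower <- setNames(rep(-Inf, length(par_names)), par_names)
  for (k in seq_along(free_rows)) {
    start[par_id[k]] <- pt$value[free_rows[k]]
    lower[par_id[k]] <- max(lower[par_id[k]], pt$lower[free_rows[k]])
  }

  # fill instructions as linear indices into m x m matrices
  lin <- function(r, c) (idx[c] - 1L) * m + idx[r]
  A_rows <- pt[pt$mat == "A", , drop = FALSE]
  S_rows <- pt[pt$mat == "S", , drop = FALSE]
  mk_fill <- function(rows) {
    list(
      i1 = lin(rows$row, rows$col),
      i2 = lin(rows$col, rows$row), # symmetric mirror (S only)
      par = ifelse(rows$free, match(rows$label, par_names), NA_integer_),
      value = rows$value
    )
  }
  structure(
    list(
      spec = spec, nodes = nodes, ov = ov, lv = lv, p = p, m = m,
      idx = idx, node_of = node_of, ov_ordinal = ov_ordinal,
      derived = derived, partable = pt,
      A_fill = mk_fill(A_rows), S_fill = mk_fill(S_rows),
      par_names = par_names, start = start, lower = lower,
      par_group = setNames(pt$group[free_rows][!duplicated(par_id)],
                           par_names)
    ),
    class = "clp_compiled"
  )
}

# Model-implied covariance over all nodes for a parameter vector.
# Derived diagonal entries of S (ordinal latent responses on the unit
# variance metric) are solved from the linear system that keeps their total
# implied variance at 1.
implied_covariance <- function(cmp, theta) {
  m <- cmp$m
  A <- matrix(0, m, m)
  S <- matrix(0, m, m)
  af <- cmp$A_fill
  av <- ifelse(is.na(af$par), af$value, theta[af$par])
  A[af$i1] <- av
  sf <- cmp$S_fill
  sv <- ifelse(is.na(sf$par), sf$value, theta[sf$par])
  S[sf$i1] <- sv
  S[sf$i2] <- sv

  E <- solve(diag(m) - A)
  sigma0 <- E %*% S %*% t(E)

  dn <- which(cmp$nodes %in% names(cmp$derived)[cmp$derived])
  if (length(dn)) {
    G <- E[dn, dn, drop = FALSE]^2
    d <- solve(G, 1 - diag(sigma0)[dn])
    Ed <- E[, dn, drop = FALSE]
    sigma <- sigma0 + Ed %*% (d * t(Ed))
    attr(sigma, "derived_resid") <- setNames(d, cmp$nodes[dn])
  } else {
    sigma <- sigma0
  }
  attr(sigma, "E") <- E
  sigma
}

# Observed-block implied covariance.
implied_observed <- function(cmp, theta) {
  implied_covariance(cmp, theta)[seq_len(cmp$p), seq_len(cmp$p),
                                 drop = FALSE]
}
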