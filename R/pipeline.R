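#' Configuration for an end-to-end analysis run
#'
#' @param input either a [sim_config()] (simulate the panel) or a path to a
#'   wide panel CSV following the package's column convention.
#' @param exposure `"support"` or `"demands"`.
#' @param mediators character vector among `"smoking"`, `"alcohol"`,
#'   `"diet"`, `"inactivity"`, `"unhealthy_count"`.
#' @param engine `"sem"` (latent/ordinal models) or `"composite"`
#'   (observed-score path models; much faster).
#' @param estimator `"wls"` or `"ml"` for the sem engine.
#' @param adjust adjust all models for baseline age, sex, civil status and
#'   education.
#' @param smoking_variant,inactivity_variant operationalizations passed to
#'   [derive_variables()].
#' @param n_draws,level Monte Carlo interval settings.
#' @param alpha screening significance level.
#' @param seed master seed (simulation substreams and Monte Carlo draws).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return A `clp_run_config` list.
#' @export
run_config <- function(input, exposure = c("support", "demands"),
                       mediators = c("alcohol"),
                       engine = c("sem", "composite"),
                       estimator = "wls", adjust = FALSE,
                       smoking_variant = "daily",
                       inactivity_variant = "main",
                       n_draws = 20000, level = 0.95, alpha = 0.05,
                       seed = 1L, out_dir = NULL) {
  exposure <- match.arg(exposure)
  engine <- match.arg(engine)
  ok <- c("smoking", "alcohol", "diet", "inactivity", "unhealthy_count")
  if (!length(mediators) || !all(mediators %in% ok)) {
    stop("mediators must be a non-empty subset of: ",
         paste(ok, collapse = ", "))
  }
  if (inherits(input, "clp_sim_config") + is.character(input) != 1L) {
    stop("input must be exactly one of: a sim_config, a CSV path")
  }
  structure(
    list(input = input, exposure = exposure, mediators = mediators,
         engine = engine, estimator = estimator, adjust = adjust,
         smoking_variant = smoking_variant,
         inactivity_variant = inactivity_variant,
         n_draws = n_draws, level = level, alpha = alpha,
         seed = as.integer(seed), out_dir = out_dir),
    class = "clp_run_config"
  )
}

#' Run the full screening-gating-mediation pipeline
#'
#' Executes the analysis end to end: obtain the panel (simulate or read),
#' derive analysis variables, fit the bivariate cross-lagged screens for
#' each candidate mediator (exposure-mediator and mediator-outcome), apply
#' the gating rule, fit mediation models for gated-in mediators, and
#' assemble the mediation summary table plus a reproducibility manifest.
#' Mediators whose gate closes are recorded explicitly as "no mediation
#' model fitted".
#'
#' @param config a [run_config()].
#' @return A `clp_run` object: `screens`, `gates`, `mediations`,
#'   `mediation_table`, `screening_table`, `manifest`. If
#'   `config$out_dir` is set, `screening.csv`, `mediation.csv` and
#'   `manifest.json` are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "clp_run_config"))
  t_start <- Sys.time()
  timings <- c()
  tick <- function(stage, t0) {
    timings[stage] <<- round(as.numeric(Sys.time() - t0, units = "secs"),
                             3)
  }

  t0 <- Sys.time()
  panel <- if (inherits(config$input, "clp_sim_config")) {
    generate_panel(config$input)
  } else {
    read_panel(config$input)
  }
  tick("input", t0)

  t0 <- Sys.time()
  derived <- derive_variables(
    panel,
    smoking_variant = config$smoking_variant,
    inactivity_variant = config$inactivity_variant
  )
  new_cols <- setdiff(names(derived), names(panel))
  adat <- cbind(as.data.frame(panel),
                derived[, new_cols, drop = FALSE])
  tick("derive", t0)

  covariates <- if (config$adjust) c("age", "female", "single", "edu")
  exp_items <- if (config$exposure == "demands") paste0("dem", 1:4) else
    paste0("sup", 1:5)
  exposure_def <- list(items = exp_items, ordinal = TRUE)
  outcome_def <- list(items = paste0("dep", 1:6), ordinal = TRUE)

  screens <- list()
  gates <- list()
  mediations <- list()
  gate_log <- list()
  t0 <- Sys.time()
  for (med in config$mediators) {
    if (config$engine == "sem") {
      med_def <- list(observed = med, ordinal = TRUE)
      s_xm <- fit_bivariate(
        adat, setNames(list(exposure_def, med_def),
                       c(config$exposure, med)),
        engine = "sem", estimator = config$estimator,
        covariates = covariates, alpha = config$alpha
      )
      s_my <- fit_bivariate(
        adat, setNames(list(med_def, outcome_def), c(med, "depressive")),
        engine = "sem", estimator = config$estimator,
        covariates = covariates, alpha = config$alpha
      )
    } else {
      s_xm <- fit_bivariate(adat, c(config$exposure, med),
                            engine = "composite",
                            covariates = covariates,
                            alpha = config$alpha)
      s_my <- fit_bivariate(adat, c(med, "depressive"),
                            engine = "composite",
                            covariates = covariates,
                            alpha = config$alpha)
    }
    screens[[paste0(config$exposure, "-", med)]] <- s_xm
    screens[[paste0(med, "-depressive")]] <- s_my
    gate <- gate_mediation(s_xm, s_my)
    gates[[med]] <- gate
    gate_log[[med]] <- if (gate$open) "mediation model fitted" else
      "no mediation model fitted"
    if (gate$open) {
      constructs <- if (config$engine == "sem") {
        setNames(list(exposure_def, med_def, outcome_def),
                 c(config$exposure, med, "depressive"))
      } else {
        c(config$exposure, med, "depressive")
      }
      mediations[[paste0(config$exposure, "-", med, "-depressive")]] <-
        fit_mediation(
          adat, constructs, engine = config$engine,
          estimator = config$estimator, covariates = covariates,
          n_draws = config$n_draws, level = config$level,
          seed = substream_seed(config$seed, paste0("mc-", med))
        )
    }
  }
  tick("screen+mediate", t0)

  med_table <- mediation_report(mediations)
  scr_table <- screening_table(screens)
  manifest <- list(
    package_version = tryCatch(
      as.character(utils::packageVersion("clpmed")),
      error = function(e) "dev"
    ),
    seed = config$seed,
    config = manifest_config(config),
    gates = gate_log,
    timings_sec = as.list(timings),
    total_sec = round(as.numeric(Sys.time() - t_start, units = "secs"), 3)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(scr_table, file.path(config$out_dir, "screening.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(med_table),
              file.path(config$out_dir, "mediation.csv"),
              row.names = FALSE)
    for (nm in names(mediations)) {
      write.csv(mediations[[nm]]$path_table,
                file.path(config$out_dir,
                          paste0("paths_", gsub("[^A-Za-z0-9_-]", "_",
                                                nm), ".csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(
    list(screens = screens, gates = gates, mediations = mediations,
         mediation_table = med_table, screening_table = scr_table,
         manifest = manifest, config = config),
    class = "clp_run"
  )
}

manifest_config <- function(config) {
  out <- unclass(config)
  if (inherits(out$input, "clp_sim_config")) {
    out$input <- unclass_config_for_json(out$input)
  }
  out
}

#' @export
print.clp_run <- function(x, ...) {
  cat("<clp_run>", x$config$exposure, "exposure;",
      length(x$config$mediators), "candidate mediator(s);",
      x$config$engine, "engine\n")
  for (med in names(x$gates)) {
    cat(sprintf("  %-16s %s\n", med, x$manifest$gates[[med]]))
  }
  if (nrow(x$mediation_table)) {
    cat("\n")
    print(x$mediation_table)
  }
  invisible(x)
}

#' Sensitivity analyses under alternative operationalizations
#'
#' Re-runs screening and mediation under variant definitions -- any smoking
#' instead of daily smoking, irregular physical inactivity instead of the
#' main inactivity definition, covariate adjustment on or off -- and
#' collects the indirect-effect rows side by side.
#'
#' @param config a [run_config()]; the variants are applied on top of it.
#' @param variants character vector among `"main"`, `"any_smoking"`,
#'   `"irregular_inactivity"`, `"adjusted"`, `"unadjusted"`.
#' @return A `clp_sensitivity` object: `runs` (per-variant `clp_run`) and
#'   `comparison` (one row per variant x mediator with gate status and the
#'   indirect effect and interval where fitted).
#' @export
sensitivity_suite <- function(config,
                              variants = c("main", "any_smoking",
                                           "irregular_inactivity")) {
  stopifnot(inherits(config, "clp_run_config"))
  apply_variant <- function(cfg, v) {
    if (v == "any_smoking") cfg$smoking_variant <- "any"
    if (v == "irregular_inactivity") cfg$inactivity_variant <- "irregular"
    if (v == "adjusted") cfg$adjust <- TRUE
    if (v == "unadjusted") cfg$adjust <- FALSE
    cfg$out_dir <- NULL
    cfg
  }
  runs <- list()
  rows <- list()
  for (v in variants) {
    run <- run_pipeline(apply_variant(config, v))
    runs[[v]] <- run
    for (med in names(run$gates)) {
      key <- paste0(config$exposure, "-", med, "-depressive")
      m <- run$mediations[[key]]
      rows[[paste(v, med)]] <- data.frame(
        variant = v, mediator = med,
        gate = if (run$gates[[med]]$open) "open" else "closed",
        indirect = if (!is.null(m)) m$effects$indirect else NA_real_,
        indirect_lower = if (!is.null(m)) {
          m$effects$ci["indirect", "lower"]
        } else {
          NA_real_
        },
        indirect_upper = if (!is.null(m)) {
          m$effects$ci["indirect", "upper"]
        } else {
          NA_real_
        },
        indirect_sig = if (!is.null(m)) {
          unname(m$effects$significant[["indirect"]])
        } else {
          NA
        }
      )
    }
  }
  comparison <- do.call(rbind, rows)
  rownames(comparison) <- NULL
  structure(list(runs = runs, comparison = comparison),
            class = "clp_sensitivity")
}

#' @export
print.clp_sensitivity <- function(x, ...) {
  cat("<clp_sensitivity>\n")
  print(x$comparison, digits = 4)
  invisible(x)
}
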