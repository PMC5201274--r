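#' Generate a synthetic multi-wave panel dataset
#'
#' Simulates a wide person-by-wave panel with the structure the cross-lagged
#' mediation analysis assumes: standardized latent constructs evolving by the
#' configured lag-1 linear system, ordinal questionnaire items produced from
#' the latents through loadings and thresholds on normal latent responses,
#' binary behavior indicators produced by thresholding the behavior
#' propensities, and baseline covariates. Deterministic given the
#' configuration seed.
#'
#' Columns follow the `<item>_<wave>` convention, e.g. `dem2_1` (second
#' demand item, wave 1), `sup5_3`, `dep6_4`, `smoking_2`. Baseline
#' covariates are `age`, `female`, `single`, `edu`.
#'
#' @param config a [sim_config()] object.
#' @return A `data.frame` of class `clp_panel`, one row per subject, with the
#'   generating configuration in `attr(, "config")` and the latent construct
#'   scores in `attr(, "latents")`. If `config$missingness$mechanism` is not
#'   `"none"`, [apply_missingness()] is applied before returning.
#' @examples
#' cfg <- sim_config(n_subjects = 200, seed = 7)
#' panel <- generate_panel(cfg)
#' mean(panel$smoking_1) # close to 0.083 at large n
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "clp_sim_config"))
  n <- config$n_subjects
  n_waves <- config$n_waves

  covars <- with_substream(config$seed, "covariates", draw_covariates(n))
  lat <- with_substream(
    config$seed, "latents",
    draw_latent_system(config, covars)
  )
  items <- with_substream(
    config$seed, "items",
    draw_ordinal_items(config, lat)
  )
  beh <- behavior_indicators(config, lat)

  out <- data.frame(id = seq_len(n), covars, items, beh,
                    check.names = FALSE)
  if (config$emit_raw_items) {
    raw <- with_substream(
      config$seed, "raw-items",
      draw_raw_behavior_items(config, lat, covars, beh)
    )
    out <- cbind(out, raw)
  }
  attr(out, "config") <- config
  attr(out, "latents") <- lat
  class(out) <- c("clp_panel", "data.frame")
  if (config$missingness$mechanism != "none") {
    out <- apply_missingness(out, config)
  }
  out
}

draw_covariates <- function(n) {
  age <- round(pmin(pmax(rnorm(n, 47.6, 8.9), 20), 67))
  female <- rbinom(n, 1, 0.575)
  single <- rbinom(n, 1, 0.206)
  edu_probs <- c(0.009, 0.059, 0.444, 0.070, 0.402, 0.016)
  edu <- sample.int(6, n, replace = TRUE, prob = edu_probs)
  data.frame(age = age, female = female, single = single, edu = edu)
}

# Latent scores for every construct at every wave.
# System constructs X, M, Y follow the configured lag-1 matrices with
# innovation variances keeping each marginal variance at 1; the remaining
# behavior propensities and the non-exposure work construct are independent
# AR(1) processes with coefficient behavior_ar.
draw_latent_system <- function(config, covars) {
  n <- config$n_subjects
  n_waves <- config$n_waves
  sig <- latent_wave_covariances(config)

  cmat <- cbind(
    age10 = (covars$age - mean(covars$age)) / 10,
    female = covars$female - mean(covars$female),
    single = covars$single - mean(covars$single),
    edu = covars$edu - mean(covars$edu)
  )
  mu1 <- sapply(c("X", "M", "Y"), function(k) {
    drop(cmat %*% config$covariate_effects[[k]])
  })

  eta <- array(NA_real_, dim = c(n, 3, n_waves),
               dimnames = list(NULL, c("X", "M", "Y"), NULL))
  eta[, , 1] <- mu1 + rmvn(n, rep(0, 3), sig$sigma[[1]])
  for (t in seq_len(n_waves - 1L)) {
    innov <- rmvn(n, rep(0, 3), sig$psi[[t]])
    eta[, , t + 1] <- eta[, , t] %*% t(config$B_list[[t]]) + innov
  }

  rho <- config$behavior_ar
  indep <- function() {
    z <- matrix(NA_real_, n, n_waves)
    z[, 1] <- rnorm(n)
    for (t in seq_len(n_waves - 1L)) {
      z[, t + 1] <- rho * z[, t] + sqrt(1 - rho^2) * rnorm(n)
    }
    z
  }
  behaviors <- c("smoking", "alcohol", "diet", "inactivity")
  prop <- setNames(vector("list", 4), behaviors)
  for (b in behaviors) {
    prop[[b]] <- if (b == config$mediator) eta[, "M", ] else indep()
  }
  other_work <- indep()

  list(eta = eta, behavior = prop, other_work = other_work)
}

# Ordinal item emission: item latent response u = lambda * eta + e with
# var(e) = 1 - lambda^2; the item-specific error carries a stable
# person-level component so that corr(e_t, e_t') = residual_cor at any lag.
draw_ordinal_items <- function(config, lat) {
  n <- config$n_subjects
  n_waves <- config$n_waves
  r <- config$residual_cor

  construct_scores <- function(scale_name) {
    if (scale_name == "depressive") {
      return(lat$eta[, "Y", , drop = FALSE][, 1, ])
    }
    if (scale_name == config$exposure) {
      lat$eta[, "X", , drop = FALSE][, 1, ]
    } else {
      lat$other_work
    }
  }
  prefixes <- c(demands = "dem", support = "sup", depressive = "dep")
  offsets <- c(demands = 1L, support = 1L, depressive = 0L)

  cols <- list()
  for (sc in c("demands", "support", "depressive")) {
    eta_sc <- construct_scores(sc)
    lam <- config$loadings[[sc]]
    for (i in seq_along(lam)) {
      stable <- rnorm(n)
      cuts <- config$thresholds[[sc]][[i]]
      sd_e <- sqrt(max(1 - lam[i]^2, 1e-12))
      for (w in seq_len(n_waves)) {
        e <- sqrt(r) * stable + sqrt(1 - r) * rnorm(n)
        u <- lam[i] * eta_sc[, w] + sd_e * e
        code <- offsets[[sc]] + findInterval(u, cuts)
        cols[[paste0(prefixes[[sc]], i, "_", w)]] <- code
      }
    }
  }
  as.data.frame(cols)
}

behavior_indicators <- function(config, lat) {
  n_waves <- config$n_waves
  cols <- list()
  for (b in names(config$behavior_thresholds)) {
    tau <- config$behavior_thresholds[[b]]
    for (w in seq_len(n_waves)) {
      cols[[paste0(b, "_", w)]] <-
        as.integer(lat$behavior[[b]][, w] > tau)
    }
  }
  as.data.frame(cols)
}

# Raw behavior questionnaire items, constructed to be exactly consistent
# with the binary indicators so the scoring rules round-trip.
draw_raw_behavior_items <- function(config, lat, covars, beh) {
  n <- config$n_subjects
  n_waves <- config$n_waves
  cols <- list()

  # smoking: daily iff above the indicator threshold; the remaining mass is
  # split into "sometimes" (next 10 points of latent probability) and "never"
  tau <- config$behavior_thresholds[["smoking"]]
  tau_some <- qnorm(pnorm(tau) - 0.10)
  for (w in seq_len(n_waves)) {
    z <- lat$behavior$smoking[, w]
    cols[[paste0("smoke_status_", w)]] <-
      ifelse(z > tau, "daily", ifelse(z > tau_some, "sometimes", "never"))
  }

  # alcohol: AUDIT-style items in waves 1-2 (weekly units + weekly binge
  # flag), CAGE items in waves 3-4; positives get either high weekly units
  # or a binge flag, negatives stay strictly below both rules
  male_thr <- ifelse(covars$female == 1, 14, 21)
  for (w in seq_len(n_waves)) {
    pos <- beh[[paste0("alcohol_", w)]] == 1
    if (w <= 2) {
      heavy <- pos & (runif(n) < 0.7)
      units <- numeric(n)
      units[heavy] <- male_thr[heavy] + round(runif(sum(heavy), 0, 15))
      binge <- as.integer(pos & !heavy)
      light <- !pos
      units[light] <- floor(runif(sum(light)) * (male_thr[light] - 1))
      units[pos & !heavy] <- floor(
        runif(sum(pos & !heavy)) * (male_thr[pos & !heavy] - 1)
      )
      cols[[paste0("alc_units_", w)]] <- units
      cols[[paste0("alc_binge_", w)]] <- binge
    } else {
      k <- integer(n)
      k[pos] <- sample(2:4, sum(pos), replace = TRUE)
      k[!pos] <- sample(0:1, sum(!pos), replace = TRUE)
      flags <- matrix(0L, n, 4)
      for (i in seq_len(n)) {
        if (k[i] > 0) flags[i, sample.int(4, k[i])] <- 1L
      }
      for (j in 1:4) cols[[paste0("cage", j, "_", w)]] <- flags[, j]
    }
  }

  # diet: single category item; healthy mass split across the three healthy
  # response options
  for (w in seq_len(n_waves)) {
    pos <- beh[[paste0("diet_", w)]] == 1
    healthy_opts <- c("varying/average diet", "avoid fat and sugar",
                      "special diet")
    cat <- character(n)
    cat[pos] <- "a lot of fat, sugar or fast food"
    cat[!pos] <- sample(healthy_opts, sum(!pos), replace = TRUE,
                        prob = c(0.7, 0.25, 0.05))
    cols[[paste0("diet_cat_", w)]] <- cat
  }

  # exercise frequency: four ordered categories on the inactivity propensity
  tau <- config$behavior_thresholds[["inactivity"]]
  tau_never <- qnorm(pnorm(tau) + 0.7 * (1 - pnorm(tau)))
  tau_now <- qnorm(pnorm(tau) - 0.30)
  for (w in seq_len(n_waves)) {
    z <- lat$behavior$inactivity[, w]
    cols[[paste0("exercise_", w)]] <- ifelse(
      z > tau_never, "never",
      ifelse(z > tau, "very little",
             ifelse(z > tau_now, "now and then", "regularly"))
    )
  }
  as.data.frame(cols)
}

#' Apply cell-level missingness to a panel
#'
#' Masks measurement cells (questionnaire items and behavior indicators;
#' never baseline covariates) under the configured mechanism. `MCAR` masks
#' every maskable cell independently at the configured rate. `MAR` masks
#' cells of waves 2 and later with a probability that depends on the
#' subject's observed wave-1 depressive sum score through a logistic model,
#' so missingness is ignorable given observed data; wave-1 cells stay
#' observed. Deterministic given the configuration seed.
#'
#' @param data a `clp_panel` (or any wide panel data.frame with the package's
#'   column convention).
#' @param config a [sim_config()]; `config$missingness` holds `mechanism`
#'   (`"none"`, `"MCAR"`, `"MAR"`), `rate` and, for MAR, `strength`.
#' @return The panel with masked cells set to `NA`.
#' @export
apply_missingness <- function(data, config) {
  mech <- config$missingness$mechanism
  rate <- config$missingness$rate
  if (!mech %in% c("none", "MCAR", "MAR")) {
    stop("unknown missingness mechanism: ", mech)
  }
  if (mech == "none" || rate == 0) {
    return(data)
  }
  n <- nrow(data)
  maskable <- grep("_[0-9]+$", names(data), value = TRUE)
  with_substream(config$seed, "missingness", {
    if (mech == "MCAR") {
      for (cl in maskable) {
        data[[cl]][runif(n) < rate] <- NA
      }
    } else {
      dep1 <- rowSums(data[, paste0("dep", 1:6, "_1"), drop = FALSE])
      zdep <- as.numeric(scale(dep1))
      zdep[is.na(zdep)] <- 0
      p <- plogis(qlogis(rate) + config$missingness$strength * zdep)
      later <- maskable[!grepl("_1$", maskable)]
      for (cl in later) {
        data[[cl]][runif(n) < p] <- NA
      }
    }
    data
  })
}

#' Write a panel and its manifest to disk
#'
#' Writes the wide panel as CSV (missing cells as empty fields) plus a JSON
#' manifest recording the generating configuration, seed and the true
#' overall effects, sufficient to reproduce the dataset exactly.
#'
#' @param panel a `clp_panel`.
#' @param dir output directory (created if needed).
#' @param name file stem, default `"panel"`.
#' @return Invisibly, the paths written.
#' @export
write_panel <- function(panel, dir, name = "panel") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  write.csv(as.data.frame(panel), csv, row.names = FALSE, na = "")
  cfg <- attr(panel, "config")
  manifest <- file.path(dir, paste0(name, "_manifest.json"))
  te <- true_effects(cfg)
  jsonlite::write_json(
    list(
      config = unclass_config_for_json(cfg),
      seed = cfg$seed,
      true_effects = list(
        total = te$total, direct = te$direct, indirect = te$indirect
      )
    ),
    manifest,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(csv = csv, manifest = manifest))
}

unclass_config_for_json <- function(cfg) {
  out <- unclass(cfg)
  out$B_list <- lapply(out$B_list, function(m) {
    apply(m, 1, identity, simplify = FALSE)
  })
  out
}

#' Read a panel written by [write_panel()]
#' @param csv path to the CSV file.
#' @return A `clp_panel` data.frame (without generator attributes).
#' @export
read_panel <- function(csv) {
  out <- read.csv(csv, check.names = FALSE)
  class(out) <- c("clp_panel", "data.frame")
  out
}
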