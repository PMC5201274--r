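test_that("generation is deterministic given the seed and seed-sensitive", {
  cfg <- sim_config(n_subjects = 150, seed = 42,
                    crosslag = fix_crosslag())
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  cfg2 <- sim_config(n_subjects = 150, seed = 43,
                     crosslag = fix_crosslag())
  expect_false(identical(as.data.frame(p1),
                         as.data.frame(generate_panel(cfg2))))
})

test_that("binary prevalence converges to the normal-CDF complement", {
  cfg <- sim_config(n_subjects = 40000, seed = 7)
  panel <- generate_panel(cfg)
  targets <- c(smoking = 0.083, alcohol = 0.052, diet = 0.068,
               inactivity = 0.161)
  for (b in names(targets)) {
    for (w in c(1, 4)) {
      prev <- mean(panel[[paste0(b, "_", w)]])
      tol <- 3 * sqrt(targets[[b]] * (1 - targets[[b]]) / 40000)
      expect_lt(abs(prev - targets[[b]]), tol + 0.004)
    }
  }
  # a custom threshold: standard-normal quantile of 0.917 -> 8.3%
  cfg2 <- sim_config(n_subjects = 40000, seed = 8,
                     behavior_thresholds = c(diet = qnorm(0.917)))
  prev <- mean(generate_panel(cfg2)$diet_1)
  expect_lt(abs(prev - 0.083), 0.006)
})

test_that("composite means match the baseline calibration targets", {
  cfg <- sim_config(n_subjects = 20000, seed = 12)
  panel <- generate_panel(cfg)
  dem <- score_scale(as.matrix(panel[, paste0("dem", 1:4, "_1")]),
                     "demands")
  sup <- score_scale(as.matrix(panel[, paste0("sup", 1:5, "_1")]),
                     "support")
  dep <- score_scl_cd6(as.matrix(panel[, paste0("dep", 1:6, "_1")]))
  expect_lt(abs(mean(dem) - 2.6), 0.05)
  expect_lt(abs(mean(sup) - 3.1), 0.05)
  expect_lt(abs(mean(dep) - 5.4), 0.15)
})

test_that("zero cross-lags leave items and next-wave behaviors uncorrelated", {
  cfg <- sim_config(n_subjects = 20000, seed = 5) # crosslag NULL -> zeros
  panel <- generate_panel(cfg)
  for (i in 1:5) {
    r <- cor(panel[[paste0("sup", i, "_1")]], panel$alcohol_2)
    expect_lt(abs(r), 3 / sqrt(20000) + 0.005)
  }
})

test_that("latent stability matches the configured AR coefficient", {
  cfg <- sim_config(n_subjects = 30000, seed = 9,
                    ar = c(X = 0.7, M = 0.6, Y = 0.5))
  panel <- generate_panel(cfg)
  lat <- attr(panel, "latents")
  expect_lt(abs(cor(lat$eta[, "X", 1], lat$eta[, "X", 2]) - 0.7), 0.02)
  expect_lt(abs(cor(lat$eta[, "Y", 2], lat$eta[, "Y", 3]) - 0.5), 0.02)
  # behaviors: tetrachoric autocorrelation of adjacent indicators
  pc <- polychoric_matrix(panel[, c("alcohol_1", "alcohol_2")])
  expect_lt(abs(pc$rho[1, 2] - 0.6), 0.05)
})

test_that("latent variances stay at one across waves", {
  cfg <- sim_config(n_subjects = 30000, seed = 14,
                    crosslag = fix_crosslag(0.25, 0.25, 0.15))
  lat <- attr(generate_panel(cfg), "latents")
  for (w in 1:4) {
    expect_equal(unname(apply(lat$eta[, , w], 2, var)), rep(1, 3),
                 tolerance = 0.05)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(-5), "positive")
  expect_error(sim_config(100, missingness = list(mechanism = "MCAR",
                                                  rate = 1.2)),
               "rate")
  expect_error(sim_config(100, missingness = list(mechanism = "weird",
                                                  rate = 0.1)),
               "unknown missingness")
  expect_error(
    sim_config(100, thresholds = list(
      demands = rep(list(c(0.5, 0.2, 1)), 4)
    )),
    "strictly increasing"
  )
  expect_error(sim_config(100, ar = c(X = 1.2, M = 0.9, Y = 0.9)),
               "non-positive innovation")
})

test_that("MCAR masks cells at the nominal rate and rate 0 is identity", {
  cfg <- sim_config(n_subjects = 4000, seed = 3,
                    missingness = list(mechanism = "MCAR", rate = 0.1))
  panel <- generate_panel(cfg)
  cells <- unlist(panel[, grep("_[0-9]+$", names(panel))])
  frac <- mean(is.na(cells))
  expect_lt(abs(frac - 0.10), 0.01)
  # covariates never masked
  expect_false(anyNA(panel$age))

  cfg0 <- sim_config(n_subjects = 200, seed = 3)
  p0 <- generate_panel(cfg0)
  expect_identical(apply_missingness(p0, cfg0), p0)
})

test_that("MAR masking depends on the wave-1 depressive score", {
  cfg <- sim_config(n_subjects = 8000, seed = 6,
                    missingness = list(mechanism = "MAR", rate = 0.15,
                                       strength = 1))
  panel <- generate_panel(cfg)
  # wave-1 cells stay observed under MAR
  expect_false(anyNA(panel[, grep("_1$", names(panel))]))
  dep1 <- rowSums(panel[, paste0("dep", 1:6, "_1")])
  tert <- cut(dep1, quantile(dep1, c(0, 1 / 3, 2 / 3, 1)),
              include.lowest = TRUE, labels = FALSE)
  later <- grep("_[234]$", names(panel), value = TRUE)
  miss_by_subj <- rowMeans(is.na(panel[, later]))
  rates <- tapply(miss_by_subj, tert, mean)
  expect_gt(rates[[3]], rates[[1]] + 0.05)
})

test_that("panels round-trip through CSV with manifest", {
  cfg <- sim_config(n_subjects = 60, seed = 2,
                    crosslag = fix_crosslag(),
                    missingness = list(mechanism = "MCAR", rate = 0.05))
  panel <- generate_panel(cfg)
  dir <- tempfile()
  paths <- write_panel(panel, dir)
  back <- read_panel(paths[["csv"]])
  expect_equal(dim(back), dim(panel))
  expect_equal(back$dep3_2, panel$dep3_2)
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$seed, 2)
  te <- true_effects(cfg)
  expect_equal(man$true_effects$indirect, te$indirect, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
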