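test_that("ml route reproduces equation-wise OLS on a recursive system", {
  d <- fix_toy_panel(600, seed = 17)
  fit <- fit_sem(fix_observed_spec(), d)
  for (t in 1:2) {
    ols <- lm(stats::reformulate(paste0(c("X", "M", "Y"), "_", t),
                                 paste0("Y_", t + 1)), d)
    expect_equal(unname(fit$estimates[paste0("b_X.Y_t", t)]),
                 unname(coef(ols)[paste0("X_", t)]), tolerance = 1e-5)
    expect_equal(unname(fit$estimates[paste0("b_M.Y_t", t)]),
                 unname(coef(ols)[paste0("M_", t)]), tolerance = 1e-5)
    # normal-theory SEs agree with OLS up to the n/(n-k) correction
    se_sem <- sqrt(fit$vcov[paste0("b_X.Y_t", t), paste0("b_X.Y_t", t)])
    se_ols <- sqrt(vcov(ols)[paste0("X_", t), paste0("X_", t)])
    expect_equal(se_sem, se_ols, tolerance = 0.02)
  }
  expect_true(fit$converged)
})

test_that("saturated structural model fits the moments exactly", {
  # two waves with full cross-lags and free within-wave covariances is
  # saturated: zero discrepancy, CFI 1, RMSEA 0
  d <- simulate_path_panel(300, fix_B(), n_waves = 2, seed = 4)
  fit <- fit_sem(fix_observed_spec(n_waves = 2), d)
  expect_equal(fit$df, 0)
  expect_lt(fit$chi_square, 0.01)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$rmsea, 0)
  # implied moments reproduce the sample covariance
  expect_equal(unname(fit$implied), unname(fit$sample_moments),
               tolerance = 1e-3)
})

test_that("fit indices follow the standard formulas", {
  fi <- fit_indices(150, 100, 1100, 120, 1000)
  expect_equal(unname(fi["cfi"]), 1 - 50 / 980, tolerance = 1e-7)
  expect_equal(unname(fi["rmsea"]), sqrt(50 / (100 * 999)),
               tolerance = 1e-7)
  # frozen values from the formulas
  expect_equal(unname(fi["cfi"]), 0.9489796, tolerance = 1e-4)
  expect_equal(unname(fi["rmsea"]), 0.0223719, tolerance = 1e-4)

  perfect <- fit_indices(100, 100, 900, 120, 500)
  expect_equal(unname(perfect["cfi"]), 1)
  expect_equal(unname(perfect["rmsea"]), 0)
  floored <- fit_indices(80, 100, 900, 120, 500)
  expect_equal(unname(floored["rmsea"]), 0)
  expect_error(fit_indices(10, 0, 90, 12, 100), "df_model")
  expect_error(fit_indices(10, 5, 90, 12, 1), "n must")
})

test_that("wls route recovers loadings and structural paths", {
  cfg <- sim_config(n_subjects = 2000, seed = 51,
                    crosslag = fix_crosslag(0, 0, 0.2))
  panel <- generate_panel(cfg)
  spec <- clpm_spec(
    list(X = list(items = paste0("sup", 1:5), ordinal = TRUE),
         Y = list(items = paste0("dep", 1:6), ordinal = TRUE)),
    n_waves = 4, structural = "full", estimator = "wls"
  )
  fit <- fit_sem(spec, panel)
  expect_true(fit$converged)
  expect_gt(fit$cfi, 0.95)
  expect_lt(fit$rmsea, 0.05)
  std <- fit$standardized
  # standardized loadings close to the generating ones
  lam_true <- c(sup2 = 0.80, sup3 = 0.70, sup4 = 0.72, sup5 = 0.68)
  for (nm in names(lam_true)) {
    expect_equal(unname(std[paste0("std_lam_X_", nm)]),
                 unname(lam_true[nm]), tolerance = 0.05)
  }
  # cross-lagged paths: X->Y about 0.2, reverse about 0
  sc <- standardized_coefficients(fit)
  xy <- sc[grep("std_b_X.Y", names(sc), fixed = TRUE)]
  yx <- sc[grep("std_b_Y.X", names(sc), fixed = TRUE)]
  expect_true(all(abs(xy - 0.2) < 0.08))
  expect_true(all(abs(yx) < 0.06))
})

test_that("error covariances recover the item-stability structure", {
  cfg <- sim_config(n_subjects = 3000, seed = 52, residual_cor = 0.3)
  panel <- generate_panel(cfg)
  spec <- clpm_spec(
    list(Y = list(items = paste0("dep", 1:6), ordinal = TRUE)),
    n_waves = 4, estimator = "wls"
  )
  fit <- fit_sem(spec, panel)
  # generating cross-wave error covariance = residual_cor * (1 - lambda^2)
  lam <- c(0.80, 0.78, 0.75, 0.70, 0.72, 0.76)
  for (i in seq_along(lam)) {
    expect_lt(abs(fit$estimates[[paste0("ecov_dep", i)]] -
                    0.3 * (1 - lam[i]^2)), 0.03)
  }
})

test_that("standardization rescales by the implied standard deviations", {
  d <- fix_toy_panel(2000, seed = 19)
  # rescale the mediator by a constant: raw coefficients change,
  # standardized coefficients are invariant
  d2 <- d
  for (w in 1:3) d2[[paste0("M_", w)]] <- 10 * d2[[paste0("M_", w)]]
  f1 <- fit_sem(fix_observed_spec(), d)
  f2 <- fit_sem(fix_observed_spec(), d2)
  s1 <- standardized_coefficients(f1)
  s2 <- standardized_coefficients(f2)
  expect_equal(s1, s2, tolerance = 1e-4)
  expect_equal(unname(f2$estimates["b_X.M_t1"]),
               unname(10 * f1$estimates["b_X.M_t1"]), tolerance = 1e-3)
  # explicit rescaling identity: std = raw * sd(source) / sd(target)
  sdX <- sd(d$X_1)
  sdM <- sd(d$M_2)
  expect_equal(unname(s1["std_b_X.M_t1"]),
               unname(f1$estimates["b_X.M_t1"] * sdX / sdM),
               tolerance = 0.02)
})

test_that("nested chi-square difference test behaves at both extremes", {
  d <- fix_toy_panel(500, seed = 23)
  fit_free <- fit_sem(fix_observed_spec(), d)
  # identical models: zero difference on zero df
  nt0 <- nested_test(fit_free, fit_free)
  expect_equal(nt0$delta_chi_sq, 0)
  expect_equal(nt0$delta_df, 0)
  expect_true(is.na(nt0$p_value))
  # time-constant constraint on time-constant data: modest statistic
  fit_eq <- fit_sem(fix_observed_spec(constraints = "equal"), d)
  nt <- nested_test(fit_free, fit_eq)
  expect_equal(nt$delta_df, 9) # 18 free - 9 shared
  expect_gt(nt$p_value, 0.001)
  expect_error(nested_test(fit_eq, fit_free), "not nested")
})

test_that("equality constraints are rejected when paths vary over time", {
  B1 <- fix_B(xm = 0.6, my = 0.5, xy = 0.3,
              ar = c(0.2, 0.2, 0.2))
  B2 <- fix_B(xm = -0.4, my = -0.3, xy = -0.3,
              ar = c(0.7, 0.6, 0.6))
  d <- simulate_path_panel(2000, list(B1, B2), n_waves = 3, seed = 29)
  fit_free <- fit_sem(fix_observed_spec(), d)
  fit_eq <- fit_sem(fix_observed_spec(constraints = "equal"), d)
  nt <- nested_test(fit_free, fit_eq)
  expect_lt(nt$p_value, 1e-6)
})

test_that("nested test keeps its size under a true time-constant model", {
  # replicated two-construct ml fits; the 5% level should reject rarely
  rejections <- 0L
  n_reps <- 25L
  spec_free <- clpm_spec(
    list(X = list(observed = "X"), Y = list(observed = "Y")),
    n_waves = 3, structural = "full", estimator = "ml"
  )
  spec_eq <- clpm_spec(
    list(X = list(observed = "X"), Y = list(observed = "Y")),
    n_waves = 3, structural = "full", constraints = "equal",
    estimator = "ml"
  )
  for (r in seq_len(n_reps)) {
    z <- simulate_path_panel(400, fix_B(xy = 0.2), n_waves = 3,
                             seed = 700 + r)
    d <- z[, c(paste0("X_", 1:3), paste0("Y_", 1:3))]
    ff <- fit_sem(spec_free, d, se = FALSE)
    fe <- fit_sem(spec_eq, d, se = FALSE)
    if (nested_test(ff, fe)$p_value < 0.05) rejections <- rejections + 1L
  }
  # binomial(25, 0.05): more than 6 rejections would be wildly off
  expect_lte(rejections, 6L)
})

test_that("fiml matches complete-data estimates and handles MCAR cells", {
  d <- fix_toy_panel(400, seed = 37)
  dm <- d
  set.seed(38)
  for (cl in grep("_[23]$", names(dm), value = TRUE)) {
    dm[[cl]][runif(400) < 0.12] <- NA
  }
  fit_fiml <- fit_sem(fix_observed_spec(missing = "fiml"), dm,
                      se = FALSE)
  fit_full <- fit_sem(fix_observed_spec(), d, se = FALSE)
  keep <- grep("^b_", names(fit_full$estimates), value = TRUE)
  expect_equal(fit_fiml$estimates[keep], fit_full$estimates[keep],
               tolerance = 0.12)
  expect_true(fit_fiml$converged)
  expect_gt(fit_fiml$cfi, 0.95)
})

test_that("vcov shrinks at the 1/n rate", {
  v <- sapply(c(300, 1200), function(n) {
    d <- simulate_path_panel(n, fix_B(), n_waves = 3, seed = 50 + n)
    fit <- fit_sem(fix_observed_spec(), d)
    fit$vcov["b_X.M_t1", "b_X.M_t1"]
  })
  expect_equal(v[1] / v[2], 4, tolerance = 1.5)
})

test_that("misspecified columns and identification problems error early", {
  d <- fix_toy_panel(100)
  spec <- clpm_spec(list(X = list(observed = "X"),
                         Z = list(observed = "Z")),
                    n_waves = 3, estimator = "ml")
  expect_error(fit_sem(spec, d), "lacks columns")
})
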