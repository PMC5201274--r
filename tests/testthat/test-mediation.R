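test_that("path-model mediation recovers the generating decomposition", {
  B <- fix_B(xm = 0.3, my = 0.3, xy = 0.1)
  true <- effect_decomposition(structural_graph(rep(list(B), 3)))
  d <- simulate_path_panel(20000, B, n_waves = 4, seed = 83)
  med <- fit_mediation(d, c("X", "M", "Y"), engine = "composite",
                       n_draws = 10000, seed = 3)
  eff <- med$effects
  expect_equal(eff$total, true$total, tolerance = 0.05)
  expect_equal(eff$indirect, true$indirect, tolerance = 0.05)
  expect_identical(eff$total, eff$direct + eff$indirect)
  expect_true(eff$significant[["indirect"]])
  # interval brackets the point estimate
  expect_lte(eff$ci["indirect", "lower"], eff$indirect)
  expect_gte(eff$ci["indirect", "upper"], eff$indirect)
})

test_that("latent mediation model recovers the generating effects", {
  cfg <- sim_config(n_subjects = 2500, seed = 85,
                    crosslag = fix_crosslag(0.3, 0.3, 0.1))
  true <- true_effects(cfg)
  panel <- generate_panel(cfg)
  med <- fit_mediation(
    panel,
    list(support = list(items = paste0("sup", 1:5), ordinal = TRUE),
         alcohol = list(observed = "alcohol", ordinal = TRUE),
         depressive = list(items = paste0("dep", 1:6), ordinal = TRUE)),
    engine = "sem", estimator = "wls", n_draws = 10000, seed = 5
  )
  eff <- med$effects
  # single replication of the two-stage latent route: the band reflects
  # its sampling spread at n = 2500 with a 5%-prevalence binary mediator
  expect_lt(abs(eff$total - true$total), 0.10)
  expect_lt(abs(eff$direct - true$direct), 0.08)
  expect_lt(abs(eff$indirect - true$indirect), 0.10)
  expect_identical(eff$total, eff$direct + eff$indirect)
  expect_true(eff$significant[["total"]])
  # the path breakdown covers all six wave-spanning paths
  expect_equal(nrow(med$path_table), 6)
  expect_setequal(med$path_table$kind, c("indirect", "direct"))
})

test_that("zero mediation pathways give a null indirect effect", {
  d <- simulate_path_panel(5000, fix_B(xm = 0, my = 0.3, xy = 0.15),
                           n_waves = 4, seed = 87)
  med <- fit_mediation(d, c("X", "M", "Y"), engine = "composite",
                       n_draws = 10000, seed = 7)
  expect_lt(abs(med$effects$indirect), 0.03)
  expect_equal(med$effects$total, med$effects$direct, tolerance = 0.03)
})

test_that("mediation report renders and round-trips its rows", {
  d <- simulate_path_panel(3000, fix_B(), n_waves = 4, seed = 89)
  med <- fit_mediation(d, c("X", "M", "Y"), engine = "composite",
                       n_draws = 5000, seed = 9)
  tab <- mediation_report(list("X-M-Y" = med))
  expect_equal(attr(tab, "status"), "ok")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$indirect, med$effects$indirect)
  expect_equal(tab$indirect_lower,
               unname(med$effects$ci["indirect", "lower"]))
  expect_equal(tab$total, tab$direct + tab$indirect)
  # round-trip through CSV preserves the numbers
  path <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  back <- read.csv(path)
  expect_equal(back$indirect, tab$indirect, tolerance = 1e-12)
  unlink(path)

  # four named models give the four-row layout
  tab4 <- mediation_report(setNames(
    rep(list(med), 4),
    paste0("support-", c("alcohol", "diet", "inactivity",
                         "unhealthy_count"), "-depressive")
  ))
  expect_equal(nrow(tab4), 4)

  # empty set: header only, gate-closed status
  empty <- mediation_report(list())
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "status"), "gate-closed")
  expect_true(all(c("model", "total", "indirect_upper",
                    "proportion_mediated") %in% names(empty)))
})

test_that("proportion mediated is flagged when the total is null", {
  d <- simulate_path_panel(800, fix_B(xm = 0.02, my = 0.02, xy = 0),
                           n_waves = 4, seed = 91)
  med <- fit_mediation(d, c("X", "M", "Y"), engine = "composite",
                       n_draws = 5000, seed = 11)
  if (!med$effects$significant[["total"]]) {
    expect_false(med$effects$proportion_interpretable)
  }
  # and a strong total keeps it interpretable
  d2 <- simulate_path_panel(3000, fix_B(), n_waves = 4, seed = 92)
  med2 <- fit_mediation(d2, c("X", "M", "Y"), engine = "composite",
                        n_draws = 5000, seed = 12)
  expect_true(med2$effects$proportion_interpretable)
  expect_equal(med2$effects$proportion_mediated,
               med2$effects$indirect / med2$effects$total)
})
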