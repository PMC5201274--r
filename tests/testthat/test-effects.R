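test_that("path enumeration matches the known catalogs for small T", {
  # T = 4, full forward edge set: 6 paths, 3 indirect / 3 direct
  g <- structural_graph(rep(list(fix_B()), 3))
  paths <- enumerate_paths(g)
  expect_length(paths$indirect, 3)
  expect_length(paths$direct, 3)
  expect_setequal(
    paths$labels$indirect,
    c("X1 -> M2 -> M3 -> Y4", "X1 -> M2 -> Y3 -> Y4",
      "X1 -> X2 -> M3 -> Y4")
  )
  expect_setequal(
    paths$labels$direct,
    c("X1 -> X2 -> X3 -> Y4", "X1 -> X2 -> Y3 -> Y4",
      "X1 -> Y2 -> Y3 -> Y4")
  )

  # T = 2: the single direct edge
  g2 <- structural_graph(list(fix_B()))
  p2 <- enumerate_paths(g2)
  expect_length(p2$indirect, 0)
  expect_identical(p2$labels$direct, "X1 -> Y2")

  # T = 3: three paths, one indirect
  g3 <- structural_graph(rep(list(fix_B()), 2))
  p3 <- enumerate_paths(g3)
  expect_length(p3$indirect, 1)
  expect_identical(p3$labels$indirect, "X1 -> M2 -> Y3")
  expect_length(p3$direct, 2)
})

test_that("single-product decomposition is exact", {
  B1 <- fix_B(xm = 0.5, my = 0, xy = 0, ar = c(0, 0, 0))
  B2 <- fix_B(xm = 0, my = 0.4, xy = 0, ar = c(0, 0, 0))
  eff <- effect_decomposition(structural_graph(list(B1, B2)))
  expect_equal(eff$indirect, 0.2)
  expect_equal(eff$direct, 0)
  expect_equal(eff$total, 0.2)
  expect_equal(eff$proportion_mediated, 1)
})

test_that("zero exposure-to-mediator edges give exactly zero indirect", {
  B <- fix_B(xm = 0, my = 0.4, xy = 0.2)
  eff <- effect_decomposition(structural_graph(rep(list(B), 3)))
  expect_identical(eff$indirect, 0)
  expect_identical(eff$total, eff$direct)
})

test_that("path-sum decomposition equals the matrix-product oracle", {
  set.seed(401)
  for (rep in 1:120) {
    n_waves <- sample(2:5, 1)
    B_list <- random_B_list(n_waves)
    eff <- effect_decomposition(structural_graph(B_list))
    ora <- oracle_effects(B_list)
    expect_equal(eff$total, ora$total, tolerance = 1e-13)
    expect_equal(eff$direct, ora$direct, tolerance = 1e-13)
    expect_equal(eff$indirect, ora$indirect, tolerance = 1e-13)
    expect_identical(eff$total, eff$direct + eff$indirect)
  }
})

test_that("degenerate Monte Carlo draws collapse onto point estimates", {
  fit <- list(
    estimates = c(b_a = 0.5, b_b = 0.4),
    vcov = matrix(0, 2, 2, dimnames = list(c("b_a", "b_b"),
                                           c("b_a", "b_b")))
  )
  B1 <- fix_B(xm = 0.5, my = 0, xy = 0, ar = c(0, 0, 0))
  B2 <- fix_B(xm = 0, my = 0.4, xy = 0, ar = c(0, 0, 0))
  P1 <- matrix(NA_character_, 3, 3, dimnames = dimnames(B1))
  P1["M", "X"] <- "b_a"
  P2 <- matrix(NA_character_, 3, 3, dimnames = dimnames(B2))
  P2["Y", "M"] <- "b_b"
  g <- structural_graph(list(B1, B2), par_list = list(P1, P2))
  eff <- monte_carlo_ci(fit, g, n_draws = 2000, seed = 7)
  expect_equal(unname(eff$ci["indirect", ]), c(0.2, 0.2))
  expect_equal(unname(eff$ci["total", ]), c(0.2, 0.2))
  expect_false(eff$significant[["direct"]])
  expect_true(eff$significant[["indirect"]])
})

test_that("single-edge percentile interval matches the normal quantiles", {
  se <- 0.05
  fit <- list(estimates = c(b = 0.3),
              vcov = matrix(se^2, dimnames = list("b", "b")))
  B <- matrix(0, 3, 3, dimnames = list(c("X", "M", "Y"),
                                       c("X", "M", "Y")))
  B["Y", "X"] <- 0.3
  P <- matrix(NA_character_, 3, 3, dimnames = dimnames(B))
  P["Y", "X"] <- "b"
  g <- structural_graph(list(B), par_list = list(P))
  eff <- monte_carlo_ci(fit, g, n_draws = 20000, seed = 3)
  # quantile Monte Carlo error at 20000 draws is about 0.001
  expect_lt(abs(eff$ci["total", "lower"] - (0.3 - 1.96 * se)), 0.005)
  expect_lt(abs(eff$ci["total", "upper"] - (0.3 + 1.96 * se)), 0.005)
})

test_that("Monte Carlo intervals are deterministic given the seed", {
  fit <- fit_path_model(fix_toy_panel(300, seed = 5),
                        n_waves = 3, edges = "forward")
  e1 <- monte_carlo_ci(fit, fit$graph, n_draws = 5000, seed = 9)
  e2 <- monte_carlo_ci(fit, fit$graph, n_draws = 5000, seed = 9)
  expect_identical(e1$ci, e2$ci)
  e3 <- monte_carlo_ci(fit, fit$graph, n_draws = 5000, seed = 10)
  expect_false(identical(e1$ci, e3$ci))
})

test_that("additivity total = direct + indirect carries into the draws", {
  # when the direct paths are all zero the total and indirect draws are
  # the same sample, so their intervals must coincide exactly
  B1 <- fix_B(xm = 0.5, my = 0, xy = 0, ar = c(0, 0, 0))
  B2 <- fix_B(xm = 0, my = 0.4, xy = 0, ar = c(0, 0, 0))
  P1 <- matrix(NA_character_, 3, 3, dimnames = dimnames(B1))
  P1["M", "X"] <- "b_a"
  P2 <- matrix(NA_character_, 3, 3, dimnames = dimnames(B2))
  P2["Y", "M"] <- "b_b"
  g <- structural_graph(list(B1, B2), par_list = list(P1, P2))
  fit <- list(estimates = c(b_a = 0.5, b_b = 0.4),
              vcov = diag(c(0.01, 0.01)) |>
                (\(m) {
                  dimnames(m) <- list(c("b_a", "b_b"), c("b_a", "b_b"))
                  m
                })())
  eff <- monte_carlo_ci(fit, g, n_draws = 10000, seed = 2)
  expect_identical(eff$ci["total", ], eff$ci["indirect", ])
})

test_that("interval width shrinks like 1/sqrt(n)", {
  widths <- sapply(c(250, 1000, 4000), function(n) {
    d <- simulate_path_panel(n, fix_B(), n_waves = 4, seed = 100 + n)
    fit <- fit_path_model(d, n_waves = 4, edges = "forward")
    eff <- monte_carlo_ci(fit, fit$graph, n_draws = 5000, seed = 1)
    diff(eff$ci["indirect", ])
  })
  # quadrupling n should roughly halve the width
  expect_lt(widths[2] / widths[1], 0.72)
  expect_lt(widths[3] / widths[2], 0.72)
})

test_that("true_effects agrees with the oracle and is exactly additive", {
  set.seed(402)
  for (rep in 1:25) {
    cl <- fix_crosslag(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3),
                       runif(1, -0.3, 0.3))
    cfg <- sim_config(50, crosslag = cl, seed = rep)
    te <- true_effects(cfg)
    ora <- oracle_effects(cfg$B_list)
    expect_equal(te$total, ora$total, tolerance = 1e-13)
    expect_identical(te$total, te$direct + te$indirect)
  }
})
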