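# Shared fixtures: small generating systems used across test files.

# forward-edge transition matrix (rows = target, cols = source; X, M, Y)
fix_B <- function(xm = 0.3, my = 0.3, xy = 0.1,
                  ar = c(0.6, 0.5, 0.5)) {
  B <- diag(ar)
  dimnames(B) <- list(c("X", "M", "Y"), c("X", "M", "Y"))
  B["M", "X"] <- xm
  B["Y", "M"] <- my
  B["Y", "X"] <- xy
  B
}

# crosslag argument for sim_config() (diagonal ignored there)
fix_crosslag <- function(xm = 0.3, my = 0.3, xy = 0.1) {
  matrix(c(0, 0, 0, xm, 0, 0, xy, my, 0), 3, 3, byrow = TRUE)
}

# random DAG coefficients on the full forward edge set for T waves
random_B_list <- function(n_waves, scale = 0.5) {
  lapply(seq_len(n_waves - 1L), function(t) {
    B <- matrix(0, 3, 3, dimnames = list(c("X", "M", "Y"),
                                         c("X", "M", "Y")))
    B["X", "X"] <- runif(1, -scale, scale)
    B["M", "X"] <- runif(1, -scale, scale)
    B["M", "M"] <- runif(1, -scale, scale)
    B["Y", "X"] <- runif(1, -scale, scale)
    B["Y", "M"] <- runif(1, -scale, scale)
    B["Y", "Y"] <- runif(1, -scale, scale)
    B
  })
}

# matrix-product oracle for total and direct overall effects:
# total = (Y,X) entry of the ordered product of transition matrices;
# direct = same product with every X->M entry zeroed
oracle_effects <- function(B_list) {
  prod_of <- function(mats) {
    P <- diag(3)
    for (B in mats) P <- B %*% P
    P
  }
  # construct order (X, M, Y): total is the (Y, X) = (3, 1) entry
  total <- unname(prod_of(B_list)[3, 1])
  B0 <- lapply(B_list, function(B) {
    B[2, 1] <- 0 # remove every X -> M edge
    B
  })
  direct <- unname(prod_of(B0)[3, 1])
  list(total = total, direct = direct, indirect = total - direct)
}

# three-wave observed toy panel for estimator cross-checks
fix_toy_panel <- function(n = 500, seed = 1) {
  simulate_path_panel(n, fix_B(), n_waves = 3, seed = seed)
}

# internal numeric kernel, exposed for oracle comparison in tests
pbinorm_for_test <- function(...) clpmed:::pbinorm(...)

# observed X/M/Y model specification for the ml route
fix_observed_spec <- function(n_waves = 3, structural = "full",
                              estimator = "ml", ...) {
  clpm_spec(
    list(X = list(observed = "X"), M = list(observed = "M"),
         Y = list(observed = "Y")),
    n_waves = n_waves, structural = structural, estimator = estimator,
    ...
  )
}
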