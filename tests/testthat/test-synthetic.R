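test_that("synthetic generators are deterministic under (config, seed)", {
  cfg <- sim_config(n_group_a = 2, n_group_b = 2, N = 3, T = 96,
                    labels = c("A", "B", "C"), seed = 5)
  expect_identical(gen_var_cohort(cfg), gen_var_cohort(cfg))
  b1 <- gen_benchmark_dataset(seed = 3, n_aca = 2, n_control = 2, T = 96)
  b2 <- gen_benchmark_dataset(seed = 3, n_aca = 2, n_control = 2, T = 96)
  expect_identical(b1, b2)
  A <- matrix(c(0, 0.3, -0.3, 0), 2, 2)
  expect_identical(gen_egn_ts(A, c(0.4, 0.6), seed = 9),
                   gen_egn_ts(A, c(0.4, 0.6), seed = 9))
  # adding subjects does not perturb existing streams
  b3 <- gen_benchmark_dataset(seed = 3, n_aca = 2, n_control = 3, T = 96)
  expect_identical(b3$rs1$sessions[[1]]$values, b1$rs1$sessions[[1]]$values)
})

test_that("uncoupled VAR channels are nearly uncorrelated", {
  cfg <- sim_config(n_group_a = 1, n_group_b = 1, N = 3, T = 2000,
                    labels = c("A", "B", "C"), seed = 11)
  ts <- gen_var_cohort(cfg)$sessions[[1]]
  r <- cor(ts$values)
  expect_lt(max(abs(r[upper.tri(r)])), 0.2)
})

test_that("planted lag-1 coupling matches the Yule-Walker cross-covariance", {
  phi <- 0.3; c12 <- 0.5
  cfg <- sim_config(n_group_a = 1, n_group_b = 1, N = 2, T = 2000,
                    labels = c("A", "B"), ar1_coef = phi, seed = 13,
                    effects = list(list(kind = "var_coupling", from = "A",
                                        to = "B", lag = 1, coef = c12,
                                        both_groups = TRUE)))
  ts <- gen_var_cohort(cfg)$sessions[[1]]
  x <- ts$values
  samp <- cor(x[-nrow(x), 1], x[-1, 2])
  # oracle: stationary covariance from the discrete Lyapunov equation
  Phi <- matrix(c(phi, c12, 0, phi), 2, 2)
  Sigma <- matrix(solve(diag(4) - kronecker(Phi, Phi), c(diag(2))), 2, 2)
  lag1 <- Phi %*% Sigma
  expected <- lag1[2, 1] / sqrt(Sigma[1, 1] * Sigma[2, 2])
  expect_gt(samp, 0.3)
  expect_lt(abs(samp - expected), 0.1)
})

test_that("unstable VAR coefficients are refused with the spectral radius", {
  cfg <- sim_config(n_group_a = 1, n_group_b = 1, N = 2, T = 96,
                    labels = c("A", "B"), ar1_coef = 0.9, seed = 1,
                    effects = list(list(kind = "var_coupling", from = "A",
                                        to = "B", lag = 1, coef = 0.9,
                                        both_groups = TRUE),
                                   list(kind = "var_coupling", from = "B",
                                        to = "A", lag = 1, coef = 0.9,
                                        both_groups = TRUE)))
  expect_error(gen_var_cohort(cfg), "spectral radius")
  expect_error(sim_config(N = 3, labels = c("A", "B", "C"),
                          effects = list(list(kind = "var_coupling",
                                              from = "Z", to = "A",
                                              lag = 1, coef = 0.1))),
               "unknown network")
})

test_that("phase-locked pairs honour fraction, offset, and noise limits", {
  p0 <- gen_phase_locked_pair(20, 1, 0, T = 208, dt = 2, noise_sd = 0,
                              seed = 1)
  expect_equal(p0$values[, 1], p0$values[, 2], ignore_attr = TRUE)
  ppi <- gen_phase_locked_pair(20, 0.5, pi, T = 208, dt = 2, noise_sd = 0,
                               seed = 1)
  win <- attr(ppi, "coherent_window")
  expect_lt(cor(ppi$values[win, 1], ppi$values[win, 2]), -0.95)
  expect_length(win, 104)
  expect_error(gen_phase_locked_pair(2, 0.5, 0, T = 208, dt = 2),
               "resolvable")
  expect_error(gen_phase_locked_pair(400, 0.5, 0, T = 208, dt = 2),
               "resolvable")
})

test_that("replicator simulator fixes A = 0 and refuses boundary starts", {
  e0 <- gen_egn_ts(matrix(0, 3, 3), c(0.3, 0.5, 0.7), T = 64, dt = 1,
                   noise_sd = 0, seed = 1)
  expect_equal(max(abs(sweep(e0$values, 2, c(0.3, 0.5, 0.7)))), 0)
  expect_error(gen_egn_ts(matrix(0, 2, 2), c(0, 0.5), T = 64, dt = 1),
               "degenerate")
  # with a positive emulation weight and no noise, the follower moves
  # monotonically toward the strategy signalled by its source
  A <- matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE)
  e <- gen_egn_ts(A, c(0.3, 0.8), T = 100, dt = 0.5, noise_sd = 0, seed = 1)
  expect_true(all(diff(e$values[, 1]) >= -1e-12))
  expect_equal(max(e$values[, 1]), 0.95)
})

test_that("benchmark dataset has the study shape and planted separation", {
  b <- gen_benchmark_dataset(seed = 2, n_aca = 3, n_control = 4, T = 160)
  expect_equal(length(b$rs1), 7)
  expect_equal(length(b$rs2), 7)
  expect_equal(dim(b$rs1$sessions[[1]]$values), c(160, 14))
  expect_identical(b$rs1$network_labels, BENCHMARK_LABELS)
  # ACA carries the planted DMN->AUDI lag coupling; controls do not
  lagcor <- function(ts) {
    x <- ts$values
    cor(x[-nrow(x), "DMN"], x[-1, "AUDI"])
  }
  aca <- mean(vapply(b$rs1$sessions[1:3], lagcor, numeric(1)))
  ctl <- mean(vapply(b$rs1$sessions[4:7], lagcor, numeric(1)))
  expect_gt(aca, ctl + 0.15)
})
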