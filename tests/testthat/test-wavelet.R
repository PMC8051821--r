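test_that("Morlet transform localizes a pure tone and is linear", {
  dt <- 2; T <- 208; tt <- (0:(T - 1)) * dt
  x <- sin(2 * pi * tt / 20)
  cw <- morlet_cwt(x, dt)
  pw <- Mod(cw$wave)^2
  ridge <- cw$periods[which.max(rowMeans(pw[, 50:150]))]
  step <- 2^(1 / 12)
  expect_lt(abs(log(ridge / 20)), log(step) + 1e-9)
  expect_true(all(Mod(morlet_cwt(rep(0, T), dt)$wave) == 0))
  cw2 <- morlet_cwt(2 * x, dt)
  expect_equal(Mod(cw2$wave), 2 * Mod(cw$wave), tolerance = 1e-10)
  # record too short for the largest period: truncated with warning
  expect_warning(short <- morlet_cwt(rnorm(80), dt), "truncat")
  expect_lte(max(short$periods), 80 * dt / 2 * 2^(1 / 12))
})

test_that("self-coherence saturates inside the cone of influence", {
  set.seed(4)
  x <- rnorm(256)
  sc <- coherence_pair(x, x, 2)
  expect_gte(min(sc$coherence[sc$coi_mask]), 0.99)
  expect_true(all(sc$coherence >= 0 & sc$coherence <= 1))
  expect_true(all(sc$phase > -pi - 1e-9 & sc$phase <= pi + 1e-9))
})

test_that("a quarter-period delay shows up as +pi/2 phase (x leads y)", {
  dt <- 2; T <- 256; tt <- (0:(T - 1)) * dt
  set.seed(5)
  x <- sin(2 * pi * tt / 20) + 0.01 * rnorm(T)
  y <- sin(2 * pi * (tt - 5) / 20) + 0.01 * rnorm(T)
  sc <- coherence_pair(x, y, dt)
  i20 <- which.min(abs(sc$periods - 20))
  med_phase <- median(sc$phase[i20, sc$coi_mask[i20, ]])
  expect_lt(abs(med_phase - pi / 2), 0.2)
})

test_that("independent noise stays weakly coherent on average", {
  set.seed(6)
  sc <- coherence_pair(rnorm(2000), rnorm(2000), 2)
  expect_lt(mean(sc$coherence[sc$coi_mask]), 0.5)
})

test_that("phase quadrants partition (-pi, pi] with the stated boundaries", {
  expect_identical(classify_phase(0), "IN_PHASE")
  expect_identical(classify_phase(pi), "ANTI_PHASE")
  expect_identical(classify_phase(pi / 2), "LEADING")
  expect_identical(classify_phase(-pi / 2), "LAGGING")
  # half-open lower boundaries
  expect_identical(classify_phase(c(-pi / 4, pi / 4, 3 * pi / 4, -3 * pi / 4)),
                   c("IN_PHASE", "LEADING", "ANTI_PHASE", "LAGGING"))
  grid <- seq(-pi + 1e-9, pi, length.out = 1000)
  cls <- classify_phase(grid)
  expect_true(all(cls %in% c("IN_PHASE", "ANTI_PHASE", "LEADING", "LAGGING")))
  expect_error(classify_phase(4), "-pi")
})

test_that("significance masks are seed-deterministic and saturate on identity", {
  set.seed(7)
  x <- rnorm(128); y <- rnorm(128)
  sc <- coherence_pair(x, y, 2)
  m1 <- significance_mask(x, y, sc, n_surrogates = 60, seed = 3)
  m2 <- significance_mask(x, y, sc, n_surrogates = 60, seed = 3)
  expect_identical(m1$sig_mask, m2$sig_mask)
  expect_error(significance_mask(x, y, sc, n_surrogates = 10), ">= 50")
  sc_id <- coherence_pair(x, x, 2)
  sc_id <- significance_mask(x, x, sc_id, n_surrogates = 60, seed = 3)
  expect_gte(mean(sc_id$sig_mask[sc_id$coi_mask]), 0.99)
})

test_that("time-of-coherence counts dominant phases and respects totals", {
  set.seed(8)
  x <- rnorm(208); y <- rnorm(208)
  sc <- coherence_pair(x, y, 2)
  # all-false mask -> all zero
  sc$sig_mask <- matrix(FALSE, length(sc$periods), 208)
  expect_true(all(time_of_coherence(sc) == 0))
  # random mask: per band, phases sum to the total significant-time share
  set.seed(9)
  sc$sig_mask <- matrix(runif(length(sc$periods) * 208) < 0.3,
                        length(sc$periods), 208)
  toc <- time_of_coherence(sc)
  M <- sc$sig_mask & sc$coi_mask
  for (k in 1:5) {
    rows <- rsndyn:::band_scale_rows(sc$periods)[[k]]
    total <- 100 * mean(colSums(M[rows, , drop = FALSE]) > 0)
    expect_equal(sum(toc[k, ]), total, tolerance = 1e-12)
  }
  expect_true(all(toc >= 0 & toc <= 100))
})

test_that("planted in-phase windows are recovered at their true share", {
  p <- gen_phase_locked_pair(20, 0.5, 0, T = 208, dt = 2, noise_sd = 0.7,
                             seed = 44)
  sc <- coherence_pair(p$values[, 1], p$values[, 2], 2)
  sc <- significance_mask(p$values[, 1], p$values[, 2], sc,
                          n_surrogates = 100, seed = 45)
  toc <- time_of_coherence(sc)
  expect_gt(toc["s3", "IN_PHASE"], 35)
  expect_lt(toc["s3", "IN_PHASE"], 65)
})

test_that("leading for (A,B) equals lagging for (B,A)", {
  p <- gen_phase_locked_pair(24, 0.7, pi / 2, T = 256, dt = 2,
                             noise_sd = 0.3, seed = 10)
  x <- p$values[, 1]; y <- p$values[, 2]
  sab <- coherence_pair(x, y, 2)
  sba <- coherence_pair(y, x, 2)
  mask <- matrix(TRUE, length(sab$periods), 256)
  sab$sig_mask <- mask; sba$sig_mask <- mask
  tab <- time_of_coherence(sab); tba <- time_of_coherence(sba)
  expect_equal(tab[, "LEADING"], tba[, "LAGGING"], tolerance = 1e-9)
  expect_equal(tab[, "LAGGING"], tba[, "LEADING"], tolerance = 1e-9)
  expect_equal(tab[, "IN_PHASE"], tba[, "IN_PHASE"], tolerance = 1e-9)
})

test_that("coherence feature rows have the advertised grammar and count", {
  ts <- toy_ts(T = 160, N = 2, seed = 11, labels = c("MVISU", "DMN"))
  f <- wcoh_features(ts, n_surrogates = 60, seed = 12)
  expect_length(f, 20)
  expect_true(all(c("ip_MVISU-DMN_s2", "ap_MVISU-DMN_s5",
                    "lead_MVISU-DMN_s1", "lag_MVISU-DMN_s4") %in% names(f)))
  expect_true(all(f >= 0 & f <= 100))
  # determinism through the cache path
  cache <- rsndyn:::new_threshold_cache()
  f2 <- wcoh_features(ts, n_surrogates = 60, seed = 12, cache = cache)
  f3 <- wcoh_features(ts, n_surrogates = 60, seed = 12, cache = cache)
  expect_identical(f2, f3)
  expect_identical(f, f2)
})
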