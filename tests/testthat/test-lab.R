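test_that("flask reduction: symmetric mix is lossless, and scales linearly", {
  sym <- calorimetry_record(M_cw = 0.1, M_hw = 0.1, T_cw = 293, T_hw = 337,
                            T_e = 315)   # equal swings of 22 K
  expect_equal(flask_heat_capacity(sym), 0)
  rec <- calorimetry_record(M_cw = 0.1, M_hw = 0.1, T_cw = 293, T_hw = 343,
                            T_e = 315, C_w = 4186)
  # direct arithmetic: (0.1*4186*22 - 0.1*4186*28) / 28
  expect_equal(flask_heat_capacity(rec), -89.7, tolerance = 1e-10)
  dbl <- calorimetry_record(M_cw = 0.2, M_hw = 0.2, T_cw = 293, T_hw = 343,
                            T_e = 315, C_w = 4186)
  expect_equal(flask_heat_capacity(dbl), 2 * flask_heat_capacity(rec))
  expect_error(calorimetry_record(M_cw = 0.1, M_hw = 0.1, T_cw = 293,
                                  T_hw = 315, T_e = 315), "T_hw > T_e")
})

test_that("capsule reduction has the right null, sign and degeneracies", {
  base <- calorimetry_record(M_cw = 0.12, T_cw = 300, T_e = 300.0,
                             T_c = 360)
  expect_equal(capsule_heat_capacity(base, Hf = 80), 0)   # T_e = T_cw
  warm <- calorimetry_record(M_cw = 0.12, T_cw = 295, T_e = 301, T_c = 360)
  expect_gt(capsule_heat_capacity(warm, Hf = 80), 0)      # T_c > T_e > T_cw
  deg <- calorimetry_record(M_cw = 0.12, T_cw = 295, T_e = 301, T_c = 301)
  expect_error(capsule_heat_capacity(deg, Hf = 80), "degenerate")
})

test_that("calorimetry round-trip recovers the generating truths", {
  for (cp_true in c(2489, 1640)) {
    cs <- generate_calorimetry(true_Hf = 80, true_Hc = 45, true_Cp = cp_true)
    Hf <- flask_heat_capacity(cs$flask)
    expect_equal(Hf, 80, tolerance = 1e-9)
    Hc <- capsule_heat_capacity(cs$capsule, Hf)
    expect_equal(Hc, 45, tolerance = 1e-9)
    expect_equal(sample_specific_heat(cs$sample, Hf, Hc), cp_true,
                 tolerance = 1e-9)
  }
  # generator honours the mixing-run temperature ordering
  cs <- generate_calorimetry(true_Hf = 80, true_Hc = 45, true_Cp = 2489)
  expect_true(cs$flask$T_hw > cs$flask$T_e && cs$flask$T_e > cs$flask$T_cw)
})

test_that("sample reduction scales inversely with sample mass", {
  cs <- generate_calorimetry(true_Hf = 80, true_Hc = 45, true_Cp = 2000)
  Hf <- flask_heat_capacity(cs$flask)
  Hc <- capsule_heat_capacity(cs$capsule, Hf)
  rec <- cs$sample
  half <- rec; half$M_m <- rec$M_m / 2
  expect_equal(sample_specific_heat(half, Hf, Hc),
               2 * sample_specific_heat(rec, Hf, Hc))
})

test_that("log-time slope fit recovers exact lines and rejects degenerate input", {
  t <- seq(3, 300, by = 3)
  exact <- data.frame(time = t, temperature = 300 + 2.5 * log(t))
  fit <- fit_log_slope(exact)
  expect_equal(fit$S, 2.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # pure noise around a constant: no explanatory power
  set.seed(7)
  noisy <- data.frame(time = t, temperature = 300 + rnorm(length(t), 0, 0.5))
  expect_lt(fit_log_slope(noisy)$r_squared, 0.3)
  flat <- data.frame(time = t, temperature = rep(300, length(t)))
  expect_error(fit_log_slope(flat), "degenerate")
  expect_error(fit_log_slope(exact, window = 1:3), "at least 5")
})

test_that("auto window excludes nonlinear flanks of a hot-wire trace", {
  t <- seq(3, 600, by = 3)
  S_core <- 1.4
  temp <- 298 + S_core * log(t)
  early <- t < 40                        # probe/contact transient
  temp[early] <- temp[early] - 2 * (40 - t[early]) / 40
  late <- t > 420                        # boundary losses flatten the rise
  temp[late] <- temp[late] - 0.004 * (t[late] - 420)
  fit <- fit_log_slope(data.frame(time = t, temperature = temp))
  expect_equal(fit$S, S_core, tolerance = 0.02)
  expect_gt(min(fit$window), 1)          # early flank dropped
})

test_that("log-time slope is invariant to time-unit rescaling", {
  t <- seq(3, 300, by = 3)
  d1 <- data.frame(time = t, temperature = 300 + 1.8 * log(t))
  d2 <- d1; d2$time <- d2$time / 60      # minutes instead of seconds
  f1 <- fit_log_slope(d1); f2 <- fit_log_slope(d2)
  expect_equal(f2$S, f1$S, tolerance = 1e-10)
  # intercept shifts by the analytically expected S * log(60)
  expect_equal(f2$intercept - f1$intercept, 1.8 * log(60), tolerance = 1e-8)
})

test_that("hot-wire conductivity reduction matches hand arithmetic and scalings", {
  t <- seq(3, 300, by = 3)
  S <- 3.0
  rec <- hotwire_record(I = 1, R = 11.49, heater_length = 0.235,
                        samples = data.frame(time = t,
                                             temperature = 300 + S * log(t)))
  out <- hotwire_conductivity(rec)
  # I^2 (R/L) / (4 pi S) = (11.49/0.235) / (12 pi)
  expect_equal(out$k, (11.49 / 0.235) / (4 * pi * 3), tolerance = 1e-10)
  expect_equal(out$k, 1.297, tolerance = 1e-3)
  rec2 <- rec; rec2$I <- 2
  expect_equal(hotwire_conductivity(rec2)$k, 4 * out$k)    # I^2 scaling
  # literal total-resistance mode
  expect_equal(hotwire_conductivity(rec, r_mode = "total")$k,
               11.49 / (4 * pi * 3))
  cooling <- hotwire_record(I = 1, R = 11.49,
                            samples = data.frame(time = t,
                                                 temperature = 300 - log(t)))
  expect_error(hotwire_conductivity(cooling), "non-positive")
})

test_that("hot-wire round-trip recovers the study conductivities", {
  for (k_true in c(0.18, 0.28)) {
    rec <- generate_hotwire(true_k = k_true, seed = 1)
    expect_equal(hotwire_conductivity(rec)$k, k_true, tolerance = 1e-6)
  }
})

test_that("lab CSV readers reconstruct records", {
  cs <- generate_calorimetry(true_Hf = 80, true_Hc = 45, true_Cp = 2489)
  f <- tempfile(fileext = ".csv")
  df <- data.frame(M_cw = cs$flask$M_cw, M_hw = cs$flask$M_hw,
                   T_cw = cs$flask$T_cw, T_hw = cs$flask$T_hw,
                   T_e = cs$flask$T_e, C_w = cs$flask$C_w)
  write.csv(df, f, row.names = FALSE)
  recs <- read_calorimetry_csv(f)
  expect_length(recs, 1)
  expect_equal(flask_heat_capacity(recs[[1]]), 80, tolerance = 1e-9)

  hw <- generate_hotwire(true_k = 0.18, seed = 1)
  f2 <- tempfile(fileext = ".csv")
  df2 <- hw$samples
  df2$I <- hw$I; df2$R <- hw$R; df2$heater_length <- hw$heater_length
  write.csv(df2, f2, row.names = FALSE)
  rec2 <- read_hotwire_csv(f2)
  expect_equal(hotwire_conductivity(rec2)$k, 0.18, tolerance = 1e-6)
})
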