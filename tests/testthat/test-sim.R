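# Solver tests run on a coarse grid (41 nodes) or a reduced radius where the
# property under test does not depend on the full-resolution study setup.

test_that("radial grid is uniform, surface-terminated and volume-consistent", {
  g <- radial_grid(25, 0.061)
  expect_length(g$r, 25)
  expect_equal(g$r[1], 0)
  expect_equal(g$r[25], 0.061)
  expect_true(all(diff(g$r) > 0))
  expect_equal(sum(g$volumes), 0.061^2 / 2)   # cross-section per radian
  expect_error(radial_grid(5, 0.061), "at least 10")
})

test_that("an equilibrated oven is a fixed point of the solver", {
  # T_oven = T0 and saturated ambient humidity: no driving force at all
  p <- unclass(bake_params("control")); p$RH <- 100
  p <- do.call(parameter_set, p)
  res <- solve_bake(bake_config(p, T_oven = 297.15, T0 = 297.15,
                                duration = 600, n_nodes = 41))
  expect_equal(max(abs(res$T - 297.15)), 0)
  expect_equal(max(abs(res$W - p$W0)), 0)
  expect_equal(max(abs(res$weight_loss)), 0)
})

test_that("sealed boundaries conserve volume-integrated water", {
  p <- bake_params("control")
  g <- radial_grid(41, p$r)
  W_init <- 0.3 + 0.2 * cos(pi * g$r / p$r)   # non-uniform profile
  res <- solve_bake(bake_config(p, T_oven_C = 190, n_nodes = 41,
                                mass_transfer = FALSE, h = 0, epsilon = 1e-9,
                                W_init = W_init, rtol = 1e-10, atol = 1e-12,
                                duration = 2400))
  total <- as.numeric(res$W %*% g$volumes)
  expect_lt(max(abs(total - total[1])) / total[1], 1e-8)
})

test_that("convection-only constant-property run matches the Bessel series", {
  p <- bake_params("control")
  res <- solve_bake(bake_config(p, T_oven_C = 190, cp_mode = "constant",
                                epsilon = 0, mass_transfer = FALSE))
  Bi <- p$h * p$r / p$k
  alpha <- p$k / (p$rho * p$Cp_meas)
  for (tt in c(600, 1200, 2400)) {
    i <- which(res$times == tt)
    exp_center <- cylinder_series_T(0, tt, p$r, alpha, Bi, 297.15, 463.15)
    exp_surf <- cylinder_series_T(p$r, tt, p$r, alpha, Bi, 297.15, 463.15)
    expect_equal(res$T[i, 1], exp_center, tolerance = 5e-3)
    expect_equal(res$T[i, ncol(res$T)], exp_surf, tolerance = 5e-3)
  }
})

test_that("with evaporation disabled the surface relaxes to the oven temperature", {
  p <- small_params(r = 0.01)
  res <- solve_bake(bake_config(p, T_oven_C = 190, cp_mode = "constant",
                                mass_transfer = FALSE, n_nodes = 41,
                                duration = 6000))
  expect_lt(463.15 - res$T[length(res$times), 41], 1)
  # and never exceeds it (second-law bound for this boundary condition)
  expect_true(all(res$T < 463.15))
})

test_that("default bake keeps moisture within physical bounds", {
  p <- bake_params("control")
  res <- solve_bake(bake_config(p, T_oven_C = 230, n_nodes = 41))
  expect_true(all(res$W >= 0))
  expect_true(all(res$W <= p$W0 + 1e-9))
  expect_true(all(res$T >= 297.15 - 1e-6 & res$T <= 503.15 + 1e-6))
})

test_that("centre symmetry holds at all saved times", {
  p <- bake_params("control")
  res <- solve_bake(bake_config(p, T_oven_C = 190, n_nodes = 41))
  dr <- res$grid$dr
  for (i in seq(1, length(res$times), by = 40)) {
    grad_c <- abs(res$T[i, 2] - res$T[i, 1]) / dr
    grad_max <- max(abs(diff(res$T[i, ]))) / dr
    if (grad_max > 1e-6) expect_lt(grad_c, 0.05 * grad_max)
    grad_cw <- abs(res$W[i, 2] - res$W[i, 1]) / dr
    grad_maxw <- max(abs(diff(res$W[i, ]))) / dr
    if (grad_maxw > 1e-8) expect_lt(grad_cw, 0.05 * grad_maxw)
  }
})

test_that("derived crust and weight-loss series behave like a heating bake", {
  p <- bake_params("control")
  res <- solve_bake(bake_config(p, T_oven_C = 190, n_nodes = 41))
  crust <- crust_temperature_series(res)
  expect_equal(crust[1], 24, tolerance = 1e-8)        # 297.15 K start
  expect_true(all(diff(crust) > -1e-9))               # monotone heating
  expect_true(all(crust < 190))                       # below the oven
  wl <- weight_loss_series(res)
  expect_equal(wl[1], 0)
  expect_true(all(diff(wl) > -1e-9))
  expect_equal(wl, res$weight_loss)
  # hand values of the weight-loss formula at the control moisture
  expect_equal(100 * (0.58 - 0) / 1.58, 36.7089, tolerance = 1e-4)
  expect_equal(100 * (0.58 - 0.0253) / 1.58, 35.1076, tolerance = 1e-4)
  st <- res$sample_table
  expect_equal(st$time_s, c(0, seq(300, 2400, by = 300)))
  expect_equal(st$crust_T_C[1], 24, tolerance = 1e-8)
})

test_that("wet-basis configuration converts the initial moisture", {
  p <- bake_params("control")
  res <- solve_bake(bake_config(p, T_oven_C = 190, n_nodes = 41,
                                wl_basis = "wet", duration = 60))
  expect_equal(res$W0_eff, 0.58 / (1 - 0.58))
  expect_equal(res$W[1, 1], 0.58 / 0.42)
})

test_that("grid refinement leaves the 40-min crust temperature unchanged", {
  p <- bake_params("control")
  cT <- function(n) {
    r <- solve_bake(bake_config(p, T_oven_C = 190, n_nodes = n))
    r$crust_T[length(r$times)]
  }
  c1 <- cT(51); c2 <- cT(101)
  expect_lt(abs(c2 - c1) / abs(c1), 0.005)
})

test_that("run_grid tabulates sweeps and tolerates per-row failures", {
  p <- bake_params("control")
  cfg <- bake_config(p, T_oven_C = 190, n_nodes = 41)
  tab1 <- run_grid(list(cfg))
  expect_equal(nrow(tab1), 1)
  res <- solve_bake(cfg)
  expect_equal(tab1$crust_T_C, res$crust_T[length(res$times)])
  expect_equal(tab1$weight_loss_pct, res$weight_loss[length(res$times)])
  expect_equal(nrow(run_grid(list())), 0)
  # a failing configuration is reported in-row, not fatal
  bad <- cfg; bad$rtol <- -1
  tab2 <- run_grid(list(cfg, bad))
  expect_equal(tab2$status[1], "ok")
  expect_false(tab2$status[2] == "ok")
  expect_true(is.na(tab2$crust_T_C[2]))
})

test_that("crust temperature orderings hold across formulations and ovens", {
  tabs <- run_grid(default_sweep_configs(ovens_C = c(190, 230), n_nodes = 41))
  ct <- function(f, Tc) tabs$crust_T_C[tabs$formulation == f &
                                         tabs$T_oven_C == Tc]
  expect_gt(ct("control", 230), ct("control", 190))
  expect_gt(ct("guar", 230), ct("guar", 190))
  expect_gt(ct("control", 190), ct("guar", 190))
  expect_gt(ct("control", 230), ct("guar", 230))
})

test_that("bake_result methods print and plot without error", {
  p <- bake_params("control")
  res <- solve_bake(bake_config(p, T_oven_C = 190, n_nodes = 41,
                                duration = 300))
  expect_output(print(res), "control formulation")
  expect_output(summary(res), "solver")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(res))
})
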