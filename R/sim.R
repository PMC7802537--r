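#' Configure a baking simulation
#'
#' Assembles a validated configuration for [solve_bake()]: formulation
#' parameters, oven setting, grid and integrator resolution, and the model
#' options (evaporation-front treatment, saturation-pressure modes,
#' moisture basis).
#'
#' @param params A [parameter_set()].
#' @param T_oven Oven temperature, K. Alternatively give `T_oven_C`.
#' @param T_oven_C Oven temperature, degrees Celsius.
#' @param duration Bake duration, s.
#' @param n_nodes Number of radial nodes (centre to surface), at least 10.
#' @param T0 Initial dough temperature, K. Default 297.15 K (the 24 degC
#'   starting crust temperature reported for every bake); pass `params$T0`
#'   to use the tabulated 293 K instead.
#' @param delta_mode Evaporation-front treatment in the apparent specific
#'   heat: `"literal"` (the tabulated constant delta, default) or
#'   `"smoothed"` (Gaussian at 373.15 K), see [apparent_specific_heat()]
#'   and the methods vignette for why the literal mode is the default.
#' @param delta_width Width of the smoothed front, K.
#' @param psat_mode Saturation pressure at the bread surface: `"constant"`
#'   (the tabulated reference value at all temperatures, default) or
#'   `"correlation"` (temperature-dependent Magnus form).
#' @param psat_ambient Saturation pressure mode for the oven ambient term
#'   `P_inf`; default `"constant"` (a Magnus value at 460-500 K would exceed
#'   atmospheric pressure, which oven air cannot hold).
#' @param cp_mode `"apparent"` (full `Cp(T, W)` submodel) or `"constant"`
#'   (the measured `Cp_meas`, no evaporation term) for the heat balance.
#' @param wl_basis Basis on which `params$W0` is expressed: `"dry"`
#'   (kg water / kg dry solid, default) or `"wet"` (kg water / kg total,
#'   converted to dry basis before solving).
#' @param mass_transfer If `FALSE`, the surface moisture flux is switched
#'   off (sealed moisture boundary).
#' @param allow_condensation If `FALSE` (default) the surface moisture flux
#'   is clamped to evaporation only, so moisture never rises above its
#'   initial value.
#' @param h,epsilon Optional overrides of the surface heat-transfer
#'   coefficient and emissivity (used e.g. to disable radiation).
#' @param c_exp Water-activity constant, see [water_activity()].
#' @param w_reg Moisture scale (dry basis) of the smooth low-moisture cutoff
#'   applied to the drying flux; prevents flux chatter as the surface dries
#'   out (the sorption isotherm is a near-step at vanishing moisture).
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @param sample_dt Spacing of the dense output grid, s.
#' @param W_init Optional initial radial moisture profile (length
#'   `n_nodes`, dry basis); default uniform at `W0`.
#' @return A list of class `bake_config`.
#' @export
#' @examples
#' cfg <- bake_config(bake_params("control"), T_oven_C = 190)
bake_config <- function(params, T_oven = NULL, T_oven_C = NULL,
                        duration = 2400, n_nodes = 101, T0 = 297.15,
                        delta_mode = c("literal", "smoothed"),
                        delta_width = 0.5,
                        psat_mode = c("constant", "correlation"),
                        psat_ambient = c("constant", "correlation"),
                        cp_mode = c("apparent", "constant"),
                        wl_basis = c("dry", "wet"),
                        mass_transfer = TRUE, allow_condensation = FALSE,
                        h = params$h, epsilon = params$epsilon,
                        c_exp = 55, w_reg = 0.01,
                        rtol = 1e-6, atol = 1e-8, sample_dt = 10,
                        W_init = NULL) {
  validate_parameter_set(params)
  if (is.null(T_oven)) {
    if (is.null(T_oven_C)) stop("give the oven temperature (T_oven or T_oven_C)")
    T_oven <- T_oven_C + 273.15
  }
  if (T_oven < T0) stop("T_oven must not be below the initial temperature")
  if (duration <= 0) stop("duration must be positive")
  if (n_nodes < 10) stop("n_nodes must be at least 10")
  if (h < 0 || epsilon < 0 || epsilon > 1) stop("invalid h or epsilon")
  if (!is.null(W_init) && (length(W_init) != n_nodes || any(W_init < 0)))
    stop("W_init must be a non-negative vector of length n_nodes")
  cfg <- list(params = params, T_oven = T_oven, duration = duration,
              n_nodes = as.integer(n_nodes), T0 = T0,
              delta_mode = match.arg(delta_mode), delta_width = delta_width,
              psat_mode = match.arg(psat_mode),
              psat_ambient = match.arg(psat_ambient),
              cp_mode = match.arg(cp_mode), wl_basis = match.arg(wl_basis),
              mass_transfer = isTRUE(mass_transfer),
              allow_condensation = isTRUE(allow_condensation),
              h = h, epsilon = epsilon, c_exp = c_exp, w_reg = w_reg,
              rtol = rtol, atol = atol, sample_dt = sample_dt,
              W_init = W_init)
  structure(cfg, class = "bake_config")
}

#' Uniform radial grid and finite-volume weights
#'
#' Nodes run from the centre (`r = 0`) to the surface (`r = radius`).
#' `volumes` are the per-radian control-volume areas around each node
#' (half cells at the two ends); they sum to `radius^2 / 2` exactly, so
#' volume-weighted means and conservation checks are discrete identities.
#'
#' @param n_nodes Number of nodes (>= 10).
#' @param radius Cylinder radius, m.
#' @return A list with `r` (node positions), `r_face` (interior face
#'   positions), `dr`, and `volumes`.
#' @export
radial_grid <- function(n_nodes, radius) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 10) stop("n_nodes must be at least 10")
  dr <- radius / (n_nodes - 1)
  r <- seq(0, radius, length.out = n_nodes)
  r_face <- (r[-1] + r[-n_nodes]) / 2
  v <- r * dr
  v[1] <- dr^2 / 8
  v[n_nodes] <- (radius^2 - (radius - dr / 2)^2) / 2
  list(r = r, r_face = r_face, dr = dr, volumes = v)
}

#' Solve the coupled heat and moisture balances for one bake
#'
#' Method-of-lines solution of the radial balances in an infinite cylinder:
#' `rho Cp(T, W) dT/dt = (1/r) d/dr (r k dT/dr)` and
#' `dW/dt = (1/r) d/dr (r D dW/dr)`, with a combined convective-radiative
#' heat flux and a Chilton-Colburn evaporative moisture flux at the surface,
#' zero-gradient symmetry at the centre, and uniform initial conditions.
#' Space is discretised with a conservative second-order finite-volume
#' scheme ([radial_grid()]); time integration uses the stiff-capable
#' adaptive `lsoda` solver.
#'
#' @param config A [bake_config()].
#' @return An object of class `bake_result`: dense time series of the full
#'   temperature and moisture fields, derived crust/centre temperature and
#'   weight-loss curves, a table at the standard 5-40 min sampling times,
#'   and metadata echoing the configuration and solver diagnostics.
#' @export
#' @examples
#' \donttest{
#' res <- solve_bake(bake_config(bake_params("control"), T_oven_C = 190,
#'                               n_nodes = 41))
#' res
#' }
solve_bake <- function(config) {
  stopifnot(inherits(config, "bake_config"))
  p <- config$params
  n <- config$n_nodes
  g <- radial_grid(n, p$r)
  W0_eff <- if (config$wl_basis == "wet") p$W0 / (1 - p$W0) else p$W0
  if (config$wl_basis == "wet" && p$W0 >= 1)
    stop("wet-basis W0 must be below 1")

  kg <- if (config$mass_transfer)
    mass_transfer_coefficient(config$h, p)$kg else 0
  P_inf <- ambient_vapor_pressure(config$T_oven, p$RH, p,
                                  psat_mode = config$psat_ambient)
  sigma <- physical_constants()$sigma
  diag_env <- new.env(parent = emptyenv())
  diag_env$clip_events <- 0L

  ii <- 2:(n - 1)
  rhs <- function(t, y, parms) {
    T <- y[1:n]
    W <- y[n + (1:n)]
    if (any(W < 0)) {
      diag_env$clip_events <- diag_env$clip_events + 1L
      W <- pmax(W, 0)
    }
    # heat: conservative fluxes F = r k dT/dr at faces
    Fh <- g$r_face * p$k * diff(T) / g$dr
    q_surf <- config$h * (config$T_oven - T[n]) +
      config$epsilon * sigma * (config$T_oven^4 - T[n]^4)
    dT <- numeric(n)
    dT[1] <- Fh[1] / g$volumes[1]
    dT[ii] <- (Fh[ii] - Fh[ii - 1]) / g$volumes[ii]
    dT[n] <- (p$r * q_surf - Fh[n - 1]) / g$volumes[n]
    Cp <- if (config$cp_mode == "constant") p$Cp_meas else
      apparent_specific_heat(T, W, p, delta_mode = config$delta_mode,
                             delta_width = config$delta_width)
    dT <- dT / (p$rho * Cp)
    # moisture: F = r D dW/dr at faces; evaporative flux at the surface
    Fm <- g$r_face * p$D * diff(W) / g$dr
    dW <- numeric(n)
    dW[1] <- Fm[1] / g$volumes[1]
    dW[ii] <- (Fm[ii] - Fm[ii - 1]) / g$volumes[ii]
    if (kg > 0) {
      Ps <- surface_vapor_pressure(T[n], W[n], p,
                                   psat_mode = config$psat_mode,
                                   c_exp = config$c_exp) *
        (1 - exp(-W[n] / config$w_reg))
      J_w <- kg * (Ps - P_inf)
      if (!config$allow_condensation) J_w <- max(J_w, 0)
    } else J_w <- 0
    dW[n] <- (-p$r * J_w / p$rho_s - Fm[n - 1]) / g$volumes[n]
    list(c(dT, dW))
  }

  times <- sort(unique(c(seq(0, config$duration, by = config$sample_dt),
                         config$duration)))
  W_init <- if (is.null(config$W_init)) rep(W0_eff, n) else config$W_init
  y0 <- c(rep(config$T0, n), W_init)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = config$rtol,
                      atol = config$atol, maxsteps = 100000)
  di <- attr(sol, "istate")
  if (any(!is.finite(sol)) || nrow(sol) < length(times))
    stop("bake solver failed: non-finite fields or early termination ",
         "(istate = ", di[1], ")")

  Tm <- unname(sol[, 1 + (1:n), drop = FALSE])
  Wm <- pmax(unname(sol[, 1 + n + (1:n), drop = FALSE]), 0)
  wv <- g$volumes / sum(g$volumes)
  mean_W <- as.numeric(Wm %*% wv)
  W0_bar <- sum(W_init * wv)
  res <- structure(list(
    times = times,
    grid = g,
    T = Tm, W = Wm,
    crust_T = Tm[, n] - 273.15,
    center_T = Tm[, 1] - 273.15,
    mean_W = mean_W,
    weight_loss = 100 * (W0_bar - mean_W) / (1 + W0_bar),
    W0_eff = W0_eff,
    config = config,
    diagnostics = list(clip_events = diag_env$clip_events,
                       n_steps = di[2], n_rhs = di[3], kg = kg,
                       P_inf = P_inf)
  ), class = "bake_result")
  res$sample_table <- sample_bake(res)
  res
}

# Interpolate the derived curves onto the standard 5..40 min sampling times
# (truncated to the simulated duration), always including t = 0.
sample_bake <- function(result) {
  tt <- c(0, 60 * seq(5, 40, by = 5))
  tt <- tt[tt <= max(result$times)]
  data.frame(
    time_s = tt,
    crust_T_C = stats::approx(result$times, result$crust_T, tt)$y,
    center_T_C = stats::approx(result$times, result$center_T, tt)$y,
    mean_W_db = stats::approx(result$times, result$mean_W, tt)$y,
    weight_loss_pct = stats::approx(result$times, result$weight_loss, tt)$y
  )
}

#' Weight-loss trajectory of a bake
#'
#' Percent of the initial (wet) mass lost to evaporation:
#' `WL(t) = 100 (W0 - Wbar(t)) / (1 + W0)` with `Wbar` the volume-weighted
#' mean dry-basis moisture over the cylinder cross-section. If
#' `basis = "wet"`, the stored `W0` is interpreted as a wet-basis fraction
#' and converted before use (this is also how the solver was initialised
#' when the configuration said so).
#'
#' @param result A [solve_bake()] result.
#' @param basis `"dry"` or `"wet"`; defaults to the basis the simulation
#'   was configured with.
#' @return Numeric vector of weight loss (percent) at `result$times`;
#'   starts at 0 and is non-decreasing.
#' @export
weight_loss_series <- function(result, basis = result$config$wl_basis) {
  stopifnot(inherits(result, "bake_result"))
  basis <- match.arg(basis, c("dry", "wet"))
  if (basis != result$config$wl_basis)
    warning("requested basis differs from the one the simulation used; ",
            "re-deriving from the stored moisture fields")
  wv <- result$grid$volumes / sum(result$grid$volumes)
  W0_bar <- sum((if (is.null(result$config$W_init))
    rep(result$W0_eff, result$config$n_nodes) else result$config$W_init) * wv)
  100 * (W0_bar - result$mean_W) / (1 + W0_bar)
}

#' Crust (surface-node) temperature trajectory
#'
#' @param result A [solve_bake()] result.
#' @return Surface temperature in degrees Celsius at `result$times`.
#' @export
crust_temperature_series <- function(result) {
  stopifnot(inherits(result, "bake_result"))
  result$T[, ncol(result$T)] - 273.15
}

#' Run a sweep of bake configurations
#'
#' Solves each configuration and tabulates the end-of-bake crust temperature
#' and weight loss, one row per configuration in input order. Individual
#' solver failures are reported in the `status` column rather than aborting
#' the sweep.
#'
#' @param configs A list of [bake_config()] objects.
#' @return A data frame with columns `formulation`, `T_oven_C`, `time_min`,
#'   `crust_T_C`, `weight_loss_pct`, `status`.
#' @export
run_grid <- function(configs) {
  stopifnot(is.list(configs))
  if (length(configs) == 0)
    return(data.frame(formulation = character(0), T_oven_C = numeric(0),
                      time_min = numeric(0), crust_T_C = numeric(0),
                      weight_loss_pct = numeric(0), status = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(configs, function(cfg) {
    stopifnot(inherits(cfg, "bake_config"))
    out <- data.frame(formulation = cfg$params$formulation,
                      T_oven_C = cfg$T_oven - 273.15,
                      time_min = cfg$duration / 60,
                      crust_T_C = NA_real_, weight_loss_pct = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch(solve_bake(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      out$status <- conditionMessage(res)
    } else {
      nt <- length(res$times)
      out$crust_T_C <- res$crust_T[nt]
      out$weight_loss_pct <- res$weight_loss[nt]
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.bake_result <- function(x, ...) {
  nt <- length(x$times)
  cfg <- x$config
  cat(sprintf("Bake simulation: %s formulation, oven %.1f degC, %.0f min\n",
              cfg$params$formulation, cfg$T_oven - 273.15,
              cfg$duration / 60))
  cat(sprintf("  modes: delta=%s, psat=%s/%s, cp=%s, basis=%s\n",
              cfg$delta_mode, cfg$psat_mode, cfg$psat_ambient, cfg$cp_mode,
              cfg$wl_basis))
  cat(sprintf("  final crust T: %.2f degC   final weight loss: %.2f %%\n",
              x$crust_T[nt], x$weight_loss[nt]))
  invisible(x)
}

#' @export
summary.bake_result <- function(object, ...) {
  nt <- length(object$times)
  Tn <- object$T[nt, ]
  crust_frac <- mean(Tn > 373.15)
  cat("Bake simulation summary\n")
  print(object)
  cat(sprintf("  centre T: %.2f degC   mean moisture: %.4f kg/kg db\n",
              object$center_T[nt], object$mean_W[nt]))
  cat(sprintf("  crust zone (T > 100 degC): %.0f %% of radius\n",
              100 * crust_frac))
  cat(sprintf("  solver: %d steps, %d rhs evaluations, %d moisture clips\n",
              object$diagnostics$n_steps, object$diagnostics$n_rhs,
              object$diagnostics$clip_events))
  invisible(object)
}

#' Diagnostic plot of a bake simulation
#'
#' Four panels: crust and centre temperature, weight loss, mean moisture,
#' and the final radial temperature profile with the boiling isotherm.
#'
#' @param x A [solve_bake()] result.
#' @param ... Unused.
#' @export
plot.bake_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tm <- x$times / 60
  graphics::plot(tm, x$crust_T, type = "l", xlab = "time (min)",
                 ylab = "temperature (degC)", main = "crust and centre")
  graphics::lines(tm, x$center_T, lty = 2)
  graphics::legend("bottomright", c("crust", "centre"), lty = 1:2, bty = "n")
  graphics::plot(tm, x$weight_loss, type = "l", xlab = "time (min)",
                 ylab = "weight loss (%)", main = "weight loss")
  graphics::plot(tm, x$mean_W, type = "l", xlab = "time (min)",
                 ylab = "mean W (kg/kg db)", main = "moisture")
  nt <- length(x$times)
  graphics::plot(x$grid$r * 1000, x$T[nt, ] - 273.15, type = "l",
                 xlab = "radius (mm)", ylab = "temperature (degC)",
                 main = "final radial profile")
  graphics::abline(h = 100, lty = 3)
  invisible(x)
}
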