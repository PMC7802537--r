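#' Specific heat of the dry solid matrix
#'
#' Linear correlation for the bread solid fraction, `Cp_s(T) = 5 T + 24`
#' J/kg K with `T` in kelvin.
#'
#' @param T Temperature, K (vectorised).
#' @return Specific heat, J/kg K.
#' @export
#' @examples
#' specific_heat_solid(293)   # 1489
specific_heat_solid <- function(T) {
  if (any(!is.finite(T)) || any(T <= 0)) stop("T must be positive (kelvin)")
  5 * T + 24
}

#' Specific heat of liquid water
#'
#' Quadratic correlation `(a0 + a1 T + a2 T^2) * 1000` J/kg K. The default
#' coefficients give the familiar shallow minimum near ambient temperature
#' (about 4181 J/kg K at 310 K); they are exposed so alternative readings of
#' the correlation can be evaluated.
#'
#' @param T Temperature, K (vectorised); must lie in 200-600 K.
#' @param coef Polynomial coefficients `c(a0, a1, a2)` in kJ/kg K.
#' @return Specific heat, J/kg K.
#' @export
#' @examples
#' specific_heat_water(300)   # 4226.9
specific_heat_water <- function(T, coef = c(5.207, -73.17e-4, 1.35e-5)) {
  if (any(!is.finite(T)) || any(T < 200) || any(T > 600))
    stop("T outside the correlation's validity range (200-600 K)")
  (coef[1] + coef[2] * T + coef[3] * T^2) * 1000
}

#' Latent heat of vaporisation of water
#'
#' `lambda_v(T) = 2502535.259 - 212.56384 (T - 273)` J/kg; monotone
#' decreasing in temperature.
#'
#' @param T Temperature, K (vectorised).
#' @return Latent heat, J/kg.
#' @export
latent_heat <- function(T) {
  if (any(!is.finite(T)) || any(T <= 0)) stop("T must be positive (kelvin)")
  2502535.259 - 212.56384 * (T - 273)
}

#' Apparent specific heat with an evaporation term
#'
#' The sensible part is `Cp*(T, W) = Cp_s(T) + W Cp_w(T)`. Latent heat of the
#' crumb-to-crust phase change is folded in as `lambda_v(T) W delta(T)`
#' (apparent- or effective-heat-capacity method), so the evaporation front
#' needs no explicit tracking. Two forms of `delta` are available:
#'
#' * `"smoothed"` (default): a normalised Gaussian in temperature centred at
#'   373.15 K with standard deviation `delta_width` (unit integral over T),
#'   the standard apparent-heat-capacity treatment; the latent heat is paid
#'   as a node's temperature crosses the boiling point.
#' * `"literal"`: the constant `params$delta_const`, which spreads the
#'   latent term over all temperatures.
#'
#' @param T Temperature, K (vectorised).
#' @param W Moisture content, dry basis (vectorised, recycled with `T`).
#' @param params A [parameter_set()].
#' @param delta_mode `"smoothed"` or `"literal"`.
#' @param delta_width Gaussian width of the smoothed front, K.
#' @return Apparent specific heat, J/kg K.
#' @export
#' @examples
#' p <- bake_params("control")
#' apparent_specific_heat(350, 0.58, p)            # sensible part only
#' apparent_specific_heat(373.15, 0.58, p)         # at the front
apparent_specific_heat <- function(T, W, params,
                                   delta_mode = c("smoothed", "literal"),
                                   delta_width = 0.5) {
  delta_mode <- match.arg(delta_mode)
  if (any(W < 0)) stop("moisture content W must be non-negative")
  cp_star <- specific_heat_solid(T) + W * specific_heat_water(T)
  delta <- switch(delta_mode,
    smoothed = stats::dnorm(T, mean = 373.15, sd = delta_width),
    literal  = params$delta_const)
  cp_star + latent_heat(T) * W * delta
}

#' Water activity of the dough
#'
#' Sorption relation `a_w = [(100 W exp(-0.0056 T + c))^(-10.38) + 1]^(-1)`,
#' evaluated in log space for numerical stability (it is a logistic in
#' `log(100 W) - 0.0056 T + c`). Bounded in `[0, 1]`, zero at `W = 0`,
#' tending to 1 as `W` grows, non-decreasing in `W`. With the default
#' `c_exp = 55` the isotherm is a near-step at vanishing moisture, so
#' `a_w` is effectively 1 at any practical moisture content; `c_exp` is
#' exposed because the printed constant is uncertain.
#'
#' @param T Temperature, K.
#' @param W Moisture content, dry basis.
#' @param c_exp Additive constant in the exponential term.
#' @param T_coef Temperature coefficient (default -0.0056 per K).
#' @param power Outer exponent magnitude (default 10.38).
#' @return Water activity in `[0, 1]` (vectorised).
#' @export
water_activity <- function(T, W, c_exp = 55, T_coef = -0.0056, power = 10.38) {
  if (any(!is.finite(T)) || any(T <= 0)) stop("T must be positive (kelvin)")
  if (any(W < 0)) stop("moisture content W must be non-negative")
  # a_w = 1 / (x^(-power) + 1) with x = 100 W exp(T_coef*T + c_exp)
  # log x = log(100 W) + T_coef*T + c_exp; a_w = plogis(power * log x)
  logx <- ifelse(W > 0, log(100 * W) + T_coef * T + c_exp, -Inf)
  stats::plogis(power * logx)
}

#' Saturation pressure of water vapour
#'
#' Two modes: `"constant"` returns the tabulated reference value at all
#' temperatures; `"correlation"` uses the Magnus (Alduchov-Eskridge) form
#' `610.94 exp(17.625 Tc / (243.04 + Tc))` Pa with `Tc` in Celsius, which
#' reproduces about 1 atm at 100 degC and is extrapolated above it.
#'
#' @param T Temperature, K (vectorised).
#' @param mode `"constant"` or `"correlation"`.
#' @param P_sat_const Reference value for constant mode, Pa.
#' @return Saturation pressure, Pa.
#' @export
saturation_pressure <- function(T, mode = c("constant", "correlation"),
                                P_sat_const = 0.98e5) {
  mode <- match.arg(mode)
  if (any(!is.finite(T)) || any(T <= 0)) stop("T must be positive (kelvin)")
  if (mode == "constant") return(rep_len(P_sat_const, length(T)))
  Tc <- T - 273.15
  610.94 * exp(17.625 * Tc / (243.04 + Tc))
}

#' Water vapour pressure at the bread surface
#'
#' `Ps = a_w(Ts, Ws) * P_sat(Ts)`.
#'
#' @param Ts Surface temperature, K.
#' @param Ws Surface moisture content, dry basis.
#' @param params A [parameter_set()] supplying the constant-mode `P_sat`.
#' @param psat_mode Saturation-pressure mode, see [saturation_pressure()].
#' @param c_exp Water-activity constant, see [water_activity()].
#' @return Surface vapour pressure, Pa; never exceeds `P_sat`.
#' @export
surface_vapor_pressure <- function(Ts, Ws, params,
                                   psat_mode = c("constant", "correlation"),
                                   c_exp = 55) {
  psat_mode <- match.arg(psat_mode)
  water_activity(Ts, Ws, c_exp = c_exp) *
    saturation_pressure(Ts, mode = psat_mode, P_sat_const = params$P_sat)
}

#' Water vapour pressure of the oven ambient
#'
#' `P_inf = (RH / 100) * P_sat(T_inf)`.
#'
#' @param T_inf Ambient (oven) temperature, K.
#' @param RH Relative humidity, percent (0-100).
#' @param params A [parameter_set()] supplying the constant-mode `P_sat`.
#' @param psat_mode Saturation-pressure mode; the default `"constant"` uses
#'   the tabulated reference value, appropriate for oven air whose
#'   temperature is far above the boiling point.
#' @return Ambient vapour pressure, Pa.
#' @export
ambient_vapor_pressure <- function(T_inf, RH, params,
                                   psat_mode = c("constant", "correlation")) {
  psat_mode <- match.arg(psat_mode)
  if (any(RH < 0) || any(RH > 100)) stop("RH must lie in [0, 100]")
  (RH / 100) *
    saturation_pressure(T_inf, mode = psat_mode, P_sat_const = params$P_sat)
}

#' Mass-transfer coefficient by the Chilton-Colburn analogy
#'
#' Converts the convective heat-transfer coefficient `h` into a
#' pressure-driven mass-transfer coefficient:
#' `kg* = h / ((M_air/M_w) P_atm Cp_air (Sc/Pr)^(2/3))`, with
#' `Sc = nu / D` and `Pr = nu / alpha`, then applies the empirical
#' correction `kg = kg_correction * kg*`.
#'
#' @param h Heat-transfer coefficient, W/m^2 K.
#' @param params A [parameter_set()] supplying `nu`, `D`, `alpha`.
#' @param consts A [physical_constants()] object.
#' @return A list with `kg` (kg/Pa m^2 s), `kg_star`, `Sc`, `Pr`.
#' @export
#' @examples
#' mass_transfer_coefficient(10, bake_params("control"))$kg
mass_transfer_coefficient <- function(h, params,
                                      consts = physical_constants()) {
  if (h <= 0) stop("h must be positive")
  if (params$D <= 0 || params$alpha <= 0) stop("D and alpha must be positive")
  Sc <- params$nu / params$D
  Pr <- params$nu / params$alpha
  kg_star <- h / ((consts$M_air / consts$M_w) * consts$P_atm *
                    consts$Cp_air * (Sc / Pr)^(2 / 3))
  list(kg = consts$kg_correction * kg_star, kg_star = kg_star,
       Sc = Sc, Pr = Pr)
}
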