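#' Physical constants used by the transfer models
#'
#' Returns the universal constants and air/water properties entering the
#' radiative surface boundary and the Chilton-Colburn analogy. The
#' Stefan-Boltzmann constant and the analogy correction factor are fixed by
#' the model; the air and water constants are standard handbook values and
#' can be overridden.
#'
#' @param sigma Stefan-Boltzmann constant, W/m^2 K^4.
#' @param M_air Molar mass of dry air, kg/mol.
#' @param M_w Molar mass of water, kg/mol.
#' @param P_atm Atmospheric pressure, Pa.
#' @param Cp_air Specific heat of air at constant pressure, J/kg K.
#' @param kg_correction Dimensionless empirical correction applied to the
#'   Chilton-Colburn mass-transfer coefficient.
#' @return A list of class `physical_constants`.
#' @export
#' @examples
#' physical_constants()$sigma
physical_constants <- function(sigma = 5.67e-8,
                               M_air = 0.028966,
                               M_w = 0.018015,
                               P_atm = 101325,
                               Cp_air = 1006,
                               kg_correction = 7.83e-3) {
  vals <- list(sigma = sigma, M_air = M_air, M_w = M_w, P_atm = P_atm,
               Cp_air = Cp_air, kg_correction = kg_correction)
  bad <- names(vals)[!vapply(vals, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    stop("physical constants must be positive finite scalars: ",
         paste(bad, collapse = ", "))
  structure(vals, class = "physical_constants")
}

.param_fields <- c("formulation", "P_sat", "RH", "T0", "W0", "r", "rho",
                   "rho_s", "epsilon", "delta_const", "h", "lambda_v_ref",
                   "D", "nu", "alpha", "Cp_meas", "k")

#' Construct a formulation parameter set
#'
#' Bundles one formulation's physical constants and initial state: geometry,
#' densities, moisture, transport coefficients and measured thermal
#' properties. All magnitudes are SI; temperature kelvin; moisture content
#' dry basis (kg water per kg dry solid).
#'
#' @param formulation `"control"` or `"guar"` (1% guar gum).
#' @param P_sat Reference water-vapour saturation pressure, Pa.
#' @param RH Oven ambient relative humidity, percent (0-100).
#' @param T0 Initial dough temperature, K.
#' @param W0 Initial moisture content, dry basis.
#' @param r Loaf radius (infinite-cylinder geometry), m.
#' @param rho Initial dough density, kg/m^3.
#' @param rho_s Solid-matrix density, kg/m^3.
#' @param epsilon Surface emissivity, in (0, 1].
#' @param delta_const Delta-type function value used by the literal
#'   evaporation mode (dimensionless).
#' @param h Surface convective heat-transfer coefficient, W/m^2 K.
#' @param lambda_v_ref Reference latent heat of evaporation, J/kg.
#' @param D Effective water diffusion coefficient, m^2/s.
#' @param nu Kinematic viscosity of air, m^2/s.
#' @param alpha Thermal diffusivity of air, m^2/s.
#' @param Cp_meas Measured specific heat of the bread, J/kg K.
#' @param k Bread thermal conductivity, W/m K.
#' @return A list of class `parameter_set`.
#' @seealso [bake_params()] for the packaged control and guar sets.
#' @export
parameter_set <- function(formulation, P_sat, RH, T0, W0, r, rho, rho_s,
                          epsilon, delta_const, h, lambda_v_ref, D, nu,
                          alpha, Cp_meas, k) {
  p <- list(formulation = as.character(formulation), P_sat = P_sat, RH = RH,
            T0 = T0, W0 = W0, r = r, rho = rho, rho_s = rho_s,
            epsilon = epsilon, delta_const = delta_const, h = h,
            lambda_v_ref = lambda_v_ref, D = D, nu = nu, alpha = alpha,
            Cp_meas = Cp_meas, k = k)
  validate_parameter_set(p)
  structure(p, class = "parameter_set")
}

validate_parameter_set <- function(p) {
  stopifnot(setequal(names(p), .param_fields))
  num <- setdiff(.param_fields, c("formulation", "RH"))
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", f, "' must be a positive finite scalar")
  }
  if (p$RH < 0 || p$RH > 100) stop("RH must lie in [0, 100]")
  if (p$epsilon > 1) stop("emissivity must lie in (0, 1]")
  invisible(p)
}

#' Load a packaged formulation parameter set
#'
#' Reads one of the two parameter sets shipped with the package
#' (`control.params`, `guar.params`), or any user file in the same
#' key-value (YAML) format.
#'
#' @param formulation `"control"` or `"guar"`, or the path of a `.params`
#'   file via `file`.
#' @param file Optional explicit path; overrides `formulation`.
#' @return A [parameter_set()].
#' @export
#' @examples
#' p <- bake_params("control")
#' p$k            # thermal conductivity, W/m K
bake_params <- function(formulation = c("control", "guar"), file = NULL) {
  if (is.null(file)) {
    formulation <- match.arg(formulation)
    file <- system.file("extdata", paste0(formulation, ".params"),
                        package = "bakesim", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(file)
  missing <- setdiff(.param_fields, names(raw))
  if (length(missing))
    stop("parameter file '", file, "' is missing fields: ",
         paste(missing, collapse = ", "))
  do.call(parameter_set, raw[.param_fields])
}

#' Write a parameter set to a key-value file
#'
#' @param params A [parameter_set()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_params <- function(params, file) {
  validate_parameter_set(params)
  yaml::write_yaml(unclass(params), file)
  invisible(file)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Bake parameter set:", x$formulation, "formulation\n")
  num <- setdiff(.param_fields, "formulation")
  vals <- vapply(num, function(f) format(x[[f]], digits = 6), character(1))
  cat(paste0("  ", format(num, width = 14), " ", vals, collapse = "\n"), "\n")
  invisible(x)
}
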