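#' A mixing-calorimetry run record
#'
#' Raw masses and temperatures of one mixing-method calorimetry experiment.
#' The three reduction stages use different subsets of the fields: the
#' flask (calorimeter) calibration needs the hot/cold water mix; the capsule
#' calibration additionally needs the capsule temperature `T_c`; the sample
#' measurement needs the sample mass `M_m` and temperature `T_m`.
#'
#' @param M_cw,M_hw Cold and hot water masses, kg (`M_hw` may be `NA` for
#'   capsule/sample runs).
#' @param T_cw,T_hw,T_e Cold-water, hot-water and equilibrium temperatures,
#'   K. A valid mixing run has `T_hw > T_e > T_cw`.
#' @param C_w Specific heat of water, J/kg K.
#' @param T_c Capsule temperature at insertion, K (capsule runs).
#' @param M_m,T_m Sample mass (kg) and temperature (K) (sample runs).
#' @return A list of class `calorimetry_record`.
#' @export
calorimetry_record <- function(M_cw, T_cw, T_e, M_hw = NA_real_,
                               T_hw = NA_real_, C_w = 4186,
                               T_c = NA_real_, M_m = NA_real_,
                               T_m = NA_real_) {
  rec <- list(M_cw = M_cw, M_hw = M_hw, T_cw = T_cw, T_hw = T_hw,
              T_e = T_e, C_w = C_w, T_c = T_c, M_m = M_m, T_m = T_m)
  if (M_cw <= 0) stop("cold-water mass must be positive")
  if (!is.na(M_hw) && M_hw <= 0) stop("hot-water mass must be positive")
  if (!is.na(M_m) && M_m <= 0) stop("sample mass must be positive")
  if (!is.na(T_hw) && !(T_hw > T_e && T_e > T_cw))
    stop("a valid mixing run requires T_hw > T_e > T_cw")
  structure(rec, class = "calorimetry_record")
}

#' Heat capacity of the calorimeter flask
#'
#' Reduction of the water-mixing calibration:
#' `Hf = (M_cw C_w (T_e - T_cw) - M_hw C_w (T_hw - T_e)) / (T_hw - T_e)`.
#' A lossless symmetric mix (equal masses, equal temperature swings) yields
#' exactly zero.
#'
#' @param rec A [calorimetry_record()] with the hot-water fields set.
#' @return Flask heat capacity, J/K.
#' @export
flask_heat_capacity <- function(rec) {
  stopifnot(inherits(rec, "calorimetry_record"))
  if (is.na(rec$M_hw) || is.na(rec$T_hw))
    stop("flask calibration needs the hot-water mass and temperature")
  if (rec$T_hw == rec$T_e) stop("degenerate run: T_hw equals T_e")
  (rec$M_cw * rec$C_w * (rec$T_e - rec$T_cw) -
     rec$M_hw * rec$C_w * (rec$T_hw - rec$T_e)) / (rec$T_hw - rec$T_e)
}

#' Heat capacity of the sample capsule
#'
#' `Hc = (Hf + M_cw C_w) (T_e - T_cw) / (T_c - T_e)`: the hot capsule is
#' quenched in the calibrated calorimeter and its heat capacity follows from
#' the energy the water-plus-flask absorbed.
#'
#' @param rec A [calorimetry_record()] with `T_c` set.
#' @param Hf Flask heat capacity from [flask_heat_capacity()], J/K.
#' @return Capsule heat capacity, J/K.
#' @export
capsule_heat_capacity <- function(rec, Hf) {
  stopifnot(inherits(rec, "calorimetry_record"))
  if (is.na(rec$T_c)) stop("capsule run needs the capsule temperature T_c")
  if (rec$T_c == rec$T_e) stop("degenerate run: T_c equals T_e")
  (Hf + rec$M_cw * rec$C_w) * (rec$T_e - rec$T_cw) / (rec$T_c - rec$T_e)
}

#' Specific heat capacity of a bread sample
#'
#' `Cp = ((Hf + M_cw C_w)(T_e - T_cw) - Hc (T_m - T_e)) / (M_m (T_m - T_e))`:
#' the heated capsule-plus-sample is quenched; subtracting the capsule's
#' known contribution leaves the sample's.
#'
#' @param rec A [calorimetry_record()] with `M_m`, `T_m` set.
#' @param Hf Flask heat capacity, J/K.
#' @param Hc Capsule heat capacity, J/K.
#' @return Sample specific heat, J/kg K.
#' @export
sample_specific_heat <- function(rec, Hf, Hc) {
  stopifnot(inherits(rec, "calorimetry_record"))
  if (is.na(rec$M_m) || is.na(rec$T_m))
    stop("sample run needs the sample mass and temperature")
  if (rec$T_m == rec$T_e) stop("degenerate run: T_m equals T_e")
  ((Hf + rec$M_cw * rec$C_w) * (rec$T_e - rec$T_cw) -
     Hc * (rec$T_m - rec$T_e)) / (rec$M_m * (rec$T_m - rec$T_e))
}

#' A transient hot-wire run record
#'
#' @param I Heating current, A.
#' @param R Wire resistance, ohm (total for the wire; see
#'   [hotwire_conductivity()] for the per-length convention).
#' @param samples Data frame with columns `time` (s, strictly increasing,
#'   positive) and `temperature` (K); at least 10 samples.
#' @param heater_length Heated wire length, m.
#' @return A list of class `hotwire_record`.
#' @export
hotwire_record <- function(I, R, samples, heater_length = 0.235) {
  if (I <= 0 || R <= 0 || heater_length <= 0)
    stop("current, resistance and heater length must be positive")
  stopifnot(is.data.frame(samples),
            all(c("time", "temperature") %in% names(samples)))
  if (nrow(samples) < 10) stop("need at least 10 samples")
  if (any(samples$time <= 0) || any(diff(samples$time) <= 0))
    stop("sample times must be positive and strictly increasing")
  structure(list(I = I, R = R, samples = samples,
                 heater_length = heater_length), class = "hotwire_record")
}

#' Slope of temperature against log-time
#'
#' Ordinary least squares of temperature on `ln(t)`, the reduction step of
#' the transient hot-wire method. With `window = "auto"` every contiguous
#' window of at least half the samples is scanned and the one with the
#' highest coefficient of determination is returned (ties broken towards
#' the earliest window), which excludes the early and late nonlinear flanks
#' of a real trace.
#'
#' @param samples Data frame with `time` (s) and `temperature` (K) columns.
#' @param window `"auto"`, or an integer vector of row indices to fit on.
#' @return A list with `S` (slope, K per ln s), `r_squared`, `window`
#'   (indices used), and `intercept`.
#' @export
fit_log_slope <- function(samples, window = "auto") {
  stopifnot(is.data.frame(samples),
            all(c("time", "temperature") %in% names(samples)))
  if (any(samples$time <= 0)) stop("times must be positive")
  n <- nrow(samples)
  lt <- log(samples$time)
  Tv <- samples$temperature

  fit_window <- function(idx) {
    x <- lt[idx]; y <- Tv[idx]
    if (stats::sd(y) == 0) return(NULL)   # degenerate: constant temperature
    f <- stats::lm.fit(cbind(1, x), y)
    ssr <- sum(f$residuals^2)
    sst <- sum((y - mean(y))^2)
    list(S = unname(f$coefficients[2]), intercept = unname(f$coefficients[1]),
         r_squared = 1 - ssr / sst, window = idx)
  }

  if (identical(window, "auto")) {
    # closed-form OLS over every contiguous window via prefix sums
    cx <- c(0, cumsum(lt)); cy <- c(0, cumsum(Tv))
    cxx <- c(0, cumsum(lt^2)); cyy <- c(0, cumsum(Tv^2))
    cxy <- c(0, cumsum(lt * Tv))
    wmin <- max(5L, ceiling(n / 2))
    best_r2 <- -Inf; best_se <- NULL
    for (len in wmin:n) {
      starts <- 1:(n - len + 1L)
      ends <- starts + len - 1L
      sx <- cx[ends + 1L] - cx[starts]; sy <- cy[ends + 1L] - cy[starts]
      sxx <- cxx[ends + 1L] - cxx[starts]; syy <- cyy[ends + 1L] - cyy[starts]
      sxy <- cxy[ends + 1L] - cxy[starts]
      vx <- sxx - sx^2 / len; vy <- syy - sy^2 / len
      cv <- sxy - sx * sy / len
      r2 <- ifelse(vx > 0 & vy > 0, cv^2 / (vx * vy), NA_real_)
      if (all(is.na(r2))) next
      i <- which.max(replace(r2, is.na(r2), -Inf))   # earliest max
      if (r2[i] > best_r2 + 1e-12) {
        best_r2 <- r2[i]
        best_se <- c(starts[i], ends[i])
      }
    }
    if (is.null(best_se)) stop("degenerate trace: constant temperature")
    fit_window(best_se[1]:best_se[2])
  } else {
    if (length(window) < 5) stop("window must contain at least 5 points")
    out <- fit_window(window)
    if (is.null(out)) stop("degenerate window: constant temperature")
    out
  }
}

#' Thermal conductivity from a hot-wire trace
#'
#' Line-source reduction `k = I^2 R' / (4 pi S)` with `S` the log-time slope
#' from [fit_log_slope()]. By default the recorded resistance is interpreted
#' as the whole wire's and converted to a per-unit-length value
#' `R' = R / heater_length`, which makes `I^2 R'` the linear power density
#' (W/m) the line-source solution requires; `r_mode = "total"` uses the
#' recorded resistance as-is.
#'
#' @param rec A [hotwire_record()].
#' @param r_mode `"per_length"` (default) or `"total"`.
#' @param window Passed to [fit_log_slope()].
#' @return A list with `k` (W/m K), `S`, `r_squared`, `q` (linear power,
#'   W/m under the per-length convention), and the fit window.
#' @export
#' @examples
#' tr <- generate_hotwire(true_k = 0.18, seed = 1)
#' hotwire_conductivity(tr)$k
hotwire_conductivity <- function(rec, r_mode = c("per_length", "total"),
                                 window = "auto") {
  stopifnot(inherits(rec, "hotwire_record"))
  r_mode <- match.arg(r_mode)
  R_eff <- if (r_mode == "per_length") rec$R / rec$heater_length else rec$R
  fit <- fit_log_slope(rec$samples, window = window)
  if (fit$S <= 0)
    stop("invalid run: non-positive log-time slope (no heating detected)")
  list(k = rec$I^2 * R_eff / (4 * pi * fit$S), S = fit$S,
       r_squared = fit$r_squared, q = rec$I^2 * R_eff, window = fit$window)
}

#' Read calorimetry records from CSV
#'
#' One row per run; columns named as the [calorimetry_record()] arguments
#' (missing stages may be empty).
#'
#' @param file CSV path.
#' @return A list of [calorimetry_record()] objects.
#' @export
read_calorimetry_csv <- function(file) {
  df <- utils::read.csv(file)
  lapply(seq_len(nrow(df)), function(i) {
    args <- as.list(df[i, intersect(names(df), c(
      "M_cw", "M_hw", "T_cw", "T_hw", "T_e", "C_w", "T_c", "M_m", "T_m"))])
    do.call(calorimetry_record, args)
  })
}

#' Read a hot-wire trace from CSV
#'
#' Long format: columns `time`, `temperature`; current, resistance and
#' heater length given as arguments (or as `I`, `R`, `heater_length`
#' columns constant over the file).
#'
#' @param file CSV path.
#' @param I,R,heater_length Run constants; taken from the file's columns
#'   when omitted.
#' @return A [hotwire_record()].
#' @export
read_hotwire_csv <- function(file, I = NULL, R = NULL, heater_length = NULL) {
  df <- utils::read.csv(file)
  grab <- function(arg, col) {
    if (!is.null(arg)) return(arg)
    if (col %in% names(df)) return(df[[col]][1])
    stop("'", col, "' not given and not present in the file")
  }
  hotwire_record(I = grab(I, "I"), R = grab(R, "R"),
                 samples = df[, c("time", "temperature")],
                 heater_length = grab(heater_length, "heater_length"))
}
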