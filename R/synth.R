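#' Measurement-noise specification for synthetic experiments
#'
#' @param sd_T Standard deviation of crust-temperature noise, K (equivalently
#'   degC). The defaults are stated noise magnitudes of the synthetic design,
#'   not estimates from the study, which published no replicate scatter.
#' @param sd_WL Standard deviation of weight-loss noise, percentage points.
#' @param replicates Replicates per condition (the study ran three).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sd_T = 1.5, sd_WL = 0.8, replicates = 3L, seed = 1L) {
  if (sd_T < 0 || sd_WL < 0) stop("noise standard deviations must be >= 0")
  if (replicates < 1) stop("need at least one replicate")
  structure(list(sd_T = sd_T, sd_WL = sd_WL,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Generate a pseudo-experimental bake dataset
#'
#' Runs [solve_bake()] for each configuration, samples the curves at the
#' eight standard times (5-40 min), and adds independent Gaussian
#' measurement noise per replicate, reproducing the study's design
#' (formulations x oven settings x 8 times x replicates). Fully reproducible
#' from the seed in `noise`.
#'
#' @param configs List of [bake_config()] objects (one per
#'   formulation-by-oven condition).
#' @param noise A [noise_spec()].
#' @return A list of class `bake_dataset`: `replicates` (long data frame:
#'   `formulation`, `T_oven_C`, `time_min`, `replicate`, `crust_T_C`,
#'   `weight_loss_pct`), `means` (replicate means per condition and time),
#'   and `model` (the noise-free model values).
#' @export
generate_bake_dataset <- function(configs, noise = noise_spec()) {
  stopifnot(inherits(noise, "noise_spec"), is.list(configs))
  model <- do.call(rbind, lapply(configs, function(cfg) {
    res <- solve_bake(cfg)
    st <- res$sample_table
    st <- st[st$time_s > 0, , drop = FALSE]
    data.frame(formulation = cfg$params$formulation,
               T_oven_C = cfg$T_oven - 273.15,
               time_min = st$time_s / 60,
               crust_T_C = st$crust_T_C,
               weight_loss_pct = st$weight_loss_pct,
               stringsAsFactors = FALSE)
  }))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(noise$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  reps <- do.call(rbind, lapply(seq_len(noise$replicates), function(rep) {
    out <- model
    out$replicate <- rep
    out$crust_T_C <- out$crust_T_C + stats::rnorm(nrow(out), 0, noise$sd_T)
    out$weight_loss_pct <- out$weight_loss_pct +
      stats::rnorm(nrow(out), 0, noise$sd_WL)
    out
  }))
  reps <- reps[, c("formulation", "T_oven_C", "time_min", "replicate",
                   "crust_T_C", "weight_loss_pct")]
  agg <- stats::aggregate(
    reps[, c("crust_T_C", "weight_loss_pct")],
    by = reps[, c("formulation", "T_oven_C", "time_min")], FUN = mean)
  # keep the means in the same condition-by-time order as the model table
  key <- function(d) paste(d$formulation, d$T_oven_C, d$time_min)
  agg <- agg[match(key(model), key(agg)), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(replicates = reps, means = agg, model = model,
                 noise = noise), class = "bake_dataset")
}

#' Generate calorimetry records with known ground truth
#'
#' Constructs a flask-calibration, a capsule-calibration and a sample run
#' whose masses and temperatures are exactly consistent with the supplied
#' true heat capacities, so the reduction chain
#' [flask_heat_capacity()] -> [capsule_heat_capacity()] ->
#' [sample_specific_heat()] recovers them (to rounding at zero noise). The
#' equilibrium temperatures are obtained by inverting each reduction
#' formula; optional Gaussian noise perturbs the recorded temperatures.
#'
#' @param true_Hf Flask heat capacity, J/K.
#' @param true_Hc Capsule heat capacity, J/K.
#' @param true_Cp Sample specific heat, J/kg K.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param noise_sd Temperature noise, K.
#' @param C_w Specific heat of water, J/kg K.
#' @param M_cw,M_hw,M_m Water and sample masses, kg.
#' @param T_cw,T_hw,T_c,T_m Cold-water, hot-water, capsule and sample
#'   temperatures, K.
#' @return A list of class `calorimetry_set` with elements `flask`,
#'   `capsule`, `sample` ([calorimetry_record()]s) and `truth`.
#' @export
#' @examples
#' cs <- generate_calorimetry(true_Hf = 80, true_Hc = 45, true_Cp = 2489)
#' Hf <- flask_heat_capacity(cs$flask)
#' Hc <- capsule_heat_capacity(cs$capsule, Hf)
#' sample_specific_heat(cs$sample, Hf, Hc)   # 2489
generate_calorimetry <- function(true_Hf, true_Hc, true_Cp, seed = 1L,
                                 noise_sd = 0, C_w = 4186,
                                 M_cw = 0.12, M_hw = 0.10, M_m = 0.02,
                                 T_cw = 293.15, T_hw = 343.15, T_c = 368.15,
                                 T_m = 368.15) {
  if (true_Hf <= 0 || true_Hc <= 0 || true_Cp <= 0)
    stop("true heat capacities must be positive")
  # flask run: T_e from Hf = (Mcw Cw (Te-Tcw) - Mhw Cw (Thw-Te))/(Thw-Te)
  a <- M_cw * C_w; b <- M_hw * C_w
  T_e_f <- (a * T_cw + b * T_hw + true_Hf * T_hw) / (true_Hf + a + b)
  # capsule run: T_e from Hc = (Hf + Mcw Cw)(Te - Tcw)/(Tc - Te)
  fw <- true_Hf + a
  T_e_c <- (true_Hc * T_c + fw * T_cw) / (true_Hc + fw)
  # sample run: T_e from energy balance with capsule + sample
  cs <- true_Hc + M_m * true_Cp
  T_e_s <- (cs * T_m + fw * T_cw) / (cs + fw)
  jitter <- function(x) x
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    jitter <- function(x) x + stats::rnorm(length(x), 0, noise_sd)
  }
  structure(list(
    flask = calorimetry_record(M_cw = M_cw, M_hw = M_hw, T_cw = T_cw,
                               T_hw = T_hw, T_e = jitter(T_e_f), C_w = C_w),
    capsule = calorimetry_record(M_cw = M_cw, T_cw = T_cw,
                                 T_e = jitter(T_e_c), C_w = C_w, T_c = T_c),
    sample = calorimetry_record(M_cw = M_cw, T_cw = T_cw, T_e = jitter(T_e_s),
                                C_w = C_w, M_m = M_m, T_m = T_m),
    truth = list(Hf = true_Hf, Hc = true_Hc, Cp = true_Cp)
  ), class = "calorimetry_set")
}

#' Generate a hot-wire temperature trace with known conductivity
#'
#' Line-source model trace `T(t) = T0 + (q / 4 pi k) ln(t)` with
#' `q = I^2 R / heater_length` the linear power density, sampled on the
#' instrument's 3-second cadence. The duration is chosen so the total
#' temperature rise equals `target_rise`, keeping the trace inside the
#' 5-14 degC band the measurement protocol reports; optional Gaussian noise
#' is added on top.
#'
#' @param true_k Thermal conductivity, W/m K.
#' @param I Heating current, A. The default gives a linear power inside the
#'   instrument's 2.5-6 W/m operating range for the stock wire.
#' @param R Total wire resistance, ohm.
#' @param heater_length Heated length, m.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param noise_sd Temperature noise, K.
#' @param T0 Sample temperature at switch-on, K.
#' @param target_rise Temperature rise over the trace, K (clamped to 5-14).
#' @param dt Sampling cadence, s.
#' @return A [hotwire_record()] with a `truth` attribute.
#' @export
generate_hotwire <- function(true_k, I = 0.25, R = 11.49,
                             heater_length = 0.235, seed = 1L, noise_sd = 0,
                             T0 = 298.15, target_rise = 6, dt = 3) {
  if (true_k <= 0) stop("true_k must be positive")
  target_rise <- min(max(target_rise, 5), 14)
  q <- I^2 * R / heater_length
  S <- q / (4 * pi * true_k)
  t_end <- dt * exp(target_rise / S)
  times <- seq(dt, t_end, by = dt)
  if (length(times) < 10) times <- dt * seq_len(10)
  temp <- T0 + S * log(times)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    temp <- temp + stats::rnorm(length(temp), 0, noise_sd)
  }
  rec <- hotwire_record(I = I, R = R, heater_length = heater_length,
                        samples = data.frame(time = times, temperature = temp))
  attr(rec, "truth") <- list(k = true_k, S = S, q = q)
  rec
}
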