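#' Oxygen incubation time series
#'
#' Headspace O2 mass versus time for one incubation flask. Blank flasks
#' (ultra-high-purity water, used to correct for probe drift) carry no dry
#' sediment mass.
#'
#' @param flask_id flask identifier.
#' @param times days since incubation start, strictly increasing, >= 0.
#' @param o2_mass headspace O2 mass in mg per time point, >= 0.
#' @param temperature_c incubation temperature in degrees Celsius.
#' @param is_blank logical.
#' @param dry_mass_g grams of dry sediment (NA for blanks, > 0 otherwise).
#' @return an `oxygen_series`.
#' @export
oxygen_series <- function(flask_id, times, o2_mass, temperature_c,
                          is_blank = FALSE, dry_mass_g = NA_real_) {
  times <- as.numeric(times); o2_mass <- as.numeric(o2_mass)
  if (length(times) != length(o2_mass)) {
    stop("oxygen_series: times and o2_mass lengths differ", call. = FALSE)
  }
  if (any(times < 0)) stop("oxygen_series: negative times", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("oxygen_series: times must be strictly increasing (duplicate or ",
         "reversed time stamps)", call. = FALSE)
  }
  if (any(o2_mass < 0)) stop("oxygen_series: negative O2 mass", call. = FALSE)
  if (!is_blank && (is.na(dry_mass_g) || dry_mass_g <= 0)) {
    stop("oxygen_series: sample flask needs dry_mass_g > 0", call. = FALSE)
  }
  structure(list(flask_id = flask_id, times = times, o2_mass = o2_mass,
                 temperature_c = temperature_c, is_blank = isTRUE(is_blank),
                 dry_mass_g = dry_mass_g),
            class = "oxygen_series")
}

#' Sediment oxygen consumption rates per interval
#'
#' SOC over \[t1, t2\] = (m1 - m2) / (t2 - t1) in mg O2 per day — positive
#' while oxygen is being consumed. Rates are assigned to interval midpoints
#' for subsequent trapezoidal integration.
#'
#' @param series an [oxygen_series()].
#' @return a `soc_rates` data.frame with columns `t_mid`, `rate`; the span
#'   of the raw series rides along as attribute `span`.
#' @export
soc_rate <- function(series) {
  stopifnot(inherits(series, "oxygen_series"))
  t <- series$times; m <- series$o2_mass
  if (length(t) < 2L) stop("soc_rate: need >= 2 time points", call. = FALSE)
  dt <- diff(t)
  out <- data.frame(t_mid = t[-length(t)] + dt / 2,
                    rate = -diff(m) / dt)
  attr(out, "span") <- range(t)
  attr(out, "temperature_c") <- series$temperature_c
  class(out) <- c("soc_rates", "data.frame")
  out
}

#' Blank-correct sample consumption rates
#'
#' Subtracts the blank flask's rate (probe drift) from the sample's, after
#' interpolating the blank onto the sample's interval midpoints. The blank
#' series must span the sample series.
#'
#' @param sample_rates,blank_rates `soc_rates` from [soc_rate()].
#' @return corrected `soc_rates` on the sample grid.
#' @export
blank_correct <- function(sample_rates, blank_rates) {
  sp_s <- attr(sample_rates, "span"); sp_b <- attr(blank_rates, "span")
  if (sp_b[1] > sp_s[1] || sp_b[2] < sp_s[2]) {
    stop("blank_correct: blank series [", sp_b[1], ", ", sp_b[2],
         "] does not cover the sample span [", sp_s[1], ", ", sp_s[2], "]",
         call. = FALSE)
  }
  b <- stats::approx(blank_rates$t_mid, blank_rates$rate,
                     xout = sample_rates$t_mid, rule = 2)$y
  out <- sample_rates
  out$rate <- sample_rates$rate - b
  out
}

#' Q10 (Van't Hoff) temperature normalization to 20 degrees C
#'
#' `rate_20 = 1.065^(20 - T) * rate_T`. The correction is valid for
#' incubation temperatures of 10 degrees C or more; lower temperatures are
#' an error.
#'
#' @param rate consumption rate(s) in mg O2 per day, or a `soc_rates`
#'   data.frame.
#' @param temperature_c measurement temperature in degrees C (>= 10); taken
#'   from the `soc_rates` attribute when omitted.
#' @return normalized rate(s) of the same shape.
#' @export
q10_normalize <- function(rate, temperature_c = NULL) {
  if (inherits(rate, "soc_rates")) {
    if (is.null(temperature_c)) temperature_c <- attr(rate, "temperature_c")
    out <- rate
    out$rate <- q10_normalize(rate$rate, temperature_c)
    return(out)
  }
  if (is.null(temperature_c) || is.na(temperature_c)) {
    stop("q10_normalize: temperature required", call. = FALSE)
  }
  if (temperature_c < 10) {
    stop("q10_normalize: correction only valid for temperatures >= 10 C ",
         "(got ", temperature_c, ")", call. = FALSE)
  }
  rate * 1.065^(20 - temperature_c)
}

#' Integrate consumption rates over a time window
#'
#' Trapezoidal accumulation of the (temperature-normalized) interval rates
#' over \[0, d\] days, with constant extrapolation of the first/last
#' midpoint rate to the window edges. The window must lie inside the
#' series' time span.
#'
#' @param rates a `soc_rates` data.frame.
#' @param window numeric length-2, e.g. `c(0, 5)` for SOC5.
#' @return total O2 mass consumed over the window, in mg.
#' @export
integrate_soc <- function(rates, window) {
  sp <- attr(rates, "span")
  if (is.null(sp)) sp <- range(rates$t_mid)
  if (window[1] < sp[1] - 1e-9 || window[2] > sp[2] + 1e-9) {
    stop("integrate_soc: window [", window[1], ", ", window[2],
         "] exceeds the data span [", sp[1], ", ", sp[2], "]", call. = FALSE)
  }
  if (window[2] <= window[1]) return(0)
  inside <- rates$t_mid > window[1] & rates$t_mid < window[2]
  ts <- unique(sort(c(window[1], rates$t_mid[inside], window[2])))
  vs <- stats::approx(rates$t_mid, rates$rate, xout = ts, rule = 2)$y
  pracma::trapz(ts, vs)
}

#' Sediment oxygen demand from consumed mass
#'
#' Divides the total consumed O2 mass by the dry sediment mass, giving SOD
#' in mg O2 per g dry sediment. Negative consumptions (blank exceeding the
#' sample) are clamped to 0 with a warning — demand is physically
#' non-negative.
#'
#' @param soc5,soc20 consumed O2 mass (mg) over 0-5 and 0-20 days.
#' @param dry_mass_g dry sediment mass (> 0).
#' @return named numeric vector `c(sod5 = , sod20 = )`.
#' @export
sod_values <- function(soc5, soc20, dry_mass_g) {
  if (is.na(dry_mass_g) || !is.numeric(dry_mass_g)) {
    stop("sod_values: dry mass missing", call. = FALSE)
  }
  if (dry_mass_g <= 0) stop("sod_values: dry mass must be > 0", call. = FALSE)
  v <- c(sod5 = soc5, sod20 = soc20) / dry_mass_g
  if (any(v < 0)) {
    warning("sod_values: negative consumption clamped to 0", call. = FALSE)
    v <- pmax(v, 0)
  }
  v
}

#' Full SOD computation chain for one flask
#'
#' Interval rates, blank correction, Q10 normalization to 20 C, trapezoidal
#' SOC5/SOC20, and division by dry mass.
#'
#' @param sample an [oxygen_series()] (not a blank).
#' @param blank an [oxygen_series()] blank covering the sample's span.
#' @return a `sod_result` list: `flask_id`, `rates` (blank-corrected,
#'   normalized `soc_rates`), `soc5`, `soc20`, `sod5`, `sod20`.
#' @export
compute_sod <- function(sample, blank) {
  stopifnot(inherits(sample, "oxygen_series"), !sample$is_blank)
  rs <- soc_rate(sample)
  if (!is.null(blank)) {
    rb <- soc_rate(blank)
    rs <- blank_correct(rs, rb)
  }
  rs <- q10_normalize(rs)
  soc5 <- integrate_soc(rs, c(0, 5))
  soc20 <- integrate_soc(rs, c(0, 20))
  sod <- sod_values(soc5, soc20, sample$dry_mass_g)
  structure(list(flask_id = sample$flask_id, rates = rs,
                 soc5 = soc5, soc20 = soc20,
                 sod5 = unname(sod["sod5"]), sod20 = unname(sod["sod20"])),
            class = "sod_result")
}

#' Headspace O2 mass from volume fraction (ideal gas)
#'
#' Optional helper converting a probe's O2 volume fraction to mass:
#' `n = P V / (R T)` moles of headspace gas, times the fraction, times
#' 32 g/mol.
#'
#' @param fraction O2 volume fraction (0-1).
#' @param headspace_l headspace volume in litres.
#' @param temperature_c gas temperature in degrees C.
#' @param pressure_pa pressure in Pa (default one atmosphere).
#' @return O2 mass in mg.
#' @export
o2_mass_from_fraction <- function(fraction, headspace_l, temperature_c,
                                  pressure_pa = 101325) {
  n_total <- pressure_pa * (headspace_l / 1000) / (8.314462 * (temperature_c + 273.15))
  fraction * n_total * 31.998 * 1000
}
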