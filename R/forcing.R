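#' Generate the artificial diurnal boundary conditions
#'
#' Daily cycle with a 14-h light period and 10-h darkness. Transpiration and
#' photosynthesis share a trapezoidal shape: linear rise from lights-on to a
#' 2-h flat peak centered on midday, then linear fall to lights-off.
#' Transpiration peaks at the standard rate (0.4 ml cm^-2 day^-1) and holds a
#' night floor of 10% of the standard rate; photosynthesis peaks at the
#' standard model-unit rate and is zero in darkness. Temperature is constant.
#'
#' @param days number of simulated days (>= 1).
#' @param dt sample spacing (h); snapped to divide 24 h exactly, with a
#'   warning, if it does not.
#' @param config configuration list (forcing section).
#' @return A `forcing` data frame with columns `time_h`, `transpiration`
#'   (ml cm^-2 day^-1), `photosynthesis` (model units), `temperature` (K)
#'   and `day_mask`.
#' @export
generate_standard_forcing <- function(days = 4, dt = 0.05,
                                      config = default_config()) {
  stopifnot(days >= 1)
  fc <- config$forcing
  steps_per_day <- 24 / dt
  if (abs(steps_per_day - round(steps_per_day)) > 1e-9) {
    dt <- 24 / round(steps_per_day)
    warning("dt does not divide the 24-h photoperiod; snapped to ", dt,
            call. = FALSE)
  }
  t <- seq(0, days * 24, by = dt)
  s <- diurnal_shape(t, fc$day_hours, fc$peak_hours)
  f <- data.frame(
    time_h = t,
    transpiration = fc$trans_standard *
      (fc$trans_night_frac + (1 - fc$trans_night_frac) * s),
    photosynthesis = fc$photo_standard * s,
    temperature = fc$temperature_K,
    day_mask = (t %% 24) < fc$day_hours
  )
  class(f) <- c("forcing", "data.frame")
  f
}

# trapezoidal diurnal shape factor in [0,1]: 0 in darkness, linear rise from
# lights-on to the flat peak centered on the middle of the light period
diurnal_shape <- function(t, day_hours = 14, peak_hours = 2) {
  td <- t %% 24
  rise <- (day_hours - peak_hours) / 2
  s <- numeric(length(t))
  up <- td < rise
  s[up] <- td[up] / rise
  flat <- td >= rise & td <= rise + peak_hours
  s[flat] <- 1
  down <- td > rise + peak_hours & td < day_hours
  s[down] <- (day_hours - td[down]) / rise
  s
}

#' Write a forcing table to CSV
#'
#' Full-precision export (round-trips bit-identically through
#' [read_forcing_csv()]).
#'
#' @param forcing a `forcing` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_forcing_csv <- function(forcing, path) {
  out <- forcing
  for (cl in c("time_h", "transpiration", "photosynthesis", "temperature")) {
    out[[cl]] <- sprintf("%.17g", forcing[[cl]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a model-unit forcing table from CSV
#'
#' Requires columns `time_h`, `transpiration`, `photosynthesis`,
#' `temperature`; an optional `day_mask` column is used if present and
#' otherwise derived from positive photosynthesis.
#'
#' @param path CSV path.
#' @return A `forcing` data frame.
#' @export
read_forcing_csv <- function(path) {
  f <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "transpiration", "photosynthesis", "temperature")
  miss <- setdiff(need, names(f))
  if (length(miss)) stop("forcing CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.unsorted(f$time_h, strictly = TRUE)) {
    stop("forcing time column must be strictly increasing", call. = FALSE)
  }
  if (!"day_mask" %in% names(f)) f$day_mask <- f$photosynthesis > 0
  f$day_mask <- as.logical(f$day_mask)
  f <- f[, c(need, "day_mask")]
  class(f) <- c("forcing", "data.frame")
  f
}

#' Derive model forcing from eddy-covariance field measurements
#'
#' Converts latent heat flux (LE, W m^-2) to a transpiration rate and net
#' ecosystem CO2 exchange (NEE) to a photosynthesis rate, assuming soil
#' evaporation and heterotrophic respiration are negligible: transpiration is
#' LE divided by the latent heat of vaporization (giving an evaporation-mass
#' flux) times a unit-conversion scale; photosynthesis is -NEE clipped at 0,
#' scaled. Gaps (NA) in LE/NEE are linearly interpolated with a warning.
#'
#' @param path CSV with columns `time` (h), `LE` (W m^-2), `NEE`, optional
#'   `temperature` (K).
#' @param conversion list of constants: `latent_heat` (flux units per unit
#'   evaporation-mass flux, default 2.45e6 J kg^-1), `trans_scale`
#'   (model transpiration units per evaporation-mass unit; the default 8640
#'   turns kg m^-2 s^-1 into ml cm^-2 day^-1 -- 86400 s/day times
#'   0.1 ml cm^-2 per mm), `photo_scale` (model photosynthesis units per NEE
#'   unit, default 1).
#' @param config configuration list (fallback temperature).
#' @return A `forcing` data frame (transpiration in ml cm^-2 day^-1).
#' @export
read_field_forcing <- function(path,
                               conversion = list(),
                               config = default_config()) {
  conv <- merge_config(
    list(latent_heat = 2.45e6, trans_scale = 8640, photo_scale = 1),
    conversion)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "LE", "NEE")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("field CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.unsorted(d$time, strictly = TRUE)) {
    stop("field time column must be strictly increasing", call. = FALSE)
  }
  for (cl in c("LE", "NEE")) {
    if (anyNA(d[[cl]])) {
      warning("gaps in ", cl, " linearly interpolated", call. = FALSE)
      d[[cl]] <- approx(d$time, d[[cl]], xout = d$time, rule = 2)$y
    }
  }
  trans <- pmax(0, d$LE) / conv$latent_heat * conv$trans_scale
  photo <- pmax(0, -d$NEE) * conv$photo_scale
  f <- data.frame(
    time_h = d$time,
    transpiration = trans,
    photosynthesis = photo,
    temperature = if ("temperature" %in% names(d)) d$temperature
                  else config$forcing$temperature_K,
    day_mask = photo > 0
  )
  class(f) <- c("forcing", "data.frame")
  f
}
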