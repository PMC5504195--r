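#' Investment efficiency of transporter expression
#'
#' IE = (Si delivered to the top-leaf tissue) / (integrated transporter
#' expression): the time integral of the top-leaf unloading flux divided by
#' the time integral of alpha over `[stri, endi]`, both by trapezoidal
#' quadrature on the recorded grid. The expression integral is also split into
#' light-period and dark-period investment using the forcing's day mask (each
#' inter-sample interval is attributed to the mask of its left endpoint, so
#' aligned photoperiod boundaries are split exactly).
#'
#' @param traj a `trajectory`.
#' @param stri,endi integration window (h); defaults to the full span.
#' @return An `efficiency_report` list: `ie`, `si_top_leaf` (numerator, umol),
#'   `investment` (denominator, h), `investment_day`, `investment_night`,
#'   `night_day_ratio_pct`, `window`.
#' @export
#' @examples
#' g <- build_standard_plant()
#' f <- generate_standard_forcing(days = 1)
#' traj <- run_simulation(g, f, control_config("constant"))
#' investment_efficiency(traj)
investment_efficiency <- function(traj, stri = NULL, endi = NULL) {
  t <- traj$time
  if (is.null(stri)) stri <- t[1]
  if (is.null(endi)) endi <- t[length(t)]
  sel <- t >= stri - 1e-9 & t <= endi + 1e-9
  if (sum(sel) < 2) stop("integration window too narrow", call. = FALSE)
  t <- t[sel]
  a <- traj$alpha[sel]
  ju <- traj$j_unload_top[sel]
  dm <- traj$day_mask[sel]

  w <- diff(t)
  mid_a <- (a[-1] + a[-length(a)]) / 2
  mid_j <- (ju[-1] + ju[-length(ju)]) / 2
  left_day <- dm[-length(dm)]

  inv_day <- sum(w[left_day] * mid_a[left_day])
  inv_night <- sum(w[!left_day] * mid_a[!left_day])
  investment <- inv_day + inv_night
  if (investment <= 0) {
    stop("integrated expression is zero: investment efficiency undefined",
         call. = FALSE)
  }
  si_top <- sum(w * mid_j)
  structure(list(
    ie = si_top / investment,
    si_top_leaf = si_top,
    investment = investment,
    investment_day = inv_day,
    investment_night = inv_night,
    night_day_ratio_pct = 100 * inv_night / inv_day,
    window = c(stri = stri, endi = endi)
  ), class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat("investment efficiency:", signif(x$ie, 5), "umol Si per unit expression\n")
  cat("  top-leaf Si:", signif(x$si_top_leaf, 5), "umol; expression integral:",
      signif(x$investment, 5), "h\n")
  cat("  night/day investment ratio:", signif(x$night_day_ratio_pct, 4), "%\n")
  invisible(x)
}

#' Investment-efficiency experiment across expression sensitivities
#'
#' Runs a constant-expression reference and a set of water-stress-control
#' settings of increasing sensitivity on identical forcing, and reports each
#' setting's investment efficiency, its percent change relative to the
#' constant run, and the night/day investment split.
#'
#' @param g a `plant_graph`.
#' @param forcing a `forcing` covering the span.
#' @param config configuration list.
#' @param sensitivities named list of `c(dec = ..., slp = ...)` settings; the
#'   default is the standard low / intermediate / high ladder
#'   (dec = 0.2 with slp_J = 0.05, 0.1, 0.2).
#' @param dt Euler step (h).
#' @return Data frame with one row per setting (`constant` first): columns
#'   `setting`, `dec`, `slp`, `ie`, `ie_change_vs_constant_pct`,
#'   `investment_day`, `investment_night`, `night_day_ratio_pct`.
#' @export
efficiency_experiment <- function(g, forcing, config = default_config(),
                                  sensitivities = list(
                                    low = c(dec = 0.2, slp = 0.05),
                                    intermediate = c(dec = 0.2, slp = 0.1),
                                    high = c(dec = 0.2, slp = 0.2)),
                                  dt = config$numerics$dt) {
  runs <- c(list(constant = NULL), sensitivities)
  rows <- lapply(names(runs), function(nm) {
    ctrl <- if (nm == "constant") control_config("constant")
            else control_config("water_stress",
                                slp = runs[[nm]][["slp"]],
                                dec = runs[[nm]][["dec"]])
    traj <- run_simulation(g, forcing, ctrl, config, dt = dt)
    rep <- investment_efficiency(traj)
    data.frame(setting = nm,
               dec = if (nm == "constant") 0 else runs[[nm]][["dec"]],
               slp = if (nm == "constant") 0 else runs[[nm]][["slp"]],
               ie = rep$ie,
               investment_day = rep$investment_day,
               investment_night = rep$investment_night,
               night_day_ratio_pct = rep$night_day_ratio_pct)
  })
  out <- do.call(rbind, rows)
  ie_const <- out$ie[out$setting == "constant"]
  out$ie_change_vs_constant_pct <- 100 * (out$ie - ie_const) / ie_const
  out[, c("setting", "dec", "slp", "ie", "ie_change_vs_constant_pct",
          "investment_day", "investment_night", "night_day_ratio_pct")]
}
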