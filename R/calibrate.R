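#' Default settings for the root-transporter calibration experiment
#'
#' The calibration emulates the hydroponic exposure experiment: seedlings in
#' 1.0 mM Si solution, xylem-sap Si sampled every 5 min, full transporter
#' expression (alpha = 1), no shoot feedback, and a constant first-order
#' efflux from the stele toward the shoot (a sealed stele could not reproduce
#' the saturating sap-concentration curves).
#'
#' @return List with `exposure_mM`, `duration_h`, `step_min`, `k_efflux`
#'   (h^-1), `v_cor`, `v_st` (ml), `dt` (integration step, h).
#' @export
calibration_settings <- function() {
  list(exposure_mM = 1.0, duration_h = 20, step_min = 5,
       k_efflux = 0.2, v_cor = 1.0, v_st = 1.0, dt = 0.1)
}

#' Forward model: xylem-sap Si time series of the root two-compartment model
#'
#' Integrates the cortex/stele system at full expression (alpha = 1) from
#' zero initial Si: the cortex gains the exodermal influx and loses the
#' endodermal flux; the stele gains the endodermal flux and turns over toward
#' the shoot at rate `k_efflux`. The system is linear with constant
#' coefficients, so it is solved exactly through the eigendecomposition of
#' its rate matrix (a fixed-step RK4 integrator, `settings$dt`, covers the
#' degenerate-eigenvalue corner). Returns the stele (xylem sap) concentration
#' at the requested times.
#'
#' @param theta named or positional vector `(tr_exo, tr_end, p_cm)`, ml h^-1.
#' @param exposure external Si concentration, mM.
#' @param times_min sampling times, minutes, strictly increasing, >= 0.
#' @param settings list from [calibration_settings()].
#' @return Numeric vector of stele Si (mM) at `times_min`.
#' @export
forward_xylem_series <- function(theta, exposure = 1.0, times_min,
                                 settings = calibration_settings()) {
  if (any(theta < 0)) stop("theta components must be >= 0", call. = FALSE)
  if (is.unsorted(times_min, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  tr_exo <- theta[[1]]; tr_end <- theta[[2]]; p_cm <- theta[[3]]
  v_cor <- settings$v_cor; v_st <- settings$v_st
  k_eff <- settings$k_efflux
  t_h <- times_min / 60

  # linear constant-coefficient system y' = A y + b, y = (C_cor, C_stele),
  # y(0) = 0; solved exactly through the eigendecomposition of A
  a11 <- -(tr_end + 2 * p_cm) / v_cor
  a12 <- p_cm / v_cor
  a21 <- (tr_end + p_cm) / v_st
  a22 <- -(p_cm / v_st + k_eff)
  b1 <- (tr_exo + p_cm) * exposure / v_cor
  if (b1 == 0) return(rep(0, length(times_min)))

  disc <- (a11 - a22)^2 + 4 * a12 * a21
  lam1 <- (a11 + a22 + sqrt(disc)) / 2
  lam2 <- (a11 + a22 - sqrt(disc)) / 2
  det_a <- a11 * a22 - a12 * a21
  if (abs(lam1 - lam2) < 1e-10 || abs(det_a) < 1e-14) {
    return(forward_xylem_rk4(theta, exposure, times_min, settings))
  }
  # particular (steady-state) solution y* = -A^-1 b
  ys1 <- -(a22 * b1) / det_a
  ys2 <- (a21 * b1) / det_a
  # homogeneous part y(t) = y* + c1 v1 e^(lam1 t) + c2 v2 e^(lam2 t) with
  # y(0) = 0; eigenvectors v_k = (a12, lam_k - a11)
  v1_1 <- a12; v1_2 <- lam1 - a11
  v2_1 <- a12; v2_2 <- lam2 - a11
  dn <- v1_1 * v2_2 - v2_1 * v1_2
  if (abs(dn) < 1e-14) {
    return(forward_xylem_rk4(theta, exposure, times_min, settings))
  }
  c1 <- (-ys1 * v2_2 + ys2 * v2_1) / dn
  c2 <- (ys1 * v1_2 - ys2 * v1_1) / dn
  ys2 + c1 * v1_2 * exp(lam1 * t_h) + c2 * v2_2 * exp(lam2 * t_h)
}

# classical fixed-step RK4 fallback for (near-)degenerate eigenstructure
forward_xylem_rk4 <- function(theta, exposure, times_min,
                              settings = calibration_settings()) {
  tr_exo <- theta[[1]]; tr_end <- theta[[2]]; p_cm <- theta[[3]]
  v_cor <- settings$v_cor; v_st <- settings$v_st
  k_eff <- settings$k_efflux
  dt <- settings$dt
  t_end <- max(times_min) / 60
  if (t_end <= 0) return(rep(0, length(times_min)))
  n_steps <- max(1L, ceiling(t_end / dt - 1e-12))
  h <- t_end / n_steps

  deriv <- function(cor, st) {
    j_oc <- tr_exo * exposure - p_cm * (cor - exposure)
    j_cs <- tr_end * cor - p_cm * (st - cor)
    c((j_oc - j_cs) / v_cor, j_cs / v_st - k_eff * st)
  }
  tt <- numeric(n_steps + 1)
  cc <- matrix(0, n_steps + 1, 2)  # columns: cortex, stele; zero init
  for (k in seq_len(n_steps)) {
    y <- cc[k, ]
    k1 <- deriv(y[1], y[2])
    k2 <- deriv(y[1] + h / 2 * k1[1], y[2] + h / 2 * k1[2])
    k3 <- deriv(y[1] + h / 2 * k2[1], y[2] + h / 2 * k2[2])
    k4 <- deriv(y[1] + h * k3[1], y[2] + h * k3[2])
    cc[k + 1, ] <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    tt[k + 1] <- k * h
  }
  approx(tt, cc[, 2], xout = times_min / 60, rule = 2)$y
}

#' Construct a calibration series
#'
#' @param times_min sampling times (min), strictly increasing.
#' @param concentration_mM observed xylem-sap Si (mM).
#' @param sigma_mM per-time standard deviation (mM), > 0.
#' @return A `calibration_series` data frame.
#' @export
calibration_series <- function(times_min, concentration_mM, sigma_mM) {
  if (is.unsorted(times_min, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(sigma_mM <= 0)) stop("sigma must be > 0", call. = FALSE)
  structure(data.frame(time_min = times_min,
                       concentration_mM = concentration_mM,
                       sigma_mM = sigma_mM),
            class = c("calibration_series", "data.frame"))
}

#' Read a calibration series from CSV
#'
#' Columns: `time_min`, `concentration_mM`, `sigma_mM`.
#'
#' @param path CSV path.
#' @return A `calibration_series`.
#' @export
read_calibration_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "concentration_mM", "sigma_mM")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("calibration CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  calibration_series(d$time_min, d$concentration_mM, d$sigma_mM)
}

#' Gaussian log-likelihood of transporter parameters
#'
#' Independent Gaussian errors with the per-time standard deviations of the
#' data: log L = sum_t [ -1/2 log(2 pi sigma_t^2)
#' - (C_model(t) - C_obs(t))^2 / (2 sigma_t^2) ], with model predictions from
#' [forward_xylem_series()].
#'
#' @param theta parameter vector `(tr_exo, tr_end, p_cm)`.
#' @param data a `calibration_series`.
#' @param exposure external Si concentration (mM).
#' @param settings calibration settings.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(theta, data, exposure = 1.0,
                           settings = calibration_settings()) {
  pred <- forward_xylem_series(theta, exposure, data$time_min, settings)
  resid <- pred - data$concentration_mM
  sum(-0.5 * log(2 * pi * data$sigma_mM^2) -
        resid^2 / (2 * data$sigma_mM^2))
}

#' Default bounded-uniform priors for the transporter parameters
#'
#' Roughly two orders of magnitude around plausible values.
#'
#' @return Data frame with rownames `tr_exo`, `tr_end`, `p_cm` and columns
#'   `lower`, `upper`.
#' @export
default_priors <- function() {
  data.frame(lower = c(tr_exo = 0.01, tr_end = 0.01, p_cm = 0.001),
             upper = c(tr_exo = 5, tr_end = 5, p_cm = 0.5))
}

#' Metropolis-Hastings sampling of the transporter posterior
#'
#' Random-walk Metropolis with Gaussian proposals under bounded uniform
#' priors. During burn-in the proposal is adapted twice over: the proposal
#' covariance is learned from the chain history (scaled 2.38^2/d), which lets
#' the walker track the correlated ridge that the three transporter
#' parameters form, and a global step-size factor is tuned toward a 20-40%
#' acceptance rate. Both are frozen after burn-in. Reproducible from `seed`.
#'
#' @param data a `calibration_series`.
#' @param priors bounds data frame, see [default_priors()].
#' @param n_iter total iterations (burn-in included).
#' @param seed RNG seed.
#' @param burn_frac fraction of iterations discarded as burn-in.
#' @param exposure external Si concentration (mM).
#' @param settings calibration settings.
#' @param log_lik_fn log-likelihood function of `(theta, data)`; defaults to
#'   [log_likelihood()]. Replace with a constant function to sample the prior.
#' @param init optional starting point; by default the chain starts at the
#'   posterior mode located by bounded optimization from the prior midpoint.
#' @return A `posterior_sample`: post-burn-in `draws` matrix (one column per
#'   parameter), `log_lik`, `acceptance_rate`, `proposal_sd`, `seed`.
#' @export
run_mcmc <- function(data, priors = default_priors(), n_iter = 4000,
                     seed = 1, burn_frac = 0.5, exposure = 1.0,
                     settings = calibration_settings(),
                     log_lik_fn = NULL, init = NULL) {
  stopifnot(n_iter >= 20, burn_frac > 0, burn_frac < 1)
  if (is.null(log_lik_fn)) {
    log_lik_fn <- function(theta, data) {
      log_likelihood(theta, data, exposure, settings)
    }
  }
  lower <- priors$lower; upper <- priors$upper
  p <- length(lower)
  par_names <- rownames(priors)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  if (is.null(init)) {
    mid <- (lower + upper) / 2
    opt <- tryCatch(
      stats::optim(mid, function(th) -log_lik_fn(th, data),
                   method = "L-BFGS-B",
                   lower = lower + 1e-9, upper = upper - 1e-9,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    init <- if (!is.null(opt) && is.finite(opt$value)) opt$par else mid
  }
  theta <- as.numeric(init)
  ll <- log_lik_fn(theta, data)
  if (!is.finite(ll)) stop("initial point has non-finite log-likelihood")

  prop_chol <- diag((upper - lower) / 20, p)  # initial diagonal proposal
  step_scale <- 1
  n_burn <- floor(n_iter * burn_frac)
  adapt_every <- 50
  cov_floor <- diag((1e-6 * (upper - lower))^2, p)

  draws <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, par_names))
  logls <- numeric(n_iter)
  acc <- logical(n_iter)
  window_acc <- 0L

  for (it in seq_len(n_iter)) {
    prop <- theta + step_scale * as.numeric(prop_chol %*% rnorm(p))
    if (all(prop >= lower & prop <= upper)) {
      ll_prop <- log_lik_fn(prop, data)
      if (is.finite(ll_prop) && log(runif(1)) < ll_prop - ll) {
        theta <- prop; ll <- ll_prop
        acc[it] <- TRUE
        window_acc <- window_acc + 1L
      }
    }
    draws[it, ] <- theta
    logls[it] <- ll
    if (it <= n_burn && it %% adapt_every == 0) {
      rate <- window_acc / adapt_every
      if (rate < 0.2) step_scale <- step_scale / 1.5
      if (rate > 0.4) step_scale <- step_scale * 1.5
      window_acc <- 0L
      # learn the proposal covariance from the chain history (needs some
      # accepted spread first)
      if (it >= 200) {
        S <- stats::cov(draws[seq_len(it), , drop = FALSE])
        if (all(is.finite(S)) && any(diag(S) > 0)) {
          S <- 2.38^2 / p * S + cov_floor
          ch <- tryCatch(chol(S), error = function(e) NULL)
          if (!is.null(ch)) prop_chol <- t(ch)
        }
      }
    }
  }

  keep <- (n_burn + 1):n_iter
  acc_rate <- mean(acc[keep])
  if (acc_rate == 0) {
    stop("zero acceptance after tuning; proposal scale = ",
         signif(step_scale, 3), call. = FALSE)
  }
  structure(list(draws = draws[keep, , drop = FALSE],
                 log_lik = logls[keep],
                 acceptance_rate = acc_rate,
                 proposal_sd = step_scale * prop_chol,
                 seed = seed),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("posterior_sample:", nrow(x$draws), "draws, acceptance",
      signif(100 * x$acceptance_rate, 3), "%\n")
  print(t(apply(x$draws, 2, quantile, c(0.025, 0.5, 0.975))))
  invisible(x)
}

#' Equal-tailed credible intervals of a posterior sample
#'
#' @param post a `posterior_sample`.
#' @param level credibility level (default 0.95).
#' @return Matrix with one row per parameter, columns `lower`, `upper`.
#' @export
credible_interval <- function(post, level = 0.95) {
  a <- (1 - level) / 2
  t(apply(post$draws, 2, quantile, probs = c(a, 1 - a), names = FALSE)) |>
    `colnames<-`(c("lower", "upper"))
}

#' Write posterior draws to CSV
#'
#' Columns: `draw`, one per parameter, `logL`.
#'
#' @param post a `posterior_sample`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(post, path) {
  d <- data.frame(draw = seq_len(nrow(post$draws)), post$draws,
                  logL = post$log_lik)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic xylem-sap calibration series
#'
#' Stands in for the unavailable measured series: forward-model trajectory for
#' a known parameter set plus independent Gaussian noise with per-time
#' standard deviation sigma_t, stored alongside the series. sigma_t is
#' `frac` of the forward value with a floor of `floor_frac` of the trajectory
#' maximum (keeping every sigma_t positive).
#'
#' @param theta_true generating parameters `(tr_exo, tr_end, p_cm)`.
#' @param exposure external Si concentration (mM).
#' @param duration_h exposure duration (h).
#' @param step_min sampling interval (min).
#' @param sigma_model list with `frac` and `floor_frac`.
#' @param seed RNG seed.
#' @param settings calibration settings.
#' @return A `calibration_series`.
#' @export
generate_synthetic_series <- function(theta_true,
                                      exposure = 1.0,
                                      duration_h = 20,
                                      step_min = 5,
                                      sigma_model = list(frac = 0.05,
                                                         floor_frac = 0.02),
                                      seed = 1,
                                      settings = calibration_settings()) {
  stopifnot(duration_h > 0, step_min > 0)
  times <- seq(step_min, duration_h * 60, by = step_min)
  truth <- forward_xylem_series(theta_true, exposure, times, settings)
  sigma <- pmax(sigma_model$frac * truth,
                sigma_model$floor_frac * max(truth, 1e-9))
  if (all(sigma == 0)) {
    noise <- 0
    sigma <- rep(1e-12, length(times))
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    noise <- rnorm(length(times), 0, sigma)
  }
  calibration_series(times, pmax(0, truth + noise), sigma)
}
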