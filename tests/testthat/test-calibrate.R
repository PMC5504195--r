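test_that("forward model honors boundary and initial conditions", {
  times <- seq(5, 600, by = 5)
  expect_equal(forward_xylem_series(c(0, 0, 0), 1, times), rep(0, 120))
  expect_equal(forward_xylem_series(c(0.5, 1, 0.05), 1, c(1e-9, 60))[1], 0,
               tolerance = 1e-8)
  # rejects negative parameters and unsorted times
  expect_error(forward_xylem_series(c(-1, 1, 0.05), 1, times), ">= 0")
  expect_error(forward_xylem_series(c(0.5, 1, 0.05), 1, c(10, 5)),
               "increasing")
})

test_that("forward model agrees with independent integrators", {
  times <- seq(5, 1200, by = 5)
  set.seed(8)
  for (i in 1:5) {
    theta <- c(runif(1, 0.05, 2), runif(1, 0.05, 2), runif(1, 0.001, 0.3))
    a <- forward_xylem_series(theta, 1, times)
    # refined fixed-step reference
    s <- calibration_settings(); s$dt <- s$dt / 100
    b <- riceSiDyn:::forward_xylem_rk4(theta, 1, times, s)
    expect_lt(max(abs(a - b)) / max(b), 0.005)
  }
  # deSolve as a fully external oracle
  theta <- c(0.5, 1, 0.05)
  st <- calibration_settings()
  rhs <- function(t, y, p) {
    j_oc <- p[1] * 1 - p[3] * (y[1] - 1)
    j_cs <- p[2] * y[1] - p[3] * (y[2] - y[1])
    list(c(j_oc - j_cs, j_cs - st$k_efflux * y[2]))
  }
  sol <- deSolve::lsoda(c(0, 0), c(0, times / 60), rhs, theta,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(forward_xylem_series(theta, 1, times), sol[-1, 3],
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("log-likelihood is the Gaussian sum with per-time sigmas", {
  times <- c(10, 20, 30)
  theta <- c(0.5, 1, 0.05)
  pred <- forward_xylem_series(theta, 1, times)
  d <- calibration_series(times, pred, sigma_mM = c(0.1, 0.2, 0.3))
  expect_equal(log_likelihood(theta, d), sum(-0.5 * log(2 * pi * d$sigma_mM^2)))

  # single point, unit sigma, unit residual
  d1 <- calibration_series(60, forward_xylem_series(theta, 1, 60) + 1, 1)
  expect_equal(log_likelihood(theta, d1), -0.5 * log(2 * pi) - 0.5,
               tolerance = 1e-12)

  # quadratic penalty: likelihood falls as a residual grows
  lls <- vapply(c(0, 0.5, 1, 2), function(off) {
    log_likelihood(theta, calibration_series(60, pred[1] + off, 0.2))
  }, numeric(1))
  expect_true(all(diff(lls) < 0))

  # permutation invariance over time points
  d3 <- generate_synthetic_series(theta, seed = 4)
  idx <- sample(nrow(d3))
  ll_perm <- sum(vapply(idx, function(i) {
    log_likelihood(theta, calibration_series(d3$time_min[i],
                                             d3$concentration_mM[i],
                                             d3$sigma_mM[i]))
  }, numeric(1)))
  expect_equal(log_likelihood(theta, d3), ll_perm, tolerance = 1e-9)
})

test_that("synthetic series reduce to the forward model as noise vanishes", {
  theta <- c(0.5, 1, 0.05)
  d0 <- generate_synthetic_series(theta,
                                  sigma_model = list(frac = 0, floor_frac = 0),
                                  seed = 1)
  expect_equal(d0$concentration_mM,
               forward_xylem_series(theta, 1, d0$time_min))
  # default: 5-min grid over the 20-h exposure
  d <- generate_synthetic_series(theta, seed = 1)
  expect_equal(d$time_min, seq(5, 1200, by = 5))
  expect_true(all(d$sigma_mM > 0))
})

test_that("synthetic noise is centered on the forward model", {
  theta <- c(0.5, 1, 0.05)
  truth <- forward_xylem_series(theta, 1, seq(5, 1200, by = 5))
  k <- 120  # a mid-series time point
  vals <- vapply(1:400, function(r) {
    generate_synthetic_series(theta, seed = r)$concentration_mM[k]
  }, numeric(1))
  sigma <- generate_synthetic_series(theta, seed = 1)$sigma_mM[k]
  expect_lt(abs(mean(vals) - truth[k]), 3 * sigma / sqrt(400))
})

test_that("the sampler is reproducible and respects the prior support", {
  theta <- c(0.5, 1, 0.05)
  d <- generate_synthetic_series(theta, seed = 3)
  p1 <- run_mcmc(d, n_iter = 600, seed = 42)
  p2 <- run_mcmc(d, n_iter = 600, seed = 42)
  expect_identical(p1$draws, p2$draws)
  pr <- default_priors()
  expect_true(all(sweep(p1$draws, 2, pr$lower, ">=") &
                    sweep(p1$draws, 2, pr$upper, "<=")))
  expect_gt(p1$acceptance_rate, 0)
})

test_that("with a flat likelihood the chain reproduces the uniform prior", {
  d <- generate_synthetic_series(c(0.5, 1, 0.05), seed = 5)
  post <- run_mcmc(d, n_iter = 12000, seed = 11,
                   log_lik_fn = function(theta, data) 0)
  pr <- default_priors()
  for (j in 1:3) {
    ks <- suppressWarnings(
      stats::ks.test(post$draws[, j], "punif", pr$lower[j], pr$upper[j]))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("the likelihood mode approaches the truth as noise shrinks", {
  theta <- c(0.5, 1, 0.05)
  pr <- default_priors()
  set.seed(99)
  starts <- cbind(runif(8, pr$lower[1], pr$upper[1]),
                  runif(8, pr$lower[2], pr$upper[2]),
                  runif(8, pr$lower[3], pr$upper[3]))
  mode_at <- function(frac) {
    d <- generate_synthetic_series(
      theta, sigma_model = list(frac = frac, floor_frac = frac / 2), seed = 31)
    best <- NULL; bestv <- -Inf
    for (s in seq_len(nrow(starts))) {
      o <- stats::optim(log(starts[s, ]),
                        function(x) -log_likelihood(exp(x), d),
                        method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
      if (-o$value > bestv) { bestv <- -o$value; best <- exp(o$par) }
    }
    best
  }
  err <- function(m) max(abs(m - theta) / theta)
  e1 <- err(mode_at(0.01))
  e2 <- err(mode_at(0.001))
  expect_lt(e2, e1)      # tighter data pin the mode more closely
  expect_lt(e2, 0.1)     # near-noiseless data recover all three parameters
})

test_that("posterior draws and calibration series survive CSV round trips", {
  d <- generate_synthetic_series(c(0.5, 1, 0.05), seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, path, row.names = FALSE)
  d2 <- read_calibration_csv(path)
  expect_equal(d2$concentration_mM, d$concentration_mM, tolerance = 1e-12)
  expect_error(calibration_series(c(5, 5), c(0, 0), c(1, 1)), "increasing")
  expect_error(calibration_series(c(5, 10), c(0, 0), c(1, 0)), "sigma")

  post <- run_mcmc(d, n_iter = 300, seed = 2)
  pth2 <- withr::local_tempfile(fileext = ".csv")
  write_posterior_csv(post, pth2)
  back <- utils::read.csv(pth2)
  expect_named(back, c("draw", "tr_exo", "tr_end", "p_cm", "logL"))
  ci <- credible_interval(post)
  expect_true(all(ci[, "upper"] >= ci[, "lower"]))
})
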