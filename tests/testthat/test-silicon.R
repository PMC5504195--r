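test_that("root uptake fluxes follow the two-compartment law", {
  g <- chain_graph(3, root = list(tr_exo = 2, tr_end = 1, p_cm = 0.1,
                                  v_cor = 1, r_lat_root = 0.2, psi_soil = 0))
  s <- new_si_state(g, alpha = 1)
  s$c_m_out <- 1.0
  s$c_m_cor <- 0.5
  fl <- root_uptake_fluxes(s, g$root)
  expect_equal(fl$j_m_oc, 2 * 1 - 0.1 * (0.5 - 1))  # 2.05
  expect_equal(fl$j_m_cs, 1 * 0.5 - 0.1 * (0 - 0.5))

  # no transporter and equal concentrations: pure leak vanishes
  s$alpha <- 0
  s$c_m_cor <- s$c_m_out
  expect_equal(root_uptake_fluxes(s, g$root)$j_m_oc, 0)
})

test_that("cortex converges to the steady state found by bisection", {
  g <- chain_graph(3)
  s <- new_si_state(g, alpha = 0.7)
  s$c_m_out <- 1.0
  # hold the stele fixed and find C_cor with J_oc = J_cs by root finding
  c_nr <- 0.4
  bal <- function(ccor) {
    st <- s; st$c_m_cor <- ccor; st$c_m[st$nr] <- c_nr
    fl <- root_uptake_fluxes(st, g$root)
    fl$j_m_oc - fl$j_m_cs
  }
  target <- stats::uniroot(bal, c(0, 100), tol = 1e-12)$root
  s$c_m[s$nr] <- c_nr
  for (i in 1:4000) {
    s <- step_root(s, g$root, j_m_up = 0, dt = 0.05, v_mix_root = 1)
    s$c_m[s$nr] <- c_nr  # pinned boundary
  }
  expect_equal(s$c_m_cor, target, tolerance = 1e-6)
})

test_that("step_root arithmetic matches the balance equations", {
  g <- chain_graph(3, root = list(tr_exo = 2, tr_end = 0, p_cm = 0,
                                  v_cor = 1, r_lat_root = 0.2, psi_soil = 0))
  s <- new_si_state(g, alpha = 1)
  s$c_m_out <- 1.0
  s$c_m_cor <- 0.5
  s2 <- step_root(s, g$root, j_m_up = 0, dt = 0.1, v_mix_root = 1)
  expect_equal(s2$c_m_cor - s$c_m_cor, 0.1 * 2.0 / 1)  # J_oc = 2, no efflux
  # all fluxes zero: state unchanged
  g0 <- chain_graph(3, root = list(tr_exo = 0, tr_end = 0, p_cm = 0,
                                   v_cor = 1, r_lat_root = 0.2, psi_soil = 0))
  s0 <- new_si_state(g0, alpha = 1)
  s0$c_m_out <- 0
  expect_equal(step_root(s0, g0$root, 0, 0.1, 1)$c_m, s0$c_m)
})

test_that("axial Si flux is clamped to the transpiration direction", {
  expect_equal(axial_si_flux(0, 5), 0)
  expect_equal(axial_si_flux(1.5, 2), 3)
  expect_equal(axial_si_flux(1.5, -2), 0)
})

test_that("junction partitioning enriches DVB and conserves Si mass", {
  # no enrichment: both branches carry the incoming concentration
  p1 <- junction_partition(1.3, 1, 3, rho = 1)
  expect_equal(p1$c_dvb, 1.3)
  expect_equal(p1$c_evb, 1.3)

  p2 <- junction_partition(1, j_w_dvb = 1, j_w_evb = 3, rho = 2)
  expect_equal(p2$c_evb, 0.8)
  expect_equal(p2$c_dvb, 1.6)

  # mass balance across random cases
  set.seed(3)
  for (i in 1:50) {
    jd <- runif(1, 0, 3); je <- runif(1, 0, 3)
    rho <- runif(1, 1, 5); cm <- runif(1, 0, 10)
    p <- junction_partition(cm, jd, je, rho)
    expect_equal(jd * p$c_dvb + je * p$c_evb, (jd + je) * cm,
                 tolerance = 1e-12)
    expect_equal(p$c_dvb, rho * p$c_evb)
  }

  # zero DVB flow: EVB carries everything at the incoming concentration
  p3 <- junction_partition(2, 0, 1.5, rho = 3)
  expect_equal(p3$c_evb, 2)
  expect_equal(p3$c_dvb, 6)

  expect_warning(junction_partition(1, 0, 0, 2), "zero")

  # the alternative denominator variant does not conserve mass for
  # unequal branch flows
  p4 <- junction_partition(1, 1, 3, rho = 2, alt_denominator = TRUE)
  expect_false(isTRUE(all.equal(1 * p4$c_dvb + 3 * p4$c_evb, 4)))
})

test_that("unloading flux is the first-order product rule", {
  expect_equal(unload_flux(2, 0.5, 0.1), 0.1)
  expect_equal(unload_flux(0, 0.5, 0.1), 0)
})

test_that("silicon is frozen without flow or unloading, except root exchange", {
  cfg <- default_config()
  cfg$silicon$k_m_unload <- 0
  g <- std_plant(cfg)
  s <- new_si_state(g, cfg, alpha = 1)
  s$c_m <- rep(0.5, 16)
  w <- fake_water(g, j_x = 0, j_p = 0)
  s2 <- step_silicon(g, s, w, cfg$silicon, cfg, dt = 0.1)
  non_root <- setdiff(seq_len(16), s$nr)
  expect_equal(s2$c_m[non_root], s$c_m[non_root])
  expect_equal(s2$c_m_cyt, s$c_m_cyt)
  expect_gt(s2$c_m_cor, s$c_m_cor)  # uptake continues into the cortex
})

test_that("xylem advection matches a 1-D upwind reference on a chain", {
  cfg <- default_config()
  cfg$silicon$k_m_unload <- 0
  cfg$silicon$use_vst_for_root_stele <- FALSE
  g <- chain_graph(6, v_con = 0.4,
                   root = list(tr_exo = 0, tr_end = 0, p_cm = 0,
                               v_cor = 1, r_lat_root = 0.2, psi_soil = 0))
  g$nodes$tissue[2:5] <- "internode"  # no junctions on the path
  s <- new_si_state(g, cfg, alpha = 0)
  s$c_m_out <- 0
  s$c_m[1] <- 2  # pulse at the root
  J <- 0.8
  w <- fake_water(g, j_x = J)
  dt <- 0.05
  # independent reference: textbook upwind update on a line
  ref <- s$c_m
  for (step in 1:200) {
    inflow <- c(0, J * ref[-6])
    outflow <- c(J * ref[-6], 0)
    ref <- ref + dt * (inflow - outflow) / 0.4
    s <- step_silicon(g, s, w, cfg$silicon, cfg, dt)
  }
  expect_equal(s$c_m, ref, tolerance = 1e-12)
  # pulse peak has advected downstream by roughly J*t/V node spacings
  expect_gt(which.max(s$c_m), 1)
})

test_that("whole-run Si ledger closes and concentrations stay non-negative", {
  g <- std_plant()
  f <- fast_forcing(days = 1)
  traj <- run_simulation(g, f, control_config("constant"))
  # soil influx accounts for all stored plus unloaded Si
  expect_equal(traj$meta$cum_soil,
               traj$si_mass[length(traj$si_mass)] - traj$si_mass[1],
               tolerance = 1e-9)
  expect_true(all(traj$c_m >= 0))
  expect_true(all(traj$c_m_cyt >= 0))
  expect_true(all(traj$c_m_cor >= 0))
})

test_that("cumulative uptake is monotone in the expression factor", {
  cfg <- default_config()
  g <- std_plant(cfg)
  w <- fake_water(g, j_x = 0.5, j_p = 0)
  uptake <- vapply(seq(0, 1, by = 0.25), function(a) {
    s <- new_si_state(g, cfg, alpha = a)
    for (i in 1:480) s <- step_silicon(g, s, w, cfg$silicon, cfg, dt = 0.05)
    s$cum_soil
  }, numeric(1))
  expect_true(all(diff(uptake) > 0))
})

test_that("rho = 1 makes both partition denominators equivalent", {
  cfg <- default_config()
  cfg$junctions$rho <- 1
  g <- std_plant(cfg)
  f <- fast_forcing(days = 1)
  t1 <- run_simulation(g, f, control_config("constant"), cfg)
  cfg2 <- cfg
  cfg2$silicon$use_alt_partition_denominator <- TRUE
  t2 <- run_simulation(std_plant(cfg2), f, control_config("constant"), cfg2)
  expect_identical(t1$c_m, t2$c_m)
  expect_identical(t1$c_m_cyt, t2$c_m_cyt)
})
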