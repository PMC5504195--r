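# shared fixtures: all built in code at test time

std_plant <- function(config = default_config()) build_standard_plant(config)

# minimal hand-built linear plant (root - junction - sheath - leaf chain),
# used by small closed-form oracles; bypasses build_standard_plant on purpose
chain_graph <- function(n = 4, r_x = 0.1, r_p = 0.5, r_lat = 1,
                        v_st = 1, v_con = 0.5, v_cyt = 1,
                        root = list(tr_exo = 0.5, tr_end = 1, p_cm = 0.05,
                                    v_cor = 1, r_lat_root = 0.2,
                                    psi_soil = 0)) {
  stopifnot(n >= 2)
  tissue <- c("root", rep("junction", max(0, n - 2)), "leaf")
  nodes <- data.frame(
    id = seq_len(n), tissue = tissue,
    v_st = v_st, v_con = v_con, v_cyt = v_cyt,
    temperature = 298.15,
    is_root = seq_len(n) == 1,
    is_top_leaf = seq_len(n) == n,
    stringsAsFactors = FALSE
  )
  edges <- rbind(
    data.frame(i = 1:(n - 1), j = 2:n, pathway = "xylem", r = r_x,
               branch_class = "none", stringsAsFactors = FALSE),
    data.frame(i = 1:(n - 1), j = 2:n, pathway = "phloem", r = r_p,
               branch_class = "none", stringsAsFactors = FALSE)
  )
  structure(list(nodes = nodes, edges = edges,
                 junctions = data.frame(id = integer(0), rho = numeric(0)),
                 root = root, r_lat = rep(r_lat, n)),
            class = "plant_graph")
}

# a water_state with prescribed per-edge flows and zero potentials, for unit
# tests of the transport kernels in isolation
fake_water <- function(g, j_x = 0, j_p = 0) {
  n <- nrow(g$nodes)
  n_xe <- sum(g$edges$pathway == "xylem")
  n_pe <- sum(g$edges$pathway == "phloem")
  structure(list(
    psi_x = numeric(n), psi_p = numeric(n), p_p = numeric(n), pi = numeric(n),
    j_x = rep(j_x, length.out = n_xe), j_p = rep(j_p, length.out = n_pe),
    j_lat = numeric(n), j_soil = 0, transpiration = numeric(n), residual = 0
  ), class = "water_state")
}

fast_forcing <- function(days = 1, dt = 0.05, config = default_config()) {
  generate_standard_forcing(days = days, dt = dt, config = config)
}
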