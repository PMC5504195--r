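# Gas constant, J mol^-1 K^-1; Pa -> MPa conversion; model time unit is hours
R_GAS <- 8.314
PA_TO_MPA <- 1e-6
SECONDS_PER_HOUR <- 3600

#' Osmotic potential of a sucrose solution
#'
#' Van 't Hoff relation: Pi = -R * T * C, converted to MPa. With sucrose in
#' mol m^-3 and T in K the product R*T*C is in Pa.
#'
#' @param c_s sucrose concentration, mol m^-3 (vectorized).
#' @param temperature absolute temperature, K.
#' @return Osmotic potential in MPa, always <= 0.
#' @export
#' @examples
#' osmotic_potential(100, 293.15)  # -0.2437 MPa
osmotic_potential <- function(c_s, temperature) {
  if (any(c_s < 0)) stop("negative sucrose concentration", call. = FALSE)
  if (any(temperature <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  -R_GAS * temperature * c_s * PA_TO_MPA
}

#' Assemble (and factor) the linear water-potential system of a plant graph
#'
#' The quasi-static water balance is linear in the xylem and phloem potentials
#' once the osmotic potentials are fixed: axial xylem flow follows the xylem
#' potential difference over the edge resistance, axial phloem flow follows the
#' hydraulic pressure difference (P = Psi_P - Pi), and lateral flow at each
#' node follows Psi_X - Psi_P over the lateral resistance. The boundary is a
#' fixed soil water potential behind the root radial resistance and prescribed
#' transpiration sinks at leaf xylem nodes. The coefficient matrix depends only
#' on the graph, so it is factored once per simulation.
#'
#' @param g a `plant_graph`.
#' @return An opaque list holding the inverse system matrix and index maps,
#'   for use by [solve_water()].
#' @export
water_system <- function(g) {
  n <- nrow(g$nodes)
  xe <- g$edges[g$edges$pathway == "xylem", , drop = FALSE]
  pe <- g$edges[g$edges$pathway == "phloem", , drop = FALSE]
  nr <- root_id(g)

  lap <- function(ed) {
    L <- matrix(0, n, n)
    for (k in seq_len(nrow(ed))) {
      i <- ed$i[k]; j <- ed$j[k]; cnd <- 1 / ed$r[k]
      L[i, i] <- L[i, i] - cnd
      L[j, j] <- L[j, j] - cnd
      L[i, j] <- L[i, j] + cnd
      L[j, i] <- L[j, i] + cnd
    }
    L
  }
  L_x <- lap(xe)
  L_p <- lap(pe)
  g_lat <- 1 / g$r_lat

  A <- matrix(0, 2 * n, 2 * n)
  ix <- seq_len(n)
  ip <- n + ix
  A[ix, ix] <- L_x - diag(g_lat, n)
  A[ix, ip] <- diag(g_lat, n)
  A[ip, ip] <- L_p - diag(g_lat, n)
  A[ip, ix] <- diag(g_lat, n)
  A[nr, nr] <- A[nr, nr] - 1 / g$root$r_lat_root

  A_inv <- tryCatch(solve(A), error = function(e) {
    stop("singular water system: check graph connectivity (",
         conditionMessage(e), ")", call. = FALSE)
  })
  list(A_inv = A_inv, L_p = L_p, n = n, nr = nr,
       xylem_edges = xe, phloem_edges = pe)
}

#' Solve the coupled xylem/phloem water-potential network
#'
#' Solves the node-wise flow balance (sum of axial, lateral and boundary flows
#' equals zero at every node in both pathways) for the instantaneous sucrose
#' state, and returns potentials, pressures and all edge flows.
#'
#' @param g a `plant_graph`.
#' @param carbon carbon state (list with per-node sucrose `c_s`), see
#'   [new_carbon_state()].
#' @param transpiration per-leaf transpiration (ml h^-1), either one value per
#'   leaf (in leaf id order) or a full per-node vector.
#' @param system optional pre-assembled [water_system()] (factored once per
#'   simulation).
#' @return A `water_state` list: per-node `psi_x`, `psi_p`, `p_p`, `pi`,
#'   `j_lat` (xylem-to-phloem lateral flow, ml h^-1), per-edge `j_x`, `j_p`
#'   (signed along the stored edge direction), soil inflow `j_soil`, and the
#'   maximum node balance residual `residual`.
#' @export
solve_water <- function(g, carbon, transpiration, system = NULL) {
  if (is.null(system)) system <- water_system(g)
  n <- system$n
  nr <- system$nr
  lv <- leaf_ids(g)

  E <- numeric(n)
  if (length(transpiration) == length(lv)) {
    E[lv] <- transpiration
  } else if (length(transpiration) == n) {
    E <- transpiration
  } else if (length(transpiration) == 1) {
    E[lv] <- transpiration
  } else {
    stop("transpiration must have one value per leaf or per node")
  }

  Pi <- osmotic_potential(carbon$c_s, g$nodes$temperature)
  b <- c(E, as.numeric(system$L_p %*% Pi))
  b[nr] <- b[nr] - g$root$psi_soil / g$root$r_lat_root

  x <- as.numeric(system$A_inv %*% b)
  psi_x <- x[seq_len(n)]
  psi_p <- x[n + seq_len(n)]
  p_p <- psi_p - Pi

  xe <- system$xylem_edges
  pe <- system$phloem_edges
  j_x <- (psi_x[xe$i] - psi_x[xe$j]) / xe$r
  j_p <- (p_p[pe$i] - p_p[pe$j]) / pe$r
  j_lat <- (psi_x - psi_p) / g$r_lat
  j_soil <- (g$root$psi_soil - psi_x[nr]) / g$root$r_lat_root

  # node-wise conservation audit (xylem + phloem balances)
  res_x <- numeric(n); res_p <- numeric(n)
  xei <- xe$i; xej <- xe$j; pei <- pe$i; pej <- pe$j
  for (k in seq_along(j_x)) {
    res_x[xei[k]] <- res_x[xei[k]] - j_x[k]
    res_x[xej[k]] <- res_x[xej[k]] + j_x[k]
  }
  for (k in seq_along(j_p)) {
    res_p[pei[k]] <- res_p[pei[k]] - j_p[k]
    res_p[pej[k]] <- res_p[pej[k]] + j_p[k]
  }
  res_x <- res_x - j_lat - E
  res_x[nr] <- res_x[nr] + j_soil
  res_p <- res_p + j_lat

  structure(list(
    psi_x = psi_x, psi_p = psi_p, p_p = p_p, pi = Pi,
    j_x = j_x, j_p = j_p, j_lat = j_lat, j_soil = j_soil,
    transpiration = E,
    residual = max(abs(c(res_x, res_p)))
  ), class = "water_state")
}

#' Upwind axial phloem solute flow
#'
#' The solute travels with the phloem water at the concentration of the
#' upstream node: J_S = J_W * C(i) for positive flow (i toward j),
#' J_S = J_W * C(j) for negative flow, and 0 at zero flow.
#'
#' @param j_w_p axial phloem water flow on the edge, ml h^-1 (signed).
#' @param c_i,c_j solute concentration at the edge's i and j endpoints.
#' @return Solute flow (concentration unit x ml h^-1), signed like `j_w_p`.
#' @export
sucrose_axial_flow <- function(j_w_p, c_i, c_j) {
  if (any(c_i < 0) || any(c_j < 0)) {
    stop("negative solute concentration", call. = FALSE)
  }
  ifelse(j_w_p > 0, j_w_p * c_i, ifelse(j_w_p < 0, j_w_p * c_j, 0))
}

#' Initial carbon state for a plant graph
#'
#' @param g a `plant_graph`.
#' @param c_s_init initial per-node phloem sucrose (mol m^-3).
#' @param starch_init initial per-leaf starch pool (mol sucrose equivalent).
#' @return A `carbon_state` list with `starch` (per leaf) and `c_s` (per node).
#' @export
new_carbon_state <- function(g, c_s_init = 0, starch_init = 0) {
  n <- nrow(g$nodes)
  lv <- leaf_ids(g)
  structure(list(
    starch = setNames(rep(starch_init, length.out = length(lv)), lv),
    c_s = rep(c_s_init, length.out = n)
  ), class = "carbon_state")
}

#' Advance sucrose and starch one explicit Euler step
#'
#' Leaf starch is fed by photosynthesis and converted to sucrose at first-order
#' rate `k4` (per hour); the converted sucrose is loaded into the leaf phloem
#' pool. Sucrose is advected along the phloem by the upwind scheme of
#' [sucrose_axial_flow()] using sieve-tube volumes, and every node's pool
#' respires at first-order rate `k1` (per second, applied over the hour step).
#' Lateral sucrose flow is ignored.
#'
#' @param carbon a `carbon_state`.
#' @param params list with `k1` (s^-1), `k4` (h^-1), `load_frac`.
#' @param photosynthesis per-leaf photosynthesis rate (mol sucrose equivalent
#'   h^-1), recycled over leaves.
#' @param water a `water_state` from [solve_water()].
#' @param g a `plant_graph`.
#' @param dt time step, h.
#' @return Updated `carbon_state`.
#' @export
step_carbon <- function(carbon, params, photosynthesis, water, g, dt) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  lv <- leaf_ids(g)
  n <- nrow(g$nodes)
  v_st <- g$nodes$v_st
  P <- rep(photosynthesis, length.out = length(lv))

  starch0 <- carbon$starch
  cs0 <- carbon$c_s

  starch <- starch0 + (P - params$k4 * starch0) * dt

  dcs <- numeric(n)
  # phloem loading of converted starch (mol/h over sieve-tube volume in m^3)
  loading <- params$load_frac * params$k4 * starch0
  dcs[lv] <- dcs[lv] + loading / (v_st[lv] * 1e-6)
  # upwind advection along phloem edges (ml cancels against ml volumes)
  pe <- g$edges[g$edges$pathway == "phloem", , drop = FALSE]
  pei <- pe$i; pej <- pe$j
  js <- sucrose_axial_flow(water$j_p, cs0[pei], cs0[pej])
  for (k in seq_along(js)) {
    dcs[pei[k]] <- dcs[pei[k]] - js[k] / v_st[pei[k]]
    dcs[pej[k]] <- dcs[pej[k]] + js[k] / v_st[pej[k]]
  }
  # respiration, first order on every node's pool
  k1_h <- params$k1 * SECONDS_PER_HOUR
  dcs <- dcs - k1_h * cs0

  cs <- cs0 + dcs * dt
  starch <- clip_pool(starch, starch0, "starch")
  cs <- clip_pool(cs, cs0, "sucrose")

  structure(list(starch = starch, c_s = cs), class = "carbon_state")
}

# clip small negative excursions to zero; gross overshoot (>1% of the prior
# pool) indicates an unstable step size and aborts
clip_pool <- function(new, old, what) {
  neg <- new < 0
  if (!any(neg)) return(new)
  scale <- pmax(abs(old), 1e-12)
  if (any(new[neg] < -0.01 * scale[neg])) {
    stop(what, " pool overshot zero by more than 1%: reduce dt", call. = FALSE)
  }
  if (any(new[neg] < -1e-12)) {
    warning(what, " pool clipped at zero", call. = FALSE)
  }
  new[neg] <- 0
  new
}
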