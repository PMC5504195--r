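#' Initial silicon state for a plant graph
#'
#' Tracks Si in the external solution, the root cortex, the xylem of every
#' hydraulic node, and the tissue (cytoplasm) cells, plus the transporter
#' expression factor alpha and a cumulative mass ledger (soil influx and total
#' unloading) used by the conservation audit.
#'
#' @param g a `plant_graph`.
#' @param config configuration list (silicon section supplies the external
#'   concentration and initial cortex concentration).
#' @param alpha initial expression factor in \[0, 1\].
#' @return An `si_state` list.
#' @export
new_si_state <- function(g, config = default_config(), alpha = 1) {
  n <- nrow(g$nodes)
  structure(list(
    c_m_out = config$silicon$c_m_out,
    c_m_cor = config$silicon$c_m_cor_init,
    c_m = numeric(n),
    c_m_cyt = numeric(n),
    alpha = alpha,
    nr = root_id(g),
    cum_soil = 0,
    cum_unload = 0
  ), class = "si_state")
}

#' Root Si uptake fluxes across the exodermis and endodermis
#'
#' Two-compartment root model: transporter-mediated flux (scaled by the
#' expression factor alpha) plus a passive membrane leak across each Casparian
#' band. The exodermal flux moves Si from the external solution to the cortex;
#' the endodermal flux moves it from the cortex into the stele (the root
#' hydraulic node).
#'
#' @param s an `si_state` (uses `alpha`, `c_m_out`, `c_m_cor` and the stele
#'   concentration `c_m[nr]`).
#' @param root root parameter list (`tr_exo`, `tr_end`, `p_cm`, ...).
#' @return List with `j_m_oc` (soil to cortex) and `j_m_cs` (cortex to stele),
#'   both in umol h^-1 (mM x ml h^-1).
#' @export
#' @examples
#' g <- build_standard_plant()
#' s <- new_si_state(g)
#' root_uptake_fluxes(s, g$root)
root_uptake_fluxes <- function(s, root) {
  stopifnot(s$alpha >= 0, s$alpha <= 1)
  j_m_oc <- s$alpha * root$tr_exo * s$c_m_out -
    root$p_cm * (s$c_m_cor - s$c_m_out)
  j_m_cs <- s$alpha * root$tr_end * s$c_m_cor -
    root$p_cm * (s$c_m[s$nr] - s$c_m_cor)
  list(j_m_oc = j_m_oc, j_m_cs = j_m_cs)
}

#' Advance the root Si compartments one Euler step
#'
#' @param s an `si_state`.
#' @param root root parameter list.
#' @param j_m_up Si efflux from the root stele to the node above (umol h^-1).
#' @param dt time step, h.
#' @param v_mix_root mixing volume of the root stele (ml); the model divides
#'   the stele flux by the sieve-tube tissue volume by default.
#' @return Updated `si_state` (cortex and stele concentrations, ledger).
#' @export
step_root <- function(s, root, j_m_up, dt, v_mix_root) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  fl <- root_uptake_fluxes(s, root)
  cor0 <- s$c_m_cor
  nr0 <- s$c_m[s$nr]
  s$c_m_cor <- clip_pool(cor0 + dt * (fl$j_m_oc - fl$j_m_cs) / root$v_cor,
                         cor0, "cortex Si")
  s$c_m[s$nr] <- clip_pool(nr0 + dt * (fl$j_m_cs - j_m_up) / v_mix_root,
                           nr0, "root stele Si")
  s$cum_soil <- s$cum_soil + fl$j_m_oc * dt
  s
}

#' Axial Si flux in the xylem
#'
#' Si travels with the transpiration stream only: the flux is the upstream
#' concentration times the xylem water flow when the flow is positive (rootward
#' node toward shootward node), and zero otherwise - reverse xylem flow carries
#' no Si in this model.
#'
#' @param c_m_i upstream Si concentration (mM).
#' @param j_w_x axial xylem water flow (ml h^-1, signed).
#' @return Si flux, umol h^-1 (vectorized).
#' @export
axial_si_flux <- function(c_m_i, j_w_x) {
  ifelse(j_w_x > 0, c_m_i * j_w_x, 0)
}

#' Si partitioning between DVB and EVB branches at a stem junction
#'
#' At a junction the incoming xylem Si stream splits between the diffuse
#' vascular bundle (DVB, serving younger tissue above) and the enlarged
#' vascular bundle (EVB, serving the leaf at the junction). The DVB stream is
#' enriched by factor rho >= 1; the EVB concentration follows from Si mass
#' balance over the two branch flows:
#' C_EVB = (J_DVB + J_EVB) * C / (rho * J_DVB + J_EVB), C_DVB = rho * C_EVB.
#'
#' Setting `alt_denominator = TRUE` swaps rho onto the EVB flow in the
#' denominator instead; that variant does not conserve Si mass unless the two
#' branch flows are equal and is provided only for comparison with the
#' mass-conserving default.
#'
#' @param c_m_i junction xylem Si concentration (mM).
#' @param j_w_dvb,j_w_evb branch water flows (ml h^-1, >= 0).
#' @param rho DVB enrichment factor, >= 1.
#' @param alt_denominator use the non-conservative denominator variant.
#' @return List with `c_dvb` and `c_evb` (mM).
#' @export
#' @examples
#' junction_partition(1, j_w_dvb = 1, j_w_evb = 3, rho = 2)
junction_partition <- function(c_m_i, j_w_dvb, j_w_evb, rho,
                               alt_denominator = FALSE) {
  stopifnot(j_w_dvb >= 0, j_w_evb >= 0, rho >= 1)
  total <- j_w_dvb + j_w_evb
  if (total == 0) {
    warning("both branch flows are zero; returning unpartitioned concentration",
            call. = FALSE)
    return(list(c_dvb = c_m_i, c_evb = c_m_i))
  }
  den <- if (alt_denominator) rho * j_w_evb + j_w_dvb
         else rho * j_w_dvb + j_w_evb
  c_evb <- total * c_m_i / den
  list(c_dvb = rho * c_evb, c_evb = c_evb)
}

#' Si unloading flux from the xylem into tissue cells
#'
#' First-order unloading proportional to the xylem Si concentration and the
#' conduit tissue volume. The caller advances the tissue-cell concentration by
#' dC_cyt/dt = J_unload / V_cyt.
#'
#' @param c_m_i xylem Si concentration (mM).
#' @param v_con_i conduit tissue volume (ml).
#' @param k_m_unload unloading rate constant (h^-1).
#' @return Unloading flux, umol h^-1.
#' @export
unload_flux <- function(c_m_i, v_con_i, k_m_unload) {
  stopifnot(all(c_m_i >= 0), all(v_con_i >= 0), k_m_unload >= 0)
  k_m_unload * c_m_i * v_con_i
}

# mixing volume of each node's xylem pool: conduit volume, except the root
# stele which uses the sieve-tube volume by default (config switch)
si_mixing_volumes <- function(g, config) {
  v <- g$nodes$v_con
  if (isTRUE(config$silicon$use_vst_for_root_stele)) {
    v[root_id(g)] <- g$nodes$v_st[root_id(g)]
  }
  v
}

#' Advance whole-plant silicon state one Euler step
#'
#' Composes root uptake, upwind advection along positive xylem flows with
#' DVB/EVB partitioning at junction out-edges, and first-order unloading into
#' tissue cells. The update is flux-based: every edge flux is removed from the
#' donor and added to the receiver, so Si mass is conserved exactly up to the
#' soil boundary influx and the (tracked) unloading sink.
#'
#' @param g a `plant_graph`.
#' @param s an `si_state`.
#' @param water a `water_state` for this step.
#' @param params list with `k_m_unload`.
#' @param config configuration list (volume switches).
#' @param dt time step, h.
#' @return Updated `si_state`.
#' @export
step_silicon <- function(g, s, water, params, config = default_config(), dt) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  n <- nrow(g$nodes)
  nr <- s$nr
  xe <- g$edges[g$edges$pathway == "xylem", , drop = FALSE]
  v_mix <- si_mixing_volumes(g, config)
  alt_den <- isTRUE(config$silicon$use_alt_partition_denominator)

  # donor concentration per edge: junction out-edges use the partitioned
  # branch concentration, everything else the plain upstream concentration
  c_donor <- s$c_m[xe$i]
  jn_ids <- g$nodes$id[g$nodes$tissue == "junction"]
  for (jid in jn_ids) {
    out <- which(xe$i == jid)
    if (!length(out)) next
    flows <- pmax(water$j_x[out], 0)
    cls <- xe$branch_class[out]
    j_dvb <- sum(flows[cls == "DVB"])
    j_evb <- sum(flows[cls == "EVB"])
    if (j_dvb + j_evb == 0) next
    part <- junction_partition(s$c_m[jid], j_dvb, j_evb,
                               rho = g$junctions$rho[g$junctions$id == jid],
                               alt_denominator = alt_den)
    c_donor[out][cls == "DVB"] <- part$c_dvb
    c_donor[out][cls == "EVB"] <- part$c_evb
  }
  q <- axial_si_flux(c_donor, water$j_x)  # zero on reverse-flow edges

  u <- unload_flux(s$c_m, g$nodes$v_con, params$k_m_unload)

  fl <- root_uptake_fluxes(s, g$root)
  dm <- numeric(n)              # umol h^-1 net into each xylem pool
  xei <- xe$i; xej <- xe$j
  for (k in seq_along(q)) {
    dm[xei[k]] <- dm[xei[k]] - q[k]
    dm[xej[k]] <- dm[xej[k]] + q[k]
  }
  dm <- dm - u
  dm[nr] <- dm[nr] + fl$j_m_cs

  c_m0 <- s$c_m
  s$c_m <- clip_pool(c_m0 + dm * dt / v_mix, c_m0, "xylem Si")
  s$c_m_cyt <- s$c_m_cyt + u * dt / g$nodes$v_cyt
  s$c_m_cor <- clip_pool(
    s$c_m_cor + dt * (fl$j_m_oc - fl$j_m_cs) / g$root$v_cor,
    s$c_m_cor, "cortex Si")
  s$cum_soil <- s$cum_soil + fl$j_m_oc * dt
  s$cum_unload <- s$cum_unload + sum(u) * dt
  s
}

#' Total Si mass held in the plant (umol)
#'
#' Cortex + xylem pools (at their mixing volumes) + tissue-cell pools. The
#' whole-run ledger `cum_soil` minus the change in this total audits mass
#' conservation of the transport scheme.
#'
#' @param g a `plant_graph`.
#' @param s an `si_state`.
#' @param config configuration list.
#' @return Total Si, umol.
#' @export
si_total_mass <- function(g, s, config = default_config()) {
  v_mix <- si_mixing_volumes(g, config)
  s$c_m_cor * g$root$v_cor + sum(s$c_m * v_mix) +
    sum(s$c_m_cyt * g$nodes$v_cyt)
}
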