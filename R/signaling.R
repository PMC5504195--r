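#' Signaling control configuration
#'
#' Defines which hypothesis governs the shoot-to-root signal: `accumulation`
#' (signal generated in proportion to leaf-cell Si, expression repressed by the
#' signal), `shortage` (signal generated in proportion to leaf-cell Si deficit,
#' expression activated by the signal), `water_stress` (signal generated in
#' proportion to leaf transpiration, expression repressed, with a response
#' delay), or `constant` (expression pinned at 1).
#'
#' @param mode one of `"accumulation"`, `"shortage"`, `"water_stress"`,
#'   `"constant"`.
#' @param slp signal generation-rate parameter (>= 0).
#' @param dec signal decay rate (h^-1, >= 0).
#' @param chi response delay (h); defaults to 5 for water-stress control and 0
#'   otherwise.
#' @param c_r_init initial signal concentration; defaults to 1 for shortage
#'   control (expression starts fully on) and 0 otherwise.
#' @return A `control_config` list.
#' @export
control_config <- function(mode = c("constant", "accumulation", "shortage",
                                    "water_stress"),
                           slp = 0, dec = 0, chi = NULL, c_r_init = NULL) {
  mode <- match.arg(mode)
  stopifnot(slp >= 0, dec >= 0)
  if (is.null(chi)) chi <- if (mode == "water_stress") 5 else 0
  stopifnot(chi >= 0)
  if (is.null(c_r_init)) c_r_init <- if (mode == "shortage") 1 else 0
  structure(list(mode = mode, slp = slp, dec = dec, chi = chi,
                 c_r_init = c_r_init),
            class = "control_config")
}

#' Signal generation rate in a leaf
#'
#' Accumulation control: GR = slp * C_cyt (leaf-cell Si). Shortage control:
#' GR = slp * (1 - C_rel), where `c_m_cyt` is the leaf-cell Si expressed
#' relative to a reference concentration, floored at 0. Water-stress control:
#' GR = slp * Trans (leaf transpiration). Constant: 0. Signal is generated in
#' leaf nodes only.
#'
#' @param mode control mode string.
#' @param slp generation-rate parameter.
#' @param c_m_cyt leaf-cell Si concentration (mM; for shortage control, the
#'   concentration relative to the reference, dimensionless).
#' @param trans leaf transpiration rate (ml h^-1).
#' @return Generation rate (signal units h^-1), vectorized over leaves.
#' @export
#' @examples
#' generation_rate("accumulation", 0.01, c_m_cyt = 50)  # 0.5
generation_rate <- function(mode, slp, c_m_cyt = 0, trans = 0) {
  if (any(c_m_cyt < 0) || any(trans < 0) || slp < 0) {
    stop("generation_rate inputs must be >= 0", call. = FALSE)
  }
  switch(mode,
    accumulation = slp * c_m_cyt,
    shortage     = pmax(0, slp * (1 - c_m_cyt)),
    water_stress = slp * trans,
    constant     = 0 * c_m_cyt,
    stop("unknown control mode: ", mode)
  )
}

#' Initial signal state
#'
#' @param g a `plant_graph`.
#' @param ctrl a `control_config`.
#' @return A `signal_state` with per-node concentration `c_r` and a recorded
#'   history of the root signal for delayed expression lookup.
#' @export
new_signal_state <- function(g, ctrl) {
  n <- nrow(g$nodes)
  structure(list(
    c_r = rep(ctrl$c_r_init, n),
    history = list(t = 0, c_r_root = ctrl$c_r_init)
  ), class = "signal_state")
}

#' Advance the signaling substance one Euler step
#'
#' Per node: dC_R/dt = -dec * C_R + GR (GR nonzero in leaves only), plus
#' upwind advection with the phloem water flow using sieve-tube mixing volumes
#' (same kernel as sucrose). Appends the root signal concentration to the
#' delay-lookup history.
#'
#' @param g a `plant_graph`.
#' @param sig a `signal_state`.
#' @param water a `water_state`.
#' @param ctrl a `control_config`.
#' @param gr_leaf per-leaf generation rates (recycled).
#' @param dt time step, h.
#' @param t_new time stamp after the step (h), recorded in the history.
#' @return Updated `signal_state`.
#' @export
step_signal <- function(g, sig, water, ctrl, gr_leaf, dt, t_new = NULL) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  n <- nrow(g$nodes)
  lv <- leaf_ids(g)
  v_st <- g$nodes$v_st
  c0 <- sig$c_r

  dc <- -ctrl$dec * c0
  dc[lv] <- dc[lv] + rep(gr_leaf, length.out = length(lv))
  pe <- g$edges[g$edges$pathway == "phloem", , drop = FALSE]
  pei <- pe$i; pej <- pe$j
  jr <- sucrose_axial_flow(water$j_p, c0[pei], c0[pej])
  for (k in seq_along(jr)) {
    dc[pei[k]] <- dc[pei[k]] - jr[k] / v_st[pei[k]]
    dc[pej[k]] <- dc[pej[k]] + jr[k] / v_st[pej[k]]
  }
  sig$c_r <- clip_pool(c0 + dc * dt, c0, "signal")
  if (is.null(t_new)) t_new <- sig$history$t[length(sig$history$t)] + dt
  sig$history$t <- c(sig$history$t, t_new)
  sig$history$c_r_root <- c(sig$history$c_r_root, sig$c_r[root_id(g)])
  sig
}

#' Transporter expression factor from the (possibly delayed) root signal
#'
#' Accumulation and water-stress control repress expression:
#' alpha = max(0, 1 - C_R(root, t - chi)). Shortage control activates it:
#' alpha = min(1, C_R(root, t - chi)). Constant control returns 1. The root
#' signal at t - chi is linearly interpolated from the recorded history;
#' times before the start of the record use the initial value.
#'
#' @param ctrl a `control_config`.
#' @param history list with numeric `t` and `c_r_root` (as kept by
#'   [step_signal()]).
#' @param t current time (h).
#' @return alpha in \[0, 1\].
#' @export
expression_factor <- function(ctrl, history, t) {
  if (ctrl$mode == "constant") return(1)
  tl <- t - ctrl$chi
  ht <- history$t
  hc <- history$c_r_root
  c_r <- if (tl <= ht[1]) {
    hc[1]
  } else if (tl >= ht[length(ht)]) {
    hc[length(hc)]
  } else {
    approx(ht, hc, xout = tl)$y
  }
  # both laws clamp into [0, 1] (the signal itself is non-negative in a
  # simulation; the outer clamp guards degenerate histories)
  if (ctrl$mode == "shortage") min(1, max(0, c_r)) else min(1, max(0, 1 - c_r))
}
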