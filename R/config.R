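#' Default model configuration
#'
#' Returns the full set of structural, hydraulic, carbon, silicon and signaling
#' parameters for the standard simplified rice plant: one root segment, five
#' leaves each borne on a sheath at a stem junction, identical internodes.
#'
#' Units are fixed internally: MPa (water potential, pressure), ml (volume),
#' h (time), mM (Si concentration), mol m^-3 (sucrose). Parameter values that
#' the original model description relegates to supplementary material are not
#' publicly tabulated; every such value below is a documented default chosen to
#' keep the model in its qualitative regime and is marked "default, not pinned
#' by the source description" in the comments.
#'
#' @return A nested named list with sections \code{structure},
#'   \code{resistances}, \code{volumes}, \code{root}, \code{junctions},
#'   \code{carbon}, \code{silicon}, \code{signaling}, \code{forcing},
#'   \code{numerics}.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$structure$n_leaves
default_config <- function() {
  list(
    structure = list(
      n_leaves      = 5,     # five leaves
      leaf_area_cm2 = 20     # default, not pinned; scales transpiration to ml/h
    ),
    resistances = list(      # MPa h ml^-1; defaults, not pinned
      r_x_internode      = 0.05,
      r_x_junction_sheath = 0.05,
      r_x_sheath_leaf    = 0.05,
      r_p_internode      = 0.1,
      r_p_junction_sheath = 0.1,
      r_p_sheath_leaf    = 0.1,
      r_lat              = 8.0,  # xylem<->phloem lateral, stem tissue
      r_lat_leaf         = 0.5,  # lateral at the leaf (phloem loading zone)
      r_lat_root         = 0.5   # lateral at the root (phloem unloading zone)
    ),
    volumes = list(          # ml; defaults, not pinned
      v_st       = 2.0,      # sieve-tube tissue volume per node
      v_con      = 0.5,      # conduit tissue volume per node
      v_cyt      = 1.0,      # cytoplasm volume, non-leaf tissue
      v_cyt_leaf = 0.1       # cytoplasm volume, leaf blades
    ),
    root = list(
      tr_exo     = 0.5,      # ml h^-1 at full expression; calibration target
      tr_end     = 1.0,      # ml h^-1 at full expression; calibration target
      p_cm       = 0.05,     # ml h^-1 membrane permeability; calibration target
      v_cor      = 1.0,      # cortex tissue volume, 1 ml for simplicity
      r_lat_root = 0.2,      # soil-to-root-xylem radial resistance (boundary)
      psi_soil   = 0.0       # soil water potential boundary (MPa)
    ),
    junctions = list(
      rho = 2.0              # DVB enrichment factor, >= 1; default, not pinned
    ),
    carbon = list(
      k1        = 8.0e-5,    # respiration rate constant (s^-1 grid value)
      k4        = 0.1,       # starch->sucrose conversion (h^-1 grid value)
      load_frac = 1.0        # fraction of converted starch loaded into phloem
    ),
    silicon = list(
      k_m_unload = 0.6,      # h^-1 unloading rate constant
      c_m_out    = 1.0,      # mM external (soil) Si, constant over the run
      c_m_cor_init = 0.0,    # mM initial root-cortex Si
      use_vst_for_root_stele = TRUE,  # stele mixing volume is V_st (not V_con)
      use_alt_partition_denominator = FALSE  # comparison variant; see
                                             # junction_partition()
    ),
    signaling = list(
      mode     = "constant", # accumulation | shortage | water_stress | constant
      slp      = 0.0,        # generation-rate parameter for the active mode
      dec      = 0.0,        # signal decay rate (h^-1)
      chi      = 0.0,        # response delay (h); 5 for water_stress
      c_r_init = 0.0,        # initial signal concentration (1.0 for shortage)
      trans_signal_scale = 18,  # transpiration-to-signal scale in the
                                # generation law; signal units are arbitrary
      shortage_ref = NULL    # reference leaf-cell Si (mM); NULL = auto
    ),
    forcing = list(
      trans_standard   = 0.4,     # ml cm^-2 day^-1 standard transpiration
      trans_night_frac = 0.1,     # night transpiration fraction of standard
      photo_standard   = 0.0015,  # model-unit photosynthesis peak per leaf
      day_hours        = 14,      # 14 h light / 10 h dark
      peak_hours       = 2,       # flat midday peak width
      temperature_K    = 298.15
    ),
    numerics = list(
      dt            = 0.05,  # h, explicit Euler step
      record_stride = 1
    )
  )
}

#' Read a model configuration from a YAML file
#'
#' Values absent from the file fall back to [default_config()]. The file
#' round-trips losslessly through [write_config()].
#'
#' @param path path to a YAML configuration file.
#' @return configuration list (same shape as [default_config()]).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' Write a model configuration to a YAML file
#'
#' @param config configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

# recursive override of defaults by user values; unknown keys are kept
merge_config <- function(base, user) {
  if (is.null(user)) return(base)
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[k] <- list(user[[k]])  # keeps explicit NULL entries
    }
  }
  base
}
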