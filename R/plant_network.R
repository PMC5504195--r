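#' @importFrom stats approx quantile rnorm runif setNames
#' @importFrom utils read.csv write.csv
NULL

#' Build the standard simplified rice plant graph
#'
#' Constructs the hydraulic-node network of the standard plant: one root
#' segment, five stem junctions chained by identical internodes, and one leaf
#' per junction attached through a sheath node. Xylem and phloem each form a
#' tree over the same topology and are coupled laterally at every node. The
#' youngest (top) leaf is fed by the DVB (diffuse vascular bundle) branch of
#' the highest junction; at every lower junction the DVB branch is the one
#' continuing up the stem toward younger tissue and the leaf branch is the EVB
#' (enlarged vascular bundle).
#'
#' @param config configuration list, see [default_config()].
#' @return An object of class `plant_graph`: a list with `nodes`, `edges`,
#'   `junctions`, `root` and `r_lat` components.
#' @export
#' @examples
#' g <- build_standard_plant()
#' nrow(g$nodes)
#' validate_graph(g)
build_standard_plant <- function(config = default_config()) {
  st  <- config$structure
  rs  <- config$resistances
  vol <- config$volumes
  nl  <- st$n_leaves
  stopifnot(nl >= 1)

  check_pos <- function(x, what) {
    bad <- names(x)[!vapply(x, function(v) is.numeric(v) && v > 0, logical(1))]
    if (length(bad)) {
      stop("non-positive ", what, ": ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check_pos(rs, "resistance")
  check_pos(vol, "volume")
  if (config$junctions$rho < 1) stop("rho must be >= 1", call. = FALSE)
  with(config$root, {
    if (tr_exo < 0 || tr_end < 0 || p_cm < 0) {
      stop("root transport parameters must be >= 0", call. = FALSE)
    }
    if (v_cor <= 0) stop("v_cor must be > 0", call. = FALSE)
  })

  temperature <- config$forcing$temperature_K
  # node ids: 1 root, 2..(nl+1) junctions (bottom to top),
  # then sheaths, then leaves (same bottom-to-top order)
  id_root     <- 1L
  id_junction <- 1L + seq_len(nl)
  id_sheath   <- 1L + nl + seq_len(nl)
  id_leaf     <- 1L + 2L * nl + seq_len(nl)
  n_nodes     <- 1L + 3L * nl

  tissue <- c("root", rep("junction", nl), rep("sheath", nl), rep("leaf", nl))
  v_cyt  <- ifelse(tissue == "leaf", vol$v_cyt_leaf, vol$v_cyt)
  nodes  <- data.frame(
    id = seq_len(n_nodes),
    tissue = tissue,
    v_st  = vol$v_st,
    v_con = vol$v_con,
    v_cyt = v_cyt,
    temperature = temperature,
    is_root = seq_len(n_nodes) == id_root,
    is_top_leaf = seq_len(n_nodes) == id_leaf[nl],
    stringsAsFactors = FALSE
  )

  # one topology shared by both pathways: root-J1, Jk-J(k+1), Jk-Sk, Sk-Lk
  from <- c(id_root, id_junction[-nl], id_junction, id_sheath)
  to   <- c(id_junction[1], id_junction[-1], id_sheath, id_leaf)
  seg  <- c("internode", rep("internode", nl - 1),
            rep("junction_sheath", nl), rep("sheath_leaf", nl))

  # DVB/EVB classes apply to xylem edges leaving a junction: the branch toward
  # younger tissue (next internode; top sheath for the highest junction) is DVB
  branch <- rep("none", length(from))
  for (k in seq_len(nl)) {
    e_leafward <- which(from == id_junction[k] & to == id_sheath[k])
    branch[e_leafward] <- if (k == nl) "DVB" else "EVB"
    if (k < nl) {
      e_up <- which(from == id_junction[k] & to == id_junction[k + 1])
      branch[e_up] <- "DVB"
    }
  }

  r_of <- function(prefix) {
    unname(c(internode = rs[[paste0(prefix, "_internode")]],
             junction_sheath = rs[[paste0(prefix, "_junction_sheath")]],
             sheath_leaf = rs[[paste0(prefix, "_sheath_leaf")]])[seg])
  }
  edges <- rbind(
    data.frame(i = from, j = to, pathway = "xylem", r = r_of("r_x"),
               branch_class = branch, stringsAsFactors = FALSE),
    data.frame(i = from, j = to, pathway = "phloem", r = r_of("r_p"),
               branch_class = "none", stringsAsFactors = FALSE)
  )
  rownames(edges) <- NULL

  g <- structure(
    list(
      nodes = nodes,
      edges = edges,
      junctions = data.frame(id = id_junction, rho = config$junctions$rho),
      root = config$root,
      r_lat = ifelse(tissue == "leaf", rs$r_lat_leaf,
                     ifelse(tissue == "root", rs$r_lat_root, rs$r_lat))
    ),
    class = "plant_graph"
  )
  v <- validate_graph(g)
  if (length(v)) stop("constructed graph is invalid: ", paste(v, collapse = "; "))
  g
}

#' Validate a plant graph
#'
#' Checks all structural invariants: positive volumes and resistances, exactly
#' one root node and one top leaf, DVB/EVB classes only on xylem edges leaving
#' junctions, rho >= 1, and connectivity of the xylem and phloem subgraphs
#' (every leaf must reach the root through both pathways). Validation never
#' aborts; it reports.
#'
#' @param g a `plant_graph`.
#' @return Character vector of violations; empty if the graph is valid.
#' @export
validate_graph <- function(g) {
  v <- character(0)
  nd <- g$nodes
  ed <- g$edges

  bad_vol <- nd$id[nd$v_st <= 0 | nd$v_con <= 0 | nd$v_cyt <= 0]
  if (length(bad_vol)) {
    v <- c(v, paste0("non-positive volume at node(s) ",
                     paste(bad_vol, collapse = ",")))
  }
  if (sum(nd$is_root) != 1) {
    v <- c(v, paste0("expected exactly one root node, found ", sum(nd$is_root)))
  }
  if (sum(nd$is_top_leaf) != 1) {
    v <- c(v, paste0("expected exactly one top leaf flag, found ",
                     sum(nd$is_top_leaf)))
  }
  if (any(nd$is_top_leaf & nd$tissue != "leaf")) {
    v <- c(v, "is_top_leaf set on a non-leaf node")
  }
  bad_r <- which(!(ed$r > 0))
  if (length(bad_r)) {
    v <- c(v, paste0("non-positive resistance on edge ", ed$i[bad_r], "-",
                     ed$j[bad_r], " (", ed$pathway[bad_r], ")"))
  }
  if (any(g$r_lat <= 0)) v <- c(v, "non-positive lateral resistance")
  if (any(g$junctions$rho < 1)) {
    v <- c(v, paste0("rho < 1 at junction ",
                     paste(g$junctions$id[g$junctions$rho < 1], collapse = ",")))
  }
  jn <- nd$id[nd$tissue == "junction"]
  bad_bc <- which(ed$branch_class != "none" &
                    (ed$pathway != "xylem" | !(ed$i %in% jn)))
  if (length(bad_bc)) {
    v <- c(v, paste0("branch class on non-junction or non-xylem edge ",
                     ed$i[bad_bc], "-", ed$j[bad_bc]))
  }

  # pathway connectivity: every node in one component with the root
  root_id <- nd$id[nd$is_root][1]
  for (pw in c("xylem", "phloem")) {
    sub <- ed[ed$pathway == pw, , drop = FALSE]
    ig <- igraph::graph_from_data_frame(
      sub[, c("i", "j")], directed = FALSE,
      vertices = data.frame(name = nd$id)
    )
    comp <- igraph::components(ig)$membership
    if (!is.na(root_id) && length(comp)) {
      cut_off <- nd$id[comp != comp[as.character(root_id)]]
      if (length(cut_off)) {
        v <- c(v, paste0(pw, " subgraph disconnected from root at node(s) ",
                         paste(cut_off, collapse = ",")))
      }
    }
  }
  v
}

#' @export
print.plant_graph <- function(x, ...) {
  cat("plant_graph:", nrow(x$nodes), "hydraulic nodes,",
      nrow(x$edges), "edges\n")
  cat("  tissues:", paste(sprintf("%s=%d", names(table(x$nodes$tissue)),
                                  table(x$nodes$tissue)), collapse = ", "), "\n")
  cat("  root node:", x$nodes$id[x$nodes$is_root],
      " top leaf:", x$nodes$id[x$nodes$is_top_leaf], "\n")
  invisible(x)
}

#' Export the edge list of a plant graph as CSV
#'
#' Writes columns `i, j, pathway, r, branch_class` for inspection or plotting.
#'
#' @param g a `plant_graph`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_edge_list <- function(g, path) {
  write.csv(g$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- internal index helpers ----------------------------------------------

node_ids <- function(g, tissue) g$nodes$id[g$nodes$tissue == tissue]
leaf_ids <- function(g) node_ids(g, "leaf")
root_id <- function(g) g$nodes$id[g$nodes$is_root]
top_leaf_id <- function(g) g$nodes$id[g$nodes$is_top_leaf]
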