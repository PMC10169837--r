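## 1-D hemodynamics on a vascular tree. Internal canonical units are
## micrometre / second / Newton throughout: radii and lengths in um, flows
## in um^3/s, viscosity in N s/um^2, pressure in N/um^2 (converted to mmHg
## only at the reporting boundary). A single conversion constant is used
## everywhere to avoid unit drift.

#' Unit conversions for the canonical um/s/N system
#'
#' The physical constants of the model are quoted in mixed clinical and SI
#' units (ml/min, mmHg, Pa s, J s^-1 m^-3); internally everything is
#' carried in micrometre/second/Newton units so that the material and
#' power cost terms are on the same scale. These helpers are the only
#' place conversions happen.
#'
#' @param q flow in ml/min.
#' @return `flow_ml_min_to_um3_s`: flow in um^3/s.
#' @examples
#' flow_ml_min_to_um3_s(7)          # 1.1667e11 um^3/s
#' viscosity_Pa_s_to_N_s_um2(3.6e-3) # 3.6e-15 N s/um^2
#' @export
flow_ml_min_to_um3_s <- function(q) q * 1e12 / 60

#' @rdname flow_ml_min_to_um3_s
#' @param p pressure in mmHg.
#' @export
pressure_mmHg_to_N_um2 <- function(p) p * 1.33322e-10

#' @rdname flow_ml_min_to_um3_s
#' @param pn pressure in N/um^2.
#' @export
pressure_N_um2_to_mmHg <- function(pn) pn / 1.33322e-10

#' @rdname flow_ml_min_to_um3_s
#' @param mu dynamic viscosity in Pa s.
#' @export
viscosity_Pa_s_to_N_s_um2 <- function(mu) mu * 1e-12

#' @rdname flow_ml_min_to_um3_s
#' @param w material-cost weight in J s^-1 m^-3.
#' @export
material_weight_J_s_m3_to_N_um2_s <- function(w) w * 1e-12

#' Assign vessel flows by Kirchhoff's zero-addition rule
#'
#' The inlet flow `Q0` is split equally over all terminal vessels
#' (equal-perfusion assumption for the afferent arterioles); every internal
#' vessel then carries the sum of its children's flows, so the flow at any
#' vessel equals (number of terminals below it) x Q0/N.
#'
#' @param tree a `vascular_tree` with at least one vessel.
#' @param Q0 inlet flow, um^3/s.
#' @return the tree with `vessels$flow` filled in.
#' @export
assign_flows <- function(tree, Q0) {
  nv <- nrow(tree$vessels)
  if (nv == 0) stop("tree has no vessels")
  term <- terminal_vessel_rows(tree)
  N <- length(term)
  if (N == 0) stop("tree has no terminal vessels")
  Qt <- Q0 / N
  ## count terminals below each vessel, bottom-up
  cnt <- integer(nv)
  cnt[term] <- 1L
  ord <- vessel_rows_deep_first(tree)
  crows <- child_vessel_rows(tree)
  child_node_row <- node_row(tree, tree$vessels$child)
  for (e in ord) {
    kids <- crows[[child_node_row[e]]]
    if (length(kids) > 0) cnt[e] <- sum(cnt[kids])
  }
  tree$vessels$flow <- cnt * Qt
  tree
}

#' Assign vessel radii by Murray's law
#'
#' Terminal vessels take the stored per-leaf radii (`nodes$leaf_radius` of
#' their child node, or the `leaf_radii` argument); every parent radius is
#' then the cube root of the sum of cubed child radii, computed bottom-up.
#' Degree-1 chains pass the radius through unchanged (the single-term case
#' of the cube law). Radii are never optimization variables: the cube law
#' is a hard constraint.
#'
#' @param tree a `vascular_tree`.
#' @param leaf_radii optional named numeric vector (names = terminal child
#'   node ids) of terminal radii in um; defaults to `nodes$leaf_radius`.
#' @return the tree with `vessels$radius` filled in.
#' @export
assign_radii_murray <- function(tree, leaf_radii = NULL) {
  nv <- nrow(tree$vessels)
  if (nv == 0) stop("tree has no vessels")
  term <- terminal_vessel_rows(tree)
  term_child <- tree$vessels$child[term]
  if (is.null(leaf_radii)) {
    r0 <- tree$nodes$leaf_radius[node_row(tree, term_child)]
  } else {
    r0 <- unname(leaf_radii[as.character(term_child)])
  }
  if (anyNA(r0)) stop("missing leaf radius for some terminal vessels")
  r3 <- numeric(nv)
  r3[term] <- r0^3
  ord <- vessel_rows_deep_first(tree)
  crows <- child_vessel_rows(tree)
  child_node_row <- node_row(tree, tree$vessels$child)
  for (e in ord) {
    kids <- crows[[child_node_row[e]]]
    if (length(kids) > 0) r3[e] <- sum(r3[kids])
  }
  tree$vessels$radius <- r3^(1 / 3)
  tree
}

#' Node pressures by Hagen-Poiseuille's law
#'
#' Starting from the inlet pressure at the root node, the pressure at each
#' vessel's outlet is the inlet pressure minus the Poiseuille drop
#' 8 mu l Q / (pi r^4), swept root-to-leaf. Branching losses are neglected
#' (laminar, Newtonian flow in straight cylinders). Internally the drop is
#' computed in N/um^2 and converted once to mmHg.
#'
#' @param tree a `vascular_tree` with radii and flows assigned.
#' @param p0_mmHg inlet pressure, mmHg (default 100).
#' @param mu viscosity in N s/um^2 (default 3.6e-15).
#' @return data.frame with columns `id` (node) and `pressure_mmHg`.
#' @export
pressure_profile <- function(tree, p0_mmHg = 100, mu = 3.6e-15) {
  if (anyNA(tree$vessels$radius) || anyNA(tree$vessels$flow)) {
    stop("radii and flows must be assigned first")
  }
  if (any(tree$vessels$radius <= 0)) stop("zero radius vessel")
  len <- vessel_lengths(tree)
  drop <- 8 * mu * len * tree$vessels$flow / (pi * tree$vessels$radius^4)
  p <- setNames(rep(NA_real_, nrow(tree$nodes)), tree$nodes$id)
  p[as.character(tree$root)] <- pressure_mmHg_to_N_um2(p0_mmHg)
  ## sweep by depth level so each child's parent pressure is ready
  v <- tree$vessels
  frontier <- tree$root
  while (length(frontier) > 0) {
    sel <- which(v$parent %in% frontier)
    if (length(sel) == 0) break
    p[as.character(v$child[sel])] <- p[as.character(v$parent[sel])] - drop[sel]
    frontier <- v$child[sel]
  }
  data.frame(id = tree$nodes$id,
             pressure_mmHg = pressure_N_um2_to_mmHg(unname(p)))
}

#' Assign flows and Murray radii in one pass
#'
#' Convenience wrapper used after every topology-changing optimizer pass:
#' Kirchhoff flows from the configured inlet flow, then Murray radii from
#' the stored terminal radii.
#'
#' @param tree a `vascular_tree`.
#' @param config a [gco_config()].
#' @return the tree with flows and radii assigned.
#' @export
assign_hemodynamics <- function(tree, config) {
  tree <- assign_flows(tree, config$Q0)
  assign_radii_murray(tree)
}
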