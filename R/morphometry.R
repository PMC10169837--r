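## Strahler ordering and per-order summary tables used to characterize a
## reconstructed arterial tree: radius/length/count/cross-sectional area,
## flow and outlet pressure per order, plus the parent-order histogram of
## the afferent arterioles.

#' Strahler orders of vessels
#'
#' Orders are assigned to vessels (edges), not nodes. Terminal vessels
#' (the afferent arterioles) get order 0. Going upstream, a parent vessel
#' takes order j+1 when two or more of its daughter vessels share the
#' maximum daughter order j, and order j otherwise. The root vessel carries
#' the global maximum order.
#'
#' @param tree a `vascular_tree`.
#' @return integer vector of orders, one per row of `tree$vessels`.
#' @export
strahler_orders <- function(tree) {
  nv <- nrow(tree$vessels)
  ord_out <- integer(nv)
  rows <- vessel_rows_deep_first(tree)
  crows <- child_vessel_rows(tree)
  child_node_row <- node_row(tree, tree$vessels$child)
  for (e in rows) {
    kids <- crows[[child_node_row[e]]]
    if (length(kids) == 0) {
      ord_out[e] <- 0L
    } else {
      j <- max(ord_out[kids])
      ord_out[e] <- if (sum(ord_out[kids] == j) >= 2) j + 1L else j
    }
  }
  ord_out
}

#' Per-Strahler-order summary table
#'
#' Aggregates vessel radius, length, count, total cross-sectional area
#' (sum of pi r^2 over the order's vessels, reported in mm^2), mean flow
#' and mean outlet pressure by Strahler order. When a reference table of
#' per-order means is supplied, the Pearson correlation of the shared
#' orders' mean values is attached as attribute `"pearson_r"`.
#'
#' @param tree a `vascular_tree` with radii and flows assigned.
#' @param pressures optional data.frame from [pressure_profile()].
#' @param reference optional data.frame with columns `order` and
#'   `mean_radius_um` (literature per-order means).
#' @return data.frame of class `order_stats` keyed by `order`.
#' @export
per_order_stats <- function(tree, pressures = NULL, reference = NULL) {
  if (nrow(tree$vessels) == 0) stop("empty tree")
  ord <- strahler_orders(tree)
  len <- vessel_lengths(tree)
  r <- tree$vessels$radius
  q <- tree$vessels$flow
  f <- factor(ord, levels = 0:max(ord))
  agg <- function(x, fun) as.numeric(tapply(x, f, fun))
  out <- data.frame(
    order = 0:max(ord),
    count = as.integer(table(f)),
    mean_radius_um = agg(r, mean),
    sd_radius_um = agg(r, function(x) if (length(x) > 1) sd(x) else 0),
    mean_length_um = agg(len, mean),
    sd_length_um = agg(len, function(x) if (length(x) > 1) sd(x) else 0),
    total_cross_section_mm2 = agg(r, function(x) sum(pi * x^2)) * 1e-6,
    mean_flow_um3_s = agg(q, mean)
  )
  if (!is.null(pressures)) {
    pout <- pressures$pressure_mmHg[match(tree$vessels$child, pressures$id)]
    out$mean_outlet_pressure_mmHg <- agg(pout, mean)
  }
  if (!is.null(reference)) {
    shared <- intersect(out$order, reference$order)
    if (length(shared) >= 3) {
      attr(out, "pearson_r") <- cor(
        out$mean_radius_um[match(shared, out$order)],
        reference$mean_radius_um[match(shared, reference$order)]
      )
    }
  }
  class(out) <- c("order_stats", "data.frame")
  out
}

#' Parent Strahler orders of the afferent arterioles
#'
#' For every terminal vessel, records the Strahler order of its parent
#' vessel and returns the counts per order. A terminal vessel hanging
#' directly off the root node has no parent vessel; it is counted under the
#' root vessel's order and flagged via attribute `"root_attached"`.
#'
#' @param tree a `vascular_tree`.
#' @return data.frame with columns `parent_order` and `count`; counts sum
#'   to the number of terminal vessels.
#' @export
afferent_parent_orders <- function(tree) {
  ord <- strahler_orders(tree)
  term <- terminal_vessel_rows(tree)
  prow <- parent_vessel_row(tree)   # per node row
  parent_node_rows <- node_row(tree, tree$vessels$parent[term])
  pedge <- prow[parent_node_rows]
  root_attached <- sum(is.na(pedge))
  pord <- ifelse(is.na(pedge), max(ord), ord[pedge])
  tab <- table(factor(pord, levels = 0:max(ord)))
  out <- data.frame(parent_order = as.integer(names(tab)),
                    count = as.integer(tab))
  attr(out, "root_attached") <- root_attached
  rownames(out) <- NULL
  out
}

#' Whole-tree size summary
#'
#' @param tree a `vascular_tree`.
#' @return list with `n_vessels` (segment count), `n_levels` (maximum
#'   number of vessels on any root-to-leaf path) and `n_strahler_orders`
#'   (number of distinct orders, i.e. max order + 1).
#' @export
tree_summary <- function(tree) {
  depth <- node_depths(tree)
  list(
    n_vessels = nrow(tree$vessels),
    n_levels = max(depth),
    n_strahler_orders = max(strahler_orders(tree)) + 1L
  )
}

#' Literature reference radii per Strahler order
#'
#' Small packaged table of published per-order mean radii for the rat renal
#' arterial tree (orders 0-2 and the root order), shipped purely for
#' correlation reporting against reconstructed trees. These are literature
#' values, not outputs of this package.
#'
#' @return data.frame with columns `order`, `mean_radius_um`, `sd_radius_um`.
#' @export
reference_radii_rat <- function() {
  path <- system.file("extdata", "rat_renal_reference_radii.csv",
                      package = "renalvasc")
  read.csv(path, comment.char = "#")
}

#' Plot per-order morphometry
#'
#' Base-graphics panels of mean radius (log scale), mean length, vessel
#' count (log scale) and total cross-sectional area against Strahler order.
#'
#' @param x an `order_stats` table.
#' @param ... passed to [plot()].
#' @export
plot.order_stats <- function(x, ...) {
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$order, x$mean_radius_um, log = "y", xlab = "Strahler order",
       ylab = "mean radius (um)", main = "Radius", pch = 19, ...)
  plot(x$order, x$mean_length_um, xlab = "Strahler order",
       ylab = "mean length (um)", main = "Length", pch = 19, ...)
  plot(x$order, pmax(x$count, 0.5), log = "y", xlab = "Strahler order",
       ylab = "count", main = "Vessel count", pch = 19, ...)
  plot(x$order, x$total_cross_section_mm2, xlab = "Strahler order",
       ylab = "total area (mm^2)", main = "Cross-section", pch = 19, ...)
  invisible(x)
}
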