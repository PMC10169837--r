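## Image priors: turn a whole-organ mask into a cortex shell, and turn a
## raw (possibly cyclic, noisy) centerline graph into the trustworthy
## pre-built large-artery tree that seeds the optimizer.

#' Construct a centerline graph
#'
#' Undirected spatial graph with per-node positions (um) and radii (um),
#' as produced by skeletonization of a vessel segmentation. May contain
#' cycles and spurs before preprocessing. Each edge carries a radius; when
#' not supplied it defaults to the mean of its endpoint node radii.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` and optionally
#'   `radius` (um, >= 0).
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `radius`.
#' @return object of class `centerline_graph`.
#' @export
centerline_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  stopifnot(all(c("id", "x", "y", "z") %in% names(nodes)))
  if (!"radius" %in% names(nodes)) nodes$radius <- NA_real_
  nodes$id <- as.integer(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    edges$from <- as.integer(edges$from)
    edges$to <- as.integer(edges$to)
    if (!all(c(edges$from, edges$to) %in% nodes$id)) {
      stop("edge references a non-existent node id")
    }
    if (!"radius" %in% names(edges)) edges$radius <- NA_real_
    miss <- is.na(edges$radius)
    if (any(miss)) {
      edges$radius[miss] <- (nodes$radius[match(edges$from[miss], nodes$id)] +
                             nodes$radius[match(edges$to[miss], nodes$id)]) / 2
    }
  } else {
    edges <- data.frame(from = integer(), to = integer(), radius = numeric())
  }
  structure(list(nodes = nodes, edges = edges), class = "centerline_graph")
}

#' @export
print.centerline_graph <- function(x, ...) {
  cyc <- nrow(x$edges) - nrow(x$nodes) + n_components(x)
  cat(sprintf("<centerline_graph> %d nodes, %d edges, cyclomatic number %d\n",
              nrow(x$nodes), nrow(x$edges), cyc))
  invisible(x)
}

cl_to_igraph <- function(g) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(g$edges$from),
               to = as.character(g$edges$to), radius = g$edges$radius),
    directed = FALSE,
    vertices = data.frame(name = as.character(g$nodes$id)))
}

n_components <- function(g) {
  if (nrow(g$nodes) == 0) return(0L)
  igraph::count_components(cl_to_igraph(g))
}

#' Approximate the renal cortex as an eroded shell minus a hilar ball
#'
#' The cortex is modeled as the set of foreground voxels within `R1` of the
#' organ surface (the whole mask minus its erosion by a ball of radius
#' `R1`), excluding a ball of radius `R2` around the root position so that
#' no terminals are sampled near the hilum. Defaults follow the rat-kidney
#' settings: cortex thickness R1 = 2 mm, hilar ball R2 = 5.65 mm.
#'
#' Erosion is computed from the exact Euclidean distance transform: a voxel
#' survives erosion iff its distance to background exceeds `R1`.
#'
#' @param whole_mask a `voxel_mask` of the whole organ.
#' @param R1_um shell thickness, um (default 2000).
#' @param root_position 3-vector, um: the root (renal artery inlet).
#' @param R2_um hilar ball radius, um (default 5650); 0 disables removal.
#' @return a `voxel_mask` containing the cortex shell.
#' @export
approximate_cortex <- function(whole_mask, R1_um = 2000, root_position = NULL,
                               R2_um = 5650) {
  stopifnot(R1_um > 0, R2_um >= 0)
  if (!any(whole_mask$grid)) stop("empty input mask")
  if (R1_um < whole_mask$voxel_size) {
    warning("R1 is smaller than one voxel; erosion is a no-op")
  }
  dt <- distance_transform(whole_mask)
  shell <- whole_mask$grid & dt <= R1_um
  if (R2_um > 0) {
    if (is.null(root_position)) stop("root_position needed when R2_um > 0")
    ax <- voxel_centers_axes(whole_mask)
    d <- dim(whole_mask$grid)
    dx2 <- (ax[[1]] - root_position[1])^2
    dy2 <- (ax[[2]] - root_position[2])^2
    dz2 <- (ax[[3]] - root_position[3])^2
    r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    shell <- shell & r2 > R2_um^2
  }
  if (!any(shell)) stop("cortex approximation is empty")
  voxel_mask(shell, whole_mask$voxel_size, whole_mask$origin)
}

#' Derive node radii from a Euclidean distance transform
#'
#' Sets each centerline node's radius to the distance (um) from its
#' position to the nearest background voxel of the vessel mask; edge radii
#' are refreshed as the mean of their endpoint radii. Nodes falling outside
#' the mask get radius 0 with a warning.
#'
#' @param centerline a `centerline_graph`.
#' @param vessel_mask a `voxel_mask` of the segmented vessels.
#' @return the `centerline_graph` with radii filled in.
#' @export
radii_from_distance_transform <- function(centerline, vessel_mask) {
  dt <- distance_transform(vessel_mask)
  pts <- as.matrix(centerline$nodes[, c("x", "y", "z")])
  idx <- world_to_voxel(vessel_mask, pts)
  d <- dim(vessel_mask$grid)
  ok <- idx[, 1] >= 0 & idx[, 1] < d[1] &
        idx[, 2] >= 0 & idx[, 2] < d[2] &
        idx[, 3] >= 0 & idx[, 3] < d[3]
  r <- numeric(nrow(pts))
  if (any(ok)) {
    lin <- 1 + idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3])
    r[ok] <- dt[lin]
  }
  if (any(r == 0)) warning("some nodes lie outside the vessel mask; radius set to 0")
  centerline$nodes$radius <- r
  centerline$edges$radius <- (r[match(centerline$edges$from, centerline$nodes$id)] +
                              r[match(centerline$edges$to, centerline$nodes$id)]) / 2
  centerline
}

#' Break loops with a maximum-radius spanning tree
#'
#' Computes, per connected component, the spanning tree that maximizes the
#' total kept edge radius (minimum spanning tree under edge weight =
#' negative radius). Every cycle of the input therefore loses its thinnest
#' edge -- exactly the spurious thin connections a noisy skeleton
#' introduces. Acyclic inputs pass through unchanged.
#'
#' @param centerline a `centerline_graph`.
#' @return an acyclic `centerline_graph` (forest if the input was
#'   disconnected).
#' @export
mst_by_radius <- function(centerline) {
  if (nrow(centerline$edges) == 0) return(centerline)
  g <- cl_to_igraph(centerline)
  t <- igraph::mst(g, weights = -igraph::E(g)$radius)
  kept <- igraph::as_data_frame(t, what = "edges")
  centerline$edges <- data.frame(from = as.integer(kept$from),
                                 to = as.integer(kept$to),
                                 radius = kept$radius)
  centerline
}

#' Orient an acyclic centerline into a rooted vascular tree
#'
#' Keeps only the connected component containing `root_id`, then orients
#' every edge away from the root (breadth-first). Node radii are carried
#' onto the `leaf_radius` column and edge radii onto vessel radii.
#'
#' @param centerline an acyclic `centerline_graph`.
#' @param root_id id of the root node.
#' @return a `vascular_tree`.
#' @export
to_directed_tree <- function(centerline, root_id) {
  root_id <- as.integer(root_id)
  if (!root_id %in% centerline$nodes$id) stop("root not in graph")
  g <- cl_to_igraph(centerline)
  comp <- igraph::components(g)
  keep_names <- names(comp$membership)[
    comp$membership == comp$membership[as.character(root_id)]]
  keep <- as.integer(keep_names)
  nodes <- centerline$nodes[centerline$nodes$id %in% keep, , drop = FALSE]
  edges <- centerline$edges[centerline$edges$from %in% keep &
                            centerline$edges$to %in% keep, , drop = FALSE]
  ## BFS orientation away from the root
  parent <- integer(0); child <- integer(0); radius <- numeric(0)
  visited <- root_id
  frontier <- root_id
  eused <- rep(FALSE, nrow(edges))
  while (length(frontier) > 0) {
    sel <- which(!eused & (edges$from %in% frontier | edges$to %in% frontier))
    if (length(sel) == 0) break
    ef <- edges$from[sel]; et <- edges$to[sel]
    swap <- et %in% frontier & !(ef %in% frontier)
    p <- ifelse(swap, et, ef)
    ch <- ifelse(swap, ef, et)
    new <- !(ch %in% visited)
    sel <- sel[new]; p <- p[new]; ch <- ch[new]
    ## a node can be reached via two frontier edges only in a cyclic input
    dup <- duplicated(ch)
    sel <- sel[!dup]; p <- p[!dup]; ch <- ch[!dup]
    eused[sel] <- TRUE
    parent <- c(parent, p); child <- c(child, ch)
    radius <- c(radius, edges$radius[sel])
    visited <- c(visited, ch)
    frontier <- ch
  }
  if (length(child) < nrow(edges)) {
    stop("input graph contains a cycle; run mst_by_radius first")
  }
  nodes_df <- data.frame(id = nodes$id, x = nodes$x, y = nodes$y, z = nodes$z,
                         leaf_radius = nodes$radius)
  build_tree(nodes_df, data.frame(parent = parent, child = child,
                                  radius = radius), root = root_id)
}

#' Remove intermediate degree-2 nodes along single vessels
#'
#' Vessels are straight cylinders, so skeleton sample nodes with exactly
#' one child (other than the root) are removed and each maximal chain
#' becomes one straight vessel whose radius is the length-weighted mean of
#' the constituent vessel radii. The straight-line length of the merged
#' vessel is at most the polyline length (negligible error at reasonable
#' curvature).
#'
#' @param tree a `vascular_tree`.
#' @return the collapsed `vascular_tree`.
#' @export
collapse_intermediate <- function(tree) {
  repeat {
    nchild <- table(factor(tree$vessels$parent, levels = tree$nodes$id))
    deg2 <- tree$nodes$id[nchild == 1 & tree$nodes$id != tree$root &
                          tree$nodes$id %in% tree$vessels$child]
    if (length(deg2) == 0) break
    v <- deg2[1]
    up <- match(v, tree$vessels$child)     # parent -> v
    dn <- match(v, tree$vessels$parent)    # v -> child
    l_up <- vessel_lengths(tree, up)
    l_dn <- vessel_lengths(tree, dn)
    w <- if (l_up + l_dn > 0) {
      (tree$vessels$radius[up] * l_up + tree$vessels$radius[dn] * l_dn) /
        (l_up + l_dn)
    } else {
      mean(c(tree$vessels$radius[up], tree$vessels$radius[dn]))
    }
    tree$vessels$parent[dn] <- tree$vessels$parent[up]
    tree$vessels$radius[dn] <- w
    tree$vessels <- tree$vessels[-up, , drop = FALSE]
    tree$nodes <- tree$nodes[tree$nodes$id != v, , drop = FALSE]
  }
  assign_roles(tree)
}

## Along-tree path length from `from_id` through each descendant, and the
## deepest such length through each child vessel. Used by degree pruning.
subtree_path_depths <- function(tree, node_id) {
  crows <- child_vessel_rows(tree)
  lens <- vessel_lengths(tree)
  deepest <- function(edge_row) {
    ch <- tree$vessels$child[edge_row]
    kids <- crows[[node_row(tree, ch)]]
    if (length(kids) == 0) return(lens[edge_row])
    lens[edge_row] + max(vapply(kids, deepest, 0.0))
  }
  kids <- crows[[node_row(tree, node_id)]]
  vapply(kids, deepest, 0.0)
}

#' Limit branching degree by keeping the longest paths
#'
#' Branching into more than `max_children` children is not anatomically
#' plausible for renal arteries; at each over-branched node only the
#' `max_children` children whose subtrees reach deepest (greatest along-tree
#' path length, um) are kept, the rest are removed together with their
#' subtrees. Ties break toward the lower child id.
#'
#' @param tree a `vascular_tree`.
#' @param max_children maximum out-degree (default 4).
#' @return the pruned `vascular_tree`.
#' @export
degree_prune <- function(tree, max_children = 4) {
  repeat {
    nchild <- table(factor(tree$vessels$parent, levels = tree$nodes$id))
    over <- tree$nodes$id[nchild > max_children]
    if (length(over) == 0) break
    v <- over[1]
    kids <- which(tree$vessels$parent == v)
    depths <- subtree_path_depths(tree, v)
    ord <- order(-depths, tree$vessels$child[kids])
    drop_edges <- kids[ord[-seq_len(max_children)]]
    for (e in tree$vessels$child[drop_edges]) {
      tree <- drop_subtree(tree, e)
    }
  }
  assign_roles(tree)
}

## Remove node `id` and everything below it (including its parent vessel).
drop_subtree <- function(tree, id) {
  doomed <- id
  frontier <- id
  while (length(frontier) > 0) {
    nxt <- tree$vessels$child[tree$vessels$parent %in% frontier]
    doomed <- c(doomed, nxt)
    frontier <- nxt
  }
  tree$vessels <- tree$vessels[!(tree$vessels$child %in% doomed), , drop = FALSE]
  tree$nodes <- tree$nodes[!(tree$nodes$id %in% doomed), , drop = FALSE]
  tree
}

#' Prune nodes beyond a cumulative along-tree distance from the root
#'
#' Only the first few branch generations of an extracted centerline are
#' trustworthy; nodes whose cumulative path length from the root exceeds
#' `max_path_um` are removed together with their subtrees (default 10000
#' um, i.e. 10 K um).
#'
#' @param tree a `vascular_tree`.
#' @param max_path_um cumulative distance threshold, um.
#' @return the pruned `vascular_tree`.
#' @export
depth_prune <- function(tree, max_path_um = 10000) {
  if (max_path_um <= 0) stop("threshold would remove the root")
  lens <- vessel_lengths(tree)
  dist <- setNames(rep(NA_real_, nrow(tree$nodes)), tree$nodes$id)
  dist[as.character(tree$root)] <- 0
  v <- tree$vessels
  frontier <- tree$root
  while (length(frontier) > 0) {
    sel <- which(v$parent %in% frontier)
    if (length(sel) == 0) break
    dist[as.character(v$child[sel])] <- dist[as.character(v$parent[sel])] + lens[sel]
    frontier <- v$child[sel]
  }
  too_far <- tree$nodes$id[dist > max_path_um]
  ## removing every too-far node with its subtree == dropping the shallowest
  ## too-far nodes (their descendants are at least as far)
  for (id in too_far) {
    if (id %in% tree$nodes$id) tree <- drop_subtree(tree, id)
  }
  assign_roles(tree)
}

#' Full centerline preprocessing chain
#'
#' Breaks loops (maximum-radius spanning tree), orients away from the root
#' keeping only the root's component, collapses intermediate degree-2
#' nodes, limits branching degree, and prunes beyond the trusted cumulative
#' depth. The chain is idempotent: re-applying it to its own output is the
#' identity.
#'
#' @param centerline a `centerline_graph`.
#' @param root_id root node id.
#' @param max_children maximum out-degree (default 4).
#' @param max_path_um depth-pruning threshold, um (default 10000).
#' @return a preprocessed `vascular_tree` (the pre-built large-artery tree).
#' @export
preprocess_centerline <- function(centerline, root_id, max_children = 4,
                                  max_path_um = 10000) {
  t <- mst_by_radius(centerline)
  t <- to_directed_tree(t, root_id)
  t <- collapse_intermediate(t)
  t <- degree_prune(t, max_children)
  t <- depth_prune(t, max_path_um)
  ## mark everything as image-derived scaffold
  t$nodes$role[t$nodes$id != t$root] <- "prebuilt"
  t
}

#' Undirected centerline view of a vascular tree
#'
#' Forgets directions and roles: node radii are taken from each node's
#' parent-vessel radius (the root takes its first child vessel's radius)
#' and edges keep the vessel radii. Useful for re-running the
#' preprocessing chain on its own output and for graph export.
#'
#' @param tree a `vascular_tree`.
#' @return a `centerline_graph`.
#' @export
as_centerline_graph <- function(tree) {
  prow <- parent_vessel_row(tree)
  r <- tree$vessels$radius[prow]
  root_row <- node_row(tree, tree$root)
  first_child <- which(tree$vessels$parent == tree$root)[1]
  if (!is.na(first_child)) r[root_row] <- tree$vessels$radius[first_child]
  centerline_graph(
    data.frame(id = tree$nodes$id, x = tree$nodes$x, y = tree$nodes$y,
               z = tree$nodes$z, radius = r),
    data.frame(from = tree$vessels$parent, to = tree$vessels$child,
               radius = tree$vessels$radius))
}
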