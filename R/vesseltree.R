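## Core spatial-tree data model: a vascular tree is a rooted directed acyclic
## graph whose nodes are 3-D points (um) and whose edges are straight
## cylindrical vessels carrying a radius (um) and a flow (um^3/s). Lengths
## are always derived from node positions, never stored.

#' Construct a vascular tree
#'
#' Builds and validates a rooted directed spatial tree. Nodes are 3-D points
#' in micrometres; every vessel is a straight cylinder between its two end
#' nodes. Node roles (`root`, `leaf`, `intermediate`) are assigned from the
#' topology; nodes supplied with role `"prebuilt"` keep that role so that
#' image-derived scaffold nodes stay distinguishable from nodes created by
#' the optimizer.
#'
#' @param nodes data.frame with columns `id` (integer), `x`, `y`, `z`
#'   (positions, um). Optional columns: `role`, `subtree`, `leaf_radius`.
#' @param vessels data.frame with columns `parent`, `child` (node ids).
#'   Optional columns `radius` (um) and `flow` (um^3/s).
#' @param root id of the root node.
#' @return An object of class `vascular_tree` with elements `nodes`,
#'   `vessels`, `root` and `next_id`.
#' @export
build_tree <- function(nodes, vessels, root) {
  nodes <- as.data.frame(nodes)
  vessels <- as.data.frame(vessels)
  stopifnot(all(c("id", "x", "y", "z") %in% names(nodes)))
  if (nrow(vessels) > 0) {
    stopifnot(all(c("parent", "child") %in% names(vessels)))
  } else {
    vessels <- data.frame(parent = integer(), child = integer())
  }
  nodes$id <- as.integer(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")])))) {
    stop("node positions must be finite")
  }
  if (!root %in% nodes$id) stop("missing root: root id not among nodes")
  vessels$parent <- as.integer(vessels$parent)
  vessels$child <- as.integer(vessels$child)
  if (!all(c(vessels$parent, vessels$child) %in% nodes$id)) {
    stop("vessel references a non-existent node id")
  }
  if (!"radius" %in% names(vessels)) {
    vessels$radius <- rep(NA_real_, nrow(vessels))
  }
  if (!"flow" %in% names(vessels)) vessels$flow <- rep(NA_real_, nrow(vessels))
  if (!"subtree" %in% names(nodes)) nodes$subtree <- NA_integer_
  if (!"leaf_radius" %in% names(nodes)) nodes$leaf_radius <- NA_real_

  tree <- structure(
    list(nodes = nodes, vessels = vessels, root = as.integer(root),
         next_id = max(nodes$id) + 1L),
    class = "vascular_tree"
  )
  tree <- assign_roles(tree, keep_prebuilt = "role" %in% names(nodes))
  validate_tree(tree)
  tree
}

## Assign root/leaf/intermediate roles from topology. Nodes already marked
## "prebuilt" keep the mark when keep_prebuilt is TRUE (a prebuilt node that
## ends up with no children is still a prebuilt ending node, not a terminal
## leaf in the GCO sense).
assign_roles <- function(tree, keep_prebuilt = TRUE) {
  n <- tree$nodes
  has_child <- n$id %in% tree$vessels$parent
  role <- ifelse(has_child, "intermediate", "leaf")
  if (keep_prebuilt && "role" %in% names(n)) {
    pre <- !is.na(n$role) & n$role == "prebuilt"
    role[pre] <- "prebuilt"
  }
  role[n$id == tree$root] <- "root"
  tree$nodes$role <- role
  tree
}

#' Validate the structural invariants of a vascular tree
#'
#' Checks that the graph is single-rooted, connected, acyclic, and that
#' every non-root node has exactly one parent vessel. Called after every
#' structural mutation in the test-suite.
#'
#' @param tree a `vascular_tree`.
#' @return `tree`, invisibly; stops with an informative error otherwise.
#' @export
validate_tree <- function(tree) {
  n <- tree$nodes
  v <- tree$vessels
  if (!tree$root %in% n$id) stop("missing root")
  if (anyDuplicated(v$child)) stop("multiple parents: a node has more than one parent vessel")
  if (tree$root %in% v$child) stop("root must not have a parent vessel")
  non_root <- setdiff(n$id, tree$root)
  if (!all(non_root %in% v$child)) {
    stop("disconnected node: some non-root nodes have no parent vessel")
  }
  ## Reachability from root; with unique parents and full parent coverage,
  ## reaching every node also rules out cycles.
  reached <- bfs_node_order(tree)
  if (length(reached) != nrow(n)) stop("cycle detected or disconnected subgraph")
  invisible(tree)
}

## --- internal indexing helpers ------------------------------------------

## Row index of each node id.
node_row <- function(tree, ids) match(ids, tree$nodes$id)

## List: for each node row, the vessel row indices of its child vessels.
child_vessel_rows <- function(tree) {
  f <- factor(tree$vessels$parent, levels = tree$nodes$id)
  unname(split(seq_len(nrow(tree$vessels)), f))
}

## Vessel row of the parent vessel of each node row (NA for root).
parent_vessel_row <- function(tree) {
  match(tree$nodes$id, tree$vessels$child)
}

## Breadth-first node ids, root first, computed level by level (vectorized
## per level so large trees stay fast).
bfs_node_order <- function(tree) {
  v <- tree$vessels
  frontier <- tree$root
  out <- list(frontier)
  seen <- frontier
  while (length(frontier) > 0) {
    nxt <- v$child[v$parent %in% frontier]
    nxt <- setdiff(nxt, seen)   # guards against cycles
    if (length(nxt) == 0) break
    out[[length(out) + 1L]] <- nxt
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  unlist(out)
}

## Depth of each node in vessels-from-root; named by node id.
node_depths <- function(tree) {
  v <- tree$vessels
  depth <- setNames(rep(NA_integer_, nrow(tree$nodes)), tree$nodes$id)
  depth[as.character(tree$root)] <- 0L
  frontier <- tree$root
  d <- 0L
  while (length(frontier) > 0) {
    sel <- v$parent %in% frontier
    nxt <- v$child[sel]
    if (length(nxt) == 0) break
    d <- d + 1L
    depth[as.character(nxt)] <- d
    frontier <- nxt
  }
  depth
}

## Vessel rows ordered so that every vessel appears after all vessels in the
## subtree below it (deep first). Used for bottom-up sweeps.
vessel_rows_deep_first <- function(tree) {
  depth <- node_depths(tree)
  ord <- order(depth[match(tree$vessels$child, tree$nodes$id)], decreasing = TRUE)
  ord
}

#' Vessel lengths
#'
#' Length of a vessel is the Euclidean distance between its end nodes
#' (straight cylindrical tubes: constant radius, no curvature). Always
#' derived from node positions, never cached.
#'
#' @param tree a `vascular_tree`.
#' @param rows optional vessel row indices; default all vessels.
#' @return numeric vector of lengths in um.
#' @export
vessel_lengths <- function(tree, rows = seq_len(nrow(tree$vessels))) {
  v <- tree$vessels[rows, , drop = FALSE]
  p <- node_row(tree, v$parent)
  c_ <- node_row(tree, v$child)
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
  unname(sqrt(rowSums((xyz[p, , drop = FALSE] - xyz[c_, , drop = FALSE])^2)))
}

#' @rdname vessel_lengths
#' @param child id of the vessel's child node (vessels are uniquely keyed by
#'   their child node).
#' @export
vessel_length <- function(tree, child) {
  row <- match(as.integer(child), tree$vessels$child)
  if (is.na(row)) stop("vessel not in tree")
  vessel_lengths(tree, row)
}

#' Contract a vessel
#'
#' Removes the vessel's child node and re-parents its children to the
#' vessel's parent node (the merging move of the optimizer). Terminal
#' leaves and the root can never be removed.
#'
#' @param tree a `vascular_tree`.
#' @param child id of the vessel's child node.
#' @return the modified `vascular_tree` (one node fewer).
#' @export
contract_vessel <- function(tree, child) {
  child <- as.integer(child)
  row <- match(child, tree$vessels$child)
  if (is.na(row)) stop("vessel not in tree")
  crow <- node_row(tree, child)
  if (tree$nodes$role[crow] == "leaf") {
    stop("cannot contract a terminal (leaf) vessel")
  }
  parent <- tree$vessels$parent[row]
  ## re-parent grandchildren, drop the vessel and the node
  tree$vessels$parent[tree$vessels$parent == child] <- parent
  tree$vessels <- tree$vessels[-row, , drop = FALSE]
  tree$nodes <- tree$nodes[-crow, , drop = FALSE]
  tree <- assign_roles(tree)
  tree
}

## Allocate n fresh node ids (monotonically increasing, stable across
## mutations for deterministic replay).
new_node_ids <- function(tree, n) {
  ids <- tree$next_id + seq_len(n) - 1L
  ids
}

add_nodes <- function(tree, df) {
  need <- c("id", "x", "y", "z", "role", "subtree", "leaf_radius")
  for (col in setdiff(need, names(df))) {
    df[[col]] <- if (col == "role") "intermediate" else NA
  }
  tree$nodes <- rbind(tree$nodes[, need], df[, need])
  tree$next_id <- max(tree$next_id, max(df$id) + 1L)
  tree
}

#' Leaf node ids of a tree
#'
#' Terminal nodes with role `"leaf"` (afferent-arteriole endpoints once the
#' tree has been initialized).
#'
#' @param tree a `vascular_tree`.
#' @return integer vector of node ids.
#' @export
leaf_ids <- function(tree) {
  tree$nodes$id[tree$nodes$role == "leaf"]
}

## Ids of vessels (keyed by child node) whose child has no outgoing vessel.
## These are the terminal vessels for flow splitting; note a childless
## prebuilt ending node also terminates a vessel.
terminal_vessel_rows <- function(tree) {
  which(!(tree$vessels$child %in% tree$vessels$parent))
}

#' @export
print.vascular_tree <- function(x, ...) {
  cat(sprintf("<vascular_tree> %d nodes, %d vessels, root id %d\n",
              nrow(x$nodes), nrow(x$vessels), x$root))
  roles <- table(x$nodes$role)
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  invisible(x)
}

#' Balanced bifurcating reference tree
#'
#' Builds a symmetric (balanced) binary tree with `n_leaves` terminal
#' vessels, optionally preceded by a single trunk vessel standing for the
#' renal artery. Used as the analytic worked example against which the
#' segment and level counts of a perfectly symmetric tree are computed:
#' with N leaves the tree has 2N-1 vessels (2N-2 without the trunk) and
#' about log2(2N) levels.
#'
#' Node positions are placed on a plane by depth; only topology matters for
#' the morphometric summaries this tree supports.
#'
#' @param n_leaves number of terminal vessels.
#' @param trunk if `TRUE` (default) the root node carries a single trunk
#'   vessel before the first bifurcation.
#' @return a `vascular_tree`.
#' @export
balanced_bifurcating_tree <- function(n_leaves, trunk = TRUE) {
  stopifnot(n_leaves >= 1)
  n_total <- 2L * n_leaves - 1L + if (trunk) 1L else 0L
  parent <- integer(n_total)
  nl <- integer(n_total)      # leaves in subtree
  depth <- integer(n_total)
  parent[1] <- NA_integer_
  k <- 1L
  if (trunk) {
    parent[2] <- 1L; nl[2] <- n_leaves; depth[2] <- 1L
    stack <- 2L
    k <- 2L
  } else {
    nl[1] <- n_leaves
    stack <- 1L
  }
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    n <- nl[v]
    if (n <= 1L) next
    a <- n %/% 2L
    for (m in c(a, n - a)) {
      k <- k + 1L
      parent[k] <- v
      nl[k] <- m
      depth[k] <- depth[v] + 1L
      stack <- c(stack, k)
    }
  }
  ids <- seq_len(n_total)
  nodes <- data.frame(id = ids, x = as.numeric(depth), y = as.numeric(ids),
                      z = 0)
  vessels <- data.frame(parent = parent[-1], child = ids[-1])
  build_tree(nodes, vessels, root = 1L)
}
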