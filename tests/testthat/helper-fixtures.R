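# Fixtures are generated in code; no binary data ships with the package.

# Random rooted spatial tree: node i > 1 gets a parent drawn among nodes
# 1..(i-1), positions uniform in a cube. Returns a validated tree.
random_tree <- function(n, seed, span_um = 1000) {
  set.seed(seed)
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1), 1L))
  nodes <- data.frame(id = 1:n,
                      x = runif(n, 0, span_um),
                      y = runif(n, 0, span_um),
                      z = runif(n, 0, span_um))
  build_tree(nodes, data.frame(parent = parent[-1], child = 2:n), root = 1L)
}

# Same, with leaf radii, Murray radii and Kirchhoff flows assigned.
random_hemo_tree <- function(n, seed, Q0 = 1e8, span_um = 1000) {
  tree <- random_tree(n, seed, span_um)
  term <- which(!(tree$nodes$id %in% tree$vessels$parent))
  tree$nodes$leaf_radius[term] <- runif(length(term), 8, 15)
  tree <- assign_radii_murray(tree)
  assign_flows(tree, Q0)
}

# Small kidney phantom shared by the imaging-stage tests (coarse voxels so
# the whole suite stays fast). Built once per test run.
phantom_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- make_kidney_phantom(c(8000, 5000, 4000), 200, 2000, seed = 1)
      root <- kidney_phantom_root(m)
      cache <<- list(
        mask = m,
        root = root,
        prebuilt = make_prebuilt_tree(m, root, generations = 3, seed = 2),
        cortex = approximate_cortex(m, 2000, root, 5650)
      )
    }
    cache
  }
})

# Canonical signature of the rooted topology (sorted recursive bracketing);
# equal signatures <=> isomorphic rooted trees.
topology_signature <- function(tree, id = tree$root) {
  kids <- tree$vessels$child[tree$vessels$parent == id]
  if (length(kids) == 0) return("L")
  paste0("(", paste(sort(vapply(kids, function(k) topology_signature(tree, k),
                                "")), collapse = ","), ")")
}

# Independent pairwise minimum distance (O(n^2) oracle).
min_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(Inf)
  min(stats::dist(pts))
}

# Flow conservation and Murray cube-law residuals over all internal nodes.
conservation_residuals <- function(tree) {
  v <- tree$vessels
  internal <- intersect(unique(v$parent), v$child)
  flow_res <- murray_res <- numeric(0)
  for (nid in internal) {
    pe <- which(v$child == nid)
    kids <- which(v$parent == nid)
    flow_res <- c(flow_res,
                  abs(v$flow[pe] - sum(v$flow[kids])) / v$flow[pe])
    murray_res <- c(murray_res,
                    abs(v$radius[pe]^3 - sum(v$radius[kids]^3)) /
                      v$radius[pe]^3)
  }
  list(flow = flow_res, murray = murray_res)
}

# TRUE iff pressure strictly decreases along every vessel.
pressure_strictly_decreasing <- function(tree, pressures) {
  p <- setNames(pressures$pressure_mmHg, pressures$id)
  all(p[as.character(tree$vessels$child)] <
        p[as.character(tree$vessels$parent)])
}
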