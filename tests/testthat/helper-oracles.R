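# Independent oracles shared across test files. Each re-derives the checked
# quantity by a route separate from the package implementation.

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Recursive per-vessel Strahler oracle.
strahler_oracle <- function(tree) {
  f <- function(child_id) {
    kids <- tree$vessels$child[tree$vessels$parent == child_id]
    if (length(kids) == 0) return(0L)
    sub <- vapply(kids, f, 0L)
    m <- max(sub)
    if (sum(sub == m) >= 2) m + 1L else m
  }
  vapply(tree$vessels$child, f, 0L)
}

# Brute-force maximum-total-radius spanning tree by edge-subset enumeration.
best_spanning_radius <- function(nodes, edges) {
  n <- length(nodes)
  ne <- nrow(edges)
  best <- -Inf
  for (sel in utils::combn(ne, n - 1, simplify = FALSE)) {
    sub <- edges[sel, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(sub$from), to = as.character(sub$to)),
      directed = FALSE, vertices = data.frame(name = as.character(nodes)))
    if (igraph::is_connected(g)) best <- max(best, sum(sub$radius))
  }
  best
}

# Exhaustive split oracle: best single new-node split over all child
# subsets of size >= 2 (centroid placement plus the same local relax the
# implementation uses); returns the best cost delta (<= 0).
exhaustive_split_delta <- function(tree, v, cfg) {
  dn <- which(tree$vessels$parent == v)
  ch <- tree$vessels$child[dn]
  keep <- tree$nodes$role[match(ch, tree$nodes$id)] != "prebuilt"
  dn <- dn[keep]; ch <- ch[keep]
  m <- length(dn)
  if (m < 2) return(0)
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
  xv <- xyz[match(v, tree$nodes$id), ]
  P <- xyz[match(ch, tree$nodes$id), , drop = FALSE]
  co <- renalvasc:::edge_cost_coeff(tree$vessels$radius[dn],
                                    tree$vessels$flow[dn], cfg)
  r3 <- tree$vessels$radius[dn]^3
  q <- tree$vessels$flow[dn]
  base_len <- sqrt(colSums((t(P) - xv)^2))
  best <- 0
  for (size in 2:m) {
    for (sel in utils::combn(m, size, simplify = FALSE)) {
      w0 <- (colSums(P[sel, , drop = FALSE]) + xv) / (size + 1)
      cw <- renalvasc:::edge_cost_coeff(sum(r3[sel])^(1 / 3), sum(q[sel]),
                                        cfg)
      fn <- function(p) {
        dd <- rbind(P[sel, , drop = FALSE], xv) -
          matrix(p, nrow = size + 1, ncol = 3, byrow = TRUE)
        sum(c(co[sel], cw) * sqrt(rowSums(dd * dd)))
      }
      res <- optim(w0, fn, method = "BFGS",
                   control = list(reltol = 1e-10, maxit = 200))
      w <- if (res$value < fn(w0)) res$par else w0
      dW <- sqrt(colSums((t(P[sel, , drop = FALSE]) - w)^2))
      delta <- sum(co[sel] * dW) - sum(co[sel] * base_len[sel]) +
        cw * sqrt(sum((xv - w)^2))
      best <- min(best, delta)
    }
  }
  best
}
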