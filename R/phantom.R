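## Synthetic kidney phantom: an ellipsoidal organ mask with a concave hilar
## indentation, a pre-built arterial tree with a few branch generations
## rooted at the hilum, and a noisy undirected centerline (loops, tail
## spurs, subdivided edges) emulating what skeletonization of a coarse
## vessel segmentation produces. Every downstream stage of the pipeline is
## testable on these fixtures without any scan.

#' Kidney-shaped phantom mask
#'
#' Solid ellipsoid with a paraboloid indentation (the hilum) carved into
#' the +x side. The mask is padded by two voxels of background on every
#' face. The shape itself is deterministic; `seed` is recorded for
#' provenance of derived fixtures.
#'
#' @param half_axes_um ellipsoid half-axes (a, b, c), um.
#' @param voxel_size_um isotropic voxel size, um (must not exceed the
#'   smallest half-axis).
#' @param hilum_depth_um depth of the hilar indentation, um (0 disables it).
#' @param seed recorded seed.
#' @return a `voxel_mask`.
#' @export
make_kidney_phantom <- function(half_axes_um = c(8000, 5000, 4000),
                                voxel_size_um = 100,
                                hilum_depth_um = 2000, seed = 1L) {
  stopifnot(all(half_axes_um > 0), voxel_size_um > 0)
  if (voxel_size_um > min(half_axes_um)) {
    stop("voxel size larger than the smallest half-axis")
  }
  vs <- voxel_size_um
  pad <- 2
  dims <- as.integer(ceiling(2 * half_axes_um / vs) + 2 * pad)
  ctr <- dims / 2 * vs   # world center (origin at 0)
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * vs)
  ex <- ((ax[[1]] - ctr[1]) / half_axes_um[1])^2
  ey <- ((ax[[2]] - ctr[2]) / half_axes_um[2])^2
  ez <- ((ax[[3]] - ctr[3]) / half_axes_um[3])^2
  grid <- outer(outer(ex, ey, "+"), ez, "+") <= 1
  if (hilum_depth_um > 0) {
    ## subtract a paraboloid opening toward +x: at the axis the cut reaches
    ## hilum_depth below the ellipsoid apex
    d <- hilum_depth_um
    rho2 <- outer((ax[[2]] - ctr[2])^2, (ax[[3]] - ctr[3])^2, "+")
    xcut <- ctr[1] + half_axes_um[1] - d + rho2 / (2 * d)
    keep_x <- outer(ax[[1]], c(xcut), "<=")     # dims[1] x (dims[2]*dims[3])
    grid <- grid & array(keep_x, dim = dims)
  }
  m <- voxel_mask(grid, vs, origin = c(0, 0, 0))
  attr(m, "seed") <- as.integer(seed)
  attr(m, "center") <- ctr
  attr(m, "half_axes") <- half_axes_um
  attr(m, "hilum_depth") <- hilum_depth_um
  m
}

#' Root (renal-artery inlet) position of a phantom mask
#'
#' A point on the hilum axis just inside the indentation floor.
#'
#' @param mask a mask from [make_kidney_phantom()].
#' @return 3-vector, um.
#' @export
kidney_phantom_root <- function(mask) {
  ctr <- attr(mask, "center")
  a <- attr(mask, "half_axes")[1]
  d <- attr(mask, "hilum_depth")
  if (is.null(ctr)) stop("not a phantom mask")
  p <- c(ctr[1] + a - d - 3 * mask$voxel_size, ctr[2], ctr[3])
  if (!points_in_mask(mask, matrix(p, ncol = 3))) {
    stop("computed root position falls outside the mask")
  }
  p
}

#' Pre-built arterial tree inside a phantom mask
#'
#' Grows a rooted tree from the hilum toward the organ center: a trunk
#' vessel, then `generations` levels at which every node spawns children
#' (count drawn from `n_children`) in directions spread around the parent
#' direction, with segment lengths shrinking per generation. Endpoints are
#' resampled (then shrunk) until they fall inside the mask. Tip radii are
#' `tip_radius_um` and all other radii follow Murray's law upward, so radii
#' are monotone non-increasing from root to tips.
#'
#' @param mask a `voxel_mask`.
#' @param root_position 3-vector inside the mask, um.
#' @param generations number of branch generations (2..5, default 3).
#' @param seed RNG seed.
#' @param n_children possible children counts per node (default 2:3).
#' @param tip_radius_um radius assigned to the tips, um (default 30).
#' @param trunk_length_um length of the root trunk vessel (default a
#'   quarter of the largest mask extent).
#' @return a `vascular_tree` with roles marked `prebuilt`.
#' @export
make_prebuilt_tree <- function(mask, root_position, generations = 3,
                               seed = 1L, n_children = 2:3,
                               tip_radius_um = 30,
                               trunk_length_um = NULL) {
  stopifnot(generations >= 2, generations <= 5)
  root_position <- as.numeric(root_position)
  if (!points_in_mask(mask, matrix(root_position, ncol = 3))) {
    stop("root outside mask")
  }
  ctr <- attr(mask, "center")
  if (is.null(ctr)) ctr <- mask$origin + dim(mask$grid) * mask$voxel_size / 2
  if (is.null(trunk_length_um)) {
    trunk_length_um <- max(dim(mask$grid) * mask$voxel_size) / 4
  }
  with_seed(seed, {
    unit <- function(v) v / sqrt(sum(v^2))
    place <- function(from, dir, len) {
      ## try shrinking lengths / jittered directions until inside the mask
      for (s in c(1, 0.8, 0.64, 0.5, 0.4, 0.3, 0.2)) {
        for (try in 1:8) {
          d2 <- unit(dir + 0.3 * (try - 1) * rnorm(3))
          p <- from + d2 * len * s
          if (points_in_mask(mask, matrix(p, ncol = 3))) return(p)
        }
      }
      ## fall back: walk toward the organ center
      p <- from
      step <- unit(ctr - from) * mask$voxel_size * 2
      for (i in 1:1000) {
        p <- p + step
        if (points_in_mask(mask, matrix(p, ncol = 3))) return(p)
      }
      stop("could not place a node inside the mask")
    }

    xs <- list(root_position)
    parent <- c(NA_integer_)
    gen <- c(0L)
    dirs <- list(unit(ctr - root_position))
    ## trunk
    p1 <- place(root_position, unit(ctr - root_position), trunk_length_um)
    xs[[2]] <- p1
    parent[2] <- 1L
    gen[2] <- 0L
    dirs[[2]] <- unit(p1 - root_position)
    frontier <- 2L
    len <- trunk_length_um * 0.9
    for (g in seq_len(generations)) {
      nxt <- integer(0)
      for (v in frontier) {
        nc <- if (length(n_children) == 1) n_children else
          sample(n_children, 1)
        for (ci in seq_len(nc)) {
          dir <- unit(dirs[[v]] + 0.9 * rnorm(3))
          p <- place(xs[[v]], dir, len)
          k <- length(xs) + 1L
          xs[[k]] <- p
          parent[k] <- v
          gen[k] <- g
          dirs[[k]] <- unit(p - xs[[v]])
          nxt <- c(nxt, k)
        }
      }
      frontier <- nxt
      len <- len * 0.55
    }
    pos <- do.call(rbind, xs)
    nodes <- data.frame(id = seq_along(xs), x = pos[, 1], y = pos[, 2],
                        z = pos[, 3],
                        role = c("root", rep("prebuilt", length(xs) - 1)))
    vessels <- data.frame(parent = parent[-1], child = seq_along(xs)[-1])
    tree <- build_tree(nodes, vessels, root = 1L)
    ## Murray radii upward from uniform tip radii
    tips <- tree$nodes$id[!(tree$nodes$id %in% tree$vessels$parent)]
    lr <- setNames(rep(tip_radius_um, length(tips)), tips)
    tree$nodes$leaf_radius[node_row(tree, tips)] <- tip_radius_um
    tree <- assign_radii_murray(tree, lr)
    tree
  })
}

#' Noisy synthetic centerline from a pre-built tree
#'
#' Emulates a raw skeletonization output: the tree skeleton made
#' undirected, each edge subdivided by `intermediate_per_edge` collinear
#' degree-2 nodes, plus `loop_count` spurious loop edges (direct
#' connections between random non-adjacent nodes, with an explicitly thin
#' edge radius) and `spur_count` short thin tail extensions at tip nodes.
#' Loop edges and spur radii are strictly thinner than every true edge, so
#' the preprocessing chain removes the loops (spanning tree) and absorbs
#' the tails (intermediate-node collapse), recovering the generating
#' topology.
#'
#' @param tree a `vascular_tree` (e.g. from [make_prebuilt_tree()]).
#' @param loop_count number of loop edges to add.
#' @param spur_count number of tail spurs to add (at distinct tips).
#' @param intermediate_per_edge degree-2 nodes inserted per edge.
#' @param seed RNG seed.
#' @return a `centerline_graph`.
#' @export
make_noisy_centerline <- function(tree, loop_count = 0, spur_count = 0,
                                  intermediate_per_edge = 0, seed = 1L) {
  stopifnot(loop_count >= 0, spur_count >= 0, intermediate_per_edge >= 0)
  with_seed(seed, {
    cl <- as_centerline_graph(tree)
    nodes <- cl$nodes
    edges <- cl$edges
    next_id <- max(nodes$id) + 1L
    min_true_radius <- min(edges$radius)
    thin <- 0.3 * min_true_radius

    ## subdivide edges with collinear interior nodes
    if (intermediate_per_edge > 0) {
      new_edges <- list()
      for (e in seq_len(nrow(edges))) {
        a <- nodes[match(edges$from[e], nodes$id), ]
        b <- nodes[match(edges$to[e], nodes$id), ]
        m <- intermediate_per_edge
        tseq <- seq_len(m) / (m + 1)
        ids <- next_id + seq_len(m) - 1L
        next_id <- next_id + m
        nodes <- rbind(nodes, data.frame(
          id = ids,
          x = a$x + tseq * (b$x - a$x),
          y = a$y + tseq * (b$y - a$y),
          z = a$z + tseq * (b$z - a$z),
          radius = a$radius + tseq * (b$radius - a$radius)))
        chain <- c(edges$from[e], ids, edges$to[e])
        new_edges[[e]] <- data.frame(
          from = chain[-length(chain)], to = chain[-1],
          radius = edges$radius[e])
      }
      edges <- do.call(rbind, new_edges)
    }

    ## loop edges: thin direct connections between non-adjacent nodes
    if (loop_count > 0) {
      adj_key <- c(paste(edges$from, edges$to), paste(edges$to, edges$from))
      added <- 0L
      guard <- 0L
      while (added < loop_count && guard < 10000L) {
        guard <- guard + 1L
        ab <- sample(nodes$id, 2)
        key <- paste(ab[1], ab[2])
        if (ab[1] == ab[2] || key %in% adj_key) next
        edges <- rbind(edges, data.frame(from = ab[1], to = ab[2],
                                         radius = thin))
        adj_key <- c(adj_key, key, paste(ab[2], ab[1]))
        added <- added + 1L
      }
      if (added < loop_count) stop("could not place the requested loops")
    }

    ## tail spurs: short thin chains extending tips
    if (spur_count > 0) {
      tips <- setdiff(tree$nodes$id, tree$vessels$parent)
      tips <- setdiff(tips, tree$root)
      if (spur_count > length(tips)) {
        stop("spur_count exceeds the number of tips")
      }
      at <- sample(tips, spur_count)
      for (tip in at) {
        trow <- match(tip, nodes$id)
        prow <- match(tree$vessels$parent[match(tip, tree$vessels$child)],
                      nodes$id)
        dir <- c(nodes$x[trow] - nodes$x[prow],
                 nodes$y[trow] - nodes$y[prow],
                 nodes$z[trow] - nodes$z[prow])
        dir <- dir / sqrt(sum(dir^2))
        dir <- dir + 0.5 * rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        len <- 0.15 * vessel_length(tree, tip)
        id <- next_id
        next_id <- next_id + 1L
        nodes <- rbind(nodes, data.frame(
          id = id, x = nodes$x[trow] + dir[1] * len,
          y = nodes$y[trow] + dir[2] * len,
          z = nodes$z[trow] + dir[3] * len, radius = thin))
        edges <- rbind(edges, data.frame(from = tip, to = id, radius = thin))
      }
    }
    centerline_graph(nodes, edges)
  })
}
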