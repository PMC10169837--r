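## Terminal (afferent-arteriole) position sampling: Poisson-disk (Bridson
## dart throwing) inside a masked volume with a guaranteed minimum pairwise
## distance, plus the volume-based estimate of that distance.

#' Estimate the Poisson-disk minimum distance from volume and point count
#'
#' The achievable minimum separation scales as the cube root of the volume
#' per point; `eta` is the packing factor calibrated once on the phantom
#' cortex so that sampling with the returned distance reaches at least 95%
#' of the requested point count.
#'
#' @param mask_volume_um3 perfusion-territory volume, um^3.
#' @param n_points desired number of terminals.
#' @param eta packing factor (default 0.7).
#' @return minimum distance, um.
#' @export
estimate_min_distance <- function(mask_volume_um3, n_points, eta = 0.7) {
  stopifnot(mask_volume_um3 > 0, n_points > 0)
  eta * (mask_volume_um3 / n_points)^(1 / 3)
}

#' Poisson-disk sampling inside a voxel mask
#'
#' Bridson-style dart throwing: candidates are drawn uniformly from the
#' spherical annulus `[r_min, 2 r_min]` around active points (`k = 30`
#' candidates per active point), kept only if they fall inside the mask
#' foreground and are at least `r_min` from every accepted point
#' (checked via a background grid with cell edge `r_min / sqrt(3)`).
#' Sampling stops at `n_target` points or when the active list empties.
#' The alternative `method = "cube"` draws the disk sample over the whole
#' bounding box first and filters to the mask afterwards.
#'
#' @param mask a `voxel_mask` (nonempty).
#' @param r_min_um minimum pairwise distance, um (> 0).
#' @param n_target maximum number of points.
#' @param seed RNG seed (same seed, same points, bitwise).
#' @param k candidates per active point (default 30).
#' @param method `"mask"` (default: candidates must fall in the mask) or
#'   `"cube"` (sample the bounding box, filter afterwards).
#' @return object of class `point_set`: list with `positions` (n x 3
#'   matrix, um), `r_min`, `seed`.
#' @export
poisson_disk_sample <- function(mask, r_min_um, n_target, seed = 1L,
                                k = 30L, method = c("mask", "cube")) {
  method <- match.arg(method)
  stopifnot(r_min_um > 0, n_target >= 1)
  if (!any(mask$grid)) stop("mask is empty")
  with_seed(seed, {
    d <- dim(mask$grid)
    lo <- mask$origin
    hi <- mask$origin + d * mask$voxel_size
    in_domain <- function(p) {
      if (method == "cube") {
        p[, 1] >= lo[1] & p[, 1] < hi[1] &
        p[, 2] >= lo[2] & p[, 2] < hi[2] &
        p[, 3] >= lo[3] & p[, 3] < hi[3]
      } else {
        points_in_mask(mask, p)
      }
    }
    ## background grid: cell edge r/sqrt(3) guarantees <= 1 point per cell
    cell <- r_min_um / sqrt(3)
    gdim <- pmax(1L, as.integer(ceiling((hi - lo) / cell)))
    grid <- integer(prod(gdim))          # 0 = empty, else point index
    cell_of <- function(p) {
      ci <- pmin(pmax(floor(sweep(p, 2, lo) / cell), 0),
                 matrix(rep(gdim - 1L, each = nrow(p)), ncol = 3))
      1 + ci[, 1] + gdim[1] * (ci[, 2] + gdim[2] * ci[, 3])
    }
    ## neighbor cell offsets within 2 cells (covers distance r)
    off <- as.matrix(expand.grid(dx = -2:2, dy = -2:2, dz = -2:2))

    ## seed point: rejection-sample a position in the domain
    p0 <- NULL
    for (i in 1:10000) {
      cand <- matrix(lo + runif(3) * (hi - lo), ncol = 3)
      if (in_domain(cand)) { p0 <- cand; break }
    }
    if (is.null(p0)) stop("could not place a seed point in the mask")

    cap <- as.integer(n_target)
    pts <- matrix(NA_real_, nrow = cap, ncol = 3)
    pts[1, ] <- p0
    npts <- 1L
    grid[cell_of(p0)] <- 1L
    active <- 1L

    neighbor_ok <- function(cand) {
      ## cand: 1 x 3; check all accepted points in nearby cells
      ci <- floor((cand[1, ] - lo) / cell)
      cc <- sweep(off, 2, ci, "+")
      ok <- cc[, 1] >= 0 & cc[, 1] < gdim[1] &
            cc[, 2] >= 0 & cc[, 2] < gdim[2] &
            cc[, 3] >= 0 & cc[, 3] < gdim[3]
      cc <- cc[ok, , drop = FALSE]
      lin <- 1 + cc[, 1] + gdim[1] * (cc[, 2] + gdim[2] * cc[, 3])
      occ <- grid[lin]
      occ <- occ[occ > 0L]
      if (length(occ) == 0) return(TRUE)
      dd <- pts[occ, , drop = FALSE] - matrix(cand, nrow = length(occ),
                                              ncol = 3, byrow = TRUE)
      all(rowSums(dd * dd) >= r_min_um^2)
    }

    while (length(active) > 0 && npts < cap) {
      ai <- active[sample.int(length(active), 1)]
      base <- pts[ai, ]
      ## k candidates uniform in the annulus [r, 2r]
      dir <- matrix(rnorm(3 * k), ncol = 3)
      dir <- dir / sqrt(rowSums(dir * dir))
      rad <- r_min_um * (1 + 7 * runif(k))^(1 / 3)
      cand <- sweep(dir * rad, 2, base, "+")
      keep <- in_domain(cand)
      placed <- FALSE
      if (any(keep)) {
        for (ci in which(keep)) {
          cm <- cand[ci, , drop = FALSE]
          if (neighbor_ok(cm)) {
            npts <- npts + 1L
            pts[npts, ] <- cm
            grid[cell_of(cm)] <- npts
            active <- c(active, npts)
            placed <- TRUE
            break
          }
        }
      }
      if (!placed) active <- active[active != ai]
    }

    pts <- pts[seq_len(npts), , drop = FALSE]
    if (method == "cube") {
      pts <- pts[points_in_mask(mask, pts), , drop = FALSE]
    }
    if (nrow(pts) == 1 && n_target > 1) {
      warning("r_min too large for the mask: only the seed point fits")
    }
    structure(list(positions = unname(pts), r_min = r_min_um,
                   seed = as.integer(seed)),
              class = "point_set")
  })
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points, r_min = %.4g um, seed = %d\n",
              nrow(x$positions), x$r_min, x$seed))
  invisible(x)
}
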