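## Readers and writers for every artifact boundary. All coordinates are
## serialized in um world units, never voxels. The lossless native tree
## format is the JSON dialect; SWC is supported as the widely-read but
## lossy (no flow) interchange format.

## --- volumetric masks ----------------------------------------------------

#' Read and write voxel masks (NIfTI or NRRD)
#'
#' Round-trips grid, isotropic voxel size and origin. The format is picked
#' from the file extension: `.nii` / `.nii.gz` via RNifti, `.nrrd` via a
#' minimal built-in NRRD (raw encoding) implementation. Anisotropic voxel
#' spacing is an error: the whole pipeline assumes isotropic voxels.
#'
#' @param mask a `voxel_mask`.
#' @param path file path.
#' @return `read_mask`: a `voxel_mask`. `write_mask`: `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(mask, path)
  } else {
    img <- RNifti::asNifti(array(as.integer(mask$grid), dim = dim(mask$grid)))
    RNifti::pixdim(img) <- rep(mask$voxel_size, 3)
    ## qform: world = voxel_size * index0 + center of voxel (0,0,0)
    m <- diag(c(rep(mask$voxel_size, 3), 1))
    m[1:3, 4] <- mask$origin + mask$voxel_size / 2
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    return(read_nrrd(path))
  }
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  if (diff(range(pd)) > 1e-6 * mean(pd)) {
    stop("anisotropic voxel spacing: the pipeline requires isotropic voxels")
  }
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4] - pd[1] / 2      # corner of voxel (0,0,0)
  grid <- array(as.logical(img != 0), dim = dim(img))
  voxel_mask(grid, pd[1], unname(origin))
}

## Minimal NRRD (detached-header-free, raw encoding) writer/reader.
write_nrrd <- function(mask, path) {
  d <- dim(mask$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# produced by renalvasc",
    "type: unsigned char",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            mask$voxel_size, mask$voxel_size, mask$voxel_size),
    sprintf("space origin: (%.9g,%.9g,%.9g)",
            mask$origin[1], mask$origin[2], mask$origin[3]),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.raw(as.integer(mask$grid)), con)
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    hdr <- c(hdr, line)
  }
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(paste0("^", key, ": "), "", hit[1])
  }
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file")
  if (get_field("encoding") != "raw") stop("only raw NRRD encoding supported")
  type <- get_field("type")
  if (!type %in% c("unsigned char", "uchar", "uint8", "uint8_t")) {
    stop("only unsigned char NRRD masks supported")
  }
  sizes <- as.integer(strsplit(get_field("sizes"), " ")[[1]])
  dirs <- get_field("space directions")
  nums <- regmatches(dirs, gregexpr("-?[0-9.eE+]+", dirs))[[1]]
  m <- matrix(as.numeric(nums), nrow = 3, byrow = TRUE)
  sp <- apply(m, 1, function(r) sqrt(sum(r^2)))
  if (diff(range(sp)) > 1e-6 * mean(sp)) {
    stop("anisotropic voxel spacing: the pipeline requires isotropic voxels")
  }
  orig <- get_field("space origin")
  origin <- if (is.null(orig)) c(0, 0, 0) else {
    as.numeric(regmatches(orig, gregexpr("-?[0-9.eE+]+", orig))[[1]])
  }
  raw <- readBin(con, "raw", n = prod(sizes))
  grid <- array(as.integer(raw) != 0, dim = sizes)
  voxel_mask(grid, sp[1], origin)
}

## --- trees ---------------------------------------------------------------

#' Export a vascular tree
#'
#' Formats: `"json"` (lossless native dialect), `"graphml"` (lossless,
#' via igraph), `"swc"` (standard morphology interchange; lossy: no flow),
#' `"vtk"` (legacy ASCII polydata polylines with radius/flow/pressure/
#' Strahler order as per-segment scalars; write-only).
#'
#' @param tree a `vascular_tree`.
#' @param path output path.
#' @param format one of `"json"`, `"graphml"`, `"swc"`, `"vtk"`; default
#'   guessed from the extension.
#' @param pressures optional [pressure_profile()] output (VTK export).
#' @return `path`, invisibly.
#' @export
export_tree <- function(tree, path, format = NULL, pressures = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  switch(format,
    json = write_tree_json(tree, path),
    graphml = write_tree_graphml(tree, path),
    swc = write_tree_swc(tree, path),
    vtk = write_tree_vtk(tree, path, pressures),
    stop("unknown format: ", format)
  )
  invisible(path)
}

#' Import a vascular tree written by [export_tree()]
#'
#' @param path input path.
#' @param format `"json"`, `"graphml"` or `"swc"` (default from
#'   extension).
#' @return a `vascular_tree`.
#' @export
import_tree <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
    json = read_tree_json(path),
    graphml = read_tree_graphml(path),
    swc = read_tree_swc(path),
    stop("unknown format: ", format)
  )
}

write_tree_json <- function(tree, path) {
  obj <- list(
    format = "renalvasc-tree-v1",
    units = list(position = "um", radius = "um", flow = "um^3/s"),
    root = tree$root,
    nodes = tree$nodes,
    vessels = tree$vessels
  )
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, na = "null")
}

read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes)
  vessels <- as.data.frame(obj$vessels)
  tree <- build_tree(nodes, vessels, root = obj$root)
  ## build_tree re-derives roles; restore stored prebuilt marks
  if ("role" %in% names(nodes)) tree$nodes$role <- nodes$role
  tree
}

write_tree_graphml <- function(tree, path) {
  vdf <- data.frame(name = as.character(tree$nodes$id),
                    x = tree$nodes$x, y = tree$nodes$y, z = tree$nodes$z,
                    role = tree$nodes$role,
                    subtree = ifelse(is.na(tree$nodes$subtree), -1L,
                                     tree$nodes$subtree),
                    leaf_radius = ifelse(is.na(tree$nodes$leaf_radius), -1,
                                         tree$nodes$leaf_radius))
  edf <- data.frame(from = as.character(tree$vessels$parent),
                    to = as.character(tree$vessels$child),
                    radius = ifelse(is.na(tree$vessels$radius), -1,
                                    tree$vessels$radius),
                    flow = ifelse(is.na(tree$vessels$flow), -1,
                                  tree$vessels$flow))
  g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
  g <- igraph::set_graph_attr(g, "root", as.character(tree$root))
  igraph::write_graph(g, path, format = "graphml")
}

read_tree_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vdf <- igraph::as_data_frame(g, what = "vertices")
  edf <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(id = as.integer(vdf$name), x = vdf$x, y = vdf$y,
                      z = vdf$z, role = vdf$role,
                      subtree = ifelse(vdf$subtree < 0, NA_integer_,
                                       as.integer(vdf$subtree)),
                      leaf_radius = ifelse(vdf$leaf_radius < 0, NA_real_,
                                           vdf$leaf_radius))
  vessels <- data.frame(parent = as.integer(edf$from),
                        child = as.integer(edf$to),
                        radius = ifelse(edf$radius < 0, NA_real_, edf$radius),
                        flow = ifelse(edf$flow < 0, NA_real_, edf$flow))
  root <- as.integer(igraph::graph_attr(g, "root"))
  tree <- build_tree(nodes, vessels, root = root)
  tree$nodes$role <- nodes$role[match(tree$nodes$id, nodes$id)]
  tree
}

write_tree_swc <- function(tree, path) {
  ## SWC: one sample per node; radius of a node = radius of its parent
  ## vessel (root: its first child vessel). type 5 = fork point, 6 = end
  ## point, 1 = soma-like root.
  prow <- parent_vessel_row(tree)
  r <- tree$vessels$radius[prow]
  first_child <- which(tree$vessels$parent == tree$root)[1]
  r[node_row(tree, tree$root)] <- tree$vessels$radius[first_child]
  r[is.na(r)] <- 1
  parent_id <- tree$vessels$parent[prow]
  parent_id[is.na(parent_id)] <- -1L
  type <- ifelse(tree$nodes$role == "leaf", 6L,
                 ifelse(tree$nodes$id == tree$root, 1L, 5L))
  ## SWC requires parents to precede children
  ord <- match(bfs_node_order(tree), tree$nodes$id)
  swc_id <- seq_len(nrow(tree$nodes))
  remap <- setNames(swc_id, tree$nodes$id[ord])
  df <- data.frame(
    n = swc_id,
    type = type[ord],
    x = tree$nodes$x[ord], y = tree$nodes$y[ord], z = tree$nodes$z[ord],
    radius = r[ord],
    parent = ifelse(parent_id[ord] == -1L, -1L,
                    remap[as.character(parent_id[ord])])
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# SWC export (renalvasc); coordinates and radii in um",
               "# n type x y z radius parent"), con)
  write.table(df, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
}

read_tree_swc <- function(path) {
  df <- read.csv(path, sep = "", header = FALSE, comment.char = "#")
  names(df) <- c("n", "type", "x", "y", "z", "radius", "parent")
  root <- df$n[df$parent == -1]
  if (length(root) != 1) stop("SWC file must have exactly one root")
  nodes <- data.frame(id = df$n, x = df$x, y = df$y, z = df$z,
                      leaf_radius = df$radius)
  vs <- df[df$parent != -1, , drop = FALSE]
  vessels <- data.frame(parent = vs$parent, child = vs$n, radius = vs$radius)
  build_tree(nodes, vessels, root = root)
}

write_tree_vtk <- function(tree, path, pressures = NULL) {
  n <- nrow(tree$nodes)
  nv <- nrow(tree$vessels)
  rowof <- setNames(seq_len(n) - 1L, tree$nodes$id)   # VTK is 0-based
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vascular tree (renalvasc); um units",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  write.table(tree$nodes[, c("x", "y", "z")], con, row.names = FALSE,
              col.names = FALSE)
  writeLines(sprintf("LINES %d %d", nv, 3 * nv), con)
  write.table(data.frame(2L, rowof[as.character(tree$vessels$parent)],
                         rowof[as.character(tree$vessels$child)]),
              con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_DATA %d", nv), con)
  wr_scalar <- function(name, vals) {
    writeLines(c(sprintf("SCALARS %s float 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(ifelse(is.na(vals), 0, vals), trim = TRUE), con)
  }
  wr_scalar("radius_um", tree$vessels$radius)
  wr_scalar("flow_um3_s", tree$vessels$flow)
  if (!anyNA(tree$vessels$radius) && !anyNA(tree$vessels$flow)) {
    wr_scalar("strahler_order", as.numeric(strahler_orders(tree)))
  }
  if (!is.null(pressures)) {
    pout <- pressures$pressure_mmHg[match(tree$vessels$child, pressures$id)]
    wr_scalar("outlet_pressure_mmHg", pout)
  }
}

## --- point sets and order stats -----------------------------------------

#' Write a sampled point set
#'
#' CSV (columns x,y,z in um) or JSON with metadata (r_min, seed, and the
#' MD5 checksum of the generating mask when supplied).
#'
#' @param points a `point_set`.
#' @param path output path (`.csv` or `.json`).
#' @param mask_checksum optional checksum string recorded in the JSON.
#' @return `path`, invisibly.
#' @export
write_point_set <- function(points, path, mask_checksum = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(
      r_min_um = points$r_min, seed = points$seed,
      mask_checksum = mask_checksum,
      positions = as.data.frame(points$positions) |>
        setNames(c("x", "y", "z"))
    ), path, dataframe = "columns", digits = NA, auto_unbox = TRUE)
  } else {
    df <- as.data.frame(points$positions)
    names(df) <- c("x", "y", "z")
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_point_set
#' @export
read_point_set <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    structure(list(positions = unname(as.matrix(as.data.frame(obj$positions))),
                   r_min = obj$r_min_um, seed = obj$seed),
              class = "point_set")
  } else {
    df <- read.csv(path)
    structure(list(positions = unname(as.matrix(df[, c("x", "y", "z")])),
                   r_min = NA_real_, seed = NA_integer_),
              class = "point_set")
  }
}

## --- centerline graphs ---------------------------------------------------

#' Read and write centerline graphs
#'
#' GraphML (via igraph) or a documented JSON dialect (`nodes`: id, x, y, z
#' in um, radius; `edges`: source, target, radius).
#'
#' @param graph a `centerline_graph`.
#' @param path file path (`.graphml` or `.json`).
#' @return `read_centerline`: a `centerline_graph`.
#' @export
write_centerline <- function(graph, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    vdf <- data.frame(name = as.character(graph$nodes$id), x = graph$nodes$x,
                      y = graph$nodes$y, z = graph$nodes$z,
                      radius = graph$nodes$radius)
    edf <- data.frame(from = as.character(graph$edges$from),
                      to = as.character(graph$edges$to),
                      radius = graph$edges$radius)
    g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    jsonlite::write_json(list(
      format = "renalvasc-centerline-v1",
      nodes = graph$nodes,
      edges = data.frame(source = graph$edges$from,
                         target = graph$edges$to,
                         radius = graph$edges$radius)
    ), path, dataframe = "columns", digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_centerline
#' @export
read_centerline <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    vdf <- igraph::as_data_frame(g, what = "vertices")
    edf <- igraph::as_data_frame(g, what = "edges")
    centerline_graph(
      data.frame(id = as.integer(vdf$name), x = vdf$x, y = vdf$y, z = vdf$z,
                 radius = vdf$radius),
      data.frame(from = as.integer(edf$from), to = as.integer(edf$to),
                 radius = edf$radius))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    centerline_graph(as.data.frame(obj$nodes),
                     data.frame(from = obj$edges$source,
                                to = obj$edges$target,
                                radius = obj$edges$radius))
  }
}

#' Write a per-order statistics table as CSV
#'
#' @param stats an `order_stats` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_order_stats <- function(stats, path) {
  write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}
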