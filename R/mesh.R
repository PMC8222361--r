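#' Labelled tetrahedral meshes
#'
#' A `tet_mesh` is the central geometric container of the package: node
#' coordinates in mm, 4-node (linear) or 10-node (quadratic) tetrahedra,
#' one material label per element, and named landmark node sets.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z (mm).
#' @param elems integer matrix, one row per element, 4 or 10 columns of
#'   1-based node indices. Quadratic elements use the VTK ordering:
#'   vertices 1-4, then midside nodes on edges (1,2),(2,3),(3,1),(1,4),
#'   (2,4),(3,4).
#' @param material character vector, one label per element.
#' @param node_sets named list of integer vectors (landmark node sets).
#' @return an object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elems, material, node_sets = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(elems) %in% c(4L, 10L),
            length(material) == nrow(elems))
  if (max(elems) > nrow(nodes) || min(elems) < 1L)
    stop("element connectivity references nodes outside the node table")
  structure(list(nodes = nodes, elems = elems,
                 material = as.character(material),
                 node_sets = node_sets,
                 order = if (ncol(elems) == 4L) 1L else 2L),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d order-%d tetrahedra\n",
              nrow(x$nodes), nrow(x$elems), x$order))
  tab <- table(x$material)
  cat("  materials:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  if (length(x$node_sets))
    cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  invisible(x)
}

#' Element volumes
#'
#' Signed volumes from the vertex tetrahedron formula (exact for the
#' straight-edged quadratic elements generated here). All volumes are
#' strictly positive in a valid mesh.
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector of element volumes (mm^3).
#' @export
element_volumes <- function(mesh) {
  element_volumes_cpp(mesh$nodes, mesh$elems[, 1:4, drop = FALSE])
}

#' Element centroids
#' @param mesh a [tet_mesh()].
#' @return numeric matrix (n_elem x 3) of vertex-centroid coordinates.
#' @export
element_centroids <- function(mesh) {
  e <- mesh$elems
  (mesh$nodes[e[, 1], , drop = FALSE] + mesh$nodes[e[, 2], , drop = FALSE] +
     mesh$nodes[e[, 3], , drop = FALSE] + mesh$nodes[e[, 4], , drop = FALSE]) / 4
}

# flip node ordering of elements with negative volume (in place, returns elems)
orient_positive <- function(nodes, elems) {
  v <- element_volumes_cpp(nodes, elems[, 1:4, drop = FALSE])
  bad <- which(v < 0)
  if (length(bad)) {
    tmp <- elems[bad, 3L]
    elems[bad, 3L] <- elems[bad, 4L]
    elems[bad, 4L] <- tmp
  }
  elems
}

# Tetrahedralize a set of kept voxel cells on a structured grid.
#
# Each hexahedral cell is split into 5 tetrahedra. The split has two mirror
# chiralities; alternating them in a 3D checkerboard keeps shared faces
# conforming, and makes the connectivity exactly mirror-symmetric about a
# grid plane with an even cell count on either side (a mirrored even-parity
# cell is an odd-parity cell and vice versa).
#
# keep: logical array (nx, ny, nz); label: character array, same dim;
# origin: corner of cell (1,1,1); h: scalar cell size.
voxel_tet_mesh <- function(keep, label, origin, h, node_sets = list()) {
  dm <- dim(keep)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  idx <- which(keep, arr.ind = TRUE) # kept cells
  if (nrow(idx) == 0L) stop("no cells kept")
  npx <- nx + 1L; npy <- ny + 1L
  nid <- function(i, j, k) i + npx * ((j - 1L) + npy * (k - 1L)) # 1-based grid node id
  i <- idx[, 1]; j <- idx[, 2]; k <- idx[, 3]
  # cell corner node ids, local order (dx,dy,dz) binary: 000 100 010 110 001 101 011 111
  corn <- cbind(nid(i, j, k),         nid(i + 1L, j, k),
                nid(i, j + 1L, k),    nid(i + 1L, j + 1L, k),
                nid(i, j, k + 1L),    nid(i + 1L, j, k + 1L),
                nid(i, j + 1L, k + 1L), nid(i + 1L, j + 1L, k + 1L))
  parity <- (i + j + k) %% 2L
  splitA <- rbind(c(1, 4, 6, 7), c(1, 4, 6, 2), c(1, 4, 7, 3),
                  c(1, 6, 7, 5), c(4, 6, 7, 8))
  splitB <- rbind(c(2, 3, 5, 8), c(2, 3, 5, 1), c(2, 3, 8, 4),
                  c(2, 5, 8, 6), c(3, 5, 8, 7))
  nc <- nrow(corn)
  elems <- matrix(0L, nc * 5L, 4L)
  lab <- character(nc * 5L)
  cell_lab <- label[idx]
  for (t in 1:5) {
    rows <- seq.int(t, by = 5L, length.out = nc)
    sa <- splitA[t, ]; sb <- splitB[t, ]
    pick <- ifelse(parity == 0L,
                   0L, 1L)
    sel <- matrix(0L, nc, 4L)
    sel[pick == 0L, ] <- corn[pick == 0L, sa, drop = FALSE]
    sel[pick == 1L, ] <- corn[pick == 1L, sb, drop = FALSE]
    elems[rows, ] <- sel
    lab[rows] <- cell_lab
  }
  # compress node numbering to used nodes
  used <- sort(unique(as.vector(elems)))
  remap <- integer(npx * npy * (nz + 1L))
  remap[used] <- seq_along(used)
  elems <- matrix(remap[elems], ncol = 4L)
  # grid node coordinates
  u0 <- used - 1L
  gi <- u0 %% npx
  gj <- (u0 %/% npx) %% npy
  gk <- u0 %/% (npx * npy)
  nodes <- cbind(origin[1] + gi * h, origin[2] + gj * h, origin[3] + gk * h)
  elems <- orient_positive(nodes, elems)
  ns <- lapply(node_sets, function(s) {
    r <- remap[s[s >= 1L & s <= length(remap)]]
    r[!is.na(r) & r > 0L]
  })
  tet_mesh(nodes, elems, lab, ns)
}

#' Unit cube fixture mesh
#'
#' Conforming tetrahedral mesh of the unit cube (single material "bone"),
#' used as an FE verification fixture (patch tests, rigid-body modes).
#'
#' @param n_per_edge number of cells per edge (>= 1).
#' @param order element order, 1 (4-node) or 2 (10-node).
#' @return a [tet_mesh()].
#' @export
make_unit_cube_mesh <- function(n_per_edge, order = 1) {
  stopifnot(n_per_edge >= 1)
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  n <- as.integer(n_per_edge)
  keep <- array(TRUE, c(n, n, n))
  label <- array("bone", c(n, n, n))
  m <- voxel_tet_mesh(keep, label, origin = c(0, 0, 0), h = 1 / n)
  if (order == 2) m <- make_quadratic(m)
  m
}

#' Convert a linear mesh to quadratic by edge-midpoint insertion
#'
#' Adds one midside node per unique edge (VTK 10-node tetra ordering).
#' Midside nodes are not snapped to any curved geometry; the meshes
#' generated here are piecewise planar. Node sets gain a midside node
#' whenever both edge endpoints belong to the set (keeps planar landmark
#' sets, e.g. a clamped face, closed under refinement of order).
#'
#' @param mesh a linear (order 1) [tet_mesh()].
#' @return a quadratic [tet_mesh()].
#' @export
make_quadratic <- function(mesh) {
  if (mesh$order != 1L) stop("mesh is already quadratic")
  e <- mesh$elems
  edge_local <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  n <- nrow(mesh$nodes)
  a <- c(); b <- c()
  for (q in 1:6) {
    a <- c(a, e[, edge_local[q, 1]])
    b <- c(b, e[, edge_local[q, 2]])
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- (lo - 1) * n + hi
  uk <- unique(key)
  mid_id <- n + match(key, uk)
  ulo <- ((uk - 1) %/% n) + 1
  uhi <- ((uk - 1) %% n) + 1
  midpts <- (mesh$nodes[ulo, , drop = FALSE] + mesh$nodes[uhi, , drop = FALSE]) / 2
  elems10 <- cbind(e, matrix(mid_id, ncol = 6))
  ns <- lapply(mesh$node_sets, function(s) {
    inset <- (ulo %in% s) & (uhi %in% s)
    c(s, (n + seq_along(uk))[inset])
  })
  tet_mesh(rbind(mesh$nodes, midpts), elems10, mesh$material, ns)
}

#' Cantilever beam fixture mesh
#'
#' Box beam along +x with node sets `fixed_end` (x = 0 face) and `tip`
#' (x = length face); analytic benchmark for tip deflection PL^3/(3EI).
#'
#' @param length,depth,width beam dimensions (mm); the beam bends in z
#'   (depth) under a tip load in -z.
#' @param n integer vector `c(nx, ny, nz)` of cells per direction.
#' @param order element order (1 or 2).
#' @return a [tet_mesh()].
#' @export
make_cantilever_mesh <- function(length, depth, width, n = c(20, 2, 2),
                                 order = 1) {
  if (length <= 0 || depth <= 0 || width <= 0)
    stop("beam dimensions must be positive")
  n <- as.integer(n)
  # anisotropic cells are not supported by the voxel builder; scale axes
  # separately by generating on a unit grid then stretching
  keep <- array(TRUE, n)
  label <- array("bone", n)
  m <- voxel_tet_mesh(keep, label, origin = c(0, 0, 0), h = 1)
  m$nodes[, 1] <- m$nodes[, 1] * length / n[1]
  m$nodes[, 2] <- m$nodes[, 2] * width / n[2]
  m$nodes[, 3] <- m$nodes[, 3] * depth / n[3]
  m$elems <- orient_positive(m$nodes, m$elems)
  m$node_sets <- list(
    fixed_end = which(m$nodes[, 1] == 0),
    tip = which(m$nodes[, 1] == length))
  if (order == 2) m <- make_quadratic(m)
  m
}

#' Bi-material bar fixture mesh
#'
#' Axial bar along +x split into two material regions `mat_a` (for x below
#' the first segment length) and `mat_b`; the interface is conforming by
#' construction. Used as the
#' material-interface (series-springs) benchmark.
#'
#' @param lengths numeric `c(La, Lb)` segment lengths (mm).
#' @param section numeric `c(w, h)` cross-section (mm).
#' @param n integer `c(nx, ny, nz)` cells; the interface must fall on a cell
#'   boundary (`nx * La / (La + Lb)` integer).
#' @param labels material labels for the two segments.
#' @param order element order (1 or 2).
#' @return a [tet_mesh()].
#' @export
make_bimaterial_bar <- function(lengths = c(1, 1), section = c(1, 1),
                                n = c(8, 2, 2), labels = c("mat_a", "mat_b"),
                                order = 1) {
  stopifnot(all(lengths > 0), all(section > 0))
  n <- as.integer(n)
  Ltot <- sum(lengths)
  nx_a <- n[1] * lengths[1] / Ltot
  if (abs(nx_a - round(nx_a)) > 1e-9)
    stop("material interface must coincide with a cell boundary")
  keep <- array(TRUE, n)
  label <- array(labels[2], n)
  label[seq_len(round(nx_a)), , ] <- labels[1]
  m <- voxel_tet_mesh(keep, label, origin = c(0, 0, 0), h = 1)
  m$nodes[, 1] <- m$nodes[, 1] * Ltot / n[1]
  m$nodes[, 2] <- m$nodes[, 2] * section[1] / n[2]
  m$nodes[, 3] <- m$nodes[, 3] * section[2] / n[3]
  m$elems <- orient_positive(m$nodes, m$elems)
  m$node_sets <- list(end_a = which(m$nodes[, 1] == 0),
                      end_b = which(m$nodes[, 1] == Ltot))
  if (order == 2) m <- make_quadratic(m)
  m
}

#' Element face-adjacency graph
#'
#' Two elements are adjacent when they share a triangular face (vertex
#' faces for quadratic elements). Used e.g. to verify that tooth elements
#' are separated from bone by the periodontal ligament.
#'
#' @param mesh a [tet_mesh()].
#' @return two-column integer matrix of adjacent element pairs.
#' @export
element_adjacency <- function(mesh) {
  ne <- nrow(mesh$elems)
  fl <- sorted_faces(mesh)
  owner <- rep(seq_len(ne), each = 4L)
  key <- paste(fl[, 1], fl[, 2], fl[, 3], sep = "-")
  sp <- split(owner, key)
  sp <- sp[lengths(sp) == 2L]
  if (!length(sp)) return(matrix(integer(), 0, 2))
  matrix(unlist(sp, use.names = FALSE), ncol = 2, byrow = TRUE)
}

#' Mirror-partner node map
#'
#' For a mesh that is mirror-symmetric about the mid-sagittal plane x = 0,
#' returns for every node the index of the node at (-x, y, z).
#'
#' @param mesh a [tet_mesh()].
#' @param tol coordinate matching tolerance (mm).
#' @return integer vector, `map[i]` = mirror partner of node i.
#' @export
mirror_node_map <- function(mesh, tol = 1e-8) {
  key <- function(p) paste(round(p[, 1] / tol), round(p[, 2] / tol),
                           round(p[, 3] / tol))
  k0 <- key(mesh$nodes)
  mirrored <- mesh$nodes
  mirrored[, 1] <- -mirrored[, 1]
  m <- match(key(mirrored), k0)
  if (anyNA(m)) stop("mesh is not mirror-symmetric about x = 0")
  m
}

#' Mirror-partner element map
#'
#' Matches elements to their mirror images by vertex-centroid coordinates.
#'
#' @inheritParams mirror_node_map
#' @return integer vector over elements.
#' @export
mirror_element_map <- function(mesh, tol = 1e-8) {
  cen <- element_centroids(mesh)
  key <- function(p) paste(round(p[, 1] / tol), round(p[, 2] / tol),
                           round(p[, 3] / tol))
  k0 <- key(cen)
  cen[, 1] <- -cen[, 1]
  m <- match(key(cen), k0)
  if (anyNA(m)) stop("element layout is not mirror-symmetric about x = 0")
  m
}
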