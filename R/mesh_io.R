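# Mesh readers/writers: Gmsh MSH 4.1 ASCII, VTK VTU (ASCII XML) and Abaqus
# INP export. Round trips through MSH and VTU preserve coordinates,
# connectivity, material labels and node sets; INP is export-only (one
# ELSET per material, one NSET per node set).

# permutation internal (VTK) tet10 ordering -> Gmsh tet10 ordering
GMSH_TET10_PERM <- c(1:8, 10, 9)

fmt_g <- function(x) sprintf("%.17g", x)

#' Write a mesh to disk
#'
#' @param mesh a [tet_mesh()].
#' @param path output file path.
#' @param format one of "msh" (Gmsh 4.1 ASCII), "vtu" (VTK unstructured
#'   grid, ASCII), "inp" (Abaqus, export only). Default: from extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = tools::file_ext(path)) {
  format <- tolower(format)
  switch(format,
         msh = write_msh(mesh, path),
         vtu = write_vtu_mesh(mesh, path),
         inp = write_inp(mesh, path),
         stop("unsupported mesh format: ", format))
  invisible(path)
}

#' Read a mesh from disk
#'
#' @param path input file path.
#' @param format "msh" or "vtu" (INP import is not supported).
#' @return a [tet_mesh()].
#' @export
read_mesh <- function(path, format = tools::file_ext(path)) {
  format <- tolower(format)
  switch(format,
         msh = read_msh(path),
         vtu = read_vtu_mesh(path),
         inp = stop("INP import is not supported (export only)"),
         stop("unsupported mesh format: ", format))
}

write_msh <- function(mesh, path) {
  mats <- sort(unique(mesh$material))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  w("$PhysicalNames", as.character(length(mats)))
  for (i in seq_along(mats)) w(sprintf("3 %d \"%s\"", i, mats[i]))
  w("$EndPhysicalNames")
  w("$Entities", sprintf("0 0 0 %d", length(mats)))
  bb <- apply(mesh$nodes, 2, range)
  for (i in seq_along(mats))
    w(sprintf("%d %s %s %s %s %s %s 1 %d", i,
              fmt_g(bb[1, 1]), fmt_g(bb[1, 2]), fmt_g(bb[1, 3]),
              fmt_g(bb[2, 1]), fmt_g(bb[2, 2]), fmt_g(bb[2, 3]), i))
  w("$EndEntities")
  nn <- nrow(mesh$nodes)
  w("$Nodes", sprintf("1 %d 1 %d", nn, nn), sprintf("3 1 0 %d", nn))
  w(as.character(seq_len(nn)))
  w(paste(fmt_g(mesh$nodes[, 1]), fmt_g(mesh$nodes[, 2]),
          fmt_g(mesh$nodes[, 3])))
  w("$EndNodes")
  etype <- if (mesh$order == 1L) 4L else 11L
  e <- mesh$elems
  if (mesh$order == 2L) e <- e[, GMSH_TET10_PERM, drop = FALSE]
  ne <- nrow(e)
  w("$Elements", sprintf("%d %d 1 %d", length(mats), ne, ne))
  eid <- seq_len(ne)
  for (i in seq_along(mats)) {
    sel <- mesh$material == mats[i]
    w(sprintf("3 %d %d %d", i, etype, sum(sel)))
    w(paste(eid[sel], apply(e[sel, , drop = FALSE], 1, paste, collapse = " ")))
  }
  w("$EndElements")
  # node sets as post-processing node data (one block per set)
  for (nm in names(mesh$node_sets)) {
    s <- mesh$node_sets[[nm]]
    w("$NodeData", "1", sprintf("\"nodeset:%s\"", nm), "1", "0.0",
      "3", "0", "1", as.character(length(s)))
    w(paste(s, "1"))
    w("$EndNodeData")
  }
  invisible(path)
}

read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    a <- which(lines == paste0("$", name))
    b <- which(lines == paste0("$End", name))
    if (!length(a)) return(NULL)
    Map(function(i, j) lines[(i + 1):(j - 1)], a, b)
  }
  pn <- sec("PhysicalNames")[[1]]
  nmat <- as.integer(pn[1])
  mat_names <- character(nmat)
  for (i in seq_len(nmat)) {
    parts <- strsplit(pn[1 + i], " ")[[1]]
    mat_names[as.integer(parts[2])] <- gsub("\"", "", parts[3])
  }
  nd <- sec("Nodes")[[1]]
  hdr <- as.numeric(strsplit(nd[1], " ")[[1]])
  nn <- hdr[2]
  tags <- as.integer(nd[2 + seq_len(nn)])
  coords <- do.call(rbind, lapply(nd[2 + nn + seq_len(nn)], function(s)
    as.numeric(strsplit(s, " ")[[1]])))
  nodes <- matrix(0, nn, 3)
  nodes[tags, ] <- coords
  el <- sec("Elements")[[1]]
  i <- 2
  elems <- NULL; labs <- NULL; etype0 <- NULL
  while (i <= length(el)) {
    bh <- as.integer(strsplit(el[i], " ")[[1]])
    ent <- bh[2]; etype <- bh[3]; nel <- bh[4]
    etype0 <- etype
    rows <- do.call(rbind, lapply(el[i + seq_len(nel)], function(s)
      as.integer(strsplit(s, " ")[[1]])))
    elems <- rbind(elems, cbind(rows[, -1, drop = FALSE], ent, rows[, 1]))
    i <- i + nel + 1
  }
  eid <- elems[, ncol(elems)]
  ent <- elems[, ncol(elems) - 1]
  conn <- elems[, seq_len(ncol(elems) - 2), drop = FALSE]
  ord <- order(eid)
  conn <- conn[ord, , drop = FALSE]
  ent <- ent[ord]
  if (etype0 == 11L) conn <- conn[, GMSH_TET10_PERM, drop = FALSE]
  node_sets <- list()
  for (blk in sec("NodeData") %||% list()) {
    nm <- sub("^\"nodeset:(.*)\"$", "\\1", blk[2])
    nv <- as.integer(blk[8])
    ids <- as.integer(vapply(blk[8 + seq_len(nv)], function(s)
      strsplit(s, " ")[[1]][1], ""))
    node_sets[[nm]] <- ids
  }
  tet_mesh(nodes, unname(conn), mat_names[ent], node_sets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# VTU writer for a mesh plus optional per-element data arrays.
write_vtu <- function(mesh, path, cell_data = list()) {
  mats <- sort(unique(mesh$material))
  mcode <- match(mesh$material, mats)
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  npe <- ncol(mesh$elems)
  vtk_type <- if (mesh$order == 1L) 10L else 24L
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("<?xml version=\"1.0\"?>",
    "<VTKFile type=\"UnstructuredGrid\" version=\"0.1\" byte_order=\"LittleEndian\">",
    "<UnstructuredGrid>",
    sprintf("<Piece NumberOfPoints=\"%d\" NumberOfCells=\"%d\">", nn, ne),
    "<Points>",
    "<DataArray type=\"Float64\" NumberOfComponents=\"3\" format=\"ascii\">")
  w(paste(fmt_g(mesh$nodes[, 1]), fmt_g(mesh$nodes[, 2]), fmt_g(mesh$nodes[, 3])))
  w("</DataArray>", "</Points>", "<Cells>",
    "<DataArray type=\"Int64\" Name=\"connectivity\" format=\"ascii\">")
  w(apply(mesh$elems - 1L, 1, paste, collapse = " "))
  w("</DataArray>",
    "<DataArray type=\"Int64\" Name=\"offsets\" format=\"ascii\">")
  w(as.character(seq_len(ne) * npe))
  w("</DataArray>",
    "<DataArray type=\"UInt8\" Name=\"types\" format=\"ascii\">")
  w(as.character(rep(vtk_type, ne)))
  w("</DataArray>", "</Cells>", "<CellData>")
  w(sprintf("<DataArray type=\"Int32\" Name=\"material\" format=\"ascii\" MaterialLabels=\"%s\">",
            paste(mats, collapse = ",")))
  w(as.character(mcode))
  w("</DataArray>")
  for (nm in names(cell_data)) {
    w(sprintf("<DataArray type=\"Float64\" Name=\"%s\" format=\"ascii\">", nm))
    w(fmt_g(cell_data[[nm]]))
    w("</DataArray>")
  }
  w("</CellData>", "<PointData>")
  for (nm in names(mesh$node_sets)) {
    flag <- integer(nn)
    flag[mesh$node_sets[[nm]]] <- 1L
    w(sprintf("<DataArray type=\"UInt8\" Name=\"nodeset:%s\" format=\"ascii\">", nm))
    w(as.character(flag))
    w("</DataArray>")
  }
  w("</PointData>", "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  invisible(path)
}

write_vtu_mesh <- function(mesh, path) write_vtu(mesh, path)

read_vtu_mesh <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  num <- function(node) scan(text = xml2::xml_text(node), quiet = TRUE)
  pts <- num(xml2::xml_find_first(piece, ".//Points/DataArray"))
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- num(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name='connectivity']"))
  offs <- num(xml2::xml_find_first(piece, ".//Cells/DataArray[@Name='offsets']"))
  npe <- as.integer(offs[1])
  elems <- matrix(as.integer(conn) + 1L, ncol = npe, byrow = TRUE)
  mat_node <- xml2::xml_find_first(piece,
                                   ".//CellData/DataArray[@Name='material']")
  mats <- strsplit(xml2::xml_attr(mat_node, "MaterialLabels"), ",")[[1]]
  material <- mats[as.integer(num(mat_node))]
  sets <- list()
  for (da in xml2::xml_find_all(piece, ".//PointData/DataArray")) {
    nm <- xml2::xml_attr(da, "Name")
    if (!startsWith(nm, "nodeset:")) next
    sets[[sub("^nodeset:", "", nm)]] <- which(num(da) == 1)
  }
  tet_mesh(nodes, elems, material, sets)
}

write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("*HEADING", "craniostrain mesh export")
  w("*NODE")
  w(sprintf("%d, %s, %s, %s", seq_len(nrow(mesh$nodes)),
            fmt_g(mesh$nodes[, 1]), fmt_g(mesh$nodes[, 2]),
            fmt_g(mesh$nodes[, 3])))
  etype <- if (mesh$order == 1L) "C3D4" else "C3D10"
  mats <- sort(unique(mesh$material))
  for (m in mats) {
    sel <- which(mesh$material == m)
    w(sprintf("*ELEMENT, TYPE=%s, ELSET=MAT_%s", etype, toupper(m)))
    rows <- mesh$elems[sel, , drop = FALSE]
    w(paste0(sel, ", ", apply(rows, 1, paste, collapse = ", ")))
  }
  for (nm in names(mesh$node_sets)) {
    w(sprintf("*NSET, NSET=%s", toupper(nm)))
    ids <- mesh$node_sets[[nm]]
    for (chunk in split(ids, ceiling(seq_along(ids) / 10)))
      w(paste(chunk, collapse = ", "))
  }
  invisible(path)
}
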