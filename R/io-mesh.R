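#' Mesh and field file output
#'
#' VTU (ASCII XML unstructured grid) carries the mesh with arbitrary
#' point/cell data for visualisation; MSH (Gmsh 2.2 ASCII) carries the
#' tagged mesh with one physical volume group per region and round-trips
#' through \code{\link{read_msh}}.
#'
#' @name mesh-io
NULL

vtu_data_array <- function(name, values, ncomp) {
  paste0('<DataArray type="Float64" Name="', name,
         '" NumberOfComponents="', ncomp, '" format="ascii">\n',
         paste(format(t(values), trim = TRUE, digits = 12),
               collapse = " "),
         "\n</DataArray>")
}

#' Write a tet mesh (plus optional fields) as ASCII VTU
#'
#' @param mesh a \code{tet_mesh}.
#' @param path output file.
#' @param point_data named list of per-node scalars (length N) or
#'   matrices (N x 3).
#' @param cell_data named list of per-element scalars or E x 3 matrices;
#'   the region tag is always included as integer codes.
#' @return invisibly, \code{path}.
#' @export
write_vtu <- function(mesh, path, point_data = list(),
                      cell_data = list()) {
  N <- nrow(mesh$nodes); E <- nrow(mesh$elems)
  cell_data <- c(list(region = as.numeric(factor(
    mesh$region, levels = c("muscle", "tendon_proximal", "tendon_distal",
                            "aponeurosis")))), cell_data)
  fmt_data <- function(lst) paste(vapply(names(lst), function(nm) {
    v <- lst[[nm]]
    if (is.matrix(v)) vtu_data_array(nm, v, ncol(v))
    else vtu_data_array(nm, matrix(v, ncol = 1), 1L)
  }, character(1)), collapse = "\n")
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "<UnstructuredGrid>",
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', N, E),
    "<Points>", vtu_data_array("Points", mesh$nodes, 3L), "</Points>",
    "<Cells>",
    paste0('<DataArray type="Int64" Name="connectivity" format="ascii">\n',
           paste(t(mesh$elems) - 1L, collapse = " "), "\n</DataArray>"),
    paste0('<DataArray type="Int64" Name="offsets" format="ascii">\n',
           paste(seq_len(E) * 4L, collapse = " "), "\n</DataArray>"),
    paste0('<DataArray type="UInt8" Name="types" format="ascii">\n',
           paste(rep(10L, E), collapse = " "), "\n</DataArray>"),
    "</Cells>",
    if (length(point_data)) c("<PointData>", fmt_data(point_data),
                              "</PointData>") else NULL,
    "<CellData>", fmt_data(cell_data), "</CellData>",
    "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  writeLines(unlist(xml), path)
  invisible(path)
}

#' Write a tagged tet mesh as Gmsh MSH 2.2 ASCII
#'
#' Regions become physical volume groups (tags 1..4 in the order muscle,
#' tendon_proximal, tendon_distal, aponeurosis); face sets become
#' physical surface groups (tags 11..14 in the order inlet, outlet,
#' muscle_surface, aponeurosis_surface).
#'
#' @param mesh a \code{tet_mesh}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_msh <- function(mesh, path) {
  regions <- c("muscle", "tendon_proximal", "tendon_distal",
               "aponeurosis")
  sets <- c("inlet", "outlet", "muscle_surface", "aponeurosis_surface")
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  wl("$PhysicalNames", as.character(length(regions) + length(sets)))
  for (i in seq_along(regions))
    wl(sprintf('3 %d "%s"', i, regions[i]))
  for (i in seq_along(sets))
    wl(sprintf('2 %d "%s"', 10L + i, sets[i]))
  wl("$EndPhysicalNames")
  wl("$Nodes", as.character(nrow(mesh$nodes)))
  wl(sprintf("%d %.12g %.12g %.12g", seq_len(nrow(mesh$nodes)),
             mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]))
  wl("$EndNodes")
  ntri <- sum(vapply(mesh$face_sets, nrow, integer(1)))
  wl("$Elements", as.character(nrow(mesh$elems) + ntri))
  eid <- 0L
  for (i in seq_along(sets)) {
    fs <- mesh$face_sets[[sets[i]]]
    if (is.null(fs) || nrow(fs) == 0L) next
    wl(sprintf("%d 2 2 %d %d %d %d %d", eid + seq_len(nrow(fs)),
               10L + i, 10L + i, fs[, 1], fs[, 2], fs[, 3]))
    eid <- eid + nrow(fs)
  }
  rid <- match(mesh$region, regions)
  wl(sprintf("%d 4 2 %d %d %d %d %d %d", eid + seq_len(nrow(mesh$elems)),
             rid, rid, mesh$elems[, 1], mesh$elems[, 2],
             mesh$elems[, 3], mesh$elems[, 4]))
  wl("$EndElements")
  invisible(path)
}

#' Read a tagged tet mesh written by \code{\link{write_msh}}
#'
#' Supports the Gmsh 2.2 ASCII subset produced by this package (physical
#' names for volume regions and surface face sets).
#'
#' @param path MSH file path.
#' @param e2 principal axis to attach.
#' @return a \code{tet_mesh}.
#' @export
read_msh <- function(path, e2 = c(0, 0, 1)) {
  lines <- readLines(path)
  sec <- function(tag) {
    i0 <- match(paste0("$", tag), lines)
    i1 <- match(paste0("$End", tag), lines)
    if (is.na(i0) || is.na(i1)) stop("read_msh: missing section ", tag)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  pn <- sec("PhysicalNames")[-1]
  pn_split <- strsplit(pn, " ")
  phys <- data.frame(dim = vapply(pn_split, function(x)
    as.integer(x[1]), integer(1)),
    tag = vapply(pn_split, function(x) as.integer(x[2]), integer(1)),
    name = vapply(pn_split, function(x)
      gsub('"', "", paste(x[-(1:2)], collapse = " ")), character(1)))
  nd <- sec("Nodes")[-1]
  ndm <- do.call(rbind, lapply(strsplit(nd, " +"), as.numeric))
  nodes <- ndm[order(ndm[, 1]), 2:4, drop = FALSE]
  ell <- sec("Elements")[-1]
  elm <- lapply(strsplit(ell, " +"), as.integer)
  is_tet <- vapply(elm, function(x) x[2] == 4L, logical(1))
  tets <- do.call(rbind, lapply(elm[is_tet], function(x)
    x[(length(x) - 3L):length(x)]))
  tet_tag <- vapply(elm[is_tet], function(x) x[4], integer(1))
  region <- phys$name[match(tet_tag, phys$tag)]
  tris <- elm[!is_tet & vapply(elm, function(x) x[2] == 2L, logical(1))]
  face_sets <- list()
  for (i in seq_len(nrow(phys))) {
    if (phys$dim[i] != 2L) next
    sel <- vapply(tris, function(x) x[4] == phys$tag[i], logical(1))
    if (any(sel))
      face_sets[[phys$name[i]]] <-
        do.call(rbind, lapply(tris[sel], function(x)
          x[(length(x) - 2L):length(x)]))
  }
  tet_mesh(nodes, tets, region, face_sets, e2 = e2)
}

#' Export an element fibre field as CSV
#'
#' Columns: element id, centroid coordinates, fibre vector components,
#' validity flag.
#'
#' @param mesh a \code{tet_mesh}.
#' @param field an \code{element_fibre_field}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
write_field_csv <- function(mesh, field, path) {
  ctr <- tet_centroids(mesh)
  utils::write.csv(data.frame(element = seq_len(nrow(field)),
                              cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
                              ax = field[, 1], ay = field[, 2],
                              az = field[, 3],
                              valid = attr(field, "valid")),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a voxel mask as a triangulated surface (VTU)
#'
#' Boundary faces of the masked voxel region (voxel cube faces between a
#' masked and an unmasked voxel) are written as triangle pairs, giving a
#' watertight surface suitable as meshing input.
#'
#' @param mask logical array.
#' @param grid the \code{voxel_grid} the mask lives on.
#' @param path output VTU path.
#' @return invisibly, \code{path}.
#' @export
write_mask_surface_vtu <- function(mask, grid, path) {
  dims <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  verts <- matrix(0, 0, 3); tris <- matrix(0L, 0, 3)
  # voxel corner offsets of the 6 faces, each as 4 corners (ccw)
  facedef <- list(
    list(d = c(-1, 0, 0), c = rbind(c(0, 0, 0), c(0, 1, 0), c(0, 1, 1), c(0, 0, 1))),
    list(d = c(1, 0, 0), c = rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 1), c(1, 1, 0))),
    list(d = c(0, -1, 0), c = rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1), c(1, 0, 0))),
    list(d = c(0, 1, 0), c = rbind(c(0, 1, 0), c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))),
    list(d = c(0, 0, -1), c = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))),
    list(d = c(0, 0, 1), c = rbind(c(0, 0, 1), c(0, 1, 1), c(1, 1, 1), c(1, 0, 1))))
  get <- function(i, j, k) {
    ok <- i >= 1 & i <= dims[1] & j >= 1 & j <= dims[2] &
      k >= 1 & k <= dims[3]
    out <- rep(FALSE, length(i))
    out[ok] <- mask[cbind(i[ok], j[ok], k[ok])]
    out
  }
  for (fd in facedef) {
    nb <- get(idx[, 1] + fd$d[1], idx[, 2] + fd$d[2], idx[, 3] + fd$d[3])
    expose <- which(!nb)
    for (e in expose) {
      corner0 <- idx[e, ] - 1L           # 0-based voxel corner
      quad <- sweep(fd$c, 2, corner0, "+")
      w <- index_to_world(grid, quad)
      base <- nrow(verts)
      verts <- rbind(verts, w)
      tris <- rbind(tris, base + c(1L, 2L, 3L), base + c(1L, 3L, 4L))
    }
  }
  E <- nrow(tris)
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "<UnstructuredGrid>",
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">',
            nrow(verts), E),
    "<Points>", vtu_data_array("Points", verts, 3L), "</Points>",
    "<Cells>",
    paste0('<DataArray type="Int64" Name="connectivity" format="ascii">\n',
           paste(t(tris) - 1L, collapse = " "), "\n</DataArray>"),
    paste0('<DataArray type="Int64" Name="offsets" format="ascii">\n',
           paste(seq_len(E) * 3L, collapse = " "), "\n</DataArray>"),
    paste0('<DataArray type="UInt8" Name="types" format="ascii">\n',
           paste(rep(5L, E), collapse = " "), "\n</DataArray>"),
    "</Cells>", "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  writeLines(xml, path)
  invisible(path)
}
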