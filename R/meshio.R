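#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Boundary facets are emitted as lower-dimensional elements carrying the
#' physical groups `SKULL`/`VENTRICLE`; volume elements carry the physical
#' groups `GREY`/`WHITE` with the integer region label stored as the
#' elementary-entity tag. Coordinates are written in metres.
#'
#' @param mesh a `brain_mesh`.
#' @param path output path (`.msh`).
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  groups <- c(SKULL = 1L, VENTRICLE = 2L, GREY = 3L, WHITE = 4L)
  gdim <- c(SKULL = mesh$dim - 1L, VENTRICLE = mesh$dim - 1L,
            GREY = mesh$dim, WHITE = mesh$dim)
  etype <- function(nn) switch(as.character(nn), "1" = 15L, "2" = 1L, "3" = 2L, "4" = 4L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$PhysicalNames",
               as.character(length(groups))), con)
  writeLines(sprintf('%d %d "%s"', gdim, groups, names(groups)), con)
  writeLines("$EndPhysicalNames", con)
  writeLines(c("$Nodes", as.character(nrow(mesh$nodes))), con)
  xyz <- cbind(mesh$nodes, matrix(0, nrow(mesh$nodes), 3 - mesh$dim))
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(xyz)),
                     xyz[, 1], xyz[, 2], xyz[, 3]), con)
  writeLines("$EndNodes", con)
  nfac <- nrow(mesh$facets); nel <- nrow(mesh$elems)
  writeLines(c("$Elements", as.character(nfac + nel)), con)
  fl <- sprintf("%d %d 2 %d 0 %s", seq_len(nfac),
                etype(ncol(mesh$facets)), groups[mesh$facet_tag],
                apply(mesh$facets, 1, paste, collapse = " "))
  el <- sprintf("%d %d 2 %d %d %s", nfac + seq_len(nel),
                etype(ncol(mesh$elems)), groups[mesh$tissue], mesh$region,
                apply(mesh$elems, 1, paste, collapse = " "))
  writeLines(c(fl, el), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a mesh from Gmsh MSH 2.2 ASCII format
#'
#' Physical-group names are mapped to the package's boundary tags and tissue
#' labels; the mapping can be overridden (e.g. for meshes produced by other
#' pipelines) via `tag_map`. An error names any missing required tag.
#'
#' @param path path to a `.msh` file (format 2.2, ASCII).
#' @param tag_map named character vector mapping physical-group names in the
#'   file to `SKULL`, `VENTRICLE`, `GREY`, `WHITE`.
#' @param units `"m"` (default) or `"mm"`; coordinates are converted to
#'   metres on read, never implicitly.
#' @return A `brain_mesh`.
#' @export
read_msh <- function(path, tag_map = NULL, units = c("m", "mm")) {
  units <- match.arg(units)
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1):(i1 - 1)]
  }
  pn <- sect("PhysicalNames")
  phys <- list()
  if (!is.null(pn)) {
    for (ln in pn[-1]) {
      m <- regmatches(ln, regexec('^(\\d+)\\s+(\\d+)\\s+"(.*)"', ln))[[1]]
      if (length(m) == 4) phys[[m[4]]] <- as.integer(m[3])
    }
  }
  name_of <- function(id) {
    nm <- names(phys)[match(id, unlist(phys))]
    if (!is.null(tag_map) && !is.na(nm) && nm %in% names(tag_map)) tag_map[[nm]] else nm
  }
  nd <- sect("Nodes")
  nn <- as.integer(nd[1])
  ndat <- matrix(scan(text = nd[-1], quiet = TRUE), nrow = nn, byrow = TRUE)
  xyz <- ndat[order(ndat[, 1]), 2:4, drop = FALSE]
  el <- sect("Elements")
  ne <- as.integer(el[1])
  rows <- strsplit(el[-1], "\\s+")
  type_nn <- c("15" = 1L, "1" = 2L, "2" = 3L, "4" = 4L)
  parsed <- lapply(rows, function(r) {
    r <- as.integer(r)
    ntags <- r[3]
    list(type = r[2], phys = if (ntags >= 1) r[4] else NA_integer_,
         geom = if (ntags >= 2) r[5] else 0L,
         nodes = r[(4 + ntags):length(r)])
  })
  nnper <- vapply(parsed, function(p) length(p$nodes), integer(1))
  dim <- max(nnper) - 1L
  is_vol <- nnper == dim + 1L
  vols <- parsed[is_vol]; facs <- parsed[!is_vol]
  elems <- do.call(rbind, lapply(vols, `[[`, "nodes"))
  tissue <- vapply(vols, function(p) name_of(p$phys) %||% "WHITE", character(1))
  region <- vapply(vols, function(p) p$geom, integer(1))
  if (all(region == 0L)) region <- rep(1L, length(region))
  facets <- do.call(rbind, lapply(facs, `[[`, "nodes"))
  facet_tag <- vapply(facs, function(p) name_of(p$phys) %||% NA_character_, character(1))
  for (tag in c("SKULL", "VENTRICLE")) {
    if (!any(facet_tag == tag, na.rm = TRUE))
      stop("boundary tag ", tag, " not found")
  }
  scale <- if (units == "mm") 1e-3 else 1
  rid <- sort(unique(region))
  new_brain_mesh(dim, xyz[, seq_len(dim), drop = FALSE] * scale,
                 elems, facets, facet_tag,
                 tissue, match(region, rid), paste0("region_", rid))
}

# -- VTU / PVD -----------------------------------------------------------------

vtk_cell_type <- function(nn) switch(as.character(nn), "2" = 3L, "3" = 5L, "4" = 10L)

#' Write mesh and fields as ASCII VTU
#'
#' Fields whose length (or row count) equals the node count are written as
#' point data, those matching the element count as cell data; matrices with
#' `dim` columns become vector arrays (padded to 3 components).
#'
#' @param mesh a `brain_mesh`.
#' @param fields named list of numeric vectors/matrices (may be empty).
#' @param path output path (`.vtu`).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, fields = list(), path) {
  N <- nrow(mesh$nodes); M <- nrow(mesh$elems)
  pad3 <- function(x) cbind(x, matrix(0, nrow(x), 3 - ncol(x)))
  arr_xml <- function(name, x) {
    ncomp <- if (is.matrix(x)) ncol(x) else 1L
    vals <- if (is.matrix(x)) as.vector(t(x)) else x
    c(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              name, ncomp),
      paste(sprintf("%.17g", vals), collapse = " "),
      "</DataArray>")
  }
  is_point <- vapply(fields, function(x) (if (is.matrix(x)) nrow(x) else length(x)) == N,
                     logical(1))
  pf <- fields[is_point]; cf <- fields[!is_point]
  vecfix <- function(x) if (is.matrix(x) && ncol(x) == mesh$dim && mesh$dim < 3) pad3(x) else x
  out <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "<UnstructuredGrid>",
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', N, M),
    "<Points>", arr_xml("Points", pad3(mesh$nodes)), "</Points>",
    "<Cells>",
    '<DataArray type="Int32" Name="connectivity" format="ascii">',
    paste(as.vector(t(mesh$elems)) - 1L, collapse = " "),
    "</DataArray>",
    '<DataArray type="Int32" Name="offsets" format="ascii">',
    paste(seq_len(M) * ncol(mesh$elems), collapse = " "),
    "</DataArray>",
    '<DataArray type="UInt8" Name="types" format="ascii">',
    paste(rep(vtk_cell_type(ncol(mesh$elems)), M), collapse = " "),
    "</DataArray>",
    "</Cells>",
    "<PointData>",
    unlist(lapply(names(pf), function(nm) arr_xml(nm, vecfix(pf[[nm]])))),
    "</PointData>",
    "<CellData>",
    unlist(lapply(names(cf), function(nm) arr_xml(nm, vecfix(cf[[nm]])))),
    "</CellData>",
    "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  writeLines(out, path)
  invisible(path)
}

#' Read an ASCII VTU file written by [write_vtu()]
#'
#' @param path path to a `.vtu` file.
#' @return list with `nodes`, `elems`, `point_data`, `cell_data` (vector
#'   arrays as matrices, trailing zero components dropped to the mesh
#'   dimension inferred from the cell type).
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  get_arr <- function(node) {
    vals <- scan(text = xml2::xml_text(node), quiet = TRUE)
    ncomp <- as.integer(xml2::xml_attr(node, "NumberOfComponents"))
    if (!is.na(ncomp) && ncomp > 1) matrix(vals, ncol = ncomp, byrow = TRUE) else vals
  }
  pts <- get_arr(xml2::xml_find_first(piece, ".//Points/DataArray"))
  conn <- get_arr(xml2::xml_find_first(piece, './/Cells/DataArray[@Name="connectivity"]'))
  offs <- get_arr(xml2::xml_find_first(piece, './/Cells/DataArray[@Name="offsets"]'))
  nn <- offs[1]
  elems <- matrix(as.integer(conn) + 1L, ncol = nn, byrow = TRUE)
  dim <- nn - 1L
  nodes <- pts[, seq_len(max(dim, 2)), drop = FALSE]
  if (dim >= 2) nodes <- pts[, seq_len(dim), drop = FALSE]
  else nodes <- pts[, 1, drop = FALSE]
  grab <- function(xp) {
    nodeset <- xml2::xml_find_all(piece, xp)
    out <- lapply(nodeset, get_arr)
    names(out) <- xml2::xml_attr(nodeset, "Name")
    lapply(out, function(x) if (is.matrix(x)) x[, colSums(abs(x)) > 0 | seq_len(ncol(x)) <= dim,
                                                drop = FALSE] else x)
  }
  list(nodes = nodes, elems = elems,
       point_data = grab(".//PointData/DataArray"),
       cell_data = grab(".//CellData/DataArray"))
}

#' Write a PVD collection referencing a VTU time series
#'
#' @param vtu_paths character vector of VTU file names (relative to the PVD).
#' @param times numeric time stamps, s.
#' @param path output path (`.pvd`).
#' @return `path`, invisibly.
#' @export
write_pvd <- function(vtu_paths, times, path) {
  out <- c('<?xml version="1.0"?>',
           '<VTKFile type="Collection" version="0.1">',
           "<Collection>",
           sprintf('<DataSet timestep="%.17g" part="0" file="%s"/>', times, vtu_paths),
           "</Collection>", "</VTKFile>")
  writeLines(out, path)
  invisible(path)
}

#' Write a solution state as a VTU snapshot
#'
#' Emits one scalar array per pressure network, named `p_a` ... `p_g`, the
#' displacement vector `u`, plus `tissue` (1 = grey, 0 = white) and `region`
#' cell arrays.
#'
#' @param mesh a `brain_mesh`.
#' @param state a [field_state()].
#' @param path output path (`.vtu`).
#' @return `path`, invisibly.
#' @export
write_fields <- function(mesh, state, path) {
  fields <- c(
    setNames(lapply(seq_along(MPET_NETWORKS), function(i) state$p[, i]),
             paste0("p_", MPET_NETWORKS)),
    list(u = state$u,
         tissue = as.numeric(mesh$tissue == "GREY"),
         region = as.numeric(mesh$region)))
  write_vtu(mesh, fields, path)
}
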