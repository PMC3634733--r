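# Readers and writers: STL / PLY surfaces, legacy VTK / VTU volumes with
# region tags and node-set masks, Abaqus INP export.

fmt_num <- function(x) formatC(x, format = "g", digits = 9)

#' Write a surface mesh (STL or PLY by extension)
#'
#' @param mesh a `surface_mesh`.
#' @param path output path ending in .stl or .ply (ASCII).
#' @return the path, invisibly.
#' @export
write_surface <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path),
         ply = write_ply(mesh, path),
         stop("write_surface: unsupported extension '.", ext,
              "' (use .stl or .ply)"))
  invisible(path)
}

#' Read a surface mesh (STL or PLY by extension)
#'
#' @param path input path.
#' @return a `surface_mesh`.
#' @export
read_surface <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("read_surface: unsupported extension '.", ext,
              "' (use .stl or .ply)"))
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  n <- triangle_normals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid toothfem", con)
  for (k in seq_len(nrow(tr))) {
    writeLines(c(
      paste("facet normal", paste(fmt_num(n[k, ]), collapse = " ")),
      "  outer loop",
      paste("    vertex", paste(fmt_num(v[tr[k, 1], ]), collapse = " ")),
      paste("    vertex", paste(fmt_num(v[tr[k, 2], ]), collapse = " ")),
      paste("    vertex", paste(fmt_num(v[tr[k, 3], ]), collapse = " ")),
      "  endloop",
      "endfacet"), con)
  }
  writeLines("endsolid toothfem", con)
}

read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("read_stl: no vertex records in ", path)
  if (length(vl) %% 3 != 0) {
    stop("read_stl: vertex count not a multiple of 3 (truncated file?)")
  }
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(s) as.numeric(s[2:4]))
  pts <- do.call(rbind, nums)
  if (anyNA(pts)) stop("read_stl: malformed vertex line")
  key <- paste(pts[, 1], pts[, 2], pts[, 3], sep = "_")
  uid <- !duplicated(key)
  verts <- pts[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  tri <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, tri, validate = FALSE)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  lab <- mesh$facet_labels
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0")
  if (!is.null(lab)) {
    lv <- unique(lab)
    hdr <- c(hdr, paste0("comment facet_labels: ", paste(lv, collapse = ",")))
  }
  hdr <- c(hdr,
           paste("element vertex", nrow(v)),
           "property float x", "property float y", "property float z",
           paste("element face", nrow(tr)),
           "property list uchar int vertex_indices")
  if (!is.null(lab)) hdr <- c(hdr, "property int label")
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con)
  writeLines(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])), con)
  face <- paste(3, tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L)
  if (!is.null(lab)) face <- paste(face, match(lab, unique(lab)) - 1L)
  writeLines(face, con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", lines)
  if (is.na(end)) stop("read_ply: missing end_header in ", path)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)))
  if (!length(nv) || !length(nf)) stop("read_ply: missing element counts")
  lab_line <- grep("^comment facet_labels: ", hdr, value = TRUE)
  labels <- if (length(lab_line)) strsplit(sub("^comment facet_labels: ", "", lab_line), ",")[[1]] else NULL
  vl <- lines[end + seq_len(nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(s) as.numeric(s[1:3])))
  fl <- lines[end + nv + seq_len(nf)]
  frec <- strsplit(trimws(fl), "\\s+")
  tri <- do.call(rbind, lapply(frec, function(s) as.integer(s[2:4]) + 1L))
  facet_labels <- NULL
  if (!is.null(labels) && length(frec[[1]]) >= 5) {
    facet_labels <- labels[vapply(frec, function(s) as.integer(s[5]), integer(1)) + 1L]
  }
  surface_mesh(verts, tri, facet_labels = facet_labels, validate = FALSE)
}

#' Write a volume mesh (legacy VTK or VTU by extension)
#'
#' Region tags go out as cell data (`region_code`, with the code-to-name
#' table in the file header/comment), node sets as 0/1 point-data masks named
#' `set_<NAME>`. Optional nodal fields (e.g. displacement, sigma1) are written
#' as point data.
#'
#' @param mesh a `volume_mesh`.
#' @param path output path ending in .vtk or .vtu.
#' @param point_data optional named list of numeric vectors (length n) or
#'   n x k matrices to attach as point data.
#' @return the path, invisibly.
#' @export
write_volume <- function(mesh, path, point_data = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtk = write_vtk_legacy(mesh, path, point_data),
         vtu = write_vtu(mesh, path, point_data),
         stop("write_volume: unsupported extension '.", ext,
              "' (use .vtk or .vtu)"))
  invisible(path)
}

#' Read a volume mesh (legacy VTK or VTU by extension)
#'
#' @param path input path.
#' @return a `volume_mesh` (region tags and node sets restored when present).
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtk = read_vtk_legacy(path),
         vtu = read_vtu(path),
         stop("read_volume: unsupported extension '.", ext,
              "' (use .vtk or .vtu)"))
}

region_code_table <- function(mesh) {
  lev <- sort(unique(mesh$region))
  list(levels = lev, code = match(mesh$region, lev) - 1L)
}

write_vtk_legacy <- function(mesh, path, point_data = NULL) {
  rc <- region_code_table(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               paste0("toothfem mesh; regions=", paste(rc$levels, collapse = ",")),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(paste(fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
                   fmt_num(mesh$nodes[, 3])), con)
  writeLines(paste("CELLS", ne, 11 * ne), con)
  writeLines(do.call(paste, c(list(10L), as.data.frame(mesh$elements - 1L))), con)
  writeLines(paste("CELL_TYPES", ne), con)
  writeLines(as.character(rep(24L, ne)), con)
  writeLines(c(paste("CELL_DATA", ne),
               "SCALARS region_code int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(rc$code), con)
  npd <- length(mesh$node_sets) + length(point_data)
  if (npd > 0) {
    writeLines(paste("POINT_DATA", n), con)
    for (nm in names(mesh$node_sets)) {
      mask <- integer(n); mask[mesh$node_sets[[nm]]] <- 1L
      writeLines(c(paste0("SCALARS set_", nm, " int 1"),
                   "LOOKUP_TABLE default"), con)
      writeLines(as.character(mask), con)
    }
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(paste("VECTORS", nm, "double"), con)
        writeLines(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])), con)
      } else {
        writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"), con)
        writeLines(fmt_num(v), con)
      }
    }
  }
}

read_vtk_legacy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  regions_line <- grep("regions=", lines, value = TRUE)
  lev <- if (length(regions_line)) {
    strsplit(sub(".*regions=", "", regions_line[1]), ",")[[1]]
  } else NULL
  toks_at <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("read_vtk_legacy: no POINTS record in ", path)
  n <- as.integer(toks_at(ip)[2])
  pts <- scan(text = lines[(ip + 1):length(lines)], n = 3 * n, quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  ne <- as.integer(toks_at(ic)[2])
  cl <- scan(text = lines[(ic + 1):length(lines)], n = 11 * ne, quiet = TRUE)
  cl <- matrix(cl, ncol = 11, byrow = TRUE)
  if (any(cl[, 1] != 10)) stop("read_vtk_legacy: non-TET10 cell found")
  elements <- matrix(as.integer(cl[, -1] + 1L), ne, 10)
  ird <- grep("SCALARS region_code", lines)[1]
  region <- rep("DENTINE", ne)
  if (!is.na(ird)) {
    code <- scan(text = lines[(ird + 2):length(lines)], n = ne, quiet = TRUE)
    if (!is.null(lev)) region <- lev[code + 1L]
  }
  node_sets <- list()
  for (i in grep("^SCALARS set_", lines)) {
    nm <- sub("^SCALARS set_(\\S+) .*", "\\1", lines[i])
    mask <- scan(text = lines[(i + 2):length(lines)], n = n, quiet = TRUE)
    node_sets[[nm]] <- which(mask == 1)
  }
  volume_mesh(nodes, elements, region, node_sets)
}

write_vtu <- function(mesh, path, point_data = NULL) {
  rc <- region_code_table(mesh)
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("<?xml version=\"1.0\"?>")
  w("<!-- toothfem mesh; regions=", paste(rc$levels, collapse = ","), " -->")
  w("<VTKFile type=\"UnstructuredGrid\" version=\"0.1\" byte_order=\"LittleEndian\">")
  w("  <UnstructuredGrid>")
  w("    <Piece NumberOfPoints=\"", n, "\" NumberOfCells=\"", ne, "\">")
  w("      <Points>")
  w("        <DataArray type=\"Float64\" NumberOfComponents=\"3\" format=\"ascii\">")
  writeLines(paste(fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
                   fmt_num(mesh$nodes[, 3])), con)
  w("        </DataArray>")
  w("      </Points>")
  w("      <Cells>")
  w("        <DataArray type=\"Int64\" Name=\"connectivity\" format=\"ascii\">")
  writeLines(do.call(paste, as.data.frame(mesh$elements - 1L)), con)
  w("        </DataArray>")
  w("        <DataArray type=\"Int64\" Name=\"offsets\" format=\"ascii\">")
  writeLines(as.character(seq_len(ne) * 10L), con)
  w("        </DataArray>")
  w("        <DataArray type=\"UInt8\" Name=\"types\" format=\"ascii\">")
  writeLines(as.character(rep(24L, ne)), con)
  w("        </DataArray>")
  w("      </Cells>")
  w("      <CellData>")
  w("        <DataArray type=\"Int32\" Name=\"region_code\" format=\"ascii\">")
  writeLines(as.character(rc$code), con)
  w("        </DataArray>")
  w("      </CellData>")
  w("      <PointData>")
  for (nm in names(mesh$node_sets)) {
    mask <- integer(n); mask[mesh$node_sets[[nm]]] <- 1L
    w("        <DataArray type=\"Int32\" Name=\"set_", nm, "\" format=\"ascii\">")
    writeLines(as.character(mask), con)
    w("        </DataArray>")
  }
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    nc <- if (is.matrix(v)) ncol(v) else 1L
    w("        <DataArray type=\"Float64\" Name=\"", nm,
      "\" NumberOfComponents=\"", nc, "\" format=\"ascii\">")
    if (is.matrix(v)) {
      writeLines(do.call(paste, lapply(seq_len(nc), function(j) fmt_num(v[, j]))), con)
    } else {
      writeLines(fmt_num(v), con)
    }
    w("        </DataArray>")
  }
  w("      </PointData>")
  w("    </Piece>")
  w("  </UnstructuredGrid>")
  w("</VTKFile>")
}

read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  comment <- xml2::xml_find_first(doc, "//comment()")
  lev <- NULL
  if (!inherits(comment, "xml_missing")) {
    txt <- xml2::xml_text(comment)
    if (grepl("regions=", txt)) {
      lev <- strsplit(trimws(sub(".*regions=", "", txt)), ",")[[1]]
    }
  }
  arr <- function(xp) {
    node <- xml2::xml_find_first(doc, xp)
    if (inherits(node, "xml_missing")) return(NULL)
    scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  pts <- arr("//Points/DataArray")
  if (is.null(pts)) stop("read_vtu: no Points array in ", path)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- arr("//Cells/DataArray[@Name='connectivity']")
  elements <- matrix(as.integer(conn) + 1L, ncol = 10, byrow = TRUE)
  code <- arr("//CellData/DataArray[@Name='region_code']")
  region <- if (!is.null(code) && !is.null(lev)) lev[code + 1L] else rep("DENTINE", nrow(elements))
  node_sets <- list()
  for (nd in xml2::xml_find_all(doc, "//PointData/DataArray")) {
    nm <- xml2::xml_attr(nd, "Name")
    if (startsWith(nm, "set_")) {
      mask <- scan(text = xml2::xml_text(nd), quiet = TRUE)
      node_sets[[sub("^set_", "", nm)]] <- which(mask == 1)
    }
  }
  volume_mesh(nodes, elements, region, node_sets)
}

#' Export a model in Abaqus INP dialect (write-only)
#'
#' Nodes, C3D10 elements grouped by tissue ELSET, elastic materials (MPa),
#' zero-displacement boundary entries and concentrated nodal loads -- enough
#' to re-run the model in an external solver as a cross-check.
#'
#' @param mesh a `volume_mesh`.
#' @param materials named list of [material()] per region.
#' @param constraints a `constraint_set` (optional).
#' @param load_case a `load_case` (optional).
#' @param path output path (.inp).
#' @return the path, invisibly.
#' @export
write_inp <- function(mesh, materials, constraints = NULL, load_case = NULL,
                      path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("*HEADING")
  w("toothfem model export")
  w("*NODE")
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
                   fmt_num(mesh$nodes[, 3]), sep = ", "), con)
  eid <- 0L
  for (r in sort(unique(mesh$region))) {
    sel <- which(mesh$region == r)
    w("*ELEMENT, TYPE=C3D10, ELSET=", r)
    rows <- cbind(eid + seq_along(sel), mesh$elements[sel, , drop = FALSE])
    writeLines(apply(rows, 1, paste, collapse = ", "), con)
    eid <- eid + length(sel)
  }
  for (r in sort(unique(mesh$region))) {
    if (is.null(materials[[r]])) next
    w("*MATERIAL, NAME=", r)
    w("*ELASTIC")
    w(fmt_num(materials[[r]]$E * 1000), ", ", fmt_num(materials[[r]]$nu))
    w("*SOLID SECTION, ELSET=", r, ", MATERIAL=", r)
  }
  if (!is.null(constraints) && nrow(constraints)) {
    w("*BOUNDARY")
    writeLines(paste(constraints$node, constraints$axis, constraints$axis, "0.",
                     sep = ", "), con)
  }
  if (!is.null(load_case)) {
    loaded <- which(rowSums(load_case$forces != 0) > 0)
    w("*CLOAD")
    for (i in loaded) {
      for (ax in 1:3) {
        if (load_case$forces[i, ax] != 0) {
          w(i, ", ", ax, ", ", fmt_num(load_case$forces[i, ax]))
        }
      }
    }
  }
  invisible(path)
}
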