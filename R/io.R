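# Mesh and surface I/O: Gmsh MSH (v2.2 / v4.1 ASCII) input, VTU output,
# ASCII STL/PLY/OBJ triangle-surface input and output. All readers are
# ASCII-only and intentionally small; binary variants are out of scope.

#' Read a Gmsh MSH mesh into a labelled mesh
#'
#' Supports MSH format 2.2 and 4.1 (ASCII). Tetrahedra (element type 4) carry
#' a physical-group tag that is mapped to a tissue region through
#' `region_map`; triangles (element type 2) carry a physical tag mapped to a
#' boundary patch through `patch_map`. Elements whose tag has no mapping
#' raise a labelling error. Node coordinates are multiplied by `scale`
#' (use `1e-3` for meshes authored in millimetres; the package works in SI
#' metres).
#'
#' @param path path to an ASCII `.msh` file.
#' @param region_map named character vector: physical tag (as character) to
#'   region label for tetrahedra.
#' @param patch_map named character vector: physical tag to patch label for
#'   boundary triangles.
#' @param scale coordinate scale factor applied on load (default 1).
#' @param skin_thickness skin membrane thickness in metres.
#' @return a [labeled_mesh()].
#' @export
read_mesh <- function(path, region_map, patch_map, scale = 1,
                      skin_thickness = 1.5e-3) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  fmt_i <- match("$MeshFormat", lines)
  if (is.na(fmt_i)) stop("not a Gmsh MSH file: ", path, call. = FALSE)
  ver <- as.numeric(strsplit(trimws(lines[fmt_i + 1L]), "\\s+")[[1L]][1L])
  raw <- if (ver >= 4) read_msh41(lines) else read_msh22(lines)

  nodes <- raw$nodes * scale
  tet_tag <- as.character(raw$tet_tag)
  tri_tag <- as.character(raw$tri_tag)
  unmapped <- setdiff(unique(tet_tag), names(region_map))
  if (length(unmapped))
    stop("labelling error: no region mapping for physical tag(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  region <- unname(region_map[tet_tag])
  tris <- raw$tris
  patch <- NULL
  if (!is.null(tris) && nrow(tris)) {
    unmapped <- setdiff(unique(tri_tag), names(patch_map))
    if (length(unmapped))
      stop("labelling error: no patch mapping for physical tag(s): ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    patch <- unname(patch_map[tri_tag])
  } else {
    tris <- NULL
  }
  labeled_mesh(nodes, raw$tets, region, tris, patch,
               skin_thickness = skin_thickness)
}

# MSH 2.2: $Nodes (id x y z), $Elements (id type ntags tags... nodes...)
read_msh22 <- function(lines) {
  sec <- function(name) {
    i <- match(paste0("$", name), lines)
    j <- match(paste0("$End", name), lines)
    if (is.na(i) || is.na(j)) stop("MSH section missing: ", name, call. = FALSE)
    lines[(i + 1L):(j - 1L)]
  }
  nl <- sec("Nodes")
  nn <- as.integer(nl[1L])
  ntab <- matrix(scan(text = nl[-1L], quiet = TRUE), ncol = 4L, byrow = TRUE)
  ids <- as.integer(ntab[, 1L])
  nodes <- matrix(0, max(ids), 3L)
  nodes[ids, ] <- ntab[, 2:4]
  el <- sec("Elements")
  ne <- as.integer(el[1L])
  tets <- NULL; tet_tag <- integer(); tris <- NULL; tri_tag <- integer()
  for (ln in el[-1L]) {
    f <- as.integer(strsplit(trimws(ln), "\\s+")[[1L]])
    type <- f[2L]; ntags <- f[3L]
    tag <- if (ntags >= 1L) f[4L] else NA_integer_
    conn <- f[(4L + ntags):length(f)]
    if (type == 4L) {
      if (is.na(tag)) stop("labelling error: untagged tetrahedron",
                           call. = FALSE)
      tets <- rbind(tets, conn); tet_tag <- c(tet_tag, tag)
    } else if (type == 2L) {
      if (is.na(tag)) stop("labelling error: untagged triangle", call. = FALSE)
      tris <- rbind(tris, conn); tri_tag <- c(tri_tag, tag)
    }
  }
  if (is.null(tets)) stop("MSH file contains no tetrahedra", call. = FALSE)
  # compress node ids to the used range
  list(nodes = nodes, tets = unname(tets), tet_tag = tet_tag,
       tris = unname(tris), tri_tag = tri_tag)
}

# MSH 4.1: entity blocks; physical tag is taken from the entity's physical
# group (first physical tag of the entity), falling back to the entity tag
read_msh41 <- function(lines) {
  sec_bounds <- function(name) {
    i <- match(paste0("$", name), lines)
    j <- match(paste0("$End", name), lines)
    if (is.na(i) || is.na(j)) stop("MSH section missing: ", name, call. = FALSE)
    c(i + 1L, j - 1L)
  }
  num <- function(ln) scan(text = ln, quiet = TRUE)

  # entity -> physical tag map from $Entities (dim 2 and 3)
  phys <- list(`2` = integer(), `3` = integer())
  if (!is.na(match("$Entities", lines))) {
    b <- sec_bounds("Entities")
    hdr <- num(lines[b[1L]])
    np <- hdr[1L]; nc <- hdr[2L]; ns <- hdr[3L]; nv <- hdr[4L]
    at <- b[1L] + 1L
    at <- at + np + nc                       # skip points and curves
    for (k in seq_len(ns)) {
      f <- num(lines[at]); at <- at + 1L
      nphys <- f[8L]
      phys$`2`[as.character(as.integer(f[1L]))] <-
        if (nphys >= 1) as.integer(f[9L]) else as.integer(f[1L])
    }
    for (k in seq_len(nv)) {
      f <- num(lines[at]); at <- at + 1L
      nphys <- f[8L]
      phys$`3`[as.character(as.integer(f[1L]))] <-
        if (nphys >= 1) as.integer(f[9L]) else as.integer(f[1L])
    }
  }

  b <- sec_bounds("Nodes")
  hdr <- num(lines[b[1L]])
  nblocks <- hdr[1L]; ntot <- hdr[2L]; maxtag <- hdr[4L]
  nodes <- matrix(0, maxtag, 3L)
  at <- b[1L] + 1L
  for (k in seq_len(nblocks)) {
    bh <- num(lines[at]); at <- at + 1L
    nb <- bh[4L]
    if (nb == 0) next
    ids <- as.integer(vapply(lines[at:(at + nb - 1L)],
                             function(x) num(x)[1L], 0))
    at <- at + nb
    xyz <- t(vapply(lines[at:(at + nb - 1L)],
                    function(x) num(x)[1:3], numeric(3L)))
    at <- at + nb
    nodes[ids, ] <- xyz
  }

  b <- sec_bounds("Elements")
  hdr <- num(lines[b[1L]])
  nblocks <- hdr[1L]
  at <- b[1L] + 1L
  tets <- NULL; tet_tag <- integer(); tris <- NULL; tri_tag <- integer()
  for (k in seq_len(nblocks)) {
    bh <- num(lines[at]); at <- at + 1L
    dim <- as.integer(bh[1L]); ent <- as.integer(bh[2L])
    type <- as.integer(bh[3L]); nb <- as.integer(bh[4L])
    if (nb == 0) next
    rows <- lines[at:(at + nb - 1L)]; at <- at + nb
    if (type == 4L) {
      tag <- phys$`3`[as.character(ent)]
      if (is.na(tag) || is.null(tag))
        stop("labelling error: tetrahedron block on entity ", ent,
             " has no physical tag", call. = FALSE)
      conn <- t(vapply(rows, function(x) num(x)[2:5], numeric(4L)))
      tets <- rbind(tets, conn); tet_tag <- c(tet_tag, rep(tag, nb))
    } else if (type == 2L) {
      tag <- phys$`2`[as.character(ent)]
      if (is.na(tag) || is.null(tag))
        stop("labelling error: triangle block on entity ", ent,
             " has no physical tag", call. = FALSE)
      conn <- t(vapply(rows, function(x) num(x)[2:4], numeric(3L)))
      tris <- rbind(tris, conn); tri_tag <- c(tri_tag, rep(tag, nb))
    }
  }
  if (is.null(tets)) stop("MSH file contains no tetrahedra", call. = FALSE)
  list(nodes = nodes, tets = unname(tets), tet_tag = tet_tag,
       tris = unname(tris), tri_tag = tri_tag)
}

#' Write a mesh (with optional fields) as ASCII VTU
#'
#' Writes an XML VTK unstructured grid with the element region label always
#' attached as cell data, plus any user point/cell data arrays.
#'
#' @param mesh a [labeled_mesh()].
#' @param path output path (`.vtu`).
#' @param point_data named list of per-node numeric vectors or nodes-x-k
#'   matrices.
#' @param cell_data named list of per-element numeric vectors.
#' @param displacement optional nodal displacement added to coordinates
#'   before writing (deformed configuration).
#' @return invisibly `path`.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list(),
                      displacement = NULL) {
  nodes <- mesh$nodes
  if (!is.null(displacement)) nodes <- nodes + as.matrix(displacement)
  nn <- nrow(nodes); ne <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  fmt <- function(x) paste(format(x, digits = 17, scientific = TRUE,
                                  trim = TRUE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', nn,
    '" NumberOfCells="', ne, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(fmt(t(nodes)))
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(t(mesh$tets) - 1L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(seq_len(ne) * 4L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(10L, ne), collapse = " "))
  w('</DataArray></Cells>')
  w('<CellData>')
  w('<DataArray type="Int32" Name="region" format="ascii">')
  w(paste(match(mesh$tet_region, REGION_LEVELS), collapse = " "))
  w('</DataArray>')
  for (nm in names(cell_data)) {
    w('<DataArray type="Float64" Name="', nm, '" format="ascii">')
    w(fmt(cell_data[[nm]]))
    w('</DataArray>')
  }
  w('</CellData>')
  w('<PointData>')
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    ncomp <- if (is.matrix(v)) ncol(v) else 1L
    w('<DataArray type="Float64" Name="', nm, '" NumberOfComponents="',
      ncomp, '" format="ascii">')
    w(fmt(if (is.matrix(v)) t(v) else v))
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Triangle surface
#'
#' Minimal triangulated-surface container used by the evaluation module.
#'
#' @param vertices numeric matrix, one row per vertex (metres).
#' @param faces integer matrix, one row per triangle (vertex indices).
#' @return object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (nrow(faces) && max(faces) > nrow(vertices))
    stop("face index out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat("<tri_surface> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces\n", sep = "")
  invisible(x)
}

#' Extract a boundary patch as a triangle surface
#'
#' @param mesh a [labeled_mesh()].
#' @param patch patch label(s) to extract (default `"skin"`).
#' @param displacement optional nodal displacement (deformed surface).
#' @return a [tri_surface()] with vertices renumbered to the patch.
#' @export
extract_surface <- function(mesh, patch = "skin", displacement = NULL) {
  keep <- mesh$tri_patch %in% patch
  if (!any(keep)) stop("no boundary triangles with patch ",
                       paste(patch, collapse = "/"), call. = FALSE)
  tris <- mesh$boundary_tris[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tris)))
  remap <- integer(nrow(mesh$nodes))
  remap[used] <- seq_along(used)
  nodes <- mesh$nodes
  if (!is.null(displacement)) nodes <- nodes + as.matrix(displacement)
  tri_surface(nodes[used, , drop = FALSE],
              matrix(remap[tris], ncol = 3L))
}

#' Read a triangle surface from ASCII PLY, STL or OBJ
#'
#' @param path file path; format inferred from the extension.
#' @return a [tri_surface()].
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         stl = read_stl(path),
         obj = read_obj(path),
         stop("unsupported surface format: .", ext, call. = FALSE))
}

#' Write a triangle surface to ASCII PLY, STL or OBJ
#'
#' @param surface a [tri_surface()].
#' @param path output path; format inferred from the extension.
#' @param vertex_scalar optional named list with one numeric vector per
#'   vertex, written as extra PLY vertex properties (PLY only).
#' @return invisibly `path`.
#' @export
write_surface <- function(surface, path, vertex_scalar = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(surface, path, vertex_scalar),
         stl = write_stl(surface, path),
         obj = write_obj(surface, path),
         stop("unsupported surface format: .", ext, call. = FALSE))
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1L], "ply")) stop("not a PLY file", call. = FALSE)
  endh <- match("end_header", trimws(lines))
  hdr <- lines[1:endh]
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", hdr, value = TRUE)[1L]))
  body <- lines[(endh + 1L):length(lines)]
  vt <- matrix(scan(text = body[1:nv], quiet = TRUE), nrow = nv, byrow = TRUE)
  fl <- body[(nv + 1L):(nv + nf)]
  fc <- t(vapply(fl, function(x) {
    f <- as.integer(strsplit(trimws(x), "\\s+")[[1L]])
    if (f[1L] != 3L) stop("non-triangular PLY face", call. = FALSE)
    f[2:4]
  }, integer(3L)))
  tri_surface(vt[, 1:3, drop = FALSE], unname(fc) + 1L)
}

write_ply <- function(surface, path, vertex_scalar = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(surface$vertices); nf <- nrow(surface$faces)
  cat("ply\nformat ascii 1.0\n", file = con)
  cat("element vertex ", nv, "\n", sep = "", file = con)
  cat("property float x\nproperty float y\nproperty float z\n", file = con)
  for (nm in names(vertex_scalar))
    cat("property float ", nm, "\n", sep = "", file = con)
  cat("element face ", nf, "\n", sep = "", file = con)
  cat("property list uchar int vertex_indices\nend_header\n", file = con)
  vt <- surface$vertices
  for (nm in names(vertex_scalar)) vt <- cbind(vt, vertex_scalar[[nm]])
  utils::write.table(format(vt, digits = 9, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(3L, surface$faces - 1L), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_stl <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^vertex ", lines, value = TRUE)
  vt <- matrix(scan(text = sub("^vertex ", "", vl), quiet = TRUE),
               ncol = 3L, byrow = TRUE)
  if (nrow(vt) %% 3L != 0L) stop("malformed STL", call. = FALSE)
  # weld duplicate vertices
  key <- apply(vt, 1L, paste, collapse = ",")
  uid <- !duplicated(key)
  map <- match(key, key[uid])
  tri_surface(vt[uid, , drop = FALSE],
              matrix(map, ncol = 3L, byrow = TRUE))
}

write_stl <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- surface$vertices; f <- surface$faces
  cat("solid surface\n", file = con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1L], ]; b <- v[f[i, 2L], ]; c_ <- v[f[i, 3L], ]
    n <- c((b - a)[2L] * (c_ - a)[3L] - (b - a)[3L] * (c_ - a)[2L],
           (b - a)[3L] * (c_ - a)[1L] - (b - a)[1L] * (c_ - a)[3L],
           (b - a)[1L] * (c_ - a)[2L] - (b - a)[2L] * (c_ - a)[1L])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    cat("facet normal ", paste(n, collapse = " "), "\n", sep = "", file = con)
    cat("outer loop\n", file = con)
    cat("vertex ", paste(a, collapse = " "), "\n", sep = "", file = con)
    cat("vertex ", paste(b, collapse = " "), "\n", sep = "", file = con)
    cat("vertex ", paste(c_, collapse = " "), "\n", sep = "", file = con)
    cat("endloop\nendfacet\n", file = con)
  }
  cat("endsolid surface\n", file = con)
  invisible(path)
}

read_obj <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  vt <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE),
               ncol = 3L, byrow = TRUE)
  fc <- t(vapply(fl, function(x) {
    toks <- strsplit(sub("^f ", "", x), "\\s+")[[1L]]
    if (length(toks) != 3L) stop("non-triangular OBJ face", call. = FALSE)
    as.integer(sub("/.*", "", toks))
  }, integer(3L)))
  tri_surface(vt, unname(fc))
}

write_obj <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(cbind("v", format(surface$vertices, digits = 9,
                                       trim = TRUE)),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind("f", surface$faces), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
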