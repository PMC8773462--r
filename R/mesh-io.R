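# Mesh interchange: Gmsh MSH 2.2 ASCII and TetGen-style .node/.ele(/.face)
# pairs, plus a legacy-VTK unstructured-grid writer for simulation snapshots.
# Node indices are 1-based in both dialects.

GMSH_REGION_TAG_BASE <- 1L     # volume physical tags: 1, 2, ... per region
GMSH_FACESET_TAG_BASE <- 100L  # surface physical tags: 101, 102, ...

#' Write a tetrahedral mesh to disk
#'
#' Supported formats: `"msh"` (Gmsh v2.2 ASCII; tetrahedra carry a physical
#' volume tag per region, tagged boundary faces are written as triangle
#' elements with physical surface tags and named in `$PhysicalNames`) and
#' `"tetgen"` (TetGen-style `.node`/`.ele` pair plus a `.face` file with
#' boundary markers; `path` is the basename without extension).
#'
#' @param mesh a `tet_mesh`.
#' @param path output path (for `"tetgen"`, the basename).
#' @param format `"msh"` or `"tetgen"`; default guessed from the extension.
#' @return `invisible(path)`.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  format <- format %||% guess_mesh_format(path)
  switch(format,
         msh = write_msh(mesh, path),
         tetgen = write_tetgen(mesh, path),
         stop("unknown mesh format '", format, "' (use 'msh' or 'tetgen')"))
  invisible(path)
}

#' Read a tetrahedral mesh from disk
#'
#' Counterpart of [write_mesh()]. If the file carries no boundary-surface
#' tags, the surface faces are auto-classified into `"plasma_membrane"`
#' (outer) and `"perinuclear"` (inner) by distance of the face centroid from
#' the domain centroid, with a warning.
#'
#' @param path input path (for `"tetgen"`, the basename without extension).
#' @param format `"msh"` or `"tetgen"`; default guessed from the extension.
#' @return a `tet_mesh`.
#' @export
read_mesh <- function(path, format = NULL) {
  format <- format %||% guess_mesh_format(path)
  switch(format,
         msh = read_msh(path),
         tetgen = read_tetgen(path),
         stop("unknown mesh format '", format, "' (use 'msh' or 'tetgen')"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "msh") return("msh")
  if (ext %in% c("", "node", "ele")) return("tetgen")
  ext
}

num <- function(x) formatC(x, format = "g", digits = 17)

write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  regions <- sort(unique(mesh$region))
  fs_names <- names(mesh$face_sets)
  wl <- function(...) writeLines(c(...), con)
  wl("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  wl("$PhysicalNames", as.character(length(regions) + length(fs_names)))
  for (i in seq_along(fs_names))
    wl(sprintf("2 %d \"%s\"", GMSH_FACESET_TAG_BASE + i, fs_names[i]))
  for (i in seq_along(regions))
    wl(sprintf("3 %d \"%s\"", GMSH_REGION_TAG_BASE + i - 1L, regions[i]))
  wl("$EndPhysicalNames")
  wl("$Nodes", as.character(nrow(mesh$nodes)))
  wl(paste(seq_len(nrow(mesh$nodes)), num(mesh$nodes[, 1]),
           num(mesh$nodes[, 2]), num(mesh$nodes[, 3])))
  wl("$EndNodes")
  ntri <- sum(vapply(mesh$face_sets, nrow, integer(1)))
  wl("$Elements", as.character(nrow(mesh$elements) + ntri))
  eid <- 0L
  lines <- character(0)
  for (i in seq_along(fs_names)) {
    tri <- face_set_triples(mesh, mesh$face_sets[[i]])
    tag <- GMSH_FACESET_TAG_BASE + i
    ids <- eid + seq_len(nrow(tri))
    lines <- c(lines, paste(ids, 2, 2, tag, tag, tri[, 1], tri[, 2], tri[, 3]))
    eid <- eid + nrow(tri)
  }
  rtag <- match(mesh$region, regions) + GMSH_REGION_TAG_BASE - 1L
  ids <- eid + seq_len(nrow(mesh$elements))
  lines <- c(lines, paste(ids, 4, 2, rtag, rtag, mesh$elements[, 1],
                          mesh$elements[, 2], mesh$elements[, 3],
                          mesh$elements[, 4]))
  wl(lines)
  wl("$EndElements")
}

msh_section <- function(lines, name) {
  beg <- which(lines == paste0("$", name))
  end <- which(lines == paste0("$End", name))
  if (length(beg) != 1 || length(end) != 1 || end <= beg)
    stop("malformed MSH file: missing or unbalanced $", name, " section")
  lines[(beg + 1):(end - 1)]
}

read_msh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path)
  fmt <- strsplit(trimws(msh_section(lines, "MeshFormat")[1]), "\\s+")[[1]]
  if (!startsWith(fmt[1], "2"))
    stop("unsupported MSH version ", fmt[1], " (only v2.2 ASCII)")

  phys <- list()
  if (any(lines == "$PhysicalNames")) {
    pn <- msh_section(lines, "PhysicalNames")
    for (l in pn[-1]) {
      p <- strsplit(trimws(l), "\\s+")[[1]]
      phys[[p[2]]] <- gsub("\"", "", paste(p[-(1:2)], collapse = " "))
    }
  }

  nl <- msh_section(lines, "Nodes")
  nn <- as.integer(nl[1])
  ntab <- utils::read.table(text = nl[-1], col.names = c("id", "x", "y", "z"))
  if (nrow(ntab) != nn) stop("MSH $Nodes: header count ", nn,
                             " but ", nrow(ntab), " node records")
  nodes <- unname(as.matrix(ntab[order(ntab$id), c("x", "y", "z")]))
  if (!all(sort(ntab$id) == seq_len(nn)))
    stop("MSH $Nodes: node ids are not contiguous 1..", nn)

  el <- msh_section(lines, "Elements")
  ne <- as.integer(el[1])
  recs <- strsplit(trimws(el[-1]), "\\s+")
  if (length(recs) != ne) stop("MSH $Elements: header count ", ne,
                               " but ", length(recs), " element records")
  tets <- list(); ttag <- integer(0)
  tris <- list(); stag <- integer(0)
  for (k in seq_along(recs)) {
    r <- suppressWarnings(as.integer(recs[[k]]))
    if (anyNA(r) || length(r) < 4)
      stop("MSH $Elements: malformed record ", k, ": '",
           paste(recs[[k]], collapse = " "), "'")
    type <- r[2]; ntags <- r[3]
    nds <- r[(4 + ntags):length(r)]
    tag <- if (ntags >= 1) r[4] else NA_integer_
    if (type == 4L) {
      if (length(nds) != 4) stop("MSH tetrahedron record ", k,
                                 " has ", length(nds), " nodes")
      tets[[length(tets) + 1]] <- nds; ttag <- c(ttag, tag)
    } else if (type == 2L) {
      if (length(nds) != 3) stop("MSH triangle record ", k,
                                 " has ", length(nds), " nodes")
      tris[[length(tris) + 1]] <- nds; stag <- c(stag, tag)
    } # other element types ignored
  }
  if (!length(tets)) stop("MSH file contains no tetrahedra")
  elements <- do.call(rbind, tets)
  if (any(elements < 1 | elements > nn))
    stop("MSH element with out-of-range node index")
  region <- vapply(as.character(ttag), function(tg)
    phys[[tg]] %||% "cytosol", character(1))

  face_sets <- list()
  if (length(tris)) {
    tri <- do.call(rbind, tris)
    if (any(tri < 1 | tri > nn))
      stop("MSH surface triangle with out-of-range node index")
    labs <- vapply(as.character(stag), function(tg)
      phys[[tg]] %||% paste0("surface_", tg), character(1))
    for (lb in unique(labs))
      face_sets[[lb]] <- tri[labs == lb, , drop = FALSE]
  }
  mesh <- tet_mesh(nodes, elements, face_sets = face_sets, region = region)
  if (!length(face_sets)) mesh <- auto_classify_surface(mesh)
  mesh
}

write_tetgen <- function(mesh, path) {
  base <- sub("\\.(node|ele|face)$", "", path)
  n <- nrow(mesh$nodes)
  writeLines(c(paste(n, 3, 0, 0),
               paste(seq_len(n), num(mesh$nodes[, 1]), num(mesh$nodes[, 2]),
                     num(mesh$nodes[, 3]))),
             paste0(base, ".node"))
  m <- nrow(mesh$elements)
  regions <- sort(unique(mesh$region))
  writeLines(c(paste(m, 4, 1),
               paste(seq_len(m), mesh$elements[, 1], mesh$elements[, 2],
                     mesh$elements[, 3], mesh$elements[, 4],
                     match(mesh$region, regions))),
             paste0(base, ".ele"))
  fs_names <- names(mesh$face_sets)
  ft <- lapply(seq_along(fs_names), function(i) {
    cbind(face_set_triples(mesh, mesh$face_sets[[i]]),
          GMSH_FACESET_TAG_BASE + i)
  })
  ft <- do.call(rbind, ft)
  if (!is.null(ft)) {
    hdr <- paste(nrow(ft), 1)
    cmts <- paste0("# marker ", GMSH_FACESET_TAG_BASE + seq_along(fs_names),
                   " = ", fs_names)
    writeLines(c(cmts, hdr,
                 paste(seq_len(nrow(ft)), ft[, 1], ft[, 2], ft[, 3], ft[, 4])),
               paste0(base, ".face"))
  }
}

read_tetgen <- function(path) {
  base <- sub("\\.(node|ele|face)$", "", path)
  npath <- paste0(base, ".node"); epath <- paste0(base, ".ele")
  if (!file.exists(npath)) stop("mesh file not found: ", npath)
  if (!file.exists(epath)) stop("mesh file not found: ", epath)
  strip <- function(p) {
    ln <- trimws(readLines(p))
    ln <- sub("#.*$", "", ln)
    ln[nzchar(trimws(ln))]
  }
  nl <- strip(npath)
  hdr <- as.numeric(strsplit(nl[1], "\\s+")[[1]])
  nn <- hdr[1]
  ntab <- utils::read.table(text = nl[-1])
  if (nrow(ntab) != nn)
    stop(".node: header says ", nn, " nodes, found ", nrow(ntab))
  one_based <- min(ntab[, 1]) == 1
  nodes <- unname(as.matrix(ntab[order(ntab[, 1]), 2:4]))

  el <- strip(epath)
  ehdr <- as.numeric(strsplit(el[1], "\\s+")[[1]])
  etab <- utils::read.table(text = el[-1])
  if (nrow(etab) != ehdr[1])
    stop(".ele: header says ", ehdr[1], " elements, found ", nrow(etab))
  elems <- as.matrix(etab[order(etab[, 1]), 2:5])
  if (!one_based) elems <- elems + 1L
  if (any(elems < 1 | elems > nn))
    stop(".ele: element with out-of-range node index")
  region <- if (ncol(etab) >= 6) paste0("region_", etab[order(etab[, 1]), 6])
            else NULL
  if (!is.null(region) && length(unique(region)) == 1) region <- NULL

  face_sets <- list()
  fpath <- paste0(base, ".face")
  if (file.exists(fpath)) {
    fl <- readLines(fpath)
    markers <- list()
    for (l in grep("^# marker", fl, value = TRUE)) {
      mm <- regmatches(l, regexec("marker\\s+(\\d+)\\s*=\\s*(\\S+)", l))[[1]]
      if (length(mm) == 3) markers[[mm[2]]] <- mm[3]
    }
    fls <- strip(fpath)
    ftab <- utils::read.table(text = fls[-1])
    tri <- as.matrix(ftab[, 2:4])
    if (!one_based) tri <- tri + 1L
    mk <- if (ncol(ftab) >= 5) as.character(ftab[, 5])
          else rep("0", nrow(ftab))
    for (u in unique(mk)) {
      lb <- markers[[u]] %||% paste0("surface_", u)
      face_sets[[lb]] <- tri[mk == u, , drop = FALSE]
    }
  }
  mesh <- tet_mesh(nodes, elems, face_sets = face_sets, region = region)
  if (!length(face_sets)) mesh <- auto_classify_surface(mesh)
  mesh
}

# Fallback boundary classification for untagged imports: faces whose
# centroid is farther from the domain centroid than the midpoint of the
# observed range are outer ("plasma_membrane"), the rest "perinuclear".
auto_classify_surface <- function(mesh) {
  bd <- boundary_faces(mesh)
  if (!nrow(bd)) return(mesh)
  ctr <- colMeans(mesh$nodes)
  cen <- (mesh$nodes[bd$n1, , drop = FALSE] +
          mesh$nodes[bd$n2, , drop = FALSE] +
          mesh$nodes[bd$n3, , drop = FALSE]) / 3
  d <- sqrt(rowSums((cen - rep(ctr, each = nrow(cen)))^2))
  thr <- (min(d) + max(d)) / 2
  outer <- d >= thr
  warning("untagged surface: auto-classified ", sum(outer),
          " outer and ", sum(!outer),
          " inner boundary faces by centroid distance")
  fs <- list()
  if (any(outer))
    fs$plasma_membrane <- bd[outer, c("element", "face")]
  if (any(!outer))
    fs$perinuclear <- bd[!outer, c("element", "face")]
  mesh$face_sets <- lapply(fs, function(x) resolve_face_set(mesh, x))
  mesh
}

#' Write a concentration field snapshot as a legacy VTK unstructured grid
#'
#' ASCII legacy `.vtk` with the tetrahedral connectivity and one point-data
#' scalar array (default name `"cAMP_uM"`).
#'
#' @param mesh a `tet_mesh`.
#' @param values numeric vector, one value per node (uM); omit for geometry
#'   only.
#' @param path output `.vtk` path.
#' @param name scalar array name.
#' @export
write_vtk <- function(mesh, path, values = NULL, name = "cAMP_uM") {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  if (!is.null(values) && length(values) != n)
    stop("values must have one entry per node")
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "campfem snapshot", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(paste("POINTS", n, "double"))
  wl(paste(num(mesh$nodes[, 1]), num(mesh$nodes[, 2]), num(mesh$nodes[, 3])))
  wl(paste("CELLS", m, 5 * m))
  wl(paste(4, mesh$elements[, 1] - 1L, mesh$elements[, 2] - 1L,
           mesh$elements[, 3] - 1L, mesh$elements[, 4] - 1L))
  wl(paste("CELL_TYPES", m))
  wl(as.character(rep(10L, m)))
  if (!is.null(values)) {
    wl(paste("POINT_DATA", n))
    wl(paste("SCALARS", name, "double", 1), "LOOKUP_TABLE default")
    wl(num(values))
  }
  invisible(path)
}
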