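# The tet_mesh container: nodes, tetrahedral connectivity, tagged boundary
# face sets and per-element region tags.

#' Construct a tetrahedral mesh of a cellular geometry
#'
#' A `tet_mesh` holds node coordinates (um), four-node tetrahedral
#' connectivity, named boundary face sets (references to element local
#' faces), and a region tag per element. Elements are canonically reoriented
#' to positive signed volume on construction; boundary face references are
#' given as node triples and resolved against the reoriented elements, so
#' they survive the reorientation.
#'
#' @param nodes numeric n x 3 matrix of coordinates in um.
#' @param elements integer m x 4 matrix of node indices (1-based).
#' @param face_sets named list; each entry either an f x 3 matrix of node
#'   triples lying on the mesh surface, or a data.frame with columns
#'   `element`, `face` (local face id 1..4). Conventional labels are
#'   `"plasma_membrane"` (outer surface) and `"perinuclear"` (cavity
#'   surface).
#' @param region character vector of length m of per-element region tags;
#'   default `"cytosol"`.
#' @param merge_tol node-duplication tolerance, relative to the bounding-box
#'   diagonal.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elements, face_sets = list(), region = NULL,
                     merge_tol = 1e-9) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  dimnames(elements) <- NULL
  stopifnot(ncol(nodes) == 3, ncol(elements) == 4)
  n <- nrow(nodes); m <- nrow(elements)
  if (any(is.na(nodes)) || any(is.na(elements)))
    stop("mesh contains NA coordinates or connectivity")
  if (any(elements < 1L) || any(elements > n))
    stop("element connectivity references node indices outside 1..", n)
  if (any(apply(elements, 1, anyDuplicated) > 0))
    stop("element with repeated node indices")

  diag_len <- sqrt(sum((apply(nodes, 2, max) - apply(nodes, 2, min))^2))
  if (n > 1) {
    key <- round(nodes / max(diag_len * merge_tol, .Machine$double.eps)) |>
      apply(1, paste, collapse = ",")
    if (anyDuplicated(key))
      stop("duplicate nodes within merge tolerance (",
           sum(duplicated(key)), " coincident)")
  }

  elements <- orient_elements(nodes, elements)

  if (is.null(region)) region <- rep("cytosol", m)
  stopifnot(length(region) == m)

  mesh <- structure(list(nodes = nodes, elements = elements,
                         face_sets = list(), region = as.character(region)),
                    class = "tet_mesh")
  if (length(face_sets)) {
    stopifnot(!is.null(names(face_sets)), all(nzchar(names(face_sets))))
    mesh$face_sets <- lapply(face_sets, function(fs) resolve_face_set(mesh, fs))
  }
  mesh
}

# Reorient every element to positive signed volume (swap local nodes 3,4).
# Idempotent. Degenerate elements are reported with their index.
orient_elements <- function(nodes, elements) {
  for (e in seq_len(nrow(elements))) {
    sv <- tet_signed_volume(nodes[elements[e, ], , drop = FALSE])
    if (sv < 0) elements[e, 3:4] <- elements[e, c(4L, 3L)]
  }
  elements
}

# Resolve a face-set specification to a data.frame(element, face) against the
# mesh's (already reoriented) elements.
resolve_face_set <- function(mesh, fs) {
  if (is.data.frame(fs)) {
    stopifnot(all(c("element", "face") %in% names(fs)))
    bad <- fs$element < 1 | fs$element > nrow(mesh$elements) |
      fs$face < 1 | fs$face > 4
    if (any(bad)) stop("face set references invalid element/local-face ids")
    return(data.frame(element = as.integer(fs$element),
                      face = as.integer(fs$face)))
  }
  fs <- as.matrix(fs)
  stopifnot(ncol(fs) == 3)
  lut <- element_face_table(mesh$elements)
  want <- face_key(fs)
  hit <- match(want, lut$key)
  if (anyNA(hit))
    stop(sum(is.na(hit)), " face-set triples do not match any element face")
  data.frame(element = lut$element[hit], face = lut$face[hit])
}

# All 4m (element, local face) records with a sorted-triple key.
element_face_table <- function(elements) {
  m <- nrow(elements)
  tri <- matrix(0L, nrow = 4L * m, ncol = 3)
  for (f in 1:4) {
    rows <- seq.int(f, by = 4L, length.out = m)
    tri[rows, ] <- elements[, TET_LOCAL_FACES[f, ], drop = FALSE]
  }
  list(element = rep(seq_len(m), each = 4), face = rep(1:4, times = m),
       key = face_key(tri), tri = tri)
}

face_key <- function(tri) {
  lo <- pmin(tri[, 1], tri[, 2], tri[, 3])
  hi <- pmax(tri[, 1], tri[, 2], tri[, 3])
  paste(lo, tri[, 1] + tri[, 2] + tri[, 3] - lo - hi, hi, sep = "_")
}

#' Extract the boundary faces of a mesh
#'
#' A face is on the boundary iff it belongs to exactly one element; interior
#' faces are shared by exactly two.
#'
#' @param mesh a `tet_mesh`.
#' @return data.frame with columns `element`, `face` (local id), and `n1`,
#'   `n2`, `n3` (the face's node indices in element-local order).
#' @export
boundary_faces <- function(mesh) {
  lut <- element_face_table(mesh$elements)
  cnt <- table(lut$key)
  if (any(cnt > 2)) stop("non-manifold mesh: a face shared by >2 elements")
  on_bd <- cnt[lut$key] == 1
  tri <- lut$tri[on_bd, , drop = FALSE]
  data.frame(element = lut$element[on_bd], face = lut$face[on_bd],
             n1 = tri[, 1], n2 = tri[, 2], n3 = tri[, 3])
}

# Node triples (in local orientation) for a resolved face set.
face_set_triples <- function(mesh, fs) {
  t(vapply(seq_len(nrow(fs)), function(i) {
    mesh$elements[fs$element[i], TET_LOCAL_FACES[fs$face[i], ]]
  }, integer(3)))
}

#' Validate the structural invariants of a mesh
#'
#' Checks positive element volumes, boundary-face consistency of the tagged
#' face sets (every tagged face on the surface, each surface face tagged at
#' most once), and — when `partition = TRUE` — that the face sets together
#' cover the whole boundary.
#'
#' @param mesh a `tet_mesh`.
#' @param partition require the face sets to partition the surface.
#' @return `invisible(TRUE)`; stops with a message on violation.
#' @export
validate_mesh <- function(mesh, partition = length(mesh$face_sets) > 0) {
  stopifnot(inherits(mesh, "tet_mesh"))
  vols <- element_volumes(mesh)
  if (any(vols <= 0)) stop("element with non-positive volume after reorientation")
  bd <- boundary_faces(mesh)
  bd_keys <- face_key(as.matrix(bd[, c("n1", "n2", "n3")]))
  tagged <- character(0)
  for (nm in names(mesh$face_sets)) {
    tri <- face_set_triples(mesh, mesh$face_sets[[nm]])
    k <- face_key(tri)
    if (!all(k %in% bd_keys))
      stop("face set '", nm, "' contains faces interior to the mesh")
    tagged <- c(tagged, k)
  }
  if (anyDuplicated(tagged))
    stop("a boundary face is tagged by more than one face set")
  if (partition && length(mesh$face_sets) &&
      !setequal(tagged, bd_keys))
    stop("face sets do not partition the mesh surface (",
         length(setdiff(bd_keys, tagged)), " untagged faces)")
  invisible(TRUE)
}

#' Per-element volumes of a mesh
#'
#' @param mesh a `tet_mesh`.
#' @return numeric vector of element volumes (um^3).
#' @export
element_volumes <- function(mesh) {
  vapply(seq_len(nrow(mesh$elements)), function(e) {
    abs(tet_signed_volume(mesh$nodes[mesh$elements[e, ], , drop = FALSE]))
  }, numeric(1))
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$elements), "elements\n")
  if (length(x$face_sets)) {
    for (nm in names(x$face_sets))
      cat("  face set '", nm, "': ", nrow(x$face_sets[[nm]]), " faces\n",
          sep = "")
  }
  cat("  regions:", paste(unique(x$region), collapse = ", "), "\n")
  invisible(x)
}

#' Tetrahedral element quality measures
#'
#' Two normalized shape measures per element, both in (0, 1] with 1 attained
#' exactly by the regular tetrahedron and 0 the degenerate limit:
#' `aspect_ratio` = 3 * inradius / circumradius, and `solid_angle` = the
#' minimum vertex solid angle divided by the regular tetrahedron's vertex
#' solid angle, acos(23/27). Degenerate elements report 0 rather than
#' raising an error.
#'
#' @param mesh a `tet_mesh`.
#' @return An object of class `mesh_quality_report`: data.frame with columns
#'   `element_id`, `aspect_ratio`, `solid_angle`, plus a `summary` attribute
#'   holding min/max/mean per measure.
#' @export
mesh_quality <- function(mesh) {
  m <- nrow(mesh$elements)
  ar <- numeric(m); sa <- numeric(m)
  for (e in seq_len(m)) {
    co <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    rr <- tet_in_circum_radii(co)
    ar[e] <- if (is.finite(rr[2]) && rr[2] > 0) 3 * rr[1] / rr[2] else 0
    sa[e] <- min(vapply(1:4, function(v) vertex_solid_angle(co, v),
                        numeric(1))) / REGULAR_TET_SOLID_ANGLE
  }
  ar <- pmin(pmax(ar, 0), 1)
  sa <- pmin(pmax(sa, 0), 1)
  rep_ <- data.frame(element_id = seq_len(m), aspect_ratio = ar,
                     solid_angle = sa)
  attr(rep_, "summary") <- data.frame(
    measure = c("aspect_ratio", "solid_angle"),
    min = c(min(ar), min(sa)),
    max = c(max(ar), max(sa)),
    mean = c(mean(ar), mean(sa)))
  class(rep_) <- c("mesh_quality_report", "data.frame")
  rep_
}

#' @export
print.mesh_quality_report <- function(x, ...) {
  cat("Mesh quality (", nrow(x), " elements):\n", sep = "")
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}

#' Write a mesh quality report to CSV
#'
#' Columns `element_id`, `aspect_ratio`, `solid_angle`.
#'
#' @param report a `mesh_quality_report` (or the `tet_mesh` to measure).
#' @param path output CSV path.
#' @export
write_quality_csv <- function(report, path) {
  if (inherits(report, "tet_mesh")) report <- mesh_quality(report)
  utils::write.csv(as.data.frame(report)[, c("element_id", "aspect_ratio",
                                             "solid_angle")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Snap probe points to mesh nodes
#'
#' Returns the nearest mesh node for each requested coordinate, together
#' with the snap distance. Points far outside the domain still snap to the
#' nearest (surface) node, with a warning.
#'
#' @param mesh a `tet_mesh`.
#' @param points numeric k x 3 matrix (or length-3 vector) of probe
#'   coordinates in um.
#' @param warn_dist distance (um) beyond which a warning about
#'   out-of-domain probes is emitted; default 1.5 median edge lengths.
#' @return data.frame with columns `node`, `distance`, `x`, `y`, `z` (the
#'   snapped node's coordinates).
#' @export
probe_nodes <- function(mesh, points, warn_dist = NULL) {
  if (nrow(mesh$nodes) == 0) stop("empty mesh")
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (is.null(warn_dist)) {
    e1 <- mesh$nodes[mesh$elements[, 1], , drop = FALSE] -
      mesh$nodes[mesh$elements[, 2], , drop = FALSE]
    warn_dist <- 1.5 * stats::median(sqrt(rowSums(e1^2)))
  }
  idx <- integer(nrow(points)); dd <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- rowSums((mesh$nodes - rep(points[i, ], each = nrow(mesh$nodes)))^2)
    idx[i] <- which.min(d2)
    dd[i] <- sqrt(d2[idx[i]])
  }
  if (any(dd > warn_dist))
    warning(sum(dd > warn_dist), " probe point(s) snapped over more than ",
            signif(warn_dist, 3), " um (outside or far from the domain)")
  data.frame(node = idx, distance = dd,
             x = mesh$nodes[idx, 1], y = mesh$nodes[idx, 2],
             z = mesh$nodes[idx, 3])
}
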