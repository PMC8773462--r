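# Geometric primitives for four-node tetrahedral elements.
#
# All coordinates are absolute positions in micrometers (um); volumes are in
# um^3 and areas in um^2. Node indexing is 0-free: everything internal is
# 1-based R indexing, and 1-based indices are what the file dialects that
# need them receive.

# Local faces of a four-node tetrahedron, in the order used for surface-flux
# loads: face 1 = nodes 1-2-3, face 2 = 2-3-4, face 3 = 3-4-1, face 4 = 4-1-2.
TET_LOCAL_FACES <- rbind(c(1L, 2L, 3L),
                         c(2L, 3L, 4L),
                         c(3L, 4L, 1L),
                         c(4L, 1L, 2L))

# Solid angle at the apex of a regular tetrahedron (steradians); the
# normalization anchor for the solid-angle quality measure.
REGULAR_TET_SOLID_ANGLE <- acos(23 / 27)

#' Signed volume of a tetrahedron
#'
#' @param coords numeric 4 x 3 matrix of vertex positions (um).
#' @return Signed volume in um^3: positive when vertices 1-2-3 are seen
#'   counter-clockwise from vertex 4 side (right-handed orientation).
#' @keywords internal
tet_signed_volume <- function(coords) {
  e <- coords[2:4, , drop = FALSE] - rep(coords[1, ], each = 3)
  det(e) / 6
}

#' Volume of a tetrahedral element
#'
#' Computes the volume of a four-node tetrahedron as |det E| / 6 where E is
#' the matrix of edge vectors from vertex 1. The element integrals of the
#' linear tetrahedral element (mass, stiffness, source loads) are all
#' proportional to this volume.
#'
#' @param coords numeric 4 x 3 matrix of vertex positions in um (one row per
#'   vertex).
#' @param tol degeneracy tolerance: the element is rejected when its volume
#'   falls below `tol` times the cube of its bounding-box diagonal.
#' @return Volume in um^3, with attribute `negative_orientation` set to
#'   `TRUE` when the vertex ordering is left-handed (callers reorder nodes
#'   3 and 4 to canonicalize).
#' @examples
#' tet_volume(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))  # 1/6
#' @export
tet_volume <- function(coords, tol = 1e-12) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 4, ncol(coords) == 3)
  sv <- tet_signed_volume(coords)
  diag3 <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))^3
  if (abs(sv) <= tol * max(diag3, .Machine$double.xmin)) {
    stop("degenerate tetrahedral element: volume ", abs(sv),
         " below tolerance (coplanar or duplicated vertices)")
  }
  structure(abs(sv), negative_orientation = (sv < 0))
}

#' Area of a triangular face
#'
#' Half the norm of the cross product of two edge vectors; used for the
#' surface integrals behind prescribed-flux boundary loads.
#'
#' @param coords numeric 3 x 3 matrix of vertex positions in um.
#' @param tol relative tolerance below which the triangle is reported as
#'   collinear.
#' @return Area in um^2.
#' @examples
#' face_area(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))  # 0.5
#' @export
face_area <- function(coords, tol = 1e-12) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 3, ncol(coords) == 3)
  u <- coords[2, ] - coords[1, ]
  v <- coords[3, ] - coords[1, ]
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  a <- sqrt(sum(cr^2)) / 2
  scale2 <- max(sum(u^2), sum(v^2), .Machine$double.xmin)
  if (a <= tol * scale2) {
    stop("zero-area face: the three points are collinear")
  }
  a
}

# Solid angle subtended at vertex `apex` of a tetrahedron by its opposite
# face (Van Oosterom & Strackee). Returns 0 for degenerate configurations.
vertex_solid_angle <- function(coords, apex) {
  others <- setdiff(1:4, apex)
  a <- coords[others[1], ] - coords[apex, ]
  b <- coords[others[2], ] - coords[apex, ]
  cc <- coords[others[3], ] - coords[apex, ]
  la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2)); lc <- sqrt(sum(cc^2))
  if (la == 0 || lb == 0 || lc == 0) return(0)
  triple <- abs(det(rbind(a, b, cc)))
  denom <- la * lb * lc + sum(a * b) * lc + sum(a * cc) * lb + sum(b * cc) * la
  ang <- 2 * atan2(triple, denom)
  if (ang < 0) ang <- ang + 2 * pi
  ang
}

# Inradius and circumradius of a tetrahedron. Returns c(r, R); r = 3V/A_total,
# R from the circumcenter linear system. Degenerate input gives c(0, Inf).
tet_in_circum_radii <- function(coords) {
  sv <- abs(tet_signed_volume(coords))
  if (sv == 0) return(c(0, Inf))
  atot <- 0
  for (f in 1:4) {
    tri <- coords[TET_LOCAL_FACES[f, ], , drop = FALSE]
    u <- tri[2, ] - tri[1, ]; v <- tri[3, ] - tri[1, ]
    cr <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    atot <- atot + sqrt(sum(cr^2)) / 2
  }
  r <- 3 * sv / atot
  # circumcenter: solve 2 (p_i - p_1) . x = |p_i|^2 - |p_1|^2, i = 2..4
  m <- 2 * (coords[2:4, , drop = FALSE] - rep(coords[1, ], each = 3))
  rhs <- rowSums(coords[2:4, , drop = FALSE]^2) - sum(coords[1, ]^2)
  ctr <- tryCatch(solve(m, rhs), error = function(e) NULL)
  if (is.null(ctr)) return(c(0, Inf))
  bigr <- sqrt(sum((coords[1, ] - ctr)^2))
  c(r, bigr)
}
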