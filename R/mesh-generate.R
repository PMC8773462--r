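# Deterministic tetrahedral mesh generation for cellular geometries.
#
# Both generators share one construction: a subdivided-icosahedron
# triangulation supplies a set of surface directions; nodes are placed in
# layers along rays (radial for the sphere shell, from the nuclear-cavity
# center for the cell-like blob); each triangular prism between consecutive
# layers is split into three tetrahedra. Quad-face diagonals are chosen by
# the minimum-global-node-index rule, which is always realizable and makes
# neighbouring prisms conform. The seed enters only through a rigid rotation
# of the base icosahedron, so meshes are bitwise reproducible per seed and
# quality/volumes are seed-independent.

# Unit icosahedron vertices (circumradius 1) and faces.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# Loop-style subdivision on the unit sphere: each triangle -> 4, midpoints
# projected back to the sphere.
subdivide_sphere <- function(surf) {
  v <- surf$vertices; f <- surf$faces
  midkey <- new.env(parent = emptyenv())
  verts <- v
  midpoint <- function(a, b) {
    k <- paste(min(a, b), max(a, b))
    if (!is.null(midkey[[k]])) return(midkey[[k]])
    p <- verts[a, ] + verts[b, ]
    p <- p / sqrt(sum(p^2))
    verts <<- rbind(verts, p)
    midkey[[k]] <- nrow(verts)
    nrow(verts)
  }
  nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
    nf[4 * i - 3, ] <- c(a, ab, ca)
    nf[4 * i - 2, ] <- c(b, bc, ab)
    nf[4 * i - 1, ] <- c(cc, ca, bc)
    nf[4 * i, ]     <- c(ab, bc, ca)
  }
  list(vertices = verts, faces = nf)
}

# Triangulated unit sphere at a given subdivision level, rotated by a
# seed-derived rigid rotation (volumes/quality unchanged; node placement
# deterministic per seed).
unit_sphere_surface <- function(level, seed) {
  surf <- icosahedron()
  lv <- 0
  while (lv < level) {
    surf <- subdivide_sphere(surf)
    lv <- lv + 1
  }
  rot <- seed_rotation(seed)
  surf$vertices <- surf$vertices %*% t(rot)
  surf
}

# A deterministic rotation matrix from an integer seed (Rodrigues formula on
# hashed axis/angle); identity for seed 0.
seed_rotation <- function(seed) {
  seed <- as.numeric(seed) %% 2147483647
  if (seed == 0) return(diag(3))
  s <- seed %% 104729
  h <- ((s * c(48271, 16807, 69621) + c(11, 23, 37)) %% 104729) / 104729
  ang <- 2 * pi * h[1]
  z <- 2 * h[2] - 1
  az <- 2 * pi * h[3]
  axis <- c(sqrt(1 - z^2) * cos(az), sqrt(1 - z^2) * sin(az), z)
  kx <- rbind(c(0, -axis[3], axis[2]),
              c(axis[3], 0, -axis[1]),
              c(-axis[2], axis[1], 0))
  diag(3) + sin(ang) * kx + (1 - cos(ang)) * (kx %*% kx)
}

# Split the prism with bottom (b1,b2,b3) and top (t1,t2,t3) global node
# indices into 3 tets, fanning from the prism's minimum-index vertex; quad
# diagonals then follow the min-index rule on every quad, so neighbouring
# prisms built the same way share diagonals. Prisms here are convex (all
# quads planar: each quad lies in the plane spanned by two ray directions
# through the layering origin), so the fan is valid.
split_prism <- function(b, tp) {
  vs <- c(b, tp)
  quads <- list(c(1L, 2L, 5L, 4L), c(2L, 3L, 6L, 5L), c(3L, 1L, 4L, 6L))
  tris <- list(c(1L, 2L, 3L), c(4L, 5L, 6L))
  for (q in quads) {
    g <- vs[q]
    if (which.min(g) %in% c(1L, 3L)) {
      tris <- c(tris, list(q[c(1, 2, 3)]), list(q[c(1, 3, 4)]))
    } else {
      tris <- c(tris, list(q[c(1, 2, 4)]), list(q[c(2, 3, 4)]))
    }
  }
  apex <- which.min(vs)
  out <- matrix(0L, nrow = 3, ncol = 4)
  k <- 0
  for (tr in tris) {
    if (apex %in% tr) next
    k <- k + 1
    out[k, ] <- c(vs[apex], vs[tr])
  }
  stopifnot(k == 3)
  out
}

# Core layered extrusion: directions u_j (rows of surf$vertices), per-node
# radii matrix r[layer, j]; returns nodes/elements plus inner/outer surface
# triangles (node triples).
extrude_layers <- function(surf, radii, origin = c(0, 0, 0)) {
  nl <- nrow(radii)           # number of node layers (>= 2)
  nv <- nrow(surf$vertices)
  nodes <- matrix(0, nrow = nl * nv, ncol = 3)
  for (l in seq_len(nl)) {
    nodes[(l - 1) * nv + seq_len(nv), ] <-
      surf$vertices * radii[l, ] + rep(origin, each = nv)
  }
  elems <- matrix(0L, nrow = 3 * nrow(surf$faces) * (nl - 1), ncol = 4)
  k <- 0
  for (l in seq_len(nl - 1)) {
    off_b <- (l - 1L) * nv; off_t <- l * nv
    for (i in seq_len(nrow(surf$faces))) {
      f <- surf$faces[i, ]
      tets <- split_prism(f + off_b, f + off_t)
      elems[k + 1:3, ] <- tets
      k <- k + 3
    }
  }
  inner <- surf$faces                     # layer 1 (cavity surface)
  outer <- surf$faces + (nl - 1L) * nv    # last layer (outer surface)
  list(nodes = nodes, elements = elems, inner = inner, outer = outer)
}

# Subdivision level and layer count from a target edge length.
resolution_for <- function(target_edge_length, r_surface, gap) {
  ico_edge <- 4 / sqrt(10 + 2 * sqrt(5))   # icosahedron edge, circumradius 1
  level <- max(0, round(log2(ico_edge * r_surface / target_edge_length)))
  layers <- max(1, round(gap / target_edge_length))
  list(level = as.integer(level), layers = as.integer(layers))
}

#' Generate a tetrahedral mesh of a concentric spherical-shell cell model
#'
#' Meshes the cytosolic shell between the nuclear surface (radius `R_i`) and
#' the plasma membrane (radius `R_o`); the nucleus itself is excluded from
#' the domain (no transport across the nuclear envelope is modeled). The
#' outer surface is tagged `"plasma_membrane"` and the inner surface
#' `"perinuclear"`. Construction is layered: a subdivided icosahedral
#' triangulation is placed on concentric spheres and the prisms between
#' consecutive spheres are split into tetrahedra.
#'
#' @param R_o outer (cell) radius, um.
#' @param R_i inner (nuclear) radius, um; `0 < R_i < R_o`.
#' @param target_edge_length requested edge length, um; controls the
#'   icosphere subdivision level and the number of radial layers.
#' @param seed integer; rotates the base icosahedron rigidly. The mesh is
#'   identical across runs for a fixed seed.
#' @return a `tet_mesh`.
#' @examples
#' m <- generate_sphere_shell_mesh(9.34, 5.26, target_edge_length = 4, seed = 1)
#' @export
generate_sphere_shell_mesh <- function(R_o, R_i, target_edge_length,
                                       seed = 1L) {
  stopifnot(R_i > 0, R_o > R_i, target_edge_length > 0)
  gap <- R_o - R_i
  if (target_edge_length > gap)
    stop("target edge length ", target_edge_length,
         " um is coarser than the shell gap R_o - R_i = ", gap,
         " um; choose an edge length at or below the gap")
  res <- resolution_for(target_edge_length, (R_o + R_i) / 2, gap)
  surf <- unit_sphere_surface(res$level, seed)
  nv <- nrow(surf$vertices)
  rr <- seq(R_i, R_o, length.out = res$layers + 1)
  radii <- matrix(rep(rr, each = nv), nrow = length(rr), byrow = TRUE)
  ex <- extrude_layers(surf, radii)
  tet_mesh(ex$nodes, ex$elements,
           face_sets = list(plasma_membrane = ex$outer,
                            perinuclear = ex$inner))
}

# Flattened super-ellipsoid used as the outer surface of the cell-like
# geometry: (|x/a|^p + |y/b|^p + |z/c|^p) = 1.
superellipsoid_implicit <- function(p, semi, power) {
  sum(abs(p / semi)^power) - 1
}

#' Generate a synthetic cell-like tetrahedral mesh with a nuclear cavity
#'
#' A stand-in for image-derived cell geometries: a flattened super-ellipsoid
#' outer surface (semi-axes `outer_semi`, exponent `outer_power`) enclosing
#' an off-center ellipsoidal nuclear cavity. For each direction of a
#' subdivided icosahedron centered on the cavity, the cavity and outer
#' surfaces are ray-cast and nodes laid out in layers between them; the
#' resulting prisms are split into tetrahedra. Both surfaces are star-shaped
#' from the cavity center, so the construction is watertight. The outer
#' surface is tagged `"plasma_membrane"`, the cavity `"perinuclear"`. This
#' is a synthetic geometry; real geometries can be imported with
#' [read_mesh()].
#'
#' @param seed integer; rigidly rotates the direction set (deterministic per
#'   seed).
#' @param target_edge_length requested edge length, um.
#' @param outer_semi outer super-ellipsoid semi-axes (um); default
#'   `c(12, 8, 3.5)` gives a flattened ~24 x 16 x 7 um cell.
#' @param outer_power super-ellipsoid exponent (2 = ellipsoid; larger =
#'   boxier); default 2.5.
#' @param cavity_semi nuclear-cavity ellipsoid semi-axes (um).
#' @param cavity_center cavity center (um), offset from the cell center.
#' @return a `tet_mesh`.
#' @export
generate_cell_like_mesh <- function(seed = 1L, target_edge_length = 2,
                                    outer_semi = c(12, 8, 3.5),
                                    outer_power = 2.5,
                                    cavity_semi = c(3.5, 2.5, 1.8),
                                    cavity_center = c(2, 1, 0.3)) {
  stopifnot(target_edge_length > 0, all(outer_semi > 0), all(cavity_semi > 0))
  if (superellipsoid_implicit(cavity_center, outer_semi, outer_power) >= 0)
    stop("cavity center lies outside the outer surface")
  # characteristic radius/gap for resolution selection
  r_char <- mean(outer_semi)
  gap_char <- mean(outer_semi) - mean(cavity_semi)
  res <- resolution_for(target_edge_length, r_char, 0.5 * gap_char)
  surf <- unit_sphere_surface(res$level, seed)
  nv <- nrow(surf$vertices)

  t_in <- numeric(nv); t_out <- numeric(nv)
  t_max <- 4 * max(outer_semi)
  for (j in seq_len(nv)) {
    u <- surf$vertices[j, ]
    t_in[j] <- 1 / sqrt(sum((u / cavity_semi)^2))
    g <- function(t) superellipsoid_implicit(cavity_center + t * u,
                                             outer_semi, outer_power)
    if (g(t_in[j]) >= 0)
      stop("cavity surface touches or crosses the outer surface ",
           "(direction ", j, "); shrink the cavity or recenter it")
    t_out[j] <- stats::uniroot(g, c(t_in[j], t_max), tol = 1e-12)$root
  }
  nl <- res$layers + 1L
  w <- seq(0, 1, length.out = nl)
  radii <- outer(rep(1, nl), t_in) + outer(w, t_out - t_in)
  ex <- extrude_layers(surf, radii, origin = cavity_center)
  tet_mesh(ex$nodes, ex$elements,
           face_sets = list(plasma_membrane = ex$outer,
                            perinuclear = ex$inner))
}
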