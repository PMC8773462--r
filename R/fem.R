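# Four-node tetrahedral element matrices, global sparse assembly, and
# Dirichlet reduction.
#
# For the P1 tetrahedron every element integral is exact in closed form:
# the consistent mass matrix is (V/20) * (ones + I), the stiffness matrix is
# V * D * B' B with B the constant-gradient operator, a prescribed-flux face
# load spreads beta * A / 3 over the face's three nodes, and a uniform
# volumetric source spreads V * rate / 4 over the element's four nodes.

#' Consistent mass matrix of a tetrahedral element
#'
#' `(V / 20) * (J + I)` where `J` is the all-ones 4 x 4 matrix: diagonal
#' entries `2V/20`, off-diagonal `V/20`. Row sums are `V/4` and the total
#' sum is `V` (the element volume), which is what makes the assembled
#' quantity `1' K1 c` the discrete total cAMP content.
#'
#' @param coords numeric 4 x 3 matrix of vertex positions (um).
#' @return 4 x 4 symmetric positive-definite matrix.
#' @export
element_mass_matrix <- function(coords) {
  v <- as.numeric(tet_volume(coords))
  (v / 20) * (matrix(1, 4, 4) + diag(4))
}

#' Constant-gradient operator of a tetrahedral element
#'
#' The 3 x 4 matrix `B` mapping nodal values to the (constant) concentration
#' gradient of the P1 interpolant: `B = E^{-T} G` with `E` the edge matrix
#' from vertex 1 and `G` the nodal difference stencil. `B` annihilates
#' constants and reproduces linear fields exactly.
#'
#' @param coords numeric 4 x 3 matrix of vertex positions (um).
#' @return 3 x 4 matrix (units 1/um).
#' @export
element_gradient_matrix <- function(coords) {
  coords <- as.matrix(coords)
  tet_volume(coords)  # degeneracy guard
  e <- coords[2:4, , drop = FALSE] - rep(coords[1, ], each = 3)
  g <- rbind(c(-1, 1, 0, 0), c(-1, 0, 1, 0), c(-1, 0, 0, 1))
  solve(e, g)
}

#' Diffusion stiffness matrix of a tetrahedral element
#'
#' `V * D * B' B` for isotropic diffusivity `D` (the diffusion tensor is
#' `D * I`). Symmetric positive semidefinite with zero row sums.
#'
#' @param coords numeric 4 x 3 matrix of vertex positions (um).
#' @param D diffusion coefficient, um^2/s; must be non-negative.
#' @return 4 x 4 matrix (units um^3/s).
#' @export
element_stiffness_matrix <- function(coords, D) {
  if (D < 0) stop("diffusion coefficient D must be non-negative")
  v <- as.numeric(tet_volume(coords))
  b <- element_gradient_matrix(coords)
  v * D * crossprod(b)
}

#' Prescribed-flux load vector for one element face
#'
#' For a constant normal flux `beta` over local face `face` of the element,
#' the consistent load puts `beta * A / 3` on each of the face's three nodes
#' and zero on the opposite node (`A` = face area). Positive `beta` is
#' influx into the domain (used to model membrane-bound adenylyl-cyclase
#' activity).
#'
#' @param coords numeric 4 x 3 matrix of the element's vertex positions (um).
#' @param beta flux, uM um / s (any sign).
#' @param face local face id 1..4 (face 1 = nodes 1-2-3, 2 = 2-3-4,
#'   3 = 3-4-1, 4 = 4-1-2).
#' @return length-4 load vector (uM um^3 / s).
#' @export
face_flux_vector <- function(coords, beta, face) {
  stopifnot(face %in% 1:4)
  fnodes <- TET_LOCAL_FACES[face, ]
  a <- face_area(as.matrix(coords)[fnodes, , drop = FALSE])
  out <- numeric(4)
  out[fnodes] <- beta * a / 3
  out
}

#' Uniform volumetric source load vector
#'
#' `V * rate / 4` at each node: the consistent load of a spatially uniform
#' production (or quasi-linearization constant) rate over the element.
#'
#' @param volume element volume, um^3.
#' @param rate volumetric rate, uM/s.
#' @return length-4 load vector.
#' @export
element_source_vector <- function(volume, rate) {
  stopifnot(volume > 0)
  rep(volume * rate / 4, 4)
}

#' Assemble the global finite element system
#'
#' Builds the global sparse consistent mass matrix `K1`, the diffusion
#' stiffness `K2`, the boundary-flux load `R1` (from `face_flux_map`), and
#' the volumetric synthesis load `R2s` (from `volumetric_rate_map`), plus
#' the bookkeeping needed to rebuild the state-dependent degradation matrix
#' `K3` and load `R2b` cheaply during time stepping: the per-element mass
#' triplets (K3 is a per-element scalar multiple of the element mass
#' matrix) and a node-element incidence operator.
#'
#' @param mesh a `tet_mesh`.
#' @param D diffusion coefficient, um^2/s.
#' @param face_flux_map named numeric vector/list: flux `beta` (uM um/s) per
#'   boundary face-set label. Labels must exist in the mesh.
#' @param volumetric_rate_map named numeric vector/list: uniform synthesis
#'   rate `E_AC` (uM/s) per region tag. Labels must exist in the mesh.
#' @return An object of class `assembled_system` with elements `K1`, `K2`
#'   (`dgCMatrix`), `R1`, `R2s` (numeric vectors), `n_nodes`, `mesh`, and
#'   internal fields for the degradation rebuild.
#' @export
assemble_global <- function(mesh, D, face_flux_map = list(),
                            volumetric_rate_map = list()) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (D < 0) stop("diffusion coefficient D must be non-negative")
  face_flux_map <- as.list(face_flux_map)
  volumetric_rate_map <- as.list(volumetric_rate_map)
  bad <- setdiff(names(face_flux_map), names(mesh$face_sets))
  if (length(bad))
    stop("face_flux_map labels not present in mesh: ",
         paste(bad, collapse = ", "))
  badr <- setdiff(names(volumetric_rate_map), unique(mesh$region))
  if (length(badr))
    stop("volumetric_rate_map regions not present in mesh: ",
         paste(badr, collapse = ", "))
  if (!all(vapply(c(face_flux_map, volumetric_rate_map), is.finite,
                  logical(1))))
    stop("fluxes and rates must be finite")

  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  vols <- element_volumes(mesh)

  # element mass pattern: 16 triplets per element, value = V/20 * (1 + I)
  massu <- (matrix(1, 4, 4) + diag(4)) / 20
  loc_i <- rep(rep(1:4, times = 4), m)
  loc_j <- rep(rep(1:4, each = 4), m)
  eoff <- rep(seq_len(m), each = 16L)
  gi <- mesh$elements[cbind(eoff, loc_i)]
  gj <- mesh$elements[cbind(eoff, loc_j)]
  mass_x <- rep(vols, each = 16L) * massu[cbind(loc_i, loc_j)]
  K1 <- Matrix::sparseMatrix(i = gi, j = gj, x = mass_x, dims = c(n, n))

  # stiffness triplets
  stiff_x <- numeric(16L * m)
  for (e in seq_len(m)) {
    co <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    b <- element_gradient_matrix(co)
    ke <- vols[e] * D * crossprod(b)
    stiff_x[(e - 1L) * 16L + 1:16] <- as.vector(ke)  # column-major = [i,j]
  }
  # as.vector(ke) is column-major: index (loc_i, loc_j) with i fastest = ours
  K2 <- Matrix::sparseMatrix(i = gi, j = gj, x = stiff_x, dims = c(n, n))

  # boundary flux load
  R1 <- numeric(n)
  for (lb in names(face_flux_map)) {
    beta <- as.numeric(face_flux_map[[lb]])
    fs <- mesh$face_sets[[lb]]
    for (k in seq_len(nrow(fs))) {
      enodes <- mesh$elements[fs$element[k], ]
      co <- mesh$nodes[enodes, , drop = FALSE]
      R1[enodes] <- R1[enodes] + face_flux_vector(co, beta, fs$face[k])
    }
  }

  # node-element incidence weighted by V_e/4: R2(rate per element) = P rate
  pmat <- Matrix::sparseMatrix(i = as.vector(mesh$elements),
                               j = rep(seq_len(m), times = 4),
                               x = rep(vols / 4, times = 4),
                               dims = c(n, m))
  erate <- vapply(mesh$region, function(rg) {
    v <- volumetric_rate_map[[rg]]
    if (is.null(v)) 0 else as.numeric(v)
  }, numeric(1))
  R2s <- as.numeric(pmat %*% erate)

  # element-mean restriction: c1_e = mean of the element's 4 nodal values
  qmat <- Matrix::sparseMatrix(i = rep(seq_len(m), times = 4),
                               j = as.vector(mesh$elements),
                               x = rep(0.25, 4L * m), dims = c(m, n))

  structure(list(K1 = K1, K2 = K2, R1 = R1, R2s = R2s,
                 n_nodes = n, n_elements = m, mesh = mesh, D = D,
                 elem_volumes = vols, elem_rate = erate,
                 tri_i = gi, tri_j = gj, mass_x = mass_x,
                 pmat = pmat, qmat = qmat),
            class = "assembled_system")
}

#' @export
print.assembled_system <- function(x, ...) {
  cat("assembled_system:", x$n_nodes, "nodes,", x$n_elements, "elements\n")
  cat("  D =", x$D, "um^2/s; |R1| support:", sum(x$R1 != 0),
      "nodes; sum R2s =", sum(x$R2s), "uM um^3/s\n")
  invisible(x)
}

# State-dependent degradation matrix K3(C1) = sum_e a_e * K1_e and load
# R2b(C1) = sum_e b_e * (V_e/4) at the element's nodes, with (a_e, b_e) the
# quasi-linearization coefficients at the element-mean expansion point.
degradation_terms <- function(system, c1, V_max, K_M) {
  c1e <- as.numeric(system$qmat %*% c1)
  ql <- quasi_linearize(c1e, V_max, K_M, system$elem_rate)
  K3 <- Matrix::sparseMatrix(i = system$tri_i, j = system$tri_j,
                             x = rep(ql$a, each = 16L) * system$mass_x,
                             dims = c(system$n_nodes, system$n_nodes))
  R2b <- as.numeric(system$pmat %*% ql$b)
  list(K3 = K3, R2b = R2b)
}

#' Reduce a linear system under Dirichlet (prescribed-value) conditions
#'
#' Symmetric row/column elimination: prescribed rows and columns are removed
#' and the known values are moved to the right-hand side, preserving
#' symmetry and conditioning. The returned recovery function re-embeds a
#' reduced solution into the full node vector.
#'
#' @param matrix n x n (sparse) system matrix.
#' @param rhs length-n right-hand side.
#' @param nodes integer vector of prescribed node indices.
#' @param values prescribed values, recycled to `length(nodes)`.
#' @return list with `matrix` (reduced), `rhs` (reduced), `free` (indices of
#'   retained nodes), and `recover(x_reduced)` returning the full vector.
#' @export
apply_dirichlet <- function(matrix, rhs, nodes, values) {
  n <- length(rhs)
  nodes <- as.integer(nodes)
  values <- rep_len(as.numeric(values), length(nodes))
  if (anyDuplicated(nodes)) {
    dup <- unique(nodes[duplicated(nodes)])
    agg <- tapply(values, nodes, function(v) length(unique(v)))
    if (any(agg > 1))
      stop("conflicting Dirichlet values prescribed on node(s) ",
           paste(dup, collapse = ", "))
    keep <- !duplicated(nodes)
    nodes <- nodes[keep]; values <- values[keep]
  }
  if (length(nodes) && (min(nodes) < 1 || max(nodes) > n))
    stop("Dirichlet node index out of range")
  free <- setdiff(seq_len(n), nodes)
  if (!length(nodes)) {
    return(list(matrix = matrix, rhs = rhs, free = free,
                recover = function(x) as.numeric(x)))
  }
  full <- numeric(n); full[nodes] <- values
  if (length(free)) {
    red <- matrix[free, free, drop = FALSE]
    rr <- rhs[free] - as.numeric(matrix[free, nodes, drop = FALSE] %*% values)
  } else {
    red <- matrix[0, 0, drop = FALSE]
    rr <- numeric(0)
  }
  list(matrix = red, rhs = rr, free = free,
       recover = function(x) {
         out <- full
         out[free] <- as.numeric(x)
         out
       })
}

#' Export an assembled sparse matrix to MatrixMarket format
#'
#' Debugging aid; writes `K1` or `K2` (or any Matrix object) via
#' [Matrix::writeMM()].
#'
#' @param mat a sparse `Matrix`.
#' @param path output `.mtx` path.
#' @export
write_matrix_market <- function(mat, path) {
  Matrix::writeMM(methods::as(mat, "CsparseMatrix"), path)
  invisible(path)
}
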