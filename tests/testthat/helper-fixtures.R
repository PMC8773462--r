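# Shared fixtures. Meshes are cached per session so repeated tests do not
# regenerate them.

REF_TET <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

REGULAR_TET <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))

# two tets sharing face (2,3,4)
TWO_TET_NODES <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                       c(1, 1, 1))
TWO_TET_ELEMS <- rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L))

two_tet_mesh <- function() tet_mesh(TWO_TET_NODES, TWO_TET_ELEMS)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# concentric-sphere cell model at the published radii
sphere_mesh <- function(edge = 2.4, seed = 1) {
  cached(paste0("sphere_", edge, "_", seed),
         generate_sphere_shell_mesh(9.34, 5.26, edge, seed = seed))
}

cell_mesh <- function(edge = 2, seed = 1) {
  cached(paste0("cell_", edge, "_", seed),
         generate_cell_like_mesh(seed = seed, target_edge_length = edge))
}

# random non-degenerate tetrahedra for property-style loops
random_tets <- function(n, seed = 42) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    co <- matrix(stats::rnorm(12), 4, 3)
    sv <- abs(det(co[2:4, ] - rep(co[1, ], each = 3))) / 6
    if (sv > 1e-3) out[[length(out) + 1]] <- co
  }
  out
}

# amplitude-normalized maximum curve discrepancy
curve_discrepancy <- function(x, ref) max(abs(x - ref)) / max(abs(ref))

# published reference parameter set
PAR <- list(E_AC = 0.1412, D_range = c(0.3, 300), V_max = 0.295, K_M = 2,
            C_o = 0.05, R_o = 9.34, R_i = 5.26)
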