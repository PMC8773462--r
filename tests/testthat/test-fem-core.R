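test_that("element mass matrix has the exact consistent-mass structure", {
  k1 <- element_mass_matrix(REF_TET)
  expect_equal(diag(k1), rep(1 / 60, 4))
  expect_equal(k1[1, 2], 1 / 120)
  expect_equal(k1, t(k1))

  for (co in random_tets(6)) {
    v <- as.numeric(tet_volume(co))
    k <- element_mass_matrix(co)
    expect_equal(rowSums(k), rep(v / 4, 4), tolerance = 1e-12)
    expect_equal(sum(k), v, tolerance = 1e-12)
    expect_true(all(eigen(k, symmetric = TRUE, only.values = TRUE)$values > 0))
    # depends only on volume: rigid rotation leaves it unchanged
    rot <- campfem:::seed_rotation(5)
    expect_equal(element_mass_matrix(co %*% t(rot)), k, tolerance = 1e-9)
  }
})

test_that("gradient operator annihilates constants and is exact on linears", {
  b <- element_gradient_matrix(REF_TET)
  expect_equal(b, rbind(c(-1, 1, 0, 0), c(-1, 0, 1, 0), c(-1, 0, 0, 1)))
  for (co in random_tets(6)) {
    bb <- element_gradient_matrix(co)
    expect_equal(as.numeric(bb %*% rep(1, 4)), rep(0, 3), tolerance = 1e-10)
    # nodal values of x, y, z give the exact unit gradients
    expect_equal(bb %*% co, diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("stiffness matrix is V D B'B: PSD, zero row sums, linear in D", {
  k2 <- element_stiffness_matrix(REF_TET, 1)
  expect_equal(k2, (1 / 6) * rbind(c(3, -1, -1, -1), c(-1, 1, 0, 0),
                                   c(-1, 0, 1, 0), c(-1, 0, 0, 1)))
  for (co in random_tets(6)) {
    k <- element_stiffness_matrix(co, 2.5)
    expect_equal(as.numeric(k %*% rep(1, 4)), rep(0, 4), tolerance = 1e-9)
    expect_equal(element_stiffness_matrix(co, 25), 10 * k, tolerance = 1e-9)
    ev <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
  expect_error(element_stiffness_matrix(REF_TET, -1), "non-negative")
})

test_that("face flux loads place beta A/3 on the correct local faces", {
  expect_equal(face_flux_vector(REF_TET, 3, 1), c(0.5, 0.5, 0.5, 0))
  expect_equal(face_flux_vector(REF_TET, 0, 1), rep(0, 4))
  # face 2 (nodes 2-3-4) leaves node 1 unloaded
  v2 <- face_flux_vector(REF_TET, 3, 2)
  expect_equal(v2[1], 0)
  a234 <- face_area(REF_TET[c(2, 3, 4), ])
  expect_equal(v2[2:4], rep(3 * a234 / 3, 3))
  # total load equals beta * area for every face
  for (f in 1:4)
    expect_equal(sum(face_flux_vector(REF_TET, 2, f)),
                 2 * face_area(REF_TET[campfem:::TET_LOCAL_FACES[f, ], ]))
})

test_that("volumetric source loads are V rate / 4 per node and conservative", {
  v <- element_source_vector(1 / 6, 0.1412)
  expect_equal(v, rep(0.1412 / 24, 4))
  expect_equal(sum(element_source_vector(3.7, 0.2)), 3.7 * 0.2)
  expect_equal(element_source_vector(1, 0), rep(0, 4))
})

test_that("global assembly matches a dense oracle on small fixtures", {
  m <- two_tet_mesh()
  sys <- assemble_global(m, 2, volumetric_rate_map = list(cytosol = 0.1412))
  n <- nrow(m$nodes)
  kd <- matrix(0, n, n); md <- matrix(0, n, n); r2 <- numeric(n)
  for (e in seq_len(nrow(m$elements))) {
    en <- m$elements[e, ]
    co <- m$nodes[en, ]
    kd[en, en] <- kd[en, en] + element_stiffness_matrix(co, 2)
    md[en, en] <- md[en, en] + element_mass_matrix(co)
    r2[en] <- r2[en] + element_source_vector(as.numeric(tet_volume(co)),
                                             0.1412)
  }
  expect_equal(as.matrix(sys$K2), kd, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.matrix(sys$K1), md, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sys$R2s, r2, tolerance = 1e-12)
  expect_equal(sum(sys$K1), sum(element_volumes(m)), tolerance = 1e-12)
  expect_equal(as.numeric(sys$K2 %*% rep(1, n)), rep(0, n),
               tolerance = 1e-12)
  # same oracle on a larger generated fixture
  ms <- sphere_mesh(edge = 4, seed = 1)
  sys2 <- assemble_global(ms, 3)
  expect_equal(sum(sys2$K1), sum(element_volumes(ms)), tolerance = 1e-9)
  expect_lt(max(abs(sys2$K2 %*% rep(1, nrow(ms$nodes)))), 1e-9)
})

test_that("assembled flux load totals beta times the tagged surface area", {
  m <- sphere_mesh(edge = 2.4, seed = 1)
  beta <- 0.3611
  sys <- assemble_global(m, 3, face_flux_map = list(plasma_membrane = beta))
  fs <- m$face_sets$plasma_membrane
  area <- sum(vapply(seq_len(nrow(fs)), function(k) {
    tri <- m$elements[fs$element[k],
                      campfem:::TET_LOCAL_FACES[fs$face[k], ]]
    face_area(m$nodes[tri, ])
  }, numeric(1)))
  expect_equal(sum(sys$R1), beta * area, tolerance = 1e-10)
  # flux support restricted to tagged face nodes
  pm_nodes <- unique(as.vector(campfem:::face_set_triples(m, fs)))
  expect_true(all(which(sys$R1 != 0) %in% pm_nodes))

  expect_error(assemble_global(m, 3, face_flux_map = list(nope = 1)),
               "not present")
  expect_error(assemble_global(m, 3,
                               volumetric_rate_map = list(nucleus = 1)),
               "not present")
})

test_that("Dirichlet elimination matches hand reduction and handles edge cases", {
  a <- rbind(c(4, -1, 0, -1), c(-1, 4, -1, 0), c(0, -1, 4, -1),
             c(-1, 0, -1, 4))
  b <- c(1, 2, 3, 4)
  red <- apply_dirichlet(Matrix::Matrix(a, sparse = TRUE), b,
                         c(1, 4), c(10, 20))
  sol <- red$recover(as.numeric(Matrix::solve(red$matrix, red$rhs)))
  hand <- solve(a[2:3, 2:3], b[2:3] - a[2:3, c(1, 4)] %*% c(10, 20))
  expect_equal(sol, c(10, as.numeric(hand), 20))

  # prescribe none: identity
  red0 <- apply_dirichlet(Matrix::Matrix(a, sparse = TRUE), b,
                          integer(0), numeric(0))
  expect_equal(as.matrix(red0$matrix), a, ignore_attr = TRUE)
  expect_equal(red0$rhs, b)

  # prescribe all: empty system, solution = prescription
  redall <- apply_dirichlet(Matrix::Matrix(a, sparse = TRUE), b,
                            1:4, c(5, 6, 7, 8))
  expect_equal(dim(redall$matrix), c(0L, 0L))
  expect_equal(redall$recover(numeric(0)), c(5, 6, 7, 8))

  expect_error(apply_dirichlet(Matrix::Matrix(a, sparse = TRUE), b,
                               c(2, 2), c(1, 3)), "conflicting")
  expect_error(apply_dirichlet(Matrix::Matrix(a, sparse = TRUE), b,
                               9, 1), "out of range")
})
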