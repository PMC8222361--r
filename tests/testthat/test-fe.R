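# dense reference assembly in R (independent of the compiled path):
# constant-strain tetrahedra, K_e = V B' D B with B from the inverse
# vertex Jacobian computed by solve().
dense_assembly_oracle <- function(mesh, materials) {
  nd <- 3 * nrow(mesh$nodes)
  K <- matrix(0, nd, nd)
  for (e in seq_len(nrow(mesh$elems))) {
    vid <- mesh$elems[e, 1:4]
    X <- mesh$nodes[vid, ]
    M <- t(X[2:4, ]) - X[1, ] # columns x2-x1, x3-x1, x4-x1
    V <- det(M) / 6
    # gradients: row a of (dN/dxi) %*% M^{-1}
    dN <- rbind(c(-1, -1, -1), diag(3))
    G <- dN %*% solve(M)
    B <- matrix(0, 6, 12)
    for (a in 1:4) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- G[a, 1]; B[2, c0 + 2] <- G[a, 2]
      B[3, c0 + 3] <- G[a, 3]
      B[4, c0 + 1] <- G[a, 2]; B[4, c0 + 2] <- G[a, 1]
      B[5, c0 + 2] <- G[a, 3]; B[5, c0 + 3] <- G[a, 2]
      B[6, c0 + 1] <- G[a, 3]; B[6, c0 + 3] <- G[a, 1]
    }
    mat <- materials[materials$label == mesh$material[e], ]
    lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
    mu <- mat$E / (2 * (1 + mat$nu))
    D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
    D[1:3, 1:3] <- D[1:3, 1:3] + lam
    Ke <- V * t(B) %*% D %*% B
    dofs <- as.vector(vapply(vid, function(v) 3 * (v - 1) + 1:3,
                             numeric(3)))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  K
}

test_that("single-element stiffness is symmetric with rigid-body nullspace", {
  m <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                matrix(1:4, 1), "bone")
  sys <- assemble_system(m)
  K <- as.matrix(sys$K)
  expect_equal(dim(K), c(12L, 12L))
  expect_lt(max(abs(K - t(K))), 1e-12 * max(abs(K)))
  # six rigid-body modes: translations and linearized rotations
  X <- m$nodes
  modes <- cbind(
    rep(c(1, 0, 0), 4), rep(c(0, 1, 0), 4), rep(c(0, 0, 1), 4),
    as.vector(t(cbind(-X[, 2], X[, 1], 0))),
    as.vector(t(cbind(0, -X[, 3], X[, 2]))),
    as.vector(t(cbind(X[, 3], 0, -X[, 1]))))
  expect_lt(max(abs(K %*% modes)), 1e-9 * max(abs(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(ev < 1e-8 * max(ev)), 6L)
})

test_that("compiled assembly matches the dense R oracle on a random mesh", {
  set.seed(11)
  m <- make_unit_cube_mesh(2)
  # jitter interior coordinates, keeping volumes positive
  jitter <- matrix(stats::runif(length(m$nodes), -0.04, 0.04),
                   ncol = 3)
  m$nodes <- m$nodes + jitter
  expect_true(all(element_volumes(m) > 0))
  mats <- default_materials()
  K1 <- as.matrix(assemble_system(m, mats)$K)
  K2 <- dense_assembly_oracle(m, mats)
  expect_equal(K1, K2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("patch test is exact for linear and quadratic elements", {
  mats <- default_materials()
  for (ord in 1:2) {
    m <- make_unit_cube_mesh(2, order = ord)
    sol <- axial_patch(m, mats)
    sf <- element_strains(sol, m, materials = mats)
    expect_equal(sf$tensor[, 1], rep(1000, nrow(m$elems)),
                 tolerance = 1e-7)
    expect_equal(sf$principal[, 1], rep(1000, nrow(m$elems)),
                 tolerance = 1e-7)
    # uniaxial stress state: lateral contraction -nu * axial
    expect_equal(sf$principal[, 3], rep(-300, nrow(m$elems)),
                 tolerance = 1e-6)
    expect_equal(sf$vm, rep(1000, nrow(m$elems)), tolerance = 1e-6)
  }
})

test_that("cantilever tip deflection approaches the beam closed form and
           converges monotonically", {
  mats <- default_materials()
  E <- mats$E[mats$label == "bone"]
  L <- 20; P <- 1; I <- 1 / 12
  exact <- P * L^3 / (3 * E * I)
  tip_def <- function(n, order) {
    m <- make_cantilever_mesh(L, 1, 1, n = n, order = order)
    sys <- assemble_system(m, mats)
    fixed <- m$node_sets$fixed_end
    cons <- data.frame(node = rep(fixed, each = 3),
                       axis = rep(1:3, length(fixed)), value = 0)
    tip <- m$node_sets$tip
    loads <- data.frame(node = tip, fx = 0, fy = 0,
                        fz = -P / length(tip))
    sol <- solve_static(sys, cons, loads)
    -mean(sol$u[3 * (tip - 1) + 3])
  }
  # quadratic elements resolve bending: within 5% of PL^3 / 3EI
  expect_equal(tip_def(c(20, 2, 2), 2), exact, tolerance = 0.05)
  # linear tets converge monotonically from below over three refinements
  d <- c(tip_def(c(10, 1, 1), 1), tip_def(c(20, 2, 2), 1),
         tip_def(c(40, 2, 2), 1))
  err <- abs(d - exact) / exact
  expect_true(all(diff(err) < 0))
})

test_that("bi-material bar strains follow the inverse stiffness ratio", {
  mats <- default_materials(mat_a = c(200, 0), mat_b = c(100, 0))
  m <- make_bimaterial_bar(c(1, 1), c(1, 1), n = c(8, 2, 2))
  sol <- axial_patch(m, mats, strain = 1e-3)
  sf <- element_strains(sol, m, materials = mats)
  ea <- sf$tensor[m$material == "mat_a", 1]
  eb <- sf$tensor[m$material == "mat_b", 1]
  # piecewise uniform axial strain, ratio = E_a / E_b = 2
  expect_lt(diff(range(ea)), 1e-6 * mean(eb))
  expect_lt(diff(range(eb)), 1e-6 * mean(eb))
  expect_equal(mean(eb) / mean(ea), 2, tolerance = 1e-9)
  # equal stiffness degenerates to the single-material bar
  mats1 <- default_materials(mat_a = c(100, 0), mat_b = c(100, 0))
  sf1 <- element_strains(axial_patch(m, mats1), m, materials = mats1)
  expect_equal(sf1$tensor[, 1], rep(1000, nrow(m$elems)),
               tolerance = 1e-7)
})

test_that("rigid rotation produces no strain to linearization tolerance", {
  m <- make_unit_cube_mesh(2)
  th <- 1e-6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  u <- as.vector(t(m$nodes %*% t(R) - m$nodes))
  sf <- element_strains(u, m)
  expect_lt(max(abs(sf$tensor)), 1e-4) # microstrain; O(theta^2) residue
})

test_that("principal strains match an eigen-decomposition oracle", {
  set.seed(5)
  n <- 200
  eps <- matrix(stats::rnorm(6 * n, sd = 500), n, 6)
  pr <- principal_strains(eps)
  for (i in seq_len(n)) {
    A <- matrix(c(eps[i, 1], eps[i, 4] / 2, eps[i, 6] / 2,
                  eps[i, 4] / 2, eps[i, 2], eps[i, 5] / 2,
                  eps[i, 6] / 2, eps[i, 5] / 2, eps[i, 3]), 3, 3)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(pr[i, ], sort(ev, decreasing = TRUE),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_true(all(pr[, 1] >= pr[, 2] & pr[, 2] >= pr[, 3]))
})

test_that("equivalent strain closed forms hold", {
  # uniaxial stress state recovers the axial strain
  expect_equal(von_mises_strain(1000, -300, -300, 0.3), 1000)
  # hydrostatic strain gives zero
  expect_equal(von_mises_strain(250, 250, 250, 0.3), 0)
  expect_equal(von_mises_strain(-80, -80, -80, 0.49), 0)
  # invariant to permutation of the principal values
  set.seed(3)
  v <- stats::rnorm(3, sd = 400)
  base <- von_mises_strain(v[1], v[2], v[3], 0.3)
  for (p in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1)))
    expect_equal(von_mises_strain(v[p[1]], v[p[2]], v[p[3]], 0.3), base)
  expect_true(von_mises_strain(100, 0, -100, 0.3) >= 0)
})

test_that("truss link chains transmit axial force and resist transverse
           load only through anchors", {
  m <- make_unit_cube_mesh(2)
  sys <- assemble_system(m)
  # two-segment path along +x just above the top surface
  path <- rbind(c(0, 0, 1), c(0.6, 0, 1.2), c(1.2, 0, 1.4))
  sys2 <- add_link_elements(sys, list(p = path))
  expect_identical(sys2$n_extra_nodes, 2L)
  # pull the far joint axially: full force reaches the mesh (reactions
  # at a fully clamped base balance it)
  base <- which(m$nodes[, 3] == 0)
  cons <- data.frame(node = rep(base, each = 3),
                     axis = rep(1:3, length(base)), value = 0)
  far <- nrow(m$nodes) + 2L
  dir <- path[3, ] - path[2, ]
  dir <- dir / sqrt(sum(dir^2))
  loads <- data.frame(node = far, fx = 2 * dir[1], fy = 2 * dir[2],
                      fz = 2 * dir[3])
  sol <- solve_static(sys2, cons, loads)
  react <- matrix(0, 3, 1)
  for (ax in 1:3)
    react[ax] <- sum(sol$reactions[sol$constraints$axis == ax])
  expect_equal(as.numeric(react), -2 * dir, tolerance = 1e-9)
  # zero-length path segment errors
  bad <- rbind(c(0, 0, 1), c(0, 0, 1))
  expect_error(add_link_elements(sys, list(p = bad)), "zero-length|mesh node")
})

test_that("solutions are linear in the applied loads", {
  m <- make_unit_cube_mesh(2)
  sys <- assemble_system(m)
  base <- which(m$nodes[, 3] == 0)
  cons <- data.frame(node = rep(base, each = 3),
                     axis = rep(1:3, length(base)), value = 0)
  top <- which(m$nodes[, 3] == 1)
  l1 <- data.frame(node = top, fx = 1, fy = 0, fz = 0)
  l2 <- data.frame(node = top, fx = 0, fy = 0.5, fz = -2)
  u1 <- solve_static(sys, cons, l1)$u
  u2 <- solve_static(sys, cons, l2)$u
  l12 <- data.frame(node = top, fx = 2 * l1$fx + l2$fx,
                    fy = 2 * l1$fy + l2$fy, fz = 2 * l1$fz + l2$fz)
  u12 <- solve_static(sys, cons, l12)$u
  expect_equal(u12, 2 * u1 + u2, tolerance = 1e-9)
  # zero loads give zero strains
  u0 <- solve_static(sys, cons, l1[0, ])$u
  expect_equal(max(abs(u0)), 0)
})

test_that("under-constrained systems are reported as singular", {
  m <- make_unit_cube_mesh(2)
  sys <- assemble_system(m)
  cons <- data.frame(node = c(1L, 1L, 1L), axis = 1:3, value = 0)
  loads <- data.frame(node = nrow(m$nodes), fx = 1, fy = 0, fz = 0)
  expect_error(solve_static(sys, cons, loads), "singular|rigid-body")
})

test_that("conjugate-gradient fallback agrees with the direct solver", {
  m <- make_unit_cube_mesh(2)
  sys <- assemble_system(m)
  base <- which(m$nodes[, 3] == 0)
  cons <- data.frame(node = rep(base, each = 3),
                     axis = rep(1:3, length(base)), value = 0)
  top <- which(m$nodes[, 3] == 1)
  loads <- data.frame(node = top, fx = 0.2, fy = -0.1, fz = -1)
  ud <- solve_static(sys, cons, loads)$u
  uc <- solve_static(sys, cons, loads, method = "cg")$u
  expect_equal(uc, ud, tolerance = 1e-7)
})
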