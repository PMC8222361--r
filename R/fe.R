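#' Material table
#'
#' Isotropic linear-elastic properties per material label: Young's modulus
#' E (MPa) and Poisson's ratio nu. Defaults: cortical bone 13 700 MPa /
#' 0.3, tooth (dentine, enamel merged) 19 890 MPa / 0.31, periodontal
#' ligament 50 MPa / 0.49, suture 20 MPa / 0.49, pulp 2 MPa / 0.49, and
#' truss link elements with the bone values so they transfer force with
#' minimal deformation.
#'
#' @param ... named overrides or additions, each `c(E, nu)`.
#' @return data.frame with columns label, E, nu.
#' @export
default_materials <- function(...) {
  tab <- data.frame(
    label = c("bone", "tooth", "pdl", "suture", "pulp", "link"),
    E = c(13700, 19890, 50, 20, 2, 13700),
    nu = c(0.3, 0.31, 0.49, 0.49, 0.49, 0.3),
    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) {
    v <- extra[[nm]]
    if (nm %in% tab$label) {
      tab[tab$label == nm, c("E", "nu")] <- as.list(v)
    } else {
      tab <- rbind(tab, data.frame(label = nm, E = v[1], nu = v[2]))
    }
  }
  validate_materials(tab)
  tab
}

validate_materials <- function(tab) {
  if (any(tab$E <= 0)) stop("Young's modulus must be positive")
  if (any(tab$nu < 0 | tab$nu >= 0.5))
    stop("Poisson's ratio must satisfy 0 <= nu < 0.5")
  invisible(tab)
}

# 6x6 isotropic elasticity matrix (engineering shear convention)
elasticity_matrix <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

#' Assemble the global stiffness operator
#'
#' Sparse symmetric stiffness matrix of a labelled tetrahedral mesh with
#' homogeneous, isotropic, linear-elastic materials (3 displacement DOFs
#' per node). Before constraints the operator is positive semi-definite
#' with exactly six rigid-body zero-energy modes.
#'
#' @param mesh a [tet_mesh()].
#' @param materials material table, see [default_materials()].
#' @return an `fe_system` list: `K` (sparse dsCMatrix, N), `mesh`,
#'   `materials`, `ndof`.
#' @export
assemble_system <- function(mesh, materials = default_materials()) {
  mi <- match(mesh$material, materials$label)
  if (anyNA(mi))
    stop("material label(s) missing from the material table: ",
         paste(unique(mesh$material[is.na(mi)]), collapse = ", "))
  Dm <- sapply(seq_len(nrow(materials)), function(i)
    as.vector(elasticity_matrix(materials$E[i], materials$nu[i])))
  trip <- assemble_tets_cpp(mesh$nodes, mesh$elems, Dm, mi)
  ndof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(ndof, ndof))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  structure(list(K = K, mesh = mesh, materials = materials, ndof = ndof,
                 n_extra_nodes = 0L, extra_nodes = NULL,
                 surface = surface_nodes(mesh)),
            class = "fe_system")
}

#' @export
print.fe_system <- function(x, ...) {
  cat(sprintf("fe_system: %d DOFs, %d elements", x$ndof,
              nrow(x$mesh$elems)))
  if (x$n_extra_nodes > 0)
    cat(sprintf(" + %d link joint nodes", x$n_extra_nodes))
  cat("\n")
  invisible(x)
}

# nodes on the mesh boundary (belonging to a face owned by one element)
surface_nodes <- function(mesh) {
  fl <- sorted_faces(mesh)
  key <- paste(fl[, 1], fl[, 2], fl[, 3], sep = "-")
  once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  sort(unique(as.vector(fl[once, ])))
}

# all element faces with vertex triples sorted ascending (4 per element)
sorted_faces <- function(mesh) {
  e <- mesh$elems[, 1:4, drop = FALSE]
  faces_local <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  ne <- nrow(e)
  fl <- matrix(0L, 4L * ne, 3L)
  for (f in 1:4) {
    tri <- e[, faces_local[f, ], drop = FALSE]
    lo <- pmin(tri[, 1], tri[, 2], tri[, 3])
    hi <- pmax(tri[, 1], tri[, 2], tri[, 3])
    fl[seq.int(f, by = 4L, length.out = ne), ] <-
      cbind(lo, tri[, 1] + tri[, 2] + tri[, 3] - lo - hi, hi)
  }
  fl
}

#' Add truss link elements for muscle wrapping paths
#'
#' Each wrapping path becomes a chain of axial-only (truss) elements: the
#' first path point must coincide with a mesh surface node (the strand
#' origin); subsequent joints become new nodes, each anchored to its
#' nearest mesh surface node by a short truss (the perpendicular
#' attachment). Links carry the bone material properties so they transfer
#' force with minimal deformation.
#'
#' @param system an [assemble_system()] result.
#' @param paths named list of point matrices (one polyline per wrapped
#'   strand).
#' @param area truss cross-section area (mm^2).
#' @return the augmented `fe_system` (expanded K and node table).
#' @export
add_link_elements <- function(system, paths, area = 1) {
  if (!length(paths)) return(system)
  mesh <- system$mesh
  Eb <- system$materials$E[match("link", system$materials$label)]
  if (is.na(Eb)) Eb <- system$materials$E[match("bone", system$materials$label)]
  surf <- system$surface %||% surface_nodes(mesh)
  snodes <- mesh$nodes[surf, , drop = FALSE]
  coords <- mesh$nodes
  extra <- NULL
  trusses <- list() # (node a id, node b id) with coordinates
  at_node <- function(p) {
    d2 <- colSums((t(coords) - p)^2)
    j <- which.min(d2)
    if (d2[j] < 1e-12) j else NA_integer_
  }
  find_node <- function(p) {
    j <- at_node(p)
    if (is.na(j)) stop("path origin is not a mesh node")
    if (!(j %in% surf)) stop("path node not on surface")
    j
  }
  nearest_surface <- function(p, k = 1) {
    d2 <- colSums((t(snodes) - p)^2)
    surf[order(d2)[seq_len(k)]]
  }
  nid <- nrow(coords)
  for (nm in names(paths)) {
    pts <- matrix(paths[[nm]], ncol = 3)
    a <- find_node(pts[1, ])
    prev <- a
    for (r in 2:nrow(pts)) {
      hit <- at_node(pts[r, ])
      if (!is.na(hit)) {
        # joint coincides with a mesh node: chain through it directly
        trusses[[length(trusses) + 1]] <- c(prev, hit)
        prev <- hit
      } else {
        # off-surface joint: new node with a short anchor to the nearest
        # surface node; two further anchors stabilize the joint (a truss
        # joint with fewer than three independent axial directions is a
        # mechanism in statics)
        nid <- nid + 1L
        extra <- rbind(extra, pts[r, ])
        trusses[[length(trusses) + 1]] <- c(prev, nid)
        for (an in nearest_surface(pts[r, ], k = 3))
          trusses[[length(trusses) + 1]] <- c(nid, an)
        prev <- nid
      }
    }
  }
  allc <- rbind(coords, extra)
  ndof <- 3L * nrow(allc)
  ii <- c(); jj <- c(); xx <- c()
  for (tr in trusses) {
    pa <- allc[tr[1], ]; pb <- allc[tr[2], ]
    d <- pb - pa
    len <- sqrt(sum(d^2))
    if (len < 1e-9) stop("zero-length link element segment")
    n <- d / len
    k <- Eb * area / len
    kb <- k * (n %o% n)
    dofs <- c(3 * (tr[1] - 1) + 1:3, 3 * (tr[2] - 1) + 1:3)
    Ke <- rbind(cbind(kb, -kb), cbind(-kb, kb))
    ii <- c(ii, rep(dofs, times = 6))
    jj <- c(jj, rep(dofs, each = 6))
    xx <- c(xx, as.vector(Ke))
  }
  Kl <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  K0 <- system$K
  Kbig <- Matrix::bdiag(K0, Matrix::Diagonal(ndof - system$ndof, 0))
  K <- Matrix::forceSymmetric(Kbig + (Kl + Matrix::t(Kl)) / 2)
  out <- system
  out$K <- K
  out$ndof <- ndof
  out$n_extra_nodes <- nrow(allc) - nrow(coords)
  out$extra_nodes <- extra
  out$trusses <- trusses
  out
}

#' Constraint scheme for a bite loading regime
#'
#' Exactly six scalar displacement constraints, the statically determinate
#' suppression of rigid-body motion used for every bite analysis:
#' molar - bite node dorsoventral (z); working-side TMJ dorsoventral and
#' anteroposterior (z, y); balancing-side TMJ all three.
#' incisor - bite node z; working-side TMJ all three; balancing-side TMJ
#' z and y. Axes: mediolateral = x, anteroposterior = y, dorsoventral = z.
#'
#' @param mode "molar" or "incisor".
#' @param bite_node,tmj_working,tmj_balancing node indices.
#' @return data.frame with columns node, axis (1 = x, 2 = y, 3 = z),
#'   value (prescribed displacement, all zero).
#' @export
constraint_scheme <- function(mode, bite_node, tmj_working, tmj_balancing) {
  if (mode == "molar") {
    df <- data.frame(
      node = c(bite_node, tmj_working, tmj_working, rep(tmj_balancing, 3)),
      axis = c(3L, 3L, 2L, 1L, 2L, 3L))
  } else if (mode == "incisor") {
    df <- data.frame(
      node = c(bite_node, rep(tmj_working, 3), tmj_balancing, tmj_balancing),
      axis = c(3L, 1L, 2L, 3L, 3L, 2L))
  } else stop("unknown constraint scheme: ", mode)
  df$value <- 0
  df
}

#' Solve the constrained static problem
#'
#' Direct sparse (Cholesky) solution of `K u = f` under prescribed
#' displacement constraints, with an optional conjugate-gradient fallback.
#' Reports an explicit error when the constraints leave rigid-body modes
#' (singular system).
#'
#' @param system an [assemble_system()] (optionally link-augmented) result.
#' @param constraints data.frame with columns node, axis (1..3), value
#'   (prescribed displacement, mm).
#' @param loads data.frame with columns node, fx, fy, fz (N).
#' @param method "direct" (default) or "cg" (Jacobi-preconditioned
#'   conjugate gradients, relative tolerance 1e-10).
#' @return an `fe_solution`: `u` (ndof), `reactions` at constrained DOFs,
#'   `constraints`, `loads`.
#' @export
solve_static <- function(system, constraints, loads, method = "direct") {
  K <- system$K
  ndof <- system$ndof
  f <- numeric(ndof)
  if (nrow(loads)) {
    for (c_ in 1:3) {
      idx <- 3 * (loads$node - 1) + c_
      comp <- loads[[c("fx", "fy", "fz")[c_]]]
      f[idx] <- f[idx] + comp
    }
  }
  cdof <- 3L * (constraints$node - 1L) + constraints$axis
  if (anyDuplicated(cdof)) stop("duplicate constraint on the same DOF")
  uc <- constraints$value
  free <- setdiff(seq_len(ndof), cdof)
  Kff <- K[free, free, drop = FALSE]
  rhs <- f[free] - as.numeric(K[free, cdof, drop = FALSE] %*% uc)
  uf <- if (method == "cg") {
    cg_solve(Kff, rhs, tol = 1e-10)
  } else {
    ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE),
                   error = function(e)
                     stop("singular system: constraints do not remove all ",
                          "rigid-body modes"))
    as.numeric(Matrix::solve(ch, rhs))
  }
  u <- numeric(ndof)
  u[free] <- uf
  u[cdof] <- uc
  res <- max(abs(as.numeric(Kff %*% uf) - rhs))
  if (!all(is.finite(uf)) || res > 1e-6 * max(1e-12, max(abs(rhs))))
    stop("singular system: constraints do not remove all rigid-body modes")
  r <- as.numeric(K %*% u) - f
  structure(list(u = u, reactions = r[cdof], constrained_dofs = cdof,
                 constraints = constraints, f = f),
            class = "fe_solution")
}

# Jacobi-preconditioned conjugate gradients
cg_solve <- function(A, b, tol = 1e-10, maxit = 10000) {
  d <- Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  b2 <- sqrt(sum(b^2))
  if (b2 == 0) return(x)
  for (i in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) < tol * b2) return(x)
    z <- r / d
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  warning("conjugate gradients did not reach tolerance")
  x
}

#' Per-element strain field
#'
#' Recovers the symmetric strain tensor per element (centroid value for
#' linear tets, average over the four quadrature points for quadratic),
#' its principal strains sorted `e1 >= e2 >= e3`, and the equivalent (von
#' Mises) strain, all in microstrain.
#'
#' @param solution an [solve_static()] result (or a displacement vector).
#' @param mesh the [tet_mesh()] that was solved.
#' @param nu_eff effective Poisson's ratio for the equivalent strain:
#'   "material" (default; per-element material value) or a single number.
#' @param materials material table (needed for `nu_eff = "material"`).
#' @param regime_id identifier carried into the result.
#' @return a `strain_field`: `tensor` (n x 6 Voigt, microstrain),
#'   `principal` (n x 3), `vm` (n), `regime_id`.
#' @export
element_strains <- function(solution, mesh, nu_eff = "material",
                            materials = default_materials(),
                            regime_id = NA_character_) {
  u <- if (is.list(solution)) solution$u else solution
  u <- u[seq_len(3L * nrow(mesh$nodes))] # drop link joint DOFs
  eps <- element_strains_cpp(mesh$nodes, mesh$elems, u) * 1e6
  pr <- principal_strains(eps)
  nu <- if (identical(nu_eff, "material")) {
    materials$nu[match(mesh$material, materials$label)]
  } else rep(nu_eff, nrow(eps))
  vm <- von_mises_strain(pr[, 1], pr[, 2], pr[, 3], nu)
  structure(list(tensor = eps, principal = pr, vm = vm,
                 regime_id = regime_id),
            class = "strain_field")
}

#' Principal strains of Voigt strain tensors
#'
#' Closed-form eigenvalues of the symmetric 3x3 strain tensors (vectorized
#' trigonometric method), sorted descending. Engineering shears are halved
#' to tensor shears internally.
#'
#' @param eps matrix (n x 6): exx, eyy, ezz, gxy, gyz, gzx.
#' @return matrix (n x 3): e1 >= e2 >= e3.
#' @export
principal_strains <- function(eps) {
  eps <- matrix(eps, ncol = 6)
  a11 <- eps[, 1]; a22 <- eps[, 2]; a33 <- eps[, 3]
  a12 <- eps[, 4] / 2; a23 <- eps[, 5] / 2; a13 <- eps[, 6] / 2
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  out <- cbind(a11, a22, a33)
  nz <- p > 1e-300
  if (any(nz)) {
    b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
    b12 <- a12 / p; b23 <- a23 / p; b13 <- a13 / p
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q + 2 * p * cos(phi)
    e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    e2 <- 3 * q - e1 - e3
    out[nz, ] <- cbind(e1, e2, e3)[nz, ]
  }
  diag_only <- !nz
  if (any(diag_only)) {
    sorted <- t(apply(cbind(a11, a22, a33)[diag_only, , drop = FALSE], 1,
                      sort, decreasing = TRUE))
    out[diag_only, ] <- sorted
  }
  colnames(out) <- c("e1", "e2", "e3")
  out
}

#' Equivalent (von Mises) strain
#'
#' Scalar combining the three principal strains,
#' `e_vm = sqrt(((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2) / 2) / (1 + nu_eff)`,
#' the effective-Poisson's-ratio convention of commercial FE solvers. It
#' vanishes for pure hydrostatic strain and is invariant to permuting the
#' principal values.
#'
#' @param e1,e2,e3 principal strains.
#' @param nu_eff effective Poisson's ratio (scalar or per element).
#' @return equivalent strain, same units as the inputs.
#' @export
von_mises_strain <- function(e1, e2, e3, nu_eff = 0.3) {
  sqrt(((e1 - e2)^2 + (e2 - e3)^2 + (e3 - e1)^2) / 2) / (1 + nu_eff)
}

#' Run one bite loading case
#'
#' Full FE analysis of a cranium mesh under one loading regime: assemble
#' (or reuse) the stiffness, add truss link chains for the wrapped
#' muscles, apply every strand force as a nodal load at its origin
#' landmark, constrain the bite and TMJ contact nodes per the regime's
#' scheme, solve, and recover element strains. Deterministic for fixed
#' inputs.
#'
#' @param mesh the phantom [tet_mesh()] (with landmark node sets).
#' @param materials material table.
#' @param regime a `load_regime` from [extract_load_regime()].
#' @param system optional pre-assembled [assemble_system()] to reuse.
#' @param link_area truss cross-section (mm^2).
#' @return a `strain_field` (regime id attached); the `fe_solution` is
#'   available as attribute "solution".
#' @export
run_load_case <- function(mesh, materials = default_materials(), regime,
                          system = NULL, link_area = 1) {
  if (is.null(system)) system <- assemble_system(mesh, materials)
  lookup <- function(nm) {
    s <- mesh$node_sets[[nm]]
    if (is.null(s) || !length(s)) stop("missing landmark node set: ", nm)
    s[1]
  }
  sys2 <- add_link_elements(system, regime$paths, area = link_area)
  onode <- vapply(regime$origin_landmark, lookup, 0L)
  loads <- data.frame(node = onode, fx = regime$force[, 1],
                      fy = regime$force[, 2], fz = regime$force[, 3])
  loads <- stats::aggregate(cbind(fx, fy, fz) ~ node, data = loads, FUN = sum)
  cons <- constraint_scheme(regime$constraint_scheme,
                            bite_node = lookup(regime$bite_landmark),
                            tmj_working = lookup(regime$tmj_working_landmark),
                            tmj_balancing = lookup(regime$tmj_balancing_landmark))
  sol <- solve_static(sys2, cons, loads)
  sf <- element_strains(sol, mesh, materials = materials,
                        regime_id = regime$id)
  attr(sf, "solution") <- sol
  sf
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("strain_field (%s): %d elements, max von Mises %.1f microstrain\n",
              x$regime_id, length(x$vm), max(x$vm)))
  invisible(x)
}
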