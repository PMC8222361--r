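# independent oracle: exhaustive grid search over the feasible set of the
# activation QP. Free activations are gridded; the remaining ones are
# solved from the equality constraints, and out-of-bound points discarded.
grid_search_qp <- function(contrib, required, weights, res = 0.01) {
  n <- ncol(contrib)
  m <- nrow(contrib)
  stopifnot(n - m >= 0, n <= 4)
  obj <- function(a) sum((a / weights)^2)
  best <- NULL; best_obj <- Inf
  free <- seq_len(n - m)
  bound <- setdiff(seq_len(n), free)
  Ab <- contrib[, bound, drop = FALSE]
  grid <- seq(0, 1, by = res)
  pts <- as.matrix(do.call(expand.grid, rep(list(grid), length(free))))
  if (length(free) == 0) pts <- matrix(numeric(), 1, 0)
  for (r in seq_len(nrow(pts))) {
    af <- as.numeric(pts[r, ])
    rhs <- required - if (length(free))
      as.numeric(contrib[, free, drop = FALSE] %*% af) else 0
    ab <- tryCatch(solve(Ab, rhs), error = function(e) NULL)
    if (is.null(ab) || any(ab < -1e-9) || any(ab > 1 + 1e-9)) next
    a <- numeric(n); a[free] <- af; a[bound] <- ab
    o <- obj(a)
    if (o < best_obj) { best_obj <- o; best <- a }
  }
  list(activation = best, objective = best_obj)
}


# nested-loop reference for the peak map (independent of the vectorized
# implementation)
peak_oracle <- function(fields, mesh) {
  bone <- which(mesh$material == "bone")
  vols <- element_volumes(mesh)[bone]
  out <- data.frame(element = bone, volume = vols, peak_vm = NA_real_,
                    argmax_index = NA_integer_, peak_e1 = NA_real_,
                    peak_e3 = NA_real_)
  for (r in seq_along(bone)) {
    e <- bone[r]
    best <- -Inf; bi <- NA_integer_; b1 <- -Inf; b3 <- Inf
    for (k in seq_along(fields)) {
      v <- fields[[k]]$vm[e]
      if (v > best) { best <- v; bi <- k } # ties keep the earliest regime
      b1 <- max(b1, fields[[k]]$principal[e, 1])
      b3 <- min(b3, fields[[k]]$principal[e, 3])
    }
    out$peak_vm[r] <- best; out$argmax_index[r] <- bi
    out$peak_e1[r] <- b1; out$peak_e3[r] <- b3
  }
  out
}


# uniaxial prescribed-displacement patch setup shared across FE tests
axial_patch <- function(mesh, mats, strain = 1e-3) {
  nn <- mesh$nodes
  L <- max(nn[, 1])
  cons <- rbind(
    data.frame(node = which(nn[, 1] == 0), axis = 1L, value = 0),
    data.frame(node = which(nn[, 1] == L), axis = 1L, value = strain * L),
    data.frame(node = 1L, axis = 2L, value = 0),
    data.frame(node = 1L, axis = 3L, value = 0),
    data.frame(node = which(nn[, 1] == 0 & nn[, 2] == max(nn[, 2]) &
                              nn[, 3] == 0)[1], axis = 3L, value = 0))
  sys <- assemble_system(mesh, mats)
  solve_static(sys, cons,
               data.frame(node = integer(), fx = numeric(),
                          fy = numeric(), fz = numeric()))
}

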