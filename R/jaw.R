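#' Jaw poses
#'
#' The mandible is a rigid body whose frame coincides with the cranium
#' frame in the closed pose. A pose is a sagittal gape rotation about the
#' mediolateral (x) axis through the line joining the two TMJ pivots,
#' followed by a frontal-plane excursion rotation about the
#' anteroposterior (y) axis through the TMJ midpoint, toward the working
#' side. Angles in degrees; excursion is non-negative by convention with
#' the direction carried by `side`.
#'
#' @param gape_deg sagittal opening angle (deg, >= 0 opens).
#' @param excursion_deg frontal excursion toward the working side (deg).
#' @param side working side, "L" (+x) or "R" (-x).
#' @param centre TMJ midpoint (rotation centre), length-3 (mm).
#' @return a `jaw_pose` object.
#' @export
jaw_pose <- function(gape_deg = 0, excursion_deg = 0, side = "R",
                     centre = c(0, 0, 0)) {
  s <- if (identical(side, "L")) 1 else -1
  a <- gape_deg * pi / 180
  Rs <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  phi <- -s * excursion_deg * pi / 180
  Rf <- rbind(c(cos(phi), 0, sin(phi)), c(0, 1, 0), c(-sin(phi), 0, cos(phi)))
  structure(list(gape_deg = gape_deg, excursion_deg = excursion_deg,
                 side = side, centre = centre, R = Rf %*% Rs),
            class = "jaw_pose")
}

#' Apply a jaw pose to mandible-frame points
#' @param pose a [jaw_pose()].
#' @param pts matrix (n x 3) or length-3 vector of mandible-frame points.
#' @return posed points, same shape.
#' @export
apply_pose <- function(pose, pts) {
  v <- is.vector(pts)
  p <- matrix(pts, ncol = 3)
  out <- sweep(sweep(p, 2, pose$centre) %*% t(pose$R), 2, pose$centre, "+")
  if (v) drop(out) else out
}

#' Muscle strand geometry at a pose
#'
#' Path length and unit lines of action of a strand whose origin and via
#' (wrapping) points are fixed to the cranium and whose insertion rides on
#' the mandible. The path is piecewise straight through the via points.
#'
#' @param strand a list/row with `origin` (or ox/oy/oz), optional `via`
#'   matrix, and `insertion` (or ix/iy/iz), all mm.
#' @param pose a [jaw_pose()] applied to the insertion.
#' @return list with `length` (mm), `u_origin` (unit pull direction on the
#'   cranium at the origin), `u_insertion` (unit pull direction on the
#'   mandible at the insertion), and `path` (points matrix at this pose).
#' @export
strand_kinematics <- function(strand, pose = jaw_pose()) {
  o <- strand_origin(strand)
  ins <- apply_pose(pose, strand_insertion(strand))
  via <- strand_via(strand)
  path <- rbind(o, via, matrix(ins, 1))
  seg <- diff(path)
  lens <- sqrt(rowSums(seg^2))
  if (any(lens < 1e-9))
    stop("degenerate strand: coincident consecutive path points")
  list(length = sum(lens),
       u_origin = seg[1, ] / lens[1],
       u_insertion = -seg[nrow(seg), ] / lens[length(lens)],
       path = path)
}

strand_origin <- function(s) {
  if (!is.null(s$origin)) as.numeric(s$origin) else c(s$ox, s$oy, s$oz)
}
strand_insertion <- function(s) {
  if (!is.null(s$insertion)) as.numeric(s$insertion) else c(s$ix, s$iy, s$iz)
}
strand_via <- function(s) {
  v <- s$via
  if (is.null(v)) return(matrix(numeric(), 0, 3))
  if (is.list(v)) v <- v[[1]]
  if (is.null(v)) matrix(numeric(), 0, 3) else matrix(v, ncol = 3)
}

#' Passive muscle tension
#'
#' A small exponential passive tension resists strand elongation beyond
#' the slack length and saturates at a fixed fraction of the maximum
#' isometric force (default 0.1%):
#' `T_p(L) = p_cap * F_max * (exp(k * s) - 1) / (exp(k * s_max) - 1)`
#' with strain `s = max(0, (L - L0) / L0)`, clipped at the cap.
#'
#' @param strand list/row with `f_max` (N), `L0` (slack length, mm) and
#'   optionally `p_cap` (default 0.001), `k` (default 3), `s_max`
#'   (cap strain, default 0.05).
#' @param length current strand length (mm).
#' @return passive force (N), a total function of `length >= 0`.
#' @export
passive_tension <- function(strand, length) {
  p_cap <- strand$p_cap %||% 0.001
  k <- strand$k %||% 3
  s_max <- strand$s_max %||% 0.05
  s <- pmax(0, (length - strand$L0) / strand$L0)
  cap <- p_cap * strand$f_max
  pmin(cap, cap * expm1(k * s) / expm1(k * s_max))
}

#' Build the synthetic jaw model
#'
#' Assembles the rigid-mandible musculoskeletal model that matches a
#' cranium phantom: 65 muscle strands per side (130 in total) from
#' [strand_layout()], TMJ pivot points, and tooth bite points. Slack
#' lengths are set to the strand lengths in the closed pose so passive
#' tension vanishes at occlusion.
#'
#' @param params a [phantom_params()] object (the jaw model shares the
#'   phantom's parametric geometry).
#' @param mass_kg mandible mass (kg), used only in dynamic mode.
#' @param passive list of passive-tension parameters `p_cap`, `k`, `s_max`.
#' @return an object of class `jaw_model`.
#' @export
build_jaw_model <- function(params = phantom_params(), mass_kg = 0.02,
                            passive = list(p_cap = 0.001, k = 3,
                                           s_max = 0.05)) {
  strands <- strand_layout(params)
  tmj_l <- tmj_point(params)
  tmj_r <- tmj_l * c(-1, 1, 1)
  centre <- (tmj_l + tmj_r) / 2
  closed <- jaw_pose(centre = centre)
  strands$L0 <- vapply(seq_len(nrow(strands)), function(i)
    strand_kinematics(strands[i, ], closed)$length, 0)
  strands$p_cap <- passive$p_cap
  strands$k <- passive$k
  strands$s_max <- passive$s_max
  teeth <- tooth_layout(params)
  h <- params$elem_size
  tips <- do.call(rbind, lapply(c("L", "R"), function(sd) {
    s <- if (sd == "L") 1 else -1
    data.frame(tooth = teeth$id, side = sd,
               x = s * floor(teeth$x / h) * h, y = floor(teeth$y / h) * h,
               z = -params$crown_height, stringsAsFactors = FALSE)
  }))
  # box-estimate inertia of the mandible about the TMJ midpoint (kg mm^2)
  dims <- c(params$width, params$length, params$height / 2)
  inertia <- diag(mass_kg * (sum(dims^2) - dims^2) / 12) +
    mass_kg * (sum(centre^2) * diag(3) - centre %o% centre)
  structure(list(params = params, strands = strands, tmj_left = tmj_l,
                 tmj_right = tmj_r, centre = centre, teeth = tips,
                 mass_kg = mass_kg, inertia = inertia),
            class = "jaw_model")
}

#' @export
print.jaw_model <- function(x, ...) {
  cat(sprintf("jaw_model: %d muscle strands (%d per side), %d bite points per side\n",
              nrow(x$strands), nrow(x$strands) / 2, nrow(x$teeth) / 2))
  invisible(x)
}

#' Bite-cycle specification
#'
#' A unilateral bite cycle with three phases: opening (to the maximum
#' gape), fast closing (to food-bolus contact, with the working-side
#' frontal excursion for molar bites), and slow closing (bolus
#' processing: the vertical resistance ramps with compression to `R_v`
#' while a constant mediolateral resistance `R_ml` opposes the return to
#' the midline). Incisor cycles are mirror-symmetric: excursion and
#' mediolateral resistance are zero.
#'
#' @param mode "molar" or "incisor".
#' @param tooth bite tooth id (e.g. "incisor", "cheek3").
#' @param side working side, "L" or "R".
#' @param gape_deg maximum mid-sagittal gape (deg; default 12).
#' @param excursion_deg working-side frontal excursion (deg; default 5.5
#'   for molar, 0 for incisor).
#' @param R_v vertical bolus resistance at full compression (N; default 30).
#' @param R_ml mediolateral bolus resistance (N; default 30, molar only).
#' @param t_open,t_fast,t_slow phase durations (s).
#' @param dt time step (s).
#' @param contact_gape_deg gape at bolus contact (deg); the bolus is
#'   compressed completely when the gape returns to zero.
#' @return a `bite_cycle_spec` object.
#' @export
bite_cycle_spec <- function(mode = c("molar", "incisor"), tooth = "cheek3",
                            side = "R",
                            gape_deg = 12,
                            excursion_deg = if (mode == "molar") 5.5 else 0,
                            R_v = 30,
                            R_ml = if (mode == "molar") 30 else 0,
                            t_open = 0.12, t_fast = 0.08, t_slow = 0.15,
                            dt = 0.005, contact_gape_deg = 2) {
  mode <- match.arg(mode)
  if (any(c(t_open, t_fast, t_slow, dt) <= 0))
    stop("phase durations and time step must be strictly positive")
  if (mode == "incisor" && excursion_deg != 0)
    stop("incisor cycles are symmetric: excursion must be 0")
  if (mode == "molar" && excursion_deg <= 0)
    stop("molar cycles require a positive working-side excursion")
  structure(list(mode = mode, tooth = tooth, side = side,
                 gape_deg = gape_deg, excursion_deg = excursion_deg,
                 R_v = R_v, R_ml = R_ml, t_open = t_open, t_fast = t_fast,
                 t_slow = t_slow, dt = dt,
                 contact_gape_deg = contact_gape_deg),
            class = "bite_cycle_spec")
}

# prescribed pose angles at time t for a spec; returns list(phase, gape,
# excursion, compression in [0,1])
cycle_profile <- function(spec, t) {
  T1 <- spec$t_open; T2 <- T1 + spec$t_fast; T3 <- T2 + spec$t_slow
  ramp <- function(tau) (1 - cos(pi * pmin(pmax(tau, 0), 1))) / 2
  if (t <= T1) {
    list(phase = "opening", gape = spec$gape_deg * ramp(t / T1),
         excursion = 0, compression = 0)
  } else if (t <= T2) {
    tau <- (t - T1) / spec$t_fast
    list(phase = "fast_close",
         gape = spec$contact_gape_deg +
           (spec$gape_deg - spec$contact_gape_deg) * (1 - ramp(tau)),
         excursion = spec$excursion_deg * ramp(tau), compression = 0)
  } else {
    tau <- min((t - T2) / spec$t_slow, 1)
    list(phase = "slow_close", gape = spec$contact_gape_deg * (1 - tau),
         excursion = spec$excursion_deg * (1 - tau), compression = tau)
  }
}

# external bolus wrench (force, moment about jaw centre) on the mandible
# at time t; also returns the bite reaction force vector
bolus_load <- function(jaw, spec, prof) {
  tip <- jaw$teeth[jaw$teeth$tooth == spec$tooth &
                     jaw$teeth$side == spec$side, ]
  if (nrow(tip) != 1) stop("unknown bite tooth: ", spec$tooth)
  s <- if (spec$side == "L") 1 else -1
  Fv <- c(0, 0, -spec$R_v * prof$compression)
  Fml <- if (spec$mode == "molar" && prof$phase == "slow_close" &&
             prof$excursion > 1e-9) c(s * spec$R_ml, 0, 0) else c(0, 0, 0)
  Fb <- Fv + Fml
  p <- c(tip$x, tip$y, tip$z)
  r <- p - jaw$centre
  list(force = Fb, moment = cross3(r, Fb), point = p)
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Required generalized load for a prescribed jaw motion
#'
#' The net force/moment (about the TMJ midpoint) that the muscles and TMJ
#' reactions together must supply at time `t` of a bite cycle: minus the
#' external bolus wrench, plus (in dynamic mode) the inertial wrench of
#' the prescribed motion obtained by central finite differences.
#'
#' @param jaw a [build_jaw_model()] object.
#' @param spec a [bite_cycle_spec()] (the prescribed trajectory).
#' @param t time (s).
#' @param dynamic include rigid-body inertia terms (default FALSE:
#'   quasi-static, appropriate for slow chewing).
#' @param gravity gravitational acceleration (mm/s^2) along -z, default 0.
#' @return length-6 vector `c(Fx, Fy, Fz, Mx, My, Mz)` (N, N mm).
#' @export
inverse_required_load <- function(jaw, spec, t, dynamic = FALSE,
                                  gravity = 0) {
  prof <- cycle_profile(spec, t)
  bl <- bolus_load(jaw, spec, prof)
  req <- -c(bl$force, bl$moment)
  if (gravity > 0) {
    Fg <- c(0, 0, -jaw$mass_kg * gravity / 1000)
    req <- req - c(Fg, cross3(c(0, 0, -8) , Fg)) # mass centre ~8 mm below pivot
  }
  if (dynamic) {
    dt <- 1e-4
    ang <- function(tt) {
      p <- cycle_profile(spec, max(tt, 0))
      s <- if (spec$side == "L") 1 else -1
      c(p$gape * pi / 180, -s * p$excursion * pi / 180, 0)
    }
    a0 <- ang(t - dt); a1 <- ang(t); a2 <- ang(t + dt)
    alpha <- (a2 - 2 * a1 + a0) / dt^2   # angular acceleration (x, y, z)
    Mi <- jaw$inertia %*% alpha / 1000   # kg mm^2 / s^2 -> N mm
    req <- req + c(0, 0, 0, as.numeric(Mi))
  }
  req
}

#' Solve for muscle activations (DGO-style quadratic program)
#'
#' Given per-strand generalized-force contributions at full activation,
#' finds activations in `[0, 1]` that reproduce the required load on the
#' free axes exactly while minimizing `sum((a_i / w_i)^2)`, so strands
#' with larger EMG weights take proportionally more of the load. The
#' contributions already account for the instantaneous strand
#' orientations at the current pose.
#'
#' @param contrib matrix (n_free x n_strands): generalized force per
#'   strand at activation 1 (includes F_max).
#' @param required length-n_free vector: required generalized load net of
#'   passive-tension contributions.
#' @param weights EMG weights in (0, 1]; a small floor is applied.
#' @param w_floor weight floor (avoids division by zero).
#' @return list with `activation`, `achieved`, `residual`.
#' @export
dgo_solve <- function(contrib, required, weights = rep(1, ncol(contrib)),
                      w_floor = 0.05) {
  contrib <- matrix(contrib, nrow = length(required))
  n <- ncol(contrib)
  w <- pmax(weights, w_floor)
  if (max(abs(required)) < 1e-12) {
    # required load zero: minimum-norm solution is identically zero
    return(list(activation = numeric(n), achieved = required * 0,
                residual = required * 0))
  }
  C <- diag(2 / w^2, n)
  sol <- tryCatch(
    pracma::quadprog(C, rep(0, n), Aeq = contrib, beq = required,
                     lb = rep(0, n), ub = rep(1, n)),
    error = function(e) NULL)
  ok <- !is.null(sol) && isTRUE(sol$eflag > 0)
  if (ok) {
    a <- pmin(pmax(sol$xmin, 0), 1)
    ach <- as.numeric(contrib %*% a)
    if (max(abs(ach - required)) < 1e-6 * max(1, max(abs(required))))
      return(list(activation = a, achieved = ach, residual = ach - required))
  }
  # infeasible: bounded least squares to identify the violated component
  H <- 2 * (crossprod(contrib) + diag(1e-9, n))
  f <- 2 * as.numeric(crossprod(contrib, required))
  ls <- pracma::quadprog(H, -f, lb = rep(0, n), ub = rep(1, n))
  resid <- as.numeric(contrib %*% ls$xmin) - required
  k <- which.max(abs(resid))
  stop(sprintf(paste0("insufficient muscle capacity: required load ",
                      "component %d unreachable (shortfall %.3g)"),
               k, resid[k]))
}

# EMG weight profile (synthetic trapezoidal stand-in, per muscle group):
# working-side closers fully weighted in the slow-closing phase, balancing
# side down-weighted for molar bites; incisor bites weight both sides
# equally (symmetric task).
emg_weights <- function(jaw, spec, prof, balancing_weight = 0.6) {
  w <- rep(0.3, nrow(jaw$strands))
  if (prof$phase == "slow_close") {
    working <- jaw$strands$side == spec$side
    w[working] <- 1
    w[!working] <- if (spec$mode == "molar") balancing_weight else 1
  } else if (prof$phase == "fast_close") {
    w[] <- 0.6
  }
  w
}

#' Simulate a bite cycle
#'
#' Drives the prescribed jaw motion through the three bite phases and at
#' each time step solves the activation quadratic program so the muscles
#' supply the required load on the free axes (sagittal-moment axis;
#' plus the frontal-moment axis for molar bites). Records poses, strand
#' forces, bite force and TMJ reactions over time.
#'
#' @param jaw a [build_jaw_model()].
#' @param spec a [bite_cycle_spec()].
#' @param dynamic include inertia terms (default FALSE: quasi-static).
#' @return a `bite_trajectory` object.
#' @export
simulate_bite_cycle <- function(jaw, spec, dynamic = FALSE) {
  times <- seq(0, spec$t_open + spec$t_fast + spec$t_slow, by = spec$dt)
  ns <- nrow(jaw$strands)
  strand_list <- lapply(seq_len(ns), function(i) as.list(jaw$strands[i, ]))
  nt <- length(times)
  axes <- if (spec$mode == "molar") c(1, 2) else 1 # moment axes x (,y)
  act <- matrix(0, nt, ns, dimnames = list(NULL, jaw$strands$id))
  pas <- matrix(0, nt, ns, dimnames = list(NULL, jaw$strands$id))
  bite <- numeric(nt)
  bite_vec <- matrix(0, nt, 3)
  tmj_w <- matrix(0, nt, 3)
  tmj_b <- matrix(0, nt, 3)
  phase <- character(nt)
  gape <- numeric(nt); exc <- numeric(nt)
  poses <- vector("list", nt)
  for (it in seq_len(nt)) {
    t <- times[it]
    prof <- cycle_profile(spec, t)
    pose <- jaw_pose(prof$gape, prof$excursion, spec$side, jaw$centre)
    poses[[it]] <- pose
    phase[it] <- prof$phase
    gape[it] <- prof$gape; exc[it] <- prof$excursion
    kin <- lapply(strand_list, strand_kinematics, pose = pose)
    pas[it, ] <- vapply(seq_len(ns), function(i)
      passive_tension(strand_list[[i]], kin[[i]]$length), 0)
    # generalized contributions (moments about centre) per unit force
    momu <- t(vapply(seq_len(ns), function(i) {
      p_ins <- kin[[i]]$path[nrow(kin[[i]]$path), ]
      cross3(p_ins - jaw$centre, kin[[i]]$u_insertion)
    }, numeric(3)))
    req6 <- inverse_required_load(jaw, spec, t, dynamic = dynamic)
    reqM <- req6[3 + axes]
    pasM <- as.numeric(t(momu[, axes, drop = FALSE]) %*% pas[it, ])
    contrib <- t(momu[, axes, drop = FALSE] * jaw$strands$f_max)
    wts <- emg_weights(jaw, spec, prof)
    if (max(abs(reqM)) < 1e-9) {
      # no external load to work against: muscles stay inactive and the
      # (tiny, capped) passive tensions are carried by the joint
      act[it, ] <- 0
    } else {
      sol <- dgo_solve(contrib, reqM - pasM, wts)
      act[it, ] <- sol$activation
    }
    bl <- bolus_load(jaw, spec, prof)
    bite_vec[it, ] <- -bl$force # reaction at the tooth (force on the food)
    bite[it] <- sqrt(sum(bl$force^2))
    # TMJ reactions close the full 6-component balance (minimum norm
    # along the intercondylar axis, which is statically indeterminate)
    fstr <- act[it, ] * jaw$strands$f_max + pas[it, ]
    Fm <- colSums(t(vapply(seq_len(ns), function(i)
      kin[[i]]$u_insertion, numeric(3))) * fstr)
    Mm <- as.numeric(t(momu) %*% fstr)
    resid <- -(c(Fm, Mm) + c(bl$force, bl$moment))
    rw <- (if (spec$side == "L") jaw$tmj_left else jaw$tmj_right) - jaw$centre
    rb <- (if (spec$side == "L") jaw$tmj_right else jaw$tmj_left) - jaw$centre
    X <- function(r) rbind(c(0, -r[3], r[2]), c(r[3], 0, -r[1]),
                           c(-r[2], r[1], 0))
    A <- rbind(cbind(diag(3), diag(3)), cbind(X(rw), X(rb)))
    sv <- svd(A)
    pos <- sv$d > 1e-9 * sv$d[1]
    Ft <- sv$v[, pos] %*% ((t(sv$u[, pos]) %*% resid) / sv$d[pos])
    tmj_w[it, ] <- Ft[1:3]
    tmj_b[it, ] <- Ft[4:6]
  }
  structure(list(time = times, phase = phase, gape_deg = gape,
                 excursion_deg = exc, activation = act, passive = pas,
                 strand_force = sweep(act, 2, jaw$strands$f_max, "*") + pas,
                 bite_force = bite, bite_force_vec = bite_vec,
                 tmj_working = tmj_w, tmj_balancing = tmj_b,
                 poses = poses, spec = spec, jaw = jaw),
            class = "bite_trajectory")
}

#' @export
print.bite_trajectory <- function(x, ...) {
  cat(sprintf("bite_trajectory: %s bite on tooth %s (%s side), %d steps\n",
              x$spec$mode, x$spec$tooth, x$spec$side, length(x$time)))
  cat(sprintf("  max gape %.2f deg, max excursion %.2f deg, max bite force %.2f N\n",
              max(x$gape_deg), max(x$excursion_deg), max(x$bite_force)))
  invisible(x)
}

#' Extract the FE loading regime from a bite trajectory
#'
#' Snapshots the cycle at the instant of maximum bite force (earliest
#' instant on ties) and converts the strand forces, along their
#' instantaneous lines of action, into nodal loads at the strand origins,
#' together with wrapping paths, the bite contact point and the TMJ
#' contact points. Landmark references are stored by name and resolved
#' against a phantom mesh at solve time.
#'
#' @param traj a [simulate_bite_cycle()] result.
#' @param regime_id identifier for the regime.
#' @return a `load_regime` object.
#' @export
extract_load_regime <- function(traj, regime_id = NULL) {
  it <- which.max(traj$bite_force)
  jaw <- traj$jaw
  spec <- traj$spec
  pose <- traj$poses[[it]]
  ns <- nrow(jaw$strands)
  mag <- traj$strand_force[it, ]
  origins <- matrix(0, ns, 3)
  forces <- matrix(0, ns, 3)
  paths <- list()
  for (i in seq_len(ns)) {
    kin <- strand_kinematics(jaw$strands[i, ], pose)
    origins[i, ] <- kin$path[1, ]
    forces[i, ] <- mag[i] * kin$u_origin
    via <- strand_via(jaw$strands[i, ])
    if (nrow(via) > 0)
      paths[[jaw$strands$id[i]]] <- rbind(kin$path[1, , drop = FALSE], via)
  }
  if (is.null(regime_id))
    regime_id <- sprintf("%s_%s_%s", spec$mode, spec$tooth, spec$side)
  structure(list(
    id = regime_id, mode = spec$mode, side = spec$side, tooth = spec$tooth,
    strand_id = jaw$strands$id, origin = origins, force = forces,
    force_mag = mag, paths = paths,
    origin_landmark = paste0("origin_", jaw$strands$id),
    bite_landmark = paste0("tooth_tip_", spec$tooth, "_", spec$side),
    bite_force = traj$bite_force[it],
    bite_force_vec = traj$bite_force_vec[it, ],
    tmj_working_landmark = paste0("tmj_", if (spec$side == "L") "left" else "right"),
    tmj_balancing_landmark = paste0("tmj_", if (spec$side == "L") "right" else "left"),
    tmj_working_force = traj$tmj_working[it, ],
    tmj_balancing_force = traj$tmj_balancing[it, ],
    constraint_scheme = spec$mode, snapshot_time = traj$time[it]),
    class = "load_regime")
}

#' @export
print.load_regime <- function(x, ...) {
  cat(sprintf("load_regime %s: %s bite, tooth %s, working side %s\n",
              x$id, x$mode, x$tooth, x$side))
  cat(sprintf("  bite force %.2f N; total muscle force %.2f N; %d wrapped paths\n",
              x$bite_force, sum(x$force_mag), length(x$paths)))
  invisible(x)
}

#' Reflect a loading regime across the mid-sagittal plane
#'
#' Mirrors every point and force vector (x -> -x), swaps the working side
#' and remaps strand and landmark names left/right. Reflecting twice is
#' the identity.
#'
#' @param regime a [extract_load_regime()] result.
#' @return the mirrored `load_regime`.
#' @export
reflect_load_regime <- function(regime) {
  swap_lr <- function(s) {
    s <- gsub("_L_", "_\001_", s, fixed = TRUE)
    s <- gsub("_R_", "_L_", s, fixed = TRUE)
    s <- gsub("_\001_", "_R_", s, fixed = TRUE)
    s <- sub("_L$", "_\001", s)
    s <- sub("_R$", "_L", s)
    s <- sub("_\001$", "_R", s)
    s <- sub("^tmj_left$", "tmj_\001", s)
    s <- sub("^tmj_right$", "tmj_left", s)
    sub("^tmj_\001$", "tmj_right", s)
  }
  r <- regime
  r$side <- if (regime$side == "L") "R" else "L"
  r$strand_id <- swap_lr(regime$strand_id)
  r$origin_landmark <- swap_lr(regime$origin_landmark)
  r$bite_landmark <- swap_lr(regime$bite_landmark)
  r$tmj_working_landmark <- swap_lr(regime$tmj_working_landmark)
  r$tmj_balancing_landmark <- swap_lr(regime$tmj_balancing_landmark)
  mir <- function(m) {
    m[, 1] <- -m[, 1]
    m
  }
  r$origin <- mir(regime$origin)
  r$force <- mir(regime$force)
  r$bite_force_vec <- regime$bite_force_vec * c(-1, 1, 1)
  r$tmj_working_force <- regime$tmj_working_force * c(-1, 1, 1)
  r$tmj_balancing_force <- regime$tmj_balancing_force * c(-1, 1, 1)
  r$paths <- lapply(regime$paths, mir)
  names(r$paths) <- swap_lr(names(regime$paths))
  r$id <- swap_lr(regime$id)
  r
}

#' Enumerate all bite loading regimes
#'
#' Simulates one right-side bite cycle per bite point (an incisor cycle
#' at the incisor, a molar cycle at each cheek tooth) and reflects each
#' to the left, giving `2 * (1 + n_cheek_teeth)` regimes (12 with the
#' default 5 cheek teeth per side).
#'
#' @param jaw a [build_jaw_model()].
#' @param spec_defaults optional list of [bite_cycle_spec()] arguments to
#'   override per cycle (e.g. time step).
#' @param teeth optional subset of bite tooth ids (default: all).
#' @return list of `load_regime` objects with unique, stable ids.
#' @export
enumerate_bite_regimes <- function(jaw, spec_defaults = list(),
                                   teeth = NULL) {
  teeth <- teeth %||% unique(jaw$teeth$tooth)
  if (!all(teeth %in% jaw$teeth$tooth))
    stop("unknown bite tooth id(s)")
  regimes <- list()
  for (tooth in teeth) {
    mode <- if (tooth == "incisor") "incisor" else "molar"
    args <- utils::modifyList(list(mode = mode, tooth = tooth, side = "R"),
                              spec_defaults)
    spec <- do.call(bite_cycle_spec, args)
    traj <- simulate_bite_cycle(jaw, spec)
    right <- extract_load_regime(traj)
    left <- reflect_load_regime(right)
    regimes[[right$id]] <- right
    regimes[[left$id]] <- left
  }
  regimes
}
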