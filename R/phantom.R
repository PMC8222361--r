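#' Parameters of the synthetic cranium phantom
#'
#' The phantom is a deliberately simple, mirror-symmetric, shell-like box
#' "cranium" built on a structured voxel grid: solid bone walls, a
#' fenestrated lateral wall on each side (discrete vertical struts), tooth
#' pegs (1 incisor + `n_cheek_teeth` cheek teeth per side) passing through
#' the ventral wall, each with a pulp core and wrapped in a periodontal
#' ligament (PDL) layer inside its socket, and suture seams crossing the
#' roof. Its purpose is to exercise every material type, the fenestration
#' concept and left/right symmetry - not anatomical realism.
#'
#' All lengths in mm. The voxel grid has a single element size `elem_size`;
#' PDL, suture and shell thicknesses must be at least two element sizes so
#' thin structures carry at least two elements through their thickness.
#'
#' @param length,width,height outer dimensions (mm): length runs
#'   anteroposterior (y, 0 = anterior), width mediolateral (x, symmetric
#'   about 0), height dorsoventral (z, roof at `height`).
#' @param shell shell (wall) thickness (mm).
#' @param elem_size voxel edge length (mm); must divide all dimensions.
#' @param n_fenestrations number of rectangular openings per lateral wall
#'   (0 = solid wall).
#' @param strut_width width of the bone struts between openings (mm).
#' @param n_cheek_teeth cheek teeth per side (default 5: two premolars and
#'   three molars, plus the incisor).
#' @param tooth_width tooth peg cross-section width (mm).
#' @param pdl_thickness PDL layer thickness around each tooth root (mm).
#' @param suture_thickness suture seam thickness (mm).
#' @param suture_layout character subset of `c("coronal", "sagittal")`:
#'   seams crossing the roof transversely and/or along the midline.
#' @param crown_height how far tooth pegs protrude ventrally (mm).
#' @param seed integer seed recorded with the parameters (the phantom
#'   itself is deterministic; the seed is used by any randomized fixtures
#'   derived from it).
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(length = 64, width = 24, height = 16,
                           shell = 2, elem_size = 1,
                           n_fenestrations = 4, strut_width = 2,
                           n_cheek_teeth = 5, tooth_width = 3,
                           pdl_thickness = 2, suture_thickness = 2,
                           suture_layout = c("coronal", "sagittal"),
                           crown_height = 4, seed = 1L) {
  p <- list(length = length, width = width, height = height, shell = shell,
            elem_size = elem_size, n_fenestrations = n_fenestrations,
            strut_width = strut_width, n_cheek_teeth = n_cheek_teeth,
            tooth_width = tooth_width, pdl_thickness = pdl_thickness,
            suture_thickness = suture_thickness,
            suture_layout = suture_layout, crown_height = crown_height,
            seed = as.integer(seed))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  h <- p$elem_size
  if (h <= 0) stop("elem_size must be positive")
  for (nm in c("length", "width", "height", "shell", "strut_width",
               "tooth_width", "pdl_thickness", "suture_thickness",
               "crown_height"))
    if (abs(p[[nm]] / h - round(p[[nm]] / h)) > 1e-9)
      stop(sprintf("%s must be a multiple of elem_size", nm))
  if ((p$width / h) %% 2 != 0)
    stop("width must span an even number of elements (mirror symmetry)")
  if (p$pdl_thickness < 2 * h - 1e-12)
    stop("pdl_thickness below two element sizes through-thickness")
  if (p$suture_thickness < 2 * h - 1e-12)
    stop("suture_thickness below two element sizes through-thickness")
  if (p$shell < 2 * h - 1e-12)
    stop("shell thickness below two element sizes through-thickness")
  if (p$n_fenestrations > 0 && p$strut_width < h - 1e-12)
    stop("strut_width incompatible with element size")
  if (p$n_cheek_teeth < 1) stop("need at least one cheek tooth per side")
  invisible(p)
}

# Tooth centres (x > 0 side), in mm grid-aligned so that a block of
# tooth_width cells is centred on them. Returns data.frame(id, x, y).
tooth_layout <- function(p) {
  h <- p$elem_size
  half_cells <- p$tooth_width / h / 2
  # centre must sit on a cell boundary (even cell count) or centre (odd)
  snap <- function(v) {
    cells <- round(v / h)
    if ((p$tooth_width / h) %% 2 == 0) cells * h else (cells + 0.5) * h
  }
  x_inc <- snap(4.5 * p$length / 64)
  x_cheek <- snap(6.5 * p$length / 64)
  pitch <- p$tooth_width + 2 * p$pdl_thickness + h
  y0 <- snap(p$length * 0.3)
  ys <- y0 + pitch * (seq_len(p$n_cheek_teeth) - 1)
  y_inc <- snap(p$shell + p$pdl_thickness + p$tooth_width / 2 + h)
  d <- data.frame(
    id = c("incisor", paste0("cheek", seq_len(p$n_cheek_teeth))),
    x = c(x_inc, rep(x_cheek, p$n_cheek_teeth)),
    y = c(y_inc, ys), stringsAsFactors = FALSE)
  ymax <- max(d$y) + p$tooth_width / 2 + p$pdl_thickness
  if (ymax > p$length - p$shell)
    stop("tooth row does not fit inside the phantom; increase length")
  d
}

#' Build the synthetic cranium phantom
#'
#' Generates the labelled, conforming, mirror-symmetric voxel-tetrahedral
#' phantom described in [phantom_params()], with landmark node sets:
#' `tmj_left`, `tmj_right`, `tooth_tip_<id>_<L|R>` for every tooth,
#' `origin_<strand id>` for every muscle strand origin, and
#' `midsagittal_plane`.
#'
#' @param params a [phantom_params()] object.
#' @param order element order (1 or 2).
#' @return a [tet_mesh()].
#' @export
make_cranium_phantom <- function(params = phantom_params(), order = 1) {
  p <- validate_phantom_params(params)
  h <- p$elem_size
  W2 <- p$width / 2
  nx <- as.integer(round(p$width / h))
  ny <- as.integer(round(p$length / h))
  nzc <- as.integer(round(p$crown_height / h)) # cells below z = 0
  nz <- as.integer(round(p$height / h)) + nzc
  origin <- c(-W2, 0, -p$crown_height)
  # cell centres
  cx <- origin[1] + (seq_len(nx) - 0.5) * h
  cy <- origin[2] + (seq_len(ny) - 0.5) * h
  cz <- origin[3] + (seq_len(nz) - 0.5) * h
  CX <- array(rep(cx, times = ny * nz), c(nx, ny, nz))
  CY <- array(rep(rep(cy, each = nx), times = nz), c(nx, ny, nz))
  CZ <- array(rep(cz, each = nx * ny), c(nx, ny, nz))

  t <- p$shell
  H <- p$height
  L <- p$length
  lab <- array("", c(nx, ny, nz))

  inbox <- CZ > 0 # the cranium box proper; below 0 only tooth crowns exist
  floorc <- inbox & CZ < t
  roof <- CZ > H - t
  antero <- inbox & CY < t
  postero <- inbox & CY > L - t
  lateral <- inbox & abs(CX) > W2 - t & CZ >= t & CZ <= H - t &
    CY >= t & CY <= L - t
  lab[floorc | roof | antero | postero | lateral] <- "bone"

  # fenestration: openings in each lateral wall within a window
  if (p$n_fenestrations > 0) {
    yf0 <- t + 2 * h
    # window stays anterior of the muscle attachment field (posterior 22 mm)
    yf1 <- min(L * 0.66, L - 22)
    if (yf1 - yf0 < p$n_fenestrations * h + (p$n_fenestrations - 1) * p$strut_width)
      stop("fenestration window incompatible with phantom length")
    Lw <- yf1 - yf0
    nfen <- p$n_fenestrations
    wo <- (Lw - (nfen - 1) * p$strut_width) / nfen
    if (wo < h) stop("fenestration openings incompatible with element size")
    open <- array(FALSE, c(nx, ny, nz))
    for (q in seq_len(nfen)) {
      a <- yf0 + (q - 1) * (wo + p$strut_width)
      open <- open | (CY > a & CY < a + wo)
    }
    drop <- lateral & open & CZ > t & CZ < H - t
    lab[drop] <- ""
  }

  # suture seams crossing the roof (full thickness of the roof shell)
  if ("coronal" %in% p$suture_layout) {
    ysut <- round(L * 0.6 / h) * h
    lab[roof & abs(CY - ysut) < p$suture_thickness / 2] <- "suture"
  }
  if ("sagittal" %in% p$suture_layout) {
    lab[roof & abs(CX) < p$suture_thickness / 2] <- "suture"
  }

  # teeth: peg through the ventral wall, pulp core, PDL socket ring
  teeth <- tooth_layout(p)
  tw2 <- p$tooth_width / 2
  ring2 <- tw2 + p$pdl_thickness
  pulp_top <- t
  pulp_bot <- -min(p$crown_height / 2, p$crown_height - h)
  for (s in c(1, -1)) {
    for (r in seq_len(nrow(teeth))) {
      dx <- abs(CX - s * teeth$x[r])
      dy <- abs(CY - teeth$y[r])
      block <- dx < tw2 & dy < tw2 & CZ > -p$crown_height & CZ < t
      ring <- dx < ring2 & dy < ring2 & !(dx < tw2 & dy < tw2) &
        CZ > 0 & CZ < t
      pulp <- dx < h & dy < h & CZ > pulp_bot & CZ < pulp_top &
        (p$tooth_width / h) >= 3
      lab[ring] <- "pdl"
      lab[block] <- "tooth"
      lab[block & pulp] <- "pulp"
    }
  }

  keep <- lab != ""
  # landmark node sets, addressed by grid node ids
  npx <- nx + 1L; npy <- ny + 1L
  node_id_at <- function(pt) {
    gi <- round((pt[1] - origin[1]) / h)
    gj <- round((pt[2] - origin[2]) / h)
    gk <- round((pt[3] - origin[3]) / h)
    off <- max(abs(c(pt[1] - (origin[1] + gi * h), pt[2] - (origin[2] + gj * h),
                     pt[3] - (origin[3] + gk * h))))
    if (off > 1e-9 || gi < 0 || gi > nx || gj < 0 || gj > ny ||
        gk < 0 || gk > nz)
      stop(sprintf("landmark (%g, %g, %g) is not a grid node",
                   pt[1], pt[2], pt[3]))
    as.integer(1L + gi + npx * (gj + npy * gk)) # grid id before compression
  }
  lmk <- landmark_points(p)
  node_sets <- lapply(lmk, function(pts) {
    apply(matrix(pts, ncol = 3), 1, node_id_at)
  })
  mesh <- voxel_tet_mesh(keep, lab, origin, h, node_sets = node_sets)
  lost <- names(node_sets)[lengths(mesh$node_sets) < lengths(node_sets)]
  if (length(lost))
    stop("landmark nodes fell outside the mesh: ",
         paste(lost, collapse = ", "))
  mesh$node_sets$midsagittal_plane <- which(abs(mesh$nodes[, 1]) < 1e-9)
  attr(mesh, "phantom_params") <- p
  mesh
}

# Landmark target points (exact grid nodes) for the phantom: TMJs, tooth
# tips, and all muscle strand origins / via anchor points.
landmark_points <- function(p) {
  h <- p$elem_size
  W2 <- p$width / 2
  snapf <- function(v) floor(v / h) * h
  teeth <- tooth_layout(p)
  out <- list()
  tmj <- tmj_point(p)
  out$tmj_right <- c(-tmj[1], tmj[2], tmj[3])
  out$tmj_left <- tmj
  for (s in c(1, -1)) {
    sd <- if (s > 0) "L" else "R"
    for (r in seq_len(nrow(teeth))) {
      tip <- c(s * snapf(teeth$x[r]), snapf(teeth$y[r]), -p$crown_height)
      out[[paste0("tooth_tip_", teeth$id[r], "_", sd)]] <- tip
    }
  }
  st <- strand_layout(p)
  for (r in seq_len(nrow(st)))
    out[[paste0("origin_", st$id[r])]] <- c(st$ox[r], st$oy[r], st$oz[r])
  out
}

# TMJ contact point on the left (+x) side, on the inner ventral corner of
# the posterior lateral wall.
tmj_point <- function(p) {
  h <- p$elem_size
  c(floor((p$width / 2 - p$shell) / h) * h,
    floor((p$length - 6 * p$length / 64) / h) * h,
    p$shell)
}

#' Muscle strand layout of the phantom jaw model
#'
#' Places the origin (cranium), optional via (wrapping) points and
#' insertion (mandible, coordinates in the cranium frame at the closed
#' pose) of every muscle strand, grouped into masseter,
#' zygomaticomandibularis, superficial temporalis (wrapped), deep
#' temporalis, medial pterygoid and lateral pterygoid (wrapped) - 65
#' strands per side, 130 in total. Origin and via points lie on phantom
#' surface grid nodes so they can serve as FE landmarks. Maximum isometric
#' forces are divided equally within each group.
#'
#' @param p a [phantom_params()] object.
#' @return data.frame with one row per strand: id, group, side (L/R),
#'   origin/insertion coordinates, via points (list column), f_max (N).
#' @export
strand_layout <- function(p = phantom_params()) {
  h <- p$elem_size
  W2 <- p$width / 2
  L <- p$length
  H <- p$height
  sn <- function(v) round(v / h) * h
  # group definitions: counts and total F_max per side (N)
  groups <- list(
    masseter = list(n = c(5, 4), total = 90,
                    pts = function(i, j) c(W2, sn(L - 20 + 3 * (i - 1)),
                                           sn(2 + 2 * (j - 1))),
                    ins = c(W2 - 2, L - 16, -10), via = NULL),
    zygomand = list(n = c(5, 2), total = 40,
                    pts = function(i, j) c(W2, sn(L - 20 + 3 * (i - 1)),
                                           sn(H - 6 + 2 * (j - 1))),
                    ins = c(W2 - 3, L - 18, -8), via = NULL),
    temp_sup = list(n = c(5, 3), total = 30,
                    pts = function(i, j) c(sn(2 + 2 * (j - 1)),
                                           sn(L - 20 + 3 * (i - 1)), H),
                    ins = c(6 * W2 / 12, L - 12, -4),
                    via = function(o) rbind(c(o[1], L, H),
                                            c(o[1], L, sn(H / 2)))),
    temp_deep = list(n = c(5, 2), total = 15,
                     pts = function(i, j) c(sn(min(8 + 2 * (j - 1), W2 - 2)),
                                            sn(L - 18 + 3 * (i - 1)), H),
                     ins = c(7 * W2 / 12, L - 10, -4), via = NULL),
    med_pter = list(n = c(7, 1), total = 30,
                    pts = function(i, j) c(sn(2), sn(L - 18 + 2 * (i - 1)), 0),
                    ins = c(8 * W2 / 12, L - 8, -12), via = NULL),
    lat_pter = list(n = c(3, 1), total = 8,
                    pts = function(i, j) c(sn(2), sn(L - 24 + 2 * (i - 1)), 0),
                    ins = c(9 * W2 / 12, L - 6, -2),
                    via = function(o) rbind(c(sn(W2 / 2), o[2], 0))))
  rows <- list()
  for (g in names(groups)) {
    gg <- groups[[g]]
    nstr <- gg$n[1] * gg$n[2]
    fmax <- gg$total / nstr
    k <- 0
    for (i in seq_len(gg$n[1])) for (j in seq_len(gg$n[2])) {
      k <- k + 1
      o <- gg$pts(i, j)
      via <- if (is.null(gg$via)) NULL else gg$via(o)
      for (s in c(1, -1)) {
        sd <- if (s > 0) "L" else "R"
        os <- o * c(s, 1, 1)
        vs <- if (is.null(via)) NULL else via %*% diag(c(s, 1, 1))
        is_ <- gg$ins * c(s, 1, 1)
        rows[[length(rows) + 1]] <- list(
          id = sprintf("%s_%s_%02d", g, sd, k), group = g, side = sd,
          ox = os[1], oy = os[2], oz = os[3],
          ix = is_[1], iy = is_[2], iz = is_[3],
          via = vs, f_max = fmax)
      }
    }
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(r[setdiff(names(r), "via")], stringsAsFactors = FALSE)))
  df$via <- lapply(rows, `[[`, "via")
  rownames(df) <- df$id
  df
}
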