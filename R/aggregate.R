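#' Cumulative peak element strain table
#'
#' Combines the strain fields of all bite loading regimes by selecting,
#' for every bone element, the largest equivalent strain from any of the
#' separate bites, together with the regime that produced it (ties go to
#' the earliest regime in the list), the peak tensile principal strain
#' and the peak compressive (most negative) principal strain. Statistics
#' downstream are restricted to bone-labelled elements; teeth, sutures
#' and the other soft tissues are solved but not reported.
#'
#' @param fields list of `strain_field`s sharing one mesh (>= 1).
#' @param mesh the [tet_mesh()] the fields were computed on.
#' @return a `peak_strain_table` data.frame: element, volume, peak_vm,
#'   argmax_regime (id), argmax_index, peak_e1, peak_e3; attribute
#'   "regime_modes" maps regime id to bite mode when available.
#' @export
peak_strain_map <- function(fields, mesh) {
  if (!length(fields)) stop("need at least one strain field")
  ne <- nrow(mesh$elems)
  for (f in fields)
    if (length(f$vm) != ne)
      stop("strain field does not match the mesh element count")
  bone <- which(mesh$material == "bone")
  vols <- element_volumes(mesh)[bone]
  vm <- sapply(fields, function(f) f$vm[bone])
  vm <- matrix(vm, nrow = length(bone))
  idx <- max.col(vm, ties.method = "first")
  e1 <- matrix(sapply(fields, function(f) f$principal[bone, 1]),
               nrow = length(bone))
  e3 <- matrix(sapply(fields, function(f) f$principal[bone, 3]),
               nrow = length(bone))
  ids <- vapply(seq_along(fields), function(i)
    fields[[i]]$regime_id %||% as.character(i), "")
  ids[is.na(ids)] <- as.character(seq_along(fields))[is.na(ids)]
  out <- data.frame(
    element = bone, volume = vols,
    peak_vm = vm[cbind(seq_along(bone), idx)],
    argmax_regime = ids[idx], argmax_index = idx,
    peak_e1 = apply(e1, 1, max), peak_e3 = apply(e3, 1, min),
    stringsAsFactors = FALSE)
  class(out) <- c("peak_strain_table", "data.frame")
  out
}

#' Dominant bite mode per element
#'
#' Classifies every bone element by the bite mode (incisor or molar) of
#' the regime that produced its peak equivalent strain, and reports the
#' bone-volume fraction (and element-count fraction) of each mode.
#'
#' @param table a [peak_strain_map()] result.
#' @param regime_modes named character vector: regime id -> "incisor" or
#'   "molar".
#' @return list: `class` (per element), `volume_fraction`,
#'   `count_fraction` (named, sum to 1).
#' @export
dominant_bite_mode <- function(table, regime_modes) {
  cls <- unname(regime_modes[table$argmax_regime])
  if (anyNA(cls)) stop("regime id(s) missing from regime_modes")
  lv <- sort(unique(unname(regime_modes)))
  vf <- vapply(lv, function(m) sum(table$volume[cls == m]), 0) /
    sum(table$volume)
  cf <- vapply(lv, function(m) sum(cls == m), 0) / nrow(table)
  list(class = cls, volume_fraction = vf, count_fraction = cf)
}

#' Dominant principal strain per element
#'
#' An element is compressive-dominant when the magnitude of its peak
#' compressive principal strain exceeds its peak tensile principal
#' strain, tensile-dominant otherwise (ties classify as tensile).
#'
#' @param table a [peak_strain_map()] result.
#' @return list: `class`, `volume_fraction`, `count_fraction`.
#' @export
dominant_principal <- function(table) {
  cls <- ifelse(abs(table$peak_e3) > table$peak_e1, "compressive", "tensile")
  lv <- c("compressive", "tensile")
  vf <- vapply(lv, function(m) sum(table$volume[cls == m]), 0) /
    sum(table$volume)
  cf <- vapply(lv, function(m) sum(cls == m), 0) / nrow(table)
  list(class = cls, volume_fraction = vf, count_fraction = cf)
}

#' Strain histogram
#'
#' Element counts in half-open strain bins `[k w, (k+1) w)` of width `w`
#' (default 20 microstrain, the frequency bin size used for strain
#' distribution plots).
#'
#' @param values strain values (microstrain), non-empty.
#' @param bin_width bin width (microstrain).
#' @return data.frame: lower, upper, count; counts sum to length(values).
#' @export
strain_histogram <- function(values, bin_width = 20) {
  if (!length(values)) stop("empty strain vector")
  if (bin_width <= 0) stop("bin width must be positive")
  k <- floor(values / bin_width)
  tab <- table(k)
  kk <- as.integer(names(tab))
  data.frame(lower = kk * bin_width, upper = (kk + 1) * bin_width,
             count = as.integer(tab))
}

#' Volume fraction inside a strain band
#'
#' Volume-weighted fraction of bone elements whose peak equivalent strain
#' lies strictly above `low` and strictly below `high`. The default band,
#' 100-1500 microstrain, is the range suggested for normal bone
#' remodelling (mechanostat homeostasis).
#'
#' @param table a [peak_strain_map()] result.
#' @param low,high band limits (microstrain, exclusive).
#' @return scalar fraction in `[0, 1]`.
#' @export
band_volume_fraction <- function(table, low = 100, high = 1500) {
  sel <- table$peak_vm > low & table$peak_vm < high
  sum(table$volume[sel]) / sum(table$volume)
}

#' Soft-tissue sensitivity comparison
#'
#' Per-element absolute change in peak equivalent strain between a base
#' run and a variant run (e.g. PDL and suture stiffness lowered tenfold),
#' summarized as the median |change| of bone elements near the PDL or
#' sutures versus far from them. Localized sensitivity shows as a larger
#' near-field median.
#'
#' @param table_base,table_variant [peak_strain_map()] results on the same
#'   mesh.
#' @param mesh the phantom mesh.
#' @param distance near/far threshold (mm) from any pdl or suture element
#'   centroid.
#' @return list: `delta` (per bone element), `near` (logical),
#'   `median_near`, `median_far`.
#' @export
sensitivity_compare <- function(table_base, table_variant, mesh,
                                distance = 3) {
  if (!identical(table_base$element, table_variant$element))
    stop("tables cover different element sets")
  delta <- abs(table_variant$peak_vm - table_base$peak_vm)
  cen <- element_centroids(mesh)
  soft <- cen[mesh$material %in% c("pdl", "suture"), , drop = FALSE]
  bonec <- cen[table_base$element, , drop = FALSE]
  if (nrow(soft) == 0) stop("mesh has no pdl or suture elements")
  # nearest soft-tissue centroid distance per bone element (blocked)
  dmin <- rep(Inf, nrow(bonec))
  blk <- 2000
  for (i0 in seq(1, nrow(soft), by = blk)) {
    i1 <- min(i0 + blk - 1, nrow(soft))
    d2 <- outer(rowSums(bonec^2), rep(1, i1 - i0 + 1)) +
      outer(rep(1, nrow(bonec)), rowSums(soft[i0:i1, , drop = FALSE]^2)) -
      2 * bonec %*% t(soft[i0:i1, , drop = FALSE])
    dmin <- pmin(dmin, sqrt(pmax(apply(d2, 1, min), 0)))
  }
  near <- dmin <= distance
  list(delta = delta, near = near,
       median_near = stats::median(delta[near]),
       median_far = stats::median(delta[!near]))
}
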