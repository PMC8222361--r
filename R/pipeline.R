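#' Run configuration
#'
#' Assembles (or reads from a YAML file) the single configuration object
#' that drives the whole pipeline: phantom parameters, material table
#' overrides, sensitivity variants (per-label stiffness multipliers),
#' bite-cycle overrides, element order, and the output directory.
#'
#' @param path optional YAML file to read; fields below override it.
#' @param phantom list of [phantom_params()] arguments.
#' @param materials named list of `c(E, nu)` overrides for
#'   [default_materials()].
#' @param variants named list of sensitivity variants, each a named list
#'   of stiffness multipliers per material label, e.g.
#'   `list(soft = list(pdl = 0.1, suture = 0.1))`.
#' @param bite list of [bite_cycle_spec()] overrides applied to every
#'   cycle.
#' @param teeth optional subset of bite tooth ids to simulate (default:
#'   the incisor and every cheek tooth).
#' @param order element order for the FE mesh (1 or 2).
#' @param out_dir output directory (created on run); `NULL` disables
#'   file output.
#' @param sensitivity_distance near/far threshold (mm) for
#'   [sensitivity_compare()].
#' @param seed integer seed forwarded to the phantom parameters.
#' @param write_cases write one VTU per load case (default TRUE when
#'   `out_dir` is set).
#' @return a `run_config` list.
#' @export
run_config <- function(path = NULL, phantom = list(), materials = list(),
                       variants = list(soft_tissue = list(pdl = 0.1,
                                                          suture = 0.1)),
                       bite = list(), teeth = NULL, order = 1,
                       out_dir = NULL,
                       sensitivity_distance = 3, seed = 1L,
                       write_cases = !is.null(out_dir)) {
  cfg <- list(phantom = phantom, materials = materials, variants = variants,
              bite = bite, teeth = teeth, order = order, out_dir = out_dir,
              sensitivity_distance = sensitivity_distance,
              seed = as.integer(seed), write_cases = write_cases)
  if (!is.null(path)) {
    fromfile <- yaml::read_yaml(path)
    cfg <- utils::modifyList(fromfile, cfg[!vapply(cfg, is.null, TRUE)])
  }
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Static checks before running: Poisson's ratios below 0.5, positive
#' Young's moduli and variant multipliers, strictly positive bite-cycle
#' phases, and (when a mesh is supplied) presence of every required
#' landmark node set. An empty result means the configuration is
#' runnable.
#'
#' @param config a [run_config()].
#' @param mesh optional phantom mesh whose landmark sets are checked.
#' @return character vector of findings (empty when valid).
#' @export
validate_config <- function(config, mesh = NULL) {
  findings <- character()
  mats <- try(do.call(default_materials, config$materials), silent = TRUE)
  if (inherits(mats, "try-error")) {
    for (nm in names(config$materials)) {
      v <- config$materials[[nm]]
      if (v[1] <= 0)
        findings <- c(findings, sprintf("material %s: non-positive E", nm))
      if (length(v) > 1 && (v[2] >= 0.5 || v[2] < 0))
        findings <- c(findings,
                      sprintf("material %s: Poisson's ratio %g outside [0, 0.5)",
                              nm, v[2]))
    }
  }
  for (vn in names(config$variants)) {
    mult <- unlist(config$variants[[vn]])
    if (any(mult <= 0))
      findings <- c(findings,
                    sprintf("variant %s: non-positive stiffness multiplier", vn))
  }
  for (ph in c("t_open", "t_fast", "t_slow", "dt")) {
    v <- config$bite[[ph]]
    if (!is.null(v) && v <= 0)
      findings <- c(findings, sprintf("bite cycle: non-positive %s", ph))
  }
  pp <- try(do.call(phantom_params, config$phantom), silent = TRUE)
  if (inherits(pp, "try-error")) {
    findings <- c(findings, paste("phantom parameters:",
                                  attr(pp, "condition")$message))
  } else if (!is.null(mesh)) {
    required <- c("tmj_left", "tmj_right", "midsagittal_plane",
                  names(landmark_points(pp)))
    for (nm in unique(required)) {
      s <- mesh$node_sets[[nm]]
      if (is.null(s) || !length(s))
        findings <- c(findings,
                      sprintf("missing landmark node set: %s", nm))
    }
  }
  findings
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full multi-bite strain pipeline
#'
#' Orchestrates phantom generation, bite-cycle simulation for every bite
#' point, one FE solve per loading regime, peak-strain aggregation,
#' dominance maps, histograms, band fractions and the configured
#' soft-tissue sensitivity variants. Reruns with the same configuration
#' are bit-identical (all stages are deterministic).
#'
#' @param config a [run_config()].
#' @return a `strain_run` object: peak table, dominance maps, histogram,
#'   band fractions, sensitivity summaries and an artifact manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  t0 <- proc.time()[3]
  findings <- validate_config(config)
  if (length(findings))
    stop("invalid configuration:\n  ", paste(findings, collapse = "\n  "))
  params <- stage("phantom", do.call(phantom_params,
                                     utils::modifyList(config$phantom,
                                                       list(seed = config$seed))))
  mesh <- stage("phantom", make_cranium_phantom(params, order = config$order))
  jaw <- stage("mda", build_jaw_model(params))
  regimes <- stage("mda", enumerate_bite_regimes(jaw, config$bite,
                                                 teeth = config$teeth))
  materials <- stage("materials", do.call(default_materials, config$materials))
  system <- stage("assemble", assemble_system(mesh, materials))
  fields <- list()
  for (id in names(regimes))
    fields[[id]] <- stage(paste0("solve regime ", id),
                          run_load_case(mesh, materials, regimes[[id]],
                                        system = system))
  table <- stage("aggregate", peak_strain_map(fields, mesh))
  modes <- vapply(regimes, function(r) r$mode, "")
  bite_mode <- stage("aggregate", dominant_bite_mode(table, modes))
  principal <- stage("aggregate", dominant_principal(table))
  hist <- stage("aggregate", strain_histogram(table$peak_vm))
  band <- stage("aggregate", band_volume_fraction(table))
  sens <- list()
  tables_v <- list()
  for (vn in names(config$variants)) {
    mult <- config$variants[[vn]]
    mats_v <- materials
    for (lbl in names(mult))
      mats_v$E[mats_v$label == lbl] <- mats_v$E[mats_v$label == lbl] *
        mult[[lbl]]
    sys_v <- stage(paste0("assemble variant ", vn),
                   assemble_system(mesh, mats_v))
    fields_v <- list()
    for (id in names(regimes))
      fields_v[[id]] <- stage(paste0("solve variant ", vn, " regime ", id),
                              run_load_case(mesh, mats_v, regimes[[id]],
                                            system = sys_v))
    tab_v <- peak_strain_map(fields_v, mesh)
    tables_v[[vn]] <- tab_v
    sens[[vn]] <- stage(paste0("sensitivity ", vn),
                        sensitivity_compare(table, tab_v, mesh,
                                            distance = config$sensitivity_distance))
  }
  manifest <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    if (isTRUE(config$write_cases)) {
      dir.create(file.path(od, "cases"), showWarnings = FALSE)
      for (id in names(fields)) {
        f <- fields[[id]]
        p <- file.path(od, "cases", paste0(id, ".vtu"))
        write_vtu(mesh, p, cell_data = list(
          eps1 = f$principal[, 1], eps2 = f$principal[, 2],
          eps3 = f$principal[, 3], eps_vm = f$vm))
        manifest[[paste0("case_", id)]] <- p
      }
    }
    peak_arrays <- list(peak_vm = numeric(nrow(mesh$elems)),
                        argmax_regime = numeric(nrow(mesh$elems)),
                        mode_class = numeric(nrow(mesh$elems)),
                        principal_class = numeric(nrow(mesh$elems)))
    peak_arrays$peak_vm[table$element] <- table$peak_vm
    peak_arrays$argmax_regime[table$element] <- table$argmax_index
    peak_arrays$mode_class[table$element] <-
      as.integer(bite_mode$class == "molar") + 1L
    peak_arrays$principal_class[table$element] <-
      as.integer(principal$class == "compressive") + 1L
    pv <- file.path(od, "peak_strain.vtu")
    write_vtu(mesh, pv, cell_data = peak_arrays)
    manifest$peak_vtu <- pv
    hv <- file.path(od, "histogram.csv")
    utils::write.csv(hist, hv, row.names = FALSE)
    manifest$histogram_csv <- hv
    sj <- file.path(od, "summary.json")
    jsonlite::write_json(strain_run_summary_list(
      table, bite_mode, principal, band, sens), sj,
      auto_unbox = TRUE, digits = NA)
    manifest$summary_json <- sj
    mj <- file.path(od, "manifest.json")
    jsonlite::write_json(manifest, mj, auto_unbox = TRUE)
    manifest$manifest_json <- mj
  }
  structure(list(config = config, params = params,
                 mesh_info = list(nodes = nrow(mesh$nodes),
                                  elements = nrow(mesh$elems)),
                 mesh = mesh, regimes = regimes, fields = fields,
                 peak_table = table, bite_mode = bite_mode,
                 principal = principal, histogram = hist,
                 band_fraction = band, sensitivity = sens,
                 variant_tables = tables_v, manifest = manifest,
                 elapsed_s = proc.time()[3] - t0),
            class = "strain_run")
}

strain_run_summary_list <- function(table, bite_mode, principal, band,
                                    sens) {
  list(
    n_bone_elements = nrow(table),
    bone_volume_mm3 = sum(table$volume),
    peak_vm_max = max(table$peak_vm),
    peak_vm_median = stats::median(table$peak_vm),
    bite_mode_volume_fraction = as.list(bite_mode$volume_fraction),
    bite_mode_count_fraction = as.list(bite_mode$count_fraction),
    principal_volume_fraction = as.list(principal$volume_fraction),
    principal_count_fraction = as.list(principal$count_fraction),
    band_volume_fraction_100_1500 = band,
    sensitivity = lapply(sens, function(s)
      list(median_near = s$median_near, median_far = s$median_far)))
}

#' @export
print.strain_run <- function(x, ...) {
  cat(sprintf("strain_run: %d load cases on %d elements (%d nodes), %.1f s\n",
              length(x$fields), x$mesh_info$elements, x$mesh_info$nodes,
              x$elapsed_s))
  vf <- x$bite_mode$volume_fraction
  pf <- x$principal$volume_fraction
  cat(sprintf("  molar-dominant bone volume: %.1f%%\n",
              100 * (vf["molar"] %||% 0)))
  cat(sprintf("  compressive-dominant bone volume: %.1f%%\n",
              100 * (pf["compressive"] %||% 0)))
  cat(sprintf("  bone volume with peak strain in 100-1500 microstrain: %.1f%%\n",
              100 * x$band_fraction))
  invisible(x)
}

#' @export
summary.strain_run <- function(object, ...) {
  s <- strain_run_summary_list(object$peak_table, object$bite_mode,
                               object$principal, object$band_fraction,
                               object$sensitivity)
  structure(s, class = "summary.strain_run")
}

#' @export
print.summary.strain_run <- function(x, ...) {
  str(x, give.attr = FALSE)
  invisible(x)
}

#' @param x a `strain_run`.
#' @param which "histogram" (peak-strain distribution with the 20
#'   microstrain bins) or "cumulative".
#' @param ... passed to plotting primitives.
#' @rdname run_pipeline
#' @export
plot.strain_run <- function(x, which = "histogram", ...) {
  h <- x$histogram
  if (which == "histogram") {
    graphics::plot(h$lower + diff(c(h$lower[1], h$upper[1])) / 2, h$count,
                   type = "h", xlab = "peak von Mises strain (microstrain)",
                   ylab = "number of bone elements", ...)
    graphics::abline(v = c(100, 1500), lty = 2, col = "grey40")
  } else {
    v <- sort(x$peak_table$peak_vm)
    graphics::plot(v, seq_along(v) / length(v), type = "l",
                   xlab = "peak von Mises strain (microstrain)",
                   ylab = "cumulative fraction of bone elements", ...)
  }
  invisible(x)
}
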