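#' Run the virtual-intervention pipeline from a configuration
#'
#' Wires the stages synth (or read) -> stent -> mesh -> solve -> vffr ->
#' tandem -> stats in order; each stage's output is the next stage's input.
#' Only the stages present in the configuration run. A run manifest
#' (command-line equivalent, configuration snapshot, seed, package version,
#' output file digests, wall time) is written next to the outputs, so
#' reruns with identical inputs are reproducible and auditable.
#'
#' Configuration schema (a named list, or a path to a JSON file):
#' \describe{
#'   \item{vessel}{either `list(file = "path")` or a `synth` block with
#'     arguments for [make_synthetic_vessel()] (`length`, `radius`,
#'     `stenoses` as a list of `(s_center, length, severity)`,
#'     `curvature`, `step`, `seed`).}
#'   \item{stents}{optional list of `(s_proximal, s_distal, diameter)`.}
#'   \item{mesh}{optional: `surface = TRUE` and/or `volume = TRUE` with
#'     optional `n_circ`, `n_layers`, `growth`, `target_edge`,
#'     `axial_step`; meshes are exported when `out_surface`/`out_volume`
#'     paths are given.}
#'   \item{solve}{optional: `backend` ("reduced" or "fvm3d"),
#'     `pa_mmhg`, `resistance`, `p_venous`, `density`, `viscosity`,
#'     `ffr_from`, `ffr_to`. vFFR is computed pre- and (when stents are
#'     given) post-deployment.}
#'   \item{tandem}{optional: `lesions` list of `(s_proximal, s_distal,
#'     diameter)` plus optional `s_measure`, `backend`.}
#'   \item{stats}{optional: `pairs_file` (CSV with header `mFFR,vFFR`) or
#'     inline `mffr`/`vffr` vectors, optional `threshold`.}
#'   \item{out_dir}{directory for outputs (default `tempdir()`).}
#' }
#'
#' @param config named list or path to a JSON config file.
#' @return (invisibly) a list of stage results plus `manifest`; the
#'   manifest and a `results.json` are written to `out_dir`.
#' @export
run_pipeline <- function(config) {
  t_start <- Sys.time()
  if (is.character(config) && length(config) == 1L) {
    config_path <- config
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  } else config_path <- NA_character_
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  .validate_pipeline_config(config)

  out_dir <- config$out_dir %||% tempdir()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }

  # --- vessel stage -----------------------------------------------------
  vc <- config$vessel
  if (!is.null(vc$file)) {
    vessel <- read_vessel(vc$file)
    say("vessel: read %d sections from %s", nrow(vessel$sections), vc$file)
  } else {
    syn <- vc$synth %||% vc
    stens <- lapply(syn$stenoses %||% list(), function(st) do.call(stenosis_spec, st))
    vessel <- make_synthetic_vessel(
      length = syn$length %||% 50, base_radius = syn$radius %||% 1.5,
      stenoses = stens, curvature = syn$curvature %||% 0,
      step = syn$step %||% 0.25, seed = syn$seed %||% 1L,
      noise_sd = syn$noise_sd %||% 0)
    say("vessel: synthesized %.0f mm tube, base radius %.2f mm, %d stenoses",
        vessel_length(vessel), syn$radius %||% 1.5, length(stens))
  }
  results$vessel <- vessel
  vessel_out <- file.path(out_dir, "vessel.txt")
  write_vessel(vessel, vessel_out)

  # --- stent stage ------------------------------------------------------
  stented <- NULL
  if (length(config$stents)) {
    stents <- lapply(config$stents, function(s) do.call(stent_spec, s))
    stented <- deploy_stents(vessel, stents)
    results$stented <- stented
    write_vessel(stented, file.path(out_dir, "stented.txt"))
    say("stent: deployed %d stent(s)", length(stents))
  }

  # --- mesh stage -------------------------------------------------------
  mc <- config$mesh
  active_vessel <- stented %||% vessel
  if (isTRUE(mc$surface) || !is.null(mc$out_surface)) {
    sm <- build_surface_mesh(active_vessel, n_circ = mc$n_circ %||% 64L)
    results$surface_mesh <- sm
    if (!is.null(mc$out_surface))
      export_mesh(sm, file.path(out_dir, mc$out_surface), "stl")
    say("mesh: surface with %d triangles", nrow(sm$triangles))
  }
  if (isTRUE(mc$volume) || !is.null(mc$out_volume)) {
    vm <- build_volume_mesh(active_vessel,
      n_circ = mc$vol_n_circ %||% 32L, n_layers = mc$n_layers %||% 3L,
      growth = mc$growth %||% 1.2, target_edge = mc$target_edge %||% 0.3,
      axial_step = mc$axial_step %||% 1.25)
    results$volume_mesh <- vm
    if (!is.null(mc$out_volume))
      export_mesh(vm, file.path(out_dir, mc$out_volume), "vtu")
    say("mesh: volume with %d tetrahedra", nrow(vm$tets))
  }

  # --- solve / vffr stage -----------------------------------------------
  sc <- config$solve
  if (!is.null(sc)) {
    bc <- boundary_conditions(p_inlet_mmhg = sc$pa_mmhg %||% 93,
                              r_distal = sc$resistance %||% 8.721e9,
                              p_venous = sc$p_venous %||% 0)
    blood <- blood_properties(density = sc$density %||% 1056,
                              viscosity = sc$viscosity %||% 3.5e-3)
    backend <- sc$backend %||% "reduced"
    s_from <- sc$ffr_from %||% 0
    s_to <- sc$ffr_to %||% vessel_length(vessel)
    solve_one <- function(v) {
      if (backend == "reduced") solve_reduced(v, bc, blood)
      else solve_3d(build_volume_mesh(v,
             n_circ = mc$vol_n_circ %||% 32L, n_layers = mc$n_layers %||% 3L,
             growth = mc$growth %||% 1.2, target_edge = mc$target_edge %||% 0.3,
             axial_step = mc$axial_step %||% 1.25), bc, blood)
    }
    sol_pre <- solve_one(vessel)
    ffr_pre <- compute_vffr(sol_pre, s_from, s_to)
    results$solution_pre <- sol_pre
    results$vffr_pre <- ffr_pre
    say("solve: pre-stent vFFR = %.3f (%s backend)", ffr_pre$vffr, backend)
    if (!is.null(stented)) {
      sol_post <- solve_one(stented)
      ffr_post <- compute_vffr(sol_post, s_from, s_to)
      results$solution_post <- sol_post
      results$vffr_post <- ffr_post
      say("solve: post-stent vFFR = %.3f (delta %+.3f)",
          ffr_post$vffr, ffr_post$vffr - ffr_pre$vffr)
    }
  }

  # --- tandem stage -----------------------------------------------------
  tc <- config$tandem
  if (!is.null(tc)) {
    lesions <- lapply(tc$lesions, function(s) do.call(stent_spec, s))
    bc <- boundary_conditions(p_inlet_mmhg = tc$pa_mmhg %||% 93)
    rep_ <- tandem_analysis(vessel, lesions, bc = bc,
                            backend = tc$backend %||% "reduced",
                            s_measure = tc$s_measure %||% vessel_length(vessel))
    results$tandem <- rep_
    say("tandem: %d strategies; baseline vFFR %.3f, all-stented %.3f",
        nrow(rep_), rep_$vffr[1], max(rep_$vffr))
  }

  # --- stats stage ------------------------------------------------------
  stc <- config$stats
  if (!is.null(stc)) {
    if (!is.null(stc$pairs_file)) {
      pairs <- utils::read.csv(stc$pairs_file)
      mffr <- pairs[[1]]; vffr <- pairs[[2]]
    } else {
      mffr <- unlist(stc$mffr); vffr <- unlist(stc$vffr)
    }
    results$bland_altman <- bland_altman(mffr, vffr)
    results$diagnostic <- diagnostic_accuracy(mffr, vffr,
                                              stc$threshold %||% 0.80)
    results$correlation <- ffr_correlation(mffr, vffr)
    say("stats: bias %+.4f, accuracy %.1f%%, r %.3f",
        results$bland_altman$bias, 100 * results$diagnostic$accuracy,
        results$correlation$r)
  }

  # --- manifest ---------------------------------------------------------
  summary_json <- .pipeline_summary(results)
  results_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(summary_json, results_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    tool = "coroflow::run_pipeline",
    version = as.character(utils::packageVersion("coroflow")),
    timestamp = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    config_file = config_path,
    config = config,
    seed = config$vessel$synth$seed %||% config$vessel$seed %||% NA,
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))),
    log = log,
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_pipeline_config <- function(config) {
  known <- c("vessel", "stents", "mesh", "solve", "tandem", "stats", "out_dir")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  if (is.null(config$vessel))
    stop("config must contain a 'vessel' section")
  if (!is.null(config$solve$backend) &&
      !config$solve$backend %in% c("reduced", "fvm3d"))
    stop("solve$backend must be 'reduced' or 'fvm3d'")
  invisible(TRUE)
}

.pipeline_summary <- function(results) {
  out <- list()
  if (!is.null(results$vessel))
    out$vessel <- list(length_mm = vessel_length(results$vessel),
                       n_sections = nrow(results$vessel$sections),
                       min_radius_mm = min(results$vessel$sections$r))
  if (!is.null(results$stented))
    out$stented <- list(min_radius_mm = min(results$stented$sections$r))
  if (!is.null(results$vffr_pre))
    out$vffr_pre <- results$vffr_pre$vffr
  if (!is.null(results$vffr_post)) {
    out$vffr_post <- results$vffr_post$vffr
    out$delta_vffr <- results$vffr_post$vffr - results$vffr_pre$vffr
  }
  if (!is.null(results$solution_pre)) {
    out$Q_pre_ml_s <- results$solution_pre$Q * 1e6
  }
  if (!is.null(results$tandem))
    out$tandem <- lapply(seq_len(nrow(results$tandem)), function(i)
      list(strategy = results$tandem$strategy[i],
           vffr = results$tandem$vffr[i]))
  if (!is.null(results$bland_altman))
    out$bland_altman <- list(bias = results$bland_altman$bias,
                             sd = results$bland_altman$sd,
                             limits = as.numeric(results$bland_altman$limits))
  if (!is.null(results$diagnostic))
    out$diagnostic <- list(
      sensitivity = results$diagnostic$sensitivity,
      specificity = results$diagnostic$specificity,
      ppv = results$diagnostic$ppv, npv = results$diagnostic$npv,
      accuracy = results$diagnostic$accuracy)
  if (!is.null(results$correlation))
    out$correlation_r <- results$correlation$r
  out
}
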