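# Config-driven workflow runner: localization (distances + RDF + inversion +
# peaks), pmf (work -> PMF + barriers + optional RDF correlation), pca
# (model + projections + modality), census (motif tallies + geometry), or
# all four ("full"). Every run writes a manifest recording inputs,
# parameters, seed and package version; identical config + seed gives
# byte-identical outputs.

#' Default run configuration
#'
#' Every tunable consumed by any stage, with the module-level defaults.
#' `inputs` entries left `NULL` are replaced by the seeded synthetic demo of
#' the corresponding stage.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    workflow = "full",
    seed = 1L,
    output_dir = "ionprobe_out",
    temperature = 300,
    inputs = list(trajectory = NULL, pulls = NULL, structures = NULL,
                  rdf = NULL),
    rdf = list(bin_width = 0.25, r_max = 20,
               ion_query = "element=Cd",
               reference_query = "resname=ASP and name=OD1,OD2",
               reducer = "centroid", box_volume = NA,
               peak_prominence = 0.5),
    pmf = list(estimator = "mean_work", spring_constant = 20,
               spring_convention = "amber", smooth_window = 5,
               min_prominence = 1, correlate_mode = "invert_a_first"),
    pca = list(selection = "name=CA", component = 1,
               bic_margin = 10, weight_floor = 0.2, min_separation_sd = 1,
               distance_bin = 0.5),
    scan = list(metals = "Cd", cutoff = 3.0, motif = "ung_like"),
    demo = list(rdf_n_samples = 2000L, rdf_potential_k = 2,
                rdf_potential_r0 = 5,
                pull_n_replicates = 4L, pull_velocity = 0.01,
                pull_time_step = 0.02, pull_start = 2, pull_distance = 6,
                pull_friction = 10, pull_stride = 250L,
                pca_n_atoms = 30L, pca_n_frames = 400L, pca_mode_sd = 2,
                pca_noise_sd = 0.1)
  )
}

merge_config <- function(user, defaults = default_config(), path = "") {
  if (is.null(user)) return(defaults)
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop_ionprobe("unknown config key: ", full)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(user[[key]], defaults[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read a YAML run configuration
#'
#' Unknown keys fail naming the key; omitted keys take the
#' [default_config()] values.
#'
#' @param path YAML file path.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_ionprobe("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_config(user)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

motif_from_name <- function(name) {
  switch(name,
         ung_like = motif_ung_like(),
         exact = motif_exact_site(),
         stop_ionprobe("unknown motif name '", name,
                       "' (use 'ung_like' or 'exact')"))
}

run_stage <- function(stage_name, fun) {
  tryCatch(fun(), error = function(e) {
    stop_ionprobe("stage '", stage_name, "' failed: ", conditionMessage(e))
  })
}

stage_localization <- function(config, out_dir, log) {
  demo <- is.null(config$inputs$trajectory)
  if (demo) {
    log("localization: no trajectory input, using seeded Boltzmann-ion demo")
    pot <- radial_potential("harmonic", k = config$demo$rdf_potential_k,
                            r0 = config$demo$rdf_potential_r0,
                            temperature = config$temperature)
    sim <- gen_boltzmann_ions(pot, n_samples = config$demo$rdf_n_samples,
                              seed = config$seed)
    ens <- sim$ensemble
    box_volume <- value_or(config$rdf$box_volume, 40^3)
    ion_query <- "element=Cd"
    ref_query <- "name=OD1"
  } else {
    ens <- read_trajectory(config$inputs$trajectory)
    box_volume <- value_or(
      config$rdf$box_volume,
      if (!is.null(ens$box)) prod(ens$box) else
        stop_ionprobe("rdf.box_volume required when trajectory has no box"))
    ion_query <- config$rdf$ion_query
    ref_query <- config$rdf$reference_query
  }
  series <- track_distances(ens, ion_query, ref_query,
                            reducer = config$rdf$reducer)
  rdf <- compute_rdf(series, bin_width = config$rdf$bin_width,
                     r_max = config$rdf$r_max, box_volume = box_volume)
  fe <- boltzmann_invert(rdf, config$temperature)
  peaks <- detect_extrema(rdf, "maxima", smooth_window = 5,
                          min_prominence = config$rdf$peak_prominence)
  write_profile(rdf, file.path(out_dir, "rdf.csv"))
  write_profile(fe, file.path(out_dir, "free_energy.csv"))
  dist_df <- do.call(rbind, lapply(series, function(s) {
    data.frame(ion_id = attr(s, "ion_id"), frame = s$frame,
               distance = s$distance)
  }))
  utils::write.csv(dist_df, file.path(out_dir, "distances.csv"),
                   row.names = FALSE)
  write_json_out(as.list(as.data.frame(peaks)),
                 file.path(out_dir, "rdf_peaks.json"))
  log(sprintf("localization: %d frames, %d ion(s), %d bins, %d peak(s)",
              rdf$meta$n_frames, rdf$meta$n_ions, length(rdf$grid),
              nrow(peaks)))
  list(rdf = rdf, free_energy = fe, peaks = peaks,
       outputs = c("rdf.csv", "free_energy.csv", "distances.csv",
                   "rdf_peaks.json"))
}

read_pull_dir <- function(dir, config) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop_ionprobe("no pull CSVs in ", dir)
  works <- list()
  for (i in seq_along(files)) {
    tab <- utils::read.csv(files[i])
    need <- c("time_ns", "lambda_A", "x_A")
    if (!all(need %in% names(tab))) {
      stop_ionprobe(files[i], ": pull CSV needs columns ",
                    paste(need, collapse = ","))
    }
    dt <- tab$time_ns[2L] - tab$time_ns[1L]
    v <- (tab$lambda_A[2L] - tab$lambda_A[1L]) / dt
    sched <- pull_schedule(
      start_position = tab$lambda_A[1L],
      pull_distance = tab$lambda_A[nrow(tab)] - tab$lambda_A[1L],
      velocity = v, spring_constant = config$pmf$spring_constant,
      spring_convention = config$pmf$spring_convention, time_step = dt)
    works[[i]] <- accumulate_work(tab$x_A, sched, replicate_id = i)
  }
  works
}

stage_pmf <- function(config, out_dir, log, rdf = NULL) {
  demo <- is.null(config$inputs$pulls)
  if (demo) {
    log("pmf: no pull input, using seeded Langevin-pull demo")
    pot <- radial_potential("harmonic", k = config$demo$rdf_potential_k,
                            r0 = config$demo$rdf_potential_r0,
                            temperature = config$temperature)
    sched <- pull_schedule(start_position = config$demo$pull_start,
                           pull_distance = config$demo$pull_distance,
                           velocity = config$demo$pull_velocity,
                           spring_constant = config$pmf$spring_constant,
                           spring_convention = config$pmf$spring_convention,
                           time_step = config$demo$pull_time_step)
    sim <- gen_smd_pulls(sched, pot,
                         friction = config$demo$pull_friction,
                         temperature = config$temperature,
                         n_replicates = config$demo$pull_n_replicates,
                         seed = config$seed + 1L,
                         stride = config$demo$pull_stride)
    works <- sim$works
  } else {
    works <- read_pull_dir(config$inputs$pulls, config)
  }
  pmf <- estimate_pmf(works, temperature = config$temperature,
                      estimator = config$pmf$estimator)
  barriers <- detect_extrema(pmf, "maxima",
                             smooth_window = config$pmf$smooth_window,
                             min_prominence = config$pmf$min_prominence)
  write_profile(pmf, file.path(out_dir, "pmf.csv"))
  write_json_out(as.list(as.data.frame(barriers)),
                 file.path(out_dir, "pmf_barriers.json"))
  outputs <- c("pmf.csv", "pmf_barriers.json")
  r2 <- NULL
  if (is.null(rdf) && !is.null(config$inputs$rdf)) {
    rdf <- read_profile(config$inputs$rdf)
  }
  if (!is.null(rdf)) {
    r2 <- correlate_profiles(rdf, pmf, mode = config$pmf$correlate_mode,
                             temperature = config$temperature)
    write_json_out(list(r_squared = r2, mode = config$pmf$correlate_mode),
                   file.path(out_dir, "rdf_pmf_correlation.json"))
    outputs <- c(outputs, "rdf_pmf_correlation.json")
    log(sprintf("pmf: RDF-PMF r^2 = %.4f (%s)", r2,
                config$pmf$correlate_mode))
  }
  log(sprintf("pmf: %d replicate(s), estimator %s, %d barrier(s)",
              length(works), config$pmf$estimator, nrow(barriers)))
  list(pmf = pmf, barriers = barriers, r_squared = r2, outputs = outputs)
}

stage_pca <- function(config, out_dir, log) {
  demo <- is.null(config$inputs$trajectory)
  if (demo) {
    log("pca: no trajectory input, using seeded planted-mode demo")
    sim <- gen_mode_ensemble(config$demo$pca_n_atoms,
                             mode_spec("gaussian",
                                       sd = config$demo$pca_mode_sd),
                             n_frames = config$demo$pca_n_frames,
                             noise_sd = config$demo$pca_noise_sd,
                             rigid_jitter = TRUE,
                             seed = config$seed + 2L)
    ens <- sim$ensemble
  } else {
    ens <- read_trajectory(config$inputs$trajectory)
  }
  sel <- select_atoms(ens, config$pca$selection)
  if (length(sel) < 3L) {
    stop_ionprobe("pca selection '", config$pca$selection,
                  "' matched ", length(sel), " atom(s); need >= 3")
  }
  aligned <- align_ensemble(ens, sel)
  model <- build_pca(aligned, sel)
  proj <- project_frames(aligned, model, config$pca$component)
  modality <- classify_modality(proj,
                                bic_margin = config$pca$bic_margin,
                                weight_floor = config$pca$weight_floor,
                                min_separation_sd =
                                  config$pca$min_separation_sd)
  write_json_out(list(selection = config$pca$selection,
                      n_atoms = length(sel),
                      n_components = length(model$eigenvalues),
                      eigenvalues = model$eigenvalues,
                      mean_coords = model$mean_coords,
                      eigenvector_pc1 = model$eigenvectors[, 1L]),
                 file.path(out_dir, "pca_model.json"))
  utils::write.csv(data.frame(frame = seq_along(proj),
                              displacement = as.numeric(proj)),
                   file.path(out_dir, sprintf("pc%d_displacement.csv",
                                              config$pca$component)),
                   row.names = FALSE)
  write_json_out(list(verdict = modality$verdict,
                      bic_1 = modality$bic_1, bic_2 = modality$bic_2,
                      component_means = modality$component_means,
                      weights = modality$weights, sds = modality$sds),
                 file.path(out_dir, "modality.json"))
  log(sprintf("pca: %d atoms -> %d components; PC%d verdict: %s",
              length(sel), length(model$eigenvalues),
              config$pca$component, modality$verdict))
  list(model = model, projection = proj, modality = modality,
       outputs = c("pca_model.json",
                   sprintf("pc%d_displacement.csv", config$pca$component),
                   "modality.json"))
}

stage_census <- function(config, out_dir, log) {
  demo <- is.null(config$inputs$structures)
  if (demo) {
    log("census: no structure input, using seeded 10-site fixture demo")
    fixtures <- ung_like_fixture_set(seed = config$seed + 3L)
    structures <- fixtures$structures
  } else {
    paths <- sort(list.files(config$inputs$structures,
                             pattern = "\\.(pdb|ent)$", full.names = TRUE))
    if (length(paths) == 0L) {
      stop_ionprobe("no PDB files in ", config$inputs$structures)
    }
    structures <- lapply(paths, read_structure)
    names(structures) <- basename(paths)
  }
  spec <- motif_from_name(config$scan$motif)
  result <- census(structures, metals = config$scan$metals, spec = spec,
                   cutoff = config$scan$cutoff)
  utils::write.csv(as.data.frame(result),
                   file.path(out_dir, "census.csv"), row.names = FALSE)
  geom <- list()
  for (id in names(structures)) {
    sites <- extract_sites(structures[[id]], metals = config$scan$metals,
                           cutoff = config$scan$cutoff, source_id = id)
    for (s in sites) {
      if (nrow(s$ligands) >= 2L) {
        g <- coordination_geometry(s)
        geom[[length(geom) + 1L]] <- list(
          structure = id, metal = normalize_element(s$metal$element),
          coordination_number = g$coordination_number,
          distances = g$distances, tau4 = g$tau4,
          mean_abs_dev_from_109_47 = g$mean_abs_dev_from_109_47)
      }
    }
  }
  write_json_out(geom, file.path(out_dir, "site_geometry.json"))
  log(sprintf("census: %d structure(s), %d site geometry report(s)",
              length(structures), length(geom)))
  list(census = result, geometry = geom,
       outputs = c("census.csv", "site_geometry.json"))
}

#' Run an analysis workflow
#'
#' Executes one of the workflows `"localization"`, `"pmf"`, `"pca"`,
#' `"census"` or `"full"` (all four, with the RDF feeding the PMF
#' correlation) as described by a config (see [default_config()] /
#' [read_run_config()]). Inputs left `NULL` are replaced by the seeded
#' synthetic demo, so `run_workflow(default_config())` is a self-contained
#' end-to-end run. All artifacts land in `config$output_dir` together with
#' a `manifest.json` recording the workflow, seed, every parameter, the
#' inputs, the package version and the output file list. A stage failure
#' aborts naming the stage; outputs of completed stages are preserved.
#'
#' @param config config list (merged over [default_config()]) or a path to
#'   a YAML config file.
#' @return Invisibly, a list of stage results plus the manifest.
#' @export
run_workflow <- function(config = default_config()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(config)
  workflow <- config$workflow
  if (!workflow %in% c("localization", "pmf", "pca", "census", "full")) {
    stop_ionprobe("unknown workflow '", workflow, "'")
  }
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message("[ionprobe] ", msg)
  }
  set.seed(config$seed)
  results <- list()
  outputs <- character(0)
  if (workflow %in% c("localization", "full")) {
    results$localization <- run_stage("localization", function()
      stage_localization(config, out_dir, log))
    outputs <- c(outputs, results$localization$outputs)
  }
  if (workflow %in% c("pmf", "full")) {
    rdf <- if (!is.null(results$localization))
      results$localization$rdf else NULL
    results$pmf <- run_stage("pmf", function()
      stage_pmf(config, out_dir, log, rdf = rdf))
    outputs <- c(outputs, results$pmf$outputs)
  }
  if (workflow %in% c("pca", "full")) {
    results$pca <- run_stage("pca", function()
      stage_pca(config, out_dir, log))
    outputs <- c(outputs, results$pca$outputs)
  }
  if (workflow %in% c("census", "full")) {
    results$census <- run_stage("census", function()
      stage_census(config, out_dir, log))
    outputs <- c(outputs, results$census$outputs)
  }
  manifest <- list(
    workflow = workflow,
    seed = config$seed,
    parameters = config[setdiff(names(config), "output_dir")],
    package_version = as.character(utils::packageVersion("ionprobe")),
    outputs = outputs
  )
  if (!is.null(results$pmf$r_squared)) {
    manifest$rdf_pmf_r_squared <- results$pmf$r_squared
  }
  write_json_out(manifest, file.path(out_dir, "manifest.json"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  results$manifest <- manifest
  invisible(results)
}
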