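#' Default pipeline configuration
#'
#' One master seed fans out to every stage through [derive_seed()], so a whole
#' pipeline run is reproducible from its config. Defaults mirror the study
#' layout the toolkit targets: one resting-state dataset plus thirteen
#' logarithmically spaced time delays (16 ns to 1.725 ms), 100 fixed-size
#' bootstrap replicates per dataset, occupancy 27%, a 0.8 Angstrom integration
#' radius and pedestals of 2.0 sigma (difference maps) / 0.1 sigma (omit
#' maps). Problem sizes (atoms, frames, resolution) are desk-scale so the full
#' pipeline runs in minutes.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param ... Overrides for any default field.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("serialboot_run_"),
                            ...) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    n_delays = 13, f = 0.27, d_min = 2.0, cell_edge = 12, n_atoms = 8,
    displacement = 0.35,
    n_frames = 300, obs_fraction = 0.7, scale_sigma = 0.3,
    partiality_min = 0.2, noise_frac = 0.05,
    sample_size = 300, n_resamples = 100, min_measurements = 3,
    refine_replicates = 10, radius = 0.8,
    pedestal_diff = 2.0, pedestal_omit = 0.1,
    delay_min = 16e-9, delay_max = 1.725e-3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose keys override [pipeline_config()] defaults.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals$seed)) stop("config must provide a seed")
  do.call(pipeline_config, vals)
}

write_manifest <- function(path, command, config, counts = list(),
                           outputs = character()) {
  manifest <- list(
    command = command,
    config = config[setdiff(names(config), character(0))],
    seed = config$seed,
    counts = counts,
    outputs = outputs,
    tool = "serialboot",
    version = as.character(utils::packageVersion("serialboot")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate the synthetic study fixture tree
#'
#' Builds the toy analogue of a time-resolved serial-crystallography study:
#' a resting (dark) model, a fully activated model, and one stream file per
#' dataset — the dark dataset plus `n_delays` logarithmically spaced time
#' delays whose activation occupancy ramps up to `f` and in which a transient
#' water is present only at intermediate delays. Writes PDB models, truth
#' reflection tables, stream files and a run manifest under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return List with paths, models, delay table and the water site, invisibly
#'   usable by [run_pipeline()].
#' @export
simulate_study <- function(config = pipeline_config()) {
  if (is.null(config$seed)) stop("config must provide a seed")
  dir.create(file.path(config$out_dir, "models"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "truth"), showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "streams"), showWarnings = FALSE)
  sys <- toy_two_state(seed = config$seed, n_atoms = config$n_atoms,
                       cell_edge = config$cell_edge,
                       displacement = config$displacement, water = TRUE)
  delays <- 10^seq(log10(config$delay_min), log10(config$delay_max),
                   length.out = config$n_delays)
  F_dark <- structure_factors(sys$dark, config$d_min)
  write_pdb(sys$dark, file.path(config$out_dir, "models", "dark.pdb"))
  write_pdb(sys$light, file.path(config$out_dir, "models", "light.pdb"))
  write_reflections(F_dark, file.path(config$out_dir, "truth", "F_dark.txt"))

  dark_frames <- simulate_frames(
    F_dark, config$n_frames, obs_fraction = config$obs_fraction,
    scale_sigma = config$scale_sigma, partiality_min = config$partiality_min,
    noise_frac = config$noise_frac, seed = derive_seed(config$seed, 1000L))
  write_stream(dark_frames, file.path(config$out_dir, "streams", "dark.stream"))

  # activation builds up over the delay series toward the plateau occupancy;
  # the transient water is ordered only at intermediate delays
  idx <- seq_len(config$n_delays)
  f_delay <- config$f * pmin(1, idx / ceiling(config$n_delays / 3))
  water_on <- idx > config$n_delays / 4 & idx <= 3 * config$n_delays / 4
  light_atoms_nw <- sys$light$atoms[!grepl("^WAT", sys$light$atoms$name), ,
                                    drop = FALSE]
  light_nw <- atomic_model(sys$light$cell, light_atoms_nw, "light no water")
  F_light_nw <- structure_factors(light_nw, config$d_min)
  F_light_w <- structure_factors(sys$light, config$d_min)
  stream_paths <- character(config$n_delays)
  for (i in idx) {
    F_li <- if (water_on[i]) F_light_w else F_light_nw
    F_mix <- mix_states(F_dark, F_li, f_delay[i])
    fr <- simulate_frames(
      F_mix, config$n_frames, obs_fraction = config$obs_fraction,
      scale_sigma = config$scale_sigma, partiality_min = config$partiality_min,
      noise_frac = config$noise_frac, seed = derive_seed(config$seed, 2000L + i))
    stream_paths[i] <- file.path(config$out_dir, "streams",
                                 sprintf("delay_%02d.stream", i))
    write_stream(fr, stream_paths[i])
  }
  info <- list(delays_seconds = delays, f_delay = f_delay,
               water_on = water_on, water_site = sys$water_site,
               moved_atoms = sys$moved)
  jsonlite::write_json(info, file.path(config$out_dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(file.path(config$out_dir, "manifest.json"), "simulate",
                 config,
                 counts = list(datasets = config$n_delays + 1,
                               frames_per_dataset = config$n_frames),
                 outputs = c("models", "truth", "streams", "study.json"))
  invisible(list(dir = config$out_dir, dark = sys$dark, light = sys$light,
                 F_dark = F_dark, delays = delays, f_delay = f_delay,
                 water_site = sys$water_site, stream_paths = stream_paths))
}

#' Run the end-to-end resampling appraisal pipeline
#'
#' Executes, on a fixture tree from [simulate_study()] (or user data laid out
#' the same way): bootstrap resampling and Monte-Carlo merging of every
#' dataset; per-replicate difference Fourier maps against matched resampled
#' dark data with dark-model phases; SVD consensus (principal-component) maps
#' per delay; sphere-integrated density time series with resampling error
#' bars; structure-factor extrapolation at the configured occupancy; and
#' partial-occupancy plus extrapolated-data refinements of a replicate subset
#' with bootstrap coordinate spreads and the closed-form coordinate-error
#' estimate. Emits a structured report and a run manifest.
#'
#' @param config A [pipeline_config()] whose `out_dir` holds the fixture tree.
#' @param focal_delay Index of the delay used for the refinement stages
#'   (default: last).
#' @return A list report (also written to `report.json`).
#' @export
run_pipeline <- function(config, focal_delay = NULL) {
  dir <- config$out_dir
  if (!file.exists(file.path(dir, "streams", "dark.stream")))
    stop("pipeline stage 'input': no fixture tree under ", dir)
  study <- jsonlite::read_json(file.path(dir, "study.json"),
                               simplifyVector = TRUE)
  dark_model <- read_pdb(file.path(dir, "models", "dark.pdb"))
  light_model <- read_pdb(file.path(dir, "models", "light.pdb"))
  cell <- dark_model$cell
  F_dark_calc <- structure_factors(dark_model, config$d_min)
  focal_delay <- focal_delay %||% config$n_delays

  stage <- function(name, rep_id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' (replicate %s) failed: %s",
                   name, rep_id, conditionMessage(e)), call. = FALSE))
  }

  datasets <- c("dark", sprintf("delay_%02d", seq_len(config$n_delays)))
  merged <- list()      # per dataset: list of replicate reflection_sets
  n_merged <- 0L
  for (ds in datasets) {
    fs <- stage("read_stream", ds,
                read_stream(file.path(dir, "streams", paste0(ds, ".stream")),
                            cell = cell))
    plan <- bootstrap_plan(fs$n_frames, config$sample_size,
                           config$n_resamples,
                           seed = derive_seed(config$seed, 3000L + match(ds, datasets)))
    merged[[ds]] <- lapply(seq_len(config$n_resamples), function(r) {
      m <- stage("merge", sprintf("%s/%d", ds, r),
                 merge_frames(fs, plan$indices[[r]], config$min_measurements))
      n_merged <<- n_merged + 1L
      intensities_to_amplitudes(m, cell = cell, d_min = config$d_min,
                                role = if (ds == "dark") "reference" else "activated")
    })
  }

  # difference maps per replicate, SVD consensus per delay, quantification
  grid <- map_grid(F_dark_calc, d_min = config$d_min)
  water_center <- as.numeric(study$water_site)
  centers <- list(WAT99 = water_center)
  pc1_by_delay <- list()
  maps_by_delay <- list()
  svd_spectra <- list()
  for (i in seq_len(config$n_delays)) {
    ds <- sprintf("delay_%02d", i)
    maps <- lapply(seq_len(config$n_resamples), function(r)
      stage("diffmap", sprintf("%s/%d", ds, r),
            difference_map(merged[[ds]][[r]], merged[["dark"]][[r]],
                           phases_ref = F_dark_calc, grid = grid)))
    stk <- stack_maps(maps)
    sv <- stage("svd", ds, svd_decompose(stk))
    pc1_by_delay[[ds]] <- principal_map(sv, stk)
    svd_spectra[[ds]] <- sv$d[seq_len(min(10, length(sv$d)))]
    maps_by_delay[[ds]] <- maps
  }
  quant <- quantify_series(maps_by_delay, centers, radius = config$radius,
                           pedestal = config$pedestal_diff)

  # extrapolation at the focal delay
  ds_focal <- sprintf("delay_%02d", focal_delay)
  f_focal <- study$f_delay[focal_delay]
  ext <- lapply(seq_len(config$n_resamples), function(r)
    stage("extrapolate", r,
          extrapolate(merged[[ds_focal]][[r]], merged[["dark"]][[r]], f_focal)))
  rejection <- vapply(ext, function(e) e$rejection_fraction, 0)

  # refinement of a replicate subset: dark spread + two-mode light recovery
  nr <- min(config$refine_replicates, config$n_resamples)
  light_init <- atomic_model(cell, light_model$atoms[
    !grepl("^WAT", light_model$atoms$name), , drop = FALSE], "light init")
  dark_ref <- lapply(seq_len(nr), function(r)
    stage("refine_dark", r,
          refine(merged[["dark"]][[r]], dark_model,
                 refine_options(mode = "extrapolated"))))
  part_ref <- lapply(seq_len(nr), function(r)
    stage("refine_partial", r,
          refine(merged[[ds_focal]][[r]],
                 two_state_model(dark_model, light_init, f_focal),
                 refine_options(mode = "partial_occupancy", f = f_focal))))
  extr_ref <- lapply(seq_len(nr), function(r)
    stage("refine_extrapolated", r,
          refine(ext[[r]]$F_ext, light_init,
                 refine_options(mode = "extrapolated"))))

  ca_names <- dark_model$atoms$name[grepl("^CA", dark_model$atoms$name)]
  spread_dark <- coordinate_spread(dark_ref, selection = ca_names)
  part_models <- lapply(part_ref, activated_model)
  extr_models <- lapply(extr_ref, function(r) activated_model(r, conformer = NULL))
  cmp <- compare_approaches(part_models, extr_models, selection = ca_names,
                            model_ref = dark_model)
  rfree_mean <- mean(vapply(dark_ref, function(r) r$r_free, 0))
  sf <- sigma_free(N_a = n_atoms(dark_model),
                   N_o = nrow(merged[["dark"]][[1]]),
                   R_free = rfree_mean, d_min = config$d_min, C = 1)

  report <- list(
    n_datasets = length(datasets),
    n_resamples = config$n_resamples,
    n_resampled_datasets = n_merged,
    refine_replicates = nr,
    mean_rejection_fraction = mean(rejection),
    spread_ca_mean = attr(spread_dark, "mean_selection"),
    spread_all_mean = attr(spread_dark, "mean_all"),
    sigma_free = sf,
    mean_r_work_dark = mean(vapply(dark_ref, function(r) r$r_work, 0)),
    mean_r_free_dark = rfree_mean,
    mean_b_u = b_to_u(mean(dark_model$atoms$b_iso)),
    approach_profile_correlation = attr(cmp, "profile_correlation"),
    approach_fraction_agreeing = attr(cmp, "fraction_agreeing"),
    svd_spectra = svd_spectra,
    quantification = as.data.frame(quant)
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (ds in names(pc1_by_delay))
    write_map(sigma_scale(pc1_by_delay[[ds]]),
              file.path(dir, sprintf("pc1_%s.map", ds)))
  write_manifest(file.path(dir, "pipeline_manifest.json"), "pipeline", config,
                 counts = list(datasets = length(datasets),
                               resampled_datasets = n_merged,
                               refine_replicates = nr),
                 outputs = c("report.json", sprintf("pc1_%s.map", names(pc1_by_delay))))
  report
}
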