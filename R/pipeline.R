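#' Analyze a set of spectra into normalized survival points
#'
#' The per-spectrum half of the pipeline: assigns each species' charge-state
#' series, fits Gaussian envelopes, and normalizes the educt against the
#' products. Shared by the file-based runner and in-memory workflows.
#'
#' @param spectra Data frame with columns `replicate`, `delta_cv` and a
#'   `spectrum` list-column (as produced by [generate_cid_series()]), or a
#'   plain list of `spectrum` objects (replicate 1 assumed).
#' @param species List of [species_definition()]s, exactly one with role
#'   `"educt"`.
#' @param normalization_mode Passed to [normalize_step()].
#' @param mz_tolerance Passed to [assign_charge_series()].
#' @param smoothing NULL, or list(window, polyorder, cycles) applied to
#'   each spectrum first.
#' @return List with `points` (normalized rows), `envelopes` (tidy per-step
#'   table: delta_cv, replicate, species, apex_intensity, apex_mz,
#'   mean_charge), and `educt_mean_charge` (intensity-weighted over steps).
#' @export
analyze_spectra <- function(spectra, species,
                            normalization_mode = "pairs-mean",
                            mz_tolerance = 0.5, smoothing = NULL) {
  if (!is.data.frame(spectra)) {
    lst <- spectra
    spectra <- data.frame(replicate = 1L,
                          delta_cv = vapply(lst, function(s) s$delta_cv, 0))
    spectra$spectrum <- lst
  }
  roles <- vapply(species, function(s) s$role, "")
  if (sum(roles == "educt") != 1L)
    stop("exactly one species must have role 'educt'", call. = FALSE)
  points <- list(); envs <- list(); k <- 0L
  charges <- numeric(0); weights <- numeric(0)
  for (i in seq_len(nrow(spectra))) {
    sp <- spectra$spectrum[[i]]
    if (!is.null(smoothing))
      sp <- smooth_spectrum(sp, smoothing$window, smoothing$polyorder,
                            smoothing$cycles)
    fits <- lapply(species, function(sd)
      fit_envelope(assign_charge_series(sp, sd, mz_tolerance = mz_tolerance)))
    educt <- fits[[which(roles == "educt")]]
    prods <- fits[roles == "product"]
    k <- k + 1L
    points[[k]] <- normalize_step(educt, prods, mode = normalization_mode,
                                  delta_cv = spectra$delta_cv[i],
                                  replicate_id = spectra$replicate[i])
    envs[[k]] <- data.frame(
      delta_cv = spectra$delta_cv[i], replicate = spectra$replicate[i],
      species = vapply(fits, function(f) f$species, ""),
      apex_intensity = vapply(fits, function(f) f$apex_intensity, 0),
      apex_mz = vapply(fits, function(f) f$apex_mz, 0),
      mean_charge = vapply(fits, function(f) f$mean_charge, 0))
    if (!educt$absent) {
      charges <- c(charges, educt$mean_charge)
      weights <- c(weights, educt$apex_intensity)
    }
  }
  list(points = do.call(rbind, points),
       envelopes = do.call(rbind, envs),
       educt_mean_charge = if (length(charges))
         sum(charges * weights) / sum(weights) else NA_real_)
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.ya?ml$", config)) return(yaml::read_yaml(config))
    if (grepl("\\.json$", config)) return(jsonlite::read_json(config, simplifyVector = TRUE))
    stop("config file must be .yaml/.yml/.json", call. = FALSE)
  }
  stopifnot(is.list(config))
  config
}

.provenance <- function(config, seed) {
  canon <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                            digits = NA, force = TRUE)
  tmp <- tempfile(); writeLines(as.character(canon), tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  list(config_md5 = hash, seed = seed,
       package_version = as.character(utils::packageVersion("itemtwo")))
}

.species_from_config <- function(cfg) {
  lapply(cfg, function(s)
    species_definition(s$name, s$mass, seq(s$charge_min, s$charge_max),
                       role = s$role))
}

#' Run the survival-yield analysis end to end from a manifest of peak lists
#'
#' Reads every peak list named in the manifest, optionally smooths it, fits
#' envelopes and normalizes per step, aggregates replicates, fits the
#' Boltzmann survival curve and derives the apparent kinetic/thermodynamic
#' quantities. Writes a course-parameter table (`table_course.csv`), an
#' apparent-quantities table (`table_thermo.csv`), JSON diagnostics with a
#' provenance block, and a plain-text log of warnings (smoothing window
#' adjustments, quality-gate failures, assumption-bearing defaults in use).
#'
#' @param config Path to a YAML/JSON config file or an equivalent list.
#'   Recognized fields: `manifest`, `species` (list of name/mass/
#'   charge_min/charge_max/role), `normalization_mode`, `kd_mode`,
#'   `mz_tolerance`, `smoothing` (window/polyorder/cycles or NULL),
#'   `r2_threshold`, `residence_time`, `temperature`
#'   (t_amb/gas_mass/ion_mass/dof_scale), `out_dir`, `seed`.
#' @return Invisibly, list with `thermo` ([analyze_series()] result),
#'   `aggregated`, `analysis`, `warnings` (character vector) and the output
#'   paths.
#' @export
run_analysis <- function(config) {
  cfg <- .read_config(config)
  for (f in c("manifest", "species", "out_dir"))
    if (is.null(cfg[[f]])) stop("config is missing field: ", f, call. = FALSE)
  if (!file.exists(cfg$manifest))
    stop("manifest not found: ", cfg$manifest, call. = FALSE)
  manifest <- read_manifest(cfg$manifest)
  missing <- !file.exists(manifest$file)
  if (any(missing))
    stop("manifest references missing file(s): ",
         paste(manifest$file[missing], collapse = ", "), call. = FALSE)
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)
  species <- .species_from_config(cfg$species)
  smoothing <- cfg$smoothing
  if (!is.null(smoothing) && smoothing$window %% 2 == 0) {
    note(sprintf("smoothing window %d is even; using %d",
                 smoothing$window, smoothing$window + 1))
  }
  if (is.null(cfg$normalization_mode)) {
    cfg$normalization_mode <- "pairs-mean"
    note("normalization_mode not set; using default 'pairs-mean'")
  }
  if (is.null(cfg$kd_mode)) {
    cfg$kd_mode <- "mass-action-normalized"
    note("kd_mode not set; using default 'mass-action-normalized' (flagged strategy)")
  }
  if (is.null(cfg$residence_time)) {
    cfg$residence_time <- 8.8e-5
    note("residence_time not set; using default 8.8e-5 s (pusher period)")
  }
  if (is.null(cfg$temperature)) {
    cfg$temperature <- list()
    note("temperature model not set; using default center-of-mass collision-energy mapping")
  }
  if (is.null(cfg$mz_tolerance)) cfg$mz_tolerance <- 0.5
  if (is.null(cfg$r2_threshold)) cfg$r2_threshold <- 0.98
  if (is.null(cfg$seed)) cfg$seed <- 1L
  spectra <- data.frame(replicate = manifest$replicate,
                        delta_cv = manifest$delta_cv)
  spectra$spectrum <- lapply(seq_len(nrow(manifest)), function(i)
    load_peak_list(manifest$file[i], manifest$delta_cv[i]))
  analysis <- withCallingHandlers(
    analyze_spectra(spectra, species,
                    normalization_mode = cfg$normalization_mode,
                    mz_tolerance = cfg$mz_tolerance,
                    smoothing = smoothing),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  agg <- aggregate_replicates(analysis$points)
  tm <- cfg$temperature
  educt <- species[[which(vapply(species, function(s) s$role, "") == "educt")]]
  model <- temperature_model(
    t_amb = tm$t_amb %||% 298,
    gas_mass = tm$gas_mass %||% 39.948,
    ion_mass = tm$ion_mass %||% educt$mass,
    mean_charge = tm$mean_charge %||% analysis$educt_mean_charge,
    dof_scale = tm$dof_scale %||% 0.02)
  thermo <- analyze_series(agg, model, residence_time = cfg$residence_time,
                           kd_mode = cfg$kd_mode,
                           r2_threshold = cfg$r2_threshold)
  if (!thermo$boltzmann$accepted)
    note(sprintf("Boltzmann fit R2 = %.4f below acceptance threshold %.2f",
                 thermo$boltzmann$r_squared, cfg$r2_threshold))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  bz <- thermo$boltzmann
  course <- data.frame(mean_charge = analysis$educt_mean_charge,
                       initial_educt_rate = bz$a1, final_educt_rate = bz$a2,
                       cv50 = bz$x0, dx = bz$dx,
                       slope = midpoint_slope(bz), r_squared = bz$r_squared)
  utils::write.csv(course, file.path(cfg$out_dir, "table_course.csv"),
                   row.names = FALSE)
  tt <- data.frame(k_m0g = thermo$k_m0g, kd_m0g = thermo$kd_m0g,
                   dg_m0g = thermo$dg_m0g, dh_m0g = thermo$dh_m0g,
                   tds_m0g = thermo$tds_m0g)
  utils::write.csv(tt, file.path(cfg$out_dir, "table_thermo.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$envelopes,
                   file.path(cfg$out_dir, "envelopes.csv"), row.names = FALSE)
  diag <- list(provenance = .provenance(cfg, cfg$seed),
               boltzmann = bz[c("a1", "a2", "x0", "dx", "r_squared", "accepted")],
               thermo = tt, warnings = warnings,
               n_spectra = nrow(spectra))
  jsonlite::write_json(diag, file.path(cfg$out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(c(sprintf("[%s] survival-yield analysis", format(Sys.time())),
               paste("warning:", warnings)),
             file.path(cfg$out_dir, "run.log"))
  invisible(list(thermo = thermo, aggregated = agg, analysis = analysis,
                 warnings = warnings, out_dir = cfg$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run protonation-pattern sampling and MMSA selection
#'
#' @param config Path to a YAML/JSON config or a list with fields: `sites`
#'   (site-table CSV path or data frame), `k`, `steps`, `seed`,
#'   `n_lowest`, `n_select`, `relative_permittivity`, `exhaustive`
#'   (logical: brute-force enumeration instead of Monte Carlo), `out_dir`.
#' @return Invisibly, list with `scored`, `selected`, output paths.
#' @export
run_protonation <- function(config) {
  cfg <- .read_config(config)
  for (f in c("sites", "k", "out_dir"))
    if (is.null(cfg[[f]])) stop("config is missing field: ", f, call. = FALSE)
  sites <- if (is.character(cfg$sites)) read_site_table(cfg$sites)
           else site_table(cfg$sites$index, cfg$sites$residue_type,
                           cfg$sites$x, cfg$sites$y, cfg$sites$z)
  eps <- cfg$relative_permittivity %||% 1
  scored <- if (isTRUE(cfg$exhaustive)) {
    enumerate_patterns(sites, cfg$k, relative_permittivity = eps)
  } else {
    monte_carlo_minimize(sites, cfg$k, steps = cfg$steps %||% 5e4,
                         relative_permittivity = eps,
                         seed = cfg$seed %||% 1L)
  }
  selected <- mmsa_select(scored, n_lowest = cfg$n_lowest %||% 100,
                          n_select = cfg$n_select %||% 10)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  scored_out <- utils::head(scored, cfg$n_lowest %||% 100)
  scored_out$rank <- seq_len(nrow(scored_out))
  utils::write.csv(scored_out, file.path(cfg$out_dir, "scored_patterns.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(selected, file.path(cfg$out_dir, "mmsa_selected.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(provenance = .provenance(cfg, cfg$seed %||% 1L),
                            n_distinct = nrow(scored),
                            min_energy = scored$energy[1]),
                       file.path(cfg$out_dir, "protonation.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(scored = scored, selected = selected, out_dir = cfg$out_dir))
}

#' Run inter-chain contact analysis over a structure ensemble
#'
#' @param config Path to a YAML/JSON config or a list with fields: `pdb`
#'   (file path or character lines), `peptide_chain`, `protein_chain`,
#'   `cutoff` (default 4.0), `residue_range` (optional integer vector),
#'   `out_dir`.
#' @return Invisibly, list with `contacts`, `summary` (classified), paths.
#' @export
run_contacts <- function(config) {
  cfg <- .read_config(config)
  for (f in c("pdb", "peptide_chain", "protein_chain", "out_dir"))
    if (is.null(cfg[[f]])) stop("config is missing field: ", f, call. = FALSE)
  ens <- parse_ensemble(cfg$pdb)
  contacts <- ensemble_contacts(ens, cfg$peptide_chain, cfg$protein_chain,
                                cutoff = cfg$cutoff %||% 4.0,
                                residue_range = cfg$residue_range)
  summ <- classify_residues(position_to_sum(contacts,
                                            peptide_residues = cfg$residue_range))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(contacts, file.path(cfg$out_dir, "contacts.csv"),
                   row.names = FALSE)
  utils::write.csv(summ, file.path(cfg$out_dir, "residue_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(provenance = .provenance(cfg, cfg$seed %||% 1L),
                            n_models = ens$n_models,
                            total_positions = sum(summ$position_contacts),
                            total_sum = sum(summ$sum_contacts)),
                       file.path(cfg$out_dir, "contacts.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(contacts = contacts, summary = summ, out_dir = cfg$out_dir))
}
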