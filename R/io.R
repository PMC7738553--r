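#' Derive a reproducible stage seed from a global seed
#'
#' Fixed arithmetic derivation mapping (seed, stage label) to a child seed,
#' so pipeline stages can be re-run independently yet reproducibly from one
#' global seed. Always returns a non-negative integer below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return Integer child seed.
#' @export
derive_seed <- function(seed, stage) {
  u <- utf8ToInt(stage)
  h <- sum(u * seq_along(u))
  as.integer(((as.numeric(seed) %% 1e6) * 2123 + h * 7919) %% 2147483647)
}

#' Write / read a reflectance spectrum as CSV
#'
#' Plain two-column CSV (`wavelength_nm`, `reflectance`) written at full
#' double precision so that a write/read round-trip is lossless. Reading
#' validates the header, numeric parsing (reporting the offending line) and
#' strictly ascending wavelengths.
#'
#' @param spectrum an `"irido_spectrum"` (or compatible data frame).
#' @param path file path.
#' @return `read_spectrum_csv()` returns an `"irido_spectrum"`;
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  lines <- c("wavelength_nm,reflectance",
             sprintf("%.17g,%.17g", spectrum$wavelength_nm, spectrum$reflectance))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L || trimws(lines[1L]) != "wavelength_nm,reflectance")
    stop("bad spectrum CSV header (expected 'wavelength_nm,reflectance'): ", path)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    stop(sprintf("malformed spectrum CSV at line %d: '%s'", bad[1L] + 1L, body[bad[1L]]))
  wl <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  refl <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  nonnum <- which(is.na(wl) | is.na(refl))
  if (length(nonnum) > 0L)
    stop(sprintf("non-numeric value in spectrum CSV at line %d", nonnum[1L] + 1L))
  if (is.unsorted(wl, strictly = TRUE))
    stop("spectrum CSV wavelengths must be strictly ascending: ", path)
  new_spectrum(wl, refl)
}

#' Write / read a track dataset as CSV
#'
#' Tracks go to one CSV (`cell_id`, `class`, `t_hr`, `x_um`, `y_um`) and
#' division events to another (`cell_id`, `t_hr`, `angle_deg`).
#'
#' @param dataset a `"track_dataset"`.
#' @param tracks_path,divisions_path file paths.
#' @return `read_tracks_csv()` returns a `"track_dataset"` (without
#'   generator parameters); the writer returns the paths invisibly.
#' @export
write_tracks_csv <- function(dataset, tracks_path, divisions_path) {
  utils::write.csv(dataset$tracks, tracks_path, row.names = FALSE)
  utils::write.csv(dataset$divisions, divisions_path, row.names = FALSE)
  invisible(c(tracks_path, divisions_path))
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(tracks_path, divisions_path) {
  tracks <- utils::read.csv(tracks_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "class", "t_hr", "x_um", "y_um")
  if (!all(need %in% names(tracks)))
    stop("tracks CSV must have columns: ", paste(need, collapse = ", "))
  divisions <- utils::read.csv(divisions_path, stringsAsFactors = FALSE)
  need_d <- c("cell_id", "t_hr", "angle_deg")
  if (!all(need_d %in% names(divisions)))
    stop("divisions CSV must have columns: ", paste(need_d, collapse = ", "))
  structure(list(tracks = tracks, divisions = divisions, params = NULL,
                 seed = NULL),
            class = "track_dataset")
}

default_config <- function() {
  p <- default_presets()
  list(
    presets = list(
      ordered = unclass(p$ordered)[setdiff(names(p$ordered), "name")],
      disordered = unclass(p$disordered)[setdiff(names(p$disordered), "name")]
    ),
    simulation = list(n_runs = 500L, wavelength_min = 380, wavelength_max = 780,
                      wavelength_step = 1, angle = 0,
                      convention = "amplitude"),
    ne = list(dilation_ordered = 1.35, dilation_disordered = 1.0),
    morphometry = morphometry_presets(),
    tracks = list(n_dense = 50L, n_loose = 50L, enabled = FALSE)
  )
}

merge_config <- function(defaults, override, path = character(0)) {
  for (key in names(override)) {
    here <- paste(c(path, key), collapse = "$")
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", here)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(override[[key]]))
        stop("configuration key ", here, " must be a table of settings")
      defaults[[key]] <- merge_config(defaults[[key]], override[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- override[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a JSON configuration file, applies the built-in defaults (the two
#' crystallotype presets at their measured parameters, 500-run simulation on
#' a 380--780 nm grid, NE dilations 1.35/1.0, printed morphometry
#' parameters) and rejects unknown keys with their full key path. An empty
#' file yields the pure defaults.
#'
#' @param path path to a JSON file, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    override <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt, simplifyVector = TRUE)
    else list()
    cfg <- merge_config(cfg, override)
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  config_presets(cfg)  # errors if preset parameters are invalid
  s <- cfg$simulation
  if (s$n_runs < 1) stop("simulation$n_runs must be >= 1")
  if (s$wavelength_min >= s$wavelength_max || s$wavelength_step <= 0)
    stop("invalid simulation wavelength grid")
  if (s$angle < 0 || s$angle > 70)
    stop("simulation$angle must lie within [0, 70] degrees")
  if (cfg$ne$dilation_ordered <= 0 || cfg$ne$dilation_disordered <= 0)
    stop("ne dilation factors must be > 0")
  invisible(TRUE)
}

config_presets <- function(cfg) {
  mk <- function(name, p) crystallotype_preset(
    name, p$crystal_thickness_mean, p$crystal_thickness_sd,
    p$cytoplasm_mean, p$cytoplasm_sd, p$layer_count_min, p$layer_count_max,
    p$n_crystal, p$n_cytoplasm)
  list(ordered = mk("ordered", cfg$presets$ordered),
       disordered = mk("disordered", cfg$presets$disordered))
}

config_grid <- function(cfg) {
  seq(cfg$simulation$wavelength_min, cfg$simulation$wavelength_max,
      by = cfg$simulation$wavelength_step)
}

#' Run the full analysis pipeline
#'
#' End-to-end seeded run: Monte Carlo spectra for both crystallotypes,
#' colorimetric summaries, the NE response report, synthetic morphometry
#' tables with their comparison, and (optionally) a synthetic track dataset
#' with its behavioural statistics. All outputs are written under `out_dir`
#' as CSV/JSON, together with a run manifest recording the configuration
#' snapshot, seed, package version and MD5 checksum of every output file.
#' Stage seeds are derived from the global seed with [derive_seed()], so any
#' stage can be reproduced in isolation.
#'
#' @param config configuration list from [load_config()] (default: built-in
#'   defaults).
#' @param out_dir output directory (created if missing).
#' @param seed integer global seed.
#' @return The manifest, invisibly.
#' @export
pipeline_run <- function(config = load_config(), out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  presets <- config_presets(config)
  grid <- config_grid(config)
  sim <- config$simulation
  outputs <- character(0)
  emit <- function(name) {
    path <- file.path(out_dir, name)
    outputs[[length(outputs) + 1L]] <<- path
    path
  }

  summaries <- list()
  for (type in c("ordered", "disordered")) {
    sp <- monte_carlo_spectrum(presets[[type]], n_runs = sim$n_runs,
                               wavelengths = grid, angle = sim$angle,
                               convention = sim$convention,
                               seed = derive_seed(seed, paste0("spectrum_", type)))
    write_spectrum_csv(sp, emit(paste0("spectrum_", type, ".csv")))
    summaries[[type]] <- spectrum_summary(sp)
  }
  jsonlite::write_json(summaries, emit("colorimetry_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  ne <- ne_response(presets$ordered, presets$disordered,
                    ne_model(config$ne$dilation_ordered,
                             config$ne$dilation_disordered),
                    n_runs = sim$n_runs, wavelengths = grid,
                    seed = derive_seed(seed, "ne"))
  for (type in c("ordered", "disordered")) {
    write_spectrum_csv(ne[[type]]$pre, emit(paste0("ne_", type, "_pre.csv")))
    write_spectrum_csv(ne[[type]]$post, emit(paste0("ne_", type, "_post.csv")))
  }
  ne_json <- list(
    ordered = list(peaks = as.list(ne$ordered$peaks),
                   shift_nm = ne$ordered$shift_nm),
    disordered = list(peaks = as.list(ne$disordered$peaks),
                      shift_nm = ne$disordered$shift_nm),
    contrast = as.list(ne$contrast),
    model = unclass(ne$model)
  )
  jsonlite::write_json(ne_json, emit("ne_report.json"),
                       auto_unbox = TRUE, digits = NA)

  mp <- config$morphometry
  stripe <- sample_morphometry(mp$stripe$mean_len, mp$stripe$sd_len,
                               mp$stripe$mean_ar, mp$stripe$sd_ar,
                               mp$stripe$n, crystallotype = "stripe",
                               seed = derive_seed(seed, "morph_stripe"))
  inter <- sample_morphometry(mp$interstripe$mean_len, mp$interstripe$sd_len,
                              mp$interstripe$mean_ar, mp$interstripe$sd_ar,
                              mp$interstripe$n, crystallotype = "interstripe",
                              seed = derive_seed(seed, "morph_interstripe"))
  utils::write.csv(rbind(stripe, inter), emit("morphometry.csv"),
                   row.names = FALSE)
  cmp <- summarize_morphometry(stripe, inter)
  jsonlite::write_json(list(groups = cmp$groups, p_value = cmp$p_value),
                       emit("morphometry_comparison.json"),
                       auto_unbox = TRUE, digits = NA)

  if (isTRUE(config$tracks$enabled)) {
    td <- generate_tracks(config$tracks$n_dense, config$tracks$n_loose,
                          seed = derive_seed(seed, "tracks"))
    write_tracks_csv(td, emit("tracks.csv"), emit("divisions.csv"))
    dense_angles <- td$divisions$angle_deg[
      td$divisions$cell_id %in% td$tracks$cell_id[td$tracks$class == "dense"]]
    track_json <- list(
      dense_division_axial = if (length(dense_angles) > 0)
        unclass(division_angle_stats(dense_angles)) else NULL,
      migration_loose = {
        mb <- migration_bias(td, "loose", seed = derive_seed(seed, "boot"))
        mb$displacements <- NULL
        unclass(mb)
      },
      proliferation = unclass(proliferation_rates(td))
    )
    jsonlite::write_json(track_json, emit("track_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    command = "pipeline_run",
    package_version = as.character(utils::packageVersion("iridoptics")),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = config,
    outputs = as.list(tools::md5sum(unlist(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
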