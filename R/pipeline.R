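#' Run a full simulation pipeline from a configuration
#'
#' Executes build -> plan -> simulate -> score for one of the study setups
#' and writes every artifact (metrics JSON, profile and DVH tables, dose
#' grid, run manifest) under an output directory. The configuration is a
#' named list, or the path of a YAML file holding one:
#'
#' \describe{
#'   \item{run}{one of `"validate-range"`, `"fwhm-scan"`, `"rs-study"`,
#'     `"sobp"`, `"irradiate-water"`, `"irradiate-eye"`, `"make-ct"`,
#'     `"irradiate-dicom"`.}
#'   \item{energy}{nominal beam energy, MeV (default 100.51).}
#'   \item{rs_thickness}{range-shifter thickness, mm (default 43).}
#'   \item{collimator}{logical, insert the brass collimator (default for
#'     the eye run).}
#'   \item{distal_range, sobp_width, spacing}{SOBP plan inputs.}
#'   \item{mode}{`"analytic"` or `"mc"`.}
#'   \item{events}{mc primaries.}
#'   \item{seed}{integer seed; mandatory in mc mode.}
#'   \item{voxel_size, gaze_angle, sclera_radius}{eye-run geometry.}
#' }
#'
#' @param config Named list or YAML path.
#' @param out_dir Output directory (created).
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(run = "sobp", energy = 100.51, rs_thickness = 43,
                   collimator = FALSE, distal_range = 35.5, sobp_width = 18,
                   spacing = 2, mode = "analytic", events = NULL,
                   seed = NULL, voxel_size = 0.4, gaze_angle = 40,
                   sclera_radius = 12.25)
  cfg <- utils::modifyList(defaults, config)
  if (identical(cfg$mode, "mc") && is.null(cfg$seed)) {
    stop("configuration error: mc mode requires a seed", call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- switch(cfg$run,
    "validate-range" = .pipe_validate_range(cfg, out_dir),
    "fwhm-scan" = .pipe_fwhm_scan(cfg, out_dir),
    "rs-study" = .pipe_rs_study(cfg, out_dir),
    "sobp" = .pipe_sobp(cfg, out_dir),
    "irradiate-water" = .pipe_water(cfg, out_dir),
    "irradiate-eye" = .pipe_eye(cfg, out_dir),
    "make-ct" = .pipe_make_ct(cfg, out_dir),
    "irradiate-dicom" = .pipe_dicom(cfg, out_dir),
    stop("unknown run type '", cfg$run, "'", call. = FALSE)
  )
  manifest <- list(
    run = cfg$run,
    config = cfg,
    config_hash = .config_hash(cfg),
    seed = cfg$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("oculardose")),
    outputs = res
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

## order-independent hash of the configuration list (no digest dependency:
## fold the serialized bytes)
.config_hash <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  b <- serialize(cfg, NULL, version = 2)
  h <- 0
  for (chunk in split(as.integer(b), ceiling(seq_along(b) / 4096))) {
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%08x", h)
}

.write_tbl <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  path
}

.pipe_validate_range <- function(cfg, out_dir) {
  model <- cnao_range_model()
  tab <- cnao_range_table() |>
    dplyr::mutate(fitted_range = range_in_water(model, .data$energy))
  f <- .write_tbl(tab, file.path(out_dir, "range_validation.csv"))
  list(tables = f)
}

.pipe_fwhm_scan <- function(cfg, out_dir) {
  src <- cnao_source(cfg$energy)
  lay <- build_standard_layout(cfg$energy)
  planes <- c(-1093.6, -654.6, -350, 0, 500)
  tab <- tibble::tibble(position = planes,
                        fwhm = fwhm_at(lay, src, planes))
  f <- .write_tbl(tab, file.path(out_dir, "fwhm_scan.csv"))
  list(tables = f)
}

.pipe_rs_study <- function(cfg, out_dir) {
  th <- seq(0, 70, by = 5)
  tab <- dplyr::bind_rows(
    dplyr::mutate(fwhm_vs_rs_thickness(cfg$energy, th, FALSE),
                  plane = "optimised"),
    dplyr::mutate(fwhm_vs_rs_thickness(cfg$energy, th, TRUE),
                  plane = "standard"))
  f <- .write_tbl(tab, file.path(out_dir, "rs_study.csv"))
  list(tables = f)
}

.pipe_sobp <- function(cfg, out_dir) {
  plan <- sobp_plan_for(cfg$distal_range, cfg$sobp_width, cfg$spacing)
  met <- sobp_metrics(plan$sobp,
                      plateau_span = range(plan$layers$peak_depth))
  f1 <- .write_tbl(plan$layers, file.path(out_dir, "sobp_layers.csv"))
  f2 <- .write_tbl(plan$sobp, file.path(out_dir, "sobp_curve.csv"))
  jsonlite::write_json(as.list(met), file.path(out_dir, "sobp_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  list(tables = c(f1, f2), metrics = file.path(out_dir, "sobp_metrics.json"))
}

.pipe_water <- function(cfg, out_dir) {
  plan <- sobp_plan_for(cfg$distal_range, cfg$sobp_width, cfg$spacing)
  coll <- if (isTRUE(cfg$collimator)) collimator_spec() else NULL
  dg <- irradiate_water(plan, cfg$rs_thickness, coll,
                        mode = cfg$mode, n_primaries = cfg$events,
                        seed = cfg$seed)
  dp <- depth_profile(dg)
  f1 <- .write_tbl(dp, file.path(out_dir, "depth_profile.csv"))
  met <- sobp_metrics(tibble::tibble(coordinate = dp$coordinate,
                                     value = dp$value),
                      plateau_span = range(plan$layers$peak_depth) -
                        cnao_depth_offset())
  jsonlite::write_json(as.list(met), file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  list(tables = f1, metrics = file.path(out_dir, "metrics.json"))
}

.pipe_eye <- function(cfg, out_dir) {
  eye <- build_eye(cfg$sclera_radius, cfg$gaze_angle)
  plan <- sobp_plan_for(35.5, 10, 2)
  dg <- irradiate_eye(eye, plan, cfg$rs_thickness,
                      collimator = collimator_spec(),
                      voxel_size = cfg$voxel_size, mode = cfg$mode,
                      n_primaries = cfg$events, seed = cfg$seed)
  d <- dvh(dg)
  f1 <- .write_tbl(d, file.path(out_dir, "dvh.csv"))
  pc <- prescription_coverage(dg)
  jsonlite::write_json(
    list(iso_level = pc$iso_level,
         coverage = as.list(stats::setNames(pc$coverage$volume_fraction,
                                            pc$coverage$structure))),
    file.path(out_dir, "coverage.json"), auto_unbox = TRUE, digits = NA)
  list(tables = f1, metrics = file.path(out_dir, "coverage.json"))
}

.pipe_make_ct <- function(cfg, out_dir) {
  spec <- synthetic_head_spec(seed = if (is.null(cfg$seed)) 1 else cfg$seed)
  out <- generate_head_ct(spec, file.path(out_dir, "series"))
  list(series = out$files)
}

.pipe_dicom <- function(cfg, out_dir) {
  spec <- synthetic_head_spec(seed = if (is.null(cfg$seed)) 1 else cfg$seed)
  ser_dir <- file.path(out_dir, "series")
  generate_head_ct(spec, ser_dir)
  ser <- read_dicom_series(ser_dir)
  tg <- ct_target_grid(crop_roi(ser, spec$eye_center))
  ## the imaging pathway uses the thicker 46 mm shifter so the beam stops
  ## inside the imaged globe
  dg <- irradiate_dicom(tg, mode = cfg$mode, n_primaries = cfg$events,
                        seed = cfg$seed)
  dp <- depth_profile(dg, half_window = 3)
  f1 <- .write_tbl(dp, file.path(out_dir, "depth_profile.csv"))
  list(tables = f1)
}
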