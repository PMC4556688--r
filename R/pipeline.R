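## End-to-end run: simulate -> segment -> measure -> dsc -> report, with a
## flat key-value config, stage logging and a provenance record. One config
## seed is expanded into per-stage sub-seeds (see split_seed) so any stage
## can be rerun independently.

run_config_defaults <- function() {
  list(
    calibration_nm_per_px = NULL,   # required, no safe default exists
    block_size_px = 51L, threshold_offset = 0.01, opening_radius_px = 2L,
    max_eccentricity = 0.90, min_area_px2 = 30L,
    window_size_px = 300L, n_windows = 200L,
    polarity = "bright_objects", seed = 1L,
    ## simulation stage
    sim_density_per_window = 18, sim_diam_mean_nm = 40.67,
    sim_diam_sd_nm = 2, sim_min_gap_nm = 4, sim_n_artifacts = 5L,
    sim_image_px = 1024L, sim_noise_sd = 0.05, sim_blur_px = 1,
    sim_peak_temp_C = 71.99, sim_peak_width_C = 4, sim_dsc_noise_sd = 0.02,
    sim_group_n = 3L)
}

#' Build and validate a pipeline configuration
#'
#' All downstream operation constraints are checked here, before any file is
#' read: the calibration is mandatory, the threshold block must be odd, the
#' window must fit inside the image, and so on.
#'
#' @param ... configuration values overriding the defaults (see
#'   [run_config_defaults] values in the vignette); `calibration_nm_per_px`
#'   is required
#' @return validated configuration list of class `run_config`
#' @export
run_config <- function(...) {
  cfg <- utils::modifyList(run_config_defaults(), list(...))
  unknown <- setdiff(names(list(...)), names(run_config_defaults()))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$calibration_nm_per_px))
    stop("configuration error: calibration_nm_per_px is required",
         call. = FALSE)
  stopifnot_scalar_positive(cfg$calibration_nm_per_px,
                            "calibration_nm_per_px")
  if (cfg$block_size_px %% 2L == 0L || cfg$block_size_px < 3L)
    stop("block_size_px must be odd and >= 3", call. = FALSE)
  if (cfg$opening_radius_px < 0L) stop("opening_radius_px must be >= 0",
                                       call. = FALSE)
  if (cfg$max_eccentricity <= 0 || cfg$max_eccentricity > 1)
    stop("max_eccentricity must be in (0, 1]", call. = FALSE)
  if (cfg$window_size_px > cfg$sim_image_px)
    stop("window_size_px larger than the image", call. = FALSE)
  if (!cfg$polarity %in% c("bright_objects", "dark_objects"))
    stop("polarity must be bright_objects or dark_objects", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a flat key-value (YAML) file
#'
#' @param path file of `key: value` lines
#' @return validated `run_config`
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full pipeline into a directory
#'
#' Stages run in order (simulate, segment, measure, dsc, report); every
#' intermediate artifact is written, a log echoes the parameters per stage,
#' and `provenance.yaml` records config, per-stage sub-seeds and versions so
#' the run can be reproduced exactly. With `inputs = NULL` the simulate
#' stage generates the micrograph, thermogram and group table from the
#' config; otherwise `inputs` names existing files
#' (`image`, `thermogram`, `group_table`).
#'
#' @param config a [run_config()]
#' @param out_dir output directory, created if needed
#' @param inputs optional named list of input file paths
#' @return (invisibly) named list of artifact paths plus the morphometry and
#'   transition results
#' @export
run_pipeline <- function(config, out_dir, inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  say <- function(stage, fmt, ...) {
    cat(sprintf("[%s] %s\n", stage, sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  seeds <- stats::setNames(
    vapply(1:5, function(k) split_seed(config$seed, k), integer(1)),
    c("simulate", "segment", "measure", "dsc", "report"))
  artifacts <- list()

  ## -- simulate ------------------------------------------------------------
  if (is.null(inputs)) {
    say("simulate", "density=%g/window diam=%g+/-%g nm seed=%d",
        config$sim_density_per_window, config$sim_diam_mean_nm,
        config$sim_diam_sd_nm, seeds[["simulate"]])
    dens_um2 <- config$sim_density_per_window /
      ((config$window_size_px * config$calibration_nm_per_px)^2 / 1e6)
    scene <- generate_scene(
      density_per_um2 = dens_um2, diam_mean_nm = config$sim_diam_mean_nm,
      diam_sd_nm = config$sim_diam_sd_nm,
      min_gap_nm = config$sim_min_gap_nm,
      n_artifacts = config$sim_n_artifacts,
      image_shape_px = c(config$sim_image_px, config$sim_image_px),
      nm_per_px = config$calibration_nm_per_px, seed = seeds[["simulate"]])
    img <- render_micrograph(scene, noise_sd = config$sim_noise_sd,
                             blur_sigma_px = config$sim_blur_px)
    artifacts$image <- file.path(out_dir, "micrograph.tiff")
    write_micrograph(img, artifacts$image)
    artifacts$annotations <- write_scene_annotations(
      scene, file.path(out_dir, "annotations.csv"))
    tg <- generate_thermogram(config$sim_peak_temp_C,
                              peak_width_C = config$sim_peak_width_C,
                              noise_sd = config$sim_dsc_noise_sd,
                              seed = seeds[["simulate"]])
    artifacts$thermogram <- write_thermogram(
      tg, file.path(out_dir, "thermogram.csv"))
    ref <- load_reference_table("cct")
    swl <- ref[ref$measure == "swelled_cct_um", ]
    gt <- generate_group_table(
      data.frame(group = swl$group, mean = swl$mean, sd = swl$sd,
                 n = config$sim_group_n),
      measure = "swelled_cct_um", seed = seeds[["simulate"]])
    artifacts$group_table <- file.path(out_dir, "group_table.csv")
    utils::write.csv(gt, artifacts$group_table, row.names = FALSE)
  } else {
    for (f in unlist(inputs)) if (!file.exists(f))
      stop("simulate: missing input file: ", f, call. = FALSE)
    img <- read_micrograph(inputs$image, config$calibration_nm_per_px)
    tg <- read_thermogram(inputs$thermogram)
    gt <- utils::read.csv(inputs$group_table)
    say("simulate", "skipped: external inputs supplied")
  }

  ## -- segment -------------------------------------------------------------
  say("segment", "block=%d offset=%g opening=%d ecc<=%g area>=%d",
      config$block_size_px, config$threshold_offset,
      config$opening_radius_px, config$max_eccentricity, config$min_area_px2)
  seg <- segment_micrograph(img, config$block_size_px,
                            config$threshold_offset, config$polarity,
                            config$opening_radius_px, config$min_area_px2,
                            config$max_eccentricity)
  artifacts$mask <- file.path(out_dir, "mask.tiff")
  tiff::writeTIFF(seg$mask * 1, artifacts$mask, bits.per.sample = 8L)
  artifacts$components <- file.path(out_dir, "components.csv")
  utils::write.csv(as.data.frame(seg$components), artifacts$components,
                   row.names = FALSE)
  censored <- mean(seg$components$on_border)
  if (is.finite(censored) && censored > 0.2)
    say("segment", "warning: %.0f%% of components border-censored",
        100 * censored)

  ## -- measure -------------------------------------------------------------
  say("measure", "window=%d n_windows=%d seed=%d", config$window_size_px,
      config$n_windows, seeds[["measure"]])
  morph <- summarize_image(seg$components, img, config$window_size_px,
                           config$n_windows, seed = seeds[["measure"]])
  artifacts$morphometry_csv <- file.path(out_dir, "morphometry.csv")
  utils::write.csv(as.data.frame(morph), artifacts$morphometry_csv,
                   row.names = FALSE)

  ## -- dsc -----------------------------------------------------------------
  say("dsc", "baseline tails + smoothing window 5")
  trans <- transition_temperature(tg)
  artifacts$transitions <- file.path(out_dir, "transitions.csv")
  utils::write.csv(data.frame(sample_id = tg$sample_id,
                              transition_temp_C = trans$transition_temp_C,
                              peak_height = trans$peak_height),
                   artifacts$transitions, row.names = FALSE)

  ## -- report --------------------------------------------------------------
  say("report", "planned pairwise Student t-tests, alpha=0.05")
  rep_tables <- build_report(gt)
  artifacts$report <- write_report(rep_tables, file.path(out_dir, "report"))
  comp <- pairwise_ttests(gt[gt$measure == gt$measure[1], ])
  artifacts$comparisons <- file.path(out_dir, "comparisons.csv")
  utils::write.csv(comp, artifacts$comparisons, row.names = FALSE)

  prov <- list(config = unclass(config), stage_seeds = as.list(seeds),
               r_version = R.version.string,
               package_version =
                 as.character(utils::packageVersion("fibrilquant")))
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  say("done", "artifacts in %s", normalizePath(out_dir))
  invisible(c(artifacts, list(morphometry = morph, transition = trans)))
}
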