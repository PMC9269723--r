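# End-to-end pipeline ---------------------------------------------------------

#' Pipeline configuration
#'
#' Collects every stage parameter with its canonical default: 4th-order 3 Hz
#' Butterworth segmentation filter, 75%-of-period peak spacing, 100-point
#' stride normalization, 10 Hz SPARC cutoff, alpha = 0.05 and a 0.80 CC
#' retention threshold. Overrides of these defaults are reported via
#' `message()` when the pipeline runs.
#'
#' @param mode `"synthetic"` (generate a herd) or `"directory"` (read a herd
#'   tree written by [write_herd()])
#' @param input_dir herd directory (directory mode)
#' @param out_dir output directory for report files
#' @param seed integer seed for synthetic mode
#' @param gait `"trot"` or `"canter"`
#' @param n_horses,passages_per_run,duration_s,fs,noise_acc_sd,noise_gyro_sd,jitter_sd,sensors
#'   herd parameters, see [herd_spec()] (synthetic mode)
#' @param effect a [fatigue_effect()] applied to after-runs (synthetic mode)
#' @param fc_filter,filter_order,min_sep,n_points,fc_sparc stage parameters,
#'   see [analysis_params()]
#' @param alpha significance level
#' @param cc_retention CC retention threshold
#' @param pool_cannon_sides,bh screening options, see [screen_indicators()]
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(mode = c("synthetic", "directory"),
                            input_dir = NULL, out_dir = NULL, seed = 1,
                            gait = "trot", n_horses = 10, passages_per_run = 2,
                            duration_s = 8, fs = 128, noise_acc_sd = 0.3,
                            noise_gyro_sd = 0.05, jitter_sd = 0.02,
                            sensors = DEFAULT_SENSORS,
                            effect = fatigue_effect(),
                            fc_filter = 3, filter_order = 4, min_sep = 0.75,
                            n_points = 100, fc_sparc = 10, alpha = 0.05,
                            cc_retention = 0.80, pool_cannon_sides = TRUE,
                            bh = FALSE) {
  mode <- match.arg(mode)
  if (mode == "directory" && is.null(input_dir))
    stop("directory mode requires input_dir")
  cfg <- list(mode = mode, input_dir = input_dir, out_dir = out_dir,
              seed = as.integer(seed), gait = gait, n_horses = n_horses,
              passages_per_run = passages_per_run, duration_s = duration_s,
              fs = fs, noise_acc_sd = noise_acc_sd,
              noise_gyro_sd = noise_gyro_sd, jitter_sd = jitter_sd,
              sensors = sensors, effect = effect, fc_filter = fc_filter,
              filter_order = filter_order, min_sep = min_sep,
              n_points = n_points, fc_sparc = fc_sparc, alpha = alpha,
              cc_retention = cc_retention,
              pool_cannon_sides = pool_cannon_sides, bh = bh)
  defaults <- list(fc_filter = 3, filter_order = 4, min_sep = 0.75,
                   n_points = 100, fc_sparc = 10, alpha = 0.05,
                   cc_retention = 0.80)
  cfg$overrides <- names(defaults)[vapply(names(defaults), function(nm)
    !identical(cfg[[nm]], defaults[[nm]]), logical(1))]
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with fields named as in [pipeline_config()]
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$effect)) raw$effect <- do.call(fatigue_effect, raw$effect)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Synthesizes or loads a herd of paired before/after sessions, derives the
#' kinematic channels, segments and normalizes strides, computes similarity
#' and smoothness indicators, screens them with paired Wilcoxon tests and the
#' CC retention rule, and (when `out_dir` is set) writes `indicators.csv`,
#' `screen.csv`, `screen_cc.csv`, `screen_rmsd.csv`, `screen_sparc.csv`,
#' `sensor_counts.csv`, `qc.csv` and `manifest.yaml`. Identical configuration
#' and seed produce identical outputs.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) list with `records`, `screen`, `tables`, `qc`,
#'   `config`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (nm in config$overrides)
    message("parameter override: ", nm, " = ", config[[nm]])
  if (config$fs <= 2 * config$fc_filter)
    stop("stage segmentation: cutoff above Nyquist (fs = ", config$fs,
         ", fc = ", config$fc_filter, ")")

  herd <- if (config$mode == "synthetic") {
    spec <- herd_spec(
      n_horses = config$n_horses, passages_per_run = config$passages_per_run,
      duration_s = config$duration_s, fs = config$fs,
      noise_acc_sd = config$noise_acc_sd, noise_gyro_sd = config$noise_gyro_sd,
      jitter_sd = config$jitter_sd, seed = config$seed,
      sensors = config$sensors)
    generate_herd(spec, gait_template(config$gait), config$effect)
  } else {
    read_herd(config$input_dir)
  }
  message("herd: ", length(herd), " horses")

  params <- analysis_params(
    fc_filter = config$fc_filter, filter_order = config$filter_order,
    min_sep = config$min_sep, n_points = config$n_points,
    fc_sparc = config$fc_sparc)
  records <- herd_indicators(herd, params)
  message("indicators: ", nrow(records), " records")

  screen <- screen_indicators(records, alpha = config$alpha,
                              pool_cannon_sides = config$pool_cannon_sides,
                              bh = config$bh)
  screen <- apply_cc_retention(screen, config$cc_retention)
  tables <- report_tables(screen)
  message("screen: ", sum(screen$significant), " significant of ",
          nrow(screen), " keys")

  qc <- attr(records, "qc")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_indicator_table(records, out("indicators.csv"))
    utils::write.csv(screen, out("screen.csv"), row.names = FALSE)
    utils::write.csv(tables$cc, out("screen_cc.csv"), row.names = FALSE)
    utils::write.csv(tables$rmsd, out("screen_rmsd.csv"), row.names = FALSE)
    utils::write.csv(tables$sparc, out("screen_sparc.csv"), row.names = FALSE)
    utils::write.csv(tables$sensor_counts, out("sensor_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(qc, out("qc.csv"), row.names = FALSE)
    manifest <- unclass(config)
    manifest$effect <- unclass(manifest$effect)
    manifest$package_version <- as.character(utils::packageVersion("equigait"))
    yaml::write_yaml(manifest, out("manifest.yaml"))
  }
  invisible(list(records = records, screen = screen, tables = tables,
                 qc = qc, config = config))
}
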