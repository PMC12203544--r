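# End-to-end pipeline: phantom simulation -> segmentation -> ratio mapping
# -> cohort simulation -> trajectory estimation -> association analysis,
# with every stage writing versioned JSON artifacts so the final report only
# aggregates numbers already on disk.

#' Pipeline configuration
#'
#' @param seed Master integer seed, recorded in every stage artifact.
#' @param out_dir Output directory.
#' @param stages Named logical vector toggling stages: `phantom`, `segment`,
#'   `ratio`, `cohort`, `trajectory`, `associations`.
#' @param phantom A [phantom_spec()]; its seed is overridden by `seed`.
#' @param seg A [seg_params()].
#' @param calib A [calibration_params()].
#' @param cohort A [cohort_spec()]; its seed is overridden by `seed`.
#' @param grace_ctrl A [grace_control()].
#' @param analysis An [analysis_config()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("plexdyn_run_"),
                            stages = c(phantom = TRUE, segment = TRUE,
                                       ratio = TRUE, cohort = TRUE,
                                       trajectory = TRUE,
                                       associations = TRUE),
                            phantom = phantom_spec(),
                            seg = seg_params(),
                            calib = calibration_params(),
                            cohort = cohort_spec(),
                            grace_ctrl = grace_control(),
                            analysis = analysis_config()) {
  full <- c(phantom = TRUE, segment = TRUE, ratio = TRUE, cohort = TRUE,
            trajectory = TRUE, associations = TRUE)
  full[names(stages)] <- stages
  phantom$seed <- as.integer(seed)
  cohort$seed <- as.integer(seed)
  grace_ctrl$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir, stages = full,
                 phantom = phantom, seg = seg, calib = calib,
                 cohort = cohort, grace_ctrl = grace_ctrl,
                 analysis = analysis),
            class = "pipeline_config")
}

write_stage_json <- function(obj, path, seed) {
  obj$seed <- seed
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  path
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writing per-stage JSON and data
#' artifacts under `config$out_dir`, and returns (and writes) an aggregate
#' report echoing the configuration and its hash. Any stage failure halts
#' the run with an error naming the stage; artifacts from completed stages
#' are retained on disk.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list), invisibly also written to `report.json`.
#' @export
run_full <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed,
                 stages = list())
  seed <- config$seed

  stage <- function(name, enabled, fun) {
    if (!enabled) {
      message("[", name, "] skipped")
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    report$stages[[name]] <<- c(list(status = "done"), res)
    invisible(NULL)
  }

  phantom <- NULL
  stage("phantom", config$stages[["phantom"]], function() {
    phantom <<- make_phantom(config$phantom)
    write_phantom(phantom, file.path(config$out_dir, "phantom"))
    list(icv_ml = phantom$icv_ml,
         chp_truth_voxels = sum(phantom$chp_truth_mask))
  })

  seg <- NULL
  stage("segment", config$stages[["segment"]] &&
          config$stages[["phantom"]], function() {
    seg <<- segment_chp(phantom$t1w, phantom$ventricle_mask,
                        phantom$voxel_dims, phantom$icv_ml, config$seg)
    out <- list(volume_ml = seg$volume_ml,
                normalized_volume = seg$normalized_volume,
                dice_vs_truth = dice_coefficient(seg$mask,
                                                 phantom$chp_truth_mask),
                stage1_means = seg$stage1_fit$means,
                stage2_means = seg$stage2_fit$means)
    write_stage_json(out, file.path(config$out_dir, "segmentation.json"),
                     seed)
    out
  })

  stage("ratio", config$stages[["ratio"]] && config$stages[["phantom"]] &&
          config$stages[["segment"]], function() {
    rr <- ratio_pipeline(phantom$t1w, phantom$t2w, seg$mask,
                         phantom$ref_masks, params = config$calib)
    out <- list(mean_ratio = rr$mean_ratio,
                eroded_voxels = sum(rr$eroded_mask),
                peaks_t1 = as.list(rr$peaks_t1),
                peaks_t2 = as.list(rr$peaks_t2))
    write_stage_json(out, file.path(config$out_dir, "ratio.json"), seed)
    out
  })

  cohort <- NULL
  stage("cohort", config$stages[["cohort"]], function() {
    cohort <<- sample_cohort(config$cohort)
    export_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    list(n_subjects = length(unique(cohort$subject_id)),
         n_rows = nrow(cohort),
         mean_age = mean(cohort$age[cohort$time_years == 0]))
  })

  stage("trajectory", config$stages[["trajectory"]] &&
          config$stages[["cohort"]], function() {
    out <- lapply(c(nchpv = "nchpv", t1t2 = "t1t2", nlvv = "nlvv"),
                  function(v) {
      fit <- fit_grace(cohort$duration_years, cohort[[v]],
                       cohort$subject_id, rescale = "ecdf",
                       control = config$grace_ctrl)
      tp <- find_turning_points(fit)
      list(grid = fit$grid, g_hat = fit$g_hat, ci_lo = fit$ci_lo,
           ci_hi = fit$ci_hi, converged = fit$converged,
           turning_points = tp)
    })
    write_stage_json(out, file.path(config$out_dir, "trajectory.json"),
                     seed)
    lapply(out, function(o) o["turning_points"])
  })

  stage("associations", config$stages[["associations"]] &&
          config$stages[["cohort"]], function() {
    res <- association_tables(cohort, config$analysis)
    write_stage_json(res, file.path(config$out_dir, "associations.json"),
                     seed)
    list(n_cross_sectional = nrow(res$cross_sectional),
         n_selected = length(attr(res$stepwise, "selected")))
  })

  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_dump <- rapply(unclass(config), function(x)
    if (is.function(x)) NULL else x, how = "replace")
  jsonlite::write_json(cfg_dump, cfg_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  report$config_hash <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
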