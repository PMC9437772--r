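#' Pipeline configuration
#'
#' One object holding every stage's settings; a run writes the resolved
#' configuration (YAML) and a machine-readable run record (JSON) next to
#' its outputs.
#'
#' @param input path to a 4D NIFTI, or a [time_series4d()].
#' @param weights path to a weight container ([save_weights()]) or a
#'   `unet_model`.
#' @param out_dir output directory.
#' @param grid a [grid_spec()].
#' @param postprocess a [postprocess_config()].
#' @param fd_threshold_mm censoring threshold.
#' @param fd_radius_mm rotation-to-arc radius for FD.
#' @param sweep_mm threshold grid for the censoring sweep.
#' @param template optional template path or `volume3d` for normalization.
#' @param fwhm_mm Gaussian smoothing kernel FWHM (mm).
#' @param stop_after run a prefix of the pipeline: one of `"mask"`,
#'   `"realign"`, `"censor"`, `"normalize"`, `"smooth"` (full run).
#' @param seed seed recorded with the run.
#' @export
pipeline_config <- function(input, weights, out_dir,
                            grid = grid_spec(),
                            postprocess = postprocess_config(),
                            fd_threshold_mm = 1, fd_radius_mm = 50,
                            sweep_mm = seq(0.5, 3.8, by = 0.3),
                            template = NULL, fwhm_mm = 4,
                            stop_after = "smooth", seed = 1) {
  stop_after <- match.arg(stop_after, c("mask", "realign", "censor", "normalize", "smooth"))
  structure(list(input = input, weights = weights, out_dir = out_dir,
                 grid = grid, postprocess = postprocess,
                 fd_threshold_mm = fd_threshold_mm, fd_radius_mm = fd_radius_mm,
                 sweep_mm = sweep_mm, template = template, fwhm_mm = fwhm_mm,
                 stop_after = stop_after, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolved_config_list <- function(cfg) {
  list(input = if (is.character(cfg$input)) cfg$input else "<in-memory series>",
       weights = if (is.character(cfg$weights)) cfg$weights else "<in-memory model>",
       out_dir = cfg$out_dir,
       grid = list(target_shape = as.integer(cfg$grid$target_shape),
                   target_spacing = cfg$grid$target_spacing),
       postprocess = list(threshold = cfg$postprocess$threshold,
                          connectivity = cfg$postprocess$connectivity),
       fd_threshold_mm = cfg$fd_threshold_mm, fd_radius_mm = cfg$fd_radius_mm,
       sweep_mm = as.numeric(cfg$sweep_mm),
       template = if (is.character(cfg$template)) cfg$template
                  else if (is.null(cfg$template)) NULL else "<in-memory volume>",
       fwhm_mm = cfg$fwhm_mm, stop_after = cfg$stop_after, seed = cfg$seed)
}

#' Run the preprocessing pipeline
#'
#' Stage order: split the series into timepoints, standardize each,
#' predict brain probability, post-process to a native-space mask, mask
#' the native image, realign the masked series, compute framewise
#' displacement and censoring, then (optionally) normalize to a template
#' and smooth. QC artifacts - mean images for visual checking and summary
#' CSVs - are written after masking, realignment and normalization, the
#' points where visual quality checking is recommended. Each stage is
#' timed and logged; a failure halts with a stage-named error, preserving
#' partial outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list of in-memory results per completed stage.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  qc_dir <- file.path(cfg$out_dir, "qc")
  dir.create(qc_dir, showWarnings = FALSE)
  record <- list(stages = list(), config = resolved_config_list(cfg))
  yaml::write_yaml(record$config, file.path(cfg$out_dir, "config.yaml"))
  res <- list()
  t_all <- proc.time()[3]

  stage <- function(name, fun) {
    t0 <- proc.time()[3]
    message(sprintf("[fetalmask] stage %-10s ...", name))
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    record$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 3))
    out
  }

  series <- stage("read", function() {
    if (is.character(cfg$input)) read_series(cfg$input) else cfg$input
  })
  model <- stage("weights", function() {
    if (is.character(cfg$weights)) load_weights(cfg$weights) else cfg$weights
  })

  masked <- stage("mask", function() {
    frames <- split_series(series)
    masks <- vector("list", length(frames))
    for (i in seq_along(frames)) {
      std <- standardize_volume(frames[[i]], cfg$grid)
      prob <- predict_probability(model, std$volume)
      mstd <- withCallingHandlers(binarize_mask(prob, cfg$postprocess),
                                  warning = function(w) {
                                    message(sprintf("frame %d: %s", i - 1, conditionMessage(w)))
                                    invokeRestart("muffleWarning")
                                  })
      masks[[i]] <- invert_standardization(mstd, std$record)
    }
    mask_series <- merge_volumes(masks, tr_seconds = series$tr_seconds)
    write_series(mask_series, file.path(cfg$out_dir, "brainmask_bold.nii.gz"),
                 datatype = "uint8")
    out <- apply_mask_series(series, masks)
    write_series(out, file.path(cfg$out_dir, "masked_bold.nii.gz"))
    mean_mask <- masks[[1]]
    mean_mask$data <- Reduce(`+`, lapply(masks, `[[`, "data")) / length(masks)
    write_volume(mean_mask, file.path(qc_dir, "qc_mask_mean.nii.gz"))
    utils::write.csv(tibble::tibble(frame = seq_along(masks) - 1L,
                                    mask_voxels = vapply(masks, function(m) sum(m$data), 0)),
                     file.path(qc_dir, "qc_mask_summary.csv"), row.names = FALSE)
    list(series = out, masks = masks)
  })
  res$masked <- masked
  if (cfg$stop_after == "mask") return(finish_pipeline(record, cfg, res, t_all))

  re <- stage("realign", function() {
    out <- realign_series(masked$series, fd_radius_mm = cfg$fd_radius_mm)
    write_series(out$series, file.path(cfg$out_dir, "realigned_bold.nii.gz"))
    write_motion_outputs(out$trace, out$fd_mm, cfg$out_dir)
    mv <- get_frame(out$series, 1)
    mv$data <- apply(out$series$data, 1:3, mean)
    write_volume(mv, file.path(qc_dir, "qc_realigned_mean.nii.gz"))
    out
  })
  res$realign <- re
  if (cfg$stop_after == "realign") return(finish_pipeline(record, cfg, res, t_all))

  cen <- stage("censor", function() {
    cm <- censor_frames(re$fd_mm, cfg$fd_threshold_mm, series$tr_seconds)
    sweep_tbl <- fd_sweep(re$fd_mm, cfg$sweep_mm, series$tr_seconds)
    utils::write.csv(tibble::tibble(frame = seq_along(cm$keep) - 1L, keep = cm$keep),
                     file.path(cfg$out_dir, "censor_mask.csv"), row.names = FALSE)
    utils::write.csv(sweep_tbl, file.path(cfg$out_dir, "censor_sweep.csv"),
                     row.names = FALSE)
    list(censor = cm, sweep = sweep_tbl)
  })
  res$censor <- cen
  if (cfg$stop_after == "censor" || is.null(cfg$template))
    return(finish_pipeline(record, cfg, res, t_all))

  norm <- stage("normalize", function() {
    template <- if (is.character(cfg$template)) read_volume(cfg$template) else cfg$template
    mv <- get_frame(re$series, 1)
    mv$data <- apply(re$series$data, 1:3, mean)
    xfm <- register_affine(mv, template)
    out <- warp_series(re$series, xfm, template)
    write_series(out, file.path(cfg$out_dir, "normalized_bold.nii.gz"))
    write_transform(xfm, file.path(cfg$out_dir, "template_transform.mat"))
    qmv <- get_frame(out, 1)
    qmv$data <- apply(out$data, 1:3, mean)
    write_volume(qmv, file.path(qc_dir, "qc_normalized_mean.nii.gz"))
    list(series = out, transform = xfm)
  })
  res$normalize <- norm
  if (cfg$stop_after == "normalize") return(finish_pipeline(record, cfg, res, t_all))

  res$smooth <- stage("smooth", function() {
    out <- smooth_series(norm$series, cfg$fwhm_mm)
    write_series(out, file.path(cfg$out_dir, "smoothed_bold.nii.gz"))
    out
  })
  finish_pipeline(record, cfg, res, t_all)
}

finish_pipeline <- function(record, cfg, res, t_all) {
  record$total_seconds <- round(proc.time()[3] - t_all, 3)
  jsonlite::write_json(record, file.path(cfg$out_dir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("[fetalmask] done in %.1f s (through stage '%s')",
                  record$total_seconds, cfg$stop_after))
  invisible(res)
}
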