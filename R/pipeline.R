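#' Read a pipeline run configuration
#'
#' YAML key-value file mirroring the four interactive steps of the original
#' workflow (open video, set parameters, set output, run):
#' \preformatted{
#' video: path/to/video.avi        # or an image-sequence directory
#' model: path/to/checkpoint.rds
#' interval: 20                    # sample every k-th frame
#' boxes:                          # one "x,y,w,h" quadruple per stoma
#'   - "12,20,40,30"
#'   - "80,60,40,30"
#' out_dir: results/
#' smooth_window: 5
#' seed: 1
#' }
#'
#' @param path YAML file path.
#' @return a named list usable by [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$boxes <- lapply(cfg$boxes, parse_box)
  cfg
}

parse_box <- function(b) {
  if (inherits(b, "bounding_box")) return(b)
  v <- if (is.character(b)) as.numeric(strsplit(b, ",")[[1]]) else as.numeric(b)
  if (length(v) != 4 || any(is.na(v))) {
    stop("box must be an \"x,y,w,h\" quadruple: ", paste(b, collapse = ","))
  }
  bounding_box(v[1], v[2], v[3], v[4])
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full tracking + segmentation + quantification pipeline
#'
#' Executes read video -> KCF track & crop -> segment each crop -> count SOA
#' -> write CSVs. The output table has one row per sampled frame per stoma;
#' rows where the tracker had to be clamped at the frame border are flagged
#' rather than dropped. Deterministic given the config and checkpoint.
#'
#' @param config list (or YAML path) with entries `video`, `boxes`, `model`,
#'   `out_dir`, and optionally `interval` (default 1), `smooth_window`
#'   (default 5), `fps` fallback, `kcf` hyperparameter overrides.
#' @return invisibly, a list with `soa` (the result data.frame), `series`
#'   (per-stoma [soa_series()]), `rates`, and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(!is.null(config$video), !is.null(config$model),
            !is.null(config$out_dir))
  boxes <- lapply(config$boxes, parse_box)
  if (length(boxes) < 1) stop("at least one stoma box is required")
  interval <- if (is.null(config$interval)) 1L else as.integer(config$interval)
  smooth_window <- if (is.null(config$smooth_window)) 5L
                   else as.integer(config$smooth_window)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logcon))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      log_line(logcon, "ERROR in stage '", stage, "': ", conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  log_line(logcon, "reading video: ", config$video, " (interval ", interval,
           ")")
  fs <- run_stage("read_video", {
    fps <- if (is.null(config$fps)) 20 else config$fps
    read_video(config$video, interval = interval, fps = fps)
  })
  log_line(logcon, length(fs$frames), " sampled frames, ", length(boxes),
           " stomata")

  kcf <- if (is.null(config$kcf)) kcf_params() else
    do.call(kcf_params, config$kcf)
  tr <- run_stage("tracking", track_and_crop(fs, boxes, kcf))

  model <- run_stage("load_model", {
    if (inherits(config$model, "seg_model")) config$model
    else load_segnet(config$model)
  })

  log_line(logcon, "segmenting ", length(boxes) * length(fs$frames), " crops")
  series <- vector("list", length(boxes))
  rows <- list()
  for (s in seq_along(boxes)) {
    masks <- run_stage("segmentation",
                       lapply(tr$crops[[s]],
                              function(cr) predict_mask(model, cr)))
    series[[s]] <- compute_soa(masks, fs$times, stoma_id = s)
    rows[[s]] <- data.frame(time_s = fs$times, stoma_id = s,
                            soa_px = series[[s]]$soa,
                            flagged = tr$flagged[, s])
  }
  soa_df <- do.call(rbind, rows)
  soa_df <- soa_df[order(soa_df$time_s, soa_df$stoma_id), ]
  soa_path <- file.path(config$out_dir, "soa.csv")
  run_stage("write_results", write_results(soa_df, soa_path))

  rates <- lapply(series, rate_curve, smooth_window = smooth_window)
  rate_df <- do.call(rbind, lapply(rates, function(r) {
    data.frame(time_s = r$times, stoma_id = r$stoma_id, rate_px_s = r$rate)
  }))
  rate_path <- file.path(config$out_dir, "rate.csv")
  write.csv(rate_df, rate_path, row.names = FALSE)
  log_line(logcon, "wrote ", soa_path, " (", nrow(soa_df), " rows) and ",
           rate_path)
  invisible(list(soa = soa_df, series = series, rates = rates,
                 soa_path = soa_path, rate_path = rate_path))
}

#' Evaluate predicted masks against ground-truth masks
#'
#' Directory-level evaluation: pairs files by name between a truth and a
#' prediction directory and micro-aggregates the confusion counts.
#'
#' @param truth_dir,pred_dir directories of `{0,1}` PNG masks with matching
#'   file names.
#' @return a `metrics_report`.
#' @export
evaluate_mask_dirs <- function(truth_dir, pred_dir) {
  tf <- sort(list.files(truth_dir, pattern = "\\.png$"))
  if (length(tf) == 0) stop("no masks found in ", truth_dir)
  items <- lapply(tf, function(f) {
    pf <- file.path(pred_dir, f)
    if (!file.exists(pf)) stop("missing prediction for ", f)
    list(truth = read_mask(file.path(truth_dir, f)), pred = read_mask(pf))
  })
  aggregate_metrics(items)
}
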