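# Batch orchestration: segment a directory of images, evaluate predictions
# against ground truth, write CSV/JSON reports. Per-image recognition
# failures are recorded and skipped; only I/O and configuration problems are
# hard errors.

list_images <- function(input) {
  if (length(input) == 1L && !file.exists(input) && !dir.exists(input))
    return(character(0))
  if (length(input) == 1L && dir.exists(input))
    input <- list.files(input, pattern = "\\.(png|jpe?g|tiff?)$",
                        full.names = TRUE, ignore.case = TRUE)
  input
}

stem_of <- function(path) tools::file_path_sans_ext(basename(path))

#' Segment a batch of images
#'
#' Runs [segment_ulcer()] over every image, writing per image a final ulcer
#' mask (`<stem>_mask.png`), an overlay (`<stem>_overlay.png`), and
#' optionally the intermediate stage images. A JSON run log records the
#' recognized border pose, rejected segments and any per-image failures.
#' When a truth directory is given (masks named `<stem>*.png`), a metrics
#' report is written as CSV and JSON.
#'
#' @param input directory of images, or character vector of image paths.
#' @param out_dir output directory, created if needed.
#' @param config a [seg_control()] object.
#' @param truth_dir optional directory of ground-truth ulcer masks paired to
#'   the inputs by file stem (a `<stem>_ulcer.png` or `<stem>.png` file).
#' @param save_stages write the intermediate preprocessing/recognition images
#'   for each input (the reflection mask through the candidate mask).
#' @return invisibly, a list with `results` (per-image status), `metrics`
#'   (data frame or NULL), and the log path.
#' @export
run_segment <- function(input, out_dir, config = seg_control(),
                        truth_dir = NULL, save_stages = FALSE) {
  files <- list_images(input)
  if (length(files) == 0L)
    stop("no input images found under: ", paste(input, collapse = ", "),
         call. = FALSE)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  preds <- list(); truths <- list()
  for (f in files) {
    stem <- stem_of(f)
    rec <- tryCatch({
      seg <- segment_ulcer(f, config)
      write_mask(seg$ulcer_mask, file.path(out_dir, paste0(stem, "_mask.png")))
      write_rgb(seg$overlay, file.path(out_dir, paste0(stem, "_overlay.png")))
      if (save_stages) {
        sd <- file.path(out_dir, "stages", stem)
        dir.create(sd, recursive = TRUE, showWarnings = FALSE)
        st <- seg$stages
        write_mask(st$reflection_mask, file.path(sd, "01_reflection_mask.png"))
        write_rgb(array(rep(st$green_smooth, 3L), c(dim(st$green_smooth), 3L)),
                  file.path(sd, "02_green_smooth.png"))
        write_mask(st$green_bin, file.path(sd, "03_green_binarized.png"))
        write_mask(st$premask, file.path(sd, "04_ellipse_premask.png"))
        write_mask(st$pre_edges, file.path(sd, "05_premasked.png"))
        write_mask(st$edges, file.path(sd, "06_thinned.png"))
        write_mask(seg$border_mask, file.path(sd, "07_border.png"))
        write_mask(seg$cornea_mask, file.path(sd, "08_cornea_disk.png"))
        write_mask(seg$candidates, file.path(sd, "09_candidates.png"))
      }
      fit <- seg$border_fit
      if (!is.null(truth_dir)) {
        tf <- c(file.path(truth_dir, paste0(stem, "_ulcer.png")),
                file.path(truth_dir, paste0(stem, ".png")))
        tf <- tf[file.exists(tf)][1L]
        if (!is.na(tf)) {
          preds[[stem]] <- seg$ulcer_mask
          truths[[stem]] <- read_mask(tf)
        }
      }
      list(stem = stem, status = "ok",
           center = unname(fit$center), semi_major = fit$semi_major,
           semi_minor = fit$semi_minor, rotation = fit$rotation,
           vote_fraction = fit$vote_fraction,
           ulcer_pixels = sum(seg$ulcer_mask),
           n_rejected = nrow(seg$rejected_segments),
           rejected = if (nrow(seg$rejected_segments))
             seg$rejected_segments else NULL)
    }, error = function(e) {
      message(sprintf("skipping %s: %s", stem, conditionMessage(e)))
      list(stem = stem, status = "failed", error = conditionMessage(e))
    })
    results[[stem]] <- rec
  }

  metrics <- NULL
  if (length(preds)) {
    metrics <- evaluate_batch(preds, truths, ids = names(preds))
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    write_metrics_json(metrics, file.path(out_dir, "metrics.json"))
  }
  n_fail <- sum(vapply(results, function(r) r$status == "failed", logical(1)))
  log <- list(n_images = length(files), n_failed = n_fail, results = results)
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(results = results, metrics = metrics, log = log_path))
}

# JSON summary mirroring the columns of the batch report.
write_metrics_json <- function(metrics, path) {
  agg <- function(id) {
    r <- metrics[metrics$id == id, ]
    list(`Global Accuracy` = r$accuracy, Specificity = r$specificity,
         Sensitivity = r$sensitivity, `Jaccard Similarity` = r$iou,
         `Dice Similarity` = r$dice)
  }
  jsonlite::write_json(list(per_image = metrics[!metrics$id %in%
                                                  c("pooled", "mean"), ],
                            pooled = agg("pooled"), mean = agg("mean")),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(path)
}

#' Evaluate predicted masks against ground truth
#'
#' Pairs prediction and truth mask files by stem (a truth file whose stem is
#' the prediction stem, with an optional `_mask` suffix stripped and an
#' optional `_ulcer` suffix added). Unpaired or unreadable files are listed
#' and skipped with a warning; mismatched sizes become per-file error
#' entries.
#'
#' @param pred_dir directory (or vector) of predicted mask PNGs.
#' @param truth_dir directory (or vector) of ground-truth mask PNGs.
#' @param out_dir optional; when given, `metrics.csv` and `metrics.json` are
#'   written there.
#' @return the [evaluate_batch()] data frame (invisibly if `out_dir` given).
#' @export
run_evaluate <- function(pred_dir, truth_dir, out_dir = NULL) {
  pf <- if (length(pred_dir) == 1L && dir.exists(pred_dir)) {
    # prefer *_mask.png when present (a run_segment output directory also
    # holds overlays)
    masks <- list.files(pred_dir, pattern = "_mask\\.png$", full.names = TRUE)
    if (length(masks)) masks
    else list.files(pred_dir, pattern = "\\.png$", full.names = TRUE)
  } else pred_dir
  tf <- if (length(truth_dir) == 1L && dir.exists(truth_dir))
    list.files(truth_dir, pattern = "\\.png$", full.names = TRUE) else truth_dir
  tstem <- stem_of(tf)
  preds <- list(); truths <- list(); unpaired <- character()
  for (f in pf) {
    stem <- sub("_mask$", "", stem_of(f))
    hit <- match(TRUE, tstem %in% c(stem, paste0(stem, "_ulcer")))
    if (is.na(hit)) { unpaired <- c(unpaired, stem); next }
    preds[[stem]] <- read_mask(f)
    truths[[stem]] <- read_mask(tf[hit])
  }
  if (length(unpaired))
    warning("unpaired prediction(s) skipped: ",
            paste(unpaired, collapse = ", "), call. = FALSE)
  if (!length(preds)) stop("no paired prediction/truth masks", call. = FALSE)
  metrics <- evaluate_batch(preds, truths, ids = names(preds))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    write_metrics_json(metrics, file.path(out_dir, "metrics.json"))
    return(invisible(metrics))
  }
  metrics
}

#' Write a synthetic suite to disk
#'
#' Renders `n` scenes with [generate_suite()] and writes them with
#' [write_scene()] plus a `scenes.json` manifest.
#'
#' @inheritParams generate_suite
#' @param dir output directory.
#' @return invisibly, the manifest list.
#' @export
run_synth <- function(n, difficulty = "easy", seed = 0L, dir) {
  scenes <- generate_suite(n, difficulty, seed)
  manifest <- lapply(seq_along(scenes), function(i)
    write_scene(scenes[[i]], dir, sprintf("scene_%03d", i)))
  jsonlite::write_json(list(n = n, difficulty = difficulty, seed = seed,
                            scenes = manifest),
                       file.path(dir, "scenes.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
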