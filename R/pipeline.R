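# End-to-end pipeline: preprocess -> (dbscan | fcm) -> lesion mask ->
# evaluation, with a flat serializable configuration.

#' Pipeline run configuration
#'
#' Defaults encode the operating points used throughout: DBSCAN with
#' `eps = 5`, `min_pxl = 60` on an Otsu-binarized luminance image (lesion
#' darker than skin), or FCM with `c = 5` clusters, fuzzifier `m = 2` and
#' membership threshold `T = 30`.
#'
#' @param method `"dbscan"` or `"fcm"`.
#' @param channel,binarize_method,binarize_threshold,polarity Binarization
#'   settings, see [binarize()] (DBSCAN path only).
#' @param eps,min_pxl DBSCAN density parameters.
#' @param select,fill_holes Lesion selection, see [select_lesion_mask()].
#' @param c,m,T,tol,max_iter,lesion_cluster FCM settings, see
#'   [fcm_segment_image()].
#' @param seed Top-level RNG seed; all randomness (FCM initialization) flows
#'   from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(method = c("dbscan", "fcm"),
                       channel = "luminance", binarize_method = "otsu",
                       binarize_threshold = NA, polarity = "dark",
                       eps = 5, min_pxl = 60,
                       select = "largest", fill_holes = TRUE,
                       c = 5, m = 2, T = 30, tol = 1e-5, max_iter = 300,
                       lesion_cluster = "auto",
                       seed = 1) {
  cfg <- list(method = match.arg(method), channel = channel,
              binarize_method = binarize_method,
              binarize_threshold = binarize_threshold, polarity = polarity,
              eps = eps, min_pxl = min_pxl, select = select,
              fill_holes = fill_holes, c = c, m = m, T = T, tol = tol,
              max_iter = max_iter, lesion_cluster = lesion_cluster,
              seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration as a flat key=value text file
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, "=", format(config[[k]], digits = 17)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#'
#' @param path Path to the key=value file.
#' @return A [run_config()] equal to the one written.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) {
    v <- x[2]
    if (v == "NA") return(NA)
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }), vapply(kv, `[[`, character(1), 1))
  do.call(run_config, vals)
}

#' Segment one image with the configured method
#'
#' @param image A [raster_image()].
#' @param config A [run_config()].
#' @return The lesion [binary_mask()].
#' @export
segment_image <- function(image, config = run_config()) {
  if (config$method == "dbscan") {
    mask <- binarize(image, method = config$binarize_method,
                     threshold = if (is.na(config$binarize_threshold)) NULL
                                 else config$binarize_threshold,
                     channel = config$channel, polarity = config$polarity)
    labels <- dbscan_mask(mask, eps = config$eps, min_pxl = config$min_pxl)
    select_lesion_mask(labels, policy = config$select,
                       fill_holes = config$fill_holes)
  } else {
    fcm_segment_image(image, c = config$c, m = config$m, T = config$T,
                      tol = config$tol, max_iter = config$max_iter,
                      seed = config$seed,
                      lesion_cluster = config$lesion_cluster)$mask
  }
}

#' Run the pipeline on one image file
#'
#' Looks for a manual mask at `<stem>_manual.png` next to the image (or an
#' explicit `manual_path`); when found, the result is evaluated against it.
#' Written outputs: `<stem>_mask.png` and, when requested, an overlay PNG
#' with the manual border in red and the automatic border in blue (DBSCAN)
#' or green (FCM).
#'
#' @param image_path Path to the input image.
#' @param config A [run_config()].
#' @param manual_path Optional explicit manual-mask path.
#' @param out_dir Optional output directory for mask/overlay PNGs.
#' @param emit_overlay Write the overlay PNG (default `FALSE`).
#' @return List: `mask` (the lesion [binary_mask()]) and `record` (an
#'   [evaluate_pair()] row, or `NULL` with a warning when no manual mask
#'   exists).
#' @export
run_single <- function(image_path, config = run_config(), manual_path = NULL,
                       out_dir = NULL, emit_overlay = FALSE) {
  stem <- tools::file_path_sans_ext(basename(image_path))
  image <- load_image(image_path)
  mask <- segment_image(image, config)
  if (mask_area(mask) == 0) warning("empty segmentation for ", image_path)

  if (is.null(manual_path)) {
    cand <- file.path(dirname(image_path), paste0(stem, "_manual.png"))
    if (file.exists(cand)) manual_path <- cand
  }
  record <- NULL
  if (!is.null(manual_path)) {
    record <- evaluate_pair(mask, load_mask(manual_path), image_id = stem)
  } else {
    warning("no manual mask for ", image_path, "; skipping evaluation")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_mask(mask, file.path(out_dir, paste0(stem, "_mask.png")))
    if (emit_overlay) {
      auto_color <- if (config$method == "dbscan") c(0, 0, 255) else c(0, 255, 0)
      layers <- list(list(mask = mask, color = auto_color, style = "contour"))
      if (!is.null(manual_path))
        layers <- c(list(list(mask = load_mask(manual_path),
                              color = c(255, 0, 0), style = "contour")), layers)
      render_overlay(image, layers,
                     file.path(out_dir, paste0(stem, "_overlay.png")))
    }
  }
  list(mask = mask, record = record)
}

#' Run the pipeline on a batch of images
#'
#' Continues past per-image failures, recording them. The written CSV holds
#' one row per evaluated image plus the `"mean"` aggregate row.
#'
#' @param image_paths Character vector of image paths (at least one).
#' @param config A [run_config()].
#' @param out_dir Optional output directory; the report is written there as
#'   `report.csv` together with the serialized configuration.
#' @return List: `report` (data frame as from [batch_evaluate()]) and
#'   `failures` (named character vector of error messages, empty when clean).
#' @export
run_batch <- function(image_paths, config = run_config(), out_dir = NULL) {
  if (length(image_paths) == 0) stop("run_batch needs at least one image")
  records <- list()
  failures <- character(0)
  for (p in image_paths) {
    res <- tryCatch(run_single(p, config, out_dir = out_dir),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[basename(p)] <- conditionMessage(res)
    } else if (!is.null(res$record)) {
      records[[length(records) + 1L]] <- res$record
    }
  }
  report <- NULL
  if (length(records) > 0) {
    report <- do.call(rbind, records)
    metric_cols <- c("border_error_pct", "precision", "recall")
    agg <- data.frame(image_id = "mean", tp = NA_integer_, tn = NA_integer_,
                      fp = NA_integer_, fn = NA_integer_)
    for (k in metric_cols) agg[[k]] <- mean(report[[k]], na.rm = TRUE)
    report <- rbind(report, agg)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report))
      write_report(report, file.path(out_dir, "report.csv"))
    write_run_config(config, file.path(out_dir, "run_config.txt"))
  }
  list(report = report, failures = failures)
}
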