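#' Configuration for a batch pipeline run
#'
#' @param input_dir Directory of plot images named
#'   \code{{variety}_{treatment}_{replicate}_{k}.png} (a manifest CSV can
#'   override the naming convention).
#' @param output_dir Directory for reports and masks; \code{NULL} disables
#'   file output.
#' @param layout An \code{"experiment_layout"}, or a path to a YAML/JSON
#'   layout config, or \code{NULL} to infer plots from filenames alone.
#' @param segmentation A \code{\link{segment_params}} list.
#' @param withered A \code{\link{withered_thresholds}} list, or \code{NULL}
#'   to skip withered-leaf extraction.
#' @param mapping Grade mapping variant, see \code{\link{grade}}.
#' @param manifest Optional path to a CSV with columns \code{image},
#'   \code{variety}, \code{treatment}, \code{replicate} overriding the
#'   filename convention.
#' @param write_masks Write each image's plant mask PNG to
#'   \code{output_dir}?
#' @param seed Integer seed for any sampling (the core pipeline is
#'   deterministic; kept for forward compatibility).
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(input_dir, output_dir = NULL, layout = NULL,
                       segmentation = segment_params(),
                       withered = withered_thresholds(),
                       mapping = "severity",
                       manifest = NULL,
                       write_masks = FALSE,
                       seed = 1L) {
  if (is.character(layout)) layout <- read_layout(layout)
  if (!is.null(layout)) stopifnot(inherits(layout, "experiment_layout"))
  stopifnot(inherits(segmentation, "segment_params"))
  if (!is.null(withered)) stopifnot(inherits(withered, "withered_thresholds"))
  mapping <- match.arg(mapping, c("severity", "literal"))
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 layout = layout, segmentation = segmentation,
                 withered = withered, mapping = mapping,
                 manifest = manifest, write_masks = isTRUE(write_masks),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{run_config}};
#' \code{segmentation} and \code{withered} are nested maps of their
#' respective parameters, \code{layout} is either a nested layout map or a
#' path string.
#'
#' @param path Path to a YAML file.
#' @return A \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$input_dir)) stop("config must set input_dir")
  layout <- cfg$layout
  if (is.list(layout)) layout <- layout_from_config(layout)
  seg <- do.call(segment_params, as.list(cfg$segmentation %||% list()))
  wth <- if (identical(cfg$withered, FALSE)) NULL
         else do.call(withered_thresholds, as.list(cfg$withered %||% list()))
  run_config(input_dir = cfg$input_dir,
             output_dir = cfg$output_dir,
             layout = layout,
             segmentation = seg,
             withered = wth,
             mapping = cfg$mapping %||% "severity",
             manifest = cfg$manifest,
             write_masks = isTRUE(cfg$write_masks),
             seed = cfg$seed %||% 1L)
}

#' Write a run configuration to YAML
#'
#' \code{read_run_config(write_run_config(cfg, f))} reproduces a
#' semantically identical configuration.
#'
#' @param config A \code{"run_config"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lay <- config$layout
  out <- list(
    input_dir = config$input_dir,
    output_dir = config$output_dir,
    layout = if (is.null(lay)) NULL else list(
      varieties = as.list(lay$varieties),
      treatments = lapply(lay$treatments, function(t)
        list(label = t$label, rate = t$rate)),
      replicates = lay$replicates,
      images_per_plot = lay$images_per_plot,
      plot_size_m = lay$plot_size_m,
      rows_per_plot = lay$rows_per_plot,
      row_spacing_cm = lay$row_spacing_cm,
      replicate_kind = lay$replicate_kind),
    segmentation = unclass(config$segmentation),
    withered = if (is.null(config$withered)) FALSE
               else unclass(config$withered),
    mapping = config$mapping,
    manifest = config$manifest,
    write_masks = config$write_masks,
    seed = config$seed
  )
  yaml::write_yaml(out[!vapply(out, is.null, logical(1))], path)
  invisible(path)
}

parse_image_names <- function(files) {
  pat <- "^(.+)_([^_]+)_([0-9]+)_([0-9]+)\\.(png|jpe?g)$"
  ok <- grepl(pat, files, ignore.case = TRUE)
  variety <- treatment <- rep(NA_character_, length(files))
  replicate <- img_index <- rep(NA_integer_, length(files))
  variety[ok] <- sub(pat, "\\1", files[ok], ignore.case = TRUE)
  treatment[ok] <- sub(pat, "\\2", files[ok], ignore.case = TRUE)
  replicate[ok] <- as.integer(sub(pat, "\\3", files[ok], ignore.case = TRUE))
  img_index[ok] <- as.integer(sub(pat, "\\4", files[ok], ignore.case = TRUE))
  data.frame(image = files, variety = variety, treatment = treatment,
             replicate = replicate, img_index = img_index,
             stringsAsFactors = FALSE)
}

#' Run the batch phenotyping pipeline
#'
#' Discovers images, maps them to plots, segments each one, extracts
#' coverage, frost grade and withered fraction, and aggregates to plot and
#' variety-by-treatment level with a treatment-ranking summary. Per-image
#' failures are logged and excluded, never fatal: a field batch survives a
#' corrupt file. Deterministic for fixed inputs and configuration.
#'
#' @param config A \code{"run_config"}.
#' @param verbose Print per-image progress lines (threshold, coverage)?
#' @return A list of class \code{"frost_run"}: \code{images} (per-image
#'   rows), \code{plots}, \code{variety_treatment} (aggregates),
#'   \code{ranking} (\code{"treatment_ranking"} or NULL), \code{failed}
#'   (data.frame of file/reason), counts, and the config.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$input_dir))
    stop("input directory does not exist: ", config$input_dir)
  files <- sort(list.files(config$input_dir,
                           pattern = "\\.(png|jpe?g)$", ignore.case = TRUE))
  files <- files[!grepl("_truth\\.png$", files)]
  if (!length(files)) stop("no images found in ", config$input_dir)

  if (!is.null(config$manifest)) {
    man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    need <- c("image", "variety", "treatment", "replicate")
    if (!all(need %in% names(man)))
      stop("manifest must have columns ", paste(need, collapse = ", "))
    info <- merge(data.frame(image = files, stringsAsFactors = FALSE),
                  man, by = "image", all.x = TRUE)
    info$img_index <- stats::ave(seq_along(info$image),
                                 paste(info$variety, info$treatment,
                                       info$replicate),
                                 FUN = seq_along)
  } else {
    info <- parse_image_names(files)
  }
  info <- info[order(info$image), , drop = FALSE]

  failed <- list()
  unmapped <- is.na(info$variety)
  for (f in info$image[unmapped]) {
    warning("cannot map filename to a plot, skipping: ", f, call. = FALSE)
    failed[[length(failed) + 1L]] <- data.frame(image = f,
                                                reason = "unmappable filename")
  }
  info <- info[!unmapped, , drop = FALSE]

  if (!is.null(config$layout)) {
    plots <- enumerate_plots(config$layout)
    known <- paste(info$variety, info$treatment, info$replicate) %in%
      paste(plots$variety, plots$treatment, plots$replicate)
    for (f in info$image[!known]) {
      warning("image does not match any plot in the layout, skipping: ", f,
              call. = FALSE)
      failed[[length(failed) + 1L]] <- data.frame(image = f,
                                                  reason = "not in layout")
    }
    info <- info[known, , drop = FALSE]
  }

  if (config$write_masks && !is.null(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- vector("list", nrow(info))
  for (i in seq_len(nrow(info))) {
    f <- info$image[i]
    res <- tryCatch({
      img <- read_rgb_image(file.path(config$input_dir, f))
      seg <- segment(img, config$segmentation)
      cov <- coverage(seg$mask)
      g <- grade(cov, config$mapping)
      wf <- if (is.null(config$withered)) NA_real_
            else withered_extract(img, thresholds = config$withered)$withered_fraction
      if (config$write_masks && !is.null(config$output_dir))
        write_mask_png(seg$mask,
                       file.path(config$output_dir,
                                 sub("\\.[^.]+$", "_mask.png", f)))
      if (verbose)
        message(sprintf("%s: otsu t=%d coverage=%.2f%% grade=%d",
                        f, seg$threshold, cov$coverage_pct, g$grade))
      data.frame(image = f,
                 plot_id = paste(info$variety[i], info$treatment[i],
                                 info$replicate[i], sep = "_"),
                 variety = info$variety[i], treatment = info$treatment[i],
                 replicate = info$replicate[i],
                 otsu_t = seg$threshold,
                 coverage_pct = cov$coverage_pct,
                 grade = g$grade, grade_label = g$label,
                 withered_fraction = wf,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("failed to process ", f, ": ", conditionMessage(e),
              call. = FALSE)
      failed[[length(failed) + 1L]] <<- data.frame(image = f,
                                                   reason = conditionMessage(e))
      NULL
    })
    rows[[i]] <- res
  }
  images <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  failed_df <- if (length(failed)) do.call(rbind, failed)
               else data.frame(image = character(0), reason = character(0))

  plots_df <- NULL; vt_df <- NULL; ranking <- NULL
  if (!is.null(images) && nrow(images)) {
    sp <- split(images, images$plot_id)
    plots_df <- do.call(rbind, lapply(sp, function(d) {
      agg <- aggregate_plot(d$coverage_pct, config$mapping)
      data.frame(plot_id = d$plot_id[1], variety = d$variety[1],
                 treatment = d$treatment[1], replicate = d$replicate[1],
                 n_images = agg$n_images,
                 mean_coverage_pct = agg$mean_coverage_pct,
                 grade = agg$grade, grade_label = agg$grade_label,
                 mean_withered_fraction = mean(d$withered_fraction),
                 stringsAsFactors = FALSE)
    }))
    rownames(plots_df) <- NULL
    plots_df <- plots_df[order(plots_df$plot_id), , drop = FALSE]
    sv <- split(plots_df, paste(plots_df$variety, plots_df$treatment))
    vt_df <- do.call(rbind, lapply(sv, function(d) {
      m <- mean(d$mean_coverage_pct)
      data.frame(variety = d$variety[1], treatment = d$treatment[1],
                 n_plots = nrow(d), mean_coverage_pct = m,
                 grade = grade(m, config$mapping)$grade,
                 stringsAsFactors = FALSE)
    }))
    rownames(vt_df) <- NULL
    vt_df <- vt_df[order(vt_df$variety, vt_df$treatment), , drop = FALSE]
    complete <- all(table(vt_df$variety) == length(unique(vt_df$treatment))) &&
      length(unique(vt_df$treatment)) > 1L
    if (complete) {
      tab <- vt_df[, c("variety", "treatment", "mean_coverage_pct")]
      names(tab)[3] <- "coverage"
      ranking <- treatment_ranking_summary(tab)
    }
  }

  run <- structure(list(images = images, plots = plots_df,
                        variety_treatment = vt_df, ranking = ranking,
                        failed = failed_df,
                        n_discovered = length(files),
                        n_processed = if (is.null(images)) 0L else nrow(images),
                        n_failed = nrow(failed_df),
                        config = config),
                   class = "frost_run")
  if (!is.null(config$output_dir)) write_report(run, config$output_dir)
  run
}

#' Write a run's reports to disk
#'
#' Emits \code{images.csv}, \code{plots.csv}, \code{variety_treatment.csv},
#' \code{failed.csv} and a JSON \code{summary.json} into \code{dir}.
#'
#' @param run A \code{"frost_run"}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(run, dir) {
  stopifnot(inherits(run, "frost_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$images))
    utils::write.csv(run$images, file.path(dir, "images.csv"),
                     row.names = FALSE)
  if (!is.null(run$plots))
    utils::write.csv(run$plots, file.path(dir, "plots.csv"),
                     row.names = FALSE)
  if (!is.null(run$variety_treatment))
    utils::write.csv(run$variety_treatment,
                     file.path(dir, "variety_treatment.csv"),
                     row.names = FALSE)
  utils::write.csv(run$failed, file.path(dir, "failed.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(summary(run)), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.frost_run <- function(x, ...) {
  cat("Frost-phenotyping run\n")
  cat(sprintf("  images: %d discovered, %d processed, %d failed\n",
              x$n_discovered, x$n_processed, x$n_failed))
  if (!is.null(x$plots))
    cat(sprintf("  plots:  %d, coverage %.1f-%.1f%%\n", nrow(x$plots),
                min(x$plots$mean_coverage_pct),
                max(x$plots$mean_coverage_pct)))
  if (!is.null(x$ranking)) print(x$ranking)
  invisible(x)
}

#' Summarize a pipeline run
#'
#' Per-grade plot counts, per-treatment coverage quartiles, and the
#' lowest/highest-coverage treatment fractions across varieties.
#'
#' @param object A \code{"frost_run"}.
#' @param ... Unused.
#' @return A list (class \code{"frost_run_summary"}): \code{counts},
#'   \code{grade_counts}, \code{coverage_quartiles_by_treatment},
#'   \code{treatment_ranking}.
#' @export
summary.frost_run <- function(object, ...) {
  if (is.null(object$plots) || !nrow(object$plots))
    stop("run report is empty")
  gc <- table(factor(object$plots$grade, levels = 1:4))
  quart <- lapply(split(object$plots$mean_coverage_pct,
                        object$plots$treatment),
                  function(x) as.list(stats::quantile(x, names = TRUE)))
  rank <- if (is.null(object$ranking)) NULL else
    list(lowest = as.list(object$ranking$lowest),
         highest = as.list(object$ranking$highest),
         n_varieties = object$ranking$n_varieties,
         n_ties_lowest = length(object$ranking$ties_lowest),
         n_ties_highest = length(object$ranking$ties_highest))
  structure(list(
    counts = list(discovered = object$n_discovered,
                  processed = object$n_processed,
                  failed = object$n_failed,
                  plots = nrow(object$plots)),
    grade_counts = stats::setNames(as.list(as.integer(gc)), names(gc)),
    coverage_quartiles_by_treatment = quart,
    treatment_ranking = rank
  ), class = "frost_run_summary")
}

#' @export
print.frost_run_summary <- function(x, ...) {
  cat("Run summary\n")
  cat(sprintf("  %d processed / %d discovered (%d failed), %d plots\n",
              x$counts$processed, x$counts$discovered, x$counts$failed,
              x$counts$plots))
  cat("  plots per grade: ",
      paste(sprintf("g%s=%d", names(x$grade_counts),
                    unlist(x$grade_counts)), collapse = ", "), "\n")
  for (t in names(x$coverage_quartiles_by_treatment)) {
    q <- unlist(x$coverage_quartiles_by_treatment[[t]])
    cat(sprintf("  %s coverage quartiles: %s\n", t,
                paste(sprintf("%.1f", q), collapse = " / ")))
  }
  if (!is.null(x$treatment_ranking)) {
    r <- x$treatment_ranking
    cat("  lowest-coverage fractions: ",
        paste(sprintf("%s %.1f%%", names(r$lowest),
                      100 * unlist(r$lowest)), collapse = ", "), "\n")
    cat("  highest-coverage fractions:",
        paste(sprintf("%s %.1f%%", names(r$highest),
                      100 * unlist(r$highest)), collapse = ", "), "\n")
  }
  invisible(x)
}
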