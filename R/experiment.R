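#' Define a nitrogen fertilizer treatment
#'
#' A treatment is a short label (e.g. \code{"N2"}) plus a urea-nitrogen
#' application rate in kg/ha.
#'
#' @param label Short character label, unique within a layout.
#' @param rate Non-negative application rate in kg/ha.
#' @return An object of class \code{"nitrogen_treatment"}.
#' @examples
#' nitrogen_treatment("N2", 180)
#' @export
nitrogen_treatment <- function(label, rate) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("treatment label must be a single non-empty string")
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    stop("treatment rate must be a single non-negative number (kg/ha)")
  structure(list(label = label, rate = as.numeric(rate)),
            class = "nitrogen_treatment")
}

#' Describe a field-experiment layout
#'
#' Captures the design of a varieties-by-nitrogen frost trial: which
#' varieties were sown, which fertilizer treatments applied, how many
#' replicates, and how many nadir photographs are taken of each plot.
#' Plot geometry (size, row count, row spacing) is carried as metadata
#' only; no downstream computation uses it.
#'
#' @param varieties Character vector of unique variety names.
#' @param treatments List of \code{\link{nitrogen_treatment}} objects with
#'   unique labels.
#' @param replicates Positive integer number of replicates per
#'   variety-treatment combination.
#' @param images_per_plot Positive integer, photographs per plot.
#' @param plot_size_m Length-2 positive numeric, plot length and width in m.
#' @param rows_per_plot Positive integer, sowing rows per plot.
#' @param row_spacing_cm Positive number, row spacing in cm.
#' @param replicate_kind Free-text note on what the replicate axis is
#'   (biological, technical, ...).
#' @return An object of class \code{"experiment_layout"}.
#' @seealso \code{\link{default_layout}}, \code{\link{enumerate_plots}},
#'   \code{\link{count_images}}
#' @export
experiment_layout <- function(varieties, treatments, replicates,
                              images_per_plot = 3L,
                              plot_size_m = c(1.5, 1.5),
                              rows_per_plot = 6L,
                              row_spacing_cm = 25,
                              replicate_kind = "biological and technical") {
  if (!is.character(varieties) || length(varieties) < 1L)
    stop("layout must name at least one variety")
  if (anyDuplicated(varieties))
    stop("variety names must be unique")
  if (inherits(treatments, "nitrogen_treatment")) treatments <- list(treatments)
  if (!is.list(treatments) || length(treatments) < 1L ||
      !all(vapply(treatments, inherits, logical(1), "nitrogen_treatment")))
    stop("treatments must be a non-empty list of nitrogen_treatment objects")
  labels <- vapply(treatments, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("treatment labels must be unique")
  replicates <- as.integer(replicates)
  images_per_plot <- as.integer(images_per_plot)
  if (is.na(replicates) || replicates < 1L)
    stop("replicates must be a positive integer")
  if (is.na(images_per_plot) || images_per_plot < 1L)
    stop("images_per_plot must be a positive integer")
  if (!is.numeric(plot_size_m) || length(plot_size_m) != 2L || any(plot_size_m <= 0))
    stop("plot_size_m must be two positive numbers (length, width)")
  rows_per_plot <- as.integer(rows_per_plot)
  if (is.na(rows_per_plot) || rows_per_plot < 1L)
    stop("rows_per_plot must be a positive integer")
  if (!is.numeric(row_spacing_cm) || length(row_spacing_cm) != 1L || row_spacing_cm <= 0)
    stop("row_spacing_cm must be a positive number")
  structure(list(
    varieties = varieties,
    treatments = treatments,
    replicates = replicates,
    images_per_plot = images_per_plot,
    plot_size_m = as.numeric(plot_size_m),
    rows_per_plot = rows_per_plot,
    row_spacing_cm = as.numeric(row_spacing_cm),
    replicate_kind = as.character(replicate_kind)
  ), class = "experiment_layout")
}

#' @export
print.experiment_layout <- function(x, ...) {
  rates <- vapply(x$treatments, `[[`, numeric(1), "rate")
  labels <- vapply(x$treatments, `[[`, character(1), "label")
  cat("Field-experiment layout\n")
  cat(sprintf("  varieties:      %d\n", length(x$varieties)))
  cat(sprintf("  treatments:     %s\n",
              paste(sprintf("%s=%g kg/ha", labels, rates), collapse = ", ")))
  cat(sprintf("  replicates:     %d (%s)\n", x$replicates, x$replicate_kind))
  cat(sprintf("  images/plot:    %d\n", x$images_per_plot))
  cat(sprintf("  plots:          %d   images: %d\n",
              nrow(enumerate_plots(x)), count_images(x)))
  cat(sprintf("  plot geometry:  %g x %g m, %d rows @ %g cm\n",
              x$plot_size_m[1], x$plot_size_m[2], x$rows_per_plot,
              x$row_spacing_cm))
  invisible(x)
}

#' The default frost-trial layout
#'
#' 128 varieties (auto-named \code{V001}..\code{V128}), three nitrogen
#' treatments (N1 = 0, N2 = 180, N3 = 240 kg/ha urea-N), two replicates and
#' three images per plot, on 1.5 x 1.5 m plots with six sowing rows at 25 cm
#' spacing: 768 plots and 2304 images in total.
#'
#' @param varieties Optional character vector of variety names to use
#'   instead of the auto-generated placeholders.
#' @return An \code{"experiment_layout"}.
#' @examples
#' lay <- default_layout()
#' count_images(lay)  # 2304
#' @export
default_layout <- function(varieties = sprintf("V%03d", 1:128)) {
  experiment_layout(
    varieties = varieties,
    treatments = list(nitrogen_treatment("N1", 0),
                      nitrogen_treatment("N2", 180),
                      nitrogen_treatment("N3", 240)),
    replicates = 2L,
    images_per_plot = 3L
  )
}

#' Enumerate all plots of a layout
#'
#' Produces the plot inventory in a deterministic variety-major order
#' (variety, then treatment, then replicate), the order used by all batch
#' output.
#'
#' @param layout An \code{"experiment_layout"}.
#' @return A data.frame with columns \code{plot_id}, \code{variety},
#'   \code{treatment}, \code{replicate}; one row per plot,
#'   \code{|varieties| * |treatments| * replicates} rows in total.
#' @examples
#' nrow(enumerate_plots(default_layout()))  # 768
#' @export
enumerate_plots <- function(layout) {
  stopifnot(inherits(layout, "experiment_layout"))
  labels <- vapply(layout$treatments, `[[`, character(1), "label")
  grid <- expand.grid(replicate = seq_len(layout$replicates),
                      treatment = labels,
                      variety = layout$varieties,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("variety", "treatment", "replicate")]
  grid$plot_id <- paste(grid$variety, grid$treatment, grid$replicate, sep = "_")
  rownames(grid) <- NULL
  grid[, c("plot_id", "variety", "treatment", "replicate")]
}

#' Count the images a layout implies
#'
#' @param layout An \code{"experiment_layout"}.
#' @return Number of plots times images per plot.
#' @examples
#' count_images(default_layout())  # 2304
#' @export
count_images <- function(layout) {
  stopifnot(inherits(layout, "experiment_layout"))
  nrow(enumerate_plots(layout)) * layout$images_per_plot
}

#' Read a layout from a YAML or JSON config file
#'
#' The file mirrors the fields of \code{\link{experiment_layout}}:
#' \code{varieties} (a list of names, or an integer \code{n_varieties} for
#' auto-named placeholders), \code{treatments} (list of \code{label}/
#' \code{rate} pairs), \code{replicates}, \code{images_per_plot}, and the
#' optional geometry fields.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return An \code{"experiment_layout"}.
#' @export
read_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  layout_from_config(cfg)
}

layout_from_config <- function(cfg) {
  varieties <- if (!is.null(cfg$varieties)) unlist(cfg$varieties)
               else if (!is.null(cfg$n_varieties))
                 sprintf("V%03d", seq_len(cfg$n_varieties))
               else stop("config must give 'varieties' or 'n_varieties'")
  if (is.null(cfg$treatments)) stop("config must give 'treatments'")
  trt <- cfg$treatments
  if (is.data.frame(trt))
    trt <- lapply(seq_len(nrow(trt)), function(i) as.list(trt[i, ]))
  treatments <- lapply(trt, function(t)
    nitrogen_treatment(t$label, t$rate))
  args <- list(varieties = as.character(varieties), treatments = treatments,
               replicates = cfg$replicates %||% 1L)
  for (f in c("images_per_plot", "plot_size_m", "rows_per_plot",
              "row_spacing_cm", "replicate_kind"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  do.call(experiment_layout, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a layout to a YAML config file
#'
#' @param layout An \code{"experiment_layout"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "experiment_layout"))
  cfg <- list(
    varieties = as.list(layout$varieties),
    treatments = lapply(layout$treatments, function(t)
      list(label = t$label, rate = t$rate)),
    replicates = layout$replicates,
    images_per_plot = layout$images_per_plot,
    plot_size_m = layout$plot_size_m,
    rows_per_plot = layout$rows_per_plot,
    row_spacing_cm = layout$row_spacing_cm,
    replicate_kind = layout$replicate_kind
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
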