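#' Image stack container
#'
#' An `ImageStack` holds one channel's z-stack at one timepoint together with
#' the acquisition metadata the pipeline needs. Pixels are stored as a
#' `[row, column, plane]` array (one matrix per z-plane); coordinates used in
#' all outputs are zero-based with `x` = column and `y` = row, pixel centers
#' at integer positions.
#'
#' @param pixels numeric matrix or 3-D array `[row, col, plane]`.
#' @param channel channel name, e.g. `"tumor"`, `"lymphatic"`, `"brightfield"`.
#' @param timepoint_hours acquisition time in hours (nonnegative).
#' @param exposure_ms exposure time in milliseconds (positive).
#' @param pixel_size_mm physical size of one pixel side in millimeters.
#' @param bit_depth one of `8`, `16`, or `"real"` for floating-point data
#'   (e.g. after exposure normalization).
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(pixels, channel = "tumor", timepoint_hours = 0,
                        exposure_ms = 20, pixel_size_mm = 0.0051,
                        bit_depth = 16) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, all(dim(pixels) >= 1L))
  stop_if_not_scalar_pos(exposure_ms, "exposure_ms")
  stop_if_not_scalar_pos(pixel_size_mm, "pixel_size_mm")
  if (timepoint_hours < 0) stop("`timepoint_hours` must be nonnegative")
  structure(list(pixels = pixels, channel = channel,
                 timepoint_hours = timepoint_hours, exposure_ms = exposure_ms,
                 pixel_size_mm = pixel_size_mm, bit_depth = bit_depth),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageStack: %s, %d x %d px, %d plane(s), t = %g h, %g ms, %s-bit\n",
              x$channel, d[2], d[1], d[3], x$timepoint_hours, x$exposure_ms,
              as.character(x$bit_depth)))
  invisible(x)
}

n_planes <- function(stack) dim(stack$pixels)[3]

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' One grayscale page per z-plane. Acquisition metadata is carried in a YAML
#' sidecar (`<path>.yaml`) because the vendor metadata formats are out of
#' scope. Integer values in `[0, 65535]` round-trip exactly.
#'
#' @param stack an [image_stack()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  px <- stack$pixels
  if (any(px < 0) || any(px > 65535))
    stop("pixel values outside [0, 65535]; cannot write 16-bit TIFF")
  pages <- lapply(seq_len(dim(px)[3]), function(p) px[, , p] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(channel = stack$channel,
               timepoint_hours = stack$timepoint_hours,
               exposure_ms = stack$exposure_ms,
               pixel_size_mm = stack$pixel_size_mm,
               bit_depth = stack$bit_depth)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' Read a multi-page grayscale TIFF as an image stack
#'
#' The plane count equals the page count and 16-bit values are preserved
#' exactly. Metadata is taken from the YAML sidecar written by
#' [write_stack()]; fields missing there fall back to the arguments, with a
#' warning when neither source provides a value and a default is used.
#'
#' @param path TIFF file path.
#' @param channel,timepoint_hours,exposure_ms,pixel_size_mm fallback metadata
#'   used when the sidecar is absent or incomplete.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, channel = NULL, timepoint_hours = NULL,
                       exposure_ms = NULL, pixel_size_mm = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (pg in pages) {
    if (!is.matrix(pg))
      stop("non-grayscale TIFF page in ", path, " (expected one sample per pixel)")
  }
  shp <- vapply(pages, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("inconsistent page shapes in ", path)
  px <- array(0, dim = c(shp[1, 1], shp[2, 1], length(pages)))
  for (p in seq_along(pages)) px[, , p] <- pages[[p]]
  meta <- if (file.exists(sidecar_path(path))) yaml::read_yaml(sidecar_path(path)) else list()
  pick <- function(field, arg, default) {
    if (!is.null(meta[[field]])) return(meta[[field]])
    if (!is.null(arg)) return(arg)
    warning(sprintf("metadata field '%s' missing for %s; using default %s",
                    field, basename(path), format(default)), call. = FALSE)
    default
  }
  image_stack(px,
              channel = pick("channel", channel, "unknown"),
              timepoint_hours = pick("timepoint_hours", timepoint_hours, 0),
              exposure_ms = pick("exposure_ms", exposure_ms, 20),
              pixel_size_mm = pick("pixel_size_mm", pixel_size_mm, 0.0051),
              bit_depth = if (!is.null(meta$bit_depth)) meta$bit_depth else 16)
}

#' Import hand-traced vessel centerlines
#'
#' Reads a CSV with columns `trace_id, point_index, x_px, y_px` (the dialect
#' [write_truth_tables()] emits). Points are ordered by `point_index` within
#' each trace; traces with fewer than two points are rejected by name.
#'
#' @param path CSV file path.
#' @return a list of `VesselTrace` objects, each
#'   `list(trace_id, points)` with `points` an n x 2 matrix of `(x, y)`
#'   pixel coordinates.
#' @export
read_vessel_traces <- function(path) {
  if (!file.exists(path)) stop("cannot read vessel trace file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trace_id", "point_index", "x_px", "y_px")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("vessel trace file missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(list())
  for (col in c("point_index", "x_px", "y_px"))
    if (!is.numeric(df[[col]]))
      stop("non-numeric values in column '", col, "'")
  key <- paste(df$trace_id, df$point_index)
  if (anyDuplicated(key))
    stop("duplicate (trace_id, point_index) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  ids <- unique(df$trace_id)
  short <- ids[vapply(ids, function(i) sum(df$trace_id == i) < 2, logical(1))]
  if (length(short))
    stop("trace(s) with fewer than 2 points: ", paste(short, collapse = ", "))
  lapply(ids, function(i) {
    sub <- df[df$trace_id == i, , drop = FALSE]
    sub <- sub[order(sub$point_index), , drop = FALSE]
    list(trace_id = i,
         points = unname(cbind(x = sub$x_px, y = sub$y_px)))
  })
}

# Euclidean arc length of an ordered (x, y) point matrix, in pixels.
polyline_length_px <- function(points) {
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

#' Pipeline run configuration
#'
#' Defaults are the published analysis settings: threshold at background mean
#' plus `k = 2` standard deviations, particle filter at areas strictly greater
#' than 50 px^2, 10-plane stacks, focus kernel 7 (the reference plugin's
#' kernel "6" rounded up to the nearest odd size for a centered window).
#' `pixel_size_mm` has no trustworthy published value and must always be
#' supplied explicitly for real data; the default matches the synthetic
#' scenes (50 px^2 ~ 0.0013 mm^2).
#'
#' @param pixel_size_mm calibration, millimeters per pixel side.
#' @param threshold_k background threshold multiplier k.
#' @param min_cluster_area_px2 strict lower area bound for particle analysis.
#' @param morphology_iterations integer number of binary openings, or
#'   `"auto"` to choose the smallest count in 0..5 that clears sub-threshold
#'   specks (see [morphological_clean()]).
#' @param focus_kernel_px odd window size for the focus metric.
#' @param reference_exposure_ms exposure all acquisitions are normalized to.
#' @param roi region of interest for vessel density; `NULL` means a centered
#'   square covering 50% of each image dimension.
#' @param channel_roles named character vector mapping channel names to roles
#'   (`tumor`, `lymphatic`, `blood`, `brightfield`).
#' @param com_mode `"weighted"` (area-weighted center of mass, default) or
#'   `"unweighted"` (plain mean of cluster centroids), for sensitivity
#'   analysis.
#' @return a list of class `RunConfig`.
#' @export
run_config <- function(pixel_size_mm = 0.0051, threshold_k = 2,
                       min_cluster_area_px2 = 50,
                       morphology_iterations = "auto",
                       focus_kernel_px = 7L, reference_exposure_ms = 20,
                       roi = NULL,
                       channel_roles = c(tumor = "tumor",
                                         lymphatic = "lymphatic",
                                         brightfield = "brightfield"),
                       com_mode = "weighted") {
  stop_if_not_scalar_pos(pixel_size_mm, "pixel_size_mm")
  if (!is.finite(threshold_k)) stop("`threshold_k` must be finite")
  if (min_cluster_area_px2 < 0) stop("`min_cluster_area_px2` must be >= 0")
  if (focus_kernel_px %% 2 == 0) {
    message("focus kernel ", focus_kernel_px, " is even; using ",
            focus_kernel_px + 1)
    focus_kernel_px <- focus_kernel_px + 1L
  }
  structure(list(pixel_size_mm = pixel_size_mm, threshold_k = threshold_k,
                 min_cluster_area_px2 = min_cluster_area_px2,
                 morphology_iterations = morphology_iterations,
                 focus_kernel_px = as.integer(focus_kernel_px),
                 reference_exposure_ms = reference_exposure_ms,
                 roi = roi, channel_roles = channel_roles,
                 com_mode = match.arg(com_mode, c("weighted", "unweighted"))),
            class = "RunConfig")
}

#' Write result tables for a processed series
#'
#' Emits one per-cluster CSV per timepoint (`clusters_<hours>h.csv`), a
#' one-row-per-timepoint `summary.csv`, and `vessel_density.csv`. Column
#' order is stable and values round-trip at full double precision.
#'
#' @param results a list as returned by [process_series()] (fields
#'   `clusters` — list of per-timepoint data frames, `summary`, `vessels`).
#' @param dir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  wr <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
  }
  for (cl in results$clusters) {
    hrs <- attr(cl, "timepoint_hours")
    wr(cl, sprintf("clusters_%03dh.csv", as.integer(round(hrs))))
  }
  if (!is.null(results$summary)) wr(results$summary, "summary.csv")
  if (!is.null(results$vessels)) wr(results$vessels, "vessel_density.csv")
  invisible(written)
}

#' Export a binary mask as PNG and run-length CSV
#'
#' @param mask a [binary_mask()].
#' @param png_path output PNG (foreground 255, background 0), or `NULL`.
#' @param rle_path output run-length CSV (`row, col_start, run_length`,
#'   zero-based columns), or `NULL`.
#' @return invisibly, the paths written.
#' @export
write_mask <- function(mask, png_path = NULL, rle_path = NULL) {
  px <- mask$pixels
  out <- character()
  if (!is.null(png_path)) {
    png::writePNG(px * 1, png_path)
    out <- c(out, png_path)
  }
  if (!is.null(rle_path)) {
    rows <- which(rowSums(px) > 0)
    recs <- list(data.frame(row = integer(), col_start = integer(),
                            run_length = integer()))
    for (r in rows) {
      rl <- rle(as.integer(px[r, ]))
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      keep <- rl$values == 1L
      if (any(keep))
        recs[[length(recs) + 1L]] <-
          data.frame(row = r - 1L, col_start = starts[keep] - 1L,
                     run_length = rl$lengths[keep])
    }
    utils::write.csv(do.call(rbind, recs), rle_path, row.names = FALSE)
    out <- c(out, rle_path)
  }
  invisible(out)
}
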