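#' Center of mass of a cluster set
#'
#' Area-weighted mean of cluster centroids, i.e. the centroid of all
#' retained foreground pixels, in millimeters. `mode = "unweighted"` gives
#' the plain mean of centroids instead (sensitivity switch).
#'
#' @param clusters data frame from [detect_clusters()].
#' @param mode `"weighted"` (default) or `"unweighted"`.
#' @return numeric `c(x_mm, y_mm)`.
#' @export
center_of_mass <- function(clusters, mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  if (nrow(clusters) == 0) stop("cannot compute center of mass of 0 clusters")
  ps <- attr(clusters, "pixel_size_mm")
  w <- if (mode == "weighted") clusters$area_px2 else rep(1, nrow(clusters))
  c(x_mm = sum(clusters$centroid_x_px * w) / sum(w) * ps,
    y_mm = sum(clusters$centroid_y_px * w) / sum(w) * ps)
}

#' Annotate clusters with dispersal metrics
#'
#' Fills per-cluster distance to the center of mass (mm), the area moment
#' (distance x area, mm^3) — the dispersal statistic describing directional
#' growth — and, when `origin_mm` is given, the distance to a fixed origin
#' such as the implantation site (mm).
#'
#' @param clusters data frame from [detect_clusters()].
#' @param com `c(x_mm, y_mm)` from [center_of_mass()] on the same clusters.
#' @param origin_mm optional fixed reference point `c(x_mm, y_mm)`.
#' @return the cluster data frame with `distance_to_com_mm`,
#'   `area_moment_mm3`, `percent_area`, and (if requested)
#'   `distance_to_origin_mm` columns added.
#' @export
annotate_distances_and_moments <- function(clusters, com, origin_mm = NULL) {
  ps <- attr(clusters, "pixel_size_mm")
  if (nrow(clusters) == 0) {
    clusters$distance_to_com_mm <- numeric(0)
    clusters$area_moment_mm3 <- numeric(0)
    clusters$percent_area <- numeric(0)
    if (!is.null(origin_mm)) clusters$distance_to_origin_mm <- numeric(0)
    return(clusters)
  }
  x <- clusters$centroid_x_px * ps
  y <- clusters$centroid_y_px * ps
  clusters$distance_to_com_mm <- sqrt((x - com[1])^2 + (y - com[2])^2)
  clusters$area_moment_mm3 <- clusters$distance_to_com_mm * clusters$area_mm2
  clusters$percent_area <- 100 * clusters$area_mm2 / sum(clusters$area_mm2)
  if (!is.null(origin_mm))
    clusters$distance_to_origin_mm <-
      sqrt((x - origin_mm[1])^2 + (y - origin_mm[2])^2)
  clusters
}

sem <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))

#' Per-timepoint summary statistics
#'
#' The published per-timepoint summary: cluster count, total area, mean
#' (+/- SEM) cluster area, equivalent diameter, distance to the center of
#' mass, and area moment. SEM uses the sample standard deviation (n - 1)
#' over sqrt(n) and is reported as missing (`NA`) when fewer than two
#' clusters are present rather than fabricating precision. Per-cluster
#' percent-of-total-area lives on the annotated cluster table.
#'
#' @param clusters annotated data frame from
#'   [annotate_distances_and_moments()].
#' @param timepoint_hours acquisition time of this frame.
#' @return one-row data frame (`ClusterSummary`).
#' @export
summarize_timepoint <- function(clusters, timepoint_hours) {
  n <- nrow(clusters)
  has_origin <- "distance_to_origin_mm" %in% names(clusters)
  data.frame(
    timepoint_hours = timepoint_hours,
    n_clusters = n,
    total_area_mm2 = if (n) sum(clusters$area_mm2) else 0,
    mean_area_mm2 = if (n) mean(clusters$area_mm2) else NA_real_,
    sem_area_mm2 = if (n) sem(clusters$area_mm2) else NA_real_,
    mean_diameter_mm = if (n) mean(clusters$diameter_mm) else NA_real_,
    sem_diameter_mm = if (n) sem(clusters$diameter_mm) else NA_real_,
    mean_distance_mm = if (n) mean(clusters$distance_to_com_mm) else NA_real_,
    sem_distance_mm = if (n) sem(clusters$distance_to_com_mm) else NA_real_,
    mean_distance_origin_mm =
      if (n && has_origin) mean(clusters$distance_to_origin_mm) else NA_real_,
    sem_distance_origin_mm =
      if (n && has_origin) sem(clusters$distance_to_origin_mm) else NA_real_,
    mean_moment_mm3 = if (n) mean(clusters$area_moment_mm3) else NA_real_,
    sem_moment_mm3 = if (n) sem(clusters$area_moment_mm3) else NA_real_)
}

#' Longitudinal time-series table
#'
#' Stacks per-timepoint summaries, sorted by time, and appends
#' first-difference columns (`d_` prefix) for trend inspection of the key
#' quantities.
#'
#' @param summaries list of one-row data frames from
#'   [summarize_timepoint()], distinct timepoints.
#' @return data frame sorted by `timepoint_hours`.
#' @export
longitudinal_table <- function(summaries) {
  if (!length(summaries)) stop("need at least one summary")
  tab <- do.call(rbind, summaries)
  if (anyDuplicated(tab$timepoint_hours))
    stop("duplicate timepoints: ",
         paste(unique(tab$timepoint_hours[duplicated(tab$timepoint_hours)]),
               collapse = ", "))
  tab <- tab[order(tab$timepoint_hours), , drop = FALSE]
  rownames(tab) <- NULL
  for (q in c("total_area_mm2", "mean_area_mm2", "mean_distance_mm",
              "mean_distance_origin_mm", "mean_moment_mm3")) {
    tab[[paste0("d_", q)]] <- c(NA_real_, diff(tab[[q]]))
  }
  tab
}
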