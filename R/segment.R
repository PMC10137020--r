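#' Binary mask container
#'
#' @param pixels logical (or 0/1) matrix.
#' @param provenance list recording how the mask was produced (threshold
#'   value, k, morphology iterations, ...).
#' @return object of class `BinaryMask`.
#' @export
binary_mask <- function(pixels, provenance = list()) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  px <- pixels != 0
  structure(list(pixels = px, provenance = provenance), class = "BinaryMask")
}

#' Estimate background intensity statistics
#'
#' Tumor cells are implanted at the center of the window, so by default the
#' background is sampled from the union of four corner patches, each 5% x 5%
#' of the image dimensions. The region can be overridden with an explicit
#' logical mask of the same shape. Mean and standard deviation are the
#' sample statistics (denominator n - 1).
#'
#' @param image 2-D numeric matrix.
#' @param region `"corners"` (default) or a logical matrix selecting
#'   background pixels.
#' @param corner_frac side fraction of each corner patch when
#'   `region = "corners"`.
#' @return a `BackgroundStats` list: `mean`, `sd`, `n_pixels`, `region`.
#' @export
estimate_background <- function(image, region = "corners",
                                corner_frac = 0.05) {
  stopifnot(is.matrix(image))
  if (is.character(region) && identical(region, "corners")) {
    nr <- nrow(image); nc <- ncol(image)
    h <- max(1L, floor(nr * corner_frac)); w <- max(1L, floor(nc * corner_frac))
    sel <- matrix(FALSE, nr, nc)
    sel[c(1:h, (nr - h + 1):nr), c(1:w, (nc - w + 1):nc)] <- TRUE
    region_desc <- sprintf("corners(%g)", corner_frac)
  } else if (is.logical(region) || (is.matrix(region) && all(region %in% c(0, 1)))) {
    if (!all(dim(region) == dim(image)))
      stop("background region mask shape does not match the image")
    sel <- region != 0
    region_desc <- "mask"
  } else stop("`region` must be \"corners\" or a logical matrix")
  vals <- image[sel]
  if (length(vals) < 100)
    stop("background region has ", length(vals),
         " pixels; at least 100 required for a stable estimate")
  list(mean = mean(vals), sd = stats::sd(vals), n_pixels = length(vals),
       region = region_desc)
}

#' Background-relative intensity threshold
#'
#' A pixel is foreground iff its value is strictly greater than
#' `mean + k * sd` of the background signal. Only the upper tail is used:
#' reporter fluorescence is strictly brighter than background, so the
#' conventional "mean +/- k sd" phrasing is read as an upper threshold.
#'
#' @param image 2-D numeric matrix.
#' @param stats a `BackgroundStats` list from [estimate_background()].
#' @param k threshold multiplier (default 2).
#' @return a [binary_mask()] whose provenance records the numeric threshold.
#' @export
threshold_mask <- function(image, stats, k = 2) {
  stopifnot(is.matrix(image), is.finite(stats$mean), is.finite(stats$sd),
            is.finite(k))
  thr <- stats$mean + k * stats$sd
  binary_mask(image > thr,
              provenance = list(threshold = thr, k = k,
                                background_mean = stats$mean,
                                background_sd = stats$sd))
}

#' Morphological noise cleanup by binary opening
#'
#' Applies `iterations` rounds of binary opening (erosion then dilation with
#' a 3x3 cross structuring element), the reproducible counterpart of the
#' manual "erode/dilate until the noise no longer contributes" step. With
#' `iterations = "auto"` the smallest n in 0..5 is chosen such that no
#' connected component smaller than `min_area_px2` remains (n = 5 if none
#' succeeds); the chosen n is recorded in the provenance.
#'
#' @param mask a [binary_mask()].
#' @param iterations nonnegative integer or `"auto"`.
#' @param min_area_px2 speck-size bound used by the `"auto"` rule.
#' @return cleaned [binary_mask()]; opening is anti-extensive, so the result
#'   is a subset of the input.
#' @export
morphological_clean <- function(mask, iterations = "auto", min_area_px2 = 50) {
  stopifnot(inherits(mask, "BinaryMask"))
  kern <- EBImage::makeBrush(3L, shape = "diamond")
  open_n <- function(px, n) {
    m <- px * 1
    for (i in seq_len(n)) m <- EBImage::dilate(EBImage::erode(m, kern), kern)
    m != 0
  }
  if (identical(iterations, "auto")) {
    chosen <- 5L
    for (n in 0:5) {
      cand <- open_n(mask$pixels, n)
      areas <- component_areas(cand)
      if (!any(areas < min_area_px2)) { chosen <- n; break }
    }
    out <- open_n(mask$pixels, chosen)
    n_used <- chosen
  } else {
    if (!is.numeric(iterations) || iterations < 0 || iterations %% 1 != 0)
      stop("`iterations` must be a nonnegative integer or \"auto\"")
    out <- open_n(mask$pixels, iterations)
    n_used <- as.integer(iterations)
  }
  binary_mask(out, provenance = c(mask$provenance,
                                  list(morphology_iterations = n_used,
                                       morphology_rule = if (identical(iterations, "auto")) "auto" else "fixed")))
}

# ---- connected-component labeling (8-connectivity) -------------------------

#' Label connected components under 8-connectivity
#'
#' Main labeling path: 4-connected labeling (EBImage's `bwlabel`) followed by
#' union-find merging of labels that touch diagonally, which yields exactly
#' the 8-connected components. Labels are renumbered 1..n in raster order of
#' each component's first pixel.
#'
#' @param px logical matrix.
#' @return integer matrix of labels (0 = background).
#' @export
label_components <- function(px) {
  stopifnot(is.matrix(px))
  lab <- EBImage::bwlabel(px * 1)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nlab <- max(lab)
  if (nlab == 0L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  # diagonal adjacencies: offsets (+1,+1) and (+1,-1) cover all diagonal pairs
  for (dc in c(1L, -1L)) {
    a <- lab[-nrow(lab), if (dc == 1L) -1L else -ncol(lab), drop = FALSE]
    b <- lab[-1L, if (dc == 1L) -ncol(lab) else -1L, drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      prs <- unique(cbind(a[sel], b[sel]))
      for (r in seq_len(nrow(prs))) {
        ra <- find(prs[r, 1]); rb <- find(prs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  merged <- root[lab[lab > 0L]]
  # renumber in raster (column-major) order of first appearance
  newid <- integer(nlab)
  first <- unique(merged)
  newid[first] <- seq_along(first)
  out <- lab
  out[lab > 0L] <- newid[merged]
  out
}

#' Reference flood-fill labeling (validation oracle)
#'
#' An independent 8-connected labeling implemented as breadth-first flood
#' fill from scratch, sharing no code with [label_components()]. Used to
#' validate the main path; not intended for large production images.
#'
#' @param px logical matrix.
#' @return integer matrix of labels (0 = background), numbered in raster
#'   order of each component's first pixel.
#' @export
label_components_bruteforce <- function(px) {
  stopifnot(is.matrix(px))
  nr <- nrow(px); nc <- ncol(px)
  lab <- matrix(0L, nr, nc)
  fg <- which(px != 0)
  nextlab <- 0L
  for (start in fg) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    lab[start] <- nextlab
    frontier <- start
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      nbr <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- c + dc
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (any(ok)) nbr <- c(nbr, (cc[ok] - 1L) * nr + rr[ok])
      }
      nbr <- unique(nbr)
      nbr <- nbr[px[nbr] != 0 & lab[nbr] == 0L]
      lab[nbr] <- nextlab
      frontier <- nbr
    }
  }
  lab
}

component_areas <- function(px) {
  lab <- label_components(px)
  if (max(lab) == 0L) return(numeric(0))
  as.numeric(tabulate(lab[lab > 0L]))
}

#' Particle analysis: detect tumor-cell clusters in a binary mask
#'
#' Connected components under 8-connectivity whose pixel area is strictly
#' greater than `min_area_px2` become clusters; no shape or circularity
#' exclusion is applied. Clusters are ordered by descending area (ties by
#' first raster appearance) and numbered in that order. The centroid is the
#' unweighted mean of member pixel coordinates (zero-based, x = column);
#' the equivalent diameter assumes a circular cluster,
#' `d = 2 sqrt(area / pi)`.
#'
#' @param mask a [binary_mask()].
#' @param min_area_px2 strict lower area bound in px^2 (default 50).
#' @param pixel_size_mm calibration, millimeters per pixel side.
#' @return data frame with one row per cluster (`cluster_id`, `area_px2`,
#'   `area_mm2`, `centroid_x_px`, `centroid_y_px`, `diameter_mm`), with the
#'   relabeled cluster image in attribute `"label_matrix"` and
#'   `pixel_size_mm` attached as an attribute.
#' @export
detect_clusters <- function(mask, min_area_px2 = 50, pixel_size_mm) {
  stopifnot(inherits(mask, "BinaryMask"))
  stop_if_not_scalar_pos(pixel_size_mm, "pixel_size_mm")
  lab <- label_components(mask$pixels)
  empty <- data.frame(cluster_id = integer(), area_px2 = numeric(),
                      area_mm2 = numeric(), centroid_x_px = numeric(),
                      centroid_y_px = numeric(), diameter_mm = numeric())
  nlab <- max(lab)
  if (nlab == 0L) {
    attr(empty, "label_matrix") <- lab
    attr(empty, "pixel_size_mm") <- pixel_size_mm
    return(empty)
  }
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- which(areas > min_area_px2) # strict "greater than"
  if (!length(keep)) {
    attr(empty, "label_matrix") <- matrix(0L, nrow(lab), ncol(lab))
    attr(empty, "pixel_size_mm") <- pixel_size_mm
    return(empty)
  }
  ord <- keep[order(-areas[keep], keep)]
  idx <- which(lab > 0L)
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  l <- lab[idx]
  cx <- tapply(cc - 1L, l, mean) # zero-based x = column
  cy <- tapply(rr - 1L, l, mean)
  a_px <- areas[ord]
  a_mm <- a_px * pixel_size_mm^2
  df <- data.frame(cluster_id = seq_along(ord),
                   area_px2 = a_px,
                   area_mm2 = a_mm,
                   centroid_x_px = as.numeric(cx[as.character(ord)]),
                   centroid_y_px = as.numeric(cy[as.character(ord)]),
                   diameter_mm = 2 * sqrt(a_mm / pi))
  newlab <- matrix(0L, nrow(lab), ncol(lab))
  remap <- integer(nlab)
  remap[ord] <- seq_along(ord)
  newlab[idx] <- remap[l]
  attr(df, "label_matrix") <- newlab
  attr(df, "pixel_size_mm") <- pixel_size_mm
  df
}
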