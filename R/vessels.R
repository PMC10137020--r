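#' Region of interest for vessel density
#'
#' Rectangle or circle in pixel coordinates (zero-based, continuous). The
#' ROI area in mm^2 is derived from the geometry and the calibration.
#'
#' @param x0,y0 rectangle corner (pixels).
#' @param width,height rectangle extent (pixels).
#' @param pixel_size_mm calibration.
#' @return object of class `ROI`.
#' @export
roi_rect <- function(x0, y0, width, height, pixel_size_mm) {
  stop_if_not_scalar_pos(width, "width"); stop_if_not_scalar_pos(height, "height")
  stop_if_not_scalar_pos(pixel_size_mm, "pixel_size_mm")
  structure(list(shape = "rectangle", x0 = x0, y0 = y0,
                 width = width, height = height,
                 pixel_size_mm = pixel_size_mm,
                 area_mm2 = width * height * pixel_size_mm^2),
            class = "ROI")
}

#' @rdname roi_rect
#' @param cx,cy circle center (pixels).
#' @param radius circle radius (pixels).
#' @export
roi_circle <- function(cx, cy, radius, pixel_size_mm) {
  stop_if_not_scalar_pos(radius, "radius")
  stop_if_not_scalar_pos(pixel_size_mm, "pixel_size_mm")
  structure(list(shape = "circle", cx = cx, cy = cy, radius = radius,
                 pixel_size_mm = pixel_size_mm,
                 area_mm2 = pi * radius^2 * pixel_size_mm^2),
            class = "ROI")
}

#' Default ROI: centered square covering 50% of each image dimension
#'
#' @param dim_px image dimensions `c(nrow, ncol)`.
#' @param pixel_size_mm calibration.
#' @export
default_roi <- function(dim_px, pixel_size_mm) {
  h <- dim_px[1] / 2; w <- dim_px[2] / 2
  roi_rect(x0 = (dim_px[2] - 1) / 2 - w / 2, y0 = (dim_px[1] - 1) / 2 - h / 2,
           width = w, height = h, pixel_size_mm = pixel_size_mm)
}

roi_check_inside <- function(roi, dim_px) {
  ok <- if (roi$shape == "rectangle")
    roi$x0 >= -0.5 && roi$y0 >= -0.5 &&
      roi$x0 + roi$width <= dim_px[2] - 0.5 &&
      roi$y0 + roi$height <= dim_px[1] - 0.5
  else
    roi$cx - roi$radius >= -0.5 && roi$cy - roi$radius >= -0.5 &&
      roi$cx + roi$radius <= dim_px[2] - 0.5 &&
      roi$cy + roi$radius <= dim_px[1] - 0.5
  if (!ok) stop("ROI extends outside the image")
  invisible(TRUE)
}

# Fraction [t0, t1] of the parameterized segment p0 + t (p1 - p0), t in [0,1],
# lying inside the ROI; NULL when disjoint. Liang-Barsky for rectangles,
# quadratic intersection for circles.
clip_segment_t <- function(p0, p1, roi) {
  d <- p1 - p0
  if (roi$shape == "rectangle") {
    t0 <- 0; t1 <- 1
    bounds <- list(c(-d[1], p0[1] - roi$x0),
                   c(d[1], roi$x0 + roi$width - p0[1]),
                   c(-d[2], p0[2] - roi$y0),
                   c(d[2], roi$y0 + roi$height - p0[2]))
    for (b in bounds) {
      p <- b[1]; q <- b[2]
      if (p == 0) { if (q < 0) return(NULL) }
      else {
        t <- q / p
        if (p < 0) { if (t > t1) return(NULL); if (t > t0) t0 <- t }
        else { if (t < t0) return(NULL); if (t < t1) t1 <- t }
      }
    }
    c(t0, t1)
  } else {
    f <- p0 - c(roi$cx, roi$cy)
    a <- sum(d^2); b <- 2 * sum(f * d); cc <- sum(f^2) - roi$radius^2
    if (a == 0) return(if (cc <= 0) c(0, 1) else NULL)
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NULL)
    r <- sqrt(disc)
    t0 <- max(0, (-b - r) / (2 * a)); t1 <- min(1, (-b + r) / (2 * a))
    if (t1 <= t0) NULL else c(t0, t1)
  }
}

#' Linear vessel density from hand-traced centerlines
#'
#' Each polyline is clipped to the ROI; the summed Euclidean length of the
#' clipped segments, converted to millimeters, divided by the ROI area gives
#' the linear vascular density (mm / mm^2 = 1/mm). An empty trace set yields
#' zero density.
#'
#' @param traces list of vessel traces from [read_vessel_traces()].
#' @param roi an [roi_rect()] / [roi_circle()].
#' @param pixel_size_mm calibration.
#' @param channel channel label carried into the result.
#' @return a `VesselDensityResult` list: `channel`, `total_length_mm`,
#'   `roi_area_mm2`, `density_per_mm`, `method = "traced"`.
#' @export
trace_length <- function(traces, roi, pixel_size_mm, channel = "lymphatic") {
  stopifnot(inherits(roi, "ROI"))
  stop_if_not_scalar_pos(pixel_size_mm, "pixel_size_mm")
  total_px <- 0
  for (tr in traces) {
    pts <- tr$points
    for (i in seq_len(nrow(pts) - 1)) {
      t01 <- clip_segment_t(pts[i, ], pts[i + 1, ], roi)
      if (!is.null(t01))
        total_px <- total_px +
          unname((t01[2] - t01[1]) * sqrt(sum((pts[i + 1, ] - pts[i, ])^2)))
    }
  }
  len <- total_px * pixel_size_mm
  list(channel = channel, total_length_mm = len, roi_area_mm2 = roi$area_mm2,
       density_per_mm = len / roi$area_mm2, method = "traced")
}

#' Morphological skeletonization (Zhang-Suen thinning)
#'
#' Iterative two-subcycle thinning to one-pixel-wide 8-connected
#' centerlines.
#'
#' @param px logical matrix.
#' @return logical matrix of the skeleton.
#' @export
skeletonize <- function(px) {
  stopifnot(is.matrix(px))
  m <- (px != 0) * 1L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbors in circular order P2..P9: N, NE, E, SE, S, SW, W, NW
      # (y is the row axis; "north" = row - 1)
      nb <- list(shift_mat(m, -1, 0), shift_mat(m, -1, 1), shift_mat(m, 0, 1),
                 shift_mat(m, 1, 1), shift_mat(m, 1, 0), shift_mat(m, 1, -1),
                 shift_mat(m, 0, -1), shift_mat(m, -1, -1))
      B <- Reduce(`+`, nb)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) {
        j <- if (i == 8) 1 else i + 1
        A <- A + (nb[[i]] == 0L & nb[[j]] == 1L)
      }
      cond <- m == 1L & B >= 2 & B <= 6 & A == 1L
      if (sub == 1) {
        cond <- cond & (nb[[1]] * nb[[3]] * nb[[5]] == 0L) &
          (nb[[3]] * nb[[5]] * nb[[7]] == 0L)
      } else {
        cond <- cond & (nb[[1]] * nb[[3]] * nb[[7]] == 0L) &
          (nb[[1]] * nb[[5]] * nb[[7]] == 0L)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m != 0L
}

# Grow skeleton endpoints along their local direction while still inside the
# original mask, undoing the ~half-stroke-width endpoint erosion of thinning.
extend_endpoints <- function(sk, mask, max_iter = 50L) {
  nr <- nrow(sk); nc <- ncol(sk)
  nbr_count <- function(s) {
    tot <- matrix(0L, nr, nc)
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) tot <- tot + shift_mat(s, dr, dc)
    tot
  }
  for (it in seq_len(max_iter)) {
    s <- sk * 1L
    ends <- which(sk & nbr_count(s) == 1L)
    if (!length(ends)) break
    grew <- FALSE
    for (e in ends) {
      r <- ((e - 1L) %% nr) + 1L; c <- ((e - 1L) %/% nr) + 1L
      nb <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && sk[rr, cc])
          nb <- c(rr, cc)
      }
      if (is.null(nb)) next
      tr <- r + (r - nb[1]); tc <- c + (c - nb[2])
      if (tr >= 1 && tr <= nr && tc >= 1 && tc <= nc &&
          mask[tr, tc] && !sk[tr, tc]) {
        sk[tr, tc] <- TRUE
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  sk
}

# Trace a 1-px skeleton into ordered pixel paths (each 8-adjacency used
# once), preferring the straightest continuation at junctions, then resample
# each path every `stride` pixels into a polyline.
skeleton_to_traces <- function(sk, stride = 5L) {
  nr <- nrow(sk); nc <- ncol(sk)
  idx <- which(sk)
  if (!length(idx)) return(list())
  node <- matrix(0L, nr, nc)
  node[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  adj <- vector("list", length(idx))
  off <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  at <- function(r, c) if (r >= 1 && r <= nr && c >= 1 && c <= nc) node[r, c] else 0L
  for (i in seq_along(idx)) {
    nn <- integer(0)
    for (k in 1:8) {
      r2 <- rr[i] + off[k, 1]; c2 <- cc[i] + off[k, 2]
      j <- at(r2, c2)
      if (j == 0L) next
      # drop a diagonal edge that is shortcut by an orthogonal 2-step path
      if (off[k, 1] != 0 && off[k, 2] != 0 &&
          (at(rr[i], c2) > 0L || at(r2, cc[i]) > 0L)) next
      nn <- c(nn, j)
    }
    adj[[i]] <- nn
  }
  used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  deg_unused <- vapply(adj, length, integer(1))
  traces <- list()
  walk_from <- function(start) {
    path <- start
    prev_dir <- NULL
    cur <- start
    repeat {
      cand <- adj[[cur]]
      cand <- cand[!vapply(cand, function(b)
        exists(ekey(cur, b), envir = used), logical(1))]
      if (!length(cand)) break
      if (length(cand) > 1 && !is.null(prev_dir)) {
        al <- vapply(cand, function(b) {
          d <- c(rr[b] - rr[cur], cc[b] - cc[cur])
          sum(d * prev_dir) / sqrt(sum(d^2))
        }, numeric(1))
        nxt <- cand[which.max(al)]
      } else nxt <- cand[1]
      assign(ekey(cur, nxt), TRUE, envir = used)
      deg_unused[cur] <<- deg_unused[cur] - 1L
      deg_unused[nxt] <<- deg_unused[nxt] - 1L
      prev_dir <- c(rr[nxt] - rr[cur], cc[nxt] - cc[cur])
      prev_dir <- prev_dir / sqrt(sum(prev_dir^2))
      path <- c(path, nxt)
      cur <- nxt
    }
    path
  }
  tid <- 0L
  repeat {
    starts <- which(deg_unused == 1L)
    if (!length(starts)) starts <- which(deg_unused > 0L)
    if (!length(starts)) break
    p <- walk_from(starts[1])
    if (length(p) >= 2) {
      anchors <- unique(c(seq(1L, length(p), by = stride), length(p)))
      tid <- tid + 1L
      traces[[tid]] <- list(trace_id = tid,
                            points = cbind(x = cc[p[anchors]] - 1,
                                           y = rr[p[anchors]] - 1))
    } else if (all(deg_unused[p] == 0L)) next
  }
  traces
}

#' Linear vessel density from a skeletonized mask
#'
#' The binary vessel mask is thinned to one-pixel centerlines
#' ([skeletonize()]), skeleton endpoints are extended along their local
#' direction to the mask boundary (compensating the half-width endpoint
#' erosion of thinning), and the skeleton is traced into ordered polylines
#' resampled every 5 px. Length and density are then measured exactly as
#' for hand-traced centerlines ([trace_length()], including ROI clipping),
#' so the automated and manual paths share one measurement definition.
#' Polyline arc length is unbiased for straight and gently curved vessels
#' at any orientation, unlike pixel-step (chain-code) counting.
#'
#' @param vessel_mask a [binary_mask()] of the vessel channel.
#' @param roi an [roi_rect()] / [roi_circle()].
#' @param pixel_size_mm calibration.
#' @param channel channel label carried into the result.
#' @return a `VesselDensityResult` list with `method = "skeletonized"`.
#' @export
skeleton_length <- function(vessel_mask, roi, pixel_size_mm,
                            channel = "lymphatic") {
  stopifnot(inherits(vessel_mask, "BinaryMask"), inherits(roi, "ROI"))
  stop_if_not_scalar_pos(pixel_size_mm, "pixel_size_mm")
  if (roi$area_mm2 <= 0) stop("empty ROI")
  sk <- skeletonize(vessel_mask$pixels)
  sk <- extend_endpoints(sk, vessel_mask$pixels)
  traces <- skeleton_to_traces(sk)
  res <- trace_length(traces, roi, pixel_size_mm, channel)
  res$method <- "skeletonized"
  res
}

# Logical matrix of pixels whose (zero-based) centers fall inside the ROI.
roi_pixel_mask <- function(roi, dim_px) {
  x <- matrix(rep(0:(dim_px[2] - 1), each = dim_px[1]), dim_px[1], dim_px[2])
  y <- matrix(rep(0:(dim_px[1] - 1), dim_px[2]), dim_px[1], dim_px[2])
  if (roi$shape == "rectangle")
    x >= roi$x0 & x <= roi$x0 + roi$width & y >= roi$y0 & y <= roi$y0 + roi$height
  else
    (x - roi$cx)^2 + (y - roi$cy)^2 <= roi$radius^2
}

#' Two-channel mask overlap (colocalization fractions)
#'
#' Quantifies tumor signal on lymphatic structures and vice versa: the
#' pixelwise AND of the two masks, expressed as a fraction of each mask.
#' A fraction with an empty denominator is reported as `NA`.
#'
#' @param tumor_mask,lymph_mask [binary_mask()] objects of identical shape.
#' @param pixel_size_mm calibration for the overlap area.
#' @return list `tumor_on_lymph_fraction`, `lymph_on_tumor_fraction`,
#'   `overlap_area_mm2`.
#' @export
channel_overlap <- function(tumor_mask, lymph_mask, pixel_size_mm) {
  stopifnot(inherits(tumor_mask, "BinaryMask"), inherits(lymph_mask, "BinaryMask"))
  if (!all(dim(tumor_mask$pixels) == dim(lymph_mask$pixels)))
    stop("mask shapes differ")
  stop_if_not_scalar_pos(pixel_size_mm, "pixel_size_mm")
  a <- sum(tumor_mask$pixels); b <- sum(lymph_mask$pixels)
  o <- sum(tumor_mask$pixels & lymph_mask$pixels)
  list(tumor_on_lymph_fraction = if (a > 0) o / a else NA_real_,
       lymph_on_tumor_fraction = if (b > 0) o / b else NA_real_,
       overlap_area_mm2 = o * pixel_size_mm^2)
}
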