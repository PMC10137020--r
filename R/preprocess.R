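#' Normalize an acquisition to a reference exposure time
#'
#' Pixel values are scaled by `reference_exposure_ms / exposure_ms`, undoing
#' exposure-time differences between acquisitions so that intensities are
#' comparable across tiles, timepoints, and animals. The output is
#' real-valued with its exposure metadata set to the reference.
#' Normalization precedes focus fusion and 8-bit conversion in the pipeline.
#'
#' @param stack an [image_stack()] with exposure metadata.
#' @param reference_exposure_ms target exposure in milliseconds.
#' @return a real-valued [image_stack()].
#' @export
normalize_exposure <- function(stack, reference_exposure_ms) {
  stopifnot(inherits(stack, "ImageStack"))
  stop_if_not_scalar_pos(reference_exposure_ms, "reference_exposure_ms")
  stop_if_not_scalar_pos(stack$exposure_ms, "exposure_ms")
  out <- stack
  out$pixels <- stack$pixels * (reference_exposure_ms / stack$exposure_ms)
  out$exposure_ms <- reference_exposure_ms
  out$bit_depth <- "real"
  out
}

#' Linear 8-bit conversion
#'
#' Maps `[lo, hi]` linearly onto `[0, 255]` with clipping outside the range
#' and half-up rounding; monotone non-decreasing in the input. By default
#' `lo`/`hi` are the image minimum/maximum, an admissible choice because the
#' downstream threshold is background-relative and therefore invariant under
#' any strictly monotone rescaling of the occupied intensity range.
#'
#' @param image 2-D or 3-D numeric array.
#' @param lo,hi input values mapped to 0 and 255; `hi` must exceed `lo`.
#' @return array of the same shape with integer values in 0..255.
#' @export
convert_to_8bit <- function(image, lo = min(image), hi = max(image)) {
  if (hi <= lo) stop("`hi` must be strictly greater than `lo`")
  v <- (image - lo) / (hi - lo) * 255
  v <- pmin(pmax(v, 0), 255)
  out <- floor(v + 0.5) # round half up
  storage.mode(out) <- "integer"
  out
}

#' Fuse a z-stack into a single all-in-focus image
#'
#' For every plane, a per-pixel sharpness score is computed as the sum of
#' squared first-difference gradient magnitudes over a `kernel_px` x
#' `kernel_px` window centered at the pixel (reflect-padded at borders).
#' The per-pixel decision map is the argmax over planes (ties broken toward
#' the lowest plane index), then median-filtered with the same kernel, and
#' the output pixel is copied from its decided plane. Every fused value
#' therefore occurs in the input stack at that pixel position.
#'
#' @param stack an [image_stack()].
#' @param kernel_px odd window size, at least 3.
#' @return a `FocusedImage`: list with `pixels` (2-D), `decision_map`
#'   (2-D, zero-based plane indices), and `source` metadata.
#' @export
focus_stack <- function(stack, kernel_px = 7L) {
  stopifnot(inherits(stack, "ImageStack"))
  if (kernel_px %% 2 == 0 || kernel_px < 3)
    stop("`kernel_px` must be odd and >= 3")
  np <- n_planes(stack)
  src <- list(channel = stack$channel, timepoint_hours = stack$timepoint_hours,
              exposure_ms = stack$exposure_ms,
              pixel_size_mm = stack$pixel_size_mm, kernel_px = kernel_px)
  if (np == 1L) {
    return(structure(list(pixels = stack$pixels[, , 1],
                          decision_map = matrix(0L, dim(stack$pixels)[1],
                                                dim(stack$pixels)[2]),
                          source = src),
                     class = "FocusedImage"))
  }
  nr <- dim(stack$pixels)[1]; nc <- dim(stack$pixels)[2]
  best <- matrix(1L, nr, nc)
  best_score <- matrix(-Inf, nr, nc)
  for (p in seq_len(np)) {
    pl <- stack$pixels[, , p]
    gx <- pl[, c(2:nc, nc), drop = FALSE] - pl
    gy <- pl[c(2:nr, nr), , drop = FALSE] - pl
    score <- box_sum(gx^2 + gy^2, kernel_px)
    upd <- score > best_score # strict: ties keep the lower plane index
    best[upd] <- p
    best_score[upd] <- score[upd]
  }
  dm <- median_filter_int(best - 1L, kernel_px, np)
  out <- matrix(0, nr, nc)
  for (p in seq_len(np)) {
    sel <- dm == (p - 1L)
    if (any(sel)) out[sel] <- stack$pixels[, , p][sel]
  }
  structure(list(pixels = out, decision_map = dm, source = src),
            class = "FocusedImage")
}

# Exact median filter for small-integer matrices (values 0..nv-1), via
# per-value box-sums of indicators: the median over a k x k window is the
# smallest value whose cumulative window count reaches ceil(k^2 / 2).
median_filter_int <- function(m, k, nv) {
  need <- ceiling(k^2 / 2)
  med <- matrix(NA_integer_, nrow(m), ncol(m))
  cum <- matrix(0, nrow(m), ncol(m))
  for (v in 0:(nv - 1L)) {
    cum <- cum + box_sum((m == v) * 1, k)
    hit <- is.na(med) & cum >= need
    med[hit] <- v
  }
  med
}
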