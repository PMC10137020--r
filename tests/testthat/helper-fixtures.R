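# Shared fixtures built in code.

# Small, fast scene for unit tests.
tiny_scene_config <- function(...) {
  args <- utils::modifyList(
    list(field_size_px = c(128L, 128L), n_clusters_initial = 5L,
         n_timepoints = 3L, vessel_count = 2L, seed = 11L),
    list(...))
  do.call(scene_config, args)
}

# A 10-plane stack whose left half is sharp at plane `p_left` and right half
# at `p_right` (zero-based), built from a textured base image blurred per
# plane by |plane - focus| * sigma_step. Returns the stack and the truth map.
two_zone_stack <- function(n = 128L, p_left = 0L, p_right = 9L,
                           n_planes = 10L, sigma_step = 1.5, seed = 42L) {
  set.seed(seed)
  base <- windowquant:::gblur_safe(matrix(stats::runif(n * n, 0, 1000), n, n), 1)
  pmap <- matrix(p_left, n, n)
  pmap[, (n %/% 2 + 1):n] <- p_right
  blur_of <- list()
  stk <- array(0, dim = c(n, n, n_planes))
  for (p in 0:(n_planes - 1)) {
    pl <- matrix(0, n, n)
    for (m in c(p_left, p_right)) {
      s <- abs(p - m) * sigma_step
      key <- as.character(s)
      if (is.null(blur_of[[key]]))
        blur_of[[key]] <- windowquant:::gblur_safe(base, s)
      sel <- pmap == m
      pl[sel] <- blur_of[[key]][sel]
    }
    stk[, , p + 1] <- pl
  }
  list(stack = image_stack(stk, bit_depth = "real"), truth_map = pmap)
}

# Independent brute-force binary opening (3x3 cross), double-loop reference.
brute_open <- function(px, n_iter = 1L) {
  cross <- rbind(c(0, 1, 0), c(1, 1, 1), c(0, 1, 0))
  erode1 <- function(m) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
      keep <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        if (cross[dr + 2, dc + 2] == 0) next
        rr <- r + dr; cc <- c + dc
        v <- if (rr < 1 || rr > nrow(m) || cc < 1 || cc > ncol(m)) FALSE else m[rr, cc]
        if (!v) keep <- FALSE
      }
      out[r, c] <- keep
    }
    out
  }
  dilate1 <- function(m) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
      hit <- FALSE
      for (dr in -1:1) for (dc in -1:1) {
        if (cross[dr + 2, dc + 2] == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) && m[rr, cc])
          hit <- TRUE
      }
      out[r, c] <- hit
    }
    out
  }
  m <- px
  for (i in seq_len(n_iter)) m <- dilate1(erode1(m))
  m
}

# Sorted component areas from a label matrix.
label_areas <- function(lab) sort(as.numeric(tabulate(lab[lab > 0])))

# Mean truth distance of cluster centroids to the field center, per timepoint.
truth_mean_distance <- function(scene) {
  cfg <- scene$config
  ctr <- c((cfg$field_size_px[1] - 1) / 2, (cfg$field_size_px[2] - 1) / 2)
  tr <- scene$clusters_truth
  tapply(sqrt((tr$x_px - ctr[1])^2 + (tr$y_px - ctr[2])^2),
         tr$timepoint, mean)
}
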