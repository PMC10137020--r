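#' Synthetic scene configuration
#'
#' Parameters of the ground-truth scene generator that stands in for the
#' window-chamber imaging data. Defaults describe the study conditions the
#' pipeline is validated under: a 256 x 256 px field at 0.0051 mm/px (the
#' calibration implied by 50 px^2 ~ 0.0013 mm^2), 10-plane z-stacks, five
#' daily timepoints over 0-96 h, ~12 bright clusters implanted near the
#' field center that drift radially outward at 5 px per step while growing,
#' tortuous vessels spanning the field, one z-plane of defocus blur per
#' plane of depth offset, and detector noise at 20% of the cluster signal.
#'
#' @param field_size_px integer pair `c(width, height)` in pixels.
#' @param pixel_size_mm calibration (mm per pixel side).
#' @param n_planes z-planes per stack (>= 1).
#' @param n_timepoints number of acquisitions.
#' @param timepoint_hours acquisition times; default daily (24 h steps).
#' @param background_mean,background_sd additive Gaussian detector noise
#'   parameters (16-bit counts at the nominal exposure); `background_sd > 0`.
#' @param cluster_intensity cluster signal amplitude above background.
#' @param n_clusters_initial clusters present at t = 0.
#' @param mean_cluster_area_px2 lognormal mean of initial truth areas.
#' @param cluster_spread_px s.d. of initial placement around the field
#'   center (the implantation site).
#' @param migration_rate_px_per_step radial outward drift per step; 0 gives
#'   the stationary (non-migratory control) phenotype.
#' @param growth_rate_per_step log-area growth per step.
#' @param fragmentation_prob per-step probability that a cluster splits.
#' @param vessel_count,vessel_tortuosity,vessel_width_px vessel polylines
#'   spanning the field; tortuosity scales the lateral excursion.
#' @param defocus_sigma_per_plane Gaussian blur sigma (px) per plane of
#'   offset from the locally in-focus plane.
#' @param exposure_times_ms per-timepoint exposure; recycled if scalar.
#' @param nominal_exposure_ms exposure at which the intensity parameters are
#'   defined; rendered values scale linearly with
#'   `exposure_times_ms / nominal_exposure_ms`.
#' @param n_artifacts number of thin, bright coverslip-scratch line
#'   artifacts rendered per timepoint into the tumor channel (not part of
#'   the truth); exercises the morphological cleanup.
#' @param artifact_intensity scratch amplitude.
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return a validated list of class `SceneConfig`.
#' @export
scene_config <- function(field_size_px = c(256L, 256L),
                         pixel_size_mm = 0.0051,
                         n_planes = 10L,
                         n_timepoints = 5L,
                         timepoint_hours = 24 * (seq_len(n_timepoints) - 1),
                         background_mean = 2000,
                         background_sd = 600,
                         cluster_intensity = 3000,
                         n_clusters_initial = 12L,
                         mean_cluster_area_px2 = 200,
                         cluster_spread_px = 18,
                         migration_rate_px_per_step = 5,
                         growth_rate_per_step = 0.15,
                         fragmentation_prob = 0.1,
                         vessel_count = 4L,
                         vessel_tortuosity = 0.15,
                         vessel_width_px = 5L,
                         defocus_sigma_per_plane = 1,
                         exposure_times_ms = 20,
                         nominal_exposure_ms = 20,
                         n_artifacts = 0L,
                         artifact_intensity = 20000,
                         seed = 1L) {
  if (length(field_size_px) != 2 || any(field_size_px < 8))
    stop("`field_size_px` must be a pair of positive sizes (>= 8 px)")
  if (n_planes < 1) stop("`n_planes` must be >= 1")
  if (n_timepoints < 1) stop("`n_timepoints` must be >= 1")
  if (length(timepoint_hours) != n_timepoints)
    stop("`timepoint_hours` must have length `n_timepoints`")
  stop_if_not_scalar_pos(pixel_size_mm, "pixel_size_mm")
  stop_if_not_scalar_pos(background_sd, "background_sd")
  if (fragmentation_prob < 0 || fragmentation_prob > 1)
    stop("`fragmentation_prob` must be in [0, 1]")
  if (migration_rate_px_per_step < 0)
    stop("`migration_rate_px_per_step` must be nonnegative")
  if (length(exposure_times_ms) == 1)
    exposure_times_ms <- rep(exposure_times_ms, n_timepoints)
  if (length(exposure_times_ms) != n_timepoints || any(exposure_times_ms <= 0))
    stop("`exposure_times_ms` must be positive, one per timepoint")
  stop_if_not_scalar_pos(nominal_exposure_ms, "nominal_exposure_ms")
  structure(as.list(environment()), class = "SceneConfig")
}

ellipse_pixels <- function(cx, cy, a, b, theta, nx, ny) {
  # zero-based pixel centers strictly inside the ellipse quadratic form
  xr <- max(0L, floor(cx - a - 1)):min(nx - 1L, ceiling(cx + a + 1))
  yr <- max(0L, floor(cy - a - 1)):min(ny - 1L, ceiling(cy + a + 1))
  if (!length(xr) || !length(yr)) return(integer(0))
  dx <- outer(rep(1, length(yr)), xr) - cx
  dy <- outer(yr, rep(1, length(xr))) - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  q <- (u / a)^2 + (v / b)^2
  sel <- which(q <= 1)
  if (!length(sel)) return(integer(0))
  rows <- yr[((sel - 1L) %% length(yr)) + 1L] + 1L
  cols <- xr[((sel - 1L) %/% length(yr)) + 1L] + 1L
  (cols - 1L) * ny + rows # linear indices into an ny x nx matrix
}

#' Generate a ground-truth synthetic scene
#'
#' Clusters are hard-edged anisotropic ellipses placed near the field
#' center; their truth area is the exact rasterized pixel count, so a
#' perfect segmentation recovers it exactly. Per step, each cluster drifts
#' radially away from the implantation site by a strictly positive multiple
#' of `migration_rate_px_per_step` plus tangential jitter (tangential moves
#' can only increase the distance to the center), grows in log-area, and may
#' fragment into two tangentially separated children. With migration, growth
#' and fragmentation all zero the truth is identical at every timepoint.
#' Clusters are kept pairwise disjoint (outward nudges on contact) so truth
#' counts are well defined. Vessels are smooth non-self-crossing polylines
#' spanning the field (lateral excursion is a low-order sinusoid in the
#' spanning coordinate, hence a function graph). A smooth in-focus plane map
#' assigns each pixel the z-plane at which it is sharp.
#'
#' @param config a [scene_config()].
#' @return a `SyntheticScene`: `config`, `clusters_truth` (data frame over
#'   all timepoints: `timepoint` in hours, `cluster_id`, `x_px`, `y_px`,
#'   `area_px2`, plus ellipse shape columns), `vessels_truth` (list with
#'   `traces` and per-trace `length_mm`), `in_focus_plane_map` (matrix of
#'   zero-based plane indices), `artifacts` (per-timepoint scratch segments).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "SceneConfig"))
  nx <- config$field_size_px[1]; ny <- config$field_size_px[2]
  cx0 <- (nx - 1) / 2; cy0 <- (ny - 1) / 2
  with_seed(config$seed, {
    ## ---- initial cluster placement ----
    n0 <- config$n_clusters_initial
    cl <- data.frame(cluster_id = seq_len(n0),
                     x = rep(NA_real_, n0), y = rep(NA_real_, n0),
                     area = rep(NA_real_, n0), rho = rep(NA_real_, n0),
                     theta = rep(NA_real_, n0))
    margin <- 4
    for (i in seq_len(n0)) {
      area <- min(max(stats::rlnorm(1, log(config$mean_cluster_area_px2), 0.3),
                      100), 4 * config$mean_cluster_area_px2)
      rho <- stats::runif(1, 0.65, 1)
      th <- stats::runif(1, 0, pi)
      a <- sqrt(area / (pi * rho))
      ok <- FALSE
      for (try in 1:2000) {
        # widen the placement spread gradually if the center is crowded
        sp <- config$cluster_spread_px * (1 + (try %/% 400) * 0.3)
        p <- c(cx0, cy0) + stats::rnorm(2, 0, sp)
        if (p[1] < a + margin || p[1] > nx - 1 - a - margin ||
            p[2] < a + margin || p[2] > ny - 1 - a - margin) next
        if (i > 1) {
          prev <- cl[seq_len(i - 1), ]
          amax <- sqrt(prev$area / (pi * prev$rho))
          if (any(sqrt((prev$x - p[1])^2 + (prev$y - p[2])^2) < amax + a + margin))
            next
        }
        ok <- TRUE; break
      }
      if (!ok) stop("could not place ", n0, " disjoint clusters; ",
                    "reduce n_clusters_initial or enlarge the field")
      cl$x[i] <- p[1]; cl$y[i] <- p[2]
      cl$area[i] <- area; cl$rho[i] <- rho; cl$theta[i] <- th
    }
    next_id <- n0 + 1L

    ## ---- temporal evolution ----
    states <- vector("list", config$n_timepoints)
    states[[1]] <- cl
    rate <- config$migration_rate_px_per_step
    for (t in seq_len(config$n_timepoints - 1)) {
      s <- states[[t]]
      if (rate > 0) {
        for (i in seq_len(nrow(s))) {
          dx <- s$x[i] - cx0; dy <- s$y[i] - cy0
          r <- sqrt(dx^2 + dy^2)
          u <- if (r < 1e-9) { ang <- stats::runif(1, 0, 2 * pi); c(cos(ang), sin(ang)) } else c(dx, dy) / r
          tp <- c(-u[2], u[1])
          step <- rate * stats::runif(1, 0.85, 1.15)
          jit <- stats::rnorm(1, 0, 0.3 * rate)
          s$x[i] <- s$x[i] + step * u[1] + jit * tp[1]
          s$y[i] <- s$y[i] + step * u[2] + jit * tp[2]
        }
      }
      if (config$growth_rate_per_step != 0)
        s$area <- s$area * exp(config$growth_rate_per_step * stats::runif(nrow(s), 0.85, 1.15))
      if (config$fragmentation_prob > 0) {
        out <- s[0, ]
        for (i in seq_len(nrow(s))) {
          if (stats::runif(1) < config$fragmentation_prob && s$area[i] >= 240) {
            f <- stats::runif(1, 0.4, 0.6)
            kids <- s[c(i, i), ]
            kids$area <- s$area[i] * c(f, 1 - f)
            kids$cluster_id[2] <- next_id; next_id <- next_id + 1L
            ak <- sqrt(kids$area / (pi * kids$rho))
            dx <- s$x[i] - cx0; dy <- s$y[i] - cy0
            r <- sqrt(dx^2 + dy^2)
            u <- if (r < 1e-9) c(1, 0) else c(dx, dy) / r
            tp <- c(-u[2], u[1])
            kids$x <- s$x[i] + c(ak[2] + 3, -(ak[1] + 3)) * tp[1]
            kids$y <- s$y[i] + c(ak[2] + 3, -(ak[1] + 3)) * tp[2]
            out <- rbind(out, kids)
          } else out <- rbind(out, s[i, ])
        }
        s <- out
      }
      # Keep clusters pairwise disjoint: move the pair member farther from
      # the implantation center away from the other along their connecting
      # line. That strictly grows the gap, and the mover's distance to the
      # center cannot decrease (r_outer >= r_inner implies a nonnegative
      # radial component), so dispersal monotonicity survives the nudges.
      for (pass in 1:100) {
        amax <- sqrt(s$area / (pi * s$rho))
        moved <- FALSE
        if (nrow(s) > 1) for (i in 1:(nrow(s) - 1)) for (j in (i + 1):nrow(s)) {
          d <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2)
          need <- amax[i] + amax[j] + 3
          if (d < need) {
            ri <- sqrt((s$x[i] - cx0)^2 + (s$y[i] - cy0)^2)
            rj <- sqrt((s$x[j] - cx0)^2 + (s$y[j] - cy0)^2)
            outer_k <- if (ri >= rj) i else j
            inner_k <- if (ri >= rj) j else i
            u <- c(s$x[outer_k] - s$x[inner_k], s$y[outer_k] - s$y[inner_k])
            if (d < 1e-9) {
              dx <- s$x[outer_k] - cx0; dy <- s$y[outer_k] - cy0
              r <- sqrt(dx^2 + dy^2)
              u <- if (r < 1e-9) c(1, 0) else c(dx, dy) / r
            } else u <- u / d
            s$x[outer_k] <- s$x[outer_k] + u[1] * (need - d + 0.5)
            s$y[outer_k] <- s$y[outer_k] + u[2] * (need - d + 0.5)
            moved <- TRUE
          }
        }
        if (!moved) break
      }
      amax <- sqrt(s$area / (pi * s$rho))
      s$x <- pmin(pmax(s$x, amax + margin), nx - 1 - amax - margin)
      s$y <- pmin(pmax(s$y, amax + margin), ny - 1 - amax - margin)
      states[[t + 1]] <- s
    }

    ## ---- rasterized truth areas ----
    truth <- do.call(rbind, lapply(seq_len(config$n_timepoints), function(t) {
      s <- states[[t]]
      if (nrow(s) == 0)
        return(data.frame(timepoint = numeric(0), cluster_id = integer(0),
                          x_px = numeric(0), y_px = numeric(0),
                          area_px2 = numeric(0), a_px = numeric(0),
                          b_px = numeric(0), theta = numeric(0)))
      a <- sqrt(s$area / (pi * s$rho)); b <- s$rho * a
      area_px <- vapply(seq_len(nrow(s)), function(i)
        length(ellipse_pixels(s$x[i], s$y[i], a[i], b[i], s$theta[i], nx, ny)),
        numeric(1))
      data.frame(timepoint = config$timepoint_hours[t],
                 cluster_id = s$cluster_id, x_px = s$x, y_px = s$y,
                 area_px2 = area_px, a_px = a, b_px = b, theta = s$theta)
    }))

    ## ---- vessels ----
    vt <- vector("list", config$vessel_count)
    for (k in seq_len(config$vessel_count)) {
      horiz <- stats::runif(1) < 0.5
      L <- if (horiz) nx else ny
      Lp <- if (horiz) ny else nx
      tt <- seq(0, 1, length.out = 101)
      base <- stats::runif(1, 0.2, 0.8) * (Lp - 1)
      lat <- base
      for (h in 1:3)
        lat <- lat + config$vessel_tortuosity * Lp * stats::runif(1, 0.3, 1) / h *
          sin(h * pi * tt + stats::runif(1, 0, 2 * pi))
      lat <- pmin(pmax(lat, 3), Lp - 4)
      main <- tt * (L - 1)
      pts <- if (horiz) cbind(x = main, y = lat) else cbind(x = lat, y = main)
      vt[[k]] <- list(trace_id = k, points = pts,
                      length_mm = polyline_length_px(pts) * config$pixel_size_mm)
    }

    ## ---- in-focus plane map: smooth seeded surface ----
    if (config$n_planes > 1) {
      X <- matrix(rep(seq(0, 1, length.out = nx), each = ny), ny, nx)
      Y <- matrix(rep(seq(0, 1, length.out = ny), nx), ny, nx)
      g <- matrix(0, ny, nx)
      for (h in 1:2) {
        f <- stats::runif(2, 0.3, 0.8)
        ph <- stats::runif(1, 0, 2 * pi)
        g <- g + (1 / h) * sin(2 * pi * (f[1] * X + f[2] * Y) + ph)
      }
      g <- (g - min(g)) / (max(g) - min(g) + 1e-12)
      pmap <- matrix(as.integer(round(g * (config$n_planes - 1))), ny, nx)
    } else pmap <- matrix(0L, ny, nx)

    ## ---- scratch artifacts (per timepoint, not part of truth) ----
    arts <- do.call(rbind, lapply(seq_len(config$n_timepoints), function(t) {
      if (config$n_artifacts < 1) return(NULL)
      data.frame(timepoint_index = t,
                 x0 = stats::runif(config$n_artifacts, 0, nx - 1),
                 y0 = stats::runif(config$n_artifacts, 0, ny - 1),
                 ang = stats::runif(config$n_artifacts, 0, pi),
                 len = stats::runif(config$n_artifacts, 0.2, 0.5) * min(nx, ny))
    }))

    structure(list(config = config, clusters_truth = truth,
                   vessels_truth = vt, in_focus_plane_map = pmap,
                   artifacts = arts),
              class = "SyntheticScene")
  })
}

channel_code <- function(channel) {
  match(channel, c("tumor", "lymphatic", "brightfield"))
}

# Sharp (all-in-focus) signal canvas for one channel/timepoint, in counts at
# the nominal exposure, before background noise.
sharp_canvas <- function(scene, t_idx, channel) {
  cfg <- scene$config
  nx <- cfg$field_size_px[1]; ny <- cfg$field_size_px[2]
  canvas <- matrix(0, ny, nx)
  if (channel == "tumor") {
    tr <- scene$clusters_truth[scene$clusters_truth$timepoint ==
                                 cfg$timepoint_hours[t_idx], ]
    for (i in seq_len(nrow(tr)))
      canvas[ellipse_pixels(tr$x_px[i], tr$y_px[i], tr$a_px[i], tr$b_px[i],
                            tr$theta[i], nx, ny)] <- cfg$cluster_intensity
    if (!is.null(scene$artifacts)) {
      ar <- scene$artifacts[scene$artifacts$timepoint_index == t_idx, ]
      for (i in seq_len(nrow(ar))) {
        s <- seq(0, ar$len[i], by = 0.3)
        xs <- round(ar$x0[i] + s * cos(ar$ang[i]))
        ys <- round(ar$y0[i] + s * sin(ar$ang[i]))
        keep <- xs >= 0 & xs < nx & ys >= 0 & ys < ny
        canvas[cbind(ys[keep] + 1, xs[keep] + 1)] <- cfg$artifact_intensity
      }
    }
  } else if (channel == "lymphatic") {
    hit <- matrix(0L, ny, nx)
    for (v in scene$vessels_truth) {
      pts <- v$points
      for (i in seq_len(nrow(pts) - 1)) {
        seg <- pts[i + 1, ] - pts[i, ]
        len <- sqrt(sum(seg^2))
        s <- seq(0, len, by = 0.3)
        xs <- round(pts[i, 1] + s / max(len, 1e-9) * seg[1])
        ys <- round(pts[i, 2] + s / max(len, 1e-9) * seg[2])
        keep <- xs >= 0 & xs < nx & ys >= 0 & ys < ny
        hit[cbind(ys[keep] + 1, xs[keep] + 1)] <- 1L
      }
    }
    w <- max(1L, as.integer(cfg$vessel_width_px))
    if (w %% 2 == 0) w <- w + 1L
    if (w > 1) hit <- EBImage::dilate(hit, EBImage::makeBrush(w, shape = "disc"))
    canvas <- (hit != 0) * cfg$cluster_intensity
  } else if (channel == "brightfield") {
    xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
    ysm <- matrix(rep(0:(ny - 1), nx), ny, nx)
    rad <- sqrt(((xs - (nx - 1) / 2) / nx)^2 + ((ysm - (ny - 1) / 2) / ny)^2)
    # speckle-rich reflectance texture: sharp enough that the in-focus plane
    # carries far more gradient energy than the per-plane detector noise
    tex <- with_seed(derive_seed(cfg$seed, 777), {
      gblur_safe(matrix(stats::rnorm(ny * nx), ny, nx), 0.8)
    })
    tex <- tex / max(abs(tex))
    canvas <- 25000 * (1 - 0.3 * rad) * (1 + 0.35 * tex)
    tr <- scene$clusters_truth[scene$clusters_truth$timepoint ==
                                 cfg$timepoint_hours[t_idx], ]
    absorb <- matrix(0, ny, nx)
    for (i in seq_len(nrow(tr)))
      absorb[ellipse_pixels(tr$x_px[i], tr$y_px[i], tr$a_px[i], tr$b_px[i],
                            tr$theta[i], nx, ny)] <- 0.2
    canvas <- canvas * (1 - absorb)
  } else stop("unknown channel: ", channel)
  canvas
}

#' Render a multichannel z-stack from a synthetic scene
#'
#' Plane `p` of each pixel is the sharp signal blurred with a Gaussian of
#' sigma `|p - in_focus_plane| * defocus_sigma_per_plane`, plus per-plane
#' additive Gaussian background noise `N(background_mean, background_sd^2)`;
#' the whole frame scales linearly with the timepoint's exposure relative to
#' the nominal exposure, and is clipped to 16 bits (a saturation warning is
#' emitted when clipping occurs). The tumor channel renders clusters (and
#' any scratch artifacts), the lymphatic channel renders vessels only, the
#' brightfield channel a textured illumination field. Noise streams are
#' derived deterministically from the scene seed, timepoint, and channel.
#'
#' @param scene a [generate_scene()] result.
#' @param timepoint timepoint index (1-based).
#' @param channel `"tumor"`, `"lymphatic"`, or `"brightfield"`.
#' @return a 16-bit [image_stack()] with `n_planes` planes.
#' @export
render_zstack <- function(scene, timepoint, channel) {
  stopifnot(inherits(scene, "SyntheticScene"))
  cfg <- scene$config
  if (is.na(channel_code(channel))) stop("unknown channel: ", channel)
  if (timepoint < 1 || timepoint > cfg$n_timepoints)
    stop("timepoint out of range 1..", cfg$n_timepoints)
  nx <- cfg$field_size_px[1]; ny <- cfg$field_size_px[2]
  np <- cfg$n_planes
  sharp <- sharp_canvas(scene, timepoint, channel)
  dmax <- max(abs(outer(0:(np - 1), as.vector(scene$in_focus_plane_map), "-")))
  blurred <- vector("list", dmax + 1)
  blurred[[1]] <- sharp
  for (d in seq_len(dmax))
    blurred[[d + 1]] <- gblur_safe(sharp, d * cfg$defocus_sigma_per_plane)
  pmap <- scene$in_focus_plane_map
  stack <- array(0, dim = c(ny, nx, np))
  for (p in 0:(np - 1)) {
    pl <- matrix(0, ny, nx)
    for (m in unique(as.vector(pmap))) {
      sel <- pmap == m
      pl[sel] <- blurred[[abs(p - m) + 1]][sel]
    }
    stack[, , p + 1] <- pl
  }
  noise <- with_seed(derive_seed(cfg$seed, timepoint, channel_code(channel)), {
    array(stats::rnorm(ny * nx * np, cfg$background_mean, cfg$background_sd),
          dim = c(ny, nx, np))
  })
  e <- cfg$exposure_times_ms[timepoint]
  vals <- (stack + noise) * (e / cfg$nominal_exposure_ms)
  nsat <- sum(vals > 65535)
  if (nsat > 0)
    warning(sprintf("%d pixel(s) saturated at 65535 (%.3f%%)", nsat,
                    100 * nsat / length(vals)), call. = FALSE)
  vals <- round(pmin(pmax(vals, 0), 65535))
  image_stack(vals, channel = channel,
              timepoint_hours = cfg$timepoint_hours[timepoint],
              exposure_ms = e, pixel_size_mm = cfg$pixel_size_mm,
              bit_depth = 16)
}

#' Render the reference all-in-focus acquisition
#'
#' A single-plane 16-bit acquisition of the sharp scene (no defocus), with
#' the same noise model and exposure scaling as [render_zstack()] but an
#' independent noise stream. Serves as the ground-truth in-focus image for
#' validating segmentation and metrics independently of focus fusion.
#'
#' @inheritParams render_zstack
#' @return a 1-plane [image_stack()].
#' @export
render_infocus <- function(scene, timepoint, channel) {
  stopifnot(inherits(scene, "SyntheticScene"))
  cfg <- scene$config
  if (is.na(channel_code(channel))) stop("unknown channel: ", channel)
  if (timepoint < 1 || timepoint > cfg$n_timepoints)
    stop("timepoint out of range 1..", cfg$n_timepoints)
  nx <- cfg$field_size_px[1]; ny <- cfg$field_size_px[2]
  sharp <- sharp_canvas(scene, timepoint, channel)
  noise <- with_seed(derive_seed(cfg$seed, timepoint, channel_code(channel), 7), {
    matrix(stats::rnorm(ny * nx, cfg$background_mean, cfg$background_sd), ny, nx)
  })
  e <- cfg$exposure_times_ms[timepoint]
  vals <- round(pmin(pmax((sharp + noise) * (e / cfg$nominal_exposure_ms), 0), 65535))
  image_stack(vals, channel = channel,
              timepoint_hours = cfg$timepoint_hours[timepoint],
              exposure_ms = e, pixel_size_mm = cfg$pixel_size_mm,
              bit_depth = 16)
}

#' Write ground-truth tables for a scene
#'
#' Emits `clusters.csv` (`timepoint,cluster_id,x_px,y_px,area_px2` plus
#' ellipse shape columns) and `vessels.csv`
#' (`trace_id,point_index,x_px,y_px`, the dialect [read_vessel_traces()]
#' imports). Values round-trip at full double precision.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory, created if needed.
#' @return paths written, invisibly.
#' @export
write_truth_tables <- function(scene, dir) {
  stopifnot(inherits(scene, "SyntheticScene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cpath <- file.path(dir, "clusters.csv")
  utils::write.csv(format(scene$clusters_truth, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   cpath, row.names = FALSE, quote = FALSE)
  vdf <- do.call(rbind, lapply(scene$vessels_truth, function(v)
    data.frame(trace_id = v$trace_id,
               point_index = seq_len(nrow(v$points)) - 1L,
               x_px = v$points[, 1], y_px = v$points[, 2])))
  if (is.null(vdf))
    vdf <- data.frame(trace_id = integer(), point_index = integer(),
                      x_px = numeric(), y_px = numeric())
  vpath <- file.path(dir, "vessels.csv")
  utils::write.csv(format(vdf, digits = 17, trim = TRUE, scientific = FALSE),
                   vpath, row.names = FALSE, quote = FALSE)
  invisible(c(cpath, vpath))
}
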