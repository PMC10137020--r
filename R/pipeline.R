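#' Process one timepoint: stacks to cluster and vessel statistics
#'
#' Composes the full per-timepoint chain: exposure normalization, focus
#' fusion, background estimation, thresholding, morphological cleanup,
#' particle analysis, and dispersal metrics on the tumor channel; threshold,
#' cleanup, and skeleton-based linear density on each vessel channel; and
#' tumor/lymphatic overlap fractions. Deterministic given inputs and
#' configuration; every auto-chosen parameter (background stats, numeric
#' threshold, morphology iterations) is recorded in the returned provenance.
#'
#' @param stacks named list of [image_stack()] objects; a channel whose
#'   configured role is `tumor` is required, vessel channels are optional
#'   (skipped with a warning when absent).
#' @param config a [run_config()].
#' @param origin_mm optional implantation-site reference `c(x_mm, y_mm)`;
#'   when given, per-cluster distances to it are emitted alongside the
#'   center-of-mass distances.
#' @return list with `clusters` (annotated data frame), `summary` (one-row
#'   data frame), `vessels` (data frame of vessel density rows), `overlap`,
#'   `tumor_mask`, `fused`, and `provenance`.
#' @export
process_timepoint <- function(stacks, config = run_config(), origin_mm = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  roles <- config$channel_roles
  role_of <- function(ch) if (ch %in% names(roles)) roles[[ch]] else ch
  tumor_ch <- names(stacks)[vapply(names(stacks), function(ch)
    identical(role_of(ch), "tumor"), logical(1))]
  if (length(tumor_ch) != 1)
    stop("exactly one tumor-role channel is required; got ",
         length(tumor_ch))
  ps <- config$pixel_size_mm
  fuse <- function(stack) {
    norm <- normalize_exposure(stack, config$reference_exposure_ms)
    focus_stack(norm, config$focus_kernel_px)
  }
  segment <- function(fused) {
    bg <- estimate_background(fused$pixels)
    m <- threshold_mask(fused$pixels, bg, config$threshold_k)
    morphological_clean(m, config$morphology_iterations,
                        config$min_cluster_area_px2)
  }

  tum <- stacks[[tumor_ch]]
  fused <- fuse(tum)
  tumor_mask <- segment(fused)
  clusters <- detect_clusters(tumor_mask, config$min_cluster_area_px2, ps)
  if (nrow(clusters) > 0) {
    com <- center_of_mass(clusters, config$com_mode)
    clusters <- annotate_distances_and_moments(clusters, com, origin_mm)
  } else com <- c(NA_real_, NA_real_)
  attr(clusters, "timepoint_hours") <- tum$timepoint_hours
  summary <- summarize_timepoint(clusters, tum$timepoint_hours)

  roi <- if (is.null(config$roi))
    default_roi(dim(fused$pixels), ps) else config$roi
  roi_check_inside(roi, dim(fused$pixels))
  vrows <- list()
  lymph_mask <- NULL
  vessel_channels <- names(stacks)[vapply(names(stacks), function(ch)
    role_of(ch) %in% c("lymphatic", "blood"), logical(1))]
  for (ch in vessel_channels) {
    vf <- fuse(stacks[[ch]])
    vm <- segment(vf)
    # drop sub-threshold specks before thinning
    lab <- label_components(vm$pixels)
    if (max(lab) > 0) {
      small <- which(tabulate(lab[lab > 0]) <= config$min_cluster_area_px2)
      if (length(small)) vm$pixels[lab %in% small] <- FALSE
    }
    if (role_of(ch) == "lymphatic") lymph_mask <- vm
    vd <- skeleton_length(vm, roi, ps, channel = ch)
    vrows[[ch]] <- data.frame(channel = ch, role = role_of(ch),
                              timepoint_hours = tum$timepoint_hours,
                              method = vd$method,
                              total_length_mm = vd$total_length_mm,
                              roi_area_mm2 = vd$roi_area_mm2,
                              density_per_mm = vd$density_per_mm)
  }
  expected_roles <- unname(roles[roles %in% c("lymphatic", "blood")])
  have_roles <- vapply(vessel_channels, role_of, character(1))
  for (r in setdiff(expected_roles, have_roles))
    warning("no channel with role '", r, "' at t = ", tum$timepoint_hours,
            " h; vessel density skipped", call. = FALSE)

  overlap <- if (!is.null(lymph_mask))
    channel_overlap(tumor_mask, lymph_mask, ps) else NULL

  list(clusters = clusters, summary = summary,
       vessels = if (length(vrows)) do.call(rbind, c(vrows, list(make.row.names = FALSE))) else NULL,
       overlap = overlap, tumor_mask = tumor_mask, fused = fused,
       provenance = list(center_of_mass_mm = com,
                         origin_mm = origin_mm,
                         threshold = tumor_mask$provenance$threshold,
                         background_mean = tumor_mask$provenance$background_mean,
                         background_sd = tumor_mask$provenance$background_sd,
                         morphology_iterations = tumor_mask$provenance$morphology_iterations,
                         roi = unclass(roi)[c("shape", "area_mm2")]))
}

#' Read a run manifest
#'
#' YAML with a `config` block (fields of [run_config()]) and a `timepoints`
#' list, each entry `hours` plus `channels` (a map channel name -> TIFF
#' path, relative to the manifest's directory). All referenced files are
#' checked up front and every missing one is reported at once.
#'
#' @param path manifest YAML path.
#' @return list with `config` (a `RunConfig`) and `timepoints`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- yaml::read_yaml(path)
  base <- dirname(path)
  if (is.null(m$timepoints) || !length(m$timepoints))
    stop("manifest has no timepoints")
  if (is.null(m$config$pixel_size_mm))
    stop("manifest config must state pixel_size_mm explicitly; ",
         "the calibration is never inferred")
  if (is.null(m$config$reference_exposure_ms))
    stop("manifest config must state reference_exposure_ms explicitly")
  cfg <- do.call(run_config, c(m$config[setdiff(names(m$config), "channel_roles")],
                               if (!is.null(m$config$channel_roles))
                                 list(channel_roles = unlist(m$config$channel_roles))))
  problems <- character()
  hours <- vapply(m$timepoints, function(tp) as.numeric(tp$hours), numeric(1))
  if (anyDuplicated(hours))
    problems <- c(problems, paste("duplicate timepoints:",
                                  paste(hours[duplicated(hours)], collapse = ", ")))
  tps <- lapply(m$timepoints, function(tp) {
    chans <- lapply(tp$channels, function(p) file.path(base, p))
    missing <- unlist(chans)[!file.exists(unlist(chans))]
    if (length(missing))
      problems <<- c(problems, paste("missing file(s):",
                                     paste(missing, collapse = ", ")))
    list(hours = as.numeric(tp$hours), channels = chans)
  })
  if (length(problems))
    stop("manifest validation failed:\n  ", paste(problems, collapse = "\n  "))
  list(config = cfg, timepoints = tps)
}

#' Process a longitudinal series
#'
#' Runs [process_timepoint()] for every manifest entry in time order. The
#' implantation-site reference for origin distances is the center of mass
#' measured at the first timepoint (the center of mass itself is recomputed
#' per timepoint, so both dispersal readings are emitted). A timepoint that
#' fails is skipped with a warning and a gap row rather than aborting the
#' series. Results are written to `output_dir` when given.
#'
#' @param manifest path to a manifest YAML, or a list as returned by
#'   [read_manifest()].
#' @param output_dir optional directory for [write_results()] output.
#' @return list with `summary` (the [longitudinal_table()]), `clusters`
#'   (per-timepoint annotated tables), `vessels`, `overlaps`, and
#'   `provenance`.
#' @export
process_series <- function(manifest, output_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  cfg <- manifest$config
  ord <- order(vapply(manifest$timepoints, `[[`, numeric(1), "hours"))
  origin <- NULL
  summaries <- list(); clusters <- list(); vrows <- list(); overlaps <- list()
  prov <- list()
  for (i in ord) {
    tp <- manifest$timepoints[[i]]
    res <- tryCatch({
      stacks <- lapply(tp$channels, read_stack)
      process_timepoint(stacks, cfg, origin_mm = origin)
    }, error = function(e) {
      warning("timepoint ", tp$hours, " h failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) {
      gap <- summarize_timepoint(
        annotate_distances_and_moments(
          detect_clusters(binary_mask(matrix(FALSE, 1, 1)),
                          pixel_size_mm = cfg$pixel_size_mm),
          c(NA, NA)), tp$hours)
      gap$n_clusters <- NA_integer_
      summaries[[length(summaries) + 1]] <- gap
      next
    }
    if (is.null(origin) && nrow(res$clusters) > 0) {
      origin <- res$provenance$center_of_mass_mm
      # re-annotate the first processed timepoint against its own origin
      bare <- res$clusters[setdiff(names(res$clusters),
                                   c("distance_to_com_mm", "area_moment_mm3",
                                     "percent_area", "distance_to_origin_mm"))]
      attr(bare, "pixel_size_mm") <- attr(res$clusters, "pixel_size_mm")
      attr(bare, "label_matrix") <- attr(res$clusters, "label_matrix")
      res$clusters <- annotate_distances_and_moments(bare, origin,
                                                     origin_mm = origin)
      attr(res$clusters, "timepoint_hours") <- tp$hours
      res$summary <- summarize_timepoint(res$clusters, tp$hours)
    }
    summaries[[length(summaries) + 1]] <- res$summary
    clusters[[length(clusters) + 1]] <- res$clusters
    if (!is.null(res$vessels)) vrows[[length(vrows) + 1]] <- res$vessels
    if (!is.null(res$overlap))
      overlaps[[length(overlaps) + 1]] <-
        data.frame(timepoint_hours = tp$hours,
                   tumor_on_lymph_fraction = res$overlap$tumor_on_lymph_fraction,
                   lymph_on_tumor_fraction = res$overlap$lymph_on_tumor_fraction,
                   overlap_area_mm2 = res$overlap$overlap_area_mm2)
    prov[[length(prov) + 1]] <- res$provenance
  }
  out <- list(summary = longitudinal_table(summaries),
              clusters = clusters,
              vessels = if (length(vrows)) do.call(rbind, vrows) else NULL,
              overlaps = if (length(overlaps)) do.call(rbind, overlaps) else NULL,
              provenance = prov)
  if (!is.null(output_dir)) {
    write_results(out, output_dir)
    if (!is.null(out$overlaps))
      utils::write.csv(out$overlaps, file.path(output_dir, "overlap.csv"),
                       row.names = FALSE, quote = FALSE)
  }
  out
}

#' Scenario configurations for the demonstration scenes
#'
#' `migrating` emulates the disseminating phenotype (clusters drift away
#' from the implantation site, grow, and occasionally fragment);
#' `stationary` emulates the non-migratory control (clusters remain in
#' place, no growth or fragmentation). All other conditions are shared.
#'
#' @param scenario `"migrating"` or `"stationary"`.
#' @param seed integer seed.
#' @param ... overrides passed on to [scene_config()].
#' @return a [scene_config()].
#' @export
demo_scene_config <- function(scenario = c("migrating", "stationary"),
                              seed = 1L, ...) {
  scenario <- match.arg(scenario)
  base <- list(n_timepoints = 5L, seed = seed)
  scen <- if (scenario == "migrating")
    list(migration_rate_px_per_step = 5, growth_rate_per_step = 0.15,
         fragmentation_prob = 0.1)
  else
    list(migration_rate_px_per_step = 0, growth_rate_per_step = 0,
         fragmentation_prob = 0)
  args <- utils::modifyList(c(base, scen), list(...))
  if (is.null(args$exposure_times_ms)) # acquisitions vary across sessions
    args$exposure_times_ms <- rep(c(20, 25, 20, 30, 20),
                                  length.out = args$n_timepoints)
  do.call(scene_config, args)
}

#' Build a ready-to-run demonstration dataset
#'
#' Generates a scenario scene, renders every channel and timepoint to
#' multi-page 16-bit TIFFs with metadata sidecars, writes the ground-truth
#' tables and a manifest, and returns the manifest path. Running
#' [process_series()] on it reproduces the longitudinal phenotype contrast
#' on purely synthetic data.
#'
#' @param dir output directory.
#' @inheritParams demo_scene_config
#' @param channels channels to render.
#' @return list with `manifest` (path), `scene`, and `dir`, invisibly.
#' @export
make_demo <- function(dir, scenario = c("migrating", "stationary"),
                      seed = 1L, channels = c("tumor", "lymphatic", "brightfield"),
                      ...) {
  scenario <- match.arg(scenario)
  cfg <- demo_scene_config(scenario, seed = seed, ...)
  scene <- generate_scene(cfg)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  write_truth_tables(scene, file.path(dir, "truth"))
  tps <- lapply(seq_len(cfg$n_timepoints), function(t) {
    chans <- list()
    for (ch in channels) {
      fn <- sprintf("images/t%02d_%s.tif", t, ch)
      suppressWarnings(write_stack(render_zstack(scene, t, ch),
                                   file.path(dir, fn)))
      chans[[ch]] <- fn
    }
    list(hours = cfg$timepoint_hours[t], channels = chans)
  })
  manifest <- list(
    scenario = scenario,
    truth_migration_rate_px_per_step = cfg$migration_rate_px_per_step,
    config = list(pixel_size_mm = cfg$pixel_size_mm,
                  reference_exposure_ms = cfg$nominal_exposure_ms),
    timepoints = tps)
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  yaml::write_yaml(unclass(cfg), file.path(dir, "scene_config.yaml"))
  invisible(list(manifest = mpath, scene = scene, dir = dir))
}
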