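# End-to-end pipeline: seeds -> vesselness -> fast marching -> active
# contour -> resample -> split -> lengths -> foot-to-foot -> PWV.

#' Pipeline run configuration
#'
#' Aggregates the tunable parameters of every stage. Defaults are the
#' best-performing configuration: scale set \{4, 6\} mm and 0.1 mm
#' resampling.
#'
#' @param scales Vesselness scale set in mm.
#' @param alpha,beta,c,polarity Vesselness parameters
#'   (see [vesselness_params()]).
#' @param speed_floor Speed-map floor.
#' @param snake A [snake_params].
#' @param resample_spacing Centreline resampling interval in mm.
#' @param n_rays Ray count for seed re-centering / lumen circle fits.
#' @param gradient_threshold Foot-to-foot tangent-window threshold.
#' @param seed RNG seed for phantom-generating commands.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scales = c(4, 6), alpha = 0.5, beta = 0.5,
                       c = "auto", polarity = "bright", speed_floor = 1e-3,
                       snake = snake_params(), resample_spacing = 0.1,
                       n_rays = 36, gradient_threshold = 0.8, seed = 1L) {
  structure(list(scales = scales,
                 vesselness = vesselness_params(alpha, beta, c, polarity),
                 speed_floor = speed_floor, snake = snake,
                 resample_spacing = resample_spacing, n_rays = n_rays,
                 gradient_threshold = gradient_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Serialise / deserialise a run configuration as JSON
#' @param config A [run_config].
#' @param path JSON file path.
#' @export
write_config_json <- function(config, path) {
  obj <- list(scales = config$scales,
              alpha = config$vesselness$alpha,
              beta = config$vesselness$beta,
              c = config$vesselness$c,
              polarity = config$vesselness$polarity,
              speed_floor = config$speed_floor,
              snake = unclass(config$snake),
              resample_spacing = config$resample_spacing,
              n_rays = config$n_rays,
              gradient_threshold = config$gradient_threshold,
              seed = config$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(scales = o$scales, alpha = o$alpha, beta = o$beta,
             c = if (identical(o$c, "auto")) "auto" else as.numeric(o$c),
             polarity = o$polarity, speed_floor = o$speed_floor,
             snake = do.call(snake_params, as.list(o$snake)),
             resample_spacing = o$resample_spacing, n_rays = o$n_rays,
             gradient_threshold = o$gradient_threshold, seed = o$seed)
}

#' Track a centreline in a volume between two seeds
#'
#' The tracking core: optional ray-cast seed re-centering, multi-scale
#' vesselness, speed map, bidirectional fast marching, open-active-contour
#' refinement and resampling.
#'
#' @param volume A [volume_image].
#' @param seed_start,seed_end World seed points (mm), e.g. the lumen
#'   centres on the first phase-contrast phase at the ascending and
#'   diaphragmatic aorta.
#' @param config A [run_config].
#' @param recenter Re-centre the seeds with [recenter_seed()] first?
#' @param axis_hint_start,axis_hint_end Local vessel directions for the
#'   re-centering planes; default to the seed-to-seed direction.
#' @param vesselness Optionally a precomputed [vesselness_map] (skips the
#'   filtering stage).
#' @return `list(centreline, raw_path, vesselness, seeds)`; the centreline
#'   is refined and resampled at `config$resample_spacing`.
#' @export
track_centreline <- function(volume, seed_start, seed_end,
                             config = run_config(), recenter = TRUE,
                             axis_hint_start = NULL, axis_hint_end = NULL,
                             vesselness = NULL) {
  hint <- .unit(seed_end - seed_start)
  if (recenter) {
    seed_start <- tryCatch(
      recenter_seed(volume, seed_start, axis_hint_start %||% hint,
                    n_rays = config$n_rays),
      error = function(e) {
        warning("start-seed re-centering failed, keeping original seed: ",
                conditionMessage(e))
        seed_start
      })
    seed_end <- tryCatch(
      recenter_seed(volume, seed_end, axis_hint_end %||% hint,
                    n_rays = config$n_rays),
      error = function(e) {
        warning("end-seed re-centering failed, keeping original seed: ",
                conditionMessage(e))
        seed_end
      })
  }
  if (is.null(vesselness))
    vesselness <- multiscale_vesselness(volume, config$scales,
                                        config$vesselness)
  speed <- build_speed_map(vesselness, config$speed_floor)
  raw <- bidirectional_track(speed, seed_start, seed_end)
  refined <- refine_active_contour(raw, volume, config$snake)
  out <- resample_centreline(refined, config$resample_spacing)
  list(centreline = out, raw_path = raw, vesselness = vesselness,
       seeds = list(start = seed_start, end = seed_end))
}

#' Run the full centreline + PWV pipeline
#'
#' Tracks the aortic centreline between the ascending and diaphragmatic
#' seeds, splits it at the descending-aorta landmark, measures segment
#' lengths, estimates foot-to-foot transit times from the three flow
#' waveforms, and reports PWV for ASC-DESC, DESC-DIAPH and ASC-DIAPH.
#'
#' @param volume A [volume_image].
#' @param seed_start,seed_end Ascending / diaphragmatic seed points (mm).
#' @param desc_point Descending-aorta landmark (mm) for the split.
#' @param waveforms `list(asc =, desc =, diaph =)` of [flow_waveform]s.
#' @param config A [run_config].
#' @param ... Passed to [track_centreline()].
#' @return An object of class `pwv_run`: `centreline`, `segments`,
#'   `lengths` (mm), `transit` (ms), `pwv` (list of [compute_pwv()]
#'   results), `log` (character).
#' @export
run_full_pipeline <- function(volume, seed_start, seed_end, desc_point,
                              waveforms, config = run_config(), ...) {
  stopifnot(all(c("asc", "desc", "diaph") %in% names(waveforms)))
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  note("scales: ", paste(config$scales, collapse = ","), " mm; polarity: ",
       config$vesselness$polarity, "; speed floor: ", config$speed_floor)
  tr <- track_centreline(volume, seed_start, seed_end, config, ...)
  note("tracked centreline: ", nrow(tr$centreline$points), " points, ",
       signif(arc_length(tr$centreline), 6), " mm")
  seg <- split_at_location(tr$centreline, desc_point)
  len <- c(`ASC-DESC` = arc_length(seg$arch),
           `DESC-DIAPH` = arc_length(seg$descending),
           `ASC-DIAPH` = arc_length(tr$centreline))
  note("segment lengths (mm): ", paste(signif(len, 6), collapse = ", "))
  tt <- c(`ASC-DESC` = as.numeric(foot_to_foot(waveforms$asc, waveforms$desc,
                                               config$gradient_threshold)),
          `DESC-DIAPH` = as.numeric(foot_to_foot(waveforms$desc,
                                                 waveforms$diaph,
                                                 config$gradient_threshold)),
          `ASC-DIAPH` = as.numeric(foot_to_foot(waveforms$asc,
                                                waveforms$diaph,
                                                config$gradient_threshold)))
  note("transit times (ms): ", paste(signif(tt, 6), collapse = ", "))
  pwv <- lapply(names(len), function(sg) compute_pwv(len[[sg]], tt[[sg]], sg))
  names(pwv) <- names(len)
  structure(list(centreline = tr$centreline, segments = seg,
                 lengths = len, transit = tt, pwv = pwv,
                 raw_path = tr$raw_path, log = log),
            class = "pwv_run")
}

#' @export
print.pwv_run <- function(x, ...) {
  cat("PWV pipeline run:\n")
  for (p in x$pwv) print(p)
  invisible(x)
}

#' Scripted phantom study
#'
#' Generates a battery of tube phantoms (straight / arc / candy-cane,
#' bright- and dark-lumen), tracks each with the given scale sets, and
#' reports per-cell length error, mean centreline distance to the analytic
#' truth and failure flags, plus a 2D-vs-3D length comparison of the
#' tracked centrelines (projection onto the fitted oblique-sagittal plane)
#' with Bland-Altman and Wilcoxon summaries.
#'
#' @param config A [run_config] (its `seed` seeds the phantom noise).
#' @param scale_sets List of scale sets (mm) to compare.
#' @param geometries Subset of `c("straight", "arc", "candy_cane")`.
#' @param polarities Subset of `c("bright", "dark")`.
#' @param grid_dim Phantom grid size (default 128^3 at 1 mm).
#' @param include_dropout Also run an arch-dropout candy-cane expected to
#'   fail?
#' @param out_dir Optional directory for a JSON + CSV report.
#' @return An object of class `phantom_study`: `cells` (data.frame),
#'   `comparison_2d3d`, and optionally report paths.
#' @export
run_phantom_study <- function(config = run_config(),
                              scale_sets = list(c(4, 6)),
                              geometries = c("straight", "arc",
                                             "candy_cane"),
                              polarities = c("bright", "dark"),
                              grid_dim = c(128, 128, 128),
                              include_dropout = FALSE, out_dir = NULL) {
  fixtures <- list()
  for (geom in geometries)
    for (pol in polarities)
      fixtures[[paste(geom, pol, sep = "_")]] <-
        phantom_fixture(geom, pol, grid_dim = grid_dim, seed = config$seed)
  if (include_dropout)
    fixtures[["candy_cane_bright_dropout"]] <-
      phantom_fixture("candy_cane", "bright", grid_dim = grid_dim,
                      seed = config$seed, dropout = TRUE)

  rows <- list()
  len2d <- c(); len3d <- c()
  for (nm in names(fixtures)) {
    fx <- fixtures[[nm]]
    for (ss in scale_sets) {
      cfg <- config
      cfg$scales <- ss
      cfg$vesselness$polarity <- fx$polarity
      res <- tryCatch(
        track_centreline(fx$volume, fx$seed_start, fx$seed_end, cfg,
                         axis_hint_start = fx$axis_hint_start,
                         axis_hint_end = fx$axis_hint_end),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          cell = nm, scales = paste(ss, collapse = ","),
          truth_length_mm = attr(fx$truth, "analytic_length"),
          tracked_length_mm = NA, length_error_pct = NA,
          mean_distance_mm = NA, failed = TRUE)
        next
      }
      fail <- detect_failure(res$centreline, fx$truth,
                             lumen_radius = fx$lumen_radius)
      L0 <- attr(fx$truth, "analytic_length")
      L <- arc_length(res$centreline)
      dist <- centreline_distance(res$centreline, fx$truth)
      rows[[length(rows) + 1]] <- data.frame(
        cell = nm, scales = paste(ss, collapse = ","),
        truth_length_mm = L0, tracked_length_mm = L,
        length_error_pct = 100 * abs(L - L0) / L0,
        mean_distance_mm = dist$summary$mean, failed = fail$failed)
      if (!fail$failed) {
        pl <- fit_oblique_sagittal(res$centreline)
        len2d <- c(len2d, arc_length_2d(project_to_plane(res$centreline, pl)))
        len3d <- c(len3d, L)
      }
    }
  }
  cells <- do.call(rbind, rows)
  cmp <- NULL
  if (length(len2d) >= 3) {
    cmp <- list(bland_altman = bland_altman(len2d, len3d),
                wilcoxon = tryCatch(wilcoxon_signed_rank(len2d, len3d),
                                    error = function(e) NULL),
                lengths_2d = len2d, lengths_3d = len3d)
  }
  out <- structure(list(cells = cells, comparison_2d3d = cmp),
                   class = "phantom_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cells, file.path(out_dir, "phantom_study.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(cells = cells,
           comparison_2d3d = if (is.null(cmp)) NULL else
             list(bias = cmp$bland_altman$bias,
                  loa = c(cmp$bland_altman$loa_lower,
                          cmp$bland_altman$loa_upper),
                  wilcoxon_p = cmp$wilcoxon$p_value)),
      file.path(out_dir, "phantom_study.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    out$report_csv <- file.path(out_dir, "phantom_study.csv")
    out$report_json <- file.path(out_dir, "phantom_study.json")
  }
  out
}

#' @export
print.phantom_study <- function(x, ...) {
  print(x$cells, row.names = FALSE)
  if (!is.null(x$comparison_2d3d)) {
    cat("\n2D-vs-3D length comparison:\n")
    print(x$comparison_2d3d$bland_altman)
  }
  invisible(x)
}

#' Standard phantom fixture used by the study and the tests
#'
#' The three geometries emulate a straight vessel (100 mm), an aortic-arch
#' half circle (R = 30 mm) and a full thoracic candy-cane (R = 25 mm with
#' 30 mm / 50 mm limbs), all with a 6 mm lumen radius in a 128 mm field of
#' view. The dark variant swaps the lumen/background intensities; the
#' dropout variant attenuates the arch to background intensity.
#'
#' @param geometry `"straight"`, `"arc"` or `"candy_cane"`.
#' @param polarity `"bright"` or `"dark"`.
#' @param grid_dim Grid size (voxels, 1 mm spacing).
#' @param seed Noise seed.
#' @param dropout Attenuate the arch to background?
#' @return `list(volume, truth, seed_start, seed_end, desc_point,
#'   lumen_radius, polarity, curve)`.
#' @export
phantom_fixture <- function(geometry = c("candy_cane", "straight", "arc"),
                            polarity = c("bright", "dark"),
                            grid_dim = c(128, 128, 128), seed = 1L,
                            dropout = FALSE) {
  geometry <- match.arg(geometry)
  polarity <- match.arg(polarity)
  ext <- (grid_dim - 1)  # world extent at 1 mm spacing
  curve <- switch(geometry,
    straight = aorta_curve("straight", start = c(ext[1] / 2, ext[2] / 2, 14),
                           direction = c(0, 0, 1), length = 100),
    arc = aorta_curve("arc", centre = c(ext[1] / 2, ext[2] / 2, 50),
                      radius = 30, u = c(1, 0, 0), v = c(0, 0, 1),
                      theta0 = pi, span = pi),
    candy_cane = aorta_curve("candy_cane",
                             base = c(ext[1] / 2 - 25, ext[2] / 2, 35),
                             radius = 25, limb1 = 30, limb2 = 50))
  lum <- if (polarity == "bright") c(100, 10) else c(10, 100)
  dr <- NULL
  if (dropout) {
    arc_mid <- switch(geometry,
                      straight = curve$length / 2,
                      arc = curve$length / 2,
                      candy_cane = 30 + pi * 25 / 2)
    # the window must be wide enough that the straight shortcut across it
    # leaves the lumen (chord sagitta > lumen radius): 50 mm of the R=25
    # arch gives a ~11.5 mm sagitta against the 6 mm lumen
    dr <- list(position = arc_mid, extent = 50, attenuation = 0)
  }
  spec <- tube_spec(curve, lumen_radius = 6, lumen_intensity = lum[1],
                    background_intensity = lum[2], blur_sigma = 1,
                    noise_sigma = 2, dropout = dr, seed = seed)
  ph <- make_tube_phantom(spec, grid_dim = grid_dim)
  p0 <- drop(curve$point_at(0))
  p1 <- drop(curve$point_at(curve$length))
  eps <- 0.05
  hint0 <- .unit(drop(curve$point_at(eps)) - p0)
  hint1 <- .unit(p1 - drop(curve$point_at(curve$length - eps)))
  desc <- switch(geometry,
                 straight = drop(curve$point_at(0.4 * curve$length)),
                 arc = drop(curve$point_at(0.5 * curve$length)),
                 candy_cane = drop(curve$point_at(30 + pi * 25)))
  list(volume = ph$volume, truth = ph$truth, seed_start = p0, seed_end = p1,
       axis_hint_start = hint0, axis_hint_end = hint1,
       desc_point = desc, lumen_radius = 6, polarity = polarity,
       curve = curve)
}
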