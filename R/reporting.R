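#' Molar concentration of a mass-ratio epinephrine dilution
#'
#' Converts a `1 g : D mL` dilution of (-)-epinephrine to micromolar:
#' `1e9 / (D * molar_mass)` uM. A 1:80 000 dilution gives 68.23 uM. Note a
#' published-literature quirk this helper documents rather than resolves:
#' 34.12 uM is exactly half of 68.23 uM, i.e. a 1:160 000 dilution, yet is
#' sometimes quoted alongside a "1:175 000" label (which would give
#' 31.19 uM); both readings are returned by the example below.
#'
#' @param dilution_denominator D in the `1 g : D mL` ratio (positive).
#' @param molar_mass g/mol (default 183.20 for (-)-epinephrine).
#' @return concentration in micromolar.
#' @examples
#' epinephrineMolarity(80000)    # 68.23
#' epinephrineMolarity(160000)   # 34.12
#' epinephrineMolarity(175000)   # 31.19
#' @export
epinephrineMolarity <- function(dilution_denominator, molar_mass = 183.20) {
  if (any(dilution_denominator <= 0) || molar_mass <= 0)
    stop("dilution denominator and molar mass must be positive")
  1e9 / (dilution_denominator * molar_mass)
}

starsForP <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
         ifelse(p <= 0.05, "*", "")))
}

#' Compare condition groups against a control
#'
#' Routine reporting statistics: Shapiro-Wilk normality per group, then a
#' two-tailed unpaired Student's t-test of each treatment group against the
#' control, with star annotation at p <= 0.05 (*), 0.01 (**) and 0.001
#' (***); strictly greater p-values (e.g. 0.052) receive no star.
#'
#' @param groups named list of numeric vectors (replicate metric values).
#' @param control name of the control group (default the first).
#' @return data frame: group, n, mean, sd, shapiro_p, t_p, stars. Groups
#'   with n < 3 are reported but skipped from testing, with a warning.
#' @export
compareConditions <- function(groups, control = names(groups)[1]) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            control %in% names(groups))
  ctrl <- groups[[control]]
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    sh <- if (length(v) >= 3 && stats::sd(v) > 0)
      stats::shapiro.test(v)$p.value else NA_real_
    tp <- NA_real_
    if (g != control) {
      if (length(v) < 3 || length(ctrl) < 3) {
        warning("group '", g, "' or control has n < 3: test skipped")
      } else {
        tp <- stats::t.test(v, ctrl, var.equal = TRUE,
                            alternative = "two.sided")$p.value
      }
    }
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = stats::sd(v), shapiro_p = sh, t_p = tp,
               stars = if (is.na(tp)) "" else starsForP(tp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

pipelineDefaults <- function() {
  list(
    seed = 1L,
    out = ".",
    scale = list(pixel_pitch_um = NULL, length_px = NULL, length_mm = NULL),
    growth = list(frames_dir = NULL, interval_s = 60, window = 71,
                  offset = 4, denoise = FALSE, strength = 8,
                  template_window = 5, search_window = 21,
                  horizon_h = 24, condition = "unlabelled"),
    roi = list(detect = FALSE, min_radius = NULL, max_radius = NULL,
               min_dist = NULL),
    fractal = list(every_minutes = 10),
    veins = list(frames_dir = NULL, interval_s = 4, window = 79, offset = 2,
                 threshold = 25, min_line_length = 10, spacing = 5,
                 contrast_min = 10, max_mean_width_um = 1000),
    contraction = list(fs = 0.25, segment = 256, overlap = 0.9),
    volume = list(n_intervals = 50, alpha_max = pi / 2, x_max = 0.5)
  )
}

mergeConfig <- function(defaults, user) {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]))
      defaults[[k]] <- mergeConfig(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Load and validate a pipeline run configuration
#'
#' Reads YAML (or takes a list), merges it over the package defaults and
#' rejects unknown keys, so configuration round-trips through serialisation
#' unchanged.
#'
#' @param config YAML file path or a nested list.
#' @return validated configuration list.
#' @export
loadRunConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  mergeConfig(pipelineDefaults(), config)
}

loadStageFrames <- function(dir, interval_s) {
  paths <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (!length(paths)) stop("no image frames found in ", dir)
  loadFrameSeries(paths, interval_s = interval_s)
}

resolveCalibration <- function(cfg) {
  if (!is.null(cfg$scale$pixel_pitch_um))
    return(new("ScaleCalibration", pixelPitch = cfg$scale$pixel_pitch_um,
               source = "configured pixel pitch"))
  if (!is.null(cfg$scale$length_px) && !is.null(cfg$scale$length_mm))
    return(calibrateScale(cfg$scale$length_px, cfg$scale$length_mm))
  stop("config must set scale.pixel_pitch_um or scale.length_px/length_mm")
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on disk-resident frame directories: growth and
#' exploration (24 h regime), fractal complexity, vein morphometry and QC,
#' contraction spectral analysis (1 h regime), and network-volume
#' estimation. Writes `growth.csv`, `fractal.csv`, `sections.csv`,
#' `widths.csv`, `frequency.csv`, `volume.json`, `volume_intervals.csv`,
#' `summary.json` and a `manifest.json` recording the configuration and
#' seed. Stages whose inputs are not configured are skipped.
#'
#' @param config configuration list or YAML path (see [loadRunConfig()]).
#' @return invisibly, a list with the stage results.
#' @export
runPipeline <- function(config) {
  cfg <- loadRunConfig(config)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  cal <- resolveCalibration(cfg)
  res <- list(config = cfg)
  summary <- list()

  if (!is.null(cfg$growth$frames_dir)) {
    gs <- loadStageFrames(cfg$growth$frames_dir, cfg$growth$interval_s)
    frm <- frames(gs)
    if (isTRUE(cfg$growth$denoise))
      frm <- lapply(frm, denoiseFrame, strength = cfg$growth$strength,
                    template_window = cfg$growth$template_window,
                    search_window = cfg$growth$search_window)
    roi <- NULL
    if (isTRUE(cfg$roi$detect)) {
      roi <- detectDishROI(frm[[1L]], cfg$roi$min_radius,
                           cfg$roi$max_radius, cfg$roi$min_dist)
      frm <- lapply(frm, applyROI, roi = roi)
    }
    masks <- lapply(frm, segmentNetwork, window = cfg$growth$window,
                    offset = cfg$growth$offset, roi = roi)
    a <- areaSeries(masks, cal, timestamps(gs),
                    condition = cfg$growth$condition)
    e <- explorationSeries(masks, cal, timestamps(gs))
    gr <- growthRate(a, cfg$growth$horizon_h)
    er <- explorationRate(e, cfg$growth$horizon_h)
    utils::write.csv(
      data.frame(t_hours = a@timesH, area_mm2 = a@areaMm2,
                 area_norm_mm2 = a@areaNormMm2,
                 explored_mm2 = e@exploredMm2,
                 condition = a@condition),
      file.path(cfg$out, "growth.csv"), row.names = FALSE)
    summary$growth_rate <- gr
    summary$exploration_rate_mm2_per_h <- er
    res$area <- a; res$exploration <- e; res$masks <- masks
    res$mask_times_s <- timestamps(gs)

    fs <- fractalSeries(masks, timestamps(gs),
                        every_minutes = cfg$fractal$every_minutes)
    utils::write.csv(
      data.frame(t_hours = fs@timesH, dimension = fs@dimension,
                 fit_r2 = fs@fitR2),
      file.path(cfg$out, "fractal.csv"), row.names = FALSE)
    res$fractal <- fs
  }

  if (!is.null(cfg$veins$frames_dir)) {
    vs <- loadStageFrames(cfg$veins$frames_dir, cfg$veins$interval_s)
    pitch <- pixelPitch(cal)
    first <- vs[[1L]]
    mask <- segmentNetwork(first, window = cfg$veins$window,
                           offset = cfg$veins$offset)
    skel <- skeletonize(mask)
    vss <- detectSections(skel, threshold = cfg$veins$threshold,
                          min_line_length = cfg$veins$min_line_length,
                          spacing = cfg$veins$spacing)
    fw <- measureFrameWidths(first, vss, pixel_pitch = pitch)
    vss <- qcCascade(vss, first, fw, pixel_pitch = pitch,
                     max_mean_width_um = cfg$veins$max_mean_width_um,
                     contrast_min = cfg$veins$contrast_min)
    p <- positions(vss)
    s <- sections(vss)
    st <- s$status[match(p$section_id, s$section_id)]
    rr <- s$reject_reason[match(p$section_id, s$section_id)]
    utils::write.csv(
      data.frame(section_id = p$section_id, pos_index = p$pos_index,
                 x_px = p$c, y_px = p$r, nx = p$nc, ny = p$nr,
                 status = ifelse(p$keep, st, "dropped"),
                 reject_reason = rr),
      file.path(cfg$out, "sections.csv"), row.names = FALSE)
    pixelPitch(vs) <- pitch
    widths <- trackSections(vs, vss)
    utils::write.csv(widths, file.path(cfg$out, "widths.csv"),
                     row.names = FALSE)
    res$sections <- vss; res$widths <- widths

    traces <- sectionTraces(widths)
    est <- lapply(split(traces, traces$section_id), function(tr)
      contractionFrequency(tr$width_um, fs = cfg$contraction$fs,
                           segment_length = cfg$contraction$segment,
                           overlap = cfg$contraction$overlap,
                           section_id = as.character(tr$section_id[1L])))
    org <- organismAverage(est)
    freq_df <- do.call(rbind, lapply(est, function(e)
      data.frame(section_id = e@sectionId,
                 slice_index = seq_along(e@sliceFreqs),
                 slice_freq_hz = e@sliceFreqs,
                 est_frequency_hz = e@estFrequencyHz,
                 outlier_flag = e@sectionId %in% org$excluded)))
    utils::write.csv(freq_df, file.path(cfg$out, "frequency.csv"),
                     row.names = FALSE)
    summary$contraction_mean_hz <- org$mean_hz
    summary$contraction_sd_hz <- org$sd_hz
    res$spectral <- est; res$organism <- org

    if (!is.null(res$area)) {
      # per-position time-mean widths pooled over the vein set
      pos_mean <- stats::aggregate(
        width_um ~ section_id + pos_index,
        data = widths[widths$width_um > 0, , drop = FALSE], FUN = mean)
      i24 <- nearestTimeIndex(res$area@timesH, cfg$growth$horizon_h)
      a24 <- res$area@areaMm2[i24]
      dist <- diameterDistribution(pos_mean$width_um,
                                   n_intervals = cfg$volume$n_intervals)
      vol <- estimateVolume(dist, a24, alpha_max = cfg$volume$alpha_max,
                            x_max = cfg$volume$x_max)
      utils::write.csv(vol@perInterval,
                       file.path(cfg$out, "volume_intervals.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(total_mm3 = vol@totalMm3, normalized_mm = vol@normalizedMm,
             area_mm2 = vol@areaMm2, error_range = vol@errorRange),
        file.path(cfg$out, "volume.json"), auto_unbox = TRUE, digits = NA)
      summary$volume_mm3 <- vol@totalMm3
      summary$normalized_volume_mm <- vol@normalizedMm
      res$volume <- vol
    }
  }

  jsonlite::write_json(summary, file.path(cfg$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = "myxometry",
         version = as.character(utils::packageVersion("myxometry")),
         seed = cfg$seed, config = cfg),
    file.path(cfg$out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
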