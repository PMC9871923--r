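# End-to-end orchestration: simulate -> extract -> analyse -> report.
# One global seed is fanned out to per-stage child streams so each stage is
# independently reproducible.

#' Simulate a photoconversion session through the full pipeline
#'
#' Generates a population, renders pre-conversion stacks at every readout
#' wavelength (from which dark current and bleed-through are estimated,
#' exactly as on real data), then applies the photoconversion events one by
#' one, re-rendering and re-extracting after each to obtain the pooled median
#' RGR at each cumulative dose.
#'
#' @param seed integer seed for the whole session.
#' @param nCells cells in the field of view.
#' @param frameShape frame rows/cols (default 160 x 160).
#' @param eventDoses per-event light doses, mJ/mm^2.
#' @param wavelengths readout wavelengths, nm.
#' @param power readout laser power, mW.
#' @param nFrames frames per readout stack.
#' @param optics an \linkS4class{OpticsModel}.
#' @param conversion a \linkS4class{ConversionModel}.
#' @param fovId field-of-view identifier.
#' @return list: \code{points} (data.frame event, cumulative_dose,
#'   wavelength_nm, n_cells, median_rgr), \code{betaHat} (estimated
#'   bleed-through per wavelength), \code{darkHat}, \code{preTable}
#'   (pre-conversion cell table), \code{population} (final ground truth).
#' @export
simulatePcSession <- function(seed, nCells = 150, frameShape = c(160, 160),
                              eventDoses = c(104, 104), wavelengths = 1000,
                              power = 1, nFrames = 3,
                              optics = opticsModel(),
                              conversion = conversionModel(), fovId = 1L) {
  pop <- generatePopulation(nCells, frameShape,
                            seed = childSeed(seed, "pcsession"))
  mask <- labelSynthetic(pop)
  wl <- as.character(wavelengths)
  betaHat <- stats::setNames(numeric(length(wavelengths)), wl)
  darkHat <- stats::setNames(vector("list", length(wavelengths)), wl)
  preTables <- vector("list", length(wavelengths))
  for (j in seq_along(wavelengths)) {
    pre <- renderStack(pop, optics, wavelengths[j], power, nFrames,
                       seed = childSeed(seed, paste0("pre", wl[j])))
    darkHat[[j]] <- estimateDarkCurrent(pre)
    tab <- extractCellSignals(pre, mask, dark = darkHat[[j]], fovId = fovId)
    betaHat[j] <- estimateBleedthrough(tab)
    preTables[[j]] <- tab
  }
  points <- NULL
  cumDose <- 0
  for (e in seq_along(eventDoses)) {
    pop <- applyPhotoconversion(pop, conversion, eventDoses[e])
    cumDose <- cumDose + eventDoses[e]
    for (j in seq_along(wavelengths)) {
      st <- renderStack(pop, optics, wavelengths[j], power, nFrames,
                        seed = childSeed(seed, paste0("post", e, "w", wl[j])))
      tab <- extractCellSignals(st, mask, dark = estimateDarkCurrent(st),
                                fovId = fovId)
      rgr <- computeRgr(tab, betaHat[j])
      med <- poolMedianRgr(rgr)
      points <- rbind(points,
                      data.frame(event = e, cumulative_dose = cumDose,
                                 wavelength_nm = wavelengths[j],
                                 n_cells = med$n_cells,
                                 median_rgr = med$median_rgr))
    }
  }
  list(points = points, betaHat = betaHat, darkHat = darkHat,
       preTable = do.call(rbind, preTables), population = pop)
}

#' Simulate and analyse a dynamic recording session
#'
#' Generates a tuned population, simulates its drifting-grating traces
#' (negative-indicator dips, bleaching, noise), then runs the full dynamic
#' analysis: bleach correction, trial responses, tuned/oriented gates, and
#' the population summary.
#'
#' @param seed integer seed.
#' @param nCells cells in the recording.
#' @param fractionTuned fraction of cells given a preferred direction.
#' @param responseAmplitude planted dip depth at the preferred direction.
#' @param noiseSd additive noise sd as a fraction of baseline.
#' @param bleachHalfLifeS bleaching half-life, seconds.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @return list: \code{tuning} (per-cell classification), \code{summary}
#'   (population summary), \code{groundTruth}.
#' @export
simulateDynamicSession <- function(seed, nCells = 50, fractionTuned = 0.125,
                                   responseAmplitude = 0.105,
                                   noiseSd = 0.02, bleachHalfLifeS = 2000,
                                   protocol = stimulusProtocol()) {
  pop <- generatePopulation(nCells, c(256, 256),
                            fractionTuned = fractionTuned,
                            seed = childSeed(seed, "dynsession"))
  sim <- simulateDynamicTraces(pop, protocol,
                               responseAmplitude = responseAmplitude,
                               bleachHalfLifeS = bleachHalfLifeS,
                               noiseSd = noiseSd,
                               seed = childSeed(seed, "traces"))
  tuning <- analyzeDynamicRecording(sim$traces, protocol,
                                    onsets = sim$onsets)
  list(tuning = tuning, summary = populationSummary(tuning),
       groundTruth = sim$groundTruth)
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path configuration file; format chosen by extension.
#' @return the configuration list.
#' @export
readRunConfig <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the whole pipeline end to end
#'
#' Executes both arms on synthetic data -- photoconversion (simulate,
#' extract, correct, pool, zero-intercept fit) and dynamic recording
#' (simulate, bleach-correct, classify) -- and writes every table and report
#' plus a checksummed artifact manifest to \code{config$out_dir}. The same
#' configuration and seed reproduce byte-identical artifacts.
#'
#' @param config configuration list (or path to a YAML/JSON file): fields
#'   \code{seed}, \code{out_dir}, and optional \code{pc} / \code{dynamic}
#'   parameter blocks mirroring the arguments of
#'   \code{\link{simulatePcSession}} and
#'   \code{\link{simulateDynamicSession}}.
#' @return invisibly, a list with the PC fit, dynamic summary, the paths
#'   written, and the manifest data.frame.
#' @export
runEndToEnd <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(config$seed) || is.null(config$out_dir))
    stop("config must provide seed and out_dir", call. = FALSE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  pcCfg <- config$pc
  pcRes <- NULL
  if (is.null(pcCfg) || !isFALSE(pcCfg$enabled)) {
    events <- if (!is.null(pcCfg$events)) as.data.frame(pcCfg$events)
      else data.frame(power_mW = c(100, 100), n_pulses = 40, pulse_s = 1,
                      spot_mm = 7)
    events <- doseFromEvents(events)
    sess <- simulatePcSession(
      seed = childSeed(config$seed, "pc"),
      nCells = pcCfg$n_cells %||% 150,
      eventDoses = events$dose,
      wavelengths = pcCfg$wavelengths %||% 1000,
      nFrames = pcCfg$n_frames %||% 3)
    fitWl <- (pcCfg$wavelengths %||% 1000)[1]
    pts <- sess$points[sess$points$wavelength_nm == fitWl, ]
    fit <- fitDoseResponse(pts$cumulative_dose, pts$median_rgr)
    p1 <- file.path(out, "pc_event_log.csv")
    utils::write.csv(events, p1, row.names = FALSE)
    p2 <- file.path(out, "pc_median_rgr.csv")
    utils::write.csv(sess$points, p2, row.names = FALSE)
    p3 <- file.path(out, "pc_fit_report.json")
    jsonlite::write_json(
      list(wavelength_nm = fitWl, slope = fit@slope, se = fit@se,
           ci95 = fit@ci95, t = fit@tStat, p = fit@pValue,
           n_points = fit@nPoints,
           beta_hat = as.list(sess$betaHat)),
      p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p1, p2, p3)
    pcRes <- list(fit = fit, session = sess)
  }

  dynCfg <- config$dynamic
  dynRes <- NULL
  if (is.null(dynCfg) || !isFALSE(dynCfg$enabled)) {
    proto <- stimulusProtocol(grayS = dynCfg$gray_s %||% 4)
    sess <- simulateDynamicSession(
      seed = childSeed(config$seed, "dynamic"),
      nCells = dynCfg$n_cells %||% 40,
      fractionTuned = dynCfg$fraction_tuned %||% 0.125,
      responseAmplitude = dynCfg$response_amplitude %||% 0.105,
      noiseSd = dynCfg$noise_sd %||% 0.02,
      bleachHalfLifeS = dynCfg$bleach_half_life_s %||% 2000,
      protocol = proto)
    p4 <- file.path(out, "dynamic_tuning.csv")
    utils::write.csv(sess$tuning, p4, row.names = FALSE)
    p5 <- file.path(out, "dynamic_summary.json")
    s <- sess$summary
    jsonlite::write_json(
      list(n_cells = s$n_cells, fraction_tuned = s$fraction_tuned,
           fraction_oriented = s$fraction_oriented,
           median_peak_amplitude = s$median_peak_amplitude),
      p5, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p4, p5)
    dynRes <- sess
  }

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  pm <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, pm, pretty = TRUE)
  invisible(list(pc = pcRes, dynamic = dynRes, paths = c(paths, pm),
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
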