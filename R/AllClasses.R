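#' @import methods
NULL

#' Synthetic scene population
#'
#' Holds the ground-truth description of a simulated field of view: one row
#' per cell with its disk footprint, fluorophore expression level, relative
#' calcium load ("activity"), region label (stimulated vs reference), tuning
#' assignment, and the cumulative true red-to-green ratio accumulated over
#' photoconversion events.
#'
#' The true ratio \code{trueRgr} is the state variable of the conversion
#' model: after cumulative light dose D a cell's true ratio is
#' \code{(slopeBaseline + slopeActive * activity) * D}.  Species amounts are
#' derived from it so that green + red is conserved:
#' \code{green = expression / (1 + r)}, \code{red = expression * r / (1 + r)}.
#'
#' @slot cells data.frame with columns \code{cell_id}, \code{row}, \code{col},
#'   \code{radius}, \code{expression}, \code{activity}, \code{region},
#'   \code{preferred_direction} (integer 0..7 or NA), \code{tuning_depth},
#'   \code{trueRgr}.
#' @slot frameShape integer(2), image rows and columns.
#' @slot seed integer seed used to generate the population.
#' @export
setClass("ScenePopulation",
  slots = c(cells = "data.frame", frameShape = "integer", seed = "integer"))

setValidity("ScenePopulation", function(object) {
  cl <- object@cells
  need <- c("cell_id", "row", "col", "radius", "expression", "activity",
            "region", "preferred_direction", "tuning_depth", "trueRgr")
  if (!all(need %in% names(cl)))
    return(paste("cells is missing columns:",
                 paste(setdiff(need, names(cl)), collapse = ", ")))
  if (length(object@frameShape) != 2L || any(object@frameShape < 1L))
    return("frameShape must be two positive integers")
  if (nrow(cl) == 0L)
    return("population must contain at least one cell")
  if (any(cl$expression <= 0)) return("expression must be > 0")
  if (any(cl$activity < 0)) return("activity must be >= 0")
  if (any(cl$trueRgr < 0)) return("trueRgr must be >= 0")
  if (any(cl$row - cl$radius < 1 | cl$row + cl$radius > object@frameShape[1] |
          cl$col - cl$radius < 1 | cl$col + cl$radius > object@frameShape[2]))
    return("cell footprints must lie inside the frame")
  if (!all(cl$region %in% c("stimulated", "reference")))
    return("region must be 'stimulated' or 'reference'")
  TRUE
})

#' Two-channel optics model
#'
#' Wavelength-dependent excitation efficiencies of the green and red species,
#' the green-to-red channel contamination (bleed-through) fraction, per-channel
#' dark current, and the shot-noise gain used by the renderer.
#'
#' Defaults encode the conditions of a dual-wavelength two-photon readout of a
#' green-to-red photoconvertible integrator: contamination fractions 13.1\%
#' at 1000 nm and 14.6\% at 1040 nm, and an excitation-efficiency shift at
#' 1040 nm that multiplies the measured red-to-green ratio by 9.05 relative
#' to 1000 nm (longer wavelengths excite the red species more efficiently and
#' the green species less).
#'
#' @slot wavelengths numeric, wavelengths (nm) the model knows about.
#' @slot effGreen,effRed numeric, excitation efficiency per wavelength
#'   (dimensionless, >= 0), parallel to \code{wavelengths}.
#' @slot bleed numeric in [0, 1), green-to-red contamination per wavelength.
#' @slot dark numeric(2) named \code{green}, \code{red}: detector offset (a.u.).
#' @slot noiseScale numeric >= 0, gain of the signal-proportional-variance
#'   Gaussian noise (sd = noiseScale * sqrt(fluorescence signal)).
#' @export
setClass("OpticsModel",
  slots = c(wavelengths = "numeric", effGreen = "numeric", effRed = "numeric",
            bleed = "numeric", dark = "numeric", noiseScale = "numeric"))

setValidity("OpticsModel", function(object) {
  n <- length(object@wavelengths)
  if (length(object@effGreen) != n || length(object@effRed) != n ||
      length(object@bleed) != n)
    return("effGreen, effRed and bleed must be parallel to wavelengths")
  if (any(object@effGreen < 0) || any(object@effRed < 0))
    return("excitation efficiencies must be >= 0")
  if (any(object@bleed < 0) || any(object@bleed >= 1))
    return("bleed must lie in [0, 1)")
  if (length(object@dark) != 2L || any(object@dark < 0))
    return("dark must be two non-negative values (green, red)")
  if (length(object@noiseScale) != 1L || object@noiseScale < 0)
    return("noiseScale must be a single non-negative number")
  TRUE
})

#' Photoconversion model
#'
#' Linear dose-response model of green-to-red photoconversion: after a light
#' dose D (mJ/mm^2) a cell with relative calcium load a gains true
#' red-to-green ratio \code{(slopeBaseline + slopeActive * a) * D},
#' accumulated additively over successive events.
#'
#' @slot slopeActive ratio units per (mJ/mm^2) per unit activity.
#' @slot slopeBaseline ratio units per (mJ/mm^2) at zero activity
#'   (calcium-independent conversion).
#' @export
setClass("ConversionModel",
  slots = c(slopeActive = "numeric", slopeBaseline = "numeric"))

setValidity("ConversionModel", function(object) {
  if (length(object@slopeActive) != 1L || object@slopeActive < 0)
    return("slopeActive must be a single non-negative number")
  if (length(object@slopeBaseline) != 1L || object@slopeBaseline < 0)
    return("slopeBaseline must be a single non-negative number")
  TRUE
})

#' Two-channel image stack
#'
#' A registered green/red fluorescence recording: two frames x rows x cols
#' arrays plus the acquisition metadata the analysis needs (excitation
#' wavelength, laser power, frame rate).
#'
#' @slot green,red numeric 3-d arrays (frame, row, col), identical dims.
#' @slot wavelength excitation wavelength, nm.
#' @slot power laser power on sample, mW.
#' @slot frameRate frames per second.
#' @slot metadata free-form list (provenance, generator parameters, ...).
#' @export
setClass("TwoChannelStack",
  slots = c(green = "array", red = "array", wavelength = "numeric",
            power = "numeric", frameRate = "numeric", metadata = "list"))

setValidity("TwoChannelStack", function(object) {
  if (length(dim(object@green)) != 3L || length(dim(object@red)) != 3L)
    return("green and red must be 3-d arrays (frame, row, col)")
  if (!identical(dim(object@green), dim(object@red)))
    return("green and red arrays must have identical dimensions")
  if (any(dim(object@green) < 1L)) return("stack must be non-empty")
  if (length(object@power) != 1L || object@power <= 0)
    return("power must be a single positive number")
  TRUE
})

#' Drifting-grating stimulus protocol
#'
#' Timing of the standard orientation-tuning protocol: gratings drifting in
#' \code{nDirections} directions, each shown for \code{gratingS} seconds and
#' followed by \code{grayS} seconds of gray screen, the whole cycle repeated
#' \code{nRepetitions} times. An initial gray period of \code{grayS} seconds
#' precedes the first grating so that every trial has a baseline window.
#'
#' @slot nDirections integer, number of drift directions (default 8).
#' @slot gratingS grating duration, seconds (default 4).
#' @slot grayS inter-grating gray screen, seconds (default 8; 4-12 typical).
#' @slot nRepetitions integer, cycles (default 5).
#' @slot frameRate acquisition rate, Hz (default 30).
#' @slot directionOrder integer matrix (nRepetitions x nDirections) of
#'   direction ids 0..nDirections-1, the presentation order per repetition.
#' @export
setClass("StimulusProtocol",
  slots = c(nDirections = "integer", gratingS = "numeric", grayS = "numeric",
            nRepetitions = "integer", frameRate = "numeric",
            directionOrder = "matrix"))

setValidity("StimulusProtocol", function(object) {
  if (object@nDirections < 1L || object@nRepetitions < 1L)
    return("nDirections and nRepetitions must be >= 1")
  if (object@gratingS <= 0 || object@grayS < 0 || object@frameRate <= 0)
    return("gratingS and frameRate must be > 0, grayS >= 0")
  d <- object@directionOrder
  if (!identical(dim(d), c(object@nRepetitions, object@nDirections)))
    return("directionOrder must be nRepetitions x nDirections")
  ok <- apply(d, 1L, function(r) setequal(r, 0:(object@nDirections - 1L)))
  if (!all(ok))
    return("each repetition must present every direction exactly once")
  TRUE
})

#' Zero-intercept dose-response fit
#'
#' Result of regressing pooled median RGR on cumulative photoconversion light
#' dose through the origin: slope = sum(x*y)/sum(x^2), with standard error,
#' two-tailed t test against slope = 0 on n-1 degrees of freedom, and the
#' matching 95\% confidence interval.
#'
#' @slot slope ratio units per mJ/mm^2.
#' @slot se standard error of the slope.
#' @slot ci95 numeric(2), 95\% confidence interval.
#' @slot tStat t statistic for H0: slope = 0.
#' @slot pValue two-tailed p-value.
#' @slot nPoints number of (dose, median RGR) points.
#' @slot df residual degrees of freedom (nPoints - 1).
#' @export
setClass("DoseResponseFit",
  slots = c(slope = "numeric", se = "numeric", ci95 = "numeric",
            tStat = "numeric", pValue = "numeric", nPoints = "integer",
            df = "integer"))

setValidity("DoseResponseFit", function(object) {
  if (length(object@ci95) != 2L) return("ci95 must be length 2")
  if (object@ci95[1] > object@slope || object@ci95[2] < object@slope)
    return("ci95 must contain the slope")
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})

setMethod("show", "ScenePopulation", function(object) {
  cl <- object@cells
  cat("ScenePopulation:", nrow(cl), "cells in a",
      paste(object@frameShape, collapse = " x "), "frame\n")
  cat("  tuned:", sum(!is.na(cl$preferred_direction)),
      " stimulated:", sum(cl$region == "stimulated"),
      " reference:", sum(cl$region == "reference"), "\n")
  cat("  median activity:", signif(stats::median(cl$activity), 4),
      " median true RGR:", signif(stats::median(cl$trueRgr), 4), "\n")
})

setMethod("show", "OpticsModel", function(object) {
  cat("OpticsModel over wavelengths:",
      paste(object@wavelengths, collapse = ", "), "nm\n")
  tab <- data.frame(wavelength = object@wavelengths,
                    effGreen = object@effGreen, effRed = object@effRed,
                    bleed = object@bleed)
  print(tab, row.names = FALSE)
  cat("  dark (green, red):", paste(object@dark, collapse = ", "),
      " noiseScale:", object@noiseScale, "\n")
})

setMethod("show", "TwoChannelStack", function(object) {
  d <- dim(object@green)
  cat("TwoChannelStack:", d[1], "frame(s) of", d[2], "x", d[3], "pixels\n")
  cat("  wavelength:", object@wavelength, "nm  power:", object@power,
      "mW  frame rate:", object@frameRate, "Hz\n")
})

setMethod("show", "StimulusProtocol", function(object) {
  cat("StimulusProtocol:", object@nDirections, "directions x",
      object@nRepetitions, "repetitions (",
      object@nDirections * object@nRepetitions, "trials )\n")
  cat("  grating:", object@gratingS, "s  gray:", object@grayS,
      "s  frame rate:", object@frameRate, "Hz\n")
})

setMethod("show", "DoseResponseFit", function(object) {
  cat("Zero-intercept dose-response fit on", object@nPoints, "points\n")
  cat(sprintf("  slope: %.4g per mJ/mm^2 (se %.3g, 95%% CI [%.4g, %.4g])\n",
              object@slope, object@se, object@ci95[1], object@ci95[2]))
  cat(sprintf("  t = %.3g on %d df, two-tailed p = %.3g\n",
              object@tStat, object@df, object@pValue))
})
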