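# Synthetic two-channel imaging generator.
#
# Every downstream stage of the package is exercised against scenes produced
# here, with planted ground truth: disk-shaped cells on a dark background,
# activity- and dose-dependent green-to-red conversion that is exactly linear
# in cumulative light dose, wavelength-dependent excitation efficiencies,
# green-to-red channel contamination, dark current, shot-like noise, slow
# bleaching, and stimulus-locked fluorescence *decreases* (the sensor is a
# negative indicator: calcium dims the green channel).

# Evaluate fn() under a temporary RNG state so generators are deterministic
# without clobbering the caller's stream.
withSeed <- function(seed, fn) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Construct an optics model
#'
#' @param wavelengths wavelengths (nm) the model covers.
#' @param effGreen,effRed excitation efficiency of the green / red species at
#'   each wavelength (dimensionless). The defaults put the two species on an
#'   equal footing at 1000 nm and plant a 9.05-fold boost of the measured
#'   red-to-green ratio at 1040 nm (red excited more efficiently, green less),
#'   the behaviour expected near the red edge of the green excitation
#'   spectrum.
#' @param bleed green-to-red channel contamination fraction per wavelength;
#'   defaults 0.131 (1000 nm) and 0.146 (1040 nm).
#' @param dark detector offset per channel (a.u.), named green/red.
#' @param noiseScale gain of the shot-like noise: pixel noise is zero-mean
#'   Gaussian with sd = noiseScale * sqrt(fluorescence signal). The dark
#'   offset carries no noise (no read-noise model).
#' @return an \linkS4class{OpticsModel}.
#' @export
opticsModel <- function(wavelengths = c(1000, 1040),
                        effGreen = c(1, 0.45),
                        effRed = c(1, 0.45 * 9.05),
                        bleed = c(0.131, 0.146),
                        dark = c(green = 100, red = 100),
                        noiseScale = 2) {
  new("OpticsModel", wavelengths = wavelengths, effGreen = effGreen,
      effRed = effRed, bleed = bleed, dark = dark, noiseScale = noiseScale)
}

#' Construct a photoconversion model
#'
#' @param slopeActive true ratio gained per mJ/mm^2 per unit activity.
#'   Default 7.9e-4, a stimulated-cortex value for a first-generation
#'   integrator read out at 1000 nm.
#' @param slopeBaseline calcium-independent conversion per mJ/mm^2 (default 0).
#' @return a \linkS4class{ConversionModel}.
#' @export
conversionModel <- function(slopeActive = 7.9e-4, slopeBaseline = 0) {
  new("ConversionModel", slopeActive = slopeActive,
      slopeBaseline = slopeBaseline)
}

#' Construct a drifting-grating stimulus protocol
#'
#' @param nDirections number of drift directions (default 8).
#' @param gratingS grating duration in seconds (default 4).
#' @param grayS gray-screen duration between gratings in seconds (default 8).
#' @param nRepetitions number of stimulation cycles (default 5).
#' @param frameRate acquisition frame rate in Hz (default 30).
#' @param directionOrder optional nRepetitions x nDirections integer matrix of
#'   direction ids (0-based); defaults to sequential order each repetition.
#' @return a \linkS4class{StimulusProtocol}.
#' @export
stimulusProtocol <- function(nDirections = 8L, gratingS = 4, grayS = 8,
                             nRepetitions = 5L, frameRate = 30,
                             directionOrder = NULL) {
  nDirections <- as.integer(nDirections)
  nRepetitions <- as.integer(nRepetitions)
  if (is.null(directionOrder))
    directionOrder <- matrix(rep(0:(nDirections - 1L), nRepetitions),
                             nrow = nRepetitions, byrow = TRUE)
  storage.mode(directionOrder) <- "integer"
  new("StimulusProtocol", nDirections = nDirections, gratingS = gratingS,
      grayS = grayS, nRepetitions = nRepetitions, frameRate = frameRate,
      directionOrder = directionOrder)
}

#' Generate a synthetic cell population
#'
#' Places \code{nCells} non-overlapping disk-shaped cells uniformly inside a
#' frame and assigns each an expression level (per-pixel fluorophore density,
#' log-normal), a relative calcium load ("activity", log-normal with median
#' 1), a region label, and -- for a fixed fraction -- an orientation-tuning
#' preference.
#'
#' @param nCells number of cells (>= 1).
#' @param frameShape integer(2), frame rows and columns.
#' @param fractionTuned fraction of cells given a preferred direction
#'   (\code{round(fractionTuned * nCells)} cells, directions 0..7).
#' @param seed integer seed; identical seed and parameters reproduce the
#'   population bit for bit.
#' @param fractionReference fraction of cells labelled \code{"reference"}
#'   (a non-stimulated control region); the rest are \code{"stimulated"}.
#' @param radiusRange min/max disk radius in pixels.
#' @param expressionMeanlog,expressionSdlog log-normal parameters of the
#'   per-pixel expression density (a.u.).
#' @param activitySdlog log-normal sd (log scale) of activity; meanlog is 0 so
#'   the population median activity is 1 and planted dose-response slopes are
#'   recovered directly from pooled medians.
#' @param maxAttempts placement attempts per cell before giving up.
#' @return a \linkS4class{ScenePopulation} with \code{trueRgr = 0} everywhere.
#' @examples
#' pop <- generatePopulation(50, c(128, 128), fractionTuned = 0.2, seed = 1)
#' sum(!is.na(cells(pop)$preferred_direction))  # 10 tuned cells
#' @export
generatePopulation <- function(nCells, frameShape, fractionTuned = 0,
                               seed, fractionReference = 0,
                               radiusRange = c(3, 5),
                               expressionMeanlog = log(1000),
                               expressionSdlog = 0.25,
                               activitySdlog = 0.5,
                               maxAttempts = 200L) {
  if (nCells < 1) stop("nCells must be >= 1", call. = FALSE)
  if (fractionTuned < 0 || fractionTuned > 1)
    stop("fractionTuned must lie in [0, 1]", call. = FALSE)
  frameShape <- as.integer(frameShape)
  withSeed(childSeed(seed, "population"), function() {
    radius <- stats::runif(nCells, radiusRange[1], radiusRange[2])
    rows <- cols <- numeric(nCells)
    for (i in seq_len(nCells)) {
      placed <- FALSE
      for (a in seq_len(maxAttempts)) {
        r <- stats::runif(1, 1 + radius[i], frameShape[1] - radius[i])
        cc <- stats::runif(1, 1 + radius[i], frameShape[2] - radius[i])
        if (radius[i] + 1 >= frameShape[1] - radius[i] ||
            radius[i] + 1 >= frameShape[2] - radius[i]) break
        if (i == 1L ||
            all(sqrt((rows[seq_len(i - 1)] - r)^2 +
                     (cols[seq_len(i - 1)] - cc)^2) >=
                radius[seq_len(i - 1)] + radius[i])) {
          rows[i] <- r; cols[i] <- cc; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not place ", nCells, " cells in a ",
             paste(frameShape, collapse = " x "),
             " frame: frame too small", call. = FALSE)
    }
    nTuned <- round(fractionTuned * nCells)
    pref <- rep(NA_integer_, nCells)
    depth <- rep(0, nCells)
    if (nTuned > 0) {
      idx <- sample.int(nCells, nTuned)
      pref[idx] <- sample(0:7, nTuned, replace = TRUE)
      depth[idx] <- stats::runif(nTuned, 0.6, 1)
    }
    nRef <- round(fractionReference * nCells)
    region <- rep("stimulated", nCells)
    if (nRef > 0) region[sample.int(nCells, nRef)] <- "reference"
    cellsDf <- data.frame(
      cell_id = seq_len(nCells), row = rows, col = cols, radius = radius,
      expression = stats::rlnorm(nCells, expressionMeanlog, expressionSdlog),
      activity = stats::rlnorm(nCells, 0, activitySdlog),
      region = region, preferred_direction = pref, tuning_depth = depth,
      trueRgr = 0)
    new("ScenePopulation", cells = cellsDf, frameShape = frameShape,
        seed = as.integer(seed))
  })
}

#' Apply a photoconversion event to a population
#'
#' Adds \code{(slopeBaseline + slopeActive * activity) * dose} to every
#' cell's cumulative true red-to-green ratio. Species amounts follow from the
#' ratio under conservation (green decreases as red appears; total green+red
#' per cell is constant), so the true ratio is exactly linear in cumulative
#' dose and additive over events.
#'
#' @param pop a \linkS4class{ScenePopulation}.
#' @param conversion a \linkS4class{ConversionModel}.
#' @param dose light dose of this event, mJ/mm^2 (>= 0).
#' @param activity optional per-cell activity override (defaults to the
#'   population's activity column).
#' @return the updated \linkS4class{ScenePopulation}.
#' @examples
#' pop <- generatePopulation(5, c(64, 64), seed = 1)
#' pop2 <- applyPhotoconversion(pop, conversionModel(7.9e-4, 0), dose = 100)
#' @export
applyPhotoconversion <- function(pop, conversion, dose, activity = NULL) {
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (is.null(activity)) activity <- pop@cells$activity
  if (length(activity) != nCells(pop))
    stop("activity must have one value per cell", call. = FALSE)
  pop@cells$trueRgr <- pop@cells$trueRgr +
    (conversion@slopeBaseline + conversion@slopeActive * activity) * dose
  validObject(pop)
  pop
}

#' Render a two-channel image stack
#'
#' Rasterises the population into green and red frames under the optics
#' model. Per pixel,
#' \deqn{green = dark_g + effGreen(\lambda) P^2 g + \epsilon_g}
#' \deqn{red   = dark_r + effRed(\lambda) P^2 r
#'               + bleed(\lambda) effGreen(\lambda) P^2 g + \epsilon_r}
#' where g and r are the per-pixel green/red species densities, P the laser
#' power (two-photon excitation scales with power squared), and the noise is
#' zero-mean Gaussian with variance proportional to the fluorescence signal
#' (sd = noiseScale * sqrt(signal); background pixels carry only the
#' noiseless dark offset).
#'
#' @param pop a \linkS4class{ScenePopulation}.
#' @param optics an \linkS4class{OpticsModel}; must know \code{wavelength}.
#' @param wavelength excitation wavelength, nm.
#' @param power laser power, mW (> 0).
#' @param nFrames frames to render (noise redrawn per frame).
#' @param seed integer seed for the noise draws.
#' @return a \linkS4class{TwoChannelStack}.
#' @export
renderStack <- function(pop, optics, wavelength, power, nFrames = 1L,
                        seed = 1L) {
  if (power <= 0) stop("power must be > 0", call. = FALSE)
  i <- opticsIndex(optics, wavelength)
  fs <- pop@frameShape
  sp <- speciesAmounts(pop)
  gmap <- matrix(0, fs[1], fs[2])
  rmap <- matrix(0, fs[1], fs[2])
  cl <- pop@cells
  for (k in seq_len(nrow(cl))) {
    px <- diskPixels(cl$row[k], cl$col[k], cl$radius[k], fs)
    gmap[px] <- gmap[px] + sp$green[k]
    rmap[px] <- rmap[px] + sp$red[k]
  }
  p2 <- power^2
  gSig <- optics@effGreen[i] * p2 * gmap
  rSig <- optics@effRed[i] * p2 * rmap + optics@bleed[i] * gSig
  nm <- names(optics@dark)
  darkG <- if (!is.null(nm)) optics@dark[["green"]] else optics@dark[1]
  darkR <- if (!is.null(nm)) optics@dark[["red"]] else optics@dark[2]
  green <- array(0, c(nFrames, fs[1], fs[2]))
  red <- array(0, c(nFrames, fs[1], fs[2]))
  withSeed(childSeed(seed, paste0("render", wavelength)), function() {
    for (f in seq_len(nFrames)) {
      eg <- er <- 0
      if (optics@noiseScale > 0) {
        eg <- stats::rnorm(length(gSig), 0, optics@noiseScale * sqrt(gSig))
        er <- stats::rnorm(length(rSig), 0, optics@noiseScale * sqrt(rSig))
      }
      green[f, , ] <<- darkG + gSig + eg
      red[f, , ] <<- darkR + rSig + er
    }
  })
  new("TwoChannelStack", green = green, red = red, wavelength = wavelength,
      power = power, frameRate = NA_real_,
      metadata = list(seed = seed, nFrames = nFrames,
                      dark = c(green = darkG, red = darkR),
                      bleed = optics@bleed[i]))
}

# Stimulus-locked multiplicative dip of a tuned cell at a given direction:
# 1 at the preferred direction, cosine-squared falloff scaled by the cell's
# tuning depth (depth 1 = fully direction-selective, 0 = untuned response).
tuningProfile <- function(direction, preferred, depth, nDirections = 8L) {
  delta <- abs(direction - preferred)
  delta <- pmin(delta, nDirections - delta)
  (1 - depth) + depth * cos(pi * delta / nDirections)^2
}

#' Simulate dynamic green-channel fluorescence traces
#'
#' Builds per-cell traces for a drifting-grating session. The sensor is a
#' negative indicator: tuned cells show multiplicative fluorescence
#' \emph{decreases} of depth \code{responseAmplitude * tuningProfile}
#' throughout each grating. A single-exponential bleaching envelope
#' multiplies every trace and additive Gaussian noise is applied.
#'
#' @param pop a \linkS4class{ScenePopulation} (its tuned cells respond).
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param responseAmplitude dip depth at the preferred direction (a positive
#'   magnitude; the sign convention is fixed by the negative-indicator
#'   model). Default 0.105.
#' @param bleachHalfLifeS bleaching half-life in seconds (\code{Inf} = off).
#' @param noiseSd additive Gaussian noise sd, expressed as a fraction of each
#'   cell's baseline fluorescence.
#' @param seed integer seed.
#' @return list with \code{traces} (cells x frames matrix), \code{protocol},
#'   \code{onsets} (1-based grating onset frames), \code{directions}
#'   (direction id per trial), and \code{groundTruth} (planted per-cell dip
#'   depths per direction, generator parameters, seed).
#' @export
simulateDynamicTraces <- function(pop, protocol, responseAmplitude = 0.105,
                                  bleachHalfLifeS = Inf, noiseSd = 0,
                                  seed = 1L) {
  if (responseAmplitude < 0)
    stop("responseAmplitude is a magnitude and must be >= 0", call. = FALSE)
  fps <- protocol@frameRate
  trialS <- protocol@gratingS + protocol@grayS
  totalS <- protocol@grayS + nTrials(protocol) * trialS
  nFrames <- round(totalS * fps)
  trialIdx <- seq_len(nTrials(protocol)) - 1L
  onsetS <- protocol@grayS + trialIdx * trialS
  onsets <- round(onsetS * fps) + 1L
  gratingLen <- round(protocol@gratingS * fps)
  directions <- as.integer(t(protocol@directionOrder))
  cl <- pop@cells
  n <- nrow(cl)
  dipTable <- matrix(0, n, protocol@nDirections)
  tuned <- !is.na(cl$preferred_direction)
  for (d in seq_len(protocol@nDirections) - 1L) {
    dipTable[tuned, d + 1L] <- responseAmplitude *
      tuningProfile(d, cl$preferred_direction[tuned],
                    cl$tuning_depth[tuned], protocol@nDirections)
  }
  tsec <- (seq_len(nFrames) - 1L) / fps
  envelope <- if (is.finite(bleachHalfLifeS))
    2^(-tsec / bleachHalfLifeS) else rep(1, nFrames)
  base <- matrix(rep(cl$expression, nFrames), n, nFrames)
  stim <- matrix(1, n, nFrames)
  for (k in seq_along(onsets)) {
    win <- onsets[k]:(onsets[k] + gratingLen - 1L)
    stim[, win] <- 1 - dipTable[, directions[k] + 1L]
  }
  traces <- base * stim * matrix(envelope, n, nFrames, byrow = TRUE)
  if (noiseSd > 0) {
    traces <- withSeed(childSeed(seed, "dynamic"), function()
      traces + matrix(stats::rnorm(n * nFrames, 0, noiseSd), n, nFrames) *
        cl$expression)
  }
  rownames(traces) <- cl$cell_id
  list(traces = traces, protocol = protocol, onsets = onsets,
       directions = directions,
       groundTruth = list(cells = cl, dipTable = dipTable,
                          responseAmplitude = responseAmplitude,
                          bleachHalfLifeS = bleachHalfLifeS,
                          noiseSd = noiseSd, seed = seed))
}

#' Draw region-separated RGR populations at a planted sensitivity index
#'
#' Draws Gaussian red-to-green ratio values for a stimulated and a reference
#' region whose true separation equals \code{dPrime} under the standardised
#' mean difference d' = (mu_stim - mu_ref) / sqrt(0.5 (var_stim + var_ref)).
#'
#' @param n cells per region.
#' @param dPrime planted separation.
#' @param muRef reference-region mean RGR.
#' @param sd common standard deviation.
#' @param seed integer seed.
#' @return list with numeric vectors \code{stimulated} and \code{reference}.
#' @export
simulateRegionRgr <- function(n, dPrime, muRef = 0.1, sd = 0.05, seed = 1L) {
  if (n < 2) stop("need at least 2 cells per region", call. = FALSE)
  withSeed(childSeed(seed, "regions"), function()
    list(stimulated = stats::rnorm(n, muRef + dPrime * sd, sd),
         reference = stats::rnorm(n, muRef, sd)))
}
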