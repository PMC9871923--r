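# Photoconversion arm: bleed-through correction, red-to-green ratio (RGR),
# pooled medians, light dose, zero-intercept dose-response fits,
# dual-wavelength ratios, brightness normalisation, d', group comparisons.

#' Estimate green-to-red bleed-through from pre-conversion data
#'
#' Before any photoconversion the red channel of a green-only sensor carries
#' nothing but contamination from the green emission, so the contamination
#' fraction is estimated as the median over cells of dark-subtracted
#' red/green. Robust to segmentation outliers.
#'
#' @param cellTable cell table of pre-conversion records (one wavelength),
#'   as returned by \code{\link{extractCellSignals}}.
#' @return beta, the contamination fraction (dimensionless scalar).
#' @examples
#' estimateBleedthrough(data.frame(green_dsub = 1000, red_dsub = 131))
#' @export
estimateBleedthrough <- function(cellTable) {
  valid <- cellTable$green_dsub > 0
  if (!any(valid)) stop("no cells with positive green signal", call. = FALSE)
  beta <- stats::median(cellTable$red_dsub[valid] /
                          cellTable$green_dsub[valid])
  if (beta >= 1)
    stop("estimated bleed-through >= 1; check channel assignment",
         call. = FALSE)
  beta
}

#' Compute per-cell red-to-green ratios
#'
#' The corrected ratio per cell is
#' \deqn{RGR = \frac{(red_{raw} - dark_r) - \beta (green_{raw} - dark_g)}
#'                  {green_{raw} - dark_g}}
#' i.e. dark subtraction first, then removal of the bleed-through fraction of
#' the green signal from the red channel. Cells whose green signal does not
#' exceed the dark current are excluded (flagged, with a warning giving the
#' count) rather than clipped.
#'
#' @param cellTable cell table (dark-subtracted columns present).
#' @param beta bleed-through fraction: a scalar, or a named numeric vector
#'   keyed by wavelength (e.g. \code{c("1000" = 0.131, "1040" = 0.146)}).
#' @param keys optional data.frame of grouping keys (mouse, session, ...)
#'   with one row per cell table row, carried through to the output.
#' @return data.frame of valid records with columns of \code{cellTable},
#'   any \code{keys}, and \code{rgr}.
#' @export
computeRgr <- function(cellTable, beta, keys = NULL) {
  b <- if (length(beta) > 1L || !is.null(names(beta))) {
    i <- match(as.character(cellTable$wavelength_nm), names(beta))
    if (anyNA(i))
      stop("no beta supplied for wavelength(s): ",
           paste(unique(cellTable$wavelength_nm[is.na(i)]), collapse = ", "),
           call. = FALSE)
    unname(beta[i])
  } else rep(beta, nrow(cellTable))
  out <- cellTable
  if (!is.null(keys)) out <- cbind(out, keys)
  valid <- out$green_dsub > 0
  if (any(!valid))
    warning(sum(!valid), " cell(s) with green signal <= dark current ",
            "excluded from RGR computation")
  out <- out[valid, , drop = FALSE]
  out$rgr <- (out$red_dsub - b[valid] * out$green_dsub) / out$green_dsub
  rownames(out) <- NULL
  out
}

#' Pool cells and compute median RGR per group
#'
#' Because photoconversion acts on all expressing cells at once, cells are
#' piled across fields of view and the median is taken over the pooled cell
#' population per group -- not a median of per-FOV medians.
#'
#' @param rgrRecords data.frame with an \code{rgr} column.
#' @param groupKeys character vector of grouping columns (default none:
#'   a single pooled median).
#' @return data.frame of group keys plus \code{n_cells} and
#'   \code{median_rgr}; empty groups are omitted with a warning.
#' @export
poolMedianRgr <- function(rgrRecords, groupKeys = character()) {
  if (length(groupKeys) == 0L) {
    if (nrow(rgrRecords) == 0L) stop("no records to pool", call. = FALSE)
    return(data.frame(n_cells = nrow(rgrRecords),
                      median_rgr = stats::median(rgrRecords$rgr)))
  }
  f <- interaction(rgrRecords[groupKeys], drop = FALSE, lex.order = TRUE)
  if (any(tabulate(f) == 0L))
    warning("empty group(s) omitted from pooled medians")
  med <- stats::aggregate(rgrRecords["rgr"], rgrRecords[groupKeys],
                          stats::median)
  cnt <- stats::aggregate(rgrRecords["rgr"], rgrRecords[groupKeys], length)
  out <- med[groupKeys]
  out$n_cells <- cnt$rgr
  out$median_rgr <- med$rgr
  out <- out[do.call(order, out[groupKeys]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Photoconversion light dose
#'
#' Energy per unit area delivered by one illumination epoch:
#' \deqn{dose = \frac{power \times n_{pulses} \times pulse_s}
#'                   {\pi (spot/2)^2} \quad [mJ/mm^2]}
#' with power in mW and the illuminated spot a circle of the given diameter.
#' A full stimulation block of 8 directions x 5 repetitions with one 1-s
#' pulse per grating at 200 mW over a 7-mm spot delivers ~208 mJ/mm^2.
#' Cumulative dose over events is additive.
#'
#' @param powerMw lamp power on sample, mW (> 0).
#' @param nPulses number of pulses (>= 0).
#' @param pulseS single-pulse duration, seconds.
#' @param spotDiameterMm illuminated-spot diameter, mm (> 0).
#' @return dose in mJ/mm^2.
#' @examples
#' lightDose(200, nPulses = 40, pulseS = 1, spotDiameterMm = 7)  # ~207.9
#' @export
lightDose <- function(powerMw, nPulses, pulseS, spotDiameterMm = 7) {
  if (any(powerMw <= 0)) stop("power must be > 0", call. = FALSE)
  if (any(spotDiameterMm <= 0))
    stop("spot diameter must be > 0", call. = FALSE)
  if (any(nPulses < 0) || any(pulseS < 0))
    stop("pulse count and duration must be >= 0", call. = FALSE)
  powerMw * nPulses * pulseS / (pi * (spotDiameterMm / 2)^2)
}

#' Cumulative light dose of an event log
#'
#' @param events data.frame with columns \code{power_mW}, \code{n_pulses},
#'   \code{pulse_s}, \code{spot_mm}.
#' @return data.frame of the events with per-event \code{dose} and
#'   \code{cumulative_dose} (mJ/mm^2).
#' @export
doseFromEvents <- function(events) {
  events$dose <- lightDose(events$power_mW, events$n_pulses,
                           events$pulse_s, events$spot_mm)
  events$cumulative_dose <- cumsum(events$dose)
  events
}

#' Zero-intercept dose-response fit
#'
#' Fits median RGR against cumulative light dose through the origin:
#' slope = sum(x y) / sum(x^2), se = sqrt(RSS / (n-1) / sum(x^2)), and a
#' two-tailed t test of slope = 0 on n-1 degrees of freedom, with the 95\%
#' confidence interval from the same t distribution.
#'
#' @param doses cumulative light doses, mJ/mm^2 (> 0).
#' @param medianRgrs pooled median RGR at each dose.
#' @return a \linkS4class{DoseResponseFit}.
#' @examples
#' fitDoseResponse(c(100, 200), c(0.079, 0.158))  # slope 7.9e-4 exactly
#' @export
fitDoseResponse <- function(doses, medianRgrs) {
  n <- length(doses)
  if (n < 2L || length(medianRgrs) != n)
    stop("need >= 2 paired (dose, median RGR) points", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  if (length(unique(doses)) == 1L)
    warning("all doses identical: slope identifiable but CI fragile")
  sxx <- sum(doses^2)
  slope <- sum(doses * medianRgrs) / sxx
  df <- n - 1L
  rss <- sum((medianRgrs - slope * doses)^2)
  se <- sqrt(rss / df / sxx)
  if (se == 0) {
    tStat <- if (slope == 0) 0 else Inf
    p <- if (slope == 0) 1 else .Machine$double.xmin  # perfect fit
  } else {
    tStat <- slope / se
    p <- 2 * stats::pt(-abs(tStat), df)
  }
  ci <- slope + c(-1, 1) * stats::qt(0.975, df) * se
  new("DoseResponseFit", slope = slope, se = se, ci95 = ci, tStat = tStat,
      pValue = max(p, .Machine$double.xmin), nPoints = as.integer(n),
      df = as.integer(df))
}

#' Dual-wavelength RGR ratios
#'
#' For recordings read out sequentially at two excitation wavelengths, forms
#' the per-recording ratio of pooled median RGR (long over short wavelength)
#' and its mean and sd across recordings. Recordings lacking either
#' wavelength are excluded with a warning.
#'
#' @param summaryTable data.frame with columns \code{recording},
#'   \code{wavelength_nm}, \code{median_rgr} (one row per recording x
#'   wavelength).
#' @param high,low the two wavelengths (nm), default 1040 and 1000.
#' @return list with \code{ratios} (named per recording), \code{mean},
#'   \code{sd}, \code{n}.
#' @export
wavelengthRatio <- function(summaryTable, high = 1040, low = 1000) {
  sp <- split(summaryTable, summaryTable$recording)
  ratios <- vapply(sp, function(df) {
    hi <- df$median_rgr[df$wavelength_nm == high]
    lo <- df$median_rgr[df$wavelength_nm == low]
    if (length(hi) == 1L && length(lo) == 1L) hi / lo else NA_real_
  }, numeric(1))
  if (anyNA(ratios))
    warning(sum(is.na(ratios)), " unpaired recording(s) excluded")
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0L) stop("no paired recordings", call. = FALSE)
  list(ratios = ratios, mean = mean(ratios),
       sd = stats::sd(ratios), n = length(ratios))
}

#' Power-normalised green brightness
#'
#' Two-photon excitation scales with the square of the laser power, so
#' pre-conversion somatic green brightness is compared across recordings as
#' median dark-subtracted green divided by power squared.
#'
#' @param medianGreenDsub median somatic green signal, dark-subtracted (a.u.).
#' @param powerMw excitation power, mW (> 0).
#' @return brightness in a.u./mW^2.
#' @export
normalizedGreenBrightness <- function(medianGreenDsub, powerMw) {
  if (any(powerMw <= 0)) stop("power must be > 0", call. = FALSE)
  medianGreenDsub / powerMw^2
}

#' Sensitivity index d'
#'
#' Standardised separation between the RGR populations of a stimulated and a
#' reference region:
#' \deqn{d' = \frac{\bar x_{stim} - \bar x_{ref}}
#'                 {\sqrt{0.5 (s^2_{stim} + s^2_{ref})}}}
#' with sample variances (n-1 denominator) over pooled cells per region.
#' Antisymmetric under group swap, invariant to a common shift or positive
#' rescaling of both groups.
#'
#' @param stim,ref numeric RGR vectors (>= 2 cells each; at least one group
#'   with nonzero variance).
#' @return list with \code{d_prime}, \code{mean_stim}, \code{mean_ref},
#'   \code{var_stim}, \code{var_ref}, \code{n_stim}, \code{n_ref}.
#' @examples
#' sensitivityIndex(c(2, 3, 4), c(0, 1, 2))$d_prime  # 2
#' @export
sensitivityIndex <- function(stim, ref) {
  if (length(stim) < 2L || length(ref) < 2L)
    stop("need >= 2 cells per group", call. = FALSE)
  vs <- stats::var(stim); vr <- stats::var(ref)
  if (vs == 0 && vr == 0)
    stop("both group variances are zero: d' undefined", call. = FALSE)
  list(d_prime = (mean(stim) - mean(ref)) / sqrt(0.5 * (vs + vr)),
       mean_stim = mean(stim), mean_ref = mean(ref),
       var_stim = vs, var_ref = vr,
       n_stim = length(stim), n_ref = length(ref))
}

#' Two-group comparisons
#'
#' Thin wrapper over the standard tests used for group parity in reports:
#' Wilcoxon rank-sum (exact null enumeration when the smaller group has
#' <= 8 observations and no ties; normal approximation with tie and
#' continuity correction otherwise), two-sample t, and paired t. All
#' two-tailed.
#'
#' @param a,b numeric samples; paired kinds require equal lengths.
#' @param kind one of \code{"ranksum"}, \code{"t_two_sample"},
#'   \code{"t_paired"}.
#' @return list with \code{statistic}, \code{p_value}, \code{method},
#'   \code{degenerate} (TRUE when a paired t on zero-variance differences
#'   could not be computed; then p is NaN).
#' @export
compareGroups <- function(a, b, kind = c("ranksum", "t_two_sample",
                                         "t_paired")) {
  kind <- match.arg(kind)
  if (kind == "ranksum") {
    if (length(a) < 1L || length(b) < 1L)
      stop("both samples must be non-empty", call. = FALSE)
    exact <- min(length(a), length(b)) <= 8L &&
      !any(duplicated(c(a, b)))
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method = if (exact) "ranksum (exact)"
                         else "ranksum (normal approximation)",
                degenerate = FALSE))
  }
  if (kind == "t_paired" && length(a) != length(b))
    stop("paired test requires equal lengths", call. = FALSE)
  if (length(a) < 2L || length(b) < 2L)
    stop("t tests require >= 2 observations per sample", call. = FALSE)
  ht <- tryCatch(
    stats::t.test(a, b, paired = (kind == "t_paired")),
    error = function(e) NULL)
  if (!is.null(ht) && is.nan(ht$p.value)) ht <- NULL
  if (is.null(ht)) {
    warning("degenerate t test (zero variance); p set to NaN")
    return(list(statistic = NaN, p_value = NaN, method = kind,
                degenerate = TRUE))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = kind, degenerate = FALSE)
}
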