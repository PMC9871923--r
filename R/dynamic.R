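# Dynamic-recording arm: bleach correction, trial segmentation, the
# lowest-quartile response statistic of the negative indicator, delta-F/F0,
# and ANOVA-based tuned/oriented cell classification.

#' Divisive polynomial bleach correction
#'
#' Fits a degree-7 polynomial p(t) to the whole trace by least squares and
#' returns \code{raw(t) * p(t1) / p(t)}, i.e. a divisive correction anchored
#' at the fitted value of the first timepoint, which preserves the initial
#' brightness scale and the ratio semantics of delta-F/F0. The fit must stay
#' strictly positive over the recording; otherwise the trace is unusable and
#' an error is raised.
#'
#' @param trace numeric fluorescence trace (length > 8, the degrees of
#'   freedom a degree-7 fit needs).
#' @param degree polynomial degree (default 7).
#' @return the corrected trace.
#' @export
correctBleaching <- function(trace, degree = 7L) {
  n <- length(trace)
  if (n <= degree + 1L)
    stop("trace too short for a degree-", degree, " fit", call. = FALSE)
  t <- seq_len(n)
  fit <- stats::lm(trace ~ stats::poly(t, degree))
  p <- stats::fitted(fit)
  if (any(p <= 0))
    stop("bleach fit crosses zero inside the recording; trace unusable",
         call. = FALSE)
  unname(trace * p[1L] / p)
}

#' Trial windows of a drifting-grating recording
#'
#' For each trial of the protocol, computes a baseline window covering the
#' 0.66 s immediately before grating onset and a response window covering
#' the grating. Frame counts are \code{round(seconds * frameRate)} (20
#' baseline and 120 response frames at 30 Hz). Trials whose baseline would
#' start before the first frame, or whose response window would overrun the
#' trace, are dropped with a warning.
#'
#' @param nFrames length of the trace in frames.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param onsets optional 1-based grating-onset frames; derived from the
#'   protocol timing (initial gray period, then grating+gray cycles) when
#'   missing.
#' @param baselineS baseline duration before onset, seconds (default 0.66).
#' @return data.frame with one row per kept trial: \code{trial},
#'   \code{direction}, \code{base_start}, \code{base_end}, \code{resp_start},
#'   \code{resp_end}.
#' @export
segmentTrials <- function(nFrames, protocol, onsets = NULL,
                          baselineS = 0.66) {
  fps <- protocol@frameRate
  nt <- nTrials(protocol)
  if (is.null(onsets)) {
    trialS <- protocol@gratingS + protocol@grayS
    onsets <- round((protocol@grayS + (seq_len(nt) - 1L) * trialS) * fps) + 1L
  }
  baseLen <- round(baselineS * fps)
  respLen <- round(protocol@gratingS * fps)
  if (max(onsets) + respLen - 1L > nFrames)
    stop("protocol does not fit inside the recording (",
         nFrames, " frames)", call. = FALSE)
  directions <- as.integer(t(protocol@directionOrder))
  out <- data.frame(trial = seq_len(nt), direction = directions,
                    base_start = onsets - baseLen, base_end = onsets - 1L,
                    resp_start = onsets, resp_end = onsets + respLen - 1L)
  bad <- out$base_start < 1L
  if (any(bad)) {
    warning(sum(bad), " trial(s) without enough pre-onset frames dropped")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Per-trial responses of a negative indicator
#'
#' For each trial window: \code{f_base} is the plain mean over the baseline
#' window; \code{f_resp} is the mean of the k smallest response-window
#' samples with \code{k = round(0.25 * window length)} (k = 30 at 30 Hz for
#' a 4-s grating) -- the lowest-quartile statistic that targets the
#' fluorescence \emph{dip} of a negative indicator; and
#' \code{dff = (f_resp - f_base) / f_base}, negative on responsive trials.
#' Note the statistic is order-biased: under pure noise its expectation is
#' below the baseline mean, so dff is negatively biased on null trials.
#'
#' @param trace (bleach-corrected) fluorescence trace.
#' @param windows trial windows from \code{\link{segmentTrials}}.
#' @param lowestFraction fraction of smallest samples averaged (default
#'   0.25). Setting this to 1 gives the plain-mean diagnostic estimator.
#' @return data.frame with \code{trial}, \code{direction}, \code{f_base},
#'   \code{f_resp}, \code{dff}, \code{valid} (FALSE when f_base <= 0).
#' @export
computeResponses <- function(trace, windows, lowestFraction = 0.25) {
  nt <- nrow(windows)
  fBase <- fResp <- numeric(nt)
  for (i in seq_len(nt)) {
    fBase[i] <- mean(trace[windows$base_start[i]:windows$base_end[i]])
    w <- trace[windows$resp_start[i]:windows$resp_end[i]]
    k <- max(1L, round(lowestFraction * length(w)))
    fResp[i] <- mean(sort(w, method = "radix")[seq_len(k)])
  }
  valid <- fBase > 0
  if (any(!valid))
    warning(sum(!valid), " trial(s) with non-positive baseline flagged ",
            "invalid")
  data.frame(trial = windows$trial, direction = windows$direction,
             f_base = fBase, f_resp = fResp,
             dff = ifelse(valid, (fResp - fBase) / fBase, NA_real_),
             valid = valid)
}

# One-way ANOVA p-value with graceful degeneracy handling.
anovaP <- function(values, groups) {
  ok <- tryCatch(
    stats::oneway.test(values ~ groups, var.equal = TRUE)$p.value,
    error = function(e) NA_real_)
  if (is.nan(ok)) NA_real_ else ok
}

#' Classify a cell as tuned
#'
#' One-way ANOVA over the trial baseline and response values of one recorded
#' movie (40 f_base and 40 f_resp values under the default 8 directions x 5
#' repetitions). The default mode compares the two groups baseline vs
#' response; \code{mode = "direction_condition"} instead groups the 80
#' values by direction x condition (16 groups of 5). Cells with p below
#' \code{alpha} are tuned.
#'
#' @param responses data.frame from \code{\link{computeResponses}}.
#' @param alpha significance threshold (default 0.01).
#' @param mode \code{"two_group"} (default) or \code{"direction_condition"}.
#' @return list with \code{p_tuned}, \code{is_tuned}, \code{degenerate}
#'   (TRUE when within-group variance vanished and no p could be computed;
#'   then the cell is not tuned).
#' @export
classifyTuned <- function(responses, alpha = 0.01,
                          mode = c("two_group", "direction_condition")) {
  mode <- match.arg(mode)
  resp <- responses[responses$valid, , drop = FALSE]
  vals <- c(resp$f_base, resp$f_resp)
  groups <- if (mode == "two_group")
    factor(rep(c("base", "resp"), each = nrow(resp)))
  else
    interaction(rep(resp$direction, 2L),
                rep(c("base", "resp"), each = nrow(resp)))
  p <- anovaP(vals, groups)
  list(p_tuned = p, is_tuned = !is.na(p) && p < alpha,
       degenerate = is.na(p))
}

#' Classify a tuned cell as oriented
#'
#' Only evaluated for tuned cells: one-way ANOVA among the 40 response
#' values grouped by drift direction (8 groups of 5). Cells with p below
#' \code{alpha} are oriented. The preferred direction is the direction with
#' the most negative mean dff (deepest dip), reported for every cell.
#'
#' @param responses data.frame from \code{\link{computeResponses}}.
#' @param isTuned logical from \code{\link{classifyTuned}}; when FALSE the
#'   ANOVA is skipped and the cell is not oriented.
#' @param alpha significance threshold (default 0.01).
#' @return list with \code{p_oriented}, \code{is_oriented},
#'   \code{preferred_direction}, \code{peak_amplitude} (mean dff at the
#'   preferred direction, signed), \code{degenerate}.
#' @export
classifyOriented <- function(responses, isTuned, alpha = 0.01) {
  resp <- responses[responses$valid, , drop = FALSE]
  meanDff <- tapply(resp$dff, resp$direction, mean)
  pref <- as.integer(names(meanDff)[which.min(meanDff)])
  peak <- unname(min(meanDff))
  if (!isTuned)
    return(list(p_oriented = NA_real_, is_oriented = FALSE,
                preferred_direction = pref, peak_amplitude = peak,
                degenerate = FALSE))
  p <- anovaP(resp$f_resp, factor(resp$direction))
  list(p_oriented = p, is_oriented = !is.na(p) && p < alpha,
       preferred_direction = pref, peak_amplitude = peak,
       degenerate = is.na(p))
}

#' Analyse one cell's dynamic trace
#'
#' Bleach correction, trial segmentation, response extraction, and the
#' tuned/oriented classification gates, in the order the quantities are
#' defined: correction precedes response extraction, and the oriented test
#' runs only on tuned cells.
#'
#' @param trace raw fluorescence trace.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param onsets optional grating-onset frames (see
#'   \code{\link{segmentTrials}}).
#' @param alpha significance threshold for both gates (default 0.01).
#' @param mode tuned-test grouping mode (see \code{\link{classifyTuned}}).
#' @param lowestFraction response statistic fraction (see
#'   \code{\link{computeResponses}}).
#' @param bleachDegree polynomial degree of the bleach fit (default 7).
#' @return one-row data.frame: \code{p_tuned}, \code{is_tuned},
#'   \code{p_oriented}, \code{is_oriented}, \code{preferred_direction},
#'   \code{peak_amplitude}.
#' @export
analyzeDynamicCell <- function(trace, protocol, onsets = NULL, alpha = 0.01,
                               mode = "two_group", lowestFraction = 0.25,
                               bleachDegree = 7L) {
  corrected <- correctBleaching(trace, degree = bleachDegree)
  windows <- segmentTrials(length(trace), protocol, onsets = onsets)
  responses <- computeResponses(corrected, windows,
                                lowestFraction = lowestFraction)
  tuned <- classifyTuned(responses, alpha = alpha, mode = mode)
  oriented <- classifyOriented(responses, tuned$is_tuned, alpha = alpha)
  data.frame(p_tuned = tuned$p_tuned, is_tuned = tuned$is_tuned,
             p_oriented = oriented$p_oriented,
             is_oriented = oriented$is_oriented,
             preferred_direction = oriented$preferred_direction,
             peak_amplitude = oriented$peak_amplitude)
}

#' Analyse a cells-x-frames trace matrix
#'
#' @param traces numeric matrix, one row per cell.
#' @inheritParams analyzeDynamicCell
#' @return data.frame with one row per cell (\code{cell_id} from rownames)
#'   and the columns of \code{\link{analyzeDynamicCell}}.
#' @export
analyzeDynamicRecording <- function(traces, protocol, onsets = NULL,
                                    alpha = 0.01, mode = "two_group",
                                    lowestFraction = 0.25,
                                    bleachDegree = 7L) {
  rows <- lapply(seq_len(nrow(traces)), function(i)
    analyzeDynamicCell(traces[i, ], protocol, onsets = onsets, alpha = alpha,
                       mode = mode, lowestFraction = lowestFraction,
                       bleachDegree = bleachDegree))
  out <- do.call(rbind, rows)
  out <- cbind(cell_id = if (!is.null(rownames(traces)))
    rownames(traces) else as.character(seq_len(nrow(traces))), out)
  rownames(out) <- NULL
  out
}

#' Population summary of a dynamic recording
#'
#' Fractions of tuned and oriented cells, the per-cell peak response
#' amplitudes (mean dff at the preferred direction; negative for a negative
#' indicator), their median, and the pooled empirical CDF.
#'
#' @param tuningResults data.frame from \code{\link{analyzeDynamicRecording}}.
#' @return list with \code{n_cells}, \code{fraction_tuned},
#'   \code{fraction_oriented}, \code{median_peak_amplitude},
#'   \code{peak_amplitudes} (sorted), \code{cdf} (an \code{ecdf} function).
#' @export
populationSummary <- function(tuningResults) {
  n <- nrow(tuningResults)
  if (n < 1L) stop("no cells", call. = FALSE)
  peaks <- sort(tuningResults$peak_amplitude)
  list(n_cells = n,
       fraction_tuned = mean(tuningResults$is_tuned),
       fraction_oriented = mean(tuningResults$is_oriented),
       median_peak_amplitude = stats::median(peaks),
       peak_amplitudes = peaks,
       cdf = stats::ecdf(peaks))
}
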