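# ROI extraction: image stacks + integer label masks -> per-cell,
# per-channel fluorescence with dark current removed.

#' Estimate dark current from a recording
#'
#' The detector offset of each channel is estimated as the 0.2 percentile
#' (0.002 quantile) of that channel's pixel distribution, pooled over every
#' pixel of every frame. Quantiles use linear interpolation between order
#' statistics (\code{stats::quantile} type 7) so the estimate is
#' bit-reproducible.
#'
#' @param stack a \linkS4class{TwoChannelStack}.
#' @return list with numeric scalars \code{green} and \code{red} (a.u.).
#' @examples
#' pop <- generatePopulation(5, c(64, 64), seed = 1)
#' st <- renderStack(pop, opticsModel(noiseScale = 0), 1000, power = 1)
#' estimateDarkCurrent(st)
#' @export
estimateDarkCurrent <- function(stack) {
  g <- as.numeric(stack@green)
  r <- as.numeric(stack@red)
  if (length(g) == 0L) stop("empty stack", call. = FALSE)
  list(green = unname(stats::quantile(g, 0.002, type = 7)),
       red = unname(stats::quantile(r, 0.002, type = 7)))
}

#' Extract per-cell channel signals
#'
#' For every label in the mask, averages each channel over the cell's pixels
#' and over frames (time-averaged snapshot readout), and stores both the raw
#' and dark-subtracted means. The mean is unweighted over the footprint; no
#' neuropil annulus is subtracted.
#'
#' @param stack a \linkS4class{TwoChannelStack}.
#' @param mask integer matrix, same shape as one frame; 0 = background,
#'   k >= 1 = cell k.
#' @param dark optional dark-current list as returned by
#'   \code{\link{estimateDarkCurrent}}; estimated from \code{stack} when
#'   missing.
#' @param fovId identifier stored in the \code{fov_id} column.
#' @return a cell table: data.frame with columns \code{fov_id},
#'   \code{cell_id}, \code{wavelength_nm}, \code{power_mW}, \code{n_pixels},
#'   \code{green_raw}, \code{red_raw}, \code{green_dsub}, \code{red_dsub}.
#'   An all-background mask yields a zero-row table.
#' @export
extractCellSignals <- function(stack, mask, dark = NULL, fovId = 1L) {
  d <- dim(stack@green)
  if (!identical(as.integer(dim(mask)), as.integer(d[2:3])))
    stop("mask shape must match the stack frames", call. = FALSE)
  if (is.null(dark)) dark <- estimateDarkCurrent(stack)
  # time-average each channel first: mean over frames, then over footprint
  gMean <- apply(stack@green, c(2, 3), mean)
  rMean <- apply(stack@red, c(2, 3), mean)
  idx <- which(mask > 0)
  tmpl <- data.frame(fov_id = integer(), cell_id = integer(),
                     wavelength_nm = numeric(), power_mW = numeric(),
                     n_pixels = integer(), green_raw = numeric(),
                     red_raw = numeric(), green_dsub = numeric(),
                     red_dsub = numeric())
  if (length(idx) == 0L) return(tmpl)
  lab <- factor(mask[idx])
  greenRaw <- tapply(gMean[idx], lab, mean)
  redRaw <- tapply(rMean[idx], lab, mean)
  nPix <- as.integer(table(lab))
  data.frame(fov_id = fovId,
             cell_id = as.integer(levels(lab)),
             wavelength_nm = stack@wavelength,
             power_mW = stack@power,
             n_pixels = nPix,
             green_raw = as.numeric(greenRaw),
             red_raw = as.numeric(redRaw),
             green_dsub = as.numeric(greenRaw) - dark$green,
             red_dsub = as.numeric(redRaw) - dark$red,
             row.names = NULL)
}

#' Label mask for a synthetic population
#'
#' Paints each cell's true disk footprint with its id; exact by construction
#' (stands in for automated segmentation, which this package does not do).
#'
#' @param pop a \linkS4class{ScenePopulation}.
#' @return integer matrix of the population's frame shape.
#' @export
labelSynthetic <- function(pop) {
  fs <- pop@frameShape
  mask <- matrix(0L, fs[1], fs[2])
  cl <- pop@cells
  for (k in seq_len(nrow(cl))) {
    px <- diskPixels(cl$row[k], cl$col[k], cl$radius[k], fs)
    mask[px] <- cl$cell_id[k]
  }
  mask
}

#' Rigid integer-pixel shift of a mask
#'
#' Optional registration plumbing: shifts a label mask by whole pixels,
#' filling exposed borders with background.
#'
#' @param mask integer matrix.
#' @param dRow,dCol shift in rows / columns (integer, may be negative).
#' @return the shifted mask.
#' @export
shiftMask <- function(mask, dRow = 0L, dCol = 0L) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  rs <- seq_len(nrow(mask)); cs <- seq_len(ncol(mask))
  rOk <- rs - dRow >= 1L & rs - dRow <= nrow(mask)
  cOk <- cs - dCol >= 1L & cs - dCol <= ncol(mask)
  out[rs[rOk], cs[cOk]] <- mask[rs[rOk] - dRow, cs[cOk] - dCol]
  out
}
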