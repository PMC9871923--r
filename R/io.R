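# File interfaces: multi-page 16-bit TIFF stacks with a JSON metadata
# sidecar, integer-TIFF label masks, and CSV cell tables.

#' Write a two-channel stack as TIFF + JSON sidecar
#'
#' Each channel is written as one multi-page 16-bit TIFF
#' (\code{<prefix>_green.tif}, \code{<prefix>_red.tif}); pixel values are
#' scaled into [0, 1] by a per-file scale recorded, with the acquisition
#' metadata, in \code{<prefix>_meta.json}.
#'
#' @param stack a \linkS4class{TwoChannelStack}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
writeTwoChannelStack <- function(stack, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeOne <- function(arr, path) {
    lo <- min(arr); hi <- max(arr)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(arr)[1]),
                    function(f) (arr[f, , ] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    c(offset = lo, scale = scale)
  }
  pg <- file.path(dir, paste0(prefix, "_green.tif"))
  pr <- file.path(dir, paste0(prefix, "_red.tif"))
  sg <- writeOne(stack@green, pg)
  sr <- writeOne(stack@red, pr)
  meta <- list(layout = "one multi-page TIFF per channel",
               n_frames = dim(stack@green)[1],
               shape = dim(stack@green)[2:3],
               wavelength_nm = stack@wavelength,
               power_mW = stack@power,
               frame_rate_hz = if (is.finite(stack@frameRate))
                 stack@frameRate else NULL,
               green = as.list(sg), red = as.list(sr),
               extra = stack@metadata)
  pm <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, pm, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(green = pg, red = pr, meta = pm))
}

#' Read a two-channel stack written by \code{\link{writeTwoChannelStack}}
#'
#' @param dir directory holding the files.
#' @param prefix file-name prefix used at write time.
#' @return a \linkS4class{TwoChannelStack} (16-bit quantisation applies).
#' @export
readTwoChannelStack <- function(dir, prefix = "stack") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  readOne <- function(path, sc) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, c(length(pages), dim(pages[[1]])))
    for (f in seq_along(pages))
      arr[f, , ] <- pages[[f]] * sc$scale + sc$offset
    arr
  }
  g <- readOne(file.path(dir, paste0(prefix, "_green.tif")), meta$green)
  r <- readOne(file.path(dir, paste0(prefix, "_red.tif")), meta$red)
  new("TwoChannelStack", green = g, red = r,
      wavelength = meta$wavelength_nm, power = meta$power_mW,
      frameRate = if (length(meta$frame_rate_hz) == 1L &&
                      is.numeric(meta$frame_rate_hz))
                    as.numeric(meta$frame_rate_hz) else NA_real_,
      metadata = as.list(meta$extra))
}

#' Write / read an integer label mask as 16-bit TIFF
#'
#' @param mask integer matrix (labels < 65536).
#' @param path output .tif path.
#' @return \code{readLabelMask} returns the integer matrix.
#' @export
writeLabelMask <- function(mask, path) {
  if (max(mask) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write / read a cell table as CSV
#'
#' @param cellTable data.frame from \code{\link{extractCellSignals}}.
#' @param path .csv path.
#' @return \code{readCellTable} returns the data.frame.
#' @export
writeCellTable <- function(cellTable, path) {
  utils::write.csv(cellTable, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(path) {
  utils::read.csv(path)
}
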