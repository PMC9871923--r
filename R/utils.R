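# internal helpers

# Deterministic child seed: fan one user seed out to independent per-stage
# streams so pipeline stages are individually reproducible. Knuth
# multiplicative hashing on the tag, folded into 31-bit range.
childSeed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Pixel coordinates of a disk footprint, clipped to the frame.
diskPixels <- function(row, col, radius, frameShape) {
  r0 <- max(1L, floor(row - radius)); r1 <- min(frameShape[1], ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(frameShape[2], ceiling(col + radius))
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  keep <- (rr - row)^2 + (cc - col)^2 <= radius^2
  cbind(row = rr[keep], col = cc[keep])
}

# Species amounts implied by a population's cumulative true ratio.
# Conversion, not creation: green + red = expression for every cell.
speciesAmounts <- function(pop) {
  cl <- pop@cells
  r <- cl$trueRgr
  data.frame(cell_id = cl$cell_id,
             green = cl$expression / (1 + r),
             red = cl$expression * r / (1 + r))
}

# Index of a wavelength in an OpticsModel, with a clear error.
opticsIndex <- function(optics, wavelength) {
  i <- match(wavelength, optics@wavelengths)
  if (is.na(i))
    stop("optics model has no entry for wavelength ", wavelength,
         " nm (knows: ", paste(optics@wavelengths, collapse = ", "), ")",
         call. = FALSE)
  i
}
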