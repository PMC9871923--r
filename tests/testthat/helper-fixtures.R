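# Shared fixtures, built in code.

noiseFreeOptics <- function(...) opticsModel(noiseScale = 0, ...)

# A small rendered scene with its mask and ground truth, reused across files.
smallScene <- function(nCells = 20, seed = 1, noise = 0, wavelength = 1000,
                       power = 1, nFrames = 1, fractionTuned = 0) {
  pop <- generatePopulation(nCells, c(128, 128),
                            fractionTuned = fractionTuned, seed = seed)
  opt <- opticsModel(noiseScale = noise)
  st <- renderStack(pop, opt, wavelength, power, nFrames,
                    seed = seed + 1000L)
  list(pop = pop, optics = opt, stack = st, mask = labelSynthetic(pop))
}

# Closed-form per-cell channel means implied by the render equation
# (noise-free): used as the oracle for extraction tests.
renderOracle <- function(pop, optics, wavelength, power) {
  i <- match(wavelength, optics@wavelengths)
  cl <- cells(pop)
  r <- cl$trueRgr
  gdens <- cl$expression / (1 + r)
  rdens <- cl$expression * r / (1 + r)
  p2 <- power^2
  g <- optics@effGreen[i] * p2 * gdens
  data.frame(cell_id = cl$cell_id,
             green_dsub = g,
             red_dsub = optics@effRed[i] * p2 * rdens + optics@bleed[i] * g)
}

# Exact two-sided rank-sum p-value by enumeration of all rank assignments.
ranksumEnumP <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  ranks <- rank(pooled)
  wObs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2, function(ix) sum(ranks[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(ws - mu) >= abs(wObs - mu))
}
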