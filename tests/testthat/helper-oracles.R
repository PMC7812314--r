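# Independent oracles and small fixture builders used across the suite.

# Brute-force elemental isotope convolution of the averagine composition:
# exponentiates each element's isotope polynomial and convolves across
# elements. Returns relative intensities (max = 1) of the first nPeaks
# aggregated isotope peaks.
convolutionEnvelope <- function(mass, nPeaks = 6) {
  counts <- round(c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773,
                    S = 0.0417) * mass / 111.1254)
  iso <- list(C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
              N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
              S = c(0.9499, 0.0075, 0.0425))
  lim <- nPeaks + 4
  polymul <- function(a, b) {
    out <- convolve(a, rev(b), type = "open")
    out[seq_len(min(length(out), lim))]
  }
  total <- 1
  for (el in names(counts)) {
    p <- 1; b <- iso[[el]]; e <- counts[[el]]
    while (e > 0) {
      if (e %% 2 == 1) p <- polymul(p, b)
      b <- polymul(b, b)
      e <- e %/% 2
    }
    total <- polymul(total, p)
  }
  (total / max(total))[seq_len(nPeaks)]
}

# All-pairs Mann-Whitney AUC with ties counted one half.
bruteForceAuc <- function(inValues, outValues) {
  wins <- 0
  for (a in inValues) {
    wins <- wins + sum(a > outValues) + 0.5 * sum(a == outValues)
  }
  wins / (length(inValues) * length(outValues))
}

# Exact upper-tail hypergeometric probability by direct enumeration with
# binomial coefficients (independent of stats::phyper).
enumerationHyper <- function(k, K, n, N) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
}

# Small two-group peptide table with explicit intensities.
makePeptideTable <- function(ctrl, dis, mass = NULL, protein = NULL,
                             uniqueFlag = TRUE) {
  n <- nrow(ctrl)
  tab <- data.frame(
    sequence = sprintf("PEP%03dK", seq_len(n)),
    mass = mass %||% seq(800, by = 7.3, length.out = n),
    protein = protein %||% sprintf("P%03d", seq_len(n)),
    unique = rep_len(uniqueFlag, n))
  cc <- paste0("Intensity WT_", seq_len(ncol(ctrl)))
  dc <- paste0("Intensity AROM_", seq_len(ncol(dis)))
  tab[cc] <- as.data.frame(ctrl)
  tab[dc] <- as.data.frame(dis)
  attr(tab, "controlCols") <- cc
  attr(tab, "diseaseCols") <- dc
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny IMS dataset on an nr x nc grid from a list of planted peaks:
# peaks is a data.frame(mz, intensity) rendered identically in the pixels
# given by `where` (logical or index vector per peak list).
makeTinyIms <- function(nr = 4, nc = 4, pixelPeaks, massRange = c(600, 3200)) {
  coords <- expand.grid(x = seq_len(nc) - 1L, y = seq_len(nr) - 1L)
  stopifnot(length(pixelPeaks) == nrow(coords))
  imsDataset(coords = coords, peaks = pixelPeaks, massRange = massRange)
}

# Uniform empty peak list
emptyPeaks <- function() data.frame(mz = numeric(0), intensity = numeric(0))
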