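#' @importFrom stats rnorm runif
NULL

# Average isotope spacing for singly charged peptides (averagine), Da.
ISOTOPE_SPACING <- 1.00235

# Mass of a proton, Da; added to neutral peptide masses to obtain MH+.
PROTON_MASS <- 1.007276

# Summed A+1 isotope abundance of the averagine residue
# C4.9384 H7.7583 N1.3577 O1.4773 S0.0417 per 111.1254 Da, i.e. the Poisson
# rate of heavy-isotope substitutions per Da of peptide mass.
AVERAGINE_LAMBDA_PER_DA <- 5.359e-4

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

#' Averagine isotope envelope
#'
#' Predicts the relative isotope intensity pattern of a peptide from its
#' monoisotopic mass alone, using the averagine model: the number of
#' heavy-isotope substitutions is approximated as Poisson with rate
#' proportional to mass (5.359e-4 per Da, the summed A+1 abundance of the
#' averagine residue). Intensities are normalized so the maximum is 1;
#' isotope peaks are spaced by the average spacing 1.00235 Da.
#'
#' @param monoMass neutral (or MH+) monoisotopic mass in Da; must be > 0.
#' @param nPeaks number of isotope peaks to return, >= 1 (default 4).
#' @return data.frame with columns \code{offset} (m/z offset of isotope k,
#'   equal to k * 1.00235 for k = 0..nPeaks-1) and \code{intensity}
#'   (relative, max 1).
#' @examples
#' averagineEnvelope(1000)
#' averagineEnvelope(3000, nPeaks = 6)
#' @export
averagineEnvelope <- function(monoMass, nPeaks = 4L) {
  stopIfNot(is.numeric(monoMass) && length(monoMass) == 1L && monoMass > 0,
            "monoMass must be a single positive number")
  stopIfNot(nPeaks >= 1, "nPeaks must be >= 1")
  nPeaks <- as.integer(nPeaks)
  k <- seq_len(nPeaks) - 1L
  lambda <- AVERAGINE_LAMBDA_PER_DA * monoMass
  rel <- stats::dpois(k, lambda)
  data.frame(offset = k * ISOTOPE_SPACING, intensity = rel / max(rel))
}

#' Construct an IMSDataset
#'
#' Builds a validated [IMSDataset-class] from raw per-pixel peak lists.
#' Unsorted peak lists are sorted by m/z and duplicate m/z values within a
#' pixel are summed, so the class invariant (strictly increasing m/z) holds
#' for any input.
#'
#' @param coords data.frame with integer columns \code{x}, \code{y}
#'   (0-based; x = column, y = row, origin top-left).
#' @param peaks list of data.frames with numeric columns \code{mz},
#'   \code{intensity}, one per pixel (same order as \code{coords} rows).
#' @param massRange numeric(2) declared mass range in Da.
#' @param spatialResolution pixel pitch in micrometres (metadata only;
#'   default 25).
#' @param normalized whether the intensities are already TIC-normalized.
#' @return an [IMSDataset-class].
#' @export
imsDataset <- function(coords, peaks, massRange,
                       spatialResolution = 25, normalized = FALSE) {
  coords <- data.frame(x = as.integer(coords$x), y = as.integer(coords$y))
  peaks <- lapply(peaks, function(p) {
    p <- data.frame(mz = as.numeric(p$mz), intensity = as.numeric(p$intensity))
    if (nrow(p) == 0L) return(p)
    if (is.unsorted(p$mz)) p <- p[order(p$mz), , drop = FALSE]
    if (anyDuplicated(p$mz)) {
      grp <- cumsum(c(TRUE, diff(p$mz) > 0))
      p <- data.frame(
        mz = p$mz[!duplicated(grp)],
        intensity = as.numeric(tapply(p$intensity, grp, sum)))
    }
    rownames(p) <- NULL
    p
  })
  new("IMSDataset", coords = coords, peaks = peaks,
      massRange = as.numeric(massRange),
      spatialResolution = as.numeric(spatialResolution),
      normalized = isTRUE(normalized))
}
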