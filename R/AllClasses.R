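#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums t
#' @importClassesFrom Matrix dgCMatrix
NULL

setOldClass("hclust")

#' IMSDataset: per-pixel centroided imaging mass spectrometry data
#'
#' Container for a MALDI imaging dataset: one centroided peak list per
#' pixel, pixel grid coordinates, and acquisition metadata. Pixel
#' coordinates are 0-based with \code{x} the column and \code{y} the row,
#' origin top-left (imaging convention). Peak lists are sorted by m/z,
#' strictly increasing; duplicate m/z values within a pixel are summed on
#' construction.
#'
#' @slot coords data.frame with integer columns \code{x}, \code{y}; one row
#'   per pixel, rows unique.
#' @slot peaks list of data.frames, one per pixel, each with numeric
#'   columns \code{mz} (Da) and \code{intensity} (arbitrary units).
#' @slot massRange numeric(2), declared acquisition mass range in Da. All
#'   peaks lie within this range +/- 0.5 Da.
#' @slot spatialResolution numeric(1), pixel pitch in micrometres
#'   (metadata only).
#' @slot normalized logical(1), whether TIC normalization has been applied.
#'
#' @seealso [imsDataset()], [readIms()], [ticNormalize()], [binSpectra()]
#' @export
setClass("IMSDataset",
  representation(
    coords = "data.frame",
    peaks = "list",
    massRange = "numeric",
    spatialResolution = "numeric",
    normalized = "logical"
  )
)

setValidity("IMSDataset", function(object) {
  msg <- character()
  cd <- object@coords
  if (!all(c("x", "y") %in% names(cd)))
    msg <- c(msg, "coords must have columns 'x' and 'y'")
  if (nrow(cd) != length(object@peaks))
    msg <- c(msg, "one peak list per pixel required")
  if (anyDuplicated(paste(cd$x, cd$y, sep = "_")))
    msg <- c(msg, "pixel coordinates must be unique")
  mr <- object@massRange
  if (length(mr) != 2L || any(!is.finite(mr)) || mr[1] >= mr[2] || any(mr <= 0))
    msg <- c(msg, "massRange must be two positive finite values, low < high")
  npk <- vapply(object@peaks, nrow, integer(1))
  if (length(npk) && sum(npk) < 1L)
    msg <- c(msg, "dataset must contain at least one peak in at least one pixel")
  ok <- vapply(object@peaks, function(p) {
    (nrow(p) == 0L) ||
      (!is.unsorted(p$mz, strictly = TRUE) &&
         all(p$mz >= mr[1] - 0.5) && all(p$mz <= mr[2] + 0.5))
  }, logical(1))
  if (!all(ok))
    msg <- c(msg, sprintf(
      "peak lists must be strictly increasing in m/z and within [%.3f, %.3f] Da (pixel %d violates)",
      mr[1] - 0.5, mr[2] + 0.5, which(!ok)[1]))
  if (length(msg)) msg else TRUE
})

#' BinnedMatrix: pixels-by-bins intensity matrix on a uniform m/z axis
#'
#' Result of binning an [IMSDataset-class] onto uniform half-open bins
#' \code{[lo, lo + w)}. Stored sparse; most bins are empty for centroided
#' peptide data.
#'
#' @slot mat a \code{\link[Matrix]{dgCMatrix-class}}, pixels x bins,
#'   non-negative.
#' @slot binCenters numeric, bin center m/z values in Da.
#' @slot binWidth numeric(1), bin width w in Da.
#' @slot massRange numeric(2), the binned mass range.
#' @slot coords data.frame of pixel coordinates, aligned to matrix rows.
#'
#' @seealso [binSpectra()], [segmentPixels()], [discriminativeMz()]
#' @export
setClass("BinnedMatrix",
  representation(
    mat = "dgCMatrix",
    binCenters = "numeric",
    binWidth = "numeric",
    massRange = "numeric",
    coords = "data.frame"
  )
)

setValidity("BinnedMatrix", function(object) {
  msg <- character()
  nb <- as.integer(ceiling(round((object@massRange[2] - object@massRange[1]) /
                                   object@binWidth, 9)))
  if (ncol(object@mat) != nb)
    msg <- c(msg, sprintf("bin count %d != ceil(range/width) = %d",
                          ncol(object@mat), nb))
  if (length(object@binCenters) != ncol(object@mat))
    msg <- c(msg, "binCenters length must equal bin count")
  if (length(object@mat@x) && min(object@mat@x) < 0)
    msg <- c(msg, "matrix entries must be non-negative")
  if (nrow(object@coords) != nrow(object@mat))
    msg <- c(msg, "coords must have one row per pixel")
  if (length(msg)) msg else TRUE
})

#' SegmentationResult: hierarchical segmentation of pixel spectra
#'
#' A dendrogram over (possibly subsampled) pixels plus a mapping that
#' extends cluster labels to every pixel. Cutting the tree at any k in
#' [1, number of tree pixels] yields exactly k non-empty clusters via
#' [labelsAt()].
#'
#' @slot tree an object of class \code{hclust} built on the sampled pixels.
#' @slot coords data.frame of all pixel coordinates.
#' @slot sampleIdx integer indices (into pixels) used to build the tree.
#' @slot nearestSample for every pixel, the index (into \code{sampleIdx})
#'   of its nearest sampled pixel in spectral space; identity when no
#'   subsampling occurred.
#' @slot linkage character(1), linkage criterion name.
#' @slot distance character(1), distance name.
#'
#' @seealso [segmentPixels()], [labelsAt()]
#' @export
setClass("SegmentationResult",
  representation(
    tree = "hclust",
    coords = "data.frame",
    sampleIdx = "integer",
    nearestSample = "integer",
    linkage = "character",
    distance = "character"
  )
)

setValidity("SegmentationResult", function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (length(object@nearestSample) != n)
    msg <- c(msg, "nearestSample must map every pixel")
  if (any(object@nearestSample < 1L) ||
      any(object@nearestSample > length(object@sampleIdx)))
    msg <- c(msg, "nearestSample indices out of range")
  if (length(msg)) msg else TRUE
})

#' MonoisotopicList: deisotoped monoisotopic masses per cluster
#'
#' Output of cluster-wise deisotoping: one entry per inferred isotope
#' envelope, carrying the monoisotopic m/z, the cluster it was observed in,
#' the summed envelope intensity and the member peak m/z values. Peaks that
#' did not pass the peak-set support filter are kept in the
#' \code{unassigned} slot so that peak conservation can be audited:
#' every input peak is either a member of exactly one entry or unassigned.
#'
#' @slot entries data.frame with columns \code{mono_mz}, \code{cluster},
#'   \code{intensity}, \code{n_member_peaks} and a list column
#'   \code{members} of member peak m/z vectors.
#' @slot unassigned data.frame with columns \code{cluster}, \code{mz},
#'   \code{intensity}: low-support peaks treated as noise.
#'
#' @seealso [deisotopeCluster()], [deisotopeAll()], [exportMonoList()]
#' @export
setClass("MonoisotopicList",
  representation(
    entries = "data.frame",
    unassigned = "data.frame"
  )
)

setValidity("MonoisotopicList", function(object) {
  msg <- character()
  need <- c("mono_mz", "cluster", "intensity", "n_member_peaks", "members")
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@entries)) {
    nm <- vapply(object@entries$members, length, integer(1))
    if (!identical(nm, as.integer(object@entries$n_member_peaks)))
      msg <- c(msg, "n_member_peaks must equal length of members")
  }
  if (length(msg)) msg else TRUE
})
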