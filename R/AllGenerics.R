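#' Pixel coordinates of an object
#'
#' @param x an [IMSDataset-class], [BinnedMatrix-class] or
#'   [SegmentationResult-class].
#' @return data.frame with 0-based integer columns \code{x}, \code{y}.
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' Per-pixel peak lists
#'
#' @param x an [IMSDataset-class].
#' @return list of data.frames with columns \code{mz}, \code{intensity}.
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' Number of pixels
#'
#' @param x an object with a pixel grid.
#' @return integer(1).
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' Declared acquisition mass range
#'
#' @param x an [IMSDataset-class] or [BinnedMatrix-class].
#' @return numeric(2), low and high bound in Da.
#' @export
setGeneric("massRange", function(x) standardGeneric("massRange"))

#' Cluster labels at a requested cluster count
#'
#' Cuts the segmentation dendrogram so that exactly \code{k} non-empty
#' clusters cover all pixels; pixels not used for tree construction (when
#' the tree was built on a subsample) inherit the label of their nearest
#' sampled pixel.
#'
#' @param x a [SegmentationResult-class].
#' @param k integer cluster count, \code{1 <= k <= } number of tree pixels.
#' @return integer vector of cluster ids in \code{1:k}, one per pixel.
#' @export
setGeneric("labelsAt", function(x, k) standardGeneric("labelsAt"))

#' Bin intensity matrix
#'
#' @param x a [BinnedMatrix-class].
#' @return sparse pixels x bins \code{dgCMatrix}.
#' @export
setGeneric("binMatrix", function(x) standardGeneric("binMatrix"))

#' Bin centers
#'
#' @param x a [BinnedMatrix-class].
#' @return numeric vector of bin center m/z values (Da).
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' Deisotoped monoisotopic entries
#'
#' @param x a [MonoisotopicList-class].
#' @return data.frame of monoisotopic entries.
#' @export
setGeneric("monoEntries", function(x) standardGeneric("monoEntries"))

#' Peaks left unassigned during deisotoping
#'
#' @param x a [MonoisotopicList-class].
#' @return data.frame of unassigned (noise-like) peaks.
#' @export
setGeneric("unassignedPeaks", function(x) standardGeneric("unassignedPeaks"))
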