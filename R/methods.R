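#' @describeIn pixelCoords pixel grid of an IMS dataset
#' @export
setMethod("pixelCoords", "IMSDataset", function(x) x@coords)

#' @describeIn pixelCoords pixel grid of a binned matrix
#' @export
setMethod("pixelCoords", "BinnedMatrix", function(x) x@coords)

#' @describeIn pixelCoords pixel grid of a segmentation
#' @export
setMethod("pixelCoords", "SegmentationResult", function(x) x@coords)

#' @describeIn spectra per-pixel centroided peak lists
#' @export
setMethod("spectra", "IMSDataset", function(x) x@peaks)

#' @describeIn nPixels pixel count of an IMS dataset
#' @export
setMethod("nPixels", "IMSDataset", function(x) nrow(x@coords))

#' @describeIn nPixels pixel count of a binned matrix
#' @export
setMethod("nPixels", "BinnedMatrix", function(x) nrow(x@mat))

#' @describeIn nPixels pixel count of a segmentation
#' @export
setMethod("nPixels", "SegmentationResult", function(x) nrow(x@coords))

#' @describeIn massRange mass range of an IMS dataset
#' @export
setMethod("massRange", "IMSDataset", function(x) x@massRange)

#' @describeIn massRange mass range of a binned matrix
#' @export
setMethod("massRange", "BinnedMatrix", function(x) x@massRange)

#' @describeIn binMatrix sparse intensity matrix
#' @export
setMethod("binMatrix", "BinnedMatrix", function(x) x@mat)

#' @describeIn binCenters bin center m/z values
#' @export
setMethod("binCenters", "BinnedMatrix", function(x) x@binCenters)

#' @describeIn labelsAt cut the dendrogram at k clusters
#' @export
setMethod("labelsAt", "SegmentationResult", function(x, k) {
  k <- as.integer(k)
  nTree <- length(x@sampleIdx)
  if (k < 1L || k > nTree)
    stop("k must be between 1 and the number of tree pixels (", nTree, ")")
  treeLabels <- stats::cutree(x@tree, k = k)
  as.integer(treeLabels[x@nearestSample])
})

#' @describeIn monoEntries deisotoped entries
#' @export
setMethod("monoEntries", "MonoisotopicList", function(x) x@entries)

#' @describeIn unassignedPeaks unassigned noise-like peaks
#' @export
setMethod("unassignedPeaks", "MonoisotopicList", function(x) x@unassigned)

setMethod("show", "IMSDataset", function(object) {
  npk <- vapply(object@peaks, nrow, integer(1))
  cat("IMSDataset with", nrow(object@coords), "pixels\n")
  cat(sprintf("  mass range: %.1f - %.1f Da | spatial resolution: %g um\n",
              object@massRange[1], object@massRange[2],
              object@spatialResolution))
  cat(sprintf("  peaks per pixel: median %d (total %d) | TIC-normalized: %s\n",
              as.integer(stats::median(npk)), sum(npk), object@normalized))
})

setMethod("show", "BinnedMatrix", function(object) {
  cat("BinnedMatrix:", nrow(object@mat), "pixels x", ncol(object@mat),
      "bins (width", object@binWidth, "Da)\n")
  cat(sprintf("  non-empty bins: %d | total intensity: %.4g\n",
              sum(Matrix::colSums(object@mat) > 0), sum(object@mat)))
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult over", nrow(object@coords), "pixels\n")
  cat(sprintf("  linkage: %s | distance: %s | tree built on %d pixels\n",
              object@linkage, object@distance, length(object@sampleIdx)))
})

setMethod("show", "MonoisotopicList", function(object) {
  cat("MonoisotopicList with", nrow(object@entries), "monoisotopic entries",
      "(", nrow(object@unassigned), "unassigned peaks )\n")
  if (nrow(object@entries)) {
    cl <- table(object@entries$cluster)
    cat("  entries per cluster:",
        paste(sprintf("%s: %d", names(cl), as.integer(cl)), collapse = ", "),
        "\n")
  }
})
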