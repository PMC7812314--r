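# Squared Euclidean distances via BLAS (gram matrix), clipped at zero.
euclideanDistMatrix <- function(X) {
  G <- tcrossprod(X)
  sq <- diag(G)
  D2 <- outer(sq, sq, "+") - 2 * G
  D2[D2 < 0] <- 0
  sqrt(D2)
}

#' Unbiased hierarchical segmentation of pixel spectra
#'
#' Clusters pixels by their binned spectra with agglomerative hierarchical
#' clustering (default: Ward linkage on Euclidean distances of
#' square-root-transformed intensities). For large pixel counts the tree
#' is built on a seeded random subsample and the remaining pixels are
#' assigned the label of their nearest sampled pixel in spectral space;
#' exact mode is used whenever the pixel count does not exceed
#' \code{maxPixels}.
#'
#' @param bm a [BinnedMatrix-class] (typically from TIC-normalized data).
#' @param k optional cluster count to validate up front (\code{2 <= k <=}
#'   pixel count); the returned object supports any cut via [labelsAt()].
#' @param linkage linkage criterion passed to [stats::hclust()]
#'   (default \code{"ward.D2"}).
#' @param distance distance name; only \code{"euclidean"} is supported.
#' @param sqrtTransform apply a square-root variance-stabilizing transform
#'   to intensities before distance computation (default TRUE).
#' @param maxPixels largest pixel count clustered exactly; above this a
#'   random subsample of \code{maxPixels} pixels builds the tree
#'   (default 5000).
#' @param seed seed for the subsampling step (ignored in exact mode).
#' @return a [SegmentationResult-class].
#' @export
segmentPixels <- function(bm, k = NULL, linkage = "ward.D2",
                          distance = "euclidean", sqrtTransform = TRUE,
                          maxPixels = 5000L, seed = 1L) {
  stopIfNot(is(bm, "BinnedMatrix"), "bm must be a BinnedMatrix")
  n <- nrow(bm@mat)
  if (!is.null(k)) {
    if (k < 2L) stop("k must be >= 2", call. = FALSE)
    if (k > n) stop("k (", k, ") exceeds pixel count (", n, ")",
                    call. = FALSE)
  }
  if (distance != "euclidean")
    stop("only euclidean distance is supported", call. = FALSE)
  keep <- which(Matrix::colSums(bm@mat) > 0)
  X <- as.matrix(bm@mat[, keep, drop = FALSE])
  if (sqrtTransform) X <- sqrt(X)

  if (n > maxPixels) {
    set.seed(seed)
    sampleIdx <- sort(sample.int(n, maxPixels))
  } else {
    sampleIdx <- seq_len(n)
  }
  Xs <- X[sampleIdx, , drop = FALSE]
  D <- euclideanDistMatrix(Xs)
  tree <- stats::hclust(stats::as.dist(D), method = linkage)

  if (length(sampleIdx) < n) {
    # nearest sampled pixel in spectral space, blockwise to bound memory
    nearest <- integer(n)
    nearest[sampleIdx] <- seq_along(sampleIdx)
    rest <- setdiff(seq_len(n), sampleIdx)
    sqS <- rowSums(Xs^2)
    blk <- 2000L
    for (start in seq(1L, length(rest), by = blk)) {
      ii <- rest[start:min(start + blk - 1L, length(rest))]
      G <- tcrossprod(X[ii, , drop = FALSE], Xs)
      D2 <- outer(rowSums(X[ii, , drop = FALSE]^2), sqS, "+") - 2 * G
      nearest[ii] <- max.col(-D2, ties.method = "first")
    }
  } else {
    nearest <- seq_len(n)
  }
  new("SegmentationResult", tree = tree, coords = bm@coords,
      sampleIdx = as.integer(sampleIdx), nearestSample = as.integer(nearest),
      linkage = linkage, distance = distance)
}

# Mann-Whitney AUC (ties counted 1/2) of values[inGroup] vs values[!inGroup]
aucStatistic <- function(values, inGroup) {
  n1 <- sum(inGroup)
  n2 <- length(values) - n1
  r <- rank(values)
  (sum(r[inGroup]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Discriminative m/z values of a cluster (ROC)
#'
#' For every non-empty bin, computes the area under the receiver operating
#' characteristic curve for in-cluster vs out-of-cluster per-pixel
#' intensities (the probability that a random in-cluster pixel has higher
#' intensity than a random out-of-cluster pixel; ties counted one half).
#' The orientation is one-sided: only cluster-enriched bins (high AUC) are
#' markers, bins with AUC < 0.5 are not flipped. The list is filtered at
#' \code{aucThreshold} and sorted by AUC descending, ties broken by
#' ascending m/z.
#'
#' @param bm a [BinnedMatrix-class].
#' @param labels integer cluster labels per pixel (from [labelsAt()]).
#' @param cluster the cluster id to characterize.
#' @param aucThreshold minimum AUC to report (default 0.7).
#' @return data.frame with columns \code{mz} (bin center), \code{cluster},
#'   \code{auc}, \code{bin} (bin index).
#' @export
discriminativeMz <- function(bm, labels, cluster, aucThreshold = 0.7) {
  stopIfNot(is(bm, "BinnedMatrix"), "bm must be a BinnedMatrix")
  stopIfNot(length(labels) == nrow(bm@mat),
            "labels must have one entry per pixel")
  inC <- labels == cluster
  if (!any(inC)) stop("cluster ", cluster, " is empty", call. = FALSE)
  if (all(inC)) stop("cluster complement is empty", call. = FALSE)
  keep <- which(Matrix::colSums(bm@mat) > 0)
  X <- as.matrix(bm@mat[, keep, drop = FALSE])
  auc <- apply(X, 2L, aucStatistic, inGroup = inC)
  out <- data.frame(mz = bm@binCenters[keep], cluster = cluster, auc = auc,
                    bin = keep)
  out <- out[out$auc >= aucThreshold, , drop = FALSE]
  out <- out[order(-out$auc, out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a discriminative mass list
#'
#' Writes the (m/z, cluster, auc) table as tab-separated text, the input
#' dialect consumed by the mass-matching stage.
#'
#' @param massList data.frame from [discriminativeMz()]; must be non-empty.
#' @param path output path.
#' @return the path, invisibly.
#' @export
exportMassList <- function(massList, path) {
  if (is.null(massList) || nrow(massList) == 0L)
    stop("refusing to export an empty mass list", call. = FALSE)
  utils::write.table(massList[, c("mz", "cluster", "auc")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a discriminative mass list written by [exportMassList()]
#'
#' @param path input path.
#' @return data.frame with columns \code{mz}, \code{cluster}, \code{auc}.
#' @export
readMassList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path)
}

#' Export a segmentation label map as a tabular grid
#'
#' @param seg a [SegmentationResult-class].
#' @param k cluster count for the cut.
#' @param path output path (tab-separated: x, y, cluster).
#' @return the path, invisibly.
#' @export
exportLabelMap <- function(seg, k, path) {
  lab <- labelsAt(seg, k)
  utils::write.table(
    data.frame(x = seg@coords$x, y = seg@coords$y, cluster = lab),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
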