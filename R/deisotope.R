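#' Spatial co-localization of two ion images
#'
#' Pearson correlation of per-pixel intensities of two ion-image vectors
#' over the same pixel set. Used as the co-localization criterion during
#' deisotoping: all isotopes of one peptide share the same spatial
#' distribution, so a candidate isotope peak must correlate with its
#' monoisotopic anchor.
#'
#' @param imageA,imageB numeric vectors of per-pixel intensities over the
#'   same pixels; each must have nonzero variance.
#' @return correlation in [-1, 1].
#' @export
colocalization <- function(imageA, imageB) {
  stopIfNot(length(imageA) == length(imageB),
            "ion images must cover the same pixel set")
  if (stats::sd(imageA) == 0 || stats::sd(imageB) == 0)
    stop("undefined correlation: zero-variance ion image", call. = FALSE)
  stats::cor(imageA, imageB)
}

# Gap-based grouping cannot separate two centroid clouds whose tails
# bridge the gap threshold; any group wider than maxWidth is split
# recursively at the deepest internal minimum of a kernel density over its
# m/z values. mz must be sorted; grp must be non-decreasing group ids.
splitWideClouds <- function(mz, grp, maxWidth) {
  splitOne <- function(idx) {
    x <- mz[idx]
    if (x[length(x)] - x[1] <= maxWidth || length(x) < 4L) return(list(idx))
    d <- stats::density(x, bw = maxWidth / 10, n = 256)
    inner <- which(diff(sign(diff(d$y))) == 2) + 1L
    inner <- inner[d$x[inner] > x[1] & d$x[inner] < x[length(x)]]
    if (!length(inner)) return(list(idx))
    cut <- d$x[inner[which.min(d$y[inner])]]
    left <- idx[x <= cut]
    right <- idx[x > cut]
    if (!length(left) || !length(right)) return(list(idx))
    c(splitOne(left), splitOne(right))
  }
  pieces <- unlist(lapply(split(seq_along(mz), grp), splitOne),
                   recursive = FALSE)
  out <- integer(length(mz))
  for (i in seq_along(pieces)) out[pieces[[i]]] <- i
  # renumber in m/z order (pieces are contiguous and ordered)
  match(out, unique(out))
}

# correlation that treats zero-variance images as "not co-localized"
colocOrNegInf <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
  stats::cor(a, b)
}

#' Build the peak set of a spatial cluster
#'
#' Pools the peaks of all in-cluster pixels, groups them into aligned
#' peaks by splitting the sorted pooled m/z values at gaps larger than
#' \code{gapTol}, and attaches to each aligned peak its intensity-weighted
#' mean m/z, mean in-cluster intensity and its ion-image vector over the
#' cluster's pixels. Aligned peaks supported by fewer than
#' \code{minPixelFraction} of the cluster's pixels are set aside as
#' unassigned noise (not deisotoped).
#'
#' @param ds an [IMSDataset-class].
#' @param labels integer cluster labels per pixel.
#' @param cluster cluster id.
#' @param gapTol gap (Da) that separates two aligned peaks (default 0.05).
#' @param minPixelFraction minimum fraction of cluster pixels an aligned
#'   peak must appear in (default 0.05).
#' @param maxCloudWidth m/z spread (Da) beyond which a pooled peak group is
#'   treated as several unresolved peaks and split at the deepest density
#'   minimum (default 0.25, about twice the spread a single centroid
#'   cloud shows at the stated +/-0.1 Da accuracy).
#' @return list of class \code{ClusterPeakSet}: \code{cluster},
#'   \code{peaks} (data.frame mz, intensity, support, sorted by m/z),
#'   \code{images} (peaks x cluster-pixels matrix), \code{pixels}
#'   (pixel indices), \code{noise} (data.frame of low-support peaks).
#' @export
clusterPeakSet <- function(ds, labels, cluster, gapTol = 0.05,
                           minPixelFraction = 0.05, maxCloudWidth = 0.25) {
  stopIfNot(is(ds, "IMSDataset"), "ds must be an IMSDataset")
  pix <- which(labels == cluster)
  stopIfNot(length(pix) > 0, "cluster ", cluster, " is empty")
  npk <- vapply(ds@peaks[pix], nrow, integer(1))
  pixLocal <- rep(seq_along(pix), npk)
  mz <- unlist(lapply(ds@peaks[pix], `[[`, "mz"), use.names = FALSE)
  inten <- unlist(lapply(ds@peaks[pix], `[[`, "intensity"), use.names = FALSE)
  if (!length(mz)) {
    return(structure(list(cluster = cluster,
                          peaks = data.frame(mz = numeric(0),
                                             intensity = numeric(0),
                                             support = integer(0)),
                          images = matrix(0, 0, length(pix)),
                          pixels = pix,
                          noise = data.frame(mz = numeric(0),
                                             intensity = numeric(0))),
                     class = "ClusterPeakSet"))
  }
  ord <- order(mz)
  mz <- mz[ord]; inten <- inten[ord]; pixLocal <- pixLocal[ord]
  grp <- cumsum(c(1, as.integer(diff(mz) > gapTol)))
  grp <- splitWideClouds(mz, grp, maxWidth = maxCloudWidth)
  nGrp <- grp[length(grp)]
  wSum <- as.numeric(tapply(inten, grp, sum))
  mzMean <- as.numeric(tapply(mz * inten, grp, sum)) / wSum
  support <- as.integer(tapply(pixLocal, grp, function(i) length(unique(i))))
  img <- as.matrix(Matrix::sparseMatrix(i = grp, j = pixLocal, x = inten,
                                        dims = c(nGrp, length(pix))))
  lowSupport <- support < minPixelFraction * length(pix)
  peaks <- data.frame(mz = mzMean, intensity = wSum / length(pix),
                      support = support)
  structure(list(cluster = cluster,
                 peaks = peaks[!lowSupport, , drop = FALSE],
                 images = img[!lowSupport, , drop = FALSE],
                 pixels = pix,
                 noise = peaks[lowSupport, c("mz", "intensity"), drop = FALSE]),
            class = "ClusterPeakSet")
}

# all unconsumed candidate indices for isotope k of an anchor, with the
# three admission tests (mass spacing, averagine intensity ratio, spatial
# co-localization); returns indices ordered by closeness in m/z
envelopeCandidates <- function(cps, consumed, anchor, k, rel, mzTol,
                               intensityTol, colocMin) {
  expectMz <- cps$peaks$mz[anchor] + k * ISOTOPE_SPACING
  expectInt <- cps$peaks$intensity[anchor] * rel[k + 1L] / rel[1L]
  j <- which(!consumed & abs(cps$peaks$mz - expectMz) <= mzTol)
  if (!length(j)) return(integer(0))
  okInt <- cps$peaks$intensity[j] >= (1 - intensityTol) * expectInt &
    cps$peaks$intensity[j] <= (1 + intensityTol) * expectInt
  j <- j[okInt]
  if (!length(j)) return(integer(0))
  okCo <- vapply(j, function(jj)
    colocOrNegInf(cps$images[jj, ], cps$images[anchor, ]) >= colocMin,
    logical(1))
  j <- j[okCo]
  j[order(abs(cps$peaks$mz[j] - expectMz))]
}

#' Deisotope one cluster's peak set
#'
#' Greedy envelope growth ascending in m/z: each unconsumed peak anchors a
#' new envelope; its k-th isotope member must (i) lie within \code{mzTol}
#' of mono + k * 1.00235 Da, (ii) have intensity within a factor
#' (1 +/- \code{intensityTol}) of the averagine-expected intensity for
#' isotope k at the anchor mass, and (iii) have ion-image correlation of
#' at least \code{colocMin} with the anchor. Consumed peaks are not
#' reused; peaks that start no envelope and join none become singleton
#' monoisotopic entries. An exhaustive mode searches all valid envelope
#' partitions and keeps one maximizing the number of explained (member)
#' peaks; it is exponential and intended for small instances and testing.
#'
#' @param cps a [clusterPeakSet()] result.
#' @param mzTol m/z tolerance in Da (default 0.15).
#' @param intensityTol relative intensity tolerance (default 0.5, i.e.
#'   within +/-50\% of the averagine expectation).
#' @param colocMin minimum ion-image correlation (default 0.7).
#' @param maxIso maximum isotope index tried per envelope (default 5).
#' @param method \code{"greedy"} (default) or \code{"exhaustive"}.
#' @return a [MonoisotopicList-class] for this cluster; the cluster's
#'   low-support noise peaks appear in its \code{unassigned} slot.
#' @export
deisotopeCluster <- function(cps, mzTol = 0.15, intensityTol = 0.5,
                             colocMin = 0.7, maxIso = 5L,
                             method = c("greedy", "exhaustive")) {
  stopIfNot(inherits(cps, "ClusterPeakSet"), "cps must be a ClusterPeakSet")
  stopIfNot(mzTol > 0 && intensityTol > 0, "tolerances must be positive")
  stopIfNot(colocMin > 0 && colocMin <= 1, "colocMin must be in (0, 1]")
  method <- match.arg(method)
  n <- nrow(cps$peaks)
  emptyEntries <- data.frame(mono_mz = numeric(0), cluster = integer(0),
                             intensity = numeric(0),
                             n_member_peaks = integer(0))
  emptyEntries$members <- list()
  noise <- if (nrow(cps$noise)) {
    data.frame(cluster = cps$cluster, mz = cps$noise$mz,
               intensity = cps$noise$intensity)
  } else data.frame(cluster = integer(0), mz = numeric(0),
                    intensity = numeric(0))
  if (n == 0L)
    return(new("MonoisotopicList", entries = emptyEntries, unassigned = noise))

  relCache <- function(mono) averagineEnvelope(mono, maxIso + 1L)$intensity

  envelopes <- if (method == "greedy") {
    consumed <- rep(FALSE, n)
    out <- list()
    for (i in order(cps$peaks$mz)) {
      if (consumed[i]) next
      consumed[i] <- TRUE
      members <- i
      rel <- relCache(cps$peaks$mz[i])
      for (k in seq_len(maxIso)) {
        cand <- envelopeCandidates(cps, consumed, i, k, rel, mzTol,
                                   intensityTol, colocMin)
        if (!length(cand)) break
        consumed[cand[1L]] <- TRUE
        members <- c(members, cand[1L])
      }
      out[[length(out) + 1L]] <- members
    }
    out
  } else {
    deisotopeExhaustive(cps, mzTol, intensityTol, colocMin, maxIso, relCache)
  }

  entries <- data.frame(
    mono_mz = vapply(envelopes, function(m) cps$peaks$mz[m[1L]], numeric(1)),
    cluster = cps$cluster,
    intensity = vapply(envelopes, function(m) sum(cps$peaks$intensity[m]),
                       numeric(1)),
    n_member_peaks = vapply(envelopes, length, integer(1)))
  entries$members <- lapply(envelopes, function(m) cps$peaks$mz[m])
  entries <- entries[order(entries$mono_mz), , drop = FALSE]
  rownames(entries) <- NULL
  new("MonoisotopicList", entries = entries, unassigned = noise)
}

# exhaustive search over valid envelope partitions, maximizing the number
# of explained member peaks; exponential, small instances only
deisotopeExhaustive <- function(cps, mzTol, intensityTol, colocMin, maxIso,
                                relCache) {
  n <- nrow(cps$peaks)
  ordIdx <- order(cps$peaks$mz)
  best <- NULL
  bestScore <- -1L

  extend <- function(anchor, members, consumed, k, rel) {
    # returns list of complete member vectors for this anchor
    res <- list(members)
    if (k > maxIso) return(res)
    cand <- envelopeCandidates(cps, consumed, anchor, k, rel, mzTol,
                               intensityTol, colocMin)
    for (j in cand) {
      consumed2 <- consumed
      consumed2[j] <- TRUE
      res <- c(res, extend(anchor, c(members, j), consumed2, k + 1L, rel))
    }
    res
  }
  recurse <- function(consumed, envs, explained) {
    i <- ordIdx[!consumed[ordIdx]][1L]
    if (is.na(i)) {
      if (explained > bestScore) {
        bestScore <<- explained
        best <<- envs
      }
      return(invisible())
    }
    consumed[i] <- TRUE
    rel <- relCache(cps$peaks$mz[i])
    for (members in extend(i, i, consumed, 1L, rel)) {
      consumed2 <- consumed
      consumed2[members] <- TRUE
      recurse(consumed2, c(envs, list(members)),
              explained + length(members) - 1L)
    }
  }
  recurse(rep(FALSE, n), list(), 0L)
  best
}

#' Deisotope every cluster of a segmentation
#'
#' Builds each cluster's peak set, deisotopes it, and pools the per-cluster
#' monoisotopic lists into a unique list deduplicated at \code{dedupTol}.
#'
#' @param ds an [IMSDataset-class].
#' @param labels integer cluster labels covering all pixels (e.g. from
#'   [labelsAt()]).
#' @param mzTol,intensityTol,colocMin,maxIso see [deisotopeCluster()].
#' @param gapTol,minPixelFraction,maxCloudWidth see [clusterPeakSet()].
#' @param dedupTol pooled masses closer than this (Da) count as one unique
#'   deisotoped peptide (default 0.1).
#' @return list with \code{monoList} (a [MonoisotopicList-class] over all
#'   clusters), \code{pooled} (data.frame of unique monoisotopic masses
#'   with occurrence counts) and \code{counts} (per-cluster entry counts).
#' @export
deisotopeAll <- function(ds, labels, mzTol = 0.15, intensityTol = 0.5,
                         colocMin = 0.7, maxIso = 5L, gapTol = 0.05,
                         minPixelFraction = 0.05, maxCloudWidth = 0.25,
                         dedupTol = 0.1) {
  stopIfNot(is(ds, "IMSDataset"), "ds must be an IMSDataset")
  stopIfNot(length(labels) == nPixels(ds), "labels must cover all pixels")
  clusters <- sort(unique(labels))
  allEntries <- list(); allNoise <- list()
  for (cl in clusters) {
    cps <- clusterPeakSet(ds, labels, cl, gapTol = gapTol,
                          minPixelFraction = minPixelFraction,
                          maxCloudWidth = maxCloudWidth)
    ml <- deisotopeCluster(cps, mzTol = mzTol, intensityTol = intensityTol,
                           colocMin = colocMin, maxIso = maxIso)
    allEntries[[as.character(cl)]] <- ml@entries
    allNoise[[as.character(cl)]] <- ml@unassigned
  }
  entries <- do.call(rbind, allEntries)
  rownames(entries) <- NULL
  noise <- do.call(rbind, allNoise)
  rownames(noise) <- NULL
  mono <- new("MonoisotopicList", entries = entries, unassigned = noise)

  pooledMz <- sort(entries$mono_mz)
  pooled <- if (length(pooledMz)) {
    grp <- cumsum(c(1, as.integer(diff(pooledMz) > dedupTol)))
    data.frame(mono_mz = as.numeric(tapply(pooledMz, grp, mean)),
               n_clusters = as.integer(tapply(pooledMz, grp, length)))
  } else data.frame(mono_mz = numeric(0), n_clusters = integer(0))
  counts <- vapply(allEntries, nrow, integer(1))
  list(monoList = mono, pooled = pooled, counts = counts)
}

#' Export a monoisotopic list as tab-separated text
#'
#' Columns: mono_mz, cluster, intensity, n_member_peaks — the input
#' dialect for the mass-matching stage.
#'
#' @param mono a [MonoisotopicList-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
exportMonoList <- function(mono, path) {
  stopIfNot(is(mono, "MonoisotopicList"), "mono must be a MonoisotopicList")
  utils::write.table(
    mono@entries[, c("mono_mz", "cluster", "intensity", "n_member_peaks")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a monoisotopic list written by [exportMonoList()] (or hand-curated)
#'
#' @param path input path (tab-separated with at least mono_mz and cluster
#'   columns).
#' @return a data.frame.
#' @export
readMonoList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path)
}
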