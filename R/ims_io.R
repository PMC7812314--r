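#' Read an IMS dataset from imzML or a tabular dump
#'
#' @param path input path: a .imzML file (with companion .ibd) or a
#'   tab-separated dump with columns \code{pixel_x}, \code{pixel_y},
#'   \code{mz}, \code{intensity}.
#' @param format \code{"imzml"} or \code{"tabular"}; default guessed from
#'   the file extension.
#' @param massRange optional numeric(2) declared mass range (tabular only;
#'   defaults to floor/ceiling of the observed m/z range).
#' @return an [IMSDataset-class]; unsorted peak lists are sorted and
#'   duplicate m/z within a pixel summed.
#' @seealso [writeIms()]
#' @export
readIms <- function(path, format = c("auto", "imzml", "tabular"),
                    massRange = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.imzML$", path, ignore.case = TRUE)) "imzml"
              else "tabular"
  if (format == "imzml") return(readImzml(path))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- readLines(path, n = 1L)
  spatialResolution <- 25
  normalized <- FALSE
  if (startsWith(meta, "#")) {
    kv <- strsplit(sub("^#\\s*", "", meta), "\t")[[1]]
    if (length(kv) >= 3 && kv[1] == "massRange" && is.null(massRange))
      massRange <- as.numeric(kv[2:3])
    if (length(kv) >= 4) spatialResolution <- as.numeric(kv[4])
    if (length(kv) >= 5) normalized <- identical(kv[5], "TRUE")
  }
  tab <- tryCatch(
    utils::read.delim(path, check.names = FALSE, comment.char = "#"),
    error = function(e) stop("malformed tabular IMS file (", path, "): ",
                             conditionMessage(e), call. = FALSE))
  need <- c("pixel_x", "pixel_y", "mz", "intensity")
  if (!all(need %in% names(tab)))
    stop("tabular IMS file must have columns: ", paste(need, collapse = ", "),
         " (line 1 of ", path, ")", call. = FALSE)
  if (nrow(tab) == 0L) stop("no spectra in tabular IMS file: ", path,
                            call. = FALSE)
  key <- paste(tab$pixel_x, tab$pixel_y, sep = "_")
  keys <- unique(key)
  idx <- split(seq_len(nrow(tab)), factor(key, levels = keys))
  coords <- data.frame(
    x = tab$pixel_x[!duplicated(key)],
    y = tab$pixel_y[!duplicated(key)])
  peaks <- lapply(idx, function(i)
    data.frame(mz = tab$mz[i], intensity = tab$intensity[i]))
  if (is.null(massRange))
    massRange <- c(floor(min(tab$mz)), ceiling(max(tab$mz)))
  imsDataset(coords = coords, peaks = peaks, massRange = massRange,
             spatialResolution = spatialResolution, normalized = normalized)
}

#' Write an IMS dataset to imzML or a tabular dump
#'
#' @param ds an [IMSDataset-class].
#' @param path output path.
#' @param format \code{"imzml"} (writes .imzML + .ibd) or \code{"tabular"}
#'   (tab-separated pixel_x, pixel_y, mz, intensity).
#' @return the written path, invisibly.
#' @export
writeIms <- function(ds, path, format = c("imzml", "tabular")) {
  stopIfNot(is(ds, "IMSDataset"), "ds must be an IMSDataset")
  format <- match.arg(format)
  if (format == "imzml") return(writeImzml(ds, path))
  npk <- vapply(ds@peaks, nrow, integer(1))
  tab <- data.frame(
    pixel_x = rep(ds@coords$x, npk),
    pixel_y = rep(ds@coords$y, npk),
    mz = unlist(lapply(ds@peaks, `[[`, "mz"), use.names = FALSE),
    intensity = unlist(lapply(ds@peaks, `[[`, "intensity"), use.names = FALSE))
  # leading metadata line so the round trip preserves the declared range
  writeLines(sprintf("#massRange\t%.9g\t%.9g\t%g\t%s", ds@massRange[1],
                     ds@massRange[2], ds@spatialResolution, ds@normalized),
             path)
  suppressWarnings(utils::write.table(tab, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE,
                                      col.names = TRUE))
  invisible(path)
}

#' Total-ion-current normalization
#'
#' Scales each pixel's intensities so its total ion current equals the
#' dataset-wide mean TIC; this keeps intensities on the acquisition scale
#' rather than normalizing totals to 1. Pixels with zero total intensity
#' are left untouched and reported via the \code{flaggedPixels} attribute.
#' Applying the normalization twice is the identity (within float
#' tolerance).
#'
#' @param ds an [IMSDataset-class].
#' @return the normalized [IMSDataset-class], with attribute
#'   \code{flaggedPixels} listing indices of zero-TIC pixels.
#' @export
ticNormalize <- function(ds) {
  stopIfNot(is(ds, "IMSDataset"), "ds must be an IMSDataset")
  tic <- vapply(ds@peaks, function(p) sum(p$intensity), numeric(1))
  flagged <- which(tic <= 0)
  meanTic <- mean(tic[tic > 0])
  peaks <- ds@peaks
  for (i in which(tic > 0)) {
    peaks[[i]]$intensity <- peaks[[i]]$intensity * (meanTic / tic[i])
  }
  out <- new("IMSDataset", coords = ds@coords, peaks = peaks,
             massRange = ds@massRange,
             spatialResolution = ds@spatialResolution, normalized = TRUE)
  attr(out, "flaggedPixels") <- flagged
  out
}

#' Bin spectra onto a uniform m/z axis
#'
#' Adds each peak's intensity to the half-open bin \code{[lo, lo + w)}
#' containing its m/z (a peak exactly on a boundary goes to the higher
#' bin). Peaks in the +/-0.5 Da guard band outside the declared mass range
#' are clamped into the first/last bin so total intensity is conserved
#' exactly.
#'
#' @param ds an [IMSDataset-class].
#' @param width bin width w in Da, > 0; default 0.1, the minimal interval
#'   width used for unbiased hierarchical segmentation.
#' @return a [BinnedMatrix-class] with \code{ceil((high - low)/w)} bins.
#' @export
binSpectra <- function(ds, width = 0.1) {
  stopIfNot(is(ds, "IMSDataset"), "ds must be an IMSDataset")
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("width must be a single positive number", call. = FALSE)
  lo <- ds@massRange[1]
  nBins <- as.integer(ceiling(round((ds@massRange[2] - lo) / width, 9)))
  npk <- vapply(ds@peaks, nrow, integer(1))
  pix <- rep(seq_along(ds@peaks), npk)
  mz <- unlist(lapply(ds@peaks, `[[`, "mz"), use.names = FALSE)
  inten <- unlist(lapply(ds@peaks, `[[`, "intensity"), use.names = FALSE)
  bin <- pmin(pmax(floor((mz - lo) / width) + 1, 1), nBins)
  mat <- Matrix::sparseMatrix(i = pix, j = as.integer(bin), x = inten,
                              dims = c(length(ds@peaks), nBins))
  new("BinnedMatrix",
      mat = as(as(mat, "generalMatrix"), "CsparseMatrix"),
      binCenters = lo + (seq_len(nBins) - 0.5) * width,
      binWidth = width, massRange = ds@massRange, coords = ds@coords)
}

#' Ion image of a narrow m/z window
#'
#' Sums, per pixel, the intensities of all peaks with
#' \code{|mz - target| <= halfWindow}.
#'
#' @param ds an [IMSDataset-class].
#' @param mz target m/z in Da; must lie within the declared mass range.
#' @param halfWindow half-window in Da (default 0.1).
#' @return list of class \code{IonImage}: \code{grid} (matrix rows x cols
#'   over the bounding pixel grid, NA where no pixel was acquired),
#'   \code{values} (per-pixel sums aligned to \code{pixelCoords(ds)}),
#'   \code{mz}, \code{halfWindow}.
#' @export
ionImage <- function(ds, mz, halfWindow = 0.1) {
  stopIfNot(is(ds, "IMSDataset"), "ds must be an IMSDataset")
  if (mz < ds@massRange[1] || mz > ds@massRange[2])
    stop("target m/z ", mz, " outside mass range [", ds@massRange[1], ", ",
         ds@massRange[2], "]", call. = FALSE)
  if (halfWindow < 0) stop("halfWindow must be >= 0", call. = FALSE)
  vals <- vapply(ds@peaks, function(p) {
    sel <- abs(p$mz - mz) <= halfWindow
    if (any(sel)) sum(p$intensity[sel]) else 0
  }, numeric(1))
  cd <- ds@coords
  nr <- max(cd$y) - min(cd$y) + 1L
  nc <- max(cd$x) - min(cd$x) + 1L
  grid <- matrix(NA_real_, nr, nc)
  grid[cbind(cd$y - min(cd$y) + 1L, cd$x - min(cd$x) + 1L)] <- vals
  structure(list(grid = grid, values = vals, mz = mz,
                 halfWindow = halfWindow, coords = cd),
            class = "IonImage")
}

#' Export an ion image as a tabular grid
#'
#' @param img an \code{IonImage} from [ionImage()].
#' @param path output path (tab-separated x, y, intensity; one row per
#'   acquired pixel).
#' @return the path, invisibly.
#' @export
exportIonImage <- function(img, path) {
  stopIfNot(inherits(img, "IonImage"), "img must be an IonImage")
  utils::write.table(
    data.frame(x = img$coords$x, y = img$coords$y, intensity = img$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn ionImage display an ion image with base graphics
#' @param x an \code{IonImage}.
#' @param ... passed to [graphics::image()].
#' @export
plot.IonImage <- function(x, ...) {
  g <- x$grid[rev(seq_len(nrow(x$grid))), , drop = FALSE]  # origin top-left
  graphics::image(t(g), axes = FALSE, useRaster = TRUE,
                  main = sprintf("m/z %.3f +/- %.2f", x$mz, x$halfWindow),
                  ...)
  invisible(x)
}
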