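#' Simulation configuration for synthetic two-condition testis-like data
#'
#' Collects every knob of the synthetic-data generator into a validated
#' configuration object. Defaults emulate the study design the pipeline
#' assumes: two conditions (control "WT" and diseased "AROM") times three
#' replicates, missing-not-at-random low-abundance values, planted log2
#' fold changes, a pixel grid with a small number of spatial regions
#' (tubular vs interstitial analogues), tryptic-like peptides with
#' averagine isotope envelopes, centroid mass error such that +/-0.1 Da
#' covers about 2.5 sigma, and a mass range of 600-3,200 Da.
#'
#' @param nProteins number of simulated proteins.
#' @param peptidesPerProtein integer range (low, high) of peptides drawn
#'   per protein.
#' @param nReplicatesPerGroup replicates per condition (>= 2; default 3).
#' @param foldChangeEffect planted |log2FC| for differential proteins;
#'   planted values are point masses at 0 and +/- this effect.
#' @param fracDifferential fraction of proteins given a non-zero planted
#'   fold change (split evenly between signs).
#' @param missingQuantile detection-limit quantile of the log2 intensity
#'   distribution around which the logistic missingness model is centred;
#'   0 disables missingness entirely.
#' @param missingSteepness steepness of the logistic missingness curve
#'   (per log2-intensity unit).
#' @param intensityLogMean,intensityLogSd mean and sd of per-peptide base
#'   abundance on the log2 scale.
#' @param replicateSd replicate-to-replicate sd on the log2 scale.
#' @param gridShape pixel grid (rows, cols); each dimension >= 8.
#' @param nRegions number of spatial regions, 2-5.
#' @param massRange neutral mass interval in Da (default c(600, 3200)).
#' @param massErrorSd per-peak centroid mass error sd in Da (default 0.04,
#'   so +/-0.1 Da covers about 2.5 sigma).
#' @param isotopePeaks isotope peaks rendered per envelope (default 4).
#' @param imsPeptidesPerRegion differential peptides planted per region in
#'   the IMS dataset.
#' @param decoysPerPeptide near-isobaric decoy peptides added to the LC-MS
#'   table per planted IMS peptide (within +/-0.09 Da of its mass, same
#'   fold-change sign, lower abundance and smaller effect; never planted
#'   in the image). Default 0.
#' @param noiseMultSd multiplicative intensity noise sd (natural-log
#'   scale) on rendered peaks.
#' @param pixelGainSd per-pixel gain sd (natural-log scale); makes total
#'   signal vary across pixels to exercise normalization.
#' @param baselinePeaksPerPixel uniform-random baseline noise peaks per
#'   pixel.
#' @param seed integer seed; fully determines all generated outputs.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nProteins = 60L,
                      peptidesPerProtein = c(3L, 8L),
                      nReplicatesPerGroup = 3L,
                      foldChangeEffect = 3,
                      fracDifferential = 0.5,
                      missingQuantile = 0.10,
                      missingSteepness = 1.5,
                      intensityLogMean = 25,
                      intensityLogSd = 2,
                      replicateSd = 0.5,
                      gridShape = c(64L, 64L),
                      nRegions = 3L,
                      massRange = c(600, 3200),
                      massErrorSd = 0.04,
                      isotopePeaks = 4L,
                      imsPeptidesPerRegion = 30L,
                      decoysPerPeptide = 0L,
                      noiseMultSd = 0.15,
                      pixelGainSd = 0.2,
                      baselinePeaksPerPixel = 2L,
                      seed = 1L) {
  cfg <- list(nProteins = as.integer(nProteins),
              peptidesPerProtein = as.integer(peptidesPerProtein),
              nReplicatesPerGroup = as.integer(nReplicatesPerGroup),
              foldChangeEffect = foldChangeEffect,
              fracDifferential = fracDifferential,
              missingQuantile = missingQuantile,
              missingSteepness = missingSteepness,
              intensityLogMean = intensityLogMean,
              intensityLogSd = intensityLogSd,
              replicateSd = replicateSd,
              gridShape = as.integer(gridShape),
              nRegions = as.integer(nRegions),
              massRange = as.numeric(massRange),
              massErrorSd = massErrorSd,
              isotopePeaks = as.integer(isotopePeaks),
              imsPeptidesPerRegion = as.integer(imsPeptidesPerRegion),
              decoysPerPeptide = as.integer(decoysPerPeptide),
              noiseMultSd = noiseMultSd,
              pixelGainSd = pixelGainSd,
              baselinePeaksPerPixel = as.integer(baselinePeaksPerPixel),
              seed = as.integer(seed))
  bad <- function(field, why) stop("invalid SimConfig field '", field, "': ",
                                   why, call. = FALSE)
  if (cfg$nProteins < 1L) bad("nProteins", "must be >= 1")
  if (length(cfg$peptidesPerProtein) != 2L ||
      cfg$peptidesPerProtein[1] < 1L ||
      cfg$peptidesPerProtein[1] > cfg$peptidesPerProtein[2])
    bad("peptidesPerProtein", "must be an increasing positive range")
  if (cfg$nReplicatesPerGroup < 2L) bad("nReplicatesPerGroup", "must be >= 2")
  if (cfg$fracDifferential < 0 || cfg$fracDifferential > 1)
    bad("fracDifferential", "must be in [0, 1]")
  if (cfg$missingQuantile < 0 || cfg$missingQuantile >= 1)
    bad("missingQuantile", "must be in [0, 1)")
  if (length(cfg$gridShape) != 2L || any(cfg$gridShape < 8L))
    bad("gridShape", "grid dimensions must be >= 8x8")
  if (cfg$nRegions < 2L || cfg$nRegions > 5L) bad("nRegions", "must be 2-5")
  if (length(cfg$massRange) != 2L || any(cfg$massRange <= 0) ||
      cfg$massRange[1] >= cfg$massRange[2])
    bad("massRange", "bounds must be positive with low < high")
  if (cfg$massErrorSd < 0) bad("massErrorSd", "must be >= 0")
  if (cfg$isotopePeaks < 1L) bad("isotopePeaks", "must be >= 1")
  if (cfg$decoysPerPeptide < 0L) bad("decoysPerPeptide", "must be >= 0")
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  class(cfg) <- "SimConfig"
  cfg
}

randomTrypticSequence <- function(mass) {
  # cosmetic tryptic-like sequence: length matched to mass, C-terminal K/R
  aa <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "N",
          "P", "Q", "S", "T", "V", "W", "Y")
  len <- max(5L, as.integer(round(mass / 111.1254)))
  paste0(paste(sample(aa, len - 1L, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1L))
}

#' Generate a ground-truthed synthetic LC-MS peptide evidence table
#'
#' Simulates a MaxQuant "peptides.txt"-style table for a two-condition,
#' replicated shotgun experiment with planted protein-level log2 fold
#' changes, log-normal base abundances, replicate noise and
#' missing-not-at-random values (logistic in log2 intensity around a
#' detection-limit quantile, so low-abundance peptides are missing more
#' often). Also selects the peptides planted in the paired synthetic IMS
#' dataset and assigns them to spatial regions: regions alternate between
#' the two conditions and each region receives peptides whose planted fold
#' change matches its condition.
#'
#' @param config a [simConfig()] object.
#' @return list with elements \code{table} (data.frame in the
#'   "peptides.txt" dialect: Sequence, Mass, Proteins, Leading razor
#'   protein, Unique, Intensity <group>_<rep> columns) and \code{truth}
#'   (a \code{GroundTruth} list recording all planted values: the peptide
#'   to protein map, planted log2FC, planted IMS regions and monoisotopic
#'   masses, plus the region-condition table).
#' @export
generateLcmsTable <- function(config) {
  stopIfNot(inherits(config, "SimConfig"), "config must be a SimConfig")
  set.seed(config$seed)
  nRep <- config$nReplicatesPerGroup
  groups <- c("WT", "AROM")

  # planted protein fold changes: point masses at 0 and +/- effect
  nDiff <- round(config$nProteins * config$fracDifferential)
  nUp <- floor(nDiff / 2)
  nDown <- nDiff - nUp
  protFC <- c(rep(config$foldChangeEffect, nUp),
              rep(-config$foldChangeEffect, nDown),
              rep(0, config$nProteins - nDiff))
  protFC <- sample(protFC)
  protein <- sprintf("P%04d", seq_len(config$nProteins))

  nPep <- sample(seq(config$peptidesPerProtein[1], config$peptidesPerProtein[2]),
                 config$nProteins, replace = TRUE)
  pepProt <- rep(seq_len(config$nProteins), nPep)
  n <- length(pepProt)
  envelopeExtent <- (config$isotopePeaks - 1L) * ISOTOPE_SPACING
  mass <- runif(n, config$massRange[1] + 1,
                config$massRange[2] - envelopeExtent - 1)
  sequence <- vapply(mass, randomTrypticSequence, character(1))
  uniqueFlag <- runif(n) < 0.9
  pepFC <- protFC[pepProt]

  base <- rnorm(n, config$intensityLogMean, config$intensityLogSd)
  logI <- matrix(NA_real_, n, 2L * nRep)
  for (r in seq_len(nRep)) {
    logI[, r] <- base + rnorm(n, 0, config$replicateSd)
    logI[, nRep + r] <- base + pepFC + rnorm(n, 0, config$replicateSd)
  }

  # region-condition layout: alternate WT / AROM
  condition <- rep(groups, length.out = config$nRegions)
  regions <- data.frame(region = seq_len(config$nRegions),
                        condition = condition)

  # plant differential peptides in condition-matched regions (disjoint sets)
  imsRegion <- rep(NA_integer_, n)
  for (g in groups) {
    want <- which(regions$condition == g)
    sgn <- if (g == "AROM") 1 else -1
    pool <- which(sign(pepFC) == sgn & is.na(imsRegion))
    need <- config$imsPeptidesPerRegion * length(want)
    if (length(pool) < need)
      stop("not enough ", g, "-side differential peptides to plant ",
           need, " IMS peptides; increase nProteins or fracDifferential",
           call. = FALSE)
    picked <- sample(pool, need)
    imsRegion[picked] <- rep(want, each = config$imsPeptidesPerRegion)
  }

  # near-isobaric decoys for planted peptides (LC-MS only)
  isDecoy <- rep(FALSE, n)
  if (config$decoysPerPeptide > 0L) {
    planted <- which(!is.na(imsRegion))
    nD <- length(planted) * config$decoysPerPeptide
    src <- rep(planted, each = config$decoysPerPeptide)
    dMass <- mass[src] + runif(nD, -0.09, 0.09)
    dFC <- pepFC[src] * runif(nD, 0.3, 0.8)
    dBase <- base[src] - runif(nD, 1, 3)
    dLog <- matrix(NA_real_, nD, 2L * nRep)
    for (r in seq_len(nRep)) {
      dLog[, r] <- dBase + rnorm(nD, 0, config$replicateSd)
      dLog[, nRep + r] <- dBase + dFC + rnorm(nD, 0, config$replicateSd)
    }
    dProt <- sprintf("P%04dD%d", pepProt[src],
                     rep(seq_len(config$decoysPerPeptide), length(planted)))
    mass <- c(mass, dMass)
    sequence <- c(sequence, vapply(dMass, randomTrypticSequence, character(1)))
    uniqueFlag <- c(uniqueFlag, rep(TRUE, nD))
    pepFC <- c(pepFC, dFC)
    protein <- c(protein, dProt)
    pepProt <- c(pepProt, seq_along(dProt) + config$nProteins)
    logI <- rbind(logI, dLog)
    imsRegion <- c(imsRegion, rep(NA_integer_, nD))
    isDecoy <- c(isDecoy, rep(TRUE, nD))
    n <- length(mass)
  }
  leading <- protein[pepProt]

  intensity <- 2^logI
  # missing-not-at-random: logistic in log2 intensity around the
  # detection-limit quantile; quantile 0 disables missingness
  if (config$missingQuantile > 0) {
    thr <- stats::quantile(logI, config$missingQuantile, names = FALSE)
    pMiss <- stats::plogis(-(logI - thr) * config$missingSteepness)
    intensity[matrix(runif(length(pMiss)), nrow(pMiss)) < pMiss] <- NA_real_
  }

  cols <- c(outer(seq_len(nRep), groups[1], function(r, g) paste0("Intensity ", g, "_", r)),
            outer(seq_len(nRep), groups[2], function(r, g) paste0("Intensity ", g, "_", r)))
  colnames(intensity) <- cols
  tab <- data.frame(Sequence = sequence,
                    Mass = mass,
                    Proteins = leading,
                    `Leading razor protein` = leading,
                    Unique = ifelse(uniqueFlag, "yes", "no"),
                    check.names = FALSE)
  tab <- cbind(tab, as.data.frame(intensity, check.names = FALSE))

  truth <- list(
    peptides = data.frame(sequence = sequence,
                          protein = leading,
                          mass = mass,
                          plantedLog2FC = pepFC,
                          imsRegion = imsRegion,
                          monoMH = mass + PROTON_MASS,
                          isDecoy = isDecoy),
    regions = regions,
    config = config)
  class(truth) <- "GroundTruth"
  list(table = tab, truth = truth)
}

# deterministic Voronoi region layout over the pixel grid
regionLayout <- function(gridShape, nRegions) {
  rows <- gridShape[1]; cols <- gridShape[2]
  px <- expand.grid(x = seq_len(cols) - 1L, y = seq_len(rows) - 1L)
  seeds <- cbind(x = sample(seq_len(cols) - 1L, nRegions),
                 y = sample(seq_len(rows) - 1L, nRegions))
  d2 <- outer(px$x, seeds[, "x"], "-")^2 + outer(px$y, seeds[, "y"], "-")^2
  region <- max.col(-d2, ties.method = "first")
  data.frame(x = px$x, y = px$y, region = region)
}

#' Render a ground truth into a synthetic IMS dataset
#'
#' Renders every planted peptide in its assigned spatial region as a full
#' isotope envelope (averagine relative intensities) with multiplicative
#' intensity noise, a per-pixel gain (so total signal varies across
#' pixels), per-peak centroid mass error ~ Normal(0, massErrorSd), and
#' uniform-random baseline noise peaks. Regions are a deterministic
#' Voronoi partition of the grid given the configuration seed.
#'
#' @param config the [simConfig()] used to generate \code{truth}.
#' @param truth the \code{GroundTruth} from [generateLcmsTable()].
#' @return list with \code{dataset} (an [IMSDataset-class]) and
#'   \code{truth} (the input ground truth with a \code{pixelRegions}
#'   data.frame of x, y, region recording the rendered layout).
#' @export
generateImsDataset <- function(config, truth) {
  stopIfNot(inherits(config, "SimConfig"), "config must be a SimConfig")
  stopIfNot(inherits(truth, "GroundTruth"), "truth must be a GroundTruth")
  set.seed(config$seed + 1L)
  layout <- regionLayout(config$gridShape, config$nRegions)
  nPix <- nrow(layout)
  k <- seq_len(config$isotopePeaks) - 1L

  planted <- truth$peptides[!is.na(truth$peptides$imsRegion), , drop = FALSE]
  tooWide <- planted$monoMH + (config$isotopePeaks - 1L) * ISOTOPE_SPACING >
    config$massRange[2] + 0.5 | planted$monoMH < config$massRange[1] - 0.5
  if (any(tooWide)) {
    warning(sum(tooWide), " planted peptide(s) skipped: envelope outside mass range")
    planted <- planted[!tooWide, , drop = FALSE]
  }
  baseIms <- 2^rnorm(nrow(planted), 10, 1)
  gain <- exp(rnorm(nPix, 0, config$pixelGainSd))

  # per-peptide smooth spatial abundance modulation within its region: a
  # random Gaussian bump shared by all isotopes of the peptide, emulating
  # the within-region abundance structure that makes isotope images of one
  # peptide co-localize while different peptides do not
  bumpAmp <- runif(nrow(planted), 1.5, 3)
  bumpCx <- numeric(nrow(planted)); bumpCy <- numeric(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    pixR <- which(layout$region == planted$imsRegion[i])
    j <- pixR[sample.int(length(pixR), 1L)]
    bumpCx[i] <- layout$x[j]; bumpCy[i] <- layout$y[j]
  }

  pixIdx <- integer(0); mzAll <- numeric(0); intAll <- numeric(0)
  for (r in seq_len(config$nRegions)) {
    pix <- which(layout$region == r)
    rows <- which(planted$imsRegion == r)
    if (!length(pix) || !length(rows)) next
    relList <- lapply(planted$monoMH[rows], function(m)
      averagineEnvelope(m, config$isotopePeaks)$intensity)
    nPep <- length(rows); nIso <- config$isotopePeaks; nPx <- length(pix)
    # index order: isotope fastest, then peptide, then pixel
    pepLocal <- rep(rep(seq_len(nPep), each = nIso), times = nPx)
    isoIdx <- rep(rep.int(k, nPep), times = nPx)
    pxIdx <- rep(pix, each = nPep * nIso)
    mono <- planted$monoMH[rows][pepLocal]
    rel <- rep.int(unlist(relList, use.names = FALSE), nPx)
    baseI <- baseIms[rows][pepLocal]
    nn <- length(mono)
    mz <- mono + isoIdx * ISOTOPE_SPACING + rnorm(nn, 0, config$massErrorSd)
    pepGlobal <- rows[pepLocal]
    bumpW <- 0.4 * sqrt(nPx)
    d2 <- (layout$x[pxIdx] - bumpCx[pepGlobal])^2 +
      (layout$y[pxIdx] - bumpCy[pepGlobal])^2
    modulation <- exp(bumpAmp[pepGlobal] * exp(-d2 / (2 * bumpW^2)))
    inten <- baseI * rel * modulation *
      exp(rnorm(nn, 0, config$noiseMultSd)) * gain[pxIdx]
    pixIdx <- c(pixIdx, pxIdx); mzAll <- c(mzAll, mz); intAll <- c(intAll, inten)
  }
  # baseline noise peaks
  if (config$baselinePeaksPerPixel > 0L) {
    nb <- nPix * config$baselinePeaksPerPixel
    pixIdx <- c(pixIdx, rep(seq_len(nPix), each = config$baselinePeaksPerPixel))
    mzAll <- c(mzAll, runif(nb, config$massRange[1], config$massRange[2]))
    medBase <- if (length(baseIms)) stats::median(baseIms) else 1000
    intAll <- c(intAll, medBase * 0.02 * runif(nb))
  }
  mzAll <- pmin(pmax(mzAll, config$massRange[1] - 0.5), config$massRange[2] + 0.5)

  ord <- order(pixIdx)
  pixIdx <- pixIdx[ord]; mzAll <- mzAll[ord]; intAll <- intAll[ord]
  splitIdx <- split(seq_along(pixIdx), factor(pixIdx, levels = seq_len(nPix)))
  peaks <- lapply(splitIdx, function(i)
    data.frame(mz = mzAll[i], intensity = intAll[i]))
  ds <- imsDataset(coords = layout[, c("x", "y")], peaks = peaks,
                   massRange = config$massRange, spatialResolution = 25,
                   normalized = FALSE)
  truth$pixelRegions <- layout
  list(dataset = ds, truth = truth)
}

#' Write a synthetic LC-MS table in the MaxQuant "peptides.txt" dialect
#'
#' @param table the table from [generateLcmsTable()].
#' @param path output file path (tab-separated text).
#' @return the path, invisibly.
#' @export
writeLcmsTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NaN")
  invisible(path)
}

#' Serialize a GroundTruth to tabular text files
#'
#' Writes \code{truth_peptides.tsv}, \code{truth_regions.tsv} and (when
#' present) \code{truth_pixel_regions.tsv} into a directory.
#'
#' @param truth a \code{GroundTruth}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeGroundTruth <- function(truth, dir) {
  stopIfNot(inherits(truth, "GroundTruth"), "truth must be a GroundTruth")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(truth$peptides, file.path(dir, "truth_peptides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$regions, file.path(dir, "truth_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth$pixelRegions))
    utils::write.table(truth$pixelRegions,
                       file.path(dir, "truth_pixel_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
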