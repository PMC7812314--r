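#' Pipeline run configuration
#'
#' Collects the paths and stage parameters of an end-to-end run. Stage
#' parameters default to the values the method was designed around: bin
#' width 0.1 Da, ROC threshold 0.7, deisotoping tolerances 0.15 Da and
#' 50\% with co-localization 0.7, imputation downshift 1.8 and width 0.3,
#' and mass-match tolerance tau = 0.1 Da.
#'
#' @param imsPath path to the IMS dataset (imzML or tabular dump).
#' @param peptidePath path to the LC-MS peptide evidence table.
#' @param outDir output run directory.
#' @param k cluster count for the segmentation cut.
#' @param clusterConditions named vector mapping each cluster id (after
#'   the cut at \code{k}) to a condition label ("WT"/"AROM").
#' @param imsFormat \code{"auto"}, \code{"imzml"} or \code{"tabular"}.
#' @param binWidth bin width in Da (default 0.1).
#' @param aucThreshold discriminative-mass ROC threshold (default 0.7).
#' @param mzTol,intensityTol,colocMin deisotoping tolerances (defaults
#'   0.15 Da, 0.5, 0.7).
#' @param downshift,width imputation parameters (defaults 1.8, 0.3).
#' @param tau mass-match tolerance in Da (default 0.1).
#' @param terms optional named list of term -> member vectors for
#'   over-representation analysis of each cluster's protein list.
#' @param controlPattern,diseasePattern intensity column patterns for the
#'   peptide table.
#' @param seed integer seed used for every stochastic stage.
#' @return validated list of class \code{RunConfig}.
#' @export
runConfig <- function(imsPath, peptidePath, outDir, k, clusterConditions,
                      imsFormat = "auto", binWidth = 0.1,
                      aucThreshold = 0.7, mzTol = 0.15, intensityTol = 0.5,
                      colocMin = 0.7, downshift = 1.8, width = 0.3,
                      tau = 0.1, terms = NULL,
                      controlPattern = "^Intensity WT",
                      diseasePattern = "^Intensity AROM", seed = 1L) {
  cfg <- list(imsPath = imsPath, peptidePath = peptidePath, outDir = outDir,
              k = as.integer(k), clusterConditions = clusterConditions,
              imsFormat = imsFormat, binWidth = binWidth,
              aucThreshold = aucThreshold, mzTol = mzTol,
              intensityTol = intensityTol, colocMin = colocMin,
              downshift = downshift, width = width, tau = tau,
              terms = terms, controlPattern = controlPattern,
              diseasePattern = diseasePattern, seed = as.integer(seed))
  for (f in c("imsPath", "peptidePath", "outDir"))
    if (!is.character(cfg[[f]]) || !nzchar(cfg[[f]]))
      stop("RunConfig validation: missing required path '", f, "'",
           call. = FALSE)
  if (cfg$k < 2L) stop("RunConfig validation: k must be >= 2", call. = FALSE)
  if (length(cfg$clusterConditions) < cfg$k)
    stop("RunConfig validation: clusterConditions must cover all k clusters",
         call. = FALSE)
  class(cfg) <- "RunConfig"
  cfg
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the stages in order: read IMS data, TIC-normalize, bin,
#' segment, find discriminative m/z values per cluster, deisotope; in
#' parallel on the shotgun side: read the peptide table, impute, moderated
#' t-test, fold-change classification; then tau-search, MLP assignment,
#' per-cluster protein reports and (when term sets are supplied)
#' over-representation analysis. Every output is a plain tabular file; a
#' \code{manifest.json} records input hashes, all parameters and the seed
#' so the run can be reproduced exactly. A stage failure aborts with the
#' stage name and leaves a \code{FAILED} marker file in the run directory.
#'
#' @param config a [runConfig()].
#' @return the output directory path, invisibly; side effect: files
#'   written under it.
#' @export
runAll <- function(config) {
  stopIfNot(inherits(config, "RunConfig"), "config must be a RunConfig")
  if (!file.exists(config$imsPath))
    stop("RunConfig validation: IMS input not readable: ", config$imsPath,
         call. = FALSE)
  if (!file.exists(config$peptidePath))
    stop("RunConfig validation: peptide table not readable: ",
         config$peptidePath, call. = FALSE)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  failed <- file.path(config$outDir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0(name, ": ", conditionMessage(e)), failed)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ds <- stage("read", readIms(config$imsPath, format = config$imsFormat))
  ds <- stage("normalize", ticNormalize(ds))
  bm <- stage("bin", binSpectra(ds, width = config$binWidth))
  seg <- stage("segment", segmentPixels(bm, k = config$k, seed = config$seed))
  labels <- labelsAt(seg, config$k)
  writeTsv(data.frame(x = pixelCoords(seg)$x, y = pixelCoords(seg)$y,
                      cluster = labels),
           file.path(config$outDir, "segmentation_labels.tsv"))

  stage("discriminative_mz", for (cl in sort(unique(labels))) {
    dm <- discriminativeMz(bm, labels, cl, aucThreshold = config$aucThreshold)
    if (nrow(dm))
      exportMassList(dm, file.path(config$outDir,
                                   sprintf("mass_list_cluster_%d.tsv", cl)))
  })

  deiso <- stage("deisotope",
                 deisotopeAll(ds, labels, mzTol = config$mzTol,
                              intensityTol = config$intensityTol,
                              colocMin = config$colocMin))
  exportMonoList(deiso$monoList, file.path(config$outDir, "mono_list.tsv"))
  writeTsv(deiso$pooled, file.path(config$outDir, "pooled_unique.tsv"))

  tab <- stage("read_peptides",
               readPeptideTable(config$peptidePath,
                                controlPattern = config$controlPattern,
                                diseasePattern = config$diseasePattern))
  imp <- stage("impute", imputeMissing(tab, downshift = config$downshift,
                                       width = config$width,
                                       seed = config$seed))
  mt <- stage("moderated_test", moderatedTTest(imp$table))
  stats <- stage("classify", foldChangeClassify(mt$table))
  writeTsv(stats[, setdiff(names(stats), character(0))],
           file.path(config$outDir, "peptide_stats.tsv"))
  writeTsv(volcanoData(stats), file.path(config$outDir, "volcano.tsv"))

  cand <- stage("tau_search",
                tauSearch(monoEntries(deiso$monoList), stats,
                          clusterConditions = config$clusterConditions,
                          tau = config$tau))
  assignments <- stage("mlp_assign", assignProteins(cand))
  writeTsv(assignments[, setdiff(names(assignments), "members")],
           file.path(config$outDir, "assignments.tsv"))
  reports <- stage("cluster_report", clusterReport(assignments))
  exportClusterReports(reports, config$outDir)

  if (!is.null(config$terms)) {
    stage("ora", for (cl in names(reports)) {
      sel <- unique(reports[[cl]]$protein)
      if (!length(sel)) next
      universe <- unique(stats$protein)
      ora <- oraHypergeometric(intersect(sel, universe), config$terms,
                               universe)
      writeTsv(ora, file.path(config$outDir,
                              sprintf("ora_cluster_%s.tsv", cl)))
    })
  }

  manifest <- list(
    package = "maldiMLP",
    version = as.character(utils::packageVersion("maldiMLP")),
    inputs = list(
      ims = unname(tools::md5sum(config$imsPath)),
      peptides = unname(tools::md5sum(config$peptidePath))),
    parameters = config[setdiff(names(config),
                                c("imsPath", "peptidePath", "outDir",
                                  "terms"))],
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$outDir)
}

#' Simulate a ground-truthed dataset, run the pipeline, score recovery
#'
#' Generates the synthetic LC-MS table and IMS dataset, writes them to the
#' run directory, executes [runAll()] with cluster conditions derived from
#' the planted region layout (majority region per cluster), and compares
#' every stage output against the planted ground truth.
#'
#' @param simCfg a [simConfig()].
#' @param outDir run directory.
#' @param k segmentation cut (default: number of planted regions).
#' @param imsFormat format used to write/read the IMS data
#'   (default "tabular"; "imzml" exercises the binary path).
#' @param ... further arguments passed to [runConfig()].
#' @return list with \code{runDir}, \code{truth}, \code{metrics} (a list:
#'   \code{segmentationARI}, \code{envelopeRecovery},
#'   \code{monoMassTolerance}, \code{top1Recovery}, \code{precision}
#'   per-cluster and mean, \code{typeIError}) and \code{labels}.
#' @export
simulateAndRun <- function(simCfg, outDir, k = NULL, imsFormat = "tabular",
                           ...) {
  stopIfNot(inherits(simCfg, "SimConfig"), "simCfg must be a SimConfig")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  k <- k %||% simCfg$nRegions

  gen <- generateLcmsTable(simCfg)
  ims <- generateImsDataset(simCfg, gen$truth)
  truth <- ims$truth
  pepPath <- file.path(outDir, "peptides.tsv")
  writeLcmsTable(gen$table, pepPath)
  imsPath <- file.path(outDir,
                       if (imsFormat == "imzml") "ims.imzML" else "ims.tsv")
  writeIms(ims$dataset, imsPath, format = imsFormat)
  writeGroundTruth(truth, outDir)

  # provisional segmentation to derive cluster -> condition declarations
  # from the planted layout (stands in for the manual histology call)
  bm <- binSpectra(ticNormalize(ims$dataset))
  seg <- segmentPixels(bm, k = k, seed = simCfg$seed)
  labels <- labelsAt(seg, k)
  region <- truth$pixelRegions$region
  cl2region <- vapply(split(region, labels), function(r)
    as.integer(names(which.max(table(r)))), integer(1))
  conds <- stats::setNames(
    truth$regions$condition[cl2region], names(cl2region))

  cfg <- runConfig(imsPath = imsPath, peptidePath = pepPath,
                   outDir = outDir, k = k, clusterConditions = conds,
                   imsFormat = imsFormat, seed = simCfg$seed, ...)
  runAll(cfg)

  metrics <- scoreRun(outDir, truth, labels, cl2region)
  list(runDir = outDir, truth = truth, metrics = metrics, labels = labels)
}

# Compare a finished run directory against the planted ground truth.
scoreRun <- function(runDir, truth, labels, cl2region) {
  region <- truth$pixelRegions$region
  ari <- mclust::adjustedRandIndex(labels, region)

  mono <- utils::read.delim(file.path(runDir, "mono_list.tsv"))
  planted <- truth$peptides[!is.na(truth$peptides$imsRegion), , drop = FALSE]
  tol <- 0.05
  recovered <- vapply(seq_len(nrow(planted)), function(i) {
    cl <- names(cl2region)[cl2region == planted$imsRegion[i]]
    any(mono$cluster %in% as.integer(cl) &
          abs(mono$mono_mz - planted$monoMH[i]) <= tol)
  }, logical(1))
  envelopeRecovery <- mean(recovered)

  # cross-region merges: a mono entry in a cluster whose members span
  # peptides planted in a different region cannot be detected directly
  # from files; approximated as planted masses recovered in a
  # non-matching cluster only
  asg <- utils::read.delim(file.path(runDir, "assignments.tsv"))
  asg <- asg[asg$status == "assigned", , drop = FALSE]
  nearest <- vapply(asg$ims_mz, function(q) {
    d <- abs(planted$monoMH - q)
    i <- which.min(d)
    if (d[i] <= tol) i else NA_integer_
  }, integer(1))
  matched <- !is.na(nearest)
  top1 <- if (any(matched))
    mean(asg$protein[matched] == planted$protein[nearest[matched]])
  else NA_real_

  precision <- vapply(names(cl2region), function(cl) {
    f <- file.path(runDir, sprintf("cluster_%s_proteins.tsv", cl))
    if (!file.exists(f)) return(NA_real_)
    rep <- utils::read.delim(f)
    if (!nrow(rep)) return(NA_real_)
    regionProts <- unique(planted$protein[planted$imsRegion ==
                                            cl2region[[cl]]])
    mean(rep$protein %in% regionProts)
  }, numeric(1))

  stats <- utils::read.delim(file.path(runDir, "peptide_stats.tsv"))
  nullSeq <- truth$peptides$sequence[truth$peptides$plantedLog2FC == 0]
  nullP <- stats$p[stats$sequence %in% nullSeq]
  typeI <- if (length(nullP)) mean(nullP < 0.05) else NA_real_

  list(segmentationARI = ari,
       envelopeRecovery = envelopeRecovery,
       top1Recovery = top1,
       precision = precision,
       meanPrecision = mean(precision, na.rm = TRUE),
       typeIError = typeI)
}
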