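#' Mass-tolerance (tau) search of IMS masses against LC-MS peptides
#'
#' Matches each deisotoped IMS m/z (observed singly protonated) against
#' the theoretical MH+ of every LC-MS peptide (neutral monoisotopic mass
#' plus the proton mass 1.007276 Da) within \code{|ims - MH+| <= tau}.
#' The search space is restricted per cluster to the condition the cluster
#' was assigned to (a cluster occurring in diseased tissue is only
#' compared against disease-classified peptides, and conversely), so no
#' candidate ever crosses conditions. IMS masses with no candidate are
#' reported with an \code{unmatched} status, not dropped.
#'
#' @param mono data.frame of deisotoped masses with columns \code{mono_mz}
#'   and \code{cluster} (e.g. [monoEntries()] of a
#'   [MonoisotopicList-class], or a hand-curated list from
#'   [readMonoList()]).
#' @param stats classified, tested peptide table (from
#'   [foldChangeClassify()] after [moderatedTTest()]): columns
#'   \code{sequence}, \code{mass}, \code{protein}, \code{group},
#'   \code{mu}, \code{log2FC}, \code{p}.
#' @param clusterConditions named character vector mapping cluster id to
#'   its condition label (values of \code{stats$group}, e.g. "WT" or
#'   "AROM"); the user declaration mirroring the manual histology-based
#'   assignment.
#' @param tau mass tolerance in Da, > 0 (default 0.1).
#' @return data.frame with one row per (IMS m/z, candidate) pair and one
#'   \code{status = "unmatched"} row for every candidate-free IMS m/z;
#'   columns \code{ims_mz}, \code{cluster}, \code{condition},
#'   \code{sequence}, \code{protein}, \code{mh}, \code{delta}, \code{mu},
#'   \code{log2FC}, \code{p}, \code{status}.
#' @export
tauSearch <- function(mono, stats, clusterConditions, tau = 0.1) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a single positive number", call. = FALSE)
  stopIfNot(all(c("mono_mz", "cluster") %in% names(mono)),
            "mono needs mono_mz and cluster columns")
  need <- c("sequence", "mass", "protein", "group", "mu", "log2FC", "p")
  stopIfNot(all(need %in% names(stats)),
            "stats table lacks required columns")
  clusterConditions <- stats::setNames(as.character(clusterConditions),
                                       names(clusterConditions))
  mh <- stats$mass + PROTON_MASS
  rows <- vector("list", nrow(mono))
  for (i in seq_len(nrow(mono))) {
    cl <- as.character(mono$cluster[i])
    cond <- if (cl %in% names(clusterConditions)) clusterConditions[[cl]]
            else NA_character_
    if (is.na(cond))
      stop("no condition declared for cluster ", cl, call. = FALSE)
    q <- mono$mono_mz[i]
    hit <- which(stats$group == cond & abs(q - mh) <= tau)
    rows[[i]] <- if (length(hit)) {
      data.frame(ims_mz = q, cluster = mono$cluster[i], condition = cond,
                 sequence = stats$sequence[hit], protein = stats$protein[hit],
                 mh = mh[hit], delta = q - mh[hit], mu = stats$mu[hit],
                 log2FC = stats$log2FC[hit], p = stats$p[hit],
                 status = "candidate")
    } else {
      data.frame(ims_mz = q, cluster = mono$cluster[i], condition = cond,
                 sequence = NA_character_, protein = NA_character_,
                 mh = NA_real_, delta = NA_real_, mu = NA_real_,
                 log2FC = NA_real_, p = NA_real_, status = "unmatched")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MLP score of a match candidate
#'
#' The most-likely-peptide score MLP = mu * |log2FC| / p: the product of a
#' peptide's mean LC-MS intensity in its condition (abundant peptides are
#' preferentially detected by MALDI without pre-separation), the magnitude
#' of its differential fold change, and the reciprocal of its moderated
#' p-value (confidently differential peptides score higher). The absolute
#' value keeps control-side scores positive and comparable within the
#' condition-restricted search space; \code{signed = TRUE} uses the raw
#' log2FC instead.
#'
#' @param mu mean linear-scale intensity across the condition's
#'   replicates.
#' @param log2FC the peptide's log2 fold change.
#' @param p its moderated p-value, > 0 (floored upstream at 1e-300).
#' @param signed use signed log2FC (default FALSE).
#' @return numeric score(s), finite, and non-negative unless
#'   \code{signed}.
#' @export
mlpScore <- function(mu, log2FC, p, signed = FALSE) {
  stopIfNot(all(p > 0, na.rm = TRUE), "p must be positive (floor upstream)")
  fc <- if (signed) log2FC else abs(log2FC)
  mu * fc / p
}

#' Assign each IMS mass to its maximum-MLP candidate protein
#'
#' Per IMS m/z, selects the candidate with the highest MLP score. Ties are
#' broken deterministically by larger mu, then smaller |mass delta|, then
#' lexicographic protein accession. An assignment is flagged ambiguous
#' when the runner-up score is within a factor \code{ambiguityRatio} of
#' the winner (reporting honesty; the winner is unchanged). Unmatched IMS
#' masses are carried through with \code{status = "unmatched"}.
#'
#' @param candidates data.frame from [tauSearch()].
#' @param signed use signed MLP scores (default FALSE).
#' @param ambiguityRatio flag assignments whose top two scores differ by
#'   less than this factor (default 2).
#' @return data.frame with one row per IMS m/z: candidate columns plus
#'   \code{mlp}, \code{n_candidates}, \code{runner_up_mlp},
#'   \code{ambiguous}, \code{status}.
#' @export
assignProteins <- function(candidates, signed = FALSE, ambiguityRatio = 2) {
  key <- paste(candidates$cluster, format(candidates$ims_mz, digits = 15),
               sep = "|")
  out <- lapply(split(seq_len(nrow(candidates)), factor(key, unique(key))),
                function(idx) {
    cand <- candidates[idx, , drop = FALSE]
    if (all(cand$status == "unmatched")) {
      cand$mlp <- NA_real_
      cand$n_candidates <- 0L
      cand$runner_up_mlp <- NA_real_
      cand$ambiguous <- FALSE
      return(cand[1L, , drop = FALSE])
    }
    score <- mlpScore(cand$mu, cand$log2FC, cand$p, signed = signed)
    ord <- order(-score, -cand$mu, abs(cand$delta), cand$protein)
    win <- cand[ord[1L], , drop = FALSE]
    win$mlp <- score[ord[1L]]
    win$n_candidates <- nrow(cand)
    win$runner_up_mlp <- if (nrow(cand) > 1L) score[ord[2L]] else NA_real_
    win$ambiguous <- nrow(cand) > 1L &&
      score[ord[1L]] < ambiguityRatio * score[ord[2L]]
    win$status <- "assigned"
    win
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-cluster protein report
#'
#' Aggregates assignments into one table per cluster: each protein's best
#' (highest-MLP) assigned IMS mass with its score and statistics, sorted
#' by MLP descending. The protein lists are the input for
#' over-representation analysis.
#'
#' @param assignments data.frame from [assignProteins()].
#' @return named list of data.frames, one per cluster (possibly
#'   zero-row), with columns \code{protein}, \code{ims_mz}, \code{mlp},
#'   \code{mu}, \code{log2FC}, \code{p}, \code{n_candidates},
#'   \code{ambiguous}.
#' @export
clusterReport <- function(assignments) {
  cols <- c("protein", "ims_mz", "mlp", "mu", "log2FC", "p",
            "n_candidates", "ambiguous")
  clusters <- sort(unique(assignments$cluster))
  reports <- lapply(clusters, function(cl) {
    a <- assignments[assignments$cluster == cl &
                       assignments$status == "assigned", , drop = FALSE]
    if (nrow(a) == 0L) {
      empty <- assignments[0, cols, drop = FALSE]
      return(empty)
    }
    a <- a[order(-a$mlp, a$protein), , drop = FALSE]
    best <- a[!duplicated(a$protein), cols, drop = FALSE]
    rownames(best) <- NULL
    best
  })
  names(reports) <- as.character(clusters)
  reports
}

#' Write per-cluster protein reports as TSV files
#'
#' @param reports list from [clusterReport()].
#' @param dir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
exportClusterReports <- function(reports, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(reports), function(cl) {
    p <- file.path(dir, sprintf("cluster_%s_proteins.tsv", cl))
    utils::write.table(reports[[cl]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
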