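#' Read an LC-MS peptide evidence table (MaxQuant "peptides.txt" dialect)
#'
#' Expects tab-separated text with at least the columns Sequence, Mass,
#' Leading razor protein (or Proteins), Unique, and per-sample intensity
#' columns. Missing intensities may be encoded as NaN, NA, empty or 0
#' (MaxQuant writes 0 for not-quantified).
#'
#' @param path input path.
#' @param controlPattern,diseasePattern regular expressions selecting the
#'   control and disease intensity columns.
#' @param zeroAsMissing treat exact zeros as missing (default TRUE).
#' @return data.frame with columns \code{sequence}, \code{mass},
#'   \code{protein}, \code{unique} plus the intensity columns; attributes
#'   \code{controlCols} and \code{diseaseCols} name them.
#' @export
readPeptideTable <- function(path, controlPattern = "^Intensity WT",
                             diseasePattern = "^Intensity AROM",
                             zeroAsMissing = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", "NaN", ""))
  protCol <- if ("Leading razor protein" %in% names(raw)) "Leading razor protein"
             else "Proteins"
  need <- c("Sequence", "Mass", protCol)
  if (!all(need %in% names(raw)))
    stop("peptide table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ctrl <- grep(controlPattern, names(raw), value = TRUE)
  dis <- grep(diseasePattern, names(raw), value = TRUE)
  if (!length(ctrl) || !length(dis))
    stop("no intensity columns matched the group patterns", call. = FALSE)
  tab <- data.frame(sequence = raw$Sequence, mass = as.numeric(raw$Mass),
                    protein = raw[[protCol]],
                    unique = if ("Unique" %in% names(raw))
                      tolower(raw$Unique) %in% c("yes", "true", "+") else TRUE,
                    check.names = FALSE)
  for (cc in c(ctrl, dis)) {
    v <- as.numeric(raw[[cc]])
    if (zeroAsMissing) v[v == 0] <- NA_real_
    tab[[cc]] <- v
  }
  attr(tab, "controlCols") <- ctrl
  attr(tab, "diseaseCols") <- dis
  tab
}

groupCols <- function(tab, cols, which) {
  if (!is.null(cols)) return(cols)
  got <- attr(tab, paste0(which, "Cols"))
  if (is.null(got)) stop("specify ", which, "Cols (no attribute found)",
                         call. = FALSE)
  got
}

#' Impute missing intensities from a down-shifted normal distribution
#'
#' Models values missing because they fell below the instrument detection
#' limit: for every sample column, missing cells are drawn on the log2
#' scale from Normal(mean - downshift * sd, (width * sd)^2) where mean and
#' sd are the column's observed log2 statistics. Observed cells are never
#' altered; draws are deterministic given the seed.
#'
#' @param tab peptide table with linear-scale intensity columns; NA marks
#'   missing.
#' @param cols intensity column names (default: both group attributes).
#' @param downshift shift in column sds (default 1.8).
#' @param width sd of the imputation distribution in column sds
#'   (default 0.3).
#' @param seed integer seed.
#' @return list with \code{table} (imputed, linear scale) and \code{flags}
#'   (logical matrix, TRUE exactly where input was missing).
#' @export
imputeMissing <- function(tab, cols = NULL, downshift = 1.8, width = 0.3,
                          seed = 1L) {
  cols <- cols %||% c(groupCols(tab, NULL, "control"),
                      groupCols(tab, NULL, "disease"))
  X <- log2(as.matrix(tab[, cols, drop = FALSE]))
  flags <- is.na(X)
  set.seed(as.integer(seed))
  for (j in seq_along(cols)) {
    obs <- X[!flags[, j], j]
    if (length(obs) < 3L)
      stop("column '", cols[j], "' has fewer than 3 observed values",
           call. = FALSE)
    nMiss <- sum(flags[, j])
    if (nMiss > 0L) {
      m <- mean(obs); s <- stats::sd(obs)
      X[flags[, j], j] <- rnorm(nMiss, m - downshift * s, width * s)
    }
  }
  tab[, cols] <- 2^X
  colnames(flags) <- cols
  list(table = tab, flags = flags)
}

# Newton inversion of the trigamma function (for prior df estimation)
trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# empirical-Bayes moment matching of a scaled inverse chi-square prior to
# the observed per-feature variances (log-variance method of moments)
estimatePriorVariance <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = exp(emean)))
  d0 <- 2 * trigammaInverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Computes per-peptide pooled within-group variances on the log2 scale,
#' shrinks them towards a pooled prior estimated from all peptides by
#' moment matching on log variances (prior degrees of freedom d0 and prior
#' variance s0^2), and tests the group difference with the moderated t
#' statistic t = (mean_disease - mean_control) / (s_tilde * sqrt(1/n1 +
#' 1/n2)), where s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g), on
#' d0 + d_g degrees of freedom. With \code{d0 = 0} this is exactly the
#' ordinary pooled-variance two-sample t-test; d0 = Inf fully pools the
#' variance. p-values are floored at 1e-300 so downstream likelihood
#' ratios stay finite.
#'
#' @param tab peptide table with complete (imputed) linear-scale intensity
#'   columns.
#' @param controlCols,diseaseCols intensity column names (defaults: table
#'   attributes).
#' @param d0 prior degrees of freedom: NULL (default) estimates d0 and
#'   s0^2 from the data; 0 gives the ordinary t-test; Inf fully pools.
#' @param s02 prior variance, required if \code{d0} is given as Inf and
#'   otherwise estimated.
#' @return list with \code{table} (input plus columns \code{t_mod},
#'   \code{p}, \code{df_total}) and \code{params} (list with \code{d0},
#'   \code{s02}).
#' @export
moderatedTTest <- function(tab, controlCols = NULL, diseaseCols = NULL,
                           d0 = NULL, s02 = NULL) {
  controlCols <- groupCols(tab, controlCols, "control")
  diseaseCols <- groupCols(tab, diseaseCols, "disease")
  n1 <- length(controlCols); n2 <- length(diseaseCols)
  stopIfNot(n1 >= 2 && n2 >= 2, "both groups need >= 2 replicates")
  Xc <- log2(as.matrix(tab[, controlCols, drop = FALSE]))
  Xd <- log2(as.matrix(tab[, diseaseCols, drop = FALSE]))
  if (anyNA(Xc) || anyNA(Xd))
    stop("intensities contain missing values; impute first", call. = FALSE)
  mC <- rowMeans(Xc); mD <- rowMeans(Xd)
  ssC <- rowSums((Xc - mC)^2); ssD <- rowSums((Xd - mD)^2)
  dg <- n1 + n2 - 2L
  s2 <- (ssC + ssD) / dg

  if (is.null(d0)) {
    prior <- estimatePriorVariance(s2, dg)
    d0 <- prior$d0; s02 <- prior$s02
  } else if (is.infinite(d0) && is.null(s02)) {
    s02 <- mean(s2[is.finite(s2) & s2 > 0])
  } else if (d0 > 0 && is.null(s02)) {
    stop("s02 must be supplied with a fixed finite d0 > 0", call. = FALSE)
  }
  postVar <- if (d0 == 0) s2
             else if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + dg * s2) / (d0 + dg)
  se <- sqrt(postVar * (1 / n1 + 1 / n2))
  t <- ifelse(mD == mC, 0, (mD - mC) / se)
  dfTotal <- d0 + dg
  p <- if (is.infinite(dfTotal)) 2 * stats::pnorm(-abs(t))
       else 2 * stats::pt(-abs(t), df = dfTotal)
  # zero pooled variance with d0 = 0 gives t = +/-Inf; flag via p-floor
  p[!is.finite(t)] <- 0
  p <- pmax(p, 1e-300)
  tab$t_mod <- t
  tab$p <- p
  tab$df_total <- dfTotal
  list(table = tab, params = list(d0 = d0, s02 = s02, dg = dg))
}

#' Fold-change computation and group classification
#'
#' Computes log2FC = log2(mu_disease / mu_control) from the group mean
#' intensities on the linear scale and classifies every peptide:
#' log2FC > 0 is disease-like ("AROM"), log2FC < 0 control-like ("WT"),
#' log2FC = 0 unclassified. Peptides with a non-positive group mean are
#' unclassified with a warning. The group-side mean intensity \code{mu}
#' (the mean of the group the peptide is classified to) is attached for
#' downstream likelihood scoring.
#'
#' @param tab peptide table with complete linear-scale intensities.
#' @param controlCols,diseaseCols intensity column names (defaults: table
#'   attributes).
#' @param groupNames character(2): labels for (control, disease); default
#'   c("WT", "AROM").
#' @return the table with columns \code{mu_control}, \code{mu_disease},
#'   \code{log2FC}, \code{group}, \code{mu}.
#' @export
foldChangeClassify <- function(tab, controlCols = NULL, diseaseCols = NULL,
                               groupNames = c("WT", "AROM")) {
  controlCols <- groupCols(tab, controlCols, "control")
  diseaseCols <- groupCols(tab, diseaseCols, "disease")
  muC <- rowMeans(as.matrix(tab[, controlCols, drop = FALSE]))
  muD <- rowMeans(as.matrix(tab[, diseaseCols, drop = FALSE]))
  bad <- !(muC > 0 & muD > 0) | is.na(muC) | is.na(muD)
  if (any(bad))
    warning(sum(bad), " peptide(s) with non-positive group mean left unclassified")
  fc <- rep(NA_real_, nrow(tab))
  fc[!bad] <- log2(muD[!bad] / muC[!bad])
  group <- rep("unclassified", nrow(tab))
  group[!bad & fc > 0] <- groupNames[2]
  group[!bad & fc < 0] <- groupNames[1]
  tab$mu_control <- muC
  tab$mu_disease <- muD
  tab$log2FC <- fc
  tab$group <- group
  tab$mu <- ifelse(group == groupNames[2], muD,
                   ifelse(group == groupNames[1], muC, (muC + muD) / 2))
  tab
}

#' Protein presence calls per condition
#'
#' A protein is called present in a condition iff at least one of its
#' unique peptides has an observed (non-imputed) intensity in at least
#' \code{minReplicates} of that condition's replicates. Outputs the
#' shared/exclusive partition of the protein universe.
#'
#' @param tab peptide table with NA marking missing (pre-imputation)
#'   intensities and a logical \code{unique} column.
#' @param controlCols,diseaseCols intensity column names (defaults: table
#'   attributes).
#' @param minReplicates m in the "m of n replicates" rule (default 2).
#' @return data.frame with one row per protein: \code{protein},
#'   \code{present_control}, \code{present_disease}, \code{status} in
#'   {shared, exclusive_control, exclusive_disease, absent}.
#' @export
validateProteins <- function(tab, controlCols = NULL, diseaseCols = NULL,
                             minReplicates = 2L) {
  controlCols <- groupCols(tab, controlCols, "control")
  diseaseCols <- groupCols(tab, diseaseCols, "disease")
  obsC <- rowSums(!is.na(as.matrix(tab[, controlCols, drop = FALSE])))
  obsD <- rowSums(!is.na(as.matrix(tab[, diseaseCols, drop = FALSE])))
  u <- tab$unique
  okC <- u & obsC >= minReplicates
  okD <- u & obsD >= minReplicates
  prots <- sort(unique(tab$protein))
  presentC <- vapply(split(okC, tab$protein)[prots], any, logical(1))
  presentD <- vapply(split(okD, tab$protein)[prots], any, logical(1))
  status <- ifelse(presentC & presentD, "shared",
            ifelse(presentC, "exclusive_control",
            ifelse(presentD, "exclusive_disease", "absent")))
  data.frame(protein = prots, present_control = presentC,
             present_disease = presentD, status = status, row.names = NULL)
}

#' Protein-level intensities by peptide summation
#'
#' @param tab peptide table with intensity columns.
#' @param cols intensity column names.
#' @param uniqueOnly sum only unique peptides (default FALSE).
#' @return matrix proteins x columns of summed intensities (NA ignored;
#'   all-NA sums are NA).
#' @export
proteinIntensities <- function(tab, cols, uniqueOnly = FALSE) {
  keep <- if (uniqueOnly) tab$unique else rep(TRUE, nrow(tab))
  X <- as.matrix(tab[keep, cols, drop = FALSE])
  prot <- tab$protein[keep]
  out <- rowsum(ifelse(is.na(X), 0, X), prot)
  anyObs <- rowsum((!is.na(X)) * 1, prot) > 0
  out[!anyObs] <- NA_real_
  out
}

#' Condition-enriched proteins (fold-change in replicated animals)
#'
#' A protein is enriched in a condition iff its per-animal ratio against
#' the other condition exceeds \code{foldThreshold} (strict) in at least
#' \code{minAnimals} animals. By default the comparison is unpaired: each
#' animal of the candidate condition is compared against the mean of the
#' other condition's animals (the two conditions are distinct
#' individuals); \code{paired = TRUE} instead pairs replicates by index.
#' Optionally intersects with moderated-test significance.
#'
#' @param Xc,Xd numeric matrices proteins x replicates (linear scale) for
#'   the control and disease condition, same rownames.
#' @param foldThreshold ratio threshold, strict inequality (default 4).
#' @param minAnimals minimum number of animals exceeding it (default 2).
#' @param paired pair replicates by index instead of comparing to the
#'   other group's mean (default FALSE).
#' @param p optional named vector of per-protein p-values; with
#'   \code{alpha}, enrichment additionally requires p < alpha.
#' @param alpha significance cutoff used with \code{p}.
#' @return data.frame \code{protein}, \code{enriched_in} in
#'   {control, disease, none}.
#' @export
enrichedProteins <- function(Xc, Xd, foldThreshold = 4, minAnimals = 2L,
                             paired = FALSE, p = NULL, alpha = NULL) {
  stopIfNot(nrow(Xc) == nrow(Xd), "matrices must have the same proteins")
  ratioUp <- if (paired) Xd / Xc else Xd / rowMeans(Xc, na.rm = TRUE)
  ratioDn <- if (paired) Xc / Xd else Xc / rowMeans(Xd, na.rm = TRUE)
  nUp <- rowSums(ratioUp > foldThreshold, na.rm = TRUE)
  nDn <- rowSums(ratioDn > foldThreshold, na.rm = TRUE)
  enriched <- ifelse(nUp >= minAnimals, "disease",
              ifelse(nDn >= minAnimals, "control", "none"))
  if (!is.null(p) && !is.null(alpha)) {
    sig <- p[rownames(Xc)] < alpha
    sig[is.na(sig)] <- FALSE
    enriched[!sig] <- "none"
  }
  data.frame(protein = rownames(Xc), enriched_in = enriched,
             row.names = NULL)
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the selected set contains more term
#' members than expected by chance: p = P(X >= k) with X ~
#' Hypergeometric(N, K, n), where N is the universe size, K the term size
#' within the universe, n the selection size and k the overlap.
#' Benjamini-Hochberg adjustment across terms.
#'
#' @param selected character vector, a subset of \code{universe}.
#' @param terms named list of character vectors (term -> members); members
#'   outside the universe are ignored.
#' @param universe character vector of all eligible items.
#' @return data.frame per term: \code{term}, \code{k}, \code{K}, \code{n},
#'   \code{N}, \code{p}, \code{p_adj}, sorted by p ascending.
#' @export
oraHypergeometric <- function(selected, terms, universe) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(selected)) stop("empty selection", call. = FALSE)
  if (!all(selected %in% universe))
    stop("selected set must be a subset of the universe", call. = FALSE)
  N <- length(universe)
  n <- length(selected)
  res <- lapply(names(terms), function(tm) {
    members <- intersect(unique(terms[[tm]]), universe)
    K <- length(members)
    k <- length(intersect(selected, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p)
  })
  out <- do.call(rbind, res)
  out$p <- pmin(out$p, 1)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Volcano-plot data (log2FC vs -log10 p)
#'
#' @param tab a classified, tested peptide table (with \code{log2FC} and
#'   \code{p} columns).
#' @return data.frame \code{log2FC}, \code{neg_log10_p} plus identifier
#'   columns.
#' @export
volcanoData <- function(tab) {
  stopIfNot(all(c("log2FC", "p") %in% names(tab)),
            "table needs log2FC and p columns")
  keep <- intersect(c("sequence", "protein"), names(tab))
  cbind(tab[, keep, drop = FALSE],
        data.frame(log2FC = tab$log2FC, neg_log10_p = -log10(tab$p)))
}
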