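test_that("imputation draws from the down-shifted column distribution", {
  set.seed(101)
  n <- 20000
  # one column with mean 25, sd 2 on the log2 scale and many missing cells
  obs <- rnorm(n, 25, 2)
  ctrl <- matrix(2^obs, ncol = 1)
  ctrl[sample(n, 10000), 1] <- NA
  tab <- makePeptideTable(cbind(ctrl, 2^rnorm(n, 25, 2), 2^rnorm(n, 25, 2)),
                          matrix(2^rnorm(3 * n, 25, 2), ncol = 3))
  imp <- imputeMissing(tab, seed = 42)
  cc <- attr(tab, "controlCols")
  miss <- imp$flags[, cc[1]]
  obsMean <- mean(log2(tab[[cc[1]]]), na.rm = TRUE)
  obsSd <- sd(log2(tab[[cc[1]]]), na.rm = TRUE)
  drawn <- log2(imp$table[[cc[1]]][miss])
  nDraw <- length(drawn)
  # empirical mean within 3 standard errors of mean - 1.8 sd
  expect_lt(abs(mean(drawn) - (obsMean - 1.8 * obsSd)),
            3 * (0.3 * obsSd) / sqrt(nDraw))
  expect_lt(abs(sd(drawn) - 0.3 * obsSd),
            3 * (0.3 * obsSd) / sqrt(2 * (nDraw - 1)))
  # observed cells never altered; flags partition exactly the missing cells
  expect_identical(imp$table[[cc[1]]][!miss], tab[[cc[1]]][!miss])
  expect_identical(unname(imp$flags), unname(is.na(as.matrix(
    tab[, c(attr(tab, "controlCols"), attr(tab, "diseaseCols"))]))))
})

test_that("imputation is deterministic and a no-op without missing values", {
  set.seed(7)
  full <- makePeptideTable(matrix(2^rnorm(30, 25, 2), ncol = 3),
                           matrix(2^rnorm(30, 25, 2), ncol = 3))
  impFull <- imputeMissing(full, seed = 1)
  expect_identical(impFull$table, full)
  expect_false(any(impFull$flags))

  holey <- full
  holey[["Intensity WT_2"]][c(2, 5)] <- NA
  i1 <- imputeMissing(holey, seed = 9)
  i2 <- imputeMissing(holey, seed = 9)
  expect_identical(i1$table, i2$table)
  i3 <- imputeMissing(holey, seed = 10)
  expect_false(identical(i1$table, i3$table))

  sparse <- holey
  sparse[["Intensity WT_1"]][1:8] <- NA
  expect_error(imputeMissing(sparse, seed = 1), "Intensity WT_1")
})

test_that("moderated test with d0 = 0 is exactly the pooled t-test", {
  set.seed(11)
  n <- 200
  Xc <- 2^matrix(rnorm(3 * n, 25, 2), ncol = 3)
  Xd <- 2^matrix(rnorm(3 * n, 25.5, 2), ncol = 3)
  tab <- makePeptideTable(Xc, Xd)
  mt <- moderatedTTest(tab, d0 = 0)
  ref <- vapply(seq_len(n), function(i) {
    tt <- t.test(log2(Xd[i, ]), log2(Xc[i, ]), var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  }, numeric(2))
  expect_equal(mt$table$t_mod, unname(ref[1, ]), tolerance = 1e-10)
  expect_equal(mt$table$p, unname(ref[2, ]), tolerance = 1e-10)
})

test_that("prior estimation agrees with the limma oracle", {
  set.seed(13)
  n <- 3000
  # heterogeneous true variances so d0 is finite
  sds <- sqrt(1 / rgamma(n, shape = 3, rate = 3))
  Xc <- 2^(25 + matrix(rnorm(3 * n), ncol = 3) * sds)
  Xd <- 2^(25 + matrix(rnorm(3 * n), ncol = 3) * sds)
  tab <- makePeptideTable(Xc, Xd)
  mt <- moderatedTTest(tab)
  fit <- limma::lmFit(log2(cbind(Xc, Xd)),
                      design = cbind(1, rep(0:1, each = 3)))
  eb <- limma::eBayes(fit)
  expect_true(is.finite(mt$params$d0))
  expect_equal(mt$params$d0, eb$df.prior, tolerance = 0.02)
  expect_equal(mt$params$s02, eb$s2.prior, tolerance = 0.02)
  expect_equal(mt$table$t_mod, unname(eb$t[, 2]), tolerance = 1e-6)
  expect_equal(mt$table$p, unname(eb$p.value[, 2]), tolerance = 1e-6)
})

test_that("moderated test limits behave: t = 0 at equal means, d0 = Inf", {
  Xc <- 2^rbind(c(25, 25, 25), c(20, 21, 22))
  Xd <- 2^rbind(c(25, 25, 25), c(22, 21, 20))
  tab <- makePeptideTable(Xc, Xd)
  mt <- moderatedTTest(tab, d0 = 0)
  expect_equal(mt$table$t_mod[1], 0)
  expect_equal(mt$table$p[1], 1)
  # d0 = Inf: z-style statistic with the pooled prior variance
  mtInf <- moderatedTTest(tab, d0 = Inf, s02 = 1)
  expect_equal(mtInf$table$t_mod[2],
               (mean(log2(Xd[2, ])) - mean(log2(Xc[2, ]))) / sqrt(2 / 3))
  expect_equal(mtInf$table$p[2], 2 * pnorm(-abs(mtInf$table$t_mod[2])))
})

test_that("null p-values are calibrated and uniform", {
  set.seed(17)
  n <- 10000
  tab <- makePeptideTable(2^matrix(rnorm(3 * n, 25, 2), ncol = 3),
                          2^matrix(rnorm(3 * n, 25, 2), ncol = 3))
  p <- moderatedTTest(tab)$table$p
  expect_gte(mean(p < 0.05), 0.04)
  expect_lte(mean(p < 0.05), 0.06)
  ks <- max(abs(sort(p) - seq_len(n) / n))
  expect_lt(ks, 0.02)
})

test_that("fold-change classification implements the mean-ratio rule", {
  Xc <- rbind(c(100, 100, 100), c(50, 50, 50), c(80, 80, 80))
  Xd <- rbind(c(400, 400, 400), c(50, 50, 50), c(20, 20, 20))
  tab <- makePeptideTable(Xc, Xd)
  out <- foldChangeClassify(tab)
  expect_equal(out$log2FC, c(2, 0, -2))
  expect_identical(out$group, c("AROM", "unclassified", "WT"))
  expect_equal(out$mu, c(400, 50, 80))  # group-side mean
  # planted negative fold changes classify control-side at default noise
  cfg <- simConfig(nProteins = 80, missingQuantile = 0, seed = 19,
                   imsPeptidesPerRegion = 10)
  gen <- generateLcmsTable(cfg)
  ptab <- readPeptideTable({
    f <- tempfile(); writeLcmsTable(gen$table, f); f
  })
  cls <- foldChangeClassify(ptab)
  down <- gen$truth$peptides$plantedLog2FC == -3
  expect_gte(mean(cls$group[down] == "WT"), 0.95)
})

test_that("protein validation applies the m-of-n unique peptide rule", {
  ctrl <- rbind(c(10, 20, NA), c(10, NA, NA), c(5, 5, 5), c(NA, NA, NA))
  dis <- rbind(c(NA, NA, NA), c(1, 2, 3), c(7, NA, 8), c(4, 4, NA))
  tab <- makePeptideTable(ctrl, dis,
                          protein = c("A", "B", "C", "D"),
                          uniqueFlag = c(TRUE, TRUE, TRUE, FALSE))
  v <- validateProteins(tab)
  expect_identical(v$status[v$protein == "A"], "exclusive_control")  # T,T,F
  expect_identical(v$status[v$protein == "B"], "exclusive_disease")  # T,F,F ctrl
  expect_identical(v$status[v$protein == "C"], "shared")
  expect_identical(v$status[v$protein == "D"], "absent")  # not unique
  # permuting rows never changes the outcome
  perm <- tab[c(3, 1, 4, 2), ]
  attr(perm, "controlCols") <- attr(tab, "controlCols")
  attr(perm, "diseaseCols") <- attr(tab, "diseaseCols")
  expect_identical(validateProteins(perm), v)
})

test_that("exclusive sets equal planted sets at zero missingness", {
  cfg <- simConfig(nProteins = 40, missingQuantile = 0, seed = 23,
                   imsPeptidesPerRegion = 5)
  gen <- generateLcmsTable(cfg)
  f <- tempfile(); writeLcmsTable(gen$table, f)
  tab <- readPeptideTable(f)
  v <- validateProteins(tab)
  # nothing missing, so every protein is shared
  expect_true(all(v$status == "shared"))
})

test_that("enrichment uses a strict >4-fold rule in >= 2 animals", {
  Xc <- rbind(A = c(10, 10, 10), B = c(10, 10, 10), C = c(10, 10, 10))
  Xd <- rbind(A = c(50, 50, 10), B = c(40, 40, 40), C = c(50, 10, 50))
  out <- enrichedProteins(Xc, Xd, paired = TRUE)
  expect_identical(out$enriched_in, c("disease", "none", "disease"))
  # unpaired default compares each animal to the other group's mean
  outU <- enrichedProteins(Xc, Xd)
  expect_identical(outU$enriched_in[1], "disease")
  expect_identical(outU$enriched_in[2], "none")  # ratio exactly 4, strict
  # significance gate
  p <- c(A = 0.001, B = 0.5, C = 0.2)
  gated <- enrichedProteins(Xc, Xd, paired = TRUE, p = p, alpha = 0.05)
  expect_identical(gated$enriched_in, c("disease", "none", "none"))
})

test_that("hypergeometric ORA is exact and BH-monotone", {
  # zero overlap is never over-represented: p = P(X >= 0) = 1, and the
  # same configuration with k = 1 gives P(X >= 1) = K*n/N = 0.1 exactly
  ora0 <- oraHypergeometric("g2", list(t1 = "g1"), paste0("g", 1:10))
  expect_equal(ora0$p, 1, tolerance = 1e-12)
  ora1 <- oraHypergeometric("g1", list(t1 = "g1"), paste0("g", 1:10))
  expect_equal(ora1$p, 0.1, tolerance = 1e-12)
  expect_equal(ora1$p, enumerationHyper(1, 1, 1, 10), tolerance = 1e-12)
  # N = 20, K = 5, n = 6, k = 4
  uni <- paste0("g", 1:20)
  sel <- c(paste0("g", 1:4), "g10", "g11")
  term <- list(path = paste0("g", 1:5))
  ora <- oraHypergeometric(sel, term, uni)
  expect_equal(ora$p,
               (choose(5, 4) * choose(15, 2) + choose(5, 5) * choose(15, 1)) /
                 choose(20, 6), tolerance = 1e-12)
  expect_equal(ora$p, enumerationHyper(4, 5, 6, 20), tolerance = 1e-12)
  # term = universe: certain event
  oraAll <- oraHypergeometric(sel, list(all = uni), uni)
  expect_equal(oraAll$p, 1)
  # BH monotone in p
  set.seed(31)
  terms <- lapply(1:20, function(i) sample(uni, sample(3:10, 1)))
  names(terms) <- paste0("t", 1:20)
  res <- oraHypergeometric(sel, terms, uni)
  expect_identical(order(res$p), order(rank(res$p_adj, ties.method = "first")))
  expect_true(all(res$p_adj >= res$p))
  expect_error(oraHypergeometric(character(0), terms, uni), "empty")
  expect_error(oraHypergeometric(c("zz"), terms, uni), "subset")
})

test_that("volcano export carries the plot axes", {
  set.seed(5)
  tab <- makePeptideTable(2^matrix(rnorm(30, 25, 2), ncol = 3),
                          2^matrix(rnorm(30, 25, 2), ncol = 3))
  cls <- foldChangeClassify(moderatedTTest(tab)$table)
  v <- volcanoData(cls)
  expect_equal(v$neg_log10_p, -log10(cls$p))
  expect_equal(v$log2FC, cls$log2FC)
})
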