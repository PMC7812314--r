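statsFixture <- function(n = 50, seed = 1, group = NULL) {
  set.seed(seed)
  data.frame(
    sequence = sprintf("PEP%04dK", seq_len(n)),
    mass = sort(runif(n, 700, 3000)),
    protein = sprintf("P%04d", seq_len(n)),
    group = group %||% sample(c("WT", "AROM"), n, replace = TRUE),
    mu = 2^runif(n, 20, 30),
    log2FC = round(runif(n, -4, 4), 2),
    p = 10^runif(n, -8, -0.5))
}

test_that("tau search matches exact masses and rejects out-of-window ones", {
  stats <- statsFixture(5, seed = 2, group = rep("AROM", 5))
  mh <- stats$mass[3] + 1.007276
  mono <- data.frame(mono_mz = c(mh, mh + 0.11), cluster = 1L)
  cand <- tauSearch(mono, stats, clusterConditions = c("1" = "AROM"),
                    tau = 0.1)
  exact <- cand[cand$ims_mz == mh & cand$status == "candidate", ]
  expect_true(stats$sequence[3] %in% exact$sequence)
  expect_equal(exact$delta[exact$sequence == stats$sequence[3]], 0)
  # 0.11 beyond tau = 0.1 (strict <=): unmatched, but still reported
  off <- cand[cand$ims_mz == mh + 0.11, ]
  expect_identical(off$status, "unmatched")
  expect_error(tauSearch(mono, stats, c("1" = "AROM"), tau = 0), "positive")
  expect_error(tauSearch(mono, stats, c("2" = "AROM")), "cluster")
})

test_that("tau search equals the brute-force all-pairs oracle", {
  set.seed(3)
  nPep <- 2000
  stats <- statsFixture(nPep, seed = 3)
  queries <- data.frame(mono_mz = runif(500, 700, 3001), cluster = 1L)
  conds <- c("1" = "AROM")
  cand <- tauSearch(queries, stats, conds, tau = 0.1)
  mh <- stats$mass + 1.007276
  for (i in sample(nrow(queries), 50)) {
    q <- queries$mono_mz[i]
    oracle <- which(abs(q - mh) <= 0.1 & stats$group == "AROM")
    got <- cand$sequence[cand$ims_mz == q & cand$status == "candidate"]
    expect_setequal(got, stats$sequence[oracle])
  }
  # group restriction is a hard invariant
  expect_true(all(cand$condition == "AROM"))
  matchedGroups <- stats$group[match(cand$sequence[cand$status == "candidate"],
                                     stats$sequence)]
  expect_true(all(matchedGroups == "AROM"))
})

test_that("MLP score implements mu * |log2FC| / p and its monotonicity", {
  expect_equal(mlpScore(1e6, 2, 1e-3), 2e9)
  expect_equal(mlpScore(1e6, -2, 1e-3), 2e9)
  expect_equal(mlpScore(1e6, -2, 1e-3, signed = TRUE), -2e9)
  expect_equal(mlpScore(5, 0, 0.01), 0)
  set.seed(4)
  for (i in 1:20) {
    mu <- runif(1, 1, 1e6); fc <- runif(1, 0.1, 4); p <- runif(1, 1e-8, 0.9)
    base <- mlpScore(mu, fc, p)
    expect_gt(mlpScore(mu * 1.1, fc, p), base)   # increasing in mu
    expect_gt(mlpScore(mu, fc * 1.1, p), base)   # increasing in |FC|
    expect_gt(mlpScore(mu, fc, p * 0.9), base)   # decreasing in p
  }
  expect_error(mlpScore(1, 1, 0), "positive")
})

test_that("higher-abundance candidate wins at equal fold change and p", {
  stats <- data.frame(
    sequence = c("AK", "BK"), mass = c(1000, 1000.02),
    protein = c("PA", "PB"), group = "AROM",
    mu = c(1e5, 1e6), log2FC = c(2, 2), p = c(1e-3, 1e-3))
  mono <- data.frame(mono_mz = 1001.01, cluster = 1L)
  cand <- tauSearch(mono, stats, c("1" = "AROM"))
  asg <- assignProteins(cand)
  expect_identical(asg$protein, "PB")
  expect_identical(asg$n_candidates, 2L)
  expect_false(asg$ambiguous)  # equal FC and p, mu 10x apart: ratio 10 >= 2
})

test_that("assignment tie-breaks and statuses are deterministic", {
  stats <- data.frame(
    sequence = c("AK", "BK", "CK"), mass = c(1000, 1000.05, 1000.01),
    protein = c("PC", "PB", "PA"), group = "WT",
    mu = c(10, 10, 10), log2FC = c(-1, -1, -1), p = c(0.01, 0.01, 0.01))
  mono <- data.frame(mono_mz = 1001.017276, cluster = 2L)
  asg <- assignProteins(tauSearch(mono, stats, c("2" = "WT")))
  # all scores equal, mu equal: smallest |delta| wins (mass 1000.01)
  expect_identical(asg$protein, "PA")
  expect_true(asg$ambiguous)

  # permutation invariance of candidate order
  cand <- tauSearch(mono, stats, c("2" = "WT"))
  candPerm <- cand[c(2, 3, 1), ]
  expect_identical(assignProteins(candPerm)$protein, "PA")

  # no candidates: unmatched carried through
  asgNone <- assignProteins(tauSearch(data.frame(mono_mz = 2500, cluster = 2L),
                                      stats, c("2" = "WT")))
  expect_identical(asgNone$status, "unmatched")
  expect_identical(asgNone$n_candidates, 0L)

  # single candidate: wins, not ambiguous
  one <- assignProteins(tauSearch(data.frame(mono_mz = 1001.06, cluster = 2L),
                                  stats[2, ], c("2" = "WT")))
  expect_identical(one$protein, "PB")
  expect_false(one$ambiguous)
})

test_that("cluster reports partition by cluster and handle empties", {
  stats <- statsFixture(40, seed = 6, group = rep(c("WT", "AROM"), 20))
  wt <- stats[stats$group == "WT", ]
  ar <- stats[stats$group == "AROM", ]
  mono <- data.frame(
    mono_mz = c(wt$mass[1:5] + 1.007276, ar$mass[1:5] + 1.007276,
                650.123),
    cluster = rep(c(1L, 2L, 3L), c(5, 5, 1)))
  conds <- c("1" = "WT", "2" = "AROM", "3" = "AROM")
  asg <- assignProteins(tauSearch(mono, stats, conds))
  reports <- clusterReport(asg)
  expect_setequal(names(reports), c("1", "2", "3"))
  # disjoint planted sets give disjoint protein lists
  expect_length(intersect(reports[["1"]]$protein, reports[["2"]]$protein), 0)
  # cluster with zero matched masses: empty table with the right columns
  expect_identical(nrow(reports[["3"]]), 0L)
  expect_true(all(c("protein", "mlp", "ims_mz") %in% names(reports[["3"]])))
  # regenerating the report from the same assignments is identical
  d1 <- tempfile(); d2 <- tempfile()
  exportClusterReports(reports, d1)
  exportClusterReports(clusterReport(asg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("planted parent proteins beat decoy near-isobars", {
  cfg <- simConfig(nProteins = 80, imsPeptidesPerRegion = 15,
                   decoysPerPeptide = 3, missingQuantile = 0.05, seed = 8)
  gen <- generateLcmsTable(cfg)
  f <- tempfile(); writeLcmsTable(gen$table, f)
  tab <- readPeptideTable(f)
  imp <- imputeMissing(tab, seed = 8)
  cls <- foldChangeClassify(moderatedTTest(imp$table)$table)
  tp <- gen$truth$peptides
  planted <- tp[!is.na(tp$imsRegion), ]
  regionCond <- gen$truth$regions$condition
  mono <- data.frame(mono_mz = planted$monoMH, cluster = planted$imsRegion)
  conds <- stats::setNames(regionCond, gen$truth$regions$region)
  asg <- assignProteins(tauSearch(mono, cls, conds))
  ok <- asg$status == "assigned"
  recovery <- mean(asg$protein[ok] ==
                     planted$protein[match(asg$ims_mz[ok], planted$monoMH)])
  expect_gte(recovery, 0.9)
})
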