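# hand-built cluster peak set: peaks (mz, intensity), images = matrix
# peaks x pixels
makeCps <- function(mz, intensity, images, cluster = 1L) {
  structure(list(cluster = cluster,
                 peaks = data.frame(mz = mz, intensity = intensity,
                                    support = ncol(images)),
                 images = images, pixels = seq_len(ncol(images)),
                 noise = data.frame(mz = numeric(0), intensity = numeric(0))),
            class = "ClusterPeakSet")
}

# an averagine-consistent envelope at mono mass m with a given image
plantEnvelope <- function(m, image, base = 100, nIso = 4) {
  rel <- averagineEnvelope(m, nIso)$intensity
  list(mz = m + (seq_len(nIso) - 1) * 1.00235, intensity = base * rel,
       images = matrix(rep(image, nIso), nrow = nIso, byrow = TRUE))
}

test_that("colocalization is Pearson correlation with explicit errors", {
  img <- c(1, 4, 2, 8, 5, 7)
  expect_equal(colocalization(img, img), 1.0)
  expect_equal(colocalization(img, mean(img) - (img - mean(img))), -1.0)
  expect_error(colocalization(img, rep(3, 6)), "zero-variance")
  expect_error(colocalization(img, img[-1]), "same pixel set")
  # disjoint-region images anticorrelate on a two-region layout
  a <- c(5, 6, 7, 0, 0, 0)
  b <- c(0, 0, 0, 4, 6, 5)
  expect_lt(colocalization(a, b), 0)
})

test_that("a clean envelope collapses to one entry with all members", {
  img <- c(10, 3, 7, 1, 9, 4, 6, 2)
  env <- plantEnvelope(1200, img)
  cps <- makeCps(env$mz, env$intensity, env$images)
  ml <- deisotopeCluster(cps)
  e <- monoEntries(ml)
  expect_identical(nrow(e), 1L)
  expect_equal(e$mono_mz, 1200)
  expect_identical(e$n_member_peaks, 4L)
  expect_equal(e$members[[1]], env$mz)
  expect_equal(e$intensity, sum(env$intensity))
})

test_that("non-co-localized peaks 1 Da apart stay separate (overlap case)", {
  # the overlapping-envelope scenario: two peptides in disjoint regions
  imgA <- c(9, 8, 7, 9, 0, 0, 0, 0)
  imgB <- c(0, 0, 0, 0, 6, 7, 8, 6)
  rel2 <- averagineEnvelope(900, 2)$intensity[2]
  cps <- makeCps(c(900, 900 + 1.00235), c(100, 100 * rel2),
                 rbind(imgA, imgB))
  e <- monoEntries(deisotopeCluster(cps))
  expect_identical(nrow(e), 2L)
  expect_true(all(e$n_member_peaks == 1L))
  # same masses, shared image: they merge
  cpsSame <- makeCps(c(900, 900 + 1.00235), c(100, 100 * rel2),
                     rbind(imgA, imgA))
  expect_identical(nrow(monoEntries(deisotopeCluster(cpsSame))), 1L)
})

test_that("spacing outside the m/z tolerance separates peaks", {
  img <- c(5, 1, 4, 2, 6, 3, 7, 2)
  cps <- makeCps(c(900, 901.25), c(100, 50), rbind(img, img))
  e <- monoEntries(deisotopeCluster(cps, mzTol = 0.15))
  expect_identical(nrow(e), 2L)  # 1.25 is outside 1.00235 +/- 0.15
})

test_that("intensity outside the averagine tolerance separates peaks", {
  img <- c(5, 1, 4, 2, 6, 3, 7, 2)
  rel2 <- averagineEnvelope(900, 2)$intensity[2]
  # observed second isotope at 3x expectation: rejected at 50% tolerance
  cps <- makeCps(c(900, 900 + 1.00235), c(100, 300 * rel2),
                 rbind(img, img))
  e <- monoEntries(deisotopeCluster(cps, intensityTol = 0.5))
  expect_identical(nrow(e), 2L)
})

test_that("peak conservation holds cluster-wise on noisy synthetic data", {
  cfg <- simConfig(gridShape = c(16, 16), imsPeptidesPerRegion = 6,
                   nRegions = 2, seed = 13)
  gen <- generateLcmsTable(cfg)
  out <- generateImsDataset(cfg, gen$truth)
  ds <- ticNormalize(out$dataset)
  labels <- out$truth$pixelRegions$region
  for (cl in 1:2) {
    cps <- clusterPeakSet(ds, labels, cl)
    nInput <- nrow(cps$peaks) + nrow(cps$noise)
    ml <- deisotopeCluster(cps)
    nExplained <- sum(monoEntries(ml)$n_member_peaks)
    expect_identical(nInput, nExplained + nrow(unassignedPeaks(ml)))
  }
})

test_that("greedy matches exhaustive search on small instances", {
  set.seed(29)
  for (rep in 1:6) {
    nEnv <- sample(2:3, 1)
    monos <- sort(600 + cumsum(runif(nEnv, 6, 30)))
    pieces <- lapply(monos, function(m)
      plantEnvelope(m, runif(8, 0, 10), base = runif(1, 50, 200),
                    nIso = sample(2:4, 1)))
    mz <- unlist(lapply(pieces, `[[`, "mz"))
    intensity <- unlist(lapply(pieces, `[[`, "intensity"))
    images <- do.call(rbind, lapply(pieces, `[[`, "images"))
    # add detached noise singletons far from any envelope
    mz <- c(mz, max(mz) + c(10.5, 25.7))
    intensity <- c(intensity, 20, 30)
    images <- rbind(images, runif(8, 0, 10), runif(8, 0, 10))
    cps <- makeCps(mz, intensity, images)
    g <- monoEntries(deisotopeCluster(cps, method = "greedy"))
    x <- monoEntries(deisotopeCluster(cps, method = "exhaustive"))
    expect_equal(g$mono_mz, x$mono_mz)
    expect_identical(g$n_member_peaks, x$n_member_peaks)
    expect_equal(g$members, x$members)
  }
})

test_that("deisotopeAll pools clusters and degenerates sensibly", {
  cfg <- simConfig(gridShape = c(16, 16), imsPeptidesPerRegion = 6,
                   nRegions = 2, seed = 17)
  gen <- generateLcmsTable(cfg)
  out <- generateImsDataset(cfg, gen$truth)
  ds <- ticNormalize(out$dataset)
  labels <- out$truth$pixelRegions$region
  res <- deisotopeAll(ds, labels)
  planted <- out$truth$peptides[!is.na(out$truth$peptides$imsRegion), ]
  # pooled unique count equals the planted count (no collisions this seed)
  expect_equal(nrow(res$pooled), nrow(planted), tolerance = 0.15)
  # each planted mono recovered in its own cluster within 0.05 Da
  e <- monoEntries(res$monoList)
  hit <- vapply(seq_len(nrow(planted)), function(i)
    any(e$cluster == planted$imsRegion[i] &
          abs(e$mono_mz - planted$monoMH[i]) <= 0.05), logical(1))
  expect_gte(mean(hit), 0.95)

  # k = 1 equals deisotoping the whole image as one cluster
  one <- deisotopeAll(ds, rep(1L, nPixels(ds)))
  direct <- deisotopeCluster(clusterPeakSet(ds, rep(1L, nPixels(ds)), 1L))
  expect_equal(monoEntries(one$monoList)$mono_mz,
               monoEntries(direct)$mono_mz)

  # dataset with zero peaks in a cluster yields empty lists, not errors
  empty <- deisotopeCluster(clusterPeakSet(
    imsDataset(coords = data.frame(x = 0:1, y = c(0L, 0L)),
               peaks = list(data.frame(mz = 700, intensity = 1),
                            emptyPeaks()),
               massRange = c(600, 3200)),
    labels = c(2L, 1L), cluster = 1L))
  expect_identical(nrow(monoEntries(empty)), 0L)
})

test_that("mono list export round-trips", {
  env <- plantEnvelope(1000, c(5, 2, 8, 1, 9, 3, 7, 4))
  cps <- makeCps(env$mz, env$intensity, env$images)
  ml <- deisotopeCluster(cps)
  path <- tempfile()
  exportMonoList(ml, path)
  back <- readMonoList(path)
  expect_equal(back$mono_mz, monoEntries(ml)$mono_mz)
  expect_identical(back$n_member_peaks, monoEntries(ml)$n_member_peaks)
})
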