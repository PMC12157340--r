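# pair_search: chi-square engine, stage-1 screen, stage-2 packed scan

test_that("chi-square engine matches hand-evaluated tables", {
  expect_equal(chiSquare2x2(10, 10, 10, 10), data.frame(chi2 = 0, p = 1))
  # hand evaluation: n(ad-bc)^2/margins = 60*450^2/787500 = 108/7,
  # survival via the normal tail 2*pnorm(-sqrt(108/7)) = 8.5683e-05
  r <- chiSquare2x2(20, 10, 5, 25)
  expect_equal(r$chi2, 108 / 7, tolerance = 1e-12)
  expect_equal(r$p, 8.5682980109e-05, tolerance = 1e-9)
  # case/control swap symmetry
  expect_equal(chiSquare2x2(20, 10, 5, 25), chiSquare2x2(5, 25, 20, 10))
  # zero margin is defined non-significant
  expect_equal(chiSquare2x2(0, 0, 3, 7), data.frame(chi2 = 0, p = 1))
  expect_error(chiSquare2x2(-1, 2, 3, 4), "negative")
})

test_that("chi-square engine agrees with stats::chisq.test on random
           tables and the Yates option matches the corrected test", {
  set.seed(99)
  for (i in 1:50) {
    t <- matrix(rpois(4, 30) + 1, 2)
    mine <- chiSquare2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
    ref <- suppressWarnings(chisq.test(t, correct = FALSE))
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    refY <- suppressWarnings(chisq.test(t, correct = TRUE))
    mineY <- chiSquare2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2],
                          correct = TRUE)
    expect_equal(mineY$chi2, unname(refY$statistic), tolerance = 1e-12)
  }
})

test_that("stage-1 screen retains maximal-association variants and
           nests across thresholds", {
  set.seed(7)
  nFam <- 40L
  coh <- makeToyCohort(probandSex = rep("M", nFam),
                       siblingSex = rep("M", nFam))
  fam <- families(coh)
  ids <- sampleInfo(coh)$sample_id
  P <- matrix(runif(length(ids) * 30) < 0.3, length(ids), 30,
              dimnames = list(ids, NULL))
  P[, 1] <- FALSE
  P[fam$proband_id, 1] <- TRUE      # present in all cases, no controls
  pm <- makeToyPresence(P)
  lab <- associationLabels(coh, "screen")
  sc <- screenVariants(pm, lab, pInitial = 1e-3)
  expect_true(1L %in% sc$preselected)
  strict <- screenVariants(pm, lab, pInitial = 1e-4)$preselected
  expect_true(all(strict %in% sc$preselected))
  # summary counts are consistent with the per-variant results
  expect_identical(sum(sc$summary$n_significant[
    sc$summary$threshold == 1e-3]), length(sc$preselected))
})

test_that("packed pair scan equals the naive per-genotype oracle", {
  set.seed(42)
  for (rep in 1:10) {
    ns <- sample(20:200, 1); nv <- sample(4:40, 1)
    P <- matrix(runif(ns * nv) < runif(1, 0.1, 0.5), ns, nv,
                dimnames = list(sprintf("s%03d", seq_len(ns)), NULL))
    pm <- makeToyPresence(P)
    caseRows <- seq_len(ns %/% 2); ctrlRows <- (ns %/% 2 + 1L):ns
    lab <- data.frame(sample_id = rownames(P),
                      label = c(rep(1L, length(caseRows)),
                                rep(0L, length(ctrlRows))),
                      weight = 1)
    got <- scanPairs(pm, seq_len(nv), lab, pFinal = 0.6)
    want <- naivePairScan(P, caseRows, ctrlRows, 0.6)
    expect_identical(nrow(got), nrow(want))
    gi <- match(got$id1, variantInfo(pm)$id)
    gj <- match(got$id2, variantInfo(pm)$id)
    expect_identical(unname(gi), want$i)
    expect_identical(unname(gj), want$j)
    expect_identical(got$a, want$a)
    expect_identical(got$c, want$c)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("pair scan honours its contracts: membership, threshold,
           Bonferroni mode and label-swap symmetry", {
  sim <- simulateCohort(simulationConfig(nFamilies = 80L,
                                         nVariants = 400L,
                                         nPlantedPairs = 6L, seed = 3L))
  lab <- associationLabels(sim$cohort, "screen")
  sc <- screenVariants(sim$presence, lab)
  pr <- scanPairs(sim$presence, sc$preselected, lab)
  pre <- variantInfo(sim$presence)$id[sc$preselected]
  expect_true(all(pr$id1 %in% pre) && all(pr$id2 %in% pre))
  expect_true(all(pr$p < attr(pr, "p_final")))

  bon <- scanPairs(sim$presence, sc$preselected, lab,
                   bonferroniAuto = TRUE)
  expect_equal(attr(bon, "p_final"),
               0.05 / choose(length(sc$preselected), 2))

  swapped <- lab
  swapped$label <- 1L - swapped$label
  pr2 <- scanPairs(sim$presence, sc$preselected, swapped)
  expect_identical(pr[, c("id1", "id2")], pr2[, c("id1", "id2")])
  expect_equal(pr$p, pr2$p)
})

test_that("search summary aggregates counts consistently", {
  empty <- summarizeSearch(data.frame(id1 = character(0),
                                      id2 = character(0),
                                      chrom1 = character(0),
                                      chrom2 = character(0)))
  expect_identical(empty$n_pairs, 0L)
  expect_identical(empty$n_unique_variants, 0L)

  pr <- data.frame(id1 = c("chr1:1:A:T", "chr1:1:A:T", "chr1:1:A:T"),
                   id2 = c("chr2:2:A:T", "chr2:2:A:T", "chr3:3:A:T"),
                   chrom1 = "chr1", chrom2 = c("chr2", "chr2", "chr3"))
  s <- summarizeSearch(pr)
  expect_identical(s$n_pairs, 3L)
  expect_lte(s$n_unique_variants, 6L)
  expect_identical(s$n_unique_variants, 3L)
})

test_that("paired family sampling makes the naive chi-square
           conservative, while unrelated groups are calibrated", {
  sim <- simulateCohort(simulationConfig(nFamilies = 300L,
                                         nVariants = 3000L,
                                         nPlantedPairs = 0L, seed = 17L))
  P <- presence(sim$presence)
  fam <- families(sim$cohort)
  lab <- associationLabels(sim$cohort, "screen")
  sc <- screenVariants(sim$presence, lab, pInitial = 0.05)
  # proband-vs-sibling contrast: fewer hits than nominal (conservative)
  expect_lt(length(sc$preselected) / 3000, 0.05)
  # two unrelated groups of probands: nominal calibration
  pro <- fam$proband_id
  a <- colSums(P[pro[1:150], ]); c <- colSums(P[pro[151:300], ])
  p <- chiSquare2x2(a, 150 - a, c, 150 - c)$p
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 3000))
})
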