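# synthetic cohort generator

test_that("identical seed and configuration give byte-identical output", {
  cfg <- simulationConfig(nFamilies = 30L, nVariants = 120L,
                          nPlantedPairs = 4L, seed = 11L)
  s1 <- simulateCohort(cfg)
  s2 <- simulateCohort(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(families(s1$cohort), families(s2$cohort))
  d1 <- file.path(tempdir(), "emit1"); d2 <- file.path(tempdir(), "emit2")
  f1 <- emitVcfPed(s1, d1); f2 <- emitVcfPed(s2, d2)
  expect_identical(readLines(f1$vcf), readLines(f2$vcf))
  expect_identical(readLines(f1$ped), readLines(f2$ped))
})

test_that("non-de-novo child alleles are Mendelian-consistent and the
           violation count equals the recorded de novo count", {
  cfg <- simulationConfig(nFamilies = 60L, nVariants = 300L,
                          nPlantedPairs = 5L, deNovoRate = 0.05,
                          backgroundDeNovoRate = 0.002,
                          somaticNoiseRate = 0, seed = 4L)
  sim <- simulateCohort(cfg)
  G <- sim$genotypes
  fam <- families(sim$cohort)
  violations <- 0L
  for (i in seq_len(nrow(fam))) {
    for (child in c(fam$proband_id[i], fam$sibling_id[i])) {
      carrier <- G[child, ] > 0L
      parentHas <- G[fam$father_id[i], ] > 0L | G[fam$mother_id[i], ] > 0L
      violations <- violations + sum(carrier & !parentHas)
    }
  }
  expect_identical(violations, nrow(sim$truth$deNovo))
})

test_that("proband male fraction hits the ascertainment target at scale", {
  cfg <- simulationConfig(nFamilies = 1926L, nVariants = 40L,
                          nPlantedPairs = 0L, seed = 8L)
  sim <- simulateCohort(cfg)
  frac <- mean(families(sim$cohort)$proband_sex == "M")
  tol <- 3 * sqrt(0.868 * 0.132 / 1926)
  expect_lt(abs(frac - 0.868), tol)
})

test_that("null cohort is exchangeable between probands and siblings", {
  sim <- simulateCohort(simulationConfig(nFamilies = 200L,
                                         nVariants = 500L,
                                         nPlantedPairs = 0L, seed = 2L))
  P <- presence(sim$presence)
  fam <- families(sim$cohort)
  diff <- colMeans(P[fam$proband_id, ]) - colMeans(P[fam$sibling_id, ])
  # mean carrier-frequency difference is zero up to sampling noise
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(length(diff)))
})

test_that("case prevalence ratio among joint carriers matches the
           closed-form enumeration over the generator's law", {
  cfg <- simulationConfig(nFamilies = 1200L, nVariants = 30L,
                          nPlantedPairs = 1L, deNovoRate = 0,
                          somaticNoiseRate = 0, seed = 21L)
  expected <- prevalenceRatioOracle(cfg)
  sim <- simulateCohort(cfg)
  fam <- families(sim$cohort)
  P <- presence(sim$presence)
  tp <- sim$truth$plantedPairs
  children <- c(fam$proband_id, fam$sibling_id)
  joint <- P[children, tp$idx1] & P[children, tp$idx2]
  case <- children %in% fam$proband_id
  ratio <- (mean(case[joint]) / mean(case[!joint]))
  expect_lt(abs(ratio - expected) / expected, 0.2)
})

test_that("degenerate liability configurations fail explicitly", {
  expect_error(simulationConfig(baselineLiability = 0, nPlantedPairs = 0L),
               "no achievable case")
})

test_that("emitted allele depths are binomial around the expected alt
           fraction and artifact genotypes stay under 25%", {
  cfg <- simulationConfig(nFamilies = 40L, nVariants = 200L,
                          nPlantedPairs = 2L, somaticNoiseRate = 0.01,
                          seed = 14L)
  sim <- simulateCohort(cfg)
  out <- emitVcfPed(sim, file.path(tempdir(), "adcheck"))
  vcf <- vcfR::read.vcfR(out$vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, "GT")
  ad <- vcfR::extract.gt(vcf, "AD")
  frac <- function(x) {
    p <- as.numeric(strsplit(x, ",")[[1]])
    p[2] / sum(p)
  }
  # map genotype-matrix (sample x variant) linear indices into the
  # vcfR matrices (variant x sample)
  G <- sim$genotypes
  nV <- ncol(G)
  toVcfCell <- function(lin) {
    rv <- arrayInd(lin, dim(G))
    (rv[, 1] - 1L) * nV + rv[, 2]
  }
  # true het genotypes concentrate near 0.5
  het <- setdiff(which(G == 1L), sim$truth$noiseIdx)
  hetFrac <- vapply(ad[toVcfCell(het[1:500])], frac, numeric(1))
  expect_lt(abs(mean(hetFrac) - 0.5), 0.02)
  # artifact genotypes: written 0/1 with alt fraction strictly < 0.25
  ni <- toVcfCell(sim$truth$noiseIdx)
  expect_true(all(gt[ni] == "0/1"))
  noiseFrac <- vapply(ad[ni], frac, numeric(1))
  expect_true(all(noiseFrac < 0.25))
  expect_true(all(noiseFrac > 0))
})

test_that("emit -> ingest at threshold 0 reproduces the presence matrix", {
  cfg <- simulationConfig(nFamilies = 40L, nVariants = 250L,
                          nPlantedPairs = 3L, somaticNoiseRate = 0.005,
                          seed = 6L)
  sim <- simulateCohort(cfg)
  out <- emitVcfPed(sim, file.path(tempdir(), "rt"))
  ing <- ingestCohort(out$vcf, out$ped, minAdFraction = 0,
                      genderPolicy = "none")
  P0 <- presence(sim$presence)
  keep <- colSums(P0) > 0           # zero-carrier sites are dropped
  expect_identical(
    unname(presence(ing$presence)[rownames(P0), colnames(P0)[keep]]),
    unname(P0[, keep]))
  # and the 25% filter removes every planted artifact genotype
  ing25 <- ingestCohort(out$vcf, out$ped, minAdFraction = 0.25,
                        genderPolicy = "none")
  P25 <- presence(ing25$presence)
  common <- intersect(colnames(P25), colnames(P0))
  ni <- sim$truth$noiseIdx
  noisePairs <- arrayInd(ni, dim(P0))
  keepNoise <- colnames(P0)[noisePairs[, 2]] %in% common
  idx <- cbind(rownames(P0)[noisePairs[keepNoise, 1]],
               colnames(P0)[noisePairs[keepNoise, 2]])
  expect_true(all(!P25[idx]))
})
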