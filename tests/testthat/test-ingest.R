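# cohort_io: VCF/PED ingestion, presence rules, gender policy, labels

writeToyVcf <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

writeToyPed <- function(path) {
  ped <- c("F01\tF01_fa\t0\t0\t1\t1",
           "F01\tF01_mo\t0\t0\t2\t1",
           "F01\tF01_p\tF01_fa\tF01_mo\t1\t2",
           "F01\tF01_s\tF01_fa\tF01_mo\t2\t1")
  writeLines(ped, path)
  path
}

toySamples <- c("F01_fa", "F01_mo", "F01_p", "F01_s")

test_that("allele-depth fraction filter applies the inclusive boundary", {
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"), c(
    # proband 0/1 at exactly 25% alt fraction; sibling far below
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/0:40,0\t0/0:40,0\t0/1:30,10\t0/1:38,2",
    "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT:AD\t0/0:40,0\t0/0:40,0\t0/0:20,20\t1/1:0,40"),
    toySamples)
  ped <- writeToyPed(tempfile(fileext = ".ped"))
  at0 <- presence(ingestCohort(vcf, ped, minAdFraction = 0)$presence)
  at25 <- presence(ingestCohort(vcf, ped, minAdFraction = 0.25)$presence)
  v1 <- "chr1:100:A:T"; v2 <- "chr1:200:G:C"
  expect_true(at25["F01_p", v1])     # 10/40 = 0.25 passes (>=)
  expect_false(at25["F01_s", v1])    # 2/40 = 0.05 filtered
  expect_true(at0["F01_s", v1])      # threshold 0 keeps it
  expect_false(at0["F01_fa", v1])    # hom-ref is absence, any AD
  expect_false(at25["F01_p", v2])    # genotype 0/0 despite alt reads
  expect_true(at25["F01_s", v2])     # hom-alt passes
})

test_that("multi-allelic records are split into per-alt variant keys", {
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"), c(
    "chr2\t500\t.\tA\tT,G\t.\tPASS\t.\tGT:AD\t0/1:20,20,0\t0/2:20,0,20\t1/2:0,20,20\t0/0:40,0,0"),
    toySamples)
  ped <- writeToyPed(tempfile(fileext = ".ped"))
  pm <- ingestCohort(vcf, ped, minAdFraction = 0.25)$presence
  expect_setequal(variantInfo(pm)$id, c("chr2:500:A:T", "chr2:500:A:G"))
  P <- presence(pm)
  expect_true(P["F01_fa", "chr2:500:A:T"])
  expect_false(P["F01_fa", "chr2:500:A:G"])
  expect_true(P["F01_mo", "chr2:500:A:G"])
  expect_true(all(P["F01_p", ]))     # 1/2 carries both alts
  expect_false(any(P["F01_s", ]))
})

test_that("missing genotypes are recorded and PED/VCF mismatches fail", {
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD\t./.:0,0\t0/0:40,0\t0/1:20,20\t0/0:40,0"),
    toySamples)
  ped <- writeToyPed(tempfile(fileext = ".ped"))
  res <- ingestCohort(vcf, ped)
  expect_true(missingMask(res$presence)["F01_fa", "chr1:100:A:T"])
  expect_false(presence(res$presence)["F01_fa", "chr1:100:A:T"])

  vcf2 <- writeToyVcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/0:40,0\t0/0:40,0\t0/1:20,20\t0/0:40,0"),
    c("F01_fa", "F01_mo", "F01_p", "OTHER"))
  expect_error(ingestCohort(vcf2, ped), "F01_s")
})

test_that("raising the AD threshold never adds presences", {
  sim <- simulateCohort(simulationConfig(nFamilies = 25L,
                                         nVariants = 150L,
                                         nPlantedPairs = 2L,
                                         somaticNoiseRate = 0.01,
                                         seed = 31L))
  out <- emitVcfPed(sim, file.path(tempdir(), "mono"))
  p0 <- ingestCohort(out$vcf, out$ped, minAdFraction = 0,
                     dropEmpty = FALSE)$presence
  p25 <- ingestCohort(out$vcf, out$ped, minAdFraction = 0.25,
                      dropEmpty = FALSE)$presence
  expect_true(all(presence(p0)[presence(p25)]))
})

test_that("gender-mismatch policies pick the documented control designates", {
  coh <- makeToyCohort(probandSex = c("M", "M", "F"),
                       siblingSex = c("M", "F", "M"))
  none <- families(applyGenderPolicy(coh, "none"))
  expect_identical(none$control_designate_id, none$sibling_id)

  rep <- families(applyGenderPolicy(coh, "replace_sibling"))
  expect_identical(rep$control_designate_id[1], rep$sibling_id[1])
  expect_identical(rep$control_designate_id[2], rep$father_id[2])
  expect_identical(rep$control_designate_id[3], rep$mother_id[3])
  expect_identical(nrow(rep), 3L)    # family count unchanged

  skp <- applyGenderPolicy(coh, "skip_family")
  expect_identical(nrow(families(skp)), 1L)   # 2 mismatches dropped
  expect_identical(families(skp)$family_id, "F01")
  expect_identical(nrow(sampleInfo(skp)), 4L)
})

test_that("association labels and weights follow the two modes", {
  coh <- makeToyCohort(probandSex = rep("M", 5), siblingSex = rep("M", 5))
  scr <- associationLabels(coh, "screen")
  expect_identical(sum(scr$label == 1L), 5L)
  expect_identical(sum(scr$label == 0L), 5L)

  prd <- associationLabels(coh, "predict")
  expect_identical(sum(prd$label == 1L), 5L)
  expect_identical(sum(prd$label == 0L), 15L)
  wPos <- unique(prd$weight[prd$label == 1L])
  wNeg <- unique(prd$weight[prd$label == 0L])
  expect_equal(wPos / wNeg, 3)                      # inverse frequency
  expect_equal(sum(prd$weight[prd$label == 1L]),
               sum(prd$weight[prd$label == 0L]))    # equal class totals
})
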