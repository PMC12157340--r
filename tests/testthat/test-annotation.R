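# annotation_map: gene mapping, network, inheritance, scores

toyAnnotation <- function() {
  geneAnnotation(
    genes = data.frame(
      gene_id = c("GA", "GB", "GC", "PS1", "GL"),
      name = c("GA", "GB", "GC", "PS1", "GL"),
      chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
      start = c(100L, 450L, 2000L, 480L, 100L),
      end = c(500L, 900L, 2500L, 520L, 400L),
      biotype = c("protein_coding", "protein_coding", "protein_coding",
                  "pseudogene", "lncRNA"),
      stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "GC", chrom = "chr1",
                       start = 2100L, end = 2200L))
}

test_that("variant-to-gene mapping applies the exclusion rules", {
  ann <- toyAnnotation()
  v <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr9"),
    pos = c(200L, 470L, 510L, 5000L, 200L, 50L))
  expect_warning(m <- mapVariant(v, ann), "chr9")
  expect_identical(m[1], "GA")          # unique gene
  expect_identical(m[2], "overlap")     # two real genes
  expect_identical(m[3], "GB")          # pseudogene does not block
  expect_identical(m[4], "intergenic")
  expect_identical(m[5], "GL")
  expect_identical(m[6], "intergenic")  # unknown chromosome
})

test_that("gene network counts edges as a multiset and skips
           unmappable pairs", {
  ann <- toyAnnotation()
  mk <- function(c1, p1, c2, p2)
    data.frame(chrom1 = c1, pos1 = p1, ref1 = "A", alt1 = "T",
               chrom2 = c2, pos2 = p2, ref2 = "A", alt2 = "T",
               id1 = variantId(c1, p1, "A", "T"),
               id2 = variantId(c2, p2, "A", "T"))
  pairs <- rbind(
    mk("chr1", 200L, "chr2", 200L),   # GA-GL
    mk("chr1", 210L, "chr2", 210L),   # GA-GL again (distinct variants)
    mk("chr1", 220L, "chr1", 2050L),  # GA-GC
    mk("chr1", 230L, "chr1", 5000L),  # partner intergenic: skipped
    mk("chr1", 240L, "chr1", 495L))   # partner in overlap: skipped
  net <- buildGeneNetwork(pairs, ann)
  expect_identical(net$n_mappable_pairs, 3L)
  e <- net$edges
  expect_identical(e$n_variant_pairs[e$gene1 == "GA" & e$gene2 == "GL"], 2L)
  expect_identical(e$n_variant_pairs[e$gene1 == "GA" & e$gene2 == "GC"], 1L)
  # classes partition the unique variants
  expect_identical(length(net$variant_class),
                   length(unique(c(pairs$id1, pairs$id2))))
  expect_false(any(is.na(net$variant_class)))
})

test_that("synthetic annotation reproduces its planted region fractions
           exactly", {
  sim <- simulateCohort(simulationConfig(nFamilies = 5L,
                                         nVariants = 500L,
                                         nPlantedPairs = 0L, seed = 12L))
  fr <- c(exon = 0.05, protein_coding_noncoding = 0.4, lncRNA = 0.1,
          pseudogene = 0.02)
  ann <- simulateGeneAnnotation(sim$panel, fractions = fr, seed = 3L)
  tally <- table(ann$classes) / length(ann$classes)
  expect_equal(unname(tally["exon"]), floor(0.05 * 500) / 500)
  expect_equal(unname(tally["protein_coding_noncoding"]),
               floor(0.4 * 500) / 500)
  expect_equal(unname(tally["lncRNA"]), floor(0.1 * 500) / 500)
  expect_equal(unname(tally["pseudogene"]), floor(0.02 * 500) / 500)
  # and mapVariant recovers the planted class for every variant
  mapped <- mapVariant(sim$panel, ann$annotation)
  genic <- !(ann$classes %in% c("intergenic", "pseudogene"))
  expect_identical(unname(mapped[genic]), unname(ann$geneOf[genic]))
  expect_true(all(mapped[ann$classes == "pseudogene"] == "pseudogene"))
  expect_true(all(mapped[ann$classes == "intergenic"] == "intergenic"))
})

test_that("inheritance classification matches the exhaustive trio table", {
  states <- c("carrier", "noncarrier", "missing")
  combos <- expand.grid(father = states, mother = states,
                        stringsAsFactors = FALSE)
  coh <- makeToyCohort(probandSex = rep("M", nrow(combos)),
                       siblingSex = rep("M", nrow(combos)))
  fam <- families(coh)
  ids <- sampleInfo(coh)$sample_id
  P <- matrix(FALSE, length(ids), 1L, dimnames = list(ids, NULL))
  M <- matrix(FALSE, length(ids), 1L, dimnames = list(ids, NULL))
  P[fam$proband_id, 1] <- TRUE        # every proband carries
  for (i in seq_len(nrow(combos))) {
    P[fam$father_id[i], 1] <- combos$father[i] == "carrier"
    M[fam$father_id[i], 1] <- combos$father[i] == "missing"
    P[fam$mother_id[i], 1] <- combos$mother[i] == "carrier"
    M[fam$mother_id[i], 1] <- combos$mother[i] == "missing"
  }
  pm <- makeToyPresence(P, missing = M)
  res <- classifyInheritance(pm, coh, children = "proband")
  got <- res$occurrences$status[match(fam$proband_id,
                                      res$occurrences$sample_id)]
  want <- mapply(trioStatusOracle, combos$father, combos$mother)
  expect_identical(got, unname(want))
  expect_equal(sum(res$fractions), 1)
})

test_that("gene score join marks unscored genes and rejects duplicates", {
  net <- list(nodes = c("G1", "G2", "G3", "G4", "G5"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tscore", "G1\t2", "G4\tS"), tsv)
  out <- joinGeneScores(net, tsv)
  expect_identical(out$n_unscored, 3L)
  expect_identical(out$gene_scores$score[out$gene_scores$gene == "G4"], "S")

  writeLines(c("gene\tscore", "G1\t2", "G1\t3"), tsv)
  expect_error(joinGeneScores(net, tsv), "duplicate")

  empty <- tempfile(fileext = ".tsv")
  writeLines("gene\tscore", empty)
  expect_identical(joinGeneScores(net, empty)$n_unscored, 5L)
})

test_that("GFF3 gene models round-trip through rtracklayer", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t100\t500\t.\t+\t.\tID=GX;Name=GX;biotype=protein_coding",
    "chr1\ttest\texon\t150\t250\t.\t+\t.\tID=GX.e1;Parent=GX",
    "chr1\ttest\tgene\t1000\t1500\t.\t-\t.\tID=GY;Name=GY;biotype=lncRNA"),
    gff)
  ann <- readGeneModels(gff)
  m <- mapVariant(data.frame(chrom = "chr1", pos = c(200L, 1200L, 700L)),
                  ann)
  expect_identical(m, c("GX", "GY", "intergenic"))
})
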