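# Synthetic annotation generators and the end-to-end pipeline driver.

#' Synthetic gene annotation with planted region-class fractions
#'
#' Builds a gene annotation over a simulated variant panel such that each
#' variant falls in a region class with exactly the planted fractions:
#' `exon`, `protein_coding_noncoding` (intronic/UTR of a protein-coding
#' gene), `lncRNA`, `pseudogene`, or `intergenic`. Each genic variant gets
#' its own non-overlapping gene interval (panel positions are spaced to
#' guarantee this); exon-class variants get an exon interval covering
#' their position, other protein-coding variants an exon elsewhere in the
#' gene. Optionally, `overlapIdx` variants are covered by a second
#' protein-coding gene so they map to the `overlap` class.
#'
#' @param panel variant panel data.frame (`chrom`, `pos`), e.g.
#'   `simulateCohort(...)$panel`.
#' @param fractions named fractions for the five classes (summing to <= 1;
#'   the remainder is intergenic).
#' @param forceGenic variant indices forced into the
#'   `protein_coding_noncoding` class (so planted risk variants are
#'   mappable); drawn before the random class assignment.
#' @param overlapIdx variant indices additionally covered by a second gene.
#' @param seed seed for the class assignment.
#' @return list with `annotation` (a [geneAnnotation()]), `classes`
#'   (planted class per variant) and `geneOf` (gene id per variant or NA).
#' @export
simulateGeneAnnotation <- function(panel,
                                   fractions = c(
                                     exon = 0.046,
                                     protein_coding_noncoding = 0.382,
                                     lncRNA = 0.112,
                                     pseudogene = 0.018),
                                   forceGenic = integer(0),
                                   overlapIdx = integer(0),
                                   seed = 1L) {
  nV <- nrow(panel)
  stopifnot(sum(fractions) <= 1)
  withSeed(deriveSeed(seed, 31L), {
    classes <- rep("intergenic", nV)
    counts <- floor(fractions * nV)
    classes[forceGenic] <- "protein_coding_noncoding"
    counts["protein_coding_noncoding"] <-
      max(0L, counts["protein_coding_noncoding"] - length(forceGenic))
    free <- setdiff(seq_len(nV), forceGenic)
    for (cl in names(counts)) {
      take <- min(counts[[cl]], length(free))
      if (take > 0L) {
        pick <- sample(free, take)
        classes[pick] <- cl
        free <- setdiff(free, pick)
      }
    }
    genic <- which(classes != "intergenic")
    geneOf <- rep(NA_character_, nV)
    geneOf[genic] <- sprintf("G%05d", genic)
    biotype <- c(exon = "protein_coding",
                 protein_coding_noncoding = "protein_coding",
                 lncRNA = "lncRNA", pseudogene = "pseudogene")
    genes <- data.frame(
      gene_id = geneOf[genic], name = geneOf[genic],
      chrom = panel$chrom[genic],
      start = pmax(1L, panel$pos[genic] - 500L),
      end = panel$pos[genic] + 500L,
      biotype = unname(biotype[classes[genic]]),
      stringsAsFactors = FALSE)
    isExonClass <- classes[genic] == "exon"
    isPc <- classes[genic] == "protein_coding_noncoding"
    exons <- rbind(
      data.frame(gene_id = geneOf[genic][isExonClass],
                 chrom = panel$chrom[genic][isExonClass],
                 start = panel$pos[genic][isExonClass] - 10L,
                 end = panel$pos[genic][isExonClass] + 10L),
      data.frame(gene_id = geneOf[genic][isPc],
                 chrom = panel$chrom[genic][isPc],
                 start = panel$pos[genic][isPc] + 300L,
                 end = panel$pos[genic][isPc] + 400L))
    if (length(overlapIdx)) {
      genes <- rbind(genes, data.frame(
        gene_id = sprintf("OVL%05d", overlapIdx),
        name = sprintf("OVL%05d", overlapIdx),
        chrom = panel$chrom[overlapIdx],
        start = pmax(1L, panel$pos[overlapIdx] - 200L),
        end = panel$pos[overlapIdx] + 200L,
        biotype = "protein_coding", stringsAsFactors = FALSE))
    }
    list(annotation = geneAnnotation(genes, exons),
         classes = classes, geneOf = geneOf)
  })
}

#' Synthetic gene-to-GO-term annotation
#'
#' Random term memberships over a gene universe, optionally with one
#' planted term concentrated on a study subset so overrepresentation is
#' detectable.
#'
#' @param genes character universe of gene ids.
#' @param nTerms number of random terms.
#' @param sizeRange term size range.
#' @param planted optional character vector of genes forming an extra
#'   term (`"TERM_PLANTED"`).
#' @param seed seed.
#' @return data.frame (`gene`, `term`) suitable for [annotationSet()].
#' @export
simulateGoAnnotation <- function(genes, nTerms = 40L,
                                 sizeRange = c(5L, 20L),
                                 planted = NULL, seed = 1L) {
  withSeed(deriveSeed(seed, 47L), {
    rows <- lapply(seq_len(nTerms), function(i) {
      size <- sample(sizeRange[1L]:sizeRange[2L], 1L)
      data.frame(gene = sample(genes, min(size, length(genes))),
                 term = sprintf("TERM%04d", i))
    })
    out <- do.call(rbind, rows)
    if (!is.null(planted) && length(planted))
      out <- rbind(out, data.frame(gene = planted,
                                   term = "TERM_PLANTED"))
    # every universe gene annotated at least once
    missing <- setdiff(genes, out$gene)
    if (length(missing))
      out <- rbind(out, data.frame(gene = missing, term = "TERM0001"))
    unique(out)
  })
}

#' Synthetic biological-interaction edges inducing gene triplets
#'
#' Fabricates a biological edge list from a statistical gene network so
#' that triplet structure exists: for genes with at least two statistical
#' partners, a biological edge is drawn between two of the partners; a
#' few statistical edges are also copied verbatim (direct coincident
#' interactions).
#'
#' @param statEdges data.frame with `gene1`, `gene2`.
#' @param nTriplets target number of induced triplets.
#' @param nDirect number of coincident edges to copy.
#' @param seed seed.
#' @return data.frame (`gene1`, `gene2`) of biological edges.
#' @export
simulateBioEdges <- function(statEdges, nTriplets = 5L, nDirect = 2L,
                             seed = 1L) {
  withSeed(deriveSeed(seed, 53L), {
    adj <- split(c(statEdges$gene2, statEdges$gene1),
                 c(statEdges$gene1, statEdges$gene2))
    hubs <- names(adj)[lengths(adj) >= 2L]
    rows <- list()
    for (h in utils::head(hubs, nTriplets)) {
      nb <- sort(unique(adj[[h]]))
      rows[[length(rows) + 1L]] <- data.frame(gene1 = nb[1L],
                                              gene2 = nb[2L])
    }
    if (nDirect > 0L && nrow(statEdges))
      rows[[length(rows) + 1L]] <-
        utils::head(statEdges[, c("gene1", "gene2")], nDirect)
    out <- unique(do.call(rbind, c(rows, list(
      data.frame(gene1 = character(0), gene2 = character(0))))))
    rownames(out) <- NULL
    out
  })
}

#' Run the whole analysis end to end on a synthetic cohort
#'
#' simulate -> emit VCF/PED -> ingest (AD filter + gender policy) ->
#' stage-1 screen -> stage-2 pair scan -> gene network mapping +
#' inheritance classification -> case-status predictor -> subtype
#' clustering with FPR sweep -> GO overrepresentation -> gene triplets.
#' All intermediate artifacts are returned; tab-separated outputs are
#' written when `outdir` is given.
#'
#' @param simConfig a [simulationConfig()].
#' @param minAdFraction allele-depth fraction filter (default 0.25).
#' @param genderPolicy gender-mismatch policy (default `"none"`: the
#'   synthetic cohort's liability carries no sex-linked component, so
#'   there is no sex-chromosome artifact to correct and the sibling is
#'   the natural control; `"replace_sibling"` and `"skip_family"` are
#'   available for data where the imbalance matters).
#' @param pInitial,pFinal,bonferroniAuto two-stage thresholds.
#' @param kRange,nReference clustering controls.
#' @param fprGrid FPR sweep grid.
#' @param nCycles predictor cycles; `sweepCycles` cycles are used inside
#'   the per-cluster sweep.
#' @param sweepCycles per-cluster predictor cycles in the FPR sweep.
#' @param algorithm classifier algorithm.
#' @param outdir optional output directory for TSV artifacts.
#' @return a named list with every stage's outputs.
#' @export
runPipeline <- function(simConfig = simulationConfig(),
                        minAdFraction = 0.25,
                        genderPolicy = "none",
                        pInitial = 1e-3, pFinal = 1.3e-5,
                        bonferroniAuto = FALSE,
                        kRange = 1:8, nReference = 10L,
                        fprGrid = c(0.01, 0.05, 0.2, 0.5),
                        nCycles = 20L, sweepCycles = 5L,
                        algorithm = "linear_svm", outdir = NULL) {
  sim <- simulateCohort(simConfig)
  ioDir <- if (is.null(outdir)) file.path(tempdir(), "episcreen-run")
           else outdir
  filePaths <- emitVcfPed(sim, ioDir)
  ing <- ingestCohort(filePaths$vcf, filePaths$ped,
                      minAdFraction = minAdFraction,
                      genderPolicy = genderPolicy)
  cohort <- ing$cohort; pm <- ing$presence
  labels <- associationLabels(cohort, "screen")
  screen <- screenVariants(pm, labels, pInitial, pFinal)
  pairs <- scanPairs(pm, screen$preselected, labels, pFinal,
                     bonferroniAuto)
  riskVariants <- unique(c(pairs$id1, pairs$id2))
  if (!length(riskVariants))
    stop("pair scan emitted no significant pairs; relax thresholds or ",
         "strengthen the simulated effect")

  plantedIdx <- unique(as.vector(as.matrix(
    sim$truth$plantedPairs[, c("idx1", "idx2")])))
  ann <- simulateGeneAnnotation(sim$panel, forceGenic = plantedIdx,
                                seed = simConfig$seed)
  network <- buildGeneNetwork(pairs, ann$annotation)
  inheritance <- classifyInheritance(pm, cohort, riskVariants)

  ft <- buildFeatures(pm, riskVariants, cohort)
  report <- trainEval(ft$features, ft$labels, ft$weights, cohort,
                      algorithm, nCycles = nCycles,
                      seed = simConfig$seed)

  model <- clusterCases(cohort, pm, riskVariants, kRange, nReference,
                        seed = simConfig$seed)
  sweep <- sweepFpr(cohort, pm, riskVariants, model, fprGrid,
                    algorithm = algorithm, nCycles = sweepCycles,
                    seed = simConfig$seed)

  universe <- ann$geneOf[!is.na(ann$geneOf)]
  study <- network$nodes
  goTab <- simulateGoAnnotation(universe,
                                planted = utils::head(study, 10L),
                                seed = simConfig$seed)
  annSet <- annotationSet(goTab)
  enrich <- hypergeomEnrich(study, annSet, alpha = 0.05, maxGenes = 50L)

  bio <- simulateBioEdges(network$edges, seed = simConfig$seed)
  triplets <- findTriplets(bio, network$edges)

  result <- list(sim = sim, cohort = cohort, presence = pm,
                 screen = screen, pairs = pairs,
                 riskVariants = riskVariants, annotation = ann,
                 network = network, inheritance = inheritance,
                 report = report, clusterModel = sweep$model,
                 sweep = sweep$sweep, chosenFpr = sweep$chosenFpr,
                 enrichment = enrich, bioEdges = bio,
                 triplets = triplets, files = filePaths)
  if (!is.null(outdir)) writePipelineOutputs(result, outdir)
  result
}

# Write the standard TSV artifacts of a pipeline run.
writePipelineOutputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) write.table(
    x, file.path(outdir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  w(result$screen$results, "variants.tsv")
  w(result$pairs, "pairs.tsv")
  w(result$network$edges, "gene_pairs.tsv")
  gl <- data.frame(gene = result$network$nodes)
  if (!is.null(result$network$gene_scores)) gl <- result$network$gene_scores
  w(gl, "gene_list.tsv")
  w(result$inheritance$occurrences, "inheritance.tsv")
  model <- result$clusterModel
  smp <- sampleInfo(result$cohort)
  w(data.frame(sample = names(model@memberAssignment),
               cluster = as.integer(model@memberAssignment),
               role = smp$role[match(names(model@memberAssignment),
                                     smp$sample_id)]),
    "clusters.tsv")
  w(gapTrace(model), "gap_trace.tsv")
  w(result$sweep, "sweep.tsv")
  w(result$enrichment, "enrichment.tsv")
  w(result$triplets$triplets, "triplets.tsv")
  w(reportCycles(result$report), "report.tsv")
  invisible(outdir)
}
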