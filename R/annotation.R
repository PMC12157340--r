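# annotation_map: variant-to-gene mapping, region/inheritance
# classification, gene network construction, external score joins.

#' Gene annotation container
#'
#' Wraps gene (and optional exon) intervals as `GRanges` for interval
#' lookup. Intervals are 1-based inclusive, matching GFF3; VCF positions
#' are already 1-based.
#'
#' @param genes data.frame with columns `gene_id`, `name`, `chrom`,
#'   `start`, `end`, `biotype` (one of `protein_coding`, `lncRNA`,
#'   `pseudogene`, `other`).
#' @param exons optional data.frame with `gene_id`, `chrom`, `start`,
#'   `end` giving exon intervals.
#' @return a `GeneAnnotation` (classed list holding `GRanges`).
#' @export
geneAnnotation <- function(genes, exons = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "biotype")
  stopifnot(all(need %in% names(genes)))
  if (!"name" %in% names(genes)) genes$name <- genes$gene_id
  stopifnot(all(genes$start <= genes$end))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    gene_id = genes$gene_id, name = genes$name, biotype = genes$biotype)
  er <- NULL
  if (!is.null(exons) && nrow(exons)) {
    er <- GenomicRanges::GRanges(
      seqnames = exons$chrom,
      ranges = IRanges::IRanges(exons$start, exons$end),
      gene_id = exons$gene_id)
  }
  structure(list(genes = gr, exons = er, table = genes),
            class = "GeneAnnotation")
}

#' Read gene models from GFF3 or a biotype-augmented BED-like TSV
#'
#' For GFF3, `gene` features (with a `biotype` or `gene_biotype`
#' attribute) and optional `exon` features are used. For TSV, the columns
#' `gene_id`, `name`, `chrom`, `start`, `end`, `biotype` are expected
#' (BED-style half-open input is not assumed; intervals are taken as
#' 1-based inclusive).
#'
#' @param path file path; format chosen by extension (`.gff`/`.gff3` vs
#'   anything else).
#' @return a `GeneAnnotation`; see [geneAnnotation()].
#' @export
readGeneModels <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- rtracklayer::import(path)
    md <- S4Vectors::mcols(g)
    bt <- if ("biotype" %in% names(md)) md$biotype
          else if ("gene_biotype" %in% names(md)) md$gene_biotype
          else rep("other", length(g))
    isGene <- md$type == "gene"
    gid <- if ("ID" %in% names(md)) md$ID else md$gene_id
    nm <- if ("Name" %in% names(md)) md$Name else gid
    genes <- data.frame(
      gene_id = as.character(gid[isGene]),
      name = as.character(nm[isGene]),
      chrom = as.character(GenomicRanges::seqnames(g))[isGene],
      start = GenomicRanges::start(g)[isGene],
      end = GenomicRanges::end(g)[isGene],
      biotype = as.character(bt[isGene]),
      stringsAsFactors = FALSE)
    isExon <- md$type == "exon"
    exons <- if (any(isExon)) {
      parent <- if ("Parent" %in% names(md))
        vapply(md$Parent[isExon], function(x) as.character(x)[1L], "")
      else as.character(gid[isExon])
      data.frame(gene_id = sub("^gene:", "", parent),
                 chrom = as.character(GenomicRanges::seqnames(g))[isExon],
                 start = GenomicRanges::start(g)[isExon],
                 end = GenomicRanges::end(g)[isExon],
                 stringsAsFactors = FALSE)
    } else NULL
    geneAnnotation(genes, exons)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    geneAnnotation(tab)
  }
}

#' Map variant positions to genes under the exclusion rules
#'
#' A position inside two or more overlapping non-pseudogene genes maps to
#' `"overlap"` (there is no statistically neutral way to pick one gene);
#' inside pseudogenes only, to `"pseudogene"`; inside no gene, to
#' `"intergenic"`; otherwise to the unique gene id. Pseudogenes do not
#' block mapping: a variant inside one real gene and one pseudogene maps
#' to the real gene. Chromosomes absent from the annotation are treated as
#' intergenic with a warning.
#'
#' @param variants data.frame with columns `chrom` and `pos`.
#' @param annotation a `GeneAnnotation`.
#' @return character vector: gene id or one of `"intergenic"`,
#'   `"pseudogene"`, `"overlap"`.
#' @export
mapVariant <- function(variants, annotation) {
  stopifnot(inherits(annotation, "GeneAnnotation"))
  gr <- annotation$genes
  known <- as.character(GenomicRanges::seqnames(gr)@values)
  unknown <- setdiff(unique(variants$chrom), known)
  if (length(unknown))
    warning("chromosome(s) absent from annotation, treated as intergenic: ",
            paste(unknown, collapse = ", "))
  q <- GenomicRanges::GRanges(variants$chrom,
                              IRanges::IRanges(variants$pos, variants$pos))
  GenomeInfoDb::seqlevels(q) <-
    union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(gr))
  hits <- GenomicRanges::findOverlaps(q, gr)
  out <- rep("intergenic", nrow(variants))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    pseudo <- gr$biotype[sh] == "pseudogene"
    realHits <- split(sh[!pseudo], qh[!pseudo])
    pseudoOnly <- setdiff(unique(qh[pseudo]), as.integer(names(realHits)))
    out[pseudoOnly] <- "pseudogene"
    nReal <- lengths(realHits)
    qi <- as.integer(names(realHits))
    out[qi[nReal >= 2L]] <- "overlap"
    single <- nReal == 1L
    out[qi[single]] <- gr$gene_id[unlist(realHits[single], use.names = FALSE)]
  }
  out
}

#' Build the gene-interaction network from significant variant pairs
#'
#' A variant pair contributes an edge iff both variants map to unique
#' genes; pairs touching intergenic, pseudogene or overlap positions are
#' skipped. Pairs whose two variants fall in the same gene form self-edges
#' and are reported separately. The region tally classifies every unique
#' variant of the input pairs into `exon`, `protein_coding_noncoding`,
#' `lncRNA`, `pseudogene`, `intergenic` (and `overlap` / `other_gene`
#' where applicable), as fractions of unique variants; the `exon` class is
#' only available when exon intervals were supplied.
#'
#' @param pairs data.frame from [scanPairs()].
#' @param annotation a `GeneAnnotation`.
#' @return list with `edges` (`gene1`, `gene2`, `n_variant_pairs`;
#'   `gene1 < gene2`), `selfEdges`, `nodes`, `n_mappable_pairs`,
#'   `variant_class` (per unique variant) and `region_tally` (fractions).
#' @export
buildGeneNetwork <- function(pairs, annotation) {
  uniqIds <- unique(c(pairs$id1, pairs$id2))
  parts <- strsplit(uniqIds, ":", fixed = TRUE)
  uv <- data.frame(id = uniqIds,
                   chrom = vapply(parts, `[`, "", 1L),
                   pos = as.integer(vapply(parts, `[`, "", 2L)),
                   stringsAsFactors = FALSE)
  mapped <- if (nrow(uv)) mapVariant(uv, annotation) else character(0)
  names(mapped) <- uv$id

  cls <- mapped
  genic <- !(cls %in% c("intergenic", "pseudogene", "overlap"))
  if (any(genic)) {
    bt <- annotation$table$biotype[match(cls[genic],
                                         annotation$table$gene_id)]
    sub <- ifelse(bt == "lncRNA", "lncRNA",
           ifelse(bt == "protein_coding", "protein_coding_noncoding",
                  "other_gene"))
    if (!is.null(annotation$exons)) {
      q <- GenomicRanges::GRanges(uv$chrom[genic],
                                  IRanges::IRanges(uv$pos[genic],
                                                   uv$pos[genic]))
      GenomeInfoDb::seqlevels(q) <- union(
        GenomeInfoDb::seqlevels(q),
        GenomeInfoDb::seqlevels(annotation$exons))
      inExon <- GenomicRanges::countOverlaps(q, annotation$exons) > 0L
      sub[inExon & bt == "protein_coding"] <- "exon"
    }
    cls[genic] <- sub
  }

  g1 <- mapped[pairs$id1]
  g2 <- mapped[pairs$id2]
  ok <- !(g1 %in% c("intergenic", "pseudogene", "overlap")) &
        !(g2 %in% c("intergenic", "pseudogene", "overlap"))
  a <- pmin(g1[ok], g2[ok]); b <- pmax(g1[ok], g2[ok])
  self <- a == b
  edgeTab <- if (any(!self))
    as.data.frame(table(gene1 = a[!self], gene2 = b[!self]),
                  stringsAsFactors = FALSE)
  else data.frame(gene1 = character(0), gene2 = character(0),
                  Freq = integer(0))
  edgeTab <- edgeTab[edgeTab$Freq > 0L, , drop = FALSE]
  names(edgeTab)[3L] <- "n_variant_pairs"
  edgeTab <- edgeTab[order(edgeTab$gene1, edgeTab$gene2), , drop = FALSE]
  rownames(edgeTab) <- NULL
  selfTab <- if (any(self))
    setNames(as.data.frame(table(gene = a[self]), stringsAsFactors = FALSE),
             c("gene", "n_variant_pairs"))
  else data.frame(gene = character(0), n_variant_pairs = integer(0))

  tally <- if (length(cls)) table(cls) / length(cls) else table(character(0))
  list(edges = edgeTab, selfEdges = selfTab,
       nodes = sort(unique(c(edgeTab$gene1, edgeTab$gene2, selfTab$gene))),
       n_mappable_pairs = sum(ok),
       variant_class = cls, region_tally = tally)
}

#' Classify child variant occurrences as de novo or inherited
#'
#' For every (child, variant) occurrence — a child carrying the variant
#' after filtering — the occurrence is `de_novo` iff neither parent
#' carries it, `inherited` iff at least one parent carries it, and
#' `unknown` iff any parental genotype is missing. Presence is the
#' filtered presence of the matrix (same AD threshold as the search), so a
#' low-allele-depth parental read does not rescue a de novo call.
#'
#' @param pm a [PresenceMatrix-class].
#' @param cohort a [FamilyCohort-class].
#' @param variants variant ids to assess (default: all columns).
#' @param children which children to count: `"proband"`, `"sibling"` or
#'   `"both"` (default).
#' @return list with `occurrences` (data.frame `sample_id`, `variant`,
#'   `status`), `fractions` (named de_novo / inherited / unknown,
#'   summing to 1 over counted occurrences) and
#'   `mixed_mode_variant_fraction`: the fraction of assessed variants that
#'   are de novo in at least one family and inherited in at least one
#'   other.
#' @export
classifyInheritance <- function(pm, cohort,
                                variants = variantInfo(pm)$id,
                                children = c("both", "proband",
                                             "sibling")) {
  children <- match.arg(children)
  P <- presence(pm); M <- missingMask(pm)
  cols <- match(variants, colnames(P))
  if (anyNA(cols)) stop("unknown variant id(s)")
  fam <- families(cohort)
  childIds <- switch(children,
                     both = c(fam$proband_id, fam$sibling_id),
                     proband = fam$proband_id,
                     sibling = fam$sibling_id)
  famOf <- rep(fam$family_id, times = if (children == "both") 2L else 1L)
  ci <- match(childIds, rownames(P))
  fi <- match(fam$father_id[match(famOf, fam$family_id)], rownames(P))
  mi <- match(fam$mother_id[match(famOf, fam$family_id)], rownames(P))
  if (anyNA(c(ci, fi, mi))) stop("cohort member missing from matrix")

  CP <- P[ci, cols, drop = FALSE]
  FP <- P[fi, cols, drop = FALSE]; MP <- P[mi, cols, drop = FALSE]
  FM <- M[fi, cols, drop = FALSE]; MM <- M[mi, cols, drop = FALSE]
  occ <- which(CP, arr.ind = TRUE)
  status <- character(nrow(occ))
  pMiss <- FM[occ] | MM[occ]
  pCarry <- (FP[occ] & !FM[occ]) | (MP[occ] & !MM[occ])
  status[pCarry] <- "inherited"
  status[!pCarry & pMiss] <- "unknown"
  status[!pCarry & !pMiss] <- "de_novo"

  occurrences <- data.frame(sample_id = childIds[occ[, "row"]],
                            variant = variants[occ[, "col"]],
                            status = status, stringsAsFactors = FALSE)
  fr <- c(de_novo = 0, inherited = 0, unknown = 0)
  if (nrow(occurrences)) {
    t <- table(factor(status, levels = names(fr)))
    fr <- as.numeric(t) / nrow(occurrences)
    names(fr) <- c("de_novo", "inherited", "unknown")
  }
  byVar <- split(status, occurrences$variant)
  mixed <- vapply(byVar, function(s)
    any(s == "de_novo") && any(s == "inherited"), logical(1))
  list(occurrences = occurrences, fractions = fr,
       mixed_mode_variant_fraction =
         if (length(byVar)) mean(mixed) else NA_real_)
}

#' Join external gene scores (SFARI-style) onto a gene network
#'
#' Left-joins a two-column `gene`, `score` TSV onto the network's node
#' list. Genes absent from the table are marked unscored; an unscored gene
#' typically means it has not been previously associated with the
#' condition.
#'
#' @param network list from [buildGeneNetwork()].
#' @param scorePath path to a TSV with header columns `gene` and `score`
#'   (scores free-form, e.g. `1`, `2`, `3`, `S`, `2S`).
#' @return the network with an added `gene_scores` data.frame (`gene`,
#'   `score`, `scored`) and `n_unscored` count.
#' @export
joinGeneScores <- function(network, scorePath) {
  tab <- tryCatch(
    read.table(scorePath, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("malformed score TSV: ", conditionMessage(e)))
  if (!all(c("gene", "score") %in% names(tab)))
    stop("malformed score TSV (line 1): need columns 'gene' and 'score'")
  dup <- duplicated(tab$gene)
  if (any(dup))
    stop("duplicate gene rows in score table at line(s) ",
         paste(which(dup) + 1L, collapse = ", "))
  genes <- network$nodes
  idx <- match(genes, tab$gene)
  network$gene_scores <- data.frame(
    gene = genes,
    score = ifelse(is.na(idx), NA_character_, tab$score[idx]),
    scored = !is.na(idx), stringsAsFactors = FALSE)
  network$n_unscored <- sum(is.na(idx))
  network
}
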