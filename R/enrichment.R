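# enrichment_triplets: hypergeometric GO-term overrepresentation with
# BH-FDR control, and the gene-triplet finder.

#' Build a term-to-gene annotation set
#'
#' The universe is the set of annotated genes ("whole annotation"
#' reference semantics): genes with no annotation do not enter `N`. When a
#' child-to-parent term relation is supplied, annotations are propagated
#' to all ancestor terms (transitive closure), as ontology
#' overrepresentation tools do.
#'
#' @param annotation data.frame (`gene`, `term`) or path to a two-column
#'   TSV without header.
#' @param parents optional data.frame (`child`, `parent`) or TSV path for
#'   ancestor propagation.
#' @return an `AnnotationSet`: classed list with `termGenes` (term ->
#'   character vector) and `universe`.
#' @export
annotationSet <- function(annotation, parents = NULL) {
  if (is.character(annotation))
    annotation <- read.table(annotation, header = FALSE, sep = "\t",
                             col.names = c("gene", "term"),
                             stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  if (!is.null(parents)) {
    if (is.character(parents))
      parents <- read.table(parents, header = FALSE, sep = "\t",
                            col.names = c("child", "parent"),
                            stringsAsFactors = FALSE)
    # transitive closure: annotate each gene to every ancestor term
    up <- split(parents$parent, parents$child)
    ancestors <- function(term) {
      seen <- character(0)
      frontier <- term
      while (length(frontier)) {
        nxt <- setdiff(unique(unlist(up[frontier], use.names = FALSE)),
                       seen)
        seen <- c(seen, nxt)
        frontier <- nxt
      }
      seen
    }
    extra <- lapply(unique(annotation$term), function(tm) {
      anc <- ancestors(tm)
      if (!length(anc)) return(NULL)
      g <- annotation$gene[annotation$term == tm]
      data.frame(gene = rep(g, times = length(anc)),
                 term = rep(anc, each = length(g)))
    })
    annotation <- unique(rbind(annotation, do.call(rbind, extra)))
  }
  termGenes <- lapply(split(annotation$gene, annotation$term), unique)
  structure(list(termGenes = termGenes,
                 universe = unique(annotation$gene)),
            class = "AnnotationSet")
}

#' Hypergeometric term overrepresentation with BH-FDR control
#'
#' For a term annotating `K` of the `N` universe genes, of which `k` fall
#' in the `n`-gene study set, the p-value is the upper tail
#' `P(X >= k)` of the hypergeometric distribution. P-values are adjusted
#' across all tested terms by Benjamini-Hochberg, and terms with adjusted
#' p below `alpha` are returned sorted by raw p. Terms with more than
#' `maxGenes` study genes can be filtered from the output (an
#' interpretability filter for very broad terms). Study genes outside the
#' universe are dropped with a warning.
#'
#' @param study character vector of study genes.
#' @param annSet an [annotationSet()].
#' @param alpha adjusted-significance cutoff (default 0.05).
#' @param maxGenes drop terms with more than this many study genes
#'   (default `Inf`).
#' @return data.frame `term, k, K, n, N, p, p_adj, genes` for significant
#'   terms; the full tested table is attached as attribute `"all"`.
#' @export
hypergeomEnrich <- function(study, annSet, alpha = 0.05,
                            maxGenes = Inf) {
  stopifnot(inherits(annSet, "AnnotationSet"))
  N <- length(annSet$universe)
  if (N == 0L) stop("empty annotation universe")
  outside <- setdiff(study, annSet$universe)
  if (length(outside))
    warning(length(outside), " study gene(s) outside the universe dropped")
  study <- intersect(unique(study), annSet$universe)
  n <- length(study)
  rows <- lapply(names(annSet$termGenes), function(tm) {
    tg <- annSet$termGenes[[tm]]
    hit <- intersect(study, tg)
    data.frame(term = tm, k = length(hit), K = length(tg), n = n, N = N,
               p = phyper(length(hit) - 1L, length(tg), N - length(tg),
                          n, lower.tail = FALSE),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$p, tab$term), ]
  rownames(tab) <- NULL
  sig <- tab[tab$p_adj < alpha & tab$k <= maxGenes,
             c("term", "k", "K", "n", "N", "p", "p_adj", "genes"),
             drop = FALSE]
  rownames(sig) <- NULL
  attr(sig, "all") <- tab
  sig
}

normalizeEdges <- function(edges, c1, c2) {
  a <- pmin(edges[[c1]], edges[[c2]])
  b <- pmax(edges[[c1]], edges[[c2]])
  unique(data.frame(g1 = a, g2 = b, stringsAsFactors = FALSE))
}

#' Find gene triplets linking biological to statistical interactions
#'
#' A triplet (gene1, gene2, gene3) satisfies: gene1-gene2 is a known
#' biological interaction, and gene3 interacts statistically with both
#' gene1 and gene2 (gene3 distinct from both). Also reports the pairs
#' that are simultaneously biological and statistical edges (direct
#' coincident interactions). Edges are unordered; output is deduplicated
#' and deterministically ordered.
#'
#' @param bioEdges data.frame with two columns of gene names (or a
#'   headerless two-column TSV path).
#' @param statEdges data.frame of statistical edges, e.g.
#'   `buildGeneNetwork()$edges` (columns `gene1`, `gene2`).
#' @return list with `triplets` (data.frame `gene1`, `gene2`, `gene3`,
#'   with `gene1 < gene2`) and `direct` (coincident pairs).
#' @export
findTriplets <- function(bioEdges, statEdges) {
  if (is.character(bioEdges))
    bioEdges <- read.table(bioEdges, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  bio <- normalizeEdges(bioEdges, names(bioEdges)[1L], names(bioEdges)[2L])
  stat <- normalizeEdges(statEdges, "gene1", "gene2")
  statKey <- paste(stat$g1, stat$g2, sep = "\r")
  neighbors <- function(g) {
    c(stat$g2[stat$g1 == g], stat$g1[stat$g2 == g])
  }
  rows <- lapply(seq_len(nrow(bio)), function(i) {
    g1 <- bio$g1[i]; g2 <- bio$g2[i]
    third <- setdiff(intersect(neighbors(g1), neighbors(g2)), c(g1, g2))
    if (!length(third)) return(NULL)
    data.frame(gene1 = g1, gene2 = g2, gene3 = sort(third),
               stringsAsFactors = FALSE)
  })
  triplets <- do.call(rbind, rows)
  if (is.null(triplets))
    triplets <- data.frame(gene1 = character(0), gene2 = character(0),
                           gene3 = character(0))
  triplets <- unique(triplets)
  triplets <- triplets[order(triplets$gene1, triplets$gene2,
                             triplets$gene3), , drop = FALSE]
  rownames(triplets) <- NULL
  direct <- bio[paste(bio$g1, bio$g2, sep = "\r") %in% statKey, ,
                drop = FALSE]
  names(direct) <- c("gene1", "gene2")
  rownames(direct) <- NULL
  list(triplets = triplets, direct = direct)
}
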