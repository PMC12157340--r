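# pair_search: chi-square engine, stage-1 screen, stage-2 packed pair scan.

#' Pearson chi-square for 2x2 carrier contingency tables
#'
#' Uncorrected Pearson statistic on the carrier table
#' \eqn{X^2 = n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))} with the p-value from
#' the 1-df chi-square survival function. A table with any zero margin is
#' defined as non-significant, `(0, 1)`, so monomorphic-after-filter
#' variants can never be hits. Vectorized over the four counts. A Yates
#' continuity correction is available but off by default, matching common
#' GWAS practice for carrier tables.
#'
#' @param a,b,c,d case carriers, case non-carriers, control carriers,
#'   control non-carriers (non-negative, recycled).
#' @param correct apply the Yates continuity correction.
#' @return data.frame with columns `chi2` and `p`.
#' @export
chiSquare2x2 <- function(a, b, c, d, correct = FALSE) {
  if (any(c(a, b, c, d) < 0)) stop("negative counts in contingency table")
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  diff <- abs(a * d - b * c)
  if (correct) diff <- pmax(0, diff - n / 2)
  chi2 <- ifelse(denom > 0, n * diff^2 / denom, 0)
  chi2[n == 0] <- 0
  p <- ifelse(denom > 0, pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  data.frame(chi2 = chi2, p = p)
}

# Resolve label data.frame to row indices of the presence matrix.
labelRows <- function(pm, labels) {
  rows <- match(labels$sample_id, rownames(presence(pm)))
  if (anyNA(rows))
    stop("labelled sample(s) missing from presence matrix: ",
         paste(labels$sample_id[is.na(rows)], collapse = ", "))
  list(case = rows[labels$label == 1L], ctrl = rows[labels$label == 0L])
}

#' Stage-1 single-variant chi-square screen
#'
#' Builds the carrier 2x2 table for every variant (cases vs controls from
#' `labels`, normally [associationLabels()] in `screen` mode) and retains
#' variants with `p < pInitial`. The summary reports counts split by
#' autosomes vs sex chromosomes at both the initial and the final
#' significance level, the shape in which two-stage searches are usually
#' tabulated.
#'
#' @param pm a [PresenceMatrix-class].
#' @param labels data.frame from [associationLabels()] (screen mode).
#' @param pInitial initial screening significance level (default `1e-3`).
#' @param pFinal final significance level used only in the summary split
#'   (default `1.3e-5`).
#' @return list with `results` (per-variant table and p), `preselected`
#'   (column indices, genomic order) and `summary` (counts by chromosome
#'   class and threshold).
#' @export
screenVariants <- function(pm, labels, pInitial = 1e-3, pFinal = 1.3e-5) {
  P <- presence(pm)
  if (ncol(P) == 0L || nrow(P) == 0L) stop("empty presence matrix")
  rows <- labelRows(pm, labels)
  nCase <- length(rows$case); nCtrl <- length(rows$ctrl)
  a <- .colSums(P[rows$case, , drop = FALSE], nCase, ncol(P))
  c <- .colSums(P[rows$ctrl, , drop = FALSE], nCtrl, ncol(P))
  st <- chiSquare2x2(a, nCase - a, c, nCtrl - c)
  vi <- variantInfo(pm)
  results <- data.frame(vi[, c("id", "chrom", "pos", "ref", "alt",
                               "chrom_class")],
                        a = a, b = nCase - a, c = c, d = nCtrl - c,
                        chi2 = st$chi2, p = st$p)
  preselected <- which(st$p < pInitial)
  summary <- data.frame(
    chrom_class = rep(c("autosome", "sex"), 2L),
    threshold = rep(c(pInitial, pFinal), each = 2L),
    n_significant = c(
      sum(st$p < pInitial & vi$chrom_class == "autosome"),
      sum(st$p < pInitial & vi$chrom_class == "sex"),
      sum(st$p < pFinal & vi$chrom_class == "autosome"),
      sum(st$p < pFinal & vi$chrom_class == "sex")))
  list(results = results, preselected = preselected, summary = summary)
}

#' Stage-2 exhaustive chi-square scan over preselected variant pairs
#'
#' For every unordered pair of preselected variants, joint presence is the
#' bitwise AND of the two packed carrier columns; joint-carrier counts in
#' the case and control blocks come from popcounts. Pairs with
#' `p < pFinal` are emitted in genomic order (first member, then second).
#' With `bonferroniAuto = TRUE` the final level is derived as
#' `0.05 / choose(length(preselected), 2)` instead of the fixed default.
#'
#' @param pm a [PresenceMatrix-class].
#' @param preselected column indices from [screenVariants()].
#' @param labels data.frame from [associationLabels()] (screen mode).
#' @param pFinal fixed final significance level (default `1.3e-5`).
#' @param bonferroniAuto derive `pFinal` from the number of pairs tested.
#' @return data.frame of emitted pairs: `chrom1, pos1, ref1, alt1, chrom2,
#'   pos2, ref2, alt2, id1, id2, a, b, c, d, chi2, p`, with attributes
#'   `n_tested` and `p_final`.
#' @export
scanPairs <- function(pm, preselected, labels, pFinal = 1.3e-5,
                      bonferroniAuto = FALSE) {
  stopifnot(length(preselected) >= 0L)
  rows <- labelRows(pm, labels)
  nTested <- choose(length(preselected), 2)
  if (bonferroniAuto) pFinal <- if (nTested > 0) 0.05 / nTested else 0.05
  vi <- variantInfo(pm)
  empty <- data.frame(chrom1 = character(0), pos1 = integer(0),
                      ref1 = character(0), alt1 = character(0),
                      chrom2 = character(0), pos2 = integer(0),
                      ref2 = character(0), alt2 = character(0),
                      id1 = character(0), id2 = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), chi2 = numeric(0), p = numeric(0))
  if (length(preselected) < 2L) {
    attr(empty, "n_tested") <- nTested
    attr(empty, "p_final") <- pFinal
    return(empty)
  }
  preselected <- sort(as.integer(preselected))
  hits <- .scanPairsPacked(presence(pm), preselected,
                           as.integer(rows$case), as.integer(rows$ctrl),
                           pFinal)
  if (!nrow(hits)) {
    out <- empty
  } else {
    # columns are in genomic order, so i < j is already genomic order
    out <- data.frame(
      chrom1 = vi$chrom[hits$i], pos1 = vi$pos[hits$i],
      ref1 = vi$ref[hits$i], alt1 = vi$alt[hits$i],
      chrom2 = vi$chrom[hits$j], pos2 = vi$pos[hits$j],
      ref2 = vi$ref[hits$j], alt2 = vi$alt[hits$j],
      id1 = vi$id[hits$i], id2 = vi$id[hits$j],
      a = hits$a, b = hits$b, c = hits$c, d = hits$d,
      chi2 = hits$chi2, p = hits$p)
    out <- out[order(hits$i, hits$j), ]
    rownames(out) <- NULL
  }
  attr(out, "n_tested") <- nTested
  attr(out, "p_final") <- pFinal
  out
}

#' Summarize a pair-search result
#'
#' @param pairs data.frame from [scanPairs()].
#' @param annotation optional gene annotation (see [geneAnnotation()]);
#'   when supplied, the number of unique mappable genes is included.
#' @return list with `n_pairs`, `n_unique_variants`, `per_chrom_class`
#'   pair counts (by the classes of both members) and, when annotation is
#'   given, `n_unique_genes`.
#' @export
summarizeSearch <- function(pairs, annotation = NULL) {
  uniq <- unique(c(pairs$id1, pairs$id2))
  cls <- paste(chromClass(pairs$chrom1), chromClass(pairs$chrom2),
               sep = "-")
  out <- list(n_pairs = nrow(pairs),
              n_unique_variants = length(uniq),
              per_chrom_class = if (nrow(pairs)) table(cls) else table(character(0)))
  if (!is.null(annotation) && length(uniq)) {
    ids <- strsplit(uniq, ":", fixed = TRUE)
    vk <- data.frame(chrom = vapply(ids, `[`, "", 1L),
                     pos = as.integer(vapply(ids, `[`, "", 2L)))
    mapped <- mapVariant(vk, annotation)
    out$n_unique_genes <- length(setdiff(
      unique(mapped), c("intergenic", "pseudogene", "overlap")))
  }
  out
}
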