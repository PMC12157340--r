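# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All package randomness flows through this.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a 32-bit-safe stream seed from a base seed and a small index.
deriveSeed <- function(seed, index) {
  (abs(as.integer(seed)) %% 200000L) * 10000L + as.integer(index) %% 10000L
}

variantId <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

chromClass <- function(chrom) {
  s <- sub("^chr", "", chrom)
  ifelse(s %in% c("X", "Y"), "sex", "autosome")
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Area under the ROC curve computed from the rank statistic: the probability
#' that a randomly chosen positive scores above a randomly chosen negative,
#' with ties counted half.
#'
#' @param scores numeric decision scores, higher meaning more case-like.
#' @param labels logical or 0/1 vector, `TRUE`/1 for cases.
#' @return AUC in `[0, 1]`, or `NA` if either class is empty.
#' @export
aucRank <- function(scores, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# Geometric-mean aggregation of p-values on the log10 scale; zeros are
# clamped to the smallest representable double.
logAverageP <- function(p) {
  p <- pmax(p, .Machine$double.xmin)
  10^mean(log10(p))
}
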