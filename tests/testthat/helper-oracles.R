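# Independent oracles and small fixtures shared across the suite.
# Each oracle recomputes a quantity by a route disjoint from the
# implementation it checks.

# Exhaustive pair scan by direct per-genotype counting (no bit packing).
naivePairScan <- function(P, caseRows, ctrlRows, pFinal) {
  nv <- ncol(P)
  out <- list()
  nCase <- length(caseRows); nCtrl <- length(ctrlRows)
  for (i in seq_len(max(nv - 1L, 0L))) {
    for (j in (i + 1L):nv) {
      joint <- P[, i] & P[, j]
      a <- sum(joint[caseRows]); cc <- sum(joint[ctrlRows])
      b <- nCase - a; d <- nCtrl - cc
      n <- a + b + cc + d
      denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
      chi2 <- if (denom > 0) n * (a * d - b * cc)^2 / denom else 0
      p <- if (denom > 0) pchisq(chi2, 1, lower.tail = FALSE) else 1
      if (p < pFinal)
        out[[length(out) + 1L]] <- data.frame(
          i = i, j = j, a = a, b = b, c = cc, d = d, chi2 = chi2, p = p)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(i = integer(0), j = integer(0), a = integer(0),
                  b = integer(0), c = integer(0), d = integer(0),
                  chi2 = numeric(0), p = numeric(0))
}

# Globally optimal k-medoids cost by exhaustive search over medoid sets.
bruteForcePamCost <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  sets <- utils::combn(n, k)
  for (s in seq_len(ncol(sets))) {
    cost <- sum(apply(D[, sets[, s], drop = FALSE], 1L, min))
    if (cost < best) best <- cost
  }
  best
}

# Upper-tail hypergeometric probability by direct combinatorial sum.
hyperTailEnum <- function(k, K, n, N) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
}

# Benjamini-Hochberg step-up computed by hand.
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Expected trio inheritance status for a carrier child.
trioStatusOracle <- function(fatherState, motherState) {
  # states: "carrier", "noncarrier", "missing"
  if (fatherState == "carrier" || motherState == "carrier") return("inherited")
  if (fatherState == "missing" || motherState == "missing") return("unknown")
  "de_novo"
}

# Closed-form expectation of case prevalence among joint carriers vs
# non-carriers of a single planted pair, by enumeration over the
# generator's family law (informative carrier-parent pairs, linkage,
# logistic liability, simplex ascertainment). Assumes deNovoRate = 0.
prevalenceRatioOracle <- function(cfg) {
  rho <- cfg$plantedPairLinkage
  pif <- cfg$plantedInformativeFraction
  pA <- function(k) plogis(qlogis(cfg$baselineLiability) +
                             k * log(cfg$pairRelativeRisk))
  # within an informative family, a child's joint-carrier probability
  pBoth <- 0.5 * (rho + (1 - rho) * 0.5)
  num <- den <- numN <- denN <- 0
  for (type in c("inf", "non")) {
    wType <- if (type == "inf") pif else 1 - pif
    pk <- if (type == "inf") pBoth else 0
    for (k1 in 0:1) for (k2 in 0:1) {
      w <- wType * (if (k1) pk else 1 - pk) * (if (k2) pk else 1 - pk)
      if (w == 0) next
      p1 <- pA(k1); p2 <- pA(k2)
      case1 <- p1 * (1 - p2)   # child1 proband
      case2 <- (1 - p1) * p2
      acc <- case1 + case2
      num <- num + w * (case1 * k1 + case2 * k2)
      den <- den + w * acc * (k1 + k2)
      numN <- numN + w * (case1 * (1 - k1) + case2 * (1 - k2))
      denN <- denN + w * acc * ((1 - k1) + (1 - k2))
    }
  }
  (num / den) / (numN / denN)
}

# Tiny hand-built quad cohort for label and policy tests.
makeToyCohort <- function(probandSex = c("M", "M"),
                          siblingSex = c("M", "F")) {
  nF <- length(probandSex)
  famId <- sprintf("F%02d", seq_len(nF))
  fam <- data.frame(
    family_id = famId,
    father_id = paste0(famId, "_fa"), mother_id = paste0(famId, "_mo"),
    proband_id = paste0(famId, "_p"), sibling_id = paste0(famId, "_s"),
    proband_sex = probandSex, sibling_sex = siblingSex,
    control_designate_id = paste0(famId, "_s"),
    stringsAsFactors = FALSE)
  samples <- do.call(rbind, lapply(seq_len(nF), function(i) data.frame(
    sample_id = c(fam$father_id[i], fam$mother_id[i],
                  fam$proband_id[i], fam$sibling_id[i]),
    family_id = famId[i],
    role = c("father", "mother", "proband", "sibling"),
    sex = c("M", "F", probandSex[i], siblingSex[i]),
    affected = c(FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)))
  new("FamilyCohort", families = fam, samples = samples)
}

# Presence matrix over named samples / variant keys built from a logical
# matrix (optionally with a missingness mask).
makeToyPresence <- function(P, chrom = NULL, pos = NULL, missing = NULL) {
  nv <- ncol(P)
  if (is.null(chrom)) chrom <- rep("chr1", nv)
  if (is.null(pos)) pos <- seq_len(nv) * 1000L
  vars <- data.frame(id = variantId(chrom, pos, "A", "T"),
                     chrom = chrom, pos = pos, ref = "A", alt = "T",
                     chrom_class = ifelse(sub("chr", "", chrom) %in%
                                            c("X", "Y"), "sex", "autosome"),
                     stringsAsFactors = FALSE)
  colnames(P) <- vars$id
  if (is.null(missing)) missing <- matrix(FALSE, nrow(P), nv,
                                          dimnames = dimnames(P))
  colnames(missing) <- vars$id
  new("PresenceMatrix", presence = P, missing = missing,
      variants = vars, adThreshold = 0)
}

# Binary profiles with g planted groups for clustering tests.
plantedProfiles <- function(nPerGroup = 20L, nGroups = 3L,
                            nFeatures = 120L, blockSize = 40L,
                            baseRate = 0.1, blockRate = 0.85, seed = 1L) {
  set.seed(seed)
  x <- matrix(rbinom(nPerGroup * nGroups * nFeatures, 1L, baseRate),
              nPerGroup * nGroups, nFeatures)
  for (g in seq_len(nGroups)) {
    rows <- ((g - 1L) * nPerGroup + 1L):(g * nPerGroup)
    cols <- ((g - 1L) * blockSize + 1L):(g * blockSize)
    x[rows, cols] <- rbinom(length(rows) * length(cols), 1L, blockRate)
  }
  x
}
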