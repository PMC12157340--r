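# subtype_clustering: PAM (BUILD + SWAP), gap statistic with
# first-local-maximum selection, FPR feature selection, FPR sweep.

# Pairwise distances between binary profiles.
profileDist <- function(x, distance = c("hamming", "jaccard")) {
  distance <- match.arg(distance)
  m <- switch(distance,
              hamming = stats::dist(x, method = "manhattan"),
              jaccard = stats::dist(x, method = "binary"))
  as.matrix(m)
}

#' Partitioning Around Medoids (BUILD + SWAP with seeded restarts)
#'
#' Greedy BUILD initialization (first medoid minimizes total distance;
#' each next medoid maximizes the cost reduction) followed by SWAP:
#' repeatedly apply the single medoid-for-non-medoid exchange with the
#' largest cost decrease until none decreases the cost. Because
#' single-swap descent can stall in a local optimum, the search is
#' additionally restarted from `nStart - 1` seeded random medoid sets
#' and the best solution kept; on small instances this reliably reaches
#' the exhaustive-search optimum while remaining a local search. All
#' ties break to the lowest index, so the result is deterministic for a
#' given distance matrix and seed. Every point is assigned to its
#' nearest medoid.
#'
#' @param d distance matrix (n x n) or a binary matrix with
#'   `distance` naming how to compute one.
#' @param k number of medoids, `1 <= k <= n`.
#' @param distance used only when `d` is a data matrix.
#' @param seed seed for the restart initializations.
#' @param nStart number of initializations (1 = BUILD only).
#' @return list with `medoids` (indices), `assignment` (cluster per
#'   point), `cost` (total distance to nearest medoid).
#' @export
pamCluster <- function(d, k, distance = "hamming", seed = 1L,
                       nStart = 5L) {
  D <- if (is.matrix(d) && nrow(d) == ncol(d) &&
           all(abs(diag(d)) < 1e-12)) d
       else profileDist(d, distance)
  n <- nrow(D)
  k <- as.integer(k)
  if (k > n) stop("k (", k, ") exceeds number of points (", n, ")")
  if (k < 1L) stop("k must be >= 1")

  nearTwo <- function(medoids) {
    Dm <- D[, medoids, drop = FALSE]
    nearCol <- max.col(-Dm, ties.method = "first")
    dNear <- Dm[cbind(seq_len(n), nearCol)]
    dSecond <- if (length(medoids) == 1L) rep(Inf, n) else {
      Dm2 <- Dm
      Dm2[cbind(seq_len(n), nearCol)] <- Inf
      Dm2[cbind(seq_len(n), max.col(-Dm2, ties.method = "first"))]
    }
    list(near = medoids[nearCol], dNear = dNear, dSecond = dSecond)
  }

  # steepest-descent SWAP from a given initial medoid set
  swapDescent <- function(medoids) {
    repeat {
      nt <- nearTwo(medoids)
      nonMed <- setdiff(seq_len(n), medoids)
      if (!length(nonMed) || k == n) break
      best <- list(delta = -1e-12, m = NA, h = NA)
      grp <- factor(nt$near, levels = medoids)
      for (h in nonMed) {
        Dh <- D[, h]
        common <- pmin(Dh - nt$dNear, 0)
        altGain <- pmin(Dh, nt$dSecond) - nt$dNear
        sums <- rowsum(cbind(common, altGain), grp)
        delta <- sum(common) - sums[, 1L] + sums[, 2L]
        i <- which.min(delta)
        if (delta[i] < best$delta) {
          best <- list(delta = delta[i], m = medoids[i], h = h)
        }
      }
      if (is.na(best$m)) break
      medoids[medoids == best$m] <- best$h
    }
    medoids
  }

  # BUILD
  medoids <- integer(0)
  dNear <- numeric(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(n), medoids)
    if (step == 1L) {
      tot <- vapply(cand, function(cdd) sum(D[, cdd]), numeric(1))
      pick <- cand[which.min(tot)]
      dNear <- D[, pick]
    } else {
      gain <- vapply(cand, function(cdd)
        sum(pmax(dNear - D[, cdd], 0)), numeric(1))
      pick <- cand[which.max(gain)]
      dNear <- pmin(dNear, D[, pick])
    }
    medoids <- c(medoids, pick)
  }

  totalCost <- function(medoids)
    sum(apply(D[, medoids, drop = FALSE], 1L, min))
  bestMedoids <- swapDescent(medoids)
  bestCost <- totalCost(bestMedoids)
  if (nStart > 1L && k < n) {
    starts <- withSeed(deriveSeed(seed, 97L), lapply(
      seq_len(nStart - 1L), function(s) sort(sample.int(n, k))))
    for (s in starts) {
      m <- swapDescent(s)
      cost <- totalCost(m)
      if (cost < bestCost - 1e-12) {
        bestMedoids <- m
        bestCost <- cost
      }
    }
  }
  medoids <- sort(bestMedoids)
  Dm <- D[, medoids, drop = FALSE]
  assignCol <- max.col(-Dm, ties.method = "first")
  list(medoids = medoids, assignment = assignCol,
       cost = sum(Dm[cbind(seq_len(n), assignCol)]))
}

#' Gap statistic for PAM with first-local-maximum selection
#'
#' For each k in `kRange`, the within dispersion `W_k` is the PAM total
#' cost; reference datasets destroy the joint structure by independently
#' permuting each binary feature column (preserving column marginals,
#' which suits binary profiles better than the uniform-box reference).
#' `gap(k) = mean_ref log W_k^ref - log W_k`. The chosen k is the smallest
#' `k >= 2` with `gap(k) >= gap(k-1)` and `gap(k) >= gap(k+1)`; if no
#' local maximum exists, the largest k is returned with a warning. If all
#' profiles are identical, `k = 1`.
#'
#' @param x binary matrix (points x features).
#' @param kRange integer vector of candidate cluster counts.
#' @param nReference number of reference datasets.
#' @param distance `"hamming"` or `"jaccard"`.
#' @param seed seed for the reference permutations.
#' @return list with `trace` (data.frame `k`, `logW`, `gap`, `se`) and
#'   `kChosen`.
#' @export
gapStatistic <- function(x, kRange = 1:20, nReference = 20L,
                         distance = "hamming", seed = 1L) {
  stopifnot(min(kRange) >= 1L)
  x <- as.matrix(x)
  kRange <- sort(unique(as.integer(kRange)))
  kRange <- kRange[kRange <= nrow(x)]
  if (all(x[rep(1L, nrow(x)), , drop = FALSE] == x))
    return(list(trace = data.frame(k = 1L, logW = -Inf, gap = 0,
                                   se = 0),
                kChosen = 1L))
  logSafe <- function(w) log(max(w, .Machine$double.eps))
  # two starts per PAM call: dispersion estimates need consistency, not
  # global optimality, and the gap loop dominates the runtime
  D <- profileDist(x, distance)
  logW <- vapply(kRange, function(k)
    logSafe(pamCluster(D, k, seed = seed, nStart = 2L)$cost),
    numeric(1))
  refLogW <- matrix(NA_real_, nReference, length(kRange))
  for (b in seq_len(nReference)) {
    xr <- withSeed(deriveSeed(seed, b),
                   apply(x, 2L, sample))
    Dr <- profileDist(xr, distance)
    refLogW[b, ] <- vapply(kRange, function(k)
      logSafe(pamCluster(Dr, k, seed = seed, nStart = 2L)$cost),
      numeric(1))
  }
  gap <- colMeans(refLogW) - logW
  se <- apply(refLogW, 2L, sd) * sqrt(1 + 1 / nReference)
  trace <- data.frame(k = kRange, logW = logW, gap = gap, se = se)
  kChosen <- NA_integer_
  for (i in seq_along(kRange)) {
    if (kRange[i] < 2L || i == 1L || i == length(kRange)) next
    if (gap[i] >= gap[i - 1L] && gap[i] >= gap[i + 1L]) {
      kChosen <- kRange[i]
      break
    }
  }
  if (is.na(kChosen)) {
    warning("no local maximum in gap curve; using largest k")
    kChosen <- max(kRange)
  }
  list(trace = trace, kChosen = kChosen)
}

#' Cluster cases by risk-variant profiles; relatives follow their case
#'
#' Only probands are clustered (PAM on their binary risk-variant
#' profiles, k chosen by [gapStatistic()]); every other family member is
#' assigned to its proband's cluster.
#'
#' @param cohort a [FamilyCohort-class].
#' @param pm a [PresenceMatrix-class].
#' @param riskVariants variant ids to profile on.
#' @param kRange,nReference,distance,seed passed to [gapStatistic()].
#' @param k optional fixed cluster count (skips the gap statistic).
#' @return a [ClusterModel-class].
#' @export
clusterCases <- function(cohort, pm, riskVariants, kRange = 1:20,
                         nReference = 20L, distance = "hamming",
                         seed = 1L, k = NULL) {
  fam <- families(cohort)
  rows <- match(fam$proband_id, rownames(presence(pm)))
  cols <- match(riskVariants, colnames(presence(pm)))
  if (anyNA(rows) || anyNA(cols)) stop("unknown samples or variants")
  x <- presence(pm)[rows, cols, drop = FALSE] * 1L
  if (is.null(k)) {
    gs <- gapStatistic(x, kRange, nReference, distance, seed)
    kChosen <- gs$kChosen
    trace <- gs$trace
  } else {
    kChosen <- as.integer(k)
    trace <- data.frame(k = integer(0), logW = numeric(0),
                        gap = numeric(0), se = numeric(0))
  }
  pc <- pamCluster(profileDist(x, distance), kChosen)
  assignment <- setNames(pc$assignment, fam$proband_id)
  smp <- sampleInfo(cohort)
  famCluster <- setNames(assignment[fam$proband_id], fam$family_id)
  memberAssignment <- setNames(as.integer(famCluster[smp$family_id]),
                               smp$sample_id)
  new("ClusterModel", kChosen = kChosen,
      medoids = fam$proband_id[pc$medoids],
      assignment = assignment, memberAssignment = memberAssignment,
      gapTrace = trace, selected = list(), reports = list(),
      distance = distance)
}

#' Chi-square FPR univariate feature selection
#'
#' Keeps feature `v` iff the chi-square p-value of its carrier 2x2 table
#' (within the supplied samples only) is below the FPR threshold.
#'
#' @param features 0/1 matrix (samples x features).
#' @param labels 0/1 vector aligned to rows.
#' @param fpr false-positive-rate threshold in `(0, 1]`.
#' @return integer indices of selected features.
#' @export
selectFeaturesFpr <- function(features, labels, fpr) {
  stopifnot(fpr > 0, fpr <= 1)
  y <- as.integer(labels)
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  a <- .colSums(features[y == 1L, , drop = FALSE] > 0, nPos,
                ncol(features))
  c <- .colSums(features[y == 0L, , drop = FALSE] > 0, nNeg,
                ncol(features))
  st <- chiSquare2x2(a, nPos - a, c, nNeg - c)
  which(st$p < fpr)
}

# Restrict a cohort to the given families.
subsetCohort <- function(cohort, familyIds) {
  fam <- families(cohort)
  fam <- fam[fam$family_id %in% familyIds, , drop = FALSE]
  smp <- sampleInfo(cohort)
  smp <- smp[smp$family_id %in% familyIds, , drop = FALSE]
  rownames(fam) <- rownames(smp) <- NULL
  new("FamilyCohort", families = fam, samples = smp)
}

#' Sweep the FPR grid over fixed clusters and pick the best threshold
#'
#' Clusters are fixed before the sweep. For each FPR value: per-cluster
#' chi-square feature selection (within the cluster's samples, case vs
#' other members), then a per-cluster classifier evaluated with
#' family-wise splits inside the cluster; the sweep reports the mean test
#' AUC and weighted accuracy across clusters. The chosen FPR maximizes
#' mean AUC (ties break to the smaller threshold). Clusters too small to
#' split, or left with no selected feature, are excluded with a warning.
#'
#' @param cohort,pm,riskVariants as in [clusterCases()].
#' @param model a [ClusterModel-class].
#' @param fprGrid thresholds to try (default spans 0.001 to 0.5).
#' @param algorithm,trainFraction,nCycles,seed passed to [trainEval()].
#' @return list with `sweep` (data.frame `fpr`, `mean_auc`,
#'   `mean_weighted_accuracy`, `n_clusters_used`), `chosenFpr`, and
#'   `model` updated with per-cluster selections and reports at the
#'   chosen threshold.
#' @export
sweepFpr <- function(cohort, pm, riskVariants, model,
                     fprGrid = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2,
                                 0.3, 0.5),
                     algorithm = "linear_svm", trainFraction = 0.67,
                     nCycles = 10L, seed = 1L) {
  fam <- families(cohort)
  famCluster <- setNames(clusterAssignment(model)[fam$proband_id],
                         fam$family_id)
  evalCluster <- function(cl, fpr) {
    famIds <- names(famCluster)[famCluster == cl]
    if (length(famIds) < 3L) {
      warning("cluster ", cl, ": too few families, excluded")
      return(NULL)
    }
    sub <- subsetCohort(cohort, famIds)
    ft <- buildFeatures(pm, riskVariants, sub)
    sel <- selectFeaturesFpr(ft$features, ft$labels, fpr)
    if (!length(sel)) {
      warning("cluster ", cl, ": no features at fpr ", fpr, ", excluded")
      return(NULL)
    }
    rep <- trainEval(ft$features[, sel, drop = FALSE], ft$labels,
                     ft$weights, sub, algorithm, trainFraction,
                     nCycles, seed)
    list(selected = colnames(ft$features)[sel], report = rep)
  }
  rows <- list()
  perFprDetails <- list()
  for (fpr in fprGrid) {
    det <- lapply(seq_len(model@kChosen), evalCluster, fpr = fpr)
    used <- !vapply(det, is.null, logical(1))
    aucs <- vapply(det[used], function(d)
      reportAggregate(d$report)$test_auc, numeric(1))
    waccs <- vapply(det[used], function(d)
      reportAggregate(d$report)$test_weighted_accuracy, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      fpr = fpr,
      mean_auc = if (any(used)) mean(aucs) else NA_real_,
      mean_weighted_accuracy = if (any(used)) mean(waccs) else NA_real_,
      n_clusters_used = sum(used))
    perFprDetails[[as.character(fpr)]] <- det
  }
  sweep <- do.call(rbind, rows)
  ok <- !is.na(sweep$mean_auc)
  if (!any(ok)) stop("no cluster could be evaluated at any FPR")
  best <- which(sweep$mean_auc == max(sweep$mean_auc[ok]) & ok)[1L]
  chosenFpr <- sweep$fpr[best]
  det <- perFprDetails[[as.character(chosenFpr)]]
  model@selected <- lapply(det, function(d)
    if (is.null(d)) character(0) else d$selected)
  model@reports <- lapply(det, function(d)
    if (is.null(d)) NULL else d$report)
  list(sweep = sweep, chosenFpr = chosenFpr, model = model)
}
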