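# case_predictor: risk-variant features, family-wise splits, weighted
# train/eval of three classifier families behind one surface.

#' Build binary risk-variant features for case-status prediction
#'
#' One binary feature per risk variant per sample; all family members are
#' included, which improves the sample-to-feature ratio at the cost of a
#' class imbalance that is handled by inverse-class-frequency weighting
#' (see [associationLabels()] in `predict` mode).
#'
#' @param pm a [PresenceMatrix-class].
#' @param riskVariants variant ids (typically the unique variants of the
#'   significant pairs).
#' @param cohort a [FamilyCohort-class].
#' @return list with `features` (0/1 integer matrix samples x variants),
#'   `labels` and `weights` (aligned to feature rows).
#' @export
buildFeatures <- function(pm, riskVariants, cohort) {
  if (!length(riskVariants))
    stop("empty risk-variant set; relax the search thresholds")
  cols <- match(riskVariants, colnames(presence(pm)))
  if (anyNA(cols)) stop("unknown risk variant id(s)")
  lab <- associationLabels(cohort, "predict")
  rows <- match(lab$sample_id, rownames(presence(pm)))
  if (anyNA(rows)) stop("cohort sample(s) missing from presence matrix")
  X <- presence(pm)[rows, cols, drop = FALSE] * 1L
  rownames(X) <- lab$sample_id
  list(features = X, labels = setNames(lab$label, lab$sample_id),
       weights = setNames(lab$weight, lab$sample_id))
}

#' Deterministic family-wise train/test split
#'
#' Permutes family ids with a seed derived from `(seed, cycle)` and sends
#' the first `ceiling(trainFraction * F)` families' members to the
#' training set, the rest to the test set. No family ever contributes to
#' both sets.
#'
#' @param cohort a [FamilyCohort-class].
#' @param trainFraction fraction of families to train on (default 0.67).
#' @param seed base seed.
#' @param cycle cycle index (1-based).
#' @return list with `train` and `test` sample-id vectors and the family
#'   partitions.
#' @export
splitFamilies <- function(cohort, trainFraction = 0.67, seed = 1L,
                          cycle = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  fam <- families(cohort)
  if (nrow(fam) < 2L) stop("need at least two families to split")
  perm <- withSeed(deriveSeed(seed, cycle),
                   sample(fam$family_id))
  nTrain <- ceiling(trainFraction * length(perm))
  trainFams <- perm[seq_len(nTrain)]
  testFams <- perm[-seq_len(nTrain)]
  smp <- sampleInfo(cohort)
  list(train = smp$sample_id[smp$family_id %in% trainFams],
       test = smp$sample_id[smp$family_id %in% testFams],
       trainFamilies = trainFams, testFamilies = testFams)
}

# Fit one algorithm on the training block; return a scoring closure.
fitClassifier <- function(X, y, w, algorithm) {
  yf <- factor(y, levels = c(0L, 1L))
  switch(algorithm,
    linear_svm = {
      cw <- c("0" = mean(w[y == 0L]), "1" = mean(w[y == 1L]))
      cw <- cw / min(cw)
      fit <- e1071::svm(X, yf, kernel = "linear", cost = 1,
                        scale = FALSE, class.weights = cw)
      function(Xn) {
        pr <- predict(fit, Xn, decision.values = TRUE)
        dv <- drop(attr(pr, "decision.values"))
        # orient decision values so higher means case
        if (!startsWith(colnames(attr(pr, "decision.values"))[1L], "1"))
          dv <- -dv
        list(score = dv, class = as.integer(as.character(pr)))
      }
    },
    logistic = {
      fit <- suppressWarnings(
        glm.fit(cbind(1, X), y, weights = w, family = binomial()))
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      function(Xn) {
        eta <- drop(cbind(1, Xn) %*% beta)
        list(score = eta, class = as.integer(eta > 0))
      }
    },
    naive_bayes = {
      df <- as.data.frame(lapply(as.data.frame(X), factor,
                                 levels = c(0L, 1L)))
      fit <- e1071::naiveBayes(df, yf, laplace = 1)
      function(Xn) {
        dfn <- as.data.frame(lapply(as.data.frame(Xn), factor,
                                    levels = c(0L, 1L)))
        pr <- predict(fit, dfn, type = "raw")
        sc <- pr[, "1"]
        list(score = sc, class = as.integer(sc > 0.5))
      }
    },
    stop("unknown algorithm: ", algorithm))
}

# Weighted confusion metrics for one phase of one cycle.
phaseMetrics <- function(scored, y) {
  pred <- scored$class
  tp <- sum(pred == 1L & y == 1L); fn <- sum(pred == 0L & y == 1L)
  fp <- sum(pred == 1L & y == 0L); tn <- sum(pred == 0L & y == 0L)
  nPos <- tp + fn; nNeg <- fp + tn
  # inverse-class-frequency weights within the evaluated fold: equals
  # balanced accuracy, (TPR + TNR) / 2
  wacc <- if (nPos > 0 && nNeg > 0) (tp / nPos + tn / nNeg) / 2
          else NA_real_
  st <- chiSquare2x2(tp, fn, fp, tn)
  data.frame(TP = tp, FN = fn, FP = fp, TN = tn,
             weighted_accuracy = wacc,
             auc = aucRank(scored$score, y == 1L),
             chi2 = st$chi2, p = st$p)
}

#' Train and evaluate a case-status classifier over repeated splits
#'
#' Per cycle: families are split ([splitFamilies()]), the model is fitted
#' on the training members with class weights, and both folds are scored.
#' Metrics per fold: the weighted (balanced) accuracy, the rank-statistic
#' AUC on decision scores, and the chi-square significance of the
#' confusion table. Aggregates are means over cycles, with p-values
#' combined by averaging logarithms (geometric mean). Cycles whose test
#' fold contains a single class are skipped with a warning and excluded
#' from aggregates.
#'
#' @param features,labels,weights from [buildFeatures()].
#' @param cohort the [FamilyCohort-class] the features came from.
#' @param algorithm `"linear_svm"` (default), `"logistic"` or
#'   `"naive_bayes"`.
#' @param trainFraction,nCycles,seed split plan (defaults 0.67, 100, 1).
#' @return a [ClassifierReport-class].
#' @export
trainEval <- function(features, labels, weights, cohort,
                      algorithm = c("linear_svm", "logistic",
                                    "naive_bayes"),
                      trainFraction = 0.67, nCycles = 100L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  rowsOf <- function(ids) match(ids, rownames(features))
  cycles <- list()
  skipped <- 0L
  for (cy in seq_len(nCycles)) {
    sp <- splitFamilies(cohort, trainFraction, seed, cy)
    trIdx <- rowsOf(intersect(sp$train, rownames(features)))
    teIdx <- rowsOf(intersect(sp$test, rownames(features)))
    yTr <- labels[trIdx]; yTe <- labels[teIdx]
    if (length(unique(yTe)) < 2L || length(unique(yTr)) < 2L) {
      warning("cycle ", cy, ": single-class fold, skipped")
      skipped <- skipped + 1L
      next
    }
    scorer <- fitClassifier(features[trIdx, , drop = FALSE], yTr,
                            weights[trIdx], algorithm)
    for (phase in c("train", "test")) {
      idx <- if (phase == "train") trIdx else teIdx
      m <- phaseMetrics(scorer(features[idx, , drop = FALSE]),
                        labels[idx])
      m$cycle <- cy; m$phase <- phase
      cycles[[length(cycles) + 1L]] <- m
    }
  }
  cyc <- do.call(rbind, cycles)
  if (is.null(cyc))
    stop("all cycles skipped; folds degenerate")
  agg <- function(phase, col) mean(cyc[cyc$phase == phase, col])
  aggregate <- list(
    test_weighted_accuracy = agg("test", "weighted_accuracy"),
    test_auc = agg("test", "auc"),
    test_log_avg_p = logAverageP(cyc$p[cyc$phase == "test"]),
    train_weighted_accuracy = agg("train", "weighted_accuracy"),
    train_auc = agg("train", "auc"),
    train_log_avg_p = logAverageP(cyc$p[cyc$phase == "train"]),
    n_cycles_used = nCycles - skipped,
    n_cycles_skipped = skipped)
  new("ClassifierReport", algorithm = algorithm,
      cycles = cyc[, c("cycle", "phase", "TP", "FN", "FP", "TN",
                       "weighted_accuracy", "auc", "chi2", "p")],
      aggregate = aggregate)
}
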