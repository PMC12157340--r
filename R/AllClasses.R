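#' FamilyCohort: a pedigree-structured sample set
#'
#' Holds quad (simplex) families — father, mother, affected proband,
#' unaffected sibling — together with a flat sample table. The
#' `control_designate_id` column records which member stands in as the
#' family's control after a gender-mismatch policy has been applied
#' (the sibling by default).
#'
#' @slot families data.frame with one row per family: `family_id`,
#'   `father_id`, `mother_id`, `proband_id`, `sibling_id`, `proband_sex`,
#'   `sibling_sex` (`"M"`/`"F"`), `control_designate_id`.
#' @slot samples data.frame with one row per individual: `sample_id`,
#'   `family_id`, `role` (father/mother/proband/sibling), `sex`, `affected`.
#'
#' @seealso [ingestCohort()], [simulateCohort()], [applyGenderPolicy()]
#' @export
setClass("FamilyCohort",
  representation(families = "data.frame", samples = "data.frame"))

setValidity("FamilyCohort", function(object) {
  fam <- object@families
  smp <- object@samples
  need <- c("family_id", "father_id", "mother_id", "proband_id",
            "sibling_id", "proband_sex", "sibling_sex",
            "control_designate_id")
  if (!all(need %in% names(fam)))
    return(paste("families missing columns:",
                 paste(setdiff(need, names(fam)), collapse = ", ")))
  if (anyDuplicated(fam$family_id)) return("duplicate family ids")
  if (anyDuplicated(smp$sample_id)) return("duplicate sample ids")
  aff <- smp$affected[match(fam$proband_id, smp$sample_id)]
  if (!all(aff)) return("every proband must be affected")
  others <- smp$affected[!(smp$sample_id %in% fam$proband_id)]
  if (any(others)) return("non-proband members must be unaffected")
  ok <- fam$control_designate_id == fam$sibling_id |
    fam$control_designate_id == fam$father_id |
    fam$control_designate_id == fam$mother_id
  if (!all(ok)) return("control designate must be sibling or a parent")
  TRUE
})

#' PresenceMatrix: post-filter variant presence
#'
#' Boolean samples-by-variants matrix of carrier status after reference
#' removal and the allele-depth fraction filter: entry `[s, v]` is `TRUE`
#' iff sample `s` carries at least one alternate allele of `v` and the
#' alternate-depth fraction meets the threshold. A parallel missingness
#' matrix records genotypes that were absent from the input (`./.`), which
#' matters for de novo classification. Variant metadata keeps the
#' chromosome class (autosome vs sex) used in search summaries.
#'
#' @slot presence logical matrix, samples x variants; rownames are sample
#'   ids, colnames variant ids (`chrom:pos:ref:alt`).
#' @slot missing logical matrix of the same shape marking missing genotypes.
#' @slot variants data.frame: `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `chrom_class`.
#' @slot adThreshold minimum alternate-depth fraction applied (in `[0, 1]`).
#'
#' @seealso [ingestCohort()], [screenVariants()], [scanPairs()]
#' @export
setClass("PresenceMatrix",
  representation(presence = "matrix", missing = "matrix",
                 variants = "data.frame", adThreshold = "numeric"))

setValidity("PresenceMatrix", function(object) {
  if (!is.logical(object@presence)) return("presence must be logical")
  if (!identical(dim(object@presence), dim(object@missing)))
    return("presence and missing dimensions differ")
  if (nrow(object@variants) != ncol(object@presence))
    return("variant metadata rows must match presence columns")
  if (anyDuplicated(object@variants$id))
    return("variant ids must be unique")
  if (object@adThreshold < 0 || object@adThreshold > 1)
    return("adThreshold must be in [0, 1]")
  TRUE
})

#' ClassifierReport: repeated family-wise train/test evaluation
#'
#' Per-cycle confusion counts and metrics for a case-status classifier
#' evaluated over repeated family-wise splits, plus aggregates: mean
#' weighted accuracy, mean AUC and the log-averaged significance
#' (geometric mean of the per-cycle chi-square p-values).
#'
#' @slot algorithm one of `"linear_svm"`, `"logistic"`, `"naive_bayes"`.
#' @slot cycles data.frame with columns `cycle`, `phase` (train/test),
#'   `TP`, `FN`, `FP`, `TN`, `weighted_accuracy`, `auc`, `chi2`, `p`.
#' @slot aggregate named list: `test_weighted_accuracy`, `test_auc`,
#'   `test_log_avg_p`, `train_weighted_accuracy`, `train_auc`,
#'   `train_log_avg_p`, `n_cycles_used`, `n_cycles_skipped`.
#' @export
setClass("ClassifierReport",
  representation(algorithm = "character", cycles = "data.frame",
                 aggregate = "list"))

#' ClusterModel: PAM subtype clustering of cases
#'
#' Result of clustering cases by their risk-variant presence profiles with
#' PAM, choosing the cluster count by the gap statistic (first local
#' maximum). Only cases are clustered; every other family member follows
#' its case. Per-cluster selected variant sets and classifier reports are
#' attached by the FPR sweep.
#'
#' @slot kChosen integer number of clusters.
#' @slot medoids character sample ids of the medoid cases.
#' @slot assignment named integer vector: case sample id -> cluster.
#' @slot memberAssignment named integer vector over all cohort members.
#' @slot gapTrace data.frame: `k`, `logW`, `gap`, `se`.
#' @slot selected list (per cluster) of selected variant ids, possibly empty.
#' @slot reports list (per cluster) of [ClassifierReport-class] or `NULL`.
#' @slot distance distance used (`"hamming"` or `"jaccard"`).
#' @export
setClass("ClusterModel",
  representation(kChosen = "integer", medoids = "character",
                 assignment = "integer", memberAssignment = "integer",
                 gapTrace = "data.frame", selected = "list",
                 reports = "list", distance = "character"))

setValidity("ClusterModel", function(object) {
  if (length(object@assignment) &&
      any(object@assignment < 1 | object@assignment > object@kChosen))
    return("cluster labels out of range")
  if (is.null(names(object@assignment)))
    return("assignment must be named by case sample id")
  TRUE
})
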