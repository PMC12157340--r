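# Generics, accessors and show methods for the core containers.

#' @describeIn FamilyCohort-class family table accessor
#' @param object a `FamilyCohort`
#' @export
setGeneric("families", function(object) standardGeneric("families"))
#' @export
setMethod("families", "FamilyCohort", function(object) object@families)

#' @describeIn FamilyCohort-class sample table accessor
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))
#' @export
setMethod("sampleInfo", "FamilyCohort", function(object) object@samples)

#' @describeIn FamilyCohort-class number of families
#' @export
setGeneric("nFamilies", function(object) standardGeneric("nFamilies"))
#' @export
setMethod("nFamilies", "FamilyCohort",
          function(object) nrow(object@families))

setMethod("show", "FamilyCohort", function(object) {
  fam <- object@families
  cat("FamilyCohort with", nrow(fam), "quad families (",
      nrow(object@samples), "samples )\n")
  pm <- mean(fam$proband_sex == "M")
  cat(sprintf("  proband male fraction: %.3f\n", pm))
  cat(sprintf("  control designate = sibling in %d families\n",
              sum(fam$control_designate_id == fam$sibling_id)))
})

#' @describeIn PresenceMatrix-class presence matrix accessor
#' @param object a `PresenceMatrix`
#' @export
setGeneric("presence", function(object) standardGeneric("presence"))
#' @export
setMethod("presence", "PresenceMatrix", function(object) object@presence)

#' @describeIn PresenceMatrix-class missing-genotype mask accessor
#' @export
setGeneric("missingMask", function(object) standardGeneric("missingMask"))
#' @export
setMethod("missingMask", "PresenceMatrix", function(object) object@missing)

#' @describeIn PresenceMatrix-class variant metadata accessor
#' @export
setGeneric("variantInfo", function(object) standardGeneric("variantInfo"))
#' @export
setMethod("variantInfo", "PresenceMatrix", function(object) object@variants)

#' @describeIn PresenceMatrix-class allele-depth threshold used at ingest
#' @export
setGeneric("adThreshold", function(object) standardGeneric("adThreshold"))
#' @export
setMethod("adThreshold", "PresenceMatrix",
          function(object) object@adThreshold)

#' @export
setMethod("dim", "PresenceMatrix", function(x) dim(x@presence))

setMethod("show", "PresenceMatrix", function(object) {
  d <- dim(object@presence)
  cat("PresenceMatrix:", d[1], "samples x", d[2], "variants",
      sprintf("(AD threshold %.2f)\n", object@adThreshold))
  cat(sprintf("  carrier density: %.4f;  %d sex-chromosome variants\n",
              mean(object@presence),
              sum(object@variants$chrom_class == "sex")))
})

#' @describeIn ClusterModel-class chosen number of clusters
#' @param object a `ClusterModel`
#' @export
setGeneric("kChosen", function(object) standardGeneric("kChosen"))
#' @export
setMethod("kChosen", "ClusterModel", function(object) object@kChosen)

#' @describeIn ClusterModel-class gap-statistic trace
#' @export
setGeneric("gapTrace", function(object) standardGeneric("gapTrace"))
#' @export
setMethod("gapTrace", "ClusterModel", function(object) object@gapTrace)

#' @describeIn ClusterModel-class case-to-cluster assignment
#' @export
setGeneric("clusterAssignment",
           function(object) standardGeneric("clusterAssignment"))
#' @export
setMethod("clusterAssignment", "ClusterModel",
          function(object) object@assignment)

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel:", object@kChosen, "clusters (", object@distance,
      "distance )\n")
  print(table(cluster = object@assignment))
})

#' @describeIn ClassifierReport-class aggregate metrics
#' @param object a `ClassifierReport`
#' @export
setGeneric("reportAggregate",
           function(object) standardGeneric("reportAggregate"))
#' @export
setMethod("reportAggregate", "ClassifierReport",
          function(object) object@aggregate)

#' @describeIn ClassifierReport-class per-cycle metric table
#' @export
setGeneric("reportCycles", function(object) standardGeneric("reportCycles"))
#' @export
setMethod("reportCycles", "ClassifierReport", function(object) object@cycles)

setMethod("show", "ClassifierReport", function(object) {
  a <- object@aggregate
  cat("ClassifierReport [", object@algorithm, "] over",
      a$n_cycles_used, "cycles\n")
  cat(sprintf("  test: weighted accuracy %.3f, AUC %.3f, log-avg p %.3g\n",
              a$test_weighted_accuracy, a$test_auc, a$test_log_avg_p))
  cat(sprintf("  train: weighted accuracy %.3f, AUC %.3f\n",
              a$train_weighted_accuracy, a$train_auc))
})
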