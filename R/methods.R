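#' @describeIn GuideLibrary guide records in load order
#' @param object a GuideLibrary
#' @export
setMethod("guideRecords", "GuideLibrary", function(object) object@records)

#' @export
setMethod("guideRecords", "ScreenExperiment", function(object)
  as.data.frame(SummarizedExperiment::rowData(object)))

#' @export
setMethod("guideIds", "GuideLibrary", function(object) object@records$guide_id)

#' @export
setMethod("guideIds", "ScreenExperiment", function(object) rownames(object))

#' @export
setMethod("length", "GuideLibrary", function(x) nrow(x@records))

#' @export
setMethod("controlGuides", "GuideLibrary", function(object) {
  rec <- object@records
  rec$guide_id[rec$category %in% c("safe", "non_targeting")]
})

#' @export
setMethod("controlGuides", "ScreenExperiment", function(object) {
  rec <- guideRecords(object)
  rec$guide_id[rec$category %in% c("safe", "non_targeting")]
})

#' @export
setMethod("categoryCounts", "GuideLibrary", function(object) {
  n <- table(factor(object@records$category, levels = .GUIDE_CATEGORIES))
  stats::setNames(as.integer(n), names(n))
})

#' @export
setMethod("targetedGenes", "GuideLibrary", function(object) {
  rec <- object@records
  unique(rec$gene[rec$category == "targeting"])
})

#' @export
setMethod("guidesForGene", "GuideLibrary", function(object, gene) {
  rec <- object@records
  rec$guide_id[rec$gene == gene & rec$category == "targeting"]
})

setMethod("show", "GuideLibrary", function(object) {
  cc <- categoryCounts(object)
  cat("GuideLibrary with", length(object), "guides:",
      cc[["targeting"]], "targeting (", length(targetedGenes(object)),
      "genes ),", cc[["safe"]], "safe,", cc[["non_targeting"]],
      "non-targeting\n")
})

#' Extract the count matrix of a ScreenExperiment
#' @param object a [ScreenExperiment-class]
#' @return integer matrix, guides x samples
#' @export
setMethod("counts", "ScreenExperiment", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' Count matrix accessor (function form)
#' @inheritParams ScreenExperiment
#' @param se a [ScreenExperiment-class]
#' @export
screenCounts <- function(se) counts(se)

#' Sample sheet of a ScreenExperiment
#' @param se a [ScreenExperiment-class]
#' @return data.frame with sample_id, condition, day, replicate
#' @export
screenDesign <- function(se) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  rownames(cd) <- NULL
  cd
}

#' Guide library of a ScreenExperiment
#' @param se a [ScreenExperiment-class]
#' @return a [GuideLibrary-class]
#' @export
guideLibrary <- function(se) GuideLibrary(guideRecords(se))

setMethod("show", "ScreenExperiment", function(object) {
  cd <- screenDesign(object)
  cat("ScreenExperiment:", nrow(object), "guides x", ncol(object), "samples\n")
  cat("  conditions:", paste(sort(unique(cd$condition)), collapse = ", "),
      "| days:", paste(sort(unique(cd$day)), collapse = ", "),
      "| replicates per cell:",
      paste(range(table(paste(cd$condition, cd$day))), collapse = "-"), "\n")
})

#' @export
setMethod("genePhenotypes", "ScreenPhenotypes", function(object) object@genes)

#' @export
setMethod("controlSummary", "ScreenPhenotypes", function(object) object@controls)

#' @export
setMethod("guideEffects", "ScreenPhenotypes", function(object) object@guideEffects)

setMethod("show", "ScreenPhenotypes", function(object) {
  cat("ScreenPhenotypes:", length(unique(object@genes$gene)), "genes x",
      length(unique(object@genes$comparison)), "comparisons\n")
  cat("  comparisons:", paste(unique(object@genes$comparison), collapse = ", "), "\n")
})

#' @export
setMethod("partitionLabels", "ExclusivityPartition", function(object) object@labels)

#' @export
setMethod("dropoutSets", "ExclusivityPartition", function(object) object@sets)

setMethod("show", "ExclusivityPartition", function(object) {
  n <- table(factor(object@labels, levels = .PARTITION_LABELS))
  cat("ExclusivityPartition over", length(object@labels), "genes:\n")
  for (lab in .PARTITION_LABELS) cat("  ", lab, ":", n[[lab]], "\n")
})

#' @export
setMethod("truthClasses", "SimTruth", function(object)
  stats::setNames(object@genes$class, object@genes$gene))

#' @export
setMethod("truthEffects", "SimTruth", function(object) object@guides)

setMethod("show", "SimTruth", function(object) {
  n <- table(object@genes$class)
  cat("SimTruth:", nrow(object@genes), "genes (",
      paste(names(n), n, sep = "=", collapse = ", "), ")\n")
})
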