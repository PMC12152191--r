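#' @importFrom BiocGenerics counts
NULL

#' Access the guide records table
#' @param object a [GuideLibrary-class] or [ScreenExperiment-class]
#' @return data.frame with columns guide_id, gene, spacer, category
#' @export
setGeneric("guideRecords", function(object) standardGeneric("guideRecords"))

#' Guide identifiers in library order
#' @param object a [GuideLibrary-class] or [ScreenExperiment-class]
#' @export
setGeneric("guideIds", function(object) standardGeneric("guideIds"))

#' Guide ids of the control set (safe plus non-targeting)
#' @param object a [GuideLibrary-class] or [ScreenExperiment-class]
#' @export
setGeneric("controlGuides", function(object) standardGeneric("controlGuides"))

#' Guide counts by category
#' @param object a [GuideLibrary-class]
#' @return named integer vector over targeting, safe, non_targeting
#' @export
setGeneric("categoryCounts", function(object) standardGeneric("categoryCounts"))

#' Targeted gene symbols (controls excluded)
#' @param object a [GuideLibrary-class]
#' @export
setGeneric("targetedGenes", function(object) standardGeneric("targetedGenes"))

#' Guide ids targeting one gene
#' @param object a [GuideLibrary-class]
#' @param gene a gene symbol
#' @export
setGeneric("guidesForGene", function(object, gene) standardGeneric("guidesForGene"))

#' Gene-level phenotype table
#' @param object a [ScreenPhenotypes-class]
#' @export
setGeneric("genePhenotypes", function(object) standardGeneric("genePhenotypes"))

#' Per-comparison control summary (u_ctrl, var_ctrl, n_ctrl)
#' @param object a [ScreenPhenotypes-class]
#' @export
setGeneric("controlSummary", function(object) standardGeneric("controlSummary"))

#' Per-guide control-centred effect sizes (pZ)
#' @param object a [ScreenPhenotypes-class]
#' @export
setGeneric("guideEffects", function(object) standardGeneric("guideEffects"))

#' Exclusivity labels per gene
#' @param object an [ExclusivityPartition-class]
#' @return named character vector of labels over the gene universe
#' @export
setGeneric("partitionLabels", function(object) standardGeneric("partitionLabels"))

#' The four underlying dropout gene sets
#' @param object an [ExclusivityPartition-class]
#' @export
setGeneric("dropoutSets", function(object) standardGeneric("dropoutSets"))

#' Ground-truth gene classes of a simulated screen
#' @param object a [SimTruth-class]
#' @export
setGeneric("truthClasses", function(object) standardGeneric("truthClasses"))

#' Realized per-guide fitness effects of a simulated screen
#' @param object a [SimTruth-class]
#' @export
setGeneric("truthEffects", function(object) standardGeneric("truthEffects"))
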