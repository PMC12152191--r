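#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Reserved gene symbol for control guides
#'
#' Safe-harbor and non-targeting guides do not target a gene; their `gene`
#' field must carry this sentinel so that no control can be mistaken for a
#' targeting guide against a real symbol.
#'
#' @export
CONTROL_SENTINEL <- "CONTROL"

.GUIDE_CATEGORIES <- c("targeting", "safe", "non_targeting")
.CONDITIONS <- c("2D", "3D")

#' GuideLibrary: a validated sgRNA library catalogue
#'
#' Holds one record per guide: a unique `guide_id`, the target `gene` (or the
#' control sentinel `"CONTROL"`), the 17-18 nt `spacer`, and a `category`
#' (`targeting`, `safe`, or `non_targeting`). Validity enforces unique guide
#' ids, globally unique spacers, A/C/G/T spacers of length 17-18, and the
#' control-sentinel rule. Load order is preserved.
#'
#' @slot records data.frame with columns guide_id, gene, spacer, category.
#'
#' @seealso [readGuideLibrary()], [guideIds()], [controlGuides()]
#' @export
setClass("GuideLibrary", representation(records = "data.frame"))

.validGuideLibrary <- function(object) {
  rec <- object@records
  msgs <- character()
  need <- c("guide_id", "gene", "spacer", "category")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(rec) == 0L)
    return("library must contain at least one guide")
  dup <- rec$guide_id[duplicated(rec$guide_id)]
  if (length(dup))
    msgs <- c(msgs, paste0("duplicate guide_id: ",
                           paste(unique(dup), collapse = ", ")))
  bad_cat <- setdiff(unique(rec$category), .GUIDE_CATEGORIES)
  if (length(bad_cat))
    msgs <- c(msgs, paste0("invalid category: ", paste(bad_cat, collapse = ", ")))
  bad_sp <- !grepl("^[ACGT]{17,18}$", rec$spacer)
  if (any(bad_sp))
    msgs <- c(msgs, paste0("spacer must be A/C/G/T of length 17-18; offending guides: ",
                           paste(utils::head(rec$guide_id[bad_sp], 5L), collapse = ", ")))
  dsp <- duplicated(rec$spacer) | duplicated(rec$spacer, fromLast = TRUE)
  if (any(dsp) && !any(bad_sp)) {
    culprit <- rec$guide_id[dsp]
    msgs <- c(msgs, paste0("duplicate spacers shared by guides: ",
                           paste(culprit, collapse = ", ")))
  }
  is_ctrl <- rec$category != "targeting"
  if (any(is_ctrl & rec$gene != CONTROL_SENTINEL))
    msgs <- c(msgs, paste0("control guides must use gene sentinel '",
                           CONTROL_SENTINEL, "': ",
                           paste(rec$guide_id[is_ctrl & rec$gene != CONTROL_SENTINEL],
                                 collapse = ", ")))
  if (any(!is_ctrl & rec$gene == CONTROL_SENTINEL))
    msgs <- c(msgs, paste0("targeting guides may not use the control sentinel: ",
                           paste(rec$guide_id[!is_ctrl & rec$gene == CONTROL_SENTINEL],
                                 collapse = ", ")))
  if (length(msgs)) msgs else TRUE
}
setValidity("GuideLibrary", .validGuideLibrary)

#' Construct a GuideLibrary from a records table
#'
#' @param records data.frame with columns `guide_id`, `gene`, `spacer`,
#'   `category`. Spacers are upper-cased before validation.
#' @return A validated [GuideLibrary-class] object.
#' @examples
#' lib <- GuideLibrary(data.frame(
#'   guide_id = c("g1", "g2", "s1"),
#'   gene = c("GENEA", "GENEA", "CONTROL"),
#'   spacer = c("ACGTACGTACGTACGTAC", "TGCATGCATGCATGCATG",
#'              "GGGTACGTACGTACGTAC"),
#'   category = c("targeting", "targeting", "safe")))
#' @export
GuideLibrary <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("guide_id", "gene", "spacer", "category"))
    if (col %in% names(records)) records[[col]] <- as.character(records[[col]])
  if ("spacer" %in% names(records)) records$spacer <- toupper(records$spacer)
  rownames(records) <- NULL
  new("GuideLibrary", records = records)
}

#' ScreenExperiment: counts + guide library + screen design
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the guide-by-sample
#' integer count matrix in the `"counts"` assay, the guide library in
#' `rowData` and the sample sheet (`condition`, `day`, `replicate`) in
#' `colData`. Validity enforces non-negative integer counts, one day-0
#' baseline sample per condition present, and unique
#' (condition, day, replicate) triples.
#'
#' @seealso [ScreenExperiment()], [screenCounts()], [screenDesign()],
#'   [guideLibrary()]
#' @export
setClass("ScreenExperiment", contains = "SummarizedExperiment")

.validScreenExperiment <- function(object) {
  msgs <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msgs <- c(msgs, "counts must be non-negative integers")
  cd <- as.data.frame(SummarizedExperiment::colData(object))
  need <- c("condition", "day", "replicate")
  if (!all(need %in% names(cd)))
    return(paste("colData must have columns:", paste(need, collapse = ", ")))
  if (!all(cd$condition %in% .CONDITIONS))
    msgs <- c(msgs, "condition must be one of '2D', '3D'")
  if (!all(cd$day %in% c(0L, 7L, 14L)))
    msgs <- c(msgs, "day must be one of 0, 7, 14")
  if (any(cd$replicate < 1L))
    msgs <- c(msgs, "replicate must be a positive integer")
  key <- paste(cd$condition, cd$day, cd$replicate)
  if (anyDuplicated(key))
    msgs <- c(msgs, "(condition, day, replicate) must be unique")
  for (cond in unique(cd$condition))
    if (!any(cd$condition == cond & cd$day == 0L))
      msgs <- c(msgs, paste0("condition ", cond, " has no day-0 baseline sample"))
  rd <- as.data.frame(SummarizedExperiment::rowData(object))
  if (!all(c("guide_id", "gene", "category") %in% names(rd)))
    msgs <- c(msgs, "rowData must carry guide_id, gene, category")
  if (length(msgs)) msgs else TRUE
}
setValidity("ScreenExperiment", .validScreenExperiment)

#' Build a ScreenExperiment from counts, a library and a sample sheet
#'
#' @param counts integer matrix, guides in rows (rownames = guide ids),
#'   samples in columns (colnames = sample ids).
#' @param library a [GuideLibrary-class]; row order of `counts` must match.
#' @param design data.frame sample sheet with columns `sample_id`,
#'   `condition` ("2D"/"3D"), `day` (0/7/14) and `replicate`.
#' @return A [ScreenExperiment-class].
#' @export
ScreenExperiment <- function(counts, library, design) {
  stopifnot(is(library, "GuideLibrary"))
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition", "day", "replicate") %in% names(design)))
    stop("design needs columns sample_id, condition, day, replicate",
         call. = FALSE)
  counts <- as.matrix(counts)
  rec <- guideRecords(library)
  if (is.null(rownames(counts)))
    rownames(counts) <- rec$guide_id
  if (!identical(rownames(counts), rec$guide_id)) {
    if (!setequal(rownames(counts), rec$guide_id))
      stop("count rows do not match the guide library", call. = FALSE)
    counts <- counts[rec$guide_id, , drop = FALSE]
  }
  if (is.null(colnames(counts)))
    colnames(counts) <- design$sample_id
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id))
    stop("count columns missing from the sample sheet", call. = FALSE)
  design$day <- as.integer(design$day)
  design$replicate <- as.integer(design$replicate)
  cd <- S4Vectors::DataFrame(design, row.names = design$sample_id)
  rd <- S4Vectors::DataFrame(rec, row.names = rec$guide_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
  new("ScreenExperiment", se)
}

#' EnrichmentTable: per-guide log2 fold enrichment for one or more comparisons
#'
#' @slot summary data.frame: guide_id, comparison, log2fe (replicate mean).
#' @slot replicates data.frame: guide_id, comparison, replicate, log2fe_rep.
#' @slot sizeFactors named numeric, one strictly positive factor per sample.
#' @slot pseudocount numeric pseudocount used.
#' @slot pairing "replicate" or "baseline_mean".
#' @export
setClass("EnrichmentTable", representation(
  summary = "data.frame", replicates = "data.frame",
  sizeFactors = "numeric", pseudocount = "numeric", pairing = "character"))

setValidity("EnrichmentTable", function(object) {
  if (any(object@sizeFactors <= 0)) return("size factors must be positive")
  if (!all(c("guide_id", "comparison", "log2fe") %in% names(object@summary)))
    return("summary must have guide_id, comparison, log2fe")
  TRUE
})

#' ScreenPhenotypes: gene-level phenotype scores and control summaries
#'
#' One row per (gene, comparison) in `genes` with the gene effect size
#' `u_gene` (median control-centred log2 enrichment of its guides), its
#' pooled-variance phenotype score `t_score`, guide count `n_exp`, guide
#' variance `var_gene` and the number of guides meeting the per-guide
#' drop criterion (`n_dropped`). `controls` carries, per comparison, the
#' control median `u_ctrl` (0 by construction), control variance `var_ctrl`
#' and the screen's average guides-per-gene `n_ctrl`. `guideEffects` keeps
#' the per-guide pZ values so calling thresholds can be re-applied.
#'
#' @slot genes data.frame (gene, comparison, n_exp, u_gene, var_gene,
#'   t_score, n_dropped).
#' @slot controls data.frame (comparison, u_ctrl, var_ctrl, n_ctrl).
#' @slot guideEffects data.frame (guide_id, gene, category, comparison, pZ).
#' @slot params list of scoring parameters.
#' @export
setClass("ScreenPhenotypes", representation(
  genes = "data.frame", controls = "data.frame",
  guideEffects = "data.frame", params = "list"))

#' SimTruth: ground-truth ledger of a simulated screen
#'
#' @slot genes data.frame (gene, class) with class in neutral,
#'   common_essential, essential_2D, essential_3D.
#' @slot guides data.frame (guide_id, gene, effect_2D, effect_3D): realized
#'   per-guide log2 abundance change per day in each growth condition.
#' @export
setClass("SimTruth", representation(genes = "data.frame", guides = "data.frame"))

setValidity("SimTruth", function(object) {
  msgs <- character()
  ok_class <- c("neutral", "common_essential", "essential_2D", "essential_3D")
  if (!all(object@genes$class %in% ok_class))
    msgs <- c(msgs, "unknown gene class in truth ledger")
  g <- object@guides
  cls <- object@genes$class[match(g$gene, object@genes$gene)]
  if (any(g$effect_2D[cls %in% "essential_3D"] != 0))
    msgs <- c(msgs, "essential_3D guides must have zero 2D effect")
  if (any(g$effect_3D[cls %in% "essential_2D"] != 0))
    msgs <- c(msgs, "essential_2D guides must have zero 3D effect")
  if (any(g$effect_2D[cls %in% "neutral"] != 0) ||
      any(g$effect_3D[cls %in% "neutral"] != 0))
    msgs <- c(msgs, "neutral guides must have zero effect")
  if (length(msgs)) msgs else TRUE
})

#' ExclusivityPartition: condition-exclusivity labels over the gene universe
#'
#' Genes called as dropouts in the four comparisons (2D/3D at day 7/14) are
#' partitioned into mutually exclusive labels: `THREE_D_EXCLUSIVE` (called on
#' both 3D days, neither 2D day), `TWO_D_EXCLUSIVE` (the mirror image),
#' `SHARED` (called in all four), `OTHER` (called somewhere but fitting no
#' class) and `NONE` (never called).
#'
#' @slot labels named character vector, one label per gene in the universe.
#' @slot sets list of the four underlying called-gene sets.
#' @slot membership data.frame of per-gene booleans for UpSet rendering.
#' @export
setClass("ExclusivityPartition", representation(
  labels = "character", sets = "list", membership = "data.frame"))

.PARTITION_LABELS <- c("THREE_D_EXCLUSIVE", "TWO_D_EXCLUSIVE", "SHARED",
                       "OTHER", "NONE")

setValidity("ExclusivityPartition", function(object) {
  if (!all(object@labels %in% .PARTITION_LABELS))
    return("unknown partition label")
  TRUE
})
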