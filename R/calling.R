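# Dropout calling and condition-exclusivity partitioning. A gene is called
# a dropout in a comparison when its control-centred gene effect u_gene is
# below the enrichment threshold (strictly < -0.1 by default) AND at least
# `minGuidesDropped` of its guides individually dropped (pZ <= guideDropMax).

#' Thresholds for dropout calling
#'
#' @param geneLfcMax gene-level enrichment threshold; a gene must have
#'   `u_gene < geneLfcMax` (strict; default -0.1, must be negative)
#' @param minGuidesDropped minimum number of individually dropped guides
#'   (default 3)
#' @param guideDropMax per-guide drop criterion `pZ <= guideDropMax`
#'   (default -0.1; a guide exactly at threshold counts as dropped)
#' @param geneMetric apply the gene threshold to the control-centred
#'   `u_gene` (default) or to the unnormalized gene-median log2fe
#' @return a `callConfig` list
#' @export
callConfig <- function(geneLfcMax = -0.1, minGuidesDropped = 3L,
                       guideDropMax = -0.1,
                       geneMetric = c("u_gene", "raw_median")) {
  if (!is.numeric(geneLfcMax) || geneLfcMax >= 0)
    .input_error("geneLfcMax must be negative")
  minGuidesDropped <- as.integer(minGuidesDropped)
  if (is.na(minGuidesDropped) || minGuidesDropped < 1L)
    .input_error("minGuidesDropped must be >= 1")
  structure(list(geneLfcMax = geneLfcMax,
                 minGuidesDropped = minGuidesDropped,
                 guideDropMax = guideDropMax,
                 geneMetric = match.arg(geneMetric)),
            class = "callConfig")
}

#' Call dropout genes per comparison
#'
#' @param pheno a [ScreenPhenotypes-class]
#' @param config a [callConfig()]
#' @param et optional [EnrichmentTable-class], required only for
#'   `geneMetric = "raw_median"`
#' @return named list of character vectors: called genes per comparison
#' @export
callDropouts <- function(pheno, config = callConfig(), et = NULL) {
  ge <- guideEffects(pheno)
  tg <- ge[ge$category == "targeting" & is.finite(ge$pZ), , drop = FALSE]
  raw <- NULL
  if (config$geneMetric == "raw_median") {
    if (is.null(et))
      .input_error("geneMetric = 'raw_median' needs the EnrichmentTable")
    raw <- enrichmentSummary(et)
  }
  out <- lapply(split(tg, tg$comparison), function(sub) {
    by_gene <- split(sub$pZ, sub$gene)
    metric <- if (config$geneMetric == "u_gene") {
      vapply(by_gene, stats::median, numeric(1))
    } else {
      sel <- raw[raw$comparison == sub$comparison[1] &
                   raw$guide_id %in% sub$guide_id, ]
      gene_of <- sub$gene[match(sel$guide_id, sub$guide_id)]
      vapply(split(sel$log2fe, gene_of), stats::median, numeric(1))[names(by_gene)]
    }
    n_dropped <- vapply(by_gene, function(x)
      sum(x <= config$guideDropMax), integer(1))
    sort(names(by_gene)[metric < config$geneLfcMax &
                          n_dropped >= config$minGuidesDropped])
  })
  out
}

.canon_set_name <- function(nm) {
  # accept "2D_D7", "2D_D7_vs_D0", etc.
  sub("_vs_D0$", "", nm)
}

.four_sets <- function(sets) {
  names(sets) <- .canon_set_name(names(sets))
  need <- c("2D_D7", "2D_D14", "3D_D7", "3D_D14")
  miss <- setdiff(need, names(sets))
  if (length(miss))
    .input_error("exclusivity partition needs the four comparison sets; missing: ",
                 paste(miss, collapse = ", "))
  lapply(sets[need], unique)
}

#' Partition genes by condition exclusivity
#'
#' Given the four per-comparison dropout sets, assigns each gene of the
#' universe one of five mutually exclusive labels:
#' * `THREE_D_EXCLUSIVE`: in both 3D day-sets, in neither 2D day-set
#' * `TWO_D_EXCLUSIVE`: in both 2D day-sets, in neither 3D day-set
#' * `SHARED`: in all four sets
#' * `OTHER`: called somewhere but fitting none of the above
#' * `NONE`: never called
#'
#' With `mode = "any_day"` exclusivity instead requires a call on at least
#' one day of the condition (union over days) and none in the other.
#'
#' @param sets named list of four gene sets; names must identify
#'   `2D_D7`, `2D_D14`, `3D_D7`, `3D_D14` (a `_vs_D0` suffix is accepted),
#'   e.g. the output of [callDropouts()]
#' @param universe gene universe to label (default: union of the sets)
#' @param mode "both_days" (default) or "any_day"
#' @return an [ExclusivityPartition-class]
#' @export
exclusivityPartition <- function(sets, universe = NULL,
                                 mode = c("both_days", "any_day")) {
  mode <- match.arg(mode)
  s <- .four_sets(sets)
  if (is.null(universe)) universe <- sort(unique(unlist(s)))
  in2 <- cbind(universe %in% s[["2D_D7"]], universe %in% s[["2D_D14"]])
  in3 <- cbind(universe %in% s[["3D_D7"]], universe %in% s[["3D_D14"]])
  hit2 <- if (mode == "both_days") in2[, 1] & in2[, 2] else in2[, 1] | in2[, 2]
  hit3 <- if (mode == "both_days") in3[, 1] & in3[, 2] else in3[, 1] | in3[, 2]
  any2 <- in2[, 1] | in2[, 2]
  any3 <- in3[, 1] | in3[, 2]
  labels <- rep("NONE", length(universe))
  labels[any2 | any3] <- "OTHER"
  labels[hit3 & !any2] <- "THREE_D_EXCLUSIVE"
  labels[hit2 & !any3] <- "TWO_D_EXCLUSIVE"
  labels[in2[, 1] & in2[, 2] & in3[, 1] & in3[, 2]] <- "SHARED"
  membership <- data.frame(gene = universe,
                           `2D_D7` = in2[, 1], `2D_D14` = in2[, 2],
                           `3D_D7` = in3[, 1], `3D_D14` = in3[, 2],
                           check.names = FALSE, stringsAsFactors = FALSE)
  new("ExclusivityPartition",
      labels = stats::setNames(labels, universe),
      sets = s, membership = membership)
}

#' Per-gene set membership and intersection counts for UpSet rendering
#'
#' @param sets named list of four gene sets (as in [exclusivityPartition()])
#' @return list with `membership` (one row per gene in the union, four
#'   boolean columns) and `intersections` (data.frame of exclusive
#'   intersection patterns and their sizes; sizes sum to the union size)
#' @export
upsetMembership <- function(sets) {
  s <- .four_sets(sets)
  genes <- sort(unique(unlist(s)))
  membership <- data.frame(gene = genes, check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (nm in names(s)) membership[[nm]] <- genes %in% s[[nm]]
  if (length(genes)) {
    pattern <- apply(membership[-1], 1, function(x)
      paste(names(s)[x], collapse = "&"))
    tab <- table(pattern)
    intersections <- data.frame(pattern = names(tab),
                                n_genes = as.integer(tab),
                                stringsAsFactors = FALSE)
    intersections <- intersections[order(-intersections$n_genes), , drop = FALSE]
    rownames(intersections) <- NULL
  } else {
    intersections <- data.frame(pattern = character(), n_genes = integer())
  }
  list(membership = membership, intersections = intersections)
}

#' Write partition and membership tables as TSV
#' @param partition an [ExclusivityPartition-class]
#' @param labelPath path for the (gene, label) table
#' @param membershipPath optional path for the UpSet membership table
#' @export
writePartition <- function(partition, labelPath, membershipPath = NULL) {
  lab <- partitionLabels(partition)
  .write_tsv(data.frame(gene = names(lab), label = unname(lab),
                        stringsAsFactors = FALSE), labelPath)
  if (!is.null(membershipPath)) .write_tsv(partition@membership, membershipPath)
  invisible(labelPath)
}
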