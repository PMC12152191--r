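#' Median-ratio size factors for a guide count matrix
#'
#' For each sample, the factor is the median over eligible guides of
#' `count / geometric mean across samples`, where a guide is eligible when
#' its count is positive in every sample (the DESeq/MAGeCK-style
#' median-of-ratios estimator). Factors are rescaled to geometric mean 1.
#' When fewer than `minEligible` guides are eligible, the estimator falls
#' back to total-count scaling with a warning; `method = "total"` forces
#' total-count scaling.
#'
#' @param counts integer matrix (guides x samples) or a
#'   [ScreenExperiment-class]
#' @param method "median_ratio" (default) or "total"
#' @param minEligible minimum eligible guides before the total-count
#'   fallback kicks in (default 100)
#' @return named numeric vector of strictly positive per-sample factors
#' @export
screenSizeFactors <- function(counts, method = c("median_ratio", "total"),
                              minEligible = 100L) {
  method <- match.arg(method)
  if (is(counts, "ScreenExperiment")) counts <- BiocGenerics::counts(counts)
  counts <- as.matrix(counts)
  zero_samples <- colnames(counts)[colSums(counts) == 0]
  if (length(zero_samples))
    .input_error("sample(s) with all-zero counts: ",
                 paste(zero_samples, collapse = ", "))
  total_factors <- function() {
    tot <- colSums(counts)
    tot / exp(mean(log(tot)))
  }
  sf <- if (method == "total") {
    total_factors()
  } else {
    eligible <- rowSums(counts > 0) == ncol(counts)
    if (sum(eligible) < minEligible) {
      warning(sprintf(
        "only %d guides positive in all samples (< %d); falling back to total-count size factors",
        sum(eligible), minEligible), call. = FALSE)
      total_factors()
    } else {
      geomean <- exp(rowMeans(log(counts[eligible, , drop = FALSE])))
      f <- apply(counts[eligible, , drop = FALSE], 2, function(x)
        stats::median(x / geomean))
      f / exp(mean(log(f)))
    }
  }
  stats::setNames(as.numeric(sf), colnames(counts))
}

.l2fe_one_comparison <- function(normed, design, cond, day, pseudocount, pairing) {
  base <- design[design$condition == cond & design$day == 0L, , drop = FALSE]
  end <- design[design$condition == cond & design$day == day, , drop = FALSE]
  if (!nrow(base))
    .input_error("no day-0 baseline sample for condition ", cond)
  if (!nrow(end))
    .input_error("no day-", day, " sample for condition ", cond)
  base_mean <- rowMeans(normed[, base$sample_id, drop = FALSE])
  per_rep <- lapply(seq_len(nrow(end)), function(i) {
    r <- end$replicate[i]
    endpoint <- normed[, end$sample_id[i]]
    baseline <- if (pairing == "replicate" && r %in% base$replicate) {
      normed[, base$sample_id[base$replicate == r][1]]
    } else {
      base_mean
    }
    log2((endpoint + pseudocount) / (baseline + pseudocount))
  })
  mat <- do.call(cbind, per_rep)
  list(replicate = end$replicate, per_rep = mat, mean = rowMeans(mat))
}

#' Replicate-combined log2 fold enrichment per guide
#'
#' For each comparison (a condition's day 7 or day 14 against its day 0),
#' per-replicate enrichment is
#' `log2((count_end/sf_end + pc) / (count_base/sf_base + pc))` and the
#' reported `log2fe` is the arithmetic mean over replicates. With
#' `pairing = "replicate"` an endpoint replicate is compared against the
#' baseline sample of the same replicate number when one exists, otherwise
#' (or with `pairing = "baseline_mean"`) against the mean of the normalized
#' baseline counts.
#'
#' @param se a [ScreenExperiment-class]
#' @param comparisons data.frame from [screenComparisons()] (default: all
#'   computable comparisons of the design)
#' @param pseudocount positive pseudocount guarding zero counts (default 0.5)
#' @param pairing "replicate" (default) or "baseline_mean"
#' @param sizeFactors optional precomputed per-sample factors; default
#'   [screenSizeFactors()] over all samples
#' @param ... passed to [screenSizeFactors()]
#' @return an [EnrichmentTable-class]
#' @export
logFoldEnrichment <- function(se, comparisons = NULL, pseudocount = 0.5,
                              pairing = c("replicate", "baseline_mean"),
                              sizeFactors = NULL, ...) {
  pairing <- match.arg(pairing)
  if (pseudocount <= 0) .input_error("pseudocount must be > 0")
  if (is.null(comparisons)) comparisons <- screenComparisons(se)
  design <- screenDesign(se)
  cnt <- counts(se)
  if (is.null(sizeFactors)) sizeFactors <- screenSizeFactors(cnt, ...)
  normed <- sweep(cnt, 2, sizeFactors[colnames(cnt)], "/")
  summ <- list(); reps <- list()
  for (i in seq_len(nrow(comparisons))) {
    lab <- comparisons$label[i]
    res <- .l2fe_one_comparison(normed, design, comparisons$condition[i],
                                comparisons$day[i], pseudocount, pairing)
    summ[[lab]] <- data.frame(guide_id = rownames(cnt), comparison = lab,
                              log2fe = res$mean, stringsAsFactors = FALSE)
    reps[[lab]] <- do.call(rbind, lapply(seq_along(res$replicate), function(j)
      data.frame(guide_id = rownames(cnt), comparison = lab,
                 replicate = res$replicate[j], log2fe_rep = res$per_rep[, j],
                 stringsAsFactors = FALSE)))
  }
  new("EnrichmentTable",
      summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
      replicates = do.call(rbind, c(reps, list(make.row.names = FALSE))),
      sizeFactors = sizeFactors, pseudocount = pseudocount, pairing = pairing)
}

#' Replicate-mean enrichment table
#' @param et an [EnrichmentTable-class]
#' @return data.frame (guide_id, comparison, log2fe)
#' @export
enrichmentSummary <- function(et) et@summary

#' Per-replicate enrichment values
#' @param et an [EnrichmentTable-class]
#' @return data.frame (guide_id, comparison, replicate, log2fe_rep)
#' @export
enrichmentReplicates <- function(et) et@replicates

#' Size factors stored in an enrichment table
#' @param et an [EnrichmentTable-class]
#' @export
enrichmentSizeFactors <- function(et) et@sizeFactors

setMethod("show", "EnrichmentTable", function(object) {
  cat("EnrichmentTable:", length(unique(object@summary$guide_id)), "guides x",
      length(unique(object@summary$comparison)), "comparisons",
      "(pseudocount", object@pseudocount, ", pairing", object@pairing, ")\n")
})

#' Write an enrichment table as wide TSV
#'
#' One row per (guide, comparison): `guide_id`, `comparison`, `log2fe`,
#' then one `log2fe_rep<r>` column per replicate.
#'
#' @param et an [EnrichmentTable-class]
#' @param path output path
#' @export
writeEnrichment <- function(et, path) {
  wide <- et@summary
  reps <- et@replicates
  for (r in sort(unique(reps$replicate))) {
    sub <- reps[reps$replicate == r, c("guide_id", "comparison", "log2fe_rep")]
    names(sub)[3] <- paste0("log2fe_rep", r)
    wide <- merge(wide, sub, by = c("guide_id", "comparison"),
                  all.x = TRUE, sort = FALSE)
  }
  wide <- wide[order(wide$comparison, match(wide$guide_id, unique(et@summary$guide_id))), ]
  .write_tsv(wide, path)
}
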