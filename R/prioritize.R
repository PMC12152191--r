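# Downstream triage of a called gene set against user-supplied annotation:
# (1) membership in the top-ranked molecular pathways, (2) patient survival
# statistics, (3) correlation with a proliferation meta-gene signature.
# Pathway enrichment itself and survival-model fitting are consumed as
# inputs, not computed: their tools, backgrounds and cohorts live outside
# the screen.

#' Published proliferation signature gene set
#'
#' The 19-gene proliferation meta-signature (MCM/cyclin/E2F axis) used to
#' score samples by proliferative index.
#'
#' @export
proliferationSignature <- c(
  "MCM7", "PLK1", "MCM5", "BUB1", "MCM3", "MKI67", "MCM2", "CCND3",
  "MCM4", "MYBL2", "CCNB2", "E2F1", "MCM6", "CCNE2", "PCNA", "CCND2",
  "CCNB1", "CCNE1", "CCND1")

#' Read a gene x pathway binary membership table
#'
#' First column `gene`; remaining columns are pathways in significance rank
#' order (most significant first), entries 0/1.
#'
#' @param path TSV path
#' @return numeric matrix, genes in rows, ordered pathways in columns
#' @export
readPathwayMembership <- function(path) {
  df <- .read_tsv(path, colClasses = NA)
  if (names(df)[1] != "gene")
    .input_error("membership table must have 'gene' as its first column")
  mat <- as.matrix(df[-1])
  if (anyDuplicated(names(df)[-1]))
    .input_error("pathway ids must be unique")
  if (!all(mat %in% c(0, 1)))
    .input_error("membership entries must be 0 or 1")
  rownames(mat) <- df$gene
  mat
}

#' Read per-gene survival statistics (hazard ratio, p value)
#' @param path TSV path with columns gene, hr, p
#' @return data.frame
#' @export
readSurvivalStats <- function(path) {
  df <- .read_tsv(path, colClasses = NA)
  need <- c("gene", "hr", "p")
  if (!all(need %in% names(df)))
    .input_error("survival table needs columns: ", paste(need, collapse = ", "))
  if (any(df$hr <= 0)) .input_error("hazard ratios must be positive")
  if (any(df$p < 0 | df$p > 1)) .input_error("p values must lie in [0, 1]")
  df[need]
}

#' Filter candidates by membership count in the top-ranked pathways
#'
#' A gene is retained when it belongs to at least `minCount` of the first
#' `topN` pathways (column order of the membership matrix is the
#' significance ranking). Genes absent from the matrix count zero
#' memberships and are reported via a warning.
#'
#' @param candidates character vector of gene symbols
#' @param membership matrix from [readPathwayMembership()]
#' @param topN number of top pathways to consider (default 20)
#' @param minCount minimum memberships among those (default 9)
#' @return character vector of retained genes, with attribute `"detail"`
#'   (data.frame gene, n_pathways, pass)
#' @export
pathwayCountFilter <- function(candidates, membership, topN = 20L,
                               minCount = 9L) {
  if (topN > ncol(membership))
    .input_error("topN (", topN, ") exceeds the number of pathways (",
                 ncol(membership), ")")
  top <- membership[, seq_len(topN), drop = FALSE]
  counts <- rep(0L, length(candidates))
  covered <- candidates %in% rownames(top)
  counts[covered] <- as.integer(rowSums(top[candidates[covered], , drop = FALSE]))
  if (any(!covered))
    warning("genes absent from the membership table (counted 0): ",
            paste(candidates[!covered], collapse = ", "), call. = FALSE)
  detail <- data.frame(gene = candidates, n_pathways = counts,
                       pass = counts >= minCount, stringsAsFactors = FALSE)
  structure(candidates[detail$pass], detail = detail)
}

#' Filter candidates by survival statistics
#'
#' Retains genes with hazard ratio strictly above `hrMin` and p value
#' strictly below `pMax` (poor-prognosis genes). Candidates missing from
#' the table are excluded with a warning.
#'
#' @param candidates character vector of gene symbols
#' @param stats data.frame from [readSurvivalStats()]
#' @param hrMin hazard-ratio threshold (default 1)
#' @param pMax p-value threshold (default 0.05)
#' @return character vector of retained genes, with attribute `"detail"`
#' @export
survivalFilter <- function(candidates, stats, hrMin = 1, pMax = 0.05) {
  m <- match(candidates, stats$gene)
  if (anyNA(m))
    warning("genes absent from the survival table (excluded): ",
            paste(candidates[is.na(m)], collapse = ", "), call. = FALSE)
  hr <- stats$hr[m]; p <- stats$p[m]
  pass <- !is.na(m) & hr > hrMin & p < pMax
  detail <- data.frame(gene = candidates, hr = hr, p = p, pass = pass,
                       stringsAsFactors = FALSE)
  structure(candidates[pass], detail = detail)
}

#' Proliferation-signature score per sample
#'
#' Each signature gene present in the expression table is z-scored across
#' samples (mean 0, sd 1, divisor n-1); a sample's score is the mean (or
#' median) of its available z-scores. Signature genes with zero variance
#' across samples are excluded with a warning.
#'
#' @param expression numeric matrix or data.frame, samples in rows, genes
#'   in columns
#' @param signature character vector of signature genes (default the
#'   shipped [proliferationSignature])
#' @param method "mean" (default) or "median" of the per-gene z-scores
#' @return named numeric vector of per-sample scores with attributes
#'   `"coverage"` (fraction of signature genes used) and `"genes_used"`
#' @export
signatureScore <- function(expression, signature = proliferationSignature,
                           method = c("mean", "median")) {
  method <- match.arg(method)
  expression <- as.matrix(expression)
  if (nrow(expression) < 2) .input_error("need at least 2 samples")
  present <- intersect(signature, colnames(expression))
  if (!length(present))
    .input_error("no signature gene present in the expression table")
  sub <- expression[, present, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  flat <- present[sds == 0]
  if (length(flat)) {
    warning("zero-variance signature genes excluded: ",
            paste(flat, collapse = ", "), call. = FALSE)
    sub <- sub[, sds > 0, drop = FALSE]
    if (!ncol(sub)) .input_error("all signature genes have zero variance")
  }
  z <- scale(sub)  # centre + sd with divisor n-1
  scores <- if (method == "mean") rowMeans(z) else apply(z, 1, stats::median)
  structure(stats::setNames(as.numeric(scores), rownames(expression)),
            coverage = ncol(sub) / length(signature),
            genes_used = colnames(sub))
}

#' Correlate one gene's expression with the signature score
#'
#' @param geneExpr numeric per-sample expression values
#' @param scores per-sample signature scores (same sample order)
#' @return list with `correlation` (Pearson r), `slope` (least-squares
#'   slope of expression on score), `p` (two-sided test of zero
#'   correlation) and `n`
#' @export
correlateWithSignature <- function(geneExpr, scores) {
  if (length(geneExpr) != length(scores))
    .input_error("geneExpr and scores must have equal length")
  if (length(geneExpr) < 3) .input_error("need at least 3 samples")
  if (stats::sd(geneExpr) == 0 || stats::sd(scores) == 0)
    .input_error("zero variance in expression or scores")
  ct <- stats::cor.test(scores, geneExpr, method = "pearson")
  fit <- stats::lm(geneExpr ~ scores)
  list(correlation = unname(ct$estimate),
       slope = unname(stats::coef(fit)[2]),
       p = ct$p.value, n = length(geneExpr))
}

#' Staged prioritization cascade
#'
#' Applies, in order, the pathway-membership-count filter and the survival
#' filter to a candidate gene set, recording the surviving set after each
#' stage and per-gene elimination reasons. A stage whose annotation table
#' is `NULL` is skipped with an explicit notice, never silently passed.
#'
#' @param candidates character vector of candidate genes (e.g. the
#'   3D-exclusive set)
#' @param membership optional matrix from [readPathwayMembership()]
#' @param survival optional data.frame from [readSurvivalStats()]
#' @param topN,minCount parameters of [pathwayCountFilter()]
#' @param hrMin,pMax parameters of [survivalFilter()]
#' @return a `cascadeReport` list: `stages` (name, skipped, n_in, n_out,
#'   retained, eliminated with reasons) and `final` (the surviving set)
#' @export
prioritizeCascade <- function(candidates, membership = NULL, survival = NULL,
                              topN = 20L, minCount = 9L,
                              hrMin = 1, pMax = 0.05) {
  candidates <- unique(candidates)
  stages <- list()
  current <- candidates
  run_stage <- function(name, skipped, result = NULL, reason_fun = NULL) {
    if (skipped) {
      st <- list(name = name, skipped = TRUE, n_in = length(current),
                 n_out = length(current), retained = current,
                 eliminated = data.frame(gene = character(),
                                         reason = character()),
                 notice = paste0("stage '", name,
                                 "' skipped: annotation table not provided"))
    } else {
      detail <- attr(result, "detail")
      elim <- detail[!detail$pass, , drop = FALSE]
      st <- list(name = name, skipped = FALSE, n_in = length(current),
                 n_out = length(result), retained = as.character(result),
                 eliminated = data.frame(gene = elim$gene,
                                         reason = reason_fun(elim),
                                         stringsAsFactors = FALSE),
                 notice = NULL)
    }
    st
  }
  st1 <- if (is.null(membership)) {
    run_stage("pathway_count", skipped = TRUE)
  } else {
    res <- withCallingHandlers(
      pathwayCountFilter(current, membership, topN = topN, minCount = minCount),
      warning = function(w) invokeRestart("muffleWarning"))
    run_stage("pathway_count", FALSE, res, function(e)
      sprintf("in %d of top %d pathways (< %d)", e$n_pathways, topN, minCount))
  }
  stages[[1]] <- st1
  current <- st1$retained
  st2 <- if (is.null(survival)) {
    run_stage("survival", skipped = TRUE)
  } else {
    res <- withCallingHandlers(
      survivalFilter(current, survival, hrMin = hrMin, pMax = pMax),
      warning = function(w) invokeRestart("muffleWarning"))
    run_stage("survival", FALSE, res, function(e)
      ifelse(is.na(e$hr), "absent from survival table",
             sprintf("hr=%.3g, p=%.3g fails hr>%g & p<%g", e$hr, e$p, hrMin, pMax)))
  }
  stages[[2]] <- st2
  out <- list(candidates = candidates, stages = stages, final = st2$retained)
  class(out) <- "cascadeReport"
  out
}

#' @export
print.cascadeReport <- function(x, ...) {
  cat("Prioritization cascade:", length(x$candidates), "candidates\n")
  for (st in x$stages) {
    if (st$skipped) cat("  [skipped]", st$notice, "\n")
    else cat(sprintf("  %s: %d -> %d\n", st$name, st$n_in, st$n_out))
  }
  cat("final set (", length(x$final), "): ",
      paste(x$final, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a cascade report as TSV + JSON
#' @param report a `cascadeReport`
#' @param tsvPath per-gene staged outcome table
#' @param jsonPath structured report
#' @export
writeCascadeReport <- function(report, tsvPath, jsonPath = NULL) {
  rows <- do.call(rbind, lapply(report$stages, function(st) {
    if (st$skipped)
      return(data.frame(stage = st$name, gene = NA_character_,
                        outcome = "skipped", reason = st$notice,
                        stringsAsFactors = FALSE))
    rbind(
      if (length(st$retained))
        data.frame(stage = st$name, gene = st$retained, outcome = "retained",
                   reason = "", stringsAsFactors = FALSE),
      if (nrow(st$eliminated))
        data.frame(stage = st$name, gene = st$eliminated$gene,
                   outcome = "eliminated", reason = st$eliminated$reason,
                   stringsAsFactors = FALSE))
  }))
  .write_tsv(rows, tsvPath)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(
      n_candidates = length(report$candidates),
      stages = lapply(report$stages, function(st)
        list(name = st$name, skipped = st$skipped, n_in = st$n_in,
             n_out = st$n_out, retained = st$retained)),
      final = report$final), jsonPath, auto_unbox = TRUE, pretty = TRUE,
      null = "null")
  invisible(tsvPath)
}
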