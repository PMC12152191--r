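# Control-centred effect sizes and the pooled-variance phenotype score.
#
# pZ(guide)  = log2fe(guide) - median(log2fe over control guides)
# U_gene     = median(pZ over the gene's guides)
# S_var      = Var_gene * (N_exp - 1) + Var_ctrl * (N_ctrl - 1)
# T          = (U_gene - U_ctrl) / sqrt(S_var/N_exp + S_var/N_ctrl)
#
# The same pooled S_var feeds both denominator terms (this is the score as
# used in the field, not a textbook Welch t; `welch = TRUE` switches to
# Var_gene/N_exp + Var_ctrl/N_ctrl for sensitivity analysis). N_ctrl is the
# screen's average number of guides per targeted gene; controls, having no
# gene, are excluded from that average. Sample variances use divisor n - 1.

#' Per-guide control-centred effect sizes (pZ)
#'
#' Subtracts, per comparison, the median log2 fold enrichment of the control
#' set (safe plus non-targeting guides) from every guide's log2fe, so the
#' control median lands at exactly zero.
#'
#' @param et an [EnrichmentTable-class] or its summary data.frame
#' @param library a [GuideLibrary-class]
#' @return data.frame (guide_id, gene, category, comparison, pZ)
#' @export
guidePZ <- function(et, library) {
  df <- if (is(et, "EnrichmentTable")) enrichmentSummary(et) else et
  rec <- guideRecords(library)
  ctrl <- controlGuides(library)
  if (!length(ctrl)) .input_error("library has no control guides")
  out <- lapply(split(df, df$comparison), function(sub) {
    ctrl_fe <- sub$log2fe[sub$guide_id %in% ctrl & is.finite(sub$log2fe)]
    if (!length(ctrl_fe))
      .input_error("no finite control enrichment values for comparison ",
                   sub$comparison[1])
    m <- match(sub$guide_id, rec$guide_id)
    data.frame(guide_id = sub$guide_id, gene = rec$gene[m],
               category = rec$category[m], comparison = sub$comparison,
               pZ = sub$log2fe - stats::median(ctrl_fe),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Gene effect size: median of the gene's guide pZ values
#'
#' Even guide counts take the midpoint of the two central values (the
#' ordinary sample median). Guides with non-finite pZ are dropped; genes
#' left with none are excluded and reported via an attribute.
#'
#' @param effects data.frame from [guidePZ()] (one comparison)
#' @return named numeric vector of u_gene per gene, with attribute
#'   `"excluded"` listing genes that had no finite pZ
#' @export
geneU <- function(effects) {
  tg <- effects[effects$category == "targeting", , drop = FALSE]
  fin <- tg[is.finite(tg$pZ), , drop = FALSE]
  u <- vapply(split(fin$pZ, fin$gene), stats::median, numeric(1))
  excluded <- setdiff(unique(tg$gene), names(u))
  attr(u, "excluded") <- excluded
  u
}

#' Pooled-variance phenotype score for one gene
#'
#' @param uGene gene effect size (median guide pZ)
#' @param varGene sample variance of the gene's guide pZ (divisor n-1)
#' @param nExp number of guides for the gene
#' @param uCtrl median control pZ (0 by construction)
#' @param varCtrl sample variance of all control pZ values
#' @param nCtrl average number of guides per targeted gene in the screen
#' @param welch use the conventional Welch denominator
#'   `Var_gene/N_exp + Var_ctrl/N_ctrl` instead of the pooled `S_var` form
#' @return the T score; `NA` when `nExp < 2` or the pooled variance is
#'   non-positive (degenerate constant inputs)
#' @export
tScore <- function(uGene, varGene, nExp, uCtrl, varCtrl, nCtrl,
                   welch = FALSE) {
  if (is.na(nExp) || nExp < 2 || is.na(varGene)) return(NA_real_)
  denom2 <- if (welch) {
    varGene / nExp + varCtrl / nCtrl
  } else {
    s_var <- varGene * (nExp - 1) + varCtrl * (nCtrl - 1)
    s_var / nExp + s_var / nCtrl
  }
  if (!is.finite(denom2) || denom2 <= 0) return(NA_real_)
  (uGene - uCtrl) / sqrt(denom2)
}

.phenotype_one_comparison <- function(effects, nCtrl, guideDropMax, welch) {
  ctrl <- effects[effects$category != "targeting" & is.finite(effects$pZ), ]
  u_ctrl <- stats::median(ctrl$pZ)
  var_ctrl <- stats::var(ctrl$pZ)
  tg <- effects[effects$category == "targeting" & is.finite(effects$pZ), ]
  by_gene <- split(tg$pZ, tg$gene)
  genes <- names(by_gene)
  n_exp <- lengths(by_gene)
  u_gene <- vapply(by_gene, stats::median, numeric(1))
  var_gene <- vapply(by_gene, function(x)
    if (length(x) >= 2) stats::var(x) else NA_real_, numeric(1))
  n_dropped <- vapply(by_gene, function(x) sum(x <= guideDropMax), integer(1))
  t_score <- mapply(tScore, u_gene, var_gene, n_exp,
                    MoreArgs = list(uCtrl = u_ctrl, varCtrl = var_ctrl,
                                    nCtrl = nCtrl, welch = welch))
  list(genes = data.frame(gene = genes, comparison = effects$comparison[1],
                          n_exp = as.integer(n_exp), u_gene = u_gene,
                          var_gene = var_gene, t_score = t_score,
                          n_dropped = n_dropped, stringsAsFactors = FALSE,
                          row.names = NULL),
       controls = data.frame(comparison = effects$comparison[1],
                             u_ctrl = u_ctrl, var_ctrl = var_ctrl,
                             n_ctrl = nCtrl, n_control_guides = nrow(ctrl),
                             stringsAsFactors = FALSE))
}

#' Gene-level phenotype scores for every comparison of a screen
#'
#' Runs the full cascade: log2 fold enrichment (unless a precomputed
#' [EnrichmentTable-class] is supplied), control-centred pZ, gene medians
#' `u_gene`, and pooled-variance `t_score`, per comparison. `n_ctrl` is the
#' number of targeting guides divided by the number of targeted genes.
#'
#' @param se a [ScreenExperiment-class], or an [EnrichmentTable-class]
#'   when `library` is given
#' @param library a [GuideLibrary-class]; defaults to the library embedded
#'   in `se`
#' @param guideDropMax per-guide drop criterion: a guide counts as dropped
#'   when `pZ <= guideDropMax` (default -0.1)
#' @param welch use the Welch denominator in [tScore()]
#' @param ... passed to [logFoldEnrichment()]
#' @return a [ScreenPhenotypes-class]
#' @export
screenPhenotypes <- function(se, library = NULL, guideDropMax = -0.1,
                             welch = FALSE, ...) {
  if (is(se, "ScreenExperiment")) {
    if (is.null(library)) library <- guideLibrary(se)
    et <- logFoldEnrichment(se, ...)
  } else if (is(se, "EnrichmentTable")) {
    if (is.null(library))
      .input_error("library is required when passing an EnrichmentTable")
    et <- se
  } else .input_error("se must be a ScreenExperiment or EnrichmentTable")
  effects <- guidePZ(et, library)
  rec <- guideRecords(library)
  n_targeting <- sum(rec$category == "targeting")
  n_genes <- length(targetedGenes(library))
  n_ctrl <- n_targeting / n_genes
  parts <- lapply(split(effects, effects$comparison),
                  .phenotype_one_comparison, nCtrl = n_ctrl,
                  guideDropMax = guideDropMax, welch = welch)
  new("ScreenPhenotypes",
      genes = do.call(rbind, c(lapply(parts, `[[`, "genes"),
                               list(make.row.names = FALSE))),
      controls = do.call(rbind, c(lapply(parts, `[[`, "controls"),
                                  list(make.row.names = FALSE))),
      guideEffects = effects,
      params = list(guideDropMax = guideDropMax, welch = welch,
                    n_ctrl = n_ctrl))
}

#' Write phenotype tables as TSV
#'
#' Emits one gene-level file (gene, comparison, n_exp, u_gene, var_gene,
#' t_score, n_dropped) and one control-summary file.
#'
#' @param pheno a [ScreenPhenotypes-class]
#' @param genePath path for the gene table
#' @param controlPath optional path for the control summary
#' @export
writePhenotypes <- function(pheno, genePath, controlPath = NULL) {
  .write_tsv(genePhenotypes(pheno), genePath)
  if (!is.null(controlPath)) .write_tsv(controlSummary(pheno), controlPath)
  invisible(genePath)
}
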