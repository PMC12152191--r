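# Programmatic fixtures and independent brute-force oracles. The oracles
# deliberately avoid the package's code paths (and stats::median/var) so
# equivalence tests compare two independent routes to the same quantity.

# deterministic unique spacers: integer -> base-4 ACGT word
fixed_spacers <- function(n, width = 18L) {
  alpha <- c("A", "C", "G", "T")
  vapply(seq_len(n) + 1000L, function(i) {
    digits <- integer(width)
    for (j in seq_len(width)) { digits[j] <- i %% 4L; i <- i %/% 4L }
    paste(alpha[digits + 1L], collapse = "")
  }, character(1))
}

toy_library <- function(nGenes = 2L, guidesPerGene = 2L, nSafe = 1L,
                        nNonTargeting = 1L, spacerWidth = 18L) {
  genes <- sprintf("GENE%02d", seq_len(nGenes))
  gid <- sprintf("%s_g%d", rep(genes, each = guidesPerGene),
                 rep(seq_len(guidesPerGene), nGenes))
  sid <- if (nSafe) sprintf("safe_%02d", seq_len(nSafe)) else character()
  nid <- if (nNonTargeting) sprintf("nt_%02d", seq_len(nNonTargeting)) else character()
  n <- length(gid) + length(sid) + length(nid)
  GuideLibrary(data.frame(
    guide_id = c(gid, sid, nid),
    gene = c(rep(genes, each = guidesPerGene),
             rep(CONTROL_SENTINEL, length(sid) + length(nid))),
    spacer = fixed_spacers(n, spacerWidth),
    category = c(rep("targeting", length(gid)), rep("safe", length(sid)),
                 rep("non_targeting", length(nid))),
    stringsAsFactors = FALSE))
}

full_design <- function(replicates = 2L) {
  d <- expand.grid(replicate = seq_len(replicates), day = c(0L, 7L, 14L),
                   condition = c("2D", "3D"), stringsAsFactors = FALSE)
  d$sample_id <- sprintf("S_%s_D%d_R%d", d$condition, d$day, d$replicate)
  d[c("sample_id", "condition", "day", "replicate")]
}

toy_screen <- function(library = toy_library(), design = full_design(),
                       seed = 11L, lambda = 200) {
  set.seed(seed)
  counts <- matrix(rpois(length(library) * nrow(design), lambda),
                   nrow = length(library),
                   dimnames = list(guideIds(library), design$sample_id))
  ScreenExperiment(counts, library, design)
}

write_tmp_tsv <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  con <- file(path, "wb")
  writeLines(c(paste(names(df), collapse = "\t"),
               if (nrow(df)) do.call(paste, c(lapply(df, as.character), sep = "\t"))),
             con, sep = "\n")
  close(con)
  path
}

# ---- brute-force oracles ----------------------------------------------

bf_median <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

bf_var <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- sum(x) / n
  acc <- 0
  for (v in x) acc <- acc + (v - m)^2
  acc / (n - 1)
}

# Independent implementation of the phenotype score cascade on a plain
# table of (guide, gene-or-NA, log2fe): returns per-gene u and T.
bf_phenotypes <- function(guide_gene, log2fe, is_control, n_ctrl) {
  pz <- log2fe - bf_median(log2fe[is_control])
  u_ctrl <- bf_median(pz[is_control])
  var_ctrl <- bf_var(pz[is_control])
  genes <- unique(guide_gene[!is_control])
  res <- data.frame(gene = genes, u_gene = NA_real_, t_score = NA_real_)
  for (i in seq_along(genes)) {
    v <- pz[!is_control & guide_gene == genes[i]]
    res$u_gene[i] <- bf_median(v)
    if (length(v) >= 2) {
      s_var <- bf_var(v) * (length(v) - 1) + var_ctrl * (n_ctrl - 1)
      denom <- sqrt(s_var / length(v) + s_var / n_ctrl)
      if (is.finite(denom) && denom > 0)
        res$t_score[i] <- (res$u_gene[i] - u_ctrl) / denom
    }
  }
  res
}

# Brute-force exclusivity labelling by direct set algebra
bf_partition_label <- function(gene, s2d7, s2d14, s3d7, s3d14) {
  a <- gene %in% s2d7; b <- gene %in% s2d14
  c_ <- gene %in% s3d7; d <- gene %in% s3d14
  if (a && b && c_ && d) return("SHARED")
  if (c_ && d && !a && !b) return("THREE_D_EXCLUSIVE")
  if (a && b && !c_ && !d) return("TWO_D_EXCLUSIVE")
  if (a || b || c_ || d) return("OTHER")
  "NONE"
}
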