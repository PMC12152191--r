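# Synthetic pooled dropout screen with known ground truth. The generator
# emulates the screen design it is meant to stand in for: a drug-target /
# kinase / phosphatase-style knockout library with ~10 guides per gene plus
# safe and non-targeting controls, duplicate samples at days 0/7/14 in two
# growth conditions, and ~1000x cells-per-guide coverage -- at configurable
# reduced scale.
#
# Noise model, per sample: guide abundances start log-normal, decay as
# 2^(f * day) for realized per-guide fitness f, are renormalized to sum to 1
# (competitive pooled growth: depleted guides free share for the rest), pass
# through a multinomial cell bottleneck at the configured coverage, and are
# read out as NB1 negative-binomial counts with variance (1 + dispersion) *
# mean -- modest extra-Poisson sequencing noise on top of the bottleneck.

#' Simulation configuration
#'
#' Defaults mirror the emulated screen design where it states them (10
#' guides per gene, 750 safe + 750 non-targeting controls, duplicate
#' replicates at days 0/7/14, 1000 cells per guide) and a reduced-scale
#' gene panel elsewhere.
#'
#' @param nNeutral,nCommonEssential,n2dEssential,n3dEssential gene counts
#'   per fitness class
#' @param guidesPerGene guides per targeted gene (default 10)
#' @param nSafe,nNonTargeting control guide counts (defaults 750 each,
#'   scalable down)
#' @param effect mean log2 depletion per day for essential classes
#'   (default -0.4; must be <= 0)
#' @param effectSd between-guide potency spread (sd of the per-guide
#'   effect, truncated at 0; default 0.1)
#' @param coverage cells per guide at each plating bottleneck (default 1000)
#' @param depth mean reads per guide per sample (default 500)
#' @param dispersion NB1 extra-Poisson dispersion: count variance is
#'   `(1 + dispersion) * mean`; 0 gives Poisson counts (default 0.1)
#' @param days sampling days (default 0, 7, 14)
#' @param replicates replicates per (condition, day) (default 2)
#' @param seed integer seed; every draw of the simulator flows from it
#' @return a `simConfig` list
#' @export
simConfig <- function(nNeutral = 100L, nCommonEssential = 20L,
                      n2dEssential = 20L, n3dEssential = 20L,
                      guidesPerGene = 10L, nSafe = 750L,
                      nNonTargeting = 750L, effect = -0.4, effectSd = 0.1,
                      coverage = 1000L, depth = 500, dispersion = 0.1,
                      days = c(0L, 7L, 14L), replicates = 2L, seed = 1L) {
  cfg <- list(nNeutral = as.integer(nNeutral),
              nCommonEssential = as.integer(nCommonEssential),
              n2dEssential = as.integer(n2dEssential),
              n3dEssential = as.integer(n3dEssential),
              guidesPerGene = as.integer(guidesPerGene),
              nSafe = as.integer(nSafe),
              nNonTargeting = as.integer(nNonTargeting),
              effect = effect, effectSd = effectSd,
              coverage = as.integer(coverage), depth = depth,
              dispersion = dispersion, days = as.integer(days),
              replicates = as.integer(replicates), seed = as.integer(seed))
  counts <- unlist(cfg[c("nNeutral", "nCommonEssential", "n2dEssential",
                         "n3dEssential", "guidesPerGene", "nSafe",
                         "nNonTargeting", "coverage", "replicates")])
  if (any(counts < 0)) .input_error("simulation counts must be >= 0")
  if (cfg$effect > 0) .input_error("effect must be <= 0 (log2 depletion per day)")
  if (cfg$dispersion < 0) .input_error("dispersion must be >= 0")
  if (cfg$depth <= 0) .input_error("depth must be > 0")
  ngene <- cfg$nNeutral + cfg$nCommonEssential + cfg$n2dEssential + cfg$n3dEssential
  if (ngene * cfg$guidesPerGene + cfg$nSafe + cfg$nNonTargeting < 1)
    .input_error("simulation must contain at least one guide")
  structure(cfg, class = "simConfig")
}

.random_spacers <- function(n, width = 18L) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    fresh <- vapply(seq_len(need + 16L), function(i)
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = ""), character(1))
    out <- unique(c(out, fresh))
  }
  out[seq_len(n)]
}

#' Simulate a guide library with a ground-truth ledger
#'
#' Deterministic given `config$seed`. Gene names encode nothing the
#' pipeline can see; fitness classes live only in the [SimTruth-class]
#' ledger. Per-guide realized effects are drawn once per guide
#' (`Normal(effect, effectSd)` truncated at 0, guide potency being
#' guide-intrinsic) and applied to the conditions the gene's class affects.
#'
#' @param config a [simConfig()]
#' @return list with `library` (a [GuideLibrary-class]) and `truth`
#'   (a [SimTruth-class])
#' @export
simulateLibrary <- function(config = simConfig()) {
  set.seed(config$seed)
  classes <- rep(c("neutral", "common_essential", "essential_2D", "essential_3D"),
                 c(config$nNeutral, config$nCommonEssential,
                   config$n2dEssential, config$n3dEssential))
  ngene <- length(classes)
  genes <- sprintf("GENE%04d", seq_len(ngene))
  gpg <- config$guidesPerGene
  guide_gene <- rep(genes, each = gpg)
  guide_class <- rep(classes, each = gpg)
  guide_id <- sprintf("%s_g%02d", guide_gene, rep(seq_len(gpg), times = ngene))
  n_t <- length(guide_id)
  safe_id <- if (config$nSafe) sprintf("safe_%04d", seq_len(config$nSafe)) else character()
  nt_id <- if (config$nNonTargeting) sprintf("nt_%04d", seq_len(config$nNonTargeting)) else character()
  rec <- data.frame(
    guide_id = c(guide_id, safe_id, nt_id),
    gene = c(guide_gene, rep(CONTROL_SENTINEL, length(safe_id) + length(nt_id))),
    spacer = .random_spacers(n_t + length(safe_id) + length(nt_id)),
    category = c(rep("targeting", n_t), rep("safe", length(safe_id)),
                 rep("non_targeting", length(nt_id))),
    stringsAsFactors = FALSE)
  potency <- pmin(stats::rnorm(n_t, config$effect, config$effectSd), 0)
  effect_2D <- ifelse(guide_class %in% c("common_essential", "essential_2D"),
                      potency, 0)
  effect_3D <- ifelse(guide_class %in% c("common_essential", "essential_3D"),
                      potency, 0)
  truth <- new("SimTruth",
               genes = data.frame(gene = genes, class = classes,
                                  stringsAsFactors = FALSE),
               guides = data.frame(
                 guide_id = rec$guide_id, gene = rec$gene,
                 effect_2D = c(effect_2D, rep(0, length(safe_id) + length(nt_id))),
                 effect_3D = c(effect_3D, rep(0, length(safe_id) + length(nt_id))),
                 stringsAsFactors = FALSE))
  list(library = GuideLibrary(rec), truth = truth)
}

.nb1_counts <- function(mu, dispersion) {
  out <- integer(length(mu))
  pos <- mu > 0
  if (any(pos)) {
    out[pos] <- if (dispersion == 0) {
      stats::rpois(sum(pos), mu[pos])
    } else {
      stats::rnbinom(sum(pos), mu = mu[pos], size = mu[pos] / dispersion)
    }
  }
  out
}

#' Simulate screen counts for every sample of the design
#'
#' Baseline guide abundances are log-normal(0, 0.25); in condition `c` at
#' day `t` the expected relative abundance of guide `i` is proportional to
#' `a_i * 2^(f_ic * t)`, renormalized across the library (competitive
#' growth). Each replicate draws a multinomial cell bottleneck of
#' `coverage * n_guides` cells, then NB1 read counts with mean
#' `depth * relative_abundance * n_guides`. Deterministic given the seed
#' (`config$seed + 1`, so library and screen draws never reuse a stream).
#'
#' @param library a [GuideLibrary-class] from [simulateLibrary()]
#' @param truth the matching [SimTruth-class]
#' @param config the same [simConfig()]
#' @return a [ScreenExperiment-class] covering conditions x days x replicates
#' @export
simulateScreen <- function(library, truth, config = simConfig()) {
  set.seed(config$seed + 1L)
  rec <- guideRecords(library)
  eff <- truthEffects(truth)
  m <- match(rec$guide_id, eff$guide_id)
  if (anyNA(m)) .input_error("truth ledger does not cover the library")
  f <- cbind(`2D` = eff$effect_2D[m], `3D` = eff$effect_3D[m])
  n_guides <- nrow(rec)
  a <- stats::rlnorm(n_guides, meanlog = 0, sdlog = 0.25)
  design <- expand.grid(replicate = seq_len(config$replicates),
                        day = config$days, condition = .CONDITIONS,
                        stringsAsFactors = FALSE)
  design <- design[, c("condition", "day", "replicate")]
  design$sample_id <- sprintf("S_%s_D%d_R%d", design$condition, design$day,
                              design$replicate)
  counts <- matrix(0L, nrow = n_guides, ncol = nrow(design),
                   dimnames = list(rec$guide_id, design$sample_id))
  n_cells <- config$coverage * n_guides
  for (i in seq_len(nrow(design))) {
    w <- a * 2^(f[, design$condition[i]] * design$day[i])
    p <- w / sum(w)                      # relative abundances sum to 1
    cells <- stats::rmultinom(1, n_cells, p)[, 1]
    mu <- config$depth * (cells / n_cells) * n_guides
    counts[, i] <- .nb1_counts(mu, config$dispersion)
  }
  ScreenExperiment(counts, library, design)
}

#' Simulate a complete screen in one call
#' @param config a [simConfig()]
#' @return list with `se`, `library`, `truth`
#' @export
simulateScreenExperiment <- function(config = simConfig()) {
  lib <- simulateLibrary(config)
  se <- simulateScreen(lib$library, lib$truth, config)
  list(se = se, library = lib$library, truth = lib$truth)
}

#' Write a FASTQ file realizing a guide count vector
#'
#' Emits exactly `counts[g]` reads per guide, each carrying the guide's
#' spacer at the configured 0-based offset inside random flanking sequence,
#' so re-counting the file with [countGuides()] at that offset reproduces
#' the counts exactly (the quantifier's inverse test).
#'
#' @param counts named integer vector (guide_id -> reads)
#' @param library a [GuideLibrary-class]
#' @param path output path; written gzipped when it ends in `.gz`
#' @param offset 0-based spacer start within each read (default 10)
#' @param readLength total read length (default offset + 18 + 5)
#' @param shift optional integer vector recycled over reads, displacing
#'   each read's spacer by that many bases (for window tests)
#' @param seed seed for the random flanks
#' @return `path`, invisibly
#' @export
writeFastq <- function(counts, library, path, offset = 10L,
                       readLength = offset + 23L, shift = 0L, seed = 1L) {
  set.seed(seed)
  rec <- guideRecords(library)
  counts <- counts[counts > 0]
  if (anyNA(match(names(counts), rec$guide_id)))
    .input_error("counts name guides absent from the library")
  con <- if (grepl("\\.gz$", path)) gzfile(path, open = "wb") else file(path, open = "wb")
  on.exit(close(con))
  total <- sum(counts)
  if (total > 0) {
    guide_of <- rep(names(counts), counts)
    spacer_of <- rec$spacer[match(guide_of, rec$guide_id)]
    shifts <- rep_len(shift, total)
    starts <- offset + shifts          # 0-based spacer start per read
    if (any(starts < 0)) .input_error("shift would place a spacer before the read start")
    reads <- vapply(seq_len(total), function(i) {
      sp <- spacer_of[i]
      left <- paste(sample(c("A", "C", "G", "T"), starts[i], replace = TRUE),
                    collapse = "")
      right_n <- max(0L, readLength - starts[i] - nchar(sp))
      right <- paste(sample(c("A", "C", "G", "T"), right_n, replace = TRUE),
                     collapse = "")
      paste0(left, sp, right)
    }, character(1))
    quartets <- as.vector(rbind(
      sprintf("@read%06d %s", seq_len(total), guide_of),
      reads, rep("+", total),
      vapply(nchar(reads), function(n) strrep("I", n), character(1))))
    writeLines(quartets, con, sep = "\n")
  }
  invisible(path)
}

#' Score truth recovery of an exclusivity partition
#'
#' Maps each ground-truth class to its expected label (common_essential ->
#' SHARED, essential_2D -> TWO_D_EXCLUSIVE, essential_3D ->
#' THREE_D_EXCLUSIVE, neutral -> NONE) and tabulates a confusion matrix
#' plus per-class sensitivity, specificity and precision.
#'
#' @param partition an [ExclusivityPartition-class]
#' @param truth a [SimTruth-class]
#' @return a `recoveryReport` list with `confusion` (truth class x label
#'   table) and `metrics` (per-class data.frame)
#' @export
evaluateRecovery <- function(partition, truth) {
  expected_of <- c(neutral = "NONE", common_essential = "SHARED",
                   essential_2D = "TWO_D_EXCLUSIVE",
                   essential_3D = "THREE_D_EXCLUSIVE")
  cls <- truthClasses(truth)
  labels <- partitionLabels(partition)
  common <- intersect(names(cls), names(labels))
  if (!length(common)) .input_error("partition and truth share no genes")
  cls <- cls[common]; labels <- labels[common]
  confusion <- table(truth = factor(cls, levels = names(expected_of)),
                     called = factor(labels, levels = .PARTITION_LABELS))
  metrics <- do.call(rbind, lapply(names(expected_of), function(k) {
    lab <- expected_of[[k]]
    in_class <- cls == k
    called_lab <- labels == lab
    tp <- sum(in_class & called_lab)
    data.frame(class = k, expected_label = lab,
               n = sum(in_class),
               sensitivity = if (sum(in_class)) tp / sum(in_class) else NA_real_,
               specificity = if (sum(!in_class))
                 sum(!in_class & !called_lab) / sum(!in_class) else NA_real_,
               precision = if (sum(called_lab)) tp / sum(called_lab) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- list(confusion = confusion, metrics = metrics)
  class(out) <- "recoveryReport"
  out
}

#' @export
print.recoveryReport <- function(x, ...) {
  cat("Recovery metrics:\n")
  print(x$metrics, row.names = FALSE, digits = 3)
  cat("\nConfusion (truth x called):\n")
  print(x$confusion)
  invisible(x)
}
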