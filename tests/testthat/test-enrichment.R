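test_that("median-ratio size factors satisfy their defining identities", {
  m <- cbind(s1 = c(10, 20, 30, 40), s2 = c(10, 20, 30, 40))
  sf <- screenSizeFactors(m, minEligible = 1)
  expect_equal(unname(sf), c(1, 1))

  m2 <- cbind(s1 = c(10, 20, 30, 40), s2 = 2 * c(10, 20, 30, 40))
  sf2 <- screenSizeFactors(m2, minEligible = 1)
  expect_equal(unname(sf2[2] / sf2[1]), 2)
  expect_equal(exp(mean(log(sf2))), 1)
})

test_that("guides with a zero count are excluded from the ratio median", {
  # guide 3 has a zero in s2: the s1 factor must come from guides 1-2 only
  m <- cbind(s1 = c(10, 40, 1000), s2 = c(10, 40, 0))
  sf <- screenSizeFactors(m, minEligible = 1)
  geo <- exp(rowMeans(log(m[1:2, ])))
  expect_equal(unname(sf), unname(apply(m[1:2, ], 2, function(x)
    median(x / geo)) / exp(mean(log(apply(m[1:2, ], 2, function(x)
      median(x / geo)))))))
})

test_that("sparse matrices fall back to total-count factors with a warning", {
  m <- cbind(s1 = c(10, 0), s2 = c(0, 30))
  expect_warning(sf <- screenSizeFactors(m, minEligible = 100), "total-count")
  expect_equal(unname(sf), unname(colSums(m) / exp(mean(log(colSums(m))))))
  expect_error(screenSizeFactors(cbind(s1 = c(1, 1), s2 = c(0, 0))),
               "all-zero")
})

test_that("median-ratio factors agree with the DESeq estimator", {
  set.seed(21)
  m <- matrix(rpois(600 * 4, lambda = rep(c(50, 200, 800), each = 4)),
              ncol = 4, byrow = TRUE,
              dimnames = list(NULL, paste0("s", 1:4)))
  m[, 3] <- m[, 3] * 2L
  ours <- screenSizeFactors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours / ours[1]), unname(ref / ref[1]), tolerance = 1e-6)
})

test_that("log2 fold enrichment reproduces closed-form values", {
  lib <- toy_library(nGenes = 1, guidesPerGene = 2, nSafe = 1, nNonTargeting = 1)
  design <- full_design(replicates = 1L)
  base <- c(100, 100, 50, 100)
  d7 <- c(25, 100, 100, 100)
  cnt <- matrix(rep(base, 6), ncol = 6,
                dimnames = list(guideIds(lib), design$sample_id))
  cnt[, "S_2D_D7_R1"] <- d7
  se <- ScreenExperiment(cnt, lib, design)
  et <- logFoldEnrichment(se, pseudocount = 1e-9,
                          sizeFactors = setNames(rep(1, 6), design$sample_id))
  s <- enrichmentSummary(et)
  g1 <- s[s$guide_id == "GENE01_g1" & s$comparison == "2D_D7_vs_D0", "log2fe"]
  expect_equal(g1, -2, tolerance = 1e-6)     # 100 -> 25 in the pseudocount->0 limit
  g2 <- s[s$guide_id == "GENE01_g2" & s$comparison == "2D_D7_vs_D0", "log2fe"]
  expect_equal(g2, 0, tolerance = 1e-6)      # identical counts
})

test_that("replicates average per-replicate enrichment (hand-checked)", {
  # D0 = 50 in both baselines, D7 rep1 = 40, rep2 = 10, factors 1, pc 0.5:
  # mean(log2(40.5/50.5), log2(10.5/50.5)) = -1.29215 (hand arithmetic)
  lib <- toy_library(nGenes = 1, guidesPerGene = 1, nSafe = 1, nNonTargeting = 1)
  design <- full_design()[full_design()$condition == "2D" &
                            full_design()$day %in% c(0L, 7L), ]
  cnt <- matrix(50, nrow = 3, ncol = 4,
                dimnames = list(guideIds(lib), design$sample_id))
  cnt["GENE01_g1", "S_2D_D7_R1"] <- 40
  cnt["GENE01_g1", "S_2D_D7_R2"] <- 10
  se <- ScreenExperiment(cnt, lib, design)
  sf <- setNames(rep(1, 4), design$sample_id)
  et <- logFoldEnrichment(se, pseudocount = 0.5, sizeFactors = sf)
  got <- enrichmentSummary(et)
  expect_equal(got$log2fe[got$guide_id == "GENE01_g1"],
               (log2(40.5 / 50.5) + log2(10.5 / 50.5)) / 2)
  expect_equal(got$log2fe[got$guide_id == "GENE01_g1"], -1.29215,
               tolerance = 1e-4)
  reps <- enrichmentReplicates(et)
  expect_equal(sort(reps$log2fe_rep[reps$guide_id == "GENE01_g1"]),
               sort(c(log2(40.5 / 50.5), log2(10.5 / 50.5))))
})

test_that("pairing modes differ only when baselines differ by replicate", {
  lib <- toy_library()
  design <- full_design()
  set.seed(31)
  cnt <- matrix(rpois(length(lib) * nrow(design), 300),
                nrow = length(lib),
                dimnames = list(guideIds(lib), design$sample_id))
  se <- ScreenExperiment(cnt, lib, design)
  paired <- enrichmentSummary(logFoldEnrichment(se, pairing = "replicate",
                                                minEligible = 1))
  pooled <- enrichmentSummary(logFoldEnrichment(se, pairing = "baseline_mean",
                                                minEligible = 1))
  expect_false(isTRUE(all.equal(paired$log2fe, pooled$log2fe)))
  # single baseline replicate: an unmatched endpoint replicate falls back
  # to the baseline mean, so both modes coincide
  one_base <- design[!(design$day == 0L & design$replicate == 2L), ]
  se1 <- ScreenExperiment(cnt[, one_base$sample_id], lib, one_base)
  sf <- setNames(rep(1, nrow(one_base)), one_base$sample_id)
  rep_paired <- enrichmentReplicates(logFoldEnrichment(
    se1, pairing = "replicate", sizeFactors = sf))
  rep_pooled <- enrichmentReplicates(logFoldEnrichment(
    se1, pairing = "baseline_mean", sizeFactors = sf))
  sel <- rep_paired$replicate == 2L
  expect_equal(rep_paired$log2fe_rep[sel], rep_pooled$log2fe_rep[sel])
})

test_that("scaling one sample leaves enrichment invariant (factors absorb it)", {
  # exact in the pseudocount -> 0 limit; the pseudocount deliberately
  # trades a little scale invariance for zero-count protection
  se <- toy_screen(seed = 41)
  base <- enrichmentSummary(logFoldEnrichment(se, pseudocount = 1e-9,
                                              minEligible = 1))
  cnt <- counts(se)
  cnt[, "S_3D_D7_R1"] <- cnt[, "S_3D_D7_R1"] * 7L
  se2 <- ScreenExperiment(cnt, guideLibrary(se), screenDesign(se))
  scaled <- enrichmentSummary(logFoldEnrichment(se2, pseudocount = 1e-9,
                                                minEligible = 1))
  expect_equal(base$log2fe, scaled$log2fe, tolerance = 1e-9)
  # at the default pseudocount the perturbation stays far below any
  # calling threshold
  b2 <- enrichmentSummary(logFoldEnrichment(se, minEligible = 1))
  s2 <- enrichmentSummary(logFoldEnrichment(se2, minEligible = 1))
  expect_lt(max(abs(b2$log2fe - s2$log2fe)), 1e-3)
})

test_that("swapping baseline and endpoint negates enrichment as pc -> 0", {
  lib <- toy_library()
  design <- full_design(replicates = 1L)
  set.seed(17)
  cnt <- matrix(rpois(length(lib) * nrow(design), 400) + 1L,
                nrow = length(lib),
                dimnames = list(guideIds(lib), design$sample_id))
  se <- ScreenExperiment(cnt, lib, design)
  sf <- setNames(rep(1, nrow(design)), design$sample_id)
  fwd <- enrichmentSummary(logFoldEnrichment(se, pseudocount = 1e-12,
                                             sizeFactors = sf))
  swapped <- design
  swapped$day[swapped$sample_id == "S_2D_D0_R1"] <- 7L
  swapped$day[swapped$sample_id == "S_2D_D7_R1"] <- 0L
  se_sw <- ScreenExperiment(cnt, lib, swapped)
  rev <- enrichmentSummary(logFoldEnrichment(
    se_sw, comparisons = data.frame(condition = "2D", day = 7L,
                                    label = "2D_D7_vs_D0"),
    pseudocount = 1e-12, sizeFactors = sf))
  f <- fwd[fwd$comparison == "2D_D7_vs_D0", ]
  expect_equal(f$log2fe, -rev$log2fe, tolerance = 1e-6)
})
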