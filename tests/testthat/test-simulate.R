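small_cfg <- function(seed = 7L, ...) {
  simConfig(nNeutral = 10L, nCommonEssential = 2L, n2dEssential = 2L,
            n3dEssential = 2L, guidesPerGene = 5L, nSafe = 5L,
            nNonTargeting = 5L, coverage = 100L, depth = 100, seed = seed, ...)
}

test_that("simulated libraries have the configured composition", {
  cfg <- simConfig(nNeutral = 10L, nCommonEssential = 0L, n2dEssential = 0L,
                   n3dEssential = 0L, guidesPerGene = 10L, nSafe = 5L,
                   nNonTargeting = 5L, seed = 2L)
  sim <- simulateLibrary(cfg)
  expect_equal(length(sim$library), 10L * 10L + 5L + 5L)
  cc <- categoryCounts(sim$library)
  expect_equal(unname(cc), c(100L, 5L, 5L))
  expect_equal(sum(truthClasses(sim$truth) == "neutral"), 10L)
  expect_false(any(truthClasses(sim$truth) == "essential_3D"))
  expect_false(anyDuplicated(guideRecords(sim$library)$spacer) > 0)
})

test_that("the same seed reproduces library and counts exactly", {
  cfg <- small_cfg()
  a <- simulateScreenExperiment(cfg)
  b <- simulateScreenExperiment(cfg)
  expect_identical(guideRecords(a$library), guideRecords(b$library))
  expect_identical(counts(a$se), counts(b$se))
  expect_identical(truthEffects(a$truth), truthEffects(b$truth))
  c2 <- simulateScreenExperiment(small_cfg(seed = 8L))
  expect_false(identical(counts(a$se), counts(c2$se)))
})

test_that("truth ledger obeys the class-condition contract", {
  sim <- simulateLibrary(small_cfg())
  eff <- truthEffects(sim$truth)
  cls <- truthClasses(sim$truth)[eff$gene]
  expect_true(all(eff$effect_2D <= 0 & eff$effect_3D <= 0))
  expect_true(all(eff$effect_3D[cls %in% "essential_2D"] == 0))
  expect_true(all(eff$effect_2D[cls %in% "essential_3D"] == 0))
  expect_true(all(eff$effect_2D[is.na(cls)] == 0))  # controls
  ess <- cls %in% "common_essential"
  expect_equal(eff$effect_2D[ess], eff$effect_3D[ess])
})

test_that("a depleting guide loses abundance at the expected raw rate", {
  # one strongly depleting gene in an otherwise neutral pool: with effect
  # f = -0.5/day its day-7 raw abundance ratio is 2^(-3.5) before
  # renormalization; the pool renormalization only adds a small positive
  # drift, so the guide-level log2fe must sit near -3.5
  cfg <- simConfig(nNeutral = 50L, nCommonEssential = 1L, n2dEssential = 0L,
                   n3dEssential = 0L, guidesPerGene = 10L, nSafe = 20L,
                   nNonTargeting = 20L, effect = -0.5, effectSd = 0,
                   coverage = 2000L, depth = 2000, dispersion = 0, seed = 13L)
  sim <- simulateScreenExperiment(cfg)
  pheno <- screenPhenotypes(sim$se)
  ess_gene <- names(truthClasses(sim$truth))[truthClasses(sim$truth) ==
                                               "common_essential"]
  g <- genePhenotypes(pheno)
  u <- g$u_gene[g$gene == ess_gene & g$comparison == "2D_D7_vs_D0"]
  expect_lt(u, -3.0)
  expect_gt(u, -4.0)
})

test_that("null screens are calibrated: neutral effects give near-zero gene effects", {
  cfg <- simConfig(nNeutral = 40L, nCommonEssential = 0L, n2dEssential = 0L,
                   n3dEssential = 0L, guidesPerGene = 10L, nSafe = 20L,
                   nNonTargeting = 20L, seed = 17L)
  sim <- simulateScreenExperiment(cfg)
  g <- genePhenotypes(screenPhenotypes(sim$se))
  u <- g$u_gene[g$comparison == "3D_D14_vs_D0"]
  se_mean <- sd(u) / sqrt(length(u))
  expect_lt(abs(mean(u)), 3 * se_mean + 0.02)
})

test_that("recovery metrics match a brute-force confusion tally", {
  set.seed(23)
  sim <- simulateLibrary(small_cfg())
  genes <- names(truthClasses(sim$truth))
  labels <- sample(c("THREE_D_EXCLUSIVE", "TWO_D_EXCLUSIVE", "SHARED",
                     "OTHER", "NONE"), length(genes), replace = TRUE)
  part <- new("ExclusivityPartition", labels = setNames(labels, genes),
              sets = list(), membership = data.frame())
  rec <- evaluateRecovery(part, sim$truth)
  expected_of <- c(neutral = "NONE", common_essential = "SHARED",
                   essential_2D = "TWO_D_EXCLUSIVE",
                   essential_3D = "THREE_D_EXCLUSIVE")
  cls <- truthClasses(sim$truth)
  for (k in names(expected_of)) {
    tp <- 0; fn <- 0; fp <- 0; tn <- 0
    for (g in genes) {
      hit <- labels[match(g, genes)] == expected_of[[k]]
      if (cls[[g]] == k) { if (hit) tp <- tp + 1 else fn <- fn + 1 }
      else { if (hit) fp <- fp + 1 else tn <- tn + 1 }
    }
    row <- rec$metrics[rec$metrics$class == k, ]
    expect_equal(row$sensitivity, tp / (tp + fn))
    expect_equal(row$specificity, tn / (tn + fp))
    if (tp + fp > 0) expect_equal(row$precision, tp / (tp + fp))
  }
  perfect <- new("ExclusivityPartition",
                 labels = setNames(unname(expected_of[cls]), genes),
                 sets = list(), membership = data.frame())
  expect_true(all(evaluateRecovery(perfect, sim$truth)$metrics$sensitivity == 1))
  none <- new("ExclusivityPartition",
              labels = setNames(rep("NONE", length(genes)), genes),
              sets = list(), membership = data.frame())
  m <- evaluateRecovery(none, sim$truth)$metrics
  ess <- m$class != "neutral"
  expect_true(all(m$sensitivity[ess] == 0))
  expect_true(all(m$specificity[ess] == 1))
})

test_that("writeFastq emits exactly the requested reads", {
  sim <- simulateLibrary(small_cfg())
  counts <- setNames(c(3L, rep(0L, length(sim$library) - 1L)),
                     guideIds(sim$library))
  path <- tempfile(fileext = ".fastq.gz")
  writeFastq(counts, sim$library, path, offset = 2)
  res <- countGuides(path, buildSpacerIndex(sim$library),
                     matchConfig(offset = 2))
  expect_equal(sum(res$counts), 3L)
  expect_equal(unname(res$counts[guideIds(sim$library)[1]]), 3L)

  empty <- tempfile(fileext = ".fastq")
  writeFastq(setNames(integer(length(sim$library)), guideIds(sim$library)),
             sim$library, empty, offset = 2)
  expect_equal(countGuides(empty, buildSpacerIndex(sim$library),
                           matchConfig(offset = 2))$qc$reads, 0L)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(simConfig(effect = 0.3), "<= 0")
  expect_error(simConfig(dispersion = -1), ">= 0")
  expect_error(simConfig(nNeutral = 0, nCommonEssential = 0,
                         n2dEssential = 0, n3dEssential = 0, nSafe = 0,
                         nNonTargeting = 0), "at least one guide")
})
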