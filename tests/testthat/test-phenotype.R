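make_effects <- function(lib, log2fe, comparison = "3D_D14_vs_D0") {
  data.frame(guide_id = guideIds(lib), comparison = comparison,
             log2fe = log2fe, stringsAsFactors = FALSE)
}

test_that("pZ subtracts the control median, landing controls at zero", {
  lib <- toy_library(nGenes = 1, guidesPerGene = 1, nSafe = 2, nNonTargeting = 1)
  eff <- guidePZ(make_effects(lib, c(-1.3, -0.2, 0, 0.2)), lib)
  expect_equal(eff$pZ[eff$guide_id == "GENE01_g1"], -1.3)  # control median 0
  expect_equal(median(eff$pZ[eff$category != "targeting"]), 0)

  eff2 <- guidePZ(make_effects(lib, c(-1.0, 0.4, 0.5, 0.6)), lib)
  expect_equal(eff2$pZ[eff2$guide_id == "GENE01_g1"], -1.5)
  expect_equal(eff2$pZ[eff2$guide_id == "safe_02"], 0)     # control at the median

  no_ctrl <- toy_library(nGenes = 1, guidesPerGene = 2, nSafe = 0,
                         nNonTargeting = 0)
  expect_error(guidePZ(make_effects(no_ctrl, c(-1, 0)), no_ctrl), "control")
})

test_that("gene effect size is the guide median, midpoint on even counts", {
  lib3 <- toy_library(nGenes = 1, guidesPerGene = 3, nSafe = 1, nNonTargeting = 1)
  eff <- guidePZ(make_effects(lib3, c(-2, -1, 0, 0, 0)), lib3)
  expect_equal(unname(geneU(eff)["GENE01"]), -1)

  lib2 <- toy_library(nGenes = 1, guidesPerGene = 2, nSafe = 1, nNonTargeting = 1)
  eff2 <- guidePZ(make_effects(lib2, c(-2, -1, 0, 0)), lib2)
  expect_equal(unname(geneU(eff2)["GENE01"]), -1.5)

  perm <- eff[sample(nrow(eff)), ]
  expect_equal(geneU(perm), geneU(eff))
})

test_that("the worked phenotype-score example reproduces the frozen oracle value", {
  # gene pZ {-1.2,-1.0,-0.8,-1.0}; controls {-0.1,-0.05,0,0,0.05,0.1};
  # n_ctrl = 10: var_gene = 0.02666..., var_ctrl = 0.005, S_var = 0.125,
  # T = -1/sqrt(0.125/4 + 0.125/10) = -4.780914...; value frozen from the
  # brute-force arithmetic oracle in helper-fixtures.R
  gene_pz <- c(-1.2, -1.0, -0.8, -1.0)
  ctrl_pz <- c(-0.1, -0.05, 0, 0, 0.05, 0.1)
  bf <- bf_phenotypes(c(rep("G", 4), rep(NA, 6)), c(gene_pz, ctrl_pz),
                      c(rep(FALSE, 4), rep(TRUE, 6)), n_ctrl = 10)
  expect_equal(bf$t_score, -4.7809144, tolerance = 1e-7)
  got <- tScore(uGene = bf_median(gene_pz), varGene = var(gene_pz), nExp = 4,
                uCtrl = bf_median(ctrl_pz), varCtrl = var(ctrl_pz), nCtrl = 10)
  expect_equal(got, bf$t_score, tolerance = 1e-12)
})

test_that("T score edge behaviour: zero numerator, variance monotonicity, n_exp < 2", {
  expect_equal(tScore(0.5, 0.2, 5, 0.5, 0.1, 10), 0)
  t1 <- tScore(-1, 0.05, 5, 0, 0.01, 10)
  t2 <- tScore(-1, 0.20, 5, 0, 0.01, 10)   # doubled deviations, 4x var_gene
  expect_true(t1 < 0 && t2 < 0)
  expect_lt(abs(t2), abs(t1))
  expect_true(is.na(tScore(-1, NA, 1, 0, 0.01, 10)))
  expect_true(is.na(tScore(-1, 0, 3, 0, 0, 10)))   # degenerate constant inputs
})

test_that("welch switch uses the conventional denominator", {
  got <- tScore(-1, 0.04, 4, 0, 0.01, 10, welch = TRUE)
  expect_equal(got, -1 / sqrt(0.04 / 4 + 0.01 / 10))
})

test_that("pipeline u_gene and T agree with the brute-force oracle on random tables", {
  set.seed(101)
  for (rep in 1:20) {
    n_genes <- sample(2:5, 1)
    gpg <- sample(2:6, 1)
    n_ctrl_guides <- sample(4:10, 1)
    lib <- toy_library(nGenes = n_genes, guidesPerGene = gpg,
                       nSafe = ceiling(n_ctrl_guides / 2),
                       nNonTargeting = floor(n_ctrl_guides / 2))
    log2fe <- rnorm(length(lib), sd = 1.2)
    eff <- guidePZ(make_effects(lib, log2fe), lib)
    pheno <- screenPhenotypes(
      new("EnrichmentTable", summary = make_effects(lib, log2fe),
          replicates = data.frame(), sizeFactors = c(s = 1),
          pseudocount = 0.5, pairing = "replicate"),
      lib)
    genes <- genePhenotypes(pheno)
    rec <- guideRecords(lib)
    bf <- bf_phenotypes(rec$gene, log2fe, rec$category != "targeting",
                        n_ctrl = gpg)
    m <- match(genes$gene, bf$gene)
    expect_equal(genes$u_gene, bf$u_gene[m], tolerance = 1e-9)
    expect_equal(genes$t_score, bf$t_score[m], tolerance = 1e-9)
  }
})

test_that("control median is zero and scores are shift-invariant", {
  se <- toy_screen(seed = 51)
  pheno <- screenPhenotypes(se, minEligible = 1)
  ge <- guideEffects(pheno)
  for (cmp in unique(ge$comparison))
    expect_lt(abs(median(ge$pZ[ge$category != "targeting" &
                                 ge$comparison == cmp])), 1e-12)
  et <- logFoldEnrichment(se, minEligible = 1)
  shifted <- et
  shifted@summary$log2fe <- shifted@summary$log2fe + 3.7
  p0 <- genePhenotypes(screenPhenotypes(et, guideLibrary(se)))
  p1 <- genePhenotypes(screenPhenotypes(shifted, guideLibrary(se)))
  expect_equal(p0$u_gene, p1$u_gene, tolerance = 1e-12)
  expect_equal(p0$t_score, p1$t_score, tolerance = 1e-12)
})

test_that("sign of T tracks the sign of u_gene - u_ctrl", {
  se <- toy_screen(seed = 61)
  genes <- genePhenotypes(screenPhenotypes(se, minEligible = 1))
  ok <- !is.na(genes$t_score) & abs(genes$u_gene) > 1e-12
  expect_true(all(sign(genes$t_score[ok]) == sign(genes$u_gene[ok])))
})

test_that("n_ctrl is the average guides-per-targeted-gene and singles get no T", {
  lib <- GuideLibrary(data.frame(
    guide_id = c("a1", "a2", "a3", "b1", "s1", "n1"),
    gene = c("A", "A", "A", "B", "CONTROL", "CONTROL"),
    spacer = fixed_spacers(6),
    category = c(rep("targeting", 4), "safe", "non_targeting")))
  eff <- make_effects(lib, c(-1, -0.9, -1.1, -2, 0.05, -0.05))
  pheno <- screenPhenotypes(
    new("EnrichmentTable", summary = eff, replicates = data.frame(),
        sizeFactors = c(s = 1), pseudocount = 0.5, pairing = "replicate"),
    lib)
  expect_equal(controlSummary(pheno)$n_ctrl, 4 / 2)  # 4 targeting guides, 2 genes
  genes <- genePhenotypes(pheno)
  expect_true(is.na(genes$t_score[genes$gene == "B"]))
  expect_equal(genes$u_gene[genes$gene == "B"], -2)
  expect_equal(genes$n_exp[genes$gene == "B"], 1L)
})
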