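test_that("empirical MAF counts alleles and folds", {
  expect_equal(empirical_maf(c(0, 0, 1, 1)), 0.25)
  expect_equal(empirical_maf(rep(0, 5)), 0)
  expect_equal(empirical_maf(rep(2, 5)), 0)         # folded limit
  expect_equal(empirical_maf(rep(2, 5), fold = FALSE), 1)
  expect_equal(empirical_maf(c(2, 2, 1)), 1 / 6)
})

test_that("single-SNP worked example matches the hand-derived weights", {
  geno <- genotype_dataset(matrix(c(0L, 0L, 1L, 1L), 4, 1),
                           paste0("s", 1:4), "snp1")
  ann <- annotation_table("snp1", "g1", "nonsynonymous")
  sc <- madsen_browning_scores(geno, ann)
  # q = 0.25, weight 1/sqrt(4 * 0.25 * 0.75) = 1.1547
  expect_equal(unname(sc$X[, "g1"]),
               c(0, 0, 1.1547005, 1.1547005), tolerance = 1e-7)
  expect_equal(unname(sc$maf), 0.25)
})

test_that("scores are additive over SNPs and match a brute-force oracle", {
  set.seed(11)
  n <- 30
  G <- matrix(rbinom(n * 6, 2, 0.2), n, 6)
  geno <- genotype_dataset(G, paste0("s", 1:n), paste0("p", 1:6))
  ann <- annotation_table(paste0("p", 1:6), rep(c("g1", "g2"), each = 3),
                          rep("nonsynonymous", 6))
  sc <- madsen_browning_scores(geno, ann)
  # oracle: per-SNP weighted counts summed by hand per gene
  oracle <- sapply(c(g1 = 1, g2 = 4), function(start) {
    rowSums(sapply(start:(start + 2), function(l) {
      q <- sum(G[, l]) / (2 * n)
      if (q > 0.5) { q <- 1 - q; g <- 2 - G[, l] } else g <- G[, l]
      if (q == 0) rep(0, n) else g / sqrt(n * q * (1 - q))
    }))
  })
  expect_equal(unname(sc$X), unname(oracle), tolerance = 1e-12)
  # additivity: single-SNP genes sum to the multi-SNP gene score
  ann_split <- annotation_table(paste0("p", 1:6), paste0("u", 1:6),
                                rep("nonsynonymous", 6))
  singles <- madsen_browning_scores(geno, ann_split)
  expect_equal(unname(sc$X[, "g1"]),
               unname(rowSums(singles$X[, 1:3])), tolerance = 1e-12)
})

test_that("weight is strictly decreasing in MAF on (0, 0.5]", {
  n <- 100
  q <- seq(0.005, 0.5, by = 0.005)
  w <- 1 / sqrt(n * q * (1 - q))
  expect_true(all(diff(w) < 0))
})

test_that("all-scores = syn-scores + nonsyn-scores for classified genes", {
  set.seed(3)
  cfg <- quick_config(n = 150, n_genes = 25, seed = 9L)
  sim <- simulate_genotypes(cfg)
  all <- madsen_browning_scores(sim$genotypes, sim$annotation, "all")
  nsc <- madsen_browning_scores(sim$genotypes, sim$annotation,
                                "nonsynonymous")
  ssc <- madsen_browning_scores(sim$genotypes, sim$annotation,
                                "synonymous")
  both <- intersect(nsc$gene_ids, ssc$gene_ids)
  expect_gt(length(both), 0)
  expect_equal(all$X[, both],
               nsc$X[, both] + ssc$X[, both], tolerance = 1e-12)
})

test_that("monomorphic SNPs are excluded and empty genes omitted", {
  G <- cbind(c(0L, 0L, 0L), c(0L, 1L, 1L), c(2L, 2L, 2L))
  geno <- genotype_dataset(G, paste0("s", 1:3), paste0("m", 1:3))
  ann <- annotation_table(paste0("m", 1:3), c("gEmpty", "gOK", "gEmpty"),
                          rep("synonymous", 3))
  expect_message(sc <- madsen_browning_scores(geno, ann), "omitted")
  expect_equal(sc$gene_ids, "gOK")
  expect_equal(sc$dropped_genes, "gEmpty")
  # a monomorphic SNP inside a polymorphic gene contributes zero
  ann2 <- annotation_table(paste0("m", 1:3), rep("g", 3),
                           rep("synonymous", 3))
  sc2 <- madsen_browning_scores(geno, ann2)
  sc_only <- madsen_browning_scores(
    genotype_dataset(G[, 2, drop = FALSE], paste0("s", 1:3), "m2"),
    annotation_table("m2", "g", "synonymous"))
  expect_equal(unname(sc2$X), unname(sc_only$X))
})

test_that("frequencies above 0.5 are folded during scoring", {
  G <- matrix(c(2L, 2L, 1L, 1L), 4, 1)  # unfolded q = 0.75
  geno <- genotype_dataset(G, paste0("s", 1:4), "f1")
  sc <- madsen_browning_scores(geno,
                               annotation_table("f1", "g", "synonymous"))
  expect_equal(unname(sc$maf), 0.25)
  # folded counts 2 - G = (0,0,1,1) with the q = 0.25 weight
  expect_equal(unname(sc$X[, 1]), c(0, 0, 1, 1) / sqrt(4 * 0.25 * 0.75),
               tolerance = 1e-12)
})

test_that("gene score TSV writer emits scores plus SNP sidecar", {
  d <- tiny_dataset()
  sc <- madsen_browning_scores(d$genotypes, d$annotation)
  path <- file.path(tempdir(), "gene_scores.tsv")
  write_gene_scores(sc, path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(back$sample_id, d$genotypes$sample_ids)
  expect_equal(back$gA, unname(sc$X[, "gA"]), tolerance = 1e-9)
  side <- read.delim(file.path(tempdir(), "gene_scores_snps.tsv"))
  expect_setequal(side$snp_id, d$genotypes$snp_ids)
})
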