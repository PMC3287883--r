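# in-code fixtures shared across test files

# tiny hand-checkable dataset: 4 individuals, 2 genes x 2 SNPs
tiny_dataset <- function() {
  G <- rbind(c(0L, 1L, 0L, 0L),
             c(0L, 0L, 1L, 0L),
             c(1L, 0L, 0L, 1L),
             c(1L, 1L, 1L, 0L))
  geno <- genotype_dataset(G, paste0("s", 1:4), paste0("snp", 1:4))
  ann <- annotation_table(paste0("snp", 1:4),
                          c("gA", "gA", "gB", "gB"),
                          c("nonsynonymous", "synonymous",
                            "nonsynonymous", "synonymous"))
  P <- cbind(rep1 = c(1L, 0L, 1L, 0L), rep2 = c(1L, 1L, 0L, 0L))
  rownames(P) <- paste0("s", 1:4)
  covar <- data.frame(Age = c(40, 50, 60, 55), Sex = c(0, 1, 0, 1),
                      Smoke = c(1, 0, 0, 1), row.names = paste0("s", 1:4))
  rv_dataset(geno, ann, phenotype_replicates(P), covar)
}

# exchangeable-correlation Z generator: Z_ir = delta_i + shared + noise
# with Cor(Z_is, Z_it) = rho and unit marginal error variance
sim_z_matrix <- function(n_genes, R, rho, delta = 0) {
  shared <- rnorm(n_genes, 0, sqrt(rho))
  delta + shared + matrix(rnorm(n_genes * R, 0, sqrt(1 - rho)),
                          n_genes, R)
}

# simulation world used by several classifier/CV tests: moderate panel
# with genes carrying both functional classes
quick_config <- function(...) {
  args <- list(n = 400, n_genes = 120, snps_per_gene = c(2, 12),
               n_causal = 5, effect_size = 1.5, R = 10,
               covar_effects = c(Age = 0, Sex = 0, Smoke = 0),
               seed = 42L)
  do.call(sim_config, modifyList(args, list(...)))
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
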