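test_that("generation is deterministic given the seed", {
  cfg <- quick_config(seed = 5L)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$data$genotypes$G, s2$data$genotypes$G)
  expect_identical(unclass(s1$data$phenotypes),
                   unclass(s2$data$phenotypes))
  expect_identical(s1$truth, s2$truth)
  # on-disk generation is byte-identical too
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  generate_dataset(cfg, d1); generate_dataset(cfg, d2)
  for (f in c("genotypes.tsv", "annotation.tsv", "phenotypes.tsv",
              "covariates.tsv", "ground_truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("a point-mass MAF spectrum concentrates empirically", {
  cfg <- quick_config(n = 500, n_genes = 20, snps_per_gene = c(5, 5),
                      maf_shape = c(1e6, 3e6), seed = 7L)  # Beta ~ 0.25
  sim <- simulate_genotypes(cfg)
  emp <- colSums(sim$genotypes$G) / (2 * 500)
  expect_between(mean(emp), 0.22, 0.28)
})

test_that("default spectrum is heavily rare-skewed", {
  cfg <- sim_config(n = 700, n_genes = 250, seed = 3L)  # ~5000 SNPs
  sim <- simulate_genotypes(cfg)
  emp <- colSums(sim$genotypes$G) / (2 * 700)
  emp <- pmin(emp, 1 - emp)
  poly <- emp > 0
  expect_gte(mean(emp[poly] < 0.01), 0.5)
})

test_that("prevalence is hit in expectation across replicates", {
  cfg <- quick_config(n = 500, n_causal = 0, R = 50, prevalence = 0.3,
                      seed = 9L)
  sim <- simulate_dataset(cfg)
  frac <- colMeans(sim$data$phenotypes)
  band <- 3 * sqrt(0.3 * 0.7 / 500)
  expect_true(all(frac > 0.3 - band & frac < 0.3 + band))
})

test_that("shared genotypes induce positive rho when effects are nonzero", {
  hits <- 0
  for (seed in 1:10) {
    sim <- simulate_dataset(quick_config(effect_size = 2,
                                         covar_effects = c(Age = 0.5,
                                                           Sex = 0.25,
                                                           Smoke = 0.5),
                                         seed = 300L + seed))
    sc <- madsen_browning_scores(sim$data$genotypes,
                                 sim$data$annotation, "all")
    Z <- replicate_zstats(sc$X, sim$data$phenotypes)$Z
    Z <- Z[stats::complete.cases(Z), ]
    hits <- hits + (estimate_rho(Z) > 0)
  }
  expect_gte(hits, 9)
})

test_that("null replicates share nothing: rho near zero", {
  cfg <- quick_config(n = 300, n_genes = 600, snps_per_gene = c(1, 6),
                      n_causal = 0, R = 2, seed = 19L)
  sim <- simulate_dataset(cfg)
  sc <- madsen_browning_scores(sim$data$genotypes, sim$data$annotation,
                               "all")
  Z <- replicate_zstats(sc$X, sim$data$phenotypes)$Z
  Z <- Z[stats::complete.cases(Z), ]
  expect_between(estimate_rho(Z), 0, 0.1)
})

test_that("standardized null zbar looks normal across many genes", {
  cfg <- sim_config(n = 400, n_genes = 2000, snps_per_gene = c(1, 6),
                    n_causal = 0,
                    covar_effects = c(Age = 0, Sex = 0, Smoke = 0),
                    R = 8, seed = 21L)
  sim <- simulate_dataset(cfg)
  sc <- madsen_browning_scores(sim$data$genotypes, sim$data$annotation,
                               "all")
  zr <- replicate_zstats(sc$X, sim$data$phenotypes)
  Z <- zr$Z[!zr$degenerate, ]
  rho <- estimate_rho(Z)
  zstar <- standardize_zbar(aggregate_replicates(Z), rho, ncol(Z))
  m <- mean(zstar); s <- sd(zstar)
  skew <- mean(((zstar - m) / s)^3)
  kurt <- mean(((zstar - m) / s)^4) - 3
  expect_lt(abs(skew), 0.2)
  expect_lt(abs(kurt), 0.5)
})

test_that("causal-gene Z* stochastically dominates null-gene Z*", {
  sim <- simulate_dataset(quick_config(seed = 23L))
  sc <- madsen_browning_scores(sim$data$genotypes, sim$data$annotation,
                               "all")
  zr <- replicate_zstats(sc$X, sim$data$phenotypes)
  Z <- zr$Z[!zr$degenerate, ]
  rho <- estimate_rho(Z)
  zstar <- standardize_zbar(aggregate_replicates(Z), rho, ncol(Z))
  causal <- rownames(Z) %in% sim$truth$causal_genes
  wt <- stats::wilcox.test(zstar[causal], zstar[!causal],
                           alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("generated files round-trip through the readers", {
  cfg <- quick_config(n = 60, n_genes = 15, R = 4, seed = 25L)
  dir <- file.path(tempdir(), "simRT")
  generate_dataset(cfg, dir)
  sim <- simulate_dataset(cfg)
  d <- read_rv_dataset(dir)
  expect_identical(d$genotypes$G, sim$data$genotypes$G)
  expect_identical(unclass(d$phenotypes), unclass(sim$data$phenotypes))
  expect_equal(d$covariates$Age, sim$data$covariates$Age,
               tolerance = 1e-9)
  # config echo comment matches the generating configuration
  echo <- read_config_echo(file.path(dir, "genotypes.tsv"))
  expect_equal(echo$n, cfg$n)
  expect_equal(echo$seed, cfg$seed)
  expect_equal(echo$effect_size, cfg$effect_size)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$causal_genes, sim$truth$causal_genes)
})

test_that("unattainable prevalence errors out", {
  cfg <- quick_config(n = 30, n_genes = 5, prevalence = 0.001, R = 2,
                      n_causal = 0, seed = 27L)
  expect_error(simulate_dataset(cfg), "unattainable|no cases")
})

test_that("the LD switch induces within-gene channel correlation", {
  base <- quick_config(n = 300, n_genes = 30, snps_per_gene = c(6, 10),
                       maf_shape = c(2, 5), seed = 33L)
  mean_abs_cor <- function(cfg) {
    sim <- simulate_genotypes(cfg)
    xn <- madsen_browning_scores(sim$genotypes, sim$annotation,
                                 "nonsynonymous")
    xs <- madsen_browning_scores(sim$genotypes, sim$annotation,
                                 "synonymous")
    both <- intersect(xn$gene_ids, xs$gene_ids)
    mean(abs(diag(cor(xn$X[, both], xs$X[, both]))))
  }
  ld <- do.call(sim_config, modifyList(unclass(base)[names(unclass(base))
                  %in% names(formals(sim_config))], list(ld_rho = 0.8)))
  expect_gt(mean_abs_cor(ld), mean_abs_cor(base) + 0.2)
})
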