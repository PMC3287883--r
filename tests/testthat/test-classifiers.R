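test_that("gene weight behaves at its anchor points", {
  set.seed(51)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  smoke <- rbinom(n, 1, 0.3)
  xn <- rnorm(n) + y; xs <- rnorm(n)
  gw <- gene_weight(xn, xs, y, smoke)
  expect_between(gw$w, 0, 1)
  expect_gt(gw$w, 0.5)  # nonsyn channel is the associated one
  expect_false(gw$flagged)
  # the adopted formula at stated p-values
  expect_equal(0.09 / (0.01 + 0.09), 0.9)
  # symmetric channels give w = 0.5
  gw2 <- gene_weight(xs, xs, y, smoke)
  expect_equal(gw2$w, 0.5)
  # separation flags and defaults the p-value
  ysep <- c(rep(0, 10), rep(1, 10))
  xsep <- c(rep(0, 10), rep(5, 10))
  gws <- gene_weight(xsep, rnorm(20), ysep, rep(0, 20))
  expect_true(gws$flagged)
})

test_that("weighted score interpolates the channels", {
  expect_equal(weighted_score(2, 1, 1), 2)
  expect_equal(weighted_score(2, 1, 0), 1)
  expect_equal(weighted_score(2, 1, 0.9), 1.9)
  expect_error(weighted_score(1, 1, 1.2), "w <= 1")
})

test_that("channel correlation is pooled within class and clipped", {
  set.seed(52)
  x <- rnorm(100); y <- rbinom(100, 1, 0.5)
  expect_equal(estimate_gene_correlation(x, x, y), 0.99)   # collinear
  # hand fixture: centered cross-products within each class
  xn <- c(1, 2, 3, 4, 5, 6); xs <- c(2, 1, 4, 3, 6, 5)
  lab <- c(1, 1, 1, 0, 0, 0)
  rn <- xn - ave(xn, lab); rs <- xs - ave(xs, lab)
  hand <- sum(rn * rs) / sqrt(sum(rn^2) * sum(rs^2))
  expect_equal(estimate_gene_correlation(xn, xs, lab), hand)
  # independent channels stay near zero
  expect_lte(abs(estimate_gene_correlation(rnorm(500), rnorm(500),
                                           rbinom(500, 1, 0.5))), 0.1)
})

test_that("discriminant arithmetic and threshold follow the rule form", {
  # hand-built single-gene rule: delta=1, c_n=0.1, sigma=1, x - m = 2
  rule <- structure(list(kind = "eb", genes = "g", delta = 1,
                         center = 0, scale = 1, c_n = 0.1, tau = 0,
                         covar_fit = NULL, K = 1,
                         rank_stat = 1, weights = NULL, jc = NULL,
                         fallback = NULL),
                    class = "prediction_rule")
  prepared <- list(all = list(X = matrix(c(2, 0, -4), 3, 1,
                                         dimnames = list(NULL, "g"))))
  d_stub <- structure(list(covariates = NULL), class = "rv_dataset")
  expect_equal(discriminant(rule, d_stub, prepared), c(0.2, 0, -0.4))
  rule2 <- rule; rule2$scale <- 2    # doubling sigma halves the term
  expect_equal(discriminant(rule2, d_stub, prepared),
               c(0.1, 0, -0.2))
  # threshold log(n2/n1): all-zero discriminants with tau > 0 -> control
  rule$tau <- log(488 / 209)
  expect_equal(rule$tau, 0.84798, tolerance = 1e-4)
  prepared0 <- list(all = list(X = matrix(0, 3, 1,
                                          dimnames = list(NULL, "g"))))
  pr <- predict(rule, d_stub, prepared0)
  expect_equal(pr$label, c(0L, 0L, 0L))
})

test_that("fit_rule selects causal signal and is permutation invariant", {
  set.seed(60)
  sim <- simulate_dataset(quick_config(seed = 17L))
  d <- sim$data
  rule <- fit_rule(d, "eb", K = 10, train_reps = 1:5,
                   use_covariates = FALSE)
  expect_length(rule$genes, 10)
  expect_gt(length(intersect(rule$genes, sim$truth$causal_genes)), 2)
  pr <- predict(rule, d)
  # permute gene (SNP column) order: predictions must be unchanged
  perm <- sample(ncol(d$genotypes$G))
  geno_p <- genotype_dataset(d$genotypes$G[, perm],
                             d$genotypes$sample_ids,
                             d$genotypes$snp_ids[perm])
  d_p <- rv_dataset(geno_p, d$annotation, d$phenotypes, d$covariates)
  rule_p <- fit_rule(d_p, "eb", K = 10, train_reps = 1:5,
                     use_covariates = FALSE)
  expect_equal(predict(rule_p, d_p)$score, pr$score, tolerance = 1e-10)
  # K beyond the gene count truncates with a warning
  expect_warning(big <- fit_rule(d, "eb", K = 10000, train_reps = 1:2,
                                 use_covariates = FALSE), "truncated")
  expect_lte(big$K, 120)
})

test_that("shrinkage pulls selected genes toward zero on null data", {
  hits <- 0
  for (seed in 1:10) {
    sim <- simulate_dataset(quick_config(n_causal = 0, n_genes = 150,
                                         seed = 100L + seed))
    rule <- fit_rule(sim$data, "eb", K = 10, use_covariates = FALSE)
    zb <- rule$zbar[rule$genes]
    hits <- hits + (mean(abs(rule$delta)) < mean(abs(zb)))
  }
  expect_gte(hits, 9)
})

test_that("single strong causal gene is found with K = 1", {
  found <- 0
  for (seed in 1:10) {
    sim <- simulate_dataset(quick_config(n = 600, n_genes = 80,
                                         n_causal = 1, effect_size = 2,
                                         seed = 200L + seed))
    rule <- fit_rule(sim$data, "eb", K = 1, use_covariates = FALSE)
    found <- found + (rule$genes == sim$truth$causal_genes)
  }
  expect_gte(found, 9)
})

test_that("JC falls back to univariate terms for single-channel genes", {
  set.seed(61)
  cfg <- quick_config(frac_nonsyn = 1, n_genes = 40, seed = 23L)
  sim <- simulate_dataset(cfg)   # no synonymous SNPs at all
  rule <- fit_rule(sim$data, "jc", K = 10, use_covariates = FALSE)
  expect_true(all(rule$fallback))
  expect_true(all(is.na(rule$jc$delta_s)))
  pr <- predict(rule, sim$data)
  expect_true(all(is.finite(pr$score)))
})

test_that("rules serialize to JSON and back without changing predictions", {
  set.seed(62)
  sim <- simulate_dataset(quick_config(seed = 29L))
  for (kind in c("eb", "web", "jc")) {
    rule <- fit_rule(sim$data, kind, K = 5, train_reps = 1:5)
    path <- file.path(tempdir(), paste0("rule_", kind, ".json"))
    save_rule(rule, path)
    back <- load_rule(path)
    expect_equal(predict(back, sim$data)$score,
                 predict(rule, sim$data)$score, tolerance = 1e-8)
  }
})

test_that("covariate model recovers strong covariate signal, unshrunk", {
  set.seed(63)
  cfg <- quick_config(n_causal = 0,
                      covar_effects = c(Age = 1, Sex = 0, Smoke = 1),
                      seed = 31L)
  sim <- simulate_dataset(cfg)
  rule <- fit_rule(sim$data, "eb", K = 5, train_reps = 1:5)
  expect_equal(rule$tau, 0)  # intercept absorbs the imbalance
  expect_gt(rule$covar_fit[["Age"]], 0)
  expect_gt(rule$covar_fit[["Smoke"]], 0)
  # covariate-driven predictions beat chance easily on held-out replicates
  pr <- predict(rule, sim$data)
  expect_gt(roc_auc(pr$score, sim$data$phenotypes[, 10])$auc, 0.7)
})
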