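#' Configuration for the synthetic mini-exome generator
#'
#' Describes a GAW17-like world: a fixed panel of individuals genotyped
#' at rare-skewed SNPs grouped into genes, fixed covariates, and `R`
#' phenotype replicates redrawn on the same genotypes (which induces the
#' positive inter-replicate correlation of per-gene Z statistics that the
#' analysis corrects for).
#'
#' Defaults echo the mini-exome scale: 697 individuals, 500 genes of
#' 1-40 SNPs, a Beta(0.2, 30) MAF spectrum truncated to `[1/(2n), 0.5]`
#' (about 60% of polymorphic SNPs land below empirical MAF 0.01 at
#' n = 697, ~6% above 0.05), 60% nonsynonymous SNPs, ~30% cases, and
#' liability dominated by Age/Sex/Smoke unless the covariate effects are
#' zeroed. Causal effects act on the standardized
#' nonsynonymous burden of the causal genes.
#'
#' @param n number of individuals.
#' @param n_genes number of genes.
#' @param snps_per_gene inclusive integer range for SNPs per gene.
#' @param maf_shape Beta shape parameters of the MAF spectrum.
#' @param frac_nonsyn probability a SNP is nonsynonymous.
#' @param n_causal number of causal genes (drawn among genes with at
#'   least one polymorphic nonsynonymous SNP).
#' @param effect_size liability-scale effect per causal gene, applied to
#'   its standardized nonsynonymous burden (recycled to `n_causal`).
#' @param covar_effects named liability coefficients for `Age` (per SD),
#'   `Sex` and `Smoke` (per unit).
#' @param prevalence target case fraction per replicate.
#' @param R number of phenotype replicates.
#' @param ld_rho optional within-gene genotype correlation (Gaussian
#'   copula), off by default; exercises the correlated-channel premise of
#'   the joint covariance model.
#' @param seed default seed used by the simulation functions.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n = 697, n_genes = 500, snps_per_gene = c(1, 40),
                       maf_shape = c(0.2, 30), frac_nonsyn = 0.6,
                       n_causal = 5, effect_size = 1.5,
                       covar_effects = c(Age = 0.5, Sex = 0.25,
                                         Smoke = 0.5),
                       prevalence = 0.3, R = 20, ld_rho = 0,
                       seed = 1L) {
  stopifnot(n >= 2, n_genes >= 1, n_causal <= n_genes,
            prevalence > 0, prevalence < 1, R >= 1,
            frac_nonsyn >= 0, frac_nonsyn <= 1,
            ld_rho >= 0, ld_rho < 1,
            all(is.finite(effect_size)))
  structure(list(n = n, n_genes = n_genes,
                 snps_per_gene = snps_per_gene, maf_shape = maf_shape,
                 frac_nonsyn = frac_nonsyn, n_causal = n_causal,
                 effect_size = rep_len(effect_size, max(n_causal, 1)),
                 covar_effects = covar_effects, prevalence = prevalence,
                 R = R, ld_rho = ld_rho, seed = seed),
            class = "sim_config")
}

# Beta MAF spectrum truncated to [1/(2n), 0.5] by inverse-CDF sampling
draw_maf <- function(n_snps, shape, n_ind) {
  lo <- stats::pbeta(1 / (2 * n_ind), shape[1], shape[2])
  hi <- stats::pbeta(0.5, shape[1], shape[2])
  stats::qbeta(runif(n_snps, lo, hi), shape[1], shape[2])
}

#' Simulate the genotype panel and its annotation
#'
#' Per SNP: MAF drawn from the truncated Beta spectrum, genotypes
#' Binomial(2, MAF) i.i.d. across individuals (or tied within a gene by a
#' Gaussian copula when `ld_rho > 0`); SNP counts per gene uniform on the
#' configured range; functional class Bernoulli(`frac_nonsyn`).
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed`.
#' @return list with `genotypes` ([genotype_dataset()]), `annotation`
#'   ([annotation_table()]) and `maf` (true per-SNP MAF).
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    k <- sample(config$snps_per_gene[1]:config$snps_per_gene[2],
                config$n_genes, replace = TRUE)
    gene_of <- rep(paste0("gene", seq_len(config$n_genes)), k)
    n_snps <- length(gene_of)
    snp_ids <- paste0("snp", seq_len(n_snps))
    maf <- draw_maf(n_snps, config$maf_shape, config$n)
    if (config$ld_rho > 0) {
      G <- matrix(0L, config$n, n_snps)
      off <- 0
      for (i in seq_len(config$n_genes)) {
        shared <- rnorm(config$n)
        for (l in seq_len(k[i])) {
          zl <- sqrt(config$ld_rho) * shared +
            sqrt(1 - config$ld_rho) * rnorm(config$n)
          G[, off + l] <- stats::qbinom(pnorm(zl), 2, maf[off + l])
        }
        off <- off + k[i]
      }
    } else {
      G <- matrix(rbinom(config$n * n_snps, 2, rep(maf, each = config$n)),
                  nrow = config$n)
    }
    cls <- ifelse(runif(n_snps) < config$frac_nonsyn,
                  "nonsynonymous", "synonymous")
    list(genotypes = genotype_dataset(G, paste0("ind", seq_len(config$n)),
                                      snp_ids),
         annotation = annotation_table(snp_ids, gene_of, cls),
         maf = stats::setNames(maf, snp_ids))
  })
}

#' Simulate covariates and replicated phenotypes on a fixed panel
#'
#' Liability model: `intercept-free eta = covariate terms + sum over
#' causal genes of effect x standardized nonsynonymous burden`, with
#' standard normal noise redrawn per replicate. The case threshold `t`
#' solves `mean(pnorm(eta - t)) = prevalence` over the panel, so each
#' replicate's case count is binomial around the target. Genotypes and
#' covariates are fixed across replicates: individuals with high `eta`
#' are cases in most replicates, which is exactly the mechanism that
#' makes a gene's Z statistics correlate across replicates.
#'
#' Covariates: Age ~ N(50, 10) years (its liability coefficient applies
#' per SD), Sex ~ Bernoulli(0.5), Smoke ~ Bernoulli(0.3).
#'
#' @param sim output of [simulate_genotypes()] (or a list with
#'   `genotypes` and `annotation`).
#' @param config the same [sim_config()].
#' @param seed overrides `config$seed + 1`.
#' @return list with `phenotypes`, `covariates`, `truth` (causal gene
#'   ids, effects, covariate coefficients, threshold, per-replicate case
#'   counts).
#' @export
simulate_phenotypes <- function(sim, config, seed = config$seed + 1) {
  stopifnot(inherits(config, "sim_config"))
  geno <- sim$genotypes
  with_seed(seed, {
    n <- geno$n
    age <- rnorm(n, 50, 10)
    sex <- rbinom(n, 1, 0.5)
    smoke <- rbinom(n, 1, 0.3)
    covar <- data.frame(Age = age, Sex = sex, Smoke = smoke,
                        row.names = geno$sample_ids)
    be <- config$covar_effects
    eta <- be[["Age"]] * (age - mean(age)) / sd(age) +
      be[["Sex"]] * sex + be[["Smoke"]] * smoke
    causal <- character(0); effects <- numeric(0)
    if (config$n_causal > 0) {
      ns <- madsen_browning_scores(geno, sim$annotation, "nonsynonymous")
      eligible <- ns$gene_ids
      if (length(eligible) < config$n_causal)
        stop("fewer genes with polymorphic nonsynonymous SNPs (",
             length(eligible), ") than n_causal")
      causal <- sort(sample(eligible, config$n_causal))
      effects <- stats::setNames(config$effect_size, causal)
      for (g in causal) {
        b <- ns$X[, g]
        eta <- eta + effects[[g]] * (b - mean(b)) / sd(b)
      }
    }
    # threshold achieving the target prevalence in expectation
    thr <- uniroot(function(t) mean(pnorm(eta - t)) - config$prevalence,
                   interval = range(eta) + c(-10, 10))$root
    P <- matrix(0L, n, config$R,
                dimnames = list(geno$sample_ids,
                                paste0("rep", seq_len(config$R))))
    for (r in seq_len(config$R))
      P[, r] <- as.integer(eta + rnorm(n) > thr)
    cc <- colSums(P)
    if (any(cc == 0) || any(cc == n))
      stop("unattainable prevalence: a replicate has 0 cases or 0 controls")
    list(phenotypes = phenotype_replicates(P), covariates = covar,
         truth = list(causal_genes = causal,
                      effects = as.list(effects),
                      covar_effects = as.list(be),
                      threshold = thr,
                      case_counts = as.vector(cc)))
  })
}

#' Simulate a complete dataset in memory
#'
#' Convenience wrapper chaining [simulate_genotypes()] and
#' [simulate_phenotypes()] into an [rv_dataset()].
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed`.
#' @return list with `data` (an `rv_dataset`) and `truth`.
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  sim <- simulate_genotypes(config, seed)
  ph <- simulate_phenotypes(sim, config, seed + 1)
  list(data = rv_dataset(sim$genotypes, sim$annotation, ph$phenotypes,
                         ph$covariates),
       truth = ph$truth)
}

#' Generate a dataset on disk
#'
#' Writes `genotypes.tsv`, `annotation.tsv`, `phenotypes.tsv`,
#' `covariates.tsv` and `ground_truth.json` to `dir`. Each TSV starts
#' with `#` comment lines echoing the generating configuration (as
#' compact JSON) and the seed, so a run can be reproduced from its
#' outputs alone.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
generate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(config)
  echo <- paste0("# config ",
                 jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                  digits = NA))
  d <- sim$data
  write_with_echo(echo, file.path(dir, "genotypes.tsv"),
                  data.frame(sample_id = d$genotypes$sample_ids,
                             d$genotypes$G, check.names = FALSE))
  write_with_echo(echo, file.path(dir, "annotation.tsv"),
                  as.data.frame(d$annotation))
  write_with_echo(echo, file.path(dir, "phenotypes.tsv"),
                  data.frame(sample_id = rownames(d$phenotypes),
                             unclass(d$phenotypes), check.names = FALSE))
  write_with_echo(echo, file.path(dir, "covariates.tsv"),
                  data.frame(sample_id = rownames(d$covariates),
                             d$covariates, check.names = FALSE))
  jsonlite::write_json(c(sim$truth, list(seed = config$seed)),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_with_echo <- function(echo, path, df) {
  writeLines(echo, path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read back the config echo of a generated dataset
#'
#' @param path a TSV written by [generate_dataset()].
#' @return the embedded configuration as a list.
#' @export
read_config_echo <- function(path) {
  line <- readLines(path, n = 1)
  if (!startsWith(line, "# config "))
    stop("no config echo in ", path)
  jsonlite::fromJSON(sub("^# config ", "", line))
}
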