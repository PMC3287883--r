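#' Relative importance weight of a gene's nonsynonymous channel
#'
#' Fits two logistic regressions of disease on (gene score, Smoke) --
#' once with the nonsynonymous-only burden, once with the synonymous-only
#' burden -- and converts the two-sided Wald p-values of the score
#' coefficients into
#' \deqn{w_i = p_{i|s} / (p_{i|n} + p_{i|s}) \in [0, 1],}
#' so a smaller nonsynonymous p-value (stronger association) gives the
#' nonsynonymous channel a larger weight, with `w = 0.5` at equality.
#' Non-convergence or separation sets that p-value to 1 with a flag.
#'
#' @param xn,xs per-individual nonsynonymous and synonymous gene scores.
#' @param y 0/1 disease status (may be stacked over training replicates,
#'   with `xn`, `xs`, `smoke` recycled to match).
#' @param smoke 0/1 smoking covariate entering both regressions.
#' @return list with `p_nonsyn`, `p_syn`, `w`, `flagged`.
#' @export
gene_weight <- function(xn, xs, y, smoke) {
  n <- length(y)
  pn <- wald_p_logistic(rep_len(xn, n), y, rep_len(smoke, n))
  ps <- wald_p_logistic(rep_len(xs, n), y, rep_len(smoke, n))
  list(p_nonsyn = pn$p, p_syn = ps$p,
       w = ps$p / (pn$p + ps$p),
       flagged = pn$flagged || ps$flagged)
}

# two-sided Wald p for the score coefficient in logistic(y ~ score + smoke);
# a constant smoke column is dropped rather than left rank-deficient
wald_p_logistic <- function(score, y, smoke) {
  X <- if (var(smoke) > 0) cbind(1, score, smoke) else cbind(1, score)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || fit$rank < ncol(X))
    return(list(p = 1, flagged = TRUE))
  # Wald SE from the weighted cross-product (Fisher information)
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov) || cov[2, 2] <= 0 || !is.finite(cov[2, 2]))
    return(list(p = 1, flagged = TRUE))
  se <- sqrt(cov[2, 2])
  # quasi-separated fits have exploding coefficients / standard errors
  if (abs(fit$coefficients[2]) > 15 || se > 30)
    return(list(p = 1, flagged = TRUE))
  zval <- unname(fit$coefficients[2]) / se
  if (!is.finite(zval)) return(list(p = 1, flagged = TRUE))
  list(p = 2 * pnorm(-abs(zval)), flagged = FALSE)
}

#' Weighted gene score combining the two functional channels
#'
#' `Xw = w * Xn + (1 - w) * Xs` per individual.
#'
#' @param xn,xs nonsynonymous and synonymous scores.
#' @param w weight in `[0, 1]`.
#' @export
weighted_score <- function(xn, xs, w) {
  stopifnot(w >= 0, w <= 1)
  w * xn + (1 - w) * xs
}

#' Pooled within-class correlation of a gene's two channels
#'
#' Pearson correlation of the class-centered nonsynonymous and synonymous
#' scores (residuals about each class mean), clipped to `|r| <= 0.99` so
#' the implied 2x2 correlation matrix stays invertible.
#'
#' @param xn,xs channel scores.
#' @param labels 0/1 class labels.
#' @return correlation in `[-0.99, 0.99]`.
#' @export
estimate_gene_correlation <- function(xn, xs, labels) {
  labels <- as.integer(labels)
  rn <- xn - ave(xn, labels)
  rs <- xs - ave(xs, labels)
  denom <- sqrt(sum(rn^2) * sum(rs^2))
  r <- if (denom == 0) 0 else sum(rn * rs) / denom
  min(max(r, -0.99), 0.99)
}

# per-replicate two-group summaries averaged over training replicates:
# center (mu1+mu2)/2, pooled sd, and the scale factor c_n
pooled_gene_summaries <- function(X, P) {
  R <- ncol(P)
  m <- s <- matrix(0, ncol(X), R)
  c_n <- numeric(R)
  for (r in seq_len(R)) {
    zs <- gene_zstats(X, P[, r])
    m[, r] <- (zs$mean_case + zs$mean_control) / 2
    s[, r] <- zs$pooled_sd
    c_n[r] <- zs$c_n
  }
  list(center = rowMeans(m), scale = rowMeans(s), c_n = mean(c_n))
}

# Z pipeline for one score matrix: replicate Z -> zbar -> rho -> zstar
zstat_pipeline <- function(X, P, rho = NULL) {
  zr <- replicate_zstats(X, P)
  keep <- !zr$degenerate
  Z <- zr$Z[keep, , drop = FALSE]
  zbar <- aggregate_replicates(Z)
  R <- ncol(Z)
  if (is.null(rho))
    rho <- if (R >= 2) estimate_rho(Z) else 0
  list(zbar = zbar, rho = rho, R = R,
       zstar = standardize_zbar(zbar, rho, R),
       keep = rownames(Z), c_n = mean(zr$c_n),
       n1 = mean(zr$n1), n2 = mean(zr$n2))
}

# shrink zstar and return delta_hat on the zbar scale; shrink = "identity"
# bypasses the empirical Bayes map (used by the oracle-equivalence tests)
shrink_pipeline <- function(zstar, rho, R, shrink, n_bins, degree,
                            model = NULL) {
  if (shrink == "identity")
    return(list(delta_hat = rescale_shrunken(zstar, rho, R), model = NULL))
  if (is.null(model))
    model <- fit_marginal_density(zstar, n_bins = n_bins, degree = degree)
  shrunk <- tweedie_estimate(model, zstar)
  list(delta_hat = rescale_shrunken(shrunk, rho, R), model = model)
}

#' Fit an empirical Bayes prediction rule
#'
#' Runs the full training pipeline for one of the three rules on the
#' chosen training replicates: gene scores (per model kind), per-replicate
#' Z statistics, replicate averaging with correlation correction,
#' Tweedie shrinkage of the standardized values, gene ranking, and the
#' top-`K` selection, plus an optional unshrunk logistic covariate model.
#'
#' Model kinds:
#' \describe{
#'   \item{eb}{all-SNP Madsen-Browning scores, shrunken effects ranked by
#'     `|delta_hat|`.}
#'   \item{web}{per-gene weighted combination of the nonsynonymous and
#'     synonymous channels, weights from [gene_weight()] on the pooled
#'     training replicates; genes with a single channel fall back to that
#'     channel with a flag.}
#'   \item{jc}{bivariate channel model per gene with pooled within-class
#'     channel correlation; the nonsynonymous and synonymous Z ensembles
#'     are shrunk separately and genes are ranked by the quadratic form
#'     `delta' P^{-1} delta`; single-channel genes fall back to the
#'     univariate term.}
#' }
#'
#' @param data an [rv_dataset()].
#' @param kind one of `"eb"`, `"web"`, `"jc"`.
#' @param K number of genes to keep (truncated with a warning if larger
#'   than the number of usable genes).
#' @param train_reps replicate columns to train on (default: all).
#' @param use_covariates attach the logistic covariate model (Age, Sex,
#'   Smoke, ... -- all columns of the covariate table) fitted on the
#'   pooled training replicates. Covariate effects are deliberately not
#'   shrunk. When attached, the decision threshold is 0 (the intercept
#'   already encodes the case/control imbalance); otherwise the threshold
#'   is `log(n2/n1)`.
#' @param rho override for the inter-replicate correlation (estimated
#'   from the training Z matrix when `NULL` and R >= 2; 0 for R = 1).
#' @param n_bins,degree Lindsey fit knobs, see [fit_marginal_density()].
#' @param shrink `"tweedie"` (default) or `"identity"` (no shrinkage;
#'   used for oracle comparisons).
#' @param w_override force every WEB gene weight to this value (testing
#'   aid for the algebraic reductions).
#' @param jc_identity_cor force every JC channel correlation matrix to
#'   the identity (testing aid).
#' @param prepared optionally, precomputed gene score matrices from
#'   [prepare_scores()] (avoids recomputation across CV splits).
#' @return object of class `prediction_rule`.
#' @export
fit_rule <- function(data, kind = c("eb", "web", "jc"), K,
                     train_reps = NULL, use_covariates = TRUE,
                     rho = NULL, n_bins = NULL, degree = NULL,
                     shrink = c("tweedie", "identity"),
                     w_override = NULL, jc_identity_cor = FALSE,
                     prepared = NULL) {
  kind <- match.arg(kind)
  shrink <- match.arg(shrink)
  stopifnot(inherits(data, "rv_dataset"), K >= 1)
  P <- data$phenotypes
  if (!is.null(train_reps)) P <- P[, train_reps, drop = FALSE]
  if (is.null(prepared)) prepared <- prepare_scores(data)
  covar_all <- if (!is.null(data$covariates))
    as.matrix(data$covariates) else NULL
  covar <- if (use_covariates) covar_all else NULL

  core <- switch(kind,
    eb = fit_core_univariate(prepared$all$X, P, rho, shrink,
                             n_bins, degree),
    web = fit_core_web(prepared, P, rho, shrink, n_bins, degree,
                       w_override, covar_all),
    jc = fit_core_jc(prepared, P, rho, shrink, n_bins, degree,
                     jc_identity_cor))

  n_avail <- length(core$genes)
  if (K > n_avail) {
    warning("K = ", K, " truncated to ", n_avail, " available genes")
    K <- n_avail
  }
  covar_fit <- NULL
  if (!is.null(covar)) covar_fit <- fit_covariate_model(covar, P)
  tau <- if (is.null(covar_fit)) log(core$n2 / core$n1) else 0
  rule <- structure(c(core, list(
    kind = kind, K = K, tau = tau, covar_fit = covar_fit,
    shrink = shrink)), class = "prediction_rule")
  rule_truncate(rule, K)
}

#' Precompute the three gene score matrices for a dataset
#'
#' @param data an [rv_dataset()].
#' @return list with elements `all`, `nonsyn`, `syn` (each a
#'   `gene_score_matrix`; the class-restricted ones may cover fewer
#'   genes).
#' @export
prepare_scores <- function(data) {
  has_n <- any(data$annotation$class == "nonsynonymous")
  has_s <- any(data$annotation$class == "synonymous")
  list(all = madsen_browning_scores(data$genotypes, data$annotation, "all"),
       nonsyn = if (has_n)
         madsen_browning_scores(data$genotypes, data$annotation,
                                "nonsynonymous") else NULL,
       syn = if (has_s)
         madsen_browning_scores(data$genotypes, data$annotation,
                                "synonymous") else NULL)
}

# EB core: one score matrix, rank by |delta_hat|
fit_core_univariate <- function(X, P, rho, shrink, n_bins, degree) {
  zp <- zstat_pipeline(X, P, rho)
  X <- X[, zp$keep, drop = FALSE]
  sp <- shrink_pipeline(zp$zstar, zp$rho, zp$R, shrink, n_bins, degree)
  gs <- pooled_gene_summaries(X, P)
  ord <- order(-abs(sp$delta_hat), zp$keep)
  list(genes = zp$keep[ord],
       delta = sp$delta_hat[ord],
       center = gs$center[ord], scale = gs$scale[ord],
       c_n = gs$c_n, rho = zp$rho, R = zp$R,
       n1 = zp$n1, n2 = zp$n2,
       rank_stat = abs(sp$delta_hat)[ord],
       shrink_models = list(main = sp$model),
       weights = NULL, jc = NULL, fallback = NULL,
       zbar = aggregate_replicates_named(zp))
}

aggregate_replicates_named <- function(zp) stats::setNames(zp$zbar, zp$keep)

# WEB core: weight the two channels per gene, then run the univariate
# pipeline on the weighted scores; single-channel genes fall back
fit_core_web <- function(prepared, P, rho, shrink, n_bins, degree,
                         w_override, covar) {
  Xn <- if (is.null(prepared$nonsyn)) NULL else prepared$nonsyn$X
  Xs <- if (is.null(prepared$syn)) NULL else prepared$syn$X
  if (is.null(Xn) && is.null(Xs)) stop("no classified SNPs for WEB")
  gn <- colnames(Xn); gs_ <- colnames(Xs)
  both <- intersect(gn, gs_)
  only_n <- setdiff(gn, gs_); only_s <- setdiff(gs_, gn)
  genes <- c(both, only_n, only_s)
  nsamp <- nrow(if (is.null(Xn)) Xs else Xn)
  Xw <- matrix(0, nsamp, length(genes),
               dimnames = list(rownames(if (is.null(Xn)) Xs else Xn),
                               genes))
  w <- stats::setNames(rep(NA_real_, length(genes)), genes)
  flagged <- stats::setNames(logical(length(genes)), genes)
  if (length(both)) {
    if (!is.null(w_override)) {
      w[both] <- w_override
    } else {
      y <- as.vector(P)  # phenotypes stacked over training replicates
      smoke <- if (!is.null(covar) && "Smoke" %in% colnames(covar))
        rep(covar[, "Smoke"], ncol(P)) else rep(0, length(y))
      for (g in both) {
        gw <- gene_weight(rep(Xn[, g], ncol(P)), rep(Xs[, g], ncol(P)),
                          y, smoke)
        w[g] <- gw$w; flagged[g] <- gw$flagged
      }
    }
    Xw[, both] <- sweep(Xn[, both, drop = FALSE], 2, w[both], `*`) +
      sweep(Xs[, both, drop = FALSE], 2, 1 - w[both], `*`)
  }
  # fallback: single-channel genes keep their only channel, flagged
  if (length(only_n)) Xw[, only_n] <- Xn[, only_n]
  if (length(only_s)) Xw[, only_s] <- Xs[, only_s]
  fb <- stats::setNames(genes %in% c(only_n, only_s), genes)
  core <- fit_core_univariate(Xw, P, rho, shrink, n_bins, degree)
  core$weights <- w[core$genes]
  core$fallback <- fb[core$genes]
  core
}

# JC core: bivariate channel model; separate shrinkage per channel
fit_core_jc <- function(prepared, P, rho, shrink, n_bins, degree,
                        identity_cor) {
  Xn <- if (is.null(prepared$nonsyn)) NULL else prepared$nonsyn$X
  Xs <- if (is.null(prepared$syn)) NULL else prepared$syn$X
  if (is.null(Xn) && is.null(Xs)) stop("no classified SNPs for JC")
  zp_n <- if (!is.null(Xn)) zstat_pipeline(Xn, P, rho) else NULL
  zp_s <- if (!is.null(Xs)) zstat_pipeline(Xs, P, rho) else NULL
  sp_n <- if (!is.null(zp_n))
    shrink_pipeline(zp_n$zstar, zp_n$rho, zp_n$R, shrink, n_bins, degree)
    else NULL
  sp_s <- if (!is.null(zp_s))
    shrink_pipeline(zp_s$zstar, zp_s$rho, zp_s$R, shrink, n_bins, degree)
    else NULL
  gn <- if (is.null(zp_n)) character(0) else zp_n$keep
  gs_ <- if (is.null(zp_s)) character(0) else zp_s$keep
  genes <- union(gn, gs_)
  dn <- stats::setNames(rep(NA_real_, length(genes)), genes)
  ds <- dn
  if (length(gn)) dn[gn] <- sp_n$delta_hat
  if (length(gs_)) ds[gs_] <- sp_s$delta_hat
  sum_n <- if (!is.null(Xn))
    pooled_gene_summaries(Xn[, gn, drop = FALSE], P) else NULL
  sum_s <- if (!is.null(Xs))
    pooled_gene_summaries(Xs[, gs_, drop = FALSE], P) else NULL
  cn_n <- stats::setNames(rep(NA_real_, length(genes)), genes)
  sc_n <- cn_n; cn_s <- cn_n; sc_s <- cn_n
  if (length(gn)) { cn_n[gn] <- sum_n$center; sc_n[gn] <- sum_n$scale }
  if (length(gs_)) { cn_s[gs_] <- sum_s$center; sc_s[gs_] <- sum_s$scale }
  # pooled within-class channel correlation per gene (stacked replicates)
  r <- stats::setNames(rep(0, length(genes)), genes)
  both <- intersect(gn, gs_)
  if (length(both) && !identity_cor) {
    ystack <- as.vector(P)
    # class labels and channel values stacked over replicates
    for (g in both)
      r[g] <- estimate_gene_correlation(rep(Xn[, g], ncol(P)),
                                        rep(Xs[, g], ncol(P)), ystack)
  }
  fb <- stats::setNames(!(genes %in% both), genes)
  rank_stat <- vapply(genes, function(g) {
    if (g %in% both)
      (dn[g]^2 - 2 * r[g] * dn[g] * ds[g] + ds[g]^2) / (1 - r[g]^2)
    else if (is.na(ds[g])) dn[g]^2 else ds[g]^2
  }, numeric(1))
  ord <- order(-rank_stat, genes)
  cs <- if (!is.null(sum_n)) sum_n$c_n else sum_s$c_n
  zp0 <- if (!is.null(zp_n)) zp_n else zp_s
  list(genes = genes[ord], delta = NULL,
       center = NULL, scale = NULL,
       c_n = cs, rho = zp0$rho, R = zp0$R, n1 = zp0$n1, n2 = zp0$n2,
       rank_stat = rank_stat[ord],
       shrink_models = list(nonsyn = sp_n$model, syn = sp_s$model),
       weights = NULL,
       jc = list(delta_n = dn[genes[ord]], delta_s = ds[genes[ord]],
                 center_n = cn_n[genes[ord]], center_s = cn_s[genes[ord]],
                 scale_n = sc_n[genes[ord]], scale_s = sc_s[genes[ord]],
                 r = r[genes[ord]]),
       fallback = fb[genes[ord]],
       zbar = NULL)
}

# logistic covariate model on phenotypes stacked across replicates
fit_covariate_model <- function(covar, P) {
  y <- as.vector(P)
  X <- cbind(`(Intercept)` = 1,
             covar[rep(seq_len(nrow(covar)), ncol(P)), , drop = FALSE])
  fit <- suppressWarnings(stats::glm.fit(X, y, family = binomial()))
  stats::setNames(fit$coefficients, colnames(X))
}

#' Truncate a fitted rule to its top K genes
#'
#' Cheap re-selection along the fitted ranking; used by the
#' cross-validation loop to sweep the gene-number grid without refitting.
#'
#' @param rule a `prediction_rule`.
#' @param K new (smaller or equal) number of genes.
#' @export
rule_truncate <- function(rule, K) {
  stopifnot(K >= 1, K <= length(rule$genes))
  idx <- seq_len(K)
  rule$K <- K
  rule$genes <- rule$genes[idx]
  rule$rank_stat <- rule$rank_stat[idx]
  for (f in c("delta", "center", "scale", "weights", "fallback"))
    if (!is.null(rule[[f]])) rule[[f]] <- rule[[f]][idx]
  if (!is.null(rule$jc))
    rule$jc <- lapply(rule$jc, `[`, idx)
  rule
}

#' @export
print.prediction_rule <- function(x, ...) {
  cat("prediction_rule [", toupper(x$kind), "]: ", x$K, " genes, tau = ",
      format(x$tau, digits = 4),
      if (is.null(x$covar_fit)) ", no covariates" else ", with covariates",
      "\n", sep = "")
  invisible(x)
}

# per-gene discriminant contribution matrix (n x K) for a rule applied to
# precomputed score matrices
gene_contributions <- function(rule, prepared) {
  n <- nrow(prepared$all$X)
  K <- length(rule$genes)
  M <- matrix(0, n, K, dimnames = list(rownames(prepared$all$X),
                                       rule$genes))
  if (rule$kind == "eb") {
    X <- prepared$all$X[, rule$genes, drop = FALSE]
    U <- sweep(sweep(X, 2, rule$center), 2, rule$scale, `/`)
    M <- sweep(U, 2, rule$delta * rule$c_n, `*`)
  } else if (rule$kind == "web") {
    Xn <- prepared$nonsyn$X; Xs <- prepared$syn$X
    for (k in seq_len(K)) {
      g <- rule$genes[k]
      x <- if (rule$fallback[k]) {
        if (!is.null(Xn) && g %in% colnames(Xn)) Xn[, g] else Xs[, g]
      } else weighted_score(Xn[, g], Xs[, g], rule$weights[k])
      M[, k] <- rule$delta[k] * rule$c_n * (x - rule$center[k]) /
        rule$scale[k]
    }
  } else {  # jc
    Xn <- if (is.null(prepared$nonsyn)) NULL else prepared$nonsyn$X
    Xs <- if (is.null(prepared$syn)) NULL else prepared$syn$X
    jc <- rule$jc
    for (k in seq_len(K)) {
      g <- rule$genes[k]
      has_n <- !is.na(jc$delta_n[k]); has_s <- !is.na(jc$delta_s[k])
      un <- if (has_n) (Xn[, g] - jc$center_n[k]) / jc$scale_n[k] else NULL
      us <- if (has_s) (Xs[, g] - jc$center_s[k]) / jc$scale_s[k] else NULL
      M[, k] <- if (has_n && has_s) {
        r <- jc$r[k]
        rule$c_n / (1 - r^2) *
          (jc$delta_n[k] * (un - r * us) + jc$delta_s[k] * (us - r * un))
      } else if (has_n) rule$c_n * jc$delta_n[k] * un
        else rule$c_n * jc$delta_s[k] * us
    }
  }
  M
}

#' Evaluate the discriminant of a fitted rule
#'
#' The gene part is the shrunken diagonal-LDA sum
#' \eqn{\sum_{i \in S} \hat\delta_i\, c_n\, (x_i - \hat m_i)/\hat\sigma_i}
#' (for the JC rule the per-gene term is the bivariate quadratic-form
#' analogue); the covariate part, when present, is the fitted logistic
#' linear predictor including its intercept.
#'
#' @param rule a `prediction_rule`.
#' @param data an [rv_dataset()] with the individuals to score.
#' @param prepared optional precomputed [prepare_scores()] output for
#'   `data`.
#' @return numeric vector of discriminant values (one per individual).
#' @export
discriminant <- function(rule, data, prepared = NULL) {
  if (is.null(prepared)) prepared <- prepare_scores(data)
  gene_part <- rowSums(gene_contributions(rule, prepared))
  if (!is.null(rule$covar_fit)) {
    X <- cbind(1, as.matrix(data$covariates))
    gene_part <- gene_part + as.vector(X %*% rule$covar_fit)
  }
  gene_part
}

#' Predict disease status with a fitted rule
#'
#' An individual is labelled a case when the discriminant exceeds the
#' rule's threshold: `tau = log(n2/n1)` from the training replicates when
#' no covariate model is attached (accounting for case/control
#' imbalance), and 0 when the logistic intercept already encodes the
#' prevalence. The continuous discriminant is returned for ROC analysis.
#'
#' @param object a `prediction_rule`.
#' @param data an [rv_dataset()] to score.
#' @param prepared optional precomputed score matrices.
#' @param ... unused.
#' @return list with `score` (continuous) and `label` (0/1 integer).
#' @export
predict.prediction_rule <- function(object, data, prepared = NULL, ...) {
  sc <- discriminant(object, data, prepared)
  list(score = sc, label = as.integer(sc > object$tau))
}

#' Serialize a fitted rule to JSON
#'
#' Versioned plain-text representation of everything needed to apply the
#' rule: kind, gene subset with per-gene effects/centers/scales, JC
#' blocks, covariate coefficients, threshold and shrinkage coefficients.
#'
#' @param rule a `prediction_rule`.
#' @param path output JSON path.
#' @export
save_rule <- function(rule, path) {
  ser <- rule
  ser$shrink_models <- lapply(rule$shrink_models, function(m)
    if (is.null(m)) NULL else m[c("coef", "degree", "center", "scale",
                                  "breaks", "bin_width")])
  ser$format_version <- 1L
  jsonlite::write_json(unclass(ser), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_rule
#' @export
load_rule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$format_version <- NULL
  for (f in c("delta", "center", "scale", "rank_stat", "weights"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.numeric(obj[[f]])
  structure(obj, class = "prediction_rule")
}

#' Write predictions as TSV
#'
#' @param pred output of [predict.prediction_rule()].
#' @param sample_ids individual identifiers.
#' @param path output TSV path.
#' @export
write_predictions <- function(pred, sample_ids, path) {
  write.table(data.frame(sample_id = sample_ids, score = pred$score,
                         label = pred$label),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
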