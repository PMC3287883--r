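# evaluate expr under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Randomly split replicates into train / test / validation sets
#'
#' Disjoint index sets of the requested sizes, mirroring the 50/50/100
#' split of 200 phenotype replicates used for gene-number selection:
#' Z statistics and shrinkage come from the training replicates, the
#' gene-number grid is scored on the test replicates, and the chosen rule
#' is assessed once on the validation replicates.
#'
#' @param R_total number of available replicates.
#' @param sizes integer vector `c(train, test, validation)`; must sum to
#'   at most `R_total`.
#' @param seed optional seed (the caller's RNG stream is preserved).
#' @return list with integer vectors `train`, `test`, `validation`.
#' @export
split_replicates <- function(R_total, sizes = c(50, 50, 100),
                             seed = NULL) {
  stopifnot(length(sizes) == 3, all(sizes >= 1))
  if (sum(sizes) > R_total)
    stop("split sizes sum to ", sum(sizes), " > ", R_total,
         " available replicates")
  idx <- with_seed(seed, sample.int(R_total, sum(sizes)))
  list(train = sort(idx[seq_len(sizes[1])]),
       test = sort(idx[sizes[1] + seq_len(sizes[2])]),
       validation = sort(idx[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

#' Misclassification error
#'
#' @param pred,truth 0/1 vectors of equal length.
#' @return fraction of disagreements in `[0, 1]`.
#' @export
misclassification_error <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  mean(as.integer(pred) != as.integer(truth))
}

#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney pairwise formulation (probability that a
#' random case outscores a random control, ties counted 1/2), computed
#' from midranks; ROC points are emitted at every distinct threshold.
#'
#' @param scores continuous risk scores.
#' @param labels 0/1 true status.
#' @return list with `auc` and `points` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("need both cases and controls")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each threshold
  tpr <- cumsum(y)[keep] / n1
  fpr <- cumsum(1 - y)[keep] / n0
  list(auc = auc,
       points = data.frame(threshold = c(Inf, s[keep]),
                           fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Replicate-split cross-validation of the gene number
#'
#' For each of `n_splits` random splits of the phenotype replicates:
#' fit the rule on the training replicates at the largest grid value,
#' sweep the gene-number grid by truncating the fitted ranking, score
#' each grid value by mean misclassification over the test replicates,
#' pick `K*` at the minimum (smallest K on ties), and report
#' misclassification and AUC of the K*-gene rule on the validation
#' replicates. Means and standard errors are over the splits
#' (`sd / sqrt(n_splits)`). Nothing fitted ever sees test or validation
#' phenotypes; genotypes and covariates are shared by construction.
#'
#' @param data an [rv_dataset()].
#' @param kind model kind passed to [fit_rule()].
#' @param K_grid candidate gene numbers (default 1..50, capped at the
#'   number of available genes).
#' @param n_splits number of repeated random splits.
#' @param split_sizes `c(train, test, validation)` replicate counts;
#'   default splits the available replicates roughly 1/4, 1/4, 1/2 like
#'   the 50/50/100 reference design.
#' @param seed seed for the split randomization.
#' @param ... further arguments to [fit_rule()] (e.g. `use_covariates`,
#'   `shrink`, `n_bins`, `degree`).
#' @return list of class `cv_result`: per-split error curves, chosen
#'   `K_star`, validation error and AUC with means and SEs.
#' @export
cross_validate <- function(data, kind = c("eb", "web", "jc"),
                           K_grid = 1:50, n_splits = 5,
                           split_sizes = NULL, seed = NULL, ...) {
  kind <- match.arg(kind)
  stopifnot(length(K_grid) >= 1)
  R_total <- ncol(data$phenotypes)
  if (is.null(split_sizes)) {
    tr <- max(1, floor(R_total / 4))
    te <- max(1, floor(R_total / 4))
    split_sizes <- c(tr, te, max(1, R_total - tr - te))
  }
  if (R_total < 3 && sum(split_sizes) > R_total)
    stop("need at least 3 replicates for a train/test/validation split")
  prepared <- prepare_scores(data)
  splits <- with_seed(seed, lapply(seq_len(n_splits), function(i)
    split_replicates(R_total, split_sizes)))
  per_split <- lapply(splits, function(sp) {
    rule_full <- fit_rule(data, kind, K = max(K_grid),
                          train_reps = sp$train, prepared = prepared, ...)
    K_grid_use <- K_grid[K_grid <= length(rule_full$genes)]
    M <- gene_contributions(rule_full, prepared)
    cum <- t(apply(M, 1, cumsum))   # n x Kmax discriminants
    if (!is.null(rule_full$covar_fit)) {
      cp <- as.vector(cbind(1, as.matrix(data$covariates)) %*%
                        rule_full$covar_fit)
      cum <- cum + cp
    }
    P <- data$phenotypes
    test_err <- vapply(K_grid_use, function(K) {
      pred <- as.integer(cum[, K] > rule_full$tau)
      mean(vapply(sp$test, function(r)
        misclassification_error(pred, P[, r]), numeric(1)))
    }, numeric(1))
    K_star <- K_grid_use[which.min(test_err)]  # ties -> smallest K
    sc <- cum[, K_star]
    pred <- as.integer(sc > rule_full$tau)
    val_err <- mean(vapply(sp$validation, function(r)
      misclassification_error(pred, P[, r]), numeric(1)))
    val_auc <- mean(vapply(sp$validation, function(r)
      roc_auc(sc, P[, r])$auc, numeric(1)))
    list(split = sp, K_grid = K_grid_use, test_error = test_err,
         K_star = K_star, val_error = val_err, val_auc = val_auc,
         genes = rule_full$genes[seq_len(K_star)], scores = sc)
  })
  val_err <- vapply(per_split, `[[`, numeric(1), "val_error")
  val_auc <- vapply(per_split, `[[`, numeric(1), "val_auc")
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  structure(list(kind = kind, splits = per_split,
                 K_star = vapply(per_split, `[[`, numeric(1), "K_star"),
                 val_error_mean = mean(val_err), val_error_se = se(val_err),
                 val_auc_mean = mean(val_auc), val_auc_se = se(val_auc)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result [", toupper(x$kind), "]: ", length(x$splits),
      " split(s); K* = ", paste(x$K_star, collapse = "/"),
      "; validation error ", format(x$val_error_mean, digits = 3),
      " (SE ", format(x$val_error_se, digits = 2),
      "), AUC ", format(x$val_auc_mean, digits = 3),
      " (SE ", format(x$val_auc_se, digits = 2), ")\n", sep = "")
  invisible(x)
}

#' Write a cv_result to JSON
#'
#' @param cv a `cv_result`.
#' @param path output path.
#' @export
write_cv_result <- function(cv, path) {
  out <- list(kind = cv$kind, K_star = cv$K_star,
              val_error_mean = cv$val_error_mean,
              val_error_se = cv$val_error_se,
              val_auc_mean = cv$val_auc_mean,
              val_auc_se = cv$val_auc_se,
              splits = lapply(cv$splits, function(s)
                s[c("K_grid", "test_error", "K_star", "val_error",
                    "val_auc", "genes")]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write ROC points for external plotting
#'
#' @param roc output of [roc_auc()].
#' @param path output TSV path.
#' @export
write_roc_points <- function(roc, path) {
  write.table(roc$points, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
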