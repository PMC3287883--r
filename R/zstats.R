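#' Two-sample Z statistic for one gene score
#'
#' \deqn{Z = (\bar x_{case} - \bar x_{control}) /
#'   (\hat\sigma \sqrt{1/n_1 + 1/n_2})}
#' with the pooled unbiased standard deviation (divisor `n1 + n2 - 2`).
#' Under a common-variance two-group model, Z is approximately N(delta, 1)
#' where delta is the standardized group difference.
#'
#' @param scores numeric vector of per-individual gene scores.
#' @param labels 0/1 vector (1 = case).
#' @return list with `z`, `mean_case`, `mean_control`, `pooled_sd`,
#'   `c_n` (`sqrt(1/n1 + 1/n2)`), `n1`, `n2`, `degenerate`.
#' @export
two_sample_z <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n2 <- sum(labels == 0L)
  if (n1 == 0 || n2 == 0) stop("both classes must be non-empty")
  x1 <- scores[labels == 1L]; x2 <- scores[labels == 0L]
  m1 <- mean(x1); m2 <- mean(x2)
  ss <- sum((x1 - m1)^2) + sum((x2 - m2)^2)
  s <- sqrt(ss / (n1 + n2 - 2))
  c_n <- sqrt(1 / n1 + 1 / n2)
  degen <- s == 0
  list(z = if (degen) NA_real_ else (m1 - m2) / (s * c_n),
       mean_case = m1, mean_control = m2, pooled_sd = s, c_n = c_n,
       n1 = n1, n2 = n2, degenerate = degen)
}

# vectorized two-sample Z over the columns of a score matrix
gene_zstats <- function(X, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n2 <- sum(labels == 0L)
  if (n1 == 0 || n2 == 0) stop("both classes must be non-empty")
  m1 <- colMeans(X[labels == 1L, , drop = FALSE])
  m2 <- colMeans(X[labels == 0L, , drop = FALSE])
  ss1 <- colSums(X[labels == 1L, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(X[labels == 0L, , drop = FALSE]^2) - n2 * m2^2
  s <- sqrt(pmax(ss1 + ss2, 0) / (n1 + n2 - 2))
  c_n <- sqrt(1 / n1 + 1 / n2)
  z <- ifelse(s > 0, (m1 - m2) / (s * c_n), NA_real_)
  list(z = z, mean_case = m1, mean_control = m2, pooled_sd = s,
       c_n = c_n, n1 = n1, n2 = n2, degenerate = s == 0)
}

#' Per-gene Z statistics across phenotype replicates
#'
#' Applies the two-sample Z to every gene score column for each replicate
#' column of the phenotype matrix. Genes degenerate (zero pooled variance)
#' in any replicate are flagged and get NA there.
#'
#' @param X individuals x genes score matrix.
#' @param phenotypes 0/1 matrix, individuals x replicates.
#' @return list with `Z` (genes x replicates), `degenerate` (logical per
#'   gene), `c_n` (per replicate), `n1`, `n2` (per replicate).
#' @export
replicate_zstats <- function(X, phenotypes) {
  P <- as.matrix(phenotypes)
  R <- ncol(P)
  Z <- matrix(NA_real_, ncol(X), R,
              dimnames = list(colnames(X), colnames(P)))
  c_n <- n1 <- n2 <- numeric(R)
  for (r in seq_len(R)) {
    zs <- gene_zstats(X, P[, r])
    Z[, r] <- zs$z
    c_n[r] <- zs$c_n; n1[r] <- zs$n1; n2[r] <- zs$n2
  }
  list(Z = Z, degenerate = apply(Z, 1, anyNA), c_n = c_n,
       n1 = n1, n2 = n2)
}

#' Average Z statistics across replicates
#'
#' The per-gene mean \eqn{\bar Z_i} of the replicate Z values is a better
#' estimate of the standardized effect delta_i than any single replicate's
#' Z, but no longer has unit variance when replicates are correlated.
#'
#' @param Z genes x replicates matrix.
#' @return per-gene mean vector.
#' @export
aggregate_replicates <- function(Z) rowMeans(as.matrix(Z))

#' Estimate the inter-replicate correlation rho
#'
#' Replicates share a fixed genotype panel, so a gene's Z values are
#' positively correlated across replicates. Under the exchangeable model
#' `Z_ir = delta_i + eps_ir` with unit-variance errors and pairwise
#' correlation rho, the across-replicate sample variance of each gene has
#' expectation `1 - rho` regardless of delta_i, giving the moment
#' estimator
#' \deqn{\hat\rho = 1 - \mathrm{mean}_i\, s^2_i,}
#' clipped to `[0, 1]` against sampling noise.
#'
#' @param Z genes x replicates matrix (R >= 2, >= 2 genes).
#' @return scalar rho estimate in `[0, 1]`.
#' @export
estimate_rho <- function(Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) < 2)
    stop("rho not estimable from a single replicate; supply rho explicitly")
  if (nrow(Z) < 2) stop("need at least two genes to estimate rho")
  s2 <- apply(Z, 1, var)
  min(max(1 - mean(s2, na.rm = TRUE), 0), 1)
}

#' Standardize averaged Z values to unit variance
#'
#' Under the exchangeable-correlation model, `Var(zbar) =
#' (1 + (R-1) rho) / R`; dividing by its square root restores variance 1
#' so the empirical Bayes shrinker can be applied directly.
#'
#' @param zbar per-gene mean Z vector.
#' @param rho inter-replicate correlation in `[0, 1]`.
#' @param R number of replicates averaged.
#' @return standardized vector `zstar`.
#' @export
standardize_zbar <- function(zbar, rho, R) {
  stopifnot(rho >= 0, rho <= 1, R >= 1)
  zbar / sqrt((1 + (R - 1) * rho) / R)
}

#' Map shrunken standardized values back to the zbar scale
#'
#' Shrinking `zstar` estimates its expectation `delta_i / sqrt((1 +
#' (R-1) rho)/R)`; multiplying back by the standardization factor returns
#' Bayes estimates of delta_i itself, ready for the discriminant rule.
#' `rescale_shrunken(standardize_zbar(x, rho, R), rho, R) == x`.
#'
#' @param shrunk_zstar shrunken standardized values.
#' @inheritParams standardize_zbar
#' @return effect estimates `delta_hat` on the original Z scale.
#' @export
rescale_shrunken <- function(shrunk_zstar, rho, R) {
  stopifnot(rho >= 0, rho <= 1, R >= 1)
  shrunk_zstar * sqrt((1 + (R - 1) * rho) / R)
}

#' Write per-replicate Z statistics and their aggregate summary
#'
#' `path` gets the long-format table `gene_id<TAB>rep<TAB>Z`; the sidecar
#' `<stem>_summary.tsv` holds zbar, zstar and delta_hat per gene with the
#' scalar rho estimate in a `#` header comment.
#'
#' @param Z genes x replicates matrix.
#' @param zbar,zstar,delta_hat per-gene summary vectors.
#' @param rho scalar correlation estimate.
#' @param path output TSV path.
#' @export
write_zstats <- function(Z, zbar, zstar, delta_hat, rho, path) {
  long <- data.frame(gene_id = rep(rownames(Z), ncol(Z)),
                     rep = rep(colnames(Z), each = nrow(Z)),
                     Z = as.vector(Z))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", "_summary.tsv", path)
  con <- file(side, "w")
  writeLines(paste0("# rho = ", format(rho, digits = 10)), con)
  write.table(data.frame(gene_id = rownames(Z), zbar = zbar,
                         zstar = zstar, delta_hat = delta_hat),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
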