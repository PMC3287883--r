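#' Empirical minor allele frequency
#'
#' Allele count divided by `2n`, optionally folded to `min(q, 1 - q)` so
#' the counted allele is always the minor one. Monomorphic columns give 0.
#'
#' @param g integer vector of allele counts in \{0,1,2\}.
#' @param fold fold frequencies above 0.5 onto the minor allele.
#' @return frequency in `[0, 0.5]` when folded, `[0, 1]` otherwise.
#' @export
empirical_maf <- function(g, fold = TRUE) {
  q <- sum(g) / (2 * length(g))
  if (fold) q <- min(q, 1 - q)
  q
}

#' Madsen-Browning gene burden scores
#'
#' For each gene i and individual j the score is
#' \deqn{X_{ij} = \sum_{l \in gene\,i} G'_{lj} / \sqrt{n \hat q_l (1 - \hat q_l)},}
#' the sum of rare-allele counts weighted inversely by the binomial
#' standard deviation of each SNP's empirical minor allele frequency
#' \eqn{\hat q_l}, so rarer variants are up-weighted. MAF is estimated on
#' all `n` individuals (genotypes are shared across phenotype replicates,
#' so the weights are replicate-independent). SNPs whose unfolded
#' frequency exceeds 0.5 are folded (`G' = 2 - G`, `q' = 1 - q`) so the
#' rare allele is always the one counted. Monomorphic SNPs carry no
#' information and are excluded; genes left without a polymorphic
#' qualifying SNP are omitted (not zero-filled) and reported.
#'
#' @param dataset a [genotype_dataset()].
#' @param annotation an [annotation_table()] covering the dataset's SNPs.
#' @param class_filter restrict to one functional class, or use all SNPs.
#' @param pseudocount add `1/(2n+2)` to each MAF estimate instead of
#'   excluding monomorphic SNPs (off by default).
#' @return list of class `gene_score_matrix` with fields `X` (individuals
#'   x genes), `gene_ids`, `class_filter`, `maf` (per used SNP, folded),
#'   `snp_info` (per-SNP gene, class, maf, weight) and `dropped_genes`.
#' @export
madsen_browning_scores <- function(dataset, annotation,
                                   class_filter = c("all", "synonymous",
                                                    "nonsynonymous"),
                                   pseudocount = FALSE) {
  class_filter <- match.arg(class_filter)
  stopifnot(inherits(dataset, "genotype_dataset"))
  ann <- annotation[annotation$snp_id %in% dataset$snp_ids, , drop = FALSE]
  if (class_filter != "all")
    ann <- ann[ann$class == class_filter, , drop = FALSE]
  all_genes <- unique(ann$gene_id)
  if (nrow(ann) == 0)
    stop("no SNPs pass the class filter '", class_filter, "'")
  n <- dataset$n
  G <- dataset$G[, ann$snp_id, drop = FALSE]
  q_raw <- colSums(G) / (2 * n)
  folded <- q_raw > 0.5
  if (any(folded)) G[, folded] <- 2L - G[, folded]
  q <- ifelse(folded, 1 - q_raw, q_raw)
  if (pseudocount) q <- q + 1 / (2 * n + 2)
  poly <- q > 0 & q < 1
  if (!any(poly))
    stop("all qualifying SNPs are monomorphic")
  ann <- ann[poly, , drop = FALSE]
  G <- G[, poly, drop = FALSE]
  q <- q[poly]
  w <- 1 / sqrt(n * q * (1 - q))
  # column sums by gene via rowsum on the transposed weighted counts:
  # O(n * SNPs), much cheaper than a dense SNP-by-gene matmul
  gene <- factor(ann$gene_id, levels = unique(ann$gene_id))
  Gw <- sweep(G, 2, w, `*`)
  X <- t(rowsum(t(Gw), gene, reorder = FALSE))
  rownames(X) <- dataset$sample_ids
  dropped <- setdiff(all_genes, levels(gene))
  if (length(dropped))
    message(length(dropped), " gene(s) without polymorphic ",
            class_filter, " SNPs omitted")
  structure(list(X = X, gene_ids = colnames(X),
                 class_filter = class_filter,
                 maf = stats::setNames(q, ann$snp_id),
                 snp_info = data.frame(snp_id = ann$snp_id,
                                       gene_id = ann$gene_id,
                                       class = ann$class,
                                       maf = q, weight = w,
                                       stringsAsFactors = FALSE),
                 dropped_genes = dropped),
            class = "gene_score_matrix")
}

#' @export
print.gene_score_matrix <- function(x, ...) {
  cat("gene_score_matrix (", x$class_filter, "): ", nrow(x$X),
      " individuals x ", ncol(x$X), " genes\n", sep = "")
  invisible(x)
}

#' Write gene scores and a per-gene SNP summary
#'
#' Emits `gene_scores.tsv` (`sample_id` + one column per gene) and a
#' sidecar `<stem>_snps.tsv` with each used SNP's gene, class, folded MAF
#' and weight.
#'
#' @param scores a `gene_score_matrix`.
#' @param path output TSV path; the sidecar replaces `.tsv` with
#'   `_snps.tsv`.
#' @export
write_gene_scores <- function(scores, path) {
  df <- data.frame(sample_id = rownames(scores$X), scores$X,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", "_snps.tsv", path)
  write.table(scores$snp_info, side, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
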