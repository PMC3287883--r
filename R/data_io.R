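#' @importFrom stats var sd quantile pnorm qnorm dnorm rnorm rbinom runif
#'   rbeta glm binomial poisson coef predict uniroot setNames ave
#' @importFrom utils read.delim write.table modifyList
NULL

#' Genotype dataset container
#'
#' Bundles a minor-allele count matrix (individuals x SNPs, entries 0/1/2)
#' with its sample and SNP identifiers. The row order of the genotype file
#' is canonical: phenotype and covariate tables are aligned to it by
#' sample id.
#'
#' @param G integer matrix of minor-allele counts, one row per individual.
#' @param sample_ids character vector of unique individual identifiers.
#' @param snp_ids character vector of unique SNP identifiers.
#' @return An object of class `genotype_dataset` with fields `G`,
#'   `sample_ids`, `snp_ids` and `n` (number of individuals).
#' @export
genotype_dataset <- function(G, sample_ids, snp_ids) {
  G <- as.matrix(G)
  if (nrow(G) != length(sample_ids))
    stop("row count (", nrow(G), ") != number of sample ids (",
         length(sample_ids), ")")
  if (ncol(G) != length(snp_ids))
    stop("column count (", ncol(G), ") != number of snp ids (",
         length(snp_ids), ")")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(snp_ids)) stop("duplicate snp ids")
  bad <- which(!(G %in% c(0L, 1L, 2L)) | is.na(G))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(G)) + 1
    j <- ((bad[1] - 1) %/% nrow(G)) + 1
    stop("genotype out of range {0,1,2} at sample '", sample_ids[i],
         "', SNP '", snp_ids[j], "' (value ", G[bad[1]], ")")
  }
  storage.mode(G) <- "integer"
  dimnames(G) <- list(sample_ids, snp_ids)
  structure(list(G = G, sample_ids = as.character(sample_ids),
                 snp_ids = as.character(snp_ids), n = nrow(G)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", x$n, "individuals x", length(x$snp_ids),
      "SNPs\n")
  invisible(x)
}

#' Read a genotype TSV
#'
#' Expects a header line `sample_id<TAB>snp1<TAB>...` followed by one row
#' per individual of integer minor-allele counts in \{0,1,2\}. Entries equal
#' to `missing_code` are imputed to 0 (homozygous common) with a warning
#' giving the imputed count; this is conservative for burden scores.
#'
#' @param path path to the TSV file.
#' @param missing_code optional token (e.g. `"NA"` or `"."`) marking
#'   missing genotypes.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, missing_code = NULL) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   comment.char = "#",
                   na.strings = if (is.null(missing_code)) character(0)
                                else missing_code)
  if (ncol(df) < 2 || names(df)[1] != "sample_id")
    stop("genotype file must have header 'sample_id<TAB><snp ids...>'")
  sample_ids <- df[[1]]
  snp_ids <- names(df)[-1]
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.null(missing_code)) {
    miss <- is.na(M)
    n_miss <- sum(miss)
    if (n_miss > 0) {
      warning("imputed ", n_miss, " missing genotype(s) to 0")
      M[miss] <- "0"
    }
  }
  num <- suppressWarnings(as.numeric(M))
  bad <- which(is.na(num) | num != round(num) | num < 0 | num > 2)
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(M)) + 1
    j <- ((bad[1] - 1) %/% nrow(M)) + 1
    stop("invalid genotype entry '", M[bad[1]], "' at sample '",
         sample_ids[i], "', SNP '", snp_ids[j], "'")
  }
  G <- matrix(as.integer(num), nrow = nrow(M))
  genotype_dataset(G, sample_ids, snp_ids)
}

#' Write a genotype TSV
#'
#' Inverse of [read_genotypes()]; `read_genotypes(write_genotypes(x, f))`
#' reproduces `x` exactly.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path.
#' @export
write_genotypes <- function(dataset, path) {
  df <- data.frame(sample_id = dataset$sample_ids,
                   dataset$G, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP annotation TSV
#'
#' Expects header `snp_id<TAB>gene_id<TAB>class` with `class` one of
#' `synonymous` / `nonsynonymous`.
#'
#' @param path path to the TSV file.
#' @return A data.frame of class `annotation_table` with columns
#'   `snp_id`, `gene_id`, `class`.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, colClasses = "character", comment.char = "#")
  req <- c("snp_id", "gene_id", "class")
  if (!all(req %in% names(df)))
    stop("annotation file must have columns ", paste(req, collapse = ", "))
  annotation_table(df$snp_id, df$gene_id, df$class)
}

#' @rdname read_annotation
#' @param snp_id,gene_id,class vectors defining the annotation directly.
#' @export
annotation_table <- function(snp_id, gene_id, class) {
  if (anyDuplicated(snp_id)) stop("duplicate snp_id in annotation")
  ok <- class %in% c("synonymous", "nonsynonymous")
  if (!all(ok))
    stop("unknown functional class token(s): ",
         paste(unique(class[!ok]), collapse = ", "))
  structure(data.frame(snp_id = as.character(snp_id),
                       gene_id = as.character(gene_id),
                       class = as.character(class),
                       stringsAsFactors = FALSE),
            class = c("annotation_table", "data.frame"))
}

#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read binary phenotype replicates
#'
#' Expects header `sample_id<TAB>rep1<TAB>...`; each replicate column is a
#' 0/1 disease status redrawn on the same individuals. Every replicate
#' must contain both cases and controls.
#'
#' @param path path to the TSV file.
#' @param sample_ids optional canonical sample order (from the genotype
#'   file); rows are reordered to it and ids must match exactly.
#' @return 0/1 integer matrix, individuals x replicates, of class
#'   `phenotype_replicates`.
#' @export
read_phenotypes <- function(path, sample_ids = NULL) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  if (names(df)[1] != "sample_id")
    stop("phenotype file must have header 'sample_id<TAB>rep...'")
  P <- as.matrix(df[, -1, drop = FALSE])
  rownames(P) <- df$sample_id
  P <- align_rows(P, df$sample_id, sample_ids, "phenotype")
  phenotype_replicates(P)
}

#' @rdname read_phenotypes
#' @param P 0/1 matrix of disease status, one column per replicate.
#' @export
phenotype_replicates <- function(P) {
  P <- as.matrix(P)
  if (ncol(P) < 1) stop("need at least one replicate column")
  if (!all(P %in% c(0, 1)))
    stop("phenotype values must be 0 or 1")
  n_case <- colSums(P)
  if (any(n_case == 0))
    stop("no cases in replicate ", which(n_case == 0)[1])
  if (any(n_case == nrow(P)))
    stop("no controls in replicate ", which(n_case == nrow(P))[1])
  storage.mode(P) <- "integer"
  if (is.null(colnames(P))) colnames(P) <- paste0("rep", seq_len(ncol(P)))
  structure(P, class = c("phenotype_replicates", class(matrix())))
}

#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- data.frame(sample_id = rownames(phenotypes),
                   unclass(phenotypes), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-individual covariates
#'
#' Expects header `sample_id<TAB>Age<TAB>Sex<TAB>Smoke...`; arbitrary
#' extra numeric columns are kept. Rows are aligned to the canonical
#' genotype sample order; missing values are rejected.
#'
#' @inheritParams read_phenotypes
#' @return numeric data.frame with `sample_id`s as row names.
#' @export
read_covariates <- function(path, sample_ids = NULL) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  if (names(df)[1] != "sample_id")
    stop("covariate file must have header 'sample_id<TAB>...'")
  C <- as.matrix(df[, -1, drop = FALSE])
  rownames(C) <- df$sample_id
  C <- align_rows(C, df$sample_id, sample_ids, "covariate")
  if (!is.numeric(C) || anyNA(C))
    stop("covariates must be numeric with no missing values")
  as.data.frame(C)
}

#' @export
write_covariates <- function(covariates, path) {
  df <- data.frame(sample_id = rownames(covariates), covariates,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# reorder a matrix's rows to the canonical sample order, erroring on
# any id mismatch
align_rows <- function(M, ids, sample_ids, what) {
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", what, " file")
  if (is.null(sample_ids)) return(M)
  if (!setequal(ids, sample_ids))
    stop(what, " sample ids do not match genotype sample ids")
  M[match(sample_ids, ids), , drop = FALSE]
}

#' Assemble an analysis dataset
#'
#' Joins the four inputs and checks their mutual consistency. SNPs without
#' annotation are excluded from the genotype matrix with a message giving
#' the count; annotated SNPs absent from the genotypes are an error.
#'
#' @param genotypes a [genotype_dataset()].
#' @param annotation an [annotation_table()].
#' @param phenotypes a [phenotype_replicates()] matrix.
#' @param covariates optional covariate data.frame (row order must match
#'   `genotypes$sample_ids`).
#' @return list of class `rv_dataset`.
#' @export
rv_dataset <- function(genotypes, annotation, phenotypes,
                       covariates = NULL) {
  stopifnot(inherits(genotypes, "genotype_dataset"))
  missing_geno <- setdiff(annotation$snp_id, genotypes$snp_ids)
  if (length(missing_geno))
    stop(length(missing_geno), " annotated SNP(s) absent from genotypes, ",
         "e.g. ", missing_geno[1])
  unannot <- setdiff(genotypes$snp_ids, annotation$snp_id)
  if (length(unannot)) {
    message("excluding ", length(unannot), " unannotated SNP(s)")
    keep <- setdiff(genotypes$snp_ids, unannot)
    genotypes <- genotype_dataset(genotypes$G[, keep, drop = FALSE],
                                  genotypes$sample_ids, keep)
  }
  if (nrow(phenotypes) != genotypes$n)
    stop("phenotype rows do not match genotype rows")
  if (!is.null(covariates) && nrow(covariates) != genotypes$n)
    stop("covariate rows do not match genotype rows")
  structure(list(genotypes = genotypes, annotation = annotation,
                 phenotypes = phenotypes, covariates = covariates),
            class = "rv_dataset")
}

#' Load an rv_dataset from a directory of TSVs
#'
#' Reads `genotypes.tsv`, `annotation.tsv`, `phenotypes.tsv` and (if
#' present) `covariates.tsv` from `dir`, aligning all tables to the
#' genotype sample order.
#'
#' @param dir directory containing the TSV files.
#' @param missing_code passed to [read_genotypes()].
#' @return an [rv_dataset()].
#' @export
read_rv_dataset <- function(dir, missing_code = NULL) {
  geno <- read_genotypes(file.path(dir, "genotypes.tsv"), missing_code)
  annot <- read_annotation(file.path(dir, "annotation.tsv"))
  pheno <- read_phenotypes(file.path(dir, "phenotypes.tsv"),
                           geno$sample_ids)
  cov_path <- file.path(dir, "covariates.tsv")
  covar <- if (file.exists(cov_path))
    read_covariates(cov_path, geno$sample_ids) else NULL
  rv_dataset(geno, annot, pheno, covar)
}

#' Convert a VCF to the genotype TSV schema
#'
#' Convenience converter for biallelic sites: the GT field is turned into
#' a minor-allele count (number of ALT alleles). Multi-allelic records and
#' phased separators are handled by counting non-reference alleles;
#' records with more than one ALT allele are skipped with a message.
#'
#' @param vcf_path path to an uncompressed VCF (v4.x) file.
#' @param out_path output genotype TSV path.
#' @return the output path, invisibly.
#' @export
vcf_to_genotypes <- function(vcf_path, out_path) {
  lines <- readLines(vcf_path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "#CHROM" || length(header) < 10)
    stop("not a VCF with genotype columns")
  samples <- header[-(1:9)]
  rows <- lapply(body[-1], function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (grepl(",", f[5], fixed = TRUE)) return(NULL)  # multi-allelic
    id <- if (f[3] == ".") paste0(f[1], ":", f[2]) else f[3]
    gt <- sub(":.*", "", f[-(1:9)])
    cnt <- vapply(strsplit(gt, "[/|]"), function(a)
      sum(a == "1"), integer(1))
    list(id = id, cnt = cnt)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no biallelic records in VCF")
  G <- do.call(cbind, lapply(rows, `[[`, "cnt"))
  ds <- genotype_dataset(G, samples, vapply(rows, `[[`, "", "id"))
  write_genotypes(ds, out_path)
}
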