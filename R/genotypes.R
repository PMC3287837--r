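#' Construct a genotype matrix of minor-allele dosages
#'
#' The central genotype container: an integer matrix of subjects by variants
#' holding additive minor-allele counts. Entries must lie in \{0, 1, 2\} and
#' no missingness is allowed on the analysis path; readers resolve missing
#' genotypes (by mean imputation) before this constructor is called.
#'
#' @param dosage numeric/integer matrix, subjects in rows, variants in
#'   columns, each entry the count of minor alleles (0, 1 or 2).
#' @param subject_ids character vector of subject identifiers (defaults to
#'   rownames of `dosage`).
#' @param variant_ids character vector of variant identifiers (defaults to
#'   colnames of `dosage`).
#' @return An object of class `GenotypeMatrix`: a list with elements
#'   `dosage` (integer matrix with dimnames), `subject_ids`, `variant_ids`.
#' @examples
#' g <- genotype_matrix(rbind(a = c(0, 1), b = c(2, 0)),
#'                      variant_ids = c("v1", "v2"))
#' variant_mafs(g)
#' @export
genotype_matrix <- function(dosage, subject_ids = rownames(dosage),
                            variant_ids = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) < 2L) stop("need at least 2 subjects")
  if (ncol(dosage) < 1L) stop("need at least 1 variant")
  if (anyNA(dosage)) stop("missing dosages are not allowed; impute in the reader")
  if (!all(dosage %in% c(0, 1, 2)))
    stop("dosage entries must be 0, 1 or 2 (additive minor-allele counts)")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(variant_ids)) variant_ids <- paste0("V", seq_len(ncol(dosage)))
  subject_ids <- as.character(subject_ids)
  variant_ids <- as.character(variant_ids)
  if (length(subject_ids) != nrow(dosage) || anyDuplicated(subject_ids))
    stop("subject_ids must be unique and match the number of rows")
  if (length(variant_ids) != ncol(dosage) || anyDuplicated(variant_ids))
    stop("variant_ids must be unique and match the number of columns")
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(subject_ids, variant_ids)
  structure(list(dosage = dosage, subject_ids = subject_ids,
                 variant_ids = variant_ids),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", length(x$subject_ids), "subjects x",
      length(x$variant_ids), "variants\n")
  invisible(x)
}

#' Minor allele frequency of one dosage column
#'
#' Computes `min(p, 1 - p)` where `p` is the frequency of the coded allele,
#' `sum(x) / (2 n)`. When the stored allele is already the minor allele this
#' equals `p`; the result is invariant to recoding the column as `2 - x`.
#'
#' @param x integer vector of dosages in \{0, 1, 2\}.
#' @return Minor allele frequency in `[0, 0.5]`.
#' @examples
#' compute_maf(c(0, 0, 1, 2))  # 0.375
#' compute_maf(c(2, 2, 2, 1))  # 0.125: stored allele is the major one
#' @export
compute_maf <- function(x) {
  if (length(x) == 0L) stop("empty dosage vector")
  if (anyNA(x)) stop("missing dosages are not allowed")
  s <- sum(x)
  n2 <- 2 * length(x)
  min(s, n2 - s) / n2   # minor-allele count first, so 2 - x gives the same maf
}

#' Minor allele frequencies for every variant of a genotype matrix
#'
#' @param genotypes a [genotype_matrix()].
#' @return Named numeric vector of per-variant MAFs.
#' @export
variant_mafs <- function(genotypes) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  s <- colSums(genotypes$dosage)
  n2 <- 2 * nrow(genotypes$dosage)
  pmin(s, n2 - s) / n2
}

#' Build the per-variant annotation table
#'
#' Joins sample MAFs (computed on the full analysis sample) with a
#' variant-to-gene map. Variants missing from the map are dropped with a
#' warning; the map may cover extra variants not present in the genotypes.
#'
#' @param genotypes a [genotype_matrix()].
#' @param gene_map data frame with columns `variant_id` and `gene`.
#' @return Data frame with columns `variant_id`, `gene`, `maf`.
#' @export
variant_info <- function(genotypes, gene_map) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"),
            all(c("variant_id", "gene") %in% names(gene_map)))
  maf <- variant_mafs(genotypes)
  idx <- match(genotypes$variant_ids, gene_map$variant_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " variant(s) absent from the gene map; dropped")
  }
  keep <- !is.na(idx)
  data.frame(variant_id = genotypes$variant_ids[keep],
             gene = as.character(gene_map$gene[idx[keep]]),
             maf = unname(maf[keep]),
             stringsAsFactors = FALSE)
}

#' Split one gene's variants into rare and common sets at a MAF cutoff
#'
#' Rare means MAF strictly below the cutoff; a variant whose MAF equals the
#' cutoff is common. Monomorphic variants (MAF = 0) carry no information and
#' are excluded from both sets. Empty sets are legal.
#'
#' @param info data frame of variant annotations (`variant_id`, `gene`,
#'   `maf`) for a single gene.
#' @param cutoff MAF threshold, conventionally one of 0.005, 0.01, 0.05.
#' @return A `GenePartition`: list with `gene`, `cutoff`, `rare_ids`,
#'   `common_ids` (character vectors of variant identifiers).
#' @examples
#' info <- data.frame(variant_id = c("a", "b", "c"), gene = "G1",
#'                    maf = c(0.004, 0.01, 0.2))
#' partition_gene(info, 0.01)  # "a" rare; "b" sits on the boundary: common
#' @export
partition_gene <- function(info, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  gene <- unique(as.character(info$gene))
  if (length(gene) != 1L) stop("variants must all belong to one gene")
  if (anyNA(info$maf) || any(info$maf < 0 | info$maf > 0.5))
    stop("MAFs must lie in [0, 0.5]")
  poly <- info$maf > 0
  structure(list(
    gene = gene, cutoff = cutoff,
    rare_ids = info$variant_id[poly & info$maf < cutoff],
    common_ids = info$variant_id[poly & info$maf >= cutoff]
  ), class = "GenePartition")
}

#' Partition every gene of an annotation table at a MAF cutoff
#'
#' @param info data frame of variant annotations for any number of genes.
#' @inheritParams partition_gene
#' @return Named list of `GenePartition` objects, one per gene.
#' @export
partition_genes <- function(info, cutoff) {
  lapply(split(info, info$gene), partition_gene, cutoff = cutoff)
}

#' Validate a covariate table
#'
#' Expects columns `subject_id`, `sex` (0/1), `age` (years), `smoking`
#' (0/1) and `population` (categorical label); no missing values.
#'
#' @param covariates data frame of covariates.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_covariates <- function(covariates) {
  need <- c("subject_id", "sex", "age", "smoking", "population")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("covariate table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(covariates[need])) stop("covariate table contains missing values")
  if (!all(covariates$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  if (!all(covariates$smoking %in% c(0, 1))) stop("smoking must be coded 0/1")
  if (anyDuplicated(covariates$subject_id)) stop("duplicated subject_id")
  invisible(covariates)
}

#' Numeric covariate design (without intercept) from a covariate table
#'
#' Sex, age and smoking enter as given; population enters as treatment-coded
#' dummy columns (k - 1 dummies for k groups). Rows are reordered to match
#' `subject_ids` when supplied; subjects are aligned by identifier, never by
#' file row order.
#'
#' @param covariates validated covariate data frame.
#' @param subject_ids optional character vector giving the required row order.
#' @return Numeric matrix with one row per subject.
#' @export
covariate_model_matrix <- function(covariates, subject_ids = NULL) {
  validate_covariates(covariates)
  if (!is.null(subject_ids)) {
    idx <- match(as.character(subject_ids), as.character(covariates$subject_id))
    if (anyNA(idx))
      stop("subjects absent from the covariate table: ",
           paste(head(subject_ids[is.na(idx)], 5), collapse = ", "))
    covariates <- covariates[idx, , drop = FALSE]
  }
  pop <- factor(covariates$population)
  mm <- model.matrix(~ sex + age + smoking + pop,
                     data = data.frame(sex = as.numeric(covariates$sex),
                                       age = as.numeric(covariates$age),
                                       smoking = as.numeric(covariates$smoking),
                                       pop = pop))
  mm <- mm[, -1, drop = FALSE]  # intercept is added by the test functions
  rownames(mm) <- as.character(covariates$subject_id)
  mm
}
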