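#' Read genotypes from a VCF or a tab-delimited dosage matrix
#'
#' The matrix format has a header of variant identifiers, a first column of
#' subject identifiers and entries 0/1/2. VCF input (v4.x, biallelic SNVs
#' only) requires the VariantAnnotation package and converts GT fields to
#' additive ALT-allele counts.
#'
#' In both formats columns are oriented to the minor allele: when the coded
#' (ALT) allele frequency exceeds 0.5 the column is recoded as `2 - g` and
#' the flip is recorded. Missing genotypes are imputed to the column's
#' rounded mean dosage with a warning.
#'
#' @param path file path.
#' @param format `"matrix"` (default) or `"vcf"`.
#' @return List with elements `genotypes` (a [genotype_matrix()]) and
#'   `info` (data frame `variant_id`, `maf`, `flipped_to_minor`).
#' @export
read_genotypes <- function(path, format = c("matrix", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- switch(format,
                matrix = read_genotypes_matrix(path),
                vcf = read_genotypes_vcf(path))
  orient_to_minor(raw$dosage, raw$subject_ids, raw$variant_ids)
}

read_genotypes_matrix <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("matrix file needs a subject column and >= 1 variant")
  subject_ids <- as.character(tab[[1]])
  g <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  bad <- !(g %in% c(0, 1, 2) | is.na(g))
  if (any(bad)) {
    j <- which(matrix(bad, nrow(g)), arr.ind = TRUE)[1, ]
    stop("invalid dosage ", g[j[1], j[2]], " at subject ", subject_ids[j[1]],
         ", variant ", colnames(g)[j[2]], " (entries must be 0/1/2)")
  }
  list(dosage = g, subject_ids = subject_ids, variant_ids = colnames(g))
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  nalt <- lengths(VariantAnnotation::alt(vcf))
  if (any(nalt != 1L)) {
    bad <- rownames(vcf)[which(nalt != 1L)[1]]
    stop("multiallelic record not supported: ", bad)
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  codes <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
             "1|0" = 1, "1/1" = 2, "1|1" = 2)
  miss <- c("./.", ".|.", ".")
  for (v in seq_len(nrow(gt))) {
    g <- gt[v, ]
    known <- codes[g]
    if (any(is.na(known) & !(g %in% miss)))
      stop("unparseable genotype '", g[is.na(known) & !(g %in% miss)][1],
           "' in record ", rownames(gt)[v])
    dos[, v] <- unname(known)
  }
  list(dosage = dos, subject_ids = colnames(gt), variant_ids = rownames(gt))
}

# impute missingness, flip columns coded on the major allele
orient_to_minor <- function(dosage, subject_ids, variant_ids) {
  nmiss <- colSums(is.na(dosage))
  if (any(nmiss > 0)) {
    warning(sum(nmiss), " missing genotype(s) in ", sum(nmiss > 0),
            " variant(s) imputed to the rounded mean dosage")
    for (j in which(nmiss > 0)) {
      m <- mean(dosage[, j], na.rm = TRUE)
      if (is.nan(m)) m <- 0
      dosage[is.na(dosage[, j]), j] <- round(m)
    }
  }
  p <- colMeans(dosage) / 2
  flip <- p > 0.5
  if (any(flip)) dosage[, flip] <- 2 - dosage[, flip, drop = FALSE]
  gm <- genotype_matrix(dosage, subject_ids, variant_ids)
  list(genotypes = gm,
       info = data.frame(variant_id = gm$variant_ids,
                         maf = unname(variant_mafs(gm)),
                         flipped_to_minor = unname(flip),
                         stringsAsFactors = FALSE))
}

#' Write a genotype matrix in the tab-delimited dosage format
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file path.
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  tab <- data.frame(subject_id = genotypes$subject_ids,
                    genotypes$dosage, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant-to-gene map
#'
#' Tab-delimited file with header columns `variant_id` and `gene`, in the
#' style of an exome SNP information file.
#'
#' @param path file path.
#' @return Data frame with columns `variant_id` and `gene`.
#' @export
read_gene_map <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("variant_id", "gene") %in% names(tab)))
    stop("gene map needs columns 'variant_id' and 'gene'")
  tab[c("variant_id", "gene")]
}

#' Read a covariate table
#'
#' Tab-delimited with header `subject_id, sex, age, smoking, population`.
#'
#' @param path file path.
#' @return Validated covariate data frame.
#' @export
read_covariates <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_covariates(tab)
  tab
}

#' Read a quantitative trait panel
#'
#' Tab-delimited: `subject_id` then one column per phenotype replicate.
#'
#' @param path file path.
#' @return Numeric matrix (subjects x replicates) with subject rownames.
#' @export
read_traits <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (names(tab)[1] != "subject_id") stop("first column must be subject_id")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("trait values must be finite")
  rownames(m) <- as.character(tab$subject_id)
  m
}

#' Write a trait panel
#' @param traits numeric matrix with subject rownames.
#' @param path output file path.
#' @export
write_traits <- function(traits, path) {
  tab <- data.frame(subject_id = rownames(traits), traits, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a covariate table
#' @param covariates covariate data frame.
#' @param path output file path.
#' @export
write_covariates <- function(covariates, path) {
  validate_covariates(covariates)
  write.table(covariates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a variant-to-gene map
#' @param gene_map data frame with `variant_id` and `gene`.
#' @param path output file path.
#' @export
write_gene_map <- function(gene_map, path) {
  write.table(gene_map[c("variant_id", "gene")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
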