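#' Configuration of the data-adaptive flip rule
#'
#' A rare variant's additive coding is flipped to major-allele counting when
#' its covariate-adjusted marginal regression coefficient is negative with a
#' two-sided p-value at or below `flip_alpha`.
#'
#' @param flip_alpha significance threshold of the flip rule, in (0, 1);
#'   default 0.1 (the rule is inclusive: p equal to `flip_alpha` flips).
#' @param adjust_covariates should the per-variant flip regressions adjust
#'   for the covariates? Default `TRUE`.
#' @return An `AdaptiveConfig` list.
#' @export
adaptive_config <- function(flip_alpha = 0.1, adjust_covariates = TRUE) {
  stopifnot(is.numeric(flip_alpha), length(flip_alpha) == 1L,
            flip_alpha > 0, flip_alpha < 1, is.logical(adjust_covariates))
  structure(list(flip_alpha = flip_alpha,
                 adjust_covariates = isTRUE(adjust_covariates)),
            class = "AdaptiveConfig")
}

new_rare_score <- function(method, values, flip_mask = NULL) {
  values <- as.numeric(values)
  structure(list(method = method, values = values, flip_mask = flip_mask,
                 informative = max(values) > min(values)),
            class = "RareScore")
}

#' @export
print.RareScore <- function(x, ...) {
  cat("RareScore (", x$method, "): n = ", length(x$values),
      if (!x$informative) ", constant (uninformative)", "\n", sep = "")
  if (!is.null(x$flip_mask))
    cat("  flipped variants:", sum(x$flip_mask), "of", length(x$flip_mask), "\n")
  invisible(x)
}

check_rare_submatrix <- function(rare_dosages) {
  rare_dosages <- as.matrix(rare_dosages)
  if (ncol(rare_dosages) == 0L)
    stop("gene has no rare variants at this cutoff; skip it")
  if (anyNA(rare_dosages)) stop("missing dosages are not allowed")
  rare_dosages
}

#' Indicator (carrier) rare-variant score
#'
#' Per subject, 1 if the subject carries at least one rare minor allele in
#' the gene region and 0 otherwise.
#'
#' @param rare_dosages integer matrix of dosages, subjects x rare variants.
#' @return A `RareScore` with values in \{0, 1\}.
#' @examples
#' indicator_score(rbind(c(0, 0), c(1, 0), c(2, 1)))$values  # 0 1 1
#' @export
indicator_score <- function(rare_dosages) {
  rare_dosages <- check_rare_submatrix(rare_dosages)
  new_rare_score("indicator", as.numeric(rowSums(rare_dosages > 0) > 0))
}

#' Count rare-variant score
#'
#' Per subject, the total number of rare minor alleles in the gene region.
#' With complete genotypes this equals `2 m` times the per-subject
#' proportion of rare minor alleles over the `m` rare variants, so it is
#' equivalent to the proportion parameterisation up to a constant factor.
#'
#' @inheritParams indicator_score
#' @return A `RareScore` with non-negative integer values.
#' @examples
#' count_score(rbind(c(0, 0), c(1, 0), c(2, 1)))$values  # 0 1 3
#' @export
count_score <- function(rare_dosages) {
  rare_dosages <- check_rare_submatrix(rare_dosages)
  new_rare_score("count", rowSums(rare_dosages))
}

#' Data-adaptive sum score
#'
#' For each rare variant a linear regression of the trait on the covariates
#' plus that variant's additive dosage is fitted. If the dosage coefficient
#' is negative and its two-sided p-value is at or below
#' `config$flip_alpha`, the variant's coding is flipped to count major
#' alleles (`2 - g`). The score is the per-subject row sum of the (possibly
#' recoded) columns.
#'
#' Because the trait itself drives the flip decision, testing the score
#' against the same trait replicate biases the test towards association;
#' valid inference needs an empirical null or [permutation_null()].
#'
#' Variants with zero dosage variance (or collinear with the covariates)
#' cannot be fitted and are never flipped; they contribute their constant
#' column to the sum.
#'
#' @inheritParams indicator_score
#' @param trait numeric trait vector aligned with the dosage rows; must not
#'   be constant.
#' @param covariates optional numeric covariate matrix (no intercept
#'   column), aligned with the dosage rows.
#' @param config an [adaptive_config()].
#' @return A `RareScore` with a `flip_mask` element (`TRUE` = variant
#'   recoded to major-allele counts).
#' @export
adaptive_score <- function(rare_dosages, trait, covariates = NULL,
                           config = adaptive_config()) {
  rare_dosages <- check_rare_submatrix(rare_dosages)
  stopifnot(inherits(config, "AdaptiveConfig"))
  n <- nrow(rare_dosages)
  trait <- as.numeric(trait)
  if (length(trait) != n) stop("trait and dosage rows are misaligned")
  if (max(trait) == min(trait)) stop("trait is constant")
  Z <- adaptive_design(covariates, n, config)
  dec <- flip_decisions(rare_dosages, trait, Z, config$flip_alpha)
  if (!is.null(colnames(rare_dosages))) names(dec$flip) <- colnames(rare_dosages)
  coded <- rare_dosages
  if (any(dec$flip)) coded[, dec$flip] <- 2 - coded[, dec$flip, drop = FALSE]
  new_rare_score("adaptive", rowSums(coded), flip_mask = dec$flip)
}

adaptive_design <- function(covariates, n, config) {
  if (!config$adjust_covariates || is.null(covariates)) {
    matrix(1, n, 1)
  } else {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows are misaligned")
    cbind(1, covariates)
  }
}

# Marginal covariate-adjusted slopes for each dosage column, by
# Frisch-Waugh residualisation: regress trait and each column on the
# covariate design once, then each slope is a simple-regression slope of
# the residualised pair with n - p - 1 residual df.
flip_decisions <- function(X, y, Z, flip_alpha) {
  n <- nrow(Z); p <- qr(Z)$rank
  if (p < ncol(Z)) stop("singular covariate design in flip regressions")
  qz <- qr(Z)
  ry <- qr.resid(qz, y)
  RX <- qr.resid(qz, X)
  sxx <- colSums(RX^2)
  dfres <- n - p - 1L
  if (dfres <= 0) stop("not enough residual degrees of freedom")
  estimable <- sxx > .tol * n
  slope <- pval <- rep(NA_real_, ncol(X))
  slope[estimable] <- colSums(RX[, estimable, drop = FALSE] * ry) /
    sxx[estimable]
  rss <- sum(ry^2) - slope[estimable]^2 * sxx[estimable]
  se <- sqrt(pmax(rss, 0) / dfres / sxx[estimable])
  tt <- ifelse(se > 0, slope[estimable] / se, Inf * sign(slope[estimable]))
  pval[estimable] <- 2 * pt(-abs(tt), dfres)
  flip <- !is.na(slope) & slope < 0 & pval <= flip_alpha
  list(slope = slope, pval = pval, flip = flip, estimable = estimable)
}

#' Export a rare-variant score as a two-column table
#'
#' Writes `subject_id` and the per-subject score, tab-delimited with a
#' header.
#'
#' @param score a `RareScore`.
#' @param subject_ids character vector of subject identifiers aligned with
#'   the score values.
#' @param path output file path.
#' @export
write_score <- function(score, subject_ids, path) {
  stopifnot(inherits(score, "RareScore"),
            length(subject_ids) == length(score$values))
  write.table(data.frame(subject_id = subject_ids, score = score$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
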