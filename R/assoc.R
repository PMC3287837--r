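#' Nested-model F-test of genetic terms over a covariate-only model
#'
#' Fits the reduced model (intercept + covariates) and the full model
#' (reduced + genetic terms) by least squares and compares residual sums of
#' squares:
#' \deqn{F = \frac{(RSS_{reduced} - RSS_{full})/q}{RSS_{full}/(n - p_{full})}}
#' with `q` the rank contribution of the genetic terms. Genetic columns that
#' add no rank over the reduced design (constant, or collinear with the
#' covariates or with each other) are dropped and recorded; `df_num` equals
#' the retained rank. The p-value is the upper tail of `F(q, n - p_full)`.
#'
#' @param trait numeric trait vector.
#' @param covariates numeric covariate matrix without intercept (or `NULL`).
#' @param genetic_terms numeric matrix of genetic predictors (burden score
#'   and/or common-variant dosages), one column per term.
#' @return A `GeneTestResult` list: `f_stat`, `df_num`, `df_den`, `p_value`,
#'   `dropped` (names of rank-deficient genetic columns), `skipped`,
#'   `reason`.
#' @export
nested_f_test <- function(trait, covariates, genetic_terms) {
  y <- as.numeric(trait)
  n <- length(y)
  Z <- if (is.null(covariates)) matrix(1, n, 1) else {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows are misaligned")
    cbind(1, covariates)
  }
  G <- as.matrix(genetic_terms)
  if (nrow(G) != n) stop("genetic term rows are misaligned")
  if (is.null(colnames(G))) colnames(G) <- paste0("g", seq_len(ncol(G)))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("covariate design is not full rank")
  qw <- qr(cbind(Z, G))
  q <- qw$rank - qz$rank
  nz <- ncol(Z)
  piv_g <- qw$pivot[seq_len(qw$rank)]            # columns retained by pivoting
  kept <- sort(piv_g[piv_g > nz] - nz)
  dropped <- setdiff(colnames(G), colnames(G)[kept])
  if (q == 0L)
    return(skipped_result("no genetic term adds information over the covariates"))
  df_den <- n - qw$rank
  if (df_den <= 0) stop("no residual degrees of freedom (n - p_full <= 0)")
  rss_red <- sum(qr.resid(qz, y)^2)
  rss_full <- sum(qr.resid(qw, y)^2)
  rss_full <- min(rss_full, rss_red)             # guard tiny negative diffs
  f <- if (rss_full <= .tol * max(rss_red, 1)) Inf else
    ((rss_red - rss_full) / q) / (rss_full / df_den)
  list(f_stat = f, df_num = q, df_den = df_den,
       p_value = pf(f, q, df_den, lower.tail = FALSE),
       dropped = dropped, skipped = FALSE, reason = NA_character_)
}

skipped_result <- function(reason) {
  list(f_stat = NA_real_, df_num = NA_integer_, df_den = NA_integer_,
       p_value = NA_real_, dropped = character(),
       skipped = TRUE, reason = reason)
}

#' Test a rare-variant burden score alone
#'
#' The collapse-only strategy: the only genetic term is the burden score. A
#' constant score (or one collinear with the covariates) cannot be tested
#' and yields a skipped result.
#'
#' @param score a `RareScore` from [indicator_score()], [count_score()] or
#'   [adaptive_score()].
#' @inheritParams nested_f_test
#' @return A `GeneTestResult` (see [nested_f_test()]) with
#'   `n_common_selected = 0`.
#' @export
test_collapse_only <- function(score, trait, covariates = NULL) {
  stopifnot(inherits(score, "RareScore"))
  if (!score$informative)
    return(c(skipped_result("constant score"), n_common_selected = 0L))
  res <- nested_f_test(trait, covariates,
                       matrix(score$values, ncol = 1,
                              dimnames = list(NULL, "rare_score")))
  if (!res$skipped && res$df_num == 0L)
    res <- skipped_result("score collinear with covariates")
  c(res, n_common_selected = 0L)
}

#' Combined multivariate and collapsing (CMC) test
#'
#' Joint test of the rare-variant burden score together with every common
#' variant of the gene region, each entering additively. With no common
#' variants this reduces exactly to [test_collapse_only()].
#'
#' @inheritParams test_collapse_only
#' @param common_dosages numeric matrix of common-variant dosages (may have
#'   zero columns).
#' @return A `GeneTestResult` with `n_common_selected` = number of common
#'   variants entered.
#' @export
test_cmc <- function(score, common_dosages, trait, covariates = NULL) {
  stopifnot(inherits(score, "RareScore"))
  common_dosages <- as.matrix(common_dosages)
  if (ncol(common_dosages) == 0L)
    return(test_collapse_only(score, trait, covariates))
  if (!score$informative && ncol(common_dosages) == 0L)
    return(c(skipped_result("constant score"), n_common_selected = 0L))
  G <- cbind(rare_score = score$values, common_dosages)
  res <- nested_f_test(trait, covariates, G)
  c(res, n_common_selected = ncol(common_dosages))
}

#' Select common variants by LASSO with forced-in covariates and rare score
#'
#' Solves an L1-penalised least-squares path in which the covariates and
#' the rare-variant score carry zero penalty (they are always retained) and
#' the common variants carry unit penalty, using [glmnet::cv.glmnet()] with
#' k-fold cross-validation (squared-error loss, internal standardisation).
#' The shrinkage parameter is the one-standard-error choice: the largest
#' lambda whose mean CV error is within one standard error of the minimum.
#'
#' @inheritParams test_cmc
#' @param k_folds number of cross-validation folds (default 10).
#' @param fold_seed integer seed for the random fold assignment.
#' @param lambda optional fixed lambda; when supplied, cross-validation is
#'   skipped and the selection is read off the path at this value.
#' @return A `LassoSelection` list: `lambda_path`, `cv_errors`, `cv_se`,
#'   `lambda_min`, `lambda_1se`, `selected_common_idx` (column indices into
#'   `common_dosages`), `selected_common_ids`, `fold_seed`.
#' @export
lasso_select <- function(score, common_dosages, trait, covariates = NULL,
                         k_folds = 10L, fold_seed = 1L, lambda = NULL) {
  stopifnot(inherits(score, "RareScore"))
  common_dosages <- as.matrix(common_dosages)
  y <- as.numeric(trait)
  if (max(y) == min(y)) stop("trait is constant")
  empty <- structure(list(lambda_path = numeric(), cv_errors = numeric(),
                          cv_se = numeric(), lambda_min = NA_real_,
                          lambda_1se = NA_real_,
                          selected_common_idx = integer(),
                          selected_common_ids = character(),
                          fold_seed = fold_seed),
                     class = "LassoSelection")
  if (ncol(common_dosages) == 0L) return(empty)
  if (is.null(colnames(common_dosages)))
    colnames(common_dosages) <- paste0("cv", seq_len(ncol(common_dosages)))
  n <- length(y)
  X <- cbind(if (!is.null(covariates)) as.matrix(covariates),
             rare_score = score$values, common_dosages)
  n_forced <- ncol(X) - ncol(common_dosages)
  pf_vec <- c(rep(0, n_forced), rep(1, ncol(common_dosages)))
  common_names <- colnames(common_dosages)
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(X, y, family = "gaussian", penalty.factor = pf_vec,
                          standardize = TRUE)
    beta <- as.matrix(coef(fit, s = lambda))[-1, 1]
    sel <- which(abs(beta[common_names]) > 0)
    out <- empty
    out$lambda_path <- fit$lambda
    out$lambda_min <- out$lambda_1se <- lambda
    out$selected_common_idx <- unname(sel)
    out$selected_common_ids <- common_names[sel]
    return(out)
  }
  if (n < k_folds) stop("need at least k_folds observations")
  foldid <- with_seed(fold_seed, sample(rep_len(seq_len(k_folds), n)))
  cv <- glmnet::cv.glmnet(X, y, family = "gaussian", penalty.factor = pf_vec,
                          foldid = foldid, standardize = TRUE)
  beta <- as.matrix(coef(cv, s = "lambda.1se"))[-1, 1]
  sel <- which(abs(beta[common_names]) > 0)
  structure(list(lambda_path = cv$lambda, cv_errors = cv$cvm,
                 cv_se = cv$cvsd, lambda_min = cv$lambda.min,
                 lambda_1se = cv$lambda.1se,
                 selected_common_idx = unname(sel),
                 selected_common_ids = common_names[sel],
                 fold_seed = fold_seed),
            class = "LassoSelection")
}

#' Test the rare score plus LASSO-selected common variants
#'
#' The common variants retained by [lasso_select()] are refitted together
#' with the rare score by ordinary least squares and tested with the nested
#' F statistic. Because the selection used the same trait replicate, the
#' resulting p-values are anti-conservative (post-selection inference);
#' calibrate against an empirical null.
#'
#' @inheritParams test_cmc
#' @param selection a `LassoSelection` computed on the same trait replicate.
#' @return A `GeneTestResult` with `n_common_selected` and `lambda_used`.
#' @export
test_lasso <- function(score, common_dosages, trait, covariates = NULL,
                       selection) {
  stopifnot(inherits(selection, "LassoSelection"))
  common_dosages <- as.matrix(common_dosages)
  sel <- selection$selected_common_idx
  res <- if (length(sel) == 0L) {
    test_collapse_only(score, trait, covariates)
  } else {
    r <- test_cmc(score, common_dosages[, sel, drop = FALSE], trait, covariates)
    r$n_common_selected <- length(sel)
    r
  }
  res$lambda_used <- selection$lambda_1se
  res
}
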