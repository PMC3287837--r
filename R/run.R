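#' Run gene-based association tests across methods, strategies and cutoffs
#'
#' The study driver: for every gene region, MAF cutoff, collapsing method,
#' common-variant strategy and trait replicate, computes the rare-variant
#' score and the nested F-test, producing one tidy result row per
#' combination. Genes without rare variants at a cutoff are reported as
#' skipped at that cutoff. Indicator and count scores depend only on
#' genotypes and are computed once per gene and cutoff; the data-adaptive
#' score is recomputed for every trait replicate because the trait drives
#' its flip rule.
#'
#' @param genotypes a [genotype_matrix()].
#' @param info variant annotation data frame from [variant_info()].
#' @param covariates covariate data frame (see [validate_covariates()]), or
#'   a pre-built numeric design matrix from [covariate_model_matrix()].
#' @param traits numeric trait matrix, subjects x replicates (rownames are
#'   subject identifiers when alignment checking is wanted).
#' @param methods collapsing methods, subset of
#'   `c("indicator", "count", "adaptive")`.
#' @param strategies common-variant strategies, subset of
#'   `c("none", "cmc", "lasso")`.
#' @param cutoffs MAF cutoffs defining rare variants (default
#'   `c(0.005, 0.01, 0.05)`).
#' @param replicates integer indices of trait replicates to analyse
#'   (default: all columns of `traits`).
#' @param flip_alpha flip threshold for the data-adaptive method.
#' @param fold_seed base seed for LASSO cross-validation folds; per-test
#'   fold seeds are derived deterministically from it.
#' @param k_folds folds for LASSO cross-validation.
#' @return Data frame with columns `gene`, `method`, `strategy`, `cutoff`,
#'   `replicate`, `f_stat`, `df_num`, `df_den`, `p_value`,
#'   `n_common_selected`, `lambda_used`, `skipped`, `reason`.
#' @export
run_gene_tests <- function(genotypes, info, covariates, traits,
                           methods = c("indicator", "count", "adaptive"),
                           strategies = c("none", "cmc", "lasso"),
                           cutoffs = c(0.005, 0.01, 0.05),
                           replicates = NULL,
                           flip_alpha = 0.1, fold_seed = 1L, k_folds = 10L) {
  methods <- match.arg(methods, several.ok = TRUE)
  strategies <- match.arg(strategies, several.ok = TRUE)
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  traits <- as.matrix(traits)
  if (!is.null(rownames(traits)) &&
      !identical(rownames(traits), genotypes$subject_ids)) {
    idx <- match(genotypes$subject_ids, rownames(traits))
    if (anyNA(idx)) stop("trait subjects do not match genotype subjects")
    traits <- traits[idx, , drop = FALSE]
  }
  cov_mm <- if (is.data.frame(covariates)) {
    covariate_model_matrix(covariates, genotypes$subject_ids)
  } else if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(cov_mm) && nrow(cov_mm) != nrow(traits))
    stop("covariate rows do not match subjects")
  if (is.null(replicates)) replicates <- seq_len(ncol(traits))
  cfg <- adaptive_config(flip_alpha = flip_alpha)

  rows <- vector("list", 0L)
  add <- function(gene, method, strategy, cutoff, rep, res) {
    rows[[length(rows) + 1L]] <<- list(
      gene = gene, method = method, strategy = strategy, cutoff = cutoff,
      replicate = rep, f_stat = as.numeric(res$f_stat),
      df_num = as.integer(res$df_num), df_den = as.integer(res$df_den),
      p_value = as.numeric(res$p_value),
      n_common_selected = as.integer(res$n_common_selected %||% NA_integer_),
      lambda_used = as.numeric(res$lambda_used %||% NA_real_),
      skipped = res$skipped, reason = res$reason)
  }
  # shared reduced-model machinery: the covariate design is the same for
  # every gene, so factor it once
  Z <- if (is.null(cov_mm)) matrix(1, nrow(traits), 1) else cbind(1, cov_mm)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("covariate design is not full rank")
  rss_red_all <- unname(colSums(qr.resid(qz, traits)^2))

  genes <- unique(info$gene)
  for (cutoff in cutoffs) {
    parts <- partition_genes(info, cutoff)
    for (gi in seq_along(genes)) {
      gene <- genes[gi]
      part <- parts[[gene]]
      if (length(part$rare_ids) == 0L) {
        sk <- c(skipped_result("no rare variants at this cutoff"),
                n_common_selected = NA_integer_)
        for (m in methods) for (s in strategies) for (r in replicates)
          add(gene, m, s, cutoff, r, sk)
        next
      }
      Xr <- genotypes$dosage[, part$rare_ids, drop = FALSE]
      Xc <- genotypes$dosage[, part$common_ids, drop = FALSE]
      static <- list()
      if ("indicator" %in% methods) static$indicator <- indicator_score(Xr)
      if ("count" %in% methods) static$count <- count_score(Xr)
      # indicator/count scores and the none/cmc designs do not depend on
      # the trait, so those F-tests are batched: one QR per design, RSS
      # for every replicate at once (identical to the per-test route)
      for (m in intersect(methods, c("indicator", "count"))) {
        for (s in intersect(strategies, c("none", "cmc"))) {
          common <- if (s == "cmc") Xc else Xr[, 0, drop = FALSE]
          batch <- batch_score_tests(static[[m]], common,
                                     traits[, replicates, drop = FALSE],
                                     cov_mm, qz = qz, Z = Z,
                                     rss_red = rss_red_all[replicates])
          for (k in seq_along(replicates))
            add(gene, m, s, cutoff, replicates[k], batch[[k]])
        }
      }
      need_loop <- "adaptive" %in% methods || "lasso" %in% strategies
      if (need_loop) for (r in replicates) {
        y <- traits[, r]
        scores <- static
        if ("adaptive" %in% methods)
          scores$adaptive <- adaptive_score(Xr, y, cov_mm, cfg)
        for (m in methods) {
          sc <- scores[[m]]
          for (s in strategies) {
            if (m %in% c("indicator", "count") && s %in% c("none", "cmc"))
              next  # handled by the batch path above
            res <- switch(s,
              none = test_collapse_only(sc, y, cov_mm),
              cmc = test_cmc(sc, Xc, y, cov_mm),
              lasso = {
                fs <- derive_seed(fold_seed, gi, r, match(m, methods))
                sel <- lasso_select(sc, Xc, y, cov_mm,
                                    k_folds = k_folds, fold_seed = fs)
                test_lasso(sc, Xc, y, cov_mm, sel)
              })
            add(gene, m, s, cutoff, r, res)
          }
        }
      }
    }
  }
  col <- function(field, fn, proto) fn(rows, `[[`, proto, field)
  data.frame(
    gene = col("gene", vapply, character(1)),
    method = col("method", vapply, character(1)),
    strategy = col("strategy", vapply, character(1)),
    cutoff = col("cutoff", vapply, numeric(1)),
    replicate = col("replicate", vapply, numeric(1)),
    f_stat = col("f_stat", vapply, numeric(1)),
    df_num = col("df_num", vapply, integer(1)),
    df_den = col("df_den", vapply, integer(1)),
    p_value = col("p_value", vapply, numeric(1)),
    n_common_selected = col("n_common_selected", vapply, integer(1)),
    lambda_used = col("lambda_used", vapply, numeric(1)),
    skipped = col("skipped", vapply, logical(1)),
    reason = col("reason", vapply, character(1)),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Batched equivalent of test_collapse_only / test_cmc for a fixed score and
# common-variant design across many trait replicates. The design (and hence
# its QR, rank and dropped columns) is trait-independent; only the residual
# sums of squares vary by replicate.
batch_score_tests <- function(score, common_dosages, Y, covariates,
                              qz = NULL, Z = NULL, rss_red = NULL) {
  n <- nrow(Y)
  n_common <- ncol(common_dosages)
  if (!score$informative && n_common == 0L) {
    sk <- c(skipped_result("constant score"), n_common_selected = 0L)
    return(rep(list(sk), ncol(Y)))
  }
  G <- if (n_common == 0L) {
    matrix(score$values, ncol = 1, dimnames = list(NULL, "rare_score"))
  } else cbind(rare_score = score$values, common_dosages)
  if (is.null(Z))
    Z <- if (is.null(covariates)) matrix(1, n, 1) else cbind(1, covariates)
  if (is.null(qz)) qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("covariate design is not full rank")
  if (is.null(colnames(G))) colnames(G) <- paste0("g", seq_len(ncol(G)))
  qw <- qr(cbind(Z, G))
  q <- qw$rank - qz$rank
  nz <- ncol(Z)
  piv_g <- qw$pivot[seq_len(qw$rank)]
  kept <- sort(piv_g[piv_g > nz] - nz)
  dropped <- setdiff(colnames(G), colnames(G)[kept])
  if (q == 0L) {
    sk <- c(skipped_result("no genetic term adds information over the covariates"),
            n_common_selected = n_common)
    return(rep(list(sk), ncol(Y)))
  }
  df_den <- n - qw$rank
  if (df_den <= 0) stop("no residual degrees of freedom (n - p_full <= 0)")
  if (is.null(rss_red)) rss_red <- unname(colSums(qr.resid(qz, Y)^2))
  rss_full <- pmin(unname(colSums(qr.resid(qw, Y)^2)), rss_red)
  f <- ifelse(rss_full <= .tol * pmax(rss_red, 1), Inf,
              ((rss_red - rss_full) / q) / (rss_full / df_den))
  p <- pf(f, q, df_den, lower.tail = FALSE)
  lapply(seq_len(ncol(Y)), function(k)
    list(f_stat = f[k], df_num = q, df_den = df_den, p_value = p[k],
         dropped = dropped, skipped = FALSE, reason = NA_character_,
         n_common_selected = n_common))
}

#' Write a gene test result table
#' @param results data frame from [run_gene_tests()].
#' @param path output file path (tab-delimited with header).
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene test result table
#' @param path file path written by [write_results()].
#' @return Data frame of gene test results.
#' @export
read_results <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
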