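#' Pool null-trait test results into an empirical null distribution
#'
#' Collects the p-values of all non-skipped tests of one method, strategy
#' and cutoff across gene regions and trait replicates. Pooling p-values
#' rather than F statistics keeps genes with different numerator degrees of
#' freedom comparable.
#'
#' @param results data frame of gene test results computed on a null trait
#'   (one method/strategy/cutoff, or a larger table to be filtered).
#' @param method,strategy,cutoff optional filters; each must leave exactly
#'   one level in the pool.
#' @return A `NullPool` list: `method`, `strategy`, `cutoff`, `p_values`,
#'   `n_total`, `n_skipped`.
#' @export
pool_null <- function(results, method = NULL, strategy = NULL, cutoff = NULL) {
  if (!is.null(method)) results <- results[results$method == method, ]
  if (!is.null(strategy)) results <- results[results$strategy == strategy, ]
  if (!is.null(cutoff)) results <- results[results$cutoff == cutoff, ]
  for (f in c("method", "strategy", "cutoff")) {
    if (f %in% names(results) && length(unique(results[[f]])) > 1L)
      stop("pool mixes several levels of '", f,
           "'; pool one method x strategy x cutoff at a time")
  }
  skipped <- is.na(results$p_value) | isTRUE_vec(results$skipped)
  p <- results$p_value[!skipped]
  if (length(p) == 0L) stop("empty null pool (no usable p-values)")
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  if (any(skipped))
    message(sum(skipped), " skipped result(s) excluded from the null pool")
  structure(list(method = one_or_na(results$method),
                 strategy = one_or_na(results$strategy),
                 cutoff = one_or_na(results$cutoff),
                 p_values = p, n_total = length(p),
                 n_skipped = sum(skipped)),
            class = "NullPool")
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE
one_or_na <- function(x) if (is.null(x) || length(unique(x)) != 1L) NA else x[1]

#' Empirical significance threshold from a null pool
#'
#' Returns the threshold `q` such that rejecting when `p < q` admits a
#' fraction of the pooled null p-values as close to `alpha` as possible
#' without exceeding it: `q` is the order statistic of the pool at rank
#' `ceiling(alpha * n) + 1` (or `Inf` when that rank exceeds the pool, so
#' `alpha = 1` admits everything). The rejection rule downstream is the
#' strict `p < q`.
#'
#' @param pool a `NullPool` from [pool_null()].
#' @param alpha target significance level in (0, 1].
#' @return Numeric threshold with attributes `alpha` and `rule`.
#' @export
empirical_threshold <- function(pool, alpha) {
  stopifnot(inherits(pool, "NullPool"), alpha > 0, alpha <= 1)
  n <- pool$n_total
  if (n < 1 / alpha)
    stop("null pool too small: need at least ", ceiling(1 / alpha),
         " p-values for alpha = ", alpha)
  s <- sort(pool$p_values)
  k <- ceiling(alpha * n)
  thr <- if (k + 1 > n) Inf else s[k + 1]
  structure(thr, alpha = alpha, rule = "reject iff p < threshold")
}

#' Empirical type I error at a nominal threshold
#'
#' The fraction of pooled null p-values below the nominal (asymptotic)
#' significance level — the quantity tabulated when a test's calibration is
#' reported at, say, the 5% level.
#'
#' @param pool a `NullPool`.
#' @param nominal_alpha nominal level (default 0.05).
#' @return Fraction of null tests rejected at the nominal level.
#' @export
type1_error <- function(pool, nominal_alpha = 0.05) {
  stopifnot(inherits(pool, "NullPool"))
  mean(pool$p_values < nominal_alpha)
}

#' Per-gene power at a significance threshold
#'
#' For each requested gene, the fraction of (non-skipped) trait replicates
#' whose p-value falls below the threshold. The threshold should come from
#' the [empirical_threshold()] of the matching method x strategy x cutoff
#' null pool.
#'
#' @param alt_results data frame of gene test results on the associated
#'   trait (single method/strategy/cutoff).
#' @param threshold numeric p-value threshold.
#' @param genes genes to evaluate (default: all genes present). A requested
#'   gene absent from the results is an error.
#' @return Named numeric vector of per-gene power estimates.
#' @export
power_by_gene <- function(alt_results, threshold, genes = NULL) {
  if (is.null(genes)) genes <- unique(alt_results$gene)
  missing <- setdiff(genes, alt_results$gene)
  if (length(missing))
    stop("gene(s) absent from results: ", paste(missing, collapse = ", "))
  vapply(genes, function(g) {
    p <- alt_results$p_value[alt_results$gene == g]
    p <- p[!is.na(p)]
    if (length(p) == 0L) return(NA_real_)
    mean(p < threshold)
  }, numeric(1))
}

#' Permutation p-value for a test statistic under covariate adjustment
#'
#' Re-runs an entire test procedure (for the data-adaptive method: the flip
#' decision and the F-test) on permuted traits and returns the add-one
#' permutation p-value `(1 + #{F* >= F_obs}) / (1 + n_perm)`.
#'
#' Two permutation schemes are offered. The default `"residual"`
#' (Freedman-Lane style) fits the covariate-only model once, then permutes
#' its residuals and adds them back to the fitted values, preserving the
#' covariate-trait relationship under the null. `"raw"` permutes the trait
#' vector itself, which is valid only when covariates carry no signal.
#'
#' @param stat_fun function of one argument (a trait vector) returning the
#'   test statistic; it must re-run the full procedure, including any
#'   data-dependent coding decisions. May return `NA` when the permuted
#'   statistic is undefined (such permutations are dropped with a warning).
#' @param trait observed trait vector.
#' @param covariates numeric covariate matrix (no intercept) or `NULL`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param scheme `"residual"` (default) or `"raw"`.
#' @return List: `p_value`, `observed`, `perm_stats`, `n_perm_used`.
#' @export
permutation_null <- function(stat_fun, trait, covariates = NULL, n_perm,
                             seed = 1L, scheme = c("residual", "raw")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  y <- as.numeric(trait)
  n <- length(y)
  observed <- stat_fun(y)
  if (is.na(observed)) stop("observed statistic is undefined")
  if (scheme == "residual") {
    Z <- if (is.null(covariates)) matrix(1, n, 1) else
      cbind(1, as.matrix(covariates))
    qz <- qr(Z)
    fitted <- qr.fitted(qz, y)
    res <- qr.resid(qz, y)
  }
  perm_stats <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n)
    ystar <- if (scheme == "residual") fitted + res[idx] else y[idx]
    stat_fun(ystar)
  }, numeric(1)))
  bad <- is.na(perm_stats)
  if (any(bad)) {
    warning(sum(bad), " permutation statistic(s) undefined; dropped")
    perm_stats <- perm_stats[!bad]
  }
  m <- length(perm_stats)
  if (m == 0L) stop("all permutation statistics undefined")
  list(p_value = (1 + sum(perm_stats >= observed)) / (1 + m),
       observed = observed, perm_stats = perm_stats, n_perm_used = m)
}

#' Permutation-calibrated data-adaptive test (vectorised)
#'
#' Algebraically identical to wrapping the data-adaptive score and the
#' collapse-only F-test in [permutation_null()], but evaluated for all
#' permutations with matrix algebra (Frisch-Waugh residualisation against
#' the covariate design), which makes large calibration studies feasible.
#' Given the same `seed` and `scheme` it draws the same permutations and
#' returns the same p-value as the closure route.
#'
#' @param rare_dosages integer matrix of rare-variant dosages.
#' @param trait observed trait vector.
#' @param covariates numeric covariate matrix (no intercept) or `NULL`.
#' @param config an [adaptive_config()].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param scheme `"residual"` (default) or `"raw"`.
#' @return List: `p_value`, `observed`, `perm_stats`, `n_perm_used`.
#' @export
adaptive_permutation_test <- function(rare_dosages, trait, covariates = NULL,
                                      config = adaptive_config(), n_perm,
                                      seed = 1L,
                                      scheme = c("residual", "raw")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  X <- check_rare_submatrix(rare_dosages)
  y <- as.numeric(trait)
  n <- length(y)
  Z <- adaptive_design(covariates, n, config)
  qz <- qr(Z)
  p <- qz$rank
  if (p < ncol(Z)) stop("singular covariate design")
  fitted <- qr.fitted(qz, y)
  res <- qr.resid(qz, y)
  # permutation matrix of traits, drawn exactly as permutation_null does
  Ystar <- with_seed(seed, {
    out <- matrix(0, n, n_perm)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      out[, b] <- if (scheme == "residual") fitted + res[idx] else y[idx]
    }
    out
  })
  observed <- adaptive_f_stat(X, y, qz, p, config$flip_alpha)
  if (is.na(observed)) stop("observed statistic is undefined")
  perm_stats <- adaptive_f_stat(X, Ystar, qz, p, config$flip_alpha)
  bad <- is.na(perm_stats)
  if (any(bad)) {
    warning(sum(bad), " permutation statistic(s) undefined; dropped")
    perm_stats <- perm_stats[!bad]
  }
  m <- length(perm_stats)
  list(p_value = (1 + sum(perm_stats >= observed)) / (1 + m),
       observed = observed, perm_stats = perm_stats, n_perm_used = m)
}

# F statistic of the adaptive score for one trait vector or a matrix of
# trait columns, sharing one covariate QR. Returns NA where the score is
# constant (no testable term).
adaptive_f_stat <- function(X, Y, qz, p, flip_alpha) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  dfres <- n - p - 1L
  RY <- qr.resid(qz, Y)                       # n x B
  RX <- qr.resid(qz, X)                       # n x m
  sxx <- colSums(RX^2)
  estimable <- sxx > .tol * n
  syy <- colSums(RY^2)                        # length B
  # slopes of each variant against each trait column: m x B
  slopes <- crossprod(RX, RY) / sxx
  rss <- pmax(outer(rep(1, length(sxx)), syy) - slopes^2 * sxx, 0)
  tstat <- slopes / sqrt(rss / dfres / sxx)
  pvals <- 2 * pt(-abs(tstat), dfres)
  flip <- estimable & (slopes < 0) & (pvals <= flip_alpha)
  flip[is.na(flip)] <- FALSE
  # score_b = rowSums(X) + sum_{j flipped} (2 - 2 X_j)
  base <- rowSums(X)
  S <- base + (2 - 2 * X) %*% flip            # n x B
  RS <- qr.resid(qz, S)
  ss <- colSums(RS^2)
  sy <- colSums(RS * RY)
  expl <- sy^2 / ss
  rss_full <- pmax(syy - expl, 0)
  f <- expl / (rss_full / dfres)
  f[ss <= .tol * n] <- NA_real_               # constant score
  f[rss_full <= .tol * pmax(syy, 1)] <- Inf
  as.numeric(f)
}
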