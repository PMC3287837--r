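test_that("nested F-test matches the normal-equations oracle", {
  set.seed(20)
  for (i in 1:30) {
    n <- sample(20:60, 1)
    cv <- matrix(rnorm(n), n, 1)
    G <- matrix(rnorm(n * sample(1:3, 1)), n)
    y <- rnorm(n)
    got <- nested_f_test(y, cv, G)
    want <- f_oracle(y, cbind(1, cv), cbind(1, cv, G))
    expect_equal(got$f_stat, want$f, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    expect_identical(got$df_num, want$df1)
    expect_identical(got$df_den, want$df2)
  }
})

test_that("single genetic term: F equals the squared t statistic", {
  set.seed(21)
  n <- 50
  cv <- matrix(rnorm(2 * n), n, 2)
  g <- rbinom(n, 2, 0.3)
  y <- 0.4 * g + rnorm(n)
  got <- nested_f_test(y, cv, matrix(g))
  o <- ols_oracle(cbind(1, cv, g), y)
  expect_equal(got$f_stat, unname(o$t[4]^2), tolerance = 1e-10)
  expect_equal(got$p_value, unname(o$p[4]), tolerance = 1e-10)
})

test_that("F is non-negative and RSS is monotone under nesting", {
  set.seed(22)
  for (i in 1:20) {
    n <- 40
    cv <- matrix(rnorm(n * 2), n, 2)
    G <- matrix(sample(0:2, n * 2, replace = TRUE), n, 2)
    y <- rnorm(n)
    r <- nested_f_test(y, cv, G)
    expect_gte(r$f_stat, 0)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
})

test_that("perfect fit drives the p-value to zero", {
  n <- 30
  cv <- matrix(rnorm(n), n, 1)
  g <- rnorm(n)
  y <- 2 * g + cv[, 1]          # zero residual in the full model
  r <- nested_f_test(y, cv, matrix(g))
  expect_identical(r$f_stat, Inf)
  expect_identical(r$p_value, 0)
})

test_that("rank-deficient genetic designs are reduced with df to match", {
  set.seed(23)
  n <- 45
  cv <- matrix(rnorm(n), n, 1)
  g1 <- rbinom(n, 2, 0.3)
  G <- cbind(a = g1, b = 2 * g1, c = rbinom(n, 2, 0.2))  # b collinear with a
  y <- rnorm(n)
  r <- nested_f_test(y, cv, G)
  expect_identical(r$df_num, 2L)
  expect_identical(r$dropped, "b")
  # constant column collinear with the intercept is dropped too
  r2 <- nested_f_test(y, cv, cbind(const = rep(1, n), real = g1))
  expect_identical(r2$df_num, 1L)
  # all-constant genetic design cannot be tested
  r3 <- nested_f_test(y, cv, matrix(1, n, 1))
  expect_true(r3$skipped)
})

test_that("collapse-only test skips constant and collinear scores", {
  set.seed(24)
  n <- 40
  cv <- matrix(rnorm(n), n, 1)
  y <- rnorm(n)
  s_const <- count_score(matrix(0L, n, 1))
  r <- test_collapse_only(s_const, y, cv)
  expect_true(r$skipped)
  expect_match(r$reason, "constant")
  # a score duplicating a covariate column adds no rank
  s_dup <- indicator_score(matrix(rbinom(n, 1, 0.5), n, 1))
  r2 <- test_collapse_only(s_dup, y, cbind(s_dup$values))
  expect_true(r2$skipped)
})

test_that("null p-values of the score test are uniform", {
  # distributional calibration: informative fixed score, Gaussian null
  set.seed(25)
  n <- 150
  cv <- matrix(rnorm(n * 2), n, 2)
  s <- count_score(matrix(rbinom(n * 4, 2, 0.05), n, 4))
  p <- replicate(2000, {
    y <- 0.5 * cv[, 1] + rnorm(n)
    test_collapse_only(s, y, cv)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("CMC with no common variants equals the collapse-only test", {
  set.seed(26)
  n <- 60
  cv <- matrix(rnorm(n), n, 1)
  s <- count_score(matrix(rbinom(n * 3, 2, 0.05), n, 3))
  y <- rnorm(n)
  expect_identical(test_cmc(s, matrix(0, n, 0), y, cv),
                   test_collapse_only(s, y, cv))
})

test_that("CMC rank-reduces duplicated common variants", {
  set.seed(27)
  n <- 80
  cv <- matrix(rnorm(n), n, 1)
  s <- count_score(matrix(rbinom(n * 3, 2, 0.05), n, 3))
  c1 <- rbinom(n, 2, 0.3)
  r <- test_cmc(s, cbind(u = c1, v = c1), rnorm(n), cv)
  expect_identical(r$df_num, 2L)  # score + one common variant
  expect_identical(r$dropped, "v")
})

test_that("CMC beats collapse-only when a common variant is causal", {
  # Monte Carlo power comparison at the nominal 5% level
  set.seed(28)
  n <- 697
  g_common <- matrix(rbinom(n, 2, 0.3), n, 1)
  Xr <- matrix(rbinom(n * 5, 2, 0.01), n, 5)
  s <- count_score(Xr)
  hits <- replicate(200, {
    y <- 0.5 * g_common[, 1] + rnorm(n)
    c(cmc = test_cmc(s, g_common, y, NULL)$p_value < 0.05,
      only = test_collapse_only(s, y, NULL)$p_value < 0.05)
  })
  expect_gt(mean(hits["cmc", ]), mean(hits["only", ]))
})

test_that("lasso_select honours forced-in terms and degenerate limits", {
  set.seed(29)
  n <- 100
  s <- count_score(matrix(rbinom(n * 3, 2, 0.05), n, 3))
  y <- rnorm(n)
  # zero common variants: trivially empty selection
  sel0 <- lasso_select(s, matrix(0, n, 0), y)
  expect_length(sel0$selected_common_idx, 0)
  expect_true(is.na(sel0$lambda_1se))
  # lambda far above the path maximum shrinks every common variant away
  Xc <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
  y2 <- 0.8 * Xc[, 1] + rnorm(n)
  sel_inf <- lasso_select(s, Xc, y2, lambda = 1e6)
  expect_length(sel_inf$selected_common_idx, 0)
  expect_error(lasso_select(s, Xc, rep(1, n)), "constant")
})

test_that("lasso selection matches the soft-threshold closed form", {
  # orthonormal design: common columns orthogonal to each other, to the
  # intercept and to the (forced, unpenalised) score; each coefficient is
  # then sign(b) * max(|b| - lambda, 0) with b = x.y / n, so a variant is
  # selected iff |x.y| / n > lambda
  set.seed(30)
  n <- 120
  raw_score <- rbinom(n, 2, 0.2)
  B <- cbind(1, raw_score, matrix(rnorm(n * 2), n, 2))
  Q <- qr.Q(qr(B))
  Xc <- Q[, 3:4] * sqrt(n)            # mean 0, crossprod = n I
  colnames(Xc) <- c("x1", "x2")
  s <- count_score(matrix(raw_score, ncol = 1))
  y <- 0.9 * Xc[, 1] + 0.2 * Xc[, 2] + rnorm(n)
  b <- drop(crossprod(Xc, y)) / n
  for (lam in c(0.05, 0.3, 0.6, 1.2)) {
    sel <- lasso_select(s, Xc, y, lambda = lam)
    expect_setequal(sel$selected_common_ids,
                    colnames(Xc)[abs(b) > lam])
  }
})

test_that("lasso path selection size is monotone non-increasing in lambda", {
  set.seed(31)
  n <- 150
  Xc <- matrix(rbinom(n * 6, 2, 0.3), n, 6)
  s <- count_score(matrix(rbinom(n * 3, 2, 0.04), n, 3))
  y <- 0.4 * Xc[, 1] - 0.3 * Xc[, 4] + rnorm(n)
  lams <- sort(c(0.01, 0.05, 0.1, 0.2, 0.5))
  sizes <- vapply(lams, function(l)
    length(lasso_select(s, Xc, y, lambda = l)$selected_common_idx),
    integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("test_lasso falls back to collapse-only / CMC at the selection limits", {
  set.seed(32)
  n <- 90
  cv <- matrix(rnorm(n), n, 1)
  Xc <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  colnames(Xc) <- paste0("c", 1:3)
  s <- count_score(matrix(rbinom(n * 3, 2, 0.05), n, 3))
  y <- rnorm(n)
  empty <- lasso_select(s, Xc, y, cv, lambda = 1e6)
  full <- empty; full$selected_common_idx <- 1:3
  full$selected_common_ids <- colnames(Xc)
  got_empty <- test_lasso(s, Xc, y, cv, empty)
  ref_only <- test_collapse_only(s, y, cv)
  expect_identical(got_empty[c("f_stat", "df_num", "df_den", "p_value")],
                   ref_only[c("f_stat", "df_num", "df_den", "p_value")])
  got_full <- test_lasso(s, Xc, y, cv, full)
  ref_cmc <- test_cmc(s, Xc, y, cv)
  expect_identical(got_full[c("f_stat", "df_num", "df_den", "p_value")],
                   ref_cmc[c("f_stat", "df_num", "df_den", "p_value")])
})

test_that("cross-validated selection is reproducible under a fold seed", {
  set.seed(33)
  n <- 120
  Xc <- matrix(rbinom(n * 5, 2, 0.25), n, 5)
  s <- count_score(matrix(rbinom(n * 3, 2, 0.05), n, 3))
  y <- 0.5 * Xc[, 2] + rnorm(n)
  a <- lasso_select(s, Xc, y, fold_seed = 99)
  b <- lasso_select(s, Xc, y, fold_seed = 99)
  expect_identical(a$selected_common_idx, b$selected_common_idx)
  expect_identical(a$lambda_1se, b$lambda_1se)
  expect_gte(a$lambda_1se, a$lambda_min)  # one-SE rule picks a larger lambda
})

test_that("run_gene_tests produces one row per combination with skips", {
  st <- suppressWarnings(
    simulate_study(sim_config(null_gene_specs(2, n_rare = 4, n_common = 2),
                              n_subjects = 120, n_replicates = 2),
                   seed = 5))
  res <- run_gene_tests(st$genotypes, st$info, st$covariates,
                        st$traits$null, cutoffs = c(0.01, 0.05))
  expect_identical(nrow(res), 2L * 3L * 3L * 2L * 2L)
  expect_setequal(unique(res$method), c("indicator", "count", "adaptive"))
  # a gene with no rare variants at a cutoff must be reported as skipped
  info_norare <- st$info
  info_norare$maf[info_norare$gene == "NG0001"] <- 0.4
  res2 <- run_gene_tests(st$genotypes, info_norare, st$covariates,
                         st$traits$null, methods = "count",
                         strategies = "none", cutoffs = 0.005)
  sk <- res2[res2$gene == "NG0001", ]
  expect_true(all(sk$skipped))
  expect_match(sk$reason[1], "no rare variants")
})

test_that("batched and per-test F routes agree to machine precision", {
  st <- suppressWarnings(
    simulate_study(sim_config(null_gene_specs(3, n_rare = 6, n_common = 3),
                              n_subjects = 150, n_replicates = 4),
                   seed = 6))
  cm <- covariate_model_matrix(st$covariates, st$genotypes$subject_ids)
  Y <- st$traits$null
  for (cut in c(0.01, 0.05)) {
    parts <- partition_genes(st$info, cut)
    for (part in parts) {
      if (length(part$rare_ids) == 0) next
      Xr <- st$genotypes$dosage[, part$rare_ids, drop = FALSE]
      Xc <- st$genotypes$dosage[, part$common_ids, drop = FALSE]
      for (mk in c("indicator", "count")) {
        sc <- if (mk == "indicator") indicator_score(Xr) else count_score(Xr)
        batch <- rvcollapse:::batch_score_tests(sc, Xc, Y, cm)
        for (k in seq_len(ncol(Y))) {
          ref <- test_cmc(sc, Xc, Y[, k], cm)
          expect_equal(batch[[k]]$f_stat, ref$f_stat, tolerance = 1e-12)
          expect_identical(batch[[k]]$df_num, ref$df_num)
          expect_identical(batch[[k]]$df_den, ref$df_den)
          expect_equal(batch[[k]]$p_value, ref$p_value, tolerance = 1e-12)
          expect_identical(batch[[k]]$skipped, ref$skipped)
        }
      }
    }
  }
})
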