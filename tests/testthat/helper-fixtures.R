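# Shared fixture builders and independent oracles. Oracles use explicit
# normal-equation algebra so they share no code with the package's QR path.

# small genotype fixture: n subjects, columns spanning rare and common MAFs
make_geno <- function(n = 60, seed = 1) {
  withr_seed(seed)
  d <- cbind(
    r1 = rbinom(n, 2, 0.02), r2 = rbinom(n, 2, 0.03),
    c1 = rbinom(n, 2, 0.25), c2 = rbinom(n, 2, 0.4))
  while (any(colSums(d) == 0)) {          # keep every column polymorphic
    z <- colSums(d) == 0
    d[1, z] <- 1
  }
  genotype_matrix(d, paste0("S", seq_len(n)))
}

make_covariates <- function(n = 60, n_pop = 3, seed = 2) {
  withr_seed(seed)
  data.frame(subject_id = paste0("S", seq_len(n)),
             sex = rbinom(n, 1, 0.5),
             age = round(rnorm(n, 50, 10), 1),
             smoking = rbinom(n, 1, 0.3),
             population = paste0("P", sample.int(n_pop, n, replace = TRUE)),
             stringsAsFactors = FALSE)
}

withr_seed <- function(seed) set.seed(seed)

# ordinary least squares by explicit normal equations
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  rss <- sum(resid^2)
  df <- length(y) - ncol(X)
  sigma2 <- rss / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tstat <- beta / se
  list(beta = drop(beta), se = drop(se), t = drop(tstat),
       p = drop(2 * pt(-abs(tstat), df)), rss = rss, df = df)
}

# nested F-test by two explicit normal-equation solves
f_oracle <- function(y, Z_red, Z_full) {
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  r0 <- rss(Z_red); r1 <- rss(Z_full)
  q <- ncol(Z_full) - ncol(Z_red)
  df2 <- length(y) - ncol(Z_full)
  f <- ((r0 - r1) / q) / (r1 / df2)
  list(f = f, p = pf(f, q, df2, lower.tail = FALSE), df1 = q, df2 = df2)
}
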