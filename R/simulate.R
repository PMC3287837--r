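#' Specification of one simulated gene region
#'
#' Describes the variant architecture of a gene: how many rare and common
#' variants it carries, how many of each are causal, the allele-frequency
#' ranges they are drawn from, the per-minor-allele effect sizes and the
#' adjacent-variant haplotype correlation. Effects are non-negative by
#' default, matching a design in which every causal minor allele increases
#' the trait; `allow_negative_beta = TRUE` lifts that constraint for
#' mixed-direction experiments.
#'
#' @param gene gene label.
#' @param n_rare,n_common numbers of rare and common variants.
#' @param n_causal_rare,n_causal_common numbers of causal variants among
#'   them (causal variants are the first of each class after the in-gene
#'   ordering is shuffled).
#' @param rare_maf_range,common_maf_range frequency intervals the
#'   specification frequencies are drawn from (uniformly).
#' @param beta_rare,beta_common trait-unit effect per minor allele of each
#'   causal rare / common variant.
#' @param ld_rho adjacent-variant haplotype copying probability in `[0, 1)`
#'   (first-order Markov linkage disequilibrium).
#' @param maf_dist how specification frequencies are drawn from the ranges:
#'   `"uniform"` or `"loguniform"` (density proportional to 1/f, the
#'   neutral site-frequency-spectrum shape, so most variants sit near the
#'   rare end).
#' @param allow_negative_beta permit negative effects (default `FALSE`).
#' @return A `GeneSpec` list.
#' @export
gene_spec <- function(gene, n_rare, n_common = 0L, n_causal_rare = 0L,
                      n_causal_common = 0L,
                      rare_maf_range = c(5e-4, 0.01),
                      common_maf_range = c(0.01, 0.4),
                      beta_rare = 0, beta_common = 0, ld_rho = 0.2,
                      maf_dist = c("uniform", "loguniform"),
                      allow_negative_beta = FALSE) {
  maf_dist = match.arg(maf_dist)
  stopifnot(n_rare >= 0, n_common >= 0, n_rare + n_common >= 1,
            n_causal_rare <= n_rare, n_causal_common <= n_common,
            length(rare_maf_range) == 2L, length(common_maf_range) == 2L,
            ld_rho >= 0, ld_rho < 1)
  if (!allow_negative_beta && (beta_rare < 0 || beta_common < 0))
    stop("effects must be non-negative (minor alleles increase the trait); ",
         "set allow_negative_beta = TRUE for mixed-direction designs")
  structure(list(gene = as.character(gene), n_rare = as.integer(n_rare),
                 n_common = as.integer(n_common),
                 n_causal_rare = as.integer(n_causal_rare),
                 n_causal_common = as.integer(n_causal_common),
                 rare_maf_range = as.numeric(rare_maf_range),
                 common_maf_range = as.numeric(common_maf_range),
                 beta_rare = beta_rare, beta_common = beta_common,
                 ld_rho = ld_rho, maf_dist = maf_dist),
            class = "GeneSpec")
}

#' Simulation configuration
#'
#' Describes a full synthetic study: sample size and population structure,
#' the gene architectures, covariate effects on the trait, residual noise
#' and the number of phenotype replicates. Defaults mirror an exome-panel
#' design of 697 unrelated subjects from seven populations with 200 trait
#' replicates.
#'
#' @param gene_specs list of [gene_spec()] objects.
#' @param n_subjects number of subjects (default 697).
#' @param n_populations number of population groups (default 7).
#' @param population_weights simplex vector of population proportions
#'   (default uniform).
#' @param covariate_effects list with elements `sex`, `age`, `smoking`
#'   (scalars, trait units) and `population` (vector of per-population trait
#'   shifts, length `n_populations`).
#' @param noise_sd residual standard deviation of the trait (> 0).
#' @param n_replicates number of phenotype replicates (default 200).
#' @param maf_jitter_sd standard deviation of the per-population
#'   logit-scale perturbation of allele frequencies (ancestry
#'   stratification; default 0.25).
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(gene_specs,
                       n_subjects = 697L, n_populations = 7L,
                       population_weights = NULL,
                       covariate_effects = list(
                         sex = 0.5, age = 0.02, smoking = 0.5,
                         population = NULL),
                       noise_sd = 1, n_replicates = 200L,
                       maf_jitter_sd = 0.25) {
  stopifnot(length(gene_specs) >= 1L, noise_sd > 0, n_subjects >= 2,
            n_replicates >= 1, n_populations >= 1)
  if (!all(vapply(gene_specs, inherits, logical(1), "GeneSpec")))
    stop("gene_specs must be a list of gene_spec() objects")
  if (is.null(population_weights))
    population_weights <- rep(1 / n_populations, n_populations)
  if (length(population_weights) != n_populations ||
      abs(sum(population_weights) - 1) > 1e-8 || any(population_weights < 0))
    stop("population_weights must be a length-", n_populations,
         " non-negative vector summing to 1")
  defaults <- list(sex = 0.5, age = 0.02, smoking = 0.5, population = NULL)
  covariate_effects <- modifyList(defaults, covariate_effects)
  if (is.null(covariate_effects$population))
    covariate_effects$population <-
      seq(-0.5, 0.5, length.out = n_populations)
  if (length(covariate_effects$population) != n_populations)
    stop("covariate_effects$population must have one shift per population")
  labels <- vapply(gene_specs, `[[`, character(1), "gene")
  if (anyDuplicated(labels)) stop("duplicated gene labels in gene_specs")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_populations = as.integer(n_populations),
                 population_weights = as.numeric(population_weights),
                 gene_specs = gene_specs,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 maf_jitter_sd = maf_jitter_sd),
            class = "SimulationConfig")
}

#' Gene architecture presets of the nine associated genes
#'
#' Returns [gene_spec()] presets reproducing the causal-variant
#' architecture of the nine trait-associated genes of the emulated exome
#' design (counts of causal / total rare and common variants at each MAF
#' cutoff). Effect sizes are free parameters of the preset, not part of the
#' published architecture.
#'
#' @param cutoff MAF cutoff (0.005, 0.01 or 0.05) whose architecture to use.
#' @param beta_rare,beta_common effect per causal minor allele.
#' @param ld_rho adjacent-variant haplotype correlation.
#' @return Named list of `GeneSpec` objects.
#' @export
gaw17_gene_presets <- function(cutoff = 0.01, beta_rare = 0.5,
                               beta_common = 0.3, ld_rho = 0.3) {
  key <- match.arg(as.character(cutoff), c("0.005", "0.01", "0.05"))
  arch <- list(
    "0.005" = list(ARNT  = c(4, 14, 1, 4),  ELAVL4 = c(2, 7, 0, 3),
                   FLT1  = c(8, 24, 3, 11), FLT4   = c(2, 8, 0, 2),
                   HIF1A = c(3, 6, 1, 2),   HIF3A  = c(3, 13, 0, 8),
                   KDR   = c(8, 14, 2, 2),  VEGFA  = c(1, 5, 0, 1),
                   VEGFC = c(1, 1, 0, 0)),
    "0.01" = list(ARNT  = c(4, 15, 1, 3),  ELAVL4 = c(2, 7, 0, 3),
                  FLT1  = c(8, 25, 3, 10), FLT4   = c(2, 8, 0, 2),
                  HIF1A = c(3, 7, 1, 1),   HIF3A  = c(3, 15, 0, 6),
                  KDR   = c(8, 14, 2, 2),  VEGFA  = c(1, 5, 0, 1),
                  VEGFC = c(1, 1, 0, 0)),
    "0.05" = list(ARNT  = c(5, 17, 0, 1),  ELAVL4 = c(2, 8, 0, 2),
                  FLT1  = c(10, 32, 1, 3), FLT4   = c(2, 10, 0, 0),
                  HIF1A = c(4, 8, 0, 0),   HIF3A  = c(3, 17, 0, 4),
                  KDR   = c(9, 15, 1, 1),  VEGFA  = c(1, 6, 0, 0),
                  VEGFC = c(1, 1, 0, 0)))[[key]]
  cut <- as.numeric(key)
  lapply(stats::setNames(names(arch), names(arch)), function(g) {
    a <- arch[[g]]  # causal rare, total rare, causal common, total common
    gene_spec(g, n_rare = a[2], n_common = a[4],
              n_causal_rare = a[1], n_causal_common = a[3],
              rare_maf_range = c(5e-4, cut),
              common_maf_range = c(cut, 0.4),
              beta_rare = beta_rare, beta_common = beta_common,
              ld_rho = ld_rho)
  })
}

#' Effect-free gene specifications for null studies
#'
#' Builds `n_genes` genes with an exome-like, mostly-rare variant
#' architecture and no causal variants, for type-I-error studies. Variant
#' frequencies are drawn log-uniformly (1/f-shaped spectrum): by default 13
#' variants span (5e-4, 0.05), so roughly half fall below MAF 0.005 and
#' variants reclassify from common to rare as the cutoff rises, and 5
#' clearly common variants span (0.05, 0.35).
#'
#' @param n_genes number of genes.
#' @param n_rare,n_common variants per gene in the spectrum and common
#'   blocks.
#' @param ld_rho adjacent-variant haplotype correlation.
#' @return List of `GeneSpec` objects.
#' @export
null_gene_specs <- function(n_genes, n_rare = 13L, n_common = 5L,
                            ld_rho = 0.2) {
  lapply(seq_len(n_genes), function(i)
    gene_spec(sprintf("NG%04d", i), n_rare = n_rare, n_common = n_common,
              rare_maf_range = c(5e-4, 0.05),
              common_maf_range = c(0.05, 0.35), ld_rho = ld_rho,
              maf_dist = "loguniform"))
}

# log-uniform draws on [lo, hi]: density proportional to 1/f
rlogunif <- function(n, lo, hi) {
  if (n == 0L) return(numeric(0))
  if (lo <= 0) stop("log-uniform range must be positive")
  exp(runif(n, log(lo), log(hi)))
}

#' Draw population labels
#' @noRd
simulate_population <- function(config, seed = NULL) {
  with_seed(seed, sample.int(config$n_populations, config$n_subjects,
                             replace = TRUE, prob = config$population_weights))
}

#' Simulate a genotype panel
#'
#' For each gene, per-variant specification frequencies are drawn uniformly
#' from the spec ranges and the in-gene variant order is shuffled (so rare
#' and common variants interleave along the haplotype). Each population
#' perturbs the frequencies on the logit scale (ancestry stratification),
#' and two haplotypes per subject are generated by a first-order Markov
#' copying process with adjacent-variant copying probability `ld_rho`;
#' dosage is their sum. Realised sample MAFs are recomputed afterwards, so
#' a variant specified near a cutoff may drift across it, and columns whose
#' realised coded-allele frequency exceeds 0.5 are recoded to the minor
#' allele.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param population optional pre-drawn population labels (integers in
#'   `1..n_populations`); drawn from the configuration weights when absent.
#' @return List: `genotypes` (a [genotype_matrix()]), `info` (data frame
#'   `variant_id`, `gene`, `maf`, `spec_maf`, `causal`, `beta`),
#'   `population` (integer labels).
#' @export
simulate_genotypes <- function(config, seed = 1L, population = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(population))
    population <- simulate_population(config, derive_seed(seed, 101))
  n <- config$n_subjects
  with_seed(derive_seed(seed, 202), {
    cols <- list(); meta <- list()
    for (gs in config$gene_specs) {
      m <- gs$n_rare + gs$n_common
      rfun <- if (identical(gs$maf_dist, "loguniform")) rlogunif else runif
      f <- c(rfun(gs$n_rare, gs$rare_maf_range[1], gs$rare_maf_range[2]),
             rfun(gs$n_common, gs$common_maf_range[1], gs$common_maf_range[2]))
      causal <- c(seq_len(gs$n_rare) <= gs$n_causal_rare,
                  seq_len(gs$n_common) <= gs$n_causal_common)
      beta <- ifelse(causal, c(rep(gs$beta_rare, gs$n_rare),
                               rep(gs$beta_common, gs$n_common)), 0)
      ord <- sample.int(m)                     # interleave rare and common
      f <- f[ord]; causal <- causal[ord]; beta <- beta[ord]
      expected_mac <- 2 * n * f
      if (any(expected_mac < 1))
        warning("gene ", gs$gene, ": ", sum(expected_mac < 1),
                " variant(s) expect < 1 minor allele and may be monomorphic")
      G <- matrix(0L, n, m)
      for (k in seq_len(config$n_populations)) {
        idx <- which(population == k)
        if (!length(idx)) next
        fk <- stats::plogis(stats::qlogis(pmin(pmax(f, 1e-6), 1 - 1e-6)) +
                              rnorm(m, 0, config$maf_jitter_sd))
        nh <- 2L * length(idx)
        H <- matrix(0L, nh, m)
        H[, 1] <- rbinom(nh, 1L, fk[1])
        if (m > 1) for (j in 2:m) {
          copy <- runif(nh) < gs$ld_rho
          fresh <- rbinom(nh, 1L, fk[j])
          H[, j] <- ifelse(copy, H[, j - 1], fresh)
        }
        G[idx, ] <- H[seq(1, nh, by = 2), , drop = FALSE] +
          H[seq(2, nh, by = 2), , drop = FALSE]
      }
      colnames(G) <- sprintf("%s_v%02d", gs$gene, seq_len(m))
      cols[[gs$gene]] <- G
      meta[[gs$gene]] <- data.frame(variant_id = colnames(G),
                                    gene = gs$gene, spec_maf = f,
                                    causal = causal, beta = beta,
                                    stringsAsFactors = FALSE)
    }
    dosage <- do.call(cbind, cols)
    info <- do.call(rbind, meta)
    # orient to the realised minor allele; a flipped causal column keeps its
    # per-minor-allele interpretation because traits are built from the
    # oriented dosages
    p_coded <- colMeans(dosage) / 2
    flip <- p_coded > 0.5
    if (any(flip)) dosage[, flip] <- 2L - dosage[, flip, drop = FALSE]
    gm <- genotype_matrix(dosage, paste0("S", seq_len(n)), colnames(dosage))
    info$maf <- unname(variant_mafs(gm))
    rownames(info) <- NULL
    list(genotypes = gm,
         info = info[c("variant_id", "gene", "maf", "spec_maf",
                       "causal", "beta")],
         population = population)
  })
}

#' Simulate covariates
#'
#' Sex ~ Bernoulli(0.5), age ~ Normal(50, 10) truncated to `[18, 90]`,
#' smoking ~ Bernoulli(0.3); population labels from the configuration
#' weights (or supplied, to stay aligned with a genotype panel).
#'
#' @inheritParams simulate_genotypes
#' @return Covariate data frame (`subject_id`, `sex`, `age`, `smoking`,
#'   `population`).
#' @export
simulate_covariates <- function(config, seed = 1L, population = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(population))
    population <- simulate_population(config, derive_seed(seed, 101))
  n <- config$n_subjects
  with_seed(derive_seed(seed, 303), {
    age <- rnorm(n, 50, 10)
    while (any(out <- age < 18 | age > 90))
      age[out] <- rnorm(sum(out), 50, 10)
    data.frame(subject_id = paste0("S", seq_len(n)),
               sex = rbinom(n, 1, 0.5),
               age = round(age, 1),
               smoking = rbinom(n, 1, 0.3),
               population = paste0("P", population),
               stringsAsFactors = FALSE)
  })
}

#' Simulate trait replicates
#'
#' Builds an associated trait and a null trait over a fixed genotype panel.
#' Per replicate `r`, the null trait is the covariate linear predictor plus
#' Gaussian noise; the associated trait adds, per causal variant, its
#' effect times the minor-allele dosage. Genotypes are fixed across
#' replicates; noise is redrawn for every replicate and trait.
#'
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()].
#' @param info variant metadata with `causal` and `beta` columns.
#' @param covariates covariate data frame aligned with the genotypes.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return List of two matrices `associated` and `null`
#'   (subjects x replicates, rownames = subject ids).
#' @export
simulate_traits <- function(genotypes, info, covariates, config, seed = 1L) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(genotypes, "GenotypeMatrix"))
  if (!identical(as.character(covariates$subject_id), genotypes$subject_ids))
    stop("covariates and genotypes are misaligned")
  n <- config$n_subjects
  eff <- config$covariate_effects
  popnum <- as.integer(factor(covariates$population,
                              levels = paste0("P",
                                              seq_len(config$n_populations))))
  lp <- eff$sex * covariates$sex + eff$age * covariates$age +
    eff$smoking * covariates$smoking + eff$population[popnum]
  caus <- info$causal & info$beta != 0
  gterm <- if (any(caus)) {
    as.numeric(genotypes$dosage[, info$variant_id[caus], drop = FALSE] %*%
                 info$beta[caus])
  } else rep(0, n)
  R <- config$n_replicates
  with_seed(derive_seed(seed, 404), {
    noise_a <- matrix(rnorm(n * R, 0, config$noise_sd), n, R)
    noise_n <- matrix(rnorm(n * R, 0, config$noise_sd), n, R)
    assoc <- lp + gterm + noise_a
    null <- lp + noise_n
    dimnames(assoc) <- dimnames(null) <-
      list(genotypes$subject_ids, paste0("rep", seq_len(R)))
    list(associated = assoc, null = null)
  })
}

#' Simulate a complete study
#'
#' Draws population labels once, then genotypes, covariates and both trait
#' panels, all reproducibly from one seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return An `RVStudy` list: `genotypes`, `info`, `gene_map`,
#'   `covariates`, `traits` (list `associated`, `null`), `config`, `seed`.
#' @export
simulate_study <- function(config, seed = 1L) {
  population <- simulate_population(config, derive_seed(seed, 101))
  geno <- simulate_genotypes(config, seed, population)
  covariates <- simulate_covariates(config, seed, population)
  traits <- simulate_traits(geno$genotypes, geno$info, covariates, config, seed)
  structure(list(genotypes = geno$genotypes, info = geno$info,
                 gene_map = geno$info[c("variant_id", "gene")],
                 covariates = covariates, traits = traits,
                 config = config, seed = seed),
            class = "RVStudy")
}

#' Write a simulated study to the package's file formats
#'
#' Emits the exact tab-delimited formats the readers consume (genotype
#' matrix, gene map, covariates, one trait file per panel), so pipelines
#' can be exercised through the real I/O path.
#'
#' @param study an `RVStudy` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "RVStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    gene_map = file.path(dir, "gene_map.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    trait_associated = file.path(dir, "trait_associated.tsv"),
    trait_null = file.path(dir, "trait_null.tsv"))
  write_genotypes(study$genotypes, paths["genotypes"])
  write_gene_map(study$gene_map, paths["gene_map"])
  write_covariates(study$covariates, paths["covariates"])
  write_traits(study$traits$associated, paths["trait_associated"])
  write_traits(study$traits$null, paths["trait_null"])
  paths
}
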