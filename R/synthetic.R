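#' Population structure configuration
#'
#' Describes a stratified sample drawn from several diverged populations.
#' Per-locus differentiation follows the Balding-Nichols model: given an
#' ancestral minor allele frequency \eqn{p}, the frequency in each population
#' is drawn from \eqn{Beta(p(1-F)/F, (1-p)(1-F)/F)}, so that the mean is
#' \eqn{p} and the variance is \eqn{F p (1-p)}. `differentiation = 0` means
#' a panmictic sample.
#'
#' @param n_populations number of populations.
#' @param sizes integer vector of per-population sample sizes; defaults to a
#'   near-equal split of 697 individuals (the exon-sequencing study dimension).
#' @param differentiation Balding-Nichols drift parameter F in `[0, 1)`.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_populations = 7,
                              sizes = NULL,
                              differentiation = 0.1) {
  if (!is_count(n_populations)) stopf("'n_populations' must be a positive integer")
  if (is.null(sizes)) {
    base <- 697L %/% n_populations
    sizes <- rep(base, n_populations)
    sizes[seq_len(697L %% n_populations)] <- base + 1L
    if (n_populations > 697L) stopf("default sizes need n_populations <= 697")
  }
  sizes <- as.integer(sizes)
  if (length(sizes) != n_populations) stopf("'sizes' must have length %d", n_populations)
  if (any(sizes <= 0L)) stopf("population sizes must all be positive")
  check_prob(differentiation, "differentiation", lo = 0, hi = 1, open_hi = TRUE)
  structure(list(n_populations = as.integer(n_populations),
                 sizes = sizes,
                 differentiation = differentiation),
            class = "population_config")
}

#' Gene configuration for the genotype simulator
#'
#' @param gene gene name.
#' @param snps character vector of SNP names (unique within a study).
#' @param mafs ancestral minor allele frequencies in `(0, 0.5]`, one per SNP.
#' @param effects per-SNP additive trait effect (trait units per minor allele);
#'   0 marks a non-causal SNP.
#' @param ld within-gene haplotype correlation in `[0, 1)`; alleles at the
#'   SNPs of one gene are drawn from a Gaussian copula with this
#'   equicorrelation, which leaves each SNP's marginal Binomial(2, p) HWE
#'   distribution intact while inducing linkage disequilibrium.
#' @param private logical per SNP; a private variant is carried by exactly one
#'   heterozygous individual (its `mafs` entry is ignored).
#' @param chromosome chromosome label used in the `.map` export.
#' @return An object of class `gene_config`.
#' @export
gene_config <- function(gene, snps, mafs, effects = 0, ld = 0,
                        private = FALSE, chromosome = 1L) {
  s <- length(snps)
  if (s < 1L) stopf("gene '%s' needs at least one SNP", gene)
  if (anyDuplicated(snps)) stopf("duplicate SNP names in gene '%s'", gene)
  mafs <- rep_len(as.numeric(mafs), s)
  effects <- rep_len(as.numeric(effects), s)
  private <- rep_len(as.logical(private), s)
  check_prob(mafs[!private], "mafs", lo = 0, hi = 0.5, open_lo = TRUE)
  check_prob(ld, "ld", lo = 0, hi = 1, open_hi = TRUE)
  if (any(!is.finite(effects))) stopf("non-finite effect in gene '%s'", gene)
  structure(list(gene = as.character(gene), snps = as.character(snps),
                 mafs = mafs, effects = effects, ld = ld,
                 private = private, chromosome = chromosome),
            class = "gene_config")
}

#' Trait-generating model
#'
#' The quantitative trait is
#' `Q1 = intercept + sum(effect * count) + Age*bAge + Sex*bSex + Smoke*bSmoke + N(0, residual_sd)`.
#'
#' @param intercept trait units.
#' @param covariate_effects named numeric vector with entries `Age`, `Sex`,
#'   `Smoke` (trait units per covariate unit).
#' @param residual_sd residual standard deviation (> 0).
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(intercept = 0,
                        covariate_effects = c(Age = 0.01, Sex = 0.2, Smoke = 0.3),
                        residual_sd = 1) {
  if (!is.finite(residual_sd) || residual_sd <= 0) stopf("'residual_sd' must be > 0")
  ce <- c(Age = 0, Sex = 0, Smoke = 0)
  if (length(covariate_effects)) {
    if (is.null(names(covariate_effects)) ||
        !all(names(covariate_effects) %in% names(ce)))
      stopf("'covariate_effects' must be named among Age, Sex, Smoke")
    ce[names(covariate_effects)] <- covariate_effects
  }
  structure(list(intercept = intercept, covariate_effects = ce,
                 residual_sd = residual_sd),
            class = "trait_model")
}

#' Draw per-population allele frequencies (Balding-Nichols)
#'
#' @param config a [population_config()].
#' @param ancestral_maf ancestral minor allele frequency in `(0, 0.5]`.
#' @param seed optional integer seed.
#' @return Numeric vector of length `n_populations` with frequencies in `[0, 1]`.
#'   With `differentiation = 0` every population equals `ancestral_maf` exactly.
#' @export
draw_population_freqs <- function(config, ancestral_maf, seed = NULL) {
  stopifnot(inherits(config, "population_config"))
  check_prob(ancestral_maf, "ancestral_maf", lo = 0, hi = 0.5, open_lo = TRUE)
  if (!is.null(seed)) set.seed(seed)
  f <- config$differentiation
  if (f == 0) return(rep(ancestral_maf, config$n_populations))
  a <- ancestral_maf * (1 - f) / f
  b <- (1 - ancestral_maf) * (1 - f) / f
  stats::rbeta(config$n_populations, a, b)
}

#' Construct a genotype matrix object
#'
#' @param values n x p integer matrix of minor-allele counts in `{0, 1, 2}`
#'   with individual ids as rownames and SNP ids as colnames.
#' @param gene_of_snp named character vector mapping every SNP id to one gene.
#' @param population optional per-individual population labels.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, gene_of_snp, population = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stopf("genotype matrix needs SNP ids as colnames")
  if (anyDuplicated(colnames(values))) stopf("duplicate SNP ids")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("ID%04d", seq_len(nrow(values)))
  if (!all(values %in% c(0, 1, 2))) stopf("genotype entries must be 0, 1 or 2")
  miss <- setdiff(colnames(values), names(gene_of_snp))
  if (length(miss)) stopf("no gene mapping for SNP(s): %s", paste(miss, collapse = ", "))
  gene_of_snp <- gene_of_snp[colnames(values)]
  if (!is.null(population)) {
    population <- as.character(rep_len(population, nrow(values)))
  }
  structure(list(values = values, gene_of_snp = gene_of_snp,
                 population = population),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d SNPs in %d genes\n",
              nrow(x$values), ncol(x$values), length(unique(x$gene_of_snp))))
  if (!is.null(x$population))
    cat("Populations:", paste(names(table(x$population)), table(x$population),
                              sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Simulate genotypes for a multi-population study
#'
#' Per SNP, a per-population frequency is drawn from the Balding-Nichols
#' model around the ancestral MAF; each individual then receives a
#' Binomial(2, frequency) minor-allele count under Hardy-Weinberg
#' equilibrium. Within a gene, the two allele draws of an individual use a
#' Gaussian copula with the gene's `ld` equicorrelation, so within-gene LD is
#' present while per-SNP marginals stay binomial. Private variants are
#' assigned to a single random heterozygote.
#'
#' @param pop_config a [population_config()].
#' @param gene_configs list of [gene_config()] objects; SNP names must be
#'   unique across genes.
#' @param seed optional integer seed (fixed seed gives bit-identical output).
#' @return A [genotype_matrix()] carrying per-individual population labels.
#' @export
simulate_genotypes <- function(pop_config, gene_configs, seed = NULL) {
  stopifnot(inherits(pop_config, "population_config"))
  if (inherits(gene_configs, "gene_config")) gene_configs <- list(gene_configs)
  all_snps <- unlist(lapply(gene_configs, `[[`, "snps"))
  if (anyDuplicated(all_snps))
    stopf("duplicate SNP names across genes: %s",
          paste(unique(all_snps[duplicated(all_snps)]), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n <- sum(pop_config$sizes)
  pop_of <- rep(seq_len(pop_config$n_populations), pop_config$sizes)
  G <- matrix(0L, n, length(all_snps))
  colnames(G) <- all_snps
  rownames(G) <- sprintf("ID%04d", seq_len(n))
  gene_map <- character(0)
  col0 <- 0L
  for (gc in gene_configs) {
    s <- length(gc$snps)
    gene_map <- c(gene_map, stats::setNames(rep(gc$gene, s), gc$snps))
    # Per-population allele frequencies for the non-private SNPs. Drift is
    # haplotype-level: within a gene the populations' frequency deviations
    # are shared (one Balding-Nichols quantile per gene x population, turned
    # into each SNP's frequency via its exact marginal Beta distribution).
    freqs <- matrix(0, pop_config$n_populations, s)
    fst <- pop_config$differentiation
    u <- stats::runif(pop_config$n_populations)
    for (j in seq_len(s)) {
      if (gc$private[j]) next
      if (fst == 0) {
        freqs[, j] <- gc$mafs[j]
      } else {
        a <- gc$mafs[j] * (1 - fst) / fst
        b <- (1 - gc$mafs[j]) * (1 - fst) / fst
        freqs[, j] <- stats::qbeta(u, a, b)
      }
    }
    rho <- gc$ld
    for (k in seq_len(pop_config$n_populations)) {
      rows <- which(pop_of == k)
      ni <- length(rows)
      thr <- stats::qnorm(pmin(pmax(freqs[k, ], 0), 1))
      # two haplotypes per individual; equicorrelated normals within the gene
      for (h in 1:2) {
        if (rho > 0 && s > 1L) {
          u <- stats::rnorm(ni)
          z <- sqrt(rho) * u + sqrt(1 - rho) * matrix(stats::rnorm(ni * s), ni, s)
        } else {
          z <- matrix(stats::rnorm(ni * s), ni, s)
        }
        allele <- sweep(z, 2L, thr, "<")
        G[rows, col0 + seq_len(s)] <- G[rows, col0 + seq_len(s)] + allele
      }
    }
    for (j in which(gc$private)) {
      G[, col0 + j] <- 0L
      G[sample.int(n, 1L), col0 + j] <- 1L
    }
    col0 <- col0 + s
  }
  storage.mode(G) <- "integer"
  genotype_matrix(G, gene_map, population = paste0("P", pop_of))
}

#' Simulate fixed-genotype phenotype replicates
#'
#' Covariates (Age, Sex, Smoking) are drawn once and held fixed; the trait is
#' redrawn independently for every replicate, mirroring the workshop design
#' in which genotypes are shared across replicates and only phenotypes vary.
#'
#' @param genotypes a [genotype_matrix()].
#' @param trait a [trait_model()].
#' @param gene_configs list of [gene_config()] supplying per-SNP effects.
#' @param n_replicates number of phenotype replicates (>= 1).
#' @param seed optional integer seed.
#' @return An object of class `replicate_set`: list with `genotypes`
#'   (shared), `phenotypes` (list of data frames with columns
#'   `IID Q1 Age Sex Smoke Pop`), and `truth` (causal genes/SNPs and
#'   generating parameter values).
#' @export
simulate_replicates <- function(genotypes, trait, gene_configs, n_replicates,
                                seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(trait, "trait_model"))
  if (!is_count(n_replicates)) stopf("'n_replicates' must be a positive integer")
  if (trait$residual_sd <= 0) stopf("'residual_sd' must be > 0")
  if (inherits(gene_configs, "gene_config")) gene_configs <- list(gene_configs)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes$values)
  effects <- unlist(lapply(gene_configs, function(g) stats::setNames(g$effects, g$snps)))
  effects <- effects[intersect(names(effects), colnames(genotypes$values))]
  causal_snps <- names(effects)[effects != 0]
  causal_genes <- unique(genotypes$gene_of_snp[causal_snps])
  genetic <- if (length(causal_snps))
    drop(genotypes$values[, causal_snps, drop = FALSE] %*% effects[causal_snps])
  else rep(0, n)
  age <- round(stats::runif(n, 20, 70), 1)
  sex <- stats::rbinom(n, 1L, 0.5)
  smoke <- stats::rbinom(n, 1L, 0.5)
  pop <- genotypes$population %||% rep("P1", n)
  ce <- trait$covariate_effects
  fixed_part <- trait$intercept + genetic +
    ce["Age"] * age + ce["Sex"] * sex + ce["Smoke"] * smoke
  phen <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    q1 <- fixed_part + stats::rnorm(n, 0, trait$residual_sd)
    phen[[r]] <- data.frame(IID = rownames(genotypes$values), Q1 = as.numeric(q1),
                            Age = age, Sex = sex, Smoke = smoke, Pop = pop,
                            stringsAsFactors = FALSE)
  }
  structure(list(genotypes = genotypes, phenotypes = phen,
                 truth = list(causal_genes = causal_genes,
                              causal_snps = causal_snps,
                              effects = effects[causal_snps],
                              trait = trait)),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("Replicate set: %d replicates of %d individuals, %d SNPs (%d causal in %d genes)\n",
              length(x$phenotypes), nrow(x$genotypes$values),
              ncol(x$genotypes$values), length(x$truth$causal_snps),
              length(x$truth$causal_genes)))
  invisible(x)
}

#' Default study configuration
#'
#' A desk-scale emulation of the exon-sequencing workshop data: 697
#' individuals in 7 populations, 9 causal genes carrying 39 causal SNPs
#' (common, rare and private), plus decoy genes. Effect sizes are chosen so
#' the strongest gene contributes roughly 10 percent of trait variance and
#' the remaining causal genes 3-6 percent each, yielding a trait R-squared
#' near 0.4 against a unit residual.
#'
#' @param n_decoy_genes number of non-causal genes.
#' @param snps_per_decoy SNPs per decoy gene.
#' @param differentiation Balding-Nichols drift parameter.
#' @param ld default within-gene haplotype correlation.
#' @return A list with components `population`, `genes`, `trait`,
#'   `n_replicates`; pass to [simulate_study()].
#' @export
gaw_study_config <- function(n_decoy_genes = 21, snps_per_decoy = 5,
                             differentiation = 0.1, ld = 0.9) {
  pop <- population_config(7, differentiation = differentiation)
  causal <- list(
    gene_config("FLT1", paste0("C13S", 520:526),
                mafs    = c(0.30, 0.15, 0.067, 0.028, 0.010, 0.004, 0.002),
                effects = c(0.15, 0.18, 0.45, 0.50, 0.30, 0.80, 0.25),
                ld = ld, chromosome = 13),
    gene_config("KDR", paste0("C4S", 1870:1874),
                mafs    = c(0.25, 0.12, 0.05, 0.01, 0.002),
                effects = c(0.15, 0.22, 0.35, 0.55, 0.30),
                ld = ld, chromosome = 4),
    gene_config("ARNT", paste0("C1S", 6530:6533),
                mafs    = c(0.22, 0.10, 0.03, 0.003),
                effects = c(0.18, 0.25, 0.37, 0.30),
                ld = ld, chromosome = 1),
    gene_config("ELAVL4", paste0("C1S", 2940:2943),
                mafs    = c(0.20, 0.09, 0.02, 0.002),
                effects = c(0.16, 0.25, 0.34, 0.30),
                ld = ld, chromosome = 1),
    gene_config("FLT4", paste0("C5S", 5130:5133),
                mafs    = c(0.18, 0.08, 0.03, 0.002),
                effects = c(0.17, 0.26, 0.37, 0.30),
                ld = ld, chromosome = 5),
    gene_config("HIF1A", paste0("C14S", 1730:1733),
                mafs    = c(0.15, 0.07, 0.02, 0.001),
                effects = c(0.19, 0.28, 0.37, 1.25),
                private = c(FALSE, FALSE, FALSE, TRUE),
                ld = ld, chromosome = 14),
    gene_config("HIF3A", paste0("C19S", 4810:4813),
                mafs    = c(0.16, 0.08, 0.02, 0.002),
                effects = c(0.17, 0.26, 0.37, 0.30),
                ld = ld, chromosome = 19),
    gene_config("VEGFA", paste0("C6S", 2620:2623),
                mafs    = c(0.28, 0.12, 0.04, 0.003),
                effects = c(0.16, 0.24, 0.34, 0.70),
                ld = ld, chromosome = 6),
    gene_config("VEGFC", paste0("C4S", 4150:4152),
                mafs    = c(0.20, 0.08, 0.01),
                effects = c(0.19, 0.26, 0.55),
                ld = ld, chromosome = 4))
  decoys <- lapply(seq_len(n_decoy_genes), function(i) {
    gene_config(sprintf("DECOY%02d", i),
                sprintf("D%02dS%03d", i, seq_len(snps_per_decoy)),
                mafs = stats::setNames(
                  rep(c(0.25, 0.10, 0.05, 0.02, 0.005), length.out = snps_per_decoy), NULL),
                effects = 0, ld = ld,
                chromosome = (i %% 22) + 1L)
  })
  list(population = pop, genes = c(causal, decoys),
       trait = trait_model(), n_replicates = 1L)
}

#' Simulate a full study (genotypes + phenotype replicates)
#'
#' @param config list as returned by [gaw_study_config()]; may carry an
#'   `n_replicates` override.
#' @param seed integer seed (mandatory for reproducibility).
#' @param n_replicates optional override of `config$n_replicates`.
#' @return A `replicate_set`.
#' @export
simulate_study <- function(config, seed, n_replicates = NULL) {
  if (missing(seed) || is.null(seed)) stopf("'seed' is mandatory")
  n_rep <- n_replicates %||% config$n_replicates %||% 1L
  geno <- simulate_genotypes(config$population, config$genes, seed = seed)
  simulate_replicates(geno, config$trait, config$genes, n_rep, seed = seed + 1L)
}
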