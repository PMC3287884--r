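test_that("Balding-Nichols frequency draws match the beta-model moments", {
  cfg <- population_config(7, differentiation = 0)
  expect_equal(draw_population_freqs(cfg, 0.3), rep(0.3, 7))

  cfg <- population_config(1, sizes = 1, differentiation = 0.1)
  set.seed(42)
  draws <- replicate(10000, draw_population_freqs(cfg, 0.3))
  # beta(a, b) with mean 0.3 and variance F p (1 - p) = 0.021
  mc_se_mean <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.3), 3 * mc_se_mean)
  m4 <- mean((draws - mean(draws))^4)
  mc_se_var <- sqrt((m4 - var(draws)^2) / length(draws))
  expect_lt(abs(var(draws) - 0.1 * 0.3 * 0.7), 3 * mc_se_var)
})

test_that("out-of-range generator inputs are rejected", {
  cfg <- population_config(3, sizes = c(5, 5, 5))
  expect_error(draw_population_freqs(cfg, 0.6), "ancestral_maf")
  expect_error(draw_population_freqs(cfg, NaN), "ancestral_maf")
  expect_error(population_config(2, sizes = c(5, -1)), "positive")
  expect_error(population_config(2, sizes = c(5, 5), differentiation = 1), "differentiation")
  expect_error(trait_model(residual_sd = 0), "residual_sd")
  expect_error(gene_config("g", c("a", "a"), 0.1), "duplicate")
})

test_that("genotype simulation respects marginal binomial sampling", {
  pc <- population_config(1, sizes = 5000, differentiation = 0)
  gc <- gene_config("g", c("s1", "s2"), mafs = c(0.05, 0.3), ld = 0)
  G <- simulate_genotypes(pc, gc, seed = 7)$values
  # realized allele frequency within 3 binomial SEs of the target
  for (j in 1:2) {
    p <- c(0.05, 0.3)[j]
    se3 <- 3 * sqrt(p * (1 - p) / (2 * 5000))
    expect_lt(abs(sum(G[, j]) / 10000 - p), se3)
  }
  expect_true(all(G %in% 0:2))
})

test_that("private variants are carried by exactly one heterozygote", {
  pc <- population_config(2, sizes = c(50, 50), differentiation = 0.1)
  gc <- gene_config("g", c("s1", "s2"), mafs = c(0.2, 0.2),
                    private = c(FALSE, TRUE))
  G <- simulate_genotypes(pc, gc, seed = 3)$values
  expect_equal(sum(G[, "s2"]), 1)
  expect_equal(max(G[, "s2"]), 1)
})

test_that("fixed seeds give bit-identical genotypes; duplicate SNPs are rejected", {
  pc <- population_config(2, sizes = c(30, 30), differentiation = 0.1)
  gcs <- list(gene_config("g1", c("a1", "a2"), c(0.1, 0.3), ld = 0.5),
              gene_config("g2", "b1", 0.2))
  g1 <- simulate_genotypes(pc, gcs, seed = 11)
  g2 <- simulate_genotypes(pc, gcs, seed = 11)
  expect_identical(g1$values, g2$values)
  dup <- list(gene_config("g1", "a1", 0.1), gene_config("g2", "a1", 0.1))
  expect_error(simulate_genotypes(pc, dup, seed = 1), "duplicate")
})

test_that("within-gene copula induces LD but keeps marginals", {
  pc <- population_config(1, sizes = 8000, differentiation = 0)
  gc <- gene_config("g", c("s1", "s2"), mafs = c(0.2, 0.2), ld = 0.9)
  G <- simulate_genotypes(pc, gc, seed = 9)$values
  expect_gt(cor(G[, 1], G[, 2])^2, 0.2)
  se3 <- 3 * sqrt(0.2 * 0.8 / (2 * 8000))
  expect_lt(abs(mean(G[, 1]) / 2 - 0.2), se3)
})

test_that("null trait replicates have the configured residual variance", {
  pc <- population_config(2, sizes = c(349, 348), differentiation = 0.05)
  gc <- gene_config("g", c("s1", "s2"), c(0.2, 0.1), effects = 0, ld = 0.5)
  geno <- simulate_genotypes(pc, list(gc), seed = 2)
  tm <- trait_model(covariate_effects = c(Age = 0, Sex = 0, Smoke = 0),
                    residual_sd = 1)
  rs <- simulate_replicates(geno, tm, list(gc), n_replicates = 20, seed = 4)
  v <- sapply(rs$phenotypes, function(p) var(p$Q1))
  # chi-square sampling of a unit variance at n = 697
  expect_lt(abs(mean(v) - 1), 3 * sd(v) / sqrt(length(v)))
  expect_length(rs$truth$causal_snps, 0)
})

test_that("a causal SNP's configured variance share is recovered as regression R2", {
  n <- 5000
  pc <- population_config(1, sizes = n, differentiation = 0)
  # share 0.1: beta^2 * 2 p (1-p) = 1/9 with residual_sd 1
  beta <- sqrt((1 / 9) / (2 * 0.25 * 0.75))
  gc <- gene_config("g", "s1", 0.25, effects = beta)
  geno <- simulate_genotypes(pc, gc, seed = 6)
  tm <- trait_model(covariate_effects = c(Age = 0, Sex = 0, Smoke = 0))
  rs <- simulate_replicates(geno, tm, list(gc), n_replicates = 1, seed = 8)
  r2 <- summary(lm(rs$phenotypes[[1]]$Q1 ~ geno$values[, 1]))$r.squared
  mc_se <- sqrt(4 * 0.1 * (1 - 0.1)^2 / n)
  expect_lt(abs(r2 - 0.1), 3 * mc_se)
})

test_that("replicates share genotypes and covariates but redraw the trait", {
  rs <- tiny_study(seed = 5, n_replicates = 3)
  expect_identical(rs$genotypes$values, rs$genotypes$values)
  expect_identical(rs$phenotypes[[1]]$Age, rs$phenotypes[[2]]$Age)
  expect_identical(rs$phenotypes[[1]]$Sex, rs$phenotypes[[3]]$Sex)
  expect_false(identical(rs$phenotypes[[1]]$Q1, rs$phenotypes[[2]]$Q1))
  expect_error(simulate_replicates(rs$genotypes, trait_model(), list(), 0), "n_replicates")
})

test_that("the default study mirrors the published dimensions", {
  cfg <- gaw_study_config()
  expect_equal(sum(cfg$population$sizes), 697L)
  expect_equal(cfg$population$n_populations, 7L)
  causal <- Filter(function(g) any(g$effects != 0), cfg$genes)
  expect_length(causal, 9)
  expect_equal(sum(sapply(causal, function(g) sum(g$effects != 0))), 39)
  expect_setequal(sapply(causal, `[[`, "gene"),
                  c("FLT1", "KDR", "ARNT", "ELAVL4", "FLT4",
                    "HIF1A", "HIF3A", "VEGFA", "VEGFC"))
})
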