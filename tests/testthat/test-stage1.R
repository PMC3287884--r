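test_that("minor allele frequency is the folded allele-count fraction", {
  expect_equal(compute_maf(c(0, 0, 0, 0)), 0)
  expect_equal(compute_maf(c(0, 1, 2, 0, 1)), 0.4)
  expect_equal(compute_maf(c(2, 2, 2, 2)), 0)     # folded to the minor side
  expect_error(compute_maf(numeric(0)), "empty")
  expect_error(compute_maf(c(0, 3)), "0, 1 or 2")
  # the published FLT1 frequencies against the MAF < 0.05 rule
  expect_false(0.0667 < 0.05)   # C13S523: common
  expect_true(0.0280 < 0.05)    # C13S522: rare under the stated rule
})

test_that("single-SNP regression matches the normal-equations oracle", {
  set.seed(31)
  n <- 8
  g <- c(0, 1, 2, 0, 1, 2, 0, 1)
  age <- rnorm(n, 50, 8)
  y <- 0.7 * g + 0.05 * age + rnorm(n)
  r <- ols_regression(y, g, data.frame(Age = age))
  X <- cbind(1, g, age)
  bh <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% bh
  s2 <- sum(res^2) / (n - 3)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(r$beta, bh[2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(r$se, se, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(r$p_value, 2 * pt(-abs(bh[2] / se), n - 3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("degenerate and rank-deficient designs are flagged", {
  g <- c(0, 1, 2, 0, 1, 2)
  r <- ols_regression(2 * g + 3, g)
  expect_equal(r$beta, 2)
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))
  expect_error(ols_regression(rnorm(6), g, data.frame(gg = g)), "collinear")
})

test_that("null regressions reject at the nominal rate", {
  set.seed(77)
  n <- 150
  g <- rbinom(n, 2, 0.3)
  hits <- 0L
  n_sim <- 2000
  for (i in seq_len(n_sim)) {
    p <- ols_regression(rnorm(n), g)$p_value
    if (p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.04)
  expect_lte(hits / n_sim, 0.06)
})

test_that("indicator collapsing equals a brute-force carrier scan", {
  geno <- toy_genotypes()
  mafs <- apply(geno$values, 2, compute_maf)
  cc <- collapse_rare(geno, rare_maf_threshold = 0.2)
  rare <- names(mafs)[mafs < 0.2]
  for (g in unique(geno$gene_of_snp[rare])) {
    cols <- intersect(rare, names(geno$gene_of_snp)[geno$gene_of_snp == g])
    brute <- apply(geno$values[, cols, drop = FALSE], 1,
                   function(x) as.integer(any(x >= 1)))
    expect_equal(unname(cc$X[, paste0(g, ".rare")]), unname(brute))
  }
  # common SNPs pass through unchanged
  common <- names(mafs)[mafs >= 0.2]
  expect_identical(cc$X[, common], geno$values[, common])
  expect_true(all(cc$X[, cc$is_collapsed] %in% 0:1))
  # count variant
  cnt <- collapse_rare(geno, 0.2, method = "count")
  expect_true(all(cnt$X[, cnt$is_collapsed] >=
                    cc$X[, cc$is_collapsed]))
})

test_that("carrier status covers homozygous-rare individuals", {
  G <- matrix(c(2L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), ncol = 1,
              dimnames = list(NULL, "s1"))
  geno <- genotype_matrix(G, c(s1 = "g"))
  cc <- collapse_rare(geno, 0.5)
  expect_equal(unname(cc$X[, "g.rare"]), c(1L, rep(0L, 9)))
})

test_that("the Bonferroni threshold is exactly alpha over the test count", {
  expect_equal(signif(bonferroni_threshold(24487, 0.05), 3), 2.04e-6)
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(signif(bonferroni_threshold(6000, 0.05), 3), 8.33e-6)
  for (n in c(2, 17, 3205)) expect_equal(bonferroni_threshold(n, 0.05), 0.05 / n)
  expect_error(bonferroni_threshold(0, 0.05), "n_tests")
})

test_that("genotype PCA matches a dense eigendecomposition up to sign", {
  set.seed(15)
  G <- matrix(rbinom(50, 2, 0.4), nrow = 10)
  colnames(G) <- paste0("s", 1:5)
  sc <- pca_genotypes(G, 3)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  eg <- eigen(cov(Gc))
  for (j in 1:3) {
    ref <- Gc %*% eg$vectors[, j]
    expect_equal(abs(drop(cor(sc[, j], ref))), 1, tolerance = 1e-8)
  }
  # identical rows: zero-variance scores
  G0 <- matrix(1, 6, 4, dimnames = list(NULL, paste0("s", 1:4)))
  G0[, 1] <- c(0, 0, 0, 0, 0, 0)
  expect_error(pca_genotypes(G0 * 0, 2), "monomorphic")
  expect_error(pca_genotypes(G, 10), "k")
})

test_that("identical rows give constant principal-component scores", {
  G <- matrix(rep(c(0, 1, 2, 1), each = 8), nrow = 8)
  colnames(G) <- paste0("s", 1:4)
  G[1, 1] <- 1  # minimal variation so PCA is defined
  sc <- pca_genotypes(G, 2)
  expect_lt(var(sc[-1, 2]), 1e-20)
})

test_that("PC1 separates two simulated populations", {
  pc <- population_config(2, sizes = c(200, 200), differentiation = 0.1)
  gcs <- lapply(1:120, function(i) gene_config(paste0("g", i), paste0("g", i, "snp"), 0.3))
  geno <- simulate_genotypes(pc, gcs, seed = 21)
  sc <- pca_genotypes(geno, 2)
  lab <- as.integer(factor(geno$population))
  expect_gt(abs(cor(sc[, 1], lab)), 0.9)
})

test_that("the scan equals standalone per-column regressions, ordered", {
  rs <- tiny_study(seed = 12, n_replicates = 1, n_decoys = 1)
  cfg <- screen_config(collapse = FALSE,
                       covariate_sets = list(crude = character(0),
                                             adj = c("Age", "Sex")))
  res <- scan_assoc(rs$genotypes, rs$phenotypes[[1]], cfg)
  expect_equal(nrow(res), 2 * ncol(rs$genotypes$values))
  expect_false(is.unsorted(order(res$model_tag, res$snp_id)))
  ph <- rs$phenotypes[[1]]
  idx <- match(rownames(rs$genotypes$values), ph$IID)
  for (s in sample(colnames(rs$genotypes$values), 4)) {
    row <- res[res$model_tag == "adj" & res$snp_id == s, ]
    g <- rs$genotypes$values[, s]
    if (var(g) == 0) { expect_true(is.na(row$p)); next }
    r <- ols_regression(ph$Q1[idx], g, ph[idx, c("Age", "Sex")])
    expect_equal(row$beta, r$beta, tolerance = 1e-12)
    expect_equal(row$p, r$p_value, tolerance = 1e-12)
  }
})

test_that("PIG identification equals a brute-force filter", {
  set.seed(33)
  res <- data.frame(model_tag = "m", snp_id = paste0("s", 1:40),
                    gene = rep(paste0("g", 1:8), each = 5),
                    beta = rnorm(40), se = 1, p = runif(40)^3)
  thr <- 0.01
  brute <- sort(unique(res$gene[res$p <= thr]))
  expect_equal(identify_pigs(res, thr), brute)
  expect_equal(identify_pigs(res, 0), character(0))
  one <- res[which.min(res$p), ]
  expect_equal(identify_pigs(res, min(res$p)), one$gene)
  expect_equal(identify_pigs(res[0, ], 0.05), character(0))
})

test_that("confusion counts match hand enumeration and TP+FN is invariant", {
  causal <- c("A", "B", "C")
  found <- list(c("A", "B", "C"), character(0), c("A", "X"),
                c("X", "Y", "Z"), c("B", "C", "Y"))
  cc <- confusion_counts(found, causal)
  expect_equal(cc$per_replicate$TP, c(3, 0, 1, 0, 2))
  expect_equal(cc$per_replicate$FP, c(0, 0, 1, 3, 1))
  expect_equal(cc$per_replicate$FN, c(0, 3, 2, 3, 1))
  expect_true(all(cc$per_replicate$TP + cc$per_replicate$FN == 3))
  expect_equal(cc$summary$mean[cc$summary$count == "TP"], mean(c(3, 0, 1, 0, 2)))
  expect_equal(cc$summary$min[cc$summary$count == "FP"], 0)
  expect_equal(cc$summary$max[cc$summary$count == "FP"], 3)
  expect_error(confusion_counts(found, character(0)), "non-empty")
})

test_that("PC adjustment leaves MAFs and collapsing untouched", {
  rs <- tiny_study(seed = 18, n_replicates = 1, n_decoys = 1)
  before <- collapse_rare(rs$genotypes, 0.05)
  ph2 <- add_pcs(rs$phenotypes[[1]], rs$genotypes, 3)
  after <- collapse_rare(rs$genotypes, 0.05)
  expect_identical(before$X, after$X)
  expect_true(all(paste0("PC", 1:3) %in% names(ph2)))
})
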