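test_that("Cronbach's alpha matches its defining formula", {
  # two perfectly correlated equal-variance items
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x)), 1)
  # population-uncorrelated items via a diagonal covariance input
  expect_equal(cronbach_alpha(diag(c(1, 2, 3)), covariance = TRUE), 0)
  # 3-item toy covariance against hand arithmetic
  C <- matrix(c(1.0, 0.4, 0.3,
                0.4, 1.2, 0.5,
                0.3, 0.5, 0.9), 3)
  hand <- (3 / 2) * (1 - sum(diag(C)) / sum(C))
  expect_equal(cronbach_alpha(C, covariance = TRUE), hand)
  expect_error(cronbach_alpha(matrix(0, 2, 2), covariance = TRUE), "zero total")
  expect_error(cronbach_alpha(cbind(x)), "2 items")
})

test_that("alpha rises with average inter-item covariance on a fixed scale", {
  base <- diag(3)
  lo <- base; lo[lower.tri(lo)] <- lo[upper.tri(lo)] <- 0.2
  hi <- base; hi[lower.tri(hi)] <- hi[upper.tri(hi)] <- 0.5
  expect_gt(cronbach_alpha(hi, covariance = TRUE),
            cronbach_alpha(lo, covariance = TRUE))
})

test_that("LD r-squared is the squared genotype correlation", {
  set.seed(41)
  g1 <- rbinom(10000, 2, 0.3)
  g2 <- rbinom(10000, 2, 0.3)
  expect_equal(ld_r2(g1, g1), 1)
  expect_lt(ld_r2(g1, g2), 0.01)
  g3 <- 2 - g1  # allele flip
  expect_equal(ld_r2(g1, g3), cor(g1, g3)^2)
  expect_equal(ld_r2(g1, g3), 1)
  expect_error(ld_r2(g1, rep(0, 10000)), "monomorphic")
  expect_error(ld_r2(g1, g2[1:10]), "length")
})

test_that("eigenvalue screening matches the dense eigensolver", {
  x <- c(0, 1, 0, 1); y <- c(0, 0, 1, 1)   # exactly uncorrelated
  expect_equal(eigen_screen(cbind(x, y)), c(1, 1))
  expect_equal(eigen_screen(cbind(x, x + 0)), c(2, 0), tolerance = 1e-12)
  set.seed(52)
  G <- matrix(rbinom(100, 2, 0.4), 20)
  ev <- eigen_screen(G)
  expect_equal(ev, eigen(cor(G), symmetric = TRUE)$values, tolerance = 1e-12)
  expect_false(is.unsorted(rev(ev)))
  expect_equal(sum(ev), ncol(G))
  G[, 2] <- 1
  expect_warning(ev2 <- eigen_screen(G), "monomorphic")
  expect_length(ev2, 4)
})

test_that("greedy SNP selection equals exhaustive enumeration of the rule", {
  set.seed(63)
  snps <- paste0("s", 1:8)
  res <- data.frame(model_tag = "m", snp_id = snps, gene = "G",
                    beta = 1, se = 1, p = c(1e-8, 5e-7, 2e-3, 0.2, 1e-5, 0.04, 3e-6, 0.6))
  r2 <- matrix(runif(64, 0, 0.3), 8, dimnames = list(snps, snps))
  r2 <- (r2 + t(r2)) / 2; diag(r2) <- 1
  r2["s1", "s2"] <- r2["s2", "s1"] <- 0.95   # near-duplicate pair
  r2["s1", "s7"] <- r2["s7", "s1"] <- 0.5
  sel <- select_snps("G", res, r2, r2_threshold = 0.8, r2_min = 0.1,
                     max_indicators = 4)
  # brute-force replay of the documented rule
  ord <- res$snp_id[order(res$p, res$snp_id)]
  kept <- character(0)
  for (s in ord) {
    if (!length(kept)) kept <- s
    else if (max(r2[s, kept]) <= 0.8 && max(r2[s, kept]) >= 0.1) kept <- c(kept, s)
    if (length(kept) >= 4) break
  }
  expect_equal(sel, kept)
  expect_false(all(c("s1", "s2") %in% sel))  # duplicate pruned
  # single-SNP gene
  one <- res[1, ]
  expect_equal(select_snps("G", one, r2[1, 1, drop = FALSE]), "s1")
})

test_that("selection is deterministic under permutation of the result rows", {
  set.seed(64)
  snps <- paste0("s", 1:6)
  res <- data.frame(model_tag = "m", snp_id = snps, gene = "G",
                    beta = 1, se = 1, p = c(0.2, 1e-5, 1e-5, 0.5, 1e-7, 0.9))
  r2 <- diag(6); dimnames(r2) <- list(snps, snps)
  r2[lower.tri(r2)] <- 0.2; r2[upper.tri(r2)] <- 0.2; diag(r2) <- 1
  a <- select_snps("G", res, r2)
  b <- select_snps("G", res[sample(6), ], r2)
  expect_identical(a, b)
  # ties broken by SNP id
  expect_true(which(a == "s2") < which(a == "s3"))
})

test_that("assembled models parse, are identified, and round-trip", {
  constructs <- list(FLT1 = c("a1", "a2", "a3"), KDR = c("b1", "b2"),
                     HIF1A = "c1")
  text <- assemble_model(constructs, trait = "Q1",
                         covariates = c("Age", "Sex"),
                         popstr_vars = c("Pop1", "PC1"),
                         inter_gene_paths = cbind("FLT1", "KDR"))
  m <- sem_model(text)
  expect_setequal(m$xvars, c("Age", "Sex"))
  expect_true(all(c("FLT1", "KDR", "HIF1A", "PopStr") %in% m$lvars))
  # single-indicator construct: residual fixed at zero
  pt <- m$partable
  c1 <- pt[pt$label == "c1~~c1", ]
  expect_false(c1$free)
  expect_equal(c1$value, 0)
  # two-indicator construct: tau-equivalent (second loading fixed to 1)
  b2 <- pt[pt$label == "KDR=~b2", ]
  expect_false(b2$free)
  expect_equal(b2$value, 1)
  # reparse of the stored normalized text is a fixed point
  m2 <- sem_model(m$text)
  expect_identical(m2$partable, m$partable)
  expect_identical(m2$text, m$text)
  # free-parameter hand count:
  # loadings: FLT1 2 free; KDR 0; HIF1A 0; PopStr 1 (PC1)
  # paths: 3 gene->Q1, PopStr->3 genes + PopStr->Q1, Age/Sex->Q1, FLT1->KDR = 10
  # psi: 4 latents + Q1 disturbance = 5
  # theta: a1 a2 a3 b1 b2 Pop1 PC1 free (c1 fixed) = 7
  # phi: Age, Sex, Age~~Sex = 3
  expect_equal(sum(pt$free), 3 + 10 + 5 + 7 + 3)
  expect_error(assemble_model(list(G = "Age"), covariates = "Age"), "collision")
  expect_error(assemble_model(list(G = c("x1", "x2")),
                              inter_gene_paths = cbind("G", "NOPE")), "unknown")
})

test_that("construct reports carry reliability, eigenvalues and LD", {
  rs <- tiny_study(seed = 14, n_replicates = 1, n_decoys = 0)
  snps <- names(rs$genotypes$gene_of_snp)[rs$genotypes$gene_of_snp == "FLT1"][1:3]
  rep <- construct_report("FLT1", rs$genotypes, snps)
  expect_equal(rep$gene, "FLT1")
  expect_length(rep$eigenvalues, 3)
  expect_equal(sum(rep$eigenvalues), 3, tolerance = 1e-10)
  expect_equal(dim(rep$r2), c(3L, 3L))
  expect_true(all(diag(rep$r2) == 1))
  expect_true(is.finite(rep$cronbach_alpha))
})
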