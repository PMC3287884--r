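# fixture builders shared by the suite (all generated in code, fixed seeds)

make_factor_data <- function(n, loadings, resid = 0.5, seed = 1) {
  set.seed(seed)
  f <- rnorm(n)
  d <- sapply(loadings, function(l) l * f + rnorm(n, 0, sqrt(resid)))
  colnames(d) <- paste0("y", seq_along(loadings))
  as.data.frame(d)
}

# draws from an exact covariance via Cholesky
mvn_data <- function(n, Sigma, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * nrow(Sigma)), n) %*% chol(Sigma)
  colnames(Z) <- colnames(Sigma)
  as.data.frame(Z)
}

toy_genotypes <- function() {
  G <- rbind(c(0, 1, 2, 0), c(1, 0, 0, 0), c(2, 0, 1, 0),
             c(0, 0, 0, 1), c(1, 1, 0, 0), c(0, 0, 0, 0))
  colnames(G) <- c("s1", "s2", "s3", "s4")
  rownames(G) <- paste0("I", 1:6)
  genotype_matrix(G, c(s1 = "gA", s2 = "gA", s3 = "gB", s4 = "gB"))
}

tiny_study <- function(seed = 5, n_replicates = 2, n_decoys = 2) {
  cfg <- gaw_study_config(n_decoy_genes = n_decoys, snps_per_decoy = 3)
  simulate_study(cfg, seed = seed, n_replicates = n_replicates)
}

# known 2-construct generating model used by the recovery studies
recovery_model <- function() {
  text <- paste("latent G1 = y1 + y2 + y3",
                "latent G2 = y4 + y5 + y6",
                "path G1 -> G2", sep = "\n")
  l1 <- c(1, 0.8, 0.7); l2 <- c(1, 0.9, 0.6)
  beta <- 0.5; psi1 <- 1; zeta2 <- 0.75
  th <- c(0.5, 0.45, 0.55, 0.5, 0.4, 0.6)
  v2 <- beta^2 * psi1 + zeta2
  L <- rbind(cbind(l1, 0), cbind(0, l2))
  Ceta <- matrix(c(psi1, beta * psi1, beta * psi1, v2), 2)
  Sigma <- L %*% Ceta %*% t(L) + diag(th)
  vars <- paste0("y", 1:6)
  dimnames(Sigma) <- list(vars, vars)
  truth <- c(0.8, 0.7, 0.9, 0.6, beta, psi1, zeta2, th)
  names(truth) <- c("G1=~y2", "G1=~y3", "G2=~y5", "G2=~y6", "G1->G2",
                    "G1~~G1", "G2~~G2", paste0("y", 1:6, "~~y", 1:6))
  list(text = text, Sigma = Sigma, truth = truth)
}
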