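# Independent brute-force oracles used across the suite.
#
# The SEM oracle builds each fixture's implied covariance from a hand-written
# closed-form expression and minimizes the ML discrepancy with derivative-free
# / numeric-derivative optimizers; fit indices are recomputed from the raw
# formulas. Nothing here calls the package's estimation path.

oracle_fml <- function(S, Sigma) {
  log(det(Sigma)) + sum(diag(S %*% solve(Sigma))) - log(det(S)) - nrow(S)
}

oracle_minimize <- function(sigma_fn, start, S) {
  obj <- function(par) {
    Sigma <- sigma_fn(par)
    d <- tryCatch(det(Sigma), error = function(e) NA_real_)
    if (!is.finite(d) || d <= 0) return(1e10)
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(1e10)
    v <- oracle_fml(S, Sigma)
    if (is.finite(v)) v else 1e10
  }
  o <- optim(start, obj, method = "Nelder-Mead",
             control = list(maxit = 50000, reltol = 1e-15))
  for (k in 1:3) {
    o2 <- optim(o$par, obj, method = "BFGS",
                control = list(maxit = 10000, reltol = 1e-15))
    o3 <- optim(o2$par, obj, method = "Nelder-Mead",
                control = list(maxit = 50000, reltol = 1e-15))
    o <- if (o3$value < o$value) o3 else o
  }
  o
}

oracle_indices <- function(T_stat, df, S, Sigma, n) {
  p <- nrow(S)
  Tb <- (n - 1) * oracle_fml(S, diag(diag(S), p))
  dfb <- p * (p - 1) / 2
  num <- max(T_stat - df, 0)
  den <- max(Tb - dfb, T_stat - df, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  rmsea <- if (df > 0) sqrt(max(T_stat - df, 0) / (df * (n - 1))) else NA_real_
  dd <- sqrt(diag(S))
  R <- (S - Sigma) / outer(dd, dd)
  srmr <- sqrt(mean(R[lower.tri(R, diag = TRUE)]^2))
  list(cfi = cfi, rmsea = rmsea, srmr = srmr)
}

# fixture models: hand-written implied-covariance builders whose parameter
# vectors follow the package's free-parameter order for the paired text
oracle_fixtures <- function() {
  list(
    one_factor_3 = list(
      text = "latent F = y1 + y2 + y3",
      # par: l2, l3, psi, t1, t2, t3
      start = c(0.8, 0.8, 1, 0.5, 0.5, 0.5),
      sigma = function(par) {
        l <- c(1, par[1], par[2]); psi <- par[3]; th <- par[4:6]
        psi * outer(l, l) + diag(th, 3)
      },
      vars = c("y1", "y2", "y3")),
    one_factor_4 = list(
      text = "latent F = y1 + y2 + y3 + y4",
      # par: l2, l3, l4, psi, t1..t4
      start = c(0.8, 0.8, 0.8, 1, 0.5, 0.5, 0.5, 0.5),
      sigma = function(par) {
        l <- c(1, par[1:3]); psi <- par[4]; th <- par[5:8]
        psi * outer(l, l) + diag(th, 4)
      },
      vars = paste0("y", 1:4)),
    two_factor_chain = list(
      text = paste("latent F1 = y1 + y2 + y3",
                   "latent F2 = y4 + y5",
                   "path F1 -> F2", sep = "\n"),
      # par: l2, l3, l5, beta, psi1, zeta2, t1..t5
      start = c(0.8, 0.8, 0.8, 0.3, 1, 0.7, rep(0.5, 5)),
      sigma = function(par) {
        l1 <- c(1, par[1], par[2]); l5 <- par[3]; b <- par[4]
        psi1 <- par[5]; z2 <- par[6]; th <- par[7:11]
        v2 <- b^2 * psi1 + z2             # Var(F2)
        c12 <- b * psi1                   # Cov(F1, F2)
        L <- rbind(cbind(l1, 0), c(0, 1), c(0, l5))
        Ceta <- matrix(c(psi1, c12, c12, v2), 2)
        L %*% Ceta %*% t(L) + diag(th, 5)
      },
      vars = paste0("y", 1:5)),
    latent_with_covariate = list(
      text = paste("latent G = y1 + y2 + y3",
                   "path G -> Q1",
                   "path Age -> Q1", sep = "\n"),
      # par: l2, l3, bGQ, gAQ, psiG, zQ, t1, t2, t3, phiA
      start = c(0.8, 0.8, 0.3, 0.1, 1, 1, 0.5, 0.5, 0.5, 4),
      sigma = function(par) {
        l <- c(1, par[1], par[2]); b <- par[3]; g <- par[4]
        psi <- par[5]; z <- par[6]; th <- par[7:9]; phi <- par[10]
        # order: y1 y2 y3 Q1 Age
        vQ <- b^2 * psi + g^2 * phi + z
        S <- matrix(0, 5, 5)
        S[1:3, 1:3] <- psi * outer(l, l) + diag(th, 3)
        S[1:3, 4] <- S[4, 1:3] <- l * psi * b
        S[4, 4] <- vQ
        S[1:3, 5] <- S[5, 1:3] <- 0
        S[4, 5] <- S[5, 4] <- g * phi
        S[5, 5] <- phi
        S
      },
      vars = c("y1", "y2", "y3", "Q1", "Age")))
}
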