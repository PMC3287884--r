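# Nonnormality-robust corrections: sandwich standard errors from the
# empirical fourth-moment matrix and a mean-scaled (Satorra-Bentler-type)
# test statistic.

# asymptotic covariance of vech(S): Gamma-hat from centered data (n x P)
sem_gamma_adf <- function(Yc) {
  n <- nrow(Yc); P <- ncol(Yc)
  idx <- vech_index(P)
  W <- Yc[, idx[, "row"], drop = FALSE] * Yc[, idx[, "col"], drop = FALSE]
  Wc <- sweep(W, 2L, colMeans(W))
  crossprod(Wc) / n
}

# ML weight matrix V = 0.5 D' (Sigma^-1 x Sigma^-1) D
sem_weight_ml <- function(Sigma) {
  Sinv <- chol2inv(chol(Sigma))
  D <- duplication_matrix(nrow(Sigma))
  0.5 * t(D) %*% (Sinv %x% Sinv) %*% D
}

#' Robust corrections for a fitted model
#'
#' Computes sandwich standard errors using the empirical fourth-moment
#' matrix of the raw observations and a mean-scaled test statistic
#' `T_scaled = T / c` with scaling constant
#' `c = tr(U Gamma) / df`, `U = V - V Delta (Delta' V Delta)^-1 Delta' V`.
#' Requires the raw data (not covariance-only input). Called internally by
#' [sem()] when `robust = TRUE`; exposed for direct use on a fit.
#'
#' @param fit a `semfit` object fitted from raw data.
#' @return List with `robust_acov`, `robust_se`, `scale_c`, `T_scaled`, and
#'   `fallback` (TRUE if the fourth-moment matrix was unusable and naive
#'   values were substituted).
#' @export
robust_corrections <- function(fit) {
  if (is.null(fit$data))
    stopf("robust corrections need raw data; the model was fitted from moments only")
  Yc <- sweep(fit$data, 2L, colMeans(fit$data))
  Gamma <- sem_gamma_adf(Yc)
  V <- sem_weight_ml(fit$Sigma)
  Delta <- fit$Delta
  B <- t(Delta) %*% V %*% Delta
  Binv <- tryCatch(solve(B), error = function(e) NULL)
  ok <- !is.null(Binv) && all(is.finite(Binv))
  if (!ok) {
    warnf("fourth-moment matrix is rank deficient; falling back to naive SEs")
    return(list(robust_acov = fit$acov, robust_se = fit$se,
                scale_c = NA_real_, T_scaled = fit$T_stat, fallback = TRUE))
  }
  meat <- t(Delta) %*% V %*% Gamma %*% V %*% Delta
  acov <- Binv %*% meat %*% Binv / (fit$n - 1)
  se <- sqrt(pmax(diag(acov), 0))
  U <- V - V %*% Delta %*% Binv %*% t(Delta) %*% V
  cstat <- if (fit$df > 0) sum(U * t(Gamma)) / fit$df else NA_real_
  T_scaled <- if (fit$df > 0) fit$T_stat / cstat else 0
  list(robust_acov = acov, robust_se = se, scale_c = cstat,
       T_scaled = T_scaled, fallback = FALSE)
}

# scaling constant for the independence (baseline) model, used for the
# scaled variant of CFI
sem_baseline_scale <- function(S, Gamma, n) {
  P <- nrow(S)
  Sigma_b <- diag(diag(S), P)
  V <- sem_weight_ml(Sigma_b)
  nv <- P * (P + 1L) / 2L
  idx <- vech_index(P)
  diag_cols <- which(idx[, "row"] == idx[, "col"])
  Delta <- matrix(0, nv, length(diag_cols))
  for (a in seq_along(diag_cols)) Delta[diag_cols[a], a] <- 1
  B <- t(Delta) %*% V %*% Delta
  U <- V - V %*% Delta %*% solve(B) %*% t(Delta) %*% V
  df_b <- P * (P - 1L) / 2L
  if (df_b > 0) sum(U * t(Gamma)) / df_b else NA_real_
}
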