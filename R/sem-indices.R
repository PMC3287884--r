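#' Model fit indices
#'
#' \deqn{CFI = 1 - \frac{\max(T - df, 0)}{\max(T_b - df_b, T - df, 0)}}
#' \deqn{RMSEA = \sqrt{\max(T - df, 0) / (df (n - 1))}}
#' \deqn{SRMR = \sqrt{\mathrm{mean}_{i \le j} \left[ (s_{ij} - \hat\sigma_{ij}) / \sqrt{s_{ii} s_{jj}} \right]^2}}
#' The baseline is the independence model (all covariances zero, variances
#' free), whose ML solution is `diag(S)` in closed form.
#'
#' @param T_stat,df test statistic and degrees of freedom of the fitted model.
#' @param T_base,df_base baseline statistic and degrees of freedom.
#' @param n sample size.
#' @param S,Sigma sample and implied covariance (for SRMR); may be `NULL` to
#'   skip SRMR.
#' @return List with `cfi`, `rmsea` (`NA` when `df = 0`), `srmr`.
#' @export
fit_indices <- function(T_stat, df, T_base, df_base, n, S = NULL, Sigma = NULL) {
  num <- max(T_stat - df, 0)
  den <- max(T_base - df_base, T_stat - df, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  rmsea <- if (df > 0) sqrt(max(T_stat - df, 0) / (df * (n - 1))) else NA_real_
  srmr <- NA_real_
  if (!is.null(S) && !is.null(Sigma)) {
    d <- sqrt(diag(S))
    R <- (S - Sigma) / outer(d, d)
    srmr <- sqrt(mean(R[lower.tri(R, diag = TRUE)]^2))
  }
  list(cfi = cfi, rmsea = rmsea, srmr = srmr)
}

# closed-form independence baseline
sem_baseline_stat <- function(S, n, multiplier) {
  Sigma_b <- diag(diag(S), nrow(S))
  Fb <- fml(S, Sigma_b)
  P <- nrow(S)
  list(T_stat = multiplier * Fb, df = P * (P - 1L) / 2L, F_value = Fb)
}

#' Classify fit indices against conventional cutoffs
#'
#' CFI at least 0.95 is good and at least 0.90 acceptable; RMSEA at most
#' 0.06 is good and at most 0.10 acceptable; SRMR at most 0.08 is good and
#' below 0.10 acceptable.
#'
#' @param cfi,rmsea,srmr index values (finite).
#' @return Named character vector with labels `good`, `acceptable` or `poor`.
#' @export
classify_fit <- function(cfi, rmsea, srmr) {
  for (v in c(cfi, rmsea, srmr))
    if (!is.finite(v)) stopf("fit indices must be finite")
  c(cfi = if (cfi >= 0.95) "good" else if (cfi >= 0.90) "acceptable" else "poor",
    rmsea = if (rmsea <= 0.06) "good" else if (rmsea <= 0.10) "acceptable" else "poor",
    srmr = if (srmr <= 0.08) "good" else if (srmr < 0.10) "acceptable" else "poor")
}
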