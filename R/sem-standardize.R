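# standardized solution: every estimate rescaled by the implied standard
# deviations of the variables it connects

# vector of standardized values aligned with partable rows
sem_std_values <- function(model, theta) {
  mats <- model_matrices(model, theta)
  sig <- sem_sigma(mats)
  p <- length(model$yvars); q <- length(model$xvars)
  sd_eta <- sqrt(pmax(diag(sig$C_eta), 0))
  sd_y <- sqrt(pmax(diag(sig$Sigma)[seq_len(p)], 0))
  sd_x <- if (q) sqrt(pmax(diag(mats$Ph), 0)) else numeric(0)
  pt <- model$partable
  vals <- pt$value
  vals[pt$free] <- theta[pt$free_id[pt$free]]
  std <- numeric(nrow(pt))
  guard <- function(x) ifelse(x > 0, x, NA_real_)
  for (r in seq_len(nrow(pt))) {
    v <- vals[r]; i <- pt$row[r]; j <- pt$col[r]
    std[r] <- switch(pt$mat[r],
      lambda = v * sd_eta[j] / guard(sd_y[i]),
      beta   = v * sd_eta[j] / guard(sd_eta[i]),
      gamma  = v * sd_x[j] / guard(sd_eta[i]),
      psi    = v / guard(sd_eta[i] * sd_eta[j]),
      theta  = v / guard(sd_y[i] * sd_y[j]),
      phi    = v / guard(sd_x[i] * sd_x[j]))
  }
  std
}

#' Standardized solution of a fitted model
#'
#' Rescales every parameter by the implied standard deviations of its
#' connected variables; standard errors follow by the delta method (numeric
#' Jacobian of the standardization map applied to the naive and robust
#' covariance of the free parameters). The R-squared of an endogenous
#' variable equals one minus its standardized residual (indicator) or
#' disturbance (latent/outcome) variance.
#'
#' @param fit a `semfit` object.
#' @return Data frame: one row per parameter with `label`, `class`,
#'   `std_est`, `std_se` (naive) and `std_se_robust` (if available).
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "semfit"))
  fit$std_table
}

sem_standardize_full <- function(model, theta, acov = NULL, acov_robust = NULL) {
  std <- sem_std_values(model, theta)
  nf <- length(theta)
  J <- NULL
  if (nf > 0 && (!is.null(acov) || !is.null(acov_robust))) {
    J <- matrix(0, length(std), nf)
    for (a in seq_len(nf)) {
      h <- 1e-6 * max(1, abs(theta[a]))
      tp <- theta; tm <- theta
      tp[a] <- tp[a] + h; tm[a] <- tm[a] - h
      J[, a] <- (sem_std_values(model, tp) - sem_std_values(model, tm)) / (2 * h)
    }
  }
  se_from <- function(V) {
    if (is.null(V) || is.null(J)) return(rep(NA_real_, length(std)))
    sqrt(pmax(rowSums((J %*% V) * J), 0))
  }
  list(std = std, std_se = se_from(acov), std_se_robust = se_from(acov_robust))
}

# R-squared per endogenous variable from the standardized values
sem_rsquare <- function(model, std_values) {
  pt <- model$partable
  out <- c()
  for (r in which(pt$mat == "theta" & pt$row == pt$col & pt$class == "residual")) {
    v <- model$yvars[pt$row[r]]
    out[v] <- 1 - std_values[r]
  }
  for (r in which(pt$mat == "psi" & pt$row == pt$col & pt$class == "disturbance")) {
    lv <- model$lvars[pt$row[r]]
    nm <- if (model$pseudo[lv]) lv else lv
    out[nm] <- 1 - std_values[r]
  }
  out
}
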