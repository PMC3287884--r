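#' @export
print.semfit <- function(x, ...) {
  cat("Structural equation model fit (maximum likelihood)\n")
  cat(sprintf("  n = %d, free parameters = %d, df = %d\n",
              x$n, n_free(x$model), x$df))
  cat(sprintf("  F_ML = %.6g, T = %.4g", x$F_value, x$T_stat))
  if (is.finite(x$T_scaled)) cat(sprintf(", T_scaled = %.4g (c = %.3f)", x$T_scaled, x$scale_c))
  cat("\n")
  cat(sprintf("  CFI = %.3f, RMSEA = %s, SRMR = %.3f\n",
              x$indices$cfi,
              ifelse(is.na(x$indices$rmsea), "NA (df = 0)", sprintf("%.3f", x$indices$rmsea)),
              x$indices$srmr))
  if (!x$converged) cat("  WARNING: not converged\n")
  if (!x$admissible) cat("  WARNING: solution at a variance boundary (inadmissible)\n")
  invisible(x)
}

#' Summary of a fitted structural equation model
#'
#' @param object a `semfit`.
#' @param standardized include the standardized solution columns.
#' @param ... unused.
#' @export
summary.semfit <- function(object, standardized = TRUE, ...) {
  out <- list(fit = object, standardized = standardized)
  class(out) <- "summary.semfit"
  out
}

#' @export
print.summary.semfit <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f)
  cat("\nParameter estimates:\n")
  est <- f$estimates[f$estimates$class != "resid_fixed", , drop = FALSE]
  cols <- c("label", "class", "est", "se", "se_robust")
  if (x$standardized) cols <- c(cols, "std_est", "std_se", "std_se_robust")
  tab <- est[, cols]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  if (length(f$rsquare)) {
    cat("\nR-squared:\n")
    print(round(f$rsquare, digits))
  }
  invisible(x)
}

#' @export
coef.semfit <- function(object, ...) {
  pt <- object$model$partable
  stats::setNames(object$theta, pt$label[pt$free])
}

#' @export
vcov.semfit <- function(object, robust = FALSE, ...) {
  V <- if (robust) object$acov_robust else object$acov
  if (is.null(V)) return(NULL)
  pt <- object$model$partable
  dimnames(V) <- list(pt$label[pt$free], pt$label[pt$free])
  V
}

#' @export
nobs.semfit <- function(object, ...) object$n

#' @export
fitted.semfit <- function(object, ...) object$Sigma

#' Residual covariance matrix of a fitted model
#'
#' @param object a `semfit`.
#' @param type `"raw"` for `S - Sigma(theta)`, `"standardized"` for the
#'   correlation-metric residuals used by SRMR.
#' @param ... unused.
#' @export
residuals.semfit <- function(object, type = c("raw", "standardized"), ...) {
  type <- match.arg(type)
  R <- object$S - object$Sigma
  if (type == "standardized") {
    d <- sqrt(diag(object$S))
    R <- R / outer(d, d)
  }
  R
}

#' Factor scores for a fitted model
#'
#' Regression-method scores: `E[eta | obs] = Cov(eta, obs) Sigma^-1 (obs - mean)`.
#'
#' @param object a `semfit`.
#' @param newdata optional data frame (defaults to the fitting data).
#' @param ... unused.
#' @return Matrix of factor scores (columns = latent variables, including
#'   observed-outcome pseudo-latents).
#' @export
predict.semfit <- function(object, newdata = NULL, ...) {
  m <- object$model
  vars <- c(m$yvars, m$xvars)
  if (is.null(newdata)) {
    if (is.null(object$data)) stopf("no data stored; supply 'newdata'")
    Y <- object$data
  } else {
    newdata <- as.data.frame(newdata)
    miss <- setdiff(vars, names(newdata))
    if (length(miss)) stopf("newdata lacks: %s", paste(miss, collapse = ", "))
    Y <- as.matrix(newdata[, vars, drop = FALSE])
  }
  sig <- sem_sigma(object$mats)
  q <- length(m$xvars)
  cov_eta_y <- sig$C_eta %*% t(object$mats$L)
  cov_eta_obs <- if (q) cbind(cov_eta_y, sig$A %*% object$mats$G %*% object$mats$Ph)
                 else cov_eta_y
  Yc <- sweep(Y, 2L, object$means)
  scores <- Yc %*% chol2inv(chol(object$Sigma)) %*% t(cov_eta_obs)
  colnames(scores) <- m$lvars
  scores
}

#' Simulate data from a fitted model
#'
#' Draws multivariate normal data from the implied covariance (and the
#' sample means). With `condition_on`, the named columns are held fixed at
#' the supplied values and only the remaining variables are redrawn from
#' their conditional distribution — the fixed-genotype, redrawn-phenotype
#' replicate design.
#'
#' @param object a `semfit`.
#' @param nsim number of data sets.
#' @param seed optional seed.
#' @param condition_on optional matrix/data frame of columns (a subset of
#'   the modeled variables) held fixed; its row count sets the sample size.
#' @param ... unused.
#' @return List of `nsim` data frames.
#' @export
simulate.semfit <- function(object, nsim = 1, seed = NULL, condition_on = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  vars <- c(object$model$yvars, object$model$xvars)
  Sigma <- object$Sigma
  mu <- object$means
  if (is.null(condition_on)) {
    n <- object$n
    return(lapply(seq_len(nsim), function(r)
      as.data.frame(rmvn(n, Sigma, mean = mu))))
  }
  condition_on <- as.data.frame(condition_on)
  fixed <- intersect(vars, names(condition_on))
  if (!length(fixed)) stopf("'condition_on' shares no columns with the model")
  drawn <- setdiff(vars, fixed)
  if (!length(drawn)) stopf("all modeled variables are conditioned on")
  Xf <- as.matrix(condition_on[, fixed, drop = FALSE])
  n <- nrow(Xf)
  Sff <- Sigma[fixed, fixed, drop = FALSE]
  Sdf <- Sigma[drawn, fixed, drop = FALSE]
  Sdd <- Sigma[drawn, drawn, drop = FALSE]
  K <- Sdf %*% chol2inv(chol(Sff))
  cond_mu <- sweep(sweep(Xf, 2L, mu[fixed]) %*% t(K), 2L, mu[drawn], "+")
  cond_S <- Sdd - K %*% t(Sdf)
  cond_S <- (cond_S + t(cond_S)) / 2
  lapply(seq_len(nsim), function(r) {
    Z <- rmvn(n, cond_S) + cond_mu
    colnames(Z) <- drawn
    out <- cbind(as.data.frame(Z), condition_on[, fixed, drop = FALSE])
    out[, vars]
  })
}

#' Diagnostic plot for a fitted model
#'
#' Observed versus model-implied covariances of the unique moments; a
#' well-fitting model hugs the identity line.
#'
#' @param x a `semfit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.semfit <- function(x, ...) {
  s <- vech(x$S); sg <- vech(x$Sigma)
  graphics::plot(s, sg, xlab = "observed covariance", ylab = "implied covariance",
                 main = "Covariance structure fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
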