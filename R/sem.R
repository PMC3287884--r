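#' Fit a structural equation model by maximum likelihood
#'
#' Estimates the free parameters of a latent-variable covariance-structure
#' model by minimizing the normal-theory discrepancy [fml()] with an
#' analytic-gradient quasi-Newton optimizer (variances on the log scale, so
#' they remain positive). Naive standard errors come from the inverse
#' expected-information matrix; with raw data and `robust = TRUE`, sandwich
#' standard errors and a mean-scaled test statistic robust to nonnormality
#' are added (see [robust_corrections()]). Fit indices (CFI, RMSEA, SRMR)
#' are computed against the independence baseline, in both unscaled and
#' scaled variants. Genotype indicators coded 0/1/2 are treated as
#' continuous; missing data are handled by listwise deletion.
#'
#' @param model model text in the [sem_model()] grammar, a `.sem` file path,
#'   or a parsed `sem_model`.
#' @param data data frame or matrix containing every modeled variable
#'   (matched by column name; column order is irrelevant).
#' @param sample_cov alternative to `data`: a named sample covariance matrix.
#' @param n sample size (required with `sample_cov`).
#' @param robust add sandwich SEs and the scaled statistic (needs `data`).
#' @param std_latent identify latents by unit latent variance instead of
#'   marker loadings.
#' @param test_multiplier `"n-1"` (default) or `"n"`: multiplier convention
#'   for the test statistic `T = multiplier * F_ML`.
#' @param control list: `gr_tol` (gradient-norm convergence tolerance,
#'   default 1e-6), `max_iter` (default 500), `start` (optional start
#'   vector), `ridge` (added to the sample covariance diagonal if it is not
#'   positive definite, default 0).
#' @return An object of class `semfit`; see [summary.semfit()]. Key fields:
#'   `estimates` (parameter table with `est`, `se`, `se_robust`,
#'   `std_est`, `std_se`, `std_se_robust`), `F_value`, `T_stat`, `df`,
#'   `T_scaled`, `scale_c`, `indices`, `indices_scaled`, `rsquare`,
#'   `converged`, `admissible`.
#' @export
#' @examples
#' set.seed(1)
#' f <- rnorm(500)
#' d <- data.frame(y1 = f + rnorm(500, 0, 0.7),
#'                 y2 = 0.8 * f + rnorm(500, 0, 0.7),
#'                 y3 = 0.6 * f + rnorm(500, 0, 0.7))
#' fit <- sem("latent F = y1 + y2 + y3", d)
#' coef(fit)
sem <- function(model, data = NULL, sample_cov = NULL, n = NULL,
                robust = !is.null(data), std_latent = FALSE,
                test_multiplier = c("n-1", "n"), control = list()) {
  cl <- match.call()
  test_multiplier <- match.arg(test_multiplier)
  ctl <- utils::modifyList(list(gr_tol = 1e-6, max_iter = 500,
                                start = NULL, ridge = 0), control)
  if (is.character(model)) {
    if (std_latent) model <- c("std_latent", model)
    model <- sem_model(model)
  } else if (std_latent && !model$std_latent) {
    model <- sem_model(c("std_latent", strsplit(model$text, "\n")[[1]]))
  }
  stopifnot(inherits(model, "sem_model"))
  vars <- c(model$yvars, model$xvars)

  if (!is.null(data)) {
    data <- as.data.frame(data)
    miss <- setdiff(vars, names(data))
    if (length(miss)) stopf("data lacks modeled variable(s): %s",
                            paste(miss, collapse = ", "))
    Y <- as.matrix(data[, vars, drop = FALSE])
    storage.mode(Y) <- "double"
    cc <- stats::complete.cases(Y)
    if (!all(cc)) {
      warnf("listwise deletion of %d incomplete case(s)", sum(!cc))
      Y <- Y[cc, , drop = FALSE]
    }
    n <- nrow(Y)
    S <- stats::cov(Y)
    means <- colMeans(Y)
  } else {
    if (is.null(sample_cov) || is.null(n))
      stopf("supply either 'data' or both 'sample_cov' and 'n'")
    miss <- setdiff(vars, colnames(sample_cov))
    if (length(miss)) stopf("'sample_cov' lacks variable(s): %s",
                            paste(miss, collapse = ", "))
    S <- sample_cov[vars, vars]
    means <- rep(0, length(vars))
    Y <- NULL
    if (robust) {
      warnf("robust corrections need raw data; returning naive results only")
      robust <- FALSE
    }
  }
  P <- length(vars)
  if (n <= P) warnf("sample size (%d) does not exceed the number of modeled variables (%d)", n, P)
  if (any(diag(S) <= 0)) stopf("constant modeled variable(s): %s",
                               paste(vars[diag(S) <= 0], collapse = ", "))
  if (inherits(tryCatch(chol(S), error = function(e) e), "error")) {
    if (ctl$ridge > 0) {
      S <- S + diag(ctl$ridge, P)
      warnf("sample covariance not positive definite; ridge %g added", ctl$ridge)
    } else stopf("sample covariance matrix is not positive definite (set control$ridge)")
  }
  ctl$ldS <- 2 * sum(log(diag(chol(S))))

  nf <- n_free(model)
  df <- P * (P + 1L) / 2L - nf
  if (df < 0) stopf("model has more free parameters (%d) than sample moments (%d)",
                    nf, P * (P + 1L) / 2L)
  multiplier <- if (test_multiplier == "n-1") n - 1 else n

  opt <- sem_optimize(model, S, ctl)
  mats <- model_matrices(model, opt$theta)
  sig <- sem_sigma(mats)
  Sigma <- sig$Sigma
  F_value <- max(opt$value, 0)
  T_stat <- multiplier * F_value

  # admissibility: free variances at (or beyond) the zero boundary
  fp <- free_par_info(model)
  vdiag <- fp$logscale
  admissible <- !any(opt$theta[vdiag] < 1e-8 * max(diag(S)))
  if (!opt$converged)
    warnf("optimizer did not reach the gradient tolerance (|g| = %.2e)", opt$grad_norm)

  dsig <- sem_dsigma(model, mats, sig)
  info <- sem_information(Sigma, dsig)
  acov <- tryCatch(solve(info) / (n - 1), error = function(e) NULL)
  se <- if (is.null(acov)) rep(NA_real_, nf) else sqrt(pmax(diag(acov), 0))
  Delta <- sem_delta(dsig)

  fit <- structure(list(
    model = model, call = cl, n = n, S = S, means = means, data = Y,
    theta = opt$theta, F_value = F_value, T_stat = T_stat, df = df,
    multiplier = multiplier, Sigma = Sigma, mats = mats,
    converged = opt$converged, grad_norm = opt$grad_norm,
    admissible = admissible, acov = acov, se = se, Delta = Delta),
    class = "semfit")

  base <- sem_baseline_stat(S, n, multiplier)
  fit$baseline <- base
  fit$indices <- fit_indices(T_stat, df, base$T_stat, base$df, n, S, Sigma)

  if (robust) {
    rb <- robust_corrections(fit)
    fit$acov_robust <- rb$robust_acov
    fit$se_robust <- rb$robust_se
    fit$scale_c <- rb$scale_c
    fit$T_scaled <- rb$T_scaled
    Gamma <- sem_gamma_adf(sweep(Y, 2L, colMeans(Y)))
    cb <- tryCatch(sem_baseline_scale(S, Gamma, n), error = function(e) NA_real_)
    Tb_sc <- if (is.finite(cb) && cb > 0) base$T_stat / cb else base$T_stat
    fit$indices_scaled <- if (fit$df > 0 && is.finite(rb$scale_c))
      fit_indices(rb$T_scaled, df, Tb_sc, base$df, n, S, Sigma)
    else fit$indices
  } else {
    fit$se_robust <- rep(NA_real_, nf)
    fit$acov_robust <- NULL
    fit$scale_c <- NA_real_
    fit$T_scaled <- NA_real_
    fit$indices_scaled <- NULL
  }

  stdz <- sem_standardize_full(model, opt$theta, fit$acov, fit$acov_robust)
  pt <- model$partable
  est <- pt$value
  est[pt$free] <- opt$theta[pt$free_id[pt$free]]
  se_full <- se_rob_full <- rep(NA_real_, nrow(pt))
  se_full[pt$free] <- se[pt$free_id[pt$free]]
  if (robust) se_rob_full[pt$free] <- fit$se_robust[pt$free_id[pt$free]]
  fit$estimates <- data.frame(
    label = pt$label, class = pt$class, free = pt$free, est = est,
    se = se_full, se_robust = se_rob_full,
    std_est = stdz$std, std_se = stdz$std_se,
    std_se_robust = stdz$std_se_robust,
    stringsAsFactors = FALSE)
  fit$std_table <- fit$estimates[, c("label", "class", "std_est", "std_se",
                                     "std_se_robust")]
  fit$rsquare <- sem_rsquare(model, stdz$std)
  fit
}
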