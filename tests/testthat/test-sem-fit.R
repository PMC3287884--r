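test_that("the saturated model reproduces the sample covariance exactly", {
  set.seed(4)
  d <- data.frame(a = rnorm(120), b = rnorm(120), c = rnorm(120))
  d$b <- d$b + 0.5 * d$a
  fit <- sem("covary a b\ncovary a c\ncovary b c", d, robust = FALSE)
  expect_equal(fit$F_value, 0, tolerance = 1e-10)
  expect_equal(fit$T_stat, 0, tolerance = 1e-7)
  expect_equal(fit$df, 0)
  expect_equal(unname(fit$Sigma), unname(cov(d[, c("a", "b", "c")])),
               tolerance = 1e-8)
  expect_equal(fit$indices$cfi, 1)
  expect_equal(fit$indices$srmr, 0, tolerance = 1e-8)
  expect_true(is.na(fit$indices$rmsea))
})

test_that("a just-identified CFA matches its closed-form solution", {
  set.seed(8)
  d <- make_factor_data(400, c(1, 0.8, 0.6), seed = 8)
  fit <- sem("latent F = y1 + y2 + y3", d, robust = FALSE,
             control = list(gr_tol = 1e-10))
  S <- fit$S
  s12 <- S[1, 2]; s13 <- S[1, 3]; s23 <- S[2, 3]
  psi <- s12 * s13 / s23
  l2 <- s23 / s13
  l3 <- s23 / s12
  est <- coef(fit)
  expect_equal(unname(est["F=~y2"]), l2, tolerance = 1e-8)
  expect_equal(unname(est["F=~y3"]), l3, tolerance = 1e-8)
  expect_equal(unname(est["F~~F"]), psi, tolerance = 1e-8)
  expect_equal(unname(est["y1~~y1"]), S[1, 1] - psi, tolerance = 1e-8)
  expect_equal(fit$F_value, 0, tolerance = 1e-10)
  expect_equal(fit$df, 0)
})

test_that("estimates and fit statistics match the brute-force oracle on every fixture", {
  fixtures <- oracle_fixtures()
  gen <- list(
    one_factor_3 = function(n) make_factor_data(n, c(1, 0.8, 0.6), seed = 101),
    one_factor_4 = function(n) make_factor_data(n, c(1, 0.9, 0.7, 0.5), seed = 102),
    two_factor_chain = function(n) {
      set.seed(103)
      f1 <- rnorm(n); f2 <- 0.5 * f1 + rnorm(n, 0, 0.8)
      data.frame(y1 = f1 + rnorm(n, 0, 0.7), y2 = 0.8 * f1 + rnorm(n, 0, 0.7),
                 y3 = 0.7 * f1 + rnorm(n, 0, 0.7), y4 = f2 + rnorm(n, 0, 0.7),
                 y5 = 0.9 * f2 + rnorm(n, 0, 0.7))
    },
    latent_with_covariate = function(n) {
      set.seed(104)
      age <- rnorm(n, 0, 2)
      g <- rnorm(n)
      data.frame(y1 = g + rnorm(n, 0, 0.7), y2 = 0.8 * g + rnorm(n, 0, 0.7),
                 y3 = 0.7 * g + rnorm(n, 0, 0.7),
                 Q1 = 0.4 * g + 0.15 * age + rnorm(n), Age = age)
    })
  for (nm in names(fixtures)) {
    fx <- fixtures[[nm]]
    d <- gen[[nm]](300)
    fit <- sem(fx$text, d, robust = FALSE)
    S <- cov(d[, fx$vars])
    orc <- oracle_minimize(fx$sigma, fx$start, S)
    expect_lt(abs(fit$F_value - orc$value), 1e-6 * max(1, abs(orc$value)))
    rel <- abs(coef(fit) - orc$par) / pmax(abs(orc$par), 1e-4)
    expect_lt(max(rel), 1e-4)
    T_orc <- (fit$n - 1) * orc$value
    expect_equal(fit$T_stat, T_orc, tolerance = 1e-4)
    oi <- oracle_indices(T_orc, fit$df, S, fx$sigma(orc$par), fit$n)
    expect_equal(fit$indices$cfi, oi$cfi, tolerance = 1e-4)
    if (fit$df > 0) expect_equal(fit$indices$rmsea, oi$rmsea, tolerance = 1e-4)
    expect_equal(fit$indices$srmr, oi$srmr, tolerance = 1e-4)
  }
})

test_that("permuting data columns leaves the fit invariant", {
  d <- make_factor_data(250, c(1, 0.8, 0.6, 0.9), seed = 55)
  text <- "latent F = y1 + y2 + y3 + y4"
  f1 <- sem(text, d)
  f2 <- sem(text, d[, c(3, 1, 4, 2)])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
  expect_equal(f1$T_stat, f2$T_stat, tolerance = 1e-7)
  expect_equal(f1$indices$srmr, f2$indices$srmr, tolerance = 1e-8)
  expect_equal(f1$estimates$std_est, f2$estimates$std_est, tolerance = 1e-6)
})

test_that("naive standard errors agree with the observed sampling spread", {
  rm <- recovery_model()
  ses <- NULL; devs <- NULL
  for (i in 1:40) {
    d <- mvn_data(2000, rm$Sigma, seed = 200 + i)
    fit <- sem(rm$text, d, robust = FALSE)
    est <- coef(fit)[names(rm$truth)]
    devs <- rbind(devs, est - rm$truth)
    pt <- fit$model$partable
    ses <- rbind(ses, fit$se[pt$free_id[match(names(rm$truth), pt$label)]])
  }
  # mean naive SE within 25% of the empirical SD for each parameter
  ratio <- colMeans(ses) / apply(devs, 2, sd)
  expect_true(all(ratio > 0.75 & ratio < 1.33))
})

test_that("non-convergence and inadmissibility are flagged, not hidden", {
  d <- make_factor_data(60, c(1, 0.9, 0.8), seed = 77)
  # an unattainable tolerance must leave the flag unset, with a warning
  expect_warning(
    fit <- sem("latent F = y1 + y2 + y3", d, robust = FALSE,
               control = list(gr_tol = 0)),
    "tolerance")
  expect_false(fit$converged)
})

test_that("moment input works and robust corrections then degrade gracefully", {
  rm <- recovery_model()
  expect_warning(
    fit <- sem(rm$text, sample_cov = rm$Sigma, n = 1000, robust = TRUE),
    "raw data")
  # exact population covariance: estimates equal the generating values
  expect_equal(coef(fit)[names(rm$truth)], rm$truth, tolerance = 1e-6)
  expect_equal(fit$F_value, 0, tolerance = 1e-10)
})

test_that("factor scores, simulate and residual methods are coherent", {
  d <- make_factor_data(300, c(1, 0.8, 0.6), seed = 91)
  fit <- sem("latent F = y1 + y2 + y3", d)
  sc <- predict(fit)
  expect_equal(dim(sc), c(300L, 1L))
  expect_gt(cor(sc[, 1], rowMeans(d)), 0.8)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(names(sims[[1]]), c("y1", "y2", "y3"))
  cond <- simulate(fit, nsim = 1, seed = 2, condition_on = d[, c("y1", "y2")])
  expect_equal(cond[[1]]$y1, d$y1)
  expect_false(isTRUE(all.equal(cond[[1]]$y3, d$y3)))
  R <- residuals(fit, type = "standardized")
  expect_equal(sqrt(mean(R[lower.tri(R, diag = TRUE)]^2)), fit$indices$srmr,
               tolerance = 1e-10)
})
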