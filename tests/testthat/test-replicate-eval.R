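test_that("relative bias is the scaled absolute (or signed) deviation", {
  expect_equal(relative_bias(1.0, 1.0), 0)
  expect_equal(relative_bias(1.1, 1.0), 10)
  expect_equal(relative_bias(0.9, 1.0), 10)
  expect_equal(relative_bias(0.9, 1.0, signed = TRUE), -10)
  expect_equal(relative_bias(-1.1, -1.0), 10)
  est <- c(1.05, 0.98, 1.2, 0.75, 1.0)
  pop <- c(1, 1, 1, 1, 1)
  expect_equal(mean(relative_bias(est, pop)), mean(abs(est - 1)) * 100)
  expect_error(relative_bias(1, 0), "zero")
})

test_that("relative bias is invariant to rescaling parameter and population", {
  set.seed(44)
  est <- rnorm(20, 1, 0.2); pop <- rnorm(20, 1, 0.1)
  for (k in c(-3, 0.01, 7)) {
    expect_equal(relative_bias(k * est, k * pop), relative_bias(est, pop))
  }
})

test_that("evaluating the reference against itself yields a null report", {
  d <- make_factor_data(400, c(1, 0.8, 0.6, 0.7), seed = 19)
  text <- "latent F = y1 + y2 + y3 + y4"
  fit <- sem(text, d)
  rep <- evaluate_replicates(text, fit, list(d, d))
  expect_lt(max(rep$per_parameter$mrb_est, na.rm = TRUE), 1e-3)
  expect_lt(max(rep$per_parameter$mrb_se, na.rm = TRUE), 1e-3)
  expect_equal(unname(rep$fit_means["cfi"]), fit$indices$cfi, tolerance = 1e-6)
  expect_equal(unname(rep$fit_means["srmr"]), fit$indices$srmr, tolerance = 1e-6)
  expect_equal(rep$n_nonconverged, 0L)
})

test_that("report totals reconstruct exactly from the per-parameter rows", {
  set.seed(29)
  d0 <- make_factor_data(300, c(1, 0.8, 0.7), seed = 29)
  text <- "latent F = y1 + y2 + y3"
  fit <- sem(text, d0)
  reps <- simulate(fit, nsim = 6, seed = 30)
  out <- evaluate_replicates(text, fit, reps)
  per <- out$per_parameter
  for (cl in out$class_summary$class) {
    expect_equal(out$class_summary$mrb_est[out$class_summary$class == cl],
                 mean(per$mrb_est[per$class == cl], na.rm = TRUE))
  }
  expect_equal(unname(out$overall["mrb_est"]), mean(per$mrb_est, na.rm = TRUE))
  expect_equal(unname(out$overall["mrb_se"]), mean(per$mrb_se, na.rm = TRUE))
  # headline MRB never exceeds the dispersion-inclusive variant
  expect_true(all(per$mrb_est <= per$mad_est + 1e-12, na.rm = TRUE))
})

test_that("path parameters are less stable than the measurement side when a path is weak", {
  set.seed(31)
  n <- 697
  f <- rnorm(n)
  d0 <- data.frame(y1 = f + rnorm(n, 0, 0.5), y2 = 0.9 * f + rnorm(n, 0, 0.5),
                   y3 = 0.8 * f + rnorm(n, 0, 0.5),
                   Q1 = 0.08 * f + rnorm(n))   # weak, near-zero path
  text <- "latent F = y1 + y2 + y3\npath F -> Q1"
  fit <- sem(text, d0)
  # fixed indicators, redrawn trait
  reps <- simulate(fit, nsim = 30, seed = 32,
                   condition_on = d0[, c("y1", "y2", "y3")])
  out <- evaluate_replicates(text, fit, reps)
  cs <- out$class_summary
  expect_gt(cs$mad_est[cs$class == "path"],
            cs$mad_est[cs$class == "loading"])
  expect_gt(cs$mad_est[cs$class == "path"],
            cs$mad_est[cs$class == "residual"])
})

test_that("zero population values are excluded and reported", {
  d <- make_factor_data(300, c(1, 0.8, 0.6), seed = 37)
  text <- "latent F = y1 + y2 + y3\nfix y2~~y2 = 0"
  fit <- suppressWarnings(sem(text, d))
  out <- evaluate_replicates(text, fit, simulate(fit, nsim = 3, seed = 38))
  expect_true("y2~~y2" %in% out$excluded)
  expect_false("y2~~y2" %in% out$per_parameter$label[!is.na(out$per_parameter$mrb_est)])
})

test_that("excess non-convergence is a hard error", {
  d <- make_factor_data(40, c(1, 0.9, 0.8), seed = 47)
  text <- "latent F = y1 + y2 + y3"
  fit <- sem(text, d)
  # garbage replicates: constant columns make every refit fail
  bad <- data.frame(y1 = rep(1, 40), y2 = rep(2, 40), y3 = rep(3, 40))
  expect_error(
    suppressWarnings(evaluate_replicates(text, fit, list(bad, bad, bad))),
    "non-convergence")
})

test_that("sem_data assembles genotype, trait, covariate and PC columns", {
  rs <- tiny_study(seed = 25, n_replicates = 2)
  d <- sem_data(rs, 2, snps = colnames(rs$genotypes$values)[1:4], n_pcs = 2)
  expect_equal(nrow(d), 697)
  expect_true(all(c("Q1", "Age", "Sex", "Smoke", "Pop1", "PC1", "PC2") %in% names(d)))
  expect_equal(d$Q1, rs$phenotypes[[2]]$Q1[match(rownames(rs$genotypes$values),
                                                 rs$phenotypes[[2]]$IID)])
  expect_true(all(d$Pop1 %in% 0:1))
})
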