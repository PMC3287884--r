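# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

check_prob <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) stopf("'%s' must be finite numeric", name)
  bad <- if (open_lo) x <= lo else x < lo
  bad <- bad | if (open_hi) x >= hi else x > hi
  if (any(bad)) stopf("'%s' must lie in %s%g, %g%s (got %g)", name,
                      if (open_lo) "(" else "[", lo, hi,
                      if (open_hi) ")" else "]", x[bad][1])
  invisible(x)
}

# multivariate normal draws via Cholesky; sigma must be symmetric PSD
rmvn <- function(n, sigma, mean = NULL) {
  p <- nrow(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    e <- eigen(sigma, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    ch <- t(e$vectors %*% (t(e$vectors) * sqrt(ev)))
  }
  z <- matrix(stats::rnorm(n * p), n, p) %*% ch
  if (!is.null(mean)) z <- sweep(z, 2L, mean, "+")
  colnames(z) <- colnames(sigma)
  z
}

# half-vectorization index pairs (row >= col, column-major like lavaan's vech)
vech_index <- function(p) {
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

vech <- function(m) m[lower.tri(m, diag = TRUE)]

# duplication matrix D_p: vec(S) = D %*% vech(S) for symmetric S
duplication_matrix <- function(p) {
  nv <- p * (p + 1L) / 2L
  D <- matrix(0, p * p, nv)
  k <- 0L
  for (j in seq_len(p)) for (i in j:p) {
    k <- k + 1L
    D[(j - 1L) * p + i, k] <- 1
    D[(i - 1L) * p + j, k] <- 1
  }
  D
}
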