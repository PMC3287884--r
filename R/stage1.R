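#' Minor allele frequency of a genotype column
#'
#' @param genotype_column vector of minor-allele counts in `{0, 1, 2}`.
#' @return `min(f, 1 - f)` where `f` is the counted-allele fraction; lies in
#'   `[0, 0.5]`.
#' @export
compute_maf <- function(genotype_column) {
  if (!length(genotype_column)) stopf("empty genotype column")
  if (!all(genotype_column %in% c(0, 1, 2))) stopf("genotype entries must be 0, 1 or 2")
  f <- sum(genotype_column) / (2 * length(genotype_column))
  min(f, 1 - f)
}

# columnwise MAF for a genotype matrix
snp_mafs <- function(G) {
  f <- colSums(G) / (2 * nrow(G))
  pmin(f, 1 - f)
}

#' Stage-1 screening configuration
#'
#' @param rare_maf_threshold MAF below which a variant is collapsed (default
#'   0.05, the conventional rare-variant boundary).
#' @param alpha family-wise significance level for the Bonferroni rule.
#' @param n_pcs number of genotype principal components to adjust for.
#' @param collapse collapse rare variants into per-gene carrier indicators?
#' @param covariate_sets named list of character vectors; each names
#'   phenotype-table columns used as covariates for one model.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(rare_maf_threshold = 0.05, alpha = 0.05,
                          n_pcs = 0, collapse = TRUE,
                          covariate_sets = list(crude = character(0))) {
  check_prob(rare_maf_threshold, "rare_maf_threshold", 0, 0.5,
             open_lo = TRUE, open_hi = TRUE)
  check_prob(alpha, "alpha", 0, 1, open_lo = TRUE, open_hi = TRUE)
  structure(list(rare_maf_threshold = rare_maf_threshold, alpha = alpha,
                 n_pcs = n_pcs, collapse = isTRUE(collapse),
                 covariate_sets = covariate_sets),
            class = "screen_config")
}

#' Genotype principal components
#'
#' Scores of the top-k eigenvectors of the covariance of the column-centered
#' (not variance-scaled) additive genotype matrix, ordered by decreasing
#' eigenvalue. The sign of each component is fixed so its largest-magnitude
#' loading entry is positive.
#'
#' @param genotypes a [genotype_matrix()] or a plain numeric matrix.
#' @param k number of components, `k < min(n, p)`.
#' @return n x k score matrix with columns `PC1..PCk`.
#' @export
pca_genotypes <- function(genotypes, k) {
  G <- if (inherits(genotypes, "genotype_matrix")) genotypes$values else as.matrix(genotypes)
  if (!is_count(k) || k >= min(dim(G)))
    stopf("'k' must be a positive integer below min(n, p) = %d", min(dim(G)))
  v <- apply(G, 2L, stats::var)
  if (all(v == 0)) stopf("all genotype columns are monomorphic")
  pc <- stats::prcomp(G, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(G)
  scores
}

#' Append genotype PCs to a phenotype table
#'
#' @param pheno phenotype data frame with an `IID` column.
#' @param genotypes a [genotype_matrix()].
#' @param k number of components.
#' @return `pheno` with columns `PC1..PCk` appended (matched on `IID`).
#' @export
add_pcs <- function(pheno, genotypes, k) {
  sc <- pca_genotypes(genotypes, k)
  idx <- match(pheno$IID, rownames(sc))
  if (anyNA(idx)) stopf("phenotype IIDs absent from genotype matrix: %s",
                        paste(utils::head(pheno$IID[is.na(idx)], 5), collapse = ", "))
  cbind(pheno, as.data.frame(sc[idx, , drop = FALSE], row.names = NULL))
}

#' Additive single-predictor linear regression
#'
#' Least-squares fit of `y ~ predictor + covariates`; reports the predictor's
#' coefficient, standard error and two-sided p-value from the t reference
#' distribution with `n - k` degrees of freedom.
#'
#' @param y numeric response.
#' @param predictor numeric predictor (e.g. additive genotype coding).
#' @param covariates optional data frame / matrix of covariates.
#' @return List with `beta`, `se`, `p_value`, `df`, and a `degenerate` flag
#'   (`TRUE` when the residual variance is numerically zero, in which case
#'   `se` and `p_value` are `NA`).
#' @export
ols_regression <- function(y, predictor, covariates = NULL) {
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, predictor = predictor)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    X <- cbind(X, cv)
  }
  if (n <= ncol(X)) stopf("need n > number of coefficients (%d)", ncol(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  beta <- fit$coefficients["predictor"]
  scale_y <- max(sum(y^2), .Machine$double.eps)
  if (rss / scale_y < 1e-12) {
    return(list(beta = unname(beta), se = NA_real_, p_value = NA_real_,
                df = df, degenerate = TRUE))
  }
  s2 <- rss / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(s2 * XtXinv[2L, 2L])
  tval <- beta / se
  list(beta = unname(beta), se = unname(se),
       p_value = unname(2 * stats::pt(-abs(tval), df)),
       df = df, degenerate = FALSE)
}

#' Collapse rare variants into per-gene carrier indicators
#'
#' Indicator coding with equal weighting: for each gene with at least one
#' rare SNP (MAF below the threshold), the collapsed column equals 1 for an
#' individual carrying one or more minor alleles across that gene's rare
#' SNPs and 0 otherwise. Common SNPs pass through unchanged.
#'
#' @param genotypes a [genotype_matrix()].
#' @param rare_maf_threshold MAF boundary (default 0.05).
#' @param method `"indicator"` (carrier 0/1, the default) or `"count"`
#'   (per-gene rare minor-allele count).
#' @return List with `X` (columns: common SNPs then collapsed gene columns
#'   named `<gene>.rare`), `gene` (column -> gene map), `is_collapsed`
#'   (logical per column), and `rare_snps`.
#' @export
collapse_rare <- function(genotypes, rare_maf_threshold = 0.05,
                          method = c("indicator", "count")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  method <- match.arg(method)
  G <- genotypes$values
  gmap <- genotypes$gene_of_snp
  mafs <- snp_mafs(G)
  rare <- mafs < rare_maf_threshold
  common_cols <- G[, !rare, drop = FALSE]
  genes_with_rare <- unique(gmap[colnames(G)[rare]])
  coll <- sapply(genes_with_rare, function(g) {
    cols <- colnames(G)[rare & gmap == g]
    tot <- rowSums(G[, cols, drop = FALSE])
    if (method == "indicator") as.integer(tot >= 1) else as.integer(tot)
  })
  if (length(genes_with_rare)) {
    coll <- matrix(coll, nrow = nrow(G),
                   dimnames = list(rownames(G), paste0(genes_with_rare, ".rare")))
  } else {
    coll <- matrix(integer(0), nrow = nrow(G), ncol = 0,
                   dimnames = list(rownames(G), NULL))
  }
  X <- cbind(common_cols, coll)
  gene <- c(gmap[colnames(common_cols)],
            stats::setNames(genes_with_rare, colnames(coll)))
  list(X = X, gene = gene,
       is_collapsed = c(rep(FALSE, ncol(common_cols)), rep(TRUE, ncol(coll))),
       rare_snps = colnames(G)[rare])
}

#' Bonferroni-corrected per-test threshold
#'
#' @param n_tests number of tests performed (>= 1).
#' @param alpha family-wise level in (0, 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is_count(n_tests)) stopf("'n_tests' must be a positive integer")
  check_prob(alpha, "alpha", 0, 1, open_lo = TRUE, open_hi = TRUE)
  alpha / n_tests
}

#' Stage-1 association scan
#'
#' Per tested column (raw SNPs, or common SNPs plus collapsed gene
#' indicators when `config$collapse` is `TRUE`) and per covariate set, fits
#' the additive linear model `Q1 ~ column + covariates` and records the
#' column's coefficient, SE and p-value.
#'
#' @param genotypes a [genotype_matrix()], or the list returned by
#'   [collapse_rare()] to scan pre-collapsed columns.
#' @param pheno phenotype data frame with `IID`, `Q1` and any covariate
#'   columns referenced by `config$covariate_sets`.
#' @param config a [screen_config()].
#' @return Data frame with columns `model_tag snp_id gene beta se p`,
#'   ordered by `(model_tag, snp_id)`. Degenerate fits carry `NA` se/p.
#' @export
scan_assoc <- function(genotypes, pheno, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  if (inherits(genotypes, "genotype_matrix")) {
    if (config$collapse) {
      cc <- collapse_rare(genotypes, config$rare_maf_threshold)
      X <- cc$X; gene <- cc$gene
    } else {
      X <- genotypes$values; gene <- genotypes$gene_of_snp
    }
    ids <- rownames(genotypes$values)
  } else if (is.list(genotypes) && !is.null(genotypes$X)) {
    X <- genotypes$X; gene <- genotypes$gene; ids <- rownames(X)
  } else stopf("'genotypes' must be a genotype_matrix or collapse_rare() output")
  idx <- match(ids, pheno$IID)
  if (anyNA(idx))
    stopf("IIDs missing from phenotype table: %s",
          paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  ph <- pheno[idx, , drop = FALSE]
  y <- ph$Q1
  out <- list()
  for (tag in names(config$covariate_sets)) {
    covs <- config$covariate_sets[[tag]]
    miss <- setdiff(covs, names(ph))
    if (length(miss)) stopf("covariate set '%s' references missing column(s): %s",
                            tag, paste(miss, collapse = ", "))
    cv <- if (length(covs)) cov_design(ph[, covs, drop = FALSE]) else NULL
    res <- lapply(colnames(X), function(s) {
      if (stats::var(X[, s]) == 0)
        return(data.frame(model_tag = tag, snp_id = s, gene = unname(gene[s]),
                          beta = NA_real_, se = NA_real_, p = NA_real_))
      r <- ols_regression(y, X[, s], cv)
      data.frame(model_tag = tag, snp_id = s, gene = unname(gene[s]),
                 beta = r$beta, se = r$se, p = r$p_value)
    })
    out[[tag]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(model_tag = character(0), snp_id = character(0),
                      gene = character(0), beta = numeric(0), se = numeric(0),
                      p = numeric(0))
  }
  res <- res[order(res$model_tag, res$snp_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# expand factors/characters (e.g. Pop) into dummy columns
cov_design <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  parts <- list()
  if (any(num)) parts$num <- as.matrix(df[, num, drop = FALSE])
  for (nm in names(df)[!num]) {
    f <- factor(df[[nm]])
    if (nlevels(f) < 2L) next
    m <- stats::model.matrix(~f)[, -1L, drop = FALSE]
    colnames(m) <- paste0(nm, levels(f)[-1L])
    parts[[nm]] <- m
  }
  if (!length(parts)) return(NULL)
  do.call(cbind, parts)
}

#' Identify potentially interesting genes (PIGs)
#'
#' A PIG is a gene with at least one tested column (SNP or collapsed
#' indicator) at or below the p-value threshold.
#'
#' @param results data frame from [scan_assoc()] (needs `gene` and `p`).
#' @param threshold p-value threshold, e.g. [bonferroni_threshold()].
#' @param model_tag optional: restrict to one covariate-set tag.
#' @return Character vector of gene names (sorted, unique).
#' @export
identify_pigs <- function(results, threshold, model_tag = NULL) {
  if (!nrow(results)) return(character(0))
  if (!is.null(model_tag)) results <- results[results$model_tag %in% model_tag, , drop = FALSE]
  hit <- !is.na(results$p) & results$p <= threshold
  sort(unique(results$gene[hit]))
}

#' Confusion counts of identified vs causal sets across replicates
#'
#' Per replicate, `TP = |found & causal|`, `FP = |found \ causal|`,
#' `FN = |causal \ found|`; `TP + FN` always equals the number of causal
#' entries. Works for gene sets or SNP sets alike.
#'
#' @param found_sets list of character vectors (one per replicate), e.g. PIG
#'   lists.
#' @param causal character vector of true causal entries (non-empty).
#' @return Object of class `confusion_counts`: list with `per_replicate`
#'   (data frame `replicate TP FP FN`) and `summary` (mean, sd, min, max per
#'   count).
#' @export
confusion_counts <- function(found_sets, causal) {
  if (!length(causal)) stopf("'causal' must be non-empty")
  per <- do.call(rbind, lapply(seq_along(found_sets), function(r) {
    f <- unique(found_sets[[r]])
    data.frame(replicate = r,
               TP = length(intersect(f, causal)),
               FP = length(setdiff(f, causal)),
               FN = length(setdiff(causal, f)))
  }))
  summ <- do.call(rbind, lapply(c("TP", "FP", "FN"), function(k) {
    v <- per[[k]]
    data.frame(count = k, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v))
  }))
  structure(list(per_replicate = per, summary = summ, n_causal = length(causal)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts over %d replicates (%d causal entries)\n",
              nrow(x$per_replicate), x$n_causal))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
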