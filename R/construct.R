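#' Cronbach's alpha reliability
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of the item sum)`.
#'
#' @param items n x k matrix of item scores (k >= 2, n >= 3), or a k x k
#'   covariance matrix with `covariance = TRUE`.
#' @param covariance is `items` already a covariance matrix?
#' @return Reliability in `(-Inf, 1]`.
#' @export
cronbach_alpha <- function(items, covariance = FALSE) {
  if (covariance) {
    C <- as.matrix(items)
    if (nrow(C) != ncol(C)) stopf("covariance input must be square")
  } else {
    items <- as.matrix(items)
    if (ncol(items) < 2L) stopf("need at least 2 items")
    if (nrow(items) < 3L) stopf("need at least 3 observations")
    C <- stats::cov(items)
  }
  k <- ncol(C)
  if (k < 2L) stopf("need at least 2 items")
  total_var <- sum(C)
  if (total_var <= 0) stopf("zero total variance")
  (k / (k - 1)) * (1 - sum(diag(C)) / total_var)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of additive genotype codes (composite LD).
#'
#' @param g1,g2 genotype vectors of equal length, both polymorphic.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stopf("genotype vectors differ in length")
  if (stats::var(g1) == 0 || stats::var(g2) == 0) stopf("monomorphic input")
  stats::cor(g1, g2)^2
}

#' Eigenvalue profile of a SNP correlation matrix
#'
#' Scree-plot input for judging how many dimensions a gene's SNPs span.
#' Monomorphic columns are dropped with a warning. Eigenvalues are
#' non-increasing and sum to the number of retained SNPs.
#'
#' @param snp_matrix n x s genotype matrix (s >= 2 polymorphic SNPs).
#' @return Numeric vector of eigenvalues.
#' @export
eigen_screen <- function(snp_matrix) {
  G <- as.matrix(snp_matrix)
  v <- apply(G, 2L, stats::var)
  if (any(v == 0)) {
    warnf("dropping %d monomorphic column(s)", sum(v == 0))
    G <- G[, v > 0, drop = FALSE]
  }
  if (ncol(G) < 2L) stopf("need at least 2 polymorphic SNPs")
  eigen(stats::cor(G), symmetric = TRUE, only.values = TRUE)$values
}

#' Select informative SNPs for a gene construct
#'
#' Deterministic greedy rule freezing the judgment-based selection into a
#' reproducible procedure: rank the gene's SNPs by stage-1 p-value (ties by
#' SNP id), then keep a SNP if its maximum LD r-squared with the SNPs
#' already kept is at most `r2_threshold` (near-duplicates add nothing) and
#' at least `r2_min` (an indicator uncorrelated with the construct's other
#' indicators does not measure the same latent dimension and leaves the
#' factor empirically underidentified), stopping at `max_indicators`.
#'
#' @param gene gene name.
#' @param assoc_results stage-1 results data frame (`snp_id`, `gene`, `p`);
#'   collapsed columns are ignored.
#' @param genotypes a [genotype_matrix()] used for the LD table, or a
#'   precomputed symmetric r-squared matrix with SNP dimnames.
#' @param r2_threshold maximum allowed r-squared with kept SNPs (default 0.8).
#' @param r2_min minimum r-squared with the SNPs already kept (default 0.1);
#'   the coherence floor standing in for scree/reliability screening. Set
#'   to 0 to disable.
#' @param max_indicators maximum SNPs kept (default 6).
#' @param maf_min minimum MAF for a SNP to serve as a continuous indicator
#'   (default 0.01): near-monomorphic columns define a latent poorly and
#'   destabilize the fit; their burden is the collapsing step's job. Set to
#'   0 to disable. Ignored when `genotypes` is a precomputed r-squared
#'   table.
#' @return Character vector of selected SNP ids (ordered as selected).
#' @export
select_snps <- function(gene, assoc_results, genotypes,
                        r2_threshold = 0.8, r2_min = 0.1, max_indicators = 6,
                        maf_min = 0.01) {
  res <- assoc_results[assoc_results$gene == gene &
                         assoc_results$snp_id %in% names_of_snps(genotypes), , drop = FALSE]
  if (!nrow(res)) stopf("gene '%s' has no SNP-level results", gene)
  res <- res[!is.na(res$p), , drop = FALSE]
  if (maf_min > 0 && inherits(genotypes, "genotype_matrix")) {
    mafs <- snp_mafs(genotypes$values[, res$snp_id, drop = FALSE])
    if (any(mafs >= maf_min)) res <- res[mafs >= maf_min, , drop = FALSE]
  }
  if (!nrow(res)) stopf("gene '%s' has only degenerate results", gene)
  res <- res[order(res$p, res$snp_id), , drop = FALSE]
  r2 <- ld_table(genotypes, res$snp_id)
  kept <- character(0)
  for (s in res$snp_id) {
    if (!length(kept)) { kept <- s; next }
    if (max(r2[s, kept]) <= r2_threshold && max(r2[s, kept]) >= r2_min)
      kept <- c(kept, s)
    if (length(kept) >= max_indicators) break
  }
  kept
}

names_of_snps <- function(genotypes) {
  if (inherits(genotypes, "genotype_matrix")) colnames(genotypes$values)
  else colnames(genotypes)
}

# pairwise r2 among the named SNPs (monomorphic SNPs get r2 = 0)
ld_table <- function(genotypes, snps) {
  if (inherits(genotypes, "genotype_matrix")) {
    G <- genotypes$values[, snps, drop = FALSE]
    v <- apply(G, 2L, stats::var)
    r2 <- matrix(0, length(snps), length(snps), dimnames = list(snps, snps))
    poly <- v > 0
    if (sum(poly) >= 2L)
      r2[poly, poly] <- stats::cor(G[, poly, drop = FALSE])^2
    diag(r2) <- 1
    r2
  } else {
    as.matrix(genotypes)[snps, snps, drop = FALSE]
  }
}

#' Per-gene construct diagnostics report
#'
#' @param gene gene name.
#' @param genotypes a [genotype_matrix()].
#' @param selected_snps SNPs retained for the construct.
#' @return Object of class `construct_report`: selected SNPs, eigenvalues of
#'   their correlation matrix, Cronbach's alpha and the pairwise r-squared
#'   table.
#' @export
construct_report <- function(gene, genotypes, selected_snps) {
  G <- genotypes$values[, selected_snps, drop = FALSE]
  ev <- if (length(selected_snps) >= 2L) eigen_screen(G) else 1
  alpha <- if (length(selected_snps) >= 2L) cronbach_alpha(G) else NA_real_
  structure(list(gene = gene, selected_snps = selected_snps,
                 eigenvalues = ev, cronbach_alpha = alpha,
                 r2 = ld_table(genotypes, selected_snps)),
            class = "construct_report")
}

#' @export
print.construct_report <- function(x, ...) {
  cat(sprintf("Construct %s: %d SNPs (%s)\n", x$gene, length(x$selected_snps),
              paste(x$selected_snps, collapse = ", ")))
  cat(sprintf("  Cronbach alpha: %s; eigenvalues: %s\n",
              format(x$cronbach_alpha, digits = 3),
              paste(format(x$eigenvalues, digits = 3), collapse = ", ")))
  invisible(x)
}

#' Assemble a latent-gene-construct model specification
#'
#' Emits model text in the [sem_model()] grammar: one latent per gene over
#' its selected SNPs, a path from every gene to the trait, optionally a
#' population-structure latent (marker loading on the population indicator)
#' with paths to the genes and the trait, covariate paths to the trait, and
#' user-declared gene-to-gene paths. The output always parses and is
#' identified.
#'
#' @param gene_constructs named list: gene -> character vector of SNP ids.
#' @param trait trait variable name (default `"Q1"`).
#' @param covariates observed exogenous covariates given paths to the trait.
#' @param popstr_vars indicators of the population-structure latent (e.g.
#'   `c("Pop1", "PC1", ...)`); `NULL` omits it.
#' @param popstr_targets where the population-structure latent points:
#'   `"genes"`, `"trait"`, or both (default). Pruning the trait path
#'   mirrors dropping a non-significant structure-to-trait association.
#' @param inter_gene_paths optional 2-column matrix/data frame of gene ->
#'   gene paths.
#' @param gene_covary add `covary` lines between every pair of exogenous
#'   gene latents?
#' @return Model text (character scalar). Single-SNP constructs get their
#'   indicator residual fixed to 0 (latent identical to the observed SNP),
#'   keeping the model identified.
#' @export
assemble_model <- function(gene_constructs, trait = "Q1", covariates = NULL,
                           popstr_vars = NULL,
                           popstr_targets = c("genes", "trait"),
                           inter_gene_paths = NULL,
                           gene_covary = FALSE) {
  popstr_targets <- match.arg(popstr_targets, several.ok = TRUE)
  if (!length(gene_constructs)) stopf("no gene constructs supplied")
  genes <- names(gene_constructs)
  if (is.null(genes)) stopf("'gene_constructs' must be a named list")
  all_snps <- unlist(gene_constructs)
  clash <- intersect(all_snps, c(trait, covariates, popstr_vars))
  if (length(clash)) stopf("name collision between SNPs and other variables: %s",
                           paste(clash, collapse = ", "))
  out <- character(0)
  for (g in genes)
    out <- c(out, paste0("latent ", g, " = ",
                         paste(gene_constructs[[g]], collapse = " + ")))
  if (!is.null(popstr_vars))
    out <- c(out, paste0("latent PopStr = ", paste(popstr_vars, collapse = " + ")))
  out <- c(out, paste0("path ", genes, " -> ", trait))
  if (!is.null(popstr_vars)) {
    tgt <- c(if ("genes" %in% popstr_targets) genes,
             if ("trait" %in% popstr_targets) trait)
    out <- c(out, paste0("path PopStr -> ", tgt))
  }
  for (g in genes) {
    snps <- gene_constructs[[g]]
    if (length(snps) == 1L) {
      # single indicator: latent coincides with the observed SNP
      out <- c(out, paste0("fix ", snps, "~~", snps, " = 0"))
    } else if (length(snps) == 2L) {
      # two indicators: tau-equivalent loadings, else the loading split is
      # only identified through the construct's outside correlations
      out <- c(out, paste0("fix ", g, "=~", snps[2], " = 1"))
    }
  }
  if (!is.null(covariates))
    out <- c(out, paste0("path ", covariates, " -> ", trait))
  if (!is.null(inter_gene_paths)) {
    ig <- as.matrix(inter_gene_paths)
    bad <- setdiff(c(ig), genes)
    if (length(bad)) stopf("inter-gene path names unknown: %s", paste(bad, collapse = ", "))
    out <- c(out, paste0("path ", ig[, 1], " -> ", ig[, 2]))
  }
  if (gene_covary && length(genes) > 1L) {
    pairs <- utils::combn(genes, 2L)
    out <- c(out, paste0("covary ", pairs[1, ], " ", pairs[2, ]))
  }
  paste(out, collapse = "\n")
}
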