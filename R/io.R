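#' Write a study to disk in PLINK-style text formats
#'
#' Writes `study.ped` / `study.map` (whitespace-separated, two allele columns
#' per SNP; counted minor allele written as `A`, the other as `B`), an
#' additive-coded matrix export `genotypes.tsv` (individuals x SNPs, header
#' row of SNP ids), one tab-delimited phenotype file per replicate
#' (`pheno_rep<k>.tsv` with header `IID Q1 Age Sex Smoke Pop`), a
#' `snp_genes.tsv` SNP-to-gene map, and `truth.tsv` listing causal SNPs and
#' their generating effects. The pair round-trips losslessly through
#' [read_study()].
#'
#' @param replicate_set a `replicate_set` from [simulate_replicates()].
#' @param directory target directory (created if absent).
#' @param chromosomes optional named vector gene -> chromosome for the `.map`.
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(replicate_set, directory, chromosomes = NULL) {
  stopifnot(inherits(replicate_set, "replicate_set"))
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf("cannot create directory '%s'", directory)
  geno <- replicate_set$genotypes
  G <- geno$values
  snps <- colnames(G)
  genes <- geno$gene_of_snp
  chrom <- if (is.null(chromosomes)) as.integer(factor(genes, levels = unique(genes)))
           else unname(chromosomes[genes])
  files <- character(0)
  wr <- function(path, lines) {
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) stopf("failed writing '%s': %s", path, conditionMessage(e)))
    files <<- c(files, path)
  }
  map_path <- file.path(directory, "study.map")
  wr(map_path, paste(chrom, snps, 0, seq_along(snps) * 1000L, sep = "\t"))
  # .ped: FID IID PAT MAT SEX PHENO + two alleles per SNP; A = counted allele
  allele1 <- ifelse(G >= 1, "A", "B")
  allele2 <- ifelse(G == 2, "A", "B")
  ped_geno <- matrix("", nrow(G), 2L * ncol(G))
  ped_geno[, seq(1L, 2L * ncol(G), by = 2L)] <- allele1
  ped_geno[, seq(2L, 2L * ncol(G), by = 2L)] <- allele2
  sex_col <- if (length(replicate_set$phenotypes)) replicate_set$phenotypes[[1]]$Sex + 1L
             else rep(0L, nrow(G))
  ped <- cbind(rownames(G), rownames(G), 0, 0, sex_col, -9, ped_geno)
  wr(file.path(directory, "study.ped"), apply(ped, 1L, paste, collapse = " "))
  wr(file.path(directory, "genotypes.tsv"),
     c(paste(c("IID", snps), collapse = "\t"),
       paste(rownames(G), apply(G, 1L, paste, collapse = "\t"), sep = "\t")))
  wr(file.path(directory, "snp_genes.tsv"),
     c("snp\tgene", paste(snps, genes, sep = "\t")))
  for (r in seq_along(replicate_set$phenotypes)) {
    ph <- replicate_set$phenotypes[[r]]
    p <- file.path(directory, sprintf("pheno_rep%03d.tsv", r))
    utils::write.table(ph, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, p)
  }
  tr <- replicate_set$truth
  wr(file.path(directory, "truth.tsv"),
     c("snp\tgene\teffect",
       if (length(tr$causal_snps))
         paste(tr$causal_snps, genes[tr$causal_snps],
               format(tr$effects, digits = 15, trim = TRUE), sep = "\t")))
  invisible(files)
}

#' Read a PLINK-style .ped/.map pair into a genotype matrix
#'
#' Counts occurrences of `counted_allele` (default `"A"`, the orientation
#' written by [write_study()]) at each SNP, preserving minor-allele
#' orientation across a write/read round trip.
#'
#' @param ped_path,map_path file paths.
#' @param gene_of_snp optional SNP -> gene map; if `NULL`, looks for
#'   `snp_genes.tsv` next to the `.ped`, else assigns each SNP its own gene.
#' @param counted_allele allele whose copies are counted.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path, gene_of_snp = NULL,
                         counted_allele = "A") {
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) stopf("file not found: '%s'", p)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  snps <- as.character(map[[2]])
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(ped) != 6L + 2L * length(snps))
    stopf("'%s' has %d columns; expected %d for %d SNPs",
          ped_path, ncol(ped), 6L + 2L * length(snps), length(snps))
  a1 <- as.matrix(ped[, 6L + seq(1L, 2L * length(snps), 2L), drop = FALSE])
  a2 <- as.matrix(ped[, 6L + seq(2L, 2L * length(snps), 2L), drop = FALSE])
  G <- (a1 == counted_allele) + (a2 == counted_allele)
  storage.mode(G) <- "integer"
  colnames(G) <- snps
  rownames(G) <- as.character(ped[[2]])
  if (is.null(gene_of_snp)) {
    side <- file.path(dirname(ped_path), "snp_genes.tsv")
    gene_of_snp <- if (file.exists(side)) {
      sg <- utils::read.table(side, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
      stats::setNames(sg$gene, sg$snp)
    } else stats::setNames(snps, snps)
  }
  genotype_matrix(G, gene_of_snp)
}

#' Read a tab-delimited phenotype/covariate table
#'
#' Expects the header `IID Q1 Age Sex Smoke Pop`.
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_pheno_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  ph <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("IID", "Q1", "Age", "Sex", "Smoke", "Pop")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stopf("'%s' lacks column(s): %s", path, paste(miss, collapse = ", "))
  ph$IID <- as.character(ph$IID)
  ph
}

#' Read a study directory written by [write_study()]
#'
#' @param directory path containing `study.ped`, `study.map` and
#'   `pheno_rep*.tsv` files.
#' @return A `replicate_set` (truth restored from `truth.tsv` when present).
#' @export
read_study <- function(directory) {
  geno <- read_ped_map(file.path(directory, "study.ped"),
                       file.path(directory, "study.map"))
  pf <- sort(list.files(directory, pattern = "^pheno_rep[0-9]+\\.tsv$",
                        full.names = TRUE))
  if (!length(pf)) stopf("no phenotype replicates found in '%s'", directory)
  phen <- lapply(pf, read_pheno_table)
  geno$population <- phen[[1]]$Pop[match(rownames(geno$values), phen[[1]]$IID)]
  truth <- list(causal_genes = character(0), causal_snps = character(0),
                effects = numeric(0))
  tp <- file.path(directory, "truth.tsv")
  if (file.exists(tp)) {
    tt <- utils::read.table(tp, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    if (nrow(tt)) {
      truth <- list(causal_genes = unique(tt$gene), causal_snps = tt$snp,
                    effects = stats::setNames(tt$effect, tt$snp))
    }
  }
  structure(list(genotypes = geno, phenotypes = phen, truth = truth),
            class = "replicate_set")
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' A top-level `seed` is mandatory.
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: '%s'", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stopf("config '%s' must declare a top-level 'seed'", path)
  cfg
}
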