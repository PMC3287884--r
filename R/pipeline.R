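#' Run the full two-stage pipeline
#'
#' Orchestrates simulate -> stage-1 screen -> construct building -> SEM fit
#' -> replicate evaluation, writing every stage artifact into a run
#' directory: the study files ([write_study()]), the association table, the
#' per-replicate PIG lists, a confusion summary against the simulated
#' truth, construct reports, the assembled model spec (`model.sem`), the
#' fit report, the bias report, and a machine-readable `manifest.json`.
#' Deterministic given the seed; stages log via [message()].
#'
#' @param config named list (or YAML/JSON path readable by
#'   [read_pipeline_config()]) with at least `seed` and `out_dir`. Optional
#'   blocks: `study` (arguments of [gaw_study_config()] plus
#'   `n_replicates`), `stage1` (`alpha`, `rare_maf_threshold`, `collapse`,
#'   `n_pcs`), `construct` (`max_indicators`, `r2_threshold`), `sem`
#'   (`robust`), `evaluate` (`se`, `max_nonconverged`,
#'   `reference_replicate`).
#' @param causal_gene_list optional: skip PIG selection and build constructs
#'   for these genes directly (the answer-driven variant).
#' @return Invisibly, a list with the key in-memory results (`pigs`,
#'   `confusion`, `fit`, `report`, `manifest`).
#' @export
run_two_stage <- function(config, causal_gene_list = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$seed)) stopf("config must declare 'seed'")
  if (is.null(config$out_dir)) stopf("config must declare 'out_dir'")
  seed <- as.integer(config$seed)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "genesem",
                   version = as.character(utils::packageVersion("genesem")),
                   seed = seed, stages = list())
  stage <- function(name, expr) {
    message(sprintf("[%s] running", name))
    val <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    manifest$stages[[name]] <<- TRUE
    val
  }

  st <- config$study %||% list()
  study_cfg <- gaw_study_config(
    n_decoy_genes = st$n_decoy_genes %||% 21,
    snps_per_decoy = st$snps_per_decoy %||% 5,
    differentiation = st$differentiation %||% 0.1,
    ld = st$ld %||% 0.9)
  if (!is.null(st$trait)) study_cfg$trait <- do.call(trait_model, st$trait)
  if (!is.null(st$zero_effects) && isTRUE(st$zero_effects)) {
    study_cfg$genes <- lapply(study_cfg$genes, function(g) { g$effects[] <- 0; g })
  }
  n_rep <- st$n_replicates %||% 5L
  rs <- stage("simulate", {
    r <- simulate_study(study_cfg, seed = seed, n_replicates = n_rep)
    write_study(r, file.path(out, "study"))
    r
  })

  s1 <- config$stage1 %||% list()
  scfg <- screen_config(
    rare_maf_threshold = s1$rare_maf_threshold %||% 0.05,
    alpha = s1$alpha %||% 0.05,
    n_pcs = s1$n_pcs %||% 0,
    collapse = s1$collapse %||% TRUE,
    covariate_sets = list(adjusted = c("Age", "Sex", "Smoke",
                                       if ((s1$n_pcs %||% 0) > 0)
                                         paste0("PC", seq_len(s1$n_pcs)))))
  ref_idx <- (config$evaluate %||% list())$reference_replicate %||% 1L
  stage1_out <- stage("stage1", {
    cols <- if (scfg$collapse) collapse_rare(rs$genotypes, scfg$rare_maf_threshold)
            else rs$genotypes
    n_tests <- if (scfg$collapse) ncol(cols$X) else ncol(rs$genotypes$values)
    thr <- bonferroni_threshold(n_tests, scfg$alpha)
    pigs <- vector("list", length(rs$phenotypes))
    ref_res <- NULL
    for (r in seq_along(rs$phenotypes)) {
      ph <- rs$phenotypes[[r]]
      if (scfg$n_pcs > 0) ph <- add_pcs(ph, rs$genotypes, scfg$n_pcs)
      res <- scan_assoc(cols, ph, scfg)
      if (r == ref_idx) {
        ref_res <- res
        utils::write.table(res, file.path(out, "assoc_reference.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      pigs[[r]] <- identify_pigs(res, thr)
    }
    writeLines(vapply(pigs, paste, "", collapse = ","),
               file.path(out, "pig_lists.txt"))
    conf <- NULL
    if (length(rs$truth$causal_genes)) {
      conf <- confusion_counts(pigs, rs$truth$causal_genes)
      utils::write.table(conf$summary, file.path(out, "confusion.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(pigs = pigs, threshold = thr, reference_results = ref_res,
         confusion = conf)
  })

  genes <- if (!is.null(causal_gene_list)) {
    unknown <- setdiff(causal_gene_list, unique(rs$genotypes$gene_of_snp))
    if (length(unknown)) stopf("unknown gene name(s): %s", paste(unknown, collapse = ", "))
    causal_gene_list
  } else stage1_out$pigs[[ref_idx]]

  if (!length(genes)) {
    message("[stage2] skipped: no potentially interesting genes identified")
    manifest$stages$stage2 <- "skipped: empty PIG list"
    manifest_write(manifest, out)
    return(invisible(list(pigs = stage1_out$pigs, confusion = stage1_out$confusion,
                          fit = NULL, report = NULL, manifest = manifest)))
  }

  cc <- config$construct %||% list()
  # SNP-level (non-collapsed) results for selection
  sel_res <- stage("constructs", {
    ph <- rs$phenotypes[[ref_idx]]
    raw_res <- scan_assoc(rs$genotypes, ph,
                          screen_config(collapse = FALSE,
                                        covariate_sets = list(crude = character(0))))
    constructs <- lapply(genes, function(g)
      select_snps(g, raw_res, rs$genotypes,
                  r2_threshold = cc$r2_threshold %||% 0.8,
                  max_indicators = cc$max_indicators %||% 6))
    names(constructs) <- genes
    reports <- lapply(genes, function(g)
      construct_report(g, rs$genotypes, constructs[[g]]))
    tab <- do.call(rbind, lapply(reports, function(r)
      data.frame(gene = r$gene, snps = paste(r$selected_snps, collapse = ","),
                 alpha = r$cronbach_alpha)))
    utils::write.table(tab, file.path(out, "constructs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    constructs
  })

  model_text <- assemble_model(sel_res, trait = "Q1")
  writeLines(model_text, file.path(out, "model.sem"))

  sem_opts <- config$sem %||% list()
  fit <- stage("fit", {
    d <- sem_data(rs, ref_idx)
    f <- sem(model_text, d, robust = sem_opts$robust %||% TRUE)
    est <- f$estimates
    utils::write.table(
      data.frame(label = est$label, estimate = est$est, se = est$se,
                 robust_se = est$se_robust, std_estimate = est$std_est,
                 std_se = est$std_se),
      file.path(out, "fit_parameters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sprintf("n\t%d\nT\t%.6g\ndf\t%d\nT_scaled\t%.6g\nCFI\t%.4f\nRMSEA\t%.4f\nSRMR\t%.4f",
                       f$n, f$T_stat, f$df, f$T_scaled, f$indices$cfi,
                       f$indices$rmsea, f$indices$srmr),
               file.path(out, "fit_block.tsv"))
    f
  })

  ev <- config$evaluate %||% list()
  report <- NULL
  if (length(rs$phenotypes) > 1L) {
    report <- stage("evaluate", {
      other <- setdiff(seq_along(rs$phenotypes), ref_idx)
      reps <- lapply(other, function(r) sem_data(rs, r))
      rep_out <- evaluate_replicates(model_text, fit, reps,
                                     se = ev$se %||% "robust",
                                     max_nonconverged = ev$max_nonconverged %||% 0.2)
      utils::write.table(rep_out$per_parameter, file.path(out, "bias_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rep_out
    })
  }
  manifest_write(manifest, out)
  invisible(list(pigs = stage1_out$pigs, confusion = stage1_out$confusion,
                 constructs = sel_res, model_text = model_text,
                 fit = fit, report = report, manifest = manifest))
}

manifest_write <- function(manifest, out) {
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Answer-driven pipeline run
#'
#' Identical to [run_two_stage()] but skips PIG selection: constructs are
#' built directly for the supplied causal genes.
#'
#' @param config as in [run_two_stage()].
#' @param causal_gene_list genes to model (must exist in the study).
#' @return As [run_two_stage()].
#' @export
run_answer_driven <- function(config, causal_gene_list) {
  if (!length(causal_gene_list)) stopf("'causal_gene_list' must be non-empty")
  run_two_stage(config, causal_gene_list = causal_gene_list)
}
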