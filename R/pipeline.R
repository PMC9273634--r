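# --- end-to-end orchestration: simulate -> qc -> discover -> prioritize ---

#' Pipeline run configuration
#'
#' Resolved thresholds are echoed into the run report so every
#' threshold-sensitive result is auditable. Defaults are the published
#' filters: GQ >= 20, DP >= 10, MAF <= 0.01.
#'
#' @param spec a [cohort_spec()] used by the `simulate` stage (ignored when
#'   `cohort`/`resources` are supplied directly)
#' @param thresholds a [qc_thresholds()]
#' @param min_gq,min_dp,max_maf funnel thresholds
#' @param out_dir output directory (NULL = no files written)
#' @param seed master seed; recorded in every output header
#' @param stages named logical toggles: qc, discover, prioritize, stability,
#'   enrich, expression
#' @param ddg_path optional ddG replicate TSV for the stability stage
#'   (defaults to the packaged synthetic replicate fixture)
#' @return list of class `run_config`
#' @export
run_config <- function(spec = NULL, thresholds = qc_thresholds(),
                       min_gq = 20L, min_dp = 10L, max_maf = 0.01,
                       out_dir = NULL, seed = 1L,
                       stages = c(qc = TRUE, discover = TRUE,
                                  prioritize = TRUE, stability = TRUE,
                                  enrich = TRUE, expression = TRUE),
                       ddg_path = NULL) {
  stopifnot(min_gq > 0, min_dp > 0, max_maf > 0)
  spec <- spec %||% cohort_spec(seed = seed)
  structure(list(spec = spec, thresholds = thresholds, min_gq = min_gq,
                 min_dp = min_dp, max_maf = max_maf, out_dir = out_dir,
                 seed = as.integer(seed), stages = stages,
                 ddg_path = ddg_path),
            class = "run_config")
}

.log_stage <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(log, line)
}

#' Run the full trio DNM pipeline
#'
#' simulate -> qc -> discover -> prioritize -> stability -> enrich /
#' expression, with structured per-stage logging (counts in/out and the
#' thresholds applied, so the funnel is reconstructible from the log), file
#' outputs and a Markdown report. Any stage failure aborts with the stage
#' name; outputs of earlier stages are preserved.
#'
#' @param config a [run_config()]
#' @param sim optional pre-built [generate_cohort()] result (skips the
#'   simulate stage)
#' @return list of class `pipeline_result` with elements `sim`, `qc`, `dnm`,
#'   `prioritized`, `stability`, `enrichment`, `contrasts`, `heat`,
#'   `summary`, `report` (character lines), `log`
#' @export
run_pipeline <- function(config = run_config(), sim = NULL) {
  log <- character(0)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  st <- config$stages

  sim <- sim %||% run_stage("simulate", generate_cohort(config$spec))
  log <- .log_stage(log, "simulate",
                    sprintf("%d trios, seed %d", nrow(sim$cohort$pedigree),
                            config$spec$seed))
  res <- sim$resources
  out <- list(sim = sim)

  if (isTRUE(st[["qc"]])) {
    out$qc <- run_stage("qc", apply_qc(sim$cohort, config$thresholds))
    log <- .log_stage(log, "qc", sprintf(
      "in=%d trios, retained=%d, hwe_sites_removed=%d (missingness>%.2f, hwe<%g, mendel>%gSD, hethom>%gSD)",
      nrow(sim$cohort$pedigree), nrow(out$qc$retained),
      length(out$qc$hwe_failed_sites), config$thresholds$max_missingness,
      config$thresholds$hwe_alpha, config$thresholds$mendelian_sd,
      config$thresholds$hethom_sd))
  }

  if (isTRUE(st[["discover"]]) && !is.null(out$qc)) {
    out$dnm <- run_stage("discover",
                         discover_dnms(out$qc$retained_cohort, res,
                                       min_gq = config$min_gq,
                                       min_dp = config$min_dp,
                                       max_maf = config$max_maf))
    f <- out$dnm$funnel
    log <- .log_stage(log, "discover", sprintf(
      "funnel %s (GQ>=%d, DP>=%d, MAF<=%g)",
      paste(sprintf("%s=%d", f$stage, f$retained), collapse = " "),
      config$min_gq, config$min_dp, config$max_maf))
  }

  if (isTRUE(st[["prioritize"]]) && !is.null(out$dnm)) {
    out$prioritized <- run_stage("prioritize",
                                 build_prioritized_table(out$dnm$dnms,
                                                         res$evidence))
    log <- .log_stage(log, "prioritize",
                      sprintf("in=%d DNMs, prioritized=%d",
                              nrow(out$dnm$dnms), nrow(out$prioritized)))
  }

  if (isTRUE(st[["stability"]])) {
    path <- config$ddg_path %||%
      system.file("extdata", "shh_ddg_replicates_synthetic.tsv",
                  package = "denovotrio")
    if (nzchar(path) && file.exists(path)) {
      out$stability <- run_stage("stability", stability_from_table(path))
      log <- .log_stage(log, "stability",
                        sprintf("%d variant(s) classified",
                                nrow(out$stability)))
    }
  }

  if (isTRUE(st[["enrich"]]) && !is.null(out$dnm) && nrow(out$dnm$dnms) > 0L) {
    out$enrichment <- run_stage("enrich",
                                enrich(unique(stats::na.omit(out$dnm$dnms$gene)),
                                       res$gene_sets))
    log <- .log_stage(log, "enrich",
                      sprintf("%d terms tested, %d significant at p<0.05",
                              nrow(out$enrichment),
                              sum(out$enrichment$significant)))
  }

  if (isTRUE(st[["expression"]]) && !is.null(out$dnm) &&
      nrow(out$dnm$dnms) > 0L) {
    genes <- unique(stats::na.omit(out$dnm$dnms$gene))
    out$contrasts <- run_stage("expression",
                               tissue_contrast(res$expression, genes,
                                               "maxillary_E10.5",
                                               "mandibular_E10.5"))
    present <- genes[genes %in% rownames(res$expression)]
    if (length(present))
      out$heat <- run_stage("expression", heat_values(res$expression, present))
    log <- .log_stage(log, "expression",
                      sprintf("%d genes contrasted, %d elevated, %d missing",
                              nrow(out$contrasts), sum(out$contrasts$elevated),
                              sum(out$contrasts$missing)))
  }

  out$summary <- summarize_cohort(if (!is.null(out$qc)) out$qc$retained
                                  else sim$cohort$pedigree)
  out$report <- .build_report(out, config)
  out$log <- log

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_outputs(out, config$out_dir, seed = config$seed)
    if (!is.null(out$qc))
      write_pedigree(out$qc$retained, file.path(config$out_dir, "retained.ped"))
    writeLines(out$report, file.path(config$out_dir, "report.md"))
  }
  structure(out, class = "pipeline_result")
}

.build_report <- function(out, config) {
  r <- c("# Trio de novo mutation pipeline report", "",
         sprintf("seed: %d", config$seed), "")
  if (!is.null(out$qc)) {
    excl <- out$qc$results[!out$qc$results$pass, ]
    r <- c(r, "## Quality control", "",
           sprintf("- trios screened: %d", nrow(out$qc$results)),
           sprintf("- trios retained: %d", nrow(out$qc$retained)),
           sprintf("- sites removed by HWE screen: %d",
                   length(out$qc$hwe_failed_sites)),
           if (nrow(excl)) c("- exclusions:",
                             sprintf("    - %s: %s", excl$trio_id,
                                     excl$reasons)) else NULL, "")
  }
  if (!is.null(out$dnm)) {
    f <- out$dnm$funnel
    mean_dnm <- if (nrow(out$qc$retained) > 0)
      nrow(out$dnm$dnms) / nrow(out$qc$retained) else 0
    r <- c(r, "## Filtration funnel", "",
           sprintf("- %s: %d", f$stage, f$retained), "",
           sprintf("- protein-altering DNMs: %d", nrow(out$dnm$dnms)),
           sprintf("- mean DNMs per case: %.1f", mean_dnm), "")
  }
  if (!is.null(out$prioritized))
    r <- c(r, "## Prioritization", "",
           sprintf("- DNMs in genes with craniofacial evidence: %d",
                   nrow(out$prioritized)), "")
  if (!is.null(out$stability))
    r <- c(r, "## Protein stability", "",
           sprintf("- %s: ddG %.3f +/- %.3f kcal/mol (%s)",
                   out$stability$variant, out$stability$ddg_mean,
                   out$stability$ddg_sd,
                   ifelse(out$stability$disease_likely,
                          "likely disease causing", "below 1 kcal/mol")), "")
  if (!is.null(out$enrichment)) {
    sig <- out$enrichment[out$enrichment$significant, ]
    r <- c(r, "## Gene-set enrichment", "",
           if (nrow(sig)) sprintf("- %s: p = %.4g", sig$term, sig$p)
           else "- no term reached nominal p < 0.05", "")
  }
  if (!is.null(out$contrasts))
    r <- c(r, "## Maxillary vs mandibular E10.5 expression", "",
           sprintf("- %d of %d genes elevated (%d not detected in mouse)",
                   sum(out$contrasts$elevated), nrow(out$contrasts),
                   sum(out$contrasts$missing)), "")
  tab <- out$summary$table
  r <- c(r, "## Cohort (retained trios)", "",
         paste0("| | ", paste(colnames(tab), collapse = " | "), " |"),
         paste0("|", paste(rep("---", ncol(tab) + 1L), collapse = "|"), "|"),
         vapply(rownames(tab), function(rn)
           paste0("| ", rn, " | ", paste(tab[rn, ], collapse = " | "), " |"),
           character(1)))
  r
}
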