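## Pipeline orchestration: config validation, staged execution with
## checksum-guarded re-runs, and report data (Manhattan/QQ tables,
## genomic inflation).

#' Genomic inflation factor (lambda GC)
#'
#' Median of the 1-df chi-squared quantiles implied by the p-values,
#' divided by the 1-df chi-squared median (`qchisq(0.5, 1)` =
#' 0.4549364...). All-null p-values give lambda near 1; an excess of
#' small p inflates it.
#'
#' @param p P-values in `(0, 1]`.
#' @return Lambda.
#' @export
lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values")
  stopifnot(all(p > 0), all(p <= 1))
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' QQ-plot data for a p-value vector
#'
#' @param p P-values.
#' @return Data.frame of expected vs observed -log10 p, sorted.
#' @export
qq_data <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(p))
}

#' Read and validate a pipeline configuration
#'
#' YAML with sections: `cohort` (either `simulate:` with a
#' [simulation_spec()]-shaped block, or `panels:` file paths plus
#' `sample_file`), `analysis` (`models`, `covariates`, `panel_priority`,
#' `gw_threshold`, `effective_tests`), `qc` (threshold overrides), and
#' `output` (`dir`). Validation happens before any computation.
#'
#' @param path YAML config path.
#' @return Validated config list, class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$output$dir)) stop("config error: output.dir missing")
  if (is.null(cfg$cohort)) stop("config error: cohort section missing")
  if (is.null(cfg$cohort$simulate)) {
    if (is.null(cfg$cohort$panels)) stop("config error: cohort needs simulate or panels")
    for (p in cfg$cohort$panels)
      if (!file.exists(p$gen)) stop("config error: missing panel file ", p$gen)
    if (!is.null(cfg$cohort$sample_file) && !file.exists(cfg$cohort$sample_file))
      stop("config error: missing sample file ", cfg$cohort$sample_file)
  }
  cfg$analysis$models <- cfg$analysis$models %||% MODELS
  bad <- setdiff(cfg$analysis$models, MODELS)
  if (length(bad)) stop("config error: unknown model(s) ", paste(bad, collapse = ", "))
  cfg$analysis$covariates <- cfg$analysis$covariates %||% character(0)
  cfg$analysis$gw_threshold <- cfg$analysis$gw_threshold %||% 5e-8
  cfg$analysis$effective_tests <- cfg$analysis$effective_tests %||% 2.5
  cfg$seed <- cfg$seed %||% 1L
  qc_args <- cfg$qc %||% list()
  cfg$thresholds <- do.call(qc_thresholds, qc_args)
  class(cfg) <- "pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_manifest_path <- function(outdir) file.path(outdir, "stage_manifest.json")

read_manifest <- function(outdir) {
  mp <- stage_manifest_path(outdir)
  if (file.exists(mp)) jsonlite::read_json(mp, simplifyVector = TRUE) else list()
}

## a stage re-runs only when its input checksums changed or its outputs
## are missing
stage_guard <- function(outdir, stage, inputs, outputs) {
  man <- read_manifest(outdir)
  sums <- unname(tools::md5sum(inputs[file.exists(inputs)]))
  prev <- man[[stage]]
  up_to_date <- !is.null(prev) && identical(unname(unlist(prev$checksums)), sums) &&
    all(file.exists(outputs))
  list(skip = up_to_date,
       record = function() {
         man <- read_manifest(outdir)
         man[[stage]] <- list(checksums = sums, time = as.character(Sys.time()))
         jsonlite::write_json(man, stage_manifest_path(outdir), auto_unbox = TRUE)
       })
}

#' Run the full association pipeline
#'
#' Stages: cohort (simulate or load panels), marker QC, panel
#' combination, association per phenotype, locus collapsing and
#' classification, report data (summary-statistics TSV, loci TSV,
#' Manhattan/QQ tables, lambda GC). Deterministic given the config seed;
#' a stage whose inputs are unchanged and whose outputs exist is skipped
#' (checksum guard). A structured log with per-stage record counts is
#' written to `pipeline_log.tsv`.
#'
#' @param config A [read_pipeline_config()] result or path to one.
#' @param stages Stages to run; earlier stages are reused from disk when
#'   omitted (e.g. `stages = "loci"` re-collapses loci from the existing
#'   summary-statistics file).
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config,
                         stages = c("cohort", "qc", "combine", "assoc",
                                    "loci", "report")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  outdir <- config$output$dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ## checksum guard: identical config + complete outputs => no-op
  cfg_path <- file.path(outdir, "config_used.json")
  jsonlite::write_json(config[setdiff(names(config), "thresholds")], cfg_path,
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  main_outputs <- file.path(outdir, c("summary_stats.tsv", "loci.tsv",
                                      "lambda_gc.tsv", "pipeline_log.tsv"))
  full_run <- setequal(stages, c("cohort", "qc", "combine", "assoc", "loci", "report"))
  guard <- stage_guard(outdir, "pipeline", cfg_path, main_outputs)
  if (full_run && guard$skip) {
    message("pipeline outputs up to date; nothing to do")
    return(invisible(outdir))
  }
  log_rows <- list()
  note <- function(stage, what, n) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = stage, what = what, n = n, time = as.character(Sys.time()))
  }

  need_genotypes <- any(c("cohort", "qc", "combine", "assoc") %in% stages)
  combined <- NULL; pheno <- NULL
  ss_path <- file.path(outdir, "summary_stats.tsv")
  if (need_genotypes) {
  ## --- cohort stage ---------------------------------------------------------
  if (!is.null(config$cohort$simulate)) {
    sim <- config$cohort$simulate
    vdf <- do.call(rbind, lapply(sim$variants, as.data.frame))
    spec <- simulation_spec(n_samples = sim$n_samples,
                            case_fraction = sim$case_fraction,
                            variants = vdf,
                            n_pcs = sim$n_pcs %||% 0L,
                            panels = sim$panels,
                            seed = config$seed)
    cohort <- simulate_cohort(spec)
    panels <- cohort$panels
    pheno <- cohort$phenotypes
  } else {
    panels <- lapply(config$cohort$panels, function(p) {
      gp <- read_gen(p$gen, chrom = p$chrom %||% NULL)$genotypes
      panel_result_set(p$name, gp)
    })
    pheno <- read_sample_file(config$cohort$sample_file)
    for (i in seq_along(panels))
      panels[[i]]$genotypes$samples <- pheno$sample_id
  }
  note("cohort", "panels", length(panels))
  note("cohort", "samples", nrow(pheno))

  ## --- marker QC per panel --------------------------------------------------
  th <- config$thresholds
  panels <- lapply(panels, function(ps) {
    qc <- marker_qc(ps$genotypes, th)
    keep <- qc$keep & !is.na(ps$info) & ps$info >= th$min_info
    panel_result_set(ps$panel, gpm_subset(ps$genotypes, keep), ps$info[keep])
  })
  note("qc", "variants_after_qc", sum(vapply(panels, function(p) n_variants(p$genotypes), 0)))

  ## --- combine --------------------------------------------------------------
  combined <- combine_panels(panels, config$analysis$panel_priority %||% NULL)
  note("combine", "variants", n_variants(combined$genotypes))
  }

  ## --- association ----------------------------------------------------------
  if ("assoc" %in% stages) {
    records <- run_association(combined, pheno,
                               covariate_names = config$analysis$covariates,
                               models = config$analysis$models,
                               gw_threshold = config$analysis$gw_threshold,
                               thresholds = th,
                               effective_tests = config$analysis$effective_tests)
    note("assoc", "records", nrow(records))
    if (nrow(records)) write_summary_stats(records, ss_path)
  } else {
    if (!file.exists(ss_path))
      stop("stage failure [assoc]: no summary statistics to reuse at ", ss_path)
    records <- read_summary_stats(ss_path)
    records$gw_significant <- !is.na(records$p) & records$p < config$analysis$gw_threshold
    records$ew_significant <- !is.na(records$p) &
      records$p < experimentwide_threshold(config$analysis$gw_threshold,
                                           config$analysis$effective_tests)
    note("assoc", "records_reused", nrow(records))
  }

  ## --- loci -----------------------------------------------------------------
  sig <- records[records$gw_significant, , drop = FALSE]
  loci <- collapse_loci(sig, phenotype = config$analysis$phenotype %||% "pheno")
  loci$dominance_deviation_p <- rep(NA_real_, nrow(loci))
  if (nrow(loci)) {
    loci$classification <- vapply(seq_len(nrow(loci)), function(i) {
      dd_p <- NA_real_
      if (!is.null(combined)) {
        j <- match(loci$lead_id[i], combined$genotypes$variants$id)
        dd <- dominance_deviation_test(
          matrix(combined$genotypes$probs[, j, ], ncol = 3), pheno$status,
          covariate_matrix(pheno, config$analysis$covariates))
        dd_p <- dd$p
      }
      loci$dominance_deviation_p[i] <<- dd_p
      classify_inheritance(loci[i, ], dd_p,
                           threshold = config$analysis$gw_threshold)
    }, character(1))
  }
  note("loci", "loci", nrow(loci))
  write.table(loci, file.path(outdir, "loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = NA_TOKEN)

  ## --- report data ----------------------------------------------------------
  for (m in intersect(unique(records$model), config$analysis$models)) {
    rm_ <- records[records$model == m & !is.na(records$p), , drop = FALSE]
    if (!nrow(rm_)) next
    write.table(rm_[order(chrom_rank(rm_$chrom), rm_$pos),
                    c("chrom", "pos", "id", "p")],
                file.path(outdir, sprintf("manhattan_%s.tsv", m)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(qq_data(rm_$p), file.path(outdir, sprintf("qq_%s.tsv", m)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  lam <- vapply(config$analysis$models, function(m) {
    pm <- records$p[records$model == m & !is.na(records$p)]
    if (length(pm)) lambda_gc(pm) else NA_real_
  }, numeric(1))
  write.table(data.frame(model = config$analysis$models, lambda = lam),
              file.path(outdir, "lambda_gc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  log_df <- do.call(rbind, log_rows)
  write.table(log_df, file.path(outdir, "pipeline_log.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (full_run) guard$record()
  invisible(outdir)
}
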