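## Locus collapsing of significant variants, experiment-wide threshold,
## inheritance classification, and the cross-phenotype matrix.

#' Experiment-wide significance threshold
#'
#' Bonferroni correction of the genome-wide level for the effective number
#' of inheritance-model tests (the five models are correlated, so the
#' effective count is below five; 2.5 is the simulation-derived default).
#'
#' @param alpha_gw Genome-wide level (default 5e-8).
#' @param effective_tests Effective number of tests (default 2.5).
#' @return `alpha_gw / effective_tests`.
#' @export
experimentwide_threshold <- function(alpha_gw = 5e-8, effective_tests = 2.5) {
  if (!(alpha_gw > 0 && alpha_gw < 1)) stop("alpha_gw must be in (0,1)")
  if (effective_tests < 1) stop("effective_tests must be >= 1")
  alpha_gw / effective_tests
}

#' Collapse significant variants into loci
#'
#' Transitive single-linkage merging: on each chromosome, significant
#' variants within `window` base pairs of any variant already in a locus
#' join that locus (the IRanges reduce-with-window idiom). The lead
#' variant is the global minimum p in the locus across models.
#'
#' @param records Association records already filtered to significance
#'   under at least one model (rows with `p` present).
#' @param window Merge window in base pairs (default 500,000).
#' @param phenotype Optional phenotype label stored on each locus.
#' @return Data.frame of loci: `chrom, start, end, lead_id, lead_pos,
#'   best_model, min_p, n_variants`, one `p_<model>` column per model
#'   (minimum p of that model in the locus), and `phenotype`.
#' @export
collapse_loci <- function(records, window = 500000L, phenotype = NA_character_) {
  if (!nrow(records)) return(empty_loci())
  loci <- list()
  for (ch in unique(records$chrom)) {
    rc <- records[records$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = rc$pos, end = rc$pos)
    merged <- IRanges::reduce(ir, min.gapwidth = window)
    hit <- IRanges::findOverlaps(ir, merged)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    for (g in unique(grp)) {
      sub <- rc[grp == g, , drop = FALSE]
      best <- order(sub$p, sub$pos, match(sub$model, MODELS))[1]  # deterministic ties
      per_model <- vapply(MODELS, function(m) {
        pm <- sub$p[sub$model == m]
        if (length(pm)) min(pm, na.rm = TRUE) else NA_real_
      }, numeric(1))
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = ch, start = min(sub$pos), end = max(sub$pos),
        lead_id = sub$id[best], lead_pos = sub$pos[best],
        best_model = sub$model[best], min_p = sub$p[best],
        n_variants = length(unique(sub$id)),
        t(setNames(per_model, paste0("p_", MODELS))),
        phenotype = phenotype, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, loci)
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_loci <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             lead_id = character(0), lead_pos = integer(0),
             best_model = character(0), min_p = numeric(0),
             n_variants = integer(0),
             t(setNames(numeric(5), paste0("p_", MODELS)))[0, , drop = FALSE],
             phenotype = character(0), stringsAsFactors = FALSE)
}

#' Classify the inheritance pattern of a locus
#'
#' Three significance patterns, refined by the dominance-deviation test at
#' `alpha_dev`:
#' significant only under additive -> `"additive"`; significant under
#' additive and at least one non-additive model -> non-additive only when
#' the deviation test supports it, else `"additive"`; significant only
#' under non-additive model(s) -> non-additive when supported, else
#' `"undetermined"`. The non-additive subtype is the model with the
#' smallest p. X-chromosome loci are not put through the deviation test
#' and are classified on significance alone (`"undetermined"` when the
#' pattern is ambiguous).
#'
#' @param locus One row of [collapse_loci()] output.
#' @param dominance_deviation_p Deviation p-value for the lead variant.
#' @param alpha_dev Deviation significance level (default 0.05).
#' @param threshold Significance threshold for the per-model p's
#'   (default 5e-8).
#' @return Classification string.
#' @export
classify_inheritance <- function(locus, dominance_deviation_p,
                                 alpha_dev = 0.05, threshold = 5e-8) {
  pm <- unlist(locus[paste0("p_", MODELS)])
  sig <- !is.na(pm) & pm < threshold
  names(sig) <- MODELS
  if (!any(sig)) stop("locus has no significant model: not a locus")
  non_add <- setdiff(MODELS, "additive")
  best_non_add <- non_add[which.min(pm[paste0("p_", non_add)])]
  subtype <- paste0("non-additive:", best_non_add)
  if (locus$chrom == "X") {
    if (sig[["additive"]] && !any(sig[non_add])) return("additive")
    return("undetermined")
  }
  dev_sig <- !is.na(dominance_deviation_p) && dominance_deviation_p < alpha_dev
  if (sig[["additive"]] && !any(sig[non_add])) return("additive")
  if (sig[["additive"]] && any(sig[non_add]))
    return(if (dev_sig) subtype else "additive")
  if (dev_sig) subtype else "undetermined"
}

#' Cross-phenotype association matrix
#'
#' Merges loci from all phenotypes by positional overlap within `window`
#' and reports, per merged region and phenotype, the minimum p of that
#' phenotype's records in the region together with a significance flag.
#'
#' @param loci_list Named list (by phenotype) of [collapse_loci()] outputs.
#' @param records_list Named list (by phenotype) of association records
#'   used to fill the cells.
#' @param window Merge window in base pairs (default 500,000).
#' @param threshold Flagging threshold (default 5e-8).
#' @return Data.frame: one row per merged region with `chrom, start, end`
#'   and, per phenotype, `p_<phenotype>` and `sig_<phenotype>`.
#' @export
cross_phenotype_matrix <- function(loci_list, records_list,
                                   window = 500000L, threshold = 5e-8) {
  all_loci <- do.call(rbind, unname(loci_list))
  if (is.null(all_loci) || !nrow(all_loci))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  rows <- list()
  for (ch in unique(all_loci$chrom)) {
    lc <- all_loci[all_loci$chrom == ch, , drop = FALSE]
    merged <- IRanges::reduce(IRanges::IRanges(lc$start, lc$end),
                              min.gapwidth = window)
    for (i in seq_along(merged)) {
      lo <- IRanges::start(merged)[i]; hi <- IRanges::end(merged)[i]
      row <- data.frame(chrom = ch, start = lo, end = hi,
                        stringsAsFactors = FALSE)
      for (ph in names(records_list)) {
        rr <- records_list[[ph]]
        inreg <- rr$chrom == ch & rr$pos >= lo & rr$pos <= hi & !is.na(rr$p)
        pmin_ <- if (any(inreg)) min(rr$p[inreg]) else NA_real_
        row[[paste0("p_", ph)]] <- pmin_
        row[[paste0("sig_", ph)]] <- !is.na(pmin_) && pmin_ < threshold
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
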