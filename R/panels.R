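## Combination of per-panel imputation results by best info score, and
## imputation-quality evaluation against held-out truth genotypes.

#' Bundle one panel's imputation result
#'
#' @param panel Panel name (e.g. "HRC", "1000G").
#' @param genotypes A [gpm()] of imputed probability triples.
#' @param info Per-variant info scores; computed with
#'   [impute_info_score()] when omitted.
#' @return An object of class `"panel_set"`.
#' @export
panel_result_set <- function(panel, genotypes, info = NULL) {
  if (is.null(info)) info <- impute_info_score(genotypes)
  stopifnot(length(info) == n_variants(genotypes))
  key <- variant_site_key(genotypes$variants)
  if (anyDuplicated(key))
    stop("duplicate variant within panel ", panel, ": ",
         key[duplicated(key)][1])
  structure(list(panel = panel, genotypes = genotypes, info = info),
            class = "panel_set")
}

#' Combine imputation panels by best info score
#'
#' Takes the union of variants over panels; each variant's genotypes and
#' info score come from the covering panel with the highest info score,
#' ties broken by `panel_priority` order. Variants are matched across
#' panels by (chromosome, position, unordered allele pair); panels are
#' assumed pre-harmonised to the same strand and effect allele.
#'
#' @param sets List of [panel_result_set()]s sharing the same sample order.
#' @param panel_priority Character vector of panel names, highest priority
#'   first; defaults to the order of `sets`.
#' @return An object of class `"combined_set"`: list with `genotypes`
#'   ([gpm()]), `info`, and `source_panel` per variant.
#' @export
combine_panels <- function(sets, panel_priority = NULL) {
  stopifnot(length(sets) >= 1)
  names(sets) <- vapply(sets, `[[`, "", "panel")
  if (anyDuplicated(names(sets))) stop("panel names must be unique")
  if (is.null(panel_priority)) panel_priority <- names(sets)
  if (!setequal(panel_priority, names(sets)))
    stop("panel_priority must name exactly the supplied panels")
  samples <- sets[[1]]$genotypes$samples
  for (s in sets)
    if (!identical(s$genotypes$samples, samples))
      stop("panels have different sample orderings")
  ## union of site keys, stable order: by priority then panel-internal order
  sets <- sets[panel_priority]
  keys <- lapply(sets, function(s) variant_site_key(s$genotypes$variants))
  all_keys <- unique(unlist(keys, use.names = FALSE))
  best_panel <- rep(NA_character_, length(all_keys))
  best_info <- rep(-Inf, length(all_keys))
  best_j <- rep(NA_integer_, length(all_keys))
  for (pn in panel_priority) {
    idx <- match(keys[[pn]], all_keys)
    better <- sets[[pn]]$info > best_info[idx]   # strict: ties keep higher priority
    best_info[idx[better]] <- sets[[pn]]$info[which(better)]
    best_panel[idx[better]] <- pn
    best_j[idx[better]] <- which(better)
  }
  nv <- length(all_keys)
  probs <- array(NA_real_, c(length(samples), nv, 3))
  vk <- vector("list", nv)
  for (i in seq_len(nv)) {
    s <- sets[[best_panel[i]]]
    probs[, i, ] <- s$genotypes$probs[, best_j[i], ]
    vk[[i]] <- s$genotypes$variants[best_j[i], , drop = FALSE]
  }
  variants <- do.call(rbind, vk)
  ord <- order(chrom_rank(variants$chrom), variants$pos)
  structure(list(genotypes = gpm(variants[ord, , drop = FALSE], samples,
                                 probs[, ord, , drop = FALSE], normalize = FALSE),
                 info = best_info[ord],
                 source_panel = best_panel[ord]),
            class = "combined_set")
}

#' @export
print.combined_set <- function(x, ...) {
  cat(sprintf("Combined imputation set: %d variants from %d panel(s)\n",
              n_variants(x$genotypes), length(unique(x$source_panel))))
  print(table(x$source_panel))
  invisible(x)
}

#' Build an in-silico genotyping array from sequenced truth
#'
#' Restricts a truth (hard-call, one-hot) matrix to the array's variant
#' ids — the "genotyped backbone" handed to imputation — and reports the
#' withheld variants kept back as evaluation truth.
#'
#' @param truth A [gpm()] of one-hot truth triples.
#' @param array_variant_ids Ids of the variants on the array.
#' @return List: `array` ([gpm()] restricted to the array ids), and
#'   `withheld_ids` (truth ids not on the array).
#' @export
make_insilico_array <- function(truth, array_variant_ids) {
  unknown <- setdiff(array_variant_ids, truth$variants$id)
  if (length(unknown))
    stop("array ids absent from truth: ", paste(unknown, collapse = ", "))
  j <- truth$variants$id %in% array_variant_ids
  list(array = gpm_subset(truth, j),
       withheld_ids = setdiff(truth$variants$id, array_variant_ids))
}

#' Allelic dosage R-squared
#'
#' Squared Pearson correlation between imputed expected dosages and true
#' dosages across samples — the empirical imputation-accuracy measure
#' against held-out sequenced genotypes. Invariant to swapping which
#' allele is counted (dosage reflection `g -> 2 - g`).
#'
#' @param imputed Numeric vector of expected dosages, or an `N x 3` triple
#'   matrix for one variant.
#' @param truth Numeric vector of true dosages (0/1/2).
#' @return R-squared in `[0, 1]`, or `NA` when either vector is constant
#'   or fewer than 2 complete pairs exist.
#' @export
allelic_dosage_r2 <- function(imputed, truth) {
  if (is.matrix(imputed)) imputed <- imputed[, 2] + 2 * imputed[, 3]
  ok <- !is.na(imputed) & !is.na(truth)
  if (sum(ok) < 2) return(NA_real_)
  x <- imputed[ok]; y <- truth[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Imputation quality by MAF bin
#'
#' Among variants passing the info gate in each minor-allele-frequency
#' bin, the percentage with allelic dosage R-squared at or above
#' `r2_threshold` — the standard panel-comparison summary.
#'
#' @param r2 Per-variant allelic dosage R-squared.
#' @param maf Per-variant minor allele frequency.
#' @param info Per-variant info score.
#' @param bins Bin edges for MAF intervals `(edge_i, edge_{i+1}]`.
#' @param min_info Info gate (default 0.7).
#' @param r2_threshold High-quality R-squared cutoff (default 0.5).
#' @return Data.frame with one row per bin plus an `overall` row:
#'   `bin`, `n` (variants passing the info gate), `n_high_r2`, `pct`
#'   (`NA` when the bin is empty).
#' @export
maf_binned_quality <- function(r2, maf, info,
                               bins = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5),
                               min_info = 0.7, r2_threshold = 0.5) {
  stopifnot(length(r2) == length(maf), length(maf) == length(info))
  use <- !is.na(r2) & !is.na(maf) & !is.na(info) & info >= min_info
  lab <- paste0("(", head(bins, -1), ",", tail(bins, -1), "]")
  bin_of <- cut(maf[use], breaks = bins, labels = lab)
  hi <- r2[use] >= r2_threshold
  n <- as.integer(table(bin_of))
  n_hi <- as.integer(tapply(hi, bin_of, sum, default = 0L))
  out <- data.frame(bin = c(lab, "overall"),
                    n = c(n, sum(use)),
                    n_high_r2 = c(n_hi, sum(hi)),
                    stringsAsFactors = FALSE)
  out$pct <- ifelse(out$n > 0, 100 * out$n_high_r2 / out$n, NA_real_)
  out
}
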