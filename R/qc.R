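## Marker QC: info scores, exact Hardy-Weinberg test, pre- and
## post-association filters.

#' Default marker-QC thresholds
#'
#' @param max_missingness Remove variants missing in at least this fraction
#'   of samples (default 0.05).
#' @param hwe_all_p_floor Remove variants with whole-cohort Hardy-Weinberg
#'   exact p at or below this floor (default 1e-20).
#' @param min_maf Remove variants with minor allele frequency below this
#'   (default 0.001; a variant at exactly the boundary is kept).
#' @param min_info Imputation info score gate (default 0.7).
#' @param hwe_controls_p_floor Post-association filter: drop records with
#'   Hardy-Weinberg p in controls below this (default 1e-6).
#' @param min_alt_hom_cases Post-association filter for the recessive and
#'   genotypic models: minimum hard-call count of effect-allele homozygote
#'   cases (default 3).
#' @param hard_call_threshold Per-genotype probability needed to call a
#'   genotype for integer-count criteria (default 0.9).
#' @return A list of thresholds, class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(max_missingness = 0.05,
                          hwe_all_p_floor = 1e-20,
                          min_maf = 0.001,
                          min_info = 0.7,
                          hwe_controls_p_floor = 1e-6,
                          min_alt_hom_cases = 3L,
                          hard_call_threshold = 0.9) {
  stopifnot(max_missingness > 0, max_missingness <= 1,
            hwe_all_p_floor >= 0, hwe_all_p_floor < 1,
            min_maf >= 0, min_maf <= 0.5,
            min_info <= 1,
            hwe_controls_p_floor >= 0, hwe_controls_p_floor < 1,
            min_alt_hom_cases >= 0,
            hard_call_threshold > 0.5, hard_call_threshold <= 1)
  structure(list(max_missingness = max_missingness,
                 hwe_all_p_floor = hwe_all_p_floor,
                 min_maf = min_maf, min_info = min_info,
                 hwe_controls_p_floor = hwe_controls_p_floor,
                 min_alt_hom_cases = as.integer(min_alt_hom_cases),
                 hard_call_threshold = hard_call_threshold),
            class = "qc_thresholds")
}

#' IMPUTE2-style imputation info score
#'
#' Ratio of observed to Hardy-Weinberg-expected dosage variance. With
#' per-sample expected dosage `e_i = p1 + 2 p2` and second moment
#' `f_i = p1 + 4 p2`, and `theta = sum(e_i) / (2N)` over the `N`
#' non-missing samples,
#' `info = 1 - sum(f_i - e_i^2) / (2 N theta (1 - theta))`.
#' `info = 1` when `theta` is 0 or 1 (monomorphic) and for fully certain
#' (one-hot) triples; anti-informative triples can push it below 0, which
#' is reported as-is and fails the 0.7 gate naturally.
#'
#' @param triples Numeric matrix `N x 3` of probability triples for one
#'   variant (rows with any `NA` are treated as missing), or a [gpm()]
#'   (then a vector over variants is returned).
#' @return Info score(s) in `(-Inf, 1]`; `NA` if every triple is missing.
#' @export
impute_info_score <- function(triples) {
  if (inherits(triples, "gpm")) {
    x <- triples
    return(vapply(seq_len(n_variants(x)), function(j)
      impute_info_score(matrix(x$probs[, j, ], n_samples(x), 3)), numeric(1)))
  }
  triples <- matrix(triples, ncol = 3)
  ok <- stats::complete.cases(triples)
  if (!any(ok)) return(NA_real_)
  p1 <- triples[ok, 2]; p2 <- triples[ok, 3]
  e <- p1 + 2 * p2
  f <- p1 + 4 * p2
  n <- length(e)
  theta <- sum(e) / (2 * n)
  if (theta <= 0 || theta >= 1) return(1)
  1 - sum(f - e^2) / (2 * n * theta * (1 - theta))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test on genotype counts: conditional on the
#' observed allele counts, the p-value is the sum of probabilities of all
#' heterozygote counts whose probability does not exceed that of the
#' observed configuration (the convention of the standard SNP-HWE
#' implementation used by PLINK).
#'
#' @param n_aa,n_ab,n_bb Genotype counts (hom-ref, het, hom-alt).
#' @return Exact p-value in `[0, 1]`.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("negative genotype counts")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("empty genotype table")
  rare <- n_ab + 2 * min(n_aa, n_bb)      # minor allele count
  ## heterozygote count shares parity with the minor allele count
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  ## unnormalised log-probabilities from the ratio recurrence
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i]
    ## P(h) / P(h-2) = 4 * n_hom_rare(h-2) * n_hom_common(h-2) / (h * (h-1))
    hr <- (rare - (h - 2)) / 2
    hc <- (2 * n - rare - (h - 2)) / 2
    lp[i] <- lp[i - 1] + log(4 * hr * hc) - log(h * (h - 1))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- match(n_ab, hets)
  if (is.na(obs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Marker quality control
#'
#' Removes variants with missingness at or above `max_missingness`,
#' whole-cohort Hardy-Weinberg exact p at or below `hwe_all_p_floor`
#' (computed on hard calls), or minor allele frequency strictly below
#' `min_maf` (computed from expected dosages).
#'
#' @param x A [gpm()].
#' @param thresholds A [qc_thresholds()].
#' @param sex Optional 1/2 vector over samples; on the X chromosome the
#'   Hardy-Weinberg table is built from females only (males are
#'   homozygote-coded) and the HWE filter is skipped when sex is unknown.
#' @return A list: `keep` (logical over variants), `report` (per-variant
#'   data.frame with missingness, maf, hwe p, decision and reasons) and
#'   `genotypes` (the filtered [gpm()]).
#' @export
marker_qc <- function(x, thresholds = qc_thresholds(), sex = NULL) {
  th <- thresholds
  miss <- colMeans(is.na(matrix(x$probs[, , 1], n_samples(x), n_variants(x))))
  maf <- gpm_maf(x)
  hc <- hard_calls(x, th$hard_call_threshold)
  is_x <- x$variants$chrom == "X"
  hwe_p <- vapply(seq_len(n_variants(x)), function(j) {
    g <- hc[, j]
    if (is_x[j]) {
      if (is.null(sex)) return(NA_real_)
      g <- g[!is.na(sex) & sex == 2L]
    }
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))
  reasons <- vapply(seq_len(n_variants(x)), function(j) {
    r <- character(0)
    if (miss[j] >= th$max_missingness) r <- c(r, "missingness")
    if (!is.na(hwe_p[j]) && hwe_p[j] <= th$hwe_all_p_floor) r <- c(r, "hwe")
    if (is.na(maf[j]) || maf[j] < th$min_maf) r <- c(r, "maf")
    paste(r, collapse = ";")
  }, character(1))
  keep <- !nzchar(reasons)
  report <- data.frame(x$variants,
                       missingness = miss, maf = maf, hwe_p = hwe_p,
                       decision = ifelse(keep, "keep", "remove"),
                       reason = reasons, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(keep = keep, report = report, genotypes = gpm_subset(x, keep))
}

#' Post-association record filter
#'
#' Drops association records whose control-sample Hardy-Weinberg p falls
#' below `hwe_controls_p_floor` (all models), and additionally drops
#' recessive and genotypic records whose hard-call count of effect-allele
#' homozygote cases falls below `min_alt_hom_cases`. These filters remove
#' the variants that drive genomic inflation/deflation specific to the
#' recessive and genotypic tests.
#'
#' @param records Long-format association records.
#' @param thresholds A [qc_thresholds()].
#' @return The filtered records.
#' @export
post_association_filter <- function(records, thresholds = qc_thresholds()) {
  if (!all(c("hwe_controls_p", "alt_hom_cases", "model") %in% names(records)))
    stop("records must carry model, hwe_controls_p and alt_hom_cases")
  th <- thresholds
  drop_hwe <- !is.na(records$hwe_controls_p) &
    records$hwe_controls_p < th$hwe_controls_p_floor
  drop_hom <- records$model %in% c("recessive", "genotypic") &
    !is.na(records$alt_hom_cases) &
    records$alt_hom_cases < th$min_alt_hom_cases
  out <- records[!(drop_hwe | drop_hom), , drop = FALSE]
  rownames(out) <- NULL
  out
}
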