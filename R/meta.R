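## Fixed-effect meta-analysis: inverse-variance weighting, the
## sample-size/z-score method, and Cochran heterogeneity statistics.

#' Assemble per-study statistics for one variant
#'
#' @param study Study names.
#' @param beta Log-odds effects (may be `NA` for p/direction-only studies).
#' @param se Standard errors (positive where `beta` present).
#' @param p Two-sided p-values.
#' @param direction Effect direction, +1/-1 (defaults to `sign(beta)`).
#' @param n Per-study sample sizes.
#' @return Data.frame of class `"study_stats"`.
#' @export
study_stats <- function(study, beta = NA_real_, se = NA_real_, p = NA_real_,
                        direction = NULL, n = NA_real_) {
  if (is.null(direction)) direction <- sign(beta)
  df <- data.frame(study = study, beta = beta, se = se, p = p,
                   direction = direction, n = n, stringsAsFactors = FALSE)
  if (any(!is.na(df$beta) & (is.na(df$se) | df$se <= 0)))
    stop("se must be positive wherever beta is present")
  if (any(!df$direction %in% c(-1, 1) & !is.na(df$direction)))
    stop("direction must be +1 or -1")
  class(df) <- c("study_stats", "data.frame")
  df
}

#' Effective sample size for a case-control study
#'
#' `4 / (1/n_cases + 1/n_controls)` — the weight METAL uses when studies
#' differ in case:control balance.
#' @param n_cases,n_controls Counts.
#' @return Effective N.
#' @export
effective_n <- function(n_cases, n_controls) 4 / (1 / n_cases + 1 / n_controls)

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Weights `w_i = 1/se_i^2`; pooled `beta = sum(w b)/sum(w)`, pooled
#' `se = 1/sqrt(sum(w))`, two-sided Wald p. Heterogeneity statistics are
#' attached when at least two studies contribute.
#'
#' @param stats A [study_stats()] table with `beta` and `se`.
#' @return List of class `"meta_result"`: `beta`, `se`, `z`, `p`, `k`,
#'   `Q`, `Q_p`, `I2`, `method`.
#' @export
ivw_meta <- function(stats) {
  use <- !is.na(stats$beta) & !is.na(stats$se)
  if (!any(use)) stop("no study with usable beta and se")
  b <- stats$beta[use]; s <- stats$se[use]
  w <- 1 / s^2
  beta <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  het <- if (sum(use) >= 2) heterogeneity(stats[use, , drop = FALSE])
         else list(Q = NA_real_, Q_p = NA_real_, I2 = NA_real_)
  structure(list(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)),
                 k = sum(use), Q = het$Q, Q_p = het$Q_p, I2 = het$I2,
                 method = "ivw"),
            class = "meta_result")
}

#' Sample-size-based (z-score) fixed-effect meta-analysis
#'
#' Converts each study's two-sided p and effect direction to a signed
#' z-score `z_i = qnorm(1 - p_i/2) * direction_i`, then pools with
#' square-root-of-N weights: `Z = sum(w z) / sqrt(sum(w^2))`,
#' `w_i = sqrt(n_i)`. The method of choice when a study's beta is
#' unreliable (e.g. inflated rare-homozygote effect estimates).
#'
#' @param stats A [study_stats()] table with `p`, `direction`, `n`.
#' @return A `"meta_result"` with `z`, `p`, `k`, `method`.
#' @export
samplesize_meta <- function(stats) {
  use <- !is.na(stats$p) & !is.na(stats$direction) & !is.na(stats$n)
  if (!any(use)) stop("no study with usable p, direction and n")
  p <- stats$p[use]
  if (any(p <= 0))
    stop("p = 0 is unrepresentable as a z-score; supply beta/se and use ivw_meta")
  z <- qnorm(1 - p / 2) * stats$direction[use]
  w <- sqrt(stats$n[use])
  Z <- sum(w * z) / sqrt(sum(w^2))
  structure(list(beta = NA_real_, se = NA_real_, z = Z,
                 p = 2 * pnorm(-abs(Z)), k = sum(use),
                 Q = NA_real_, Q_p = NA_real_, I2 = NA_real_,
                 method = "samplesize"),
            class = "meta_result")
}

#' Cochran heterogeneity statistics
#'
#' `Q = sum(w_i (beta_i - beta_pooled)^2)` with IVW weights, p from a
#' chi-squared with `k - 1` df, and `I2 = max(0, (Q - (k-1))/Q) * 100`.
#'
#' @param stats A [study_stats()] table with at least two beta/se studies.
#' @return List `Q`, `Q_p`, `I2` (all `NA` with fewer than 2 studies).
#' @export
heterogeneity <- function(stats) {
  use <- !is.na(stats$beta) & !is.na(stats$se)
  k <- sum(use)
  if (k < 2) return(list(Q = NA_real_, Q_p = NA_real_, I2 = NA_real_))
  b <- stats$beta[use]; w <- 1 / stats$se[use]^2
  pooled <- sum(w * b) / sum(w)
  Q <- sum(w * (b - pooled)^2)
  list(Q = Q, Q_p = pchisq(Q, df = k - 1, lower.tail = FALSE),
       I2 = if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0)
}

#' @export
print.meta_result <- function(x, ...) {
  if (x$method == "ivw")
    cat(sprintf("IVW fixed-effect meta (%d studies): beta=%.4f se=%.4f p=%.3g",
                x$k, x$beta, x$se, x$p))
  else
    cat(sprintf("Sample-size meta (%d studies): z=%.4f p=%.3g", x$k, x$z, x$p))
  if (!is.na(x$Q)) cat(sprintf("  [Q=%.3f, p=%.3g, I2=%.1f%%]", x$Q, x$Q_p, x$I2))
  cat("\n")
  invisible(x)
}

#' Align two summary-statistics tables on shared variants
#'
#' Matches variants by (chrom, pos, unordered allele pair) and flips the
#' sign of `beta` (and `direction`) in the second table where its effect
#' allele is the first table's reference allele.
#'
#' @param a,b Data.frames with `chrom, pos, ref_allele, eff_allele, beta`
#'   and optionally `direction`.
#' @return List of the two tables restricted to shared variants, `b`
#'   allele-aligned to `a`.
#' @export
align_effect_alleles <- function(a, b) {
  ka <- variant_site_key(a); kb <- variant_site_key(b)
  shared <- intersect(ka, kb)
  a2 <- a[match(shared, ka), , drop = FALSE]
  b2 <- b[match(shared, kb), , drop = FALSE]
  flip <- b2$eff_allele != a2$eff_allele
  if (any(flip)) {
    b2$beta[flip] <- -b2$beta[flip]
    if ("direction" %in% names(b2)) b2$direction[flip] <- -b2$direction[flip]
    tmp <- b2$eff_allele[flip]
    b2$eff_allele[flip] <- b2$ref_allele[flip]
    b2$ref_allele[flip] <- tmp
  }
  rownames(a2) <- rownames(b2) <- NULL
  list(a = a2, b = b2)
}
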