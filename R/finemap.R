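## Approximate-Bayes-factor fine-mapping: LD filter around the lead
## variant, Wakefield ABFs under a Gaussian effect prior, and the 99%
## credible set.

#' Pairwise LD as squared dosage correlation
#'
#' @param a,b Expected-dosage vectors over the same samples.
#' @return Squared Pearson correlation, or `NA` when either vector is
#'   constant or fewer than 2 complete pairs exist.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  if (var(a[ok]) == 0 || var(b[ok]) == 0) return(NA_real_)
  cor(a[ok], b[ok])^2
}

#' Wakefield approximate Bayes factor
#'
#' Under a Gaussian prior on the log-odds effect with mean 0 and variance
#' `prior_w`, the evidence for association given an estimate `beta` with
#' standard error `se` is
#' `ABF = sqrt(1 - r) * exp(r * z^2 / 2)` with shrinkage
#' `r = prior_w / (se^2 + prior_w)` and `z = beta / se`. The default
#' prior variance 0.04 (prior SD 0.2 on the log odds ratio) is the
#' convention of SNPTEST-style fine-mapping.
#'
#' @param beta Log-odds effect estimate(s).
#' @param se Standard error(s), positive.
#' @param prior_w Prior variance of the effect (default 0.04).
#' @return Data.frame with `z`, `r`, `abf` (vectorised over inputs).
#' @export
abf <- function(beta, se, prior_w = 0.04) {
  if (any(se <= 0)) stop("se must be positive")
  if (prior_w < 0) stop("prior_w must be non-negative")
  z <- beta / se
  r <- prior_w / (se^2 + prior_w)
  data.frame(z = z, r = r, abf = sqrt(1 - r) * exp(r * z^2 / 2))
}

#' 99% credible set for a fine-mapped region
#'
#' Retains region variants in LD with the lead (`ld_r2 > ld_floor`; the
#' lead always stays), computes ABFs, normalises them to posterior
#' probabilities, ranks by ABF in decreasing order (ties broken by
#' genomic position), and includes variants until the cumulative
#' posterior first exceeds `coverage` — inclusive of the crossing
#' variant.
#'
#' @param region Data.frame with columns `id`, `pos`, `beta`, `se`.
#' @param lead_id Id of the lead variant (must be in `region`).
#' @param dosages Matrix of expected dosages (samples x variants, columns
#'   named by variant id) used for LD.
#' @param coverage Credible-set mass (default 0.99).
#' @param ld_floor LD filter threshold on r-squared with the lead
#'   (default 0.1).
#' @param prior_w Prior effect variance (default 0.04).
#' @return An object of class `"credible_set"`: the region table ordered
#'   by rank with `ld_lead`, `z`, `r`, `abf`, `posterior`, `cumulative`
#'   and `in_set` columns; attributes `lead_id`, `coverage`, `ld_floor`,
#'   `prior_w`.
#' @export
credible_set <- function(region, lead_id, dosages = NULL,
                         coverage = 0.99, ld_floor = 0.1, prior_w = 0.04) {
  stopifnot(all(c("id", "pos", "beta", "se") %in% names(region)))
  if (!lead_id %in% region$id) stop("lead variant not in region")
  if (!is.null(dosages)) {
    lead_dos <- dosages[, lead_id]
    ld <- vapply(region$id, function(v) ld_r2(dosages[, v], lead_dos), numeric(1))
  } else {
    ld <- rep(NA_real_, nrow(region))   # no dosages: no LD filtering
  }
  keep <- if (is.null(dosages)) rep(TRUE, nrow(region))
          else region$id == lead_id | (!is.na(ld) & ld > ld_floor)
  if (!any(keep)) stop("region empty after LD filtering")
  reg <- region[keep, , drop = FALSE]
  reg$ld_lead <- ld[keep]
  w <- abf(reg$beta, reg$se, prior_w)
  reg$z <- w$z; reg$r <- w$r; reg$abf <- w$abf
  reg$posterior <- reg$abf / sum(reg$abf)
  ord <- order(-reg$abf, reg$pos)
  reg <- reg[ord, , drop = FALSE]
  reg$cumulative <- cumsum(reg$posterior)
  crossing <- match(TRUE, reg$cumulative > coverage)
  if (is.na(crossing)) crossing <- nrow(reg)   # numeric guard; mass sums to 1
  reg$in_set <- seq_len(nrow(reg)) <= crossing
  rownames(reg) <- NULL
  structure(reg, class = c("credible_set", "data.frame"),
            lead_id = lead_id, coverage = coverage,
            ld_floor = ld_floor, prior_w = prior_w)
}
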