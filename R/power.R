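## Case-control power and required sample size per inheritance model.
##
## Conventions (documented in detail in the methods vignette):
##
## * Recessive and dominant tests are treated as a binary-exposure
##   two-proportion comparison. The exposure prevalence under
##   Hardy-Weinberg equilibrium is f = q^2 (recessive) or 1 - (1-q)^2
##   (dominant); controls carry the population exposure p0 = f
##   (rare-disease convention) and the case exposure is the odds-shifted
##   p1 = OR*f/(1-f) / (1 + OR*f/(1-f)).
##
## * The additive test is a Cochran-Armitage trend contrast. Penetrances
##   rise multiplicatively with allele count on the risk scale
##   (f_g = f0 * OR^g, the genetic-power-calculator convention), with the
##   baseline f0 solved so the population case fraction matches the study
##   case fraction; case and control genotype distributions then follow
##   by Bayes' rule from the Hardy-Weinberg population frequencies.
##
## * The normal deviate of the contrast uses a symmetrised variance: the
##   mean of the pooled (null) and unpooled (alternative) variances of
##   the case-control contrast at the study's case:control allocation.
##   This is the convention that reconstructs the sample sizes printed by
##   the epidemiological calculators this module mirrors; it is
##   conservative relative to the realized power of a Wald test on the
##   same data.

#' Hardy-Weinberg genotype frequencies
#'
#' @param maf Effect-allele frequency `q` in `(0, 1)`.
#' @return Numeric triple `((1-q)^2, 2q(1-q), q^2)`.
#' @export
genotype_frequencies <- function(maf) {
  stopifnot(maf > 0, maf < 1)
  c(hom_ref = (1 - maf)^2, het = 2 * maf * (1 - maf), hom_alt = maf^2)
}

#' Specify a power calculation
#'
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @param maf Effect-allele frequency in `(0, 0.5]`.
#' @param or Odds ratio on the model's own scale (per-allele for
#'   additive).
#' @param alpha Two-sided significance level (default genome-wide 5e-8).
#' @param power Target power for sample-size search (default 0.80).
#' @param n_cases,n_controls Study case/control counts fixing the case
#'   fraction; alternatively give `case_fraction` directly.
#' @param case_fraction Cases / total.
#' @return List of class `"power_spec"`.
#' @export
power_spec <- function(model = c("additive", "dominant", "recessive"),
                       maf, or, alpha = 5e-8, power = 0.80,
                       n_cases = NULL, n_controls = NULL,
                       case_fraction = NULL) {
  model <- match.arg(model)
  stopifnot(maf > 0, maf <= 0.5, or > 0, alpha > 0, alpha < 1,
            power > 0, power < 1)
  if (is.null(case_fraction)) {
    if (is.null(n_cases) || is.null(n_controls))
      stop("give n_cases and n_controls, or case_fraction")
    case_fraction <- n_cases / (n_cases + n_controls)
  }
  stopifnot(case_fraction > 0, case_fraction < 1)
  structure(list(model = model, maf = maf, or = or, alpha = alpha,
                 power = power, case_fraction = case_fraction),
            class = "power_spec")
}

## contrast (delta) and symmetrised per-individual variance for a spec
power_contrast <- function(spec) {
  phi1 <- spec$case_fraction; phi0 <- 1 - phi1
  if (spec$model %in% c("recessive", "dominant")) {
    q <- spec$maf
    f <- if (spec$model == "recessive") q^2 else 1 - (1 - q)^2
    if (f <= 0) stop("zero exposure prevalence")
    odds1 <- spec$or * f / (1 - f)
    if (!is.finite(odds1)) stop("exposure odds overflow")
    p1 <- odds1 / (1 + odds1)
    p0 <- f
    delta <- p1 - p0
    pbar <- phi1 * p1 + phi0 * p0
    vp <- pbar * (1 - pbar) * (1 / phi1 + 1 / phi0)
    vu <- p1 * (1 - p1) / phi1 + p0 * (1 - p0) / phi0
  } else {
    g <- genotype_frequencies(spec$maf)
    f0 <- phi1 / sum(g * spec$or^(0:2))
    pen <- pmin(f0 * spec$or^(0:2), 1)
    ca <- g * pen / sum(g * pen)
    co <- g * (1 - pen) / sum(g * (1 - pen))
    x <- 0:2
    delta <- sum(x * ca) - sum(x * co)
    t <- phi1 * ca + phi0 * co
    vt <- sum(x^2 * t) - sum(x * t)^2
    vp <- vt * (1 / phi1 + 1 / phi0)
    vu <- (sum(x^2 * ca) - sum(x * ca)^2) / phi1 +
      (sum(x^2 * co) - sum(x * co)^2) / phi0
  }
  list(delta = delta, v = (vp + vu) / 2)
}

#' Power of a case-control association test
#'
#' Normal-deviate power of the model's case-control contrast at total
#' cohort size `total_n` and the spec's case fraction (both rejection
#' tails included, so `OR = 1` returns exactly `alpha`).
#'
#' @param spec A [power_spec()].
#' @param total_n Total cohort size (cases + controls), at least 10.
#' @return Power in `[0, 1]`.
#' @export
power_case_control <- function(spec, total_n) {
  stopifnot(inherits(spec, "power_spec"), total_n >= 10)
  ct <- power_contrast(spec)
  za <- qnorm(1 - spec$alpha / 2)
  ncp <- ct$delta * sqrt(total_n / ct$v)
  pnorm(ncp - za) + pnorm(-ncp - za)
}

#' Smallest total sample size reaching target power
#'
#' Bisection over total N at the spec's fixed case fraction until the
#' power crosses the target; returns the crossing N rounded up.
#'
#' @param spec A [power_spec()].
#' @param n_cap Search ceiling (default 1e9); an error is raised when the
#'   target is unreachable below it.
#' @return Required total N (integer-valued double).
#' @export
sample_size_for_power <- function(spec, n_cap = 1e9) {
  stopifnot(inherits(spec, "power_spec"))
  lo <- 10; hi <- n_cap
  if (power_case_control(spec, hi) < spec$power)
    stop("target power unreachable below n_cap = ", format(n_cap, scientific = FALSE))
  if (power_case_control(spec, lo) >= spec$power) return(lo)
  while (hi - lo > 0.5) {
    mid <- (lo + hi) / 2
    if (power_case_control(spec, mid) >= spec$power) hi <- mid else lo <- mid
  }
  ceiling(hi)
}

#' Required sample size across a MAF grid
#'
#' @param spec A [power_spec()] (its `maf` is overridden per grid point).
#' @param maf_grid Allele frequencies in `(0, 0.5]`.
#' @param n_cap Passed to [sample_size_for_power()].
#' @return Data.frame `maf`, `model`, `or`, `required_n` (`NA` with
#'   `reachable = FALSE` where the target cannot be attained).
#' @export
power_curve <- function(spec, maf_grid, n_cap = 1e9) {
  stopifnot(all(maf_grid > 0), all(maf_grid <= 0.5))
  rows <- lapply(maf_grid, function(q) {
    sp <- spec; sp$maf <- q
    n <- tryCatch(sample_size_for_power(sp, n_cap), error = function(e) NA_real_)
    data.frame(maf = q, model = spec$model, or = spec$or,
               required_n = n, reachable = !is.na(n))
  })
  do.call(rbind, rows)
}

#' Monte-Carlo power of the recessive/dominant contrast
#'
#' Simulation arbiter for [power_case_control()]: draws the binary
#' exposure in cases and controls from the binomial model the analytic
#' formula assumes and applies the same symmetrised-variance contrast
#' test. Used to verify the analytic deviate and bisection, not as a
#' user-facing estimator.
#'
#' @param spec A [power_spec()] (recessive or dominant).
#' @param total_n Total cohort size.
#' @param n_reps Simulation replicates.
#' @param seed RNG seed.
#' @return Rejection fraction.
#' @export
mc_power_contrast <- function(spec, total_n, n_reps = 2000, seed = 1L) {
  stopifnot(spec$model %in% c("recessive", "dominant"))
  set.seed(seed)
  q <- spec$maf
  f <- if (spec$model == "recessive") q^2 else 1 - (1 - q)^2
  odds1 <- spec$or * f / (1 - f)
  p1 <- odds1 / (1 + odds1); p0 <- f
  n1 <- round(total_n * spec$case_fraction); n0 <- total_n - n1
  za <- qnorm(1 - spec$alpha / 2)
  x1 <- rbinom(n_reps, n1, p1); x0 <- rbinom(n_reps, n0, p0)
  ph1 <- x1 / n1; ph0 <- x0 / n0
  pb <- (x1 + x0) / (n1 + n0)
  vp <- pb * (1 - pb) * (1 / n1 + 1 / n0)
  vu <- ph1 * (1 - ph1) / n1 + ph0 * (1 - ph0) / n0
  z <- (ph1 - ph0) / sqrt((vp + vu) / 2)
  mean(abs(z) > za, na.rm = TRUE)
}
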