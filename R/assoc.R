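## Five-inheritance-model logistic association testing on expected-dosage
## encodings, X-chromosome handling under full inactivation, and the
## dominance-deviation test.

## hg19 pseudoautosomal boundaries; association on X is restricted to
## the non-PAR region between them.
PAR_BOUNDS_HG19 <- c(par1_end = 2699520L, par2_start = 154931044L)

#' Design column(s) for an inheritance model
#'
#' Maps a probability triple `(p0, p1, p2)` to the expected value of the
#' model's genotype coding: additive `p1 + 2 p2`, dominant `p1 + p2`,
#' recessive `p2`, heterodominant `p1`, genotypic the pair `(p1, p2)`.
#' On the X chromosome males are stored homozygote-coded (a hemizygous
#' effect allele is the triple `(0, 0, 1)`), so under full X inactivation
#' the same formulas yield the required male codings: additive
#' `2 p(B)`, dominant/recessive `p(B)`, heterodominant 0, genotypic
#' `(0, p(B))`.
#'
#' @param triples `N x 3` matrix of probability triples.
#' @param model One of `"additive"`, `"dominant"`, `"recessive"`,
#'   `"heterodominant"`, `"genotypic"`.
#' @return `N x 1` (or `N x 2` for genotypic) design matrix.
#' @export
encode_model <- function(triples, model = MODELS) {
  model <- match.arg(model)
  triples <- matrix(triples, ncol = 3)
  switch(model,
         additive = cbind(g = triples[, 2] + 2 * triples[, 3]),
         dominant = cbind(g = triples[, 2] + triples[, 3]),
         recessive = cbind(g = triples[, 3]),
         heterodominant = cbind(g = triples[, 2]),
         genotypic = cbind(het = triples[, 2], hom = triples[, 3]))
}

#' Logistic regression fit by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit of case status on genotype design
#' column(s) and covariates. Covariates are standardised internally for
#' numerical stability; reported genotype effects are on the original
#' scale. Convergence tolerance is 1e-8 on the coefficient change, with
#' at most 25 iterations. Quasi-complete separation (any genotype
#' coefficient beyond 15 in absolute value, or non-convergence) is flagged
#' and statistics are reported missing rather than fabricated.
#'
#' For a single genotype column the p-value is the 1-df Wald test; for the
#' 2-column genotypic design the joint p is a 2-df likelihood-ratio test
#' against the covariate-only model (per-coefficient Wald statistics are
#' still reported).
#'
#' @param status 0/1 vector.
#' @param geno Genotype design matrix (1 or 2 columns) from
#'   [encode_model()].
#' @param covars Optional numeric covariate matrix/data.frame.
#' @return List with `coef`, `se`, `z`, `p_wald` (per genotype column),
#'   `p` (joint test), `loglik`, `converged`, `iterations`, `n`.
#' @export
fit_logistic <- function(status, geno, covars = NULL) {
  geno <- as.matrix(geno)
  ok <- stats::complete.cases(status, geno)
  if (!is.null(covars)) {
    covars <- as.matrix(covars)
    ok <- ok & stats::complete.cases(covars)
  }
  y <- status[ok]
  if (sum(y) == 0 || sum(y) == length(y)) stop("need at least one case and one control")
  g <- geno[ok, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, g)
  if (!is.null(covars)) {
    cv <- covars[ok, , drop = FALSE]
    cv <- scale(cv)
    cv <- cv[, apply(cv, 2, function(v) all(is.finite(v))), drop = FALSE]
    X <- cbind(X, cv)
  }
  ## drop constant genotype columns -> caller treats as monomorphic
  gvar <- apply(g, 2, var)
  if (any(gvar == 0)) stop("constant genotype column (monomorphic variant)")
  fit <- irls_logistic(y, X)
  k <- seq_len(ncol(g)) + 1L
  beta <- fit$coef[k]; se <- fit$se[k]
  separated <- !fit$converged || any(abs(beta) > 15)
  if (separated) {
    beta <- se <- rep(NA_real_, length(k))
    p_joint <- NA_real_
    z <- p_wald <- rep(NA_real_, length(k))
  } else {
    z <- beta / se
    p_wald <- 2 * pnorm(-abs(z))
    if (ncol(g) == 2L) {
      null_fit <- irls_logistic(y, X[, -k, drop = FALSE])
      p_joint <- pchisq(2 * (fit$loglik - null_fit$loglik), df = 2, lower.tail = FALSE)
    } else p_joint <- p_wald
  }
  list(coef = setNames(beta, colnames(g)), se = setNames(se, colnames(g)),
       z = z, p_wald = p_wald, p = p_joint, loglik = fit$loglik,
       converged = !separated, iterations = fit$iterations, n = length(y))
}

irls_logistic <- function(y, X, tol = 1e-8, maxit = 25L) {
  beta <- numeric(ncol(X))
  beta[1] <- qlogis(mean(y))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    fit <- lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    new_beta[is.na(new_beta)] <- 0
    if (max(abs(new_beta - beta)) < tol) { beta <- new_beta; converged <- TRUE; break }
    beta <- new_beta
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  XtWX <- crossprod(X * sqrt(w))
  cv <- tryCatch(chol2inv(chol(XtWX)), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  loglik <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  list(coef = beta, se = sqrt(diag(cv)), loglik = loglik,
       converged = converged, iterations = it)
}

or_ci <- function(beta, se, level = 0.95) {
  zq <- qnorm(1 - (1 - level) / 2)
  list(or = exp(beta), lo = exp(beta - zq * se), hi = exp(beta + zq * se))
}

covariate_matrix <- function(pheno, covariate_names) {
  if (!length(covariate_names)) return(NULL)
  cols <- lapply(covariate_names, function(nm) {
    if (!nm %in% names(pheno)) stop("unknown covariate: ", nm)
    as.numeric(pheno[[nm]])
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariate_names
  m
}

#' Run association tests over a combined imputation set
#'
#' Fits each requested inheritance model per variant on expected-dosage
#' encodings with covariates, attaches provenance (MAF, info, source
#' panel), hard-call control Hardy-Weinberg p and effect-allele homozygote
#' case counts, applies the post-association filter, and flags genome-wide
#' and experiment-wide significance. X-chromosome variants use the full
#' X-inactivation coding (see [encode_model()]); pseudoautosomal variants
#' are excluded with a warning, and samples with missing sex are dropped
#' for X variants.
#'
#' @param combined A [combine_panels()] result, [panel_result_set()] or
#'   bare [gpm()].
#' @param pheno A [phenotype_table()] covering the same samples.
#' @param covariate_names Columns of `pheno` used as covariates
#'   (e.g. `c("sex", "age", paste0("PC", 1:7))`).
#' @param models Inheritance models to fit.
#' @param gw_threshold Genome-wide significance level (default 5e-8).
#' @param thresholds [qc_thresholds()] for the post-association filter.
#' @param effective_tests Effective number of inheritance-model tests for
#'   the experiment-wide threshold (default 2.5).
#' @param stratify_x_on_sex Also include a sex main effect for X variants
#'   (sex-specific baselines, shared genotype effect).
#' @return Long-format association records (data.frame), one row per
#'   variant x model, with significance flag columns `gw_significant`
#'   and `ew_significant`.
#' @export
run_association <- function(combined, pheno, covariate_names = character(0),
                            models = MODELS, gw_threshold = 5e-8,
                            thresholds = qc_thresholds(),
                            effective_tests = 2.5,
                            stratify_x_on_sex = TRUE) {
  models <- match.arg(models, MODELS, several.ok = TRUE)
  if (inherits(combined, "combined_set")) {
    x <- combined$genotypes; info <- combined$info; panel <- combined$source_panel
  } else if (inherits(combined, "panel_set")) {
    x <- combined$genotypes; info <- combined$info; panel <- rep(combined$panel, n_variants(x))
  } else {
    x <- combined; info <- impute_info_score(x); panel <- rep(NA_character_, n_variants(x))
  }
  pheno <- align_phenotypes(x, pheno)
  status <- pheno$status
  covars <- covariate_matrix(pheno, covariate_names)
  maf <- gpm_maf(x)
  hc <- hard_calls(x, thresholds$hard_call_threshold)
  is_x <- x$variants$chrom == "X"
  in_par <- is_x & (x$variants$pos <= PAR_BOUNDS_HG19["par1_end"] |
                      x$variants$pos >= PAR_BOUNDS_HG19["par2_start"])
  if (any(in_par))
    warning(sum(in_par), " pseudoautosomal X variant(s) excluded from association")
  out <- list()
  for (j in which(!in_par)) {
    tri <- matrix(x$probs[, j, ], n_samples(x), 3)
    use <- rep(TRUE, nrow(tri))
    extra_cov <- covars
    if (is_x[j]) {
      use <- !is.na(pheno$sex)
      if (stratify_x_on_sex && !"sex" %in% covariate_names &&
          length(unique(pheno$sex[use])) > 1L) {
        sexcol <- cbind(sex = pheno$sex)
        extra_cov <- if (is.null(covars)) sexcol else cbind(covars, sexcol)
      }
    }
    ## on X the HWE table uses females only (males are homozygote-coded)
    hwe_use <- if (is_x[j]) use & !is.na(pheno$sex) & pheno$sex == 2L else use
    g_ctrl <- hc[hwe_use & status == 0, j]
    g_ctrl <- g_ctrl[!is.na(g_ctrl)]
    hwe_ctrl <- if (length(g_ctrl))
      hwe_exact_test(sum(g_ctrl == 0L), sum(g_ctrl == 1L), sum(g_ctrl == 2L))
    else NA_real_
    ahc <- sum(hc[use & status == 1, j] == 2L, na.rm = TRUE)
    n_cases <- sum(status[use] == 1)
    n_controls <- sum(status[use] == 0)
    cov_use <- if (is.null(extra_cov)) NULL else extra_cov[use, , drop = FALSE]
    for (m in models) {
      geno <- encode_model(tri[use, , drop = FALSE], m)
      if (any(apply(geno, 2, function(v) var(v, na.rm = TRUE) == 0 || all(is.na(v)))))
        next  # monomorphic under this coding
      fit <- tryCatch(fit_logistic(status[use], geno, cov_use),
                      error = function(e) NULL)
      if (is.null(fit)) next
      rec <- cbind(x$variants[j, , drop = FALSE],
                   maf = maf[j], info = info[j], panel = panel[j],
                   n_cases = n_cases, n_controls = n_controls,
                   alt_hom_cases = ahc, hwe_controls_p = hwe_ctrl,
                   model = m, empty_assoc_values(1))
      if (m == "genotypic") {
        ci_het <- or_ci(fit$coef[1], fit$se[1]); ci_hom <- or_ci(fit$coef[2], fit$se[2])
        rec$beta_het <- fit$coef[1]; rec$se_het <- fit$se[1]
        rec$or_het <- ci_het$or; rec$ci_lo_het <- ci_het$lo; rec$ci_hi_het <- ci_het$hi
        rec$beta_hom <- fit$coef[2]; rec$se_hom <- fit$se[2]
        rec$or_hom <- ci_hom$or; rec$ci_lo_hom <- ci_hom$lo; rec$ci_hi_hom <- ci_hom$hi
        rec$beta <- rec$se <- rec$or <- rec$ci_lo <- rec$ci_hi <- NA_real_
      } else {
        ci <- or_ci(fit$coef[1], fit$se[1])
        rec$beta <- fit$coef[1]; rec$se <- fit$se[1]
        rec$or <- ci$or; rec$ci_lo <- ci$lo; rec$ci_hi <- ci$hi
        rec$beta_het <- rec$se_het <- rec$or_het <- rec$ci_lo_het <- rec$ci_hi_het <- NA_real_
        rec$beta_hom <- rec$se_hom <- rec$or_hom <- rec$ci_lo_hom <- rec$ci_hi_hom <- NA_real_
      }
      rec$p <- fit$p
      rec$converged <- fit$converged
      out[[length(out) + 1L]] <- rec
    }
  }
  if (!length(out)) return(cbind(empty_records(), converged = logical(0)))
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  records <- post_association_filter(records, thresholds)
  ew <- experimentwide_threshold(gw_threshold, effective_tests)
  records$gw_significant <- !is.na(records$p) & records$p < gw_threshold
  records$ew_significant <- !is.na(records$p) & records$p < ew
  records
}

empty_records <- function() {
  cbind(data.frame(chrom = character(0), pos = integer(0), id = character(0),
                   ref_allele = character(0), eff_allele = character(0),
                   maf = numeric(0), info = numeric(0), panel = character(0),
                   n_cases = integer(0), n_controls = integer(0),
                   alt_hom_cases = integer(0), hwe_controls_p = numeric(0),
                   model = character(0), stringsAsFactors = FALSE),
        empty_assoc_values(0))
}

#' Sex-stratified X-chromosome association
#'
#' Fits the full-X-inactivation genotype coding with a sex-specific
#' intercept (sex main effect) and a shared genotype effect — separating
#' male and female baselines while pooling the genetic effect, with males
#' hemizygote-coded on the homozygote scale. With single-sex data it falls
#' back to the unstratified fit with a warning.
#'
#' @inheritParams run_association
#' @param x A [gpm()] of X-chromosome variants.
#' @return Association records with a `method` column
#'   (`"sex_stratified"` or `"pooled"`).
#' @export
stratified_x_association <- function(x, pheno, covariate_names = character(0),
                                     models = MODELS, ...) {
  pheno2 <- align_phenotypes(x, pheno)
  single_sex <- length(unique(pheno2$sex[!is.na(pheno2$sex)])) < 2L
  if (single_sex)
    warning("single-sex data: falling back to unstratified X association")
  rec <- run_association(x, pheno, covariate_names = covariate_names,
                         models = models, stratify_x_on_sex = !single_sex, ...)
  rec$method <- if (single_sex) "pooled" else "sex_stratified"
  rec
}

#' Dominance-deviation test
#'
#' Logistic regression of case status on the additive expected dosage plus
#' an expected heterozygote indicator (`p1`) and covariates; the Wald
#' p-value of the heterozygote coefficient measures departure from
#' additivity. Small p flags a genuinely non-additive signal; additive
#' associations give uniform p.
#'
#' @param triples `N x 3` probability triples for one variant.
#' @param status Case/control 0/1 vector.
#' @param covars Optional covariate matrix.
#' @return List: `p` (deviation p-value), `beta_dev`, `se_dev`,
#'   `reason` (non-`NA` when the test is undefined, e.g. no heterozygote
#'   carriers).
#' @export
dominance_deviation_test <- function(triples, status, covars = NULL) {
  triples <- matrix(triples, ncol = 3)
  if (all(triples[, 2] < 1e-12, na.rm = TRUE))
    return(list(p = NA_real_, beta_dev = NA_real_, se_dev = NA_real_,
                reason = "no heterozygote carriers"))
  geno <- cbind(add = triples[, 2] + 2 * triples[, 3], het = triples[, 2])
  fit <- tryCatch(fit_logistic(status, geno, covars), error = function(e) NULL)
  if (is.null(fit) || !fit$converged)
    return(list(p = NA_real_, beta_dev = NA_real_, se_dev = NA_real_,
                reason = "fit failed or separated"))
  list(p = fit$p_wald[2], beta_dev = fit$coef[[2]], se_dev = fit$se[[2]],
       reason = NA_character_)
}
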