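## Synthetic cohort generator: Hardy-Weinberg genotypes, logistic disease
## risk under a chosen inheritance model, and Dirichlet imputation noise
## with controllable per-panel certainty and coverage. Gives every
## downstream stage a self-contained test substrate with the statistical
## structure the analysis assumes (no LD between variants, no population
## structure).

#' Specify a synthetic cohort
#'
#' @param n_samples Cohort size.
#' @param case_fraction Target expected case fraction in `(0, 1)`.
#' @param variants Data.frame with columns `maf`, `model` (one of the five
#'   inheritance models or `"null"`), `or` (odds ratio on the model's own
#'   scale; ignored for `"null"`), and optionally `or_het`/`or_hom`
#'   (genotypic), `chrom`, `pos`, `id`, `ref_allele`, `eff_allele`,
#'   `is_indel`.
#' @param covariate_effects Named log-odds effects for `sex`, `age` and
#'   any simulated PCs (default: none).
#' @param n_pcs Number of standard-normal principal components to
#'   simulate (default 0).
#' @param panels List of panel descriptions: each a list with `name`,
#'   certainty `kappa >= 0` (larger = sharper triples; `Inf` = hard
#'   calls) and optional `coverage`, either a predicate
#'   `function(variants) logical` or the keyword `"no_indels"`.
#' @param seed Integer seed fixing all randomness downstream.
#' @return An object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_samples, case_fraction, variants,
                            covariate_effects = c(),
                            n_pcs = 0L,
                            panels = list(list(name = "panelA", kappa = 50)),
                            seed = 1L) {
  variants <- as.data.frame(variants)
  stopifnot(n_samples >= 2, case_fraction > 0, case_fraction < 1,
            all(variants$maf > 0), all(variants$maf <= 0.5))
  if (!"model" %in% names(variants)) variants$model <- "null"
  stopifnot(all(variants$model %in% c(MODELS, "null")))
  if (!"or" %in% names(variants)) variants$or <- 1
  stopifnot(all(variants$or > 0, na.rm = TRUE))
  if (!"or_het" %in% names(variants)) variants$or_het <- NA_real_
  if (!"or_hom" %in% names(variants)) variants$or_hom <- NA_real_
  geno_rows <- variants$model == "genotypic"
  if (any(geno_rows & (is.na(variants$or_het) | is.na(variants$or_hom))))
    stop("genotypic variants need or_het and or_hom")
  nv <- nrow(variants)
  if (!"chrom" %in% names(variants)) variants$chrom <- "1"
  if (!"pos" %in% names(variants)) variants$pos <- seq_len(nv) * 10000L
  if (!"id" %in% names(variants)) variants$id <- sprintf("var_%d", seq_len(nv))
  if (!"ref_allele" %in% names(variants)) variants$ref_allele <- "A"
  if (!"eff_allele" %in% names(variants)) variants$eff_allele <- "G"
  if (!"is_indel" %in% names(variants))
    variants$is_indel <- nchar(variants$ref_allele) != nchar(variants$eff_allele)
  structure(list(n_samples = as.integer(n_samples),
                 case_fraction = case_fraction, variants = variants,
                 covariate_effects = covariate_effects,
                 n_pcs = as.integer(n_pcs), panels = panels,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate true hard-call genotypes
#'
#' Autosomal genotypes are drawn with Hardy-Weinberg probabilities
#' `((1-q)^2, 2q(1-q), q^2)` at effect-allele frequency `q`;
#' X-chromosome males are hemizygotes drawn 0/1 and stored
#' homozygote-coded (0/2).
#'
#' @param spec A [simulation_spec()].
#' @param sex Optional 1/2 vector (needed for X variants); simulated
#'   Bernoulli(0.5) when omitted and required.
#' @return Integer matrix samples x variants of 0/1/2 counts.
#' @export
simulate_genotypes <- function(spec, sex = NULL) {
  set.seed(spec$seed)
  n <- spec$n_samples
  v <- spec$variants
  if (is.null(sex) && any(v$chrom == "X")) sex <- sample(1:2, n, replace = TRUE)
  g <- matrix(0L, n, nrow(v), dimnames = list(NULL, v$id))
  for (j in seq_len(nrow(v))) {
    q <- v$maf[j]
    if (v$chrom[j] == "X") {
      male <- sex == 1L
      g[male, j] <- 2L * rbinom(sum(male), 1L, q)
      g[!male, j] <- rbinom(sum(!male), 2L, q)
    } else {
      g[, j] <- rbinom(n, 2L, q)
    }
  }
  g
}

## genotype -> risk-scale covariate under each inheritance model
model_risk_term <- function(g, model, or, or_het = NA, or_hom = NA) {
  switch(model,
         null = 0,
         additive = log(or) * g,
         dominant = log(or) * (g >= 1),
         recessive = log(or) * (g == 2),
         heterodominant = log(or) * (g == 1),
         genotypic = log(or_het) * (g == 1) + log(or_hom) * (g == 2))
}

#' Simulate binary disease status from genotypes
#'
#' Population (prospective) disease model:
#' `P(case) = logistic(alpha + sum_v beta_v x_v + covariate terms)` with
#' `beta_v = ln(OR_v)` on the variant's declared model encoding; the
#' intercept `alpha` is solved by bisection so the expected case fraction
#' over the simulated cohort matches the target. One mechanism serves
#' association testing, power checks and calibration alike.
#'
#' @param genotypes Matrix from [simulate_genotypes()].
#' @param spec A [simulation_spec()].
#' @param sex,age,pcs Optional pre-simulated covariates (generated under
#'   the spec's seed when omitted: sex Bernoulli(0.5), age uniform 40-90,
#'   PCs standard normal).
#' @return A [phenotype_table()] with attribute `"alpha"` (the solved
#'   intercept).
#' @export
simulate_phenotype <- function(genotypes, spec, sex = NULL, age = NULL, pcs = NULL) {
  set.seed(spec$seed + 1L)
  n <- spec$n_samples
  if (is.null(sex)) sex <- sample(1:2, n, replace = TRUE)
  if (is.null(age)) age <- runif(n, 40, 90)
  if (is.null(pcs) && spec$n_pcs > 0)
    pcs <- matrix(stats::rnorm(n * spec$n_pcs), n,
                  dimnames = list(NULL, paste0("PC", seq_len(spec$n_pcs))))
  eta <- numeric(n)
  v <- spec$variants
  for (j in seq_len(nrow(v)))
    eta <- eta + model_risk_term(genotypes[, j], v$model[j], v$or[j],
                                 v$or_het[j], v$or_hom[j])
  ce <- spec$covariate_effects
  if ("sex" %in% names(ce)) eta <- eta + ce[["sex"]] * (sex - 1)
  if ("age" %in% names(ce)) eta <- eta + ce[["age"]] * (age - 65) / 10
  if (!is.null(pcs)) for (nm in colnames(pcs))
    if (nm %in% names(ce)) eta <- eta + ce[[nm]] * pcs[, nm]
  fr <- function(a) mean(plogis(a + eta)) - spec$case_fraction
  if (fr(-40) > 0 || fr(40) < 0)
    stop("target case fraction unattainable with these effects")
  alpha <- uniroot(fr, c(-40, 40), tol = 1e-10)$root
  status <- rbinom(n, 1L, plogis(alpha + eta))
  ph <- phenotype_table(sprintf("sample_%d", seq_len(n)), status, sex, age,
                        covariates = if (is.null(pcs)) NULL else as.data.frame(pcs))
  attr(ph, "alpha") <- alpha
  ph
}

## Dirichlet sampler via normalised gammas
rdirichlet_rows <- function(alpha_matrix) {
  g <- matrix(rgamma(length(alpha_matrix), shape = alpha_matrix),
              nrow(alpha_matrix), ncol(alpha_matrix))
  g / rowSums(g)
}

#' Simulate per-panel imputation of true genotypes
#'
#' Stand-in for real imputation output: for each covered variant, each
#' sample's probability triple is drawn from a Dirichlet centred on the
#' true genotype, concentration `1 + kappa` on the true cell and `0.5`
#' elsewhere, so `kappa = 0` is nearly uninformative and large `kappa`
#' approaches hard calls (`kappa >= 1e6` or `Inf` yields exact one-hot
#' triples). A panel's coverage predicate removes variants it does not
#' impute (e.g. a panel lacking indels). X-chromosome males draw from a
#' 2-component Dirichlet over the two hemizygous states. Info scores are
#' attached per variant.
#'
#' @param genotypes Truth matrix from [simulate_genotypes()].
#' @param spec A [simulation_spec()].
#' @param sex 1/2 vector for X variants.
#' @return List of [panel_result_set()]s, one per spec panel.
#' @export
simulate_imputation <- function(genotypes, spec, sex = NULL) {
  set.seed(spec$seed + 2L)
  v <- spec$variants
  n <- spec$n_samples
  out <- vector("list", length(spec$panels))
  for (pi in seq_along(spec$panels)) {
    p <- spec$panels[[pi]]
    covered <- panel_coverage(p, v)
    vj <- which(covered)
    probs <- array(NA_real_, c(n, length(vj), 3))
    kappa <- p$kappa
    hard <- is.infinite(kappa) || kappa >= 1e6
    for (jj in seq_along(vj)) {
      g <- genotypes[, vj[jj]]
      onehot <- diag(3)[g + 1L, , drop = FALSE]
      if (hard) {
        tri <- onehot
      } else {
        conc <- 0.5 + (0.5 + kappa) * onehot
        tri <- rdirichlet_rows(conc)
        if (v$chrom[vj[jj]] == "X" && !is.null(sex)) {
          male <- sex == 1L
          if (any(male)) {
            conc2 <- 0.5 + (0.5 + kappa) * cbind(g[male] == 0L, g[male] == 2L)
            d2 <- rdirichlet_rows(conc2)
            tri[male, ] <- cbind(d2[, 1], 0, d2[, 2])
          }
        }
      }
      probs[, jj, ] <- tri
    }
    gm <- gpm(variant_keys(v$chrom[vj], v$pos[vj], v$id[vj],
                           v$ref_allele[vj], v$eff_allele[vj]),
              sprintf("sample_%d", seq_len(n)), probs, normalize = FALSE)
    out[[pi]] <- panel_result_set(p$name, gm)
  }
  out
}

panel_coverage <- function(panel, variants) {
  cov <- panel$coverage
  if (is.null(cov)) return(rep(TRUE, nrow(variants)))
  if (is.character(cov) && cov == "no_indels") return(!variants$is_indel)
  if (is.function(cov)) return(cov(variants))
  stop("unrecognised coverage specification for panel ", panel$name)
}

#' Simulate a full cohort: genotypes, phenotypes and panel imputations
#'
#' @param spec A [simulation_spec()].
#' @return List: `truth` (one-hot [gpm()]), `genotypes` (integer matrix),
#'   `phenotypes` ([phenotype_table()]), `panels` (list of
#'   [panel_result_set()]s).
#' @export
simulate_cohort <- function(spec) {
  set.seed(spec$seed + 3L)   # sex drawn off the genotype stream
  n <- spec$n_samples
  sex <- sample(1:2, n, replace = TRUE)
  g <- simulate_genotypes(spec, sex = sex)
  ph <- simulate_phenotype(g, spec, sex = sex)
  v <- spec$variants
  probs <- array(0, c(n, nrow(v), 3))
  for (j in seq_len(nrow(v))) probs[, j, ] <- diag(3)[g[, j] + 1L, ]
  truth <- gpm(variant_keys(v$chrom, v$pos, v$id, v$ref_allele, v$eff_allele),
               ph$sample_id, probs, normalize = FALSE)
  panels <- simulate_imputation(g, spec, sex = sex)
  list(truth = truth, genotypes = g, phenotypes = ph, panels = panels)
}
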