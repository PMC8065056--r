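test_that("model encodings map probability triples as documented", {
  tri <- c(0.1, 0.2, 0.7)
  expect_equal(unname(drop(encode_model(tri, "additive"))), 1.6)
  expect_equal(unname(drop(encode_model(tri, "dominant"))), 0.9)
  expect_equal(unname(drop(encode_model(tri, "recessive"))), 0.7)
  expect_equal(unname(drop(encode_model(tri, "heterodominant"))), 0.2)
  expect_equal(unname(encode_model(tri, "genotypic")[1, ]), c(0.2, 0.7))
  het <- c(0, 1, 0)
  expect_equal(unname(drop(encode_model(het, "additive"))), 1)
  expect_equal(unname(drop(encode_model(het, "recessive"))), 0)
  # X male with effect allele certain, homozygote-coded triple (0,0,1)
  male <- c(0, 0, 1)
  expect_equal(unname(drop(encode_model(male, "additive"))), 2)
  expect_equal(unname(drop(encode_model(male, "recessive"))), 1)
  expect_equal(unname(drop(encode_model(male, "heterodominant"))), 0)
  expect_equal(unname(encode_model(male, "genotypic")[1, ]), c(0, 1))
})

test_that("the 2x2 binary-exposure fit reproduces the sample odds ratio", {
  status <- c(rep(1, 100), rep(0, 100))
  exposed <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  fit <- fit_logistic(status, cbind(g = exposed))
  expect_equal(exp(fit$coef[[1]]), (30 * 90) / (10 * 70), tolerance = 1e-6)
  expect_equal(round(exp(fit$coef[[1]]), 3), 3.857)
})

test_that("the IRLS fit agrees with an independent optimiser on random data", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(80:200, 1)
    k <- sample(1:3, 1)
    X <- matrix(rnorm(n * k), n, k)
    g <- rbinom(n, 2, runif(1, 0.2, 0.5))
    eta <- 0.3 * g + X %*% rnorm(k, 0, 0.4)
    y <- rbinom(n, 1, plogis(drop(eta)))
    if (sum(y) < 5 || sum(1 - y) < 5) next
    fit <- fit_logistic(y, cbind(g = g), X)
    if (!fit$converged) next
    # brute-force ML oracle on the raw (unstandardised) design
    nll <- function(b) {
      eta <- cbind(1, g, X) %*% b
      -sum(y * eta - log1p(exp(eta)))
    }
    opt <- optim(rep(0, k + 2), nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_lt(abs(fit$coef[[1]] - opt$par[2]), 1e-6)
  }
})

test_that("hard-call additive fits equal integer-dosage fits exactly", {
  set.seed(31)
  g <- rbinom(400, 2, 0.35)
  y <- rbinom(400, 1, plogis(-0.5 + 0.3 * g))
  tri <- diag(3)[g + 1L, ]
  f1 <- fit_logistic(y, encode_model(tri, "additive"))
  f2 <- fit_logistic(y, cbind(g = g))
  expect_identical(f1$coef, f2$coef)
})

test_that("separation is flagged instead of fabricating estimates", {
  status <- c(rep(1, 20), rep(0, 20))
  exposed <- c(rep(1, 20), rep(0, 20))
  fit <- fit_logistic(status, cbind(g = exposed))
  expect_false(fit$converged)
  expect_true(is.na(fit$coef[[1]]))
  expect_true(is.na(fit$p))
})

test_that("null fits are calibrated: estimates stay within 3 SEs of zero", {
  inside <- 0L
  for (r in 1:60) {
    set.seed(300 + r)
    g <- rbinom(5000, 2, 0.3)
    y <- rbinom(5000, 1, 0.3)
    fit <- fit_logistic(y, cbind(g = g))
    if (abs(fit$coef[[1]]) < 3 * fit$se[[1]]) inside <- inside + 1L
  }
  expect_gte(inside / 60, 0.95)
})

test_that("the genotypic model nests the 1-df models in likelihood", {
  # the 2-parameter genotype mean structure contains each 1-df coding,
  # so its maximised log-likelihood can never be lower
  set.seed(41)
  for (i in 1:10) {
    g <- rbinom(3000, 2, 0.3)
    y <- rbinom(3000, 1, plogis(-1 + 0.25 * (g == 2)))
    tri <- diag(3)[g + 1L, ]
    ll2 <- fit_logistic(y, encode_model(tri, "genotypic"))$loglik
    ll1 <- vapply(c("additive", "dominant", "recessive", "heterodominant"),
                  function(m) fit_logistic(y, encode_model(tri, m))$loglik,
                  numeric(1))
    expect_true(all(ll2 >= ll1 - 1e-8))
  }
})

test_that("confidence intervals bracket the odds ratio as exp(beta +/- 1.96 se)", {
  set.seed(50)
  g <- rbinom(2000, 2, 0.25)
  y <- rbinom(2000, 1, plogis(-0.8 + 0.4 * g))
  x <- onehot_gpm(cbind(g))
  ph <- phenotype_table(x$samples, y)
  rec <- run_association(x, ph, models = "additive")
  expect_equal(rec$or, exp(rec$beta))
  expect_equal(rec$ci_lo, exp(rec$beta - qnorm(0.975) * rec$se), tolerance = 1e-9)
  expect_equal(rec$ci_hi, exp(rec$beta + qnorm(0.975) * rec$se), tolerance = 1e-9)
  expect_true(rec$ci_lo < rec$or && rec$or < rec$ci_hi)
})

test_that("monomorphic variants are dropped before fitting", {
  g <- cbind(rep(0L, 100), rbinom(100, 2, 0.4))
  x <- onehot_gpm(g)
  ph <- phenotype_table(x$samples, rbinom(100, 1, 0.4))
  rec <- run_association(x, ph, models = c("additive", "recessive"))
  expect_false("v1" %in% rec$id)
})

test_that("a simulated recessive signal is detected best by the recessive test", {
  # PELO-like configuration at reduced scale: the recessive p beats the
  # additive p in most replicates
  wins <- 0L; n_rep <- 10
  for (r in seq_len(n_rep)) {
    spec <- simulation_spec(n_samples = 20000, case_fraction = 0.123,
                            variants = data.frame(maf = 0.08, model = "recessive", or = 4.32),
                            seed = 7000 + r)
    g <- simulate_genotypes(spec)
    ph <- simulate_phenotype(g, spec)
    tri <- diag(3)[g[, 1] + 1L, ]
    p_rec <- fit_logistic(ph$status, encode_model(tri, "recessive"))$p
    p_add <- fit_logistic(ph$status, encode_model(tri, "additive"))$p
    if (p_rec < p_add) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("X association under full inactivation handles sexes and strata", {
  set.seed(77)
  n <- 20000
  sex <- rep(c(1L, 2L), n / 2)
  q <- 0.3
  gx <- ifelse(sex == 1L, 2L * rbinom(n, 1, q), rbinom(n, 2, q))
  beta <- 0.25
  dose <- ifelse(sex == 1L, gx, gx)  # full inactivation: same scale
  y <- rbinom(n, 1, plogis(-1 + beta * dose / 2))
  x <- onehot_gpm(cbind(gx), chrom = "X", pos = 5000000L)
  ph <- phenotype_table(x$samples, y, sex = sex, age = 60)
  rec_strat <- stratified_x_association(x, ph, models = "additive")
  expect_equal(rec_strat$method, "sex_stratified")
  # identical effect in both sexes: stratified and pooled estimates agree
  rec_pool <- run_association(x, ph, models = "additive", stratify_x_on_sex = FALSE)
  expect_equal(rec_strat$beta, rec_pool$beta, tolerance = 5e-3)
  # missing sex drops samples rather than failing
  ph2 <- ph; ph2$sex[1:100] <- NA_integer_
  rec2 <- run_association(x, ph2, models = "additive")
  expect_equal(rec2$n_cases + rec2$n_controls, n - 100L)
  # single-sex data falls back with a warning
  keep <- sex == 2L
  x_f <- onehot_gpm(cbind(gx[keep]), chrom = "X", pos = 5000000L)
  ph_f <- phenotype_table(x_f$samples, y[keep], sex = sex[keep], age = 60)
  expect_warning(rec_f <- stratified_x_association(x_f, ph_f, models = "additive"),
                 "single-sex")
  expect_equal(rec_f$method, "pooled")
})

test_that("pseudoautosomal X variants are excluded with a warning", {
  set.seed(81)
  g <- cbind(rbinom(200, 2, 0.3), rbinom(200, 2, 0.3))
  x <- onehot_gpm(g, chrom = "X", pos = c(1000000L, 5000000L))  # PAR1, non-PAR
  ph <- phenotype_table(x$samples, rbinom(200, 1, 0.3),
                        sex = rep(c(1L, 2L), 100))
  expect_warning(rec <- run_association(x, ph, models = "additive"),
                 "pseudoautosomal")
  expect_false("v1" %in% rec$id)
  expect_true("v2" %in% rec$id)
})

test_that("dominance deviation is null under additivity and powered under recessivity", {
  # null property: additive data give uniform deviation p
  p_null <- vapply(1:40, function(r) {
    set.seed(500 + r)
    g <- rbinom(6000, 2, 0.3)
    y <- rbinom(6000, 1, plogis(-1 + log(1.5) * g))
    dominance_deviation_test(diag(3)[g + 1L, ], y)$p
  }, numeric(1))
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.001)
  # power property: recessive data reject additivity
  hits <- vapply(1:25, function(r) {
    set.seed(600 + r)
    g <- rbinom(6000, 2, 0.25)
    y <- rbinom(6000, 1, plogis(-1 + log(4) * (g == 2)))
    dominance_deviation_test(diag(3)[g + 1L, ], y)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # no heterozygote carriers -> missing with reason
  g0 <- c(rep(0L, 50), rep(2L, 50))
  dd <- dominance_deviation_test(diag(3)[g0 + 1L, ], rbinom(100, 1, 0.5))
  expect_true(is.na(dd$p))
  expect_match(dd$reason, "heterozygote")
})
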