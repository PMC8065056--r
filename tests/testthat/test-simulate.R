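test_that("genotypes follow Hardy-Weinberg frequencies at the requested MAF", {
  spec <- simulation_spec(n_samples = 10000, case_fraction = 0.2,
                          variants = data.frame(maf = c(0.2, 0.5)), seed = 10)
  g <- simulate_genotypes(spec)
  # empirical allele frequency within 3 binomial SEs
  q_hat <- mean(g[, 1]) / 2
  expect_lt(abs(q_hat - 0.2), 3 * sqrt(0.2 * 0.8 / (2 * 10000)))
  # het fraction at q = 0.5 is 2q(1-q) = 0.5
  het <- mean(g[, 2] == 1)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("the generator is deterministic under a fixed seed", {
  spec <- simulation_spec(n_samples = 500, case_fraction = 0.3,
                          variants = data.frame(maf = 0.25, model = "additive", or = 1.4),
                          panels = list(list(name = "A", kappa = 5)), seed = 99)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$phenotypes$status, c2$phenotypes$status)
  expect_identical(c1$panels[[1]]$genotypes$probs, c2$panels[[1]]$genotypes$probs)
})

test_that("null effects give the target case fraction", {
  spec <- simulation_spec(n_samples = 20000, case_fraction = 0.25,
                          variants = data.frame(maf = 0.3, model = "null", or = 1),
                          seed = 4)
  ph <- simulate_phenotype(simulate_genotypes(spec), spec)
  expect_lt(abs(mean(ph$status) - 0.25),
            3 * sqrt(0.25 * 0.75 / 20000))
})

test_that("a strong recessive effect reproduces its odds ratio in the 2x2 table", {
  spec <- simulation_spec(n_samples = 200000, case_fraction = 0.12,
                          variants = data.frame(maf = 0.017, model = "recessive", or = 19),
                          seed = 21)
  g <- simulate_genotypes(spec)
  ph <- simulate_phenotype(g, spec)
  hom <- g[, 1] == 2
  tab <- table(hom, ph$status)
  or_hat <- (tab["TRUE", "1"] * tab["FALSE", "0"]) /
    (tab["TRUE", "0"] * tab["FALSE", "1"])
  expect_lt(abs(or_hat / 19 - 1), 0.35)  # ~115 homozygotes: wide but centred
})

test_that("male X genotypes are hemizygous and homozygote-coded", {
  spec <- simulation_spec(n_samples = 4000, case_fraction = 0.2,
                          variants = data.frame(chrom = "X", pos = 5e6,
                                                maf = 0.3, model = "null", or = 1),
                          seed = 12)
  sex <- rep(c(1L, 2L), 2000)
  g <- simulate_genotypes(spec, sex = sex)
  expect_true(all(g[sex == 1, 1] %in% c(0L, 2L)))
  expect_true(any(g[sex == 2, 1] == 1L))
})

test_that("imputation certainty controls info scores monotonically", {
  spec_for <- function(kappa) simulation_spec(
    n_samples = 300, case_fraction = 0.2,
    variants = data.frame(maf = 0.3, model = "null", or = 1),
    panels = list(list(name = "hi", kappa = kappa)), seed = 1)
  info_at <- function(kappa, seed) {
    sp <- spec_for(kappa); sp$seed <- seed
    ps <- simulate_imputation(simulate_genotypes(sp), sp)
    ps[[1]]$info
  }
  infos_hi <- vapply(1:20, function(s) info_at(20, s), numeric(1))
  infos_lo <- vapply(1:20, function(s) info_at(2, s), numeric(1))
  expect_gt(mean(infos_hi), mean(infos_lo))
  # kappa -> Inf yields exact hard calls with info 1
  sp <- spec_for(Inf)
  ps <- simulate_imputation(simulate_genotypes(sp), sp)
  expect_equal(ps[[1]]$info, 1)
  expect_true(all(ps[[1]]$genotypes$probs %in% c(0, 1)))
})

test_that("coverage predicates exclude variants from a panel", {
  v <- data.frame(maf = c(0.2, 0.3), model = "null", or = 1,
                  ref_allele = c("A", "AT"), eff_allele = c("G", "A"),
                  pos = c(1000L, 2000L))
  spec <- simulation_spec(n_samples = 50, case_fraction = 0.2, variants = v,
                          panels = list(list(name = "full", kappa = 10),
                                        list(name = "snponly", kappa = 10,
                                             coverage = "no_indels")),
                          seed = 2)
  cohort <- simulate_cohort(spec)
  expect_equal(n_variants(cohort$panels[[1]]$genotypes), 2L)
  expect_equal(n_variants(cohort$panels[[2]]$genotypes), 1L)
  expect_false("var_2" %in% cohort$panels[[2]]$genotypes$variants$id)
})

test_that("null variants produce uniform association p-values", {
  sim <- get_null_sim(n_samples = 2000, n_variants = 5000)
  p_add <- sim$p[, "additive"]
  ks <- stats::ks.test(p_add[!is.na(p_add)], "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("each model's effect size is recovered within its own confidence interval", {
  # matching test applied to data generated under the same model
  for (model in c("additive", "dominant", "recessive", "heterodominant")) {
    hits <- 0L
    n_rep <- 60
    for (r in seq_len(n_rep)) {
      set.seed(1000 + r)
      g <- rbinom(8000, 2, 0.3)
      x <- drop(encode_model(diag(3)[g + 1L, ], model))
      eta <- log(1.6) * x
      a <- uniroot(function(a) mean(plogis(a + eta)) - 0.3, c(-10, 10))$root
      status <- rbinom(8000, 1, plogis(a + eta))
      fit <- fit_logistic(status, encode_model(diag(3)[g + 1L, ], model))
      ci <- c(fit$coef[1] - 1.96 * fit$se[1], fit$coef[1] + 1.96 * fit$se[1])
      if (ci[1] <= log(1.6) && log(1.6) <= ci[2]) hits <- hits + 1L
    }
    expect_gte(hits / n_rep, 0.85)
  }
})
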