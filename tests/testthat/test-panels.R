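test_that("panel combination selects the best-info panel with priority tie-breaks", {
  x <- random_gpm(n_samples = 5, n_variants = 3, seed = 2)
  y <- random_gpm(n_samples = 5, n_variants = 3, seed = 3)
  y$variants <- x$variants  # same sites, different probabilities
  a <- panel_result_set("A", x, info = c(0.85, 0.90, 0.60))
  b <- panel_result_set("B", y, info = c(0.92, 0.90, 0.55))
  comb <- combine_panels(list(a, b), panel_priority = c("A", "B"))
  key <- gwasmodels:::variant_site_key(comb$genotypes$variants)
  ord <- match(gwasmodels:::variant_site_key(x$variants), key)
  expect_equal(comb$source_panel[ord], c("B", "A", "A"))  # argmax, tie -> priority A
  expect_equal(comb$info[ord], c(0.92, 0.90, 0.60))
  expect_equal(comb$genotypes$probs[, ord[1], ], y$probs[, 1, ])
  expect_equal(comb$genotypes$probs[, ord[2], ], x$probs[, 2, ])
})

test_that("combination takes the union of variants (panel-private variants survive)", {
  x <- random_gpm(n_samples = 4, n_variants = 4, seed = 5)
  sub <- gwasmodels:::gpm_subset(x, 1:2)
  a <- panel_result_set("A", sub, info = c(0.9, 0.9))
  # panel C covers an indel absent from A
  indel <- gpm(variant_keys("7", 1234L, "indel1", "AT", "A"), x$samples,
               x$probs[, 3, , drop = FALSE], normalize = FALSE)
  c_ <- panel_result_set("C", indel, info = 0.75)
  comb <- combine_panels(list(a, c_))
  expect_equal(n_variants(comb$genotypes), 3L)
  expect_equal(comb$source_panel[comb$genotypes$variants$id == "indel1"], "C")
  expect_gte(n_variants(comb$genotypes), n_variants(sub))
})

test_that("combined info equals the per-variant maximum on random fixtures", {
  for (seed in 1:10) {
    set.seed(seed)
    base <- random_gpm(n_samples = 3, n_variants = 6, seed = seed)
    sets <- lapply(c("P1", "P2", "P3"), function(nm) {
      cov <- sort(sample(6, sample(3:6, 1)))
      panel_result_set(nm, gwasmodels:::gpm_subset(base, cov),
                       info = runif(length(cov)))
    })
    comb <- combine_panels(sets)
    key_all <- gwasmodels:::variant_site_key(comb$genotypes$variants)
    for (s in sets) {
      k <- gwasmodels:::variant_site_key(s$genotypes$variants)
      idx <- match(k, key_all)
      expect_true(all(comb$info[idx] >= s$info - 1e-12))
    }
    expect_gte(n_variants(comb$genotypes),
               max(vapply(sets, function(s) n_variants(s$genotypes), 0)))
  }
})

test_that("mismatched sample order and in-panel duplicates are rejected", {
  x <- random_gpm(n_samples = 4, n_variants = 2, seed = 1)
  y <- random_gpm(n_samples = 4, n_variants = 2, seed = 1)
  y$samples <- rev(y$samples)
  expect_error(combine_panels(list(panel_result_set("A", x),
                                   panel_result_set("B", y))),
               "sample orderings")
  dup <- x
  dup$variants <- x$variants[c(1, 1), ]
  dup$variants$id <- c("a", "b")
  expect_error(panel_result_set("D", dup), "duplicate")
})

test_that("the in-silico array masks to the requested backbone", {
  g <- matrix(rbinom(50 * 10, 2, 0.3), 50, 10)
  truth <- onehot_gpm(g)
  arr <- make_insilico_array(truth, c("v2", "v5", "v7", "v9"))
  expect_equal(n_variants(arr$array), 4L)
  expect_setequal(arr$withheld_ids, sprintf("v%d", c(1, 3, 4, 6, 8, 10)))
  expect_length(intersect(arr$array$variants$id, arr$withheld_ids), 0)
  # masked triples are one-hot copies of truth
  expect_true(all(arr$array$probs %in% c(0, 1)))
  expect_equal(drop(arr$array$probs[, 1, 2]), as.numeric(g[, 2] == 1))
  expect_error(make_insilico_array(truth, c("v2", "nope")), "nope")
})

test_that("allelic dosage R2 matches hand computation and its invariances", {
  expect_equal(allelic_dosage_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(allelic_dosage_r2(c(0.1, 0.9, 1.8, 1.2), c(0, 1, 2, 1)),
               0.9633, tolerance = 1e-4)
  # reflection invariance: swapping the counted allele leaves R2 unchanged
  expect_equal(allelic_dosage_r2(2 - c(0.1, 0.9, 1.8, 1.2), c(0, 1, 2, 1)),
               allelic_dosage_r2(c(0.1, 0.9, 1.8, 1.2), c(0, 1, 2, 1)))
  expect_true(is.na(allelic_dosage_r2(rep(1, 4), c(0, 1, 2, 1))))
  expect_true(is.na(allelic_dosage_r2(c(1, NA, NA, NA), c(0, 1, 2, 1))))
})

test_that("MAF-binned quality summarises percentages per bin", {
  r2 <- c(1, 1, 0.4, 0.6, 0.9)
  maf <- c(0.002, 0.003, 0.03, 0.03, 0.3)
  info <- c(0.9, 0.95, 0.8, 0.99, 0.9)
  tab <- maf_binned_quality(r2, maf, info)
  expect_equal(tab$pct[tab$bin == "(0.001,0.005]"], 100)
  expect_equal(tab$pct[tab$bin == "(0.01,0.05]"], 50)
  expect_true(is.na(tab$pct[tab$bin == "(0.05,0.1]"]))
  expect_equal(tab$n[tab$bin == "(0.05,0.1]"], 0L)
  expect_equal(tab$pct[tab$bin == "overall"], 80)
})

test_that("combining panels improves masked-truth imputation quality", {
  # three panels with different certainty; the combined set's high-R2
  # percentage should dominate every single panel in most replicates
  better <- 0L; n_rep <- 12
  for (r in seq_len(n_rep)) {
    spec <- simulation_spec(
      n_samples = 250, case_fraction = 0.3,
      variants = data.frame(maf = runif(40, 0.05, 0.5)),
      panels = list(list(name = "A", kappa = 1.5),
                    list(name = "B", kappa = 3),
                    list(name = "C", kappa = 6)),
      seed = 8800 + r)
    cohort <- simulate_cohort(spec)
    truth_dosage <- expected_dosage(cohort$truth)
    pct_of <- function(info, gm) {
      r2 <- vapply(seq_len(n_variants(gm)), function(j)
        allelic_dosage_r2(matrix(gm$probs[, j, ], ncol = 3),
                          truth_dosage[, gm$variants$id[j]]), numeric(1))
      tab <- maf_binned_quality(r2, gpm_maf(gm), info, min_info = 0)
      tab$pct[tab$bin == "overall"]
    }
    singles <- vapply(cohort$panels, function(ps) pct_of(ps$info, ps$genotypes),
                      numeric(1))
    comb <- combine_panels(cohort$panels)
    if (pct_of(comb$info, comb$genotypes) >= max(singles) - 1e-9) better <- better + 1L
  }
  expect_gte(better / n_rep, 0.9)
})
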