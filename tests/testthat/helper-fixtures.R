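# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

random_gpm <- function(n_samples = 6, n_variants = 4, seed = 1, missing_frac = 0) {
  set.seed(seed)
  vk <- variant_keys(chrom = rep("1", n_variants),
                     pos = sort(sample(1e6, n_variants)),
                     id = sprintf("rs%03d", seq_len(n_variants)),
                     ref_allele = sample(c("A", "C"), n_variants, TRUE),
                     eff_allele = sample(c("G", "T"), n_variants, TRUE))
  probs <- array(0, c(n_samples, n_variants, 3))
  for (j in seq_len(n_variants)) {
    raw <- matrix(rgamma(n_samples * 3, 1), n_samples, 3)
    probs[, j, ] <- raw / rowSums(raw)
  }
  if (missing_frac > 0) {
    drop <- which(matrix(runif(n_samples * n_variants) < missing_frac,
                         n_samples, n_variants), arr.ind = TRUE)
    for (r in seq_len(nrow(drop))) probs[drop[r, 1], drop[r, 2], ] <- NA_real_
  }
  gpm(vk, sprintf("sample_%d", seq_len(n_samples)), probs, normalize = FALSE)
}

onehot_gpm <- function(genotype_matrix, chrom = "1", pos = NULL) {
  n <- nrow(genotype_matrix); v <- ncol(genotype_matrix)
  if (is.null(pos)) pos <- seq_len(v) * 1000L
  probs <- array(0, c(n, v, 3))
  for (j in seq_len(v)) probs[, j, ] <- diag(3)[genotype_matrix[, j] + 1L, ]
  gpm(variant_keys(rep(chrom, v), pos, sprintf("v%d", seq_len(v)),
                   rep("A", v), rep("G", v)),
      sprintf("sample_%d", seq_len(n)), probs, normalize = FALSE)
}

# minimal association record rows for filter/loci tests
make_record <- function(chrom = "1", pos = 1L, id = paste0("rs", pos),
                        model = "additive", p = 0.5, beta = 0.1, se = 0.1,
                        hwe_controls_p = 0.5, alt_hom_cases = 10L,
                        maf = 0.2, info = 0.95) {
  rec <- cbind(data.frame(chrom = chrom, pos = as.integer(pos), id = id,
                          ref_allele = "A", eff_allele = "G",
                          maf = maf, info = info, panel = "P1",
                          n_cases = 100L, n_controls = 100L,
                          alt_hom_cases = as.integer(alt_hom_cases),
                          hwe_controls_p = hwe_controls_p,
                          model = model, stringsAsFactors = FALSE),
               gwasmodels:::empty_assoc_values(1))
  rec$beta <- beta; rec$se <- se
  rec$or <- exp(beta); rec$ci_lo <- exp(beta - 1.96 * se)
  rec$ci_hi <- exp(beta + 1.96 * se); rec$p <- p
  rec
}

# brute-force HWE oracle: enumerate all heterozygote counts compatible
# with the allele counts and sum probabilities no larger than observed
hwe_enumeration_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  rare <- n_ab + 2 * min(n_aa, n_bb)
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lchoose(n, hr) + lchoose(n - hr, h) + h * log(2) -
      lchoose(2 * n, rare)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- match(n_ab, hets)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

# cached null-variant simulation shared between calibration tests:
# n_variants independent HWE variants with no effect, one phenotype draw
.null_sim_cache <- new.env(parent = emptyenv())
get_null_sim <- function(n_samples = 2000, n_variants = 5000, maf = 0.3, seed = 42) {
  key <- paste(n_samples, n_variants, maf, seed, sep = "_")
  if (!is.null(.null_sim_cache[[key]])) return(.null_sim_cache[[key]])
  set.seed(seed)
  g <- matrix(rbinom(n_samples * n_variants, 2, maf), n_samples, n_variants)
  status <- rbinom(n_samples, 1, 0.3)
  p <- matrix(NA_real_, n_variants, length(MODELS_ALL),
              dimnames = list(NULL, MODELS_ALL))
  for (j in seq_len(n_variants)) {
    tri <- diag(3)[g[, j] + 1L, ]
    for (m in MODELS_ALL) {
      fit <- tryCatch(fit_logistic(status, encode_model(tri, m)),
                      error = function(e) NULL)
      if (!is.null(fit) && fit$converged) p[j, m] <- fit$p
    }
  }
  out <- list(p = p, status = status)
  .null_sim_cache[[key]] <- out
  out
}

MODELS_ALL <- c("additive", "dominant", "recessive", "heterodominant", "genotypic")
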