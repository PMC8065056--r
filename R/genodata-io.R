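#' @importFrom stats complete.cases cor median pchisq plogis pnorm qlogis
#'   qchisq qnorm rbinom rgamma runif setNames uniroot var lm.wfit
#' @importFrom utils read.table write.table head tail
NULL

MODELS <- c("additive", "dominant", "recessive", "heterodominant", "genotypic")
NA_TOKEN <- "NA"

## ---- variant keys -----------------------------------------------------------

#' Construct a variant key table
#'
#' A variant key identifies a variant by chromosome, 1-based position, an
#' identifier string and its two alleles. The effect allele is the allele
#' whose copy number (0/1/2) is modelled throughout the package (GEN
#' "allele B" / VCF ALT). Indels are represented by multi-base allele
#' strings.
#'
#' @param chrom Chromosome labels ("1"-"22" or "X").
#' @param pos 1-based base-pair positions.
#' @param id Variant identifier strings.
#' @param ref_allele,eff_allele Allele strings; `eff_allele` is the modelled
#'   allele.
#' @return A `data.frame` with one row per variant and columns
#'   `chrom, pos, id, ref_allele, eff_allele`.
#' @export
variant_keys <- function(chrom, pos, id, ref_allele, eff_allele) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  stopifnot(all(pos >= 1L), all(nzchar(ref_allele)), all(nzchar(eff_allele)))
  vk <- data.frame(chrom = chrom, pos = pos, id = as.character(id),
                   ref_allele = toupper(as.character(ref_allele)),
                   eff_allele = toupper(as.character(eff_allele)),
                   stringsAsFactors = FALSE)
  key <- variant_key_string(vk)
  if (anyDuplicated(key))
    stop("duplicate variant keys: ", paste(unique(key[duplicated(key)]), collapse = ", "))
  vk
}

variant_key_string <- function(vk) {
  paste(vk$chrom, vk$pos, vk$ref_allele, vk$eff_allele, sep = ":")
}

## unordered-allele key used when matching the same site across panels
variant_site_key <- function(vk) {
  a <- pmin(vk$ref_allele, vk$eff_allele)
  b <- pmax(vk$ref_allele, vk$eff_allele)
  paste(vk$chrom, vk$pos, a, b, sep = ":")
}

## ---- genotype probability matrix -------------------------------------------

#' Construct a genotype probability matrix
#'
#' The central container: for each sample and variant a probability triple
#' `(p0, p1, p2)` for carrying 0, 1 or 2 copies of the effect allele.
#' Missing genotypes are `NA` triples. Triples whose sum falls below
#' `0.98` are treated as missing (imputation software emits deflated
#' triples for uncertain genotypes, and keeping them would bias expected
#' dosages); triples with sum in `[0.98, 1)` are renormalised to sum 1.
#'
#' @param variants Variant key table (see [variant_keys()]).
#' @param samples Character vector of sample ids (unique).
#' @param probs Numeric array of dim `c(n_samples, n_variants, 3)`.
#' @param normalize Apply the deflation rule above (default `TRUE`).
#' @return An object of class `"gpm"`.
#' @export
gpm <- function(variants, samples, probs, normalize = TRUE) {
  samples <- as.character(samples)
  stopifnot(!anyDuplicated(samples),
            length(dim(probs)) == 3L,
            dim(probs)[1] == length(samples),
            dim(probs)[2] == nrow(variants),
            dim(probs)[3] == 3L)
  if (any(probs < 0, na.rm = TRUE)) stop("negative genotype probability")
  if (normalize) {
    s <- probs[, , 1, drop = FALSE] + probs[, , 2, drop = FALSE] + probs[, , 3, drop = FALSE]
    s <- s[, , 1]
    bad <- !is.na(s) & s < 0.98
    if (any(bad)) {
      for (k in 1:3) { pk <- probs[, , k]; pk[bad] <- NA_real_; probs[, , k] <- pk }
    }
    renorm <- !is.na(s) & !bad & abs(s - 1) > 1e-3
    if (any(renorm)) {
      for (k in 1:3) { pk <- probs[, , k]; pk[renorm] <- pk[renorm] / s[renorm]; probs[, , k] <- pk }
    }
  }
  structure(list(variants = variants, samples = samples, probs = probs),
            class = "gpm")
}

#' @export
print.gpm <- function(x, ...) {
  cat(sprintf("Genotype probability matrix: %d samples x %d variants (%.1f%% missing)\n",
              length(x$samples), nrow(x$variants),
              100 * mean(is.na(x$probs[, , 1]))))
  invisible(x)
}

n_variants <- function(x) nrow(x$variants)
n_samples <- function(x) length(x$samples)

#' Expected effect-allele dosage
#'
#' Posterior-mean allele count `p1 + 2 p2` per sample and variant.
#'
#' @param x A `gpm`.
#' @return Numeric matrix (samples x variants); `NA` where the triple is
#'   missing.
#' @export
expected_dosage <- function(x) {
  d <- x$probs[, , 2, drop = FALSE] + 2 * x$probs[, , 3, drop = FALSE]
  matrix(d, n_samples(x), n_variants(x),
         dimnames = list(x$samples, x$variants$id))
}

#' Hard-call genotypes from probability triples
#'
#' Returns the genotype (0/1/2) whose probability reaches `threshold`,
#' `NA` otherwise (the calling convention used for integer-count criteria
#' such as Hardy-Weinberg tables and homozygote case counts).
#'
#' @param x A `gpm`.
#' @param threshold Minimum per-genotype probability (default 0.9).
#' @return Integer matrix (samples x variants) with `NA` for uncertain calls.
#' @export
hard_calls <- function(x, threshold = 0.9) {
  ns <- n_samples(x); nv <- n_variants(x)
  g <- matrix(NA_integer_, ns, nv, dimnames = list(x$samples, x$variants$id))
  for (k in 1:3) {
    pk <- matrix(x$probs[, , k], ns, nv)
    g[!is.na(pk) & pk >= threshold] <- k - 1L
  }
  g
}

## subset a gpm by variant index
gpm_subset <- function(x, j) {
  gpm(x$variants[j, , drop = FALSE], x$samples,
      x$probs[, j, , drop = FALSE], normalize = FALSE)
}

#' Per-variant minor allele frequency from expected dosages
#'
#' @param x A `gpm`.
#' @return Numeric vector: `min(theta, 1 - theta)` where `theta` is the
#'   effect-allele frequency over non-missing samples.
#' @export
gpm_maf <- function(x) {
  theta <- colMeans(expected_dosage(x), na.rm = TRUE) / 2
  pmin(theta, 1 - theta)
}

## ---- phenotype table --------------------------------------------------------

#' Construct a phenotype/covariate table
#'
#' @param sample_id Unique sample ids.
#' @param status 0 = control, 1 = case.
#' @param sex 1 = male, 2 = female, `NA` allowed.
#' @param age Age in years.
#' @param covariates Optional data.frame of additional numeric covariates
#'   (e.g. principal components).
#' @return A `data.frame` with attribute `"covariate_names"`.
#' @export
phenotype_table <- function(sample_id, status, sex = NA_integer_, age = NA_real_,
                            covariates = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  if (!all(status %in% c(0L, 1L))) stop("status must be binary 0/1")
  if (!all(is.na(sex) | sex %in% c(1L, 2L))) stop("sex must be 1 (male) / 2 (female) / NA")
  df <- data.frame(sample_id = sample_id, status = as.integer(status),
                   sex = as.integer(sex), age = as.numeric(age),
                   stringsAsFactors = FALSE)
  cn <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == nrow(df))
    if (!all(vapply(covariates, is.numeric, TRUE))) stop("covariates must be numeric")
    if (any(!is.finite(as.matrix(covariates)))) stop("covariates must be finite")
    df <- cbind(df, covariates)
    cn <- names(covariates)
  }
  attr(df, "covariate_names") <- cn
  df
}

## align a phenotype table to a gpm's samples; error listing offenders
align_phenotypes <- function(x, pheno) {
  missing_ph <- setdiff(x$samples, pheno$sample_id)
  extra_ph <- setdiff(pheno$sample_id, x$samples)
  if (length(missing_ph) || length(extra_ph))
    stop("sample sets differ between genotypes and phenotypes; ",
         "missing from phenotypes: [", paste(head(missing_ph, 5), collapse = ", "),
         "]; absent from genotypes: [", paste(head(extra_ph, 5), collapse = ", "), "]")
  cn <- attr(pheno, "covariate_names")
  out <- pheno[match(x$samples, pheno$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "covariate_names") <- cn
  out
}

## ---- Oxford GEN / SAMPLE ----------------------------------------------------

open_maybe_gz <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read an Oxford GEN + SAMPLE file pair
#'
#' GEN rows carry 5 leading fields (chrom/id or id pair, position, alleles)
#' followed by 3 probabilities per sample for allele-B copy number 0/1/2;
#' allele B is taken as the effect allele. The SAMPLE file uses the
#' two-header-row convention (`ID_1 ID_2 missing ...` then a type row).
#'
#' @param gen_path Path to the GEN file (optionally gzipped).
#' @param sample_path Path to the SAMPLE file; `NULL` to read genotypes only.
#' @param chrom Chromosome label to use when the GEN file's first column
#'   holds a marker id rather than a chromosome; by default column 1 is used.
#' @return A list with elements `genotypes` (a [gpm()]) and `phenotypes`
#'   (a [phenotype_table()] or `NULL`).
#' @export
read_gen <- function(gen_path, sample_path = NULL, chrom = NULL) {
  con <- open_maybe_gz(gen_path); on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GEN file: ", gen_path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  n <- (nf[1] - 5L) / 3L
  if (n != floor(n) || n < 1)
    stop(sprintf("GEN parse error at line 1: %d fields is not 5 + 3*N", nf[1]))
  bad <- which(nf != nf[1])
  if (length(bad))
    stop(sprintf("GEN parse error at line %d: expected %d fields, found %d",
                 bad[1], nf[1], nf[bad[1]]))
  m <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  probs_num <- matrix(as.numeric(m[, -(1:5), drop = FALSE]), nrow = nrow(m))
  if (anyNA(probs_num)) stop("GEN parse error: non-numeric probability")
  if (any(probs_num < 0))
    stop(sprintf("GEN parse error at line %d: negative probability",
                 which(apply(probs_num < 0, 1, any))[1]))
  vk <- variant_keys(chrom = if (is.null(chrom)) m[, 1] else chrom,
                     pos = as.integer(m[, 3]), id = m[, 2],
                     ref_allele = m[, 4], eff_allele = m[, 5])
  ## GEN row-major: per variant, (p0,p1,p2) blocks per sample
  probs <- array(NA_real_, c(n, nrow(m), 3))
  for (k in 1:3) probs[, , k] <- t(probs_num[, seq(k, 3 * n, by = 3), drop = FALSE])
  pheno <- NULL
  samples <- sprintf("sample_%d", seq_len(n))
  if (!is.null(sample_path)) {
    pheno <- read_sample_file(sample_path)
    if (nrow(pheno) != n)
      stop(sprintf("SAMPLE file has %d samples but GEN file has %d", nrow(pheno), n))
    samples <- pheno$sample_id
  }
  list(genotypes = gpm(vk, samples, probs), phenotypes = pheno)
}

#' Read an Oxford SAMPLE file
#'
#' @param path SAMPLE file path. Recognised columns: `ID_1/ID_2`, `sex`,
#'   `age`, a binary phenotype column (type `B`, named `pheno` or `status`),
#'   and continuous covariates (type `C`).
#' @return A [phenotype_table()].
#' @export
read_sample_file <- function(path) {
  con <- open_maybe_gz(path); on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  types <- strsplit(trimws(lines[2]), "[ \t]+")[[1]]
  body <- do.call(rbind, strsplit(trimws(lines[-(1:2)]), "[ \t]+"))
  df <- as.data.frame(body, stringsAsFactors = FALSE)
  names(df) <- hdr
  num <- function(v) { v[v %in% c("NA", "-9", ".")] <- NA; as.numeric(v) }
  status_col <- hdr[types == "B"][1]
  if (is.na(status_col)) stop("SAMPLE file has no binary phenotype column")
  cov_cols <- setdiff(hdr[types %in% c("C", "P")], c("age"))
  covs <- if (length(cov_cols)) lapply(df[cov_cols], num) else NULL
  phenotype_table(sample_id = df$ID_1,
                  status = num(df[[status_col]]),
                  sex = if ("sex" %in% hdr) num(df$sex) else NA_integer_,
                  age = if ("age" %in% hdr) num(df$age) else NA_real_,
                  covariates = if (length(cov_cols)) as.data.frame(covs) else NULL)
}

#' Write a GEN + SAMPLE file pair
#'
#' Inverse of [read_gen()]; probabilities are written with 6 decimals so
#' a write/read round trip reproduces the matrix to that precision.
#'
#' @param x A [gpm()].
#' @param gen_path Output GEN path.
#' @param pheno Optional [phenotype_table()] aligned to `x`.
#' @param sample_path Output SAMPLE path (required when `pheno` given).
#' @return Invisibly, `gen_path`.
#' @export
write_gen <- function(x, gen_path, pheno = NULL, sample_path = NULL) {
  nv <- n_variants(x); ns <- n_samples(x)
  con <- file(gen_path, "wt"); on.exit(close(con))
  for (j in seq_len(nv)) {
    tri <- x$probs[, j, , drop = FALSE]   # ns x 1 x 3
    flat <- as.vector(t(matrix(tri, ns, 3)))  # p0,p1,p2 per sample
    flat_chr <- ifelse(is.na(flat), "0", sprintf("%.6f", flat))
    v <- x$variants[j, ]
    writeLines(paste(c(v$chrom, v$id, v$pos, v$ref_allele, v$eff_allele, flat_chr),
                     collapse = " "), con)
  }
  if (!is.null(pheno)) {
    if (is.null(sample_path)) stop("sample_path required when writing phenotypes")
    write_sample_file(pheno, sample_path)
  }
  invisible(gen_path)
}

#' Write an Oxford SAMPLE file
#' @param pheno A [phenotype_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_file <- function(pheno, path) {
  cn <- attr(pheno, "covariate_names")
  hdr <- c("ID_1", "ID_2", "missing", "sex", "age", cn, "pheno")
  types <- c("0", "0", "0", "D", "C", rep("C", length(cn)), "B")
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(paste(hdr, collapse = " "), con)
  writeLines(paste(types, collapse = " "), con)
  fmt <- function(v) ifelse(is.na(v), "NA", format(v, trim = TRUE, digits = 10, scientific = FALSE))
  body <- cbind(pheno$sample_id, pheno$sample_id, "0", fmt(pheno$sex), fmt(pheno$age))
  for (nm in cn) body <- cbind(body, fmt(pheno[[nm]]))
  body <- cbind(body, fmt(pheno$status))
  writeLines(apply(body, 1, paste, collapse = " "), con)
  invisible(path)
}

## ---- VCF with GP / DS -------------------------------------------------------

#' Read genotype probabilities from a VCF with GP or DS FORMAT fields
#'
#' Biallelic records only; the ALT allele is the effect allele. GP triples
#' are taken directly; a dosage DS `d` is expanded to the minimal-variance
#' triple consistent with it: `(1-d, d, 0)` for `d <= 1`, `(0, 2-d, d-1)`
#' otherwise. Multiallelic records and records lacking both GP and DS are
#' skipped with a warning.
#'
#' @param vcf_path Path to a VCF 4.x file (optionally gzipped).
#' @return A [gpm()].
#' @export
read_vcf_dosage <- function(vcf_path) {
  con <- open_maybe_gz(vcf_path); on.exit(close(con))
  lines <- readLines(con)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("not a VCF: missing #CHROM header")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  vlist <- list(); plist <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    if (grepl(",", f[5])) { warning("skipping multiallelic record at ", f[1], ":", f[2]); next }
    fmt <- strsplit(f[9], ":")[[1]]
    gp_i <- match("GP", fmt); ds_i <- match("DS", fmt)
    if (is.na(gp_i) && is.na(ds_i)) { warning("skipping record without GP/DS at ", f[1], ":", f[2]); next }
    cells <- strsplit(f[-(1:9)], ":")
    tri <- matrix(NA_real_, length(samples), 3)
    for (s in seq_along(cells)) {
      cell <- cells[[s]]
      if (!is.na(gp_i) && length(cell) >= gp_i && !cell[gp_i] %in% c(".", "")) {
        tri[s, ] <- as.numeric(strsplit(cell[gp_i], ",")[[1]])
      } else if (!is.na(ds_i) && length(cell) >= ds_i && !cell[ds_i] %in% c(".", "")) {
        d <- as.numeric(cell[ds_i])
        tri[s, ] <- if (d <= 1) c(1 - d, d, 0) else c(0, 2 - d, d - 1)
      }
    }
    vlist[[length(vlist) + 1L]] <- data.frame(chrom = sub("^chr", "", f[1]),
                                              pos = as.integer(f[2]), id = f[3],
                                              ref_allele = f[4], eff_allele = f[5],
                                              stringsAsFactors = FALSE)
    plist[[length(plist) + 1L]] <- tri
  }
  if (!length(vlist)) stop("no usable records in ", vcf_path)
  vk <- do.call(rbind, vlist)
  probs <- array(NA_real_, c(length(samples), nrow(vk), 3))
  for (j in seq_along(plist)) probs[, j, ] <- plist[[j]]
  gpm(variant_keys(vk$chrom, vk$pos, vk$id, vk$ref_allele, vk$eff_allele),
      samples, probs)
}

## ---- summary statistics TSV -------------------------------------------------

assoc_value_cols <- c("beta", "se", "or", "ci_lo", "ci_hi",
                      "beta_het", "se_het", "or_het", "ci_lo_het", "ci_hi_het",
                      "beta_hom", "se_hom", "or_hom", "ci_lo_hom", "ci_hi_hom",
                      "p")
assoc_shared_cols <- c("chrom", "pos", "id", "ref_allele", "eff_allele",
                       "maf", "info", "panel", "n_cases", "n_controls",
                       "alt_hom_cases", "hwe_controls_p")

#' Write association records to a summary-statistics TSV
#'
#' One row per variant, one fixed column block per inheritance model
#' (`<model>_beta`, `<model>_se`, `<model>_or`, `<model>_ci_lo`,
#' `<model>_ci_hi`, `<model>_p`, plus het/hom blocks for the genotypic
#' model). Rows are sorted by `(chrom, pos)`; missing values are written
#' as `NA`.
#'
#' @param records Long-format association records (see [run_association()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(records, path) {
  if (!nrow(records)) stop("no records to write")
  wide <- records_to_wide(records)
  ord <- order(chrom_rank(wide$chrom), wide$pos)
  wide <- wide[ord, , drop = FALSE]
  num <- vapply(wide, is.numeric, TRUE)
  for (nm in names(wide)[num]) wide[[nm]] <- format_num(wide[[nm]])
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = NA_TOKEN)
  invisible(path)
}

format_num <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.10g", x))

chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.integer(chrom))
  r[chrom %in% "X"] <- 23L
  r
}

records_to_wide <- function(records) {
  key <- do.call(paste, c(records[assoc_shared_cols], sep = "\r"))
  first <- !duplicated(key)
  wide <- records[first, assoc_shared_cols, drop = FALSE]
  rownames(wide) <- NULL
  idx <- match(key, key[first])
  for (m in MODELS) {
    cols <- if (m == "genotypic")
      c("beta_het", "se_het", "or_het", "ci_lo_het", "ci_hi_het",
        "beta_hom", "se_hom", "or_hom", "ci_lo_hom", "ci_hi_hom", "p")
    else c("beta", "se", "or", "ci_lo", "ci_hi", "p")
    sel <- records$model == m
    for (cc in cols) {
      col <- rep(NA_real_, nrow(wide))
      col[idx[sel]] <- records[[cc]][sel]
      wide[[paste0(m, "_", cc)]] <- col
    }
  }
  wide
}

#' Read a summary-statistics TSV written by [write_summary_stats()]
#'
#' @param path Input path.
#' @return Long-format association records: one row per variant and model
#'   actually present (a model whose columns are all `NA` for a variant is
#'   not emitted).
#' @export
read_summary_stats <- function(path) {
  wide <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                     na.strings = NA_TOKEN, colClasses = NA)
  wide$chrom <- as.character(wide$chrom)
  out <- list()
  for (m in MODELS) {
    cols <- if (m == "genotypic")
      c("beta_het", "se_het", "or_het", "ci_lo_het", "ci_hi_het",
        "beta_hom", "se_hom", "or_hom", "ci_lo_hom", "ci_hi_hom", "p")
    else c("beta", "se", "or", "ci_lo", "ci_hi", "p")
    sub <- wide[, paste0(m, "_", cols), drop = FALSE]
    names(sub) <- cols
    present <- rowSums(!is.na(sub)) > 0
    if (!any(present)) next
    rec <- cbind(wide[present, assoc_shared_cols, drop = FALSE],
                 model = m, empty_assoc_values(sum(present)))
    for (cc in cols) rec[[cc]] <- sub[[cc]][present]
    out[[m]] <- rec
  }
  res <- do.call(rbind, out)
  res <- res[order(chrom_rank(res$chrom), res$pos, match(res$model, MODELS)), ]
  rownames(res) <- NULL
  res[, c(assoc_shared_cols, "model", assoc_value_cols)]
}

empty_assoc_values <- function(n = 0) {
  as.data.frame(setNames(lapply(assoc_value_cols, function(x) rep(NA_real_, n)),
                         assoc_value_cols))
}
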