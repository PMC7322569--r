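## GWAS-side quality control and per-SNP association.

#' Variant quality control
#'
#' Removes variants by MAF threshold, imputation INFO threshold, region
#' exclusion (e.g. the extended MHC) and chromosome exclusion.  Thresholds
#' are pass-if-greater-or-equal (a variant with MAF exactly `maf_min` is
#' retained).  Variants with no INFO value pass the INFO rule.
#'
#' @param dataset a `genotype_dataset`.
#' @param maf_min minimum minor-allele frequency, in \[0, 0.5\].
#' @param info_min minimum imputation INFO, in \[0, 1\].
#' @param info optional per-variant INFO vector aligned with the variant
#'   table (genotyped data has none).
#' @param exclude_regions list of `c(chrom, start_bp, end_bp)` triples,
#'   inclusive 1-based coordinates.
#' @param exclude_chroms chromosome labels to drop wholesale (e.g. `"X"`).
#' @return list: `dataset` (filtered) and `report` (class `qc_report`)
#'   itemizing removals per rule (a variant can fail several rules; it is
#'   counted under each, and `n_removed` counts it once).
#' @export
variant_qc <- function(dataset, maf_min = 0, info_min = 0, info = NULL,
                       exclude_regions = list(), exclude_chroms = character()) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, info_min >= 0, info_min <= 1)
  bim <- dataset$bim
  m <- nrow(bim)
  f <- allele1_freq(dataset)
  maf <- pmin(f, 1 - f)
  fail_maf <- !is.na(maf) & maf < maf_min
  fail_maf[is.na(maf)] <- maf_min > 0          # all-missing variants fail
  fail_info <- if (is.null(info)) rep(FALSE, m) else
    (!is.na(info) & info < info_min)
  fail_region <- rep(FALSE, m)
  for (rg in exclude_regions) {
    fail_region <- fail_region |
      (bim$chrom == as.character(rg[[1]]) &
         bim$pos >= as.numeric(rg[[2]]) & bim$pos <= as.numeric(rg[[3]]))
  }
  fail_chrom <- bim$chrom %in% as.character(exclude_chroms)
  fail <- fail_maf | fail_info | fail_region | fail_chrom
  report <- structure(list(
    n_input = m,
    n_removed = sum(fail),
    n_retained = m - sum(fail),
    removed_maf = sum(fail_maf),
    removed_info = sum(fail_info),
    removed_region = sum(fail_region),
    removed_chrom = sum(fail_chrom),
    thresholds = list(maf_min = maf_min, info_min = info_min,
                      exclude_regions = exclude_regions,
                      exclude_chroms = exclude_chroms)),
    class = "qc_report")
  out <- if (any(fail)) subset_dataset(dataset, variants = !fail) else dataset
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$n_input, " variants in; removed ", x$n_removed,
      " (MAF ", x$removed_maf, ", INFO ", x$removed_info, ", region ",
      x$removed_region, ", chrom ", x$removed_chrom, "); retained ",
      x$n_retained, "\n", sep = "")
  invisible(x)
}

#' Relatedness filtering by method-of-moments IBD
#'
#' Estimates PI_HAT (proportion of the genome shared identical-by-descent)
#' for every sample pair from observed identity-by-state counts against
#' their expectations given allele frequencies (the PLINK `--genome`
#' moment estimator, without its finite-sample frequency corrections).
#' For each pair with `PI_HAT > pihat_max`, the member with the higher
#' genotype missingness is removed (ties: the later sample).
#'
#' @param dataset a `genotype_dataset`; use autosomal common variants.
#' @param pihat_max retention threshold, conventionally 0.125
#'   (third-degree relatives).
#' @param maf_min variants below this MAF are excluded from estimation.
#' @return list: `keep` (logical per sample), `pairs` (data.frame of
#'   flagged pairs with `pihat`), `pihat` (full symmetric matrix).
#' @export
relatedness_filter <- function(dataset, pihat_max = 0.125, maf_min = 0.01) {
  g <- dataset$geno
  n <- nrow(g)
  if (n < 2) stop("need at least two samples")
  f <- allele1_freq(dataset)
  use <- !is.na(f) & pmin(f, 1 - f) > maf_min
  if (sum(use) < 50)
    warning("only ", sum(use), " usable variants; IBD estimates unstable")
  g <- g[, use, drop = FALSE]
  p <- f[use]; q <- 1 - p

  ## expected IBS-class masses given IBD state, summed over variants
  e0_z0 <- sum(2 * p^2 * q^2)
  e1_z0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e1_z1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_z0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e2_z1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)

  a0 <- (!is.na(g) & g == 0L) + 0   # indicator matrices, n x m
  a1 <- (!is.na(g) & g == 1L) + 0
  a2 <- (!is.na(g) & g == 2L) + 0
  nonmiss <- a0 + a1 + a2
  ibs0 <- a0 %*% t(a2); ibs0 <- ibs0 + t(ibs0)
  ibs2 <- a0 %*% t(a0) + a1 %*% t(a1) + a2 %*% t(a2)
  npair <- nonmiss %*% t(nonmiss > 0)           # loci non-missing in both
  npair <- pmin(npair, t(npair))
  ibs1 <- npair - ibs0 - ibs2
  scale <- npair / sum(use)                     # per-pair completeness

  z0 <- ibs0 / (e0_z0 * scale)
  z1 <- (ibs1 - z0 * e1_z0 * scale) / (e1_z1 * scale)
  z2 <- (ibs2 - z0 * e2_z0 * scale - z1 * e2_z1 * scale) / scale
  z2 <- z2 / sum(use)
  pihat <- z2 + z1 / 2
  pihat <- pmin(pmax(pihat, 0), 1)
  diag(pihat) <- 1
  dimnames(pihat) <- list(dataset$fam$iid, dataset$fam$iid)

  flagged <- which(upper.tri(pihat) & pihat > pihat_max, arr.ind = TRUE)
  miss_rate <- rowMeans(is.na(dataset$geno))
  keep <- rep(TRUE, n)
  if (nrow(flagged)) {
    ord <- order(-pihat[flagged])
    for (k in ord) {
      i <- flagged[k, 1]; j <- flagged[k, 2]
      if (!keep[i] || !keep[j]) next
      drop <- if (miss_rate[j] >= miss_rate[i]) j else i
      keep[drop] <- FALSE
    }
  }
  pairs <- data.frame(iid1 = dataset$fam$iid[flagged[, 1]],
                      iid2 = dataset$fam$iid[flagged[, 2]],
                      pihat = pihat[flagged])
  list(keep = keep, pairs = pairs, pihat = pihat)
}

#' Principal components of the genotype matrix
#'
#' Dosages are mean-centered and scaled by `sqrt(2 p (1 - p))` with missing
#' values imputed to the variant mean; the top-`k` eigenvectors of the
#' sample covariance are returned.  Sign convention: each component's
#' largest-magnitude sample coordinate is positive.
#'
#' @param dataset a `genotype_dataset`.
#' @param k number of components.
#' @return matrix `n_samples x k` of PC coordinates (columns `PC1`...).
#' @export
compute_pcs <- function(dataset, k) {
  g <- dataset$geno
  n <- nrow(g); m <- ncol(g)
  if (k < 1 || k > min(n, m)) stop("k must be in [1, min(n_samples, n_snps)]")
  f <- allele1_freq(dataset)
  mu <- 2 * f
  sdv <- sqrt(2 * f * (1 - f))
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  x <- sweep(g, 2, mu)
  x[is.na(x)] <- 0                      # mean imputation after centering
  x <- sweep(x, 2, sdv, "/")
  ## eigen-decompose on the smaller dimension
  if (n <= m) {
    ev <- eigen(tcrossprod(x) / m, symmetric = TRUE)
    pcs <- ev$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(ev$values[seq_len(k)], 0)), k)
  } else {
    ev <- eigen(crossprod(x) / m, symmetric = TRUE)
    pcs <- x %*% ev$vectors[, seq_len(k), drop = FALSE] / sqrt(m)
  }
  for (j in seq_len(k)) {
    i <- which.max(abs(pcs[, j]))
    if (length(i) && pcs[i, j] < 0) pcs[, j] <- -pcs[, j]
  }
  colnames(pcs) <- paste0("PC", seq_len(k))
  rownames(pcs) <- dataset$fam$iid
  pcs
}

#' Per-SNP association tests
#'
#' Tests each variant against a binary outcome.  The effect allele is the
#' dataset's allele1; `beta` is the log odds ratio per allele-1 copy.
#' Available tests: `logistic_wald` (logistic regression Wald test,
#' supports covariates), `allelic_chisq` (Pearson chi-square on the
#' 2 x 2N allele table; beta = Woolf log allelic OR), and `trend_1df`
#' (1-df Cochran-Armitage; beta/SE from the allelic table, P from the
#' trend statistic).  Monomorphic variants are flagged and not tested.
#'
#' @param dataset a `genotype_dataset`.
#' @param outcome binary 0/1 vector, one per sample.
#' @param covariates optional numeric matrix (logistic test only).
#' @param test one of `"logistic_wald"`, `"allelic_chisq"`, `"trend_1df"`.
#' @return An `assoc_table` data.frame (columns as [load_summary_stats()]),
#'   plus a `tested` logical column; untested variants carry `NA` beta.
#' @export
snp_association <- function(dataset, outcome,
                            covariates = NULL,
                            test = c("logistic_wald", "allelic_chisq",
                                     "trend_1df")) {
  test <- match.arg(test)
  g <- dataset$geno
  n <- nrow(g); m <- ncol(g)
  outcome <- as.numeric(outcome)
  stopifnot(length(outcome) == n, all(outcome %in% c(0, 1)))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (test != "logistic_wald")
      stop("covariates are supported for the logistic test only")
  }

  f <- allele1_freq(dataset)
  mono <- !is.finite(f) | f <= 0 | f >= 1
  beta <- se <- z <- p <- rep(NA_real_, m)

  if (test %in% c("allelic_chisq", "trend_1df")) {
    case <- outcome == 1
    ## column sums per stratum; subsetting keeps peak memory at one
    ## stratum-sized copy rather than a full-matrix logical mask
    gc_ <- g[case, , drop = FALSE]
    n1 <- nrow(gc_) - colSums(is.na(gc_))       # non-missing cases
    a <- colSums(gc_, na.rm = TRUE)             # A1 alleles in cases
    rm(gc_)
    gk <- g[!case, , drop = FALSE]
    n0 <- nrow(gk) - colSums(is.na(gk))
    c_ <- colSums(gk, na.rm = TRUE)             # A1 alleles in controls
    rm(gk)
    nvec <- n1 + n0
    b <- 2 * n1 - a
    d <- 2 * n0 - c_
    ok <- !mono & n1 > 0 & n0 > 0
    beta[ok] <- log((a[ok] * d[ok]) / (b[ok] * c_[ok]))
    se[ok] <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c_[ok] + 1 / d[ok])
    z[ok] <- beta[ok] / se[ok]
    if (test == "allelic_chisq") {
      tot <- 2 * (n1 + n0)
      pr <- (a + c_) / tot; pc1 <- 2 * n1 / tot
      e_a <- tot * pr * pc1; e_b <- tot * (1 - pr) * pc1
      e_c <- tot * pr * (1 - pc1); e_d <- tot * (1 - pr) * (1 - pc1)
      chi <- (a - e_a)^2 / e_a + (b - e_b)^2 / e_b +
        (c_ - e_c)^2 / e_c + (d - e_d)^2 / e_d
      p[ok] <- pchisq(chi[ok], 1, lower.tail = FALSE)
    } else {
      ## Cochran-Armitage with weights 0/1/2 == N * cor(g, y)^2
      y <- outcome
      n_ok <- nvec
      sg <- colSums(g, na.rm = TRUE)
      sgy <- colSums(g * y, na.rm = TRUE)
      sg2 <- colSums(g * g, na.rm = TRUE)
      sy_v <- n1                                 # y over non-missing rows
      num <- sgy - sg * sy_v / n_ok
      den <- sqrt((sg2 - sg^2 / n_ok) * (sy_v - sy_v^2 / n_ok))
      r <- num / den
      chi <- n_ok * r^2
      p[ok] <- pchisq(chi[ok], 1, lower.tail = FALSE)
    }
  } else {
    nvec <- colSums(!is.na(g))
    for (j in seq_len(m)) {
      if (mono[j]) next
      gj <- g[, j]
      okr <- !is.na(gj)
      dat <- data.frame(y = outcome[okr], g = gj[okr])
      xm <- if (is.null(covariates)) dat else
        cbind(dat, as.data.frame(covariates[okr, , drop = FALSE]))
      fit <- tryCatch(
        suppressWarnings(glm(y ~ ., data = xm, family = binomial())),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      cf <- summary(fit)$coefficients
      if (!"g" %in% rownames(cf)) next
      if (abs(cf["g", 1]) > 10) next            # separation: flag, not report
      beta[j] <- cf["g", 1]; se[j] <- cf["g", 2]
      z[j] <- beta[j] / se[j]
      p[j] <- 2 * pnorm(-abs(z[j]))
    }
  }

  out <- data.frame(id = dataset$bim$id, chrom = dataset$bim$chrom,
                    pos = dataset$bim$pos, ea = dataset$bim$a1,
                    oa = dataset$bim$a2, beta = beta, se = se, z = z,
                    p = p, n = nvec, info = NA_real_, eaf = f,
                    tested = is.finite(beta) & is.finite(p),
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Genomic inflation factor and QQ pairs
#'
#' `lambda = median(Z^2) / 0.4549364` (the median of a 1-df chi-square);
#' also returns expected/observed `-log10 P` pairs for a QQ plot.
#'
#' @param assoc an `assoc_table` (rows with missing Z are ignored).
#' @return list of class `inflation_result`: `lambda`, `n_tests`, `qq`
#'   (data.frame `expected`, `observed`).
#' @export
genomic_inflation <- function(assoc) {
  z2 <- assoc$z[is.finite(assoc$z)]^2
  if (!length(z2)) stop("no tested SNPs")
  lambda <- median(z2) / qchisq(0.5, 1)
  pv <- sort(assoc$p[is.finite(assoc$p)])
  k <- length(pv)
  qq <- data.frame(expected = -log10((seq_len(k) - 0.5) / k),
                   observed = -log10(pv))
  structure(list(lambda = lambda, n_tests = length(z2), qq = qq),
            class = "inflation_result")
}

#' @export
print.inflation_result <- function(x, ...) {
  cat("<inflation_result> lambda = ", format(x$lambda, digits = 4),
      " over ", x$n_tests, " tests\n", sep = "")
  invisible(x)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Harmonizes effect alleles across tables (sign flip when effect/other
#' alleles are swapped, strand complement when needed; strand-ambiguous
#' A/T / C/G mismatches dropped), then combines with inverse-variance
#' weights `w = 1/SE^2`.  SNPs present in a single table are carried
#' through flagged `single_study`.
#'
#' @param ... two or more `assoc_table` data.frames (a single table is
#'   returned unchanged); or a list of them.
#' @return An `assoc_table` with columns `n_studies` and `single_study`.
#' @export
meta_fixed_effects <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) &&
      !is.data.frame(tabs[[1]])) tabs <- tabs[[1]]
  stopifnot(length(tabs) >= 1)
  if (length(tabs) == 1) return(tabs[[1]])
  ref <- tabs[[1]]
  acc <- data.frame(id = ref$id, chrom = ref$chrom, pos = ref$pos,
                    ea = ref$ea, oa = ref$oa,
                    sw = ref$beta / ref$se^2, w = 1 / ref$se^2,
                    k = as.integer(is.finite(ref$beta)))
  acc$sw[!is.finite(acc$sw)] <- 0
  acc$w[!is.finite(acc$w)] <- 0
  for (t in tabs[-1]) {
    al <- harmonize_alleles(t$ea, t$oa, acc$ea[match(t$id, acc$id)],
                            acc$oa[match(t$id, acc$id)])
    idx <- match(t$id, acc$id)
    known <- !is.na(idx)
    usable <- known & al$status != "drop"
    sgn <- ifelse(al$flip_effect[usable], -1, 1)
    wi <- 1 / t$se[usable]^2
    swi <- sgn * t$beta[usable] * wi
    add <- is.finite(wi) & is.finite(swi)
    ii <- idx[usable][add]
    acc$sw[ii] <- acc$sw[ii] + swi[add]
    acc$w[ii] <- acc$w[ii] + wi[add]
    acc$k[ii] <- acc$k[ii] + 1L
    ## SNPs absent from the accumulator are appended as their own rows
    new <- !known
    if (any(new)) {
      nt <- t[new, , drop = FALSE]
      acc <- rbind(acc, data.frame(
        id = nt$id, chrom = nt$chrom, pos = nt$pos, ea = nt$ea, oa = nt$oa,
        sw = ifelse(is.finite(nt$beta / nt$se^2), nt$beta / nt$se^2, 0),
        w = ifelse(is.finite(1 / nt$se^2), 1 / nt$se^2, 0),
        k = as.integer(is.finite(nt$beta))))
    }
  }
  beta <- acc$sw / acc$w
  se <- 1 / sqrt(acc$w)
  z <- beta / se
  out <- data.frame(id = acc$id, chrom = acc$chrom, pos = acc$pos,
                    ea = acc$ea, oa = acc$oa, beta = beta, se = se, z = z,
                    p = 2 * pnorm(-abs(z)), n = NA_real_, info = NA_real_,
                    eaf = NA_real_, n_studies = acc$k,
                    single_study = acc$k <= 1L, stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

## Shared allele-harmonization rule (also used by grs_engine and
## polygenic_test).  Aligns (ea, oa) to the reference (ref_ea, ref_oa):
##   status: "keep" (same orientation), "flip" (alleles swapped -> flip
##   effect sign / complement dosage), "drop" (strand-ambiguous or
##   mismatch).  Strand complements are tried before declaring mismatch;
##   A/T and C/G pairs are always dropped when any strand flip would be
##   needed -- and during cross-dataset alignment they are dropped
##   unconditionally by the callers that demand it.
harmonize_alleles <- function(ea, oa, ref_ea, ref_oa,
                              drop_ambiguous = TRUE) {
  comp <- function(x) chartr("ACGT", "TGCA", x)
  n <- length(ea)
  status <- rep("drop", n)
  ambiguous <- !is.na(ea) & !is.na(oa) & oa == comp(ea)
  same <- !is.na(ref_ea) & ea == ref_ea & oa == ref_oa
  swap <- !is.na(ref_ea) & ea == ref_oa & oa == ref_ea
  same_c <- !is.na(ref_ea) & comp(ea) == ref_ea & comp(oa) == ref_oa
  swap_c <- !is.na(ref_ea) & comp(ea) == ref_oa & comp(oa) == ref_ea
  status[same] <- "keep"
  status[!same & swap] <- "flip"
  status[!same & !swap & same_c] <- "keep"
  status[!same & !swap & !same_c & swap_c] <- "flip"
  strand_flipped <- !same & !swap & (same_c | swap_c)
  if (drop_ambiguous) status[ambiguous] <- "drop"
  data.frame(status = status, flip_effect = status == "flip",
             strand_flipped = strand_flipped & status != "drop",
             ambiguous = ambiguous)
}
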