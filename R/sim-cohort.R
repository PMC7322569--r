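## Synthetic case-control cohorts with LD, a polygenic liability
## architecture, a genetic-load-linked severity sub-phenotype, onset age,
## and optional second-ancestry allele-frequency drift.

#' Simulation configuration
#'
#' Defines the generative model for a synthetic cohort: haplotype-copying
#' LD along each chromosome, a liability-threshold disease model with
#' `n_causal` additive SNP effects explaining `h2_liab` of liability
#' variance, a within-case severity (renal) probability that is logistic in
#' standardized genetic load, and an onset age linear in genetic load.
#'
#' @param n_samples samples to draw in population mode.
#' @param n_snps total variants.
#' @param n_causal causal variants (`<= n_snps`).
#' @param maf_range range of per-SNP allele-1 frequencies, in (0, 0.5].
#' @param ld_rho target adjacent-SNP haplotype allele correlation, in
#'   \[0, 1); attained exactly when adjacent frequencies are equal,
#'   truncated to the feasible maximum otherwise.
#' @param h2_liab liability-scale variance explained by causal SNPs.
#' @param prevalence population case fraction, in (0, 1).
#' @param sev_intercept,sev_slope logistic coefficients for
#'   `P(renal | case)`; slope per SD of genetic value among cases.
#' @param onset_mean,onset_slope,onset_sd onset-age model (years); a
#'   negative slope makes high genetic load present earlier.  Onset is
#'   floored at 1 year.
#' @param fst Balding-Nichols drift parameter in \[0, 1); 0 = no drift.
#' @param n_chrom chromosomes the variants are split across (contiguous
#'   blocks; the LD chain restarts at each chromosome).
#' @param spacing_bp distance between adjacent variants, base pairs.
#' @param seed RNG seed; identical (config, seed) gives identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1000, n_snps = 1000, n_causal = 100,
                       maf_range = c(0.05, 0.5), ld_rho = 0.2,
                       h2_liab = 0.3, prevalence = 0.01,
                       sev_intercept = -0.55, sev_slope = 0.5,
                       onset_mean = 33, onset_slope = -3, onset_sd = 12,
                       fst = 0, n_chrom = 22, spacing_bp = 10000,
                       seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              n_causal = as.integer(n_causal), maf_range = as.numeric(maf_range),
              ld_rho = ld_rho, h2_liab = h2_liab, prevalence = prevalence,
              sev_intercept = sev_intercept, sev_slope = sev_slope,
              onset_mean = onset_mean, onset_slope = onset_slope,
              onset_sd = onset_sd, fst = fst,
              n_chrom = as.integer(n_chrom),
              spacing_bp = as.integer(spacing_bp), seed = as.integer(seed))
  chk <- function(ok, field, what)
    if (!ok) stop("invalid sim_config field '", field, "': ", what,
                  call. = FALSE)
  chk(cfg$n_samples >= 0, "n_samples", "must be >= 0")
  chk(cfg$n_snps >= 0, "n_snps", "must be >= 0")
  chk(cfg$n_causal >= 0 && cfg$n_causal <= cfg$n_snps, "n_causal",
      "must be in [0, n_snps]")
  chk(length(cfg$maf_range) == 2 && all(cfg$maf_range > 0) &&
        all(cfg$maf_range <= 0.5) && cfg$maf_range[1] <= cfg$maf_range[2],
      "maf_range", "must be an increasing pair in (0, 0.5]")
  chk(cfg$ld_rho >= 0 && cfg$ld_rho < 1, "ld_rho", "must be in [0, 1)")
  chk(cfg$h2_liab >= 0 && cfg$h2_liab <= 1, "h2_liab", "must be in [0, 1]")
  chk(cfg$prevalence > 0 && cfg$prevalence < 1, "prevalence",
      "must be in (0, 1)")
  chk(cfg$onset_sd >= 0, "onset_sd", "must be >= 0")
  chk(cfg$fst >= 0 && cfg$fst < 1, "fst", "must be in [0, 1)")
  chk(cfg$n_chrom >= 1, "n_chrom", "must be >= 1")
  chk(cfg$spacing_bp >= 1, "spacing_bp", "must be >= 1")
  structure(cfg, class = "sim_config")
}

## deterministic per-stage seed derived from the master seed (kept < 2^31)
stage_seed <- function(seed, label) {
  h <- 5381
  for (ch in utf8ToInt(label)) h <- (h * 33 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 97 + h) %% 2147483647)
}

## Variant panel: frequencies, causal effects, map, and chain transitions.
## When `panel` (from a previous cohort) is supplied, its map and effects
## are reused and only ancestry drift is re-drawn, so two cohorts share
## variant ids and causal architecture.
build_panel <- function(config, panel = NULL) {
  m <- config$n_snps
  if (is.null(panel)) {
    p_anc <- runif(m, config$maf_range[1], config$maf_range[2])
    causal <- sort(sample.int(m, config$n_causal))
    beta <- numeric(m)
    if (config$n_causal > 0) {
      b <- rnorm(config$n_causal)
      v <- sum(2 * p_anc[causal] * (1 - p_anc[causal]) * b^2)
      if (v > 0) b <- b * sqrt(config$h2_liab / v)
      beta[causal] <- b
    }
    ## contiguous chromosome blocks, evenly spaced positions
    chrom_sizes <- diff(round(seq(0, m, length.out = config$n_chrom + 1)))
    chrom <- rep(seq_len(config$n_chrom), chrom_sizes)
    pos <- unlist(lapply(chrom_sizes, function(k)
      seq_len(k) * config$spacing_bp), use.names = FALSE)
    ## non-ambiguous allele pairs only (emulates post-QC array content
    ## where strand-ambiguous A/T and C/G SNPs were already excluded)
    pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"), ncol = 2,
                    byrow = TRUE)
    pick <- sample.int(4, m, replace = TRUE)
    bim <- data.frame(chrom = as.character(chrom),
                      id = sprintf("snp%06d", seq_len(m)),
                      pos = as.integer(pos),
                      a1 = pairs[pick, 1], a2 = pairs[pick, 2])
    chrom_start <- c(TRUE, chrom[-1] != chrom[-m])[seq_len(max(m, 0))]
    if (m == 0) chrom_start <- logical(0)
  } else {
    p_anc <- panel$p_anc; beta <- panel$beta; causal <- panel$causal
    bim <- panel$bim; chrom_start <- panel$chrom_start
  }
  p <- p_anc
  if (config$fst > 0) p <- drift_population(p_anc, config$fst)
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  tr <- chain_transitions(p, config$ld_rho, chrom_start)
  list(p_anc = p_anc, p = p, beta = beta, causal = causal, bim = bim,
       chrom_start = chrom_start, t1 = tr$t1, t0 = tr$t0)
}

## Transition probabilities of the binary chain: marginals preserved
## exactly; correlation truncated to the feasible maximum per pair.
chain_transitions <- function(p, rho, chrom_start) {
  m <- length(p)
  t1 <- p; t0 <- p
  if (m > 1 && rho > 0) {
    q <- c(NA, p[-m])                       # previous SNP's frequency
    cov_max <- pmin(q * (1 - p), p * (1 - q))
    cov <- pmin(rho * sqrt(p * (1 - p) * q * (1 - q)), cov_max)
    t1i <- p + cov / q
    t0i <- p - cov / (1 - q)
    use <- !chrom_start
    t1[use] <- t1i[use]
    t0[use] <- t0i[use]
  }
  list(t1 = pmin(pmax(t1, 0), 1), t0 = pmin(pmax(t0, 0), 1))
}

#' Simulate genotypes for a population cohort
#'
#' Draws per-SNP allele frequencies (with optional Balding-Nichols drift),
#' causal effects rescaled so the causal SNPs explain `h2_liab` of
#' liability variance under linkage equilibrium, and `n_samples` diploid
#' genotypes from the haplotype-copying chain.
#'
#' @param config a [sim_config()].
#' @param panel optional `$panel` of a previous [grs_sim] to reuse its map
#'   and causal architecture (cross-cohort / cross-ancestry designs).
#' @return Object of class `grs_sim`: `$dataset` ([genotype_dataset()]),
#'   `$truth` (per-sample `G`; per-SNP `p_anc`, `p`, `beta_true`),
#'   `$panel`, `$config`.
#' @export
simulate_genotypes <- function(config, panel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genotypes"))
  pan <- build_panel(config, panel)
  n <- config$n_samples
  sim <- sim_population_cpp(n, pan$p, pan$t1, pan$t0, pan$chrom_start,
                            pan$beta)
  fam <- data.frame(fid = sprintf("F%05d", seq_len(n)),
                    iid = sprintf("S%05d", seq_len(n)),
                    sex = ifelse(runif(n) < 0.9, 2L, 1L),
                    pheno = rep(-9, n))
  if (n == 0) fam <- fam[0, ]
  dataset <- genotype_dataset(fam, pan$bim, sim$geno)
  truth <- list(
    samples = data.frame(iid = fam$iid, G = as.numeric(sim$G)),
    snps = data.frame(id = pan$bim$id, p_anc = pan$p_anc, p = pan$p,
                      beta_true = pan$beta,
                      causal = seq_len(config$n_snps) %in% pan$causal))
  structure(list(dataset = dataset, truth = truth, panel = pan,
                 config = config), class = "grs_sim")
}

#' @export
print.grs_sim <- function(x, ...) {
  cat("<grs_sim> ", nrow(x$dataset$fam), " samples x ",
      nrow(x$dataset$bim), " variants", sep = "")
  if (!is.null(x$truth$samples$is_case))
    cat("; ", sum(x$truth$samples$is_case), " cases", sep = "")
  cat("\n")
  invisible(x)
}

#' Assign case/control status under the liability-threshold model
#'
#' Liability `L = G + e` with `Var(e) = 1 - h2_liab`; a sample is a case
#' iff `L` exceeds the standard-normal quantile set by `prevalence`.  With
#' quotas given, the cohort is case-control sampled retrospectively: the
#' simulator keeps drawing population samples (same panel) until the case
#' and control quotas are filled, discarding the surplus stratum.
#'
#' @param sim a `grs_sim` from [simulate_genotypes()].
#' @param n_cases,n_controls optional quotas for retrospective sampling;
#'   when `NULL` the existing population samples are labelled in place.
#' @param max_draw_factor safety multiple of the expected number of
#'   population draws before the quota sampler aborts.
#' @return The augmented `grs_sim` (truth gains `L`, `is_case`; the sample
#'   table's `pheno` becomes 1 control / 2 case).
#' @export
assign_case_control <- function(sim, n_cases = NULL, n_controls = NULL,
                                max_draw_factor = 50) {
  stopifnot(inherits(sim, "grs_sim"))
  config <- sim$config
  set.seed(stage_seed(config$seed, "case_control"))
  err_sd <- sqrt(max(0, 1 - config$h2_liab))
  thresh <- qnorm(1 - config$prevalence)

  if (is.null(n_cases)) {
    n <- nrow(sim$dataset$fam)
    e <- rnorm(n, 0, err_sd)
    L <- sim$truth$samples$G + e
    sim$truth$samples$L <- L
    sim$truth$samples$is_case <- as.integer(L > thresh)
  } else {
    stopifnot(n_cases >= 0, n_controls >= 0)
    pan <- sim$panel
    expected <- n_cases / config$prevalence +
      n_controls / (1 - config$prevalence)
    cc <- sim_case_control_cpp(n_cases, n_controls, pan$p, pan$t1, pan$t0,
                               pan$chrom_start, pan$beta, err_sd, thresh,
                               max(1000, max_draw_factor * expected))
    n <- n_cases + n_controls
    fam <- data.frame(fid = sprintf("F%05d", seq_len(n)),
                      iid = sprintf("S%05d", seq_len(n)),
                      sex = ifelse(runif(n) < 0.9, 2L, 1L),
                      pheno = rep(-9, n))
    sim$dataset <- genotype_dataset(fam, pan$bim, cc$geno)
    sim$truth$samples <- data.frame(iid = fam$iid, G = as.numeric(cc$G),
                                    L = as.numeric(cc$L),
                                    is_case = as.integer(cc$is_case))
    sim$n_population_drawn <- cc$n_drawn
  }
  sim$dataset$fam$pheno <- sim$truth$samples$is_case + 1
  sim
}

#' Assign the severity sub-phenotype and onset age to cases
#'
#' Among cases, `P(renal = 1) = plogis(sev_intercept + sev_slope * G_std)`
#' and `onset = onset_mean + onset_slope * G_std + N(0, onset_sd)`, floored
#' at 1 year, where `G_std` is the genetic value standardized within the
#' case set.  Controls get `NA` for both.
#'
#' @param sim a `grs_sim` with case status assigned.
#' @return The augmented `grs_sim` (truth gains `renal`, `onset`, `G_std`).
#' @export
assign_severity_onset <- function(sim) {
  stopifnot(inherits(sim, "grs_sim"),
            !is.null(sim$truth$samples$is_case))
  config <- sim$config
  set.seed(stage_seed(config$seed, "severity_onset"))
  s <- sim$truth$samples
  case <- s$is_case == 1L
  g_std <- rep(NA_real_, nrow(s))
  if (sum(case) >= 2 && sd(s$G[case]) > 0)
    g_std[case] <- (s$G[case] - mean(s$G[case])) / sd(s$G[case])
  else g_std[case] <- 0
  renal <- rep(NA_integer_, nrow(s))
  onset <- rep(NA_real_, nrow(s))
  if (any(case)) {
    pr <- plogis(config$sev_intercept + config$sev_slope * g_std[case])
    renal[case] <- rbinom(sum(case), 1L, pr)
    onset[case] <- pmax(1, config$onset_mean +
                          config$onset_slope * g_std[case] +
                          rnorm(sum(case), 0, config$onset_sd))
  }
  sim$truth$samples$G_std <- g_std
  sim$truth$samples$renal <- renal
  sim$truth$samples$onset <- onset
  sim
}

#' Simulate a complete case-control cohort
#'
#' Convenience wrapper: [simulate_genotypes()] (panel only when quotas are
#' given), [assign_case_control()] and [assign_severity_onset()] in one
#' deterministic call.
#'
#' @inheritParams simulate_genotypes
#' @inheritParams assign_case_control
#' @return A `grs_sim` with genotypes, case status, severity and onset.
#' @export
simulate_cohort <- function(config, n_cases = NULL, n_controls = NULL,
                            panel = NULL) {
  if (!is.null(n_cases)) {
    ## avoid materializing a throwaway population cohort
    config0 <- config; config0$n_samples <- 0L
    sim <- simulate_genotypes(config0, panel = panel)
    sim$config <- config
  } else {
    sim <- simulate_genotypes(config, panel = panel)
  }
  sim <- assign_case_control(sim, n_cases = n_cases, n_controls = n_controls)
  assign_severity_onset(sim)
}

#' Phenotype table of a simulated cohort
#'
#' @param sim a fully assigned `grs_sim`.
#' @param pop population label for the `POP` column.
#' @return data.frame with columns IID, STATUS, RENAL, ONSET, SEX, POP.
#' @export
sim_phenotypes <- function(sim, pop = "SIM") {
  s <- sim$truth$samples
  data.frame(IID = s$iid, STATUS = s$is_case, RENAL = s$renal,
             ONSET = round(s$onset, 2), SEX = sim$dataset$fam$sex,
             POP = pop)
}

#' Balding-Nichols allele-frequency drift
#'
#' Draws subpopulation frequencies
#' `Beta(p (1 - fst) / fst, (1 - p)(1 - fst) / fst)`, which have mean `p`
#' and variance `fst * p * (1 - p)`.  `fst = 0` returns `p` unchanged.
#'
#' @param p ancestral allele frequencies in (0, 1).
#' @param fst drift parameter in \[0, 1).
#' @param seed optional seed for this draw alone.
#' @return Drifted frequency vector, same length as `p`.
#' @export
drift_population <- function(p, fst, seed = NULL) {
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  stopifnot(all(p > 0 & p < 1))
  if (!is.null(seed)) set.seed(seed)
  if (fst == 0) return(p)
  rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Best attainable AUC for a score explaining part of liability
#'
#' Monte-Carlo estimate of `P(score_case > score_control)` when score and
#' liability are bivariate normal with correlation `sqrt(h2_explained)` and
#' case status is liability above the prevalence threshold.  This is the
#' ceiling any risk score explaining `h2_explained` of liability can reach.
#'
#' @param h2_explained liability variance explained by the score, \[0, 1\].
#' @param prevalence population case fraction.
#' @param n_mc Monte-Carlo sample size.
#' @param seed optional seed.
#' @return AUC estimate in \[0, 1\].
#' @export
attainable_auc <- function(h2_explained, prevalence, n_mc = 1e6,
                           seed = NULL) {
  stopifnot(h2_explained >= 0, h2_explained <= 1,
            prevalence > 0, prevalence < 1)
  if (!is.null(seed)) set.seed(seed)
  l <- rnorm(n_mc)
  s <- sqrt(h2_explained) * l + sqrt(1 - h2_explained) * rnorm(n_mc)
  case <- l > qnorm(1 - prevalence)
  if (!any(case) || all(case))
    stop("Monte-Carlo sample contains a single class; increase n_mc")
  r <- rank(s)
  n1 <- sum(case); n0 <- n_mc - n1
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
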