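## ROC/AUC with DeLong inference, quintile odds ratios, severity/onset
## models, and the case-control power calculator.

## Midrank DeLong structural components for one score vector.
delong_components <- function(scores, labels) {
  case <- labels == 1
  x <- scores[case]; y <- scores[!case]
  n1 <- length(x); n0 <- length(y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r_all <- rank(c(x, y))
  r_x <- rank(x); r_y <- rank(y)
  v10 <- (r_all[seq_len(n1)] - r_x) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_y) / n1
  auc <- (sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, v10 = v10, v01 = v01, n1 = n1, n0 = n0)
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney statistic (ties count one half); its variance
#' comes from the DeLong structural components, and the 95% CI is the
#' normal approximation truncated to \[0, 1\] (degenerate zero-variance
#' cases give a point CI).
#'
#' @param scores numeric predictor.
#' @param labels binary 0/1 outcome (1 = case); both classes required.
#' @param conf confidence level (default 0.95).
#' @return list of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `var_auc`, `n_cases`, `n_controls`, `curve` (data.frame FPR, TPR).
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  dc <- delong_components(scores, labels)
  v <- if (dc$n1 > 1) var(dc$v10) / dc$n1 else 0
  v <- v + if (dc$n0 > 1) var(dc$v01) / dc$n0 else 0
  zq <- qnorm(1 - (1 - conf) / 2)
  ci <- dc$auc + c(-1, 1) * zq * sqrt(v)
  ci <- pmin(pmax(ci, 0), 1)

  ## curve: sweep thresholds from high to low
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab == 1); fp <- cumsum(lab == 0)
  last <- !duplicated(sc, fromLast = TRUE)    # one point per threshold
  curve <- data.frame(fpr = c(0, fp[last] / dc$n0),
                      tpr = c(0, tp[last] / dc$n1))
  structure(list(auc = dc$auc, ci_low = ci[1], ci_high = ci[2],
                 var_auc = v, n_cases = dc$n1, n_controls = dc$n0,
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (95%% CI %.4f-%.4f); %d cases / %d controls\n",
              x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same samples using the
#' DeLong covariance of their structural components.  An AUC difference of
#' exactly zero (e.g. one score a monotone transform of the other) reports
#' `p = 1`.
#'
#' @param scores_a,scores_b two score vectors on the same samples.
#' @param labels binary 0/1 outcome.
#' @return list: `auc_a`, `auc_b`, `diff`, `z`, `p` (two-sided).
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  v_a <- var(da$v10) / da$n1 + var(da$v01) / da$n0
  v_b <- var(db$v10) / db$n1 + var(db$v01) / db$n0
  cv <- cov(da$v10, db$v10) / da$n1 + cov(da$v01, db$v01) / da$n0
  vd <- v_a + v_b - 2 * cv
  d <- da$auc - db$auc
  if (d == 0 || vd <= 0) {
    z <- 0; p <- if (d == 0) 1 else 0
    if (d != 0) z <- sign(d) * Inf
  } else {
    z <- d / sqrt(vd)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = da$auc, auc_b = db$auc, diff = d, z = z, p = p)
}

#' AUC increment of a score over baseline covariates
#'
#' Fits `outcome ~ covariates` and `outcome ~ covariates + score` by
#' logistic regression on the same samples and compares the two fitted
#' probability vectors with the paired DeLong test.
#'
#' @param outcome binary 0/1.
#' @param covariate_matrix numeric matrix or NULL/zero-column for an
#'   intercept-only baseline.
#' @param score numeric score vector.
#' @return list: `delta_auc`, `p`, `auc_full`, `auc_base`.
#' @export
auc_increment_test <- function(outcome, covariate_matrix, score) {
  n <- length(outcome)
  if (is.null(covariate_matrix) || NCOL(covariate_matrix) == 0 ||
      (is.matrix(covariate_matrix) && ncol(covariate_matrix) == 0)) {
    base_df <- data.frame(y = outcome)
  } else {
    cm <- as.matrix(covariate_matrix)
    stopifnot(nrow(cm) == n)
    base_df <- data.frame(y = outcome, cm)
  }
  full_df <- cbind(base_df, .score = score)
  fit_base <- glm(y ~ ., data = base_df, family = binomial())
  fit_full <- glm(y ~ ., data = full_df, family = binomial())
  if (!fit_base$converged || !fit_full$converged)
    stop("logistic fit did not converge")
  dl <- delong_paired_test(fitted(fit_full), fitted(fit_base), outcome)
  list(delta_auc = dl$diff, p = dl$p, auc_full = dl$auc_a,
       auc_base = dl$auc_b)
}

#' Quintile odds ratios of an outcome across score strata
#'
#' Samples are split into `n_groups` near-equal strata by score order
#' (ties resolved by sample order after a stable sort, so tied boundary
#' values fall in the lower stratum).  Each upper stratum is compared with
#' the first by a 2x2 Pearson chi-square; the OR carries a Woolf
#' log-scale 95% CI.  Zero cells get the Haldane-Anscombe +0.5 correction
#' (flagged).
#'
#' @param scores numeric scores.
#' @param outcome binary 0/1.
#' @param n_groups number of strata (default 5, quintiles).
#' @return data.frame of class `quintile_or_table`: `quintile`, `n_pos`,
#'   `n_neg`, `or`, `ci_low`, `ci_high`, `p`, `corrected`; attribute
#'   `tied_boundaries` flags > 1% tied boundary values.
#' @export
quintile_or <- function(scores, outcome, n_groups = 5) {
  n <- length(scores)
  stopifnot(length(outcome) == n, all(outcome %in% c(0, 1)),
            n >= n_groups)
  ord <- order(scores)                        # stable: ties by sample order
  sizes <- rep(n %/% n_groups, n_groups)
  extra <- n %% n_groups
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  q <- integer(n)
  q[ord] <- rep(seq_len(n_groups), sizes)
  bounds <- cumsum(sizes)[-n_groups]
  tied <- sum(scores[ord][bounds] == scores[ord][bounds + 1])
  out <- data.frame(quintile = seq_len(n_groups),
                    n_pos = as.integer(tapply(outcome, q, sum)),
                    n_neg = as.integer(tapply(1 - outcome, q, sum)),
                    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    p = NA_real_, corrected = FALSE)
  out$or[1] <- 1
  for (g in seq_len(n_groups)[-1]) {
    a <- out$n_pos[g]; b <- out$n_neg[g]
    c_ <- out$n_pos[1]; d <- out$n_neg[1]
    corr <- any(c(a, b, c_, d) == 0)
    if (corr) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
    or <- (a * d) / (b * c_)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    tab <- rbind(c(out$n_pos[g], out$n_neg[g]),
                 c(out$n_pos[1], out$n_neg[1]))
    pv <- tryCatch(
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
      error = function(e) NA_real_)
    out$or[g] <- or
    out$ci_low[g] <- exp(log(or) - 1.96 * se)
    out$ci_high[g] <- exp(log(or) + 1.96 * se)
    out$p[g] <- pv
    out$corrected[g] <- corr
  }
  attr(out, "tied_boundaries") <- tied > 0.01 * max(1, n_groups - 1)
  class(out) <- c("quintile_or_table", "data.frame")
  out
}

#' Linear trend of scores over ordered disease levels
#'
#' Regresses the score on the numeric level code (e.g. 0 = healthy
#' control, 1 = case without renal disease, 2 = case with renal disease)
#' and Wald-tests the slope.
#'
#' @param scores numeric scores.
#' @param levels integer level codes; at least two distinct levels.
#' @return list: `slope`, `se`, `t`, `p`, `n`.
#' @export
ordinal_trend_test <- function(scores, levels) {
  stopifnot(length(scores) == length(levels))
  ok <- is.finite(scores) & is.finite(levels)
  if (length(unique(levels[ok])) < 2)
    stop("need at least two distinct levels")
  fit <- lm(scores[ok] ~ levels[ok])
  cf <- summary(fit)$coefficients
  list(slope = cf[2, 1], se = cf[2, 2], t = cf[2, 3], p = cf[2, 4],
       n = sum(ok))
}

#' Two-way ANOVA of the GRS over age-of-onset and renal groups
#'
#' Fits `aov(score ~ age_group * renal_group)` with sequential (type-I)
#' sums of squares in that order.  If any design cell is empty the
#' interaction is omitted and the result flagged.
#'
#' @param scores numeric scores.
#' @param age_group,renal_group binary factors (any two-level coding).
#' @return data.frame: `term`, `df`, `sum_sq`, `f`, `p`; attribute
#'   `interaction_omitted`.
#' @export
two_way_anova_grs <- function(scores, age_group, renal_group) {
  a <- factor(age_group); r <- factor(renal_group)
  stopifnot(nlevels(a) == 2, nlevels(r) == 2,
            length(scores) == length(a), length(scores) == length(r))
  empty_cell <- any(table(a, r) == 0)
  fml <- if (empty_cell) scores ~ a + r else scores ~ a * r
  fit <- aov(fml)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  terms[terms == "a"] <- "age_group"
  terms[terms == "r"] <- "renal_group"
  terms[terms == "a:r"] <- "age_group:renal_group"
  out <- data.frame(term = terms, df = tab$Df, sum_sq = tab$`Sum Sq`,
                    f = tab$`F value`, p = tab$`Pr(>F)`)
  attr(out, "interaction_omitted") <- empty_cell
  out
}

#' General linear-model association with Wald inference
#'
#' Fits a logistic or linear model of `outcome` on the supplied predictors
#' (optionally with interaction terms) and returns the per-term Wald
#' coefficient table.  Errors on rank deficiency naming the collinear
#' terms; logistic separation is flagged, not reported as an estimate.
#'
#' @param outcome numeric (binary for logistic).
#' @param predictors data.frame of predictors.
#' @param family `"logistic"` or `"linear"`.
#' @param interactions character vector of `"x1:x2"` interaction terms.
#' @return data.frame: `term`, `beta`, `se`, `stat`, `p`, `flagged`
#'   (logistic separation).
#' @export
glm_association <- function(outcome, predictors,
                            family = c("logistic", "linear"),
                            interactions = NULL) {
  family <- match.arg(family)
  predictors <- as.data.frame(predictors)
  stopifnot(nrow(predictors) == length(outcome))
  rhs <- c(names(predictors), interactions)
  fml <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  dat <- cbind(.y = outcome, predictors)
  mm <- stats::model.matrix(fml, dat)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  fam <- if (family == "logistic") binomial() else gaussian()
  fit <- suppressWarnings(glm(fml, data = dat, family = fam))
  cf <- summary(fit)$coefficients
  flagged <- family == "logistic" &
    (abs(cf[, 1]) > 10 | any(fitted(fit) > 1 - 1e-8 | fitted(fit) < 1e-8))
  data.frame(term = rownames(cf), beta = cf[, 1], se = cf[, 2],
             stat = cf[, 3], p = cf[, 4],
             flagged = rep(flagged, length.out = nrow(cf)),
             row.names = NULL)
}

#' Case-control power, allelic two-proportion approximation
#'
#' Power of a two-sided allele-count test: with control risk-allele
#' frequency `raf` and per-allele odds ratio `or_allele`, the case
#' frequency is `p1 = raf * OR / (1 + raf (OR - 1))`; allele counts are
#' `2 n_case` and `2 n_control`; power is
#' `Phi((|p1 - p0| - z_{1-alpha/2} SE0) / SE1)` with the pooled-null and
#' alternative standard errors of the frequency difference.
#'
#' @param or_allele per-allele odds ratio (> 0).
#' @param raf control risk-allele frequency, in (0, 1).
#' @param alpha two-sided significance level.
#' @param n_case,n_control sample counts.
#' @return power in \[0, 1\].
#' @export
case_control_power <- function(or_allele, raf, alpha, n_case, n_control) {
  stopifnot(or_allele > 0, raf > 0, raf < 1, alpha > 0, alpha < 1,
            n_case > 0, n_control > 0)
  p0 <- raf
  p1 <- p0 * or_allele / (1 + p0 * (or_allele - 1))
  m1 <- 2 * n_case; m0 <- 2 * n_control
  pbar <- (p1 * m1 + p0 * m0) / (m1 + m0)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / m1 + 1 / m0))
  se1 <- sqrt(p1 * (1 - p1) / m1 + p0 * (1 - p0) / m0)
  z <- qnorm(1 - alpha / 2)
  d <- abs(p1 - p0)
  ## both rejection tails, so the null (OR = 1) returns alpha exactly
  unname(pnorm((d - z * se0) / se1) + pnorm((-d - z * se0) / se1))
}
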