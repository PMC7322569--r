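test_that("AUC equals exhaustive pair enumeration", {
  # 4 pairs: (2>1) + (2<2.5 -> 0) + (3>1) + (3>2.5) = 3/4
  r <- roc_auc(c(2, 3, 1, 2.5), c(1, 1, 0, 0))
  expect_equal(r$auc, 0.75)

  # random instances with ties against the enumeration oracle
  for (s in 1:12) {
    set.seed(600 + s)
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc,
                 exhaustive_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("ROC degenerate and null cases behave", {
  # perfect separation: AUC 1, zero variance, point CI
  r <- roc_auc(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$var_auc, 0)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))

  # shuffled labels: AUC near 1/2
  set.seed(41)
  sc <- rnorm(2000); lb <- sample(rep(c(0, 1), 1000))
  expect_lt(abs(roc_auc(sc, lb)$auc - 0.5), 0.03)

  # one class absent errors
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")

  # curve is monotone from (0,0) to (1,1)
  cv <- roc_auc(rnorm(100), rbinom(100, 1, 0.5))$curve
  expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
  expect_equal(unlist(cv[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(cv[nrow(cv), ]), c(fpr = 1, tpr = 1))
})

test_that("AUC and DeLong CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(42)
  sc <- rnorm(300); lb <- rbinom(300, 1, 0.4)
  sc[lb == 1] <- sc[lb == 1] + 0.8
  mine <- roc_auc(sc, lb)
  ref <- pROC::roc(lb, sc, levels = c(0, 1), direction = "<", quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(mine$ci_low, mine$ci_high), ci[c(1, 3)], tolerance = 1e-9)

  sc2 <- sc + rnorm(300, 0, 0.8)
  dl <- delong_paired_test(sc, sc2, lb)
  ref2 <- pROC::roc(lb, sc2, levels = c(0, 1), direction = "<", quiet = TRUE)
  rt <- pROC::roc.test(ref, ref2, method = "delong", paired = TRUE)
  expect_equal(dl$p, rt$p.value, tolerance = 1e-9)
})

test_that("paired DeLong test handles identity and rank invariance", {
  set.seed(43)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.5)
  expect_equal(delong_paired_test(sc, sc, lb)$p, 1)
  dl <- delong_paired_test(sc, exp(sc), lb)   # monotone transform
  expect_equal(dl$diff, 0)
  expect_equal(dl$p, 1)
})

test_that("paired DeLong p is close to the sign-flip permutation oracle", {
  for (s in 1:6) {
    set.seed(700 + s)
    n <- 30
    lb <- rep(c(0, 1), each = 15)
    base <- rnorm(n) + 0.8 * lb
    sa <- base + rnorm(n, 0, 0.6)
    sb <- base + rnorm(n, 0, 0.6) + 0.15 * lb
    p_mine <- delong_paired_test(sa, sb, lb)$p
    p_perm <- permutation_delong_p(sa, sb, lb, B = 4e4, seed = s)
    expect_lt(abs(p_mine - p_perm), 0.05)
  }
})

test_that("the GRS adds AUC over covariates when truly informative", {
  set.seed(44)
  n <- 2000
  pc <- rnorm(n)
  score <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 * pc + 0.5 * score))
  inc <- auc_increment_test(y, cbind(pc = pc), score)
  expect_gt(inc$delta_auc, 0)
  expect_lt(inc$p, 0.05)

  # a redundant copy of a covariate adds nothing
  inc0 <- auc_increment_test(y, cbind(pc = pc), pc)
  expect_lt(abs(inc0$delta_auc), 1e-6)
  expect_gt(inc0$p, 0.9)

  # empty covariate set reduces to score vs constant
  inc1 <- auc_increment_test(y, NULL, score)
  expect_equal(inc1$auc_base, 0.5)
})

test_that("quintile assignment and odds ratios match hand arithmetic", {
  q <- quintile_or(1:10, rep(c(0, 1), 5))
  expect_equal(as.integer(q$n_pos + q$n_neg), rep(2L, 5))
  expect_equal(q$or[1], 1)

  # constructed 50/50 table: q1 10+/40-, q5 20+/30- -> OR = 8/3
  scores <- seq_len(250)
  outcome <- integer(250)
  outcome[1:10] <- 1L           # q1: first 50 samples, 10 positive
  outcome[201:220] <- 1L        # q5: last 50 samples, 20 positive
  q2 <- quintile_or(scores, outcome)
  expect_equal(q2$n_pos[c(1, 5)], c(10L, 20L))
  expect_equal(q2$or[5], 8 / 3, tolerance = 1e-12)
  # chi-square P from the same 2x2 computed from scratch
  tab <- rbind(c(20, 30), c(10, 40))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(q2$p[5], pchisq(sum((tab - e)^2 / e), 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # zero cell triggers the Haldane-Anscombe correction, flagged
  out0 <- integer(250); out0[201:210] <- 1L
  q3 <- quintile_or(seq_len(250), out0)
  expect_true(q3$corrected[5])
  expect_true(is.finite(q3$or[5]))
})

test_that("null quintile ORs cover 1 at the nominal rate", {
  cover <- 0; total <- 0
  for (s in 1:25) {
    set.seed(800 + s)
    sc <- rnorm(1000); y <- rbinom(1000, 1, 0.3)
    q <- quintile_or(sc, y)
    cover <- cover + sum(q$ci_low[-1] <= 1 & q$ci_high[-1] >= 1)
    total <- total + 4
  }
  expect_gte(cover / total, 0.9)
})

test_that("monotone risk in the score yields increasing quintile ORs", {
  ok <- 0
  for (s in 1:10) {
    set.seed(900 + s)
    sc <- rnorm(3000)
    y <- rbinom(3000, 1, plogis(-1 + 0.5 * sc))
    q <- quintile_or(sc, y)
    if (all(diff(q$or) > -1e-9) || sum(diff(q$or) < 0) <= 1) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("ordinal trend test recovers constructed group means", {
  lev <- rep(0:2, each = 30)
  set.seed(45)
  sc <- 10 + lev + rnorm(90, 0, 0.1)
  tr <- ordinal_trend_test(sc, lev)
  expect_equal(tr$slope, 1, tolerance = 0.05)
  expect_lt(tr$p, 1e-3)
  tr_rev <- ordinal_trend_test(sc, 2 - lev)
  expect_equal(tr_rev$slope, -tr$slope, tolerance = 1e-12)
  expect_error(ordinal_trend_test(sc, rep(1, 90)), "distinct")
})

test_that("two-way ANOVA decomposes additive and interaction structure", {
  # balanced additive means, tiny noise: huge main effects, nil interaction
  set.seed(46)
  d <- expand.grid(age = c("early", "late"), renal = c(0, 1),
                   rep = 1:25)
  mu <- 10 + 2 * (d$age == "late") + 3 * (d$renal == 1)
  sc <- mu + rnorm(nrow(d), 0, 0.2)
  out <- two_way_anova_grs(sc, d$age, d$renal)
  expect_equal(out$term[1:3],
               c("age_group", "renal_group", "age_group:renal_group"))
  expect_gt(out$f[1], 100)
  expect_gt(out$f[2], 100)
  expect_lt(out$f[3], 5)

  # balanced design: order of factors does not change the F values
  out2 <- two_way_anova_grs(sc, d$renal, d$age)
  expect_equal(sort(out$f[1:2]), sort(out2$f[1:2]), tolerance = 1e-9)

  # empty cell: interaction omitted and flagged
  keep <- !(d$age == "late" & d$renal == 1)
  out3 <- two_way_anova_grs(sc[keep], d$age[keep], d$renal[keep])
  expect_true(attr(out3, "interaction_omitted"))
  expect_false("age_group:renal_group" %in% out3$term)
})

test_that("glm_association fits, flags and errors as specified", {
  expect_error(
    glm_association(rbinom(50, 1, 0.5),
                    data.frame(x = rnorm(50), y2 = 1),
                    family = "logistic"),
    "collinear")

  # saturated logistic on a balanced 2x2: beta = ln(ad/bc)
  g <- rep(c(0, 0, 1, 1), c(40, 10, 30, 20))  # a=40 b=10 c=30 d=20
  y <- rep(c(0, 1, 0, 1), c(40, 10, 30, 20))
  fit <- glm_association(y, data.frame(g = g), family = "logistic")
  expect_equal(fit$beta[fit$term == "g"],
               log((40 * 20) / (10 * 30)), tolerance = 1e-6)

  # linear recovery of a known onset slope
  set.seed(47)
  gstd <- rnorm(400)
  onset <- 35 - 1.5 * gstd + rnorm(400, 0, 5)
  f2 <- glm_association(onset, data.frame(gstd = gstd), family = "linear")
  b <- f2[f2$term == "gstd", ]
  expect_lt(abs(b$beta - (-1.5)), 3 * b$se)

  # interactions are honoured
  x1 <- rnorm(200); x2 <- rnorm(200)
  yy <- rbinom(200, 1, plogis(x1 * x2))
  f3 <- glm_association(yy, data.frame(x1 = x1, x2 = x2),
                        family = "logistic", interactions = "x1:x2")
  expect_true("x1:x2" %in% f3$term)
})

test_that("power calculator honours its closed form and monotonicity", {
  # the published renal-GWAS scenario clears 0.8
  p <- case_control_power(1.5, 0.2, 5e-8, 1152, 1949)
  expect_gte(p, 0.8)
  expect_equal(p, 0.87, tolerance = 0.01)

  # null effect: power equals alpha
  expect_equal(case_control_power(1, 0.2, 0.05, 1000, 1000), 0.05,
               tolerance = 1e-9)

  # enormous samples push power to 1
  expect_gt(case_control_power(1.1, 0.2, 5e-8, 1e8, 1e8), 0.999)

  # monotone in OR, n and alpha
  expect_lt(case_control_power(1.2, 0.2, 5e-8, 1152, 1949),
            case_control_power(1.5, 0.2, 5e-8, 1152, 1949))
  expect_lt(case_control_power(1.5, 0.2, 5e-8, 500, 800),
            case_control_power(1.5, 0.2, 5e-8, 1152, 1949))
  expect_lt(case_control_power(1.5, 0.2, 5e-8, 1152, 1949),
            case_control_power(1.5, 0.2, 1e-5, 1152, 1949))
})
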