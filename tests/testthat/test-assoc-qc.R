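test_that("variant_qc applies MAF/INFO/region rules with closed bounds", {
  # 1000 samples; engineer exact frequencies via dosage counts
  n <- 1000
  g <- matrix(0L, n, 10)
  g[1, 1] <- 1L                 # freq 1/2000 = 0.0005 -> fails MAF 0.001
  g[1:2, 2] <- 1L               # freq 0.001 -> exactly at threshold, passes
  g[1, 3] <- 1L                 # fails MAF
  g[1, 4] <- 1L                 # fails MAF
  g[, 5:10] <- rep(rbinom(n, 2, 0.3), 6)
  info <- c(1, 1, 0.5, 1, 0.6, 1, 1, 1, 1, 1)  # SNPs 3 & 5 fail INFO 0.7
  ds <- dataset_from_matrix(g,
                            chrom = c(rep("1", 9), "6"),
                            pos = c(seq_len(9) * 1000L, 30000000L))
  out <- variant_qc(ds, maf_min = 0.001, info_min = 0.7, info = info,
                    exclude_regions = list(c("6", 24e6, 36e6)))
  # 3 fail MAF, 2 fail INFO (1 overlap), 1 in the excluded region -> 5 removed
  expect_equal(out$report$removed_maf, 3L)
  expect_equal(out$report$removed_info, 2L)
  expect_equal(out$report$removed_region, 1L)
  expect_equal(out$report$n_retained, 5L)
  expect_true("v0002" %in% out$dataset$bim$id)   # boundary MAF retained
  expect_false("v0001" %in% out$dataset$bim$id)
  expect_false("v0010" %in% out$dataset$bim$id)  # chr6:30M inside 24-36M
  expect_equal(out$report$n_removed + out$report$n_retained,
               out$report$n_input)

  # idempotence
  again <- variant_qc(out$dataset, maf_min = 0.001)
  expect_equal(again$report$n_removed, 0L)
})

test_that("relatedness filter flags duplicates and parent-offspring", {
  set.seed(77)
  m <- 4000
  p <- runif(m, 0.2, 0.5)
  draw_hap <- function() as.integer(runif(m) < p)
  geno_from <- function(h1, h2) h1 + h2
  # 6 unrelated samples, then: sample 7 = duplicate of 1;
  # sample 8 = child of samples 2 and 3 (one transmitted haplotype each)
  haps <- replicate(12, draw_hap())
  g <- matrix(0L, 8, m)
  for (i in 1:6) g[i, ] <- geno_from(haps[, 2 * i - 1], haps[, 2 * i])
  g[7, ] <- g[1, ]
  g[8, ] <- geno_from(haps[, 3], haps[, 5])   # from parents 2 and 3
  ds <- dataset_from_matrix(g)
  rf <- relatedness_filter(ds, pihat_max = 0.125)
  expect_lt(abs(rf$pihat[1, 7] - 1), 0.05)
  expect_lt(abs(rf$pihat[2, 8] - 0.5), 0.07)
  expect_lt(abs(rf$pihat[3, 8] - 0.5), 0.07)
  # unrelated pairs near zero
  expect_lt(max(abs(rf$pihat[1:6, 1:6][upper.tri(diag(6))])), 0.05)
  # one of each flagged pair removed
  expect_false(all(rf$keep[c(1, 7)]))
  expect_false(rf$keep[8] && all(rf$keep[2:3]))
})

test_that("principal components recover population structure", {
  cfg_a <- sim_config(n_samples = 400, n_snps = 600, n_causal = 0,
                      fst = 0.1, seed = 81)
  sim_a <- simulate_genotypes(cfg_a)
  cfg_b <- sim_config(n_samples = 400, n_snps = 600, n_causal = 0,
                      fst = 0.1, seed = 82)
  sim_b <- simulate_genotypes(cfg_b, panel = sim_a$panel)
  merged <- rbind(sim_a$dataset$geno, sim_b$dataset$geno)
  fam <- data.frame(fid = paste0("F", 1:800), iid = paste0("I", 1:800),
                    sex = 2L, pheno = -9)
  ds <- genotype_dataset(fam, sim_a$dataset$bim, merged)
  pcs <- compute_pcs(ds, 2)
  lab <- rep(c(0, 1), each = 400)
  expect_gt(abs(cor(pcs[, 1], lab)), 0.9)

  # no structure: no PC separates arbitrary labels
  cfg0 <- sim_config(n_samples = 2000, n_snps = 500, n_causal = 0,
                     seed = 83)
  ds0 <- simulate_genotypes(cfg0)$dataset
  pcs0 <- compute_pcs(ds0, 2)
  lab0 <- rep(c(0, 1), each = 1000)
  expect_lt(abs(cor(pcs0[, 1], lab0)), 0.1)
  expect_lt(abs(cor(pcs0[, 2], lab0)), 0.1)

  # determinism: duplicated dataset rows get identical coordinates
  dsd <- subset_dataset(ds0, samples = c(1:50, 1:50))
  dsd$fam$iid <- paste0("I", 1:100); dimnames(dsd$geno) <- NULL
  pcsd <- compute_pcs(genotype_dataset(dsd$fam, dsd$bim, dsd$geno), 2)
  expect_equal(unname(pcsd[1:50, ]), unname(pcsd[51:100, ]), tolerance = 1e-8)

  expect_error(compute_pcs(ds0, 5000), "k must be")
})

test_that("allelic chi-square matches hand 2x2 arithmetic", {
  # cases: 30 A1 alleles / 70 A2; controls: 20 / 80, via het coding
  g <- matrix(0L, 100, 1)
  g[1:30, 1] <- 1L      # 30 het cases
  g[51:70, 1] <- 1L     # 20 het controls
  y <- rep(c(1, 0), each = 50)
  ds <- dataset_from_matrix(g)
  a <- snp_association(ds, y, test = "allelic_chisq")
  or_hand <- (30 / 70) / (20 / 80)
  expect_equal(exp(a$beta), or_hand, tolerance = 1e-12)
  expect_equal(a$se, sqrt(1 / 30 + 1 / 70 + 1 / 20 + 1 / 80),
               tolerance = 1e-12)
  # Pearson chi-square computed from scratch
  tab <- rbind(c(30, 70), c(20, 80))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi_hand <- sum((tab - e)^2 / e)
  expect_equal(a$p, pchisq(chi_hand, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("association P values are uniform under the null", {
  cfg <- sim_config(n_samples = 1500, n_snps = 1000, n_causal = 0,
                    seed = 91)
  sim <- simulate_genotypes(cfg)
  set.seed(1); y <- rbinom(1500, 1, 0.4)
  a <- snp_association(sim$dataset, y, test = "allelic_chisq")
  # ties occur because genotype counts are discrete; harmless for the KS level
  ksp <- suppressWarnings(ks.test(a$p[a$tested], "punif")$p.value)
  expect_gt(ksp, 0.01)
  lam <- genomic_inflation(a)$lambda
  expect_gt(lam, 0.9); expect_lt(lam, 1.1)
})

test_that("logistic Wald agrees with the allelic test on common SNPs", {
  cfg <- sim_config(n_samples = 2000, n_snps = 30, n_causal = 10,
                    h2_liab = 0.3, prevalence = 0.3, seed = 92)
  sim <- assign_case_control(simulate_genotypes(cfg))
  y <- sim$truth$samples$is_case
  al <- snp_association(sim$dataset, y, test = "allelic_chisq")
  lo <- snp_association(sim$dataset, y, test = "logistic_wald")
  ok <- al$tested & lo$tested
  expect_gt(cor(al$beta[ok], lo$beta[ok]), 0.99)
  expect_lt(max(abs(al$beta[ok] - lo$beta[ok])), 0.05)
  # z is beta/se by construction
  expect_equal(lo$z[ok], lo$beta[ok] / lo$se[ok], tolerance = 1e-12)
})

test_that("monomorphic variants are flagged, never tested", {
  g <- cbind(rep(0L, 40), rbinom(40, 2, 0.4))
  ds <- dataset_from_matrix(g)
  a <- snp_association(ds, rep(c(0, 1), 20), test = "logistic_wald")
  expect_false(a$tested[1])
  expect_true(is.na(a$beta[1]))
})

test_that("genomic inflation is the median chi-square ratio", {
  mk <- function(z) {
    structure(data.frame(id = paste0("s", seq_along(z)), chrom = "1",
                         pos = seq_along(z), ea = "A", oa = "G",
                         beta = z, se = 1, z = z,
                         p = 2 * pnorm(-abs(z)), n = 100, info = NA,
                         eaf = 0.3), class = c("assoc_table", "data.frame"))
  }
  z0 <- rep(sqrt(0.4549364), 5)
  expect_equal(genomic_inflation(mk(z0))$lambda, 1, tolerance = 1e-6)
  # doubling every Z quadruples lambda
  set.seed(5); z <- rnorm(1000)
  l1 <- genomic_inflation(mk(z))$lambda
  l2 <- genomic_inflation(mk(2 * z))$lambda
  expect_equal(l2 / l1, 4, tolerance = 1e-9)
  # large-sample null draws give lambda ~= 1
  set.seed(6); zb <- rnorm(1e5)
  expect_lt(abs(genomic_inflation(mk(zb))$lambda - 1), 0.02)
})

test_that("fixed-effects meta-analysis has its closed forms", {
  mk <- function(beta, se, ea = "A", oa = "G") {
    structure(data.frame(id = "rs1", chrom = "1", pos = 100, ea = ea,
                         oa = oa, beta = beta, se = se, z = beta / se,
                         p = 2 * pnorm(-abs(beta / se)), n = 100,
                         info = NA, eaf = 0.3),
              class = c("assoc_table", "data.frame"))
  }
  m <- meta_fixed_effects(mk(0.2, 0.1), mk(0.2, 0.1))
  expect_equal(m$beta, 0.2, tolerance = 1e-12)
  expect_equal(m$se, 1 / sqrt(200), tolerance = 1e-6)
  expect_equal(round(m$se, 4), 0.0707)

  m2 <- meta_fixed_effects(mk(0.1, 0.1), mk(0.3, 0.1))
  expect_equal(m2$beta, 0.2, tolerance = 1e-12)

  # single input is the identity
  expect_identical(meta_fixed_effects(mk(0.1, 0.2)), mk(0.1, 0.2))

  # swapped alleles flip the sign before combining
  m3 <- meta_fixed_effects(mk(0.2, 0.1), mk(-0.2, 0.1, ea = "G", oa = "A"))
  expect_equal(m3$beta, 0.2, tolerance = 1e-12)

  # SE shrinks below the smallest input SE
  m4 <- meta_fixed_effects(mk(0.2, 0.1), mk(0.1, 0.3))
  expect_lt(m4$se, 0.1)

  # SNP present in one table only is carried through, flagged
  t2 <- mk(0.3, 0.1); t2$id <- "rs2"
  m5 <- meta_fixed_effects(mk(0.2, 0.1), t2)
  expect_true(all(m5$single_study))
  expect_equal(sort(m5$id), c("rs1", "rs2"))
})
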