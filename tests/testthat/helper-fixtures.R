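# Fixture builders and independent oracles shared across the suite.

# random genotype dataset with optional missingness
random_dataset <- function(n, m, miss_rate = 0, n_chrom = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  g <- vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
  g <- matrix(as.integer(g), nrow = n)
  if (miss_rate > 0) g[runif(length(g)) < miss_rate] <- NA_integer_
  pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"), ncol = 2,
                  byrow = TRUE)
  pick <- sample.int(4, m, replace = TRUE)
  chrom <- sort(rep_len(seq_len(n_chrom), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), seq_along)) * 1000L
  genotype_dataset(
    fam = data.frame(fid = paste0("F", seq_len(n)),
                     iid = paste0("I", seq_len(n)),
                     sex = sample(1:2, n, TRUE), pheno = -9),
    bim = data.frame(chrom = as.character(chrom),
                     id = sprintf("v%04d", seq_len(m)),
                     pos = as.integer(pos),
                     a1 = pairs[pick, 1], a2 = pairs[pick, 2]),
    geno = g)
}

# dataset built from an explicit dosage matrix (columns = variants)
dataset_from_matrix <- function(g, chrom = NULL, pos = NULL,
                                a1 = NULL, a2 = NULL) {
  n <- nrow(g); m <- ncol(g)
  genotype_dataset(
    fam = data.frame(fid = paste0("F", seq_len(n)),
                     iid = paste0("I", seq_len(n)), sex = 2L, pheno = -9),
    bim = data.frame(chrom = chrom %||% rep("1", m),
                     id = sprintf("v%04d", seq_len(m)),
                     pos = pos %||% (seq_len(m) * 1000L),
                     a1 = a1 %||% rep("A", m), a2 = a2 %||% rep("G", m)),
    geno = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles ----------------------------------------------

# brute-force clumping: materialize the full r2 matrix and simulate the
# greedy loop literally (independent of the package implementation)
brute_force_clump <- function(assoc, dataset, p1, r2_max, window_kb) {
  col <- match(assoc$id, dataset$bim$id)
  keep <- !is.na(col) & is.finite(assoc$p)
  a <- assoc[keep, ]
  col <- col[keep]
  m <- nrow(a)
  chrom <- dataset$bim$chrom[col]
  pos <- dataset$bim$pos[col]
  r2 <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    gi <- dataset$geno[, col[i]]; gj <- dataset$geno[, col[j]]
    ok <- !is.na(gi) & !is.na(gj)
    r2[i, j] <- if (sum(ok) < 2 || length(unique(gi[ok])) < 2 ||
                    length(unique(gj[ok])) < 2) -1 else
      suppressWarnings(cor(gi[ok], gj[ok])^2)
    if (!is.finite(r2[i, j])) r2[i, j] <- -1
  }
  avail <- rep(TRUE, m)
  cand <- which(a$p < p1)
  cand <- cand[order(a$p[cand], chrom[cand], pos[cand], a$id[cand])]
  index <- character(0); clumps <- list()
  for (i in cand) {
    if (!avail[i]) next
    avail[i] <- FALSE
    mem <- which(avail & chrom == chrom[i] &
                   abs(pos - pos[i]) <= window_kb * 1000 &
                   r2[i, ] >= r2_max)
    avail[mem] <- FALSE
    index <- c(index, a$id[i])
    clumps[[a$id[i]]] <- sort(a$id[mem])
  }
  list(index = index, clumps = clumps)
}

# exhaustive-pair AUC (ties half)
exhaustive_auc <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  s <- 0
  for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
  s / (length(x) * length(y))
}

# Studentized sign-flip permutation oracle for the paired AUC comparison:
# under the null the two scores of each sample are exchangeable, so every
# per-sample swap pattern is equally likely.  The permutation statistic is
# the studentized AUC difference (structural-components variance recomputed
# under each swap), which is the permutation analogue of the DeLong z.
# Everything here is recomputed from outer comparisons, independent of the
# package implementation.
permutation_delong_p <- function(sa, sb, labels, B = 1e5, seed = 1) {
  set.seed(seed)
  case <- labels == 1
  n1 <- sum(case); n0 <- sum(!case)
  cmp <- function(x, y) outer(x, y, function(a, b)
    (a > b) + 0.5 * (a == b))
  # pair contribution matrices for the four (case-score, control-score) states
  Maa <- cmp(sa[case], sa[!case]); Mbb <- cmp(sb[case], sb[!case])
  Mab <- cmp(sa[case], sb[!case]); Mba <- cmp(sb[case], sa[!case])
  colVars <- function(m)
    (colSums(m * m) - colSums(m)^2 / nrow(m)) / (nrow(m) - 1)
  # components of the first permuted score (u/v = 1 -> that sample uses b);
  # the second permuted score is the complementary assignment
  components <- function(U, V) {
    A1 <- Mbb %*% V + Mba %*% (1 - V)
    A0 <- Mab %*% V + Maa %*% (1 - V)
    V10 <- (U * A1 + (1 - U) * A0) / n0
    T1 <- t(Mbb) %*% U + t(Mab) %*% (1 - U)
    T0 <- t(Mba) %*% U + t(Maa) %*% (1 - U)
    V01 <- 1 - (V * T1 + (1 - V) * T0) / n1
    list(V10 = V10, V01 = V01, auc = colMeans(V10))
  }
  zstat <- function(U, V) {
    s1 <- components(U, V)
    s2 <- components(1 - U, 1 - V)
    d <- s1$auc - s2$auc
    cv10 <- (colSums(s1$V10 * s2$V10) -
               colSums(s1$V10) * colSums(s2$V10) / n1) / (n1 - 1)
    cv01 <- (colSums(s1$V01 * s2$V01) -
               colSums(s1$V01) * colSums(s2$V01) / n0) / (n0 - 1)
    vd <- colVars(s1$V10) / n1 + colVars(s1$V01) / n0 +
      colVars(s2$V10) / n1 + colVars(s2$V01) / n0 -
      2 * (cv10 / n1 + cv01 / n0)
    ifelse(vd > 0, d / sqrt(vd), 0)
  }
  z_obs <- zstat(matrix(0, n1, 1), matrix(0, n0, 1))
  U <- matrix(rbinom(n1 * B, 1, 0.5), n1, B)
  V <- matrix(rbinom(n0 * B, 1, 0.5), n0, B)
  mean(abs(zstat(U, V)) >= abs(z_obs) - 1e-12)
}
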