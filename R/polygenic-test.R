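## Polarized binned Z-score polygenicity test.
##
## Target-study Z scores are re-signed so their effect allele is the
## discovery study's risk allele; under the null of no shared signal the
## polarized Z scores have zero mean within any discovery-P stratum, while
## widespread weak true associations push the mean positive.

#' Polarize target Z scores to the discovery risk allele
#'
#' For each variant shared between the tables the discovery risk allele is
#' the allele with positive discovery beta; the target Z is re-signed so
#' its effect allele is that risk allele.  Allele harmonization follows
#' the [align_weights()] rules (sign flip on swapped alleles, strand
#' complement where needed, strand-ambiguous pairs dropped).  Variants
#' with discovery beta exactly zero (no defined risk allele) are dropped.
#'
#' @param discovery,target `assoc_table` data.frames.
#' @return data.frame: `id`, `z` (polarized target Z), `p_discovery`;
#'   attribute `n_dropped` (unharmonizable or zero-beta variants).
#' @export
polarize_z <- function(discovery, target) {
  idx <- match(target$id, discovery$id)
  shared <- !is.na(idx)
  t <- target[shared, , drop = FALSE]
  d <- discovery[idx[shared], , drop = FALSE]
  al <- harmonize_alleles(t$ea, t$oa, d$ea, d$oa, drop_ambiguous = TRUE)
  ok <- al$status != "drop" & is.finite(t$z) & is.finite(d$beta) &
    d$beta != 0
  z_aligned <- ifelse(al$flip_effect, -t$z, t$z)     # to the discovery EA
  z_pol <- z_aligned * sign(d$beta)                  # to the risk allele
  out <- data.frame(id = t$id[ok], z = z_pol[ok],
                    p_discovery = d$p[ok], stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- nrow(target) - nrow(out)
  out
}

#' Zero-mean test of polarized Z scores within discovery-P bins
#'
#' SNPs (assumed pre-thinned to an LD-clumped set) are stratified by their
#' discovery P value into left-open/right-closed bins and each bin's mean
#' polarized Z is tested against zero with a two-sided one-sample t-test.
#' Bins with fewer than two SNPs, or with all Z equal, report degenerate
#' results (`p = 1` for the all-equal-to-zero-variance case when the mean
#' is 0, `NA` statistics when the test is undefined).
#'
#' @param polarized output of [polarize_z()].
#' @param bin_edges decreasing edges; default `1, 0.9, ..., 0.1, 0` so
#'   `P = 1` falls in the top bin.
#' @return data.frame of class `binned_z`: `bin_lo`, `bin_hi`, `n_snps`,
#'   `mean_z`, `se_mean`, `t`, `p`.
#' @export
binned_zero_mean_test <- function(polarized, bin_edges = seq(1, 0, by = -0.1)) {
  edges <- sort(unique(bin_edges))
  if (length(edges) < 2) stop("need at least two bin edges")
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  out <- data.frame(bin_lo = lo, bin_hi = hi, n_snps = 0L,
                    mean_z = NA_real_, se_mean = NA_real_,
                    t = NA_real_, p = NA_real_)
  for (k in seq_along(lo)) {
    zz <- polarized$z[polarized$p_discovery > lo[k] &
                        polarized$p_discovery <= hi[k]]
    out$n_snps[k] <- length(zz)
    if (length(zz) == 0) next
    out$mean_z[k] <- mean(zz)
    if (length(zz) < 2) next
    s <- sd(zz)
    if (s == 0) {                      # degenerate: no sampling variance
      out$se_mean[k] <- 0
      out$p[k] <- if (out$mean_z[k] == 0) 1 else 0
      next
    }
    out$se_mean[k] <- s / sqrt(length(zz))
    tt <- t.test(zz, mu = 0)
    out$t[k] <- unname(tt$statistic)
    out$p[k] <- tt$p.value
  }
  out <- out[order(-out$bin_lo), ]
  rownames(out) <- NULL
  class(out) <- c("binned_z", "data.frame")
  out
}

#' Write the binned-Z table
#'
#' @param binned a `binned_z` data.frame.
#' @param tsv_path output path.
#' @return `tsv_path`, invisibly.
#' @export
write_binned_z <- function(binned, tsv_path) {
  out <- data.frame(BIN_LO = binned$bin_lo, BIN_HI = binned$bin_hi,
                    N_SNPS = binned$n_snps, MEAN_Z = binned$mean_z,
                    SE = binned$se_mean, T = binned$t, P = binned$p)
  data.table::fwrite(out, tsv_path, sep = "\t", na = "NA", quote = FALSE)
  invisible(tsv_path)
}
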