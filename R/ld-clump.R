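## Pairwise LD and greedy clumping over a P-value / r-squared / window grid.

#' Clumping specification
#'
#' @param p1 index-SNP P-value threshold, in (0, 1].
#' @param r2_max pairwise squared-correlation threshold: a SNP joins a
#'   clump when its r-squared with the index is `>= r2_max`, so retained
#'   indexes are mutually below `r2_max`.
#' @param window_kb half-window around the index SNP, kilobases.
#' @return list of class `clump_spec`.
#' @export
clump_spec <- function(p1, r2_max, window_kb) {
  stopifnot(p1 > 0, p1 <= 1, r2_max >= 0, r2_max <= 1, window_kb > 0)
  structure(list(p1 = p1, r2_max = r2_max, window_kb = window_kb),
            class = "clump_spec")
}

#' Pairwise squared correlation of two dosage vectors
#'
#' Composite (genotype-level) LD: squared Pearson correlation over samples
#' non-missing in both vectors.  Returns `NA` (flagged not-in-LD) when
#' either vector is constant on the shared support.
#'
#' @param dosages_a,dosages_b equal-length dosage vectors (0/1/2/NA).
#' @return r-squared in \[0, 1\], or `NA` if undefined.
#' @export
pairwise_r2 <- function(dosages_a, dosages_b) {
  stopifnot(length(dosages_a) == length(dosages_b))
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (length(a) < 2 || length(unique(a)) < 2 || length(unique(b)) < 2)
    return(NA_real_)
  cor(a, b)^2
}

#' Greedy LD clumping
#'
#' PLINK-style clumping: candidate index SNPs are those with association
#' `P < p1`, visited in ascending P (ties broken by chromosome, position,
#' then variant id).  Each still-unassigned SNP on the same chromosome
#' within `window_kb` of the index whose r-squared with the index is
#' `>= r2_max` joins the clump and leaves candidacy; every SNP appears in
#' at most one clump.  The retained set is the index SNPs.
#'
#' @param assoc an `assoc_table` for the training cohort.
#' @param dataset the training `genotype_dataset` (LD is computed
#'   in-sample).  Association rows absent from the dataset are excluded
#'   with a warning.
#' @param spec a [clump_spec()].
#' @return list of class `clump_result`: `index` (data.frame of retained
#'   index SNPs with P), `clumps` (named list: index id -> member ids),
#'   `n_excluded` (assoc rows not in the dataset).
#' @export
greedy_clump <- function(assoc, dataset, spec) {
  stopifnot(inherits(spec, "clump_spec"))
  idx_in_data <- match(assoc$id, dataset$bim$id)
  excluded <- sum(is.na(idx_in_data))
  if (excluded > 0)
    warning(excluded, " association record(s) absent from the dataset; excluded")
  keep <- !is.na(idx_in_data) & is.finite(assoc$p)
  a <- assoc[keep, , drop = FALSE]
  col <- idx_in_data[keep]                  # dataset column per assoc row
  ## positions/chroms from the dataset (the LD substrate)
  chrom <- dataset$bim$chrom[col]
  pos <- dataset$bim$pos[col]

  m <- nrow(a)
  assigned <- rep(FALSE, m)
  window_bp <- spec$window_kb * 1000
  cand <- which(a$p < spec$p1)
  ord <- cand[order(a$p[cand], chrom[cand], pos[cand], a$id[cand])]

  index_rows <- integer(0)
  clumps <- list()
  g <- dataset$geno
  for (i in ord) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    near <- which(!assigned & chrom == chrom[i] &
                    abs(pos - pos[i]) <= window_bp)
    members <- integer(0)
    if (length(near)) {
      gi <- g[, col[i]]
      gn <- g[, col[near], drop = FALSE]
      if (anyNA(gi) || anyNA(gn)) {
        r2 <- vapply(seq_along(near), function(j) {
          v <- pairwise_r2(gi, gn[, j])
          if (is.na(v)) -1 else v           # undefined LD: treat as not-in-LD
        }, numeric(1))
      } else {
        r2 <- suppressWarnings(as.numeric(cor(gi, gn))^2)
        r2[!is.finite(r2)] <- -1
      }
      members <- near[r2 >= spec$r2_max]
      assigned[members] <- TRUE
    }
    index_rows <- c(index_rows, i)
    clumps[[a$id[i]]] <- a$id[members]
  }
  index <- data.frame(id = a$id[index_rows], chrom = chrom[index_rows],
                      pos = pos[index_rows], p = a$p[index_rows],
                      beta = a$beta[index_rows], se = a$se[index_rows],
                      ea = a$ea[index_rows], oa = a$oa[index_rows],
                      n_members = lengths(clumps),
                      stringsAsFactors = FALSE)
  structure(list(index = index, clumps = clumps, n_excluded = excluded,
                 spec = spec),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat("<clump_result> ", nrow(x$index), " clumps (p1=", x$spec$p1,
      ", r2=", x$spec$r2_max, ", kb=", x$spec$window_kb, ")\n", sep = "")
  invisible(x)
}

#' Clumping-and-thresholding grid
#'
#' Runs [greedy_clump()] for every combination of the supplied P-value,
#' r-squared and window lists (Cartesian product).
#'
#' @param assoc an `assoc_table`.
#' @param dataset the training `genotype_dataset`.
#' @param p1_list,r2_list,kb_list non-empty numeric vectors.
#' @return Named list of `clump_result`s, one per spec, names
#'   `"p1=..,r2=..,kb=.."`; attribute `grid` holds the parameter table.
#' @export
ct_grid <- function(assoc, dataset, p1_list, r2_list, kb_list) {
  stopifnot(length(p1_list) > 0, length(r2_list) > 0, length(kb_list) > 0)
  grid <- expand.grid(p1 = p1_list, r2 = r2_list, kb = kb_list,
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  names(out) <- sprintf("p1=%g,r2=%g,kb=%g", grid$p1, grid$r2, grid$kb)
  for (k in seq_len(nrow(grid)))
    out[[k]] <- suppressWarnings(
      greedy_clump(assoc, dataset,
                   clump_spec(grid$p1[k], grid$r2[k], grid$kb[k])))
  attr(out, "grid") <- grid
  out
}

#' The published 32-configuration clumping grid
#'
#' The standard sweep: eight P thresholds (0.1, 0.01, 1e-3 ... 5e-8), two
#' r-squared cutoffs (0.2, 0.5) and two windows (250, 1000 kb).
#'
#' @return list with `p1_list`, `r2_list`, `kb_list`.
#' @export
default_ct_grid <- function() {
  list(p1_list = c(0.1, 0.01, 1e-3, 1e-4, 1e-5, 1e-6, 1e-7, 5e-8),
       r2_list = c(0.2, 0.5),
       kb_list = c(250, 1000))
}

#' Write a clump report table
#'
#' @param result a `clump_result`.
#' @param tsv_path output path.
#' @return `tsv_path`, invisibly.
#' @export
write_clump_report <- function(result, tsv_path) {
  members <- vapply(result$clumps, function(x)
    if (length(x)) paste(x, collapse = ",") else "NONE", character(1))
  out <- data.frame(INDEX_SNP = result$index$id, CHR = result$index$chrom,
                    BP = result$index$pos, P = result$index$p,
                    N_MEMBERS = result$index$n_members,
                    MEMBERS = members)
  data.table::fwrite(out, tsv_path, sep = "\t", quote = FALSE)
  invisible(tsv_path)
}
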