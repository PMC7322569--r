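## Weight harmonization and per-sample weighted risk scores.

#' Align a weight table to a target dataset
#'
#' For each weight the effect allele is matched against the dataset's
#' allele pair: a direct match keeps the weight; an effect allele equal to
#' allele2 keeps the weight with a dosage-flip flag (the contribution uses
#' `2 - dosage`); a match only after strand complement flips strand first;
#' strand-ambiguous variants (dataset allele pair A/T or C/G) and allele
#' mismatches are dropped.
#'
#' @param weights a `weight_table`.
#' @param dataset a `genotype_dataset`.
#' @return list of class `aligned_weights`: `table` (columns `id`, `ea`,
#'   `weight`, `source`, `col` (dataset column), `flip_dosage`) and
#'   `audit` (kept / flipped / strand_flipped / dropped counts).
#' @export
align_weights <- function(weights, dataset) {
  bim <- dataset$bim
  idx <- match(weights$id, bim$id)
  found <- !is.na(idx)
  comp <- function(x) chartr("ACGT", "TGCA", x)

  n <- nrow(weights)
  status <- rep("drop_absent", n)
  flip <- rep(FALSE, n)
  strand <- rep(FALSE, n)
  if (any(found)) {
    a1 <- bim$a1[idx[found]]; a2 <- bim$a2[idx[found]]
    ea <- weights$ea[found]
    amb <- a2 == comp(a1)                       # A/T or C/G dataset variant
    st <- ifelse(amb, "drop_ambiguous",
           ifelse(ea == a1, "keep",
            ifelse(ea == a2, "flip",
             ifelse(comp(ea) == a1, "keep_strand",
              ifelse(comp(ea) == a2, "flip_strand", "drop_mismatch")))))
    status[found] <- st
    flip[found] <- st %in% c("flip", "flip_strand")
    strand[found] <- st %in% c("keep_strand", "flip_strand")
  }
  kept <- status %in% c("keep", "flip", "keep_strand", "flip_strand")
  tab <- data.frame(id = weights$id[kept], ea = weights$ea[kept],
                    weight = weights$weight[kept],
                    source = weights$source[kept],
                    col = idx[kept], flip_dosage = flip[kept],
                    stringsAsFactors = FALSE)
  audit <- list(n_requested = n, n_kept = nrow(tab),
                kept_unflipped = sum(status == "keep"),
                flipped = sum(flip[kept]),
                strand_flipped = sum(strand[kept]),
                dropped_absent = sum(status == "drop_absent"),
                dropped_ambiguous = sum(status == "drop_ambiguous"),
                dropped_mismatch = sum(status == "drop_mismatch"))
  if (nrow(tab) == 0)
    warning("no weights could be aligned to the dataset")
  structure(list(table = tab, audit = audit), class = "aligned_weights")
}

#' Compute per-sample weighted risk scores
#'
#' `score_i = sum_j w_j * g~_ij` where `g~` is the dosage of the effect
#' allele (`2 - dosage` at flip-flagged variants).  Missing dosages are
#' replaced by `2 * EAF` (effect-allele frequency in the scored dataset)
#' under `mean_dosage`, or contribute nothing for that sample under
#' `omit`.
#'
#' @param dataset a `genotype_dataset`.
#' @param aligned an `aligned_weights` from [align_weights()].
#' @param missing_policy `"mean_dosage"` (default) or `"omit"`.
#' @return data.frame of class `score_vector`: `iid`, `score`,
#'   `n_snps_used` (per sample); attributes `n_snps_requested`,
#'   `n_snps_aligned`, `missing_policy`, `weight_source`.
#' @export
score_samples <- function(dataset, aligned,
                          missing_policy = c("mean_dosage", "omit")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(aligned, "aligned_weights"))
  tab <- aligned$table
  if (nrow(tab) == 0) stop("zero usable SNPs: no aligned weights")
  g <- dataset$geno[, tab$col, drop = FALSE]
  ## effect-allele dosage
  gf <- g
  if (any(tab$flip_dosage))
    gf[, tab$flip_dosage] <- 2L - gf[, tab$flip_dosage, drop = FALSE]
  miss <- is.na(gf)
  if (missing_policy == "mean_dosage") {
    eaf <- colMeans(gf, na.rm = TRUE) / 2
    eaf[!is.finite(eaf)] <- 0
    if (any(miss)) {
      fill <- matrix(2 * eaf, nrow = nrow(gf), ncol = ncol(gf), byrow = TRUE)
      gf[miss] <- fill[miss]
    }
    used <- rep(nrow(tab), nrow(gf))
  } else {
    gf[miss] <- 0
    used <- nrow(tab) - rowSums(miss)
  }
  score <- as.numeric(gf %*% tab$weight)
  if (any(!is.finite(score))) stop("non-finite scores produced")
  out <- data.frame(iid = dataset$fam$iid, score = score,
                    n_snps_used = used, stringsAsFactors = FALSE)
  attr(out, "n_snps_requested") <- aligned$audit$n_requested
  attr(out, "n_snps_aligned") <- nrow(tab)
  attr(out, "missing_policy") <- missing_policy
  attr(out, "weight_source") <- paste(unique(tab$source), collapse = "+")
  class(out) <- c("score_vector", "data.frame")
  out
}

## MHC tag SNPs for the two well-known class-II risk haplotypes, per
## population of the training data.
MHC_TAGS <- list(EUR = c("rs2187668", "rs9267992"),   # DRB1*03:01, *15:01
                 CHN = c("rs9271366", "rs9275328"))   # DRB1/DQA1, DQB1/DQA2

#' MHC tag-SNP weights from a training association table
#'
#' Returns the two class-II HLA haplotype tag SNPs for the requested
#' population, weighted by their training-cohort effect sizes.  Tags are
#' only meant for within-population scoring; cross-population runs omit
#' them entirely.
#'
#' @param population `"EUR"` or `"CHN"`.
#' @param training_assoc an `assoc_table` supplying the tag weights.
#' @return A `weight_table` with at most two rows; tags missing from the
#'   training table are omitted with a warning.
#' @export
mhc_tag_weights <- function(population = c("EUR", "CHN"), training_assoc) {
  population <- match.arg(population)
  tags <- MHC_TAGS[[population]]
  hit <- match(tags, training_assoc$id)
  if (any(is.na(hit)))
    warning("MHC tag SNP(s) absent from the training table: ",
            paste(tags[is.na(hit)], collapse = ", "), "; omitted")
  hit <- hit[!is.na(hit)]
  if (!length(hit))
    return(weight_table(character(0), character(0), numeric(0)))
  weight_table(id = training_assoc$id[hit], ea = training_assoc$ea[hit],
               weight = training_assoc$beta[hit], source = "trained")
}

#' Restrict weights to variants shared by two datasets
#'
#' @param weights a `weight_table`.
#' @param dataset_a,dataset_b two `genotype_dataset`s.
#' @return list: `weights` (filtered `weight_table`), `audit` (counts of
#'   dropped variants per reason).  Errors if no variant survives.
#' @export
restrict_overlap <- function(weights, dataset_a, dataset_b) {
  aligned_ids <- function(ds)
    suppressWarnings(align_weights(weights, ds)$table$id)
  keep <- weights$id %in% aligned_ids(dataset_a) &
    weights$id %in% aligned_ids(dataset_b)
  if (!any(keep)) stop("no variant is present and alignable in both datasets")
  out <- weights[keep, , drop = FALSE]
  class(out) <- class(weights)
  list(weights = out,
       audit = list(n_requested = nrow(weights), n_kept = sum(keep),
                    dropped = weights$id[!keep]))
}

#' Train-and-test clumping-and-thresholding score
#'
#' Full C+T pass: variant QC on the training data (autosomes minus the
#' extended MHC region), per-SNP association, greedy clumping under
#' `spec`, index-SNP betas as weights, alignment to the test dataset,
#' optional MHC tag augmentation (within-population European scoring
#' only), and per-sample scores on the test cohort.
#'
#' @param train_dataset,test_dataset `genotype_dataset`s.
#' @param train_outcome binary 0/1 vector for the training samples.
#' @param spec a [clump_spec()].
#' @param missing_policy passed to [score_samples()].
#' @param assoc_test association test for the training GWAS
#'   (see [snp_association()]).
#' @param covariates optional training covariates (logistic test only).
#' @param mhc_tags `"none"` (default, mandatory cross-population),
#'   `"EUR"` or `"CHN"`.
#' @param exclude_regions,exclude_chroms QC exclusions; defaults are the
#'   extended MHC (chr6:24-36 Mb) and the X chromosome.
#' @param train_assoc optional precomputed training `assoc_table`
#'   (post-QC); skips the GWAS stage.
#' @return list: `scores` (a `score_vector` on the test samples),
#'   `clump` (the `clump_result`), `assoc` (training table), `audit`.
#' @export
train_test_score <- function(train_dataset, test_dataset, train_outcome,
                             spec, missing_policy = "mean_dosage",
                             assoc_test = "logistic_wald",
                             covariates = NULL, mhc_tags = "none",
                             exclude_regions = list(c("6", 24e6, 36e6)),
                             exclude_chroms = c("X", "23"),
                             train_assoc = NULL) {
  qc <- variant_qc(train_dataset, exclude_regions = exclude_regions,
                   exclude_chroms = exclude_chroms)
  if (is.null(train_assoc))
    train_assoc <- snp_association(qc$dataset, train_outcome,
                                   covariates = covariates,
                                   test = assoc_test)
  cl <- greedy_clump(train_assoc, qc$dataset, spec)
  if (nrow(cl$index) == 0)
    stop("empty clump result: no SNP passes p1 = ", spec$p1)
  w <- weight_table(id = cl$index$id, ea = cl$index$ea,
                    weight = cl$index$beta, source = "trained")
  if (mhc_tags != "none") {
    tags <- mhc_tag_weights(mhc_tags, train_assoc)
    if (nrow(tags)) w <- rbind(w, tags[!tags$id %in% w$id, , drop = FALSE])
    class(w) <- c("weight_table", "data.frame")
  }
  al <- align_weights(w, test_dataset)
  sc <- score_samples(test_dataset, al, missing_policy = missing_policy)
  list(scores = sc, clump = cl, assoc = train_assoc,
       audit = list(qc = qc$report, alignment = al$audit))
}
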