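## Genotype container and file formats.
##
## Conventions (mirrored across the whole package):
##   * dosage counts copies of allele1 (the .bim A1 column),
##   * positions are 1-based inclusive base pairs,
##   * missing dosage is NA (never 0).

#' Construct a genotype dataset
#'
#' Bundles a sample table, a variant table and a dosage matrix into the
#' container every pipeline stage consumes.  The dosage matrix counts copies
#' of `allele1` (the PLINK A1 allele); missing genotypes are `NA`.
#'
#' @param fam data.frame with columns `fid`, `iid`, `sex` (0/1/2),
#'   `pheno` (numeric code; -9/0 = missing, 1 = control, 2 = case).
#' @param bim data.frame with columns `chrom`, `id`, `pos`, `a1`, `a2`.
#' @param geno integer matrix, rows = samples, columns = variants,
#'   values in \{0, 1, 2, NA\}.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(fam, bim, geno) {
  fam <- as.data.frame(fam)
  bim <- as.data.frame(bim)
  stopifnot(all(c("fid", "iid", "sex", "pheno") %in% names(fam)),
            all(c("chrom", "id", "pos", "a1", "a2") %in% names(bim)))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(fam) || ncol(geno) != nrow(bim))
    stop("dosage matrix dimensions (", nrow(geno), " x ", ncol(geno),
         ") do not match sample/variant tables (", nrow(fam), " x ",
         nrow(bim), ")")
  ## primitive min/max scan in place; range() would copy the matrix
  mn <- suppressWarnings(min(geno, na.rm = TRUE))
  mx <- suppressWarnings(max(geno, na.rm = TRUE))
  if (is.finite(mn) && (mn < 0L || mx > 2L))
    stop("dosages must be 0/1/2 or NA")
  if (any(bim$pos < 1L)) stop("positions must be >= 1 (1-based)")
  dup <- duplicated(paste(bim$chrom, bim$id))
  if (any(dup))
    stop("duplicate variant id within a chromosome: ",
         paste(head(bim$id[dup], 3), collapse = ", "))
  ## no dimnames on the dosage matrix: sample/variant identity lives in
  ## fam/bim, and naming an n x m matrix forces a full copy at scale
  structure(list(fam = fam, bim = bim, geno = unname(geno)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", nrow(x$fam), " samples x ", nrow(x$bim),
      " variants; ", sum(is.na(x$geno)), " missing dosages\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$geno)

#' Subset a genotype dataset by sample and/or variant index
#'
#' @param dataset a `genotype_dataset`.
#' @param samples,variants integer or logical indexes (default: keep all).
#' @return A `genotype_dataset`.
#' @export
subset_dataset <- function(dataset, samples = NULL, variants = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  fam <- dataset$fam; bim <- dataset$bim; geno <- dataset$geno
  if (!is.null(samples)) {
    fam <- fam[samples, , drop = FALSE]
    geno <- geno[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    bim <- bim[variants, , drop = FALSE]
    geno <- geno[, variants, drop = FALSE]
  }
  rownames(fam) <- NULL; rownames(bim) <- NULL
  genotype_dataset(fam, bim, geno)
}

#' Allele-1 frequency per variant
#'
#' @param dataset a `genotype_dataset`.
#' @return Numeric vector: frequency of allele1 among non-missing dosages
#'   (NaN for all-missing variants).
#' @export
allele1_freq <- function(dataset) {
  n <- colSums(!is.na(dataset$geno))
  colSums(dataset$geno, na.rm = TRUE) / (2 * n)
}

## ---------------------------------------------------------------- PLINK-1

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))  # bed magic + SNP-major flag

#' Read a PLINK-1 binary fileset
#'
#' Reads the `.bed`/`.bim`/`.fam` trio at `path_prefix`.  Only SNP-major
#' `.bed` files (the modern default) are supported.  Dosage counts copies of
#' the `.bim` A1 allele; the 0b01 "missing" code maps to `NA`.
#'
#' @param path_prefix path without extension; `path_prefix.bed` etc. must
#'   exist.
#' @return A `genotype_dataset`.
#' @export
load_genotype_fileset <- function(path_prefix) {
  paths <- paste0(path_prefix, c(".bed", ".bim", ".fam"))
  miss <- paths[!file.exists(paths)]
  if (length(miss)) stop("missing fileset member(s): ",
                         paste(miss, collapse = ", "))

  fam <- read_fam(paths[3])
  bim <- read_bim(paths[2])
  n <- nrow(fam); m <- nrow(bim)

  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || !identical(raw[1:2], PLINK_MAGIC[1:2]))
    stop("not a PLINK-1 bed: bad magic bytes in ", paths[1])
  if (raw[3] != PLINK_MAGIC[3])
    stop("only SNP-major (0x01) .bed files are supported")
  body <- raw[-(1:3)]
  bpv <- ceiling(n / 4)           # bytes per variant
  if (length(body) != bpv * m)
    stop("bed payload is ", length(body), " bytes; expected ", bpv * m,
         " for ", n, " samples x ", m, " variants")

  if (n == 0L || m == 0L)
    return(genotype_dataset(fam, bim, matrix(integer(), n, m)))

  ## 2-bit codes, little-endian within byte: 00 homA1, 01 missing,
  ## 10 het, 11 homA2.  Dosage of A1: 00->2, 10->1, 11->0, 01->NA.
  bits <- as.integer(rawToBits(body))            # length 8 * bpv * m
  b1 <- bits[seq(1L, length(bits), by = 2L)]     # low bit of each code
  b2 <- bits[seq(2L, length(bits), by = 2L)]
  code <- b1 + 2L * b2
  code <- matrix(code, nrow = 4L * bpv, ncol = m)[seq_len(n), , drop = FALSE]
  lut <- c(2L, NA_integer_, 1L, 0L)              # index by code + 1
  geno <- matrix(lut[code + 1L], nrow = n, ncol = m)
  genotype_dataset(fam, bim, geno)
}

#' Write a PLINK-1 binary fileset
#'
#' Inverse of [load_genotype_fileset()]; emits an SNP-major `.bed` with the
#' trailing byte of each variant zero-padded, plus `.bim` (with a zero cM
#' column) and `.fam`.
#'
#' @param dataset a `genotype_dataset`.
#' @param path_prefix output path without extension.
#' @return `path_prefix`, invisibly.
#' @export
write_genotype_fileset <- function(dataset, path_prefix) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  fam <- dataset$fam; bim <- dataset$bim
  n <- nrow(fam); m <- nrow(bim)

  fam_out <- data.frame(fam$fid, fam$iid, 0L, 0L, fam$sex, fam$pheno)
  utils::write.table(fam_out, paste0(path_prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim_out <- data.frame(bim$chrom, bim$id, 0, bim$pos, bim$a1, bim$a2)
  utils::write.table(bim_out, paste0(path_prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  bpv <- ceiling(n / 4)
  con <- file(paste0(path_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  if (n > 0L && m > 0L) {
    ## dosage -> code: 2->00, 1->10, 0->11, NA->01
    g <- dataset$geno
    code <- matrix(0L, nrow = 4L * bpv, ncol = m)   # pad rows -> zero bits
    code[seq_len(n), ] <- ifelse(is.na(g), 1L, c(3L, 2L, 0L)[g + 1L])
    b1 <- as.raw(code %% 2L)
    b2 <- as.raw(code %/% 2L)
    bits <- raw(2L * length(code))
    bits[seq(1L, length(bits), 2L)] <- b1
    bits[seq(2L, length(bits), 2L)] <- b2
    writeBin(packBits(bits, "raw"), con)
  }
  invisible(path_prefix)
}

read_fam <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(fid = character(), iid = character(),
                      sex = integer(), pheno = numeric()))
  x <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(x) < 6L) stop(".fam must have 6 columns")
  data.frame(fid = x[[1]], iid = x[[2]], sex = as.integer(x[[5]]),
             pheno = as.numeric(x[[6]]))
}

read_bim <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), id = character(),
                      pos = integer(), a1 = character(), a2 = character()))
  x <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(x) < 6L) stop(".bim must have 6 columns")
  data.frame(chrom = x[[1]], id = x[[2]], pos = as.integer(x[[4]]),
             a1 = x[[5]], a2 = x[[6]])
}

## ------------------------------------------------------- summary statistics

#' Load a GWAS summary-statistics table
#'
#' Canonical schema: tab-delimited with header columns `SNP`, `CHR`, `BP`,
#' `A1` (effect allele), `A2`, one of `BETA` or `OR`, `SE`, `P`; optional
#' `INFO`, `EAF`, `N`.  `OR` is converted to `beta = log(OR)`; `z` is
#' recomputed as `beta / se`.
#'
#' @param tsv_path path to the table.
#' @return data.frame of class `assoc_table` with columns `id`, `chrom`,
#'   `pos`, `ea`, `oa`, `beta`, `se`, `z`, `p`, `n`, `info`, `eaf`.
#' @export
load_summary_stats <- function(tsv_path) {
  x <- data.table::fread(tsv_path, sep = "\t", header = TRUE,
                         na.strings = "NA", data.table = FALSE)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "SE", "P")
  absent <- setdiff(need, names(x))
  if (!any(c("BETA", "OR") %in% names(x))) absent <- c(absent, "BETA|OR")
  if (length(absent))
    stop("summary-stats file lacks required column(s): ",
         paste(absent, collapse = ", "))
  beta <- if ("BETA" %in% names(x)) as.numeric(x$BETA) else log(as.numeric(x$OR))
  out <- data.frame(
    id    = as.character(x$SNP),
    chrom = as.character(x$CHR),
    pos   = as.integer(x$BP),
    ea    = toupper(as.character(x$A1)),
    oa    = toupper(as.character(x$A2)),
    beta  = beta,
    se    = as.numeric(x$SE),
    z     = beta / as.numeric(x$SE),
    p     = as.numeric(x$P),
    n     = if ("N" %in% names(x)) as.numeric(x$N) else NA_real_,
    info  = if ("INFO" %in% names(x)) as.numeric(x$INFO) else NA_real_,
    eaf   = if ("EAF" %in% names(x)) as.numeric(x$EAF) else NA_real_,
    stringsAsFactors = FALSE)
  validate_assoc_table(out)
}

validate_assoc_table <- function(x) {
  if (any(duplicated(x$id)))
    stop("duplicate variant id in association table: ",
         paste(head(unique(x$id[duplicated(x$id)]), 3), collapse = ", "))
  badp <- !is.na(x$p) & (x$p <= 0 | x$p > 1)
  if (any(badp))
    stop("P values outside (0, 1] for: ",
         paste(head(x$id[badp], 3), collapse = ", "))
  bads <- is.finite(x$beta) & (!is.finite(x$se) | x$se <= 0)
  if (any(bads))
    stop("non-positive SE with finite beta for: ",
         paste(head(x$id[bads], 3), collapse = ", "))
  badi <- !is.na(x$info) & (x$info < 0 | x$info > 1)
  if (any(badi)) stop("INFO outside [0, 1]")
  class(x) <- c("assoc_table", "data.frame")
  x
}

#' Write a summary-statistics table in the canonical schema
#'
#' @param assoc an `assoc_table` data.frame.
#' @param tsv_path output path.
#' @return `tsv_path`, invisibly.
#' @export
write_summary_stats <- function(assoc, tsv_path) {
  out <- data.frame(SNP = assoc$id, CHR = assoc$chrom, BP = assoc$pos,
                    A1 = assoc$ea, A2 = assoc$oa, BETA = assoc$beta,
                    SE = assoc$se, Z = assoc$z, P = assoc$p,
                    N = assoc$n, INFO = assoc$info, EAF = assoc$eaf)
  data.table::fwrite(out, tsv_path, sep = "\t", na = "NA", quote = FALSE)
  invisible(tsv_path)
}

## ----------------------------------------------------------- weight tables

#' Load a GRS weight table
#'
#' Tab-delimited, header columns `SNP`, `EA` (effect/risk allele), `WEIGHT`
#' (per-allele log odds ratio); optional `SOURCE` (`published`/`trained`).
#'
#' @param tsv_path path to the table.
#' @return data.frame of class `weight_table` with columns `id`, `ea`,
#'   `weight`, `source`.
#' @export
load_weights <- function(tsv_path) {
  x <- data.table::fread(tsv_path, sep = "\t", header = TRUE,
                         na.strings = "NA", data.table = FALSE)
  need <- setdiff(c("SNP", "EA", "WEIGHT"), names(x))
  if (length(need))
    stop("weight table lacks column(s): ", paste(need, collapse = ", "))
  out <- weight_table(id = as.character(x$SNP),
                      ea = toupper(as.character(x$EA)),
                      weight = as.numeric(x$WEIGHT),
                      source = if ("SOURCE" %in% names(x))
                        as.character(x$SOURCE) else "published")
  out
}

#' Build a validated weight table
#'
#' @param id variant ids.
#' @param ea effect (risk) alleles, one of A/C/G/T.
#' @param weight per-allele log odds ratios.
#' @param source `"published"` or `"trained"`, recycled.
#' @return data.frame of class `weight_table`.
#' @export
weight_table <- function(id, ea, weight, source = "trained") {
  out <- data.frame(id = as.character(id), ea = toupper(as.character(ea)),
                    weight = as.numeric(weight),
                    source = rep_len(as.character(source), length(id)),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (any(!out$ea %in% c("A", "C", "G", "T")))
      stop("effect allele must be one of A/C/G/T")
    if (any(!is.finite(out$weight))) stop("weights must be finite")
  }
  class(out) <- c("weight_table", "data.frame")
  out
}

## ------------------------------------------------------------- phenotypes

#' Load a phenotype table
#'
#' Tab-delimited, header columns `IID`, `STATUS` (0 control / 1 case);
#' optional `RENAL` (0/1/NA, cases only), `ONSET` (years, > 0), `SEX`,
#' `POP`.
#'
#' @param tsv_path path to the table.
#' @param dataset optional `genotype_dataset` to join against by IID;
#'   unmatched ids on either side are reported with a warning.
#' @return data.frame with one row per phenotype record (joined to dataset
#'   order when `dataset` is given).
#' @export
load_phenotypes <- function(tsv_path, dataset = NULL) {
  x <- data.table::fread(tsv_path, sep = "\t", header = TRUE,
                         na.strings = "NA", data.table = FALSE)
  need <- setdiff(c("IID", "STATUS"), names(x))
  if (length(need))
    stop("phenotype table lacks column(s): ", paste(need, collapse = ", "))
  x$IID <- as.character(x$IID)
  if (any(duplicated(x$IID)))
    stop("duplicate IID in phenotype table: ",
         paste(head(x$IID[duplicated(x$IID)], 3), collapse = ", "))
  if (!all(x$STATUS %in% c(0, 1)))
    stop("STATUS must be 0/1")
  if ("RENAL" %in% names(x) && !all(is.na(x$RENAL) | x$RENAL %in% c(0, 1)))
    stop("RENAL must be 0/1/NA")
  if ("ONSET" %in% names(x) && any(!is.na(x$ONSET) & x$ONSET <= 0))
    stop("ONSET must be positive (years)")
  if (!is.null(dataset)) {
    ids <- as.character(dataset$fam$iid)
    unmatched_pheno <- setdiff(x$IID, ids)
    unmatched_geno <- setdiff(ids, x$IID)
    if (length(unmatched_pheno) || length(unmatched_geno))
      warning(length(unmatched_pheno), " phenotype id(s) and ",
              length(unmatched_geno),
              " genotyped id(s) have no match and are dropped from the join")
    x <- x[match(ids, x$IID), , drop = FALSE]
    x <- x[!is.na(x$IID), , drop = FALSE]
    rownames(x) <- NULL
  }
  x
}

#' Write a phenotype table
#'
#' @param pheno data.frame with at least `IID` and `STATUS`.
#' @param tsv_path output path.
#' @return `tsv_path`, invisibly.
#' @export
write_phenotypes <- function(pheno, tsv_path) {
  data.table::fwrite(pheno, tsv_path, sep = "\t", na = "NA", quote = FALSE)
  invisible(tsv_path)
}
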