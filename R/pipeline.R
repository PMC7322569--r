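## Experiment orchestration: simulate (or load) cohorts, run
## GWAS -> clump -> score -> evaluate over training/testing pairs, the
## polarized binned-Z polygenicity test, and the severity/onset analyses.

#' Build an experiment configuration
#'
#' @param cohorts named list of cohort specs.  A simulated cohort is
#'   `list(type = "simulated", n_cases =, n_controls =, fst =, ...)` where
#'   extra entries override [sim_config()] fields; a fileset cohort is
#'   `list(type = "fileset", prefix =, pheno =)` (PLINK-1 trio plus a
#'   phenotype TSV).  The first cohort defines the variant panel that
#'   simulated cohorts share.
#' @param pairs list of `c(train, test)` cohort-name pairs for the C+T
#'   sweep; default: every ordered pair.
#' @param discovery cohort used as the polygenicity-test discovery study
#'   (default: first cohort).
#' @param polytest_target target study for the polarized-Z test (default:
#'   second cohort).
#' @param grid list with `p1_list`, `r2_list`, `kb_list`
#'   (default [default_ct_grid()]).
#' @param assoc_test association test for the training GWAS.
#' @param missing_policy,mhc_tags scoring policies (see
#'   [train_test_score()]).
#' @param published_weights optional path to a published-SNP weight TSV
#'   used for the severity/onset analyses instead of a trained score.
#' @param age_cutoff years separating early from late onset (default 30).
#' @param seed master seed; every stage derives its stream from it.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(cohorts, pairs = NULL, discovery = NULL,
                              polytest_target = NULL,
                              grid = default_ct_grid(),
                              assoc_test = "allelic_chisq",
                              missing_policy = "mean_dosage",
                              mhc_tags = "none",
                              published_weights = NULL,
                              age_cutoff = 30, seed = 1) {
  stopifnot(is.list(cohorts), length(cohorts) >= 2,
            !is.null(names(cohorts)), all(nzchar(names(cohorts))))
  stopifnot(length(grid$p1_list) > 0, length(grid$r2_list) > 0,
            length(grid$kb_list) > 0)
  nm <- names(cohorts)
  if (is.null(discovery)) discovery <- nm[1]
  if (is.null(polytest_target)) polytest_target <- nm[2]
  if (is.null(pairs)) {
    pairs <- list()
    for (a in nm) for (b in nm) if (a != b) pairs <- c(pairs, list(c(a, b)))
  }
  for (p in pairs) stopifnot(length(p) == 2, all(p %in% nm))
  structure(list(cohorts = cohorts, pairs = pairs, discovery = discovery,
                 polytest_target = polytest_target, grid = grid,
                 assoc_test = assoc_test, missing_policy = missing_policy,
                 mhc_tags = mhc_tags, published_weights = published_weights,
                 age_cutoff = age_cutoff, seed = as.integer(seed)),
            class = "experiment_config")
}

load_or_simulate_cohort <- function(name, spec, master_seed, panel) {
  if (identical(spec$type, "fileset")) {
    ds <- load_genotype_fileset(spec$prefix)
    ph <- load_phenotypes(spec$pheno, ds)
    return(list(dataset = ds, pheno = ph, panel = panel, simulated = FALSE))
  }
  over <- spec[setdiff(names(spec), c("type", "n_cases", "n_controls"))]
  over$seed <- stage_seed(master_seed, paste0("cohort:", name))
  cfg <- do.call(sim_config, over)
  sim <- simulate_cohort(cfg, n_cases = spec$n_cases,
                         n_controls = spec$n_controls, panel = panel)
  list(dataset = sim$dataset, pheno = sim_phenotypes(sim, pop = name),
       panel = sim$panel, truth = sim$truth, simulated = TRUE)
}

#' Run the full experiment
#'
#' Deterministic given the config seed.  Produces the per-pair AUC grid
#' table, the binned polarized-Z table, score distributions by disease
#' level, quintile odds-ratio tables (overall and by age-of-onset group),
#' and the onset analyses.
#'
#' @param config an [experiment_config()].
#' @return list of class `experiment_report` with elements `auc_grid`,
#'   `binned_z`, `score_levels`, `quintile_overall`, `quintile_by_age`,
#'   `anova`, `onset_glm`, `renal_onset_glm`, `qc`, `meta`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  log <- character(0)
  note <- function(...) {
    msg <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   paste0(...))
    log <<- c(log, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- cohorts
  cohorts <- list()
  panel <- NULL
  for (nm in names(config$cohorts)) {
    cohorts[[nm]] <- stage(paste0("cohort:", nm),
      load_or_simulate_cohort(nm, config$cohorts[[nm]], config$seed, panel))
    if (is.null(panel)) panel <- cohorts[[nm]]$panel
    note("cohort ", nm, ": ", nrow(cohorts[[nm]]$dataset$fam), " samples")
  }

  ## ---- per-pair GWAS -> C+T grid -> scores -> AUC
  assoc_cache <- list()
  qc_cache <- list()
  train_assoc <- function(nm) {
    if (!is.null(assoc_cache[[nm]])) return(assoc_cache[[nm]])
    co <- cohorts[[nm]]
    qc <- variant_qc(co$dataset,
                     exclude_regions = list(c("6", 24e6, 36e6)),
                     exclude_chroms = c("X", "23"))
    a <- snp_association(qc$dataset, co$pheno$STATUS, test = config$assoc_test)
    assoc_cache[[nm]] <<- list(assoc = a, dataset = qc$dataset)
    qc_cache[[nm]] <<- qc$report
    assoc_cache[[nm]]
  }

  auc_rows <- list()
  for (pr in config$pairs) {
    tr <- pr[1]; te <- pr[2]
    ta <- stage(paste0("gwas:", tr), train_assoc(tr))
    grid <- expand.grid(p1 = config$grid$p1_list, r2 = config$grid$r2_list,
                        kb = config$grid$kb_list, KEEP.OUT.ATTRS = FALSE)
    cl_all <- stage(paste0("clump:", tr),
                    ct_grid(ta$assoc, ta$dataset, config$grid$p1_list,
                            config$grid$r2_list, config$grid$kb_list))
    for (k in seq_len(nrow(grid))) {
      cl <- cl_all[[k]]
      row <- data.frame(train = tr, test = te, p1 = grid$p1[k],
                        r2 = grid$r2[k], kb = grid$kb[k],
                        n_snps = nrow(cl$index), auc = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_)
      if (nrow(cl$index) > 0) {
        w <- weight_table(cl$index$id, cl$index$ea, cl$index$beta,
                          source = "trained")
        if (config$mhc_tags != "none") {
          tags <- suppressWarnings(
            mhc_tag_weights(config$mhc_tags, ta$assoc))
          if (nrow(tags)) w <- rbind(w, tags[!tags$id %in% w$id, ])
          class(w) <- c("weight_table", "data.frame")
        }
        al <- suppressWarnings(align_weights(w, cohorts[[te]]$dataset))
        if (nrow(al$table) > 0) {
          sc <- score_samples(cohorts[[te]]$dataset, al,
                              missing_policy = config$missing_policy)
          roc <- roc_auc(sc$score, cohorts[[te]]$pheno$STATUS)
          row$auc <- roc$auc; row$ci_low <- roc$ci_low
          row$ci_high <- roc$ci_high
        }
      }
      auc_rows[[length(auc_rows) + 1]] <- row
    }
    note("pair ", tr, "->", te, ": ", nrow(grid), " grid points")
  }
  auc_grid <- do.call(rbind, auc_rows)

  ## ---- polarized binned-Z polygenicity test
  disc <- config$discovery; targ <- config$polytest_target
  binned <- stage("polytest", {
    da <- train_assoc(disc)
    ta <- train_assoc(targ)
    thin <- greedy_clump(da$assoc, da$dataset, clump_spec(1, 0.1, 250))
    d_thin <- da$assoc[da$assoc$id %in% thin$index$id, , drop = FALSE]
    pol <- polarize_z(d_thin, ta$assoc)
    binned_zero_mean_test(pol)
  })
  note("polytest ", disc, "->", targ, ": ",
       sum(binned$n_snps), " clumped SNPs")

  ## ---- severity / onset analyses on the discovery cohort, scored with
  ## weights trained out-of-sample (polytest target as training set), or
  ## with published weights when supplied.
  sev <- stage("severity", {
    co <- cohorts[[disc]]
    if (!is.null(config$published_weights)) {
      w <- load_weights(config$published_weights)
    } else {
      ta <- train_assoc(targ)
      cl <- greedy_clump(ta$assoc, ta$dataset,
                         clump_spec(config$grid$p1_list[
                           which.min(abs(log10(config$grid$p1_list) + 5))],
                           config$grid$r2_list[1], config$grid$kb_list[1]))
      weight_table(cl$index$id, cl$index$ea, cl$index$beta) -> w
    }
    al <- suppressWarnings(align_weights(w, co$dataset))
    sc <- score_samples(co$dataset, al,
                        missing_policy = config$missing_policy)
    ph <- co$pheno
    case <- ph$STATUS == 1
    level <- ifelse(!case, 0L, ifelse(is.na(ph$RENAL), NA_integer_,
                                      ph$RENAL + 1L))
    score_levels <- data.frame(iid = sc$iid, score = sc$score,
                               level = level)
    csc <- sc$score[case]
    renal <- ph$RENAL[case]
    onset <- ph$ONSET[case]
    okr <- !is.na(renal)
    q_all <- quintile_or(csc[okr], renal[okr])
    late <- !is.na(onset) & onset > config$age_cutoff
    early <- !is.na(onset) & onset <= config$age_cutoff
    q_by_age <- list(
      early = tryCatch(quintile_or(csc[okr & early], renal[okr & early]),
                       error = function(e) NULL),
      late = tryCatch(quintile_or(csc[okr & late], renal[okr & late]),
                      error = function(e) NULL))
    anova_tab <- tryCatch(
      two_way_anova_grs(csc[okr & !is.na(onset)],
                        ifelse(late[okr & !is.na(onset)], "late", "early"),
                        renal[okr & !is.na(onset)]),
      error = function(e) NULL)
    oko <- !is.na(onset)
    onset_glm <- glm_association(onset[oko],
                                 data.frame(score = csc[oko]),
                                 family = "linear")
    renal_onset_glm <- tryCatch(
      glm_association(renal[okr & oko],
                      data.frame(score = csc[okr & oko],
                                 onset = onset[okr & oko]),
                      family = "logistic"),
      error = function(e) NULL)
    list(score_levels = score_levels, quintile_overall = q_all,
         quintile_by_age = q_by_age, anova = anova_tab,
         onset_glm = onset_glm, renal_onset_glm = renal_onset_glm)
  })
  note("severity/onset analyses done")

  meta <- list(seed = config$seed,
               age_cutoff = config$age_cutoff,
               assoc_test = config$assoc_test,
               missing_policy = config$missing_policy,
               mhc_tags = config$mhc_tags,
               grid = config$grid,
               config_hash = config_hash(config),
               timestamp = format(t0, "%Y-%m-%d %H:%M:%S"),
               log = log)
  structure(c(list(auc_grid = auc_grid, binned_z = binned, qc = qc_cache,
                   meta = meta), sev),
            class = "experiment_report")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  ## strip the serialization header (timestamps/versions) is unnecessary:
  ## saveRDS output is deterministic for a fixed R version
  unname(tools::md5sum(f))
}

#' Write an experiment report bundle to disk
#'
#' Emits `summary.json`, one TSV per table, and `run.log` with per-stage
#' timings, thresholds and seeds.
#'
#' @param report an `experiment_report` from [run_experiment()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  wt <- function(x, nm) if (!is.null(x))
    data.table::fwrite(as.data.frame(x), file.path(out_dir, nm),
                       sep = "\t", na = "NA", quote = FALSE)
  wt(report$auc_grid, "auc_grid.tsv")
  if (!is.null(report$binned_z))
    write_binned_z(report$binned_z, file.path(out_dir, "binned_z.tsv"))
  wt(report$score_levels, "score_levels.tsv")
  wt(report$quintile_overall, "quintile_overall.tsv")
  wt(report$quintile_by_age$early, "quintile_early_onset.tsv")
  wt(report$quintile_by_age$late, "quintile_late_onset.tsv")
  wt(report$anova, "anova.tsv")
  wt(report$onset_glm, "onset_glm.tsv")
  wt(report$renal_onset_glm, "renal_onset_glm.tsv")

  summary <- list(
    meta = report$meta[setdiff(names(report$meta), "log")],
    qc = lapply(report$qc, unclass),
    n_grid_rows = if (is.null(report$auc_grid)) 0L else nrow(report$auc_grid),
    best_auc = if (!is.null(report$auc_grid) &&
                   any(is.finite(report$auc_grid$auc)))
      report$auc_grid[which.max(report$auc_grid$auc), ] else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(report$meta$log %||% character(0),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}
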