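# End-to-end orchestration: generate -> QC/normalize -> per-stratum training
# -> validation -> signature scoring -> treatment stratification -> report.

#' Shipped example rank-linear 10-gene signature
#'
#' Loads the synthetic example 10-gene rank-linear signature installed with
#' the package (inst/extdata/synthetic_10gs_signature.csv). The published
#' surrogate's coefficients are not redistributed here; these placeholder
#' coefficients exercise the scoring machinery and can be replaced by a
#' user-supplied signature file.
#'
#' @return a [rank_linear_signature()].
#' @export
default_ten_gs_signature <- function() {
  read_signature(system.file("extdata", "synthetic_10gs_signature.csv",
                             package = "radSSP", mustWork = TRUE))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a synthetic cohort, quality-filters and normalizes it, trains a
#' k-TSP single-sample predictor per ER-by-RT stratum in the discovery
#' cohort (strata with too few cases or controls are skipped with a
#' warning), locks the models and evaluates them in the validation cohort
#' (AUC, Kaplan-Meier and log-rank by predicted class), computes the
#' 10-gene / proliferation / immune signature scores and their pairwise
#' correlations, and applies the consecutive-classifier treatment
#' stratification per ER group. Reruns with the same configuration are
#' bit-identical.
#'
#' @param config a [cohort_config()].
#' @param manifest panel manifest.
#' @param min_k minimum number of pairs in the k grid (default 101).
#' @param folds cross-validation folds for the choice of k.
#' @param min_per_class smallest trainable class size per stratum.
#' @param signature a [rank_linear_signature()] for the 10-gene score;
#'   default: the shipped synthetic example.
#' @param qc_args list of overrides passed to [qc_filter()].
#' @param out_dir optional directory; when given, models (JSON), score table
#'   (TSV), treatment assignments (CSV) and the run report (JSON) are
#'   written there.
#' @return object of class \code{ssp_run}; see the vignette for a tour of
#'   its fields.
#' @export
run_pipeline <- function(config = cohort_config(), manifest = panel_manifest(),
                         min_k = 101L, folds = 5, min_per_class = 10L,
                         signature = NULL, qc_args = list(),
                         out_dir = NULL) {
  if (is.null(signature)) signature <- default_ten_gs_signature()
  cohort <- generate_cohort(config, manifest)
  qc <- do.call(qc_filter, c(list(cohort$counts), qc_args))
  expr_log <- normalize_counts(qc$counts)
  expr_lin <- normalize_counts(qc$counts, log2 = FALSE)

  ann <- cohort$annotation
  ann <- ann[ann$sample_id %in% colnames(expr_log), , drop = FALSE]
  ann$stratum <- stratum_of(ann$er_status, ann$rt)
  disc <- ann[ann$cohort == "discovery", ]
  val <- ann[ann$cohort == "validation", ]

  # per-stratum training in the discovery cohort
  models <- list()
  skipped <- character(0)
  for (s in STRATA) {
    ds <- disc[disc$stratum == s, ]
    n1 <- sum(ds$ibtr_event); n0 <- sum(!ds$ibtr_event)
    if (min(n1, n0) < min_per_class) {
      skipped[s] <- sprintf("%d cases / %d controls (need %d per class)",
                            n1, n0, min_per_class)
      warning("stratum ", s, " skipped: ", skipped[s])
      next
    }
    models[[s]] <- train_ssp(expr_log[, ds$sample_id, drop = FALSE],
                             ds$ibtr_event, stratum = s, min_k = min_k,
                             folds = folds, seed = config$seed,
                             min_per_class = min_per_class)
  }

  # validation of the locked models
  validation <- list()
  for (s in names(models)) {
    vs <- val[val$stratum == s, ]
    if (nrow(vs) < 2 || length(unique(vs$ibtr_event)) < 2) {
      validation[[s]] <- list(note = "too few validation samples")
      next
    }
    pr <- predict(models[[s]], expr_log[, vs$sample_id, drop = FALSE])
    auc <- roc_auc(pr$vote_fraction, vs$ibtr_event)$auc
    lr <- if (length(unique(pr$class)) == 2 && sum(vs$ibtr_event) >= 1) {
      logrank_test(vs$time_years, vs$ibtr_event, pr$class)$p
    } else NA_real_
    validation[[s]] <- list(n = nrow(vs), auc = auc, logrank_p = lr,
                            predictions = cbind(pr, ibtr_event = vs$ibtr_event))
  }

  # signature scores on all retained samples (combined cohorts)
  vote <- rep(NA_real_, nrow(ann))
  for (s in names(models)) {
    idx <- ann$stratum == s
    if (any(idx)) {
      vote[idx] <- predict(models[[s]],
                           expr_log[, ann$sample_id[idx], drop = FALSE])$vote_fraction
    }
  }
  scores <- data.frame(
    sample_id = ann$sample_id,
    ssp_vote_fraction = vote,
    ten_gs = unname(rank_linear_score(expr_log, signature)[ann$sample_id]),
    proliferation = unname(geometric_mean_score(expr_lin,
                                                proliferation_genes())[ann$sample_id]),
    immune = unname(geometric_mean_score(expr_lin, immune_genes())[ann$sample_id]))
  scores$ten_gs_high <- dichotomize_median(scores$ten_gs)

  score_cols <- c("ssp_vote_fraction", "ten_gs", "proliferation", "immune")
  correlations <- do.call(rbind, lapply(utils::combn(score_cols, 2,
                                                     simplify = FALSE),
    function(pp) {
      ok <- stats::complete.cases(scores[pp])
      cc <- correlate_scores(scores[[pp[1]]][ok], scores[[pp[2]]][ok])
      data.frame(score_x = pp[1], score_y = pp[2], pearson_r = cc$pearson_r,
                 slope = cc$slope, p_zero_slope = cc$p_zero_slope, n = cc$n)
    }))

  # consecutive-classifier treatment stratification per ER group
  stratification <- list()
  for (er in c("pos", "neg")) {
    pre <- if (er == "pos") "ER+" else "ER-"
    m_minus <- models[[paste0(pre, "RT-")]]
    m_plus <- models[[paste0(pre, "RT+")]]
    vs <- val[val$er_status == er, ]
    if (is.null(m_minus) || is.null(m_plus) || nrow(vs) < 2) {
      stratification[[er]] <- list(note = "required SSP(s) unavailable or too few samples")
      next
    }
    asg <- assign_groups(expr_log[, vs$sample_id, drop = FALSE],
                         m_minus, m_plus, er_status = vs$er_status)
    stratification[[er]] <- list(
      assignments = asg,
      evaluation = suppressWarnings(evaluate_rt_benefit(asg, vs)))
  }

  report <- structure(
    list(config = unclass(config),
         qc_report = qc$report,
         models = models,
         skipped_strata = as.list(skipped),
         validation = validation,
         scores = scores,
         correlations = correlations,
         stratification = stratification,
         seeds = list(cohort = config$seed, cv = config$seed)),
    class = "ssp_run")

  if (!is.null(out_dir)) write_run(report, out_dir)
  report
}

#' @export
print.ssp_run <- function(x, ...) {
  cat("SSP pipeline run:", length(x$models), "trained model(s) [",
      paste(names(x$models), collapse = ", "), "];",
      length(x$skipped_strata), "stratum/strata skipped\n")
  for (s in names(x$validation)) {
    v <- x$validation[[s]]
    if (!is.null(v$auc)) {
      cat(sprintf("  %s: validation AUC %.3f, log-rank p %.3g (n=%d)\n",
                  s, v$auc, v$logrank_p, v$n))
    }
  }
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Serializes every model (JSON), the score table (TSV), treatment
#' assignments (CSV) and a machine-readable run report (JSON, deterministic
#' byte-for-byte under a fixed configuration).
#'
#' @param report an \code{ssp_run}.
#' @param dir output directory.
#' @return invisibly, the report path.
#' @export
write_run <- function(report, dir) {
  stopifnot(inherits(report, "ssp_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(report$models)) {
    save_ssp(report$models[[s]],
             file.path(dir, paste0("ssp_", gsub("[+]", "p", gsub("-", "m", s)),
                                   ".json")))
  }
  utils::write.table(report$scores, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (er in names(report$stratification)) {
    asg <- report$stratification[[er]]$assignments
    if (!is.null(asg)) {
      utils::write.csv(asg, file.path(dir, paste0("assignments_ER", er, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  path <- file.path(dir, "report.json")
  jsonlite::write_json(as_report_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# plain-list view of the run report, safe for deterministic JSON
as_report_list <- function(report) {
  strip_cox <- function(cx) {
    if (is.null(cx)) return(NULL)
    list(coefficients = as.list(cx$coefficients),
         hazard_ratios = as.list(cx$hazard_ratios),
         ci95 = apply(cx$ci95, 1, as.list),
         p_values = as.list(cx$p_values),
         n = cx$n, n_events = cx$n_events, ties = cx$ties)
  }
  strat <- lapply(report$stratification, function(st) {
    if (!is.null(st$note)) return(st["note"])
    ev <- st$evaluation
    list(assignments = st$assignments,
         per_group = lapply(ev$per_group, function(g) {
           g$km <- lapply(g$km$curves, identity)
           g
         }),
         cox = strip_cox(ev$cox),
         cox_note = ev$cox_note,
         prognostic_logrank = ev$prognostic_logrank)
  })
  list(config = report$config,
       qc = unclass(report$qc_report),
       models = lapply(report$models, unclass),
       skipped_strata = report$skipped_strata,
       validation = report$validation,
       scores = report$scores,
       correlations = report$correlations,
       stratification = strat,
       seeds = report$seeds)
}
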