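# Consecutive-classifier treatment stratification: an SSP trained in
# RT-untreated patients estimates the risk without radiotherapy; samples it
# calls low risk need no RT. For the rest, an SSP trained in RT-treated
# patients estimates the risk despite radiotherapy: low risk means RT should
# suffice, high risk flags intrinsic radioresistance.

#' Assign samples to No-RT / Give-RT / More-treatment groups
#'
#' Applies two locked SSPs consecutively: samples predicted low risk by the
#' RT- model go to "No-RT" (the RT+ model is not evaluated for them); of the
#' remainder, those predicted low risk by the RT+ model go to "Give-RT" and
#' those predicted high risk go to "More-treatment".
#'
#' @param expr gene-by-sample expression matrix.
#' @param ssp_rtminus SSP trained in RT-untreated patients (stratum ending
#'   "RT-").
#' @param ssp_rtplus SSP trained in RT-treated patients (stratum ending
#'   "RT+").
#' @param er_status optional per-sample ER status ("pos"/"neg"); when given,
#'   it must match the ER arm of both models unless
#'   \code{allow_mismatch = TRUE}.
#' @param allow_mismatch skip the model/stratum consistency checks.
#' @return data.frame with sample_id, group (factor No-RT / Give-RT /
#'   More-treatment), rtminus_prediction and rtplus_prediction
#'   (high / low / not_evaluated).
#' @export
assign_groups <- function(expr, ssp_rtminus, ssp_rtplus, er_status = NULL,
                          allow_mismatch = FALSE) {
  stopifnot(inherits(ssp_rtminus, "ssp"), inherits(ssp_rtplus, "ssp"))
  if (!allow_mismatch) {
    if (!endsWith(ssp_rtminus$stratum, "RT-")) {
      stop("ssp_rtminus was trained in stratum '", ssp_rtminus$stratum,
           "', not an RT- stratum (set allow_mismatch = TRUE to override)")
    }
    if (!endsWith(ssp_rtplus$stratum, "RT+")) {
      stop("ssp_rtplus was trained in stratum '", ssp_rtplus$stratum,
           "', not an RT+ stratum (set allow_mismatch = TRUE to override)")
    }
    if (!is.null(er_status)) {
      er_arm <- function(s) if (startsWith(s, "ER+")) "pos" else "neg"
      want <- unique(c(er_arm(ssp_rtminus$stratum), er_arm(ssp_rtplus$stratum)))
      bad <- unique(er_status[!er_status %in% want])
      if (length(want) > 1 || length(bad)) {
        stop("model/sample ER status mismatch (models: ",
             ssp_rtminus$stratum, ", ", ssp_rtplus$stratum,
             "); set allow_mismatch = TRUE to override")
      }
    }
  }
  p_minus <- predict(ssp_rtminus, expr)
  p_plus <- predict(ssp_rtplus, expr)
  no_rt <- p_minus$class == "low"
  group <- ifelse(no_rt, "No-RT",
                  ifelse(p_plus$class == "low", "Give-RT", "More-treatment"))
  data.frame(sample_id = p_minus$sample_id,
             group = factor(group,
                            levels = c("No-RT", "Give-RT", "More-treatment")),
             rtminus_prediction = p_minus$class,
             rtplus_prediction = ifelse(no_rt, "not_evaluated", p_plus$class),
             row.names = NULL)
}

#' Evaluate radiotherapy benefit per treatment-stratification group
#'
#' For every group containing both RT-treated and RT-untreated samples,
#' Kaplan-Meier curves split by RT and a log-rank p-value for the RT effect
#' are computed; groups lacking one RT arm are reported prognostic-only.
#' Overall, a Cox model with the group indicators, RT and the group-by-RT
#' interaction is fitted (when feasible), plus a prognostic log-rank test
#' across groups.
#'
#' @param assignments output of [assign_groups()].
#' @param annotation sample annotation with sample_id, rt, ibtr_event,
#'   time_years.
#' @param t_risk horizon (years) for the reported cumulative risk.
#' @return object of class \code{rt_benefit}: per_group results (km,
#'   logrank_p or prognostic_only flag, risk at \code{t_risk} per arm),
#'   \code{cox} interaction fit (or NULL with a note when infeasible) and
#'   the across-group prognostic log-rank test.
#' @export
evaluate_rt_benefit <- function(assignments, annotation, t_risk = 10) {
  d <- merge(assignments, annotation, by = "sample_id")
  if (nrow(d) == 0) stop("no overlap between assignments and annotation")

  per_group <- list()
  for (g in levels(d$group)) {
    dg <- d[d$group == g, ]
    if (nrow(dg) == 0) {
      warning("group '", g, "' is empty; skipped")
      next
    }
    arms <- table(factor(dg$rt, levels = c(FALSE, TRUE)))
    res <- list(n = nrow(dg), n_rt = unname(arms["TRUE"]),
                n_nort = unname(arms["FALSE"]))
    if (all(arms >= 1) && sum(dg$ibtr_event) >= 1) {
      res$prognostic_only <- FALSE
      res$km <- km_fit(dg$time_years, dg$ibtr_event,
                       ifelse(dg$rt, "RT+", "RT-"))
      lr <- logrank_test(dg$time_years, dg$ibtr_event, dg$rt)
      res$logrank_p <- lr$p
      res$risk <- vapply(names(res$km$curves), function(a)
        risk_at(res$km, t_risk, a), numeric(1))
    } else {
      res$prognostic_only <- TRUE
      res$km <- km_fit(dg$time_years, dg$ibtr_event)
      res$risk <- c(all = risk_at(res$km, t_risk))
    }
    per_group[[g]] <- res
  }

  prognostic <- if (length(unique(d$group)) >= 2 && sum(d$ibtr_event) >= 1) {
    logrank_test(d$time_years, d$ibtr_event, as.character(d$group))
  } else NULL

  d$group <- droplevels(d$group)
  cox <- tryCatch(
    cox_fit(survival::Surv(time_years, ibtr_event) ~ group * rt, data = d),
    error = function(e) {
      structure(list(note = paste("interaction model not fitted:",
                                  conditionMessage(e))), class = "cox_skip")
    })
  if (inherits(cox, "cox_skip")) {
    note <- cox$note
    cox <- NULL
  } else note <- NULL

  structure(list(per_group = per_group, cox = cox, cox_note = note,
                 prognostic_logrank = prognostic, t_risk = t_risk),
            class = "rt_benefit")
}

#' @export
print.rt_benefit <- function(x, ...) {
  cat("RT-benefit evaluation by treatment-stratification group\n")
  for (g in names(x$per_group)) {
    res <- x$per_group[[g]]
    cat(sprintf("  %-15s n=%3d", g, res$n))
    if (isTRUE(res$prognostic_only)) {
      cat(sprintf("  prognostic-only; %g-yr risk %.2f\n", x$t_risk,
                  res$risk[["all"]]))
    } else {
      cat(sprintf("  log-rank p(RT) = %.4g; %g-yr risk RT+ %.2f / RT- %.2f\n",
                  res$logrank_p, x$t_risk, res$risk[["RT+"]], res$risk[["RT-"]]))
    }
  }
  if (!is.null(x$cox)) {
    int <- grep(":", names(x$cox$coefficients), value = TRUE)
    if (length(int)) {
      cat(sprintf("  interaction %s: HR %.3g (p = %.3g)\n", int[1],
                  x$cox$hazard_ratios[int[1]], x$cox$p_values[int[1]]))
    }
  } else if (!is.null(x$cox_note)) cat(" ", x$cox_note, "\n")
  invisible(x)
}
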