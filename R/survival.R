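# Survival evaluation layer: Kaplan-Meier, log-rank, Cox with interaction
# terms, ROC/AUC. Estimation is delegated to the survival and pROC packages;
# this file defines the package's stable result containers and guards.

#' Kaplan-Meier curves per group
#'
#' Product-limit estimate of IBTR-free survival, optionally split by group.
#'
#' @param time positive event/censoring times (years).
#' @param event logical or 0/1 event indicator (TRUE = IBTR).
#' @param group optional grouping vector; one curve per level.
#' @return object of class \code{km_curves}: per group, a data.frame with
#'   time, n_risk, n_event, survival.
#' @examples
#' km <- km_fit(c(1, 2, 3), c(1, 1, 0))
#' km$curves[["all"]]$survival  # 2/3, 1/3
#' @export
km_fit <- function(time, event, group = NULL) {
  check_survival_inputs(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.character(group)
  if (any(!table(group) >= 1)) stop("empty group")
  curves <- lapply(split(seq_along(time), group), function(idx) {
    fit <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               survival = fit$surv)
  })
  structure(list(curves = curves, n = as.list(table(group))),
            class = "km_curves")
}

check_survival_inputs <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (length(time) == 0) stop("no samples")
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be positive")
  if (anyNA(event)) stop("event must not contain NA")
  invisible(TRUE)
}

#' Cumulative risk from a Kaplan-Meier curve
#'
#' Reads 1 - S(t) off the step function at the last event time <= t
#' (e.g. the 10-year IBTR risk of a group).
#'
#' @param km a [km_fit()] result.
#' @param t time point (years).
#' @param group group name (defaults to the single curve).
#' @return numeric risk in [0, 1].
#' @export
risk_at <- function(km, t, group = NULL) {
  stopifnot(inherits(km, "km_curves"))
  if (is.null(group)) {
    if (length(km$curves) != 1) stop("specify a group")
    group <- names(km$curves)
  }
  cv <- km$curves[[group]]
  if (is.null(cv)) stop("no such group: ", group)
  past <- cv$time <= t
  if (!any(past)) return(0)
  1 - cv$survival[max(which(past))]
}

#' @export
print.km_curves <- function(x, ...) {
  cat("Kaplan-Meier curves for", length(x$curves), "group(s):",
      paste(names(x$curves), collapse = ", "), "\n")
  invisible(x)
}

#' Log-rank test
#'
#' Standard log-rank statistic (observed minus hypergeometric-expected events
#' at each event time), chi-square with (groups - 1) degrees of freedom.
#'
#' @inheritParams km_fit
#' @param group grouping vector with >= 2 non-empty levels.
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @export
logrank_test <- function(time, event, group) {
  check_survival_inputs(time, event)
  group <- as.character(group)
  tab <- table(group)
  if (length(tab) < 2) stop("log-rank needs at least two non-empty groups")
  if (sum(event) < 1) stop("log-rank needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  df <- length(tab) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with interaction support
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling by default,
#' Efron behind the \code{ties} flag) and reports coefficients, hazard
#' ratios, Wald 95% confidence intervals and p-values. Fits with fewer than
#' 5 events per coefficient, constant covariates, monotone likelihood
#' (separation) or non-convergence are rejected with an informative error.
#'
#' @param formula model formula with a \code{survival::Surv} response, e.g.
#'   \code{Surv(time_years, ibtr_event) ~ group * rt}.
#' @param data data.frame with the model variables.
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @param max_coef absolute coefficient beyond which the likelihood is
#'   declared monotone (separation guard).
#' @return object of class \code{cox_fit}: coefficients, hazard_ratios, ci95
#'   (matrix with lower/upper), p_values, converged, n, n_events, and the
#'   underlying \code{coxph} fit in \code{$fit}.
#' @export
cox_fit <- function(formula, data, ties = c("breslow", "efron"),
                    max_coef = 15) {
  ties <- match.arg(ties)
  fit <- withCallingHandlers(
    survival::coxph(formula, data = data, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        stop("Cox partial likelihood is monotone (separation) or did not ",
             "converge: ", conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("covariate(s) carry no information (constant or aliased): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  if (any(abs(cf) > max_coef)) {
    stop("coefficient exceeds ", max_coef, ": monotone likelihood / separation")
  }
  if (fit$nevent < 5 * length(cf)) {
    stop("only ", fit$nevent, " events for ", length(cf),
         " coefficients; need at least ", 5 * length(cf))
  }
  se <- sqrt(diag(fit$var))
  ci <- cbind(lower = exp(cf - 1.96 * se), upper = exp(cf + 1.96 * se))
  structure(list(coefficients = cf,
                 hazard_ratios = exp(cf),
                 ci95 = ci,
                 p_values = 2 * stats::pnorm(-abs(cf / se)),
                 converged = TRUE,
                 n = fit$n, n_events = fit$nevent,
                 ties = ties, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), ",
      x$n, " samples / ", x$n_events, " events\n", sep = "")
  out <- data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                    ci_low = x$ci95[, "lower"], ci_high = x$ci95[, "upper"],
                    p = x$p_values)
  print(round(out, 4))
  invisible(x)
}

#' ROC curve and AUC for a continuous score against binary outcome
#'
#' AUC equals the Mann-Whitney concordance probability (ties count 1/2);
#' higher scores are taken to indicate the positive outcome. Curve points are
#' given at every score threshold.
#'
#' @param scores numeric risk scores.
#' @param outcome logical or 0/1 outcome (TRUE = event).
#' @return list with \code{auc} and \code{curve} (data.frame threshold,
#'   sensitivity, specificity).
#' @export
roc_auc <- function(scores, outcome) {
  if (is.numeric(outcome)) outcome <- outcome != 0
  if (length(scores) != length(outcome)) stop("lengths differ")
  if (length(unique(outcome)) < 2) stop("both outcome classes required")
  r <- pROC::roc(response = outcome, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  list(auc = as.numeric(r$auc),
       curve = data.frame(threshold = r$thresholds,
                          sensitivity = r$sensitivities,
                          specificity = r$specificities))
}
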