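#' Configuration for the synthetic nCounter cohort generator
#'
#' Describes the study design the generator emulates: two cohorts (discovery
#' and validation), four ER-by-RT strata with case/control sampling for
#' ipsilateral breast tumor recurrence (IBTR), negative-binomial counts with
#' lognormal library-size factors, a planted within-sample pair-order signal,
#' and censored time-to-IBTR outcomes.
#'
#' The defaults mirror the study design the package targets: 172 discovery and
#' 164 validation samples, stratum frequencies that reproduce the ER/RT
#' margins of a breast-conserving-surgery case-control series (with ER-RT-
#' deliberately tiny, ~3 validation samples, to exercise the small-stratum
#' guard), roughly 40% cases per stratum, and an order-based signal of 10
#' disjoint gene pairs per stratum with a class difference of 0.6 in the
#' probability of within-sample ordering.
#'
#' @param n_discovery,n_validation cohort sizes.
#' @param stratum_fractions named fractions over the four strata
#'   (ER+RT+, ER+RT-, ER-RT+, ER-RT-); must sum to 1.
#' @param case_fraction fraction of IBTR cases per stratum (recycled to 4).
#' @param n_planted_pairs number of planted signal pairs per stratum.
#' @param planted_delta target difference P(A>B | case) - P(A>B | control)
#'   for each planted pair, in [0, 1].
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param size_factor_sd standard deviation of the per-sample log library-size
#'   factor (lognormal with log-mean 0).
#' @param median_time_to_ibtr median time to IBTR among cases, years
#'   (exponential event-time model).
#' @param followup_max_years upper bound of control follow-up, years.
#' @param seed integer RNG seed; the same config yields bit-identical cohorts.
#' @return a validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_discovery = 172,
                          n_validation = 164,
                          stratum_fractions = c("ER+RT+" = 0.55, "ER+RT-" = 0.22,
                                                "ER-RT+" = 0.21, "ER-RT-" = 0.02),
                          case_fraction = 0.4,
                          n_planted_pairs = 10,
                          planted_delta = 0.6,
                          nb_dispersion = 0.1,
                          size_factor_sd = 0.2,
                          median_time_to_ibtr = 4.4,
                          followup_max_years = 25,
                          seed = 1L) {
  cfg <- list(n_discovery = as.integer(n_discovery),
              n_validation = as.integer(n_validation),
              stratum_fractions = stratum_fractions,
              case_fraction = rep_len(case_fraction, 4L),
              n_planted_pairs = as.integer(n_planted_pairs),
              planted_delta = planted_delta,
              nb_dispersion = nb_dispersion,
              size_factor_sd = size_factor_sd,
              median_time_to_ibtr = median_time_to_ibtr,
              followup_max_years = followup_max_years,
              seed = as.integer(seed))
  names(cfg$case_fraction) <- STRATA
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_discovery + cfg$n_validation <= 0) stop("cohort sizes must be positive")
  if (cfg$n_discovery < 0 || cfg$n_validation < 0) stop("cohort sizes must be non-negative")
  sf <- cfg$stratum_fractions
  if (!setequal(names(sf), STRATA)) {
    stop("stratum_fractions must be named over ", paste(STRATA, collapse = ", "))
  }
  if (any(sf < 0) || any(sf > 1) || abs(sum(sf) - 1) > 1e-8) {
    stop("stratum_fractions must lie in [0,1] and sum to 1")
  }
  if (any(cfg$case_fraction < 0) || any(cfg$case_fraction > 1)) {
    stop("case_fraction must lie in [0,1]")
  }
  if (cfg$planted_delta < 0 || cfg$planted_delta > 1) {
    stop("planted_delta must lie in [0,1]")
  }
  if (cfg$nb_dispersion <= 0 || cfg$size_factor_sd <= 0 ||
      cfg$followup_max_years <= 0 || cfg$median_time_to_ibtr <= 0) {
    stop("dispersion, size_factor_sd and time parameters must be positive")
  }
  invisible(cfg)
}

#' Generate a synthetic nCounter cohort
#'
#' Draws a probe-by-sample count matrix and matching sample annotation under
#' the generative model described in the package vignette:
#' \itemize{
#'   \item endogenous counts are negative binomial with gene baseline means
#'     scaled by a lognormal per-sample size factor;
#'   \item housekeeping probes have high means and no case/control effect;
#'   \item positive controls follow a fixed 4-fold geometric concentration
#'     ladder scaled by the size factor, with Poisson noise; negative controls
#'     are Poisson with a small constant mean;
#'   \item for each planted pair (A, B) within a stratum the two baseline
#'     means are swapped between samples so that
#'     P(A>B | case) - P(A>B | control) is approximately
#'     \code{planted_delta} — a purely order-based signal;
#'   \item cases draw exponential event times (median
#'     \code{median_time_to_ibtr}); each control is censored at a time drawn
#'     uniformly between a matched case's event time and
#'     \code{followup_max_years}.
#' }
#'
#' @param config a [cohort_config()].
#' @param manifest a panel manifest; defaults to [panel_manifest()].
#' @return list of class \code{synthetic_cohort} with elements
#'   \code{counts} ([raw_counts]), \code{annotation} (data.frame with
#'   sample_id, cohort, er_status, rt, ibtr_event, time_years,
#'   endocrine_therapy, chemotherapy), \code{planted_pairs}
#'   (data.frame stratum, gene_a, gene_b; gene_a is the case-upregulated
#'   orientation) and \code{config}.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' table(cohort$annotation$cohort)
#' @export
generate_cohort <- function(config = cohort_config(), manifest = panel_manifest()) {
  validate_cohort_config(config)
  validate_manifest(manifest)
  endog <- manifest_genes(manifest, "endogenous")
  if (2L * config$n_planted_pairs > length(endog)) {
    stop("n_planted_pairs x 2 exceeds the ", length(endog), " endogenous genes")
  }
  n_strata_planted <- sum(config$stratum_fractions > 0)
  if (2L * config$n_planted_pairs * n_strata_planted > length(endog)) {
    stop("cannot plant ", config$n_planted_pairs,
         " disjoint pairs in each of ", n_strata_planted, " strata with only ",
         length(endog), " endogenous genes")
  }
  with_seed(config$seed, .generate_cohort_impl(config, manifest))
}

.generate_cohort_impl <- function(config, manifest) {
  annotation <- .draw_annotation(config)
  n <- nrow(annotation)
  if (n == 0) stop("empty cohort")

  endog <- manifest_genes(manifest, "endogenous")
  hk <- manifest_genes(manifest, "housekeeping")
  pos <- manifest_genes(manifest, "positive_ctrl")
  neg <- manifest_genes(manifest, "negative_ctrl")

  # gene baseline means: moderate lognormal-ish spread for endogenous probes,
  # high stable means for housekeeping
  mu <- stats::setNames(2^stats::runif(length(endog), 4, 10), endog)
  mu_hk <- stats::setNames(2^stats::runif(length(hk), 11, 13), hk)
  size_factor <- exp(stats::rnorm(n, 0, config$size_factor_sd))

  # planted pairs: disjoint within and across strata so each stratum's
  # classifier has its own clean order-based signal
  planted <- .assign_planted_pairs(config, endog)

  # per-sample means for endogenous genes, then the pair-swap signal.
  # Each pair lives in its own mean band (6-fold within-pair gap, 6-fold
  # band separation, bands cycling after 5), with all bands sitting above
  # the background-gene mean range: within a pair the two levels are
  # swapped between classes, so the signal is purely order-based, while
  # comparisons of a planted gene with any other gene keep a
  # class-independent order — the planted pairs themselves, not their
  # cross-combinations, carry the signal.
  mu_mat <- matrix(mu, nrow = length(endog), ncol = n,
                   dimnames = list(endog, annotation$sample_id))
  p_case <- 0.5 + config$planted_delta / 2
  p_ctrl <- 0.5 - config$planted_delta / 2
  if (nrow(planted)) {
    for (r in seq_len(nrow(planted))) {
      band <- (planted$pair_index[r] - 1L) %% 5L
      mu_lo <- 2048 * 6^band
      mu_hi <- 6 * mu_lo
      in_str <- annotation$stratum == planted$stratum[r]
      if (!any(in_str)) next
      p <- ifelse(annotation$ibtr_event[in_str], p_case, p_ctrl)
      a_high <- stats::rbinom(sum(in_str), 1L, p) == 1L
      mu_mat[planted$gene_a[r], in_str] <- ifelse(a_high, mu_hi, mu_lo)
      mu_mat[planted$gene_b[r], in_str] <- ifelse(a_high, mu_lo, mu_hi)
    }
  }

  nb_size <- 1 / config$nb_dispersion
  counts_endog <- matrix(
    stats::rnbinom(length(endog) * n,
                   mu = sweep(mu_mat, 2, size_factor, `*`),
                   size = nb_size),
    nrow = length(endog), dimnames = list(endog, annotation$sample_id))
  counts_hk <- matrix(
    stats::rnbinom(length(hk) * n,
                   mu = outer(mu_hk, size_factor),
                   size = nb_size),
    nrow = length(hk), dimnames = list(hk, annotation$sample_id))
  ladder <- positive_control_ladder(length(pos))
  counts_pos <- matrix(
    stats::rpois(length(pos) * n, outer(ladder, size_factor)),
    nrow = length(pos), dimnames = list(pos, annotation$sample_id))
  counts_neg <- matrix(
    stats::rpois(length(neg) * n, 2),
    nrow = length(neg), dimnames = list(neg, annotation$sample_id))

  counts <- rbind(counts_endog, counts_hk, counts_pos, counts_neg)
  counts <- counts[match(intersect(manifest$gene_id, rownames(counts)),
                         rownames(counts)), , drop = FALSE]
  storage.mode(counts) <- "integer"

  annotation$stratum <- NULL
  structure(list(counts = raw_counts(counts, manifest),
                 annotation = annotation,
                 planted_pairs = planted,
                 gene_means = c(mu, mu_hk),   # baselines before pair swaps
                 config = config),
            class = "synthetic_cohort")
}

# Sample strata, case/control labels and censored survival outcomes.
.draw_annotation <- function(config) {
  per_cohort <- function(n, cohort, id_offset) {
    if (n == 0) {
      return(NULL)
    }
    # largest-remainder rounding of stratum sizes so they sum to n
    target <- config$stratum_fractions[STRATA] * n
    sizes <- floor(target)
    rem <- n - sum(sizes)
    if (rem > 0) {
      top <- order(target - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[top] <- sizes[top] + 1L
    }
    rows <- lapply(seq_along(STRATA), function(i) {
      ns <- sizes[i]
      if (ns == 0) return(NULL)
      n_case <- round(config$case_fraction[i] * ns)
      data.frame(stratum = STRATA[i],
                 er_status = if (startsWith(STRATA[i], "ER+")) "pos" else "neg",
                 rt = grepl("RT\\+", STRATA[i]),
                 ibtr_event = seq_len(ns) <= n_case)
    })
    ann <- do.call(rbind, rows)
    ann$cohort <- cohort
    ann$sample_id <- sprintf("S%04d", id_offset + seq_len(nrow(ann)))
    ann
  }
  ann <- rbind(per_cohort(config$n_discovery, "discovery", 0L),
               per_cohort(config$n_validation, "validation",
                          config$n_discovery))
  if (is.null(ann)) stop("empty cohort")

  rate <- log(2) / config$median_time_to_ibtr
  time <- numeric(nrow(ann))
  cases <- ann$ibtr_event
  time[cases] <- pmin(stats::rexp(sum(cases), rate),
                      config$followup_max_years * 0.999)
  # each control censored after at least a matched case's time to IBTR
  for (s in unique(ann$stratum)) {
    ctl <- which(!cases & ann$stratum == s)
    if (!length(ctl)) next
    case_times <- time[cases & ann$stratum == s]
    floor_t <- if (length(case_times)) {
      case_times[sample.int(length(case_times), length(ctl), replace = TRUE)]
    } else rep(0.5, length(ctl))
    time[ctl] <- stats::runif(length(ctl), floor_t, config$followup_max_years)
  }
  ann$time_years <- pmax(time, 1e-3)
  ann$endocrine_therapy <- stats::rbinom(nrow(ann), 1L,
                                         ifelse(ann$er_status == "pos", 0.6, 0.1)) == 1L
  ann$chemotherapy <- stats::rbinom(nrow(ann), 1L, 0.2) == 1L
  rownames(ann) <- NULL
  ann[c("sample_id", "cohort", "er_status", "rt", "ibtr_event",
        "time_years", "endocrine_therapy", "chemotherapy", "stratum")]
}

.assign_planted_pairs <- function(config, endog) {
  strata <- STRATA[config$stratum_fractions[STRATA] > 0]
  k <- config$n_planted_pairs
  if (k == 0 || !length(strata)) {
    return(data.frame(stratum = character(), pair_index = integer(),
                      gene_a = character(), gene_b = character()))
  }
  picked <- sample(endog, 2L * k * length(strata))
  do.call(rbind, lapply(seq_along(strata), function(i) {
    block <- picked[((i - 1L) * 2L * k + 1L):(i * 2L * k)]
    data.frame(stratum = strata[i],
               pair_index = seq_len(k),
               gene_a = block[seq_len(k) * 2L - 1L],
               gene_b = block[seq_len(k) * 2L])
  }))
}

#' Positive-control concentration ladder
#'
#' Expected counts of the positive-control probes: a geometric titration
#' series in 4-fold steps (highest first), mirroring the standard nCounter
#' spike-in design.
#'
#' @param n number of positive-control probes.
#' @param top expected count of the most concentrated probe.
#' @return numeric vector of length \code{n}.
#' @export
positive_control_ladder <- function(n = 6, top = 32768) {
  top / 4^(seq_len(n) - 1)
}
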