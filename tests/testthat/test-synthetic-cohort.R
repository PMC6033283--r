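# Synthetic nCounter cohort generator.

test_that("default configuration reproduces the study's cohort sizes", {
  cohort <- generate_cohort(cohort_config(seed = 11))
  tab <- table(cohort$annotation$cohort)
  expect_equal(unname(tab[["discovery"]]), 172)
  expect_equal(unname(tab[["validation"]]), 164)
  expect_equal(ncol(cohort$counts$counts), 336)
  # every sample in the counts has an annotation row, times positive
  expect_setequal(colnames(cohort$counts$counts), cohort$annotation$sample_id)
  expect_true(all(cohort$annotation$time_years > 0))
  # counts are non-negative integers over the full 248-gene panel
  expect_true(all(cohort$counts$counts >= 0))
  expect_identical(storage.mode(cohort$counts$counts), "integer")
  m <- cohort$counts$manifest
  expect_equal(sum(m$probe_class %in% c("endogenous", "housekeeping")), 248)
  expect_equal(sum(m$probe_class == "housekeeping"), 13)
})

test_that("the ER-RT- stratum is deliberately tiny and case times censor controls", {
  cohort <- generate_cohort(cohort_config(seed = 2))
  ann <- cohort$annotation
  strat <- paste0(ifelse(ann$er_status == "pos", "ER+", "ER-"),
                  ifelse(ann$rt, "RT+", "RT-"))
  expect_lte(sum(strat == "ER-RT-" & ann$cohort == "validation"), 5)
  expect_true(all(ann$time_years <= cohort$config$followup_max_years))
  # controls are censored no earlier than the shortest case time per stratum
  for (s in unique(strat)) {
    ct <- ann$time_years[strat == s & ann$ibtr_event]
    if (!length(ct)) next
    expect_true(all(ann$time_years[strat == s & !ann$ibtr_event] >= min(ct)))
  }
})

test_that("same seed gives bit-identical cohorts, different seeds differ", {
  a <- generate_cohort(cohort_config(seed = 5))
  b <- generate_cohort(cohort_config(seed = 5))
  c <- generate_cohort(cohort_config(seed = 6))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$planted_pairs, b$planted_pairs)
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_discovery = 0, n_validation = 0), "positive")
  expect_error(cohort_config(planted_delta = 1.2), "planted_delta")
  expect_error(cohort_config(stratum_fractions = c("ER+RT+" = 0.5, "ER+RT-" = 0.2,
                                                   "ER-RT+" = 0.2, "ER-RT-" = 0.2)),
               "sum to 1")
  expect_error(generate_cohort(cohort_config(n_planted_pairs = 200)),
               "endogenous genes")
})

test_that("planted pairs reach the requested ordering difference (Monte Carlo)", {
  # 5 planted pairs, target class difference 0.6, 100 cases / 100 controls
  cfg <- function(seed) cohort_config(
    n_discovery = 200, n_validation = 0,
    stratum_fractions = c("ER+RT+" = 1, "ER+RT-" = 0, "ER-RT+" = 0, "ER-RT-" = 0),
    case_fraction = 0.5, n_planted_pairs = 5, planted_delta = 0.6, seed = seed)
  deltas <- vapply(1:20, function(seed) {
    cohort <- generate_cohort(cfg(seed))
    cc <- cohort$counts$counts
    case <- cohort$annotation$ibtr_event
    apply(cohort$planted_pairs, 1, function(p) {
      gt <- function(cls) {
        a <- cc[p[["gene_a"]], case == cls]; b <- cc[p[["gene_b"]], case == cls]
        mean((a > b) + 0.5 * (a == b))
      }
      abs(gt(TRUE) - gt(FALSE))
    })
  }, numeric(5))
  # Monte-Carlo estimate per pair, averaged over the 20 seeds
  expect_true(all(abs(rowMeans(deltas) - 0.6) <= 0.15))
})

test_that("without planted signal no pair shows a large ordering difference", {
  # generator null: empirical |delta| of every pair stays small at n=200/class
  manifest <- panel_manifest(n_genes = 100, n_housekeeping = 5)
  exceed <- vapply(1:20, function(seed) {
    cohort <- generate_cohort(cohort_config(
      n_discovery = 400, n_validation = 0,
      stratum_fractions = c("ER+RT+" = 1, "ER+RT-" = 0, "ER-RT+" = 0, "ER-RT-" = 0),
      case_fraction = 0.5, n_planted_pairs = 0, seed = seed), manifest)
    expr <- normalize_counts(qc_filter(cohort$counts)$counts)
    st <- radSSP:::pair_stat_matrices(expr[, cohort$annotation$sample_id],
                                      cohort$annotation$ibtr_event)
    max(abs(st$S[upper.tri(st$S)])) > 0.25
  }, logical(1))
  expect_lte(mean(exceed), 0.05)
})

test_that("housekeeping probes carry no case/control signal", {
  ok <- vapply(1:20, function(seed) {
    cohort <- generate_cohort(cohort_config(
      n_discovery = 120, n_validation = 0,
      stratum_fractions = c("ER+RT+" = 1, "ER+RT-" = 0, "ER-RT+" = 0, "ER-RT-" = 0),
      case_fraction = 0.5, seed = seed))
    hk <- cohort$counts$manifest$gene_id[
      cohort$counts$manifest$probe_class == "housekeeping"]
    lc <- log(cohort$counts$counts[hk, , drop = FALSE] + 1)
    p <- t.test(colMeans(lc[, cohort$annotation$ibtr_event]),
                colMeans(lc[, !cohort$annotation$ibtr_event]))$p.value
    p > 0.01
  }, logical(1))
  expect_gte(sum(ok), 18)
})

test_that("marginal count means converge to mu * E[size factor]", {
  cohort <- generate_cohort(cohort_config(
    n_discovery = 2000, n_validation = 0,
    stratum_fractions = c("ER+RT+" = 1, "ER+RT-" = 0, "ER-RT+" = 0, "ER-RT-" = 0),
    case_fraction = 0.5, n_planted_pairs = 0, seed = 4))
  mu <- cohort$gene_means
  ef <- exp(cohort$config$size_factor_sd^2 / 2)
  obs <- rowMeans(cohort$counts$counts[names(mu), ])
  expect_true(all(abs(obs / (mu * ef) - 1) < 0.10))
})

test_that("cohorts round-trip bit-exactly through the writers and readers", {
  cohort <- generate_cohort(cohort_config(n_discovery = 10, n_validation = 8,
                                          seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_cohort(cohort, dir = dir)
  rc <- read_counts(paths[["counts"]], paths[["manifest"]])
  expect_identical(rc$counts, cohort$counts$counts)
  ann <- read_annotation(paths[["annotation"]], colnames(rc$counts))
  expect_equal(ann$ibtr_event, cohort$annotation$ibtr_event)
  expect_equal(ann$time_years, cohort$annotation$time_years)

  # fixed seed twice -> identical files
  dir2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cohort_config(n_discovery = 10, n_validation = 8,
                                             seed = 3)), dir = dir2)
  for (f in c("counts.tsv", "manifest.csv", "annotation.csv")) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
})

test_that("writing an empty cohort is refused", {
  m <- tiny_manifest(2)
  mat <- matrix(integer(0), nrow = nrow(m), ncol = 0,
                dimnames = list(m$gene_id, NULL))
  expect_error(raw_counts(mat, m), "at least one sample")
})
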