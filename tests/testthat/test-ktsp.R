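# The k-TSP engine: pair scoring, disjoint selection, CV choice of k,
# majority-vote prediction, subsetting and serialization.

test_that("pair_score matches hand-enumerated orderings", {
  expr <- rbind(A = c(5, 6, 1, 2), B = c(1, 2, 5, 6), C = c(3, 3, 3, 3))
  colnames(expr) <- paste0("s", 1:4)
  lab <- c(TRUE, TRUE, FALSE, FALSE)

  # A above B in every class-1 sample, below in every class-0 sample
  expect_equal(pair_score(expr, lab, "A", "B")$delta, 1)
  # permuted labels so both classes see the same ordering frequencies
  expect_equal(pair_score(expr, c(TRUE, FALSE, TRUE, FALSE), "A", "B")$delta, 0)
  # class 1 orderings {A>B, A<B}, class 0 {A<B, A<B} -> |0.5 - 0| = 0.5
  expr2 <- rbind(A = c(5, 1, 1, 1), B = c(1, 5, 5, 5))
  colnames(expr2) <- paste0("s", 1:4)
  expect_equal(pair_score(expr2, lab, "A", "B")$delta, 0.5)
  # within-sample ties count half toward the ordering probability
  expr3 <- rbind(A = c(3, 3, 1, 1), B = c(3, 3, 3, 3))
  colnames(expr3) <- paste0("s", 1:4)
  expect_equal(pair_score(expr3, lab, "A", "B")$delta, 0.5)

  expect_error(pair_score(expr, lab, "A", "A"), "distinct")
  expect_error(pair_score(expr, rep(TRUE, 4), "A", "B"), "per class")
})

test_that("pair_score and select_pairs match the exhaustive counting oracle", {
  # random instances up to 8 genes x 12 samples, with ties injected
  set.seed(401)
  for (rep in 1:60) {
    g <- sample(4:8, 1); n <- sample(6:12, 1)
    expr <- matrix(sample(1:5, g * n, replace = TRUE), g,
                   dimnames = list(sprintf("G%02d", sample(seq_len(g))),
                                   sprintf("s%02d", seq_len(n))))
    labels <- rep(c(TRUE, FALSE), length.out = n)[sample.int(n)]
    i <- rownames(expr)[1]; j <- rownames(expr)[2]
    got <- pair_score(expr, labels, i, j)
    want <- oracle_pair_score(expr, labels, i, j)
    expect_equal(got$delta, want$delta)
    expect_equal(got$gamma, want$gamma)

    k_max <- floor(g / 2)
    got_sel <- select_pairs(expr, labels, k_max)
    want_sel <- oracle_select_pairs(expr, labels, k_max)
    expect_equal(got_sel[c("gene_a", "gene_b")],
                 want_sel[c("gene_a", "gene_b")])
  }
})

test_that("selection ranks a perfectly separating pair first and breaks ties lexicographically", {
  set.seed(7)
  expr <- random_expr(6, 10)
  lab <- rep(c(TRUE, FALSE), 5)
  expr["G01", ] <- ifelse(lab, 10, 0)   # G01 > G02 iff class 1
  expr["G02", ] <- 5
  sel <- select_pairs(expr, lab, 3)
  expect_identical(c(sel$gene_a[1], sel$gene_b[1]), c("G01", "G02"))
  expect_equal(sel$delta[1], 1)

  # two interchangeable pairs with identical delta and gamma: the
  # lexicographically smaller (gene_a, gene_b) is selected first
  expr2 <- rbind(A1 = c(2, 2, 1, 1), B1 = c(1, 1, 2, 2),
                 C2 = c(2, 2, 1, 1), D2 = c(1, 1, 2, 2))
  colnames(expr2) <- paste0("s", 1:4)
  sel2 <- select_pairs(expr2, c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_identical(sel2$gene_a, c("A1", "C2"))

  expect_error(select_pairs(expr2, c(TRUE, TRUE, FALSE, FALSE), 3),
               "disjoint pairs")
})

test_that("orientation always points gene_a > gene_b at the high-risk class", {
  set.seed(17)
  for (rep in 1:20) {
    expr <- random_expr(10, 14)
    lab <- rep(c(TRUE, FALSE), 7)
    sel <- select_pairs(expr, lab, 5)
    for (r in seq_len(nrow(sel))) {
      sc <- pair_score(expr, lab, sel$gene_a[r], sel$gene_b[r])
      expect_gte(sc$p1, sc$p0)
    }
    # disjointness: no gene appears in two rules
    expect_false(anyDuplicated(c(sel$gene_a, sel$gene_b)) > 0)
  }
})

test_that("cross-validated k selection is deterministic and finds planted structure", {
  set.seed(23)
  n <- 40
  lab <- rep(c(TRUE, FALSE), n / 2)
  hits <- vapply(1:20, function(seed) {
    set.seed(seed + 100)
    expr <- random_expr(12, n)
    for (p in 1:3) {  # three perfectly separating pairs, rest noise
      expr[2 * p - 1, ] <- ifelse(lab, 10 + p, p)
      expr[2 * p, ] <- 5 + p
    }
    sel <- select_k_cv(expr, lab, k_grid = c(3, 5), folds = 5,
                       seed = seed, min_k = 3)
    sel$k == 3
  }, logical(1))
  expect_gte(sum(hits), 18)

  expr <- random_expr(12, n, seed = 9)
  a <- select_k_cv(expr, lab, c(3, 5), seed = 77, min_k = 3)
  b <- select_k_cv(expr, lab, c(3, 5), seed = 77, min_k = 3)
  expect_identical(a, b)
  # a grid of length 1 is returned without cross-validation
  expect_equal(select_k_cv(expr, lab, 5, min_k = 3)$k, 5)
  expect_error(select_k_cv(expr, lab, c(4, 6), min_k = 3), "odd")
  expect_error(select_k_cv(expr, lab, c(3, 5), min_k = 7), "below the configured minimum")
  expect_error(select_k_cv(expr, lab[1:6], k_grid = c(3, 5), folds = 5, min_k = 3),
               "label")
})

test_that("the small-stratum guard refuses to train", {
  expr <- random_expr(20, 3, seed = 2)
  expect_error(train_ssp(expr, c(TRUE, FALSE, FALSE), "ER-RT-"),
               "cannot be trained")
})

test_that("training is deterministic and the model is locked", {
  set.seed(31)
  cohort <- generate_cohort(cohort_config(
    n_discovery = 60, n_validation = 0,
    stratum_fractions = c("ER+RT+" = 1, "ER+RT-" = 0, "ER-RT+" = 0, "ER-RT-" = 0),
    case_fraction = 0.5, n_planted_pairs = 5, planted_delta = 0.8, seed = 19))
  expr <- normalize_counts(cohort$counts)
  lab <- cohort$annotation$ibtr_event
  m1 <- train_ssp(expr, lab, "ER+RT+", min_k = 11, k_grid = c(11, 15), seed = 5)
  m2 <- train_ssp(expr, lab, "ER+RT+", min_k = 11, k_grid = c(11, 15), seed = 5)
  expect_identical(m1$rules, m2$rules)
  expect_identical(m1$k, m2$k)
  expect_true(m1$k %% 2 == 1)

  # serialization round trip preserves the model bit-exactly, minus nothing
  path <- withr::local_tempfile(fileext = ".json")
  save_ssp(m1, path)
  m3 <- load_ssp(path)
  expect_equal(m3$rules, m1$rules)
  expect_identical(m3$k, m1$k)
  expect_identical(m3$stratum, m1$stratum)
  # no training data (sample ids, expression) leaks into the file
  expect_false(any(grepl("S0001", readLines(path))))

  # corrupted file and version mismatch
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 50),
             path)
  expect_error(load_ssp(path), "parse|missing|corrupt")
  m_old <- m1; m_old$version <- "0.9"
  save_ssp(m_old, path)
  expect_warning(load_ssp(path), "version")
})

test_that("majority-vote prediction counts ties as half votes", {
  m <- make_ssp(gene_a = c("A", "C", "E"), gene_b = c("B", "D", "F"))
  x <- c(A = 2, B = 1, C = 1, D = 2, E = 1, F = 2)  # votes {high, low, low}
  pr <- predict(m, x)
  expect_equal(pr$vote_fraction, 1 / 3)
  expect_identical(pr$class, "low")

  x_all <- c(A = 2, B = 1, C = 2, D = 1, E = 2, F = 1)
  pr2 <- predict(m, x_all)
  expect_equal(pr2$vote_fraction, 1)
  expect_identical(pr2$class, "high")

  x_tie <- c(A = 1, B = 1, C = 2, D = 1, E = 1, F = 2)  # {tie, high, low}
  expect_equal(predict(m, x_tie)$vote_fraction, 0.5)
  expect_identical(predict(m, x_tie)$class, "low")

  expect_error(predict(m, x[-1]), "missing from data: A")

  # odd k without expression ties can never produce a tied vote
  set.seed(11)
  expr <- random_expr(6, 25)
  rownames(expr) <- c("A", "B", "C", "D", "E", "F")
  expect_true(all(predict(m, expr)$vote_fraction != 0.5))
})

test_that("predictions are invariant to strictly monotone per-sample transforms", {
  set.seed(67)
  cohort <- generate_cohort(cohort_config(
    n_discovery = 40, n_validation = 0,
    stratum_fractions = c("ER+RT+" = 1, "ER+RT-" = 0, "ER-RT+" = 0, "ER-RT-" = 0),
    case_fraction = 0.5, seed = 21))
  expr <- normalize_counts(cohort$counts)
  m <- train_ssp(expr, cohort$annotation$ibtr_event, "ER+RT+",
                 min_k = 11, k_grid = 11, seed = 1)
  base <- predict(m, expr)
  for (rep in 1:25) {
    a <- runif(ncol(expr), 0.2, 3); b <- rnorm(ncol(expr), 0, 4)
    p <- runif(ncol(expr), 1, 3)
    tr <- sweep(sweep(exp(sweep(expr, 2, p, `*`) / 10), 2, a, `*`), 2, b, `+`)
    expect_identical(predict(m, tr)$class, base$class)
    expect_equal(predict(m, tr)$vote_fraction, base$vote_fraction)
  }
})

test_that("subset_model drops rules for missing genes and keeps k odd", {
  m <- make_ssp(gene_a = sprintf("A%03d", 1:101),
                gene_b = sprintf("B%03d", 1:101))
  all_genes <- c(m$rules$gene_a, m$rules$gene_b)

  expect_identical(subset_model(m, all_genes)$rules, m$rules)

  # one missing gene: its rule is dropped, plus the lowest-ranked rule
  # to restore an odd count
  m99 <- subset_model(m, setdiff(all_genes, "A050"))
  expect_equal(m99$k, 99)
  expect_false("A050" %in% m99$rules$gene_a)
  expect_false(all_genes[101] %in% c(m99$rules$gene_a, m99$rules$gene_b))
  expect_length(m99$metadata$dropped_rules, 1)

  expect_error(subset_model(m, character(0)), "no rules remain")
})
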