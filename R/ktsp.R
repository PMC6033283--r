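# k-top-scoring-pairs single-sample predictor.
#
# The classifier is built from k disjoint gene pairs; each rule votes
# "high risk" when expression(gene_a) > expression(gene_b) within the sample,
# and the unweighted majority vote decides the class. Because only
# within-sample order is consulted, predictions are invariant to any strictly
# monotone per-sample transform of the expression values.

#' Pair-order discriminating score for one gene pair
#'
#' Computes the top-scoring-pairs statistics for genes \code{i} and \code{j}:
#' \code{delta}, the absolute difference between classes in the probability
#' that gene i exceeds gene j within a sample (within-sample ties count 1/2
#' toward the probability), and \code{gamma}, the secondary tie-breaking
#' score: the absolute between-class difference of the mean within-sample
#' rank difference rank(i) - rank(j), ranks taken over the full analysis
#' gene set with average ranks for ties.
#'
#' @param expr numeric gene-by-sample expression matrix (any per-sample
#'   monotone scale; only within-sample order matters).
#' @param labels logical (or 0/1) per sample; TRUE = class 1 (high risk).
#' @param i,j gene ids (rownames of \code{expr}), distinct.
#' @return list with \code{delta}, \code{gamma}, and the per-class ordering
#'   probabilities \code{p1}, \code{p0}.
#' @examples
#' expr <- rbind(A = c(5, 6, 1, 2), B = c(1, 2, 5, 6), C = c(3, 3, 3, 3))
#' colnames(expr) <- paste0("s", 1:4)
#' pair_score(expr, c(TRUE, TRUE, FALSE, FALSE), "A", "B")$delta  # 1
#' @export
pair_score <- function(expr, labels, i, j) {
  labels <- check_labels(expr, labels, min_per_class = 1)
  if (identical(i, j)) stop("i and j must be distinct genes")
  if (!all(c(i, j) %in% rownames(expr))) stop("genes not found in expr")
  cmp <- (expr[i, ] > expr[j, ]) + 0.5 * (expr[i, ] == expr[j, ])
  p1 <- mean(cmp[labels])
  p0 <- mean(cmp[!labels])
  rk <- apply(expr, 2, rank)
  dd <- rk[i, ] - rk[j, ]
  gamma <- abs(mean(dd[labels]) - mean(dd[!labels]))
  list(delta = abs(p1 - p0), gamma = gamma, p1 = p1, p0 = p0)
}

check_labels <- function(expr, labels, min_per_class = 2) {
  if (is.numeric(labels)) labels <- labels != 0
  if (!is.logical(labels)) stop("labels must be logical or 0/1")
  if (length(labels) != ncol(expr)) stop("one label per sample required")
  if (anyNA(labels)) stop("labels must not contain NA")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 < min_per_class || n0 < min_per_class) {
    stop("need at least ", min_per_class, " samples per class (have ",
         n1, " / ", n0, ")")
  }
  labels
}

# All-pairs statistics: signed delta matrix S[i,j] = P(i>j|1) - P(i>j|0)
# (ties 1/2) and the gamma tie-break matrix.
pair_stat_matrices <- function(expr, labels) {
  n1 <- sum(labels); n0 <- sum(!labels)
  g <- nrow(expr)
  acc1 <- matrix(0, g, g); acc0 <- matrix(0, g, g)
  for (s in seq_len(ncol(expr))) {
    cmp <- (sign(outer(expr[, s], expr[, s], `-`)) + 1) / 2
    if (labels[s]) acc1 <- acc1 + cmp else acc0 <- acc0 + cmp
  }
  S <- acc1 / n1 - acc0 / n0
  rk <- apply(expr, 2, rank)
  d <- rowMeans(rk[, labels, drop = FALSE]) - rowMeans(rk[, !labels, drop = FALSE])
  G <- abs(outer(d, d, `-`))
  dimnames(S) <- dimnames(G) <- list(rownames(expr), rownames(expr))
  list(S = S, G = G)
}

#' Rank and greedily select disjoint top-scoring gene pairs
#'
#' Scores every gene pair with [pair_score()] statistics, orients each pair so
#' that gene_a > gene_b is the class-1 (high-risk) direction, sorts by delta
#' (descending), then gamma (descending), then lexicographic
#' (gene_a, gene_b), and greedily selects pairs subject to gene disjointness
#' until \code{k_max} pairs are chosen.
#'
#' @inheritParams pair_score
#' @param k_max number of disjoint pairs to select.
#' @return data.frame with columns gene_a, gene_b, delta, gamma, in selection
#'   order.
#' @export
select_pairs <- function(expr, labels, k_max) {
  labels <- check_labels(expr, labels)
  g <- nrow(expr)
  if (k_max > floor(g / 2)) {
    stop("k_max = ", k_max, " exceeds the ", floor(g / 2),
         " disjoint pairs available from ", g, " genes")
  }
  st <- pair_stat_matrices(expr, labels)
  ut <- which(upper.tri(st$S), arr.ind = TRUE)
  s <- st$S[ut]
  genes <- rownames(expr)
  ga <- genes[ut[, 1]]; gb <- genes[ut[, 2]]
  flip <- s < 0 | (s == 0 & ga > gb)
  tmp <- ga[flip]; ga[flip] <- gb[flip]; gb[flip] <- tmp
  tab <- data.frame(gene_a = ga, gene_b = gb,
                    delta = abs(s), gamma = st$G[ut])
  # keys rounded to 10 significant digits: mathematically tied scores can
  # differ by one ulp depending on the summation route, which would make
  # the lexicographic tie-break order-dependent on floating-point noise
  ord <- order(-signif(tab$delta, 10), -signif(tab$gamma, 10),
               tab$gene_a, tab$gene_b, method = "radix")
  tab <- tab[ord, ]

  used <- structure(logical(g), names = genes)
  pick <- integer(0)
  for (r in seq_len(nrow(tab))) {
    a <- tab$gene_a[r]; b <- tab$gene_b[r]
    if (!used[a] && !used[b]) {
      pick <- c(pick, r)
      used[a] <- used[b] <- TRUE
      if (length(pick) == k_max) break
    }
  }
  if (length(pick) < k_max) {
    stop("only ", length(pick), " disjoint pairs available; k_max = ", k_max)
  }
  out <- tab[pick, ]
  rownames(out) <- NULL
  out
}

#' Choose the number of pairs by stratified cross-validation
#'
#' Evaluates each candidate k in \code{k_grid} by stratified
#' \code{folds}-fold cross-validation: pairs are re-selected on each training
#' fold, the majority vote of the first k pairs classifies the held-out
#' samples, and the k maximizing mean balanced accuracy is returned (ties go
#' to the smaller k). Deterministic given \code{seed}.
#'
#' @inheritParams pair_score
#' @param k_grid candidate numbers of pairs; all odd, minimum at least
#'   \code{min_k}.
#' @param folds number of cross-validation folds.
#' @param seed RNG seed for the fold assignment.
#' @param min_k smallest admissible k (default 101: the training floor of
#'   100 pairs rounded up to the next odd count so the majority vote cannot
#'   tie).
#' @return list with the selected \code{k} and the fold-mean balanced
#'   accuracy per candidate (\code{cv_accuracy}).
#' @export
select_k_cv <- function(expr, labels, k_grid, folds = 5, seed = 1L,
                        min_k = 101L) {
  labels <- check_labels(expr, labels)
  if (!length(k_grid)) stop("k_grid must be non-empty")
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid %% 2 == 0)) stop("all k in k_grid must be odd")
  if (min(k_grid) < min_k) {
    stop("min(k_grid) = ", min(k_grid), " is below the configured minimum ", min_k)
  }
  if (length(k_grid) == 1) {
    return(list(k = k_grid, cv_accuracy = stats::setNames(NA_real_, k_grid)))
  }
  if (folds < 2) stop("folds must be >= 2")
  if (min(sum(labels), sum(!labels)) < folds) {
    stop("too few samples in the smaller class (",
         min(sum(labels), sum(!labels)), ") for ", folds, " stratified folds")
  }

  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(TRUE, FALSE)) {
      idx <- which(labels == cl)
      fold_id[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(folds), length(idx))
    }
  })

  acc <- matrix(NA_real_, folds, length(k_grid),
                dimnames = list(NULL, k_grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    pairs <- select_pairs(expr[, tr, drop = FALSE], labels[tr], max(k_grid))
    v <- rule_votes(pairs, expr[, !tr, drop = FALSE])
    cum <- apply(v, 2, cumsum)
    y <- labels[!tr]
    for (ki in seq_along(k_grid)) {
      k <- k_grid[ki]
      pred <- cum[k, ] / k > 0.5
      acc[f, ki] <- (mean(pred[y]) + mean(!pred[!y])) / 2
    }
  }
  mean_acc <- colMeans(acc)
  k <- k_grid[which.max(mean_acc)]   # which.max takes the first (smallest) tie
  list(k = k, cv_accuracy = mean_acc)
}

# votes of each rule (rows) on each sample (cols): 1 / 0.5 / 0
rule_votes <- function(rules, expr) {
  a <- expr[rules$gene_a, , drop = FALSE]
  b <- expr[rules$gene_b, , drop = FALSE]
  v <- (a > b) + 0.5 * (a == b)
  dimnames(v) <- list(NULL, colnames(expr))
  v
}

#' Train a k-TSP single-sample predictor
#'
#' Fits the locked classifier for one ER-by-RT stratum: the number of pairs k
#' is chosen by stratified cross-validation over \code{k_grid}
#' ([select_k_cv()]), and the model's rules are the first k disjoint pairs
#' selected on the full training data ([select_pairs()]). Strata with fewer
#' than \code{min_per_class} samples in either class are refused.
#'
#' @inheritParams select_k_cv
#' @param stratum label stored in the model (e.g. \code{"ER+RT-"}).
#' @param k_grid candidate ks; default: odd values from \code{min_k} (rounded
#'   up to odd) to floor(n_genes / 2) (rounded down to odd).
#' @param min_per_class smallest admissible class size (default 10).
#' @return an object of class \code{ssp} with fields stratum, k, rules
#'   (ordered data.frame gene_a, gene_b, delta, gamma), decision and
#'   training metadata. Serialization via [save_ssp()] stores no training
#'   data: the model is locked.
#' @seealso [predict.ssp()], [subset_model()], [save_ssp()]
#' @export
train_ssp <- function(expr, labels, stratum = "unspecified", min_k = 101L,
                      k_grid = NULL, folds = 5, seed = 1L,
                      min_per_class = 10L) {
  if (is.numeric(labels)) labels <- labels != 0
  n1 <- sum(labels); n0 <- sum(!labels)
  if (min(n1, n0) < min_per_class) {
    stop("stratum '", stratum, "' cannot be trained: ", n1, " cases / ", n0,
         " controls; need at least ", min_per_class, " per class")
  }
  min_k <- as.integer(min_k)
  if (min_k %% 2 == 0) min_k <- min_k + 1L
  if (is.null(k_grid)) {
    hi <- floor(nrow(expr) / 2)
    if (hi %% 2 == 0) hi <- hi - 1L
    if (hi < min_k) {
      stop("panel too small: floor(n_genes/2) = ", floor(nrow(expr) / 2),
           " is below the minimum pair count ", min_k)
    }
    k_grid <- seq(min_k, hi, by = 2L)
  }
  sel <- select_k_cv(expr, labels, k_grid, folds = folds, seed = seed,
                     min_k = min_k)
  rules <- select_pairs(expr, labels, k_max = sel$k)
  structure(list(stratum = stratum,
                 k = sel$k,
                 rules = rules,
                 decision = "majority_vote",
                 metadata = list(seed = as.integer(seed),
                                 folds = as.integer(folds),
                                 k_grid = as.integer(k_grid),
                                 cv_accuracy = sel$cv_accuracy,
                                 n_cases = n1, n_controls = n0,
                                 n_genes = nrow(expr),
                                 dropped_rules = list()),
                 version = ssp_format_version()),
            class = "ssp")
}

ssp_format_version <- function() "1.0"

#' Predict IBTR risk class for new samples
#'
#' Applies the locked model: each rule votes high risk iff
#' expression(gene_a) > expression(gene_b) within the sample (a within-sample
#' tie contributes half a vote), and the sample is classified high risk iff
#' the vote fraction exceeds 1/2. The vote fraction is the model's raw score.
#'
#' @param object an \code{ssp} model.
#' @param newdata gene-by-sample numeric matrix, or a named vector for a
#'   single sample. All rule genes must be present; use [subset_model()]
#'   first if genes are missing.
#' @param ... unused.
#' @return data.frame with sample_id, vote_fraction and class
#'   ("high" / "low").
#' @export
predict.ssp <- function(object, newdata, ...) {
  if (is.vector(newdata)) {
    newdata <- matrix(newdata, ncol = 1,
                      dimnames = list(names(newdata), "sample_1"))
  }
  genes <- unique(c(object$rules$gene_a, object$rules$gene_b))
  missing <- setdiff(genes, rownames(newdata))
  if (length(missing)) {
    stop("model genes missing from data: ", paste(missing, collapse = ", "),
         " (use subset_model() to drop their rules explicitly)")
  }
  vf <- colMeans(rule_votes(object$rules, newdata))
  data.frame(sample_id = colnames(newdata) %||% seq_along(vf),
             vote_fraction = unname(vf),
             class = ifelse(vf > 0.5, "high", "low"),
             row.names = NULL)
}

#' Restrict a model to the genes available on another platform
#'
#' Drops every rule that involves a gene absent from \code{available_genes}.
#' If the remaining rule count is even, the lowest-ranked remaining rule is
#' also dropped so the majority vote cannot tie. Dropped rules are recorded
#' in the model metadata.
#'
#' @param ssp an \code{ssp} model.
#' @param available_genes character vector of usable gene ids.
#' @return the reduced \code{ssp} model.
#' @export
subset_model <- function(ssp, available_genes) {
  stopifnot(inherits(ssp, "ssp"))
  keep <- ssp$rules$gene_a %in% available_genes &
    ssp$rules$gene_b %in% available_genes
  dropped <- ssp$rules[!keep, , drop = FALSE]
  rules <- ssp$rules[keep, , drop = FALSE]
  if (nrow(rules) %% 2 == 0 && nrow(rules) > 0) {
    dropped <- rbind(dropped, rules[nrow(rules), , drop = FALSE])
    rules <- rules[-nrow(rules), , drop = FALSE]
  }
  if (nrow(rules) < 1) stop("no rules remain after subsetting")
  rownames(rules) <- NULL
  ssp$rules <- rules
  ssp$k <- nrow(rules)
  ssp$metadata$dropped_rules <-
    c(ssp$metadata$dropped_rules,
      list(paste(dropped$gene_a, dropped$gene_b, sep = ">")))
  ssp
}

#' Save / load a locked model as JSON
#'
#' The JSON file stores stratum, k, the ordered rules, the decision scheme
#' and training metadata — never the training data. \code{load_ssp} warns
#' when the file was written by a different format version and errors on a
#' corrupted or schema-violating file.
#'
#' @param ssp an \code{ssp} model.
#' @param path file path.
#' @return \code{save_ssp}: the path, invisibly; \code{load_ssp}: the model.
#' @export
save_ssp <- function(ssp, path) {
  stopifnot(inherits(ssp, "ssp"))
  jsonlite::write_json(unclass(ssp), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_ssp
#' @export
load_ssp <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model file: ",
                                           conditionMessage(e)))
  need <- c("stratum", "k", "rules", "decision")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop("model file missing fields: ", paste(miss, collapse = ", "))
  if (!all(c("gene_a", "gene_b") %in% names(obj$rules))) {
    stop("model rules must have gene_a and gene_b")
  }
  if (!identical(obj$version, ssp_format_version())) {
    warning("model file format version '", obj$version %||% "<none>",
            "' differs from '", ssp_format_version(), "'")
  }
  obj$k <- as.integer(obj$k)
  obj$rules <- as.data.frame(obj$rules)
  if (nrow(obj$rules) != obj$k) stop("model file corrupt: k != number of rules")
  structure(obj, class = "ssp")
}

#' @export
print.ssp <- function(x, ...) {
  cat("k-TSP single-sample predictor (stratum ", x$stratum, ")\n", sep = "")
  cat("  ", x$k, " disjoint gene-pair rules, majority vote\n", sep = "")
  cat("  trained on ", x$metadata$n_cases, " cases / ",
      x$metadata$n_controls, " controls\n", sep = "")
  invisible(x)
}

#' @export
summary.ssp <- function(object, ...) {
  cat("k-TSP single-sample predictor\n")
  cat("stratum:        ", object$stratum, "\n")
  cat("rules (k):      ", object$k, "\n")
  cat("distinct genes: ", length(unique(c(object$rules$gene_a,
                                          object$rules$gene_b))), "\n")
  cat("decision:       majority vote, high risk iff vote fraction > 0.5\n")
  if (!all(is.na(object$metadata$cv_accuracy))) {
    cat("CV balanced accuracy at selected k: ",
        round(object$metadata$cv_accuracy[as.character(object$k)], 3), "\n")
  }
  cat("top rules:\n")
  print(utils::head(object$rules, 5))
  invisible(object)
}

#' @export
coef.ssp <- function(object, ...) object$rules
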