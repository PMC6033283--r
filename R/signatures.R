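# Gene-signature scores: rank-linear surrogate (10-GS style), geometric-mean
# proliferation and immune scores, median dichotomization, and score-to-score
# correlation.

#' Define a rank-linear gene signature
#'
#' A rank-linear signature scores a sample as the weighted sum of the
#' within-sample ranks of its genes — the model family behind rank-based
#' radiosensitivity surrogates such as the 10-gene score. Ranks can be taken
#' over the whole panel or over the signature genes only, ascending or
#' descending.
#'
#' @param genes character vector of gene ids (unique).
#' @param coefficients numeric, one per gene.
#' @param rank_scope \code{"all_panel_genes"} or \code{"signature_genes"}.
#' @param rank_direction \code{"ascending"} (rank 1 = lowest expression) or
#'   \code{"descending"}.
#' @return object of class \code{rank_linear_signature}.
#' @export
rank_linear_signature <- function(genes, coefficients,
                                  rank_scope = c("all_panel_genes",
                                                 "signature_genes"),
                                  rank_direction = c("ascending",
                                                     "descending")) {
  if (length(genes) != length(coefficients)) {
    stop("genes and coefficients must have equal length")
  }
  if (anyDuplicated(genes)) stop("signature genes must be unique")
  if (anyNA(coefficients)) stop("coefficients must be finite")
  structure(list(genes = as.character(genes),
                 coefficients = as.numeric(coefficients),
                 rank_scope = match.arg(rank_scope),
                 rank_direction = match.arg(rank_direction)),
            class = "rank_linear_signature")
}

#' Read / write a rank-linear signature definition
#'
#' The on-disk format is a CSV with columns \code{gene_id,coefficient};
#' an optional JSON sidecar (same path with extension \code{.json}) carries
#' \code{rank_scope} and \code{rank_direction}, defaulting to
#' all_panel_genes / ascending when absent.
#'
#' @param path CSV path.
#' @return \code{read_signature}: a [rank_linear_signature()].
#' @export
read_signature <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "coefficient") %in% names(df))) {
    stop("signature file must have columns gene_id, coefficient")
  }
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  opts <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  rank_linear_signature(df$gene_id, df$coefficient,
                        rank_scope = opts$rank_scope %||% "all_panel_genes",
                        rank_direction = opts$rank_direction %||% "ascending")
}

#' @rdname read_signature
#' @param sig a [rank_linear_signature()].
#' @export
write_signature <- function(sig, path) {
  utils::write.csv(data.frame(gene_id = sig$genes,
                              coefficient = sig$coefficients),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(rank_scope = sig$rank_scope,
                            rank_direction = sig$rank_direction),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Score samples with a rank-linear signature
#'
#' For each sample, within-sample ranks are computed over the signature's
#' rank scope (average ranks for ties, reversed for descending direction)
#' and the score is the coefficient-weighted sum of the signature genes'
#' ranks. Like the k-TSP vote, the score is invariant to strictly monotone
#' per-sample transforms of expression.
#'
#' @param expr gene-by-sample numeric matrix.
#' @param sig a [rank_linear_signature()].
#' @return named numeric vector, one score per sample.
#' @export
rank_linear_score <- function(expr, sig) {
  stopifnot(inherits(sig, "rank_linear_signature"))
  missing <- setdiff(sig$genes, rownames(expr))
  if (length(missing)) {
    stop("signature genes missing from data: ", paste(missing, collapse = ", "))
  }
  scope <- if (sig$rank_scope == "signature_genes") {
    expr[sig$genes, , drop = FALSE]
  } else expr
  rk <- apply(scope, 2, rank)
  if (!is.matrix(rk)) {   # single-gene scope: every rank is 1
    rk <- matrix(rk, nrow = nrow(scope), dimnames = dimnames(scope))
  }
  if (sig$rank_direction == "descending") rk <- nrow(scope) + 1 - rk
  colSums(rk[sig$genes, , drop = FALSE] * sig$coefficients)
}

#' Geometric-mean expression score
#'
#' Score = geometric mean of the linear-scale expression of a gene set. The
#' preset gene sets are [proliferation_genes()] (MKI67, AURKA) and
#' [immune_genes()] (ten immune-response genes). Inputs must be on the
#' linear scale and strictly positive; log-scale input (flagged by the
#' \code{scale} attribute of [normalize_counts()] output, or by nonpositive
#' values) is rejected.
#'
#' @param expr gene-by-sample linear-scale matrix.
#' @param gene_set character vector of gene ids.
#' @return named numeric vector, one score per sample.
#' @export
geometric_mean_score <- function(expr, gene_set) {
  if (identical(attr(expr, "scale"), "log2")) {
    stop("expr is log2 scale; geometric-mean scores need linear expression ",
         "(normalize_counts(..., log2 = FALSE))")
  }
  missing <- setdiff(gene_set, rownames(expr))
  if (length(missing)) {
    stop("score genes missing from data: ", paste(missing, collapse = ", "))
  }
  sub <- expr[gene_set, , drop = FALSE]
  if (any(sub <= 0)) {
    stop("nonpositive expression values: geometric-mean scores require ",
         "strictly positive linear-scale input")
  }
  apply(sub, 2, geomean)
}

#' Dichotomize scores at the median
#'
#' Splits a score vector at its median: high iff score > median (an exact
#' median value is assigned low). The median is computed over the full vector
#' provided; which cohort that covers is the caller's choice. An all-constant
#' vector yields all-low with a warning.
#'
#' @param scores numeric vector (length >= 2).
#' @return logical vector: TRUE = high.
#' @export
dichotomize_median <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 scores")
  if (anyNA(scores)) stop("scores must not contain NA")
  m <- stats::median(scores)
  high <- scores > m
  if (!any(scores != scores[1])) {
    warning("all scores identical; every sample assigned low")
  }
  high
}

#' Correlate two score vectors
#'
#' Pearson correlation plus an ordinary least-squares fit of y on x; the
#' p-value is the two-sided test for zero slope (t with n - 2 degrees of
#' freedom).
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite.
#' @return list with \code{pearson_r}, \code{slope}, \code{p_zero_slope},
#'   \code{n}.
#' @export
correlate_scores <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(pearson_r = stats::cor(x, y),
       slope = unname(sm["x", "Estimate"]),
       p_zero_slope = unname(sm["x", "Pr(>|t|)"]),
       n = length(x))
}
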