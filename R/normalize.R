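#' Positive-control and housekeeping normalization
#'
#' Normalizes an nCounter-style count matrix in the fixed order: (1) each
#' sample is scaled so that its positive-control geometric mean equals the
#' across-sample (geometric) mean of positive-control geometric means;
#' (2) each sample is further scaled so that its housekeeping geometric mean
#' equals the across-sample (geometric) mean of housekeeping geometric
#' means; (3) optional \code{log2(x + 1)} transform. The across-sample
#' target is the geometric rather than arithmetic mean of the per-sample
#' geometric means: with that choice the two scaling steps compose
#' idempotently (re-normalizing normalized data is the identity), which an
#' arithmetic target does not achieve. Control probes (positive, negative,
#' housekeeping) are dropped from the analysis gene set unless
#' \code{drop_controls = FALSE}.
#'
#' The procedure is idempotent on already-normalized linear data (scale
#' factors become 1), and because both steps are uniform per-sample
#' rescalings, within-sample gene order — the quantity the k-TSP classifier
#' consumes — is unchanged by them.
#'
#' @param counts a [raw_counts] object, or a numeric gene-by-sample matrix
#'   with non-negative entries (then \code{manifest} is required).
#' @param manifest panel manifest (taken from \code{counts} when it is a
#'   [raw_counts]).
#' @param log2 apply the final log2(x + 1) transform (default TRUE).
#' @param drop_controls drop housekeeping and control probes from the output.
#' @return numeric matrix of normalized expression with attribute
#'   \code{scale} set to \code{"log2"} or \code{"linear"}.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_discovery = 12, n_validation = 0,
#'                                         seed = 3))
#' expr <- normalize_counts(cohort$counts)
#' attr(expr, "scale")
#' @export
normalize_counts <- function(counts, manifest = NULL, log2 = TRUE,
                             drop_controls = TRUE) {
  if (inherits(counts, "raw_counts")) {
    manifest <- counts$manifest
    mat <- counts$counts
  } else {
    if (is.null(manifest)) stop("manifest required when counts is a matrix")
    mat <- counts
  }
  if (any(mat < 0)) stop("normalization requires non-negative values")
  storage.mode(mat) <- "double"
  pos <- intersect(manifest_genes(manifest, "positive_ctrl"), rownames(mat))
  hk <- intersect(manifest_genes(manifest, "housekeeping"), rownames(mat))
  if (!length(pos) || !length(hk)) {
    stop("matrix must contain positive-control and housekeeping probes")
  }

  pos_gm <- apply(mat[pos, , drop = FALSE], 2, geomean)
  if (any(pos_gm == 0)) {
    stop("zero positive-control geometric mean in sample(s) ",
         paste(colnames(mat)[pos_gm == 0], collapse = ", "),
         " (should have been removed by QC)")
  }
  mat <- sweep(mat, 2, geomean(pos_gm) / pos_gm, `*`)

  hk_gm <- apply(mat[hk, , drop = FALSE], 2, geomean)
  if (any(hk_gm == 0)) {
    stop("zero housekeeping geometric mean in sample(s) ",
         paste(colnames(mat)[hk_gm == 0], collapse = ", "),
         " (should have been removed by QC)")
  }
  mat <- sweep(mat, 2, geomean(hk_gm) / hk_gm, `*`)

  if (drop_controls) {
    keep <- intersect(manifest_genes(manifest, "endogenous"), rownames(mat))
    mat <- mat[keep, , drop = FALSE]
  }
  if (log2) {
    mat <- log2(mat + 1)
    attr(mat, "scale") <- "log2"
  } else {
    attr(mat, "scale") <- "linear"
  }
  mat
}
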