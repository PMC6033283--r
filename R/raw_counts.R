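#' Raw probe-by-sample count container
#'
#' Bundles a non-negative integer count matrix (probes as rows, samples as
#' columns) with its panel manifest. All probes in the matrix must be listed
#' in the manifest; this is the unit of I/O, quality filtering and
#' normalization.
#'
#' @param counts numeric matrix of non-negative integers with rownames =
#'   gene_ids and colnames = sample_ids.
#' @param manifest panel manifest data.frame (see [panel_manifest()]).
#' @return an object of class \code{raw_counts}.
#' @export
raw_counts <- function(counts, manifest) {
  validate_manifest(manifest)
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (ncol(counts) < 1) stop("counts must contain at least one sample")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene_id rownames and sample_id colnames")
  }
  if (anyNA(counts)) stop("counts must not contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  missing <- setdiff(rownames(counts), manifest$gene_id)
  if (length(missing)) {
    stop("probes absent from manifest: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene_ids in counts")
  structure(list(counts = counts,
                 manifest = manifest[match(rownames(counts), manifest$gene_id), ,
                                     drop = FALSE]),
            class = "raw_counts")
}

#' @export
print.raw_counts <- function(x, ...) {
  cls <- table(x$manifest$probe_class)
  cat("raw_counts:", nrow(x$counts), "probes x", ncol(x$counts), "samples\n")
  cat("  probe classes:",
      paste(names(cls), as.integer(cls), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.raw_counts <- function(x) dim(x$counts)
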