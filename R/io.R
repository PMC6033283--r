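#' Write a cohort to plain-text files
#'
#' Serializes counts (TSV, genes as rows, first column \code{gene_id}), the
#' panel manifest (CSV) and the sample annotation (CSV) into a directory.
#' Files are deterministic: the same cohort writes byte-identical files, and
#' they round-trip exactly through [read_counts()] / [read_annotation()].
#'
#' @param counts a [raw_counts] object or a \code{synthetic_cohort}.
#' @param annotation sample annotation data.frame (ignored when \code{counts}
#'   is a \code{synthetic_cohort}).
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(counts, annotation = NULL, dir) {
  if (inherits(counts, "synthetic_cohort")) {
    annotation <- counts$annotation
    counts <- counts$counts
  }
  if (!inherits(counts, "raw_counts")) stop("counts must be a raw_counts object")
  if (ncol(counts$counts) == 0) stop("refusing to write a cohort with no samples")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             manifest = file.path(dir, "manifest.csv"),
             annotation = file.path(dir, "annotation.csv"))
  df <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                   check.names = FALSE)
  utils::write.table(df, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(counts$manifest, paths["manifest"], row.names = FALSE,
                   quote = FALSE)
  if (!is.null(annotation)) {
    utils::write.csv(annotation, paths["annotation"], row.names = FALSE,
                     quote = FALSE)
  } else {
    paths <- paths[c("counts", "manifest")]
  }
  invisible(paths)
}

#' Read a count matrix and manifest from disk
#'
#' Reads the TSV/CSV files written by [write_cohort()] and validates them into
#' a [raw_counts] object. Negative, missing or non-integer counts, duplicate
#' gene ids, unknown probe classes and probes missing from the manifest are
#' all rejected.
#'
#' @param counts_path TSV with first column \code{gene_id} and one column per
#'   sample.
#' @param manifest_path CSV with columns gene_id, probe_class, source_category.
#' @return a [raw_counts] object.
#' @export
read_counts <- function(counts_path, manifest_path) {
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path)
  if (!file.exists(manifest_path)) stop("manifest file not found: ", manifest_path)
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column of counts must be gene_id")
  mat <- as.matrix(df[-1])
  if (!is.numeric(mat)) stop("counts must be numeric")
  rownames(mat) <- df$gene_id
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  manifest$source_category[manifest$source_category %in% c("", "NA")] <- NA_character_
  raw_counts(mat, manifest)
}

#' Read sample annotation from disk
#'
#' @param path annotation CSV written by [write_cohort()].
#' @param sample_ids optional vector of sample ids that must all be annotated.
#' @return data.frame with logical rt/ibtr_event/therapy columns.
#' @export
read_annotation <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cohort", "er_status", "rt", "ibtr_event", "time_years")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  for (col in intersect(c("rt", "ibtr_event", "endocrine_therapy", "chemotherapy"),
                        names(ann))) {
    ann[[col]] <- as.logical(ann[[col]])
  }
  if (any(ann$time_years <= 0)) stop("time_years must be positive")
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample_ids in annotation")
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, ann$sample_id)
    if (length(miss)) {
      stop("samples missing from annotation: ", paste(miss, collapse = ", "))
    }
  }
  ann
}
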