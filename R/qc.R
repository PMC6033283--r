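#' Quality-filter an nCounter count matrix
#'
#' Removes failed samples and background-level probes before normalization.
#' A sample is removed when its positive-control scale factor (across-sample
#' geometric mean of positive-control geometric means divided by the
#' sample's own geometric mean) falls outside \code{pos_scale_range}, or
#' when its
#' housekeeping geometric mean falls below \code{hk_floor} counts. An
#' endogenous probe is removed when its count is at or below the sample's
#' background level (mean of negative controls + 2 SD) in at least
#' \code{bg_frac} of the retained samples. The thresholds are the
#' conventional nCounter QC defaults and are fully configurable.
#'
#' @param counts a [raw_counts] object.
#' @param pos_scale_range numeric length-2: allowed positive-control scale
#'   factor range.
#' @param hk_floor minimum housekeeping geometric mean (counts).
#' @param bg_frac fraction of samples at/below background that flags a probe.
#' @return list with elements \code{counts} (filtered [raw_counts]) and
#'   \code{report} (class \code{qc_report}: removed_samples, removed_probes,
#'   per-sample positive-control scale factors and housekeeping geometric
#'   means).
#' @export
qc_filter <- function(counts, pos_scale_range = c(1 / 3, 3),
                      hk_floor = 32, bg_frac = 0.85) {
  stopifnot(inherits(counts, "raw_counts"))
  mat <- counts$counts
  manifest <- counts$manifest
  pos <- manifest_genes(manifest, "positive_ctrl")
  neg <- manifest_genes(manifest, "negative_ctrl")
  hk <- manifest_genes(manifest, "housekeeping")

  pos_gm <- apply(mat[pos, , drop = FALSE], 2, geomean)
  # geometric-mean target, matching the normalization step
  scale_factor <- geomean(pos_gm[pos_gm > 0]) / pos_gm  # Inf when gm is 0
  hk_gm <- apply(mat[hk, , drop = FALSE], 2, geomean)

  bad_pos <- !is.finite(scale_factor) | scale_factor < pos_scale_range[1] |
    scale_factor > pos_scale_range[2]
  bad_hk <- hk_gm < hk_floor
  removed_samples <- rbind(
    data.frame(sample_id = colnames(mat)[bad_pos],
               reason = rep("positive_control_scale", sum(bad_pos))),
    data.frame(sample_id = colnames(mat)[bad_hk & !bad_pos],
               reason = rep("housekeeping_floor", sum(bad_hk & !bad_pos))))
  keep_samples <- !(bad_pos | bad_hk)
  if (!any(keep_samples)) stop("QC removed every sample")
  mat_kept <- mat[, keep_samples, drop = FALSE]

  # probe background filter on retained samples, endogenous probes only
  neg_mat <- mat_kept[neg, , drop = FALSE]
  background <- colMeans(neg_mat) + 2 * apply(neg_mat, 2, stats::sd)
  endog <- manifest_genes(manifest, "endogenous")
  below <- sweep(mat_kept[endog, , drop = FALSE], 2, background, `<=`)
  bad_probe <- rowMeans(below) >= bg_frac
  removed_probes <- data.frame(gene_id = endog[bad_probe],
                               reason = rep("background", sum(bad_probe)))

  keep_genes <- setdiff(rownames(mat), removed_probes$gene_id)
  out <- raw_counts(mat_kept[keep_genes, , drop = FALSE],
                    manifest[manifest$gene_id %in% keep_genes, , drop = FALSE])
  report <- structure(
    list(removed_samples = removed_samples,
         removed_probes = removed_probes,
         sample_stats = data.frame(sample_id = colnames(mat),
                                   pos_scale_factor = unname(scale_factor),
                                   hk_geomean = unname(hk_gm),
                                   retained = keep_samples),
         thresholds = list(pos_scale_range = pos_scale_range,
                           hk_floor = hk_floor, bg_frac = bg_frac)),
    class = "qc_report")
  list(counts = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", nrow(x$removed_samples), "samples and",
      nrow(x$removed_probes), "probes removed\n")
  if (nrow(x$removed_samples)) print(table(x$removed_samples$reason))
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report a \code{qc_report}.
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
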