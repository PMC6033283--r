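#' Default targeted radiosensitivity panel manifest
#'
#' Builds the probe manifest of the emulated nCounter radiosensitivity panel:
#' 248 unique genes (235 endogenous + 13 housekeeping) plus 6 positive-control
#' and 8 negative-control probes. Endogenous genes carry a source annotation
#' (discovery screen, published radiosensitivity signatures, literature);
#' the annotation is descriptive only and never used by the algorithms.
#' Gene symbols that feed the preset signature scores (MKI67, AURKA and the
#' ten immune-response genes) are real; the remainder are synthetic
#' placeholder identifiers.
#'
#' @param n_genes total number of unique genes (endogenous + housekeeping).
#' @param n_housekeeping number of housekeeping probes.
#' @param n_pos number of positive-control probes (geometric titration ladder).
#' @param n_neg number of negative-control probes.
#' @return data.frame with columns \code{gene_id}, \code{probe_class}
#'   (endogenous / housekeeping / positive_ctrl / negative_ctrl) and
#'   \code{source_category}.
#' @examples
#' m <- panel_manifest()
#' table(m$probe_class)
#' @export
panel_manifest <- function(n_genes = 248, n_housekeeping = 13,
                           n_pos = 6, n_neg = 8) {
  stopifnot(n_genes > n_housekeeping, n_housekeeping >= 1, n_pos >= 6, n_neg >= 1)
  n_endog <- n_genes - n_housekeeping

  rsi <- c("AR", "JUN", "STAT1", "PRKCB", "RelA",
           "ABL1", "SUMO1", "PAK2", "HDAC1", "IRF1")
  immune_extra <- setdiff(immune_genes(), rsi)   # IRF1/STAT1/RelA shared
  literature <- c("MKI67", "AURKA", "ESR1", "PGR", "ERBB2", "BCL2", "BRCA1",
                  "BRCA2", "BIRC5", "MET", "HGF", "HIF1A", "EPAS1", "WRAP53",
                  "FOXC1", immune_extra)
  rss <- sprintf("RSS%03d", seq_len(51))
  tramm <- sprintf("TRAMM%02d", seq_len(7))
  n_disc <- n_endog - length(rsi) - length(literature) - length(rss) - length(tramm)
  if (n_disc < 0) stop("panel too small for the named gene sets")
  disc <- sprintf("DISC%03d", seq_len(n_disc))

  hk <- c("ACTB", "B2M", "CLTC", "GAPDH", "GUSB", "HPRT1", "PGK1",
          "POLR1B", "PPIA", "RPL19", "RPLP0", "SDHA", "TUBB")
  hk <- if (n_housekeeping <= length(hk)) hk[seq_len(n_housekeeping)] else
    c(hk, sprintf("HK%02d", seq_len(n_housekeeping - length(hk))))

  manifest <- rbind(
    data.frame(gene_id = disc, probe_class = "endogenous", source_category = "discovery"),
    data.frame(gene_id = rsi, probe_class = "endogenous", source_category = "rsi"),
    data.frame(gene_id = rss, probe_class = "endogenous", source_category = "rss"),
    data.frame(gene_id = tramm, probe_class = "endogenous", source_category = "tramm"),
    data.frame(gene_id = literature, probe_class = "endogenous", source_category = "literature"),
    data.frame(gene_id = hk, probe_class = "housekeeping", source_category = "housekeeping"),
    data.frame(gene_id = paste0("POS_", LETTERS[seq_len(n_pos)]),
               probe_class = "positive_ctrl", source_category = NA_character_),
    data.frame(gene_id = paste0("NEG_", LETTERS[seq_len(n_neg)]),
               probe_class = "negative_ctrl", source_category = NA_character_)
  )
  rownames(manifest) <- NULL
  validate_manifest(manifest)
  manifest
}

validate_manifest <- function(manifest) {
  need <- c("gene_id", "probe_class", "source_category")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  classes <- c("endogenous", "housekeeping", "positive_ctrl", "negative_ctrl")
  bad <- setdiff(unique(manifest$probe_class), classes)
  if (length(bad)) stop("unknown probe class: ", paste(bad, collapse = ", "))
  if (anyDuplicated(manifest$gene_id)) {
    stop("duplicate gene_ids in manifest: ",
         paste(unique(manifest$gene_id[duplicated(manifest$gene_id)]), collapse = ", "))
  }
  if (sum(manifest$probe_class == "housekeeping") < 1) {
    stop("manifest needs at least one housekeeping probe")
  }
  if (sum(manifest$probe_class == "positive_ctrl") < 6) {
    stop("manifest needs at least six positive-control probes")
  }
  invisible(manifest)
}

manifest_genes <- function(manifest, class) {
  manifest$gene_id[manifest$probe_class %in% class]
}

#' Preset gene sets for the biology scores
#'
#' \code{proliferation_genes()} returns the two proliferation markers whose
#' geometric mean forms the proliferation score; \code{immune_genes()} the ten
#' immune-response genes whose geometric mean forms the immune score.
#'
#' @return character vector of gene symbols.
#' @export
proliferation_genes <- function() c("MKI67", "AURKA")

#' @rdname proliferation_genes
#' @export
immune_genes <- function() {
  c("IRF1", "IGKC", "STAT1", "OSMR", "CCL19",
    "RelA", "IRF8", "FGR", "TNFRSF1B", "C3")
}
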