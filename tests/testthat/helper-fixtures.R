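# Shared fixture builders and independent oracles.

# small manifest with configurable endogenous gene count
tiny_manifest <- function(n_endog = 8, n_hk = 2, n_pos = 6, n_neg = 2,
                          endog_ids = sprintf("G%02d", seq_len(n_endog))) {
  data.frame(
    gene_id = c(endog_ids, sprintf("HK%d", seq_len(n_hk)),
                paste0("POS_", LETTERS[seq_len(n_pos)]),
                paste0("NEG_", LETTERS[seq_len(n_neg)])),
    probe_class = rep(c("endogenous", "housekeeping", "positive_ctrl",
                        "negative_ctrl"), c(n_endog, n_hk, n_pos, n_neg)),
    source_category = NA_character_)
}

# raw_counts around an endogenous matrix, adding well-behaved control probes
tiny_counts <- function(endog_mat, n_hk = 2, n_pos = 6, n_neg = 2,
                        hk_level = 1000) {
  n <- ncol(endog_mat)
  manifest <- tiny_manifest(nrow(endog_mat), n_hk, n_pos, n_neg,
                            endog_ids = rownames(endog_mat))
  hk <- matrix(hk_level, n_hk, n,
               dimnames = list(sprintf("HK%d", seq_len(n_hk)),
                               colnames(endog_mat)))
  pos <- matrix(round(radSSP::positive_control_ladder(n_pos)), n_pos, n,
                dimnames = list(paste0("POS_", LETTERS[seq_len(n_pos)]),
                                colnames(endog_mat)))
  neg <- matrix(2L, n_neg, n,
                dimnames = list(paste0("NEG_", LETTERS[seq_len(n_neg)]),
                                colnames(endog_mat)))
  radSSP::raw_counts(rbind(endog_mat, hk, pos, neg), manifest)
}

# random log2-style expression matrix
random_expr <- function(n_genes, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(round(rnorm(n_genes * n_samples, 8, 2), 3), n_genes,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# hand-built locked model for prediction tests
make_ssp <- function(gene_a, gene_b, stratum = "ER+RT+") {
  structure(list(stratum = stratum, k = length(gene_a),
                 rules = data.frame(gene_a = gene_a, gene_b = gene_b,
                                    delta = NA_real_, gamma = NA_real_),
                 decision = "majority_vote",
                 metadata = list(dropped_rules = list()),
                 version = "1.0"),
            class = "ssp")
}

# ---- independent oracles -------------------------------------------------

# explicit counting version of the pair statistics
oracle_pair_score <- function(expr, labels, i, j) {
  p <- function(cls) {
    cols <- which(labels == cls)
    tot <- 0
    for (s in cols) {
      if (expr[i, s] > expr[j, s]) tot <- tot + 1
      else if (expr[i, s] == expr[j, s]) tot <- tot + 0.5
    }
    tot / length(cols)
  }
  rk <- apply(expr, 2, rank)
  g <- function(cls) mean(rk[i, labels == cls] - rk[j, labels == cls])
  list(delta = abs(p(TRUE) - p(FALSE)), gamma = abs(g(TRUE) - g(FALSE)))
}

# independent disjoint selection: repeatedly scan all remaining pairs and take
# the maximum under (delta desc, gamma desc, lexicographic gene_a, gene_b)
oracle_select_pairs <- function(expr, labels, k_max) {
  genes <- rownames(expr)
  pairs <- t(combn(genes, 2))
  stats <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    sc <- oracle_pair_score(expr, labels, i, j)
    cmp <- (expr[i, ] > expr[j, ]) + 0.5 * (expr[i, ] == expr[j, ])
    s <- mean(cmp[labels]) - mean(cmp[!labels])
    if (s < 0 || (s == 0 && i > j)) { tmp <- i; i <- j; j <- tmp }
    data.frame(gene_a = i, gene_b = j, delta = sc$delta, gamma = sc$gamma)
  })
  tab <- do.call(rbind, stats)
  chosen <- NULL
  used <- character(0)
  for (step in seq_len(k_max)) {
    avail <- tab[!(tab$gene_a %in% used) & !(tab$gene_b %in% used), ]
    if (nrow(avail) == 0) break
    ord <- order(-signif(avail$delta, 10), -signif(avail$gamma, 10),
                 avail$gene_a, avail$gene_b, method = "radix")
    best <- avail[ord[1], ]
    chosen <- rbind(chosen, best)
    used <- c(used, best$gene_a, best$gene_b)
  }
  rownames(chosen) <- NULL
  chosen
}

# survival data from an exponential proportional-hazards model
sim_surv <- function(n, rate = 0.2, loghr = 0, x = NULL, cens = 15) {
  if (is.null(x)) x <- rep(0, n)
  t <- rexp(n, rate * exp(loghr * x))
  data.frame(time_years = pmin(t, cens), ibtr_event = t < cens, x = x)
}
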