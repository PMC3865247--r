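#' How many members of a gene set were called differential?
#'
#' @param results DE result data frame (`gene_id`, `called`).
#' @param members Character vector of gene ids (e.g. from
#'   [read_gene_set()]). Members absent from `results` count as not
#'   called; their number is attached as attribute `n_missing` rather than
#'   silently dropped.
#' @return Integer recovery count with attribute `n_missing`.
#' @export
recovery_count <- function(results, members) {
  members <- unique(members)
  hit <- results$gene_id[results$called]
  n <- sum(members %in% hit)
  attr(n, "n_missing") <- sum(!(members %in% results$gene_id))
  n
}

# M and D for result tables that lack them (the NB engine): recomputed from
# the normalized condition means after zero replacement, so effect
# summaries are comparable across engines.
ensure_md <- function(results) {
  if (all(c("M", "D") %in% names(results))) return(results)
  mm <- replace_zeros(cbind(results$mean_A, results$mean_B))
  md <- compute_md(mm[, 1], mm[, 2])
  results$M <- md$M
  results$D <- md$D
  results
}

#' Effect-size summary of the called genes
#'
#' @param results DE result data frame. `M` and `D` are used when present
#'   and otherwise recomputed from the normalized condition means.
#' @return One-row data frame: `n_deg`, `mean_M_deg`, `mean_D_deg` (the
#'   means are `NA` when nothing is called).
#' @export
deg_effect_summary <- function(results) {
  results <- ensure_md(results)
  deg <- results[results$called, , drop = FALSE]
  data.frame(
    n_deg = nrow(deg),
    mean_M_deg = if (nrow(deg)) mean(deg$M) else NA_real_,
    mean_D_deg = if (nrow(deg)) mean(deg$D) else NA_real_
  )
}

#' Per-gene M-D table for joint-structure plots
#'
#' All expressed genes are included, with their call flag, ready for an
#' M versus D scatter.
#'
#' @param results DE result data frame.
#' @return Data frame: `gene_id`, `M`, `D`, `called`.
#' @export
md_scatter_table <- function(results) {
  results <- ensure_md(results)
  results[, c("gene_id", "M", "D", "called")]
}

#' Compare expression level of a gene set against all genes
#'
#' Welch two-sample t-test of per-gene mean normalized expression for the
#' set members versus all genes, the standard check that a class (such as
#' transcription factors) is expressed below the gene-wide mean.
#'
#' @param normalized Normalized matrix with gene rownames.
#' @param members Gene ids of the set (>= 2 must be present in the
#'   matrix).
#' @param samples Optional sample ids over which per-gene expression is
#'   averaged (default: all columns).
#' @return List: `mean_all`, `mean_set`, `t_statistic`, `p_value`,
#'   `n_set`.
#' @export
expression_class_test <- function(normalized, members, samples = NULL) {
  m <- unclass(normalized)
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  expr <- rowMeans(m)
  set_expr <- expr[names(expr) %in% members]
  if (length(set_expr) < 2) stop("gene set needs at least two members present")
  tt <- stats::t.test(set_expr, expr, var.equal = FALSE)
  list(mean_all = mean(expr), mean_set = mean(set_expr),
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       n_set = length(set_expr))
}

#' Concordance of estimated fold changes with a reference
#'
#' Spearman (average ranks on ties) and Pearson correlations between
#' estimated and reference log2 fold changes, per depth — the downstream
#' half of a qPCR cross-validation. Non-finite estimates (genes with a
#' zero condition) are dropped pairwise.
#'
#' @param fc_by_depth Named list (names are depths) of data frames with
#'   columns `gene_id`, `log2fc`.
#' @param reference Data frame with columns `gene_id`, `log2fc`.
#' @return Data frame: `depth`, `n_genes`, `spearman_rho`, `pearson_r`.
#' @export
foldchange_correlation <- function(fc_by_depth, reference) {
  rows <- lapply(names(fc_by_depth), function(d) {
    est <- fc_by_depth[[d]]
    merged <- merge(est[, c("gene_id", "log2fc")],
                    reference[, c("gene_id", "log2fc")],
                    by = "gene_id", suffixes = c("_est", "_ref"))
    merged <- merged[is.finite(merged$log2fc_est) &
                       is.finite(merged$log2fc_ref), ]
    if (nrow(merged) < 3) stop("fewer than 3 shared genes at depth ", d)
    if (stats::sd(merged$log2fc_est) == 0 || stats::sd(merged$log2fc_ref) == 0) {
      stop("zero variance in fold changes at depth ", d)
    }
    data.frame(
      depth = as.numeric(d),
      n_genes = nrow(merged),
      spearman_rho = stats::cor(merged$log2fc_est, merged$log2fc_ref,
                                method = "spearman"),
      pearson_r = stats::cor(merged$log2fc_est, merged$log2fc_ref)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
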