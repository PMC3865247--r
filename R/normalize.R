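# Normalized matrices are plain matrices carrying the method and the
# per-sample scale metadata as attributes, so downstream code can treat
# them as numeric while the scaling stays invertible.
normalized_matrix <- function(values, method, scale_metadata) {
  attr(values, "method") <- method
  attr(values, "scale_metadata") <- scale_metadata
  class(values) <- c("NormalizedMatrix", class(values))
  values
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat("NormalizedMatrix (", attr(x, "method"), "), ",
      nrow(x), " genes x ", ncol(x), " samples\n", sep = "")
  invisible(x)
}

as_counts_matrix <- function(x) {
  if (inherits(x, "CountExperiment")) x$counts else as.matrix(x)
}

#' RPKM normalization
#'
#' Reads per kilobase of gene model per million assigned reads:
#' `1e9 * count / (length_bp * sample total)`. The denominator total is the
#' sample's assigned read count (its column sum).
#'
#' @param counts A `CountExperiment` or a counts matrix.
#' @param lengths_bp Gene lengths in bp (named by gene id, or in row
#'   order). Taken from the experiment when `counts` is a
#'   `CountExperiment`.
#' @return A `NormalizedMatrix` with method `"rpkm"`; scale metadata holds
#'   the per-sample totals and the gene lengths.
#' @export
rpkm_normalize <- function(counts, lengths_bp = NULL) {
  if (inherits(counts, "CountExperiment") && is.null(lengths_bp)) {
    lengths_bp <- counts$lengths
  }
  m <- as_counts_matrix(counts)
  if (is.null(lengths_bp)) stop("gene lengths are required for RPKM")
  if (!is.null(names(lengths_bp)) && !is.null(rownames(m))) {
    if (!all(rownames(m) %in% names(lengths_bp))) {
      stop("every gene needs a length")
    }
    lengths_bp <- lengths_bp[rownames(m)]
  }
  if (length(lengths_bp) != nrow(m)) stop("lengths must match genes")
  if (any(lengths_bp <= 0)) stop("gene lengths must be positive")
  totals <- colSums(m)
  if (any(totals <= 0)) stop("every sample needs a positive total count")
  values <- 1e9 * sweep(m / lengths_bp, 2, totals, "/")
  normalized_matrix(values, "rpkm",
                    list(totals = totals, lengths_bp = lengths_bp))
}

#' Upper-quartile normalization
#'
#' Each sample is divided by the 75th percentile of its nonzero counts
#' (linear-interpolation quantile) and rescaled by a fixed factor of 1000,
#' so the 75th-percentile gene of every sample maps to 1000. The unit is
#' independent of sequencing depth, which keeps expression values — and the
#' raw-difference statistic D built from them — comparable across the rungs
#' of a depth titration.
#'
#' @param counts A `CountExperiment` or a counts matrix; each sample must
#'   have at least one nonzero gene.
#' @return A `NormalizedMatrix` with method `"uq"`; scale metadata holds the
#'   per-sample denominators and the fixed rescale factor.
#' @export
uq_normalize <- function(counts) {
  m <- as_counts_matrix(counts)
  denom <- apply(m, 2, function(x) {
    x <- x[x > 0]
    if (length(x) == 0) stop("upper-quartile undefined for an all-zero sample")
    stats::quantile(x, 0.75, names = FALSE)
  })
  rescale <- 1000
  values <- sweep(m, 2, denom, "/") * rescale
  normalized_matrix(values, "uq", list(denominators = denom, rescale = rescale))
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (positive in every sample) of the
#' ratio of that sample's count to the gene's geometric mean across samples.
#'
#' @param counts A `CountExperiment` or a counts matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- as_counts_matrix(counts)
  log_geo <- rowMeans(log(m))
  use <- is.finite(log_geo)
  if (!any(use)) stop("no gene has positive counts in every sample")
  geo <- exp(log_geo[use])
  apply(m[use, , drop = FALSE], 2, function(x) stats::median(x / geo))
}
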