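#' Replace zeros by half the smallest positive value
#'
#' M (a log2 ratio) is undefined when a value is 0; every zero in the
#' matrix is replaced by `0.5 * min(positive values)` so fold differences
#' stay finite on a scale-aware floor. Positive values are untouched.
#'
#' @param normalized Numeric matrix (typically a `NormalizedMatrix`).
#' @return The matrix with zeros replaced.
#' @export
replace_zeros <- function(normalized) {
  pos <- normalized[normalized > 0]
  if (length(pos) == 0) stop("matrix is entirely zero")
  normalized[normalized == 0] <- min(pos) / 2
  normalized
}

#' Signal statistics M and D for a pair of expression values
#'
#' M is the absolute log2 fold difference, D the absolute raw difference on
#' the normalized scale. Vectorized over pairs.
#'
#' @param x_a,x_b Positive expression values (apply [replace_zeros()]
#'   first).
#' @return Data frame with columns `M` and `D`.
#' @export
compute_md <- function(x_a, x_b) {
  if (any(x_a <= 0) || any(x_b <= 0)) {
    stop("compute_md needs positive values; replace zeros first")
  }
  data.frame(M = abs(log2(x_a / x_b)), D = abs(x_a - x_b))
}

#' Empirical noise distribution from within-condition replicate pairs
#'
#' For every unordered pair of replicate samples within the same condition
#' and every gene, the (M, D) pair of the two replicate values is added;
#' pairs are pooled across both conditions. This is the empirical null
#' against which between-condition signal is scored.
#'
#' @param normalized Positive matrix (after [replace_zeros()]) with sample
#'   columns.
#' @param design Design data frame (`sample`, `condition`, `replicate`).
#' @return Data frame of noise `M`, `D` pairs, classed `NoiseDistribution`,
#'   with attribute `n_pairs`.
#' @export
build_noise <- function(normalized, design) {
  conds <- unique(design$condition)
  pieces <- list()
  for (cond in conds) {
    smp <- design$sample[design$condition == cond]
    if (length(smp) < 2) next
    cmb <- utils::combn(smp, 2)
    for (k in seq_len(ncol(cmb))) {
      pieces[[length(pieces) + 1L]] <-
        compute_md(normalized[, cmb[1, k]], normalized[, cmb[2, k]])
    }
  }
  if (length(pieces) == 0) {
    stop("no condition has at least two replicates")
  }
  noise <- do.call(rbind, pieces)
  rownames(noise) <- NULL
  attr(noise, "n_pairs") <- nrow(noise)
  class(noise) <- c("NoiseDistribution", class(noise))
  noise
}

# Count, for each signal pair, the noise pairs it strictly dominates
# (M* < M and D* < D), with a sweep over M and a Fenwick tree over D ranks.
dominance_count <- function(M, D, noise_M, noise_D) {
  n <- length(noise_M)
  o <- order(noise_M)
  nm <- noise_M[o]
  nd <- noise_D[o]
  ud <- sort(unique(nd))
  K <- length(ud)
  nd_rank <- findInterval(nd, ud)                  # exact rank of each value
  q_rank <- findInterval(D, ud, left.open = TRUE)  # #{unique D* < D}
  go <- order(M)
  tree <- integer(K)
  res <- integer(length(M))
  j <- 1L
  for (idx in go) {
    mg <- M[idx]
    while (j <= n && nm[j] < mg) {
      i <- nd_rank[j]
      while (i <= K) {
        tree[i] <- tree[i] + 1L
        i <- i + bitwAnd(i, -i)
      }
      j <- j + 1L
    }
    r <- q_rank[idx]
    s <- 0L
    while (r > 0L) {
      s <- s + tree[r]
      r <- r - bitwAnd(r, -r)
    }
    res[idx] <- s
  }
  res
}

#' Odds that a signal exceeds the noise
#'
#' The probability of differential expression is the fraction of noise
#' pairs that the signal strictly dominates in both coordinates:
#' `signal.M > M*` and `signal.D > D*`. A (0, 0) signal therefore scores
#' exactly 0.
#'
#' @param M,D Signal statistics (vectors of equal length).
#' @param noise A `NoiseDistribution` (or any data frame with `M`, `D`).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
de_probability <- function(M, D, noise) {
  if (nrow(noise) == 0) stop("noise distribution is empty")
  dominance_count(M, D, noise$M, noise$D) / nrow(noise)
}

#' Noise-odds differential expression test
#'
#' The nonparametric engine: normalize (RPKM or upper-quartile), drop genes
#' with zero counts in every sample, replace remaining zeros, average
#' replicates per condition, score each gene's between-condition (M, D)
#' signal against the pooled within-condition noise distribution, and call
#' genes whose probability exceeds the threshold (default 0.8, the
#' method's conventional cutoff).
#'
#' @param experiment A `CountExperiment`.
#' @param normalization `"rpkm"` or `"uq"`.
#' @param threshold Probability cutoff; a gene is called when
#'   `probability > threshold` (strict).
#' @return Data frame, one row per expressed gene: `gene_id`, `mean_A`,
#'   `mean_B` (normalized condition means after zero replacement),
#'   `log2fc` (A over B, signed), `M`, `D`, `probability`, `called`.
#'   Attributes `normalization` and `threshold` record the run.
#' @export
noise_odds_test <- function(experiment,
                            normalization = c("rpkm", "uq"),
                            threshold = 0.8) {
  stopifnot(inherits(experiment, "CountExperiment"))
  normalization <- match.arg(normalization)
  norm <- switch(normalization,
                 rpkm = rpkm_normalize(experiment),
                 uq = uq_normalize(experiment))
  expressed <- rowSums(experiment$counts) > 0
  values <- replace_zeros(norm[expressed, , drop = FALSE])
  design <- experiment$design
  conds <- unique(design$condition)
  mean_a <- rowMeans(values[, design$sample[design$condition == conds[1]],
                            drop = FALSE])
  mean_b <- rowMeans(values[, design$sample[design$condition == conds[2]],
                            drop = FALSE])
  signal <- compute_md(mean_a, mean_b)
  noise <- build_noise(values, design)
  prob <- de_probability(signal$M, signal$D, noise)
  res <- data.frame(
    gene_id = rownames(values),
    mean_A = unname(mean_a),
    mean_B = unname(mean_b),
    log2fc = unname(log2(mean_a / mean_b)),
    M = signal$M,
    D = signal$D,
    probability = prob,
    called = prob > threshold,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "normalization") <- normalization
  attr(res, "threshold") <- threshold
  res
}
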