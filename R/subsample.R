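#' Define a depth ladder for titration
#'
#' @param depths Strictly increasing positive integer read depths per
#'   replicate. Default is the 1/3/6/12 million-read ladder.
#' @param seed Integer seed from which per-sample, per-rung subsampling
#'   seeds are derived.
#' @return An object of class `DepthLadder`.
#' @export
depth_ladder <- function(depths = c(1e6, 3e6, 6e6, 12e6), seed = 1L) {
  if (any(depths <= 0) || any(depths != round(depths))) {
    stop("depths must be positive integers")
  }
  if (is.unsorted(depths, strictly = TRUE)) {
    stop("depths must be strictly increasing")
  }
  structure(list(depths = as.double(depths), seed = as.integer(seed)),
            class = "DepthLadder")
}

# Deterministic per-(seed, sample, rung) stream seed, kept below 2^31.
derive_seed <- function(seed, sample_idx, rung_idx = 0L) {
  m <- 2147483647
  x <- (as.double(seed) %% m) * 48271 %% m
  x <- (x + sample_idx * 69621 + rung_idx * 16807) %% m
  as.integer(x)
}

# One multivariate hypergeometric draw: sample k reads without replacement
# from a library whose reads are distributed over genes as `counts`.
# Sequential conditional hypergeometric (the standard decomposition).
rmvhyper_once <- function(counts, k) {
  out <- numeric(length(counts))
  remaining <- sum(counts)
  for (i in seq_along(counts)) {
    if (k <= 0) break
    ci <- counts[i]
    remaining <- remaining - ci
    if (ci > 0) {
      x <- stats::rhyper(1, ci, remaining, k)
      out[i] <- x
      k <- k - x
    }
  }
  out
}

#' Subsample a count experiment to an exact target depth
#'
#' Emulates drawing reads at random, without replacement, from each sequenced
#' library: each sample column is replaced by a multivariate hypergeometric
#' draw of `target_depth` reads from its observed reads. Column sums hit the
#' target exactly and every entry is bounded by the original count.
#'
#' @param experiment A `CountExperiment`.
#' @param target_depth Non-negative integer, at most the smallest sample
#'   total.
#' @param seed Integer seed. Per-sample streams are derived from
#'   `(seed, sample index, rung)` so results are reproducible and
#'   order-independent.
#' @param rung Integer tag mixed into the per-sample seeds; [titrate()] sets
#'   it to the rung index so the rungs are independent draws.
#' @return A `CountExperiment` with the same genes, lengths and design.
#' @export
subsample_counts <- function(experiment, target_depth, seed = 1L, rung = 0L) {
  stopifnot(inherits(experiment, "CountExperiment"))
  if (length(target_depth) != 1 || is.na(target_depth) || target_depth < 0 ||
      target_depth != round(target_depth)) {
    stop("target_depth must be a single non-negative integer")
  }
  totals <- colSums(experiment$counts)
  if (any(target_depth > totals)) {
    stop("target_depth exceeds the total count of at least one sample")
  }
  out <- experiment$counts
  for (j in seq_len(ncol(out))) {
    set.seed(derive_seed(seed, j, rung))
    out[, j] <- rmvhyper_once(experiment$counts[, j], target_depth)
  }
  count_experiment(out, experiment$lengths, experiment$design)
}

#' Titrate an experiment over a ladder of depths
#'
#' Each rung is an independent random draw from the full-depth experiment
#' (not nested), mirroring independent random sampling of each depth from
#' the larger sequencing run. With `nested = TRUE` each rung is instead
#' drawn from the next deeper rung, so rung matrices are elementwise
#' monotone in depth.
#'
#' @param experiment A `CountExperiment`; every sample total must be at
#'   least the deepest rung.
#' @param ladder A [depth_ladder()].
#' @param nested Logical; draw rungs from the next deeper rung instead of
#'   from the full experiment.
#' @return Named list (names are depths) of `CountExperiment`s.
#' @export
titrate <- function(experiment, ladder, nested = FALSE) {
  stopifnot(inherits(ladder, "DepthLadder"))
  depths <- ladder$depths
  if (max(depths) > min(colSums(experiment$counts))) {
    stop("deepest rung exceeds the shallowest sample total")
  }
  out <- vector("list", length(depths))
  names(out) <- format(depths, scientific = FALSE, trim = TRUE)
  source_exp <- experiment
  for (r in rev(seq_along(depths))) {
    from <- if (nested) source_exp else experiment
    out[[r]] <- subsample_counts(from, depths[r], seed = ladder$seed, rung = r)
    if (nested) source_exp <- out[[r]]
  }
  out
}
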