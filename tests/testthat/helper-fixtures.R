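# Small experiment builders used across the suite.

make_experiment <- function(counts, conditions = NULL, lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(conditions)) {
    half <- ncol(counts) / 2
    conditions <- rep(c("A", "B"), each = half)
  }
  reps <- stats::ave(seq_along(conditions), conditions, FUN = seq_along)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0(conditions, "_", reps)
  }
  if (is.null(lengths)) {
    lengths <- stats::setNames(rep(1000, nrow(counts)), rownames(counts))
  }
  design <- data.frame(sample = colnames(counts), condition = conditions,
                       replicate = reps, stringsAsFactors = FALSE)
  count_experiment(counts, lengths, design)
}

random_experiment <- function(n_genes, n_rep = 2, lambda = 50, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * 2 * n_rep, lambda), nrow = n_genes)
  make_experiment(counts,
                  conditions = rep(c("A", "B"), each = n_rep),
                  lengths = stats::setNames(sample(200:5000, n_genes,
                                                   replace = TRUE),
                                            sprintf("g%03d", seq_len(n_genes))))
}

# Brute-force noise-odds probability: the O(genes x noise) double loop.
brute_probability <- function(M, D, noise_M, noise_D) {
  vapply(seq_along(M), function(i) {
    mean(M[i] > noise_M & D[i] > noise_D)
  }, numeric(1))
}
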