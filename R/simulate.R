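#' Configuration for the synthetic two-condition experiment
#'
#' The generator emulates the statistical structure of a glandular bulk
#' RNA-seq contrast: a heavy-tailed (log-normal) expression profile with a
#' few dominant transcripts, a small set of highly expressed, strongly
#' differential "focal" marker genes, and a low-expression transcription
#' factor like class whose mean abundance sits well below the gene-wide
#' mean but which can still carry large fold differences.
#'
#' Defaults describe the study conditions the package benchmarks: ~10^4
#' genes, 2 biological replicates per condition, 12 million reads per
#' replicate, 5% differential genes, 11 focal markers with |log2 FC| >= 3
#' drawn from the top decile of baseline abundance, and a 400-gene TF-like
#' class at one tenth of the typical abundance with roughly a third of its
#' members differential.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per condition.
#' @param depth_per_replicate Reads per replicate library (column sum).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   relative baseline abundances. `baseline_sdlog = 2` gives the heavy
#'   tail with a few dominant transcripts.
#' @param dispersion Negative-binomial overdispersion phi (>= 0); per-gene,
#'   per-replicate rates are multiplied by gamma noise with mean 1 and
#'   variance phi, so marginal counts are NB-like. `0` gives the Poisson
#'   (multinomial) limit.
#' @param frac_de Fraction of non-TF genes that are differential (the focal
#'   genes are a subset of these).
#' @param lfc_mean,lfc_sd Magnitude distribution of |log2 fold change| for
#'   ordinary DE genes: `|rnorm(lfc_mean, lfc_sd)|`, sign +/- with equal
#'   probability.
#' @param n_focal Number of focal marker genes.
#' @param focal_lfc_min Minimum |log2 fold change| of a focal gene.
#' @param focal_baseline_quantile Focal genes are drawn from baselines above
#'   this quantile of all baselines.
#' @param n_tf Number of TF-like genes.
#' @param tf_abundance_scale Multiplier in (0, 1] applied to TF-like
#'   baselines (0.1 = ten-fold lower expression).
#' @param frac_tf_de Fraction of TF-like genes that are differential.
#' @param length_min,length_max Gene length range (bp), sampled uniformly.
#' @param seed Integer seed; all randomness in [simulate_experiment()] flows
#'   from it.
#'
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 10000L,
                       n_replicates = 2L,
                       depth_per_replicate = 12e6,
                       baseline_meanlog = 0,
                       baseline_sdlog = 2,
                       dispersion = 0.05,
                       frac_de = 0.05,
                       lfc_mean = 1.5,
                       lfc_sd = 0.8,
                       n_focal = 11L,
                       focal_lfc_min = 3,
                       focal_baseline_quantile = 0.9,
                       n_tf = 400L,
                       tf_abundance_scale = 0.1,
                       frac_tf_de = 0.33,
                       length_min = 500L,
                       length_max = 5000L,
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, n_replicates = n_replicates,
              depth_per_replicate = depth_per_replicate,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              dispersion = dispersion, frac_de = frac_de,
              lfc_mean = lfc_mean, lfc_sd = lfc_sd,
              n_focal = n_focal, focal_lfc_min = focal_lfc_min,
              focal_baseline_quantile = focal_baseline_quantile,
              n_tf = n_tf, tf_abundance_scale = tf_abundance_scale,
              frac_tf_de = frac_tf_de,
              length_min = length_min, length_max = length_max,
              seed = seed)
  stopifnot(n_genes >= 1, n_replicates >= 1)
  if (depth_per_replicate <= 0 || depth_per_replicate != round(depth_per_replicate)) {
    stop("depth_per_replicate must be a positive integer")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (frac_de < 0 || frac_de > 1) stop("frac_de must be in [0, 1]")
  if (frac_tf_de < 0 || frac_tf_de > 1) stop("frac_tf_de must be in [0, 1]")
  if (n_focal < 0 || n_tf < 0) stop("n_focal and n_tf must be >= 0")
  if (n_focal + n_tf > n_genes) stop("n_focal + n_tf must not exceed n_genes")
  if (focal_lfc_min <= 0) stop("focal_lfc_min must be positive")
  if (focal_baseline_quantile < 0 || focal_baseline_quantile > 1) {
    stop("focal_baseline_quantile must be in [0, 1]")
  }
  if (tf_abundance_scale <= 0 || tf_abundance_scale > 1) {
    stop("tf_abundance_scale must be in (0, 1]")
  }
  if (length_min <= 0 || length_max < length_min) stop("invalid length range")
  n_de <- round(frac_de * (n_genes - n_tf))
  if (n_de < n_focal) {
    stop("frac_de * n_genes too small: focal genes are a subset of DE genes")
  }
  structure(cfg, class = "SimConfig")
}

#' Simulate a replicated two-condition count experiment with known truth
#'
#' Reads are allocated to genes by a multinomial draw per replicate, so each
#' sample's column sum equals `depth_per_replicate` exactly — the sequencing
#' budget is fixed, as on a real lane. Per-replicate gene rates are the
#' condition's relative abundances perturbed by gamma noise with variance
#' `dispersion`, so marginal counts are negative-binomial-like. Condition A
#' abundances equal baseline x 2^(true log2 FC), renormalized; condition B
#' uses the baseline itself.
#'
#' Gene classes in the truth table:
#' \describe{
#'   \item{`null`}{not differential, `true_log2fc = 0`.}
#'   \item{`de`}{differential, |log2 FC| drawn from `|N(lfc_mean, lfc_sd)|`.}
#'   \item{`focal`}{differential marker: baseline above the
#'     `focal_baseline_quantile` quantile and |log2 FC| >= `focal_lfc_min`.}
#'   \item{`tf_null`, `tf_de`}{TF-like genes (baseline scaled by
#'     `tf_abundance_scale`), not/differential.}
#' }
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `experiment` (a [count_experiment()]) and
#'   `truth` (data frame: `gene_id`, `gene_class`, `true_log2fc`,
#'   `baseline_abundance` — relative, summing to 1 — and `length_bp`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  length_bp <- sample(seq(config$length_min, config$length_max), n,
                      replace = TRUE)

  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  idx_tf <- if (config$n_tf > 0) sort(sample.int(n, config$n_tf)) else integer(0)
  baseline[idx_tf] <- baseline[idx_tf] * config$tf_abundance_scale

  # Class assignment: focal genes are high-baseline DE genes outside the TF
  # class; ordinary DE genes fill the rest of the DE budget.
  non_tf <- setdiff(seq_len(n), idx_tf)
  n_de_total <- round(config$frac_de * length(non_tf))
  cut <- stats::quantile(baseline, config$focal_baseline_quantile)
  eligible <- non_tf[baseline[non_tf] > cut]
  if (length(eligible) < config$n_focal) {
    stop("not enough high-baseline genes to plant the focal set")
  }
  idx_focal <- sort(sample(eligible, config$n_focal))
  pool <- setdiff(non_tf, idx_focal)
  idx_de <- sort(sample(pool, n_de_total - config$n_focal))
  n_tf_de <- round(config$frac_tf_de * config$n_tf)
  idx_tf_de <- if (n_tf_de > 0) sort(sample(idx_tf, n_tf_de)) else integer(0)

  gene_class <- rep("null", n)
  gene_class[idx_tf] <- "tf_null"
  gene_class[idx_tf_de] <- "tf_de"
  gene_class[idx_de] <- "de"
  gene_class[idx_focal] <- "focal"

  lfc <- numeric(n)
  rsign <- function(k) sample(c(-1, 1), k, replace = TRUE)
  k <- length(idx_de)
  lfc[idx_de] <- rsign(k) * abs(stats::rnorm(k, config$lfc_mean, config$lfc_sd))
  k <- length(idx_tf_de)
  lfc[idx_tf_de] <- rsign(k) * abs(stats::rnorm(k, config$lfc_mean, config$lfc_sd))
  k <- length(idx_focal)
  lfc[idx_focal] <- rsign(k) *
    (config$focal_lfc_min + abs(stats::rnorm(k, 0, config$lfc_sd)))

  prob_b <- baseline / sum(baseline)
  ab_a <- baseline * 2^lfc
  prob_a <- ab_a / sum(ab_a)

  n_rep <- config$n_replicates
  samples <- c(paste0("A_", seq_len(n_rep)), paste0("B_", seq_len(n_rep)))
  counts <- matrix(0, n, 2L * n_rep, dimnames = list(gene_id, samples))
  probs <- cbind(A = prob_a, B = prob_b)
  for (j in seq_along(samples)) {
    p <- probs[, if (j <= n_rep) "A" else "B"]
    if (config$dispersion > 0) {
      g <- stats::rgamma(n, shape = 1 / config$dispersion,
                         rate = 1 / config$dispersion)
      p <- p * g
    }
    counts[, j] <- stats::rmultinom(1, config$depth_per_replicate, p)
  }

  design <- data.frame(
    sample = samples,
    condition = rep(c("A", "B"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    gene_id = gene_id,
    gene_class = gene_class,
    true_log2fc = lfc,
    baseline_abundance = prob_b,
    length_bp = length_bp,
    stringsAsFactors = FALSE
  )
  list(
    experiment = count_experiment(counts,
                                  stats::setNames(length_bp, gene_id), design),
    truth = truth
  )
}

#' Sensitivity and false discovery proportion against the simulated truth
#'
#' @param results A DE result data frame with columns `gene_id` and `called`
#'   (as returned by [noise_odds_test()] or [nb_exact_test()]). Genes absent
#'   from `results` (e.g. dropped as unexpressed) count as not called.
#' @param truth Truth table from [simulate_experiment()].
#' @return A list: `by_class`, a data frame with per-class gene counts,
#'   calls, and sensitivity (`NA` for classes with no truly differential
#'   members); and `fdp`, the overall false discovery proportion — the
#'   fraction of called genes that are truly null (0 when nothing is
#'   called).
#' @export
truth_recall <- function(results, truth) {
  if (!all(c("gene_id", "called") %in% names(results))) {
    stop("results must have gene_id and called columns")
  }
  shared <- intersect(results$gene_id, truth$gene_id)
  if (length(shared) == 0) stop("results and truth share no genes")
  called_ids <- results$gene_id[results$called]
  truth$called <- truth$gene_id %in% called_ids
  truth$is_de <- truth$gene_class %in% c("de", "focal", "tf_de")
  by_class <- do.call(rbind, lapply(split(truth, truth$gene_class), function(d) {
    n_de <- sum(d$is_de)
    data.frame(
      gene_class = d$gene_class[1],
      n_genes = nrow(d),
      n_called = sum(d$called),
      sensitivity = if (n_de > 0) sum(d$called & d$is_de) / n_de else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(by_class) <- NULL
  n_called <- sum(truth$called)
  fdp <- if (n_called == 0) 0 else sum(truth$called & !truth$is_de) / n_called
  list(by_class = by_class, fdp = fdp)
}
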