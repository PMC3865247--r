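#' Configuration of a full depth-titration study
#'
#' @param sim A [sim_config()] describing a synthetic experiment, or `NULL`
#'   when `experiment` is given.
#' @param experiment A `CountExperiment` to titrate (ignored when `sim` is
#'   given; the simulated experiment is used).
#' @param depths Ladder of per-replicate read depths.
#' @param engines Subset of `c("noiseq", "nbexact")`.
#' @param normalizations Normalizations for the noise-odds engine, subset
#'   of `c("rpkm", "uq")`. The NB engine always uses size factors and is
#'   labelled `"sizefactor"`.
#' @param prob_threshold Noise-odds probability cutoff.
#' @param alpha Adjusted-p cutoff for the NB engine.
#' @param gene_sets Named list of gene-id vectors whose recovery is
#'   tracked per rung. When simulating, `focal` and `tf` sets are added
#'   automatically from the truth table.
#' @param reference_fc Optional reference data frame (`gene_id`,
#'   `log2fc`); fold-change concordance per depth is computed from the
#'   first noise-odds result (or the NB result if the noise-odds engine is
#'   not run).
#' @param nested Nested (instead of independent) subsampling rungs.
#' @param seed Root seed; all randomness in the run flows from it.
#' @param out_dir Optional directory; when given, per-rung DE tables, the
#'   summary and a JSON manifest are written as TSV/JSON.
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(sim = NULL, experiment = NULL,
                       depths = c(1e6, 3e6, 6e6, 12e6),
                       engines = c("noiseq", "nbexact"),
                       normalizations = c("rpkm", "uq"),
                       prob_threshold = 0.8, alpha = 0.05,
                       gene_sets = list(), reference_fc = NULL,
                       nested = FALSE, seed = 1L, out_dir = NULL) {
  if (is.null(sim) && is.null(experiment)) {
    stop("either sim or experiment is required")
  }
  if (prob_threshold <= 0 || prob_threshold >= 1) {
    stop("prob_threshold must be in (0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  engines <- match.arg(engines, c("noiseq", "nbexact"), several.ok = TRUE)
  normalizations <- match.arg(normalizations, c("rpkm", "uq"),
                              several.ok = TRUE)
  structure(list(sim = sim, experiment = experiment, depths = depths,
                 engines = engines, normalizations = normalizations,
                 prob_threshold = prob_threshold, alpha = alpha,
                 gene_sets = gene_sets, reference_fc = reference_fc,
                 nested = nested, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "RunConfig")
}

# Small deterministic content hash (31-ary rolling hash over the deparsed
# config, mod 2^31), so a manifest can witness that two runs used the same
# configuration.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[setdiff(names(config), "out_dir")]),
                           collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a complete depth-titration study
#'
#' Orchestrates simulate (optional) -> titrate -> normalize -> test (each
#' requested engine and normalization) -> benchmark, at every rung of the
#' ladder. Fully deterministic given the configuration: rerunning with the
#' same config reproduces identical tables.
#'
#' @param config A [run_config()].
#' @return A list:
#'   \describe{
#'     \item{`summary`}{data frame with one row per (depth, engine,
#'       normalization): `n_deg`, `mean_M_deg`, `mean_D_deg`, and per
#'       gene set `recovery_<set>` / `size_<set>` columns.}
#'     \item{`results`}{nested list of per-rung DE tables,
#'       `results[[depth]][[label]]` with labels like `noiseq_rpkm`,
#'       `nbexact_sizefactor`.}
#'     \item{`truth`}{truth table when simulated, else `NULL`.}
#'     \item{`fc_correlation`}{fold-change concordance per depth when
#'       `reference_fc` was given.}
#'     \item{`manifest`}{seed, config hash, package version, labels.}
#'   }
#' @export
run_titration_study <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  truth <- NULL
  gene_sets <- config$gene_sets
  if (!is.null(config$sim)) {
    simmed <- simulate_experiment(config$sim)
    experiment <- simmed$experiment
    truth <- simmed$truth
    if (!("focal" %in% names(gene_sets))) {
      gene_sets$focal <- truth$gene_id[truth$gene_class == "focal"]
    }
    if (!("tf" %in% names(gene_sets))) {
      gene_sets$tf <- truth$gene_id[truth$gene_class %in%
                                      c("tf_null", "tf_de")]
    }
    gene_sets <- Filter(length, gene_sets)
  } else {
    experiment <- config$experiment
  }

  ladder <- depth_ladder(config$depths, seed = config$seed)
  rungs <- titrate(experiment, ladder, nested = config$nested)

  labels <- character(0)
  if ("noiseq" %in% config$engines) {
    labels <- c(labels, paste0("noiseq_", config$normalizations))
  }
  if ("nbexact" %in% config$engines) {
    labels <- c(labels, "nbexact_sizefactor")
  }

  results <- list()
  rows <- list()
  for (d in names(rungs)) {
    exp_d <- rungs[[d]]
    results[[d]] <- list()
    for (lab in labels) {
      res <- if (startsWith(lab, "noiseq")) {
        noise_odds_test(exp_d, sub("noiseq_", "", lab),
                        threshold = config$prob_threshold)
      } else {
        nb_exact_test(exp_d, alpha_level = config$alpha)
      }
      results[[d]][[lab]] <- res
      eff <- deg_effect_summary(res)
      row <- data.frame(depth = as.numeric(d),
                        engine = sub("_.*", "", lab),
                        normalization = sub("^[^_]*_", "", lab),
                        eff, stringsAsFactors = FALSE)
      for (set_name in names(gene_sets)) {
        row[[paste0("recovery_", set_name)]] <-
          as.integer(recovery_count(res, gene_sets[[set_name]]))
        row[[paste0("size_", set_name)]] <- length(gene_sets[[set_name]])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL

  fc_correlation <- NULL
  if (!is.null(config$reference_fc)) {
    fc_lab <- labels[1]
    fc_by_depth <- lapply(results, function(r) r[[fc_lab]])
    fc_correlation <- foldchange_correlation(fc_by_depth, config$reference_fc)
  }

  manifest <- list(seed = config$seed,
                   config_hash = config_hash(unclass(config)),
                   package_version = as.character(
                     utils::packageVersion("shallowseq")),
                   depths = as.numeric(names(rungs)),
                   labels = labels,
                   n_genes = nrow(experiment$counts))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(summary, file.path(config$out_dir, "summary.tsv"))
    for (d in names(results)) {
      for (lab in names(results[[d]])) {
        write_tsv(results[[d]][[lab]],
                  file.path(config$out_dir,
                            sprintf("de_%s_%s.tsv", d, lab)))
      }
    }
    if (!is.null(truth)) {
      write_tsv(truth, file.path(config$out_dir, "truth.tsv"))
    }
    if (!is.null(fc_correlation)) {
      write_tsv(fc_correlation,
                file.path(config$out_dir, "fc_correlation.tsv"))
    }
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(summary = summary, results = results, truth = truth,
       fc_correlation = fc_correlation, manifest = manifest)
}
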