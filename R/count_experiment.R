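#' Construct a replicated two-condition count experiment
#'
#' Bundles a genes x samples matrix of non-negative integer read counts with
#' per-gene lengths (bp) and a sample design. This is the container every
#' other function in the package consumes, in the spirit of a `DGEList`.
#'
#' @param counts Integer matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids). All entries must be
#'   non-negative whole numbers.
#' @param lengths Numeric vector of gene lengths in bp, named by gene id, or
#'   unnamed and in row order of `counts`. All lengths must be positive.
#' @param design Data frame with columns `sample`, `condition`, `replicate`,
#'   one row per column of `counts`. Exactly two condition levels are
#'   required; the first condition in row order is taken as condition A when
#'   fold changes are reported (A over B).
#'
#' @return An object of class `CountExperiment`: a list with elements
#'   `counts`, `lengths`, `design`.
#' @export
count_experiment <- function(counts, lengths, design) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"  # keeps >2^31 column sums safe
  if (is.null(names(lengths))) {
    if (length(lengths) != nrow(counts)) {
      stop("unnamed lengths must match the number of genes")
    }
    names(lengths) <- rownames(counts)
  }
  if (!all(rownames(counts) %in% names(lengths))) {
    stop("every gene in counts needs a length")
  }
  lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  needed <- c("sample", "condition", "replicate")
  if (!all(needed %in% names(design))) {
    stop("design needs columns sample, condition, replicate")
  }
  if (!setequal(design$sample, colnames(counts)) ||
      nrow(design) != ncol(counts)) {
    stop("design samples must match count matrix columns")
  }
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  if (length(unique(design$condition)) != 2L) {
    stop("exactly two conditions are required")
  }
  structure(
    list(counts = counts, lengths = lengths, design = design),
    class = "CountExperiment"
  )
}

#' @export
print.CountExperiment <- function(x, ...) {
  cond <- table(x$design$condition)
  cat("CountExperiment:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("  conditions:",
      paste(sprintf("%s (n=%d)", names(cond), cond), collapse = ", "), "\n")
  cat("  column sums:",
      paste(format(colSums(x$counts), big.mark = ","), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountExperiment <- function(x) dim(x$counts)

#' Condition labels in A/B order
#'
#' First-appearing condition in the design is condition A; fold changes are
#' reported as A over B throughout the package.
#' @param experiment A `CountExperiment`.
#' @return Character vector of length 2.
#' @export
condition_levels <- function(experiment) {
  unique(experiment$design$condition)
}

# Columns (sample ids) belonging to one condition, in design order.
condition_samples <- function(experiment, condition) {
  experiment$design$sample[experiment$design$condition == condition]
}

#' Write a count experiment to plain TSV files
#'
#' Writes `counts.tsv` (first column `gene_id`, one column per sample),
#' `lengths.tsv` (`gene_id`, `length_bp`) and `design.tsv`
#' (`sample`, `condition`, `replicate`) into `dir`. Tab-separated, header
#' row, UTF-8, no quoting.
#'
#' @param experiment A `CountExperiment`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_count_experiment <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "lengths.tsv", "design.tsv"))
  cts <- data.frame(gene_id = rownames(experiment$counts),
                    experiment$counts, check.names = FALSE)
  write_tsv(cts, paths[1])
  write_tsv(data.frame(gene_id = names(experiment$lengths),
                       length_bp = unname(experiment$lengths)), paths[2])
  write_tsv(experiment$design, paths[3])
  invisible(paths)
}

#' Read a count experiment back from TSV files
#'
#' Inverse of [write_count_experiment()].
#' @param dir Directory holding `counts.tsv`, `lengths.tsv`, `design.tsv`.
#' @return A `CountExperiment`.
#' @export
read_count_experiment <- function(dir) {
  cts <- read_tsv(file.path(dir, "counts.tsv"))
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$gene_id
  len <- read_tsv(file.path(dir, "lengths.tsv"))
  lengths <- stats::setNames(len$length_bp, len$gene_id)
  design <- read_tsv(file.path(dir, "design.tsv"))
  count_experiment(m, lengths, design)
}

#' Read a newline-delimited gene-set file
#'
#' One gene id per line; blank lines and duplicate ids are dropped.
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  ids <- readLines(path, warn = FALSE)
  unique(ids[nzchar(trimws(ids))])
}

#' Read a reference fold-change table
#'
#' Two-column TSV (`gene_id`, `log2fc`), e.g. averaged qPCR fold changes,
#' for use as the reference in [foldchange_correlation()].
#' @param path File path.
#' @return Data frame with columns `gene_id` and `log2fc`.
#' @export
read_fold_changes <- function(path) {
  df <- read_tsv(path)
  if (!all(c("gene_id", "log2fc") %in% names(df))) {
    stop("fold-change table needs gene_id and log2fc columns")
  }
  df[, c("gene_id", "log2fc")]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
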