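test_that("simulated column sums equal the configured depth exactly", {
  cfg <- sim_config(n_genes = 500, n_tf = 50, depth_per_replicate = 20000,
                    seed = 11)
  sim <- simulate_experiment(cfg)
  expect_true(all(colSums(sim$experiment$counts) == 20000))
  expect_true(all(sim$experiment$counts >= 0))
  expect_true(all(sim$experiment$counts == round(sim$experiment$counts)))
  expect_equal(nrow(sim$truth), 500)
})

test_that("truth table respects the class invariants", {
  cfg <- sim_config(n_genes = 2000, depth_per_replicate = 1e5,
                    n_focal = 11, focal_baseline_quantile = 0.9,
                    focal_lfc_min = 3, seed = 3)
  sim <- simulate_experiment(cfg)
  tr <- sim$truth

  expect_equal(sum(tr$gene_class == "focal"), 11)
  expect_equal(sum(tr$gene_class %in% c("tf_null", "tf_de")), cfg$n_tf)
  # null-like classes carry no fold change
  expect_true(all(tr$true_log2fc[tr$gene_class %in% c("null", "tf_null")] == 0))
  # focal genes: strong fold change and top-decile baseline
  foc <- tr[tr$gene_class == "focal", ]
  expect_true(all(abs(foc$true_log2fc) >= 3))
  cut <- quantile(tr$baseline_abundance, 0.9)
  expect_true(all(foc$baseline_abundance > cut))
})

test_that("an all-null configuration has no nonzero fold changes", {
  cfg <- sim_config(n_genes = 300, depth_per_replicate = 1e4,
                    frac_de = 0, n_focal = 0, n_tf = 0, seed = 5)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$truth$true_log2fc == 0))
  expect_true(all(sim$truth$gene_class == "null"))
})

test_that("phi = 0 counts match Poisson moments across many replicates", {
  # All-null config, so every column is an iid multinomial draw from the
  # same baseline; 100 replicate columns give the Monte-Carlo sample.
  n_genes <- 50
  depth <- 5e4
  cfg <- sim_config(n_genes = n_genes, n_replicates = 50,
                    depth_per_replicate = depth, dispersion = 0,
                    frac_de = 0, n_focal = 0, n_tf = 0, seed = 1)
  sim <- simulate_experiment(cfg)
  m <- sim$experiment$counts
  n_obs <- ncol(m)
  mu <- depth * sim$truth$baseline_abundance
  emp_mean <- rowMeans(m)
  emp_var <- apply(m, 1, var)
  se_mean <- sqrt(mu) / sqrt(n_obs)          # Poisson sd / sqrt(n)
  frac_ok <- mean(abs(emp_mean - mu) <= 3 * se_mean)
  expect_gte(frac_ok, 0.95)
  # variance tracks the mean (Poisson limit): ratio near 1 for counts > 5
  big <- mu > 5
  ratio <- emp_var[big] / mu[big]
  se_ratio <- sqrt(2 / (n_obs - 1))
  expect_gte(mean(abs(ratio - 1) <= 3 * se_ratio), 0.9)
})

test_that("phi > 0 produces overdispersed counts for abundant genes", {
  cfg <- sim_config(n_genes = 200, n_replicates = 60,
                    depth_per_replicate = 1e5, dispersion = 0.05,
                    frac_de = 0, n_focal = 0, n_tf = 0, seed = 8)
  sim <- simulate_experiment(cfg)
  m <- sim$experiment$counts
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  big <- mu > 100
  expect_gt(sum(big), 20)
  expect_gte(mean(v[big] > mu[big]), 0.9)
})

test_that("TF-like genes sit below the gene-wide mean expression", {
  cfg <- sim_config(n_genes = 3000, depth_per_replicate = 5e5,
                    n_tf = 300, tf_abundance_scale = 0.1, seed = 13)
  sim <- simulate_experiment(cfg)
  norm <- rpkm_normalize(sim$experiment)
  expr <- rowMeans(norm)
  tf <- sim$truth$gene_class %in% c("tf_null", "tf_de")
  expect_lt(mean(expr[tf]), mean(expr))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(depth_per_replicate = -1), "positive integer")
  expect_error(sim_config(depth_per_replicate = 10.5), "positive integer")
  expect_error(sim_config(dispersion = -0.1), ">= 0")
  expect_error(sim_config(n_genes = 100, n_focal = 60, n_tf = 60), "exceed")
  expect_error(sim_config(n_genes = 1000, frac_de = 0.001, n_focal = 11),
               "focal")
  expect_error(sim_config(frac_de = 1.2), "frac_de")
})

test_that("simulation is deterministic given the seed", {
  mk <- function() sim_config(n_genes = 100, n_tf = 10, n_focal = 3,
                              frac_de = 0.1, depth_per_replicate = 1e4,
                              seed = 42)
  a <- simulate_experiment(mk())
  b <- simulate_experiment(mk())
  expect_identical(a$experiment$counts, b$experiment$counts)
  expect_identical(a$truth, b$truth)
})

test_that("truth_recall handles the no-call and all-call extremes", {
  sim <- simulate_experiment(sim_config(n_genes = 400, n_tf = 40,
                                        depth_per_replicate = 2e4, seed = 2))
  res <- data.frame(gene_id = sim$truth$gene_id, called = FALSE)
  tr <- truth_recall(res, sim$truth)
  de_classes <- tr$by_class$gene_class %in% c("de", "focal", "tf_de")
  expect_true(all(tr$by_class$sensitivity[de_classes] == 0))
  expect_equal(tr$fdp, 0)

  res$called <- TRUE
  tr <- truth_recall(res, sim$truth)
  expect_true(all(tr$by_class$sensitivity[de_classes] == 1))
  frac_null <- mean(sim$truth$gene_class %in% c("null", "tf_null"))
  expect_equal(tr$fdp, frac_null)
})

test_that("random calls on all-null truth give FDP 1", {
  sim <- simulate_experiment(sim_config(n_genes = 300,
                                        depth_per_replicate = 1e4,
                                        frac_de = 0, n_focal = 0, n_tf = 0,
                                        seed = 4))
  set.seed(99)
  res <- data.frame(gene_id = sim$truth$gene_id,
                    called = runif(300) < 0.3)
  tr <- truth_recall(res, sim$truth)
  # brute-force count
  expect_equal(tr$fdp, sum(res$called) / sum(res$called))
  expect_equal(tr$fdp, 1)
  expect_error(truth_recall(data.frame(gene_id = "zzz", called = TRUE),
                            sim$truth), "no genes")
})
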