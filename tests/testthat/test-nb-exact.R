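# Independent naive oracle: direct probability sums on the natural scale.
naive_nb_pvalue <- function(kA, kB, sA, sB, alpha, ssqA = sA^2 / 2,
                            ssqB = sB^2 / 2) {
  ks <- kA + kB
  q <- ks / (sA + sB)
  dens <- function(x, mu, v) {
    if (v <= mu) dpois(x, mu) else dnbinom(x, mu = mu, size = mu^2 / (v - mu))
  }
  mu_a <- q * sA
  mu_b <- q * sB
  va <- mu_a + alpha * q^2 * ssqA
  vb <- mu_b + alpha * q^2 * ssqB
  p <- sapply(0:ks, function(a) dens(a, mu_a, va) * dens(ks - a, mu_b, vb))
  obs <- p[kA + 1]
  min(1, sum(p[p <= obs * (1 + 1e-9)]) / sum(p))
}

test_that("a balanced split under equal size factors has p = 1", {
  expect_equal(nb_exact_pvalue(20, 20, 2, 2, alpha = 0.1), 1)
  expect_equal(nb_exact_pvalue(0, 0, 2, 2, alpha = 0.1), 1)
})

test_that("exact p values match full enumeration for all totals <= 50", {
  settings <- list(c(sA = 2, sB = 2, alpha = 0.05),
                   c(sA = 1.6, sB = 2.7, alpha = 0.2),
                   c(sA = 2.2, sB = 1.8, alpha = 0))
  for (st in settings) {
    for (ks in c(1, 2, 5, 17, 50)) {
      for (kA in 0:ks) {
        got <- nb_exact_pvalue(kA, ks - kA, st["sA"], st["sB"],
                               alpha = st["alpha"])
        want <- naive_nb_pvalue(kA, ks - kA, st["sA"], st["sB"],
                                alpha = st["alpha"])
        expect_equal(got, want, tolerance = 1e-9)
      }
    }
  }
})

test_that("the Poisson limit reduces to the two-sided binomial test", {
  for (kA in c(0, 3, 10, 25)) {
    for (kB in c(1, 7, 30)) {
      got <- nb_exact_pvalue(kA, kB, 2, 2, alpha = 0)
      want <- binom.test(kA, kA + kB, 0.5)$p.value
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("the windowed large-total path agrees with full enumeration", {
  # just above the windowing threshold
  kA <- 1.6e6; kB <- 1.5e6
  got <- nb_exact_pvalue(kA, kB, 2, 2, alpha = 1e-3)
  ks <- kA + kB
  q <- ks / 4
  mu <- q * 2
  v <- mu + 1e-3 * q^2 * 2
  lp <- dnbinom(0:ks, mu = mu, size = mu^2 / (v - mu), log = TRUE) +
    dnbinom(ks:0, mu = mu, size = mu^2 / (v - mu), log = TRUE)
  p <- exp(lp - max(lp))
  want <- min(1, sum(p[lp <= lp[kA + 1] + 1e-7]) / sum(p))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("invalid exact-test inputs are rejected", {
  expect_error(nb_exact_pvalue(-1, 3, 2, 2, alpha = 0.1), "non-negative")
  expect_error(nb_exact_pvalue(2.5, 3, 2, 2, alpha = 0.1), "non-negative")
  expect_error(nb_exact_pvalue(2, 3, 2, 2, alpha = -0.1), ">= 0")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.73), 0.73)

  # brute-force step-up oracle
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
      adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
    }
    adj
  }
  set.seed(31)
  p <- runif(1000)^2
  expect_equal(bh_adjust(p), step_up(p))
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(diff(bh_adjust(p)[order(p)]) >= 0))  # order preserved
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("raw dispersion is zero when variance equals the mean", {
  counts <- cbind(A_1 = c(1, 10), A_2 = c(3, 14),
                  B_1 = c(1, 10), B_2 = c(3, 14))
  rownames(counts) <- c("g1", "g2")
  design <- data.frame(sample = colnames(counts),
                       condition = c("A", "A", "B", "B"),
                       replicate = c(1, 2, 1, 2))
  # gene 1: within-condition mean 2, variance 2 -> raw = 0 with sf = 1
  d <- estimate_dispersions(counts, c(1, 1, 1, 1), design)
  expect_equal(unname(d$raw[1]), 0)
})

test_that("dispersion estimates recover the simulation parameter", {
  set.seed(41)
  n <- 2000
  mu <- exp(rnorm(n, 5, 1))
  counts <- sapply(1:4, function(j) rnbinom(n, mu = mu, size = 10))
  dimnames(counts) <- list(sprintf("g%04d", 1:n),
                           c("A_1", "A_2", "B_1", "B_2"))
  design <- data.frame(sample = colnames(counts),
                       condition = c("A", "A", "B", "B"),
                       replicate = c(1, 2, 1, 2))
  d <- estimate_dispersions(counts, rep(1, 4), design)
  expect_gt(median(d$final), 0.05)
  expect_lt(median(d$final), 0.2)
  expect_true(all(d$final >= d$raw - 1e-12))

  # Poisson counts: the fitted trend intercept stays near zero
  counts_p <- sapply(1:4, function(j) rpois(n, mu))
  dimnames(counts_p) <- dimnames(counts)
  dp <- estimate_dispersions(counts_p, rep(1, 4), design)
  expect_lt(abs(dp$fitted_a0), 0.02)
  expect_lt(median(dp$final), 0.05)
})

test_that("the NB exact engine is symmetric and filters unexpressed genes", {
  exp <- random_experiment(120, lambda = 60, seed = 51)
  exp$counts[5, ] <- 0
  res <- nb_exact_test(exp)
  expect_false("g005" %in% res$gene_id)
  expect_equal(nrow(res), 119)
  expect_true(all(res$pval > 0 & res$pval <= 1))
  expect_true(all(res$padj >= res$pval))
  expect_equal(res$called, res$padj < 0.05)

  ord <- c(3, 4, 1, 2)  # the B group becomes condition A and vice versa
  res2 <- nb_exact_test(count_experiment(exp$counts[, ord], exp$lengths,
                                         exp$design[ord, ]))
  expect_equal(res$pval, res2$pval)
  expect_equal(res$log2fc, -res2$log2fc)
})

test_that("planted strong fold changes are detected at high depth", {
  sim <- simulate_experiment(sim_config(n_genes = 1500,
                                        depth_per_replicate = 1e6,
                                        seed = 61))
  res <- nb_exact_test(sim$experiment)
  foc <- sim$truth$gene_id[sim$truth$gene_class == "focal"]
  expect_gte(recovery_count(res, foc), 10)
})
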