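# Differential methylation: logistic regression, Fisher's exact test,
# q-value correction, extraction.

test_that("logistic LRT matches direct likelihood maximization", {
  # independent oracle: maximize the binomial log-likelihood numerically
  oracle_lrt_p <- function(nm, nu, tr) {
    ll <- function(p, m, u) sum(m * log(p) + u * log(1 - p))
    full <- function(pars) {
      p <- plogis(pars[1] + pars[2] * tr)
      -ll(p, nm, nu)
    }
    null <- function(b0) -ll(plogis(rep(b0, length(nm))), nm, nu)
    f <- optim(c(0, 0), full, method = "BFGS")$value
    n0 <- optimize(null, c(-10, 10))$objective
    pchisq(2 * (n0 - f), df = 1, lower.tail = FALSE)
  }

  r <- logistic_test(c(80, 20), c(20, 80), c(1, 0))
  expect_equal(r$meth_diff, 60)
  expect_lt(r$pvalue, 1e-10)
  expect_equal(r$pvalue, oracle_lrt_p(c(80, 20), c(20, 80), c(1, 0)),
               tolerance = 1e-6)

  set.seed(61)
  for (i in 1:5) {
    cov <- sample(10:40, 6, replace = TRUE)
    nm <- rbinom(6, cov, runif(1, 0.2, 0.8))
    tr <- c(1, 1, 1, 0, 0, 0)
    got <- logistic_test(nm, cov - nm, tr)$pvalue
    expect_equal(got, oracle_lrt_p(nm, cov - nm, tr), tolerance = 1e-5)
  }
})

test_that("identical group proportions give beta1 = 0 and p = 1", {
  r <- logistic_test(c(30, 30), c(70, 70), c(1, 0))
  expect_equal(r$beta1, 0)
  expect_equal(r$pvalue, 1)
  expect_equal(r$meth_diff, 0)
})

test_that("covariate adjustment resolves a Simpson's-paradox design", {
  # two strata; within each stratum treatment and control match exactly,
  # but the strata are unbalanced across groups
  nm <- c(80, 80, 20, 80, 20, 20)
  nu <- c(20, 20, 80, 20, 80, 80)
  tr <- c(1, 1, 1, 0, 0, 0)
  stratum <- data.frame(s = factor(c("A", "A", "B", "A", "B", "B")))
  raw <- logistic_test(nm, nu, tr)
  adj <- logistic_test(nm, nu, tr, covariates = stratum)
  expect_lt(raw$pvalue, 1e-6)     # marginal difference +20 points
  expect_gt(adj$pvalue, 0.9)      # vanishes within strata
  expect_equal(raw$meth_diff, 20)
})

test_that("Wald and LRT agree on well-behaved designs", {
  nm <- c(25, 30, 28, 10, 12, 9)
  nu <- c(10, 8, 9, 25, 22, 27)
  tr <- c(1, 1, 1, 0, 0, 0)
  p_lrt <- logistic_test(nm, nu, tr, test = "likelihood_ratio")$pvalue
  p_wald <- logistic_test(nm, nu, tr, test = "wald")$pvalue
  expect_lt(abs(log10(p_lrt) - log10(p_wald)), 2)
})

test_that("separation is flagged and keeps a finite p-value", {
  r <- logistic_test(c(10, 0), c(0, 10), c(1, 0))
  expect_true(r$flagged)
  expect_true(is.finite(r$pvalue))
  expect_lt(r$pvalue, 1e-4)
  expect_true(is.infinite(r$beta1))
  expect_error(logistic_test(c(5, 5), c(5, 5), c(1, 1)), "control")
})

test_that("Fisher p-values equal hypergeometric enumeration", {
  expect_equal(fisher_test(5, 5, 5, 5)$pvalue, 1.0)
  r1 <- fisher_test(10, 0, 0, 10)
  expect_equal(r1$pvalue, enum_fisher_p(10, 0, 0, 10), tolerance = 1e-12)
  r2 <- fisher_test(3, 9, 9, 3)
  expect_equal(r2$pvalue, enum_fisher_p(3, 9, 9, 3), tolerance = 1e-12)
  expect_equal(r2$meth_diff, -50)

  # cross-check against the reference implementation on random tables
  set.seed(62)
  for (i in 1:50) {
    t4 <- c(sample(0:25, 2, TRUE), sample(0:25, 2, TRUE))
    if (t4[1] + t4[2] == 0) t4[1] <- 1
    if (t4[3] + t4[4] == 0) t4[3] <- 1
    got <- fisher_test(t4[1], t4[2], t4[3], t4[4])$pvalue
    ref <- fisher.test(matrix(t4, 2, byrow = TRUE))$p.value
    expect_equal(got, ref, tolerance = 1e-9)
  }
  expect_error(fisher_test(0, 0, 5, 5), "coverage")
})

test_that("test dispatch follows the group design", {
  sim1 <- simulate_methylomes(sim_spec(n_sites = 60, n_control = 1,
                                       n_treatment = 1, seed = 63))
  u1 <- unite_methylomes(lapply(sim1$samples, filter_by_coverage))
  d1 <- calculate_diff_meth(u1)
  expect_equal(attr(d1, "test"), "fisher")
  # per-unit agreement with the scalar Fisher test
  i <- which.max(abs(d1$meth.diff))
  expect_equal(d1$pvalue[i],
               fisher_test(u1$n_meth[i, 2], u1$n_unmeth[i, 2],
                           u1$n_meth[i, 1], u1$n_unmeth[i, 1])$pvalue)

  sim2 <- simulate_methylomes(sim_spec(n_sites = 60, n_control = 3,
                                       n_treatment = 4, seed = 64))
  u2 <- unite_methylomes(lapply(sim2$samples, filter_by_coverage))
  d2 <- calculate_diff_meth(u2)
  expect_equal(attr(d2, "test"), "logistic")
  j <- 7L
  expect_equal(d2$pvalue[j],
               logistic_test(u2$n_meth[j, ], u2$n_unmeth[j, ],
                             u2$treatments)$pvalue)
})

test_that("results are identical for any worker count", {
  sim <- simulate_methylomes(sim_spec(n_sites = 1000, seed = 65,
                                      effect_fraction = 0.05,
                                      effect_delta = 30))
  u <- unite_methylomes(lapply(sim$samples, filter_by_coverage))
  d1 <- calculate_diff_meth(u, workers = 1)
  d4 <- calculate_diff_meth(u, workers = 4)
  expect_identical(d1, d4)
})

test_that("BH q-values follow the step-up closed form", {
  expect_equal(as.numeric(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04),
                                         "bh")),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(as.numeric(adjust_pvalues(0.037, "bh")), 0.037)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(66)
  p <- runif(500)^2
  q <- as.numeric(adjust_pvalues(p, "bh"))
  # hand step-up: q_(i) = min_{j>=i} p_(j) * n / j
  o <- order(p)
  qs <- rev(cummin(rev(p[o] * length(p) / seq_along(p))))
  expect_equal(q[o], pmin(1, qs), tolerance = 1e-12)
  # monotone in ranked p
  expect_false(is.unsorted(q[o]))
})

test_that("SLIM rescales BH by a pi0 estimate in [0, 1]", {
  set.seed(67)
  p <- runif(10000)
  q_slim <- adjust_pvalues(p, "slim")
  pi0 <- attr(q_slim, "pi0")
  expect_gte(pi0, 0.9)
  expect_lte(pi0, 1)
  q_bh <- adjust_pvalues(p, "bh")
  expect_true(all(q_slim <= q_bh + 1e-15))
  expect_equal(as.numeric(q_slim),
               pmin(1, pi0 * as.numeric(q_bh)), tolerance = 1e-12)

  # strong signal drives pi0 down but never below 0
  p_mix <- c(runif(3000, 0, 1e-4), runif(7000))
  pi0_mix <- attr(adjust_pvalues(p_mix, "slim"), "pi0")
  expect_gte(pi0_mix, 0)
  expect_lt(pi0_mix, 1)

  # degenerate input falls back to BH
  expect_equal(attr(adjust_pvalues(c(0.2, 0.4), "slim"), "pi0"), 1)
})

test_that("DMC extraction applies strict cutoffs and sign classes", {
  d <- data.frame(chrom = "chr1", start = 1:4, end = 1:4, strand = "+",
                  pvalue = c(1e-5, 1e-5, 1e-5, 0.5),
                  qvalue = c(0.005, 0.005, 0.02, 0.5),
                  meth.diff = c(30, 25, 60, 80), class = "none")
  class(d) <- c("methyl_diff", "data.frame")
  got <- get_methyl_diff(d)
  expect_equal(got$start, 1L)          # q=0.02 fails, diff=25.0 is strict
  expect_equal(got$class, "hyper")

  set.seed(68)
  big <- data.frame(chrom = "chr1", start = 1:100, end = 1:100,
                    strand = "+", pvalue = runif(100),
                    qvalue = runif(100),
                    meth.diff = runif(100, -80, 80), class = "none")
  class(big) <- c("methyl_diff", "data.frame")
  kept <- get_methyl_diff(big, 0.1, 40, "hypo")
  oracle <- big[big$qvalue < 0.1 & abs(big$meth.diff) > 40 &
                  big$meth.diff < 0, ]
  expect_equal(kept$start, oracle$start)
  expect_true(all(kept$class == "hypo"))
})

test_that("per-chromosome summaries count covered units correctly", {
  units <- data.frame(chrom = rep(c("chr1", "chr2"), c(10, 5)),
                      start = 1:15, end = 1:15, strand = "+")
  u <- structure(list(units = units), class = "united_methylome")
  d <- data.frame(chrom = units$chrom, start = units$start,
                  end = units$end, strand = "+",
                  pvalue = 0.5, qvalue = 0.5, meth.diff = 0,
                  class = "none")
  d$qvalue[1:2] <- 0.001; d$meth.diff[1:2] <- 50
  class(d) <- c("methyl_diff", "data.frame")
  pc <- diff_per_chromosome(d, u)
  expect_equal(pc$hyper_pct[pc$chrom == "chr1"], 20)
  expect_equal(pc$hypo_pct[pc$chrom == "chr1"], 0)
  expect_equal(pc$covered[pc$chrom == "all"], 15L)
  expect_true(all(pc$hyper_pct + pc$hypo_pct <= 100))

  d$qvalue[] <- 0.5
  pc0 <- diff_per_chromosome(d, u)
  expect_true(all(pc0$hyper_pct == 0 & pc0$hypo_pct == 0))
})
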