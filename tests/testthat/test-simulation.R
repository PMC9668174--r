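test_that("genotypes follow Hardy-Weinberg at the requested frequency", {
  cfg <- scenario_config(n = 10000, m = 5, maf_range = c(0.3, 0.3), seed = 2)
  coh <- simulate_null(cfg)
  frac2 <- mean(coh$X[, 1] == 2)
  ci <- binom.test(sum(coh$X[, 1] == 2), 10000, p = 0.09)$conf.int
  expect_true(ci[1] <= 0.09 && 0.09 <= ci[2])
  expect_true(all(coh$X %in% c(0, 1, 2)))
})

test_that("scenario-1 regression on the true design recovers the genetic effects", {
  set.seed(41)
  cover <- replicate(40, {
    cfg <- scenario_config(n = 2000, m = 5, seed = sample.int(1e6, 1))
    coh <- simulate_null(cfg)
    truth <- attr(coh, "sim_truth")
    fit <- lm(coh$Y ~ coh$E + coh$Z + coh$X)
    cf <- summary(fit)$coefficients
    rows <- grep("coh\\$X", rownames(cf))
    est <- cf[rows, 1]; se <- cf[rows, 2]
    mean(abs(est - truth$pi0) <= 1.96 * se)
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("scenario 4 induces exposure correlation only with designated variants", {
  cfg <- scenario_config(scenario = 4, n = 8000, m = 50, seed = 5)
  coh <- simulate_null(cfg)
  truth <- attr(coh, "sim_truth")
  expect_gt(length(truth$designated), 0)
  r_designated <- abs(cor(coh$E[, 1], coh$X[, truth$designated[1]]))
  other <- setdiff(seq_len(50), truth$designated)
  r_other <- max(abs(cor(coh$E[, 1], coh$X[, other])))
  expect_gt(r_designated, 0.05)
  expect_lt(mean(abs(cor(coh$E[, 1], coh$X[, other]))), 0.05)
})

test_that("heteroscedastic scenarios scale the error variance with |E1|", {
  cfg <- scenario_config(scenario = 3, n = 20000, m = 10, seed = 6)
  coh <- simulate_null(cfg)
  truth <- attr(coh, "sim_truth")
  hi <- abs(coh$E[, 1]) > 1
  expect_gt(var(truth$eps[hi]), 1.3 * var(truth$eps[!hi]))
})

test_that("simulated errors are mean-zero given the design", {
  cfg <- scenario_config(scenario = 2, n = 20000, m = 10, seed = 7)
  coh <- simulate_null(cfg)
  truth <- attr(coh, "sim_truth")
  fit <- lm(truth$eps ~ coh$E + coh$Z + coh$X)
  cf <- summary(fit)$coefficients
  expect_true(all(abs(cf[, "Estimate"]) <= 3 * cf[, "Std. Error"] + 1e-12))
})

test_that("marginal-association selection keeps the m strongest of the pool", {
  cfg <- scenario_config(n = 2000, m = 10, m_pool = 30, select = TRUE, seed = 8)
  coh <- simulate_null(cfg)
  expect_equal(ncol(coh$X), 10)
  kept <- attr(coh, "sim_truth")$kept
  expect_equal(coh$variant_ids, paste0("v", kept))
  # selection on the same data favors large |pi0| variants
  truth <- attr(coh, "sim_truth")
  expect_gt(mean(abs(truth$pi0_pool[kept])),
            mean(abs(truth$pi0_pool[-kept])))
})

test_that("select and no-select agree when the pool equals the analysis set", {
  plain <- simulate_null(scenario_config(n = 1000, m = 12, seed = 9))
  forced <- simulate_null(scenario_config(n = 1000, m = 12, m_pool = 12,
                                          select = TRUE, seed = 9))
  expect_identical(plain$Y, forced$Y)
  expect_identical(plain$X, forced$X)
  expect_identical(plain$E, forced$E)
})

test_that("planted power signal reduces to the null at zero density", {
  base <- scenario_config(n = 800, m = 10, seed = 11)
  null_coh <- simulate_null(base)
  pow0 <- simulate_power(power_config(p_XE = 0), base)
  expect_identical(null_coh$Y, pow0$Y)
  expect_identical(null_coh$X, pow0$X)
})

test_that("the number of interacting variants is binomial in the density", {
  set.seed(12)
  counts <- replicate(60, {
    base <- scenario_config(n = 120, m = 20, seed = sample.int(1e6, 1))
    base$floor <- 1
    coh <- simulate_power(power_config(p_XE = 0.3), base)
    length(attr(coh, "sim_truth")$interacting)
  })
  expect_lt(abs(mean(counts) - 20 * 0.3), 3 * sqrt(20 * 0.3 * 0.7 / 60))
})

test_that("power increases with signal density for the subcomponent screen", {
  dens <- c(0.1, 0.5)
  med_p <- sapply(dens, function(px) {
    ps <- sapply(1:12, function(r) {
      coh <- simulate_power(power_config(p_XE = px),
                            scenario_config(n = 2000, m = 30, seed = 300 + r))
      ritss(coh, 1, 1, split_config(K = 3, seed = 1, floor = 30))$p_value
    })
    median(ps)
  })
  expect_lt(med_p[2], med_p[1])
})

test_that("the study harness is calibrated for an exact-uniform p generator", {
  unif_test <- list(u = function(coh) runif(1))
  gen <- function(seed) tiny_cohort()
  set.seed(55)
  study <- run_study(unif_test, gen, n_reps = 1000, seed = 0)
  rej <- study$rejection
  expect_true(rej$ci_lo <= 0.05 && 0.05 <= rej$ci_hi)
  expect_equal(nrow(study$pvalues), 1000)
  expect_equal(nrow(study$qq), 1000)
})

test_that("studies are deterministic and record failures as NA", {
  tests <- list(
    ok = function(coh) ritss(coh, 1, 2, split_config(K = 2, seed = 1,
                                                     floor = 30))$p_value,
    bad = function(coh) stop("boom")
  )
  gen <- null_generator(scenario_config(n = 900, m = 8, d = 2, p = 1))
  s1 <- run_study(tests, gen, n_reps = 2, seed = 7)
  s2 <- run_study(tests, gen, n_reps = 2, seed = 7)
  expect_identical(s1$pvalues, s2$pvalues)
  expect_true(all(is.na(s1$pvalues$bad)))
  expect_true(all(!is.na(s1$pvalues$ok)))
  dir <- withr::local_tempdir()
  write_study(s1, dir)
  expect_true(file.exists(file.path(dir, "pvalues.tsv")))
  expect_true(file.exists(file.path(dir, "qq.tsv")))
  expect_true(file.exists(file.path(dir, "rejection.json")))
})
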