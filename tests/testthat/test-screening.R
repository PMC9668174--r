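# Screening cohort with a planted risk-score-subcomponent interaction:
# variants `signal` interact with E1, effects proportional to pi0.
planted_cohort <- function(n, m, signal, strength, seed) {
  set.seed(seed)
  X <- vapply(runif(m, 0.2, 0.5), function(f) rbinom(n, 2, f), numeric(n))
  E <- matrix(rnorm(n * 3), n, 3)
  Z <- matrix(rnorm(n * 2), n, 2)
  # planted variants are the top risk-score components: their main effects
  # are well away from zero so the weighted interaction is detectable
  pi0 <- rnorm(m, 0, 0.08)
  pi0[signal] <- sample(c(-1, 1), length(signal), replace = TRUE) *
    runif(length(signal), 0.25, 0.4)
  delta <- numeric(m)
  delta[signal] <- strength * pi0[signal]
  Y <- drop(E %*% rep(0.3, 3)) + drop(Z %*% rep(0.2, 2)) +
    drop(X %*% pi0) + drop(X %*% delta) * E[, 1] + rnorm(n)
  coh <- cohort(Y, X, E, Z)
  attr(coh, "pi0") <- pi0
  coh
}

test_that("strategy-1 candidate size grid appends the terminal size", {
  coh <- planted_cohort(800, 23, integer(0), 0, seed = 41)
  out <- screen_strategy1(coh, seq_len(800), t = 1, seed = 3)
  expect_equal(out$diagnostics$sizes, c(10, 15, 20, 23))
})

test_that("strategy-1 score weights are exactly the step-(1) risk-score coefficients", {
  coh <- planted_cohort(800, 20, 1:5, 0.8, seed = 42)
  rows <- seq_len(800)
  out <- screen_strategy1(coh, rows, t = 1, seed = 3)
  D <- cbind(1, coh$E[rows, ], coh$Z[rows, ], coh$X[rows, ])
  pi0_hat <- lm.fit(D, coh$Y[rows])$coefficients
  pi0_hat <- tail(pi0_hat, 20)
  expect_equal(out$U1$weight, unname(pi0_hat[out$U1$variant]),
               tolerance = 1e-12)
  expect_equal(out$U2$weight, unname(pi0_hat[out$U2$variant]),
               tolerance = 1e-12)
  expect_true(all(out$U1$env == 1))
})

test_that("strategy 1 recovers a strongly interacting risk-score subcomponent", {
  hits <- replicate(8, {
    seed <- sample.int(1e6, 1)
    coh <- planted_cohort(2500, 30, 1:20, 1.2, seed = seed)
    out <- screen_strategy1(coh, seq_len(2500), t = 1, seed = seed + 1)
    mean(1:20 %in% out$U1$variant)
  })
  expect_gt(mean(hits), 0.8)
})

test_that("strategy 2 recovers planted strong single-variant interactions", {
  set.seed(99)
  recovered <- replicate(10, {
    seed <- sample.int(1e6, 1)
    coh <- planted_cohort(2000, 12, c(3, 7), 2.0, seed = seed)
    out <- screen_strategy2(coh, seq_len(2000), t = 1)
    all(c(3, 7) %in% out$U1$variant)
  })
  expect_gte(mean(recovered), 0.9)
})

test_that("strategy 2 q-value bands partition and the fallback keeps the best variant", {
  coh <- planted_cohort(1200, 15, integer(0), 0, seed = 55)
  out <- screen_strategy2(coh, seq_len(1200), t = 1)
  expect_gte(length(out$U1$variant), 1)
  expect_length(intersect(out$U1$variant, out$U2$variant), 0)
  # hard thresholding: both scores empty when nothing clears the bands
  out0 <- screen_strategy2(coh, seq_len(1200), t = 1, q1 = 1e-12, q2 = 2e-12,
                           min_keep = 0)
  expect_length(out0$U1$variant, 0)
  expect_length(out0$U2$variant, 0)
})

test_that("screening depends only on the screening rows", {
  coh <- planted_cohort(1500, 12, 1:4, 1, seed = 60)
  rows <- 1:900
  out1 <- screen_strategy1(coh, rows, t = 1, seed = 5)
  out2s <- screen_strategy2(coh, rows, t = 1)
  # perturb rows outside the screening set
  coh2 <- coh
  coh2$Y[1000:1500] <- rev(coh2$Y[1000:1500]) + 5
  out1b <- screen_strategy1(coh2, rows, t = 1, seed = 5)
  out2b <- screen_strategy2(coh2, rows, t = 1)
  expect_identical(out1[c("U1", "U2")], out1b[c("U1", "U2")])
  expect_identical(out2s[c("U1", "U2")], out2b[c("U1", "U2")])
})

test_that("combine_scores gates the second score at p < 0.05 and keeps weights", {
  # strong true U2 signal -> c2 = 1 and the combined score unions the terms
  coh <- planted_cohort(1600, 10, integer(0), 0, seed = 70)
  pi0 <- attr(coh, "pi0")
  u2_true <- drop(coh$X[, 1:3] %*% pi0[1:3]) * coh$E[, 1]
  coh$Y <- coh$Y + 0.5 * u2_true
  screen <- list(
    U1 = score_spec(4:5, c(1, 1), pi0[4:5], "U1"),
    U2 = score_spec(1:3, c(1, 1, 1), pi0[1:3], "U2"),
    env_index = 1
  )
  class(screen) <- "screen_output"
  comb <- combine_scores(coh, seq_len(1600), screen)
  expect_equal(comb$gate_c2, 1L)
  expect_lt(comb$gate_p_value, 0.05)
  expect_setequal(comb$spec$variant, 1:5)
  expect_setequal(comb$variant_set, 1:5)
  # weights are carried over unchanged, never refit
  expect_equal(comb$spec$weight[match(1:3, comb$spec$variant)], pi0[1:3],
               ignore_attr = TRUE)

  # null U2 with an exactly known p-value above the gate -> dropped
  coh0 <- planted_cohort(1600, 10, integer(0), 0, seed = 71)
  screen0 <- screen
  comb0 <- combine_scores(coh0, seq_len(1600), screen0)
  if (!is.na(comb0$gate_p_value) && comb0$gate_p_value >= 0.05) {
    expect_equal(comb0$gate_c2, 0L)
    expect_setequal(comb0$spec$variant, 4:5)
  }

  # both candidates empty -> degenerate combined score, empty variant set
  empty <- list(U1 = score_spec(label = "U1"), U2 = score_spec(label = "U2"),
                env_index = 1)
  class(empty) <- "screen_output"
  combe <- combine_scores(coh0, seq_len(1600), empty)
  expect_length(combe$spec$variant, 0)
  expect_length(combe$variant_set, 0)
  expect_equal(combe$gate_c2, 0L)
})
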