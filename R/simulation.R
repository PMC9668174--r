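#' Null-scenario simulation configuration
#'
#' Describes one of the five type-1-error scenarios: (1) no
#' misspecification, normal homoscedastic errors; (2) nonlinear environmental
#' main effect of the first exposure (quadratic plus sine) that the linear
#' screening models do not capture; (3) scenario 2 plus non-normal
#' heteroscedastic errors (centered, scaled chi-square(4), variance
#' increasing with \eqn{|E_1|}); (4) scenario 2 plus gene-environment
#' correlation (\eqn{E_1} gains a contribution from a designated 10\% of
#' variants); (5) scenario 3 plus that gene-environment correlation. With
#' \code{select = TRUE}, \code{m_pool} variants are simulated and the
#' \code{m} with the smallest marginal association p-values (computed on the
#' same simulated cohort) are kept, emulating variant selection from a GWAS
#' of the same data.
#'
#' All functional forms and effect scales are explicit parameters so
#' alternative instantiations can be dropped in.
#'
#' @param scenario integer 1..5.
#' @param select logical; GWAS-based variant selection on the same data.
#' @param n,m,d,p sample count, analysed variants, exposures, covariates.
#'   Defaults n = 3000, m = 50, d = 5, p = 2 (a desk-scale version of the
#'   reference conditions).
#' @param m_pool simulated variant pool for \code{select = TRUE}
#'   (default \code{2 * m}; at least \code{m} when selecting — with
#'   \code{m_pool = m} selection is a no-op and the cohort is identical to
#'   the unselected one).
#' @param maf_range allele-frequency range, per-variant \eqn{f_j \sim
#'   U(maf\_range)}; dosages Hardy-Weinberg \eqn{Binom(2, f_j)}.
#' @param env_correlation exchangeable correlation of the Gaussian exposure
#'   block (default 0.3).
#' @param n_env_binary how many trailing exposure columns are dichotomized
#'   at 0 (default 0).
#' @param tau genetic main-effect scale, \eqn{\pi_{0j} \sim N(0, \tau^2)}
#'   (default 0.15).
#' @param env_effect,covar_effect linear main-effect sizes (defaults 0.3,
#'   0.2).
#' @param misspec_quad,misspec_sine_amp,misspec_sine_freq the nonlinear
#'   \eqn{E_1} term \eqn{a E_1^2 + b \sin(c E_1)} of scenarios 2-5
#'   (defaults 0.5, 0.5, 2).
#' @param ge_frac,ge_strength fraction of (leading) variants designated as
#'   correlated with \eqn{E_1} and the coefficient on their standardized
#'   dosage sum, scenarios 4-5 (defaults 0.1, 0.3).
#' @param seed integer seed.
#' @return An object of class \code{"scenario_config"}.
#' @export
scenario_config <- function(scenario = 1, select = FALSE,
                            n = 3000, m = 50, d = 5, p = 2,
                            m_pool = 2 * m,
                            maf_range = c(0.05, 0.5),
                            env_correlation = 0.3, n_env_binary = 0,
                            tau = 0.15, env_effect = 0.3, covar_effect = 0.2,
                            misspec_quad = 0.5, misspec_sine_amp = 0.5,
                            misspec_sine_freq = 2,
                            ge_frac = 0.1, ge_strength = 0.3,
                            seed = 1) {
  if (!scenario %in% 1:5) stop("scenario must be in 1..5")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range >= 1) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be increasing and within (0, 1)")
  if (select && m_pool < m) stop("select = TRUE requires m_pool >= m")
  structure(as.list(environment()), class = "scenario_config")
}

#' Simulate a null-scenario cohort
#'
#' Generates a cohort under the null hypothesis of no gene-environment
#' interaction, \eqn{Y_i = \mu(E_i, Z_i) + X_i'\pi_0 + \epsilon_i(E_i, Z_i)}
#' with \eqn{E[\epsilon_i | X_i, E_i, Z_i] = 0} by construction, under the
#' scenario modifiers described in \code{\link{scenario_config}}. The
#' generating truth (genetic effects, designated correlated variants, kept
#' variant indices) is attached as attribute \code{"sim_truth"}.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return A \code{\link{cohort}}.
#' @export
simulate_null <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, simulate_null_impl(config))
}

simulate_null_impl <- function(config) {
  n <- config$n
  mm <- if (config$select) config$m_pool else config$m

  f <- stats::runif(mm, config$maf_range[1], config$maf_range[2])
  X <- vapply(seq_len(mm), function(j) stats::rbinom(n, 2, f[j]),
              numeric(n))

  d <- config$d
  shared <- stats::rnorm(n)
  rho <- config$env_correlation
  E <- sqrt(rho) * matrix(shared, n, d) +
    sqrt(1 - rho) * matrix(stats::rnorm(n * d), n, d)
  if (config$n_env_binary > 0) {
    bin_cols <- d - seq_len(config$n_env_binary) + 1
    E[, bin_cols] <- (E[, bin_cols] > 0) * 1
  }
  Z <- matrix(stats::rnorm(n * config$p), n, config$p)
  pi0 <- stats::rnorm(mm, 0, config$tau)

  designated <- integer(0)
  if (config$scenario %in% c(4, 5)) {
    designated <- seq_len(max(1, ceiling(config$ge_frac * mm)))
    g_sum <- rowSums(sweep(X[, designated, drop = FALSE], 2,
                           2 * f[designated]))
    E[, 1] <- E[, 1] + config$ge_strength * g_sum / stats::sd(g_sum)
  }

  mu <- drop(E %*% rep(config$env_effect, d)) +
    drop(Z %*% rep(config$covar_effect, config$p))
  if (config$scenario >= 2) {
    mu <- mu + config$misspec_quad * E[, 1]^2 +
      config$misspec_sine_amp * sin(config$misspec_sine_freq * E[, 1])
  }
  eps <- if (config$scenario %in% c(3, 5)) {
    (1 + abs(E[, 1]) / 2) * (stats::rchisq(n, 4) - 4) / sqrt(8)
  } else stats::rnorm(n)

  Y <- mu + drop(X %*% pi0) + eps

  keep <- seq_len(mm)
  if (config$select) {
    marg_p <- vapply(seq_len(mm), function(j) {
      ct <- stats::cor.test(Y, X[, j])
      ct$p.value
    }, 0)
    keep <- sort(order(marg_p)[seq_len(config$m)])
  }

  coh <- cohort(Y, X[, keep, drop = FALSE], E, Z,
                variant_ids = paste0("v", keep),
                env_names = paste0("e", seq_len(d)),
                covar_names = paste0("z", seq_len(config$p)))
  attr(coh, "sim_truth") <- list(
    pi0 = pi0[keep], pi0_pool = pi0, maf = f[keep],
    designated = intersect(designated, keep), kept = keep,
    scenario = config$scenario, mu = mu, eps = eps)
  coh
}

#' Power simulation configuration
#'
#' Interaction effects are planted on top of the scenario-1 null generator:
#' each variant interacts with the first exposure independently with
#' probability \code{p_XE} (the signal density); an interacting variant
#' \eqn{j} contributes \eqn{\delta_j X_{ij} E_{i1}} with
#' \eqn{\delta_j = \pi_{0j} \beta_j}, \eqn{\beta_j \sim N(\mu_{XE},
#' \sigma_{XE}^2)}, tying interaction effects to the genetic main-effect
#' weights so the planted architecture is a genetic-risk-score subcomponent.
#' \code{weighted = FALSE} switches to unweighted effects
#' \eqn{\delta_j \sim N(\mu_{XE}, \sigma_{XE}^2)}.
#'
#' The default \code{mu_XE} is sized for the desk-scale n = 3000 cohort so
#' the strategy-1 test has intermediate (~50\%) power at density 0.4.
#'
#' @param mu_XE,sigma_XE mean and SD of the interaction effect multipliers.
#' @param p_XE interaction density in \code{[0, 1]}.
#' @param alpha nominal significance level carried along for studies.
#' @param weighted tie effects to main-effect weights (default TRUE).
#' @return An object of class \code{"power_config"}.
#' @export
power_config <- function(mu_XE = 0.25, sigma_XE = 0.1, p_XE = 0.4,
                         alpha = 0.05, weighted = TRUE) {
  if (p_XE < 0 || p_XE > 1) stop("p_XE must be in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(mu_XE = mu_XE, sigma_XE = sigma_XE, p_XE = p_XE,
                 alpha = alpha, weighted = weighted),
            class = "power_config")
}

#' Simulate a cohort with planted interaction signal
#'
#' Draws a scenario-1 null cohort and adds the planted
#' variant-by-first-exposure interaction contribution described in
#' \code{\link{power_config}}. With \code{p_XE = 0} the output is identical
#' to the null cohort from the same seed. The planted truth (interacting
#' variants and their \eqn{\delta_j}) is recorded in the \code{"sim_truth"}
#' attribute.
#'
#' @param config a \code{\link{power_config}}.
#' @param scenario_base a scenario-1, \code{select = FALSE}
#'   \code{\link{scenario_config}} providing the base cohort and seed.
#' @return A \code{\link{cohort}}.
#' @export
simulate_power <- function(config, scenario_base = scenario_config()) {
  stopifnot(inherits(config, "power_config"))
  if (scenario_base$scenario != 1 || scenario_base$select)
    stop("power simulations build on scenario 1 with select = FALSE")
  coh <- simulate_null(scenario_base)
  truth <- attr(coh, "sim_truth")
  m <- ncol(coh$X)
  draws <- with_seed(child_seed(scenario_base$seed, "power"), list(
    interacts = stats::rbinom(m, 1, config$p_XE),
    beta = stats::rnorm(m, config$mu_XE, config$sigma_XE)
  ))
  delta <- if (config$weighted) draws$interacts * truth$pi0 * draws$beta
           else draws$interacts * draws$beta
  coh$Y <- coh$Y + drop(coh$X %*% delta) * coh$E[, 1]
  truth$delta <- delta
  truth$interacting <- which(draws$interacts == 1)
  attr(coh, "sim_truth") <- truth
  coh
}

#' Run a replicate simulation study
#'
#' Generates \code{n_reps} fresh cohorts (replicate \code{r} uses seed
#' \code{seed + r} in the generator) and applies each test function,
#' collecting p-values; a failing test is recorded as \code{NA} and never
#' aborts the study. Returns per-replicate p-values, empirical rejection
#' rates at the requested levels with exact binomial 95\% confidence
#' intervals, and QQ-plot coordinates (expected vs observed \eqn{-\log_{10}}
#' p).
#'
#' @param test_fns named list of functions \code{cohort -> p-value}.
#' @param generator function \code{seed -> cohort}; see
#'   \code{\link{null_generator}} and \code{\link{power_generator}}.
#' @param n_reps number of replicates.
#' @param seed base seed.
#' @param alphas rejection levels (default 0.05).
#' @return An object of class \code{"ritss_study"}: \code{pvalues} (data
#'   frame, one row per replicate), \code{rejection} (method x alpha rates
#'   with CIs), \code{qq} (long data frame of QQ coordinates).
#' @export
run_study <- function(test_fns, generator, n_reps, seed = 1, alphas = 0.05) {
  stopifnot(length(test_fns) >= 1, !is.null(names(test_fns)))
  pvals <- matrix(NA_real_, n_reps, length(test_fns),
                  dimnames = list(NULL, names(test_fns)))
  for (r in seq_len(n_reps)) {
    coh <- generator(seed + r)
    for (nm in names(test_fns)) {
      pvals[r, nm] <- tryCatch(as.numeric(test_fns[[nm]](coh)),
                               error = function(e) NA_real_)
    }
  }
  pv <- as.data.frame(pvals)
  pv$rep <- seq_len(n_reps)

  rej <- do.call(rbind, lapply(names(test_fns), function(nm) {
    do.call(rbind, lapply(alphas, function(a) {
      ok <- !is.na(pv[[nm]])
      if (!any(ok))
        return(data.frame(method = nm, alpha = a, n_ok = 0L,
                          rate = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_))
      x <- sum(pv[[nm]][ok] <= a)
      ci <- stats::binom.test(x, sum(ok))$conf.int
      data.frame(method = nm, alpha = a, n_ok = sum(ok),
                 rate = x / sum(ok), ci_lo = ci[1], ci_hi = ci[2])
    }))
  }))

  qq <- do.call(rbind, lapply(names(test_fns), function(nm) {
    p <- sort(pv[[nm]][!is.na(pv[[nm]])])
    k <- length(p)
    if (k == 0) return(NULL)
    data.frame(method = nm,
               expected = -log10((seq_len(k) - 0.5) / k),
               observed = -log10(pmax(p, 1e-300)))
  }))

  structure(list(pvalues = pv, rejection = rej, qq = qq,
                 n_reps = n_reps, seed = seed),
            class = "ritss_study")
}

#' @export
print.ritss_study <- function(x, ...) {
  cat(sprintf("simulation study: %d replicates\n", x$n_reps))
  print(x$rejection, row.names = FALSE)
  invisible(x)
}

#' Null-cohort generator for \code{\link{run_study}}
#' @param config a \code{\link{scenario_config}}; its seed is replaced per
#'   replicate.
#' @return A function \code{seed -> cohort}.
#' @export
null_generator <- function(config) {
  function(seed) {
    config$seed <- seed
    simulate_null(config)
  }
}

#' Power-cohort generator for \code{\link{run_study}}
#' @param pconfig a \code{\link{power_config}}.
#' @param base a scenario-1 \code{\link{scenario_config}}.
#' @return A function \code{seed -> cohort}.
#' @export
power_generator <- function(pconfig, base = scenario_config()) {
  function(seed) {
    base$seed <- seed
    simulate_power(pconfig, base)
  }
}

#' Write study outputs
#'
#' Writes the per-replicate p-value table and QQ coordinates as TSV and the
#' rejection-rate summary as JSON.
#'
#' @param study a \code{"ritss_study"}.
#' @param dir output directory (created if absent).
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(study$pvalues, file.path(dir, "pvalues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$qq, file.path(dir, "qq.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$rejection, file.path(dir, "rejection.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
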