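#' Per-fold product statistic
#'
#' Computes, on a fold's test samples, the product statistic
#' \eqn{T_k = \sum_i U'_i \hat Y^{resid}_i} and its variance accumulator
#' \eqn{\hat\sigma^2_k = \sum_i (U'_i \hat Y^{resid}_i)^2}.
#'
#' @param u_prime orthogonalized score predictions on the test rows.
#' @param y_resid main-effect residuals of the phenotype on the same rows.
#' @return List with elements \code{T} and \code{sigma2}.
#' @export
fold_statistic <- function(u_prime, y_resid) {
  if (length(u_prime) != length(y_resid))
    stop("u_prime and y_resid lengths differ")
  prod <- u_prime * y_resid
  list(T = sum(prod), sigma2 = sum(prod^2))
}

#' Combine fold statistics into the overall z-score
#'
#' Sums the per-fold statistics, \eqn{T = \sum_k T_k},
#' \eqn{\hat\sigma^2_T = \sum_k \hat\sigma^2_k}, and forms
#' \eqn{z = T / \sqrt{\hat\sigma^2_T}}, which is asymptotically standard
#' normal under the null hypothesis of no interaction; the two-sided p-value
#' is \eqn{2(1 - \Phi(|z|))}. If every fold is degenerate
#' (\eqn{\hat\sigma^2_T = 0}) the result is \eqn{z = 0}, \eqn{p = 1} with a
#' degenerate flag.
#'
#' @param fold_results list of \code{\link{fold_statistic}} results (fields
#'   \code{T}, \code{sigma2}).
#' @return List with \code{T}, \code{sigma2_T}, \code{z}, \code{p_value},
#'   \code{degenerate}.
#' @export
combine_folds <- function(fold_results) {
  if (length(fold_results) == 0) stop("need at least one fold")
  Tsum <- sum(vapply(fold_results, `[[`, 0, "T"))
  s2 <- sum(vapply(fold_results, `[[`, 0, "sigma2"))
  if (s2 > 0) {
    z <- Tsum / sqrt(s2)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    degen <- FALSE
  } else {
    z <- 0; p <- 1; degen <- TRUE
  }
  list(T = Tsum, sigma2_T = s2, z = z, p_value = p, degenerate = degen)
}

#' Variant overlap across fold scores
#'
#' Counts, for each variant, how many of the \eqn{K} per-fold combined
#' interaction scores include it: \eqn{m_4} (in the \eqn{K = 4} naming of the
#' default configuration) is the set present in all \eqn{K} scores,
#' \eqn{m_3} the set present in exactly \eqn{K - 1}. These sets provide a
#' fine-mapping readout of the aggregated signal.
#'
#' @param variant_sets list of \eqn{K} vectors of variant identifiers.
#' @return List with \code{m4} (all \eqn{K}) and \code{m3} (exactly
#'   \eqn{K - 1}), each sorted.
#' @export
overlap_sets <- function(variant_sets) {
  K <- length(variant_sets)
  counts <- table(unlist(lapply(variant_sets, unique)))
  list(m4 = sort(names(counts)[counts == K]),
       m3 = sort(names(counts)[counts == K - 1]))
}

#' Validation regression on an independent cohort
#'
#' Standard regression interaction test for a fixed weighted genetic score in
#' independent data: builds \eqn{G_i = \sum_{j \in set} w_j X_{ij}} with
#' weights estimated on the main data, then fits the linear model
#' \eqn{Y \sim X + E + Z + G \cdot E_t} and reports the interaction
#' coefficient with a model-based p-value and a heteroscedasticity-consistent
#' (HC0 sandwich) p-value. \eqn{G} itself is a linear combination of the
#' fitted \eqn{X} columns, so it needs (and gets) no separate main-effect
#' term.
#'
#' @param cohort an independent \code{\link{cohort}}.
#' @param variant_set integer variant indices (non-empty).
#' @param weights numeric weights for those variants, estimated on disjoint
#'   data.
#' @param t exposure column index.
#' @return List with \code{beta}, \code{se_model}, \code{p_model},
#'   \code{se_sandwich}, \code{p_sandwich}, and the fitted \code{lm} object.
#' @export
validation_test <- function(cohort, variant_set, weights, t) {
  if (length(variant_set) == 0) stop("variant_set is empty")
  if (length(weights) != length(variant_set))
    stop("weights and variant_set lengths differ")
  G <- drop(cohort$X[, variant_set, drop = FALSE] %*% weights)
  df <- data.frame(y = cohort$Y, cohort$X, cohort$E, cohort$Z,
                   GxE = G * cohort$E[, t], check.names = TRUE)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  if (!"GxE" %in% rownames(sm))
    stop("interaction term aliased in the validation regression")
  beta <- sm["GxE", "Estimate"]
  se_m <- sm["GxE", "Std. Error"]
  p_m <- sm["GxE", "Pr(>|t|)"]
  vc <- sandwich::vcovHC(fit, type = "HC0")
  se_s <- sqrt(vc["GxE", "GxE"])
  p_s <- 2 * stats::pt(abs(beta / se_s), fit$df.residual, lower.tail = FALSE)
  list(beta = beta, se_model = se_m, p_model = p_m,
       se_sandwich = se_s, p_sandwich = p_s, fit = fit)
}

ritss_engine <- function(cohort, env_index, strategy, config, spline_df,
                         grid_start, grid_step, q1, q2) {
  n <- length(cohort$Y)
  plan <- make_fold_plan(n, config)
  folds <- vector("list", plan$K)
  for (k in seq_len(plan$K)) {
    f <- plan$folds[[k]]
    screen <- if (strategy == 1)
      screen_strategy1(cohort, f$c1, env_index, grid_start = grid_start,
                       grid_step = grid_step,
                       seed = child_seed(config$seed, paste0("screen", k)))
    else screen_strategy2(cohort, f$c1, env_index, q1 = q1, q2 = q2)
    comb <- combine_scores(cohort, f$c2, screen, spline_df = spline_df)
    y_resid <- predict_residuals(comb$model, cohort, f$test)
    ortho <- fit_ortho(cohort, f$c3, comb, spline_df = spline_df)
    u_prime <- predict_ortho(ortho, cohort, f$test)
    u_raw <- evaluate_score(comb$spec, cohort, f$test)
    st <- fold_statistic(u_prime, y_resid)
    st_raw <- fold_statistic(u_raw, y_resid)
    folds[[k]] <- list(
      k = k, n_k = length(f$test),
      T = st$T, sigma2 = st$sigma2,
      T_raw = st_raw$T, sigma2_raw = st_raw$sigma2,
      variant_set = cohort$variant_ids[comb$variant_set],
      gate_c2 = comb$gate_c2, gate_p_value = comb$gate_p_value,
      ortho_iterations = ortho$iterations,
      ortho_degenerate = ortho$degenerate
    )
  }
  list(plan = plan, folds = folds)
}

#' Robust gene-environment interaction test with sample splitting
#'
#' Runs the full cross-fitting interaction test for a single exposure
#' \code{E[, env_index]}: the samples are split into \code{K} test folds; for
#' each fold, its complement is partitioned into a screening part (candidate
#' interaction scores from strategy 1 or 2), a score-combination part
#' (gating and flexible main-effect fit, retained as the fold's
#' residualization model) and an orthogonalization part (ACE transformation
#' of the combined score); the orthogonalized score and the main-effect
#' residuals are then evaluated on the held-out test fold and accumulated
#' into the product statistic. Fold statistics are summed into an overall
#' z-score with a two-sided normal p-value, and the per-fold variant sets
#' yield the \eqn{m_4}/\eqn{m_3} overlap fine-mapping sets. Fully
#' deterministic given the seed in \code{config}.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param env_index exposure column tested for interaction.
#' @param strategy screening strategy, 1 (risk-score subcomponents via
#'   approximate best subsets) or 2 (FDR-aggregated single-variant scan).
#' @param config a \code{\link{split_config}} (number of folds, complement
#'   fractions, seed).
#' @param spline_df smooth basis size for main-effect and orthogonalization
#'   models (default 5).
#' @param grid_start,grid_step strategy-1 subset-size grid.
#' @param q1,q2 strategy-2 q-value bands.
#' @return An object of class \code{"ritss"}: overall \code{z},
#'   \code{p_value}, \code{T}, \code{sigma2_T}, \code{folds} (per-fold
#'   detail), overlap sets \code{m4}/\code{m3}, the non-robust (raw-score)
#'   variant of the statistic under \code{nonrobust}, and the call
#'   configuration.
#' @seealso \code{\link{nonrobust_test}}, \code{\link{gamsv_test}},
#'   \code{\link{simulate_null}}
#' @examples
#' coh <- simulate_null(scenario_config(n = 1500, m = 10, seed = 7))
#' fit <- ritss(coh, env_index = 1, strategy = 2,
#'              config = split_config(K = 2, seed = 1))
#' print(fit)
#' @export
ritss <- function(cohort, env_index = 1, strategy = 1,
                  config = split_config(), spline_df = 5,
                  grid_start = 10, grid_step = 5, q1 = 0.05, q2 = 0.2) {
  stopifnot(inherits(cohort, "cohort"))
  if (!strategy %in% c(1, 2)) stop("strategy must be 1 or 2")
  if (env_index < 1 || env_index > ncol(cohort$E))
    stop("env_index out of range")
  eng <- ritss_engine(cohort, env_index, strategy, config, spline_df,
                      grid_start, grid_step, q1, q2)
  overall <- combine_folds(eng$folds)
  ov <- overlap_sets(lapply(eng$folds, `[[`, "variant_set"))
  structure(list(
    z = overall$z, p_value = overall$p_value,
    T = overall$T, sigma2_T = overall$sigma2_T,
    degenerate = overall$degenerate,
    folds = eng$folds, m4 = ov$m4, m3 = ov$m3,
    env_index = env_index, env_name = cohort$env_names[env_index],
    strategy = strategy, config = eng$plan$config,
    n = eng$plan$n, K = eng$plan$K
  ), class = "ritss")
}

#' Non-robust variant of the interaction test (D1/D2)
#'
#' Identical pipeline and screening output to \code{\link{ritss}} (same
#' seed, same folds) but the test statistic uses the raw combined score
#' \eqn{U_i} in place of the orthogonalized \eqn{U'_i}. This variant is not
#' protected against main-effect misspecification and is provided as a
#' comparator; D1/D2 refer to the strategy-1/strategy-2 versions.
#'
#' @inheritParams ritss
#' @return A \code{"ritss"} object whose statistic is the raw-score one
#'   (method tag \code{"D1"}/\code{"D2"}).
#' @export
nonrobust_test <- function(cohort, env_index = 1, strategy = 1,
                           config = split_config(), spline_df = 5,
                           grid_start = 10, grid_step = 5,
                           q1 = 0.05, q2 = 0.2) {
  fit <- ritss(cohort, env_index, strategy, config, spline_df,
               grid_start, grid_step, q1, q2)
  as_nonrobust(fit)
}

# Reinterpret a fitted ritss object as its non-robust (raw U) counterpart.
as_nonrobust <- function(fit) {
  raw <- combine_folds(lapply(fit$folds, function(f)
    list(T = f$T_raw, sigma2 = f$sigma2_raw)))
  out <- fit
  out$z <- raw$z; out$p_value <- raw$p_value
  out$T <- raw$T; out$sigma2_T <- raw$sigma2_T
  out$degenerate <- raw$degenerate
  out$method <- paste0("D", fit$strategy)
  class(out) <- c("ritss_nonrobust", "ritss")
  out
}

#' @export
print.ritss <- function(x, ...) {
  label <- if (inherits(x, "ritss_nonrobust")) x$method
           else paste0("RITSS", x$strategy)
  cat(sprintf("%s interaction test: exposure %s, n = %d, K = %d folds\n",
              label, x$env_name, x$n, x$K))
  cat(sprintf("  z = %.4f, two-sided p = %.4g\n", x$z, x$p_value))
  if (x$degenerate)
    cat("  all folds degenerate (no variants screened in); p set to 1\n")
  cat(sprintf("  overlap fine-mapping: |m%d| = %d, |m%d| = %d\n",
              x$K, length(x$m4), x$K - 1, length(x$m3)))
  invisible(x)
}

#' @export
summary.ritss <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$folds, function(f) data.frame(
    fold = f$k, n_k = f$n_k, T_k = f$T, sigma2_k = f$sigma2,
    n_variants = length(f$variant_set), c2 = f$gate_c2,
    gate_p = f$gate_p_value, ace_iter = f$ortho_iterations
  )))
  structure(list(fit = object, fold_table = tab), class = "summary.ritss")
}

#' @export
print.summary.ritss <- function(x, ...) {
  print(x$fit)
  cat("\nPer-fold detail:\n")
  print(x$fold_table, row.names = FALSE)
  invisible(x)
}

#' Write a test result to JSON and a variant-membership TSV
#'
#' The JSON carries z, p, per-fold statistics and variant sets, and the
#' overlap sets; the TSV lists every variant that entered at least one fold
#' score with its per-fold membership and overlap status.
#'
#' @param fit a \code{"ritss"} object.
#' @param json_path,tsv_path output paths (either may be \code{NULL} to
#'   skip).
#' @export
write_ritss_result <- function(fit, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      method = if (inherits(fit, "ritss_nonrobust")) fit$method
               else paste0("RITSS", fit$strategy),
      env = fit$env_name, n = fit$n, K = fit$K,
      z = fit$z, p_value = fit$p_value,
      T = fit$T, sigma2_T = fit$sigma2_T, degenerate = fit$degenerate,
      folds = lapply(fit$folds, function(f)
        list(k = f$k, n_k = f$n_k, T_k = f$T, sigma2_k = f$sigma2,
             variant_set = f$variant_set, c2 = f$gate_c2)),
      m4 = fit$m4, m3 = fit$m3
    ), json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(tsv_path)) {
    all_v <- sort(unique(unlist(lapply(fit$folds, `[[`, "variant_set"))))
    tab <- data.frame(variant = all_v)
    for (f in fit$folds)
      tab[[paste0("fold", f$k)]] <- as.integer(all_v %in% f$variant_set)
    tab$in_m4 <- as.integer(all_v %in% fit$m4)
    tab$in_m3 <- as.integer(all_v %in% fit$m3)
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fit)
}
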