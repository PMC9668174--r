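# --- exact OLS statistics for columns added to an already-factored design ---
#
# For a base design B (with QR factorization qrB) and added columns C, the
# OLS coefficient of each added column in y ~ B + C_col equals the slope of
# the residualized y on the residualized column (Frisch-Waugh), with
# df = n - rank(B) - (number of added columns). Used to scan m variants
# without refitting m full models.

fw_one_col <- function(qrB, y_res, rss0, n, rank0, col) {
  c_res <- qr.resid(qrB, col)
  scc <- sum(c_res^2)
  if (scc < 1e-12 * max(1, sum(col^2)))
    return(c(est = 0, se = NA_real_, t = 0, p = 1))
  est <- sum(c_res * y_res) / scc
  rss <- rss0 - est^2 * scc
  df <- n - rank0 - 1
  sigma2 <- max(rss, 0) / df
  se <- sqrt(sigma2 / scc)
  tval <- est / se
  c(est = est, se = se, t = tval,
    p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

fw_two_col <- function(qrB, y_res, n, rank0, c1, c2) {
  C_res <- qr.resid(qrB, cbind(c1, c2))
  XtX <- crossprod(C_res)
  if (rcond_2x2(XtX) < 1e-12)
    return(c(est = 0, se = NA_real_, t = 0, p = 1))
  beta <- solve(XtX, crossprod(C_res, y_res))
  rss <- sum(y_res^2) - sum(beta * crossprod(C_res, y_res))
  df <- n - rank0 - 2
  sigma2 <- max(rss, 0) / df
  v <- solve(XtX)
  se2 <- sqrt(sigma2 * v[2, 2])
  tval <- beta[2] / se2
  c(est = beta[2], se = se2, t = tval,
    p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

rcond_2x2 <- function(M) {
  d <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  s <- max(abs(M))
  if (s == 0) 0 else abs(d) / s^2
}

# All-linear base design [1, E, Z, X] on the given rows.
linear_base <- function(cohort, rows, with_geno = TRUE) {
  D <- cbind(1, cohort$E[rows, , drop = FALSE], cohort$Z[rows, , drop = FALSE])
  if (with_geno) D <- cbind(D, cohort$X[rows, , drop = FALSE])
  D
}

#' Screening strategy 1: genetic risk score subcomponents
#'
#' Searches for a subcomponent of the genetic risk score that interacts with
#' a single exposure \code{E[, t]} via approximate best-subset selection:
#' (1) fit the all-linear model \eqn{Y = \mu_0 + E'\mu_1 + Z'\mu_2 + X'\pi_0}
#' on the screening rows to estimate the risk-score weights \eqn{\hat\pi_0};
#' (2) split the screening rows in two halves; (3) in each half rank variants
#' by the absolute single-variant statistic of the weighted product term
#' \eqn{\hat\pi_{0j} X_{ij} E_{it}}, then over a grid of subset sizes (from
#' \code{grid_start} in steps of \code{grid_step} up to the number of
#' variants) evaluate the squared interaction z of the top-\eqn{s} weighted
#' score in the \emph{other} half and keep the best size; (4) the first
#' candidate score \eqn{U_1} is built on the variants both halves selected,
#' the second \eqn{U_2} on the variants exactly one half selected. Both carry
#' the step-(1) weights.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param rows screening rows (the C1 part of a fold's complement).
#' @param t exposure column index tested for interaction.
#' @param grid_start,grid_step best-subset size grid (defaults 10 and 5).
#' @param seed integer seed for the internal 2-sample split.
#' @return An object of class \code{"screen_output"}: candidate
#'   \code{\link{score_spec}}s \code{U1}, \code{U2}, the exposure index and
#'   diagnostics (sizes tried, best size per half).
#' @export
screen_strategy1 <- function(cohort, rows, t, grid_start = 10, grid_step = 5,
                             seed = 1) {
  m <- ncol(cohort$X)
  n <- length(rows)
  # (1) risk-score weights from the all-linear null model
  D <- linear_base(cohort, rows)
  pi0 <- stats::lm.fit(D, cohort$Y[rows])$coefficients
  pi0 <- pi0[ncol(D) - m + seq_len(m)]
  pi0[is.na(pi0)] <- 0

  # (2) internal 2-sample split of the screening rows
  perm <- with_seed(seed, sample.int(n))
  half <- list(A = sort(rows[perm[seq_len(floor(n / 2))]]),
               B = sort(rows[perm[(floor(n / 2) + 1):n]]))

  sizes <- unique(c(seq(min(grid_start, m), m, by = grid_step), m))

  rank_in <- function(h) {
    B <- linear_base(cohort, h)
    qrB <- qr(B)
    y_res <- qr.resid(qrB, cohort$Y[h])
    rss0 <- sum(y_res^2)
    stat <- vapply(seq_len(m), function(j) {
      col <- pi0[j] * cohort$X[h, j] * cohort$E[h, t]
      fw_one_col(qrB, y_res, rss0, length(h), qrB$rank, col)[["t"]]
    }, 0)
    order(abs(stat), decreasing = TRUE)
  }
  eval_in <- function(h, variant_sets) {
    B <- linear_base(cohort, h)
    qrB <- qr(B)
    y_res <- qr.resid(qrB, cohort$Y[h])
    rss0 <- sum(y_res^2)
    vapply(variant_sets, function(js) {
      u <- drop(cohort$X[h, js, drop = FALSE] %*% pi0[js]) * cohort$E[h, t]
      fw_one_col(qrB, y_res, rss0, length(h), qrB$rank, u)[["t"]]^2
    }, 0)
  }

  best_subset <- function(h_rank, h_eval) {
    ord <- rank_in(h_rank)
    sets <- lapply(sizes, function(s) ord[seq_len(s)])
    crit <- eval_in(h_eval, sets)
    sets[[which.max(crit)]]
  }
  bA <- best_subset(half$A, half$B)
  bB <- best_subset(half$B, half$A)

  J1 <- sort(intersect(bA, bB))
  J2 <- sort(setdiff(union(bA, bB), J1))

  mk <- function(js, label) score_spec(js, rep(t, length(js)), pi0[js], label)
  structure(list(
    U1 = mk(J1, "U1"), U2 = mk(J2, "U2"), env_index = t,
    diagnostics = list(sizes = sizes, best_A = length(bA), best_B = length(bB),
                       pi0 = pi0)
  ), class = "screen_output")
}

#' Screening strategy 2: FDR-aggregated single-variant scan
#'
#' Fits, for each variant \eqn{j}, the single-variant interaction model
#' \eqn{Y = \mu_0 + E'\mu_1 + Z'\mu_2 + X_j \pi_{0j} + E_t X_j \pi_{jt} + \epsilon}
#' on the screening rows, converts the \eqn{m} interaction p-values to
#' Benjamini-Hochberg q-values, and aggregates variants with
#' \eqn{q \le q_1} into the first candidate score and those with
#' \eqn{q_1 < q \le q_2} into the second, each weighted by the estimated
#' \eqn{\hat\pi_{jt}}.
#'
#' The first score always retains at least the \code{min_keep} variants with
#' the smallest q-values even when none pass \eqn{q_1}. A completely empty
#' fold score would contribute exactly zero to the overall statistic, and
#' when that happens in every fold the test degenerates to \eqn{p = 1};
#' under a complete null that point mass breaks the uniformity of the null
#' p-value distribution. Keeping the best-ranked candidate costs nothing in
#' validity — the statistic is valid for any screen output because screening
#' and testing use disjoint samples — and restores a continuous null
#' distribution. Set \code{min_keep = 0} for hard thresholding.
#'
#' @inheritParams screen_strategy1
#' @param q1,q2 q-value band edges (defaults 0.05 and 0.2).
#' @param min_keep minimum number of top-ranked variants always kept in the
#'   first score (default 1).
#' @return A \code{"screen_output"} (see \code{\link{screen_strategy1}});
#'   diagnostics carry the per-variant q-values.
#' @export
screen_strategy2 <- function(cohort, rows, t, q1 = 0.05, q2 = 0.2,
                             min_keep = 1) {
  m <- ncol(cohort$X)
  B <- linear_base(cohort, rows, with_geno = FALSE)
  qrB <- qr(B)
  y_res <- qr.resid(qrB, cohort$Y[rows])
  n <- length(rows)
  est <- pval <- numeric(m)
  for (j in seq_len(m)) {
    xj <- cohort$X[rows, j]
    r <- fw_two_col(qrB, y_res, n, qrB$rank, xj, cohort$E[rows, t] * xj)
    est[j] <- r[["est"]]; pval[j] <- r[["p"]]
  }
  qv <- stats::p.adjust(pval, method = "BH")
  J1 <- which(qv <= q1)
  if (length(J1) < min_keep)
    J1 <- sort(order(qv, pval)[seq_len(min_keep)])
  J2 <- setdiff(which(qv > q1 & qv <= q2), J1)
  mk <- function(js, label) score_spec(js, rep(t, length(js)), est[js], label)
  structure(list(
    U1 = mk(J1, "U1"), U2 = mk(J2, "U2"), env_index = t,
    diagnostics = list(p = pval, q = qv, estimates = est)
  ), class = "screen_output")
}

#' @export
print.screen_output <- function(x, ...) {
  cat(sprintf("screen output (E index %d): |U1| = %d, |U2| = %d variants\n",
              x$env_index, length(x$U1$weight), length(x$U2$weight)))
  invisible(x)
}

#' Combine candidate scores on the score-combination rows
#'
#' Evaluates the two candidate scores on the C2 rows and fits them as extra
#' linear predictors alongside the flexible (spline) main-effect model. The
#' second score is kept only if its coefficient p-value is below 0.05
#' (\eqn{c_2} gate); the first is always kept. The combined score is
#' \eqn{U = U_1 + c_2 U_2}, with the screening weights carried over unchanged
#' (no refit). The main-effect model fitted here is retained and later
#' residualizes the fold's test samples.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param rows score-combination rows (the C2 part).
#' @param screen_out a \code{"screen_output"}.
#' @param spline_df smooth basis size, passed to
#'   \code{\link{fit_main_effects}}.
#' @return An object of class \code{"combined_score"}: the combined
#'   \code{\link{score_spec}}, the gate \code{c2} and its p-value, the tested
#'   variant set \code{m(I_k)}, and the retained residualization
#'   \code{main_effect_model}.
#' @export
combine_scores <- function(cohort, rows, screen_out, spline_df = 5) {
  u1 <- evaluate_score(screen_out$U1, cohort, rows)
  u2 <- evaluate_score(screen_out$U2, cohort, rows)
  extra <- list()
  if (stats::var(u1) > 0) extra$U1 <- u1
  if (stats::var(u2) > 0) extra$U2 <- u2
  model <- fit_main_effects(cohort, rows, extra = if (length(extra)) extra,
                            spline_df = spline_df)
  p2 <- NA_real_
  if (!is.null(model$extra) && "U2" %in% model$extra$term)
    p2 <- model$extra$p[model$extra$term == "U2"]
  c2 <- as.integer(!is.na(p2) && p2 < 0.05)

  sp1 <- screen_out$U1
  spec <- if (c2 == 1L)
    score_spec(c(sp1$variant, screen_out$U2$variant),
               c(sp1$env, screen_out$U2$env),
               c(sp1$weight, screen_out$U2$weight), "combined")
  else score_spec(sp1$variant, sp1$env, sp1$weight, "combined")

  structure(list(
    spec = spec, gate_c2 = c2, gate_p_value = p2,
    variant_set = sort(unique(spec$variant)),
    model = model, env_index = screen_out$env_index
  ), class = "combined_score")
}

#' Serialize screening output or a combined score to JSON
#'
#' @param x a \code{"screen_output"} or \code{"combined_score"}.
#' @param cohort the cohort (for variant IDs).
#' @param path output path.
#' @export
write_screen_json <- function(x, cohort, path) {
  spec_json <- function(sp) list(
    label = sp$label,
    variants = cohort$variant_ids[sp$variant],
    env = cohort$env_names[sp$env],
    weights = sp$weight)
  out <- if (inherits(x, "screen_output")) {
    list(U1 = spec_json(x$U1), U2 = spec_json(x$U2), env_index = x$env_index,
         diagnostics = x$diagnostics[setdiff(names(x$diagnostics), "pi0")])
  } else {
    list(combined = spec_json(x$spec), c2 = x$gate_c2,
         gate_p_value = x$gate_p_value,
         variant_set = cohort$variant_ids[x$variant_set])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
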