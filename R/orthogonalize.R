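#' Orthogonalize a combined interaction score against main effects
#'
#' Estimates, on the C3 rows, the transformation
#' \eqn{U'_i = U_i - \hat f(E_i, Z_i) - X_i'\hat\gamma} whose sample
#' covariance with every environmental/covariate basis column and every
#' genotype column is (numerically) zero. The estimate alternates conditional
#' fits in the style of the ACE algorithm between two blocks:
#' \enumerate{
#'   \item given \eqn{\hat\gamma}, regress \eqn{U - X\hat\gamma} on the
#'     smooth \eqn{(E, Z)} basis (same unpenalized spline family as the
#'     main-effect model) to update \eqn{\hat f};
#'   \item given \eqn{\hat f}, regress \eqn{U - \hat f(E, Z)} on the genotype
#'     block by least squares to update \eqn{\hat\gamma}.
#' }
#' Iteration stops when the maximum coefficient change falls below \code{tol}
#' and the residual's scaled covariance with every design column is below
#' \code{ortho_tol}, or at \code{max_iter} (with a warning; the model is then
#' still valid, just less orthogonal). Because both blocks are linear in
#' their coefficients, the fixed point coincides with the joint least-squares
#' projection of \eqn{U} on the stacked design.
#'
#' A score with zero variance on the fitting rows short-circuits to the
#' identity-zero model whose predictions are exactly 0, making the fold's
#' contribution to the test statistic exactly zero.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param rows fitting rows (the C3 part of a fold's complement).
#' @param score a \code{\link{combine_scores}} result, a bare
#'   \code{\link{score_spec}}, or (for diagnostics) a numeric vector of score
#'   values aligned with \code{rows}; vector-scored models cannot predict on
#'   other rows.
#' @param tol convergence tolerance on the maximum coefficient change
#'   (default \code{1e-10}).
#' @param max_iter iteration cap (default 100).
#' @param spline_df smooth basis size (default 5), as in
#'   \code{\link{fit_main_effects}}.
#' @param ortho_tol scaled-covariance threshold declaring orthogonality
#'   (default \code{1e-8}).
#' @return An object of class \code{"ortho_model"} with the frozen basis
#'   spec, coefficients \code{f_coef} and \code{gamma}, iteration count,
#'   final change, \code{degenerate} flag, fitted \code{u_prime} and the
#'   per-iteration residual sum of squares \code{rss_trace}.
#' @export
fit_ortho <- function(cohort, rows, score, tol = 1e-10, max_iter = 100,
                      spline_df = 5, ortho_tol = 1e-8) {
  if (is.numeric(score) && is.null(attr(score, "class"))) {
    if (length(score) != length(rows))
      stop("numeric score must align with rows")
    spec <- NULL
    u <- as.numeric(score)
  } else {
    spec <- if (inherits(score, "combined_score")) score$spec else score
    u <- evaluate_score(spec, cohort, rows)
  }
  base <- list(score_spec = spec, rows = rows)
  if ((!is.null(spec) && length(spec$weight) == 0) || stats::var(u) == 0) {
    return(structure(c(base, list(degenerate = TRUE, iterations = 0L,
                                  final_change = 0, u_prime = numeric(length(rows)),
                                  rss_trace = numeric(0))),
                     class = "ortho_model"))
  }
  dspec <- make_design_spec(cohort, rows, spline_df)
  S <- cbind(1, build_smooth_block(dspec, cohort, rows))
  # centering the genotype block decouples it from the intercept (which
  # lives in the smooth block) and speeds the alternation; the joint column
  # span, hence the fixed point, is unchanged
  x_center <- colMeans(cohort$X[rows, , drop = FALSE])
  X <- sweep(cohort$X[rows, , drop = FALSE], 2, x_center)
  qrS <- qr(S)
  qrX <- qr(X)

  solve_block <- function(qrM, M, y) {
    b <- qr.coef(qrM, y)
    b[is.na(b)] <- 0
    b
  }
  gamma <- numeric(ncol(X))
  f_coef <- numeric(ncol(S))
  rss_trace <- numeric(0)
  change <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    f_new <- solve_block(qrS, S, u - drop(X %*% gamma))
    g_new <- solve_block(qrX, X, u - drop(S %*% f_new))
    change <- max(abs(c(f_new - f_coef, g_new - gamma)))
    f_coef <- f_new; gamma <- g_new
    r <- u - drop(S %*% f_coef) - drop(X %*% gamma)
    rss_trace <- c(rss_trace, sum(r^2))
    ok_ortho <- max_scaled_cov(r, cbind(S[, -1, drop = FALSE], X)) < ortho_tol
    if ((change < tol && ok_ortho) || it >= max_iter) break
  }
  if (it >= max_iter && !(change < tol))
    warning("ACE orthogonalization did not converge in ", max_iter,
            " iterations (last change ", format(change), ")")
  structure(c(base, list(
    degenerate = FALSE, design_spec = dspec, f_coef = f_coef, gamma = gamma,
    x_center = x_center, iterations = it, final_change = change, u_prime = r,
    rss_trace = rss_trace
  )), class = "ortho_model")
}

# largest |cov(r, column)| / column sd, over non-constant columns
max_scaled_cov <- function(r, M) {
  sds <- apply(M, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) return(0)
  cv <- abs(drop(stats::cov(r, M[, keep, drop = FALSE])))
  max(cv / sds[keep])
}

#' Predict the orthogonalized score on new rows
#'
#' Out-of-sample evaluation of \eqn{U - \hat f(E, Z) - X'\hat\gamma}. The
#' identity-zero (degenerate) model predicts exactly 0.
#'
#' @param model a \code{\link{fit_ortho}} result.
#' @param cohort a \code{\link{cohort}} with the schema the model was fitted
#'   on.
#' @param rows rows to predict (the fold's test samples).
#' @return Numeric vector \eqn{U'} of length \code{length(rows)}.
#' @export
predict_ortho <- function(model, cohort, rows) {
  if (model$degenerate) return(numeric(length(rows)))
  if (is.null(model$score_spec))
    stop("vector-scored orthogonalization models cannot predict on new rows")
  if (length(model$gamma) != ncol(cohort$X))
    stop("cohort schema does not match the fitted orthogonalization model")
  u <- evaluate_score(model$score_spec, cohort, rows)
  S <- cbind(1, build_smooth_block(model$design_spec, cohort, rows))
  X <- sweep(cohort$X[rows, , drop = FALSE], 2, model$x_center)
  u - drop(S %*% model$f_coef) - drop(X %*% model$gamma)
}

#' @export
print.ortho_model <- function(x, ...) {
  if (x$degenerate) cat("ortho model: degenerate (score has zero variance)\n")
  else cat(sprintf("ortho model: %d ACE iterations, final change %.2e\n",
                   x$iterations, x$final_change))
  invisible(x)
}

#' Dump an orthogonalization model to JSON
#' @param model an \code{"ortho_model"}.
#' @param path output path.
#' @export
write_ortho_model <- function(model, path) {
  out <- list(degenerate = model$degenerate, iterations = model$iterations)
  if (!model$degenerate) {
    out$f_coef <- model$f_coef
    out$gamma <- model$gamma
    out$final_change <- model$final_change
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
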