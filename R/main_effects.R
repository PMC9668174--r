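#' @importFrom splines bs
NULL

# Per-column smoother description, frozen on the training rows so that
# prediction on new rows reuses the same basis. Binary or constant columns
# get a linear term; continuous columns a cubic regression spline basis with
# `df` basis functions (unpenalized, so the fit is plain OLS and
# deterministic).
make_smoother <- function(x, binary, df) {
  if (binary || df <= 1 || length(unique(x)) <= 3) {
    list(type = "linear")
  } else {
    knots <- if (df - 3 > 0)
      stats::quantile(x, probs = seq_len(df - 3) / (df - 2), names = FALSE)
    else numeric(0)
    list(type = "bs", knots = knots, bknots = range(x), degree = 3)
  }
}

eval_smoother <- function(sm, x, name) {
  if (sm$type == "linear") {
    mat <- matrix(x, ncol = 1)
    colnames(mat) <- name
  } else {
    mat <- suppressWarnings(
      splines::bs(x, knots = sm$knots, Boundary.knots = sm$bknots,
                  degree = sm$degree))
    mat <- mat[, , drop = FALSE]
    colnames(mat) <- paste0(name, ".bs", seq_len(ncol(mat)))
  }
  mat
}

# Frozen design description for the (E, Z) smooth block of a cohort.
make_design_spec <- function(cohort, rows, spline_df) {
  spec_for <- function(mat, binary, names) {
    lapply(seq_len(ncol(mat)), function(j)
      c(make_smoother(mat[rows, j], binary[j], spline_df), name = names[j]))
  }
  list(env = spec_for(cohort$E, cohort$env_binary, cohort$env_names),
       covar = spec_for(cohort$Z, cohort$covar_binary, cohort$covar_names),
       spline_df = spline_df)
}

# Evaluate the smooth (E, Z) block, without intercept.
build_smooth_block <- function(spec, cohort, rows) {
  blocks <- c(
    lapply(seq_along(spec$env), function(j)
      eval_smoother(spec$env[[j]], cohort$E[rows, j], spec$env[[j]]$name)),
    lapply(seq_along(spec$covar), function(j)
      eval_smoother(spec$covar[[j]], cohort$Z[rows, j], spec$covar[[j]]$name))
  )
  do.call(cbind, blocks)
}

#' Fit the flexible null-model main effects
#'
#' Fits the additive working model
#' \deqn{Y_i = \mu(E_i, Z_i) + X_i'\pi_0 + \epsilon_i}
#' on the given rows by ordinary least squares, where \eqn{\mu} is an
#' additive combination of cubic regression splines (default 5 basis
#' functions) for continuous exposure/covariate columns and linear terms for
#' binary ones, and the genetic contribution is linear and additive
#' (\eqn{\pi_{0j}} constants, no gene-covariate interaction). Optional extra
#' predictors — candidate interaction scores — enter as plain linear columns
#' and get a coefficient, standard error and two-sided p-value each; they are
#' never part of the main-effect prediction.
#'
#' Aliased (rank-deficient) columns are dropped with a warning and predict as
#' zero. Perfectly collinear extra predictors are an error.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param rows integer fitting rows.
#' @param extra optional named list of numeric vectors (same length as
#'   \code{rows}) to include as linear predictors.
#' @param spline_df basis functions per continuous smooth (default 5);
#'   \code{1} makes every term linear.
#' @param min_ratio required ratio of \code{length(rows)} to the number of
#'   design columns (default 5).
#' @return An object of class \code{"main_effect_model"} with elements
#'   \code{design_spec}, \code{coef} (named, aliased as 0),
#'   \code{genetic_coefs} (\eqn{\hat\pi_0}), \code{extra} (data frame of
#'   estimate/se/p per extra predictor), \code{edf}, \code{sigma2},
#'   \code{fitted}, \code{residuals}.
#' @export
fit_main_effects <- function(cohort, rows, extra = NULL, spline_df = 5,
                             min_ratio = 5) {
  y <- cohort$Y[rows]
  spec <- make_design_spec(cohort, rows, spline_df)
  S <- build_smooth_block(spec, cohort, rows)
  Xg <- cohort$X[rows, , drop = FALSE]
  colnames(Xg) <- paste0("g.", cohort$variant_ids)
  D <- cbind(`(Intercept)` = 1, S, Xg)
  n_extra <- 0L
  if (!is.null(extra) && length(extra) > 0) {
    Emat <- do.call(cbind, extra)
    colnames(Emat) <- paste0("u.", names(extra))
    nz <- apply(Emat, 2, function(col) stats::var(col) > 0)
    if (sum(nz) > 1 && qr(Emat[, nz, drop = FALSE])$rank < sum(nz))
      stop("extra predictors are perfectly collinear")
    D <- cbind(D, Emat)
    n_extra <- ncol(Emat)
  }
  if (length(rows) < min_ratio * ncol(D))
    stop("only ", length(rows), " rows for ", ncol(D),
         " design columns; need at least ", min_ratio, "x")

  fit <- stats::lm.fit(D, y)
  beta <- fit$coefficients
  aliased <- is.na(beta)
  if (any(aliased[seq_len(ncol(D) - n_extra)]))
    warning("dropped ", sum(aliased), " aliased design column(s): ",
            paste(names(beta)[aliased], collapse = ", "))
  beta[aliased] <- 0

  rank <- fit$rank
  rdf <- length(y) - rank
  res <- fit$residuals
  sigma2 <- if (rdf > 0) sum(res^2) / rdf else 0

  extra_tab <- NULL
  if (n_extra > 0) {
    idx <- ncol(D) - n_extra + seq_len(n_extra)
    se <- est <- pval <- rep(NA_real_, n_extra)
    # covariance of the non-aliased coefficients from the pivoted QR
    R <- qr.R(fit$qr)[seq_len(rank), seq_len(rank), drop = FALSE]
    cov_unscaled <- chol2inv(R)
    piv <- fit$qr$pivot[seq_len(rank)]
    for (i in seq_len(n_extra)) {
      pos <- match(idx[i], piv)
      if (!is.na(pos) && !aliased[idx[i]]) {
        est[i] <- beta[idx[i]]
        se[i] <- sqrt(sigma2 * cov_unscaled[pos, pos])
        pval[i] <- 2 * stats::pt(abs(est[i] / se[i]), rdf, lower.tail = FALSE)
      }
    }
    extra_tab <- data.frame(term = names(extra), estimate = est,
                            se = se, p = pval, row.names = NULL)
  }

  gi <- grep("^g\\.", names(beta))
  structure(list(
    design_spec = spec,
    coef = beta[seq_len(ncol(D) - n_extra)],
    genetic_coefs = stats::setNames(beta[gi], cohort$variant_ids),
    extra = extra_tab,
    edf = rank, sigma2 = sigma2,
    fitted = drop(D[, seq_len(ncol(D) - n_extra), drop = FALSE] %*%
                    beta[seq_len(ncol(D) - n_extra)]),
    residuals = y - drop(D[, seq_len(ncol(D) - n_extra), drop = FALSE] %*%
                           beta[seq_len(ncol(D) - n_extra)]),
    rows = rows
  ), class = "main_effect_model")
}

#' Predict the main-effect model and residualize the phenotype
#'
#' Computes \eqn{\hat Y^{resid}_i = Y_i - \hat\mu(E_i, Z_i) - X_i'\hat\pi_0}
#' on the requested rows, rebuilding the frozen spline bases. Extra
#' predictors from the fit never contribute.
#'
#' @param model a \code{\link{fit_main_effects}} result.
#' @param cohort a \code{\link{cohort}} with the same column schema.
#' @param rows integer rows to residualize.
#' @return Numeric residual vector.
#' @export
predict_residuals <- function(model, cohort, rows) {
  spec <- model$design_spec
  if (length(spec$env) != ncol(cohort$E) || length(spec$covar) != ncol(cohort$Z) ||
      length(model$genetic_coefs) != ncol(cohort$X))
    stop("cohort schema does not match the fitted model")
  S <- build_smooth_block(spec, cohort, rows)
  Xg <- cohort$X[rows, , drop = FALSE]
  D <- cbind(1, S, Xg)
  cohort$Y[rows] - drop(D %*% model$coef)
}

#' Dump a main-effect model to JSON
#'
#' @param model a \code{main_effect_model}.
#' @param path output path.
#' @export
write_main_effect_model <- function(model, path) {
  sm_json <- function(sm) {
    out <- list(name = sm$name, type = sm$type)
    if (sm$type == "bs") {
      out$knots <- sm$knots; out$boundary <- sm$bknots; out$degree <- sm$degree
    }
    out
  }
  jsonlite::write_json(list(
    env = lapply(model$design_spec$env, sm_json),
    covar = lapply(model$design_spec$covar, sm_json),
    coefficients = as.list(model$coef),
    edf = model$edf, sigma2 = model$sigma2
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
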