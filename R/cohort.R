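#' Construct a cohort object
#'
#' A cohort bundles the aligned inputs of a gene-environment interaction
#' analysis: a quantitative phenotype \code{Y}, an additive genotype dosage
#' matrix \code{X} (values in \code{[0, 2]}), an environmental exposure matrix
#' \code{E} and a covariate matrix \code{Z}, all keyed by sample identifier.
#' Rows must be complete cases; validation enforces equal row counts, the
#' dosage range and unique variant identifiers.
#'
#' Environmental and covariate columns with at most two distinct values are
#' flagged as binary so that downstream main-effect smoothers treat them as
#' linear terms instead of fitting a spline basis.
#'
#' @param Y numeric phenotype vector of length \code{n}.
#' @param X numeric \code{n x m} genotype dosage matrix, entries in
#'   \code{[0, 2]}.
#' @param E numeric \code{n x d} matrix of environmental exposures.
#' @param Z numeric \code{n x p} matrix of covariates.
#' @param sample_ids character vector of unique sample identifiers
#'   (default \code{"s1".."sn"}).
#' @param variant_ids,env_names,covar_names column names; taken from the
#'   matrices when \code{NULL}.
#' @return An object of class \code{"cohort"}: a list with elements
#'   \code{sample_ids}, \code{Y}, \code{X}, \code{E}, \code{Z},
#'   \code{variant_ids}, \code{env_names}, \code{covar_names}, and logical
#'   vectors \code{env_binary}, \code{covar_binary}.
#' @export
cohort <- function(Y, X, E, Z, sample_ids = NULL,
                   variant_ids = NULL, env_names = NULL, covar_names = NULL) {
  X <- as.matrix(X); E <- as.matrix(E); Z <- as.matrix(Z)
  Y <- as.numeric(Y)
  n <- length(Y)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  name_or <- function(given, mat, prefix) {
    if (!is.null(given)) return(as.character(given))
    if (!is.null(colnames(mat))) return(colnames(mat))
    paste0(prefix, seq_len(ncol(mat)))
  }
  obj <- structure(list(
    sample_ids  = sample_ids,
    Y = Y, X = X, E = E, Z = Z,
    variant_ids = name_or(variant_ids, X, "v"),
    env_names   = name_or(env_names, E, "e"),
    covar_names = name_or(covar_names, Z, "z"),
    env_binary   = apply(E, 2, function(col) length(unique(col)) <= 2),
    covar_binary = apply(Z, 2, function(col) length(unique(col)) <= 2)
  ), class = "cohort")
  colnames(obj$X) <- obj$variant_ids
  colnames(obj$E) <- obj$env_names
  colnames(obj$Z) <- obj$covar_names
  validate_cohort(obj)
}

validate_cohort <- function(obj) {
  n <- length(obj$Y)
  if (length(obj$sample_ids) != n ||
      nrow(obj$X) != n || nrow(obj$E) != n || nrow(obj$Z) != n)
    stop("cohort components disagree on the number of samples")
  if (anyDuplicated(obj$sample_ids))
    stop("duplicate sample ids")
  if (anyDuplicated(obj$variant_ids))
    stop("duplicate variant ids")
  if (anyNA(obj$Y) || anyNA(obj$X) || anyNA(obj$E) || anyNA(obj$Z))
    stop("cohort contains missing values; load_cohort enforces complete cases")
  if (!is.numeric(obj$Y)) stop("phenotype must be numeric")
  bad <- which(obj$X < 0 | obj$X > 2, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("dosage outside [0, 2] for variant ", obj$variant_ids[bad[1, 2]])
  obj
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: n = %d samples, m = %d variants, d = %d exposures, p = %d covariates\n",
              length(x$Y), ncol(x$X), ncol(x$E), ncol(x$Z)))
  invisible(x)
}

#' Number of samples in a cohort
#' @param x a \code{cohort}.
#' @export
n_samples <- function(x) length(x$Y)

read_id_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("file ", path, " needs a sample-ID column plus data")
  ids <- as.character(df[[1]])
  rownames(df) <- NULL
  list(ids = ids, data = df[, -1, drop = FALSE])
}

read_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% names(df)[seq_along(fixed)]))
    stop("not a PLINK .raw export: expected leading columns ",
         paste(fixed, collapse = " "))
  keep <- setdiff(names(df), fixed)
  list(ids = as.character(df$IID), data = df[, keep, drop = FALSE])
}

#' Load a cohort from delimited files
#'
#' Reads phenotype, genotype, exposure and covariate tables, inner-joins them
#' on sample ID, drops incomplete rows, and returns a validated
#' \code{\link{cohort}} with rows in sorted sample-ID order (so that all
#' seed-controlled downstream splits are reproducible regardless of file row
#' order).
#'
#' @param pheno_path TSV with header; first column sample ID, second the
#'   quantitative phenotype.
#' @param geno_path genotype table; either a TSV (ID column plus one numeric
#'   dosage column per variant) or a PLINK \code{.raw} additive dosage export
#'   (columns \code{FID IID PAT MAT SEX PHENOTYPE} followed by
#'   \code{<variant>_<allele>} dosages, sample ID taken from \code{IID}).
#' @param env_path,covar_path TSVs with header, first column sample ID.
#' @param geno_dialect \code{"tsv"} or \code{"plink_raw"}.
#' @return A \code{\link{cohort}}.
#' @export
load_cohort <- function(pheno_path, geno_path, env_path, covar_path,
                        geno_dialect = c("tsv", "plink_raw")) {
  geno_dialect <- match.arg(geno_dialect)
  ph <- read_id_table(pheno_path)
  ge <- if (geno_dialect == "plink_raw") read_plink_raw(geno_path)
        else read_id_table(geno_path)
  en <- read_id_table(env_path)
  cv <- read_id_table(covar_path)

  ids <- Reduce(intersect, list(ph$ids, ge$ids, en$ids, cv$ids))
  if (length(ids) == 0) stop("no sample IDs shared by all four input files")
  ids <- sort(ids)

  pick <- function(tab) tab$data[match(ids, tab$ids), , drop = FALSE]
  Ydf <- pick(ph); Xdf <- pick(ge); Edf <- pick(en); Zdf <- pick(cv)

  Y <- suppressWarnings(as.numeric(Ydf[[1]]))
  if (any(is.na(Y) & !is.na(Ydf[[1]])))
    stop("non-numeric phenotype values in ", pheno_path)
  num_mat <- function(df) {
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    rownames(m) <- NULL
    m
  }
  X <- num_mat(Xdf); E <- num_mat(Edf); Z <- num_mat(Zdf)

  complete <- !is.na(Y) &
    stats::complete.cases(X) & stats::complete.cases(E) & stats::complete.cases(Z)
  if (!any(complete)) stop("no complete-case samples after join")
  cohort(Y[complete], X[complete, , drop = FALSE], E[complete, , drop = FALSE],
         Z[complete, , drop = FALSE], sample_ids = ids[complete])
}

#' Write a cohort back to delimited files
#'
#' Inverse of \code{\link{load_cohort}} (TSV dialect): writes the four tables
#' into \code{dir} as \code{pheno.tsv}, \code{geno.tsv}, \code{env.tsv},
#' \code{covar.tsv}. Reloading reproduces the cohort exactly.
#'
#' @param x a \code{cohort}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the four file paths.
#' @export
write_cohort <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    wt(data.frame(sample_id = x$sample_ids, phenotype = x$Y), "pheno.tsv"),
    wt(data.frame(sample_id = x$sample_ids, x$X, check.names = FALSE), "geno.tsv"),
    wt(data.frame(sample_id = x$sample_ids, x$E, check.names = FALSE), "env.tsv"),
    wt(data.frame(sample_id = x$sample_ids, x$Z, check.names = FALSE), "covar.tsv")
  )
  invisible(paths)
}

#' Write a JSON summary of a cohort
#'
#' @param x a \code{cohort}.
#' @param path output JSON path.
#' @export
write_cohort_summary <- function(x, path) {
  jsonlite::write_json(list(
    n = length(x$Y), m = ncol(x$X), d = ncol(x$E), p = ncol(x$Z),
    variant_ids = x$variant_ids, env_names = x$env_names,
    covar_names = x$covar_names
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Specify an interaction score
#'
#' An interaction score is a weighted sum of variant-by-exposure product
#' terms, \eqn{U_i = \sum_{j}\sum_{l} \pi_{jl} X_{ij} E_{il}}. The spec holds
#' the term list (variant index, exposure index, weight); an empty term list
#' is the legal degenerate score that evaluates to zero.
#'
#' @param variant integer variant indices (column of \code{X}).
#' @param env integer exposure indices (column of \code{E}).
#' @param weight numeric weights \eqn{\pi_{jl}}, finite.
#' @param label free-text tag (e.g. \code{"U1"}).
#' @return An object of class \code{"score_spec"}.
#' @export
score_spec <- function(variant = integer(0), env = integer(0),
                       weight = numeric(0), label = "") {
  variant <- as.integer(variant); env <- as.integer(env)
  weight <- as.numeric(weight)
  if (length(variant) != length(env) || length(env) != length(weight))
    stop("variant, env and weight must have equal length")
  if (anyDuplicated(cbind(variant, env)))
    stop("duplicate (variant, env) term")
  if (length(weight) && any(!is.finite(weight)))
    stop("weights must be finite")
  structure(list(variant = variant, env = env, weight = weight, label = label),
            class = "score_spec")
}

#' @export
print.score_spec <- function(x, ...) {
  cat(sprintf("interaction score %s: %d terms\n",
              if (nzchar(x$label)) x$label else "<unnamed>", length(x$weight)))
  invisible(x)
}

#' Evaluate an interaction score on cohort rows
#'
#' Computes \eqn{U_i = \sum \pi_{jl} X_{ij} E_{il}} for the requested rows.
#' Linear in the weights; an empty spec returns zeros.
#'
#' @param spec a \code{\link{score_spec}}.
#' @param cohort a \code{\link{cohort}}.
#' @param rows integer row indices (default all rows).
#' @return Numeric vector of length \code{length(rows)}.
#' @export
evaluate_score <- function(spec, cohort, rows = seq_along(cohort$Y)) {
  u <- numeric(length(rows))
  if (length(spec$weight) == 0) return(u)
  if (any(spec$variant < 1 | spec$variant > ncol(cohort$X)) ||
      any(spec$env < 1 | spec$env > ncol(cohort$E)))
    stop("score term index out of range")
  for (t in seq_along(spec$weight)) {
    u <- u + spec$weight[t] *
      cohort$X[rows, spec$variant[t]] * cohort$E[rows, spec$env[t]]
  }
  unname(u)
}
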