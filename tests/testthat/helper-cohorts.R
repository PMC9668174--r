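# Small deterministic cohorts built in code for unit tests.

# Fully hand-specified tiny cohort (n = 6, m = 3, d = 2, p = 1).
tiny_cohort <- function() {
  cohort(
    Y = c(1.2, -0.4, 0.8, 2.1, -1.0, 0.3),
    X = matrix(c(0, 1, 2, 1, 0, 2,
                 2, 0, 1, 1, 2, 0,
                 1, 1, 0, 2, 0, 1), ncol = 3,
               dimnames = list(NULL, c("rs1", "rs2", "rs3"))),
    E = matrix(c(0.5, -1.2, 0.3, 1.8, -0.7, 0.1,
                 1, 0, 1, 0, 1, 1), ncol = 2,
               dimnames = list(NULL, c("expo", "sex"))),
    Z = matrix(c(0.1, 0.4, -0.3, 0.9, -1.1, 0.6), ncol = 1,
               dimnames = list(NULL, "age"))
  )
}

# Random cohort of moderate size; genotypes HWE, exposures/covariates
# standard normal, phenotype from a linear null model.
random_cohort <- function(n = 400, m = 8, d = 3, p = 2, seed = 1) {
  set.seed(seed)
  X <- vapply(runif(m, 0.1, 0.5), function(f) rbinom(n, 2, f), numeric(n))
  E <- matrix(rnorm(n * d), n, d)
  Z <- matrix(rnorm(n * p), n, p)
  pi0 <- rnorm(m, 0, 0.2)
  Y <- drop(E %*% rep(0.3, d)) + drop(Z %*% rep(0.2, p)) +
    drop(X %*% pi0) + rnorm(n)
  coh <- cohort(Y, X, E, Z)
  attr(coh, "pi0") <- pi0
  coh
}

# Write the four TSV inputs of a cohort into a temp dir; returns the paths.
cohort_files <- function(coh, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_cohort(coh, dir)
  list(pheno = file.path(dir, "pheno.tsv"),
       geno = file.path(dir, "geno.tsv"),
       env = file.path(dir, "env.tsv"),
       covar = file.path(dir, "covar.tsv"),
       dir = dir)
}
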