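test_that("load_cohort inner-joins on sample ID and sorts rows", {
  dir <- withr::local_tempdir()
  wt <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(dir, f)
  }
  ph <- wt(data.frame(id = c("C", "A", "B"), y = c(3, 1, 2)), "p.tsv")
  ge <- wt(data.frame(id = c("B", "C"), rs1 = c(1, 2)), "g.tsv")
  en <- wt(data.frame(id = c("B", "C", "D"), e1 = c(0.5, -0.5, 9)), "e.tsv")
  cv <- wt(data.frame(id = c("C", "B"), z1 = c(0.1, 0.2)), "c.tsv")

  coh <- load_cohort(ph, ge, en, cv)
  expect_equal(coh$sample_ids, c("B", "C"))
  expect_equal(coh$Y, c(2, 3))
  expect_equal(drop(coh$X), c(1, 2), ignore_attr = TRUE)
  expect_equal(drop(coh$Z), c(0.2, 0.1), ignore_attr = TRUE)
})

test_that("PLINK .raw dialect keeps allele-suffixed dosage columns, IID as id", {
  dir <- withr::local_tempdir()
  raw <- file.path(dir, "g.raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_T",
               "f1 B 0 0 1 -9 1 0",
               "f2 A 0 0 2 -9 2 1"), raw)
  wt <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(dir, f)
  }
  ph <- wt(data.frame(id = c("A", "B"), y = c(1.5, 2.5)), "p.tsv")
  en <- wt(data.frame(id = c("A", "B"), e1 = c(0, 1)), "e.tsv")
  cv <- wt(data.frame(id = c("A", "B"), z1 = c(1, 2)), "c.tsv")

  coh <- load_cohort(ph, raw, en, cv, geno_dialect = "plink_raw")
  expect_equal(coh$variant_ids, c("rs1_A", "rs2_T"))
  expect_equal(coh$sample_ids, c("A", "B"))
  expect_equal(coh$X[, "rs1_A"], c(2, 1), ignore_attr = TRUE)
})

test_that("rows with missing values are dropped (complete-case)", {
  dir <- withr::local_tempdir()
  wt <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(dir, f)
  }
  ph <- wt(data.frame(id = c("A", "B", "C"), y = c(1, 2, 3)), "p.tsv")
  ge <- wt(data.frame(id = c("A", "B", "C"), rs1 = c(0, 1, 2)), "g.tsv")
  en <- wt(data.frame(id = c("A", "B", "C"), e1 = c(0.5, NA, 1.5)), "e.tsv")
  cv <- wt(data.frame(id = c("A", "B", "C"), z1 = c(1, 2, 3)), "c.tsv")

  coh <- load_cohort(ph, ge, en, cv)
  expect_equal(coh$sample_ids, c("A", "C"))
  expect_equal(length(coh$Y), 2)
})

test_that("load_cohort hard errors: empty ID intersection, bad dosage, non-numeric phenotype", {
  dir <- withr::local_tempdir()
  wt <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(dir, f)
  }
  ph <- wt(data.frame(id = c("A"), y = 1), "p.tsv")
  ge <- wt(data.frame(id = c("B"), rs1 = 1), "g.tsv")
  en <- wt(data.frame(id = c("A", "B"), e1 = c(1, 2)), "e.tsv")
  cv <- wt(data.frame(id = c("A", "B"), z1 = c(1, 2)), "c.tsv")
  expect_error(load_cohort(ph, ge, en, cv), "no sample IDs shared")

  ge2 <- wt(data.frame(id = c("A"), rs1 = 3), "g2.tsv")
  expect_error(load_cohort(ph, ge2, en, cv), "rs1")

  ph2 <- wt(data.frame(id = c("A"), y = "high"), "p2.tsv")
  ge3 <- wt(data.frame(id = c("A"), rs1 = 1), "g3.tsv")
  expect_error(load_cohort(ph2, ge3, en, cv), "non-numeric phenotype")
})

test_that("write_cohort / load_cohort round trip is idempotent", {
  coh <- random_cohort(n = 40, m = 3, seed = 11)
  f1 <- cohort_files(coh)
  re1 <- load_cohort(f1$pheno, f1$geno, f1$env, f1$covar)
  f2 <- cohort_files(re1)
  re2 <- load_cohort(f2$pheno, f2$geno, f2$env, f2$covar)
  expect_identical(re1, re2)
})

test_that("evaluate_score matches the brute-force double sum and handles degenerate specs", {
  coh <- tiny_cohort()
  sp <- score_spec(variant = c(1, 2), env = c(1, 1), weight = c(0.5, -1))
  u <- evaluate_score(sp, coh)
  brute <- sapply(seq_along(coh$Y), function(i)
    0.5 * coh$X[i, 1] * coh$E[i, 1] + (-1) * coh$X[i, 2] * coh$E[i, 1])
  expect_equal(u, unname(brute), tolerance = 1e-14)

  ident <- score_spec(1, 1, 1)
  expect_equal(evaluate_score(ident, coh), coh$X[, 1] * coh$E[, 1],
               ignore_attr = TRUE)

  expect_equal(evaluate_score(score_spec(), coh), rep(0, 6))
})

test_that("evaluate_score is linear in the weights", {
  set.seed(3)
  for (rep in 1:5) {
    coh <- random_cohort(n = 30, m = 5, seed = rep)
    k <- sample(3:8, 1)
    pairs <- expand.grid(v = 1:5, e = 1:3)
    pick <- pairs[sample(nrow(pairs), k), ]
    w <- rnorm(k)
    s1 <- score_spec(pick$v, pick$e, w)
    s2 <- score_spec(pick$v, pick$e, 2 * w)
    expect_equal(evaluate_score(s2, coh), 2 * evaluate_score(s1, coh),
                 tolerance = 1e-12)
  }
})

test_that("cohort validation rejects inconsistent inputs and flags binary columns", {
  expect_error(cohort(Y = 1:3, X = matrix(0, 2, 1), E = matrix(0, 3, 1),
                      Z = matrix(0, 3, 1)), "disagree")
  expect_error(cohort(Y = 1:2, X = matrix(c(0, 3), 2, 1), E = matrix(0, 2, 1),
                      Z = matrix(0, 2, 1)), "dosage")
  coh <- tiny_cohort()
  expect_equal(unname(coh$env_binary), c(FALSE, TRUE))
  ids <- withr::local_tempfile(fileext = ".json")
  write_cohort_summary(coh, ids)
  js <- jsonlite::read_json(ids)
  expect_equal(js$n, 6)
  expect_equal(js$m, 3)
})
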