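make_assoc_data <- function(n = 120, seed = 1, beta_case = 0) {
  set.seed(seed)
  pheno <- tibble::tibble(
    sample_id = paste0("S", seq_len(n)),
    status = rep(c("case", "control"), length.out = n),
    sex = rbinom(n, 1, 0.45), age = rnorm(n, 74, 8),
    pc1 = rnorm(n), pc2 = rnorm(n)
  )
  conc <- tidyr::crossing(sample_id = pheno$sample_id,
                          protein = fh_proteins()) |>
    dplyr::mutate(conc_nM = rlnorm(dplyr::n(), 3, 0.4))
  d <- prepare_analysis_data(conc, pheno)
  if (beta_case != 0) {
    d$conc_t <- d$conc_t + beta_case * (d$status == "case")
  }
  d
}

test_that("normalising transformations follow the per-protein map", {
  expect_equal(transform_concentration(100, "FH"), 10)
  expect_equal(transform_concentration(31.2, "FHR-1"), 31.2)
  expect_equal(transform_concentration(exp(1), "FHL-1"), 1)
  expect_warning(v <- transform_concentration(0, "FHR-5"), "non-positive")
  expect_true(is.na(v))
  expect_error(transform_concentration(1, "ALB"),
               class = "fhrmr_unknown_protein")
  # monotone for every protein
  x <- sort(rlnorm(50, 2, 1))
  for (p in fh_proteins()) {
    expect_false(is.unsorted(transform_concentration(x, p)), info = p)
  }
  # and untransform inverts
  for (p in fh_proteins()) {
    expect_equal(untransform_concentration(transform_concentration(x, p), p),
                 x, tolerance = 1e-12, info = p)
  }
})

test_that("linear association matches the normal-equations oracle", {
  for (i in 1:100) {
    set.seed(i)
    n <- 25
    d <- tibble::tibble(
      protein = "FHR-1",
      conc_t = rnorm(n), status = sample(c("case", "control"), n, TRUE),
      sex = rbinom(n, 1, 0.5), age = rnorm(n, 70, 5),
      pc1 = rnorm(n), pc2 = rnorm(n), conc_nM = 1
    )
    got <- assoc_linear(d)
    X <- cbind(1, as.numeric(d$status == "case"),
               d$sex, d$age, d$pc1, d$pc2)
    want <- oracle_ols(X, d$conc_t)
    expect_lt(abs(got$beta - want$beta[2]), 1e-8)
    expect_lt(abs(got$se - want$se[2]), 1e-8)
  }
})

test_that("an exact group difference is recovered exactly", {
  d <- make_assoc_data(n = 40, beta_case = 0)
  d <- d[d$protein == "FHR-1", ]
  d$conc_t <- as.numeric(d$status == "case")  # outcome equals the indicator
  got <- assoc_linear(d, covariates = character(0))
  expect_equal(got$beta, 1)
})

test_that("a covariate orthogonal to predictor and outcome leaves beta alone", {
  d <- make_assoc_data(n = 80)
  d1 <- d[d$protein == "FH", ]
  base <- assoc_linear(d1, covariates = character(0))
  X <- cbind(1, as.numeric(d1$status == "case"), d1$conc_t)
  z <- rnorm(nrow(d1))
  d1$ortho <- drop(z - X %*% qr.coef(qr(X), z))  # residualised on both
  with_cov <- assoc_linear(d1, covariates = "ortho")
  expect_lt(abs(base$beta - with_cov$beta), 1e-8)
})

test_that("rank-deficient designs fail loudly", {
  d <- make_assoc_data(n = 50)
  d$pc2 <- d$pc1
  expect_error(assoc_linear(d), class = "fhrmr_rank_deficient")
})

test_that("logistic OR matches the 2x2 cross-product for a binary exposure", {
  # exposed cases 30, unexposed cases 20; exposed controls 10, unexposed 40
  d <- tibble::tibble(
    protein = "FHR-1",
    status = rep(c("case", "control"), c(50, 50)),
    conc_nM = exp(c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40)))
  )
  got <- assoc_logistic_or(d, covariates = character(0))
  s <- sd(log(d$conc_nM))
  expect_equal(exp(got$beta / s), 6.0, tolerance = 1e-6)
})

test_that("the per-SD OR is invariant to rescaling the concentrations", {
  d <- make_assoc_data(n = 200, seed = 3)
  a <- assoc_logistic_or(d)
  d2 <- dplyr::mutate(d, conc_nM = conc_nM * 1000)
  b <- assoc_logistic_or(d2)
  expect_equal(a$or_per_sd, b$or_per_sd, tolerance = 1e-8)
})

test_that("a permuted predictor gives a null OR", {
  set.seed(5)
  d <- make_assoc_data(n = 600, seed = 6)
  d <- d[d$protein == "FHR-2", ]
  d$conc_nM <- sample(d$conc_nM)
  got <- assoc_logistic_or(d)
  expect_true(got$or_lo < 1 && got$or_hi > 1)
})

test_that("per-SD log-OR estimates are unbiased with nominal CI coverage", {
  set.seed(2024)
  true_b <- 0.5
  reps <- 200
  est <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    n <- 5000
    z <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + true_b * z))
    d <- tibble::tibble(protein = "FHR-1",
                        status = ifelse(y == 1, "case", "control"),
                        conc_nM = exp(z))
    fit <- assoc_logistic_or(d, covariates = character(0))
    est[r, ] <- c(fit$beta, log(fit$or_lo), log(fit$or_hi))
  }
  mc_se <- sd(est[, 1]) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) - true_b), 3 * mc_se)
  coverage <- mean(est[, 2] < true_b & est[, 3] > true_b)
  expect_gte(coverage, 0.92)
  expect_lte(coverage, 0.98)
})

test_that("separation is reported, not silently fitted", {
  d <- tibble::tibble(
    protein = "FHR-1",
    status = rep(c("case", "control"), each = 20),
    conc_nM = c(rlnorm(20, 5, 0.1), rlnorm(20, 0, 0.1))
  )
  expect_error(suppressWarnings(assoc_logistic_or(d, covariates = character(0))),
               class = "fhrmr_nonconvergence")
})

test_that("correlation matrices behave like Pearson r", {
  x <- c(1, 2, 3)
  d <- tibble::tibble(
    sample_id = rep(paste0("S", 1:3), 3),
    protein = rep(c("A", "B", "C"), each = 3),
    conc_nM = c(x, 2 * x + 1, c(2, 4, 7))
  )
  m <- protein_correlations(d)
  expect_equal(diag(m), c(A = 1, B = 1, C = 1))
  expect_equal(m, t(m))
  expect_equal(m["A", "B"], 1)            # affine copy
  expect_equal(m["A", "C"], 0.9934, tolerance = 1e-4)
  d$conc_nM[d$protein == "B"] <- -d$conc_nM[d$protein == "A"]
  expect_equal(protein_correlations(d)["A", "B"], -1)
})

test_that("zero-variance proteins warn and yield NA correlations", {
  d <- tibble::tibble(
    sample_id = rep(paste0("S", 1:4), 2),
    protein = rep(c("A", "B"), each = 4),
    conc_nM = c(rnorm(4), rep(5, 4))
  )
  expect_warning(m <- protein_correlations(d), "zero-variance")
  expect_true(is.na(m["A", "B"]))
})

test_that("group summaries are normal-theory means with 95% CIs", {
  d <- tibble::tibble(protein = "FH", status = "control",
                      conc_nM = c(1, 2, 3, 4, 5))
  s <- cohort_summary(d)
  expect_equal(s$mean_nM, 3)
  expect_equal(s$ci_lo, 3 - 1.96 * 0.7071068, tolerance = 1e-6)
  expect_equal(s$ci_hi, 3 + 1.96 * 0.7071068, tolerance = 1e-6)
  const <- tibble::tibble(protein = "FH", status = "control",
                          conc_nM = rep(7, 5))
  sc <- cohort_summary(const)
  expect_equal(c(sc$ci_lo, sc$ci_hi), c(7, 7))
  one <- tibble::tibble(protein = "FH", status = "case", conc_nM = 1)
  expect_error(cohort_summary(one), class = "fhrmr_group_too_small")
})
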