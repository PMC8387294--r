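random_instruments <- function(k, seed) {
  set.seed(seed)
  tibble::tibble(
    variant_id = paste0("rs", seq_len(k)),
    bx = runif(k, 0.2, 3) * sample(c(-1, 1), k, TRUE),
    sx = runif(k, 0.05, 0.3),
    by = rnorm(k, 0, 0.3),
    sy = runif(k, 0.05, 0.5)
  )
}

test_that("instrument strength inverts the F test", {
  expect_equal(iv_strength_r2(1, 252), 0)
  # monotone: stronger evidence, larger R2
  ps <- 10^seq(-2, -40, by = -2)
  expect_false(is.unsorted(iv_strength_r2(ps, 252)))
  # survives extreme underflow-range p-values via the log-scale quantile
  expect_true(is.finite(iv_strength_r2(1e-300, 252)))
  expect_lt(iv_strength_r2(1e-300, 252), 1)
  # round-trip: R2 -> F -> p -> R2
  f <- 45; n <- 252
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  expect_equal(iv_strength_r2(p, n), f / (f + n - 2), tolerance = 1e-10)
})

test_that("Wald ratio and its first-order delta SE", {
  expect_equal(wald_ratio(2, 0, 0.1)$theta, 0)
  one <- wald_ratio(1, -0.4, 0.12)
  expect_equal(one$theta, -0.4)
  expect_equal(one$se, 0.12)
  fhr3 <- wald_ratio(2.02, -0.06, 0.12)
  expect_equal(fhr3$theta, -0.0297, tolerance = 1e-3)
  expect_equal(fhr3$se, 0.0594, tolerance = 1e-3)
  expect_error(wald_ratio(0, 1, 0.1), class = "fhrmr_weak_instrument")
})

test_that("IVW reduces to the Wald ratio for one instrument", {
  iv <- random_instruments(1, 5)
  res <- mr_ivw(iv)
  wr <- wald_ratio(iv$bx, iv$by, iv$sy)
  expect_equal(res$method, "wald")
  expect_equal(res$theta, wr$theta)
  expect_equal(res$se, wr$se)
  expect_true(is.na(res$q_stat))
})

test_that("duplicating an instrument k times shrinks the SE by sqrt(k)", {
  iv <- random_instruments(1, 8)
  k <- 4
  res1 <- mr_ivw(iv)
  resk <- mr_ivw(iv[rep(1, k), ])
  expect_equal(resk$theta, res1$theta)
  expect_equal(resk$se, res1$se / sqrt(k))
})

test_that("IVW equals weighted least squares through the origin", {
  for (seed in 1:100) {
    iv <- random_instruments(sample(2:8, 1), seed)
    res <- mr_ivw(iv)
    want <- oracle_ivw_wls(iv$bx, iv$by, iv$sy)
    expect_lt(abs(res$theta - want$theta), 1e-8)
    expect_lt(abs(res$se - want$se), 1e-8)
  }
})

test_that("heterogeneity statistics follow Cochran's definitions", {
  same <- mr_heterogeneity(rep(0.3, 4), rep(0.1, 4))
  expect_equal(same$q_stat, 0)
  expect_equal(same$i2_percent, 0)
  two <- mr_heterogeneity(c(0, 1), c(1, 1), pooled = 0.5)
  expect_equal(two$q_stat, 0.5)
  expect_equal(two$df, 1L)
  expect_equal(two$i2_percent, 0)  # Q < df floors at zero
  expect_true(is.na(mr_heterogeneity(0.5, 0.1)$q_stat))
})

test_that("estimates rescale consistently with exposure units", {
  iv <- random_instruments(5, 9)
  base <- mr_ivw(iv)
  c0 <- 3.7
  scaled <- mr_ivw(dplyr::mutate(iv, bx = bx * c0, sx = sx * c0))
  expect_equal(scaled$theta, base$theta / c0, tolerance = 1e-12)
  # flipping the coded allele of one instrument changes nothing
  flip <- iv
  flip$bx[2] <- -flip$bx[2]; flip$by[2] <- -flip$by[2]
  expect_equal(mr_ivw(flip)$theta, base$theta, tolerance = 1e-12)
  expect_equal(mr_ivw(flip)$se, base$se, tolerance = 1e-12)
})

test_that("harmonization aligns alleles and drops risky palindromes", {
  exposure <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "C", "G", "A"),
    other_allele = c("G", "T", "C", "T"),
    beta = c(0.5, -0.3, 0.2, 0.4), se = rep(0.1, 4),
    p = rep(1e-10, 4), n = rep(252L, 4),
    maf = c(0.2, 0.3, 0.45, 0.45)
  )
  outcome <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("G", "C", "G", "A"),   # rs1 swapped
    other_allele = c("A", "T", "C", "T"),
    beta = c(0.1, -0.2, 0.05, 0.3), se = rep(0.05, 4)
  )
  expect_warning(h <- harmonize_instruments(exposure, outcome), "palindromic")
  expect_false("rs3" %in% h$variant_id)  # C/G palindrome at MAF 0.45
  expect_false("rs4" %in% h$variant_id)  # A/T palindrome at MAF 0.45
  expect_equal(h$by[h$variant_id == "rs1"], -0.1)  # swapped -> sign flip
  expect_equal(h$by[h$variant_id == "rs2"], -0.2)  # aligned -> unchanged
})

test_that("irreconcilable alleles are dropped with a warning", {
  exposure <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
                             other_allele = "G", beta = 1, se = 0.1,
                             p = 1e-9, n = 252L, maf = 0.2)
  outcome <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
                            other_allele = "C", beta = 0.2, se = 0.1)
  expect_warning(h <- harmonize_instruments(exposure, outcome),
                 "irreconcilable")
  expect_equal(nrow(h), 0)
})

test_that("run_mr reports a no-instrument result below the threshold", {
  exposure <- tibble::tibble(
    variant_id = "rs1", chrom = "1", pos = 1L, effect_allele = "G",
    other_allele = "A", maf = 0.3, beta = 0.5, se = 0.2, p = 1e-4, n = 252L)
  outcome <- exposure |> dplyr::mutate(beta = 0.1, se = 0.1)
  res <- run_mr(exposure, outcome, label = "FHL-1")
  expect_s3_class(res, "mr_no_instrument")
  expect_equal(glance(res)$n_iv, 0L)
})

test_that("run_mr recovers a known causal effect through a strong cis IV", {
  set.seed(31)
  theta_true <- 0.4
  reps <- 60
  est <- vapply(seq_len(reps), function(r) {
    n <- 1500
    g <- rbinom(n, 2, 0.3)
    x <- 1.0 * g + rnorm(n, 0, sqrt(var(g) * (1 - 0.3) / 0.3))
    y <- rbinom(n, 1, plogis(-2 + theta_true * (x - mean(x))))
    # exposure scan in "controls", outcome scan in everyone
    ctrl <- y == 0
    ex <- summary(lm(x[ctrl] ~ g[ctrl]))$coefficients
    ou <- summary(glm(y ~ g, family = binomial()))$coefficients
    exposure <- tibble::tibble(variant_id = "rs1", chrom = "1", pos = 1L,
                               effect_allele = "G", other_allele = "A",
                               maf = 0.3, beta = ex[2, 1], se = ex[2, 2],
                               p = ex[2, 4], n = sum(ctrl))
    outcome <- tibble::tibble(variant_id = "rs1", effect_allele = "G",
                              other_allele = "A", beta = ou[2, 1],
                              se = ou[2, 2])
    res <- run_mr(exposure, outcome, label = "X")
    if (inherits(res, "mr_no_instrument")) NA_real_ else res$theta
  }, numeric(1))
  est <- est[!is.na(est)]
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - theta_true), 3 * mc_se)
})

test_that("tidy and glance expose instrument-level and pooled views", {
  res <- mr_from_instruments("FHR-3")
  td <- tidy(res)
  expect_equal(nrow(td), 7)
  expect_true(all(c("theta_iv", "se_iv", "r2_iv") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_iv, 7L)
  expect_equal(gl$or, exp(gl$theta))
  expect_s3_class(autoplot(res), "ggplot")
})
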