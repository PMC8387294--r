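small_config <- function(seed = 99, n_cases = 30, n_controls = 30,
                         disease_model = NULL, ...) {
  sim_config(
    n_cases = n_cases, n_controls = n_controls, block_size = 3,
    n_null_blocks = 1, maf_range = c(0.1, 0.35),
    pqtl = tibble::tibble(protein = c("FHR-1", "FHR-5"),
                          target_r2 = c(0.4, 0.2), beta = c(10, 0.3)),
    disease_model = disease_model %||% tibble::tibble(
      protein = c("FHR-1", "FHR-5"),
      log_or = c(log(1.8), 0), scale = "per_sd_log"),
    seed = seed, ...)
}

test_that("the whole generator is a pure function of (config, seed)", {
  a <- simulate_cohort(small_config())
  b <- simulate_cohort(small_config())
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$conc, b$conc)
  expect_identical(a$transitions, b$transitions)
  c2 <- simulate_cohort(small_config(seed = 100))
  expect_false(identical(a$conc$conc_nM, c2$conc$conc_nM))
})

test_that("cohort sizes match the requested case/control counts", {
  sim <- simulate_cohort(small_config())
  expect_equal(sum(sim$pheno$status == "case"), 30)
  expect_equal(sum(sim$pheno$status == "control"), 30)
  expect_equal(sort(rownames(sim$geno$dosages)), sort(sim$pheno$sample_id))
})

test_that("dosage expectation matches the configured allele frequency", {
  cfg <- sim_config(maf_range = c(0.5, 0.5), block_rho = 0, block_size = 4)
  g <- simulate_genotypes(10000, cfg, seed = 1)
  expect_equal(mean(colMeans(g$dosages)), 1.0, tolerance = 0.03)
  expect_true(all(g$dosages %in% 0:2))
})

test_that("latent-Gaussian blocks induce strong within-block dosage LD", {
  cfg <- sim_config(block_rho = 0.95, block_size = 5,
                    maf_range = c(0.2, 0.4))
  g <- simulate_genotypes(2000, cfg, seed = 2)
  block1 <- g$dosages[, 1:5]
  r2 <- cor(block1)^2
  expect_gt(mean(r2[upper.tri(r2)]), 0.5)
  # across blocks: no LD by construction
  across <- cor(g$dosages[, 1:5], g$dosages[, 6:10])^2
  expect_lt(mean(across), 0.05)
})

test_that("noise-free pQTL effects are exact on the transformed scale", {
  cfg <- sim_config(pqtl = tibble::tibble(protein = "FHR-1",
                                          target_r2 = 1, beta = 1),
                    n_null_blocks = 0, block_size = 2)
  set.seed(5)
  g <- simulate_genotypes(50, cfg)
  prot <- simulate_proteins(g, cfg)
  mu <- cfg$protein_intercept[["FHR-1"]]
  expect_equal(prot$conc$conc_transformed,
               mu + unname(g$dosages[, "cis_FHR-1"]))
  # identity transform: nM equals the transformed value
  expect_equal(prot$conc$conc_nM, prot$conc$conc_transformed)
})

test_that("requested instrument R2 is recovered by the scan", {
  cfg <- sim_config(pqtl = tibble::tibble(protein = "FHR-1",
                                          target_r2 = 0.53, beta = 14),
                    n_null_blocks = 0, block_size = 2,
                    maf_range = c(0.2, 0.4))
  set.seed(17)
  reps <- 200
  in_band <- vapply(seq_len(reps), function(r) {
    g <- simulate_genotypes(252, cfg)
    prot <- simulate_proteins(g, cfg)
    y <- transform_concentration(prot$conc$conc_nM, "FHR-1")
    sc <- gwas_scan(g, tibble::tibble(sample_id = rownames(g$dosages)),
                    y, covariates = NULL)
    r2 <- iv_strength_r2(max(sc$p[sc$variant_id == "cis_FHR-1"], 1e-320), 252)
    abs(r2 - 0.53) <= 0.10
  }, logical(1))
  expect_gte(mean(in_band), 0.9)
})

test_that("a genome with no pQTL effects yields no genome-wide hits", {
  cfg <- sim_config(
    pqtl = tibble::tibble(protein = "FHR-1", target_r2 = 0, beta = 0),
    n_null_blocks = 99, block_size = 10, block_rho = 0.5)
  set.seed(23)
  reps <- 30
  hits <- vapply(seq_len(reps), function(r) {
    g <- simulate_genotypes(252, cfg)
    prot <- simulate_proteins(g, cfg)
    sc <- gwas_scan(g, tibble::tibble(sample_id = rownames(g$dosages)),
                    prot$conc$conc_transformed, covariates = NULL)
    min(sc$p) < 5e-8
  }, logical(1))
  expect_lte(mean(hits), 1 / reps)  # at most one spurious replicate
})

test_that("null disease effects leave case and control distributions equal", {
  cfg <- small_config(
    n_cases = 150, n_controls = 150,
    disease_model = tibble::tibble(protein = c("FHR-1", "FHR-5"),
                                   log_or = 0, scale = "per_sd_log"))
  sim <- simulate_cohort(cfg)
  d <- prepare_analysis_data(sim$conc, sim$pheno)
  res <- assoc_linear(d)
  expect_true(all(res$p > 1e-3))
})

test_that("simulated VCF round-trips through the VCF reader", {
  sim <- simulate_cohort(small_config())
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_dosages(sim$geno, path)
  back <- read_vcf_dosages(path)
  expect_equal(back$variants$variant_id, sim$geno$variants$variant_id)
  expect_equal(back$variants$pos, sim$geno$variants$pos)
  expect_true(all(back$variants$genotyped))
  expect_equal(unname(back$dosages[sim$pheno$sample_id, ]),
               unname(sim$geno$dosages[sim$pheno$sample_id, ]),
               tolerance = 1e-3)
  expect_equal(back$variants$maf, sim$geno$variants$maf, tolerance = 1e-3)
})

test_that("cohort outputs are written as plain-text files", {
  sim <- simulate_cohort(small_config())
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("phenotypes.csv", "transitions.csv", "genotypes.vcf",
           "truth.yaml")))))
  tr <- read_transition_report(file.path(dir, "transitions.csv"))
  expect_equal(nrow(tr), nrow(sim$transitions))
})
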