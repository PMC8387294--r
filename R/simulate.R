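# Synthetic cohort generator: LD-blocked genotypes, cis/trans pQTL effects,
# logistic case-control disease, noisy SRM peak areas.

#' Simulation configuration
#'
#' Collects every tunable of the cohort generator with defaults emulating
#' the study conditions the pipeline assumes: 352 cases and 252 controls;
#' covariates sex ~ Bernoulli(0.42), age ~ Normal(74.5, 8), two standard
#' normal principal components with null effects; one cis pQTL per FHR
#' protein with variance explained matching the published instrument
#' strengths (FHR-1 0.53, FHR-2 0.44, FHR-3 0.35, FHR-4 0.25, FHR-5 0.15)
#' and none for FH or FHL-1 (so FHL-1 reproduces the no-instrument
#' behaviour); per-SD-of-log-concentration disease odds ratios of the
#' magnitude reported for the cohort; SRM noise CV 10%.
#'
#' @param n_cases,n_controls Cohort sizes after case-control sampling.
#' @param block_size Variants per LD block.
#' @param block_rho Within-block latent-haplotype correlation, in \[0, 1).
#' @param n_null_blocks Extra LD blocks with no pQTL effect.
#' @param maf_range Range minor-allele frequencies are drawn from.
#' @param pqtl Tibble with `protein`, `target_r2` (variance of the
#'   transformed concentration explained by the cis variant; 0 = no pQTL)
#'   and `beta` (effect per allele on the transformed scale).
#' @param disease_model Tibble with `protein`, `log_or` and `scale`
#'   (`"per_sd_log"`: log-OR per SD of log concentration, as reported for
#'   observational estimates; `"per_transformed"`: log-OR per unit of the
#'   transformed concentration, the scale on which ratio estimates are
#'   reported).
#' @param disease_intercept Baseline log-odds of disease.
#' @param protein_intercept,protein_sd Named vectors: mean and residual SD
#'   of each protein on its transformed scale (defaults match the cohort's
#'   control-group marginals).
#' @param srm_noise_cv Multiplicative CV of the light-transition peak areas.
#' @param corrupt_rate Fraction of peptide transition sets with a corrupted
#'   qualifier.
#' @param batch_size Samples per SRM batch.
#' @param seed Mandatory integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 352, n_controls = 252,
                       block_size = 6, block_rho = 0.8, n_null_blocks = 2,
                       maf_range = c(0.1, 0.5),
                       pqtl = NULL, disease_model = NULL,
                       disease_intercept = 0.3,
                       protein_intercept = NULL, protein_sd = NULL,
                       srm_noise_cv = 0.1, corrupt_rate = 0,
                       batch_size = 25, seed = 1) {
  stopifnot(block_rho >= 0, block_rho < 1,
            all(maf_range > 0), all(maf_range <= 0.5), !is.null(seed))
  pqtl <- pqtl %||% tibble::tibble(
    protein = fh_proteins(),
    target_r2 = c(0, 0, 0.53, 0.44, 0.35, 0.25, 0.15),
    beta = c(0, 0, 14, 1.2, 1.4, 1.3, 0.4)
  )
  disease_model <- disease_model %||% tibble::tibble(
    protein = fh_proteins(),
    log_or = log(c(1.01, 1.35, 1.81, 1.66, 1.54, 1.27, 1.38)),
    scale = "per_sd_log"
  )
  # transformed-scale means/SDs emulating the control-group marginals
  protein_intercept <- protein_intercept %||% c(
    "FH" = 27.2, "FHL-1" = 2.34, "FHR-1" = 31.2, "FHR-2" = 6.7,
    "FHR-3" = 4.9, "FHR-4" = 6.8, "FHR-5" = 3.24)
  protein_sd <- protein_sd %||% c(
    "FH" = 2.8, "FHL-1" = 0.27, "FHR-1" = 14.1, "FHR-2" = 1.3,
    "FHR-3" = 1.9, "FHR-4" = 2.0, "FHR-5" = 0.31)
  structure(list(
    n_cases = n_cases, n_controls = n_controls, block_size = block_size,
    block_rho = block_rho, n_null_blocks = n_null_blocks,
    maf_range = maf_range, pqtl = pqtl, disease_model = disease_model,
    disease_intercept = disease_intercept,
    protein_intercept = protein_intercept, protein_sd = protein_sd,
    srm_noise_cv = srm_noise_cv, corrupt_rate = corrupt_rate,
    batch_size = batch_size, seed = seed
  ), class = "sim_config")
}

# Draw one haplotype matrix (n x m) for an equicorrelated latent-Gaussian
# block: z = sqrt(rho) u + sqrt(1-rho) e, allele = 1 where z < qnorm(maf).
sim_block_haplotypes <- function(n, mafs, rho) {
  m <- length(mafs)
  u <- stats::rnorm(n)
  z <- sqrt(rho) * u + sqrt(1 - rho) *
    matrix(stats::rnorm(n * m), n, m)
  sweep(z, 2, stats::qnorm(mafs), "<") * 1
}

#' Simulate LD-blocked genotype dosages
#'
#' Haplotypes are drawn from a latent-Gaussian threshold model with
#' equicorrelation `rho` within each block (independent across blocks) and
#' paired into diploid dosages. One block is laid down per protein (its
#' first variant is the cis pQTL), plus `n_null_blocks` effect-free blocks.
#' Deterministic given the config seed.
#'
#' @param n Number of individuals.
#' @param config A [sim_config()].
#' @param seed Optional seed for standalone use; inside [simulate_cohort()]
#'   the cohort seed governs.
#' @return A [geno_data()] object; cis variants are named
#'   `cis_<protein>`.
#' @export
simulate_genotypes <- function(n, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- nrow(config$pqtl) + config$n_null_blocks
  m <- config$block_size
  mafs <- stats::runif(n_blocks * m, config$maf_range[1], config$maf_range[2])
  dos <- matrix(0, n, n_blocks * m)
  for (b in seq_len(n_blocks)) {
    cols <- (b - 1) * m + seq_len(m)
    h1 <- sim_block_haplotypes(n, mafs[cols], config$block_rho)
    h2 <- sim_block_haplotypes(n, mafs[cols], config$block_rho)
    dos[, cols] <- h1 + h2
  }
  ids <- character(n_blocks * m)
  for (b in seq_len(n_blocks)) {
    prot <- if (b <= nrow(config$pqtl)) config$pqtl$protein[b] else
      paste0("null", b - nrow(config$pqtl))
    ids[(b - 1) * m + seq_len(m)] <- c(
      paste0("cis_", prot),
      paste0("snp_", prot, "_", seq_len(m - 1)))
  }
  colnames(dos) <- ids
  rownames(dos) <- paste0("S", seq_len(n))
  variants <- tibble::tibble(
    variant_id = ids,
    chrom = as.character(rep(seq_len(n_blocks), each = m)),
    pos = rep(seq_len(m) * 1000L, n_blocks) +
      rep((seq_len(n_blocks) - 1L) * 1000000L, each = m),
    ref = "A", alt = "G",
    maf = unname(pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2)),
    imputation_r2 = 1, genotyped = TRUE
  )
  geno_data(variants, dos)
}

simulate_covariates <- function(n) {
  tibble::tibble(
    sample_id = paste0("S", seq_len(n)),
    sex = stats::rbinom(n, 1, 0.42),
    age = stats::rnorm(n, 74.5, 8),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n)
  )
}

#' Simulate protein concentrations with cis pQTL effects
#'
#' On each protein's transformed scale the value is
#' `intercept + beta * cis dosage + noise`; the noise SD is set so the cis
#' variant explains the configured `target_r2` of the transformed variance
#' (given the realised dosage variance), falling back to the configured
#' marginal SD when there is no pQTL. Values are back-transformed to nM;
#' negative back-transformed concentrations are truncated at 0 (counted in
#' the truth record).
#'
#' @param geno A [geno_data()] from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @return List with `conc` (long tibble: `sample_id`, `protein`,
#'   `conc_nM`) and `truth` (per-protein realised beta, noise SD, target
#'   R2, truncation count).
#' @export
simulate_proteins <- function(geno, config = sim_config()) {
  n <- nrow(geno$dosages)
  out <- purrr::pmap(config$pqtl, function(protein, target_r2, beta, ...) {
    mu <- config$protein_intercept[[protein]]
    if (target_r2 > 0 && beta != 0) {
      g <- unname(geno$dosages[, paste0("cis_", protein)])
      vg <- stats::var(g) * beta^2
      noise_sd <- sqrt(vg * (1 - target_r2) / target_r2)
      y <- mu + beta * g + stats::rnorm(n, 0, noise_sd)
    } else {
      noise_sd <- config$protein_sd[[protein]]
      y <- mu + stats::rnorm(n, 0, noise_sd)
    }
    conc <- untransform_concentration(y, protein)
    truncated <- sum(is.na(conc) | conc < 0)
    conc <- pmax(conc, 0)
    list(
      conc = tibble::tibble(sample_id = rownames(geno$dosages),
                            protein = protein, conc_nM = conc,
                            conc_transformed = y),
      truth = tibble::tibble(protein = protein, beta = beta,
                             target_r2 = target_r2, noise_sd = noise_sd,
                             n_truncated = truncated)
    )
  })
  list(conc = dplyr::bind_rows(purrr::map(out, "conc")),
       truth = dplyr::bind_rows(purrr::map(out, "truth")))
}

#' Simulate case-control status from protein concentrations
#'
#' Disease follows a logistic model
#' `logit P(case) = intercept + sum_p effect_p x_p`, where `x_p` is the
#' standardised log concentration (`per_sd_log` scale, standardised against
#' the supplied population moments) or the transformed concentration
#' (`per_transformed` scale).
#'
#' @param conc Long concentration tibble from [simulate_proteins()].
#' @param config A [sim_config()].
#' @param standardize Optional tibble (`protein`, `mean_log`, `sd_log`)
#'   fixing the standardisation moments (so that case-control sampling does
#'   not redefine the per-SD unit); defaults to moments of the supplied
#'   sample.
#' @return Tibble `sample_id`, `status`.
#' @export
simulate_case_control <- function(conc, config = sim_config(),
                                  standardize = NULL) {
  dm <- config$disease_model
  if (is.null(standardize)) {
    standardize <- conc |>
      dplyr::group_by(.data$protein) |>
      dplyr::summarise(mean_log = mean(log(.data$conc_nM[.data$conc_nM > 0])),
                       sd_log = stats::sd(log(.data$conc_nM[.data$conc_nM > 0])),
                       .groups = "drop")
  }
  score <- conc |>
    dplyr::inner_join(dm, by = "protein") |>
    dplyr::inner_join(standardize, by = "protein") |>
    dplyr::mutate(x = dplyr::case_when(
      .data$scale == "per_sd_log" ~
        (log(pmax(.data$conc_nM, 1e-12)) - .data$mean_log) / .data$sd_log,
      .data$scale == "per_transformed" ~ .data$conc_transformed,
      TRUE ~ NA_real_
    )) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(eta = sum(.data$log_or * .data$x), .groups = "drop")
  score <- score[match(unique(conc$sample_id), score$sample_id), ]
  p <- stats::plogis(config$disease_intercept + score$eta)
  tibble::tibble(
    sample_id = score$sample_id,
    status = ifelse(stats::runif(length(p)) < p, "case", "control")
  )
}

#' Simulate an SRM transition report
#'
#' For each sample x protein, three transitions are generated: heavy areas
#' lognormal around transition-specific nominal intensities, light areas
#' equal to `heavy x conc / spike` times multiplicative lognormal noise with
#' coefficient of variation `cv`. With `corrupt_rate > 0`, a random subset
#' of peptide sets has one qualifier's light area corrupted (tripled), for
#' exercising the qualifier concordance check.
#'
#' @param conc Long concentration tibble (`sample_id`, `protein`,
#'   `conc_nM`).
#' @param peptides,scheme Standards and spike scheme, see [fh_peptides()]
#'   and [spike_scheme()].
#' @param cv Multiplicative CV of the light/heavy ratio (0 = noise-free).
#' @param corrupt_rate Fraction of sample x protein sets with a corrupted
#'   qualifier.
#' @param batch_size Samples per batch.
#' @return Transition tibble in the [read_transition_report()] layout.
#' @export
simulate_srm_peaks <- function(conc, peptides = fh_peptides(),
                               scheme = spike_scheme(), cv = 0.1,
                               corrupt_rate = 0, batch_size = 25) {
  spikes <- spike_concentration(peptides, scheme)
  samples <- unique(conc$sample_id)
  batch_of <- stats::setNames(
    paste0("B", (seq_along(samples) - 1) %/% batch_size + 1), samples)
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  # fixed relative heavy intensities; transition 1 is the strongest and so
  # becomes the quantifier
  rel <- c(t1 = 1, t2 = 0.6, t3 = 0.35)
  sets <- conc |>
    dplyr::distinct(.data$sample_id, .data$protein) |>
    dplyr::mutate(set_noise = if (cv > 0) {
      stats::rlnorm(dplyr::n(), -sdlog^2 / 2, sdlog)
    } else {
      1
    })
  grid <- conc |>
    dplyr::inner_join(dplyr::select(spikes, "protein", "spike_nM"),
                      by = "protein") |>
    dplyr::inner_join(sets, by = c("sample_id", "protein")) |>
    tidyr::crossing(transition_id = names(rel))
  n <- nrow(grid)
  heavy <- 5e6 * rel[grid$transition_id] *
    stats::rlnorm(n, 0, if (cv > 0) sdlog / 2 else 0)
  # the light/heavy ratio reflects the analyte, so its noise is shared by a
  # peptide's three transitions; a small per-transition jitter remains
  jitter <- if (cv > 0) stats::rlnorm(n, 0, sdlog / 5) else rep(1, n)
  light <- heavy * grid$conc_nM / grid$spike_nM * grid$set_noise * jitter
  out <- grid |>
    dplyr::mutate(
      batch = unname(batch_of[.data$sample_id]),
      heavy_area = heavy, light_area = light,
      rt_min = 10 + as.integer(factor(.data$protein)) * 2 +
        stats::rnorm(n, 0, 0.05)
    )
  if (corrupt_rate > 0) {
    sets <- out |> dplyr::distinct(.data$sample_id, .data$protein)
    corrupt <- sets[stats::runif(nrow(sets)) < corrupt_rate, ]
    corrupt$corrupt <- TRUE
    out <- out |>
      dplyr::left_join(corrupt, by = c("sample_id", "protein")) |>
      dplyr::mutate(light_area = dplyr::if_else(
        !is.na(.data$corrupt) & .data$transition_id == "t3",
        .data$light_area * 3, .data$light_area)) |>
      dplyr::select(-"corrupt")
  }
  out |>
    dplyr::select(dplyr::all_of(c("sample_id", "batch", "protein",
                                  "transition_id", "light_area",
                                  "heavy_area", "rt_min"))) |>
    dplyr::rename(peptide = "protein") |>
    tidyr::pivot_longer(c("light_area", "heavy_area"),
                        names_to = "isotope", values_to = "area") |>
    dplyr::mutate(isotope = sub("_area", "", .data$isotope)) |>
    dplyr::relocate("rt_min", .after = "area")
}

#' Simulate a complete case-control cohort
#'
#' Draws batches of individuals (genotypes, covariates, protein
#' concentrations, disease status) until the configured case and control
#' counts are reached, then truncates to exactly those counts. The per-SD
#' disease unit is fixed by the moments of the first (pre-selection) batch,
#' so case-control sampling does not redefine it. Errors after
#' `max_batches` if the intercept makes the case count unattainable.
#'
#' @param config A [sim_config()]; its `seed` drives all randomness.
#' @param max_batches Bound on the number of accumulation batches.
#' @return List of class `sim_cohort` with `geno` ([geno_data()]), `pheno`
#'   (`sample_id`, `status`, covariates), `conc` (true long concentrations),
#'   `transitions` (SRM report) and `truth` (realised causal parameters).
#' @export
simulate_cohort <- function(config = sim_config(), max_batches = 30) {
  set.seed(config$seed)
  n_target <- config$n_cases + config$n_controls
  batch_n <- max(n_target, 50)
  geno_list <- list(); pheno_list <- list(); conc_list <- list()
  truth <- NULL; standardize <- NULL
  got_cases <- 0; got_controls <- 0; b <- 0
  while ((got_cases < config$n_cases || got_controls < config$n_controls)) {
    b <- b + 1
    if (b > max_batches) {
      rlang::abort("case/control counts unattainable; adjust disease_intercept",
                   class = "fhrmr_unattainable_counts")
    }
    geno <- simulate_genotypes(batch_n, config)
    cov <- simulate_covariates(batch_n)
    prot <- simulate_proteins(geno, config)
    if (is.null(standardize)) {
      standardize <- prot$conc |>
        dplyr::group_by(.data$protein) |>
        dplyr::summarise(
          mean_log = mean(log(.data$conc_nM[.data$conc_nM > 0])),
          sd_log = stats::sd(log(.data$conc_nM[.data$conc_nM > 0])),
          .groups = "drop")
      truth <- prot$truth
    }
    status <- simulate_case_control(prot$conc, config, standardize)
    # relabel with a batch prefix so ids stay unique across batches
    relabel <- function(id) paste0("b", b, "_", id)
    rownames(geno$dosages) <- relabel(rownames(geno$dosages))
    cov$sample_id <- relabel(cov$sample_id)
    prot$conc$sample_id <- relabel(prot$conc$sample_id)
    status$sample_id <- relabel(status$sample_id)
    pheno <- dplyr::inner_join(status, cov, by = "sample_id")
    geno_list[[b]] <- geno; pheno_list[[b]] <- pheno
    conc_list[[b]] <- prot$conc
    got_cases <- got_cases + sum(pheno$status == "case")
    got_controls <- got_controls + sum(pheno$status == "control")
  }
  pheno <- dplyr::bind_rows(pheno_list)
  keep <- c(pheno$sample_id[pheno$status == "case"][seq_len(config$n_cases)],
            pheno$sample_id[pheno$status == "control"][seq_len(config$n_controls)])
  pheno <- pheno[match(keep, pheno$sample_id), ]
  dosages <- do.call(rbind, lapply(geno_list, function(g) g$dosages))[keep, ]
  variants <- geno_list[[1]]$variants
  variants$maf <- unname(pmin(colMeans(dosages) / 2, 1 - colMeans(dosages) / 2))
  conc <- dplyr::bind_rows(conc_list) |>
    dplyr::filter(.data$sample_id %in% keep)
  transitions <- simulate_srm_peaks(
    dplyr::select(conc, -"conc_transformed"),
    cv = config$srm_noise_cv, corrupt_rate = config$corrupt_rate,
    batch_size = config$batch_size)
  structure(list(
    geno = geno_data(variants, dosages),
    pheno = pheno,
    conc = conc,
    transitions = transitions,
    truth = list(pqtl = truth, disease_model = config$disease_model,
                 standardize = standardize, config = config)
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", sum(x$pheno$status == "case"), "cases /",
      sum(x$pheno$status == "control"), "controls;",
      ncol(x$geno$dosages), "variants\n")
  invisible(x)
}

#' Write simulated genotypes as a plain-text VCF
#'
#' Emits a minimal VCFv4.2 file with `GT` and `DS` FORMAT fields (hard
#' genotypes and dosages) and `MAF`/`TYPED` INFO keys, readable by
#' [read_vcf_dosages()] and standard tools.
#'
#' @param geno A [geno_data()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_dosages <- function(geno, path) {
  v <- geno$variants
  dos <- geno$dosages
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=TYPED,Number=0,Type=Flag,Description=\"Directly genotyped\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t")
  )
  gt_str <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(nrow(v)), function(i) {
    d <- dos[, i]
    info <- paste0("MAF=", signif(v$maf[i], 4),
                   if (isTRUE(v$genotyped[i])) ";TYPED" else
                     paste0(";R2=", signif(v$imputation_r2[i], 4)))
    cells <- paste0(gt_str[round(d) + 1], ":", signif(d, 4))
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i], ".",
            "PASS", info, "GT:DS", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write the tabular outputs of a simulated cohort
#'
#' Emits the phenotype CSV, the transition-report CSV, the VCF and a truth
#' JSON-like YAML into a directory.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$pheno, file.path(dir, "phenotypes.csv"))
  readr::write_csv(cohort$transitions, file.path(dir, "transitions.csv"))
  write_vcf_dosages(cohort$geno, file.path(dir, "genotypes.vcf"))
  yaml::write_yaml(list(
    pqtl = as.list(cohort$truth$pqtl),
    disease_model = as.list(cohort$truth$disease_model)
  ), file.path(dir, "truth.yaml"))
  invisible(dir)
}
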