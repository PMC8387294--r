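# Mendelian randomization: IV strength, Wald ratio, fixed-effect IVW,
# heterogeneity, one-/two-sample wiring.

#' Instrument strength R2 from a p-value and sample size
#'
#' Proportion of trait variance explained by a single variant, recovered
#' from its two-sided association p-value and the sample size by inverting
#' the F test with df (1, n - 2): `R2 = F / (F + n - 2)`. The quantile is
#' computed on the log scale so extreme p-values (e.g. 1e-300) never
#' overflow.
#'
#' @param p Two-sided p-value(s), in (0, 1\].
#' @param n Sample size(s), > 2.
#' @return R2 value(s) in \[0, 1).
#' @examples
#' iv_strength_r2(2.6e-43, 252)
#' @export
iv_strength_r2 <- function(p, n) {
  stopifnot(all(p > 0 & p <= 1), all(n > 2))
  f <- stats::qf(log(p), 1, n - 2, lower.tail = FALSE, log.p = TRUE)
  f / (f + n - 2)
}

#' Wald ratio causal estimate for a single instrument
#'
#' The ratio of the genetic association with the outcome to the genetic
#' association with the exposure, with the first-order delta-method standard
#' error `se = sy / |bx|` (the uncertainty of the exposure association is
#' ignored at first order).
#'
#' @param bx,by Exposure and outcome association estimates for the same
#'   effect allele (outcome on the log-OR scale for a binary outcome).
#' @param sy Standard error of `by`.
#' @return Tibble with `theta` and `se`; vectorised over instruments.
#' @export
wald_ratio <- function(bx, by, sy) {
  if (any(bx == 0)) {
    rlang::abort("exposure association is 0: instrument carries no signal",
                 class = "fhrmr_weak_instrument")
  }
  tibble::tibble(theta = by / bx, se = sy / abs(bx))
}

#' Fixed-effect inverse-variance weighted MR estimate
#'
#' Computes per-instrument Wald ratios, pools them with inverse-variance
#' weights `w_j = se_j^-2` under a fixed-effect model, and attaches
#' Cochran's Q and I2 heterogeneity. A single instrument reduces exactly to
#' its Wald ratio (method `"wald"`).
#'
#' @param instruments Tibble with one row per instrument: `bx`, `by`, `sy`
#'   (and anything else, carried through), e.g. assembled by
#'   [harmonize_instruments()].
#' @param label Optional trait/protein label stored on the result.
#' @param design `"one-sample"` or `"two-sample"`, metadata only.
#' @return An object of class `mr_result`; see [tidy.mr_result()] and
#'   [glance.mr_result()].
#' @examples
#' ivs <- fhr_instruments() |> dplyr::filter(protein == "FHR-3")
#' mr_ivw(dplyr::transmute(ivs, variant_id, bx = beta_exposure,
#'                         by = beta_cambridge, sy = se_cambridge))
#' @export
mr_ivw <- function(instruments, label = NULL, design = "one-sample") {
  if (nrow(instruments) == 0) {
    rlang::abort("no instruments supplied", class = "fhrmr_no_instrument")
  }
  wr <- wald_ratio(instruments$bx, instruments$by, instruments$sy)
  w <- wr$se^-2
  theta <- sum(w * wr$theta) / sum(w)
  se <- sum(w)^-0.5
  het <- mr_heterogeneity(wr$theta, wr$se, theta)
  structure(list(
    protein = label %||% NA_character_,
    method = if (nrow(instruments) == 1) "wald" else "ivw",
    design = design,
    n_iv = nrow(instruments),
    theta = theta,
    se = se,
    or = exp(theta),
    ci_lo = exp(theta - 1.96 * se),
    ci_hi = exp(theta + 1.96 * se),
    q_stat = het$q_stat, df = het$df, i2_percent = het$i2_percent,
    p = 2 * stats::pnorm(-abs(theta / se)),
    instruments = dplyr::bind_cols(instruments,
                                   theta_iv = wr$theta, se_iv = wr$se)
  ), class = "mr_result")
}

#' Cochran's Q and I2 across single-instrument estimates
#'
#' `Q = sum w_j (theta_j - theta)^2` with `w_j = se_j^-2`,
#' `df = k - 1`, `I2 = max(0, (Q - df) / Q) * 100`.
#'
#' @param theta_j Per-instrument ratio estimates.
#' @param se_j Their standard errors.
#' @param pooled The pooled estimate; defaults to the fixed-effect IVW pool
#'   of `theta_j`.
#' @return Tibble with `q_stat`, `df`, `i2_percent`; all `NA` (heterogeneity
#'   undefined) with fewer than two instruments.
#' @export
mr_heterogeneity <- function(theta_j, se_j, pooled = NULL) {
  k <- length(theta_j)
  if (k < 2) {
    return(tibble::tibble(q_stat = NA_real_, df = NA_integer_,
                          i2_percent = NA_real_))
  }
  w <- se_j^-2
  pooled <- pooled %||% (sum(w * theta_j) / sum(w))
  q <- sum(w * (theta_j - pooled)^2)
  tibble::tibble(q_stat = q, df = k - 1L,
                 i2_percent = max(0, (q - (k - 1)) / q) * 100)
}

#' @export
print.mr_result <- function(x, ...) {
  cat("MR estimate (", x$method, ", ", x$design, ")",
      if (!is.na(x$protein)) paste0(" for ", x$protein), "\n", sep = "")
  cat(sprintf("  %d instrument(s); OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$n_iv, x$or, x$ci_lo, x$ci_hi, x$p))
  if (!is.na(x$q_stat)) {
    cat(sprintf("  heterogeneity: Q = %.2f on %d df, I2 = %.1f%%\n",
                x$q_stat, x$df, x$i2_percent))
  }
  invisible(x)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Joins exposure and outcome associations by variant id, aligns the outcome
#' effect to the exposure's effect allele (flipping the sign where the
#' allele pair is swapped), drops variants whose alleles cannot be
#' reconciled, and drops palindromic (A/T or C/G) variants with MAF above
#' `palindromic_maf` whose strand cannot be resolved.
#'
#' @param exposure Tibble with `variant_id`, `beta`, `se`, `p`, `n`,
#'   `effect_allele`, `other_allele` and optionally `maf`.
#' @param outcome Tibble with `variant_id`, `beta`, `se`, `effect_allele`,
#'   `other_allele` (log-OR scale for a disease outcome).
#' @param palindromic_maf MAF above which palindromic variants are dropped
#'   (default 0.42).
#' @return Tibble of instruments with `bx`, `sx`, `by`, `sy`, `p_exposure`,
#'   `n_exposure` plus variant metadata.
#' @export
harmonize_instruments <- function(exposure, outcome, palindromic_maf = 0.42) {
  ex <- tibble::tibble(
    variant_id = exposure$variant_id,
    ea_x = exposure$effect_allele, oa_x = exposure$other_allele,
    bx = exposure$beta, sx = exposure$se,
    p_exposure = exposure$p, n_exposure = exposure$n,
    maf = if ("maf" %in% names(exposure)) exposure$maf else NA_real_
  )
  ou <- tibble::tibble(
    variant_id = outcome$variant_id,
    ea_y = outcome$effect_allele, oa_y = outcome$other_allele,
    by = outcome$beta, sy = outcome$se
  )
  joined <- dplyr::inner_join(ex, ou, by = "variant_id")
  same <- joined$ea_x == joined$ea_y & joined$oa_x == joined$oa_y
  swapped <- joined$ea_x == joined$oa_y & joined$oa_x == joined$ea_y
  bad <- !(same | swapped)
  if (any(bad)) {
    rlang::warn(paste0("dropping ", sum(bad),
                       " variant(s) with irreconcilable alleles"))
  }
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palin <- joined$oa_x == unname(comp[joined$ea_x])
  risky <- palin %in% TRUE & !is.na(joined$maf) & joined$maf > palindromic_maf
  if (any(risky)) {
    rlang::warn(paste0("dropping ", sum(risky),
                       " palindromic variant(s) with MAF > ", palindromic_maf))
  }
  keep <- (same | swapped) & !risky
  joined <- joined[keep, ]
  sign <- ifelse(same[keep], 1, -1)
  tibble::tibble(
    variant_id = joined$variant_id,
    effect_allele = joined$ea_x,
    other_allele = joined$oa_x,
    bx = joined$bx, sx = joined$sx,
    by = sign * joined$by, sy = joined$sy,
    p_exposure = joined$p_exposure, n_exposure = joined$n_exposure
  )
}

#' Mendelian randomization from summary statistics
#'
#' End-to-end MR for one protein: clump the exposure scan to independent
#' genome-wide-significant instruments, harmonize them with the outcome
#' scan, and estimate the causal effect by Wald ratio (one instrument) or
#' fixed-effect IVW (several), with heterogeneity and per-instrument
#' strength R2 attached. In a one-sample design the exposure associations
#' come from the controls of the same cohort whose case-control scan
#' supplies the outcome associations; in a two-sample design the outcome
#' scan is external.
#'
#' @param exposure Exposure summary statistics (see [gwas_scan()]).
#' @param outcome Outcome summary statistics on the log-OR scale (see
#'   [gwas_scan_logistic()] or an external file).
#' @param ld LD matrix for clumping (see [ld_matrix()]); `NULL` treats
#'   variants as independent.
#' @param design `"one-sample"` or `"two-sample"` (metadata).
#' @param label Protein label for the result.
#' @param p_threshold Genome-wide significance threshold for instrument
#'   selection (default 5e-8).
#' @param r2_cutoff Clumping LD cut-off (0.001 or 0.01).
#' @return An `mr_result`, or an object of class `mr_no_instrument` when no
#'   variant passes the significance threshold.
#' @export
run_mr <- function(exposure, outcome, ld = NULL,
                   design = c("one-sample", "two-sample"), label = NULL,
                   p_threshold = 5e-8, r2_cutoff = 0.001) {
  design <- match.arg(design)
  ivs <- clump(exposure, ld = ld, p_threshold = p_threshold,
               r2_cutoff = r2_cutoff)
  if (nrow(ivs) == 0) {
    return(structure(list(protein = label %||% NA_character_, design = design,
                          method = "none", n_iv = 0L),
                     class = "mr_no_instrument"))
  }
  harm <- harmonize_instruments(ivs, outcome)
  if (nrow(harm) == 0) {
    return(structure(list(protein = label %||% NA_character_, design = design,
                          method = "none", n_iv = 0L),
                     class = "mr_no_instrument"))
  }
  harm$r2_iv <- iv_strength_r2(harm$p_exposure, harm$n_exposure)
  mr_ivw(harm, label = label, design = design)
}

#' @export
print.mr_no_instrument <- function(x, ...) {
  cat("MR (", x$design, ")",
      if (!is.na(x$protein)) paste0(" for ", x$protein),
      ": no genome-wide-significant instrument\n", sep = "")
  invisible(x)
}

#' Bundled instrument table for the FH-family proteins
#'
#' Published instrumental-variable summary estimates at and beyond the CFH
#' locus: for each instrument, the association with the protein
#' concentration in 252 cohort controls (exposure), the association with
#' advanced AMD in the same cohort's case-control scan (one-sample outcome,
#' 845 cases / 419 controls) and in the large consortium GWAS (two-sample
#' outcome, 16,144 cases / 17,832 controls), all per copy of the effect
#' allele.
#'
#' @return Tibble with one row per instrument and columns for the variant,
#'   cis/trans status, published instrument-strength R2, exposure betas/SEs
#'   and the two outcome association sets.
#' @examples
#' fhr_instruments() |> dplyr::filter(protein == "FHR-3")
#' @export
fhr_instruments <- function() {
  path <- system.file("extdata", "fhr_instruments.csv", package = "fhrmr",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' One- and two-sample MR for a protein from the bundled instrument table
#'
#' Assembles the instruments of one protein from [fhr_instruments()] and
#' pools them with [mr_ivw()] against the chosen outcome association set.
#'
#' @param protein Protein label, e.g. `"FHR-3"`.
#' @param design `"one-sample"` (cohort case-control outcome) or
#'   `"two-sample"` (consortium outcome).
#' @return An `mr_result`.
#' @export
mr_from_instruments <- function(protein,
                                design = c("one-sample", "two-sample")) {
  design <- match.arg(design)
  ivs <- dplyr::filter(fhr_instruments(), .data$protein == !!protein)
  if (nrow(ivs) == 0) {
    rlang::abort(paste0("no instruments for ", protein),
                 class = "fhrmr_no_instrument")
  }
  instr <- tibble::tibble(
    variant_id = ivs$variant_id,
    cis_trans = ivs$cis_trans,
    bx = ivs$beta_exposure, sx = ivs$se_exposure,
    by = if (design == "one-sample") ivs$beta_cambridge else ivs$beta_iamdgc,
    sy = if (design == "one-sample") ivs$se_cambridge else ivs$se_iamdgc,
    p_exposure = ivs$p_exposure, n_exposure = ivs$n_exposure
  )
  instr$r2_iv <- iv_strength_r2(instr$p_exposure, instr$n_exposure)
  mr_ivw(instr, label = protein, design = design)
}
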