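# Case-control association of protein concentrations with disease.

# Normalising transformation per protein.
TRANSFORM_MAP <- c(
  "FH" = "sqrt", "FHR-2" = "sqrt", "FHR-3" = "sqrt", "FHR-4" = "sqrt",
  "FHL-1" = "log", "FHR-5" = "log", "FHR-1" = "identity"
)

#' Normalising transformation of a protein concentration
#'
#' Square root for FH, FHR-2, FHR-3 and FHR-4; natural log for FHL-1 and
#' FHR-5; identity for FHR-1 (already approximately normal). Vectorised over
#' both arguments.
#'
#' @param conc Concentration in nM (non-negative; strictly positive for the
#'   log-transformed proteins).
#' @param protein Protein label(s), see [fh_proteins()].
#' @return Transformed values; log of 0 yields `NA` with a warning.
#' @export
transform_concentration <- function(conc, protein) {
  protein <- as.character(protein)
  unknown <- setdiff(unique(protein), names(TRANSFORM_MAP))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown protein(s): ", paste(unknown, collapse = ", ")),
                 class = "fhrmr_unknown_protein")
  }
  kind <- TRANSFORM_MAP[protein]
  out <- conc
  out[kind == "sqrt"] <- sqrt(conc[kind == "sqrt"])
  is_log <- kind == "log"
  if (any(is_log & !is.na(conc) & conc <= 0)) {
    rlang::warn("log transform of non-positive concentration set to NA")
  }
  out[is_log] <- ifelse(conc[is_log] > 0, log(conc[is_log]), NA_real_)
  out
}

#' Inverse of [transform_concentration()]
#'
#' @param value Transformed values.
#' @param protein Protein label(s).
#' @return Concentrations on the nM scale.
#' @export
untransform_concentration <- function(value, protein) {
  kind <- TRANSFORM_MAP[as.character(protein)]
  out <- value
  out[kind == "sqrt"] <- value[kind == "sqrt"]^2
  out[kind == "log"] <- exp(value[kind == "log"])
  out
}

#' Join concentrations to phenotypes for analysis
#'
#' @param conc Long concentration tibble (`sample_id`, `protein`, `conc_nM`),
#'   e.g. from [quantify_srm()].
#' @param pheno Phenotype tibble (`sample_id`, `status` with values
#'   `"case"`/`"control"`, `sex`, `age`, `pc1`, `pc2`).
#' @return Long tibble with one row per sample x protein, adding the
#'   transformed concentration `conc_t`.
#' @export
prepare_analysis_data <- function(conc, pheno) {
  conc |>
    dplyr::inner_join(pheno, by = "sample_id") |>
    dplyr::mutate(conc_t = transform_concentration(.data$conc_nM, .data$protein))
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    rlang::abort(paste0("design matrix is rank deficient; collinear column(s): ",
                        paste(bad, collapse = ", ")),
                 class = "fhrmr_rank_deficient")
  }
  invisible(TRUE)
}

#' Linear case-control association of transformed concentrations
#'
#' Per protein, an ordinary least-squares regression of the transformed
#' concentration on case status with covariate adjustment; the reported beta,
#' classical SE and two-sided Wald p-value are those of the case-status term.
#' Missing concentrations are dropped per protein (complete case).
#'
#' @param data Long tibble from [prepare_analysis_data()].
#' @param covariates Covariate column names (default sex, age and two genetic
#'   principal components).
#' @return Tibble with `protein`, `beta`, `se`, `p`, `n_used`.
#' @export
assoc_linear <- function(data, covariates = c("sex", "age", "pc1", "pc2")) {
  data |>
    dplyr::group_by(.data$protein) |>
    dplyr::group_modify(function(d, key) {
      d <- d[stats::complete.cases(d[c("conc_t", "status", covariates)]), ]
      X <- cbind(`(Intercept)` = 1,
                 status = as.numeric(d$status == "case"),
                 as.matrix(d[covariates]))
      if (nrow(d) <= ncol(X)) {
        rlang::abort("fewer observations than model parameters",
                     class = "fhrmr_underdetermined")
      }
      check_full_rank(X)
      fit <- ols_fit(X, d$conc_t)
      tibble::tibble(beta = fit$beta[["status"]], se = fit$se[["status"]],
                     p = fit$p[["status"]], n_used = nrow(d))
    }) |>
    dplyr::ungroup()
}

# Plain QR least squares with classical SEs; the workhorse behind
# assoc_linear and gwas_scan.
ols_fit <- function(X, y) {
  qrx <- qr(X)
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  list(beta = beta, se = se, p = p, df = df, sigma2 = sigma2, residuals = res)
}

#' Odds ratio of disease per SD of log concentration
#'
#' Per protein: log-transform the concentration, standardise by the sample SD
#' of the analysis sample (cases and controls pooled), and fit a logistic
#' regression of case status on the standardised value with covariate
#' adjustment. Reported as OR per 1 SD with a 95% Wald CI.
#'
#' @inheritParams assoc_linear
#' @return Tibble with `protein`, `beta` (log-OR per SD), `se`, `p`,
#'   `or_per_sd`, `or_lo`, `or_hi`, `n_used`.
#' @export
assoc_logistic_or <- function(data, covariates = c("sex", "age", "pc1", "pc2")) {
  data |>
    dplyr::group_by(.data$protein) |>
    dplyr::group_modify(function(d, key) {
      d <- d[stats::complete.cases(d[c("conc_nM", "status", covariates)]), ]
      d <- d[d$conc_nM > 0, ]
      if (length(unique(d$status)) < 2) {
        rlang::abort("both cases and controls are required",
                     class = "fhrmr_one_class")
      }
      z <- log(d$conc_nM)
      z <- z / stats::sd(z)
      f <- stats::as.formula(paste(
        c("y ~ z", covariates), collapse = " + "))
      dd <- cbind(data.frame(y = as.numeric(d$status == "case"), z = z),
                  d[covariates])
      fit <- stats::glm(f, family = stats::binomial(), data = dd)
      if (!fit$converged || any(abs(stats::coef(fit)) > 20)) {
        rlang::abort(paste0("logistic fit did not converge (possible perfect ",
                            "separation) for ", key$protein),
                     class = "fhrmr_nonconvergence")
      }
      sm <- summary(fit)$coefficients
      tibble::tibble(
        beta = sm["z", "Estimate"], se = sm["z", "Std. Error"],
        p = sm["z", "Pr(>|z|)"],
        or_per_sd = exp(sm["z", "Estimate"]),
        or_lo = exp(sm["z", "Estimate"] - 1.96 * sm["z", "Std. Error"]),
        or_hi = exp(sm["z", "Estimate"] + 1.96 * sm["z", "Std. Error"]),
        n_used = nrow(d)
      )
    }) |>
    dplyr::ungroup()
}

#' Pairwise Pearson correlations between protein concentrations
#'
#' Pairwise-complete Pearson correlation matrix of the (untransformed)
#' concentrations, conventionally computed in controls only.
#'
#' @param data Long tibble (`sample_id`, `protein`, `conc_nM`), typically
#'   filtered to controls.
#' @return A symmetric correlation matrix with unit diagonal; zero-variance
#'   proteins give `NA` entries with a warning.
#' @export
protein_correlations <- function(data) {
  wide <- data |>
    dplyr::select(dplyr::all_of(c("sample_id", "protein", "conc_nM"))) |>
    tidyr::pivot_wider(names_from = "protein", values_from = "conc_nM")
  m <- as.matrix(wide[-1])
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    rlang::warn(paste0("zero-variance protein(s): ",
                       paste(colnames(m)[which(sds == 0)], collapse = ", ")))
  }
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
}

#' Per-group concentration summaries
#'
#' Mean concentration with a normal-theory 95% CI (mean +/- 1.96 SE) per
#' protein per status group, on the nM scale.
#'
#' @param data Long tibble with `protein`, `status` and `conc_nM`.
#' @return Tibble with `protein`, `status`, `n`, `mean_nM`, `ci_lo`, `ci_hi`.
#' @export
cohort_summary <- function(data) {
  out <- data |>
    dplyr::filter(!is.na(.data$conc_nM)) |>
    dplyr::group_by(.data$protein, .data$status) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_nM = mean(.data$conc_nM),
      se = stats::sd(.data$conc_nM) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  if (any(out$n < 2)) {
    rlang::abort("need at least 2 observations per group",
                 class = "fhrmr_group_too_small")
  }
  out |>
    dplyr::mutate(ci_lo = .data$mean_nM - 1.96 * .data$se,
                  ci_hi = .data$mean_nM + 1.96 * .data$se) |>
    dplyr::select(-"se")
}
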