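# SRM quantitation: transition report -> plasma protein concentrations (nM).

#' Read a transition-report CSV
#'
#' Reads the exported transition peak-area table. Expected columns:
#' `sample_id`, `batch`, `peptide` (protein label), `transition_id`,
#' `isotope` (`"light"` or `"heavy"`), `area`, `rt_min`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per sample x peptide x transition x isotope.
#' @export
read_transition_report <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      batch = readr::col_character(),
      peptide = readr::col_character(),
      transition_id = readr::col_character(),
      isotope = readr::col_character(),
      area = readr::col_double(),
      rt_min = readr::col_double()
    )
  )
}

# Long (light/heavy rows) -> one row per sample x peptide x transition with
# light_area / heavy_area columns.
pair_transitions <- function(transitions) {
  stopifnot(all(c("sample_id", "peptide", "transition_id", "isotope", "area")
                %in% names(transitions)))
  if (!"batch" %in% names(transitions)) transitions$batch <- "1"
  bad <- setdiff(unique(transitions$isotope), c("light", "heavy"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown isotope label(s): ", paste(bad, collapse = ", ")),
                 class = "fhrmr_bad_isotope")
  }
  transitions |>
    dplyr::select(dplyr::all_of(c("sample_id", "batch", "peptide",
                                  "transition_id", "isotope", "area"))) |>
    tidyr::pivot_wider(names_from = "isotope", values_from = "area",
                       names_glue = "{isotope}_area")
}

#' Endogenous concentration from a light/heavy peak-area pair
#'
#' Single-point stable-isotope-dilution quantitation: the endogenous (light)
#' concentration is the light/heavy peak-area ratio times the known
#' plasma-equivalent spike concentration of the heavy standard.
#'
#' @param light_area,heavy_area Peak areas (arbitrary intensity units).
#' @param spike_nM Plasma-equivalent heavy-standard concentration (nM).
#' @return Concentration in nM; `NA` where `heavy_area` is 0 (missing
#'   standard — flagged, never silently zero).
#' @export
quantify_endogenous <- function(light_area, heavy_area, spike_nM) {
  out <- light_area / heavy_area * spike_nM
  out[heavy_area <= 0] <- NA_real_
  out
}

#' Qualifier-transition concordance
#'
#' Checks that each qualifier transition's light/heavy ratio lies within a
#' relative tolerance of the quantifier's ratio, confirming peptide
#' specificity.
#'
#' @param quant_ratio Quantifier light/heavy ratio (length 1).
#' @param qual_ratios Numeric vector of qualifier ratios (length 2).
#' @param rel_tolerance Maximum allowed relative deviation (default 0.3).
#' @return `TRUE` if every qualifier agrees with the quantifier.
#' @export
check_qualifiers <- function(quant_ratio, qual_ratios, rel_tolerance = 0.3) {
  if (length(quant_ratio) != 1 || length(qual_ratios) != 2) {
    rlang::abort("expected one quantifier and two qualifier ratios",
                 class = "fhrmr_malformed_transition_set")
  }
  if (!is.finite(quant_ratio) || quant_ratio == 0) {
    return(NA)
  }
  all(abs(qual_ratios - quant_ratio) / abs(quant_ratio) <= rel_tolerance)
}

#' Quantify plasma protein concentrations from SRM transition areas
#'
#' The full quantitation step: per batch and peptide the transition with the
#' largest mean heavy-standard area becomes the quantifier; the endogenous
#' concentration is the quantifier's light/heavy ratio times the
#' plasma-equivalent spike concentration; the two remaining transitions act
#' as qualifiers whose ratios must agree with the quantifier within
#' `qualifier_tol`; concentrations below the assay LLOQ are retained but
#' flagged.
#'
#' @param transitions Tibble as from [read_transition_report()] or
#'   [simulate_srm_peaks()].
#' @param peptides Peptide standards, see [fh_peptides()].
#' @param scheme A [spike_scheme()].
#' @param lloq LLOQ table, see [lloq_table()].
#' @param qualifier_tol Relative tolerance for qualifier concordance.
#' @return Tibble with columns `sample_id`, `batch`, `protein`, `conc_nM`,
#'   `below_lloq`, `qualifier_concordant`, `flag` (`"ok"`,
#'   `"missing_standard"`).
#' @examples
#' sim <- simulate_cohort(sim_config(n_cases = 5, n_controls = 5, seed = 1))
#' quantify_srm(sim$transitions)
#' @export
quantify_srm <- function(transitions, peptides = fh_peptides(),
                         scheme = spike_scheme(), lloq = lloq_table(),
                         qualifier_tol = 0.3) {
  spikes <- spike_concentration(peptides, scheme) |>
    dplyr::select(protein = "protein", "spike_nM")
  paired <- pair_transitions(transitions)

  n_tr <- paired |>
    dplyr::count(.data$sample_id, .data$batch, .data$peptide)
  if (any(n_tr$n != 3)) {
    rlang::abort("each sample x peptide must have exactly 3 transitions",
                 class = "fhrmr_malformed_transition_set")
  }

  # quantifier: largest mean heavy area per peptide per batch
  paired <- paired |>
    dplyr::group_by(.data$batch, .data$peptide, .data$transition_id) |>
    dplyr::mutate(mean_heavy = mean(.data$heavy_area)) |>
    dplyr::group_by(.data$batch, .data$peptide) |>
    dplyr::mutate(role = dplyr::if_else(
      .data$mean_heavy == max(.data$mean_heavy), "quantifier", "qualifier")) |>
    dplyr::group_by(.data$batch, .data$peptide, .data$sample_id) |>
    # guard against ties: keep the first quantifier by transition_id
    dplyr::mutate(role = dplyr::if_else(
      .data$role == "quantifier" &
        cumsum(.data$role == "quantifier") > 1, "qualifier", .data$role)) |>
    dplyr::ungroup() |>
    dplyr::mutate(ratio = dplyr::if_else(.data$heavy_area > 0,
                                         .data$light_area / .data$heavy_area,
                                         NA_real_))

  quant <- paired |>
    dplyr::group_by(.data$sample_id, .data$batch, protein = .data$peptide) |>
    dplyr::summarise(
      quant_ratio = .data$ratio[.data$role == "quantifier"][1],
      qualifier_concordant = check_qualifiers(
        .data$ratio[.data$role == "quantifier"][1],
        .data$ratio[.data$role == "qualifier"],
        rel_tolerance = qualifier_tol),
      missing_standard = anyNA(.data$ratio),
      .groups = "drop"
    ) |>
    dplyr::left_join(spikes, by = "protein") |>
    dplyr::left_join(lloq, by = "protein") |>
    dplyr::mutate(
      conc_nM = .data$quant_ratio * .data$spike_nM,
      below_lloq = .data$conc_nM < .data$lloq_nM,
      flag = dplyr::if_else(.data$missing_standard, "missing_standard", "ok")
    ) |>
    dplyr::select(dplyr::all_of(c("sample_id", "batch", "protein", "conc_nM",
                                  "below_lloq", "qualifier_concordant", "flag")))
  quant
}

#' Coefficient of variation, percent
#'
#' Sample SD over mean, times 100. `NA` (with a warning) when the mean is 0
#' or fewer than two replicates are given.
#'
#' @param x Numeric vector of replicate measurements.
#' @return %CV as a single number.
#' @export
cv_percent <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    rlang::warn("need at least 2 replicates for %CV")
    return(NA_real_)
  }
  m <- mean(x)
  if (m == 0) {
    rlang::warn("%CV undefined for zero mean")
    return(NA_real_)
  }
  stats::sd(x) / m * 100
}

#' Batch quality control: replicate %CV per protein
#'
#' Computes the %CV across replicate measurements of the same sample within
#' each batch, per protein; the standard reproducibility summary for repeated
#' QC samples run alongside each batch.
#'
#' @param quant Output of [quantify_srm()].
#' @param qc_samples Optional character vector restricting the summary to
#'   designated QC sample ids.
#' @return Tibble with `batch`, `protein`, `n`, `cv_percent`.
#' @export
srm_batch_cv <- function(quant, qc_samples = NULL) {
  if (!is.null(qc_samples)) {
    quant <- dplyr::filter(quant, .data$sample_id %in% qc_samples)
  }
  quant |>
    dplyr::group_by(.data$batch, .data$protein) |>
    dplyr::summarise(
      n = sum(!is.na(.data$conc_nM)),
      cv_percent = suppressWarnings(cv_percent(.data$conc_nM)),
      .groups = "drop"
    )
}

#' Flag concentrations below the LLOQ
#'
#' @param quant Tibble with `protein` and `conc_nM` columns.
#' @param lloq LLOQ table, see [lloq_table()]. A concentration equal to the
#'   LLOQ counts as quantifiable.
#' @return Input with a logical `below_lloq` column (values retained, never
#'   imputed).
#' @export
apply_lloq <- function(quant, lloq = lloq_table()) {
  unknown <- setdiff(unique(quant$protein), lloq$protein)
  if (length(unknown) > 0) {
    rlang::abort(paste0("no LLOQ defined for protein(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "fhrmr_unknown_protein")
  }
  quant |>
    dplyr::left_join(lloq, by = "protein") |>
    dplyr::mutate(below_lloq = .data$conc_nM < .data$lloq_nM) |>
    dplyr::select(-"lloq_nM")
}
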