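# Peptide standards: monoisotopic masses and spike-concentration bookkeeping.

# Monoisotopic residue masses (Da), i.e. amino-acid masses minus water.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER <- 18.010565

#' Mass of a carbamidomethyl cysteine adduct
#'
#' Monoisotopic mass added to each cysteine by iodoacetamide alkylation
#' (carbamidomethylation), in Da.
#' @export
CARBAMIDOMETHYL <- 57.02146

#' Heavy-label mass shifts
#'
#' Monoisotopic mass increases for fully 13C/15N-labelled residues used in
#' stable-isotope standard (SIS) peptides: K(+8), R(+10), F(+10) and Y(+10).
#' @export
HEAVY_SHIFTS <- c(K = 8.01420, R = 10.00827, F = 10.02728, Y = 10.02728)

#' Monoisotopic peptide mass
#'
#' Sums monoisotopic residue masses plus one water, an optional heavy-isotope
#' label shift, and a fixed modification on every cysteine (carbamidomethyl by
#' default, reflecting iodoacetamide alkylation during sample preparation).
#'
#' @param sequence Character vector of peptide sequences in one-letter code
#'   (the 20 canonical residues; case-insensitive).
#' @param heavy_shift Numeric mass shift (Da) of the isotope label, one value
#'   per peptide (recycled). Use 0 for a light peptide.
#' @param cys_mod Mass (Da) added to every cysteine; default
#'   [CARBAMIDOMETHYL].
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' peptide_mass("VTYKCFE", heavy_shift = HEAVY_SHIFTS["K"])
#' @export
peptide_mass <- function(sequence, heavy_shift = 0, cys_mod = CARBAMIDOMETHYL) {
  sequence <- toupper(sequence)
  heavy_shift <- rep_len(heavy_shift, length(sequence))
  purrr::map2_dbl(sequence, heavy_shift, function(seq, shift) {
    aa <- strsplit(seq, "")[[1]]
    bad <- setdiff(aa, names(AA_MONO))
    if (length(bad) > 0) {
      rlang::abort(
        paste0("invalid residue letter(s) in sequence '", seq, "': ",
               paste(unique(bad), collapse = ", ")),
        class = "fhrmr_invalid_sequence"
      )
    }
    sum(AA_MONO[aa]) + MASS_WATER + shift + sum(aa == "C") * cys_mod
  })
}

#' Default SIS peptide standards for the FH protein family
#'
#' The Glu-C proteotypic peptides used to quantify FH, FHL-1 and FHR-1 through
#' FHR-5, with the labelled residue, its heavy mass shift and the stock
#' concentration of each peptide in the concentrated standard mixture.
#'
#' @return A tibble with columns `protein`, `sequence`, `heavy_residue`
#'   (1-based position of the labelled residue), `heavy_shift` (Da) and
#'   `stock_ng_ul` (ng/uL in the concentrated mix).
#' @export
fh_peptides <- function() {
  tibble::tribble(
    ~protein, ~sequence,              ~heavy_residue, ~heavy_shift,      ~stock_ng_ul,
    "FH",     "VTYKCFE",              4L,             HEAVY_SHIFTS[["K"]], 47.6,
    "FHL-1",  "NGWSPTPRCIRVSFTL",     8L,             HEAVY_SHIFTS[["R"]], 0.95,
    "FHR-1",  "ATFCDFPKINHGILYDEE",   6L,             HEAVY_SHIFTS[["F"]], 7.14,
    "FHR-2",  "AMFCDFPKINHGILYDEE",   6L,             HEAVY_SHIFTS[["F"]], 19,
    "FHR-3",  "VACHPGYGLPKAQTTVTCTE", 11L,            HEAVY_SHIFTS[["K"]], 4.76,
    "FHR-4",  "YQCQSYYE",             1L,             HEAVY_SHIFTS[["Y"]], 4.76,
    "FHR-5",  "RGWSTPPICSFTKGE",      1L,             HEAVY_SHIFTS[["R"]], 4.76
  )
}

#' Protein names quantified by the assay
#' @return Character vector of the seven protein labels.
#' @export
fh_proteins <- function() fh_peptides()$protein

#' Spike / dilution scheme
#'
#' Volumes describing how the concentrated standard mixture is diluted and
#' spiked into each plasma digest. The dilution factor is
#' `(aliquot_ul + diluent_ul) / aliquot_ul`.
#'
#' @param aliquot_ul Volume of concentrated standard mix diluted (uL).
#' @param diluent_ul Diluent volume added to the aliquot (uL).
#' @param spike_ul Volume of diluted standard spiked into each digest (uL).
#' @param plasma_ul Plasma volume per digest (uL).
#' @param injected_plasma_equiv_ul Plasma equivalent per injection (uL);
#'   carried as metadata (ratio-based quantitation cancels injection volume).
#' @return A list of class `spike_scheme`.
#' @export
spike_scheme <- function(aliquot_ul = 5, diluent_ul = 195, spike_ul = 2,
                         plasma_ul = 5, injected_plasma_equiv_ul = 0.4) {
  vols <- c(aliquot_ul = aliquot_ul, diluent_ul = diluent_ul,
            spike_ul = spike_ul, plasma_ul = plasma_ul,
            injected_plasma_equiv_ul = injected_plasma_equiv_ul)
  if (any(!is.finite(vols)) || any(vols <= 0)) {
    rlang::abort("all spike-scheme volumes must be finite and > 0",
                 class = "fhrmr_bad_scheme")
  }
  structure(as.list(vols), class = "spike_scheme")
}

#' @export
print.spike_scheme <- function(x, ...) {
  cat("Spike scheme: ", x$aliquot_ul, " uL mix + ", x$diluent_ul,
      " uL diluent (", dilution_factor(x), "x); ", x$spike_ul,
      " uL spiked per ", x$plasma_ul, " uL plasma\n", sep = "")
  invisible(x)
}

dilution_factor <- function(scheme) {
  (scheme$aliquot_ul + scheme$diluent_ul) / scheme$aliquot_ul
}

#' Plasma-equivalent spike concentrations of the SIS standards
#'
#' Converts each peptide's stock concentration through the dilution and spike
#' scheme into the nominal plasma-equivalent concentration of heavy standard,
#' in nM: the diluted stock (ng/uL) times `spike_ul / plasma_ul` gives ug/L in
#' plasma equivalents, which divided by the heavy peptide's molar mass (g/mol)
#' gives umol/L, i.e. 1000x nM.
#'
#' @param peptides Tibble as returned by [fh_peptides()].
#' @param scheme A [spike_scheme()].
#' @param cys_mod Cysteine fixed-modification mass (Da).
#' @return The input tibble with added columns `mass_da` and `spike_nM`.
#' @examples
#' spike_concentration(fh_peptides(), spike_scheme())
#' @export
spike_concentration <- function(peptides, scheme = spike_scheme(),
                                cys_mod = CARBAMIDOMETHYL) {
  stopifnot(inherits(scheme, "spike_scheme"))
  peptides |>
    dplyr::mutate(
      mass_da = peptide_mass(.data$sequence, .data$heavy_shift, cys_mod = cys_mod),
      # ng/uL = mg/L; after dilution and spike, concentration in plasma
      # equivalents is stock/dilution * spike/plasma mg/L = g/m^3;
      # nM = (g/L) / (g/mol) * 1e9
      spike_nM = .data$stock_ng_ul / dilution_factor(scheme) *
        scheme$spike_ul / scheme$plasma_ul * 1e-3 / .data$mass_da * 1e9
    )
}

#' Lower limits of quantitation
#'
#' Assay LLOQs on the plasma-concentration scale. Concentrations equal to the
#' LLOQ count as quantifiable.
#'
#' @return Tibble with columns `protein` and `lloq_nM`.
#' @export
lloq_table <- function() {
  tibble::tibble(
    protein = fh_proteins(),
    lloq_nM = c(25, 0.25, 2, 1, 1, 4, 3)
  )
}

#' Read a quantitation configuration file
#'
#' Reads a YAML file describing the peptide standards, spike scheme, LLOQ
#' table and qualifier tolerance. Any omitted component falls back to the
#' package defaults.
#'
#' @param path Path to a YAML file with optional keys `peptides` (list of
#'   records with `protein`, `sequence`, `heavy_residue`, `heavy_shift`,
#'   `stock_ng_ul`), `scheme` (volumes as in [spike_scheme()]), `lloq`
#'   (protein -> nM map) and `qualifier_tolerance`.
#' @return A list with elements `peptides`, `scheme`, `lloq`,
#'   `qualifier_tolerance`.
#' @export
read_quant_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  peptides <- if (!is.null(cfg$peptides)) {
    dplyr::bind_rows(lapply(cfg$peptides, tibble::as_tibble))
  } else {
    fh_peptides()
  }
  scheme <- if (!is.null(cfg$scheme)) do.call(spike_scheme, cfg$scheme) else spike_scheme()
  lloq <- if (!is.null(cfg$lloq)) {
    tibble::tibble(protein = names(cfg$lloq), lloq_nM = unlist(cfg$lloq, use.names = FALSE))
  } else {
    lloq_table()
  }
  list(
    peptides = peptides,
    scheme = scheme,
    lloq = lloq,
    qualifier_tolerance = cfg$qualifier_tolerance %||% 0.3
  )
}
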