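# Linkage disequilibrium: haplotype-frequency EM, D', r2, and p-value clumping.

#' LD measures from haplotype frequencies
#'
#' Given the frequency of the AB haplotype and the two allele frequencies,
#' computes D = pAB - pA pB, D' = |D| / Dmax and r2 = D^2 / (pA pa pB pb).
#'
#' @param p_ab Frequency of the haplotype carrying allele A at the first
#'   locus and allele B at the second.
#' @param p_a,p_b Allele frequencies at the two loci.
#' @return Tibble with `d`, `dprime`, `r2`.
#' @export
ld_from_haplotypes <- function(p_ab, p_a, p_b) {
  d <- p_ab - p_a * p_b
  dmax <- ifelse(d >= 0,
                 pmin(p_a * (1 - p_b), (1 - p_a) * p_b),
                 pmin(p_a * p_b, (1 - p_a) * (1 - p_b)))
  denom <- p_a * (1 - p_a) * p_b * (1 - p_b)
  tibble::tibble(
    d = d,
    dprime = ifelse(dmax > 0, abs(d) / dmax, NA_real_),
    r2 = ifelse(denom > 0, d^2 / denom, NA_real_)
  )
}

# EM estimate of the AB haplotype frequency from unphased biallelic
# genotypes. Only the double heterozygote is phase-ambiguous; iterate the
# standard expectation step starting from linkage equilibrium.
em_haplotype_freq <- function(ga, gb, max_iter = 50, tol = 1e-10) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- round(ga[ok]); gb <- round(gb[ok])
  n <- length(ga)
  p_a <- mean(ga) / 2
  p_b <- mean(gb) / 2
  # AB haplotype counts that are certain from each genotype combination:
  #   ga=2: every B allele travels with an A -> gb AB haplotypes
  #   ga=1, gb=2: exactly one AB (the other B sits on the a haplotype)
  #   ga=1, gb=1: phase-ambiguous (AB/ab vs Ab/aB)
  n_dh <- sum(ga == 1 & gb == 1)
  known_ab <- sum((ga == 2) * gb) + sum(ga == 1 & gb == 2)
  p_ab <- p_a * p_b
  for (i in seq_len(max_iter)) {
    # E step: expected share of AB/ab resolutions among double heterozygotes
    p_Ab <- p_a - p_ab
    p_aB <- p_b - p_ab
    p_ab_low <- 1 - p_a - p_b + p_ab
    den <- p_ab * p_ab_low + p_Ab * p_aB
    e_dh <- if (den > 0) p_ab * p_ab_low / den else 0.5
    p_ab_new <- (known_ab + n_dh * e_dh) / (2 * n)
    converged <- abs(p_ab_new - p_ab) < tol
    p_ab <- p_ab_new
    if (converged) break
  }
  list(p_ab = p_ab, p_a = p_a, p_b = p_b)
}

#' Pairwise LD between two variants
#'
#' Estimates haplotype frequencies from unphased genotype (or rounded
#' dosage) vectors by EM over the double-heterozygote ambiguity, then
#' returns D, D' and r2. When phase is unambiguous the r2 equals the squared
#' Pearson correlation of the dosages.
#'
#' @param ga,gb Genotype vectors coded 0/1/2 (dosages are rounded).
#' @return Tibble with `d`, `dprime`, `r2`; monomorphic input yields `NA`
#'   values with a warning.
#' @export
ld_stats <- function(ga, gb) {
  if (stats::var(ga, na.rm = TRUE) == 0 || stats::var(gb, na.rm = TRUE) == 0) {
    rlang::warn("monomorphic variant: LD undefined")
    return(tibble::tibble(d = NA_real_, dprime = NA_real_, r2 = NA_real_))
  }
  est <- em_haplotype_freq(ga, gb)
  ld_from_haplotypes(est$p_ab, est$p_a, est$p_b)
}

#' Pairwise dosage-correlation LD matrix
#'
#' Squared Pearson correlation of dosages for every variant pair — the
#' standard composite LD estimate used as the clumping reference.
#'
#' @param geno A [geno_data()] object.
#' @return A variants x variants matrix of r2 values with dimnames set to
#'   the variant ids.
#' @export
ld_matrix <- function(geno) {
  stopifnot(inherits(geno, "geno_data"))
  suppressWarnings(stats::cor(geno$dosages))^2
}

#' Greedy p-value clumping
#'
#' Selects index variants by repeatedly taking the remaining variant with
#' the smallest p-value below `p_threshold` and discarding every variant in
#' LD with it at `r2 >= r2_cutoff`. Ties on p are broken by genomic position
#' then variant id. Variant pairs absent from the LD source are treated as
#' independent (with a message).
#'
#' @param stats Summary-statistics tibble with `variant_id`, `p` and
#'   (optionally, for tie-breaking) `chrom`, `pos`.
#' @param ld LD matrix with variant-id dimnames, e.g. from [ld_matrix()],
#'   or `NULL` to treat all variants as independent.
#' @param p_threshold Significance threshold for index variants (default
#'   genome-wide, 5e-8).
#' @param r2_cutoff LD cut-off above which a variant is assigned to an
#'   index variant's clump (0.001 or 0.01 in typical use).
#' @return The rows of `stats` retained as index variants, in selection
#'   order.
#' @export
clump <- function(stats, ld = NULL, p_threshold = 5e-8, r2_cutoff = 0.001) {
  cand <- dplyr::filter(stats, .data$p < p_threshold)
  if (nrow(cand) == 0) return(cand)
  ord <- order(cand$p,
               if ("pos" %in% names(cand)) cand$pos else seq_len(nrow(cand)),
               cand$variant_id)
  cand <- cand[ord, ]
  missing_reported <- FALSE
  keep <- character()
  remaining <- cand$variant_id
  while (length(remaining) > 0) {
    idx <- remaining[1]
    keep <- c(keep, idx)
    if (is.null(ld)) {
      r2 <- stats::setNames(rep(0, length(remaining)), remaining)
    } else {
      r2 <- stats::setNames(rep(NA_real_, length(remaining)), remaining)
      in_ld <- intersect(remaining, rownames(ld))
      if (idx %in% rownames(ld)) r2[in_ld] <- ld[idx, in_ld]
      if (anyNA(r2) && !missing_reported) {
        rlang::inform("clump: missing LD for some pairs; treated as independent")
        missing_reported <- TRUE
      }
      r2[is.na(r2)] <- 0
    }
    remaining <- remaining[!(remaining == idx | r2[remaining] >= r2_cutoff)]
  }
  cand[match(keep, cand$variant_id), ]
}
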