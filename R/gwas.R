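# Per-variant pQTL association scans on genotype dosages.

#' Genotype container
#'
#' Bundles a per-variant metadata tibble with the samples x variants dosage
#' matrix.
#'
#' @param variants Tibble with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf`, `imputation_r2`, `genotyped`.
#' @param dosages Numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids), values in \[0, 2\]
#'   counting the effect (minor) allele.
#' @return An object of class `geno_data`.
#' @export
geno_data <- function(variants, dosages) {
  stopifnot(is.matrix(dosages), nrow(variants) == ncol(dosages),
            identical(variants$variant_id, colnames(dosages)))
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
    rlang::abort("dosages must lie in [0, 2]", class = "fhrmr_bad_dosage")
  }
  structure(list(variants = tibble::as_tibble(variants), dosages = dosages),
            class = "geno_data")
}

#' @export
print.geno_data <- function(x, ...) {
  cat("geno_data:", nrow(x$dosages), "samples x", ncol(x$dosages), "variants\n")
  print(utils::head(x$variants, 3))
  invisible(x)
}

#' Read dosages from a VCF
#'
#' Extracts per-sample dosages from the `DS` FORMAT field, falling back to
#' counting alternate alleles in `GT` where `DS` is absent. Per-variant MAF is
#' taken from the `MAF` INFO key when present, otherwise computed from the
#' dosages; imputation quality from the `R2` or `DR2` INFO key (1 for
#' genotyped variants, i.e. those without the key or flagged `TYPED`).
#' Dosages are oriented to count the minor allele.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @return A [geno_data()] object.
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  fmt <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (is.null(fmt) || all(is.na(fmt))) fmt <- NULL
  if (is.null(fmt)) {
    gt <- vcfR::extract.gt(v, element = "GT")
    fmt <- apply(gt, 2, function(col) {
      vapply(strsplit(gsub("\\|", "/", col), "/"), function(a) {
        sum(a == "1")
      }, numeric(1))
    })
    if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = nrow(gt), dimnames = dimnames(gt))
  }
  dos <- t(fmt)  # samples x variants
  alt_freq <- colMeans(dos, na.rm = TRUE) / 2
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key, as.numeric = TRUE)
    if (is.null(val)) rep(NA_real_, nrow(fix)) else val
  }
  maf <- info_field("MAF")
  maf[is.na(maf)] <- pmin(alt_freq, 1 - alt_freq)[is.na(maf)]
  r2 <- info_field("R2")
  dr2 <- info_field("DR2")
  r2[is.na(r2)] <- dr2[is.na(r2)]
  typed <- grepl("TYPED", vcfR::getINFO(v))
  genotyped <- typed | is.na(r2)
  r2[is.na(r2)] <- 1
  # orient dosages to count the minor allele
  flip <- alt_freq > 0.5
  dos[, flip] <- 2 - dos[, flip]
  variants <- tibble::tibble(
    variant_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, maf = maf, imputation_r2 = r2,
    genotyped = genotyped
  )
  colnames(dos) <- variants$variant_id
  geno_data(variants, dos)
}

#' Variant quality filters
#'
#' Keeps variants with minor-allele frequency of at least `maf_min` and, for
#' imputed variants, imputation quality of at least `r2_min`; both boundaries
#' inclusive. The counts removed per criterion are reported as a message.
#'
#' @param geno A [geno_data()] object or a variants tibble.
#' @param maf_min MAF threshold (default 0.01).
#' @param r2_min Imputation-quality threshold for imputed variants
#'   (default 0.3).
#' @return The input with only the retained variants.
#' @export
filter_variants <- function(geno, maf_min = 0.01, r2_min = 0.3) {
  variants <- if (inherits(geno, "geno_data")) geno$variants else geno
  keep_maf <- variants$maf >= maf_min
  keep_r2 <- variants$genotyped | variants$imputation_r2 >= r2_min
  rlang::inform(paste0("filter_variants: removed ", sum(!keep_maf),
                       " by MAF < ", maf_min, ", ", sum(keep_maf & !keep_r2),
                       " by imputation R2 < ", r2_min))
  keep <- keep_maf & keep_r2
  if (inherits(geno, "geno_data")) {
    geno_data(variants[keep, ], geno$dosages[, keep, drop = FALSE])
  } else {
    variants[keep, ]
  }
}

#' Per-variant association scan of a transformed protein trait
#'
#' One covariate-adjusted ordinary least-squares fit per variant with the
#' dosage as predictor and a two-sided Wald test on the dosage term,
#' vectorised across variants by residualising the trait and the dosages on
#' the covariates (Frisch-Waugh), with degrees of freedom matching the full
#' per-variant model. Monomorphic variants are skipped with a message.
#'
#' @param geno A [geno_data()] object (already filtered, see
#'   [filter_variants()]).
#' @param pheno Phenotype tibble with `sample_id` and covariate columns,
#'   rows matching the dosage matrix samples.
#' @param trait Numeric vector of transformed trait values aligned with
#'   `pheno` rows (see [transform_concentration()]).
#' @param covariates Covariate column names; `NULL` for an intercept-only
#'   adjustment.
#' @return Tibble with one row per tested variant: `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `maf`, `beta`, `se`, `p`, `n`.
#' @export
gwas_scan <- function(geno, pheno, trait,
                      covariates = c("sex", "age", "pc1", "pc2")) {
  stopifnot(inherits(geno, "geno_data"))
  G <- geno$dosages
  stopifnot(length(trait) == nrow(G))
  ok <- stats::complete.cases(trait) &
    (if (is.null(covariates)) TRUE else stats::complete.cases(pheno[covariates]))
  G <- G[ok, , drop = FALSE]
  y <- trait[ok]
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates) && length(covariates) > 0)
               as.matrix(pheno[ok, covariates]))
  check_full_rank(X)

  mono <- apply(G, 2, function(g) stats::var(g) == 0)
  if (any(mono)) {
    rlang::inform(paste0("gwas_scan: skipping ", sum(mono),
                         " monomorphic variant(s)"))
  }
  qrx <- qr(X)
  yr <- stats::lm.fit(X, y)$residuals
  Gr <- G - X %*% qr.coef(qrx, G)
  gg <- unname(colSums(Gr^2))
  beta <- as.vector(crossprod(Gr, yr)) / gg
  df <- n - ncol(X) - 1
  rss <- sum(yr^2) - beta^2 * gg
  se <- sqrt(rss / df / gg)
  p <- 2 * stats::pt(-abs(beta / se), df)
  beta <- unname(beta); se <- unname(se); p <- unname(p)
  out <- geno$variants |>
    dplyr::mutate(
      effect_allele = .data$alt, other_allele = .data$ref,
      beta = beta, se = se, p = p, n = n
    ) |>
    dplyr::select(dplyr::all_of(c("variant_id", "chrom", "pos",
                                  "effect_allele", "other_allele", "maf",
                                  "beta", "se", "p", "n")))
  out[!mono, ]
}

#' Per-variant logistic case-control scan
#'
#' Logistic regression of case status on each variant's dosage with covariate
#' adjustment, giving outcome associations on the log-odds scale (e.g. the
#' outcome arm of a one-sample Mendelian randomization analysis).
#'
#' @inheritParams gwas_scan
#' @param status Character or factor vector (`"case"`/`"control"`) aligned
#'   with the dosage matrix samples.
#' @param variant_ids Optional subset of variants to test (e.g. the clumped
#'   instruments); defaults to all.
#' @return Tibble like [gwas_scan()] with `beta` on the log-OR scale.
#' @export
gwas_scan_logistic <- function(geno, pheno, status,
                               covariates = c("sex", "age", "pc1", "pc2"),
                               variant_ids = NULL) {
  stopifnot(inherits(geno, "geno_data"))
  ids <- variant_ids %||% geno$variants$variant_id
  y <- as.numeric(status == "case")
  Xc <- if (is.null(covariates)) NULL else as.matrix(pheno[covariates])
  purrr::map_dfr(ids, function(id) {
    g <- geno$dosages[, id]
    dat <- data.frame(y = y, g = g)
    if (!is.null(Xc)) dat <- cbind(dat, Xc)
    fit <- suppressWarnings(
      stats::glm(y ~ ., family = stats::binomial(), data = dat))
    sm <- summary(fit)$coefficients
    meta <- geno$variants[geno$variants$variant_id == id, ]
    tibble::tibble(
      variant_id = id, chrom = meta$chrom, pos = meta$pos,
      effect_allele = meta$alt, other_allele = meta$ref, maf = meta$maf,
      beta = sm["g", "Estimate"], se = sm["g", "Std. Error"],
      p = sm["g", "Pr(>|z|)"], n = length(y)
    )
  })
}
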