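# Independent closed-form oracles used across the suite.

# OLS via the normal equations (never the QR path the package uses).
oracle_ols <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(beta = beta, se = sqrt(diag(xtx_inv) * sigma2))
}

# Fixed-effect IVW as weighted least squares of by on bx through the origin.
oracle_ivw_wls <- function(bx, by, sy) {
  w <- sy^-2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  list(theta = theta, se = se)
}

# Greedy clumping by exhaustive scan (no early data structures): repeatedly
# take the smallest-p variant below the threshold, drop everything in LD.
oracle_clump <- function(stats, ld, p_threshold, r2_cutoff) {
  avail <- stats[stats$p < p_threshold, ]
  avail <- avail[order(avail$p, avail$pos, avail$variant_id), ]
  chosen <- character()
  while (nrow(avail) > 0) {
    top <- avail$variant_id[1]
    chosen <- c(chosen, top)
    r2 <- ld[top, avail$variant_id]
    avail <- avail[!(avail$variant_id == top | r2 >= r2_cutoff), ]
  }
  chosen
}

# Transition report for known concentrations with zero noise: three
# transitions per peptide, heavy intensities fixed, light = heavy * conc/spike.
make_exact_transitions <- function(conc, peptides = fh_peptides(),
                                   scheme = spike_scheme(), batch = "B1") {
  spikes <- spike_concentration(peptides, scheme)
  grid <- merge(conc, spikes[, c("protein", "spike_nM")], by = "protein")
  rel <- c(t1 = 1, t2 = 0.6, t3 = 0.35)
  out <- do.call(rbind, lapply(names(rel), function(tr) {
    heavy <- 4e6 * rel[[tr]]
    data.frame(sample_id = grid$sample_id, batch = batch,
               peptide = grid$protein, transition_id = tr,
               light_area = heavy * grid$conc_nM / grid$spike_nM,
               heavy_area = heavy, rt_min = 12)
  }))
  long <- tidyr::pivot_longer(out, c("light_area", "heavy_area"),
                              names_to = "isotope", values_to = "area")
  long$isotope <- sub("_area", "", long$isotope)
  tibble::as_tibble(long)
}

# Diploid genotypes from explicit haplotype frequencies (pAB, pAb, paB, pab).
sample_genotypes_from_haplotypes <- function(n, p_ab, p_a, p_b) {
  freqs <- c(AB = p_ab, Ab = p_a - p_ab, aB = p_b - p_ab,
             ab = 1 - p_a - p_b + p_ab)
  stopifnot(all(freqs >= 0))
  hap <- function() sample(names(freqs), n, replace = TRUE, prob = freqs)
  h1 <- hap(); h2 <- hap()
  list(ga = (h1 %in% c("AB", "Ab")) + (h2 %in% c("AB", "Ab")),
       gb = (h1 %in% c("AB", "aB")) + (h2 %in% c("AB", "aB")))
}
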