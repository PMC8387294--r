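# broom-style tidiers and ggplot2 methods for MR results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-instrument tidy view of an MR fit
#'
#' One row per instrument with its Wald ratio estimate `theta_iv`, standard
#' error `se_iv` and, where present, instrument strength `r2_iv`.
#'
#' @param x An `mr_result` from [mr_ivw()] or [run_mr()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mr_result <- function(x, ...) {
  x$instruments
}

#' One-row summary of an MR fit
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return Tibble with `protein`, `design`, `method`, `n_iv`, `theta`,
#'   `se`, `or`, `ci_lo`, `ci_hi`, `p`, `q_stat`, `df`, `i2_percent`.
#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(
    protein = x$protein, design = x$design, method = x$method,
    n_iv = x$n_iv, theta = x$theta, se = x$se, or = x$or,
    ci_lo = x$ci_lo, ci_hi = x$ci_hi, p = x$p,
    q_stat = x$q_stat, df = x$df, i2_percent = x$i2_percent
  )
}

#' @export
glance.mr_no_instrument <- function(x, ...) {
  tibble::tibble(
    protein = x$protein, design = x$design, method = "none",
    n_iv = 0L, theta = NA_real_, se = NA_real_, or = NA_real_,
    ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
    q_stat = NA_real_, df = NA_integer_, i2_percent = NA_real_
  )
}

#' Forest plot of an MR fit
#'
#' Per-instrument Wald ratio odds ratios with 95% CIs and the pooled
#' estimate, on a log OR axis.
#'
#' @param object An `mr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_result <- function(object, ...) {
  iv <- tidy(object) |>
    dplyr::transmute(
      label = .data$variant_id,
      or = exp(.data$theta_iv),
      lo = exp(.data$theta_iv - 1.96 * .data$se_iv),
      hi = exp(.data$theta_iv + 1.96 * .data$se_iv),
      pooled = FALSE
    )
  all <- dplyr::bind_rows(iv, tibble::tibble(
    label = paste0("Pooled (", object$method, ")"),
    or = object$or, lo = object$ci_lo, hi = object$ci_hi, pooled = TRUE))
  all$label <- factor(all$label, levels = rev(all$label))
  ggplot2::ggplot(all, ggplot2::aes(x = .data$or, y = .data$label,
                                    colour = .data$pooled)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c("FALSE" = "black", "TRUE" = "red3")) +
    ggplot2::labs(
      x = "Odds ratio per exposure unit (95% CI)", y = NULL,
      title = paste0(object$protein %||% "", " (", object$design, ")")) +
    ggplot2::theme_minimal()
}

#' Case/control concentration boxplots
#'
#' @param data Long tibble with `protein`, `status` and `conc_nM`.
#' @return A ggplot object, faceted per protein on free y scales.
#' @export
plot_concentrations <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$status, y = .data$conc_nM,
                                     fill = .data$status)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~protein, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Concentration (nM)") +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise protein correlations
#'
#' @param cors Correlation matrix from [protein_correlations()].
#' @return A ggplot tile plot.
#' @export
plot_correlations <- function(cors) {
  df <- tibble::as_tibble(cors, rownames = "protein_a") |>
    tidyr::pivot_longer(-"protein_a", names_to = "protein_b",
                        values_to = "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$protein_a, .data$protein_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}
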