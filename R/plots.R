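#' Plot a positional motif-enrichment profile
#'
#' Observed/expected motif frequency against the offset from the peak centre.
#'
#' @param object A `clip_motif_profile` from [positional_motif_enrichment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clip_motif_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset,
                                       y = .data$enrichment)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::labs(x = "offset from peak centre (nt)",
                  y = "observed / expected",
                  title = paste(attr(object, "motif_class"),
                                "positional enrichment")) +
    ggplot2::theme_minimal()
}

#' Plot relative peak heights of the site-wise differential test
#'
#' WSC versus MN relative peak heights with over-/under-represented sites
#' highlighted.
#'
#' @param object A `clip_sites` tibble from [site_differential_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clip_sites <- function(object, ...) {
  df <- filter(object, .data$call != "untested")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rph_wsc, y = .data$rph_mn,
                                   colour = .data$call)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(over = "#1B7837",
                                            under = "#762A83",
                                            unchanged = "grey50")) +
    ggplot2::facet_wrap(~region_class) +
    ggplot2::labs(x = "relative peak height, WSC (%)",
                  y = "relative peak height, MN (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a conservation-score profile
#'
#' @param object A `clip_conservation_profile` from [conservation_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clip_conservation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset,
                                       y = .data$mean_score)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci95_low,
                                      ymax = .data$ci95_high),
                         fill = "grey80", na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::labs(x = "offset from peak centre (nt)",
                  y = "mean conservation score") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential splicing events
#'
#' @param events Quantified events from [run_splicing_analysis()].
#' @param cfg A [clip_config()] (draws the FDR threshold line).
#' @return A ggplot.
#' @export
plot_splicing_volcano <- function(events, cfg = clip_config()) {
  df <- filter(events, .data$expressed, !is.na(.data$fdr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dI,
                                   y = -log10(pmax(.data$fdr, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(cfg$splicing_fdr),
                        linetype = "dashed", colour = "#2166AC") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1B7837",
                                            `FALSE` = "grey50")) +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(x = "dI (MN - WSC)", y = "-log10 FDR", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
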