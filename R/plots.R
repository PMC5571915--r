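# ggplot2 displays for NIP profiles and enrichment results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-residue NIP profile
#'
#' Lollipop plot of NIP by residue with the hot-spot cutoff marked;
#' hot-spots and extended-interface residues are colored.
#'
#' @param object A `nip_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nip_profile <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(idx = dplyr::row_number(),
           call = ifelse(.data$hotspot, "hot-spot",
                         ifelse(.data$extended_interface,
                                "extended interface", "other")))
  cutoff <- attr(object, "cutoff") %||% 0.2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$nip)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$idx, yend = 0),
                          color = "grey70") +
    ggplot2::geom_point(ggplot2::aes(color = .data$call), size = 1.8) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(
      "hot-spot" = "#c0392b", "extended interface" = "#e67e22",
      "other" = "grey40")) +
    ggplot2::labs(x = "residue (order in structure)",
                  y = "normalized interface propensity (NIP)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.nip_profile
#' @export
plot_nip <- function(object, ...) autoplot.nip_profile(object, ...)

#' Forest plot of enrichment odds ratios
#'
#' @param results An `enrichment_result` tibble (rows may be bound
#'   together from several [odds_ratio()] calls, e.g. several contexts or
#'   categories); a `label` column, if present, is used for the axis.
#' @param ... Unused.
#' @return A ggplot object with odds ratios and confidence intervals on a
#'   log scale.
#' @export
plot_enrichment <- function(results, ...) {
  df <- as_tibble(results)
  if (!"label" %in% names(df)) {
    df$label <- paste(df$region_i, "vs", df$region_j)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.enrichment_result <- function(object, ...) {
  plot_enrichment(object, ...)
}
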