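# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a chronogram, optionally with detected pulses
#'
#' @param object A `chronogram` tibble.
#' @param pulses Optional pulse table from [detect_pulses()]; kept/rejected
#'   pulses are shaded if a `kept` column is present.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chronogram <- function(object, pulses = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                            y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "intensity (counts)",
      title = if (identical(attr(object, "kind"), "EIC")) {
        sprintf("EIC m/z %.4f", attr(object, "target_mz"))
      } else "TIC"
    )
  if (!is.null(pulses) && nrow(pulses) > 0) {
    shade <- pulses
    shade$status <- if ("kept" %in% names(shade)) {
      ifelse(shade$kept, "kept", "rejected")
    } else "detected"
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$start_time, xmax = .data$end_time,
                   ymin = -Inf, ymax = Inf, fill = .data$status),
      alpha = 0.15, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(
        values = c(kept = "steelblue", rejected = "firebrick",
                   detected = "grey40")
      )
  }
  p
}

#' Volcano plot
#'
#' log2 fold change against -log10 p, with the selection thresholds drawn and
#' passing features highlighted.
#'
#' @param object A [volcano_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.volcano_result <- function(object, ...) {
  cuts <- attr(object, "cuts")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = log2(.data$fc),
                               y = -log10(.data$p_value),
                               colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(cuts[["p_cut"]]),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = log2(c(cuts[["fc_lo"]],
                                            cuts[["fc_hi"]])),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey55")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "selected")
}

#' PLS-DA score plot
#'
#' @param object A fitted `pls_model`.
#' @param y Class labels used for colouring (training labels).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pls_model <- function(object, y = NULL, ...) {
  sc <- object$scores
  d <- tibble::tibble(
    t1 = sc[, 1],
    t2 = if (ncol(sc) >= 2) sc[, 2] else object$fitted,
    group = y %||% "sample"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t1, y = .data$t2,
                                  colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "component 1 score",
                  y = if (ncol(sc) >= 2) "component 2 score" else "fitted y")
}

#' VIP score plot
#'
#' Features ranked by VIP with the selection cutoff drawn.
#'
#' @param vip Named VIP vector from [vip_scores()].
#' @param vip_cut Cutoff line (default 1.8).
#' @param top Show only the top-n features (default 20).
#' @return A ggplot.
#' @export
plot_vip <- function(vip, vip_cut = 1.8, top = 20) {
  d <- tibble::tibble(feature = names(vip), vip = unname(vip)) |>
    dplyr::arrange(dplyr::desc(.data$vip)) |>
    dplyr::slice_head(n = top)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$vip,
                                  y = stats::reorder(.data$feature,
                                                     .data$vip))) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = vip_cut, linetype = "dashed") +
    ggplot2::labs(x = "VIP score", y = NULL)
}

#' PCA score plot
#'
#' @param object A [pca_fit()] result.
#' @param y Class labels for colouring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_result <- function(object, y = NULL, ...) {
  d <- tibble::tibble(
    pc1 = object$scores[, 1],
    pc2 = if (ncol(object$scores) >= 2) object$scores[, 2] else 0,
    group = y %||% "sample"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                  colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * if (length(object$explained) >= 2)
        object$explained[2] else 0)
    )
}

#' Correlation heat map
#'
#' @param cm Correlation matrix from [pearson_correlation_map()].
#' @return A ggplot.
#' @export
plot_correlation_map <- function(cm) {
  d <- tibble::as_tibble(as.table(cm), .name_repair = ~c("a", "b", "r"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r")
}
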