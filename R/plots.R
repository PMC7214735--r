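#' Plot the evidence heatmap
#'
#' Tile display of [heatmap_matrix()]: rows are approvals, columns the seven
#' evidence columns and five dossier flags, coloured green / orange / red
#' with grey for not-required cells.
#'
#' @param matrix_tbl Output of [heatmap_matrix()].
#' @return A ggplot object.
#' @export
plot_heatmap <- function(matrix_tbl) {
  long <- matrix_tbl |>
    tidyr::pivot_longer(-"approval_id", names_to = "column",
                        values_to = "code") |>
    dplyr::mutate(
      column = factor(.data$column, levels = setdiff(names(matrix_tbl),
                                                     "approval_id")),
      code = factor(.data$code, levels = c(2, 1, 0))
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column,
                                     y = .data$approval_id,
                                     fill = .data$code)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.4) +
    ggplot2::scale_fill_manual(
      values = c(`2` = "#2e7d32", `1` = "#ef6c00", `0` = "#c62828"),
      na.value = "grey85",
      labels = c("2 (green)", "1 (orange)", "0 (red)"),
      name = "code"
    ) +
    ggplot2::scale_y_discrete(limits = rev(sort(matrix_tbl$approval_id))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot effect sizes against p-values
#'
#' Study-level and pooled estimates on a d-versus-p display with a log
#' p-axis, faceted by design phase and comparator class; the dashed line
#' marks p = 0.05 and the dotted line d = 0 (negative favours the
#' investigational drug).
#'
#' @param scatter Output of [scatter_data()].
#' @param level `"study"`, `"meta"` or `"both"` (default).
#' @return A ggplot object.
#' @export
plot_scatter <- function(scatter, level = c("both", "study", "meta")) {
  level <- match.arg(level)
  pieces <- list()
  if (level %in% c("both", "study")) {
    pieces$study <- dplyr::mutate(scatter$study, level = "study")
  }
  if (level %in% c("both", "meta")) {
    pieces$meta <- dplyr::mutate(scatter$meta, level = "meta-analysis")
  }
  dat <- dplyr::bind_rows(
    purrr::map(pieces, ~ dplyr::select(.x, "design_phase",
                                       "comparator_class", "d", "p",
                                       "level"))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$d, y = .data$p)) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted",
                        colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_continuous(
      trans = "log10",
      labels = function(x) format(x, scientific = TRUE, digits = 2)
    ) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$level),
      cols = ggplot2::vars(.data$design_phase, .data$comparator_class)
    ) +
    ggplot2::labs(x = "Cohen's d (negative favours investigational drug)",
                  y = "two-sided p") +
    ggplot2::theme_bw()
}
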