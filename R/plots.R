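# side-chain chemistry palette used across plots (nonpolar black, polar
# green, basic blue, acidic red)
residue_class <- function(residue) {
  dplyr::case_when(
    residue %in% c("D", "E") ~ "acidic",
    residue %in% c("K", "R", "H") ~ "basic",
    residue %in% c("S", "T", "N", "Q", "C", "Y", "G") ~ "polar",
    TRUE ~ "nonpolar"
  )
}

residue_class_palette <- c(nonpolar = "grey15", polar = "forestgreen",
                           basic = "royalblue3", acidic = "firebrick3")

#' Plot a sequence logo matrix
#'
#' Stacked per-column letter heights (information content above background,
#' in bits), colored by side-chain chemistry.
#'
#' @param object A `krab_logo` from [logo_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot krab_logo
#' @export
autoplot.krab_logo <- function(object, ...) {
  df <- object %>%
    as_tibble() %>%
    arrange(.data$column, .data$height) %>%
    group_by(.data$column) %>%
    mutate(ymax = cumsum(.data$height), ymin = .data$ymax - .data$height,
           class = residue_class(.data$residue)) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$column - 0.45,
                                    xmax = .data$column + 0.45,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$class),
                       color = "white", linewidth = 0.2) +
    ggplot2::geom_text(ggplot2::aes(y = (.data$ymin + .data$ymax) / 2,
                                    label = .data$residue,
                                    size = .data$height),
                       color = "white", show.legend = FALSE) +
    ggplot2::scale_size(range = c(1, 4)) +
    ggplot2::scale_fill_manual(values = residue_class_palette, name = NULL) +
    ggplot2::scale_x_continuous(
      breaks = unique(df$column),
      labels = unique(df$coord)[order(unique(df$column))]) +
    ggplot2::labs(x = "position", y = "information content (bits)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot a cross-scoring matrix
#'
#' Clamped -log10 E-value distributions per (truth group, model), the
#' visual counterpart of the stratification table: each group should score
#' best with its own model.
#'
#' @param object A `krab_scores` tibble from [cross_score()].
#' @param truth Optional tibble `id`, `group`; without it, scores are
#'   grouped by assigned label.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot krab_scores
#' @export
autoplot.krab_scores <- function(object, truth = NULL, ...) {
  df <- as_tibble(object)
  if (is.null(truth)) {
    truth <- rename(assign_subgroup(object), group = "label")[, c("id", "group")]
  }
  df <- left_join(df, truth, by = "id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$score,
                                   fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "floor_evalue") %||% 0.01),
                        linetype = "dashed", color = "grey40") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "profile HMM", y = "-log10 E-value (clamped)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot detected helix segments
#'
#' Residue-by-segment bars with per-segment rise and twist annotations.
#'
#' @param object A `helix_segments` tibble from [detect_helices()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot helix_segments
#' @export
autoplot.helix_segments <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(segment = factor(dplyr::row_number()))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$segment, yend = .data$segment,
                                       color = .data$segment),
                          linewidth = 4, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$start + .data$end) / 2, y = .data$segment,
      label = sprintf("%.1f deg/res, %.2f A/res", .data$twist, .data$rise)),
      vjust = -1, size = 3) +
    ggplot2::labs(x = "residue", y = "helix segment") +
    ggplot2::theme_minimal()
}
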