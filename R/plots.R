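# ggplot2 views of reports and summaries.

#' Plot the token map of one processed read
#'
#' Draws the read as a horizontal bar tiled by its pattern tokens (termini
#' coloured by family, V/N context in neutral tones) with the clean insert
#' interval, if any, underneath.
#'
#' @param reports Report tibble from [process_reads()].
#' @param id Read id to draw (default: first row).
#' @return A ggplot object.
#' @export
plot_read_map <- function(reports, id = reports$id[1L]) {
  i <- match(id, reports$id)
  if (is.na(i)) stop_validation("read '%s' not in report", id)
  tok <- reports$tokens[[i]]
  if (is.null(tok) || !nrow(tok)) stop_validation("read '%s' has no tokens", id)
  fam <- function(t) {
    ifelse(t %in% c("V", "N"), t, sub("^([35]T[NS]S).*$", "\\1", t))
  }
  tok$fill <- fam(tok$token)
  g <- ggplot2::ggplot(tok) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start - 0.5,
                                    xmax = .data$end + 0.5,
                                    ymin = 0, ymax = 1, fill = .data$fill),
                       colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = 0.5, label = .data$token),
                       size = 3, angle = 90) +
    ggplot2::scale_fill_brewer(palette = "Set3", name = NULL) +
    ggplot2::labs(title = id,
                  subtitle = paste0("pattern: ", reports$pattern[i],
                                    "   call: ",
                                    reports$primary_call[i] %|na|% "none"),
                  x = "read position (bases)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.na(reports$clean_start[i])) {
    g <- g + ggplot2::annotate("segment", x = reports$clean_start[i],
                               xend = reports$clean_end[i],
                               y = -0.15, yend = -0.15,
                               linewidth = 2, colour = "firebrick")
  }
  g
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a run summary
#'
#' @param object An `est_summary` from [summarize_reports()].
#' @param ... Unused.
#' @return A ggplot object showing read counts per primary category.
#' @export
autoplot.est_summary <- function(object, ...) {
  parts <- dplyr::bind_rows(
    if (nrow(object$by_reca)) tibble(category = object$by_reca$reca_type,
                                     n = object$by_reca$n, group = "RECA"),
    if (nrow(object$by_case)) tibble(category = object$by_case$case,
                                     n = object$by_case$n, group = "Frequent case"),
    if (nrow(object$by_dbt)) tibble(category = object$by_dbt$dbt,
                                    n = object$by_dbt$n, group = "DBT"))
  if (is.null(parts) || !nrow(parts)) {
    parts <- tibble(category = "no abnormality", n = object$totals$n_reads,
                    group = "clean")
  }
  ggplot2::ggplot(parts, ggplot2::aes(x = stats::reorder(.data$category, .data$n),
                                      y = .data$n, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "reads", fill = NULL,
                  title = "Abnormality categories") +
    ggplot2::theme_minimal()
}
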