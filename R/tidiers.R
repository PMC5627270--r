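# broom-style verbs and ggplot2 displays for the result objects.

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (i in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  %-18s %5d -> %5d\n", x$stage_counts$stage[i],
                x$stage_counts$n_in[i], x$stage_counts$n_out[i]))
  }
  cat(sprintf("  final candidates: %d\n", nrow(x$candidates)))
  invisible(x)
}

#' Tidy a filter report into its per-transcript audit trail
#' @param x A `filter_report`.
#' @param ... Unused.
#' @return The audit tibble (`id`, `stage`, `metric`, `value`, `pass`).
#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) x$audit

#' One-row summary of a filter report
#' @param x A `filter_report`.
#' @param ... Unused.
#' @method glance filter_report
#' @export
glance.filter_report <- function(x, ...) {
  wide <- setNames(as.list(x$stage_counts$n_out),
                   paste0("n_after_", x$stage_counts$stage))
  dplyr::bind_cols(
    tibble(n_assembled = if (nrow(x$stage_counts)) x$stage_counts$n_out[1] else 0,
           n_candidates = nrow(x$candidates)),
    as_tibble(wide)
  )
}

#' @method tidy sexswap_control
#' @export
tidy.sexswap_control <- function(x, ...) {
  tibble(orientation = c("forward", "swapped"),
         n_candidates = c(x$n_male_specific, x$n_female_specific),
         include_species = x$include_species)
}

#' Stage-by-stage funnel of a filter report
#' @param object A `filter_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot filter_report
#' @export
autoplot.filter_report <- function(object, ...) {
  df <- object$stage_counts
  df$stage <- factor(df$stage, levels = rev(df$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_out, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), hjust = -0.2,
                       size = 3) +
    ggplot2::labs(x = "transcripts retained", y = NULL,
                  title = "Subtraction cascade") +
    ggplot2::theme_minimal()
}

#' Histogram of normalized male/female coverage ratios
#'
#' The X mode sits near -1 (hemizygosity), the autosomal mode near 0;
#' scaffolds carrying Y-candidate paralogs can be highlighted.
#'
#' @param coverage A [compute_coverage()] or [classify_scaffold()] tibble.
#' @param highlight Optional scaffold ids to mark with vertical lines.
#' @param binwidth Histogram bin width (default 0.1).
#' @return A ggplot.
#' @export
plot_coverage_ratio <- function(coverage, highlight = NULL, binwidth = 0.1) {
  ratio_col <- if ("log2_ratio" %in% names(coverage)) "log2_ratio" else
    "normalized_ratio"
  id_col <- if ("scaffold_id" %in% names(coverage)) "scaffold_id" else
    "target_id"
  df <- tibble(scaffold = coverage[[id_col]], ratio = coverage[[ratio_col]])
  df <- df[!is.na(df$ratio), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = -0.5, ymin = -Inf,
                      ymax = Inf, fill = "gold", alpha = 0.15) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::labs(x = expression(log[2] * "(male/female coverage)"),
                  y = "scaffolds") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    hl <- df[df$scaffold %in% highlight, , drop = FALSE]
    p <- p + ggplot2::geom_vline(data = hl,
                                 ggplot2::aes(xintercept = .data$ratio),
                                 colour = "red")
  }
  p
}

#' Divergence summary of Y-candidate paralog pairs
#'
#' Plots Ka, Ks and Ka/Ks per pair. Following the usual display convention,
#' Ka/Ks values above 3 are truncated at 3 in the plot; raw values stay in
#' the table.
#'
#' @param pairs A [paralog_analysis()] tibble.
#' @return A ggplot.
#' @export
plot_divergence <- function(pairs) {
  df <- pairs[!is.na(pairs$ka), , drop = FALSE]
  long <- tidyr::pivot_longer(
    tibble(id = df$y_transcript_id, Ka = df$ka, Ks = df$ks,
           `Ka/Ks` = pmin(df$ka_ks, 3)),
    cols = c("Ka", "Ks", "Ka/Ks"), names_to = "measure"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "substitutions per site (ratio for Ka/Ks)") +
    ggplot2::theme_minimal()
}

#' Heatmap of row-normalized tissue expression
#' @param zscores A [row_zscore()] tibble.
#' @return A ggplot.
#' @export
plot_expression_heatmap <- function(zscores) {
  value_cols <- setdiff(names(zscores), c("transcript_id", "constant"))
  long <- tidyr::pivot_longer(zscores[, c("transcript_id", value_cols)],
                              cols = dplyr::all_of(value_cols),
                              names_to = "sample", values_to = "z")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$transcript_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
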