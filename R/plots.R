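# Optional ggplot2 figures: GFP trajectories on a log scale and the
# fold-repression bar chart.

utils::globalVariables(c("time_h", "label", "mode", "fold_repression", "gfp"))

#' Plot GFP trajectories for all architectures
#'
#' @param tab A [repression_table()] result (its `trajectories` attribute
#'   holds the simulated systems, base expression included).
#' @param log_scale Log10 y axis (default TRUE).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(tab, log_scale = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires ggplot2", call. = FALSE)
  stopifnot(inherits(tab, "crispri_repression_table"))
  trajs <- attr(tab, "trajectories")
  long <- do.call(rbind, lapply(names(trajs), function(nm) {
    tr <- trajs[[nm]]
    data.frame(time_h = tr$times, gfp = gfp(tr), label = nm,
               mode = tr$architecture$mode,
               stringsAsFactors = FALSE)
  }))
  long$label <- factor(long$label, levels = names(trajs))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = time_h, y = gfp,
                                          colour = label, linetype = mode)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "GFP (MEFL)", colour = NULL,
                  linetype = "site mode") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Bar chart of mean fold repression per architecture
#'
#' @param tab A [repression_table()] result.
#' @return A ggplot object.
#' @export
plot_repression <- function(tab) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires ggplot2", call. = FALSE)
  stopifnot(inherits(tab, "crispri_repression_table"))
  df <- as.data.frame(tab)
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = label, y = fold_repression,
                                   fill = mode)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Mean fold repression (72-96 h)",
                  fill = "site mode") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
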