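#' Plot an empirical null distribution
#'
#' Histograms of the replicate duplication, loss and net-expansion
#' counts with the observed value marked by a vertical line — the
#' standard display for a simulation-based clade-expansion test.
#'
#' @param object A `null_distribution` from [run_null_test()].
#' @param ... Unused.
#' @return A [ggplot2::ggplot].
#' @export
autoplot.null_distribution <- function(object, ...) {
  long <- tidyr::pivot_longer(object$replicates, c("D", "L", "k"),
                              names_to = "statistic", values_to = "value")
  obs <- tidyr::pivot_longer(object$observed, c("D", "L", "k"),
                             names_to = "statistic", values_to = "value")
  long$statistic <- factor(long$statistic, levels = c("k", "D", "L"),
                           labels = c("net expansion k", "duplications D",
                                      "losses L"))
  obs$statistic <- factor(obs$statistic, levels = c("k", "D", "L"),
                          labels = levels(long$statistic))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$value),
                        linewidth = 1) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "count in focal clade", y = "replicates",
                  title = sprintf("Birth-death null (N = %d)", object$N))
}

#' Plot per-branch family-size changes
#'
#' Bar chart of the per-branch deltas of a reconstructed count history
#' (expansions up, contractions down).
#'
#' @param object A `count_history` from [sankoff_counts()] or
#'   [ml_ancestral_counts()].
#' @param ... Unused.
#' @return A [ggplot2::ggplot].
#' @export
autoplot.count_history <- function(object, ...) {
  df <- object[!is.na(object$parent) & object$delta != 0, ]
  df$direction <- ifelse(df$delta > 0, "expansion", "contraction")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$delta,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "branch (child node)", y = "copy-number change") +
    ggplot2::theme(legend.position = "bottom")
}
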