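# ggplot2 views of the main result types: enrichment dot maps, volcano
# plots, state-frequency bars, and limiting-dilution fits.

#' Dot map of feature enrichment results
#'
#' One dot per feature: position on the signed fold-change axis, size by
#' `-log_p`. Mirrors the usual likelihood-of-methylation dot map.
#'
#' @param enrichment Output of [permutation_feature_enrichment()].
#' @return A ggplot object.
#' @export
plot_feature_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$fold_change,
                               y = stats::reorder(.data$feature,
                                                  .data$fold_change))) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(size = pmin(-.data$log_p, 50)),
                        colour = "#2166ac") +
    ggplot2::scale_size_continuous(name = "-ln p (capped)") +
    ggplot2::labs(x = "fold change (signed: +enrichment / -depletion)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential proteins
#'
#' @param diff Output of [differential_proteins()].
#' @param p_col Which p-value column to plot (`"p"` or `"q"`).
#' @return A ggplot object.
#' @export
plot_protein_volcano <- function(diff, p_col = "p") {
  x <- dplyr::mutate(
    diff,
    class = dplyr::case_when(
      !is.na(.data$detected_only_in) ~ paste0("only in ",
                                              .data$detected_only_in),
      .data$is_differential ~ "differential",
      TRUE ~ "ns"
    ),
    logp = -log10(pmax(.data[[p_col]], 1e-300))
  )
  ggplot2::ggplot(x, ggplot2::aes(x = .data$log2fc, y = .data$logp,
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
    ggplot2::labs(x = "log2(fold change)",
                  y = sprintf("-log10(%s)", p_col), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of relationship-state frequencies
#'
#' Gene counts per 4-layer relationship state on a log10 axis, the
#' all-neutral reference highlighted.
#'
#' @param freq Output of [enumerate_states()].
#' @param max_states Show at most this many states. Default 20.
#' @return A ggplot object.
#' @export
plot_state_frequencies <- function(freq, max_states = 20) {
  x <- utils::head(freq, max_states)
  x$label <- apply(x[, LAYERS], 1, function(r) {
    paste(substr(toupper(sub("up_", "", r)), 1, 1), collapse = "")
  })
  x$label <- factor(x$label, levels = rev(unique(x$label)))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$n, y = .data$label,
                                  fill = .data$is_reference)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "genes (log10)",
                  y = "state (chromatin/methylation/RNA/protein)") +
    ggplot2::theme_minimal()
}

#' Plot a limiting-dilution fit
#'
#' The standard log-fraction-negative vs dose view: points are observed
#' `log(1 - take rate)` per dose, the line is the fitted single-hit
#' slope `-f`, with the profile-CI envelope.
#'
#' @param object An `lda_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.lda_fit <- function(object, ...) {
  d <- object$doses
  obs_neg <- (d$n - d$positive) / d$n
  pts <- tibble(dose = d$dose,
                log_frac_neg = log(pmax(obs_neg, 1e-6)))
  line <- tibble(dose = seq(0, max(d$dose), length.out = 50))
  env <- tidyr::expand_grid(dose = line$dose)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$dose,
                                    y = .data$log_frac_neg)) +
    ggplot2::geom_ribbon(
      data = env,
      ggplot2::aes(x = .data$dose, ymin = -object$ci_high * .data$dose,
                   ymax = -object$ci_low * .data$dose),
      inherit.aes = FALSE, alpha = 0.15) +
    ggplot2::geom_line(
      data = line,
      ggplot2::aes(x = .data$dose,
                   y = if (is.na(object$frequency)) NA_real_ else
                     -object$frequency * .data$dose),
      colour = "#2166ac", na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cells injected",
                  y = "ln(fraction negative)") +
    ggplot2::theme_minimal()
}
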