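# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an MTA ranking
#'
#' Bar chart of transformation scores by candidate, with the control
#' score as a dashed reference line.
#'
#' @param object an `mta_ranking`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mta_ranking
#' @export
autoplot.mta_ranking <- function(object, ...) {
  d <- tidy.mta_ranking(object)
  d <- d[!d$is_control, ]
  d$candidate <- stats::reorder(d$candidate, d$ts)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$candidate, y = .data$ts)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "control_ts"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "transformation score",
                  caption = "dashed line: no-perturbation control") +
    ggplot2::theme_minimal()
}

#' Plot the two Kaplan-Meier curves behind a dAUC
#'
#' @param object a `km_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot km_result
#' @export
autoplot.km_result <- function(object, ...) {
  d <- tidy.km_result(object)
  d0 <- tibble::tibble(bin = c("low", "high"), time = 0, surv = 1)
  d <- dplyr::bind_rows(d0, d[, c("bin", "time", "surv")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv,
                                  colour = .data$bin)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$horizon,
                        linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival",
                  title = paste0(object$gene, ": dAUC = ",
                                 signif(object$delta_auc, 4))) +
    ggplot2::theme_minimal()
}

#' Plot an OTS table
#'
#' @param object an `ots_table`.
#' @param top show at most this many entries.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ots_table
#' @export
autoplot.ots_table <- function(object, top = 20, ...) {
  ycol <- if ("ots_sum" %in% names(object)) "ots_sum" else "ots"
  d <- utils::head(tibble::as_tibble(object), top)
  d$id <- stats::reorder(d$id, d[[ycol]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$id, y = .data[[ycol]])) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "oncogenic transformation score") +
    ggplot2::theme_minimal()
}

#' Plot knockdown vs overexpression read-outs
#'
#' @param object a `phenotype_comparison`.
#' @param ... unused.
#' @return a ggplot object (boxplots per read-out and arm).
#' @method autoplot phenotype_comparison
#' @export
autoplot.phenotype_comparison <- function(object, ...) {
  d <- tidyr::pivot_longer(object$samples,
                           dplyr::all_of(names(object$readouts)),
                           names_to = "readout")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$arm, y = .data$value,
                                  fill = .data$arm)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~readout, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "flux",
                  title = paste0(object$gene,
                                 ": knockdown vs overexpression")) +
    ggplot2::theme_minimal()
}

#' Plot stage-specific adjustment distances
#'
#' @param object a `stage_profile`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot stage_profile
#' @export
autoplot.stage_profile <- function(object, ...) {
  d <- object$distances
  d$stage <- factor(d$stage)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$distance)) +
    ggplot2::geom_boxplot(fill = "darkseagreen") +
    ggplot2::labs(x = "tumor stage",
                  y = "squared adjustment to advanced-stage state",
                  title = paste0("post-", object$gene,
                                 "-knockout distance by stage")) +
    ggplot2::theme_minimal()
}
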