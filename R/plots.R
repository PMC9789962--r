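# ggplot2 helpers for the main result types.

#' ROC curve and AUC from per-item scores and truth
#'
#' Sorts items by decreasing score and accumulates true/false positive
#' rates; the AUC is the trapezoidal area under the curve. Used to
#' assess per-read classification of simulated reads with known truth.
#'
#' @param score Numeric scores (e.g. LLRs); larger means more likely
#'   positive.
#' @param truth Logical (or 0/1) ground truth.
#' @return A tibble of class `nj_roc` with columns `fpr`, `tpr` and an
#'   `auc` attribute.
#' @export
compute_roc <- function(score, truth) {
  truth <- as.logical(truth)
  keep <- is.finite(score) & !is.na(truth)
  score <- score[keep]; truth <- truth[keep]
  stopifnot(any(truth), any(!truth))
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(truth[ord]) / sum(truth)
  fp <- cumsum(!truth[ord]) / sum(!truth)
  # collapse ties so the curve steps once per distinct score
  last <- !duplicated(score[ord], fromLast = TRUE)
  roc <- tibble::tibble(fpr = c(0, fp[last]), tpr = c(0, tp[last]))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                              utils::tail(roc$tpr, -1)) / 2)
  structure(roc, auc = auc, class = c("nj_roc", class(roc)))
}

#' @export
print.nj_roc <- function(x, ...) {
  cat("ROC curve, AUC =", format(attr(x, "auc"), digits = 4), "\n")
  NextMethod()
}

#' @rdname compute_roc
#' @param object An `nj_roc` object.
#' @param ... Unused.
#' @export
autoplot.nj_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.3f", attr(object, "auc"))
    )
}

#' Density plot of a fitted Gaussian mixture over its events
#'
#' @param object An `nj_gmm` fit.
#' @param x Optional event values to show as a histogram underneath the
#'   fitted component densities.
#' @param ... Unused.
#' @export
autoplot.nj_gmm <- function(object, x = NULL, ...) {
  comp <- object$components
  rng <- range(comp$mean + 4 * comp$sd, comp$mean - 4 * comp$sd,
               if (!is.null(x)) range(x))
  grid <- seq(rng[1], rng[2], length.out = 400)
  dens <- purrr::pmap(comp, function(weight, mean, sd)
    tibble::tibble(x = grid, density = weight * stats::dnorm(grid, mean, sd)))
  dens <- dplyr::bind_rows(dens, .id = "component")
  p <- ggplot2::ggplot()
  if (!is.null(x)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(x = x),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = 60, fill = "grey85", colour = NA)
  }
  p +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$x, y = .data$density,
                   colour = .data$component)) +
    ggplot2::labs(x = "Transformed event level (pA)", y = "Density",
                  colour = "Component")
}

#' Histogram of per-window LLRs split by call kind
#'
#' @param calls Per-window call tibble.
#' @param th Optional [thresholds()] to draw as vertical lines.
#' @export
plot_llr_distribution <- function(calls, th = thresholds()) {
  d <- calls[is.finite(calls$llr), ]
  lines <- tibble::tibble(
    kind = c("cpg_substring", "cpg_substring", "adenine_window",
             "adenine_window"),
    x = c(th$cpg_meth, th$cpg_unmeth, th$ada_low, th$ada_high)
  )
  lines <- lines[lines$kind %in% d$kind, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$llr)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::geom_vline(data = lines,
                        ggplot2::aes(xintercept = .data$x),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::labs(x = "Log likelihood ratio", y = "Windows")
}

#' Histogram of distances between adjacent 6mA-containing windows
#'
#' @param distances Output of [linker_lengths()].
#' @param binwidth Histogram bin width in bp (default 25).
#' @export
plot_linker_lengths <- function(distances, binwidth = 25) {
  ggplot2::ggplot(distances, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "Distance between adjacent 6mA-containing sites (bp)",
                  y = "Count")
}
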