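#' Plot a slide raster
#'
#' @param object an `nm_slide`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.nm_slide <- function(object, ...) {
  d <- dim(object$image)
  ggplot2::ggplot() +
    ggplot2::annotation_raster(object$image, xmin = 0.5, xmax = d[2] + 0.5,
                               ymin = -(d[1] + 0.5), ymax = -0.5) +
    ggplot2::xlim(0.5, d[2] + 0.5) + ggplot2::ylim(-(d[1] + 0.5), -0.5) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$id,
                  subtitle = sprintf("%.3g um/px", object$mpp)) +
    ggplot2::theme_void()
}

#' Kaplan-Meier curves
#'
#' Step curves per group (non-increasing, starting at 1) annotated with the
#' log-rank p value.
#'
#' @param object an `nm_km` from [km_logrank()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.nm_km <- function(object, ...) {
  cv <- dplyr::bind_rows(
    tibble::tibble(group = names(object$groups), time = 0, surv = 1),
    object$curves[, c("group", "time", "surv")])
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  subtitle = sprintf("log-rank p = %.3g", object$p)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Consensus heatmap across annotators
#'
#' The classic palette: blue, orange, yellow, red for pixels marked by one,
#' two, three or four annotators.
#'
#' @param cmap consensus counts from [consensus_map()].
#' @return a ggplot object.
#' @export
plot_consensus_map <- function(cmap) {
  n <- attr(cmap, "n_annotators") %||% max(cmap)
  df <- tibble::tibble(
    row = rep(seq_len(nrow(cmap)), ncol(cmap)),
    col = rep(seq_len(ncol(cmap)), each = nrow(cmap)),
    count = as.vector(cmap))
  df <- df[df$count > 0, ]
  pal <- c("#3B6FB6", "#F58024", "#F5D327", "#D62728")[seq_len(max(1L, n))]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = factor(.data$count))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, name = "annotators") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' True/false positive overlay of a prediction against ground truth
#'
#' Green where prediction and truth agree on the structure, red for false
#' positives, blue for false negatives.
#'
#' @param pred,truth binary matrices in the same frame.
#' @return a ggplot object.
#' @export
plot_overlay <- function(pred, truth) {
  pred <- pred > 0; truth <- truth > 0
  cls <- matrix(NA_character_, nrow(pred), ncol(pred))
  cls[pred & truth] <- "TP"
  cls[pred & !truth] <- "FP"
  cls[!pred & truth] <- "FN"
  df <- tibble::tibble(
    row = rep(seq_len(nrow(cls)), ncol(cls)),
    col = rep(seq_len(ncol(cls)), each = nrow(cls)),
    class = as.vector(cls))
  df <- df[!is.na(df$class), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(TP = "#2CA02C", FP = "#D62728",
                                          FN = "#1F77B4")) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Training history curves
#'
#' @param model a trained `nm_model`.
#' @return a ggplot object with loss and validation Dice per epoch.
#' @export
plot_training_history <- function(model) {
  h <- model$history
  if (is.null(h)) stop("model has no training history")
  hh <- tidyr::pivot_longer(h, c("loss", "val_dice"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(hh, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}
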