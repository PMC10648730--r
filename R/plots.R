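# ggplot2 helpers for the result types.

#' Plot a per-slice pixel-count profile
#'
#' The slice-by-slice mask pixel counts with the selected kidney region
#' highlighted and the pixel-count floor drawn as a dashed line.
#'
#' @param profile A `pixel_profile` from [select_kidney_region()].
#' @return A ggplot object.
#' @export
plot_pixel_profile <- function(profile) {
  stopifnot(inherits(profile, "pixel_profile"))
  df <- data.frame(slice = seq_along(profile$counts),
                   count = profile$counts)
  df$in_region <- if (is.null(profile$run)) FALSE else
    df$slice >= profile$run[1] & df$slice <= profile$run[2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slice, y = .data$count,
                                   fill = .data$in_region)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::geom_hline(yintercept = profile$floor, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               name = "kidney region") +
    ggplot2::labs(x = "slice (table position order)",
                  y = "mask pixel count") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Per-subject difference against the pairwise mean, with the mean difference
#' and limits of agreement.
#'
#' @param ba A `bland_altman` result.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba) {
  stopifnot(inherits(ba, "bland_altman"))
  ggplot2::ggplot(ba$data, ggplot2::aes(x = .data$mean,
                                        y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$lower, ba$upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "mean of methods (ml)",
                  y = "difference between methods (ml)") +
    ggplot2::theme_minimal()
}

#' Training loss curves
#'
#' @param history Data frame from [train_unet()] (`epoch`, `train_loss`,
#'   `val_loss`).
#' @return A ggplot object.
#' @export
plot_loss_history <- function(history) {
  df <- rbind(data.frame(epoch = history$epoch, loss = history$train_loss,
                         set = "training"),
              data.frame(epoch = history$epoch, loss = history$val_loss,
                         set = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pixel_profile <- function(object, ...) plot_pixel_profile(object)

#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) plot_bland_altman(object)
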