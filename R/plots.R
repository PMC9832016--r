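# ggplot2 graphics for trial and batch results.

#' Plot closed-loop voltage tracking
#'
#' Desired versus actual membrane voltage per neuron over an optional time
#' window.
#'
#' @param object a `cae_trial`.
#' @param window optional `c(from, to)` time window, ms.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cae_trial
#' @export
autoplot.cae_trial <- function(object, window = NULL, ...) {
  tr <- object$trajectory
  if (!is.null(window))
    tr <- dplyr::filter(tr, .data$t_ms >= window[1], .data$t_ms <= window[2])
  long <- tr |>
    dplyr::select("t_ms", dplyr::starts_with("V_")) |>
    tidyr::pivot_longer(-"t_ms", names_to = "series", values_to = "v_mv") |>
    dplyr::mutate(
      role = ifelse(grepl("_desired$", .data$series), "desired", "actual"),
      neuron = sub("^V_([A-Z]+).*$", "\\1", .data$series))
  ggplot2::ggplot(long, ggplot2::aes(.data$t_ms, .data$v_mv,
                                     colour = .data$role)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~neuron, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "membrane voltage (mV)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the stimulation currents of a trial
#'
#' @param trial a `cae_trial`.
#' @param window optional `c(from, to)` time window, ms.
#' @return a ggplot object.
#' @export
plot_control <- function(trial, window = NULL) {
  tr <- trial$trajectory
  if (!is.null(window))
    tr <- dplyr::filter(tr, .data$t_ms >= window[1], .data$t_ms <= window[2])
  long <- tr |>
    dplyr::select("t_ms", dplyr::starts_with("u_")) |>
    tidyr::pivot_longer(-"t_ms", names_to = "channel", values_to = "u") |>
    dplyr::mutate(channel = c(u_1 = "TC", u_2 = "CT", u_3 = "RT")[.data$channel])
  ggplot2::ggplot(long, ggplot2::aes(.data$t_ms, .data$u)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "stimulation current (uA/cm^2)") +
    ggplot2::theme_minimal()
}

#' Plot batch RMSE summaries
#'
#' Mean tracking RMSE with +/- one standard deviation error bars per neuron
#' and condition.
#'
#' @param object a `cae_batch`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cae_batch
#' @export
autoplot.cae_batch <- function(object, ...) {
  df <- as_tibble(object)
  cond_cols <- setdiff(names(df), c("controller", "neuron", "mean_rmse_mv",
                                    "sd_rmse_mv", "n", "n_diverged"))
  df$condition <- if (length(cond_cols)) {
    do.call(paste, c(lapply(cond_cols, function(cc)
      paste0(cc, "=", df[[cc]])), sep = " "))
  } else ""
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$mean_rmse_mv,
                                   fill = .data$controller)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rmse_mv - .data$sd_rmse_mv,
                   ymax = .data$mean_rmse_mv + .data$sd_rmse_mv),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::facet_wrap(~neuron) +
    ggplot2::labs(x = NULL, y = "mean RMSE (mV)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
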