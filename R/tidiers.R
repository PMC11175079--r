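#' Turn a result into a tidy tibble
#'
#' Generic with methods for the package's result objects (no external
#' tidier package is required).
#'
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a result
#'
#' @param x Object to summarise.
#' @param ... Passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Tidy a layered fusion result
#'
#' @param x An `lf_result` from [run_lf()].
#' @param ... Unused.
#' @return A tibble with one row per supported pixel: position (row, col,
#'   x, y) and the pre-image, binary layer 1, normalized layer 2, and fused
#'   values.
#' @export
tidy.lf_result <- function(x, ...) {
  base <- as_tibble(x$image)
  base$fused <- base$value
  base$value <- NULL
  base$initial <- as.numeric(x$initial)
  base$layer1 <- as.numeric(x$layer1)
  base$layer2 <- as.numeric(x$layer2)
  base[, c("pixel", "row", "col", "x", "y",
           "initial", "layer1", "layer2", "fused")]
}

#' Summarise a layered fusion result
#'
#' @param x An `lf_result`.
#' @param ... Unused.
#' @return A one-row tibble with the method label, scale factor `a`, fusion
#'   weights, working-pixel counts, the lambda used and the anomaly-area
#'   prior (NA for FLF).
#' @export
glance.lf_result <- function(x, ...) {
  tibble(method = x$method, a = x$a,
         delta_sigma1 = x$delta_sigma1, delta_sigma2 = x$delta_sigma2,
         n1 = as.integer(x$n1), n2 = as.integer(x$n2),
         lambda = x$lambda, p = x$p %||% NA_real_)
}

#' Plot the stages of a layered fusion result
#'
#' Shows the Tikhonov pre-image, the binary main-object layer, the
#' sharpened anomaly layer, and the fused reconstruction side by side.
#'
#' @param object An `lf_result`.
#' @param ... Unused.
#' @return A ggplot object (facetted).
#' @method autoplot lf_result
#' @export
autoplot.lf_result <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("initial", "layer1", "layer2", "fused"),
                        names_to = "stage", values_to = "value") |>
    dplyr::mutate(stage = factor(.data$stage,
                                 levels = c("initial", "layer1", "layer2", "fused")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~stage, nrow = 1) +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot study metrics against noise level
#'
#' @param results Tibble from [run_study()] (noisy rows are used).
#' @param metric One of `"re"`, `"se"`, `"pe_px"`, `"pe_pct"`.
#' @return A ggplot object: mean metric per method vs SNR.
#' @export
plot_noise_robustness <- function(results, metric = "re") {
  stopifnot(metric %in% c("re", "se", "pe_px", "pe_pct"))
  df <- results |>
    dplyr::filter(!is.na(.data$snr_db)) |>
    dplyr::group_by(.data$method, .data$snr_db) |>
    dplyr::summarise(value = mean(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snr_db, y = .data$value,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNR (dB)", y = sprintf("mean %s", toupper(metric))) +
    ggplot2::theme_minimal()
}
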