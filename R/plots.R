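#' Plot a Hi-C matrix as a heatmap
#'
#' @param object A [hic_matrix()].
#' @param trans Value transform for the fill scale (default `"log10"` with a
#'   small offset applied to raw counts; `"identity"` for frequencies).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hic_matrix <- function(object, trans = NULL, ...) {
  m <- object$values
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(
      trans = trans %||% if (object$normalized) "identity" else "log1p"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "bin", y = "bin",
      fill = if (object$normalized) "frequency" else "counts",
      title = sprintf(
        "%s:%s-%s", object$locus$chrom,
        format(object$locus$start, scientific = FALSE),
        format(object$locus$end, scientific = FALSE)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot contact calls in the (i, j) plane
#'
#' @param object A `contact_calls` tibble.
#' @param ... Unused.
#' @export
autoplot.contact_calls <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  ggplot2::ggplot(df, ggplot2::aes(
    .data$i, .data$j,
    colour = .data$specific, size = .data$normalized_frequency
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_size_area(max_size = 2) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin i", y = "bin j", colour = "specific") +
    ggplot2::theme_minimal()
}

#' Plot a boundary-strength profile
#'
#' @param object A `boundary_profile` from [boundary_strength()].
#' @param ... Unused.
#' @export
autoplot.boundary_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$bin, .data$strength)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "bin", y = "boundary strength",
      title = sprintf("window = %d bins", attr(object, "window"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot random-forest feature importances
#'
#' @param object A `chromfold_rf`.
#' @param ... Unused.
#' @export
autoplot.chromfold_rf <- function(object, ...) {
  imp <- tidyr::pivot_longer(
    feature_importance(object), -"feature",
    names_to = "measure", values_to = "importance"
  )
  ggplot2::ggplot(imp, ggplot2::aes(
    .data$importance, stats::reorder(.data$feature, .data$importance)
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~measure, scales = "free_x") +
    ggplot2::labs(x = "importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the Gibbs log-posterior trace
#'
#' @param object A `deconv_fit`.
#' @param ... Unused.
#' @export
autoplot.deconv_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$trace, ggplot2::aes(.data$sweep, .data$log_posterior)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$burn_in, linetype = "dashed") +
    ggplot2::labs(x = "sweep", y = "log posterior (unnormalized)") +
    ggplot2::theme_minimal()
}
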