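#' Genome-wide windowed F_ST profile
#'
#' Manhattan-style profile of window F_ST against position, faceted by
#' chromosome, with optional per-pair threshold lines.
#'
#' @param x A `divscan_scan` object or a windowed-F_ST tibble.
#' @param pair Optional pair label to restrict a scan object to.
#' @return A ggplot object.
#' @export
plot_fst_windows <- function(x, pair = NULL) {
  if (inherits(x, "divscan_scan")) {
    w <- x$windows
    thr <- x$thresholds
    thr$pair <- paste(thr$pop_a, thr$pop_b, sep = "-")
    if (!is.null(pair)) {
      w <- w[w$pair == pair, ]
      thr <- thr[thr$pair == pair, ]
    }
  } else {
    w <- x
    thr <- NULL
  }
  w <- w[!is.na(w$fst), ]
  w$mid <- (w$start + w$end) / 2e6
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$mid, y = .data$fst)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::facet_grid(
      rows = if ("pair" %in% names(w)) ggplot2::vars(.data$pair) else NULL,
      cols = ggplot2::vars(.data$chrom),
      scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(F[ST])) +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(thr) && nrow(thr)) {
    p <- p + ggplot2::geom_hline(
      data = thr, ggplot2::aes(yintercept = .data$threshold),
      linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @rdname geno_pca
#' @param object A `divscan_pca` object.
#' @param axes Which two axes to plot.
#' @param pop_map Optional population map used to colour samples.
#' @export
autoplot.divscan_pca <- function(object, axes = c(1, 2), pop_map = NULL, ...) {
  sc <- object$scores
  ax <- paste0("PC", axes)
  df <- tibble::tibble(sample = sc$sample, x = sc[[ax[1]]], y = sc[[ax[2]]])
  if (!is.null(pop_map)) df$population <- population_of(pop_map, df$sample)
  lab <- sprintf("%s (%.1f%%)", ax, object$var_fraction[axes])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
  if (!is.null(pop_map)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$population))
  } else {
    p + ggplot2::geom_point()
  }
}

#' Delta-K profile across candidate cluster numbers
#'
#' @param evanno Tibble from [evanno_delta_k()].
#' @return A ggplot object.
#' @export
plot_delta_k <- function(evanno) {
  df <- evanno[!is.na(evanno$delta_k), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$delta_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = df$K) +
    ggplot2::labs(y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}
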