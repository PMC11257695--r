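# ggplot2 views of learnt profiles and summary statistics.

#' Plot learnt reference profiles
#'
#' Scatter of per-gene non-zero mean versus dropout rate, coloured by
#' category — the learnt analogue of the mean-dropout relationship.
#'
#' @param object A `reference_profiles` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reference_profiles
#' @export
autoplot.reference_profiles <- function(object, ...) {
  p <- object$profiles
  ggplot2::ggplot(p, ggplot2::aes(x = .data$mean_nz, y = .data$dropout_rate,
                                  colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "non-zero mean (log pseudocounts)", y = "dropout rate",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' Mean-variance and mean-dropout scatter plots
#'
#' Standard per-gene diagnostic views of a summary table; overlaying the
#' reference and a synthetic matrix shows how well generation reproduces the
#' statistics of the reference.
#'
#' @param summary Tibble from [summarise_expression()], or a named list of
#'   such tibbles (names used as panel labels).
#' @return A ggplot object.
#' @export
plot_mean_variance <- function(summary) {
  df <- bind_summaries(summary)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$variance,
                                   colour = .data$source)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "gene mean", y = "gene variance") +
    ggplot2::theme_minimal()
}

#' @rdname plot_mean_variance
#' @export
plot_mean_dropout <- function(summary) {
  df <- bind_summaries(summary)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$dropout_rate,
                                   colour = .data$source)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "gene mean", y = "dropout rate") +
    ggplot2::theme_minimal()
}

bind_summaries <- function(summary) {
  if (is.data.frame(summary)) return(dplyr::mutate(summary, source = "data"))
  dplyr::bind_rows(purrr::imap(summary, function(df, nm) dplyr::mutate(df, source = nm)))
}

#' Plot binarised-call fractions per gene
#'
#' Stacked fractions of 0 / 1 / undetermined calls per gene, optionally
#' grouped by profile category — the category-dependent binarisation
#' footprint.
#'
#' @param binary Binary tibble from [binarise()].
#' @param profiles Optional `reference_profiles` for category facets.
#' @return A ggplot object.
#' @export
plot_binarised_fractions <- function(binary, profiles = NULL) {
  counts <- purrr::map(gene_ids(binary), function(g) {
    v <- binary[[g]]
    tibble::tibble(gene = g,
                   call = c("0", "1", "undetermined"),
                   fraction = c(mean(v == 0, na.rm = TRUE) * mean(!is.na(v)),
                                mean(v == 1, na.rm = TRUE) * mean(!is.na(v)),
                                mean(is.na(v))))
  })
  df <- dplyr::bind_rows(counts)
  if (!is.null(profiles))
    df <- dplyr::left_join(df, profiles$profiles[, c("gene", "category")], by = "gene")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$fraction,
                                        fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if (!is.null(profiles))
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free_x")
  p
}
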