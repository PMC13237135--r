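# ggplot2 views of the main result types.

#' Heatmap of a scored screen
#'
#' Codon-by-substitution tile map of final functional z-scores, the standard
#' variant-effect-map view: rows are substituted amino acids (stop `*` and
#' frameshift `fs` kept as separate rows), columns are codons, fill is
#' `mean_z`. Missing scores render as blank tiles.
#'
#' @param object A `dms_scores` tibble from [dms_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dms_scores <- function(object, ...) {
  lev <- c(FRAMESHIFT_TOKEN, STOP_TOKEN, rev(AA_ALPHABET))
  df <- dplyr::mutate(as_tibble(object),
    alt_aa = factor(.data$alt_aa, levels = lev)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$codon, y = .data$alt_aa, fill = .data$mean_z
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", midpoint = 0,
      name = "mean z"
    ) +
    ggplot2::labs(x = "codon", y = "substitution") +
    ggplot2::theme_minimal()
}

#' Residue intolerance rank plot
#'
#' Residues ranked by their mean missense z-score, with the intolerance
#' cutoff drawn as a dashed line and intolerant residues highlighted.
#'
#' @param profile Tibble from [residue_profile()].
#' @return A ggplot object.
#' @export
plot_residue_profile <- function(profile) {
  check_columns(profile, c("codon", "residue_mean_z", "intolerant"), "profile")
  df <- profile %>%
    filter(!is.na(.data$residue_mean_z)) %>%
    arrange(.data$residue_mean_z) %>%
    mutate(rank = row_number())
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rank, y = .data$residue_mean_z, colour = .data$intolerant
  )) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "residue rank", y = "residue mean z", colour = "intolerant") +
    ggplot2::theme_minimal()
  cutoff <- attr(profile, "cutoff")
  if (!is.null(cutoff) && is.finite(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}

#' @rdname quadrant_concordance
#' @param object A `quadrant_test`.
#' @export
autoplot.quadrant_test <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(
    x = .data$l2fc_peak, y = .data$l2fc_gene
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      x = "peak log2 fold-change", y = "gene log2 fold-change",
      subtitle = sprintf("concordance %.1f%% (n = %d)",
        100 * object$concordance, object$n)
    ) +
    ggplot2::theme_minimal()
}
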