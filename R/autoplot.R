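#' Plot a block profile as a motif-block map
#'
#' Blocks are drawn as segments along the transcript, labelled by their
#' match count.
#'
#' @param object A `block_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot block_profile
#' @export
autoplot.block_profile <- function(object, ...) {
  df <- as_tibble(object) |> mutate(block = factor(row_number()))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = 1, yend = 1,
                   colour = .data$block),
      linewidth = 4, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(x = .data$center, y = 1.1,
                                    label = .data$n_matches), size = 3) +
    ggplot2::xlim(0, attr(object, "seq_length")) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(0.5, 1.5)) +
    ggplot2::labs(x = "Transcript position (nt)",
                  title = sprintf("Motif blocks: %s", attr(object, "seq_id"))) +
    ggplot2::theme_minimal()
}

#' Plot a block alignment as paired transcript tracks
#'
#' The two transcripts are drawn as horizontal tracks with their motif
#' blocks; aligned block pairs are connected, shaded by block similarity.
#'
#' @param object A `block_alignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot block_alignment
#' @export
autoplot.block_alignment <- function(object, ...) {
  a <- as_tibble(object$profile_a) |> mutate(y = 2)
  b <- as_tibble(object$profile_b) |> mutate(y = 1)
  blocks <- bind_rows(a, b)
  links <- tidy(object)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = blocks,
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$y,
                   yend = .data$y),
      linewidth = 4, colour = "grey35")
  if (nrow(links) > 0) {
    p <- p + ggplot2::geom_segment(
      data = links,
      ggplot2::aes(x = .data$center_a, xend = .data$center_b, y = 2, yend = 1,
                   alpha = .data$similarity),
      colour = "steelblue")
  }
  p +
    ggplot2::scale_y_continuous(NULL, breaks = c(1, 2),
                                labels = c(attr(object$profile_b, "seq_id"),
                                           attr(object$profile_a, "seq_id")),
                                limits = c(0.5, 2.5)) +
    ggplot2::labs(x = "Transcript position (nt)",
                  title = sprintf("MPSS %.2f, GPS %.1f", object$mpss, object$gps),
                  alpha = "Block similarity") +
    ggplot2::theme_minimal()
}

#' Plot gene-level screen results as a ranked rho curve
#'
#' @param object An `rra_result` from [rra_gene_scores()].
#' @param alpha Highlight genes with p-value below this level
#'   (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rra_result
#' @export
autoplot.rra_result <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object) |> mutate(hit = .data$p_value < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$rho,
                                   colour = .data$hit)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Gene rank", y = "RRA rho score",
                  colour = sprintf("p < %.2g", alpha)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
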