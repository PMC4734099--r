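## ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot candidate support against conservation
#'
#' One point per non-redundant entry: transcript length against total read
#' support (log scale), colored by total homolog count when conservation
#' was profiled.
#'
#' @param object An `srna_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot srna_result
#' @export
autoplot.srna_result <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = length_nt, y = reads_total + 1)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "candidate length (nt)",
                  y = "total dRNA-Seq reads + 1",
                  title = "Predicted sRNA candidates")
  if ("homologs_total" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = homologs_total)) +
      ggplot2::labs(color = "homologs")
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::theme_minimal()
}

#' Presence/absence conservation map
#'
#' Genomes as rows (panel order, clade genomes marked), candidates as
#' columns sorted ascending by homolog count so the most conserved sit on
#' the right — the standard display convention for such maps.
#'
#' @param object A `conservation_profiles` object.
#' @param min_homologs Display threshold on total homolog count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conservation_profiles
#' @export
autoplot.conservation_profiles <- function(object, min_homologs = 10L, ...) {
  m <- build_matrix(object, min_homologs = min_homologs, decreasing = FALSE)
  d <- tibble(genome_id = rep(rownames(m), ncol(m)),
              query_id = rep(colnames(m), each = nrow(m)),
              present = as.integer(m))
  d$genome_id <- factor(d$genome_id, levels = rev(rownames(m)))
  d$query_id <- factor(d$query_id, levels = colnames(m))
  d$clade <- d$genome_id %in% object$clade
  ggplot2::ggplot(d, ggplot2::aes(x = query_id, y = genome_id,
                                  fill = factor(present),
                                  alpha = clade)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "grey20"),
                               guide = "none") +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.6, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "candidate (ascending homolog count)", y = NULL,
                  title = "Homolog presence across the genome panel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
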