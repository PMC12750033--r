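#' Plot a residue track
#'
#' Per-residue values along the chain, one panel per chain.
#'
#' @param object A [residue_track()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.residue_track <- function(object, ...) {
  nm <- attr(object, "name") %||% "value"
  un <- attr(object, "units") %||% ""
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$resi, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chain), scales = "free_x") +
    ggplot2::labs(x = "residue",
                  y = if (nzchar(un) && un != "dimensionless")
                    sprintf("%s (%s)", nm, un) else nm) +
    ggplot2::theme_minimal()
}

#' Plot an FSC curve
#'
#' Correlation versus spatial frequency with the 0.5 (half-map local
#' resolution) and 0.143 (global resolution) thresholds marked.
#'
#' @param object An `fsc_curve` from [fsc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.fsc_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$freq, y = .data$fsc)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = c(0.5, 0.143), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "spatial frequency (1/Å)", y = "FSC") +
    ggplot2::theme_minimal()
}
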