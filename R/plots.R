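#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of marker states across a screened panel
#'
#' @param calls marker-screen calls
#' @return ggplot object
#' @export
plot_marker_profile <- function(calls) {
  calls |>
    ggplot2::ggplot(ggplot2::aes(x = .data$marker, y = .data$strain,
                                 fill = .data$state)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = NULL, fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Copy-number estimates with the integer calls
#'
#' @param cn copy-number tibble from [copy_number()]
#' @return ggplot object
#' @export
plot_copy_number <- function(cn) {
  cn |>
    ggplot2::ggplot(ggplot2::aes(x = .data$strain, y = .data$ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$rounded),
                       vjust = -0.4, size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene)) +
    ggplot2::labs(x = NULL, y = "median coverage ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' SNP-matrix allele heatmap
#'
#' @param object `snp_matrix`
#' @param ... unused
#' @return ggplot object
#' @exportS3Method ggplot2::autoplot
autoplot.snp_matrix <- function(object, ...) {
  tidy(object) |>
    mutate(allele = ifelse(.data$allele %in% DNA_BASES, .data$allele,
                           "ambiguous")) |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$pos), y = .data$strain,
                                 fill = .data$allele)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      A = "#66c2a5", C = "#fc8d62", G = "#8da0cb", T = "#e78ac3",
      ambiguous = "grey85")) +
    ggplot2::labs(x = "SNP column", y = NULL, fill = "allele") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @exportS3Method generics::tidy
tidy.domestiscan_panel <- function(x, ...) x$truth

#' @exportS3Method generics::glance
glance.domestiscan_panel <- function(x, ...) {
  tibble(n_strains = nrow(x$truth), n_presets = length(unique(x$truth$preset)),
         n_chrom = nrow(x$reference),
         genome_len = sum(nchar(x$reference$seq)),
         seed = x$params$seed)
}
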