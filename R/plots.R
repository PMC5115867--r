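#' Plot module--trait coupling
#'
#' Bar chart of per-module mean gene--trait correlation with standard-error
#' bars, the layout used to display which module tracks the induced-defense
#' trait.
#'
#' @param x Output of [module_trait_correlation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eds_trait_cor <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = stats::reorder(.data$module_name,
                                                     -.data$mean_cor),
                                  y = .data$mean_cor,
                                  fill = .data$module_name)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_cor - .data$se_cor,
                                        ymax = .data$mean_cor + .data$se_cor),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "mean gene-trait correlation") +
    ggplot2::theme_minimal()
}

#' Plot omega distributions
#'
#' Density overlay of Ka/Ks ratios for two gene sets (e.g. module vs
#' genome-wide), excluded and saturated pairs dropped.
#'
#' @param module_kaks,genome_kaks Tibbles from [kaks_pairs()].
#' @return A ggplot object.
#' @export
plot_omega_distributions <- function(module_kaks, genome_kaks) {
  df <- bind_rows(
    mutate(module_kaks, set = "module"),
    mutate(genome_kaks, set = "genome-wide")
  ) |>
    filter(!.data$excluded, !.data$saturated, !is.na(.data$omega))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$omega, fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = expression(omega ~ "(Ka/Ks)"), y = "density") +
    ggplot2::theme_minimal()
}

#' Plot preservation Z-summaries
#'
#' Dot plot of per-module Z-summary with the 2 (not preserved) and 10
#' (strongly preserved) reference lines.
#'
#' @param preservation Output of [module_preservation()].
#' @return A ggplot object.
#' @export
plot_preservation <- function(preservation) {
  ggplot2::ggplot(preservation,
                  ggplot2::aes(x = .data$module, y = .data$z_summary)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = c(2, 10), linetype = "dashed",
                        colour = c("grey40", "steelblue")) +
    ggplot2::labs(x = NULL, y = "preservation Z-summary") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.eds_network <- function(x, ...) export_edges(x, weight_cutoff = 0)

#' @export
glance.eds_network <- function(x, ...) {
  ut <- upper.tri(x$tom)
  tibble(n_genes = length(x$genes), power = x$config$power,
         signed = x$config$signed,
         mean_adjacency = mean(x$adjacency[ut]),
         mean_tom = mean(x$tom[ut]))
}

#' @export
tidy.eds_modules <- function(x, ...) as_tibble(x)

#' @export
glance.eds_modules <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_modules = length(unique(x$module[x$module > 0])),
         n_unassigned = sum(x$module == 0),
         largest = if (any(x$module > 0)) max(table(x$module[x$module > 0]))
         else 0L)
}
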