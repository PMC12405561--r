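#' Boxplots of site-level NPP by biome or climate region
#'
#' The stratified distribution view behind the outlier QC: one box per
#' stratum for site-level ANPP, BNPP or total NPP.
#'
#' @param site_means Tibble as from [site_npp_means()].
#' @param variable `"anpp"`, `"bnpp"` or `"tnpp"`.
#' @param stratify_by `"biome"` or `"climate_region"`.
#' @return A ggplot.
#' @export
plot_npp_boxplots <- function(site_means, variable = c("tnpp", "anpp", "bnpp"),
                              stratify_by = c("biome", "climate_region")) {
  variable <- match.arg(variable)
  stratify_by <- match.arg(stratify_by)
  df <- site_means[!is.na(site_means[[variable]]) &
                     !is.na(site_means[[stratify_by]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[stratify_by]],
                                   y = .data[[variable]])) +
    ggplot2::geom_boxplot(outlier.colour = "firebrick") +
    ggplot2::labs(x = NULL, y = paste(toupper(variable), "(g m⁻² yr⁻¹)"))
}
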