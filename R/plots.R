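#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.single_screen_result <- function(x, ...) {
  dplyr::mutate(x$genes, model_id = x$model_id, medium = x$medium,
                biomass = x$biomass, .before = 1)
}

#' @export
glance.single_screen_result <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, medium = x$medium, biomass = x$biomass,
                 wild_type_flux = x$wild_type_flux,
                 n_genes = sum(x$genes$in_model),
                 n_essential = sum(x$genes$essential))
}

#' @export
tidy.double_screen_result <- function(x, ...) {
  dplyr::mutate(x$pairs, model_id = x$model_id, .before = 1)
}

#' @export
glance.double_screen_result <- function(x, ...) {
  lethal <- x$pairs$pair_flux <= x$config$sl_wildtype_fraction * x$wild_type_flux
  tibble::tibble(model_id = x$model_id, n_pairs = nrow(x$pairs),
                 n_predicted_lethal = sum(lethal),
                 wild_type_flux = x$wild_type_flux)
}

#' @export
tidy.fba_result <- function(x, ...) {
  if (is.null(x$fluxes)) {
    return(tibble::tibble(reaction_id = character(), flux = numeric()))
  }
  tibble::tibble(reaction_id = names(x$fluxes), flux = unname(x$fluxes))
}

#' Heatmap of a binary incidence matrix
#'
#' Models on the vertical axis, features (ORFs or ChEBI ids) on the
#' horizontal; filled cells mark inclusion. Feature columns are ordered by
#' prevalence so shared cores group visually.
#'
#' @param object an `incidence_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.incidence_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("model_id", "feature", "present")
  ord <- names(sort(colSums(unclass(object)), decreasing = TRUE))
  df$feature <- factor(df$feature, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$model_id,
                                   fill = factor(.data$present))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "goldenrod2"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Heatmap of an MCC screening grid
#'
#' One tile per model x condition (medium, biomass, reference list), shaded
#' by MCC — the standard way to eyeball how sensitive each model's
#' essentiality predictions are to the simulation parameters.
#'
#' @param cells the `cells` tibble from [run_comparison()] (columns
#'   `model`, `medium`, `biomass`, `reference`, `mcc`).
#' @return a ggplot object.
#' @export
plot_mcc_grid <- function(cells) {
  df <- dplyr::filter(cells, !is.na(.data$mcc))
  df$condition <- paste(df$medium, df$biomass, df$reference, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$condition,
                                   fill = .data$mcc)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mcc)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "MCC") +
    ggplot2::theme_minimal()
}

#' Scatterplot of a constrained growth scan
#'
#' Predicted maximum biomass flux against observed growth rate, one point
#' per condition, with the identity-through-origin trend that a
#' well-calibrated single-limiting-nutrient regime produces.
#'
#' @param scan tibble from [constrained_growth_scan()].
#' @return a ggplot object.
#' @export
plot_growth_scan <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$growth_rate,
                                     y = .data$predicted_flux)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, color = "steelblue") +
    ggplot2::labs(x = "observed growth rate (1/h)",
                  y = "predicted max biomass flux") +
    ggplot2::theme_minimal()
}

#' MDS scatter of model scope
#'
#' @param coords tibble from [classical_mds()].
#' @return a ggplot object.
#' @export
plot_mds <- function(coords) {
  ggplot2::ggplot(coords, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                       label = .data$model_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
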