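#' Boxplots of per-species metric shifts against the reference set
#'
#' One box per predictor set (external evaluation), faceted by technique:
#' the distribution over species of the metric difference to the reference
#' set. The analogue of the classic substitution-experiment figure.
#'
#' @param x an `eiv_experiment`.
#' @param metric metric column (default `"auc"`).
#' @param reference reference predictor set (default `"M_ref"`).
#' @return A ggplot object.
#' @export
plot_performance_shift <- function(x, metric = "auc", reference = "M_ref") {
  stopifnot(inherits(x, "eiv_experiment"))
  ext <- x$metrics[x$metrics$eval_kind == "external", ]
  wide <- tidyr::pivot_wider(
    ext[, c("species_id", "technique", "predictor_set", metric)],
    names_from = "predictor_set", values_from = dplyr::all_of(metric))
  sets <- setdiff(unique(ext$predictor_set), reference)
  long <- purrr::map_dfr(sets, function(s) {
    tibble(species_id = wide$species_id, technique = wide$technique,
           predictor_set = s, delta = wide[[s]] - wide[[reference]])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$predictor_set,
                                     y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~technique) +
    ggplot2::labs(x = NULL,
                  y = sprintf("%s difference to %s (external evaluation)",
                              toupper(metric), reference)) +
    ggplot2::theme_bw()
}

#' Boxplots of normalized variable importance per predictor set
#'
#' Importances are normalized within each fitted model to fractions
#' summing to one (raw values stay available in the experiment object),
#' then shown per variable and predictor set.
#'
#' @param x an `eiv_experiment`.
#' @param technique technique to display (default: first available).
#' @param normalize normalize within model to fractions (default TRUE).
#' @return A ggplot object.
#' @export
plot_importance_profile <- function(x, technique = NULL, normalize = TRUE) {
  stopifnot(inherits(x, "eiv_experiment"))
  imp <- x$importances
  stopifnot(!is.null(imp), nrow(imp) > 0)
  technique <- technique %||% imp$technique[1]
  imp <- imp[imp$technique == technique, ]
  if (normalize) {
    imp <- imp |>
      group_by(.data$species_id, .data$predictor_set) |>
      mutate(importance = if (sum(.data$importance) > 0)
        .data$importance / sum(.data$importance) else NA_real_) |>
      ungroup()
  }
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$variable,
                                    y = .data$importance)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~predictor_set, scales = "free_x") +
    ggplot2::labs(x = NULL,
                  y = if (normalize) "normalized importance" else
                    "raw importance",
                  title = sprintf("Permutation importance (%s)", technique)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @method autoplot eiv_experiment
#' @export
#' @importFrom ggplot2 autoplot
autoplot.eiv_experiment <- function(object, metric = "auc", ...) {
  plot_performance_shift(object, metric = metric)
}
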