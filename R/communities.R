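#' Gaussian-niche occurrence probabilities
#'
#' Probability of presence for each (plot, species) pair under independent
#' Gaussian responses on the species' driving latent dimensions:
#' `P = prevalence_scale * prod_d exp(-(x_d - opt_d)^2 / (2 sd_d^2))`.
#'
#' @param species species pool tibble (needs `opt_*`, `sd_*`,
#'   `prevalence_scale`).
#' @param latent_values tibble/data frame of latent gradient values at the
#'   plots, one column per driving dimension.
#' @return A plots x species matrix of probabilities in `[0, 1]`.
#' @export
occurrence_probability <- function(species, latent_values) {
  dims <- sub("^opt_", "", grep("^opt_", names(species), value = TRUE))
  missing_cols <- setdiff(dims, names(latent_values))
  if (length(missing_cols) > 0) {
    stopf("latent values missing for dimension(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  n <- nrow(latent_values); s <- nrow(species)
  logp <- matrix(rep(log(species$prevalence_scale), each = n), n, s)
  for (d in dims) {
    x <- latent_values[[d]]
    opt <- species[[paste0("opt_", d)]]
    sdd <- species[[paste0("sd_", d)]]
    if (any(sdd <= 0)) stopf("niche breadths on '%s' must be positive", d)
    logp <- logp - outer(x, opt, "-")^2 /
      matrix(rep(2 * sdd^2, each = n), n, s)
  }
  p <- exp(logp)
  dimnames(p) <- list(NULL, species$species_id)
  p
}

#' Assemble virtual plant communities
#'
#' Samples plot locations (grid cells without replacement), draws species
#' presences as Bernoulli trials of the Gaussian-niche suitability on the
#' LATENT gradients, and records the MAPPED layer values at the plots as
#' the plot-level predictors, mirroring a field campaign where communities
#' respond to true local conditions but the analyst only has imperfect
#' maps.
#'
#' @param landscape an `eiv_landscape`.
#' @param species species pool tibble.
#' @param n_plots number of plots (<= number of grid cells).
#' @param seed integer seed.
#' @param group_prop optional named proportions splitting plots into groups
#'   (e.g. `c(forest = 0.75, grassland = 0.25)`).
#' @param detection optional named per-group detection factor multiplying
#'   occurrence probabilities (default 1 for every group).
#' @return An object of class `eiv_community`: `plots` (id, x, y, group),
#'   `predictors` (mapped layer values per plot), `latent` (latent values,
#'   kept for validation), and `presence` (plot x species 0/1 matrix).
#' @export
assemble_communities <- function(landscape, species, n_plots = 1200,
                                 seed = 1L, group_prop = NULL,
                                 detection = NULL) {
  stopifnot(inherits(landscape, "eiv_landscape"), n_plots >= 1)
  n_cells <- prod(landscape$grid)
  if (n_plots > n_cells) {
    stopf("n_plots (%d) exceeds the number of grid cells (%d)",
          n_plots, n_cells)
  }
  withr::with_seed(seed, {
    cell_idx <- sample.int(n_cells, n_plots)
    cells <- tibble(
      y = ((cell_idx - 1) %% landscape$grid[1]) + 1L,
      x = ((cell_idx - 1) %/% landscape$grid[1]) + 1L
    )
    group <- rep(NA_character_, n_plots)
    if (!is.null(group_prop)) {
      group <- sample(names(group_prop), n_plots, replace = TRUE,
                      prob = group_prop)
    }
    plots <- tibble(plot_id = sprintf("plot%05d", seq_len(n_plots)),
                    x = cells$x, y = cells$y, group = group)
    latent <- extract_layers(landscape, cells, "latent")
    mapped <- extract_layers(landscape, cells, "mapped")
    p <- occurrence_probability(species, latent)
    if (!is.null(detection)) {
      fac <- rep(1, n_plots)
      known <- !is.na(group) & group %in% names(detection)
      fac[known] <- detection[group[known]]
      p <- p * fac
    }
    presence <- matrix(rbinom(length(p), 1L, p), nrow(p), ncol(p),
                       dimnames = list(plots$plot_id, colnames(p)))
    structure(
      list(plots = plots,
           predictors = bind_cols(plots["plot_id"], mapped),
           latent = bind_cols(plots["plot_id"], latent),
           presence = presence,
           seed = as.integer(seed)),
      class = "eiv_community"
    )
  })
}

#' @export
print.eiv_community <- function(x, ...) {
  cat(sprintf("<eiv_community> %d plots x %d species (%d occurrences)\n",
              nrow(x$presence), ncol(x$presence), sum(x$presence)))
  cat("  predictors: ",
      paste(setdiff(names(x$predictors), "plot_id"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# accept an eiv_community, a 0/1 matrix, or a wide data frame with plot_id
as_presence_matrix <- function(x) {
  if (inherits(x, "eiv_community")) return(x$presence)
  if (is.matrix(x)) {
    if (is.null(colnames(x))) abort("presence matrix needs species column names")
    return(x)
  }
  if (is.data.frame(x)) {
    if (!"plot_id" %in% names(x)) abort("wide presence table needs a plot_id column")
    m <- as.matrix(x[setdiff(names(x), "plot_id")])
    rownames(m) <- x$plot_id
    return(m)
  }
  abort("cannot interpret object as a plot x species presence matrix")
}

#' Select species by prevalence
#'
#' Keeps species observed in strictly more than `min_presences` plots
#' ("more than n presence records"); a species with exactly
#' `min_presences` presences is excluded.
#'
#' @param x an `eiv_community`, presence matrix, or wide presence table.
#' @param min_presences threshold (default 50).
#' @return Character vector of retained species ids, in original column
#'   order.
#' @export
filter_species_by_prevalence <- function(x, min_presences = 50) {
  stopifnot(min_presences >= 1)
  m <- as_presence_matrix(x)
  colnames(m)[colSums(m) > min_presences]
}
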