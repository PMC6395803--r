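#' Configure a virtual species pool
#'
#' Niche breadths are expressed in units of the SD of the corresponding
#' latent layer, so the same configuration produces comparable niche widths
#' on gradients with different units.
#'
#' @param dims latent dimensions that drive niches (default: all landscape
#'   dimensions).
#' @param breadth_range range of Gaussian niche breadths, in latent-layer
#'   SD units: either a length-2 numeric applied to every dimension, or a
#'   named list of length-2 ranges with an optional `.default` entry. The
#'   default makes thermal filtering strong (mountain elevation gradients
#'   sort species sharply by temperature) and continentality filtering
#'   weak (a broad-scale gradient that constrains local occurrence least).
#' @param active_prob probability that a species' niche is actually
#'   constrained by a dimension: either a single number or a named list
#'   with `.default`. A species indifferent to a dimension gets a flat
#'   response on it (no filtering) and no indicator value there, as
#'   indicator compilations leave indifferent species unscored. Every
#'   species is thermally constrained by default.
#' @param prevalence_range range of the per-species prevalence scale
#'   (suitability at the multivariate optimum), in (0, 1].
#' @param missing_eiv_rate additional fraction of scored (species,
#'   dimension) indicator values set to missing, emulating gaps in expert
#'   indicator tables.
#' @param balanced balance the niche assignment against the thermal
#'   gradient (default TRUE). In a finite pool, randomly drawn optima
#'   leave chance smooth dependence of every other dimension's optima on
#'   the thermal optimum; community means then inherit that dependence,
#'   and an accurate temperature map can predict them for reasons that
#'   have nothing to do with the environment they indicate. Balancing
#'   re-assigns each non-thermal dimension's optima so that their smooth
#'   (spline) dependence on the thermal optimum is removed while the
#'   uniform marginal is kept exactly.
#' @return A list of class `species_config`.
#' @export
species_config <- function(dims = NULL,
                           breadth_range = list(temperature = c(0.7, 1.3),
                                                continentality = c(1.5, 3),
                                                .default = c(1.1, 2.2)),
                           active_prob = list(temperature = 1,
                                              continentality = 0.8,
                                              moisture = 0.75,
                                              .default = 0.65),
                           prevalence_range = c(0.8, 1),
                           missing_eiv_rate = 0.03,
                           balanced = TRUE) {
  if (!is.list(breadth_range)) {
    breadth_range <- list(.default = breadth_range)
  }
  if (!is.list(active_prob)) {
    active_prob <- list(.default = active_prob)
  }
  stopifnot(all(vapply(breadth_range, function(r)
    length(r) == 2 && all(r > 0), TRUE)),
    all(unlist(active_prob) >= 0), all(unlist(active_prob) <= 1),
    prevalence_range[1] > 0, prevalence_range[2] <= 1,
    missing_eiv_rate >= 0, missing_eiv_rate < 1)
  structure(list(dims = dims, breadth_range = breadth_range,
                 active_prob = active_prob,
                 prevalence_range = prevalence_range,
                 missing_eiv_rate = missing_eiv_rate,
                 balanced = isTRUE(balanced)),
            class = "species_config")
}

# ordinal bin of a niche optimum: 5 equal-width bins over the observed
# latent range, upper edge clipped into bin 5
eiv_bin <- function(opt, lo, hi, n_bins = 5L) {
  if (hi <= lo) return(rep(1L, length(opt)))
  pmin(1L + as.integer(floor(n_bins * (opt - lo) / (hi - lo))), n_bins)
}

# remove the smooth (natural-spline) dependence of `opt` on `anchor`,
# keeping the marginal exactly uniform over [lo, hi]
balance_optima <- function(opt, anchor, lo, hi, df = 8) {
  u <- rank(anchor, ties.method = "first") / (length(anchor) + 1)
  res <- stats::resid(stats::lm(opt ~ splines::ns(u, df = df)))
  lo + (hi - lo) * (rank(res, ties.method = "first") - 0.5) / length(res)
}

#' Generate a pool of virtual species
#'
#' Each species gets a Gaussian niche on every driving latent dimension:
#' an optimum drawn uniformly over the observed layer range, a breadth
#' drawn from the configured range, and a prevalence scale. Its ecological
#' indicator value on a dimension is the ordinal bin (1-5, equal-width over
#' the landscape-wide latent range) of the niche optimum, so the EIV is an
#' honest but coarse summary of the true optimum, as in real indicator
#' systems.
#'
#' @param landscape an `eiv_landscape`.
#' @param n_species number of species (>= 1).
#' @param config a [species_config()].
#' @param seed integer seed.
#' @return A tibble with one row per species: `species_id`,
#'   `prevalence_scale`, `opt_*` and `sd_*` niche columns per dimension,
#'   and ordinal indicator columns named by Landolt letter (`T`, `M`, `L`,
#'   `K`, `R`, `N`; `NA` = missing).
#' @export
generate_species_pool <- function(landscape, n_species = 250,
                                  config = species_config(), seed = 1L) {
  stopifnot(inherits(landscape, "eiv_landscape"), n_species >= 1)
  dims <- config$dims %||% names(landscape$latent)
  unknown <- setdiff(dims, names(landscape$latent))
  if (length(unknown) > 0) {
    stopf("niche dimension(s) absent from landscape: %s",
          paste(unknown, collapse = ", "))
  }
  if (length(landscape$latent) == 0) abort("landscape has no latent layers")
  withr::with_seed(seed, {
    pool <- tibble(
      species_id = sprintf("sp%04d", seq_len(n_species)),
      prevalence_scale = runif(n_species, config$prevalence_range[1],
                               config$prevalence_range[2])
    )
    anchor_dim <- if ("temperature" %in% dims) "temperature" else dims[1]
    dims <- c(anchor_dim, setdiff(dims, anchor_dim))  # anchor drawn first
    for (d in dims) {
      layer <- landscape$latent[[d]]
      lo <- min(layer); hi <- max(layer)
      opt <- runif(n_species, lo, hi)
      if (config$balanced && d != anchor_dim && n_species >= 30) {
        opt <- balance_optima(opt, pool[[paste0("opt_", anchor_dim)]], lo, hi)
      }
      br <- config$breadth_range[[d]] %||% config$breadth_range$.default
      if (is.null(br)) {
        stopf("no breadth range (and no .default) for dimension '%s'", d)
      }
      breadth <- runif(n_species, br[1], br[2]) * sd(as.vector(layer))
      p_act <- config$active_prob[[d]] %||% config$active_prob$.default %||% 1
      active <- runif(n_species) < p_act
      breadth[!active] <- Inf   # indifferent species: flat response
      pool[[paste0("opt_", d)]] <- opt
      pool[[paste0("sd_", d)]] <- breadth
      letter <- EIV_LETTERS[[d]]
      eiv <- eiv_bin(opt, lo, hi)
      eiv[!active] <- NA_integer_  # indifferent species carry no score
      if (config$missing_eiv_rate > 0) {
        eiv[runif(n_species) < config$missing_eiv_rate] <- NA_integer_
      }
      pool[[letter]] <- eiv
    }
    pool
  })
}

#' Extract the species indicator-value table from a species pool
#'
#' @param pool a tibble from [generate_species_pool()].
#' @return A tibble with `species_id` and one ordinal column per indicator
#'   dimension present in the pool.
#' @export
species_eiv_table <- function(pool) {
  pool[, c("species_id", intersect(EIV_DIMS, names(pool)))]
}
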