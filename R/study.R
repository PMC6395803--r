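#' Simulate a complete study data set
#'
#' Bundles landscape generation, the virtual species pool, and community
#' assembly into one seeded call. All stage seeds are derived from the
#' master seed, so the whole data set is a pure function of
#' `(arguments, seed)`.
#'
#' @param seed master seed.
#' @param landscape a [landscape_config()].
#' @param species a [species_config()].
#' @param n_species number of virtual species (default 250).
#' @param n_plots number of vegetation plots (default 1200).
#' @param group_prop,detection passed to [assemble_communities()].
#' @return A list of class `eiv_study_data`: `landscape`, `species`
#'   (pool tibble), `eivs` (indicator table), `community`, and the `args`
#'   needed to reproduce it.
#' @export
simulate_study <- function(seed = 1L, landscape = landscape_config(),
                           species = species_config(), n_species = 250,
                           n_plots = 1200, group_prop = NULL,
                           detection = NULL) {
  args <- list(seed = as.integer(seed), landscape = landscape,
               species = species, n_species = n_species, n_plots = n_plots,
               group_prop = group_prop, detection = detection)
  land <- generate_landscape(landscape, seed = derive_seed(seed, 1L))
  pool <- generate_species_pool(land, n_species = n_species,
                                config = species,
                                seed = derive_seed(seed, 2L))
  comm <- assemble_communities(land, pool, n_plots = n_plots,
                               seed = derive_seed(seed, 3L),
                               group_prop = group_prop,
                               detection = detection)
  structure(list(landscape = land, species = pool,
                 eivs = species_eiv_table(pool), community = comm,
                 args = args),
            class = "eiv_study_data")
}

#' @export
print.eiv_study_data <- function(x, ...) {
  cat("<eiv_study_data>\n")
  print(x$landscape)
  cat(sprintf("  %d species in pool\n", nrow(x$species)))
  print(x$community)
  invisible(x)
}

#' Run the full synthetic study
#'
#' [simulate_study()] followed by [run_experiment()]; the returned
#' experiment's manifest additionally records the simulation arguments so
#' [reproduce_study()] can re-run the whole pipeline bit-identically.
#'
#' @param seed master seed (also used as the experiment seed unless the
#'   config sets its own).
#' @param config an [experiment_config()].
#' @param ... passed to [simulate_study()].
#' @return An `eiv_experiment` whose manifest contains `simulate_args`.
#' @export
run_study <- function(seed = 1L, config = experiment_config(seed = seed),
                      ...) {
  data <- simulate_study(seed = seed, ...)
  result <- run_experiment(data$community, data$eivs, config = config)
  result$manifest$simulate_args <- data$args
  result
}

#' Re-run a study from its manifest
#'
#' Re-executes simulation and experiment from the arguments recorded in an
#' experiment manifest; with unchanged code this reproduces the original
#' result bit-identically.
#'
#' @param manifest the `manifest` element of an `eiv_experiment` produced
#'   by [run_study()].
#' @return An `eiv_experiment`.
#' @export
reproduce_study <- function(manifest) {
  if (is.null(manifest$simulate_args)) {
    abort("manifest does not record simulation arguments; was it produced by run_study()?")
  }
  a <- manifest$simulate_args
  data <- simulate_study(seed = a$seed, landscape = a$landscape,
                         species = a$species, n_species = a$n_species,
                         n_plots = a$n_plots, group_prop = a$group_prop,
                         detection = a$detection)
  result <- run_experiment(data$community, data$eivs,
                           config = manifest$config)
  result$manifest$simulate_args <- a
  result
}
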