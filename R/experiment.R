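ROLE_NAMES <- c("temperature", "ph", "precipitation", "topo_position",
                "slope", "radiation")

#' Build the predictor-substitution sets
#'
#' Constructs the named predictor sets of the substitution experiment. The
#' reference set `M_ref` holds the six mapped predictors (roles:
#' temperature, soil pH, precipitation, topographic position, slope,
#' radiation). Each substitution set replaces one role with the
#' corresponding site-EIV column: `M_T` (temperature -> T), `M_R` /
#' `M_N` / `M_Soil` (pH -> R, N, or both N and R), `M_M`
#' (precipitation -> M), `M_K` (both topographic columns -> K, so this set
#' has one predictor fewer), `M_L` (radiation -> L), and `M_EIV` uses the
#' six site EIVs only. `M_cor`, when a correlation screen is supplied,
#' holds the candidate columns most strongly rank-correlated with the site
#' EIVs (see [select_best_correlated()]).
#'
#' @param mapped_columns named character vector mapping the six roles
#'   (`temperature`, `ph`, `precipitation`, `topo_position`, `slope`,
#'   `radiation`) to predictor column names.
#' @param eiv_columns named character vector mapping indicator letters
#'   (`T`, `M`, `L`, `K`, `R`, `N`; `F` accepted as an alias of `M`) to
#'   site-EIV column names. Default `eiv_<letter>`.
#' @param cor_map optional named character vector (dimension -> column)
#'   from [select_best_correlated()]; adds the `M_cor` set (duplicated
#'   columns collapsed).
#' @return Named list of character vectors of predictor columns, class
#'   `predictor_sets`.
#' @export
build_predictor_sets <- function(mapped_columns,
                                 eiv_columns = setNames(paste0("eiv_", EIV_DIMS),
                                                        EIV_DIMS),
                                 cor_map = NULL) {
  missing_roles <- setdiff(ROLE_NAMES, names(mapped_columns))
  if (length(missing_roles) > 0) {
    stopf("mapped_columns is missing role(s): %s",
          paste(missing_roles, collapse = ", "))
  }
  names(eiv_columns) <- canonical_eiv_names(names(eiv_columns))
  missing_eiv <- setdiff(EIV_DIMS, names(eiv_columns))
  if (length(missing_eiv) > 0) {
    stopf("eiv_columns is missing dimension(s): %s",
          paste(missing_eiv, collapse = ", "))
  }
  m <- mapped_columns; e <- eiv_columns
  ref <- unname(m[ROLE_NAMES])
  swap <- function(drop_roles, add_dims) {
    unname(c(m[setdiff(ROLE_NAMES, drop_roles)], e[add_dims]))
  }
  sets <- list(
    M_ref  = ref,
    M_T    = swap("temperature", "T"),
    M_Soil = swap("ph", c("N", "R")),
    M_R    = swap("ph", "R"),
    M_N    = swap("ph", "N"),
    M_M    = swap("precipitation", "M"),
    M_K    = swap(c("topo_position", "slope"), "K"),
    M_L    = swap("radiation", "L"),
    M_EIV  = unname(e[c("T", "N", "R", "M", "K", "L")])
  )
  if (!is.null(cor_map)) {
    mc <- unique(unname(cor_map))
    if (length(mc) < length(cor_map)) {
      inform("M_cor: duplicated best-correlated columns collapsed")
    }
    sets$M_cor <- mc
  }
  structure(sets, class = c("predictor_sets", "list"))
}

#' @export
print.predictor_sets <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("%-7s (%d): %s\n", nm, length(x[[nm]]),
                paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Select the candidate predictor best correlated with each site EIV
#'
#' For every indicator dimension, computes the Spearman rank correlation
#' between the site EIV and each candidate column over plots where both
#' are non-missing, and picks the candidate with the largest absolute
#' correlation (ties broken by column order).
#'
#' @param site_eivs tibble with `plot_id` and site-EIV columns named by
#'   dimension letter (as from [compute_site_eivs()] without a focal
#'   species).
#' @param candidates tibble with `plot_id` and numeric candidate columns.
#' @param dimensions dimensions to screen (default: letters present).
#' @return Named character vector (dimension -> chosen column) with the
#'   full correlation table in the `correlations` attribute.
#' @export
select_best_correlated <- function(site_eivs, candidates,
                                   dimensions = NULL) {
  dimensions <- dimensions %||% intersect(EIV_DIMS, names(site_eivs))
  cand_cols <- setdiff(names(candidates), "plot_id")
  if (length(cand_cols) == 0) abort("no candidate predictor columns")
  joined <- inner_join(site_eivs[, c("plot_id", dimensions)], candidates,
                       by = "plot_id")
  cor_tbl <- purrr::map_dfr(dimensions, function(d) {
    purrr::map_dfr(cand_cols, function(cc) {
      ok <- !is.na(joined[[d]]) & !is.na(joined[[cc]])
      if (sum(ok) < 3) {
        stopf("fewer than 3 complete plots for dimension %s vs %s", d, cc)
      }
      tibble(dimension = d, candidate = cc,
             rho = suppressWarnings(
               cor(joined[[d]][ok], joined[[cc]][ok], method = "spearman")))
    })
  })
  cor_tbl$rho[is.na(cor_tbl$rho)] <- 0
  picks <- vapply(dimensions, function(d) {
    sub <- cor_tbl[cor_tbl$dimension == d, ]
    sub$candidate[which.max(abs(sub$rho))]   # first max = column-order tie-break
  }, "")
  structure(picks, correlations = cor_tbl)
}

#' Configure the substitution experiment
#'
#' @param techniques SDM techniques to run.
#' @param sets predictor-set names to run (default: all built sets).
#' @param mapped_columns named role -> column vector (default: the six
#'   role names themselves, matching [assemble_communities()] output).
#' @param min_presences prevalence filter threshold (strictly more than;
#'   default 30, the package's synthetic-scale default).
#' @param n_internal internal 70/30 splits per species (default 10).
#' @param n_permutations permutations per variable for importance.
#' @param importance compute permutation importances (default TRUE).
#' @param include_mcor add the correlation-screened `M_cor` set, screened
#'   on a master-seeded 70% subset of plots only (default TRUE).
#' @param eval_prop external/internal evaluation share (default 0.3).
#' @param reference reference set for comparisons (default `"M_ref"`).
#' @param comparison_metric metric for the Wilcoxon-Holm comparisons.
#' @param hyper named list of per-technique hyperparameter lists.
#' @param seed master seed; every stage seed is derived from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(techniques = c("GLM", "GAM", "RF", "MAXENT", "SRE"),
                              sets = NULL, mapped_columns = NULL,
                              min_presences = 30, n_internal = 10,
                              n_permutations = 10, importance = TRUE,
                              include_mcor = TRUE, eval_prop = 0.3,
                              reference = "M_ref",
                              comparison_metric = "auc",
                              hyper = list(), seed = 1L) {
  techniques <- match.arg(techniques, several.ok = TRUE)
  structure(
    list(techniques = techniques, sets = sets,
         mapped_columns = mapped_columns, min_presences = min_presences,
         n_internal = n_internal, n_permutations = n_permutations,
         importance = importance, include_mcor = include_mcor,
         eval_prop = eval_prop, reference = reference,
         comparison_metric = comparison_metric, hyper = hyper,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# abort if a fitting step would touch external evaluation plots
check_no_leakage <- function(train_ids, evaluation_ids) {
  leaked <- intersect(train_ids, evaluation_ids)
  if (length(leaked) > 0) {
    stopf("leakage: %d external evaluation plot(s) in a fitting step (e.g. %s)",
          length(leaked), leaked[1])
  }
  invisible(TRUE)
}

#' Run the predictor-substitution experiment
#'
#' For every modellable species: computes leave-one-out site EIVs, builds
#' all predictor sets, draws a per-species split scheme (70% calibration /
#' 30% external evaluation plus internal 70/30 re-splits of the
#' calibration data), fits every technique x predictor set on calibration
#' data only, evaluates internally and externally, and computes
#' permutation variable importances on the calibration data. External
#' evaluation plots never enter any fitting step (enforced; a violation
#' aborts the run). Individual model failures are caught, logged, and
#' recorded as missing.
#'
#' @param comm an `eiv_community` (or compatible list with `predictors`
#'   and `presence`).
#' @param eivs species indicator table (`species_id` + letter columns).
#' @param config an [experiment_config()].
#' @param species species ids to model (default:
#'   [filter_species_by_prevalence()] at `config$min_presences`).
#' @return An object of class `eiv_experiment` with tibbles `metrics`,
#'   `importances`, `comparisons`, `summaries`, the `predictor_sets`, and
#'   a `manifest` (config, seeds, drop counts, failures).
#' @export
run_experiment <- function(comm, eivs, config = experiment_config(),
                           species = NULL) {
  presence <- as_presence_matrix(comm)
  predictors <- comm$predictors
  stopifnot(!is.null(predictors), "plot_id" %in% names(predictors))
  mapped_columns <- config$mapped_columns %||%
    setNames(intersect(ROLE_NAMES, names(predictors)),
             intersect(ROLE_NAMES, names(predictors)))
  species <- species %||%
    filter_species_by_prevalence(presence, config$min_presences)
  if (length(species) == 0) abort("no species passes the prevalence filter")
  eiv_dims <- intersect(EIV_DIMS, names(eivs))
  eiv_columns <- setNames(paste0("eiv_", eiv_dims), eiv_dims)

  # correlation screen for M_cor: all-species site EIVs, on a seeded 70%
  # screening subset only, so external evaluation data cannot influence
  # predictor selection
  cor_map <- NULL
  if (isTRUE(config$include_mcor)) {
    all_site <- compute_site_eivs(presence, eivs)
    screen_ids <- withr::with_seed(
      derive_seed(config$seed, 0L, 3L),
      sample(predictors$plot_id, ceiling(0.7 * nrow(predictors))))
    cor_map <- select_best_correlated(
      all_site[all_site$plot_id %in% screen_ids, ],
      predictors[predictors$plot_id %in% screen_ids, ])
  }
  sets <- build_predictor_sets(mapped_columns, eiv_columns, cor_map = cor_map)
  if (!is.null(config$sets)) {
    bad <- setdiff(config$sets, names(sets))
    if (length(bad) > 0) stopf("unknown predictor set(s): %s",
                               paste(bad, collapse = ", "))
    sets <- structure(sets[config$sets], class = class(sets))
  }
  needed_cols <- unique(unlist(sets))

  metrics <- list(); importances <- list(); failures <- list()
  dropped <- integer(length(species)); names(dropped) <- species
  for (i in seq_along(species)) {
    sp <- species[i]
    site <- compute_site_eivs(presence, eivs, focal_species = sp)
    eiv_part <- site[, c("plot_id", eiv_dims)]
    names(eiv_part) <- c("plot_id", unname(eiv_columns))
    data <- inner_join(predictors, eiv_part, by = "plot_id")
    data$.y <- as.integer(presence[match(data$plot_id, rownames(presence)), sp])
    ok <- complete.cases(data[, intersect(needed_cols, names(data))])
    dropped[sp] <- sum(!ok)
    data <- data[ok, ]
    if (nrow(data) < 10 || length(unique(data$.y)) < 2) {
      failures[[length(failures) + 1]] <-
        tibble(species_id = sp, predictor_set = NA_character_,
               technique = NA_character_,
               message = "too few usable plots or single-class response")
      next
    }
    scheme <- make_split_scheme(data$plot_id,
                                seed = derive_seed(config$seed, i, 1L),
                                eval_prop = config$eval_prop,
                                n_internal = config$n_internal)
    rows_of <- function(ids) data[match(ids, data$plot_id), ]
    calib <- rows_of(scheme$calibration)
    ext <- rows_of(scheme$evaluation)
    fit_counter <- 0L
    for (set_name in names(sets)) {
      cols <- sets[[set_name]]
      for (tech in config$techniques) {
        fit_counter <- fit_counter + 1L
        fit_seed <- derive_seed(config$seed, i, 10L + fit_counter)
        res <- tryCatch({
          check_no_leakage(calib$plot_id, scheme$evaluation)
          fit <- fit_sdm(calib[cols], calib$.y, technique = tech,
                         hyper = config$hyper[[tech]] %||% list(),
                         seed = fit_seed)
          ext_row <- bind_cols(
            tibble(species_id = sp, technique = tech,
                   predictor_set = set_name, eval_kind = "external",
                   n_train = nrow(calib), n_test = nrow(ext)),
            evaluate_sdm(fit, ext[cols], ext$.y))
          int_rows <- purrr::map_dfr(seq_along(scheme$internal), function(j) {
            spl <- scheme$internal[[j]]
            check_no_leakage(spl$train, scheme$evaluation)
            tr <- rows_of(spl$train); te <- rows_of(spl$test)
            f <- fit_sdm(tr[cols], tr$.y, technique = tech,
                         hyper = config$hyper[[tech]] %||% list(),
                         seed = derive_seed(fit_seed, j, 5L))
            bind_cols(
              tibble(species_id = sp, technique = tech,
                     predictor_set = set_name,
                     eval_kind = sprintf("internal_%02d", j),
                     n_train = nrow(tr), n_test = nrow(te)),
              evaluate_sdm(f, te[cols], te$.y))
          })
          imp_rows <- NULL
          if (isTRUE(config$importance)) {
            imp <- permutation_importance(
              fit, calib[cols], n_permutations = config$n_permutations,
              seed = derive_seed(config$seed, i, 2L))
            imp_rows <- bind_cols(
              tibble(species_id = sp, technique = tech,
                     predictor_set = set_name)[rep(1, nrow(imp)), ],
              imp)
          }
          list(metrics = bind_rows(ext_row, int_rows), importances = imp_rows)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          if (grepl("^leakage:", conditionMessage(res))) stop(res)
          failures[[length(failures) + 1]] <-
            tibble(species_id = sp, predictor_set = set_name,
                   technique = tech, message = conditionMessage(res))
        } else {
          metrics[[length(metrics) + 1]] <- res$metrics
          importances[[length(importances) + 1]] <- res$importances
        }
      }
    }
  }
  metrics <- bind_rows(metrics)
  importances <- bind_rows(importances)
  failures <- if (length(failures) > 0) bind_rows(failures) else
    tibble(species_id = character(), predictor_set = character(),
           technique = character(), message = character())
  out <- structure(
    list(metrics = metrics, importances = importances,
         comparisons = NULL, summaries = NULL,
         predictor_sets = sets,
         manifest = list(config = config, species = species,
                         mapped_columns = mapped_columns,
                         cor_map = cor_map, n_dropped_plots = dropped,
                         failures = failures,
                         package_version = as.character(utils::packageVersion("eivsdm")))),
    class = "eiv_experiment"
  )
  if (nrow(metrics) > 0 && config$reference %in% metrics$predictor_set &&
      length(unique(metrics$predictor_set)) > 1) {
    out$summaries <- summarize_experiment(out,
                                          metric = config$comparison_metric,
                                          reference = config$reference)
    out$comparisons <- attr(out$summaries, "comparisons")
  }
  out
}

#' @export
print.eiv_experiment <- function(x, ...) {
  cat(sprintf("<eiv_experiment> %d species, %d predictor sets, techniques: %s\n",
              length(unique(x$metrics$species_id)),
              length(x$predictor_sets),
              paste(unique(x$metrics$technique), collapse = ", ")))
  cat(sprintf("  %d metric rows, %d importance rows, %d failed fits\n",
              nrow(x$metrics), nrow(x$importances %||% tibble()),
              nrow(x$manifest$failures)))
  if (!is.null(x$summaries)) {
    cat("  summaries vs ", x$manifest$config$reference, ":\n", sep = "")
    print(x$summaries, n = Inf)
  }
  invisible(x)
}

#' Summarize a substitution experiment against a reference set
#'
#' Per predictor set x technique (external evaluation only): the median
#' and 25/75 percentiles of the per-species metric difference to the
#' reference set, the fraction of species improved (difference > 0), and
#' the Holm-adjusted paired Wilcoxon p-value against the reference.
#'
#' @param x an `eiv_experiment` (or its `metrics` tibble).
#' @param metric metric column to summarize (default `"auc"`).
#' @param reference reference predictor set (default `"M_ref"`).
#' @return A tibble with one row per (technique, predictor set), the
#'   Wilcoxon table in the `comparisons` attribute.
#' @export
summarize_experiment <- function(x, metric = "auc", reference = "M_ref") {
  metrics <- if (inherits(x, "eiv_experiment")) x$metrics else x
  stopifnot(metric %in% names(metrics))
  ext <- metrics[metrics$eval_kind == "external", ]
  if (!reference %in% ext$predictor_set) {
    stopf("reference set '%s' absent from the results", reference)
  }
  wide <- tidyr::pivot_wider(
    ext[, c("species_id", "technique", "predictor_set", metric)],
    names_from = "predictor_set", values_from = dplyr::all_of(metric))
  comparisons <- purrr::map_dfr(unique(ext$technique), function(tech) {
    sub <- ext[ext$technique == tech, c("species_id", "predictor_set", metric)]
    names(sub)[3] <- "value"
    cmp <- pairwise_wilcoxon_holm(sub, reference = reference)
    bind_cols(tibble(technique = tech)[rep(1, nrow(cmp)), , drop = FALSE], cmp)
  })
  q <- function(v, p) unname(quantile(v, p, type = 7, na.rm = TRUE))
  summ <- purrr::map_dfr(unique(ext$technique), function(tech) {
    w <- wide[wide$technique == tech, ]
    other <- setdiff(unique(ext$predictor_set), reference)
    purrr::map_dfr(other, function(s) {
      d <- w[[s]] - w[[reference]]
      d <- d[!is.na(d)]
      tibble(technique = tech, predictor_set = s, metric = metric,
             n_species = length(d),
             median_delta = median(d), q25_delta = q(d, 0.25),
             q75_delta = q(d, 0.75),
             fraction_improved = mean(d > 0))
    })
  })
  summ <- left_join(
    summ,
    comparisons[, c("technique", "set_b", "p_adjusted")],
    by = c(technique = "technique", predictor_set = "set_b"))
  attr(summ, "comparisons") <- comparisons
  summ
}

#' Importance evenness per fitted model
#'
#' Normalizes each model's raw permutation importances to fractions and
#' computes their Shannon evenness, one row per (species, technique,
#' predictor set).
#'
#' @param x an `eiv_experiment` (or its `importances` tibble).
#' @return A tibble with `species_id`, `technique`, `predictor_set`,
#'   `evenness`.
#' @export
experiment_evenness <- function(x) {
  imp <- if (inherits(x, "eiv_experiment")) x$importances else x
  stopifnot(!is.null(imp), nrow(imp) > 0)
  imp |>
    group_by(.data$species_id, .data$technique, .data$predictor_set) |>
    summarise(evenness = importance_evenness(.data$importance),
              .groups = "drop")
}
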