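`%union%` <- function(a, b) union(a, b)

mapped_roles <- c(temperature = "temperature", ph = "ph",
                  precipitation = "precipitation",
                  topo_position = "topo_position", slope = "slope",
                  radiation = "radiation")

test_that("the ten predictor sets follow the substitution table", {
  sets <- build_predictor_sets(mapped_roles,
                               cor_map = c(T = "temperature", M = "ph",
                                           L = "radiation", K = "slope",
                                           R = "ph", N = "ph"))
  expect_setequal(names(sets),
                  c("M_ref", "M_T", "M_Soil", "M_R", "M_N", "M_M", "M_K",
                    "M_L", "M_EIV", "M_cor"))
  expect_setequal(sets$M_ref, unname(mapped_roles))
  expect_setequal(sets$M_T, c("ph", "precipitation", "topo_position",
                              "slope", "radiation", "eiv_T"))
  expect_setequal(sets$M_R, setdiff(sets$M_ref, "ph") %union% "eiv_R")
  expect_setequal(sets$M_N, setdiff(sets$M_ref, "ph") %union% "eiv_N")
  expect_setequal(sets$M_M, setdiff(sets$M_ref, "precipitation") %union%
                    "eiv_M")
  expect_setequal(sets$M_L, setdiff(sets$M_ref, "radiation") %union% "eiv_L")
  expect_setequal(sets$M_EIV, paste0("eiv_", c("T", "N", "R", "M", "K", "L")))
  # every set sized like the reference, except the soil (one more) and
  # continentality (one fewer) substitutions
  expect_length(sets$M_Soil, 7)
  expect_length(sets$M_K, 5)
  for (nm in c("M_T", "M_R", "M_N", "M_M", "M_L", "M_EIV")) {
    expect_length(sets[[nm]], 6)
  }
  # M_ref never contains site EIVs, M_EIV never contains mapped layers
  expect_length(grep("^eiv_", sets$M_ref), 0)
  expect_length(grep("^eiv_", sets$M_EIV), 6)
  # duplicated picks collapse in M_cor
  expect_message(
    s2 <- build_predictor_sets(mapped_roles,
                               cor_map = c(T = "temperature", M = "ph",
                                           L = "ph", K = "ph", R = "ph",
                                           N = "ph")),
    "collapsed")
  expect_setequal(s2$M_cor, c("temperature", "ph"))
})

test_that("missing roles and unknown sets are rejected by name", {
  expect_error(build_predictor_sets(mapped_roles[-2]), "ph")
  expect_error(build_predictor_sets(mapped_roles,
                                    eiv_columns = c(T = "eiv_T")),
               "missing dimension")
  # F alias accepted for the moisture indicator
  f_named <- setNames(paste0("eiv_", c("T", "M", "L", "K", "R", "N")),
                      c("T", "F", "L", "K", "R", "N"))
  expect_setequal(build_predictor_sets(mapped_roles,
                                       eiv_columns = f_named)$M_M,
                  setdiff(unname(mapped_roles), "precipitation") %union%
                    "eiv_M")
})

test_that("the correlation screen picks the strongest |Spearman| candidate", {
  withr::with_seed(10, {
    n <- 40
    site <- tibble::tibble(plot_id = sprintf("p%02d", 1:n), L = runif(n))
    cand <- tibble::tibble(
      plot_id = site$plot_id,
      radiation = site$L + rnorm(n, 0, 3),      # weak
      aspect = rnorm(n),                         # unrelated
      cloud = rank(site$L) + rnorm(n, 0, 2)      # strong
    )
    # independent spearman via pearson-on-ranks
    rho <- vapply(cand[-1], function(v)
      cor(rank(site$L), rank(v)), 0)
    expect_equal(names(which.max(abs(rho))), "cloud")
    picks <- select_best_correlated(site, cand, dimensions = "L")
    expect_equal(unname(picks["L"]), "cloud")
    cors <- attr(picks, "correlations")
    expect_equal(cors$rho, unname(rho), tolerance = 1e-12)
    # a candidate equal to the site EIV itself always wins
    cand$self <- site$L
    expect_equal(unname(select_best_correlated(site, cand,
                                               dimensions = "L")["L"]),
                 "self")
  })
})

test_that("tied absolute correlations break by column order", {
  site <- tibble::tibble(plot_id = sprintf("p%d", 1:10), T = c(1:10))
  c1 <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)  # positive spearman
  cand <- tibble::tibble(plot_id = site$plot_id, first = c1,
                         second = -c1)     # exactly opposite rank order
  picks <- select_best_correlated(site, cand, dimensions = "T")
  cors <- attr(picks, "correlations")
  expect_equal(abs(cors$rho[1]), abs(cors$rho[2]))
  expect_equal(unname(picks["T"]), "first")
})

test_that("the leakage guard aborts on any overlap", {
  expect_true(eivsdm:::check_no_leakage(c("a", "b"), c("c", "d")))
  expect_error(eivsdm:::check_no_leakage(c("a", "b"), c("b", "d")),
               "leakage")
})

study <- small_study(seed = 5)
cfg_small <- experiment_config(techniques = c("GLM", "SRE"),
                               sets = c("M_ref", "M_EIV"),
                               min_presences = 25, n_internal = 1,
                               n_permutations = 3, include_mcor = FALSE,
                               seed = 5)
exp_small <- suppressMessages(
  run_experiment(study$community, study$eivs, config = cfg_small))

test_that("the experiment produces complete bookkeeping", {
  sp <- exp_small$manifest$species
  expect_gt(length(sp), 3)
  done <- exp_small$metrics
  # one external + one internal row per (species, technique, set), minus
  # logged failures
  expected_rows <- length(sp) * 2 * 2 * 2 -
    2 * nrow(exp_small$manifest$failures)
  expect_equal(nrow(done), expected_rows)
  expect_setequal(unique(done$eval_kind), c("external", "internal_01"))
  # D2 defined exactly for the deviance-based technique
  ext <- done[done$eval_kind == "external", ]
  expect_true(all(!is.na(ext$d2[ext$technique == "GLM"])))
  expect_true(all(is.na(ext$d2[ext$technique == "SRE"])))
  # importances: one row per variable per fitted model
  imp <- exp_small$importances
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))
  expect_equal(sort(unique(imp$predictor_set)), c("M_EIV", "M_ref"))
})

test_that("experiment runs are bit-identical under a fixed seed", {
  again <- suppressMessages(
    run_experiment(study$community, study$eivs, config = cfg_small))
  expect_equal(exp_small$metrics, again$metrics)
  expect_equal(exp_small$importances, again$importances)
  expect_equal(exp_small$summaries, again$summaries)
})

test_that("summaries report deltas, quartiles, improvement fractions and p", {
  s <- exp_small$summaries
  expect_true(all(c("median_delta", "q25_delta", "q75_delta",
                    "fraction_improved", "p_adjusted") %in% names(s)))
  expect_setequal(s$predictor_set, "M_EIV")
  # constructed table: B = A + 0.1 for every species
  fake <- tibble::tibble(
    species_id = rep(sprintf("s%d", 1:7), 2),
    technique = "GLM",
    predictor_set = rep(c("M_ref", "B"), each = 7),
    eval_kind = "external",
    auc = c(seq(0.5, 0.8, length.out = 7),
            seq(0.5, 0.8, length.out = 7) + 0.1)
  )
  out <- summarize_experiment(fake, metric = "auc", reference = "M_ref")
  expect_equal(out$fraction_improved, 1)
  expect_equal(out$median_delta, 0.1)
  # quartiles equal the independent linear-interpolation computation
  deltas <- rep(0.1, 7)
  expect_equal(out$q25_delta, oracle_quantile7(deltas, 0.25))
  expect_equal(out$q75_delta, oracle_quantile7(deltas, 0.75))
  vals <- c(0.03, -0.01, 0.2, 0.07, 0.11, 0, 0.05)
  fake$auc[8:14] <- fake$auc[1:7] + vals
  out2 <- summarize_experiment(fake, metric = "auc", reference = "M_ref")
  expect_equal(out2$q25_delta, oracle_quantile7(vals, 0.25))
  expect_equal(out2$q75_delta, oracle_quantile7(vals, 0.75))
  expect_equal(out2$fraction_improved, 5 / 7)
  expect_error(summarize_experiment(fake, reference = "nope"), "absent")
})

test_that("the focal species' own scores never reach its predictors", {
  # brute force: recompute the LOO site EIVs for one modelled species and
  # compare with an all-species computation on the matrix without it
  sp <- exp_small$manifest$species[1]
  presence <- study$community$presence
  loo <- compute_site_eivs(presence, study$eivs, focal_species = sp)
  without <- compute_site_eivs(presence[, colnames(presence) != sp],
                               study$eivs)
  for (d in c("T", "M", "L", "K", "R", "N")) {
    expect_equal(loo[[d]], without[[d]])
  }
})

test_that("the M_cor screen uses only its seeded screening subset", {
  cfg <- experiment_config(techniques = "GLM", sets = c("M_ref", "M_cor"),
                           min_presences = 25, n_internal = 0,
                           n_permutations = 2, include_mcor = TRUE,
                           seed = 5)
  ex <- suppressMessages(run_experiment(study$community, study$eivs,
                                        config = cfg))
  expect_true("M_cor" %in% names(ex$predictor_sets))
  expect_length(ex$manifest$cor_map, 6)
  expect_true(all(ex$predictor_sets$M_cor %in%
                    setdiff(names(study$community$predictors), "plot_id")))
})

test_that("plots and study reproduction work end to end", {
  p1 <- plot_performance_shift(exp_small)
  p2 <- plot_importance_profile(exp_small, technique = "GLM")
  p3 <- ggplot2::autoplot(exp_small)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_s3_class(p3, "ggplot")
  ev <- experiment_evenness(exp_small)
  expect_true(all(ev$evenness >= 0 & ev$evenness <= 1, na.rm = TRUE))
})
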