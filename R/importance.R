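#' Permutation variable importance
#'
#' For each variable, predictions from the fitted model are compared with
#' predictions after shuffling that variable's column:
#' `importance = 1 - mean_r`, where `mean_r` is the mean Pearson
#' correlation between original and shuffled-variable predictions over the
#' permutations, clipped into `[0, 1]` before subtraction. A variable the
#' model ignores gets importance 0, as does any variable when the model's
#' predictions are constant (correlation undefined). Importances within a
#' model are reported raw and need not sum to one.
#'
#' @param model an `sdm_fit`.
#' @param x data frame with the model's predictor columns (typically the
#'   calibration data).
#' @param variables variables to assess (default: all model predictors).
#' @param n_permutations permutations per variable (default 10).
#' @param seed integer seed.
#' @return A tibble with `variable`, `importance`, `n_permutations`.
#' @export
permutation_importance <- function(model, x, variables = NULL,
                                   n_permutations = 10, seed = 1L) {
  stopifnot(inherits(model, "sdm_fit"), n_permutations >= 1)
  variables <- variables %||% model$predictors
  bad <- setdiff(variables, model$predictors)
  if (length(bad) > 0) {
    stopf("variable(s) not in the model: %s", paste(bad, collapse = ", "))
  }
  x <- as.data.frame(x)[model$predictors]
  orig <- predict_sdm(model, x)
  constant_orig <- sd(orig) == 0
  res <- withr::with_seed(seed, {
    vapply(variables, function(v) {
      if (constant_orig) return(0)
      r <- vapply(seq_len(n_permutations), function(k) {
        xp <- x
        xp[[v]] <- xp[[v]][sample.int(nrow(xp))]
        pp <- predict_sdm(model, xp)
        if (sd(pp) == 0) return(0)
        cor(orig, pp)
      }, 0)
      1 - min(max(mean(r), 0), 1)
    }, 0)
  })
  tibble(variable = variables, importance = unname(res),
         n_permutations = as.integer(n_permutations))
}

#' Shannon evenness of a model's variable importances
#'
#' Importances are normalized to fractions summing to one, and evenness is
#' `-(sum p log p) / log(K)` over the `K` variables; 1 means perfectly even
#' importance, values near 0 mean one variable dominates. `NA` when all
#' importances are zero.
#'
#' @param importance numeric vector of nonnegative raw importances.
#' @return Evenness in `[0, 1]`, or `NA`.
#' @export
importance_evenness <- function(importance) {
  stopifnot(all(importance >= 0))
  if (length(importance) < 2 || sum(importance) == 0) return(NA_real_)
  p <- importance / sum(importance)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(importance))
}

#' Pairwise Wilcoxon signed-rank tests with Holm correction
#'
#' Compares a per-species metric between predictor sets with two-sided
#' paired Wilcoxon signed-rank tests, either every set against a reference
#' or all pairs, and applies the Holm step-down adjustment over the family
#' of comparisons. Species with a missing value in either member of a pair
#' are dropped from that pair. When all paired differences are zero the
#' p-value is 1 by convention.
#'
#' @param data long tibble with columns `species_id`, `predictor_set`, and
#'   the metric column named by `value`.
#' @param value name of the metric column (default `"value"`).
#' @param reference optional predictor-set name; when given, only
#'   reference-vs-other comparisons are made.
#' @return A tibble with `set_a`, `set_b`, `n` (pairs used), `statistic`,
#'   `p_value`, `p_adjusted`.
#' @export
pairwise_wilcoxon_holm <- function(data, value = "value", reference = NULL) {
  stopifnot(all(c("species_id", "predictor_set", value) %in% names(data)))
  wide <- tidyr::pivot_wider(data[, c("species_id", "predictor_set", value)],
                             names_from = "predictor_set",
                             values_from = dplyr::all_of(value))
  sets <- setdiff(names(wide), "species_id")
  pairs <- if (!is.null(reference)) {
    if (!reference %in% sets) stopf("reference set '%s' not present", reference)
    lapply(setdiff(sets, reference), function(s) c(reference, s))
  } else {
    apply(utils::combn(sets, 2), 2, identity, simplify = FALSE)
  }
  rows <- purrr::map_dfr(pairs, function(pr) {
    a <- wide[[pr[1]]]; b <- wide[[pr[2]]]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (all(a == b)) {
      inform(sprintf("all paired differences zero for %s vs %s; p = 1",
                     pr[1], pr[2]))
      return(tibble(set_a = pr[1], set_b = pr[2], n = sum(ok),
                    statistic = 0, p_value = 1))
    }
    d <- a - b
    if (all(d > 0) || all(d < 0)) {
      # every difference has the same sign: the signed-rank statistic sits
      # at its extreme, whose exact two-sided permutation p is 2/2^n even
      # when tied magnitudes prevent wilcox.test() from being exact
      n <- length(d)
      return(tibble(set_a = pr[1], set_b = pr[2], n = n,
                    statistic = if (d[1] > 0) n * (n + 1) / 2 else 0,
                    p_value = min(1, 2 / 2^n)))
    }
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                       alternative = "two.sided"))
    tibble(set_a = pr[1], set_b = pr[2], n = sum(ok),
           statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  rows$p_adjusted <- p.adjust(rows$p_value, method = "holm")
  rows
}
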