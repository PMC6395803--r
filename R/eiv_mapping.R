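fit_eiv_regressor <- function(x, y, technique, hyper = list(), seed = 1L) {
  centers <- vapply(x, mean, 0)
  scales <- vapply(x, sd, 0); scales[scales == 0] <- 1
  z <- scale_predictors(x, centers, scales)
  fit <- switch(
    technique,
    GLM = {
      f <- as.data.frame(quad_features(z))
      f$.y <- y
      stats::lm(.y ~ ., data = f)
    },
    GAM = {
      g <- fit_gam_gaussian(z, y, k = hyper$k %||% 4)
      g
    },
    GBM = {
      dtrain <- xgboost::xgb.DMatrix(z, label = y)
      xgboost::xgb.train(
        params = list(max_depth = hyper$depth %||% 3,
                      eta = hyper$learning_rate %||% 0.05,
                      objective = "reg:squarederror", nthread = 1),
        data = dtrain, nrounds = hyper$n_trees %||% 500, verbose = 0)
    },
    RF = {
      d <- as.data.frame(z); d$.y <- y
      ranger::ranger(.y ~ ., data = d, num.trees = hyper$num_trees %||% 500,
                     seed = seed, num.threads = 1)
    },
    stopf("unknown EIV-mapping technique: %s", technique)
  )
  list(technique = technique, fit = fit, centers = centers, scales = scales)
}

fit_gam_gaussian <- function(z, y, k = 4) {
  d <- as.data.frame(z)
  vars <- sprintf("v%03d", seq_along(d))
  names(d) <- vars
  terms <- vapply(seq_along(vars), function(j) {
    nu <- length(unique(d[[j]]))
    if (nu <= 2) return(vars[j])
    kk <- min(k, nu - 1)
    if (kk < 3) vars[j] else sprintf("s(%s, k = %d)", vars[j], kk)
  }, "")
  d$.y <- y
  m <- mgcv::gam(stats::as.formula(paste(".y ~", paste(terms, collapse = " + "))),
                 data = d)
  list(model = m, vars = vars)
}

predict_eiv_regressor <- function(object, newdata) {
  z <- scale_predictors(newdata, object$centers, object$scales)
  switch(
    object$technique,
    GLM = as.numeric(predict(object$fit,
                             newdata = as.data.frame(quad_features(z)))),
    GAM = {
      d <- as.data.frame(z)
      names(d) <- object$fit$vars
      as.numeric(predict(object$fit$model, newdata = d))
    },
    GBM = as.numeric(predict(object$fit, xgboost::xgb.DMatrix(z))),
    RF = predict(object$fit, data = as.data.frame(z),
                 num.threads = 1)$predictions
  )
}

#' Cross-validated prediction of site EIVs from mapped predictors
#'
#' Tests whether a site indicator value is just a (possibly complex)
#' function of the available mapped predictors: `n_repeats` independent
#' random 70/30 splits, fitting on the 70% and scoring Pearson correlation
#' and RMSE of predicted vs observed site EIVs on the held-out 30%.
#' Repeats whose test fold has constant observed values have an undefined
#' correlation; they are logged and skipped in the aggregates.
#'
#' Regressors: `GLM` = Gaussian linear model with linear + quadratic
#' terms, `GAM` = Gaussian smooths (basis dimension 4), `GBM` =
#' gradient-boosted trees (500 trees, depth 3, learning rate 0.05), `RF` =
#' regression forest (500 trees).
#'
#' @param data tibble holding the response and predictor columns (site
#'   EIVs here are all-species means: no focal species is involved).
#' @param response name of the response column.
#' @param predictors predictor column names (default: all others).
#' @param technique one of `"GLM"`, `"GAM"`, `"GBM"`, `"RF"`.
#' @param n_repeats number of random 70/30 splits (default 25).
#' @param train_prop training share (default 0.7).
#' @param hyper technique hyperparameters (see above for defaults).
#' @param seed integer seed.
#' @return A tibble with one row per repeat: `repeat_id`, `pearson_r`,
#'   `rmse`; aggregate with [summarize_eiv_mapping()].
#' @export
cross_validate_eiv <- function(data, response, predictors = NULL,
                               technique = c("GLM", "GAM", "GBM", "RF"),
                               n_repeats = 25, train_prop = 0.7,
                               hyper = list(), seed = 1L) {
  technique <- match.arg(technique)
  predictors <- predictors %||% setdiff(names(data), c(response, "plot_id"))
  stopifnot(response %in% names(data), length(predictors) > 0)
  keep <- complete.cases(data[, c(response, predictors)])
  data <- data[keep, ]
  n <- nrow(data)
  if (n < 10) abort("need at least 10 complete plots")
  purrr::map_dfr(seq_len(n_repeats), function(rep_i) {
    idx <- withr::with_seed(derive_seed(seed, rep_i),
                            sample.int(n, floor(train_prop * n)))
    train <- data[idx, ]; test <- data[-idx, ]
    fit <- fit_eiv_regressor(as.data.frame(train[predictors]),
                             train[[response]], technique, hyper,
                             seed = derive_seed(seed, rep_i, 2L))
    pred <- predict_eiv_regressor(fit, as.data.frame(test[predictors]))
    obs <- test[[response]]
    r <- if (sd(obs) == 0 || sd(pred) == 0) {
      inform(sprintf("repeat %d: constant values in test fold; correlation undefined",
                     rep_i))
      NA_real_
    } else cor(pred, obs)
    tibble(repeat_id = rep_i, pearson_r = r,
           rmse = sqrt(mean((pred - obs)^2)))
  })
}

#' Map every indicator dimension from the same predictors
#'
#' Runs [cross_validate_eiv()] for each site-EIV dimension and technique
#' over a shared predictor table.
#'
#' @param site_eivs tibble with `plot_id` and site-EIV columns by letter.
#' @param predictors tibble with `plot_id` and mapped predictor columns.
#' @param dimensions dimensions to map (default: letters present).
#' @param techniques regressors to use (default `"GLM"`).
#' @inheritParams cross_validate_eiv
#' @return A tibble with `dimension`, `technique`, `repeat_id`,
#'   `pearson_r`, `rmse`.
#' @export
map_eiv_dimensions <- function(site_eivs, predictors, dimensions = NULL,
                               techniques = "GLM", n_repeats = 25,
                               hyper = list(), seed = 1L) {
  dimensions <- dimensions %||% intersect(EIV_DIMS, names(site_eivs))
  joined <- inner_join(site_eivs[, c("plot_id", dimensions)], predictors,
                       by = "plot_id")
  pred_cols <- setdiff(names(predictors), "plot_id")
  purrr::map_dfr(dimensions, function(d) {
    purrr::map_dfr(techniques, function(tech) {
      cv <- cross_validate_eiv(joined, response = d,
                               predictors = pred_cols, technique = tech,
                               n_repeats = n_repeats, hyper = hyper,
                               seed = derive_seed(seed, match(d, dimensions),
                                                  match(tech, techniques)))
      bind_cols(tibble(dimension = d, technique = tech)[rep(1, nrow(cv)), ],
                cv)
    })
  })
}

#' Aggregate an EIV-mapping cross-validation table
#'
#' @param x output of [map_eiv_dimensions()] (or [cross_validate_eiv()]
#'   with `dimension`/`technique` columns added).
#' @return One row per (dimension, technique): mean and SD of the Pearson
#'   correlation and RMSE over repeats with a defined correlation.
#' @export
summarize_eiv_mapping <- function(x) {
  x |>
    group_by(.data$dimension, .data$technique) |>
    summarise(mean_r = mean(.data$pearson_r, na.rm = TRUE),
              sd_r = sd(.data$pearson_r, na.rm = TRUE),
              mean_rmse = mean(.data$rmse),
              sd_rmse = sd(.data$rmse),
              n_repeats_used = sum(!is.na(.data$pearson_r)),
              .groups = "drop")
}
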