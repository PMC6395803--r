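#' Fit a species distribution model
#'
#' One fit/predict contract over the five classic presence/absence
#' techniques:
#'
#' * `GLM`: binomial regression with linear + quadratic terms per
#'   predictor, fitted with a very small ridge penalty so perfectly
#'   separated data keep finite coefficients.
#' * `GAM`: binomial model with univariate smooths (basis dimension 4).
#' * `RF`: probability classification forest (500 trees).
#' * `MAXENT`: maximum-entropy-style L2-regularized binomial model on
#'   linear + quadratic features, with the recorded absences playing the
#'   role of background points.
#' * `SRE`: surface range envelope — per-predictor two-sided quantile
#'   envelope of the presence points (default 0.025 per side).
#'
#' Predictors are centered and scaled before quadratic terms are formed, to
#' limit collinearity between a variable and its square. Constant predictor
#' columns are retained (their coefficients are effectively zero) with a
#' message.
#'
#' @param x data frame of numeric predictors (no missing values).
#' @param y 0/1 presence vector with at least one presence and one absence.
#' @param technique one of `"GLM"`, `"GAM"`, `"RF"`, `"MAXENT"`, `"SRE"`.
#' @param predictors columns of `x` to use (default: all).
#' @param hyper named list of technique hyperparameters: `ridge` (GLM,
#'   default 1e-6), `lambda` (MAXENT, default 1e-3), `num_trees` (RF,
#'   default 500), `k` (GAM basis dimension, default 4), `quantile` (SRE,
#'   default 0.025).
#' @param seed integer seed for stochastic techniques (RF).
#' @return An object of class `sdm_fit`.
#' @export
fit_sdm <- function(x, y, technique = c("GLM", "GAM", "RF", "MAXENT", "SRE"),
                    predictors = NULL, hyper = list(), seed = 1L) {
  technique <- match.arg(technique)
  predictors <- predictors %||% names(x)
  if (length(predictors) == 0 || anyDuplicated(predictors)) {
    abort("predictors must be non-empty and unique")
  }
  missing_cols <- setdiff(predictors, names(x))
  if (length(missing_cols) > 0) {
    stopf("predictor column(s) missing from x: %s",
          paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[predictors]
  y <- as.integer(y)
  if (anyNA(x) || anyNA(y)) abort("missing values in predictors or response")
  if (!all(y %in% c(0L, 1L))) abort("y must be a 0/1 presence vector")
  if (all(y == 1L) || all(y == 0L)) {
    abort("y must contain at least one presence and one absence")
  }
  centers <- vapply(x, mean, 0)
  scales <- vapply(x, sd, 0)
  const <- scales == 0
  if (any(const)) {
    inform(sprintf("constant predictor column(s) retained: %s",
                   paste(predictors[const], collapse = ", ")))
    scales[const] <- 1
  }
  object <- list(technique = technique, predictors = predictors,
                 hyper = hyper, seed = as.integer(seed),
                 centers = centers, scales = scales,
                 fingerprint = list(n_plots = nrow(x), n_presences = sum(y)))

  z <- scale_predictors(x, centers, scales)
  fit <- switch(
    technique,
    GLM = fit_ridge_logistic(z, y, lambda = hyper$ridge %||% 1e-6),
    MAXENT = fit_ridge_logistic(z, y, lambda = hyper$lambda %||% 1e-3),
    GAM = fit_gam_binomial(z, y, k = hyper$k %||% 4),
    RF = {
      d <- as.data.frame(z)
      d$.y <- factor(y, levels = c(0, 1))
      ranger::ranger(.y ~ ., data = d, probability = TRUE,
                     num.trees = hyper$num_trees %||% 500,
                     seed = seed, num.threads = 1)
    },
    SRE = {
      q <- hyper$quantile %||% 0.025
      stopifnot(q >= 0, q < 0.5)
      pres <- x[y == 1L, , drop = FALSE]
      lapply(setNames(predictors, predictors), function(v) {
        unname(quantile(pres[[v]], c(q, 1 - q), type = 7))
      })
    }
  )
  object$fit <- fit
  object <- structure(object, class = "sdm_fit")
  if (technique %in% c("GLM", "GAM")) {
    p <- predict_sdm(object, x)
    object$train_deviance <- c(null = binomial_deviance(y, mean(y)),
                               residual = binomial_deviance(y, p))
  }
  object
}

scale_predictors <- function(x, centers, scales) {
  z <- as.matrix(x)
  sweep(sweep(z, 2, centers, "-"), 2, scales, "/")
}

# linear + quadratic feature matrix on standardized predictors
quad_features <- function(z) {
  cbind(z, `colnames<-`(z^2, paste0(colnames(z), "_sq")))
}

# L2-penalized binomial fit; coefficients extracted so prediction is a
# plain logistic evaluation
fit_ridge_logistic <- function(z, y, lambda) {
  f <- quad_features(z)
  keep <- apply(f, 2, sd) > 0
  beta <- setNames(numeric(ncol(f)), colnames(f))
  if (!any(keep)) {
    return(list(intercept = stats::qlogis(mean(y)), beta = beta))
  }
  fk <- f[, keep, drop = FALSE]
  if (ncol(fk) == 1) fk <- cbind(fk, .pad = 0)  # glmnet needs >= 2 columns
  # warm-start path down to the target lambda for reliable convergence
  path <- unique(sort(c(0.1, 0.01, 1e-3, lambda), decreasing = TRUE))
  path <- path[path >= lambda]
  g <- glmnet::glmnet(fk, y, family = "binomial",
                      alpha = 0, lambda = path, standardize = FALSE,
                      thresh = 1e-9, maxit = 3e5)
  est <- setNames(as.numeric(g$beta[, ncol(g$beta)]), rownames(g$beta))
  est <- est[names(est) %in% names(beta)]
  beta[names(est)] <- est
  list(intercept = as.numeric(g$a0[length(g$a0)]), beta = beta)
}

fit_gam_binomial <- function(z, y, k = 4) {
  d <- as.data.frame(z)
  vars <- sprintf("v%03d", seq_along(d))
  names(d) <- vars
  terms <- vapply(seq_along(vars), function(j) {
    nu <- length(unique(d[[j]]))
    if (nu <= 2) return(vars[j])          # (near-)constant: linear term
    kk <- min(k, nu - 1)
    if (kk < 3) vars[j] else sprintf("s(%s, k = %d)", vars[j], kk)
  }, "")
  d$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  m <- mgcv::gam(fml, family = stats::binomial(), data = d)
  list(model = m, vars = vars)
}

#' Predict suitability from a fitted SDM
#'
#' @param object an `sdm_fit`.
#' @param newdata data frame holding exactly the model's predictor columns
#'   (extra or missing columns are an error, named in the message).
#' @return Numeric vector of suitabilities in `[0, 1]`; for `SRE`, 1 when
#'   the row lies inside every per-predictor envelope, else 0.
#' @export
predict_sdm <- function(object, newdata) {
  stopifnot(inherits(object, "sdm_fit"))
  missing_cols <- setdiff(object$predictors, names(newdata))
  extra_cols <- setdiff(names(newdata), object$predictors)
  if (length(missing_cols) > 0) {
    stopf("newdata is missing predictor column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (length(extra_cols) > 0) {
    stopf("newdata has column(s) not in the model: %s",
          paste(extra_cols, collapse = ", "))
  }
  newdata <- as.data.frame(newdata)[object$predictors]
  if (anyNA(newdata)) abort("missing values in newdata")
  p <- switch(
    object$technique,
    GLM = ,
    MAXENT = {
      f <- quad_features(scale_predictors(newdata, object$centers,
                                          object$scales))
      plogis(object$fit$intercept +
               as.numeric(f %*% object$fit$beta[colnames(f)]))
    },
    GAM = {
      d <- as.data.frame(scale_predictors(newdata, object$centers,
                                          object$scales))
      names(d) <- object$fit$vars
      as.numeric(predict(object$fit$model, newdata = d, type = "response"))
    },
    RF = {
      d <- as.data.frame(scale_predictors(newdata, object$centers,
                                          object$scales))
      predict(object$fit, data = d, num.threads = 1)$predictions[, "1"]
    },
    SRE = {
      inside <- rep(TRUE, nrow(newdata))
      for (v in object$predictors) {
        b <- object$fit[[v]]
        inside <- inside & newdata[[v]] >= b[1] & newdata[[v]] <= b[2]
      }
      as.numeric(inside)
    }
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> %s on %d plots (%d presences), predictors: %s\n",
              x$technique, x$fingerprint$n_plots, x$fingerprint$n_presences,
              paste(x$predictors, collapse = ", ")))
  invisible(x)
}

#' Tidy an SDM fit
#'
#' GLM/MAXENT return coefficients on the standardized linear + quadratic
#' features; GAM returns its smooth-term summary; SRE returns the envelope
#' bounds per predictor.
#'
#' @param x an `sdm_fit`.
#' @param ... unused.
#' @method tidy sdm_fit
#' @export
#' @importFrom generics tidy
tidy.sdm_fit <- function(x, ...) {
  switch(
    x$technique,
    GLM = ,
    MAXENT = tibble(term = c("(Intercept)", names(x$fit$beta)),
                    estimate = c(x$fit$intercept, unname(x$fit$beta))),
    GAM = {
      s <- summary(x$fit$model)$s.table
      if (is.null(s) || nrow(s) == 0) {
        return(tibble(term = character(), edf = double(),
                      statistic = double(), p_value = double()))
      }
      tibble(term = x$predictors[match(sub("^s\\((v\\d+).*", "\\1",
                                           rownames(s)), x$fit$vars)],
             edf = s[, "edf"], statistic = s[, "Chi.sq"],
             p_value = s[, "p-value"])
    },
    SRE = tibble(term = x$predictors,
                 lower = vapply(x$fit, `[`, 0, 1),
                 upper = vapply(x$fit, `[`, 0, 2)),
    RF = abort("no tidy method for random forests; use permutation_importance()")
  )
}

#' Glance at an SDM fit
#'
#' @param x an `sdm_fit`.
#' @param ... unused.
#' @return One-row tibble with the training fingerprint and, for GLM/GAM,
#'   the training deviance pair and explained deviance.
#' @method glance sdm_fit
#' @export
#' @importFrom generics glance
glance.sdm_fit <- function(x, ...) {
  dv <- x$train_deviance %||% c(null = NA_real_, residual = NA_real_)
  tibble(technique = x$technique,
         n_plots = x$fingerprint$n_plots,
         n_presences = x$fingerprint$n_presences,
         null_deviance = unname(dv["null"]),
         deviance = unname(dv["residual"]),
         d_squared = unname(1 - dv["residual"] / dv["null"]))
}
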