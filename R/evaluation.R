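#' Build the external/internal evaluation split scheme
#'
#' Splits the plots uniformly at random into 70% calibration and 30%
#' external evaluation (the evaluation share is `floor(eval_prop * n)`),
#' then re-splits the calibration set `n_internal` times into 70/30
#' train/test pairs for internal (repeated cross-validation) evaluation.
#' External evaluation plots must never enter any fitting step; the
#' experiment runner enforces this.
#'
#' @param plot_ids character vector of plot ids (>= 10).
#' @param seed integer seed.
#' @param eval_prop evaluation share (default 0.3).
#' @param n_internal number of internal 70/30 splits (default 10).
#' @return A `split_scheme`: `calibration`, `evaluation`, and a list
#'   `internal` of `(train, test)` pairs.
#' @export
make_split_scheme <- function(plot_ids, seed = 1L, eval_prop = 0.3,
                              n_internal = 10) {
  n <- length(plot_ids)
  if (n < 10) abort("need at least 10 plots to build a split scheme")
  n_eval <- floor(eval_prop * n)
  if (n_eval < 1 || n_eval >= n) abort("split would leave an empty partition")
  withr::with_seed(seed, {
    evaluation <- sample(plot_ids, n_eval)
    calibration <- setdiff(plot_ids, evaluation)
    internal <- lapply(seq_len(n_internal), function(i) {
      test <- sample(calibration, floor(eval_prop * length(calibration)))
      list(train = setdiff(calibration, test), test = test)
    })
    structure(list(calibration = calibration, evaluation = evaluation,
                   internal = internal, seed = as.integer(seed)),
              class = "split_scheme")
  })
}

#' @export
print.split_scheme <- function(x, ...) {
  cat(sprintf("<split_scheme> %d calibration / %d evaluation plots, %d internal splits\n",
              length(x$calibration), length(x$evaluation), length(x$internal)))
  invisible(x)
}

check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    abort("labels must be a 0/1 vector")
  }
  if (all(labels == 0L) || all(labels == 1L)) {
    abort("labels must contain at least one presence and one absence")
  }
  labels
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (presence, absence) score
#' pairs where the presence scores higher, ties counted one half.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 vector with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exact threshold grid: all midpoints between consecutive sorted unique
# scores, plus the endpoints 0 and 1. A row is classified present when its
# score is >= the threshold.
threshold_grid <- function(scores) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2 else numeric()
  unique(c(0, mids, 1))
}

confusion_at <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  c(tp = sum(pred & labels == 1L), fp = sum(pred & labels == 0L),
    fn = sum(!pred & labels == 1L), tn = sum(!pred & labels == 0L))
}

tss_from_confusion <- function(cm) {
  sens <- if (cm["tp"] + cm["fn"] > 0) cm["tp"] / (cm["tp"] + cm["fn"]) else 0
  spec <- if (cm["tn"] + cm["fp"] > 0) cm["tn"] / (cm["tn"] + cm["fp"]) else 0
  unname(sens + spec - 1)
}

kappa_from_confusion <- function(cm) {
  n <- sum(cm)
  po <- (cm[["tp"]] + cm[["tn"]]) / n
  pe <- ((cm[["tp"]] + cm[["fp"]]) * (cm[["tp"]] + cm[["fn"]]) +
           (cm[["fn"]] + cm[["tn"]]) * (cm[["fp"]] + cm[["tn"]])) / n^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

#' Maximized true skill statistic
#'
#' `TSS(t) = sensitivity(t) + specificity(t) - 1`, maximized exactly over
#' all midpoints between consecutive unique scores plus the endpoints 0
#' and 1 (so an uninformative score vector yields 0, never a negative
#' value).
#'
#' @inheritParams auc
#' @return One-row tibble with `tss` and the maximizing `threshold`.
#' @export
tss_max <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  grid <- threshold_grid(scores)
  vals <- vapply(grid, function(t) tss_from_confusion(confusion_at(scores, labels, t)), 0)
  i <- which.max(vals)
  tibble(tss = vals[i], threshold = grid[i])
}

#' Maximized Cohen's kappa
#'
#' Kappa of the thresholded confusion matrix, maximized over the same
#' exact threshold grid as [tss_max()]. Degenerate expected agreement
#' (`p_e = 1`) is defined as kappa 0.
#'
#' @inheritParams auc
#' @return One-row tibble with `kappa` and the maximizing `threshold`.
#' @export
kappa_max <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  grid <- threshold_grid(scores)
  vals <- vapply(grid, function(t) kappa_from_confusion(confusion_at(scores, labels, t)), 0)
  i <- which.max(vals)
  tibble(kappa = vals[i], threshold = grid[i])
}

#' Proportion of correct predictions at a threshold
#'
#' @inheritParams auc
#' @param threshold classification threshold in `[0, 1]`; scores at or
#'   above it are classified present.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_at <- function(scores, labels, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  labels <- as.integer(labels)
  mean((scores >= threshold) == (labels == 1L))
}

binomial_deviance <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Explained deviance of a binomial SDM
#'
#' `D^2 = 1 - Dev(model) / Dev(null)` where the null model is the
#' intercept-only model fitted to the same response vector, so on an
#' evaluation subset the null deviance is a pure evaluation-set quantity.
#' Defined for GLM and GAM only; other techniques return `NA`.
#'
#' @param model an `sdm_fit`.
#' @param x predictor data frame.
#' @param y 0/1 response.
#' @return `D^2` (may be negative on evaluation data), or `NA_real_` for
#'   techniques without a deviance.
#' @export
explained_deviance <- function(model, x, y) {
  stopifnot(inherits(model, "sdm_fit"))
  if (!model$technique %in% c("GLM", "GAM")) return(NA_real_)
  y <- as.integer(y)
  p <- predict_sdm(model, x)
  1 - binomial_deviance(y, p) / binomial_deviance(y, mean(y))
}

#' Evaluate a fitted SDM on a data set
#'
#' Computes all five evaluation metrics; accuracy is reported at the
#' TSS-maximizing threshold.
#'
#' @param model an `sdm_fit`.
#' @param x predictor data frame.
#' @param y 0/1 response with both classes present.
#' @return One-row tibble: `auc`, `tss`, `threshold_tss`, `kappa`,
#'   `threshold_kappa`, `accuracy`, `d2` (`NA` outside GLM/GAM).
#' @export
evaluate_sdm <- function(model, x, y) {
  scores <- predict_sdm(model, x)
  labels <- check_binary_labels(y)
  ts <- tss_max(scores, labels)
  kp <- kappa_max(scores, labels)
  tibble(auc = auc(scores, labels),
         tss = ts$tss, threshold_tss = ts$threshold,
         kappa = kp$kappa, threshold_kappa = kp$threshold,
         accuracy = accuracy_at(scores, labels, ts$threshold),
         d2 = if (model$technique %in% c("GLM", "GAM")) {
           1 - binomial_deviance(labels, scores) /
             binomial_deviance(labels, mean(labels))
         } else NA_real_)
}
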