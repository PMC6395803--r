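`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles: deliberately naive implementations used only to
# check the package's vectorized ones.

# AUC by exhaustive pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# brute-force threshold metrics: evaluate every candidate threshold by
# explicit confusion counting
oracle_threshold_metrics <- function(scores, labels) {
  u <- sort(unique(scores))
  grid <- unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1))
  best_tss <- -Inf; best_tss_t <- NA
  best_kap <- -Inf; best_kap_t <- NA
  for (t in grid) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    tss <- sens + spec - 1
    n <- tp + fp + fn + tn
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    kap <- if (pe >= 1) 0 else (po - pe) / (1 - pe)
    if (tss > best_tss) { best_tss <- tss; best_tss_t <- t }
    if (kap > best_kap) { best_kap <- kap; best_kap_t <- t }
  }
  list(tss = best_tss, tss_threshold = best_tss_t,
       kappa = best_kap, kappa_threshold = best_kap_t)
}

# linear-interpolation quantile computed from the definition
# (type-7: h = (n - 1) * p)
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

# brute-force SRE: per-point check against per-predictor quantile bounds
oracle_sre <- function(x_train, y_train, x_new, q) {
  vars <- names(x_train)
  bounds <- lapply(vars, function(v) {
    pres <- x_train[[v]][y_train == 1]
    c(oracle_quantile7(pres, q), oracle_quantile7(pres, 1 - q))
  })
  names(bounds) <- vars
  out <- rep(1, nrow(x_new))
  for (i in seq_len(nrow(x_new))) {
    for (v in vars) {
      if (x_new[[v]][i] < bounds[[v]][1] || x_new[[v]][i] > bounds[[v]][2]) {
        out[i] <- 0
      }
    }
  }
  out
}

# Holm step-down from the definition
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 0
  for (i in seq_len(n)) {
    running <- max(running, (n - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# binomial deviance term by term
oracle_binomial_deviance <- function(y, p) {
  -2 * sum(ifelse(y == 1, log(p), log(1 - p)))
}

# small presence/EIV fixtures -----------------------------------------------

# build a presence matrix from a named list plot -> character vector of
# species present
make_presence <- function(occupancy, species = NULL) {
  species <- species %||% sort(unique(unlist(occupancy)))
  m <- matrix(0L, length(occupancy), length(species),
              dimnames = list(names(occupancy), species))
  for (p in names(occupancy)) m[p, occupancy[[p]]] <- 1L
  m
}

# random community + EIV table for property tests
random_site_eiv_fixture <- function(n_plots = 8, n_species = 12,
                                    dims = c("T", "M", "L")) {
  presence <- matrix(rbinom(n_plots * n_species, 1, 0.4), n_plots, n_species,
                     dimnames = list(sprintf("p%02d", seq_len(n_plots)),
                                     sprintf("s%02d", seq_len(n_species))))
  eivs <- tibble::tibble(species_id = colnames(presence))
  for (d in dims) {
    v <- sample(1:5, n_species, replace = TRUE)
    v[runif(n_species) < 0.15] <- NA
    eivs[[d]] <- v
  }
  list(presence = presence, eivs = eivs)
}

# small but non-trivial landscape/community for pipeline tests
small_study <- function(seed = 5L, n_species = 60, n_plots = 220) {
  simulate_study(
    seed = seed,
    landscape = landscape_config(grid = c(48L, 48L)),
    n_species = n_species, n_plots = n_plots
  )
}

# deterministic logistic sdm_fit with fixed coefficients (GLM contract)
manual_glm_fit <- function(predictors, intercept, beta, n = 10L,
                           n_presences = 5L) {
  stopifnot(length(beta) == 2 * length(predictors))
  structure(
    list(technique = "GLM", predictors = predictors, hyper = list(),
         seed = 1L,
         centers = setNames(rep(0, length(predictors)), predictors),
         scales = setNames(rep(1, length(predictors)), predictors),
         fingerprint = list(n_plots = n, n_presences = n_presences),
         fit = list(intercept = intercept,
                    beta = setNames(beta, c(predictors,
                                            paste0(predictors, "_sq"))))),
    class = "sdm_fit"
  )
}
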