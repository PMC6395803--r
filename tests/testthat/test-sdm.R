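make_xy <- function(n = 80, p = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(x) <- paste0("v", seq_len(p))
    eta <- x$v1 - 0.5 * x$v1^2 + if (p > 1) 0.5 * x$v2 else 0
    y <- rbinom(n, 1, plogis(eta))
    # guarantee both classes
    y[1] <- 1L; y[2] <- 0L
    list(x = x, y = y)
  })
}

test_that("SRE envelope matches the independent quantile computation", {
  x <- data.frame(v = 1:100)
  y <- rep(1L, 100); y[1] <- 1L
  y2 <- c(rep(1L, 100), 0L)
  x2 <- data.frame(v = c(1:100, 50))
  fit <- fit_sdm(x2, y2, technique = "SRE", hyper = list(quantile = 0.025))
  expect_equal(fit$fit$v, c(3.475, 97.525))
  expect_equal(fit$fit$v, c(oracle_quantile7(1:100, 0.025),
                            oracle_quantile7(1:100, 0.975)))
  # quantile 0: the envelope is the presence min/max and every training
  # presence scores 1
  fit0 <- fit_sdm(x2, y2, technique = "SRE", hyper = list(quantile = 0))
  expect_equal(fit0$fit$v, c(1, 100))
  expect_true(all(predict_sdm(fit0, x2[y2 == 1, , drop = FALSE]) == 1))
})

test_that("SRE predictions equal the brute-force envelope check", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      p <- sample(1:3, 1)
      n <- sample(20:50, 1)
      x <- as.data.frame(matrix(runif(n * p), n, p))
      names(x) <- paste0("v", seq_len(p))
      y <- rbinom(n, 1, 0.5); y[1] <- 1L; y[2] <- 0L
      x_new <- as.data.frame(matrix(runif(30 * p), 30, p))
      names(x_new) <- names(x)
      fit <- fit_sdm(x, y, technique = "SRE")
      expect_equal(predict_sdm(fit, x_new), oracle_sre(x, y, x_new, 0.025))
      # inside all envelopes -> 1, outside one -> 0
      inside <- as.data.frame(as.list(vapply(fit$fit, mean, 0)))
      names(inside) <- names(x)
      expect_equal(predict_sdm(fit, inside), 1)
      outside <- inside
      outside[[1]] <- fit$fit[[1]][2] + 1
      expect_equal(predict_sdm(fit, outside), 0)
    }
  })
})

test_that("GLM ranks perfectly separable data perfectly yet stays finite", {
  x <- data.frame(v = c(-3:-1, 1:3))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  fit <- fit_sdm(x, y, technique = "GLM")
  scores <- predict_sdm(fit, x)
  expect_equal(auc(scores, y), 1)
  expect_true(all(is.finite(scores)))
  expect_gte(glance(fit)$d_squared, 0)
})

test_that("a fixed-coefficient logistic model predicts 0.5 at x = 0", {
  fit <- manual_glm_fit("v", intercept = 0, beta = c(1, 0))
  expect_equal(predict_sdm(fit, data.frame(v = 0)), 0.5)
  expect_equal(predict_sdm(fit, data.frame(v = 1)), plogis(1))
})

test_that("all techniques return deterministic scores in [0, 1]", {
  d <- make_xy(n = 120, p = 3, seed = 21)
  for (tech in c("GLM", "GAM", "RF", "MAXENT", "SRE")) {
    fit <- fit_sdm(d$x, d$y, technique = tech, seed = 42)
    s1 <- predict_sdm(fit, d$x)
    s2 <- predict_sdm(fit, d$x)
    expect_identical(s1, s2)
    expect_true(all(s1 >= 0 & s1 <= 1), label = tech)
    # refit with the same seed reproduces the predictions exactly
    refit <- fit_sdm(d$x, d$y, technique = tech, seed = 42)
    expect_equal(predict_sdm(refit, d$x), s1)
  }
})

test_that("prediction rejects missing and extra columns by name", {
  d <- make_xy(n = 40, p = 2)
  fit <- fit_sdm(d$x, d$y, technique = "GLM")
  expect_error(predict_sdm(fit, d$x["v1"]), "v2")
  expect_error(predict_sdm(fit, cbind(d$x, junk = 1)), "junk")
})

test_that("degenerate inputs are handled per contract", {
  d <- make_xy(n = 40, p = 2)
  expect_error(fit_sdm(d$x, rep(1L, 40)), "at least one presence")
  expect_error(fit_sdm(d$x, rep(0L, 40)), "at least one presence")
  d$x$v2 <- 1   # constant column retained with a message
  expect_message(fit <- fit_sdm(d$x, d$y, technique = "GLM"), "constant")
  expect_true(all(is.finite(predict_sdm(fit, d$x))))
})

test_that("tidy and glance expose the fitted state", {
  d <- make_xy(n = 100, p = 2, seed = 3)
  glm_fit <- fit_sdm(d$x, d$y, technique = "GLM")
  td <- tidy(glm_fit)
  expect_setequal(td$term,
                  c("(Intercept)", "v1", "v2", "v1_sq", "v2_sq"))
  gl <- glance(glm_fit)
  expect_equal(gl$n_plots, 100)
  expect_gte(gl$d_squared, 0)
  gam_fit <- fit_sdm(d$x, d$y, technique = "GAM")
  expect_gte(glance(gam_fit)$d_squared, 0)
  sre_fit <- fit_sdm(d$x, d$y, technique = "SRE")
  expect_equal(tidy(sre_fit)$term, c("v1", "v2"))
  rf_fit <- fit_sdm(d$x, d$y, technique = "RF")
  expect_true(is.na(glance(rf_fit)$d_squared))
  expect_error(tidy(rf_fit), "permutation_importance")
})
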