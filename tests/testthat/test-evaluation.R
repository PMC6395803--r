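test_that("the split scheme partitions plots 70/30 with internal re-splits", {
  ids <- sprintf("p%03d", 1:100)
  sch <- make_split_scheme(ids, seed = 4)
  expect_length(sch$evaluation, 30)
  expect_length(sch$calibration, 70)
  expect_setequal(c(sch$calibration, sch$evaluation), ids)
  expect_length(intersect(sch$calibration, sch$evaluation), 0)
  expect_identical(sch, make_split_scheme(ids, seed = 4))
  expect_error(make_split_scheme(ids[1:5], seed = 1), "at least 10")
})

test_that("internal splits never touch external evaluation plots", {
  withr::with_seed(8, {
    for (rep in 1:50) {
      ids <- sprintf("p%03d", seq_len(sample(10:60, 1)))
      sch <- make_split_scheme(ids, seed = sample.int(1e6, 1))
      for (spl in sch$internal) {
        expect_length(intersect(spl$train, sch$evaluation), 0)
        expect_length(intersect(spl$test, sch$evaluation), 0)
        expect_setequal(c(spl$train, spl$test), sch$calibration)
      }
    }
  })
})

test_that("AUC follows the Mann-Whitney pair-counting definition", {
  expect_equal(auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.5, 0.5), c(1, 0)), 0.5)   # single tied pair
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "at least one")
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      n <- sample(5:30, 1)
      s <- runif(n); l <- rbinom(n, 1, 0.5); l[1] <- 1; l[2] <- 0
      expect_equal(auc(plogis(3 * s - 1), l), auc(s, l))
    }
  })
})

test_that("maximized TSS and kappa match their worked confusion tables", {
  # confusion at 0.5: TP=40, FN=10, FP=15, TN=35 -> sens 0.8, spec 0.7
  scores <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 15), rep(0.1, 35))
  labels <- c(rep(1, 50), rep(0, 50))
  expect_equal(tss_max(scores, labels)$tss, 0.5)
  # confusion TP=40, FP=10, FN=10, TN=40 -> kappa 0.6, accuracy 0.8
  scores2 <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 10), rep(0.1, 40))
  ks <- kappa_max(scores2, labels)
  expect_equal(ks$kappa, 0.6)
  expect_equal(accuracy_at(scores2, labels, ks$threshold), 0.8)
  # perfect separation
  expect_equal(tss_max(c(0.8, 0.9, 0.1), c(1, 1, 0))$tss, 1)
  expect_equal(kappa_max(c(0.8, 0.9, 0.1), c(1, 1, 0))$kappa, 1)
  # uninformative scores
  expect_equal(tss_max(rep(0.4, 10), rep(c(0, 1), 5))$tss, 0)
  expect_equal(kappa_max(rep(0.4, 10), rep(c(0, 1), 5))$kappa, 0)
})

test_that("threshold metrics equal brute-force recomputation on random vectors", {
  withr::with_seed(17, {
    for (rep in 1:50) {
      n <- sample(4:30, 1)
      scores <- round(runif(n), sample(1:3, 1))  # force ties sometimes
      labels <- rbinom(n, 1, 0.5); labels[1] <- 1; labels[2] <- 0
      oracle <- oracle_threshold_metrics(scores, labels)
      ts <- tss_max(scores, labels)
      ks <- kappa_max(scores, labels)
      expect_equal(ts$tss, oracle$tss)
      expect_equal(ks$kappa, oracle$kappa)
      expect_gte(ts$tss, 0)
      expect_gte(ks$kappa, 0)
      expect_equal(auc(scores, labels), oracle_auc(scores, labels))
      expect_equal(accuracy_at(scores, labels, ts$threshold),
                   mean((scores >= ts$threshold) == labels))
    }
  })
})

test_that("accuracy handles the trivial cases", {
  expect_equal(accuracy_at(c(0.9, 0.9, 0.1), c(1, 1, 0), 0.5), 1)
  # all predicted absent at prevalence 0.3
  expect_equal(accuracy_at(rep(0, 10), c(rep(1, 3), rep(0, 7)), 1), 0.7)
})

test_that("explained deviance honours its contracts", {
  y <- c(0L, 0L, 1L, 0L, 1L, 1L, 0L, 1L)
  x <- data.frame(v = c(-1.5, -1, -0.5, 0, 0.5, 1, 1.5, 2))
  # intercept-only predictions on their own training data: D2 = 0
  null_fit <- manual_glm_fit("v", intercept = qlogis(mean(y)), beta = c(0, 0))
  expect_equal(explained_deviance(null_fit, x, y), 0)
  # near-saturated model: D2 -> 1
  sat <- manual_glm_fit("v", intercept = -15, beta = c(60, 0))
  y_sep <- as.integer(x$v > 0.25)
  expect_gt(explained_deviance(sat, x, y_sep), 0.999)
  # hand-computed 8-point deviance ratio (independent script)
  fixed <- manual_glm_fit("v", intercept = 0.2, beta = c(1, -0.3))
  expect_equal(explained_deviance(fixed, x, y), 0.1833887726773319,
               tolerance = 1e-9)
  p <- predict_sdm(fixed, x)
  expect_equal(oracle_binomial_deviance(y, p) /
                 oracle_binomial_deviance(y, rep(mean(y), 8)),
               1 - 0.1833887726773319, tolerance = 1e-9)
  # not applicable outside GLM/GAM
  d <- withr::with_seed(2, data.frame(v = rnorm(30)))
  yy <- as.integer(d$v > 0); yy[1] <- 1L; yy[2] <- 0L
  rf <- fit_sdm(d, yy, technique = "RF")
  expect_true(is.na(explained_deviance(rf, d, yy)))
})

test_that("evaluation D2 can be negative out of sample but not on training", {
  withr::with_seed(9, {
    x <- data.frame(v = rnorm(60))
    y <- rbinom(60, 1, 0.5); y[1] <- 1L; y[2] <- 0L
    fit <- fit_sdm(x, y, technique = "GLM")
    expect_gte(explained_deviance(fit, x, y), 0)
    # reversed labels out of sample: a worse-than-null model
    expect_lt(explained_deviance(fit, x, 1L - y), 0)
  })
})

test_that("evaluate_sdm assembles the full metric set", {
  d <- withr::with_seed(33, {
    x <- data.frame(a = rnorm(90), b = rnorm(90))
    y <- rbinom(90, 1, plogis(2 * x$a)); y[1] <- 1L; y[2] <- 0L
    list(x = x, y = y)
  })
  fit <- fit_sdm(d$x, d$y, technique = "GLM")
  m <- evaluate_sdm(fit, d$x, d$y)
  expect_named(m, c("auc", "tss", "threshold_tss", "kappa",
                    "threshold_kappa", "accuracy", "d2"))
  expect_gt(m$auc, 0.5)
  expect_equal(m$d2, explained_deviance(fit, d$x, d$y))
  sre <- fit_sdm(d$x, d$y, technique = "SRE")
  expect_true(is.na(evaluate_sdm(sre, d$x, d$y)$d2))
})
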