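test_that("Relief reproduces the hand-traced 6-example pass", {
  x <- data.frame(f1 = c(0, 0.1, 0.2, 1, 0.9, 0.8),
                  f2 = c(0, 0.9, 0.2, 0.1, 1, 0.3))
  lab <- rep(c("healthy", "sick"), each = 3)
  rk <- relief_rank(x, lab)
  # frozen values from an independent explicit-loop trace of the same set
  expect_equal(rk$weight[rk$feature == "f1"], 0.6, tolerance = 1e-12)
  expect_equal(rk$weight[rk$feature == "f2"], -4 / 15, tolerance = 1e-12)
  expect_identical(rk$feature, c("f1", "f2"))
})

test_that("a constant feature scores 0 and ranks behind informative ones", {
  withr::with_seed(31, {
    x <- data.frame(
      sep = rep(c(0, 4), each = 10) + rnorm(20, 0, 0.2),
      const = rep(2.5, 20),
      noise = rnorm(20)
    )
    lab <- rep(c("healthy", "sick"), each = 10)
    rk <- relief_rank(x, lab)
    expect_equal(rk$weight[rk$feature == "const"], 0)
    expect_identical(rk$feature[1], "sep")
  })
})

test_that("a separating feature beats pure noise in nearly all replicates", {
  withr::with_seed(12, {
    first <- replicate(100, {
      n <- 16
      x <- data.frame(
        sep = rep(c(0, 3), each = n / 2) + rnorm(n, 0, 0.5),
        n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n)
      )
      relief_rank(x, rep(c("healthy", "sick"), each = n / 2))$feature[1]
    })
    expect_gt(mean(first == "sep"), 0.9)
  })
})

test_that("Relief weights are centred at 0 under label permutation", {
  withr::with_seed(90, {
    mw <- replicate(60, {
      n <- 20
      x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
      lab <- sample(rep(c("healthy", "sick"), each = n / 2))
      mean(relief_rank(x, lab)$weight)
    })
    expect_lt(abs(mean(mw)), 0.05)
  })
})

test_that("Relief demands complete cases and both classes", {
  x <- data.frame(a = c(1, NA, 3, 4), b = 1:4)
  expect_error(relief_rank(x, rep(c("healthy", "sick"), 2)),
               ">= 2 complete examples")
  expect_error(relief_rank(data.frame(a = 1:4), rep("sick", 4)), "labels|class")
})

test_that("feature-count selection matches the brute-force per-k refit oracle", {
  withr::with_seed(55, {
    n <- 60
    x <- data.frame(a = rnorm(n) + rep(c(0, 1.5), each = n / 2),
                    b = rnorm(n) + rep(c(0, 0.6), each = n / 2),
                    c = rnorm(n), d = rnorm(n))
    lab <- rep(c("healthy", "sick"), each = n / 2)
    rk <- relief_rank(x, lab)
    k <- select_feature_count(x, lab, rk, k_folds = 5, seed = 9)
    folds <- stratified_kfold(lab, 5, seed = 9)
    ba <- matrix(NA_real_, 5, 4)
    for (f in 1:5) {
      for (kk in 1:4) {
        mod <- fit_gnb(x[folds != f, , drop = FALSE], lab[folds != f],
                       rk$feature[1:kk])
        pred <- predict(mod, x[folds == f, , drop = FALSE])$label
        te <- lab[folds == f]
        ba[f, kk] <- (mean(pred[te == "sick"] == "sick") +
                        mean(pred[te == "healthy"] == "healthy")) / 2
      }
    }
    mba <- colMeans(ba)
    expect_equal(as.numeric(attr(k, "balanced_accuracy")), mba)
    expect_equal(as.integer(k), which(mba >= max(mba) - 1e-12)[1])
  })
})

test_that("identical copied features give a flat profile and k = 1", {
  withr::with_seed(3, {
    v <- rnorm(40) + rep(c(0, 1), each = 20)
    x <- data.frame(a = v, b = v, c = v)
    lab <- rep(c("healthy", "sick"), each = 20)
    k <- select_feature_count(x, lab, c("a", "b", "c"), k_folds = 5, seed = 2)
    expect_equal(as.integer(k), 1L)
    ba <- attr(k, "balanced_accuracy")
    expect_equal(max(ba) - min(ba), 0)
  })
})

test_that("one informative feature among noise selects a small k", {
  withr::with_seed(44, {
    ks <- replicate(20, {
      n <- 80
      x <- data.frame(sep = rnorm(n) + rep(c(0, 2), each = n / 2),
                      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                      n4 = rnorm(n), n5 = rnorm(n))
      lab <- rep(c("healthy", "sick"), each = n / 2)
      as.integer(select_feature_count(x, lab, relief_rank(x, lab),
                                      k_folds = 5))
    })
    expect_gt(mean(ks <= 3), 0.6) # most replicates stay parsimonious
  })
  expect_error(select_feature_count(data.frame(a = rnorm(4)),
                                    rep(c("healthy", "sick"), 2), "a",
                                    k_folds = 10),
               "fewer complete cases")
})

test_that("naive Bayes moments come from available values only", {
  x <- data.frame(a = c(0, 2, NA, 5, 7, 9), b = c(1, 1, 1, 4, 4, 400))
  lab <- rep(c("healthy", "sick"), each = 3)
  mod <- fit_gnb(x, lab)
  expect_equal(mod$moments$healthy$mean[["a"]], 1) # mean of {0, 2}
  expect_equal(mod$moments$healthy$var[["a"]], 2) # sample variance of {0, 2}
  # same model as fitting on the table with the missing row's value dropped
  expect_equal(mod$moments$healthy$mean[["b"]], 1)
  expect_equal(mod$moments$sick$mean[["a"]], 7)
  # moments oracle on a random table with missingness
  withr::with_seed(66, {
    xr <- as.data.frame(matrix(rnorm(200), 50))
    names(xr) <- c("w", "x", "y", "z")
    xr$w[sample(50, 8)] <- NA
    labr <- rep(c("healthy", "sick"), 25)
    mr <- fit_gnb(xr, labr)
    for (f in names(xr)) {
      v <- xr[[f]][labr == "sick"]
      expect_equal(mr$moments$sick$mean[[f]], mean(v, na.rm = TRUE))
      expect_equal(mr$moments$sick$var[[f]], var(v, na.rm = TRUE))
    }
  })
  expect_error(fit_gnb(data.frame(a = c(1, NA, 3, 4)),
                       rep(c("healthy", "sick"), 2), "a"),
               "fewer than twice")
})

test_that("posteriors match the hand-computed Bayes rule on a 2-feature toy", {
  x <- data.frame(a = c(0, 1, 0.5, 10, 11, 10.5), b = c(5, 6, 7, 1, 2, 3))
  lab <- rep(c("healthy", "sick"), each = 3)
  mod <- fit_gnb(x, lab)
  probe <- data.frame(a = 4, b = 4)
  got <- predict(mod, probe)$posterior_sick
  dens <- function(v, m) prod(dnorm(v, m$mean, sqrt(m$var)))
  ph <- 0.5 * dens(c(4, 4), mod$moments$healthy)
  ps <- 0.5 * dens(c(4, 4), mod$moments$sick)
  expect_equal(got, ps / (ph + ps), tolerance = 1e-12)
  # equal priors, probe at the healthy class means -> healthy
  at_h <- data.frame(a = mod$moments$healthy$mean[["a"]],
                     b = mod$moments$healthy$mean[["b"]])
  expect_identical(predict(mod, at_h)$label, "healthy")
})

test_that("masking a feature equals deleting its likelihood term exactly", {
  withr::with_seed(24, {
    x <- as.data.frame(matrix(rnorm(40 * 4, 5), 40))
    names(x) <- c("a", "b", "c", "d")
    lab <- sample(rep(c("healthy", "sick"), 20))
    mod <- fit_gnb(x, lab)
    probe <- data.frame(a = 5.2, b = 4.8, c = 5.5, d = 4.4)
    masked <- probe
    masked$c <- NA_real_
    reduced <- fit_gnb(x, lab, c("a", "b", "d"))
    expect_equal(predict(mod, masked)$posterior_sick,
                 predict(reduced, probe[c("a", "b", "d")])$posterior_sick,
                 tolerance = 1e-12)
    # all selected features missing -> undecided signal
    all_na <- data.frame(a = NA_real_, b = NA_real_, c = NA_real_,
                         d = NA_real_)
    p <- predict(mod, all_na)
    expect_true(is.na(p$label))
    expect_equal(p$n_features_used, 0L)
  })
})

test_that("learned parameters recover planted Gaussians within 5%", {
  withr::with_seed(101, {
    n <- 2000
    lab <- rep(c("healthy", "sick"), each = n / 2)
    x <- data.frame(
      f1 = c(rnorm(n / 2, 10, 2), rnorm(n / 2, 13, 3)),
      f2 = c(rnorm(n / 2, -4, 1), rnorm(n / 2, -2, 1.5))
    )
    mod <- fit_gnb(x, lab)
    expect_equal(mod$moments$healthy$mean[["f1"]], 10, tolerance = 0.05)
    expect_equal(mod$moments$sick$mean[["f1"]], 13, tolerance = 0.05)
    expect_equal(sqrt(mod$moments$healthy$var[["f2"]]), 1, tolerance = 0.05)
    expect_equal(sqrt(mod$moments$sick$var[["f2"]]), 1.5, tolerance = 0.05)
  })
})

test_that("predictions agree with an independent naive Bayes on complete data", {
  skip_if_not_installed("e1071")
  withr::with_seed(40, {
    n <- 120
    x <- data.frame(a = rnorm(n) + rep(c(0, 1), each = n / 2),
                    b = rnorm(n, 3), c = rnorm(n))
    lab <- rep(c("healthy", "sick"), each = n / 2)
    mod <- fit_gnb(x, lab)
    ref <- e1071::naiveBayes(x, factor(lab, levels = c("healthy", "sick")))
    ours <- predict(mod, x)$posterior_sick
    theirs <- predict(ref, x, type = "raw")[, "sick"]
    expect_equal(ours, unname(theirs), tolerance = 1e-6)
  })
})

test_that("threshold tuning hits the requested training sensitivity", {
  withr::with_seed(58, {
    n <- 80
    x <- data.frame(a = rnorm(n) + rep(c(0, 1.2), each = n / 2))
    lab <- rep(c("healthy", "sick"), each = n / 2)
    mod <- fit_gnb(x, lab)
    post <- predict(mod, x)$posterior_sick[lab == "sick"]
    # target 1.0: threshold below the minimum sick posterior
    t1 <- tune_threshold(mod, x, lab, 1)
    expect_lt(t1, min(post))
    expect_equal(mean(post > t1), 1)
    # target 0.5 on the sick posteriors: boundary at the median order statistic
    t5 <- tune_threshold(mod, x, lab, 0.5)
    expect_gte(mean(post > t5), 0.5)
    expect_equal(t5, sort(post, decreasing = TRUE)[ceiling(0.5 * length(post))] - 1e-9)
    # target 0: maximal threshold, no constraint
    expect_equal(tune_threshold(mod, x, lab, 0), 1)
    # tuned threshold is the largest achieving the target
    for (tgt in c(0.25, 0.75)) {
      thr <- tune_threshold(mod, x, lab, tgt)
      expect_gte(mean(post > thr), tgt)
      nxt <- min(post[post > thr])
      expect_lt(mean(post > nxt), tgt)
    }
  })
})
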