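test_that("a separable training set is classified perfectly at lambda = 1", {
  ts <- toy_series(5, 8, shift = 12, sd = 0.5)
  mod <- fit_stream_ncc(ts$series, ts$labels, lambda = 1)
  expect_identical(predict(mod, ts$series), ts$labels)
})

test_that("with one example per class the centroids are the examples", {
  m <- rbind(c(1, 2, 3), c(4, 5, 6))
  mod <- fit_stream_ncc(m, c("healthy", "sick"), lambda = 0.5)
  expect_equal(mod$centroids$healthy_mean, c(1, 2, 3))
  expect_equal(mod$centroids$sick_mean, c(4, 5, 6))
  expect_error(fit_stream_ncc(m, c("sick", "sick"), 1), "both classes")
})

test_that("prediction honours zero self-distance and the tie rule", {
  ts <- toy_series(4, 6, shift = 5)
  mod <- fit_stream_ncc(ts$series, ts$labels, lambda = 1)
  expect_identical(predict(mod, mod$centroids$healthy_mean), "healthy")
  expect_identical(predict(mod, mod$centroids$sick_mean), "sick")
  # exactly equidistant point (identity weights): documented tie -> sick
  mid <- (mod$centroids$healthy_mean + mod$centroids$sick_mean) / 2
  dh <- dima_distance(mid, mod$centroids$healthy_mean, mod$weights)
  ds <- dima_distance(mid, mod$centroids$sick_mean, mod$weights)
  expect_equal(dh, ds, tolerance = 1e-12)
  expect_identical(predict(mod, mid), "sick")
  expect_error(predict(mod, 1:3), "length")
  expect_identical(predict(mod, c(1, NA, 3, 4, 5, 6)), NA_character_)
})

test_that("duplicating healthy examples never changes predictions", {
  withr::with_seed(14, {
    ts <- toy_series(6, 10, shift = 1.5)
    mod <- fit_stream_ncc(ts$series, ts$labels, lambda = 0.25)
    dup <- rbind(ts$series, ts$series[ts$labels == "healthy", ])
    dup_lab <- c(ts$labels, rep("healthy", 6))
    mod2 <- fit_stream_ncc(dup, dup_lab, lambda = 0.25)
    probe <- matrix(rnorm(20 * 10, 10), 20)
    expect_identical(predict(mod, probe), predict(mod2, probe))
  })
})

test_that("leave-one-out error matches the naive recomputation oracle", {
  ts <- toy_series(4, 6, shift = 1, seed = 3) # 8-example toy set
  for (lam in c(0, 0.25, 0.5, 1)) {
    expect_equal(loo_balanced_error(ts$series, ts$labels, lam),
                 naive_loo_error(ts$series, ts$labels, lam))
  }
  expect_error(loo_balanced_error(ts$series[1:3, ],
                                  c("healthy", "sick", "sick"), 1),
               ">= 2 examples")
})

test_that("leave-one-out error is 0 for well-separated streams, ~0.5 under the null", {
  ts <- toy_series(6, 12, shift = 20, sd = 0.5)
  for (lam in c(0, 0.5, 1)) {
    expect_equal(loo_balanced_error(ts$series, ts$labels, lam), 0)
  }
  withr::with_seed(8, {
    series <- matrix(rnorm(200 * 16), 200)
    labels <- rep(c("healthy", "sick"), 100) # independent of the series
    err <- loo_balanced_error(series, labels, 1)
    expect_gt(err, 0.4)
    expect_lt(err, 0.6)
  })
})

test_that("lambda selection minimises the leave-one-out error, ties to the largest", {
  # constant profile (separable data: error 0 everywhere) -> largest lambda
  ts <- toy_series(5, 8, shift = 15, sd = 0.5)
  lam <- select_lambda(ts$series, ts$labels)
  expect_equal(as.numeric(lam), 1)
  expect_true(all(attr(lam, "errors") == attr(lam, "errors")[1]))
  # brute force over all 31 grid values with the naive oracle
  ts2 <- toy_series(5, 6, shift = 0.8, sd = 1, seed = 42)
  lam2 <- select_lambda(ts2$series, ts2$labels)
  grid <- lambda_grid()
  errs <- vapply(grid, function(l) naive_loo_error(ts2$series, ts2$labels, l),
                 numeric(1))
  expect_equal(as.numeric(lam2), max(grid[errs == min(errs)]))
  expect_equal(unname(attr(lam2, "errors")), errs)
})

test_that("selected lambda concentrates near 1 when classes differ only pointwise", {
  withr::with_seed(19, {
    lams <- replicate(12, {
      n <- 24
      h <- matrix(rnorm(10 * n, 10), 10)
      s <- matrix(rnorm(10 * n, 11.2), 10)
      as.numeric(select_lambda(rbind(h, s),
                               rep(c("healthy", "sick"), each = 10)))
    })
    expect_gte(median(lams), 0.9)
  })
})

test_that("ensemble vote implements the 4-of-5 and strict rules", {
  expect_identical(ensemble_vote(c(rep("sick", 4), "healthy")), "sick")
  expect_identical(ensemble_vote(c(rep("sick", 3), rep("healthy", 2))),
                   "undecided")
  expect_identical(ensemble_vote(rep("healthy", 5), votes_required = 5),
                   "healthy")
  expect_identical(ensemble_vote(c(rep("sick", 4), "healthy"),
                                 votes_required = 5), "undecided")
  # missing stream -> undecided
  expect_identical(ensemble_vote(c("sick", "sick", "sick", "sick", NA)),
                   "undecided")
  expect_identical(ensemble_vote(rep("sick", 4)), "undecided")
  # tabular form: one decision per row
  votes <- rbind(rep("sick", 5), c(rep("healthy", 4), "sick"))
  expect_identical(ensemble_vote(votes), c("sick", "healthy"))
})

test_that("flipping one vote toward a class never flips the decision away", {
  withr::with_seed(77, {
    for (r in 1:200) {
      v <- sample(c("healthy", "sick"), 5, replace = TRUE)
      d0 <- ensemble_vote(v)
      i <- sample(5, 1)
      v2 <- v
      v2[i] <- "sick"
      d1 <- ensemble_vote(v2)
      # moving a vote to sick can only move the decision toward sick
      rank <- c(healthy = -1, undecided = 0, sick = 1)
      expect_gte(rank[[d1]], rank[[d0]])
    }
  })
})

test_that("stream models survive the JSON round trip", {
  ts <- toy_series(4, 6, shift = 2)
  mod <- fit_stream_ncc(ts$series, ts$labels, lambda = 0.25,
                        stream_name = "ruminating")
  path <- withr::local_tempfile(fileext = ".json")
  write_stream_ncc(mod, path)
  mod2 <- read_stream_ncc(path)
  expect_equal(mod2$centroids$healthy_mean, mod$centroids$healthy_mean)
  expect_equal(unclass(mod2$sign_matrix), unclass(mod$sign_matrix),
               ignore_attr = TRUE)
  expect_equal(mod2$lambda, mod$lambda)
  probe <- matrix(rnorm(5 * 6, 10), 5)
  expect_identical(predict(mod2, probe), predict(mod, probe))
  expect_equal(glance(mod2)$stream, "ruminating")
  expect_equal(nrow(tidy(mod)), 12)
})
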