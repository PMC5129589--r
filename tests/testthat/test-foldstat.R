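# Native-state populations and survival-analysis folding kinetics.

test_that("first-passage extraction honours the inclusive cutoff", {
  s <- data.frame(time = c(10, 20, 30), rmsd = c(2.5, 2.1, 1.9))
  o <- individualFoldingTime(s)
  expect_true(o$event); expect_equal(o$time, 30)
  # boundary value 1.96 counts as folded
  sb <- data.frame(time = c(10, 20), rmsd = c(1.96, 5))
  expect_equal(individualFoldingTime(sb)$time, 10)
  # never below cutoff -> censored at the last time
  sc <- data.frame(time = c(10, 20, 30), rmsd = c(3, 3, 3))
  oc <- individualFoldingTime(sc)
  expect_false(oc$event); expect_equal(oc$time, 30)
})

test_that("native population is the inclusive fraction and complements to 1", {
  s <- data.frame(time = 1:4, rmsd = c(1, 1.96, 2, 3))
  expect_equal(nativePopulation(s), 0.5)
  expect_equal(nativePopulation(data.frame(time = 1:3, rmsd = rep(1, 3))), 1)
  expect_equal(nativePopulation(data.frame(time = 1:3, rmsd = rep(9, 3))), 0)
  ts <- synthTwoStateRmsd(rate = 1 / 50, nSims = 5, simLength = 500,
                          saveInterval = 1, seed = 21)
  for (i in 1:5) {
    p <- nativePopulation(ts$series[[i]])
    nonnative <- mean(ts$series[[i]]$rmsd > 1.96)
    expect_equal(p + nonnative, 1)
  }
})

test_that("population aggregation gives mean, sample SD and SD/sqrt(n)", {
  a <- aggregatePopulation(c(0.5, 0.5, 0.5))
  expect_equal(a$mean, 0.5); expect_equal(a$sd, 0)
  expect_equal(aggregatePopulation(c(0, 1))$mean, 0.5)
  set.seed(13)
  p <- rbeta(20, 2, 2)
  ag <- aggregatePopulation(p)
  expect_equal(ag$sd, sd(p))
  expect_equal(ag$se, sd(p) / sqrt(20))
  expect_true(ag$se <= ag$sd)
  expect_true(is.na(aggregatePopulation(0.4)$sd))
})

test_that("KM restricted mean matches hand-computed tables", {
  # all events at one time: mean is that time with a zero-width CI
  all100 <- data.frame(time = rep(100, 20), event = TRUE)
  est <- kmFoldingTime(all100)
  expect_equal(est@mean, 100)
  expect_equal(est@lcl, 100); expect_equal(est@ucl, 100)
  # no censoring: restricted mean equals the sample mean exactly
  set.seed(14)
  t1 <- rexp(40, 1 / 150)
  e1 <- kmFoldingTime(data.frame(time = t1, event = TRUE))
  expect_equal(e1@mean, mean(t1), tolerance = 1e-9)
  expect_equal(e1@mean, kmHandTable(t1, rep(TRUE, 40))$rmean, tolerance = 1e-9)
  # half events at 10, half censored at 10: S jumps to 0.5 at 10,
  # restricted mean over [0, 10] is 10
  mix <- data.frame(time = rep(10, 20), event = rep(c(TRUE, FALSE), 10))
  expect_equal(kmFoldingTime(mix)@mean, 10)
  # censored data against the hand KM table
  set.seed(15)
  t2 <- rexp(60, 1 / 100); cens <- runif(60) < 0.3
  t2[cens] <- pmin(t2[cens], 80)
  ev <- !cens | t2 < 80
  expect_equal(kmFoldingTime(data.frame(time = t2, event = ev))@mean,
               kmHandTable(t2, ev)$rmean, tolerance = 1e-9)
  expect_error(kmFoldingTime(data.frame(time = 1:3, event = FALSE)), "event")
})

test_that("KM mean recovers the true mean of exponential draws", {
  gen <- synthTwoStateRmsd(rate = 1 / 200, nSims = 1000, simLength = 4000,
                           saveInterval = 1, seed = 16)
  obs <- data.frame(time = gen$manifest$savedTimes, event = gen$manifest$event)
  est <- kmFoldingTime(obs)
  se <- 200 / sqrt(1000)
  expect_lt(abs(est@mean - 200), 3 * se)
  expect_true(est@lcl <= est@mean && est@mean <= est@ucl)
})

test_that("parametric fit matches the closed-form exponential MLE", {
  # uncensored: mean = sample mean exactly
  set.seed(17)
  t1 <- rexp(50, 1 / 300)
  fit <- parametricFoldingTime(data.frame(time = t1, event = TRUE),
                               "exponential")
  expect_equal(fit@mean, mean(t1), tolerance = 1e-6)
  # censored: mean = total time / events
  t2 <- rexp(40, 1 / 300); ev <- t2 < 400; t2[!ev] <- 400
  fit2 <- parametricFoldingTime(data.frame(time = t2, event = ev),
                                "exponential")
  expect_equal(fit2@mean, sum(t2) / sum(ev), tolerance = 1e-6)
  # eligibility: 4 events of 20 refused
  few <- data.frame(time = c(rexp(4, 1 / 100), rep(500, 16)),
                    event = rep(c(TRUE, FALSE), c(4, 16)))
  expect_error(parametricFoldingTime(few, "exponential"),
               "insufficient events")
  # weibull mean = scale * gamma(1 + 1/shape), checked against sample mean
  set.seed(18)
  tw <- rweibull(4000, shape = 2, scale = 100)
  fw <- parametricFoldingTime(data.frame(time = tw, event = TRUE), "weibull")
  expect_equal(fw@mean, 100 * gamma(1.5), tolerance = 0.05)
})

test_that("exponential rate recovery with CI coverage across seeds", {
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    t <- rexp(1000, 1 / 200)
    fit <- parametricFoldingTime(data.frame(time = t, event = TRUE),
                                 "exponential")
    expect_lt(abs(fit@mean - 200) / 200, 0.1)
    if (fit@lcl <= 200 && 200 <= fit@ucl) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("parametric curve agreement with the KM band discriminates fits", {
  set.seed(19)
  obs <- data.frame(time = rexp(200, 1 / 100), event = TRUE)
  good <- kmParametricAgreement(obs, "exponential")
  expect_gt(good$fraction, 0.9)
  expect_true(good$agreed)
  # single event: one-point grid
  one <- kmParametricAgreement(data.frame(time = 5, event = TRUE),
                               "exponential")
  expect_true(one$fraction %in% c(0, 1))
})

test_that("two-state check finds the exponential rate on constructed quantiles", {
  n <- 30; rate <- 1 / 2000
  # event times at which the theoretical survival equals the post-event
  # empirical fraction (deterministic exponential quantiles)
  tq <- c(-log((n - seq_len(n - 1)) / n) / rate, -log(0.5 / n) / rate)
  fit <- suppressWarnings(twoStateCheck(data.frame(time = tq, event = TRUE)))
  expect_gt(fit$rSquared, 0.99)
  expect_lt(abs(fit$slope + rate) / rate, 0.05)
  # arithmetic-progression times against the hand OLS formula
  ta <- seq(10, 100, by = 10)
  fa <- twoStateCheck(data.frame(time = ta, event = TRUE))
  y <- log((10 - 1:9) / 10); x <- ta[1:9]
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fa$slope, beta, tolerance = 1e-12)
  # three equal times are degenerate
  expect_error(twoStateCheck(data.frame(time = rep(7, 5), event = TRUE)),
               "distinct")
})
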