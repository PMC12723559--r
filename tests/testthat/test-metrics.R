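# construct spike_data objects directly for metric oracles
fake_spikes <- function(time, neuron, n = 800, n_pyr = 800,
                        duration = 5000, stim_times = numeric(0)) {
  structure(list(
    time = time, neuron = neuron,
    pop = rep(c("pyr", "sst"), c(n_pyr, n - n_pyr)),
    n = n, counts = c(pyr = n_pyr, sst = n - n_pyr, pv = 0, vip = 0),
    duration = duration, stim_times = stim_times, condition = "test"
  ), class = "spike_data")
}

test_that("baseline rate windows have the forced geometry and hand-counted rates", {
  empty <- fake_spikes(numeric(0), integer(0))
  d <- baseline_rate_distribution(empty, window = 40, step = 1, span = 3000)
  expect_length(d$rates, (3000 - 40) / 1 + 1)
  expect_true(all(d$rates == 0))

  # one neuron firing every 10 ms: every 40 ms window holds 4 spikes
  tt <- seq(5, 3000, by = 10)
  sp <- fake_spikes(tt, rep(1L, length(tt)))
  d2 <- baseline_rate_distribution(sp)
  expected <- 4 / (800 * 0.04)
  expect_equal(stats::median(d2$rates), expected)
  expect_equal(mean(d2$rates), expected, tolerance = 0.01)

  d3 <- baseline_rate_distribution(sp)
  expect_identical(d2$rates, d3$rates)
})

test_that("recurrent rates are hand-countable per trial", {
  stim <- seq(3000, by = 200, length.out = 20)
  empty <- fake_spikes(numeric(0), integer(0), stim_times = stim,
                       duration = 8000)
  r0 <- recurrent_rate_distribution(empty)
  expect_equal(r0$rates, rep(0, 20))

  # exactly 8 spikes in each 10-50 ms window
  tt <- as.vector(outer(seq(12, 47, by = 5), stim, "+"))
  sp <- fake_spikes(tt, rep(1L, length(tt)), stim_times = stim,
                    duration = 8000)
  r <- recurrent_rate_distribution(sp)
  expect_equal(r$rates, rep(8 / (800 * 0.04), 20))
  expect_equal(stats::var(r$rates), 0)

  expect_error(recurrent_rate_distribution(
    fake_spikes(numeric(0), integer(0))), "no stimulus")
})

test_that("distribution overlap reproduces hand-computed cases", {
  expect_equal(detection_error(rep(c(1, 2, 3), 10), rep(c(1, 2, 3), 10),
                               n_boot = 10)$overlap, 100)
  expect_equal(detection_error(rnorm(50), rnorm(50) + 100,
                               n_boot = 10)$overlap, 0)
  # p1 = (.8, .2, 0), p2 = (0, .2, .8) on shared bins -> 20%
  x <- c(rep(0.5, 8), rep(1.5, 2))
  y <- c(rep(1.5, 2), rep(2.5, 8))
  ov <- detection_error(x, y, n_boot = 10, breaks = c(0, 1, 2, 3))
  expect_equal(ov$overlap, 20)
})

test_that("overlap is symmetric and invariant to common rescaling of counts", {
  set.seed(2)
  x <- rnorm(80); y <- rnorm(60, 1)
  br <- seq(-5, 7, length.out = 25)
  a <- detection_error(x, y, n_boot = 10, breaks = br)$overlap
  b <- detection_error(y, x, n_boot = 10, breaks = br)$overlap
  expect_equal(a, b)
  # triplicating every observation leaves the bin proportions unchanged
  a3 <- detection_error(rep(x, 3), rep(y, 3), n_boot = 10,
                        breaks = br)$overlap
  expect_equal(a3, a)
})

test_that("bootstrap interval brackets the point overlap", {
  set.seed(3)
  d <- detection_error(rnorm(100), rnorm(100, 1.5), n_boot = 200, seed = 1)
  expect_gte(d$overlap, 0)
  expect_lte(d$overlap, 100)
  expect_lt(d$ci[1], d$boot_mean)
  expect_gt(d$ci[2], d$boot_mean)
})

test_that("decoding is perfect for separable windows and at chance when shuffled", {
  n_pyr <- 40
  stim <- seq(1000, by = 200, length.out = 20)
  # every neuron spikes once in each response window, never at baseline
  tt <- as.vector(outer(rep(50, n_pyr), stim, "+"))
  nn <- rep(seq_len(n_pyr), length(stim))
  sp <- fake_spikes(tt, nn, n = n_pyr, n_pyr = n_pyr, duration = 6000,
                    stim_times = stim)
  acc <- decoding_accuracy(sp, "svm", n_perm = 20, seed = 1)
  expect_equal(mean(acc), 100)

  # irregular spiking identical in both window classes: chance
  set.seed(5)
  tt2 <- runif(4000, 0, 6000)
  nn2 <- sample.int(n_pyr, 4000, replace = TRUE)
  sp2 <- fake_spikes(tt2, nn2, n = n_pyr, n_pyr = n_pyr, duration = 6000,
                     stim_times = stim)
  acc2 <- decoding_accuracy(sp2, "svm", n_perm = 100, seed = 2,
                            shuffle_labels = TRUE)
  expect_lt(abs(mean(acc2) - 50), 5)

  expect_identical(decoding_accuracy(sp2, "svm", n_perm = 10, seed = 3),
                   decoding_accuracy(sp2, "svm", n_perm = 10, seed = 3))
})

test_that("the ANN decoder also separates trivially separable windows", {
  n_pyr <- 30
  stim <- seq(500, by = 150, length.out = 12)
  tt <- as.vector(outer(rep(40, n_pyr), stim, "+"))
  sp <- fake_spikes(tt, rep(seq_len(n_pyr), length(stim)), n = n_pyr,
                    n_pyr = n_pyr, duration = 3000, stim_times = stim)
  acc <- decoding_accuracy(sp, "ann", n_perm = 3, seed = 1)
  expect_equal(mean(acc), 100)
})

test_that("cohens_d matches the pooled-SD formula on random samples", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), 1)
  set.seed(11)
  for (i in 1:1000) {
    nx <- sample(2:30, 1); ny <- sample(2:30, 1)
    x <- rnorm(nx, sd = runif(1, 0.5, 3))
    y <- rnorm(ny, 1, sd = runif(1, 0.5, 3))
    sp <- sqrt(((nx - 1) * sd(x)^2 + (ny - 1) * sd(y)^2) / (nx + ny - 2))
    expect_equal(cohens_d(x, y), (mean(y) - mean(x)) / sp,
                 tolerance = 1e-12)
  }
  # scale-free and shift-invariant
  x <- rnorm(20); y <- rnorm(20, 1)
  expect_equal(cohens_d(2 * x, 2 * y), cohens_d(x, y), tolerance = 1e-12)
  expect_equal(cohens_d(x + 5, y + 5), cohens_d(x, y), tolerance = 1e-12)
  expect_error(cohens_d(rep(1, 5), rep(2, 5)), "zero pooled variance")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("null t-test type-I rate is close to the nominal 5%", {
  set.seed(21)
  rej <- vapply(1:1000, function(i) {
    stats::t.test(rnorm(20), rnorm(20), var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("compare_conditions flags separated groups and not identical ones", {
  df <- data.frame(condition = rep(c("middle_age", "older"), each = 4),
                   m = c(1, 2, 3, 4, 1, 2, 3, 4))
  cmp <- compare_conditions(df, "m")
  expect_equal(cmp$t, 0)
  expect_equal(cmp$d, 0)
  expect_false(cmp$significant)

  set.seed(1)
  df2 <- data.frame(condition = rep(c("middle_age", "older"), each = 4),
                    m = c(rnorm(4, 0, 0.01), rnorm(4, 1, 0.01)))
  cmp2 <- compare_conditions(df2, "m")
  expect_lt(cmp2$p, 0.05)
  expect_gt(abs(cmp2$d), 0.5)
  expect_true(cmp2$significant)
  expect_error(compare_conditions(df2, "nope"), "unknown metric")
})
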