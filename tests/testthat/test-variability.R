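test_that("coefficient of variation: worked values and edge cases", {
  expect_equal(coefficientOfVariation(c(2, 4, 6)), 0.5)
  expect_equal(coefficientOfVariation(c(5, 5, 5, 5)), 0)
  # one positive value among five: sd/mean = sqrt(5) for any x > 0
  for (x in c(1, 0.37, 1e6))
    expect_equal(coefficientOfVariation(c(x, 0, 0, 0, 0)), sqrt(5))
  expect_warning(expect_true(is.na(coefficientOfVariation(c(-1, 1)))),
                 "zero mean")
  expect_true(is.na(coefficientOfVariation(3)))
  # ddof = 0 uses the population SD
  expect_equal(coefficientOfVariation(c(2, 4, 6), ddof = 0L),
               sqrt(8 / 3) / 4)
})

test_that("CV is scale invariant", {
  set.seed(10)
  for (i in 1:20) {
    x <- rlnorm(sample(3:12, 1))
    c_ <- runif(1, 0.01, 100)
    expect_equal(coefficientOfVariation(c_ * x), coefficientOfVariation(x))
  }
})

test_that("cvTable computes per-cell CVs across vessels", {
  vessels <- paste0("V", 1:6)
  tps <- c(12, 25, 37)
  vals <- matrix(rep(c(0.2, 0.8), each = 18), 18, 2,
                 dimnames = list(NULL, c("A", "B")))
  tab <- gridSampleTable(vals, vessels, tps)
  cv <- cvTable(tab, method = "test")
  expect_true(all(tableValues(cv) == 0))
  expect_identical(rownames(tableValues(cv)), as.character(tps))

  # a single vessel gives an all-missing table
  one <- gridSampleTable(vals[1:3, , drop = FALSE], "V1", tps)
  expect_true(all(is.na(tableValues(cvTable(one)))))
})

test_that("cvTable recovers the lognormal CV at many vessels", {
  set.seed(11)
  sigma <- 0.4
  n_vessels <- 200
  vals <- matrix(rlnorm(n_vessels, 0, sigma), n_vessels, 1,
                 dimnames = list(NULL, "A"))
  tab <- gridSampleTable(vals, paste0("V", seq_len(n_vessels)), 12,
                         kind = "concentration")
  cv <- tableValues(cvTable(tab))[1, 1]
  expect_equal(cv, sqrt(exp(sigma^2) - 1), tolerance = 0.1)
})

test_that("aggregateCV averages ignoring missing cells", {
  v <- matrix(c(0.1, 0.2, NA, 0.4), 2, 2,
              dimnames = list(c("12", "25"), c("A", "B")))
  ag <- aggregateCV(v)
  expect_equal(unname(ag$row_means), c(0.1, 0.3))
  expect_equal(unname(ag$col_means), c(0.15, 0.4))
  expect_equal(ag$grand_mean, mean(c(0.1, 0.2, 0.4)))
  # excluding a column removes it from every aggregate
  ag2 <- aggregateCV(v, exclude = "B")
  expect_equal(unname(ag2$row_means), c(0.1, 0.2))
  expect_equal(ag2$grand_mean, 0.15)
  # single-cell table: all aggregates equal the cell
  one <- matrix(0.3, 1, 1, dimnames = list("12", "A"))
  ag3 <- aggregateCV(one)
  expect_equal(unname(ag3$row_means), 0.3)
  expect_equal(unname(ag3$col_means), 0.3)
  expect_equal(ag3$grand_mean, 0.3)
})

test_that("compareMethodsCV pairs shared cells and detects inflation", {
  set.seed(12)
  v <- matrix(runif(24, 0.05, 0.5), 6, 4,
              dimnames = list(c(12, 25, 37, 49, 61, 67),
                              c("RI", "BH", "BT", "CA")))
  res <- compareMethodsCV(2 * v, v)
  expect_lt(res$p_one_sided, 1e-4)  # all 24 differences positive, exact
  expect_equal(res$p_one_sided, 1 / 2^24)
  expect_equal(res$mean_ratio, 2)
  res_eq <- suppressWarnings(compareMethodsCV(v, v))
  expect_equal(res_eq$p_two_sided, 1)
  expect_error(compareMethodsCV(v[1, 1, drop = FALSE], v[1, 1, drop = FALSE]),
               "fewer than")
})

test_that("heterogeneity is the channel-range summary", {
  ch <- defaultChannels()
  m <- matrix(5, 10, 23, dimnames = list(NULL, ch))
  expect_equal(heterogeneity(EventTable(m))$value, 0)
  m[, 1] <- rep(1:5, 2)  # range 4 on one channel, 0 on the other 22
  ev <- EventTable(m)
  expect_equal(heterogeneity(ev)$value, 4 / 23)
  expect_equal(heterogeneity(ev, "sum")$value, 4)
  expect_equal(heterogeneity(ev, "sum")$value,
               23 * heterogeneity(ev, "mean")$value)
  # empty input: missing
  expect_true(is.na(heterogeneity(EventTable(m[0, , drop = FALSE]))$value))
})

test_that("heterogeneity is translation invariant and scales linearly", {
  set.seed(13)
  m <- matrix(abs(rnorm(50 * 23, 100, 10)), 50,
              dimnames = list(NULL, defaultChannels()))
  h0 <- heterogeneity(EventTable(m))$value
  expect_equal(heterogeneity(EventTable(m + 1000))$value, h0)
  expect_equal(heterogeneity(EventTable(3 * m))$value, 3 * h0)
})

test_that("methodCorrelation reports r and p", {
  x <- c(1, 2, 3, 4, 5, 7)
  expect_equal(methodCorrelation(x, 2 * x)$r, 1)
  expect_equal(methodCorrelation(x, -x)$r, -1)
  expect_warning(res <- methodCorrelation(x, rep(1, 6)), "constant")
  expect_true(is.na(res$r))
  expect_error(methodCorrelation(1:2, 1:2), "at least 3")
  sp <- methodCorrelation(x, x^3, method = "spearman")
  expect_equal(sp$r, 1)
})

test_that("pearson test calibrates to its nominal rejection rate", {
  set.seed(14)
  n <- 36
  crit <- abs(qt(0.025, n - 2)) / sqrt(n - 2 + qt(0.025, n - 2)^2)
  rej <- mean(replicate(1000, {
    abs(cor(rnorm(n), rnorm(n))) > crit
  }))
  expect_equal(rej, 0.05, tolerance = 0.4)  # 5% +/- 2% absolute
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})
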