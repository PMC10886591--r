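test_that("Grubbs filter matches the t-quantile oracle on canonical cases", {
  res <- grubbs_filter(c(1, 1, 1, 1, 1, 10))
  expect_equal(res$removed, 10)
  expect_equal(res$kept, rep(1, 5))
  expect_equal(res$G_statistics[1], 7.5 / sd(c(1, 1, 1, 1, 1, 10)))
  expect_gt(res$G_statistics[1], oracle_grubbs_crit(6))

  expect_length(grubbs_filter(rep(4, 6))$removed, 0)     # zero variance
  expect_length(grubbs_filter(c(-2, -1, 0, 1, 2))$removed, 0)
  expect_lt(max(abs(c(-2, -1, 0, 1, 2))) / sd(c(-2, -1, 0, 1, 2)),
            oracle_grubbs_crit(5))
  expect_error(grubbs_filter(c(1, 2)), "n >= 3")
})

test_that("Grubbs removal is scale and shift invariant", {
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(8)
    if (i %% 2 == 0) x[1] <- x[1] + 6          # plant an outlier sometimes
    base <- grubbs_filter(x)
    tr <- grubbs_filter(-2.5 * x + 7)
    expect_equal(sort(-2.5 * base$removed + 7), sort(tr$removed),
                 tolerance = 1e-12)
  }
})

test_that("simple regression on condition means matches the normal equations", {
  x <- c(1, 2.7, 5, 10)
  f <- simple_regression(x, 3 * x + 1)
  expect_equal(f$slope, 3); expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  fc <- simple_regression(x, rep(2, 4))
  expect_equal(fc$slope, 0); expect_equal(fc$r_squared, 0)

  set.seed(6)
  xx <- rep(c(1, 2.7, 5, 10), each = 3)
  yy <- 2 - 0.5 * xx + rnorm(12)
  f2 <- simple_regression(xx, yy)
  m <- aggregate(list(y = yy), list(x = xx), mean)
  beta <- oracle_ols(cbind(1, m$x), m$y)
  expect_equal(c(f2$intercept, f2$slope), unname(beta), tolerance = 1e-12)
  expect_error(simple_regression(rep(1, 4), 1:4), "distinct")
})

test_that("multiple regression equals the normal-equations solve", {
  set.seed(33)
  for (i in 1:25) {
    d <- data.frame(fibrinogen = runif(12, 1, 10),
                    activator = runif(12, 0.1, 1))
    d$y <- 5 + 2 * d$fibrinogen - 3 * d$activator + rnorm(12)
    m <- multiple_regression(d, "y", aggregate = FALSE)
    beta <- oracle_ols(cbind(1, d$fibrinogen, d$activator), d$y)
    expect_equal(c(m$beta0, m$beta_fib, m$beta_act), unname(beta),
                 tolerance = 1e-10)
  }
})

test_that("diameter coefficients are recovered exactly from noiseless trends", {
  grid <- expand.grid(fibrinogen = c(1, 2.7, 5, 10),
                      activator = c(0.1, 0.25, 0.5, 1))
  grid$y <- 200 + 10.89 * grid$fibrinogen - 88.73 * grid$activator
  m <- multiple_regression(grid, "y")
  expect_equal(m$beta_fib, 10.89, tolerance = 1e-10)
  expect_equal(m$beta_act, -88.73, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)

  grid$y2 <- 400 + 59.89 * grid$fibrinogen - 100.15 * grid$activator
  m2 <- multiple_regression(grid, "y2")
  expect_equal(c(m2$beta_fib, m2$beta_act), c(59.89, -100.15),
               tolerance = 1e-10)

  # pure-noise response: R^2 near zero, coefficients near zero
  set.seed(91)
  grid$z <- rnorm(16)
  mz <- multiple_regression(grid, "z")
  expect_lt(mz$r_squared, 0.5)
  expect_lt(abs(mz$beta_fib), 3 * sd(grid$z) / sd(grid$fibrinogen))

  grid$activator <- 0.1
  expect_error(multiple_regression(grid, "y"), "rank-deficient",
               class = "cq_rank_deficient")
})

test_that("sign-trend table encodes coefficient signs and disagreements", {
  mdf <- data.frame(response = c("diameter_nm", "diameter_nm", "lag_s", "lag_s"),
                    sample_type = c("purified", "plasma", "purified", "plasma"),
                    beta_fib = c(10.9, 59.9, 7.7, -14.7),
                    beta_act = c(-88.7, -100.2, -187, -229))
  tab <- sign_trend_table(mdf)
  expect_equal(tab$sign_fib, c("+", "+", "+", "-"))
  expect_equal(tab$sign_act, rep("-", 4))
  expect_equal(tab$types_disagree, c(FALSE, FALSE, TRUE, TRUE))

  zero <- sign_trend_table(data.frame(response = "x", sample_type = "purified",
                                      beta_fib = 0, beta_act = 0))
  expect_equal(c(zero$sign_fib, zero$sign_act), c("0", "0"))
  flip <- sign_trend_table(within(mdf, { beta_fib <- -beta_fib
                                         beta_act <- -beta_act }))
  expect_equal(flip$sign_fib, c("-", "-", "-", "+"))
})

test_that("summaries follow the mean/SEM and median/IQR conventions", {
  s <- summarize_values(c(1, 2, 3))
  expect_equal(s$center, 2)
  expect_equal(s$spread, 1 / sqrt(3))

  q <- summarize_values(c(1, 2, 3, 100), normal = FALSE)
  expect_equal(q$center, 2.5)
  expect_equal(q$spread, c(1.75, 27.25))   # type-7 interpolation

  one <- summarize_values(5)
  expect_equal(one$center, 5); expect_equal(one$spread, 0)
})
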