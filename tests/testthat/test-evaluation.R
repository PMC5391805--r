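## independent brute-force implementations of the agreement statistics,
## written from the computational sum formulas (with the n factors restored
## in the correlation)
brute_stats <- function(x, y) {
  n <- length(x)
  r2 <- (n * sum(x * y) - sum(x) * sum(y))^2 /
    ((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  rmse_n <- 100 * sqrt(sum((y - x)^2) / n) / (sum(x) / n)
  m_eff <- 1 - sum((x - y)^2) / sum((x - mean(x))^2)
  beta <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  alpha <- mean(y) - beta * mean(x)
  list(r2 = r2, rmse_n = rmse_n, m_eff = m_eff, alpha = alpha, beta = beta)
}

test_that("perfect agreement gives the ideal statistics", {
  r <- evaluate(paired_series(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$r2, 1)
  expect_equal(r$rmse_n, 0)
  expect_equal(r$m_eff, 1)
  expect_equal(r$alpha, 0)
  expect_equal(r$beta, 1)
  expect_equal(r$p_t, 1)
})

test_that("predicting the observed mean gives zero model efficiency", {
  r <- evaluate(paired_series(c(1, 2, 3), c(2, 2, 2)))
  expect_equal(r$m_eff, 0)
})

test_that("the normalized RMSE worked example evaluates exactly", {
  r <- evaluate(paired_series(c(2, 4, 6), c(3, 3, 6)))
  expect_equal(r$rmse_n, 100 * sqrt(2 / 3) / 4, tolerance = 1e-12)
  expect_equal(r$rmse_n, 20.41241, tolerance = 1e-5)
})

test_that("evaluate matches the brute-force formulas on random series", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    x <- rnorm(n, 10, 3)
    y <- x + rnorm(n, 0, 2)
    r <- evaluate(paired_series(x, y))
    b <- brute_stats(x, y)
    expect_equal(r$r2, b$r2, tolerance = 1e-10)
    expect_equal(r$rmse_n, b$rmse_n, tolerance = 1e-10)
    expect_equal(r$m_eff, b$m_eff, tolerance = 1e-10)
    expect_equal(r$alpha, b$alpha, tolerance = 1e-8)
    expect_equal(r$beta, b$beta, tolerance = 1e-8)
    expect_true(r$r2 >= 0 && r$r2 <= 1)
    expect_lte(r$m_eff, 1)
  }
})

test_that("model efficiency can be negative while r2 cannot", {
  x <- c(1, 2, 3, 4)
  y <- c(4, 1, 5, 0) # worse than the mean predictor
  r <- evaluate(paired_series(x, y))
  expect_lt(r$m_eff, 0)
  expect_gte(r$r2, 0)
})

test_that("degenerate inputs fail loudly", {
  expect_error(evaluate(paired_series(c(-1, 0, 1), c(1, 2, 3))), "mean")
  expect_error(evaluate(paired_series(c(2, 2, 2), c(1, 2, 3))), "variance")
  expect_error(paired_series(1, 1), "2 data pairs")
  expect_error(paired_series(1:3, 1:4), "equal length")
})

test_that("the Welch and paired t-test variants are both available", {
  set.seed(3)
  x <- rnorm(20, 10); y <- x + rnorm(20, 0, 0.5)
  rw <- evaluate(paired_series(x, y), t_test = "welch")
  rp <- evaluate(paired_series(x, y), t_test = "paired")
  expect_equal(rw$p_t, t.test(y, x, var.equal = FALSE)$p.value)
  expect_equal(rp$p_t, t.test(y, x, paired = TRUE)$p.value)
})

test_that("interpretation flags pass on ideal and fail on poor reports", {
  good <- evaluate(paired_series(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_true(all(interpret(good)))
  bad <- good
  bad$m_eff <- -0.5
  expect_false(interpret(bad)[["m_eff"]])
  bad2 <- good
  bad2$p_t <- 0.04
  expect_false(interpret(bad2)[["p_t"]])
})
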