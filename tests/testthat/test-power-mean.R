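test_that("special cases reproduce the classical means exactly", {
  expect_equal(power_mean(c(1, 4), 1), 2.5)
  expect_equal(power_mean(c(1, 4), 0), 2)
  expect_equal(power_mean(c(1, 4), -Inf), 1)
  expect_equal(power_mean(c(1, 4), Inf), 4)
  expect_equal(power_mean(c(1, 7), 2), 5)
  expect_equal(power_mean(c(2, 3, 6), -1), 3)

  withr::with_seed(7, {
    for (rep in 1:25) {
      x <- stats::runif(sample(2:30, 1), 0.01, 10)
      expect_equal(power_mean(x, -Inf), min(x), tolerance = 1e-12)
      expect_equal(power_mean(x, -1), length(x) / sum(1 / x), tolerance = 1e-12)
      expect_equal(power_mean(x, 0), exp(mean(log(x))), tolerance = 1e-12)
      expect_equal(power_mean(x, 1), mean(x), tolerance = 1e-12)
      expect_equal(power_mean(x, 2), sqrt(mean(x^2)), tolerance = 1e-12)
      expect_equal(power_mean(x, Inf), max(x), tolerance = 1e-12)
    }
  })
})

test_that("general exponents match the defining-formula oracle", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      x <- stats::runif(20, .Machine$double.eps, 1)
      for (p in c(-3, -0.5, 0.7, 4)) {
        expect_equal(power_mean(x, p), oracle_power_mean(x, p),
          tolerance = 1e-12
        )
      }
    }
  })
})

test_that("power mean is nondecreasing in p and bounded by the extremes", {
  p_grid <- c(-Inf, -10, -3, -1, -0.2, 0, 0.2, 1, 3, 10, Inf)
  withr::with_seed(3, {
    for (rep in 1:20) {
      x <- stats::runif(sample(3:25, 1), 0.01, 5)
      vals <- vapply(p_grid, function(p) power_mean(x, p), numeric(1))
      expect_true(all(diff(vals) > -1e-12))
      expect_true(all(vals >= min(x) - 1e-12 & vals <= max(x) + 1e-12))
      # strict increase between finite exponents for non-constant samples
      fin <- is.finite(p_grid)
      expect_true(all(diff(vals[fin]) > 0))
    }
    # constant samples are fixed points at every p
    for (p in p_grid) expect_equal(power_mean(rep(2.7, 6), p), 2.7)
  })
})

test_that("power mean is permutation invariant", {
  withr::with_seed(5, {
    x <- stats::runif(15, 0.1, 3)
    for (p in c(-Inf, -2, 0, 0.5, 2, Inf)) {
      expect_equal(power_mean(x, p), power_mean(sample(x), p))
    }
  })
})

test_that("finite exponents approach the limit special cases continuously", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      x <- stats::runif(12, 0.05, 4)
      g <- exp(mean(log(x)))
      expect_equal(power_mean(x, 1e-8), g, tolerance = 1e-6)
      expect_equal(power_mean(x, -1e-8), g, tolerance = 1e-6)
      # large finite exponents converge to the extremes at the exact
      # n^(-1/p) rate; the limits themselves are still returned exactly
      n <- length(x)
      expect_gte(power_mean(x, 30), max(x) * n^(-1 / 30) - 1e-12)
      expect_lte(power_mean(x, -30), min(x) * n^(1 / 30) + 1e-12)
      expect_equal(power_mean(x, 300), max(x), tolerance = 0.02)
      expect_equal(power_mean(x, -300), min(x), tolerance = 0.02)
      expect_gt(power_mean(x, 300), power_mean(x, 30) - 1e-12)
      expect_lt(power_mean(x, -300), power_mean(x, -30) + 1e-12)
    }
  })
})

test_that("large values and exponents neither overflow nor underflow", {
  withr::with_seed(17, {
    x <- stats::runif(50, 1, 1e6)
    for (p in c(-100, -37, 37, 100)) {
      v <- power_mean(x, p)
      expect_true(is.finite(v))
      expect_gte(v, min(x))
      expect_lte(v, max(x))
    }
  })
})

test_that("zeros follow the limiting convention", {
  x <- c(0, 1, 4)
  expect_equal(power_mean(x, -Inf), 0)
  expect_equal(power_mean(x, -1), 0)
  expect_equal(power_mean(x, 0), 0)
  expect_equal(power_mean(x, 1), 5 / 3)
  expect_equal(power_mean(x, Inf), 4)
  expect_equal(power_mean(c(0, 0), 2), 0)
})

test_that("invalid samples and exponents error", {
  expect_error(power_mean(numeric(0), 1), "at least one")
  expect_error(power_mean(c(1, -2), 1), "nonnegative")
  expect_error(power_mean(c(1, NA), 1), "finite")
  expect_error(power_mean(c(1, Inf), 1), "finite")
  expect_error(power_mean(1:3, "nope"), "inf")
  expect_error(power_mean(1:3, c(1, 2)), "single")
})

test_that("exponent tokens round-trip through text", {
  grid <- default_p_grid()
  toks <- format_p(grid)
  expect_identical(toks[c(1, length(toks))], c("-inf", "inf"))
  back <- vapply(toks, parse_p, numeric(1), USE.NAMES = FALSE)
  expect_identical(back, grid)
  expect_identical(parse_p("+inf"), Inf)
  expect_identical(parse_p("-2.5"), -2.5)
  expect_identical(parse_p(" INF "), Inf)
})
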