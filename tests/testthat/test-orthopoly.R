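test_that("bins are equal width, exhaustive and use the half-open convention", {
  s <- spectrum(seq(100, 1100, by = 10), rep(1, 101))
  b <- make_bins(s, 5)
  expect_equal(b$edges, c(100, 300, 500, 700, 900, 1100))
  expect_equal(b$centers, c(200, 400, 600, 800, 1000))

  # a peak exactly on an interior edge goes to the right-hand bin
  s2 <- spectrum(c(100, 300, 1100), c(1, 1, 1))
  b2 <- make_bins(s2, 5)
  expect_equal(b2$bin, c(1L, 2L, 5L))

  for (seed in 1:10) {
    sp <- random_spectrum(seed)
    for (nb in c(3, 5, 7, 9, 11)) {
      bb <- make_bins(sp, nb)
      counts <- tabulate(bb$bin, nb)
      expect_equal(sum(counts), n_peaks(sp))
    }
  }
  expect_error(make_bins(s, 1), "n_bins")
})

test_that("per-bin noise matches the per-bin oracle and imputes sparse bins", {
  # three flat bins at a constant level
  s <- spectrum(seq(100, 400, by = 10), rep(4, 31))
  b <- make_bins(s, 3)
  expect_equal(as.numeric(per_bin_noise(s, b)), c(4, 4, 4))

  # bins with distinct noise bands plus sparse tall spikes
  for (seed in 1:10) {
    dat <- withr::with_seed(seed, {
      mz <- c(runif(20, 100, 200), runif(20, 200, 300), runif(20, 300, 400))
      ints <- c(runif(20, 5, 10), runif(20, 15, 20), runif(20, 25, 30))
      spike <- sample(60, 3)
      ints[spike] <- ints[spike] * 50
      list(mz = c(100, mz, 400), ints = c(7, ints, 27))
    })
    sp <- spectrum(dat$mz, dat$ints)
    bb <- make_bins(sp, 3)
    y <- per_bin_noise(sp, bb, xu_params(3, 1))
    for (i in 1:3) {
      o <- oracle_xu(peaks(sp)$intensity[bb$bin == i], 3, 1)
      expect_equal(as.numeric(y[i]), o$noise_level)
    }
  }

  # an interior bin with < 2 peaks takes the mean of its neighbors
  s3 <- spectrum(c(100, 110, 120, 250, 380, 390, 400),
                 c(1, 1, 1, 99, 3, 3, 3))
  b3 <- make_bins(s3, 3)
  y3 <- per_bin_noise(s3, b3)
  expect_equal(as.numeric(y3[2]), mean(c(y3[1], y3[3])))
  expect_equal(attr(y3, "imputed"), c(FALSE, TRUE, FALSE))
})

test_that("the design transform is centered with unit spacing", {
  expect_equal(transform_design(3), c(-1, 0, 1))
  expect_equal(transform_design(5), c(-2, -1, 0, 1, 2))
  expect_equal(transform_design(4), c(-1.5, -0.5, 0.5, 1.5))
})

test_that("gram polynomials reproduce the classical integer tables", {
  expect_equal(gram_poly(0, c(-3, 0, 2.5), 7), c(1, 1, 1))
  # n = 3 quadratic: lambda 3 gives (1, -2, 1)
  expect_equal(gram_poly(2, transform_design(3), 3), c(1, -2, 1))
  # n = 5 linear is the design itself
  expect_equal(gram_poly(1, transform_design(5), 5), c(-2, -1, 0, 1, 2))
  # n = 5 cubic, lambda 5/6: (-1, 2, 0, -2, 1)
  expect_equal(gram_poly(3, transform_design(5), 5), c(-1, 2, 0, -2, 1))
  # n = 7 quartic, lambda 7/12: (3, -7, 1, 6, 1, -7, 3)
  expect_equal(gram_poly(4, transform_design(7), 7), c(3, -7, 1, 6, 1, -7, 3))
  expect_error(gram_poly(6, 0, 11), "degree")
  expect_error(gram_poly(3, 0, 3), "design points")
})

test_that("gram polynomial value vectors are pairwise orthogonal on every
           reference design", {
  for (n in c(3, 5, 7, 9, 11)) {
    x <- transform_design(n)
    jmax <- min(5, n - 1)
    for (j in 0:(jmax - 1)) {
      for (l in (j + 1):jmax) {
        dot <- sum(gram_poly(j, x, n) * gram_poly(l, x, n))
        expect_lt(abs(dot), 1e-9)
      }
    }
  }
})

test_that("a constant input fits as a constant at any degree", {
  for (deg in 0:4) {
    f <- fit_noise_curve(rep(6.5, 5), deg)
    expect_equal(f$beta_hat[1], 6.5)
    if (deg > 0) expect_equal(f$beta_hat[-1], rep(0, deg), tolerance = 1e-12)
    expect_equal(f$fitted, rep(6.5, 5))
  }
})

test_that("maximal-degree fits interpolate the bin levels exactly", {
  for (seed in 1:20) {
    for (n in c(3, 5)) {
      y <- withr::with_seed(seed * 100 + n, runif(n, 1, 50))
      f <- fit_noise_curve(y, n - 1)
      expect_equal(f$fitted, y, tolerance = 1e-9)
      # evaluating at the design points recovers the levels too
      expect_equal(evaluate_noise_curve(f, seq_len(n)), y, tolerance = 1e-9)
    }
  }
})

test_that("orthogonal-basis least squares equals a direct monomial solve", {
  for (n in c(3, 5, 7, 9, 11)) {
    for (degree in 0:min(5, n - 1)) {
      for (seed in 1:20) {
        y <- withr::with_seed(seed * 1000 + n * 10 + degree, runif(n, 0, 100))
        f <- fit_noise_curve(y, degree)
        expect_equal(f$fitted, oracle_ls_fitted(y, degree), tolerance = 1e-9)
      }
    }
  }
})

test_that("residual sum of squares never increases with degree", {
  for (seed in 1:10) {
    y <- withr::with_seed(seed, runif(9, 0, 100))
    rss <- vapply(0:5, function(d) sum((y - fit_noise_curve(y, d)$fitted)^2),
                  numeric(1))
    expect_true(all(diff(rss) <= 1e-9))
  }
})

test_that("degree above n - 1 is rejected by both fitter and filter", {
  expect_error(fit_noise_curve(c(1, 2, 3), 3), "n_bins - 1")
  s <- random_spectrum(1)
  expect_error(filter_orthopoly(s, n_bins = 3, degree = 3), "n_bins - 1")
})

test_that("the evaluated curve is continuous, clamped to zero and to the
           fitted m/z range", {
  sp <- random_spectrum(4)
  bins <- make_bins(sp, 5)
  y <- as.numeric(per_bin_noise(sp, bins))
  f <- fit_noise_curve(y, 4, bins)
  grid <- seq(bins$mz_lo, bins$mz_hi, length.out = 2000)
  v <- evaluate_noise_curve(f, grid)
  expect_true(all(v >= 0))
  # no jumps: adjacent evaluations differ by O(grid step)
  expect_lt(max(abs(diff(v))), (max(v) - min(v)) / 50)
  # outside the range the boundary value is used, not extrapolation
  expect_equal(evaluate_noise_curve(f, bins$mz_lo - 500),
               evaluate_noise_curve(f, bins$mz_lo))
  expect_equal(evaluate_noise_curve(f, bins$mz_hi + 500),
               evaluate_noise_curve(f, bins$mz_hi))

  # a fit that dips negative between design points returns 0 there
  # (interpolating parabola through (0, 0, 10) is 5x^2 + 5x, negative on
  # (-1, 0))
  fneg <- fit_noise_curve(c(0, 0, 10), 2)
  expect_true(any(evaluate_noise_curve(fneg, seq(1, 3, by = 0.01)) == 0))
})
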