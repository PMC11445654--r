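test_that("conversion from HPLC signals follows the external-standard formula", {
  expect_equal(conversion_from_hplc(0, 5), 1)
  expect_equal(conversion_from_hplc(3, 3), 0.5)
  expect_equal(conversion_from_hplc(4, 1), 0.2)
  expect_error(conversion_from_hplc(0, 0), class = "nk_value_error")
  expect_error(conversion_from_hplc(-1, 2), class = "nk_value_error")
})

test_that("residence time is volume over total flow, in seconds", {
  expect_equal(residence_time(4, 1, 1), 120)
  expect_equal(residence_time(4, 2, 2), 60)  # doubling flow halves t
  expect_error(residence_time(4, 0, 0), class = "nk_value_error")
  expect_error(residence_time(0, 1, 1), class = "nk_value_error")
})

test_that("excess-reagent transform has its closed-form anchors", {
  expect_equal(transform_excess(0, 4.4), 0)
  expect_equal(transform_excess(0, 2), 0)
  # (M - x)/(M (1 - x)) = 2 exactly at x = M/(2M - 1)
  expect_equal(transform_excess(4.4 / 7.8, 4.4), log(2), tolerance = 1e-12)
  expect_error(transform_excess(0.5, 1), class = "nk_domain_error")
  expect_error(transform_excess(1, 4.4), class = "nk_domain_error")
})

test_that("transform is strictly increasing in conversion for every M > 1", {
  for (m in c(1.05, 1.5, 4.4, 14, 100)) {
    x <- seq(0, 0.999, length.out = 500)
    expect_true(all(diff(transform_excess(x, m)) > 0))
  }
})

test_that("transform and predicted conversion are mutual inverses", {
  set.seed(42)
  x <- runif(100, 0, 0.99)
  m <- runif(100, 1.01, 20)
  z <- transform_excess(x, m)
  # invert via predict_conversion with (M-1) c0 k t = z
  x_back <- predict_conversion(z, m, 1, 1 / (m - 1))
  expect_lt(max(abs(x_back - x) / pmax(x, 1e-12)), 1e-10)
})

test_that("r_squared matches a hand-computed spreadsheet case", {
  obs <- c(2, 4, 5, 8); fit <- c(1.9, 4.2, 5.1, 7.6)
  # SS_res = 0.22, SS_tot = 18.75 about mean 4.75
  expect_equal(r_squared(obs, fit), 1 - 0.22 / 18.75, tolerance = 1e-12)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), class = "nk_value_error")
  expect_error(r_squared(1, 1), class = "nk_value_error")
})

test_that("apparent k is recovered exactly from noise-free series", {
  s <- exact_series(k = 0.005, m = 4.4, c_io0 = 0.5)
  f <- fit_apparent_k(s)
  expect_equal(f$k, 0.005, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_lt(abs(f$intercept), 1e-12)
})

test_that("apparent-k recovery is exact across random rate/ratio/concentration", {
  set.seed(7)
  for (i in 1:50) {
    m <- runif(1, 1.2, 10)
    c0 <- runif(1, 0.1, 2)
    # pick k so the trajectory spans a usable conversion range (z_max <= 3)
    k <- runif(1, 0.2, 3) / ((m - 1) * c0 * 200)
    s <- generate_series(k, m, c0, seq(20, 200, by = 30))
    expect_equal(fit_apparent_k(s)$k, k, tolerance = 1e-10)
  }
})

test_that("apparent k estimate is invariant to consistent time-unit changes", {
  s_sec <- exact_series(k = 0.01)
  # same trajectory with times relabeled as minutes: k comes out 60x larger,
  # i.e. per-minute; converting back must agree
  s_min <- conversion_series(s_sec$times / 60, s_sec$conversions,
                             s_sec$temperature, s_sec$w_h2so4,
                             s_sec$c_io0, s_sec$c_hno3_0)
  expect_equal(fit_apparent_k(s_min)$k / 60, fit_apparent_k(s_sec)$k,
               tolerance = 1e-9)
})

test_that("degenerate apparent fits raise structured errors", {
  flat <- conversion_series(c(10, 20, 30), c(0, 0, 0), 303.15, 94, 0.5, 2.2)
  expect_error(fit_apparent_k(flat), class = "nk_fit_error")
  short <- conversion_series(c(10, 20), c(0.1, 0.2), 303.15, 94, 0.5, 2.2)
  expect_error(fit_apparent_k(short), class = "nk_fit_error")
})

test_that("noisy apparent fits stay within 10% of the generating constant", {
  k <- 0.005
  errs <- sapply(1:20, function(s) {
    ser <- generate_series(k, 4.4, 0.5, seq(30, 300, by = 45),
                           noise_sd = 0.01, seed = 100 + s)
    fit_apparent_k(ser)$k / k - 1
  })
  expect_lt(median(abs(errs)), 0.1)
})

test_that("order inference selects the generating orders, all four combos", {
  for (alpha in c(1, 2)) {
    for (beta in c(0, 1)) {
      d <- order_design(alpha, beta)
      orders <- infer_orders(d$pseudo, d$mixed)
      expect_equal(orders$alpha, alpha)
      expect_equal(orders$beta, beta)
      expect_false(orders$ambiguous)
    }
  }
})

test_that("first-order data beats the second-order candidate on R-squared", {
  d <- order_design(1, 1)
  orders <- infer_orders(d$pseudo, d$mixed)
  expect_gt(orders$r2_by_candidate[["alpha1"]],
            orders$r2_by_candidate[["alpha2"]])
  expect_equal(orders$r2_by_candidate[["alpha1"]], 1, tolerance = 1e-10)
})

test_that("order inference enforces its preconditions", {
  t_grid <- seq(15, 240, by = 25)
  good <- generate_order_series(1, 1, 0.004, 14, 0.35, t_grid, pseudo = TRUE)
  weak <- generate_order_series(1, 1, 0.004, 4.4, 0.5, t_grid, pseudo = TRUE)
  mixed <- generate_order_series(1, 1, 0.005, 4.4, 0.5, t_grid)
  expect_error(infer_orders(weak, mixed), class = "nk_precondition_error")
  short <- generate_order_series(1, 1, 0.004, 14, 0.35, c(30, 60, 90),
                                 pseudo = TRUE)
  expect_error(infer_orders(short, mixed), class = "nk_fit_error")
})
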