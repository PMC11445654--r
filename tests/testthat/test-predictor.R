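# a small fitted model bundle from the default synthetic truth
fitted_model <- local({
  truth <- default_truth()
  camp <- generate_campaign(truth, noise_sd = 0)
  rec <- recover_campaign(camp)
  nitration_model(rec$intrinsic, rec$arrhenius, rec$nitronium)
})

test_that("predicted conversion has its closed-form anchors and saturates safely", {
  expect_equal(predict_conversion(0.05, 4.4, 0.5, 0), 0)
  # z = ln 2 at M = 4.4 gives x = 4.4/7.8
  k <- log(2) / (3.4 * 0.5 * 100)
  expect_equal(predict_conversion(k, 4.4, 0.5, 100), 4.4 / 7.8,
               tolerance = 1e-12)
  # huge exponent: saturates at 1 from below without overflow
  x_big <- predict_conversion(1, 4.4, 0.5, 1e5)
  expect_true(is.finite(x_big) && x_big < 1)
  expect_equal(x_big, 1, tolerance = 1e-9)
  expect_error(predict_conversion(0.05, 1, 0.5, 10), class = "nk_domain_error")
})

test_that("predicted conversion is monotone in k, t, c0 and M", {
  base <- list(k = 0.003, m = 4.4, c0 = 0.5, t = 120)
  f <- function(k = base$k, m = base$m, c0 = base$c0, t = base$t) {
    predict_conversion(k, m, c0, t)
  }
  grid <- seq(1, 3, length.out = 20)
  expect_true(all(diff(sapply(grid, function(g) f(k = base$k * g))) > 0))
  expect_true(all(diff(sapply(grid, function(g) f(t = base$t * g))) > 0))
  expect_true(all(diff(sapply(grid, function(g) f(c0 = base$c0 * g))) > 0))
  expect_true(all(diff(sapply(grid, function(g) f(m = 1 + 3.4 * g))) > 0))
})

test_that("transform and prediction are exact inverses over random pairs", {
  set.seed(3)
  x <- runif(1000, 0, 0.999)
  m <- runif(1000, 1.01, 20)
  x_back <- predict_conversion(transform_excess(x, m), m, 1, 1 / (m - 1))
  expect_lt(max(abs(x_back - x) / pmax(x, 1e-12)), 1e-10)
})

test_that("predict_k recomposes the three terms arithmetically", {
  # lg k = lg_ratio + n * Mc + lg k0 on a synthetic single-line model
  truth <- default_truth()
  nitro <- truth_nitronium_model(truth)
  intr <- data.frame(temperature = c(303.15, 313.15), n = c(1, 1))
  arr <- list(ea = 0, ln_a = log(10) * 12)  # lg k0 = 12 at every T
  out <- predict_k(94, 308.15, intr, arr, nitro)
  mc <- mc_at_temperature(mc_at_298(mass_fraction_to_molarity(94)), 308.15)
  lgr <- lg_ratio(nitro, 94, 308.15)$lg_ratio
  expect_equal(out$lg_k, lgr + mc + 12, tolerance = 1e-12)
  # n = 0 drops the Mc term entirely
  intr0 <- data.frame(temperature = c(303.15, 313.15), n = c(0, 0))
  out0 <- predict_k(94, 308.15, intr0, arr, nitro)
  expect_equal(out0$lg_k, lgr + 12, tolerance = 1e-12)
})

test_that("full pipeline round-trip: generated k refit end-to-end to 1e-6", {
  truth <- default_truth()
  camp <- generate_campaign(truth, noise_sd = 0)
  rec <- recover_campaign(camp)
  pred <- predict_k(camp$truth_table$w_h2so4, camp$truth_table$temperature,
                    rec$intrinsic, rec$arrhenius, rec$nitronium)
  expect_lt(max(abs(pred$k / camp$truth_table$k_true - 1)), 1e-6)
})

test_that("response surface is monotone along residence time and flags state", {
  surf <- response_surface(fitted_model, time_s = seq(30, 270, by = 30),
                           temperature = celsius_to_kelvin(c(30, 35, 40)),
                           w = 94)
  expect_true(all(surf$flag == "interior"))
  for (tt in unique(surf$temperature)) {
    expect_true(all(diff(surf$conversion[surf$temperature == tt]) > 0))
  }
  # a 1x1 grid reduces to a single prediction
  one <- response_surface(fitted_model, 120, 308.15, 94)
  expect_equal(nrow(one), 1)
  # soft extrapolation flagged, hard violation refused
  soft <- response_surface(fitted_model, 600, 308.15, 94)
  expect_equal(soft$flag, "extrapolated")
  expect_error(response_surface(fitted_model, 1200, 308.15, 94),
               class = "nk_envelope_error")
})

test_that("validation reports absolute percentage-point discrepancies", {
  rep0 <- validate_predictions(c(0.9, 0.8), c(0.9, 0.8))
  expect_equal(rep0$per_point$abs_error_pct, c(0, 0))
  rep1 <- validate_predictions(c(0.9, 0.94), c(0.86, 0.94))
  expect_equal(rep1$max_abs_error_pct, 4, tolerance = 1e-12)
  expect_equal(rep1$worst_index, 1)
  # a 0.08 miss reads as 8 percentage points
  rep2 <- validate_predictions(0.95, 0.87)
  expect_equal(rep2$mean_abs_error_pct, 8, tolerance = 1e-12)
  expect_error(validate_predictions(c(0.1, 0.2), 0.1),
               class = "nk_value_error")
  # pairing is positional: shuffling changes the error surface
  repA <- validate_predictions(c(0.5, 0.9), c(0.52, 0.88))
  repB <- validate_predictions(c(0.5, 0.9), c(0.88, 0.52))
  expect_false(isTRUE(all.equal(repA$mean_abs_error_pct,
                                repB$mean_abs_error_pct)))
})

test_that("grid optimization finds the time-capped boundary optimum", {
  opt <- optimize_conditions(fitted_model,
                             temperature = celsius_to_kelvin(c(30, 35, 40)),
                             w = c(90, 92, 94, 96),
                             time_s = seq(60, 282, length.out = 6))
  # conversion increases with t, so the optimum sits on the time cap
  expect_equal(opt$best$time_s, 282)
  expect_true(opt$on_boundary[["time"]])
  expect_equal(opt$n_evaluated, 3 * 4 * 6)
})

test_that("grid optimization matches a fine-grid oracle within one step", {
  coarse_w <- seq(88, 98, by = 2)
  opt <- optimize_conditions(fitted_model, temperature = 303.15,
                             w = coarse_w, time_s = 240)
  fine <- optimize_conditions(fitted_model, temperature = 303.15,
                              w = seq(88, 98, by = 0.1), time_s = 240)
  expect_lte(abs(opt$best$w_h2so4 - fine$best$w_h2so4), 2)
  expect_lte(fine$best$conversion - opt$best$conversion, 0.02)
  # the optimum over w is interior here and the fine grid confirms it
  expect_gt(fine$best$w_h2so4, 88)
  expect_lt(fine$best$w_h2so4, 98)
})

test_that("optimization honors target-conversion objectives and tie-breaks", {
  opt <- optimize_conditions(fitted_model, temperature = 308.15, w = 92,
                             time_s = seq(60, 282, by = 30), target = 0.5)
  # cheapest time reaching the target, not the best conversion
  reach <- response_surface(fitted_model, seq(60, 282, by = 30), 308.15, 92)
  t_min <- min(reach$time_s[reach$conversion >= 0.5])
  expect_equal(opt$best$time_s, t_min)
  expect_error(
    optimize_conditions(fitted_model, temperature = 303.15, w = 92,
                        time_s = 60, target = 0.999),
    class = "nk_fit_error")
})

test_that("the study's operating point evaluates cleanly as an extrapolation", {
  # 94 wt %, 40 degC, M = 4.4, t = 12.36 min: beyond the soft time cap but
  # inside the hard envelope, so it must evaluate with a flag, not an error
  out <- response_surface(fitted_model, 12.36 * 60,
                          celsius_to_kelvin(40), 94)
  expect_equal(out$flag, "extrapolated")
  expect_true(out$conversion > 0 && out$conversion < 1)
})
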