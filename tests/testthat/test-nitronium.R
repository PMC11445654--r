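make_exact_table <- function(slope = 0.05, intercept = -6,
                             temps = c(296.15, 313.15, 333.15),
                             ws = seq(88, 98, by = 2)) {
  grid <- expand.grid(w_h2so4 = ws, temperature = temps)
  grid$lg_ratio <- slope * grid$w_h2so4 + intercept
  grid
}

test_that("stage 1 recovers exact per-temperature lines", {
  s1 <- fit_stage1(make_exact_table())
  expect_equal(nrow(s1), 3)
  expect_equal(s1$slope, rep(0.05, 3), tolerance = 1e-12)
  expect_equal(s1$intercept, rep(-6, 3), tolerance = 1e-10)
  expect_equal(s1$r2, rep(1, 3), tolerance = 1e-12)
})

test_that("degenerate nitronium tables are rejected", {
  tab <- make_exact_table()
  one_point <- tab[tab$temperature == 296.15 & tab$w_h2so4 == 88 |
                     tab$temperature > 300, ]
  expect_error(fit_stage1(one_point), class = "nk_schema_error")
  expect_error(fit_stage1(tab[tab$temperature == 296.15, ]),
               class = "nk_schema_error")
  expect_error(fit_stage2(fit_stage1(tab), numeric(0)),
               class = "nk_value_error")
})

test_that("stage 1 on noisy data recovers the slope within 3 standard errors", {
  set.seed(11)
  tab <- make_exact_table(ws = seq(86, 99, by = 1))
  tab$lg_ratio <- tab$lg_ratio + rnorm(nrow(tab), 0, 0.02)
  s1 <- fit_stage1(tab)
  # standard error of an OLS slope with sigma = 0.02 over the w design
  w <- seq(86, 99, by = 1)
  se <- 0.02 / sqrt(sum((w - mean(w))^2))
  expect_true(all(abs(s1$slope - 0.05) < 3 * se))
})

test_that("two-stage fit recovers an exact 1/T-affine structure", {
  truth <- default_truth()
  tab <- generate_nitronium_table(truth, w_points = seq(88, 98, by = 1),
                                  t_points = c(290, 310, 330, 350))
  model <- fit_nitronium(tab)
  # stage-2 lines must reproduce a(w) (slope in 1/T) and b(w) exactly
  cf <- truth$nitronium_coefs
  expect_equal(model$stage2$slope,
               cf[["a0"]] + cf[["a1"]] * model$stage2$w_h2so4,
               tolerance = 1e-9)
  expect_equal(model$stage2$intercept,
               cf[["b0"]] + cf[["b1"]] * model$stage2$w_h2so4,
               tolerance = 1e-9)
  # evaluation reproduces the generating surface, including between nodes
  q <- expand.grid(w = c(88, 91.37, 95.5, 98), temperature = c(295, 311.2, 349))
  got <- lg_ratio(model, q$w, q$temperature)
  expect_equal(got$lg_ratio, truth_lg_ratio(truth, q$w, q$temperature),
               tolerance = 1e-9)
  expect_false(any(got$extrapolated))
})

test_that("stage 2 collapses to a constant when lines are T-independent", {
  tab <- make_exact_table(temps = c(300, 320, 340))
  s2 <- fit_stage2(fit_stage1(tab), w_grid = c(90, 94))
  expect_equal(s2$slope, c(0, 0), tolerance = 1e-8)
  expect_equal(s2$intercept, 0.05 * c(90, 94) - 6, tolerance = 1e-9)
})

test_that("extrapolation outside the calibrated ranges is flagged, not hidden", {
  model <- truth_nitronium_model()
  out <- lg_ratio(model, c(94, 102, 94), c(270, 305, 305))
  expect_equal(out$extrapolated, c(TRUE, TRUE, FALSE))
  s2 <- fit_stage2(model$stage1, w_grid = c(94, 105))
  expect_equal(s2$extrapolated, c(FALSE, TRUE))
  expect_error(lg_ratio(list(), 94, 305), class = "nk_state_error")
})

test_that("monotone input tables give lg-ratio increasing in acid strength", {
  model <- truth_nitronium_model()
  for (tt in c(300, 310, 320)) {
    vals <- lg_ratio(model, seq(88, 98, by = 0.5), tt)$lg_ratio
    expect_true(all(diff(vals) > 0))
  }
})

test_that("interpolated lg-ratio is affine between grid nodes (collinearity)", {
  model <- truth_nitronium_model()
  w3 <- c(90.2, 90.5, 90.8)  # inside one grid interval
  v <- lg_ratio(model, w3, 305)$lg_ratio
  expect_equal(v[2], (v[1] + v[3]) / 2, tolerance = 1e-10)
})

test_that("nitronium model JSON serialization round-trips", {
  model <- truth_nitronium_model()
  path <- withr::local_tempfile(fileext = ".json")
  nitronium_model_to_json(model, path)
  back <- nitronium_model_from_json(path)
  q <- lg_ratio(back, 93.3, 307)
  expect_equal(q$lg_ratio, lg_ratio(model, 93.3, 307)$lg_ratio,
               tolerance = 1e-12)
})
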