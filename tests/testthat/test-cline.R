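test_that("hill_predict has the midpoint, limit and closed-form properties", {
  pars <- c(C = 0.2, D = 0.8, B = -8, E = 70)
  expect_equal(hill_predict(pars, 70), 0.5)             # x = E -> (C + D) / 2
  # steepness limit: a step function around E
  steep <- c(C = 0, D = 1, B = -500, E = 70)
  expect_equal(hill_predict(steep, 60), 0, tolerance = 1e-10)
  expect_equal(hill_predict(steep, 80), 1, tolerance = 1e-10)
  # analytic point: 1 / (1 + exp(-5 log(x/70))) = 0.9 at x = 70 * 9^(1/5)
  expect_equal(hill_predict(c(C = 0, D = 1, B = -5, E = 70), 70 * 9^(1 / 5)), 0.9)
  expect_error(hill_predict(pars, 0), class = "hzc_domain_error")
  expect_error(hill_predict(c(C = 0, D = 1, B = -5, E = -1), 10),
               class = "hzc_domain_error")
})

test_that("noiseless four-parameter data are recovered to machine precision", {
  for (pars in list(c(C = 0.2, D = 0.8, B = -8, E = 70),
                    c(C = -1.5, D = 1.5, B = -4, E = 55),
                    c(C = 0.1, D = 0.9, B = 12, E = 90))) {
    x <- seq(2, 135, length.out = 30)
    d <- tibble::tibble(distance_km = x, value = hill_predict(pars, x + 0.1))
    f <- fit_hill(d, value)
    canonical <- if (pars[["C"]] > pars[["D"]])
      c(C = unname(pars[["D"]]), D = unname(pars[["C"]]),
        B = -unname(pars[["B"]]), E = unname(pars[["E"]])) else pars
    expect_lt(max(abs(f$params - canonical)), 1e-6)
    expect_true(f$converged)
    expect_equal(f$center_km, unname(pars[["E"]]) - 0.1, tolerance = 1e-6)
  }
})

test_that("degenerate cline inputs raise typed errors", {
  x <- seq(1, 100, length.out = 20)
  expect_error(fit_hill(tibble::tibble(distance_km = x, value = 0.5), value),
               class = "hzc_non_clinal_error")
  expect_error(fit_hill(tibble::tibble(distance_km = x[1:5], value = rnorm(5)),
                        value),
               class = "hzc_insufficient_data_error")
})

test_that("optimiser SSE is at least as good as a dense profiled grid search", {
  set.seed(51)
  for (i in 1:4) {
    d <- simulate_cline_data(40, center = runif(1, 40, 100),
                             width_km = runif(1, 15, 50),
                             noise_sd = 0.05, seed = 500 + i)
    f <- fit_hill(d, value)
    oracle <- grid_search_sse(d$distance_km, d$value)
    expect_lte(f$sse, oracle + 1e-6)
  }
})

test_that("effective doses match the closed form and numeric inversion", {
  pars <- c(C = 0, D = 1, B = -5, E = 70)
  d <- tibble::tibble(distance_km = seq(2, 135, length.out = 30))
  d$value <- hill_predict(pars, d$distance_km + 0.1)
  f <- fit_hill(d, value)
  # closed-form anchor points (offset scale E = 70 -> original scale -0.1)
  expect_equal(effective_dose(f, 50), 70 - 0.1, tolerance = 1e-6)
  expect_equal(effective_dose(f, 90), 70 * 9^(1 / 5) - 0.1, tolerance = 1e-5)
  expect_equal(effective_dose(f, 10), 70 * 9^(-1 / 5) - 0.1, tolerance = 1e-5)
  expect_equal(cline_width(f), 70 * (9^(1 / 5) - 9^(-1 / 5)), tolerance = 1e-5)
  # numeric-inversion oracle across the ED range
  for (p in c(5, 10, 25, 50, 75, 90, 95)) {
    expect_equal(effective_dose(f, p), ed_numeric(f$params, p), tolerance = 1e-8)
  }
  ed <- effective_dose(f, c(10, 50, 90))
  expect_true(ed[1] < ed[2] && ed[2] < ed[3])
  expect_error(effective_dose(f, 0), class = "hzc_domain_error")
})

test_that("width shrinks monotonically with steepness and vanishes in the limit", {
  widths <- vapply(c(0.5, 1, 2, 5, 10, 20, 50), function(b) {
    70 * (9^(1 / b) - 9^(-1 / b))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  f <- list(params = c(C = 0, D = 1, B = -1e8, E = 70), x_offset = 0.1)
  class(f) <- "hzc_cline"
  expect_lt(cline_width(f), 1e-5)
})

test_that("fits obey scale equivariance and response-affine invariance", {
  pars <- c(C = 0.2, D = 0.8, B = -6, E = 60)
  x <- seq(2, 135, length.out = 40)
  d <- tibble::tibble(distance_km = x, value = hill_predict(pars, x + 0.1))
  f <- fit_hill(d, value)

  # X -> kX: center and width scale by k; C, D, B unchanged.
  # (x_offset = 0 on exact grid data keeps the log-scale model exact.)
  k <- 2.5
  d0 <- tibble::tibble(distance_km = x, value = hill_predict(pars, x))
  f0 <- fit_hill(d0, value, x_offset = 0, domain_end_km = 140)
  dk <- tibble::tibble(distance_km = k * x, value = d0$value)
  fk <- fit_hill(dk, value, x_offset = 0, domain_end_km = 140 * k)
  expect_equal(fk$params[["E"]], k * f0$params[["E"]], tolerance = 1e-4)
  expect_equal(fk$params[["B"]], f0$params[["B"]], tolerance = 1e-4)
  expect_equal(cline_width(fk), k * cline_width(f0), tolerance = 1e-4)

  # Y -> aY + b: C, D map affinely; B, E, center, width unchanged
  da <- dplyr::mutate(d, value = 3 * value - 1)
  fa <- fit_hill(da, value)
  expect_equal(fa$params[["B"]], f$params[["B"]], tolerance = 1e-5)
  expect_equal(fa$params[["E"]], f$params[["E"]], tolerance = 1e-5)
  expect_equal(fa$params[["C"]], 3 * f$params[["C"]] - 1, tolerance = 1e-5)
  expect_equal(fa$params[["D"]], 3 * f$params[["D"]] - 1, tolerance = 1e-5)
  expect_equal(cline_width(fa), cline_width(f), tolerance = 1e-6)
})

test_that("reflecting the transect preserves width and reverses direction", {
  set.seed(52)
  d <- simulate_cline_data(60, center = 70, width_km = 30, noise_sd = 0.03,
                           seed = 53)
  f <- fit_hill(d, value)
  dr <- dplyr::mutate(d, distance_km = 136 - distance_km)
  fr <- fit_hill(dr, value)
  expect_lt(abs(cline_width(fr) - cline_width(f)) / cline_width(f), 0.1)
  expect_lt(f$params[["B"]], 0)  # rising toward inland
  expect_gt(fr$params[["B"]], 0) # falling after reflection
})

test_that("tidy, glance and autoplot expose the fit", {
  d <- simulate_cline_data(40, 70, 30, noise_sd = 0.05, seed = 54)
  f <- fit_hill(d, value, trait = "PC1", period = "P2010")
  td <- tidy(f)
  expect_equal(td$term, c("C", "D", "B", "E"))
  g <- glance(f)
  expect_equal(g$trait, "PC1")
  expect_true(g$converged)
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
  js <- jsonlite::fromJSON(cline_to_json(f))
  expect_equal(js$center_km, f$center_km)
})
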