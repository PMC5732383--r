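test_that("complete-case filtering reports per-column drops and guards minimum n", {
  d <- toy_specimens()[rep(1:3, length.out = 10), ]
  d$id <- sprintf("s%02d", 1:10)
  d$tail_mm[c(2, 7)] <- NA
  out <- complete_case_filter(d)
  expect_equal(nrow(out), 8)
  expect_equal(unname(attr(out, "dropped_by_column")["tail_mm"]), 2)

  expect_equal(nrow(complete_case_filter(toy_specimens())), 3)
  two <- toy_specimens()[1:2, ]
  expect_error(complete_case_filter(two), class = "hzc_insufficient_data_error")
})

test_that("PCA matches the eigen-decomposition oracle and fixes PC1 sign", {
  set.seed(31)
  n <- 400
  shared <- rnorm(n)
  d <- tibble::tibble(
    id = as.character(1:n), sex = "male",
    wing_mm = 70 + 2 * shared + rnorm(n, 0, 0.01),
    tail_mm = 65 + 1.5 * shared + rnorm(n, 0, 0.01),
    culmen_mm = rnorm(n, 19, 0.5), bill_depth_mm = rnorm(n, 8, 0.3),
    bill_width_mm = rnorm(n, 7.5, 0.3), tarsus_mm = rnorm(n, 19, 0.5))
  p <- compute_pca(d)
  # oracle: eigenvalues of the correlation matrix
  ev <- eigen(stats::cor(as.matrix(d[, 3:8])), symmetric = TRUE)$values
  expect_equal(p$variance_prop, ev / sum(ev), tolerance = 1e-10)
  # the two correlated columns define PC1, which carries ~2/6 of the variance
  expect_gt(p$variance_prop[1], 0.3)
  expect_gte(p$loadings["wing_mm", 1], 0)
  # scores correlate with the shared axis
  expect_gt(stats::cor(p$scores$PC1, shared), 0.99)
})

test_that("independent characters split variance evenly under the null", {
  set.seed(32)
  n <- 5000
  d <- tibble::tibble(id = as.character(1:n), sex = "male")
  for (cc in c("wing_mm", "culmen_mm", "bill_depth_mm", "bill_width_mm",
               "tail_mm", "tarsus_mm")) d[[cc]] <- rnorm(n) + 50
  p <- compute_pca(d)
  expect_true(all(abs(p$variance_prop - 1 / 6) < 0.02))
})

test_that("PCA is invariant to row duplication and column reordering", {
  set.seed(41)
  n <- 40
  d <- tibble::tibble(
    id = sprintf("s%02d", 1:n), sex = "male",
    wing_mm = 70 + rnorm(n), tail_mm = 65 + rnorm(n),
    culmen_mm = 19 + rnorm(n, 0, 0.5), bill_depth_mm = 8 + rnorm(n, 0, 0.3),
    bill_width_mm = 7.5 + rnorm(n, 0, 0.3), tarsus_mm = 19 + rnorm(n, 0, 0.5))
  p1 <- compute_pca(d)
  p2 <- compute_pca(dplyr::bind_rows(d, dplyr::mutate(d, id = paste0(id, "b"))))
  expect_equal(p1$variance_prop, p2$variance_prop, tolerance = 1e-10)
  expect_equal(abs(p1$loadings), abs(p2$loadings), tolerance = 1e-8)

  cols <- c("tail_mm", "wing_mm", "tarsus_mm", "culmen_mm",
            "bill_width_mm", "bill_depth_mm")
  p3 <- compute_pca(d, columns = cols)
  expect_equal(abs(p3$loadings[rownames(p1$loadings), 1]),
               abs(p1$loadings[, 1]), tolerance = 1e-8)

  dz <- d; dz$tarsus_mm <- 19
  expect_error(compute_pca(dz), "tarsus", class = "hzc_degenerate_data_error")
})

test_that("segment metrics reproduce hand-evaluated single-window spectra", {
  # flat spectrum: brightness only, no spectral contrast
  flat <- segment_metrics(400:700, rep(30, 301))
  expect_equal(flat$brightness, 30)
  expect_equal(flat$chroma, 0, tolerance = 1e-12)
  expect_true(flat$hue_degenerate)
  expect_equal(flat$hue, 0)

  # all reflectance in the longest-wave segment: LM = 1, hue 0
  s <- window_spectrum(626, 700)
  red <- segment_metrics(s$wavelength_nm, s$reflectance)
  expect_equal(unlist(red[, c("Q1", "Q2", "Q3", "Q4")]), c(Q1 = 0, Q2 = 0, Q3 = 0, Q4 = 1))
  expect_equal(red$LM, 1); expect_equal(red$MS, 0)
  expect_equal(red$chroma, 1); expect_equal(red$hue, 0)

  # all reflectance in the second segment: LM = -1, hue = pi
  s <- window_spectrum(476, 549)
  green <- segment_metrics(s$wavelength_nm, s$reflectance)
  expect_equal(green$LM, -1); expect_equal(green$MS, 0)
  expect_equal(green$chroma, 1); expect_equal(green$hue, pi)

  # zero spectrum: explicit missing metrics, brightness 0
  zero <- segment_metrics(400:700, rep(0, 301))
  expect_equal(zero$brightness, 0)
  expect_true(is.na(zero$chroma))
})

test_that("chroma is scale-invariant, brightness linear, Q sums to one", {
  set.seed(33)
  for (i in 1:25) {
    r <- runif(301, 0, 60)
    m1 <- segment_metrics(400:700, r)
    m2 <- segment_metrics(400:700, 3.7 * r)
    expect_equal(m2$chroma, m1$chroma, tolerance = 1e-12)
    expect_equal(m2$hue, m1$hue, tolerance = 1e-12)
    expect_equal(m2$brightness, 3.7 * m1$brightness, tolerance = 1e-10)
    expect_equal(m1$Q1 + m1$Q2 + m1$Q3 + m1$Q4, 1, tolerance = 1e-12)
    expect_lte(m1$chroma, 1)
  }
})

test_that("template mixtures give chroma and hue monotone in the mixing weight", {
  tpl <- spectral_templates()
  t <- seq(0, 1, by = 0.05)
  met <- purrr::map_dfr(t, function(tt) {
    segment_metrics(tpl$wavelength_nm, tt * tpl$red + (1 - tt) * tpl$yellow)
  })
  expect_true(all(diff(met$chroma) > 0))
  expect_true(all(diff(met$hue) < 0))  # hue rotates from yellowish toward red
})

test_that("spectrum validation rejects bad inputs", {
  expect_error(segment_metrics(c(400, 700), c(-1, 5)), class = "hzc_spectrum_error")
  expect_error(segment_metrics(seq(450, 700, 5), rep(1, 51)),
               class = "hzc_spectrum_error")  # does not cover 400-700
  expect_error(segment_metrics(c(400, 500, 700), c(1, 1, 1)),
               class = "hzc_spectrum_error")  # empty 25-nm bins
})

test_that("attach_phenotypes joins positions, scores and colours by id", {
  spec <- toy_specimens()
  m <- fit_transect(spec)
  pos <- project_onto_transect(m, spec)
  d <- spec[rep(1:3, 4), ]; d$id <- c(spec$id, sprintf("x%d", 1:9))
  pca <- compute_pca(dplyr::mutate(d, sex = "male"))
  colors <- tibble::tibble(spectrum_id = c("s1", "s2", "ghost"),
                           brightness = 1:3, chroma = c(0.5, 0.6, 0.7),
                           hue = c(0, 0.1, 0.2))
  expect_warning(expect_warning(
    tab <- attach_phenotypes(pos, spec, pca = pca, colors = colors),
    "without positions"), "without specimens")
  expect_equal(nrow(tab), 3)
  expect_true(is.na(tab$chroma[tab$id == "s3"]))  # specimen without spectrum
  expect_false(any(tab$id == "ghost"))
})
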