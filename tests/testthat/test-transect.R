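test_that("specimen tables load, validate, and reject bad rows with reasons", {
  path <- write_toy_csv(toy_specimens())
  recs <- read_specimen_table(path)
  expect_equal(nrow(recs), 3)
  expect_equal(nrow(attr(recs, "rejected")), 0)

  bad <- toy_specimens()
  bad$latitude[2] <- 91.0
  expect_warning(recs <- validate_specimens(bad), "rejected")
  expect_equal(nrow(recs), 2)
  rej <- attr(recs, "rejected")
  expect_equal(rej$id, "s2")
  expect_match(rej$reason, "latitude")

  # optional morph columns absent -> all-missing morph
  slim <- toy_specimens()[, c("id", "latitude", "longitude", "year")]
  recs <- validate_specimens(slim)
  expect_true(all(is.na(recs$wing_mm)))
  expect_equal(nrow(recs), 3)

  # schema errors
  expect_error(validate_specimens(slim[, -1]), class = "hzc_schema_error")
  dup <- toy_specimens(); dup$id[2] <- "s1"
  expect_error(validate_specimens(dup), class = "hzc_duplicate_id_error")
  # schema mapping renames columns
  renamed <- dplyr::rename(slim, lat = latitude)
  expect_equal(nrow(validate_specimens(renamed, schema = c(latitude = "lat"))), 3)
})

test_that("transect regression recovers an exactly collinear line", {
  lon <- seq(-77.2, -76.6, length.out = 12)
  lat <- 2.1 - 0.45 * lon
  recs <- tibble::tibble(id = as.character(seq_along(lon)),
                         latitude = lat, longitude = lon)
  m <- fit_transect(recs)
  expect_equal(m$slope, -0.45, tolerance = 1e-12)
  expect_equal(m$intercept, 2.1, tolerance = 1e-10)
})

test_that("planar projected distances agree with the haversine oracle", {
  skip_if_not_installed("geosphere")
  # two points on a line, roughly 100 km apart
  lat1 <- 3.9; lon1 <- -77.1
  slope <- -0.5
  # move along the line by ~100 km in planar terms
  kx <- 111.32 * cos(3.85 * pi / 180); ky <- 111.32
  u <- c(kx, slope * ky); u <- u / sqrt(sum(u^2))
  dlon <- 100 * u[1] / kx; dlat <- 100 * u[2] / ky
  recs <- tibble::tibble(id = c("a", "b"),
                         latitude = c(lat1, lat1 + dlat),
                         longitude = c(lon1, lon1 + dlon))
  m <- fit_transect(recs)
  pos <- project_onto_transect(m, recs)
  planar <- abs(diff(pos$distance_km))
  true_km <- haversine_km(lat1, lon1, lat1 + dlat, lon1 + dlon)
  expect_lt(abs(planar - true_km) / true_km, 0.005)
})

test_that("projection residuals are orthogonal and projection is idempotent", {
  set.seed(11)
  recs <- tibble::tibble(id = as.character(1:10),
                         latitude = 3.7 + rnorm(10, 0, 0.1),
                         longitude = -77 + runif(10, 0, 0.6))
  m <- fit_transect(recs)
  pos <- project_onto_transect(m, recs)
  # reconstruct planar residual vectors and check dot products with direction
  px <- m$km_per_deg_lon * recs$longitude
  py <- m$km_per_deg_lat * recs$latitude
  foot_x <- m$origin[1] + pos$distance_km * m$direction[1]
  foot_y <- m$origin[2] + pos$distance_km * m$direction[2]
  dots <- (px - foot_x) * m$direction[1] + (py - foot_y) * m$direction[2]
  expect_true(all(abs(dots) < 1e-10))
  expect_true(all(pos$distance_km >= -1e-12))

  # idempotence: projecting the foot points returns identical distances
  foot_recs <- tibble::tibble(id = recs$id,
                              latitude = foot_y / m$km_per_deg_lat,
                              longitude = foot_x / m$km_per_deg_lon)
  pos2 <- project_onto_transect(m, foot_recs)
  expect_true(all(abs(pos2$distance_km - pos$distance_km) < 1e-9))
  expect_true(all(abs(pos2$offset_km) < 1e-9))
})

test_that("distances are stable under small whole-map translations", {
  set.seed(21)
  recs <- tibble::tibble(id = as.character(1:15),
                         latitude = 3.7 + rnorm(15, 0, 0.15),
                         longitude = -77 + runif(15, 0, 0.8))
  m1 <- fit_transect(recs)
  d1 <- project_onto_transect(m1, recs)$distance_km
  shifted <- dplyr::mutate(recs, latitude = latitude + 0.4,
                           longitude = longitude + 0.4)
  m2 <- fit_transect(shifted)
  d2 <- project_onto_transect(m2, shifted)$distance_km
  expect_true(all(abs(d1 - d2) / pmax(d1, 1) < 0.001))
})

test_that("degenerate geometries error rather than fitting nonsense", {
  same <- tibble::tibble(id = c("a", "b"), latitude = c(3, 3),
                         longitude = c(-77, -77))
  expect_error(fit_transect(same), class = "hzc_degenerate_geometry_error")
  vertical <- tibble::tibble(id = as.character(1:5), latitude = seq(3, 4, length.out = 5),
                             longitude = rep(-77, 5))
  expect_error(fit_transect(vertical), class = "hzc_degenerate_geometry_error")
})

test_that("sector assignment uses half-open intervals that partition the domain", {
  expect_equal(assign_sector(30), 1L)
  expect_equal(assign_sector(76.7), 2L)   # the modern PC1 center falls in sector 2
  expect_equal(assign_sector(45), 2L)     # boundary goes to the upper sector
  expect_equal(assign_sector(90), 3L)
  expect_equal(assign_sector(135), 3L)    # domain end is closed
  expect_true(is.na(assign_sector(140)))
  expect_error(assign_sector(-1), class = "hzc_domain_error")
  # partition: every in-domain distance maps to exactly one sector
  d <- seq(0, 135, by = 0.25)
  expect_true(all(assign_sector(d) %in% 1:3))
})

test_that("period windows follow the collection gaps", {
  expect_equal(assign_period(c(1894, 1911, 1956, 1986, 2007, 2010)),
               c("P1911", "P1911", "P1956", "P1956", "P2010", "P2010"))
  expect_equal(assign_period(c(1930, 1990, 2011, NA)),
               rep("unassigned", 4))
})

test_that("locality clustering equals connected components of the radius graph", {
  # pairwise cases
  two <- tibble::tibble(id = c("a", "b"), distance_km = c(10, 10.5), offset_km = 0)
  expect_equal(length(unique(cluster_localities(two))), 1)
  far <- tibble::tibble(id = c("a", "b"), distance_km = c(10, 15), offset_km = 0)
  expect_equal(length(unique(cluster_localities(far))), 2)
  # chaining: A-B 0.9, B-C 0.9, A-C 1.8 -> one locality under single linkage
  chain <- tibble::tibble(id = c("a", "b", "c"),
                          distance_km = c(0, 0.9, 1.8), offset_km = 0)
  expect_equal(length(unique(cluster_localities(chain))), 1)

  # brute-force oracle on random point sets
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    pts <- tibble::tibble(id = sprintf("x%02d", 1:n),
                          distance_km = runif(n, 0, 12),
                          offset_km = runif(n, -1, 1))
    got <- cluster_localities(pts, radius_km = 1)
    want <- components_oracle(cbind(pts$distance_km, pts$offset_km), 1)
    # same partition (ids may differ)
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }

  # id stability under row order
  perm <- sample(nrow(chain))
  expect_equal(cluster_localities(chain)[perm], cluster_localities(chain[perm, ]))
})

test_that("FASTA reading normalises case and enforces unique clean headers", {
  dir <- withr::local_tempdir()
  fp <- file.path(dir, "toy.fasta")
  writeLines(c(">a", "acgtn-", ">b desc", "ACGTAC", ">c", "ACGTAC"), fp)
  seqs <- read_fasta(fp)
  expect_equal(seqs$id, c("a", "b", "c"))
  expect_equal(seqs$sequence[1], "ACGTN-")

  writeLines(c(">a", "ACGT", ">a", "ACGA"), fp)
  expect_error(read_fasta(fp), class = "hzc_duplicate_id_error")
  writeLines(c(">a", "ACGX"), fp)
  expect_error(read_fasta(fp), "position 4", class = "hzc_sequence_error")
})
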