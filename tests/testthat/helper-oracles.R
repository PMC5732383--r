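# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately brute-force / closed-form and shares no
# code path with the package implementation it checks.

suppressWarnings(suppressMessages(library(dplyr)))

# ---- fixtures --------------------------------------------------------------

toy_specimens <- function() {
  tibble::tibble(
    id = c("s1", "s2", "s3"),
    latitude = c(3.9, 3.7, 3.5),
    longitude = c(-77.1, -76.9, -76.7),
    year = c(1900L, 1960L, 2010L),
    sex = c("male", "male", "female"),
    wing_mm = c(70, 72, 74), culmen_mm = c(19, 19.5, 20),
    bill_depth_mm = c(8, 8.2, 8.4), bill_width_mm = c(7.4, 7.5, 7.6),
    tail_mm = c(66, 68, 70), tarsus_mm = c(19, 19.4, 19.8),
    spectrum_id = c("s1", "s2", "s3"), sequence_id = c("s1", "s2", "s3"))
}

write_toy_csv <- function(data, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "specimens.csv")
  readr::write_csv(data, path)
  path
}

# a spectrum supported on an exact wavelength window, sampled every nm
window_spectrum <- function(from, to, level = 50) {
  wl <- 400:700
  list(wavelength_nm = wl, reflectance = ifelse(wl >= from & wl <= to, level, 0))
}

# ---- geometry oracles ------------------------------------------------------

haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(c(lon1, lat1), c(lon2, lat2)) / 1000
}

# connected components of the <= radius graph, by BFS (locality oracle)
components_oracle <- function(pts, radius) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  adj <- d <= radius
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1
    queue <- i
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# ---- cline oracles ---------------------------------------------------------

# dense profiled grid search over (B, E); C and D are solved exactly for each
# grid point, which dominates any finite grid on the linear parameters
grid_search_sse <- function(x, y, x_offset = 0.1,
                            B_grid = c(-rev(seq(0.1, 30, by = 0.1)),
                                       seq(0.1, 30, by = 0.1)),
                            E_grid = seq(1, 140, by = 0.5)) {
  lx <- log(x + x_offset)
  yy <- sum(y^2)
  best <- Inf
  for (B in B_grid) {
    f <- 1 / (1 + exp(B * outer(lx, log(E_grid), `-`)))
    g <- 1 - f
    a11 <- colSums(g * g); a12 <- colSums(f * g); a22 <- colSums(f * f)
    b1 <- colSums(y * g); b2 <- colSums(y * f)
    det <- a11 * a22 - a12^2
    ok <- det > 1e-10
    C <- (b1 * a22 - b2 * a12) / det
    D <- (a11 * b2 - a12 * b1) / det
    sse <- yy - (C * b1 + D * b2)
    m <- suppressWarnings(min(sse[ok]))
    if (is.finite(m) && m < best) best <- m
  }
  best
}

# numeric inversion of the fitted curve: x where p% of |D - C| is traversed
ed_numeric <- function(params, p, x_offset = 0.1) {
  C <- params[["C"]]; D <- params[["D"]]; B <- params[["B"]]; E <- params[["E"]]
  traversed <- function(x) {
    pred <- C + (D - C) / (1 + exp(B * (log(x) - log(E))))
    from <- if (B < 0) C else D
    abs(pred - from) / abs(D - C) - p / 100
  }
  stats::uniroot(traversed, lower = E * 1e-6, upper = E * 1e6,
                 tol = 1e-12)$root - x_offset
}

# standard symmetric tanh cline for allele frequencies
tanh_cline <- function(x, center, width) {
  (1 + tanh(2 * (x - center) / width)) / 2
}

# ---- AMOVA oracle ----------------------------------------------------------

# brute-force nested decomposition from dummy-encoded sequences: encoding each
# site state as an indicator vector scaled by 1/sqrt(2) makes squared
# Euclidean distance equal the nucleotide difference count, so sums of squares
# can be computed from centroid deviations instead of pairwise distances
amova_oracle <- function(sequences, sectors, localities) {
  m <- do.call(rbind, strsplit(toupper(sequences), ""))
  states <- c("A", "C", "G", "T")
  enc <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) {
    sapply(states, function(s) (m[, j] == s) / sqrt(2))
  }))
  ss_dev <- function(rows) {
    if (length(rows) < 2) return(0)
    ctr <- colMeans(enc[rows, , drop = FALSE])
    sum(sweep(enc[rows, , drop = FALSE], 2, ctr)^2)
  }
  N <- nrow(enc)
  pop <- paste(sectors, localities)
  ss_total <- ss_dev(seq_len(N))
  ss_wp <- sum(vapply(unique(pop), function(p) ss_dev(which(pop == p)), 1))
  ss_wg <- sum(vapply(unique(sectors), function(g) ss_dev(which(sectors == g)), 1))
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_total - ss_wg

  pops <- unique(pop)
  G <- length(unique(sectors)); P <- length(pops)
  n_p <- as.numeric(table(pop)[pops])
  grp <- sectors[match(pops, pop)]
  sum_g <- vapply(unique(sectors), function(g)
    sum(n_p[grp == g]^2) / sum(n_p[grp == g]), 1)
  n_c <- (N - sum(sum_g)) / (P - G)
  n1 <- (sum(sum_g) - sum(n_p^2) / N) / (G - 1)
  n2 <- (N - sum(table(sectors)^2) / N) / (G - 1)

  sc <- ss_wp / (N - P)
  sb <- (ss_ap / (P - G) - sc) / n_c
  sa <- (ss_ag / (G - 1) - sc - n1 * sb) / n2
  list(ssd = c(total = ss_total, among_sectors = ss_ag,
               among_localities_within = ss_ap, within_localities = ss_wp),
       sigma = c(a = sa, b = sb, c = sc),
       F_CT = sa / (sa + sb + sc), F_SC = sb / (sb + sc),
       F_ST = (sa + sb) / (sa + sb + sc))
}

# small polymorphic fixture: 2 sectors x 2 localities x 3 individuals
amova_fixture <- function() {
  seqs <- c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAAAT",
            "AAAAAAATAT", "AAAAAAATAA", "AAAAAAATAT",
            "TTAAAAAAAA", "TTAAAAAAAT", "TTAAAAAAAA",
            "TTTTAAAAAA", "TTTTAAAAAT", "TTTTAAAAAA")
  list(sequences = stats::setNames(seqs, sprintf("i%02d", seq_along(seqs))),
       sectors = rep(c("S1", "S2"), each = 6),
       localities = rep(c("L1", "L2", "L3", "L4"), each = 3))
}
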