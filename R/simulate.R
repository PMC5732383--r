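# ---- synthetic hybrid-zone generator -------------------------------------
# Emulates the study's statistical structure with known ground truth: three
# collection periods sampled unevenly along a ~135 km transect, sigmoid trait
# clines whose center shifts east and width narrows over time, yellow-to-red
# rump spectra driven by transect position, and short haplotype alignments
# with sector-level frequency structure that differs between periods.

#' Solve the Hill steepness for a target cline width
#'
#' Inverts `width = E * (9^(1/|B|) - 9^(-1/|B|))` for `|B|` at fixed `E`.
#'
#' @param width_km Target ED90 - ED10 width (> 0).
#' @param E Inflection position (> 0), on the same scale as the width.
#' @param sign Sign of the returned coefficient (default -1: a curve rising
#'   from coast to inland).
#' @return Steepness coefficient `B`.
#' @export
steepness_for_width <- function(width_km, E, sign = -1) {
  stopifnot(width_km > 0, E > 0)
  k <- width_km / E
  u <- (k + sqrt(k^2 + 4)) / 2          # u = 9^(1/|B|)
  sign * log(9) / log(u)
}

#' Simulation configuration with study-scale defaults
#'
#' Defaults mirror the reported magnitudes of the study system: a ~135 km
#' transect, three periods with uneven sample sizes, body-size (PC1-scale)
#' clines centered near 67.7 / 73.8 / 76.7 km with widths 41.8 / 22.0 / 33.1
#' km, and chroma clines centered near 72.9 / 73.0 / 76.3 km with widths
#' 31.5 / 32.4 / 6.7 km. These are generator settings chosen to emulate the
#' published cline geometry, not reproduced results.
#'
#' @param n_per_period Named integer vector of specimens per period.
#' @param length_km Transect length.
#' @param pc1_centers,pc1_widths,chroma_centers,chroma_widths Named numeric
#'   vectors per period (km).
#' @param pc1_range Lower/upper plateaus of the body-size trait.
#' @param pc1_noise_sd Gaussian noise SD on the latent body-size trait
#'   (default 10% of the plateau span).
#' @param chroma_noise_sd Additive spectral noise SD (percent reflectance).
#' @param center_bias_weight,center_bias_sd_km Mixture weight and SD of the
#'   center-biased component of spatial sampling (remainder is uniform).
#' @param male_fraction Probability a simulated specimen is male.
#' @param transect Geometry: NW anchor (`lat0`, `lon0`), degree-scale `slope`
#'   of latitude on longitude, and perpendicular scatter `offset_sd_km`.
#' @param haplotypes Haplotype model: alignment `seq_length`, number of
#'   haplotypes and segregating sites, per-period `preset`
#'   (`"structured"` or `"unstructured"`) and the dominant-haplotype
#'   frequency used by the structured preset.
#' @return A list of class `hzc_sim_config`.
#' @export
sim_config <- function(
    n_per_period = c(P1911 = 40, P1956 = 60, P2010 = 45),
    length_km = 135,
    pc1_centers = c(P1911 = 67.7, P1956 = 73.8, P2010 = 76.7),
    pc1_widths = c(P1911 = 41.8, P1956 = 22.0, P2010 = 33.1),
    chroma_centers = c(P1911 = 72.9, P1956 = 73.0, P2010 = 76.3),
    chroma_widths = c(P1911 = 31.5, P1956 = 32.4, P2010 = 6.7),
    pc1_range = c(-1.5, 1.5),
    pc1_noise_sd = 0.3,
    chroma_noise_sd = 0.6,
    center_bias_weight = 0.25,
    center_bias_sd_km = 20,
    male_fraction = 0.7,
    transect = list(lat0 = 4.00, lon0 = -77.15, slope = -0.5,
                    offset_sd_km = 0.6),
    haplotypes = list(seq_length = 210, n_haplotypes = 6, n_segregating = 9,
                      preset = c(P1956 = "structured", P2010 = "unstructured"),
                      dominant_freq = 0.8)) {
  periods <- names(n_per_period)
  stopifnot(!is.null(periods), all(n_per_period >= 8))
  stopifnot(all(pc1_centers < length_km), all(chroma_centers < length_km))
  cfg <- list(
    periods = periods, n_per_period = n_per_period, length_km = length_km,
    pc1_centers = pc1_centers, pc1_widths = pc1_widths,
    chroma_centers = chroma_centers, chroma_widths = chroma_widths,
    pc1_range = pc1_range, pc1_noise_sd = pc1_noise_sd,
    chroma_noise_sd = chroma_noise_sd,
    center_bias_weight = center_bias_weight,
    center_bias_sd_km = center_bias_sd_km,
    male_fraction = male_fraction, transect = transect,
    haplotypes = haplotypes,
    x_offset = 0.1,
    year_ranges = list(P1911 = c(1894, 1911), P1956 = c(1956, 1986),
                       P2010 = c(2007, 2010)))
  class(cfg) <- "hzc_sim_config"
  cfg
}

# 4PL parameters (offset scale) for a configured center/width on the
# original distance scale
cline_params_for <- function(center, width, lower, upper, x_offset = 0.1) {
  E <- center + x_offset
  c(C = lower, D = upper, B = steepness_for_width(width, E), E = E)
}

#' Simulate raw trait-by-distance cline data
#'
#' Low-level generator used throughout the validation tests: distances drawn
#' from a uniform/center-biased mixture over `[0, length_km]`, responses from
#' the Hill curve with the given center and width plus Gaussian noise.
#'
#' @param n Number of observations.
#' @param center,width_km Cline center and width on the distance scale (km).
#' @param lower,upper Response plateaus.
#' @param noise_sd Gaussian response noise SD.
#' @param length_km Transect length.
#' @param seed Seed (mandatory).
#' @param center_bias_weight,center_bias_sd_km Spatial sampling mixture; 0
#'   weight = uniform sampling.
#' @param x_offset Log-offset used when evaluating the curve (matches
#'   [fit_hill()]'s default so noiseless data are exactly recoverable).
#' @return Tibble `distance_km`, `value`; attribute `truth` holds the
#'   generating parameters.
#' @export
simulate_cline_data <- function(n, center, width_km, lower = 0, upper = 1,
                                noise_sd = 0, length_km = 135, seed,
                                center_bias_weight = 0, center_bias_sd_km = 20,
                                x_offset = 0.1) {
  if (missing(seed)) hzc_abort("seed is required", "hzc_seed_error")
  pars <- cline_params_for(center, width_km, lower, upper, x_offset)
  with_seed(seed, {
    biased <- stats::runif(n) < center_bias_weight
    x <- ifelse(biased,
                pmin(pmax(stats::rnorm(n, center, center_bias_sd_km), 0), length_km),
                stats::runif(n, 0, length_km))
    y <- hill_predict(pars, x + x_offset) + stats::rnorm(n, 0, noise_sd)
    out <- tibble(distance_km = x, value = y)
    attr(out, "truth") <- list(params = pars, center = center, width = width_km)
    out
  })
}

#' Simulate a specimen table with known ground truth
#'
#' Generates museum-specimen rows for every configured period: coordinates
#' scattered around the configured transect line, collection years inside the
#' period windows, sexes, and six morphometric characters built from the
#' latent body-size cline (wing and tail load strongly; the four bill/tarsus
#' characters only weakly) so that correlation-matrix PC1 tracks the latent
#' cline. The latent (noise-free and noisy) trait values and all generating
#' parameters are returned as ground truth.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (mandatory).
#' @return List with `specimens` (a tibble that passes
#'   [validate_specimens()]), `latent` (per-specimen ground-truth tibble:
#'   distance, latent and noisy trait, chroma target, mixing weight), and
#'   `truth` (per-period generating parameters).
#' @export
simulate_specimens <- function(config = sim_config(), seed) {
  if (missing(seed)) hzc_abort("seed is required", "hzc_seed_error")
  stopifnot(inherits(config, "hzc_sim_config"))
  tm <- config$transect
  kx <- .KM_PER_DEG * cos(tm$lat0 * pi / 180)
  ky <- .KM_PER_DEG
  u <- c(kx, tm$slope * ky); u <- u / sqrt(sum(u^2))
  nvec <- c(-u[2], u[1])

  cal <- chroma_calibration()
  truth <- list()
  rows <- list()
  latents <- list()
  for (pi in seq_along(config$periods)) {
    p <- config$periods[pi]
    n <- config$n_per_period[[p]]
    pc1_pars <- cline_params_for(config$pc1_centers[[p]], config$pc1_widths[[p]],
                                 config$pc1_range[1], config$pc1_range[2],
                                 config$x_offset)
    chr_pars <- cline_params_for(config$chroma_centers[[p]],
                                 config$chroma_widths[[p]],
                                 cal$chroma_yellow, cal$chroma_red,
                                 config$x_offset)
    dat <- with_seed(derive_seed(seed, 100 + pi), {
      biased <- stats::runif(n) < config$center_bias_weight
      x <- ifelse(biased,
                  pmin(pmax(stats::rnorm(n, config$pc1_centers[[p]],
                                         config$center_bias_sd_km), 0),
                       config$length_km),
                  stats::runif(n, 0, config$length_km))
      off <- stats::rnorm(n, 0, tm$offset_sd_km)
      yr <- config$year_ranges[[p]]
      year <- sample(seq(yr[1], yr[2]), n, replace = TRUE)
      sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
      latent <- hill_predict(pc1_pars, x + config$x_offset)
      trait <- latent + stats::rnorm(n, 0, config$pc1_noise_sd)
      chroma_target <- hill_predict(chr_pars, x + config$x_offset)
      morph <- tibble(
        wing_mm = 72 + 2.0 * trait + stats::rnorm(n, 0, 0.8),
        tail_mm = 68 + 1.8 * trait + stats::rnorm(n, 0, 0.8),
        culmen_mm = 19 + 0.15 * trait + stats::rnorm(n, 0, 0.5),
        bill_depth_mm = 8 + 0.10 * trait + stats::rnorm(n, 0, 0.35),
        bill_width_mm = 7.5 + 0.10 * trait + stats::rnorm(n, 0, 0.30),
        tarsus_mm = 19.5 + 0.20 * trait + stats::rnorm(n, 0, 0.6))
      id <- sprintf("%s_%03d", p, seq_len(n))
      lon <- tm$lon0 + (x * u[1] + off * nvec[1]) / kx
      lat <- tm$lat0 + (x * u[2] + off * nvec[2]) / ky
      list(
        spec = dplyr::bind_cols(
          tibble(id = id, latitude = lat, longitude = lon,
                 year = as.integer(year), sex = sex),
          morph,
          tibble(spectrum_id = id, sequence_id = id)),
        lat = tibble(id = id, period = p, distance_km = x, offset_km = off,
                     pc1_latent = latent, pc1_trait = trait,
                     chroma_target = chroma_target,
                     mix_t = cal$t_for_chroma(chroma_target)))
    })
    rows[[p]] <- dat$spec
    latents[[p]] <- dat$lat
    truth[[p]] <- list(
      pc1 = list(params = as.list(pc1_pars), center = config$pc1_centers[[p]],
                 width = config$pc1_widths[[p]]),
      chroma = list(params = as.list(chr_pars),
                    center = config$chroma_centers[[p]],
                    width = config$chroma_widths[[p]]))
  }
  list(specimens = purrr::list_rbind(rows),
       latent = purrr::list_rbind(latents),
       truth = truth)
}

#' Spectral templates of the parental rump colours
#'
#' Smooth step templates on a 5-nm grid: the yellow parental form reflects
#' strongly from ~520 nm upwards (mass in the two long-wave segments), the
#' red form only from ~605 nm upwards (mass concentrated in the longest
#' segment). Both integrate to comparable totals so mixtures move reflectance
#' mass between segments.
#'
#' @return Tibble `wavelength_nm`, `yellow`, `red` (percent reflectance).
#' @export
spectral_templates <- function() {
  wl <- seq(400, 700, by = 5)
  sigm <- function(x, c, s) 1 / (1 + exp(-(x - c) / s))
  yellow <- 4 + 44 * sigm(wl, 520, 12)
  red <- 4 + 52 * sigm(wl, 605, 10)
  tibble(wavelength_nm = wl, yellow = yellow, red = red)
}

# calibration between mixing weight t and the chroma of the mixture
# t*red + (1-t)*yellow; chroma(t) is monotone, inverted by interpolation so
# the generator can realise an exact target chroma cline
chroma_calibration <- function() {
  tpl <- spectral_templates()
  tg <- seq(0, 1, length.out = 2001)
  ch <- vapply(tg, function(t) {
    mix <- t * tpl$red + (1 - t) * tpl$yellow
    segment_metrics(tpl$wavelength_nm, mix)$chroma
  }, numeric(1))
  if (any(diff(ch) <= 0)) {
    hzc_abort("template mixture chroma is not monotone in t", "hzc_template_error")
  }
  list(chroma_yellow = ch[1], chroma_red = ch[length(ch)],
       chroma_of_t = function(t) stats::approx(tg, ch, xout = t)$y,
       t_for_chroma = function(c) stats::approx(ch, tg, xout = c)$y)
}

#' Simulate reflectance spectra for positioned specimens
#'
#' Each specimen's spectrum is the template mixture
#' `t * red + (1 - t) * yellow` plus optional Gaussian noise, with the mixing
#' weight `t` calibrated (through the inverted mixture-chroma curve) so the
#' specimen's noise-free chroma equals the configured chroma cline evaluated
#' at its transect distance.
#'
#' @param latent The `latent` tibble from [simulate_specimens()] (needs `id`
#'   and `mix_t`).
#' @param config A [sim_config()].
#' @param seed Seed (mandatory).
#' @return Wide spectra tibble: `wavelength_nm` plus one column per specimen.
#' @export
simulate_spectra <- function(latent, config = sim_config(), seed) {
  if (missing(seed)) hzc_abort("seed is required", "hzc_seed_error")
  tpl <- spectral_templates()
  out <- tibble(wavelength_nm = tpl$wavelength_nm)
  specs <- with_seed(derive_seed(seed, 200), {
    lapply(seq_len(nrow(latent)), function(i) {
      t <- latent$mix_t[i]
      mix <- t * tpl$red + (1 - t) * tpl$yellow
      pmax(mix + stats::rnorm(length(mix), 0, config$chroma_noise_sd), 0)
    })
  })
  names(specs) <- latent$id
  dplyr::bind_cols(out, tibble::as_tibble(specs))
}

#' Simulate haplotype alignments with sector-level structure
#'
#' Builds `n_haplotypes` haplotypes by distributing `n_segregating` private
#' mutations over a random base sequence, then draws each individual's
#' haplotype from its sector's frequency vector. The `"structured"` preset
#' gives each sector a different dominant haplotype (positive true
#' differentiation among sectors); `"unstructured"` uses one shared frequency
#' vector (true F_CT = 0).
#'
#' @param sectors Integer/character sector label per individual.
#' @param ids Sequence ids (same length as `sectors`).
#' @param config A [sim_config()] (haplotype model settings).
#' @param preset `"structured"` or `"unstructured"`.
#' @param seed Seed (mandatory).
#' @return List: `sequences` (tibble `id`, `sequence`, `length`),
#'   `frequencies` (sector x haplotype matrix), `haplotypes` (character
#'   vector).
#' @export
simulate_sequences <- function(sectors, ids, config = sim_config(),
                               preset = c("structured", "unstructured"), seed) {
  if (missing(seed)) hzc_abort("seed is required", "hzc_seed_error")
  preset <- match.arg(preset)
  hp <- config$haplotypes
  H <- hp$n_haplotypes
  k <- hp$n_segregating
  L <- hp$seq_length
  stopifnot(k >= H - 1, L > k)
  sec_levels <- sort(unique(as.character(sectors)))
  with_seed(derive_seed(seed, 300), {
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    sites <- sort(sample.int(L, k))
    # distribute the segregating sites over haplotypes 2..H (private mutations)
    owner <- rep_len(2:H, k)
    haps <- vapply(seq_len(H), function(h) {
      s <- base
      for (j in which(owner == h)) {
        s[sites[j]] <- setdiff(c("A", "C", "G", "T"), base[sites[j]])[1]
      }
      paste(s, collapse = "")
    }, character(1))

    freq <- matrix(0, nrow = length(sec_levels), ncol = H,
                   dimnames = list(sec_levels, paste0("hap", seq_len(H))))
    if (preset == "structured") {
      for (i in seq_along(sec_levels)) {
        dom <- ((i - 1) %% H) + 1
        freq[i, ] <- (1 - hp$dominant_freq) / (H - 1)
        freq[i, dom] <- hp$dominant_freq
      }
    } else {
      shared <- c(0.7, rep(0.3 / (H - 1), H - 1))
      for (i in seq_along(sec_levels)) freq[i, ] <- shared
    }
    draw <- vapply(as.character(sectors), function(s) {
      sample.int(H, 1, prob = freq[s, ])
    }, integer(1))
    list(sequences = tibble(id = as.character(ids), sequence = haps[draw],
                            length = L),
         frequencies = freq, haplotypes = haps)
  })
}

#' Generate and write a full synthetic dataset
#'
#' Runs the whole generator with one master seed and writes
#' `specimens.csv`, `spectra.csv`, one `seqs_<period>.fasta` per period with
#' a haplotype preset, and `truth.json` (all generating parameters) to
#' `out_dir`. Outputs are plain text and byte-identical for identical seeds.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (mandatory).
#' @return Invisibly, a list with the written paths and the ground truth.
#' @export
simulate_hybrid_zone <- function(config = sim_config(), out_dir, seed) {
  if (missing(seed)) hzc_abort("seed is required", "hzc_seed_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_specimens(config, seed = seed)
  spectra <- simulate_spectra(sim$latent, config, seed = seed)

  paths <- list(specimens = file.path(out_dir, "specimens.csv"),
                spectra = file.path(out_dir, "spectra.csv"),
                truth = file.path(out_dir, "truth.json"))
  readr::write_csv(sim$specimens, paths$specimens)
  readr::write_csv(spectra, paths$spectra)

  hap_truth <- list()
  presets <- config$haplotypes$preset
  for (p in names(presets)) {
    lat <- sim$latent[sim$latent$period == p, ]
    sec <- assign_sector(pmin(lat$distance_km, config$length_km),
                         domain_end_km = config$length_km)
    gen <- simulate_sequences(sec, lat$id, config, preset = presets[[p]],
                              seed = derive_seed(seed, 400 + match(p, names(presets))))
    fp <- file.path(out_dir, paste0("seqs_", p, ".fasta"))
    write_fasta(gen$sequences, fp)
    paths[[paste0("seqs_", p)]] <- fp
    hap_truth[[p]] <- list(preset = unname(presets[[p]]),
                           frequencies = gen$frequencies,
                           haplotypes = gen$haplotypes)
  }

  truth <- list(config = unclass(config), periods = sim$truth,
                haplotypes = hap_truth,
                latent = sim$latent, seed = seed)
  jsonlite::write_json(truth_serializable(truth), paths$truth,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paths = paths, truth = truth, specimens = sim$specimens,
                 spectra = spectra, latent = sim$latent))
}

# make the truth list JSON-round-trippable (matrices -> named lists)
truth_serializable <- function(truth) {
  truth$haplotypes <- lapply(truth$haplotypes, function(h) {
    h$frequencies <- apply(h$frequencies, 1, as.list, simplify = FALSE)
    h
  })
  truth$latent <- as.list(truth$latent)
  truth
}

#' Write aligned sequences to FASTA
#'
#' @param seqs Tibble with `id` and `sequence` (or named character vector).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_sequence_tbl(seqs)
  lines <- as.vector(rbind(paste0(">", seqs$id), seqs$sequence))
  writeLines(lines, path)
  invisible(path)
}
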