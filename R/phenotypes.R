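#' Drop specimens with incomplete morphometric measurements
#'
#' @param data Specimen tibble.
#' @param required Character vector of measurement columns that must be
#'   present and non-missing (default: the six standard characters).
#' @return Tibble of complete cases. Attribute `dropped_by_column` reports
#'   how many rows each column was responsible for dropping.
#' @export
complete_case_filter <- function(data,
                                 required = c("wing_mm", "culmen_mm",
                                              "bill_depth_mm", "bill_width_mm",
                                              "tail_mm", "tarsus_mm")) {
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    hzc_abort(paste0("missing measurement column(s): ",
                     paste(missing_cols, collapse = ", ")), "hzc_schema_error")
  }
  miss <- vapply(required, function(cc) is.na(data[[cc]]), logical(nrow(data)))
  if (nrow(data) == 1) miss <- matrix(miss, nrow = 1, dimnames = list(NULL, required))
  keep <- rowSums(miss) == 0
  out <- tibble::as_tibble(data[keep, , drop = FALSE])
  if (nrow(out) < 3) {
    hzc_abort("fewer than 3 complete morphometric rows", "hzc_insufficient_data_error")
  }
  attr(out, "dropped_by_column") <- colSums(miss)
  out
}

#' Principal components of morphometric characters
#'
#' PCA on the correlation matrix of the measurement columns (each character
#' standardised), computed separately per sex as supplied. PC1 is the
#' body-size axis; its sign is fixed so that wing length loads positively
#' (larger birds score higher). Scores are centered.
#'
#' @param data Complete-case tibble (see [complete_case_filter()]) with an
#'   `id` column.
#' @param sex Optional sex label (`"male"`/`"female"`); if given, rows are
#'   subset on the `sex` column before the analysis.
#' @param columns Measurement columns to use.
#' @param use_correlation If `TRUE` (default) standardise characters
#'   (correlation-matrix PCA); if `FALSE` use the covariance matrix.
#' @return Object of class `hzc_pca` with elements `loadings`,
#'   `scores` (tibble `id`, `PC1`, ...), `variance_prop`, `sdev`, `n`, `sex`.
#' @export
compute_pca <- function(data, sex = NULL,
                        columns = c("wing_mm", "culmen_mm", "bill_depth_mm",
                                    "bill_width_mm", "tail_mm", "tarsus_mm"),
                        use_correlation = TRUE) {
  if (!is.null(sex)) data <- data[data$sex %in% sex, , drop = FALSE]
  if (nrow(data) < 3) {
    hzc_abort("fewer than 3 rows in the selected sex", "hzc_insufficient_data_error")
  }
  m <- as.matrix(data[, columns])
  if (anyNA(m)) hzc_abort("missing measurements; run complete_case_filter() first",
                          "hzc_missing_data_error")
  zero_var <- columns[apply(m, 2, stats::var) < 1e-12]
  if (length(zero_var) > 0) {
    hzc_abort(paste0("zero-variance column(s): ", paste(zero_var, collapse = ", ")),
              "hzc_degenerate_data_error")
  }
  p <- stats::prcomp(m, center = TRUE, scale. = use_correlation)
  # sign convention: wing length loads positively on PC1
  flip <- sign(p$rotation["wing_mm", 1])
  if (flip == 0) flip <- 1
  p$rotation[, 1] <- flip * p$rotation[, 1]
  p$x[, 1] <- flip * p$x[, 1]
  var_prop <- p$sdev^2 / sum(p$sdev^2)
  scores <- tibble(id = as.character(data$id))
  scores <- dplyr::bind_cols(scores, tibble::as_tibble(p$x))
  structure(
    list(loadings = p$rotation, scores = scores, variance_prop = var_prop,
         sdev = p$sdev, n = nrow(m), sex = sex %||% "all",
         use_correlation = use_correlation),
    class = "hzc_pca"
  )
}

#' @export
print.hzc_pca <- function(x, ...) {
  cat("Morphometric PCA (", if (x$use_correlation) "correlation" else "covariance",
      " matrix), n = ", x$n, ", sex = ", x$sex, "\n", sep = "")
  cat("PC1 variance share:", sprintf("%.1f%%", 100 * x$variance_prop[1]), "\n")
  invisible(x)
}

#' @rdname compute_pca
#' @param x A `hzc_pca` object.
#' @param matrix Which table to return from `tidy()`: `"loadings"` or
#'   `"scores"`.
#' @param ... Unused.
#' @export
tidy.hzc_pca <- function(x, matrix = c("loadings", "scores"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") return(x$scores)
  tibble(character = rownames(x$loadings)) |>
    dplyr::bind_cols(tibble::as_tibble(x$loadings)) |>
    tidyr::pivot_longer(-"character", names_to = "component", values_to = "loading")
}

#' @rdname compute_pca
#' @export
glance.hzc_pca <- function(x, ...) {
  tibble(component = colnames(x$loadings), sdev = x$sdev,
         variance_prop = x$variance_prop, n = x$n, sex = x$sex)
}

# resample one spectrum onto the 1-nm grid 400..700 by linear interpolation
resample_spectrum <- function(wavelength_nm, reflectance) {
  ok <- !is.na(wavelength_nm) & !is.na(reflectance)
  wl <- wavelength_nm[ok]; rf <- reflectance[ok]
  if (length(wl) < 2) hzc_abort("spectrum needs >= 2 readings", "hzc_spectrum_error")
  if (is.unsorted(wl, strictly = TRUE)) {
    o <- order(wl); wl <- wl[o]; rf <- rf[o]
    if (anyDuplicated(wl)) hzc_abort("duplicate wavelengths in spectrum",
                                     "hzc_spectrum_error")
  }
  if (min(wl) > 400 || max(wl) < 700) {
    hzc_abort("spectrum must cover 400-700 nm", "hzc_spectrum_error")
  }
  bins <- findInterval(wl, seq(400, 700, by = 25), rightmost.closed = TRUE)
  if (length(unique(bins[wl >= 400 & wl <= 700])) < 12) {
    hzc_abort("spectrum needs at least one reading per 25-nm bin", "hzc_spectrum_error")
  }
  if (any(rf < 0)) hzc_abort("negative reflectance", "hzc_spectrum_error")
  # 1-nm midpoint grid: 75 points per 75-nm segment, so a spectrally flat
  # input yields exactly equal segment masses (chroma 0)
  grid <- seq(400.5, 699.5, by = 1)
  stats::approx(wl, rf, xout = grid)$y
}

#' Segment-classification colour metrics from a reflectance spectrum
#'
#' The 400-700 nm spectrum is resampled to a 1-nm midpoint grid
#' (400.5, 401.5, ..., 699.5 nm, so each segment holds exactly 75 points) and
#' divided into four equal segments (400-475, 475-550, 550-625, 625-700 nm). With `Qk` the
#' fraction of total reflectance in segment k: `LM = Q4 - Q2`,
#' `MS = Q3 - Q1`, brightness is the mean percent reflectance on the grid,
#' chroma is `sqrt(LM^2 + MS^2)` (saturation), and hue is `atan2(MS, LM)` in
#' radians. A spectrally flat input gives chroma 0 and a degenerate hue,
#' reported as 0 with `hue_degenerate = TRUE`; a zero spectrum returns
#' missing chroma/hue.
#'
#' @param wavelength_nm Numeric vector of wavelengths (nm) within
#'   \[400, 700\], at least one reading per 25-nm bin.
#' @param reflectance Percent reflectance relative to a white standard
#'   (non-negative), same length as `wavelength_nm`.
#' @return One-row tibble: `brightness`, `Q1`..`Q4`, `LM`, `MS`, `chroma`,
#'   `hue`, `hue_degenerate`.
#' @export
segment_metrics <- function(wavelength_nm, reflectance) {
  r <- resample_spectrum(wavelength_nm, reflectance)
  grid <- seq(400.5, 699.5, by = 1)
  brightness <- mean(r)
  total <- sum(r)
  if (total <= 0) {
    return(tibble(brightness = 0, Q1 = NA_real_, Q2 = NA_real_, Q3 = NA_real_,
                  Q4 = NA_real_, LM = NA_real_, MS = NA_real_,
                  chroma = NA_real_, hue = NA_real_, hue_degenerate = NA))
  }
  seg <- pmin(findInterval(grid, c(400, 475, 550, 625)), 4L)
  q <- vapply(1:4, function(k) sum(r[seg == k]), numeric(1)) / total
  lm_ <- q[4] - q[2]
  ms_ <- q[3] - q[1]
  chroma <- sqrt(lm_^2 + ms_^2)
  degenerate <- chroma < 1e-12
  hue <- if (degenerate) 0 else atan2(ms_, lm_)
  tibble(brightness = brightness, Q1 = q[1], Q2 = q[2], Q3 = q[3], Q4 = q[4],
         LM = lm_, MS = ms_, chroma = chroma, hue = hue,
         hue_degenerate = degenerate)
}

#' Colour metrics for a wide table of spectra
#'
#' @param spectra Wide tibble: column `wavelength_nm` plus one column per
#'   spectrum id. Replicate columns for the same specimen should be averaged
#'   beforehand (or share a column).
#' @return Tibble with one row per spectrum: `spectrum_id` plus the
#'   [segment_metrics()] columns.
#' @export
color_metrics <- function(spectra) {
  ids <- setdiff(names(spectra), "wavelength_nm")
  if (!"wavelength_nm" %in% names(spectra) || length(ids) == 0) {
    hzc_abort("spectra table needs a wavelength_nm column plus spectrum columns",
              "hzc_schema_error")
  }
  purrr::map_dfr(ids, function(sid) {
    dplyr::bind_cols(tibble(spectrum_id = sid),
                     segment_metrics(spectra$wavelength_nm, spectra[[sid]]))
  })
}

#' Assemble the per-specimen analysis table
#'
#' Joins transect positions, PCA scores and colour metrics into one row per
#' specimen with `distance_km`, `period`, `sex`, `PC1`, `brightness`,
#' `chroma`, `hue`. Phenotypes missing for a specimen stay missing; phenotype
#' records whose id has no position are dropped with a warning.
#'
#' @param positions Tibble from [project_onto_transect()].
#' @param specimens Validated specimen tibble (for `sex`, `spectrum_id`).
#' @param pca Optional `hzc_pca` (scores joined on `id`).
#' @param colors Optional tibble from [color_metrics()] (joined via
#'   `spectrum_id`).
#' @return Analysis tibble, one row per positioned specimen.
#' @export
attach_phenotypes <- function(positions, specimens, pca = NULL, colors = NULL) {
  out <- positions |>
    dplyr::left_join(specimens[, intersect(c("id", "sex", "spectrum_id"),
                                           names(specimens))], by = "id")
  if (!is.null(pca)) {
    sc <- pca$scores[, c("id", "PC1")]
    orphan <- setdiff(sc$id, positions$id)
    if (length(orphan) > 0) {
      rlang::warn(paste0("PCA scores without positions dropped: ",
                         paste(orphan, collapse = ", ")))
    }
    out <- dplyr::left_join(out, sc, by = "id")
  } else out$PC1 <- NA_real_
  if (!is.null(colors) && "spectrum_id" %in% names(out)) {
    orphan <- setdiff(colors$spectrum_id, out$spectrum_id)
    if (length(orphan) > 0) {
      rlang::warn(paste0("spectra without specimens dropped: ",
                         paste(orphan, collapse = ", ")))
    }
    out <- dplyr::left_join(
      out, colors[, c("spectrum_id", "brightness", "chroma", "hue")],
      by = "spectrum_id")
  } else {
    out$brightness <- NA_real_; out$chroma <- NA_real_; out$hue <- NA_real_
  }
  out
}
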