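#' Expected cline width under neutral diffusion
#'
#' After secondary contact with no selection, a cline decays by dispersal
#' alone and its width after `generations` generations is
#' `constant * sigma * sqrt(generations)`, with `sigma` the per-generation
#' dispersal scale (km) and `constant = sqrt(2 * pi)` by default (~2.51).
#' Fitted widths far below this expectation point to selection maintaining
#' the zone (a tension zone).
#'
#' @param sigma Dispersal scale per generation, km (> 0).
#' @param generations Generations since contact (>= 0).
#' @param constant Proportionality constant (default `sqrt(2 * pi)`).
#' @return Expected width in km.
#' @export
expected_width <- function(sigma, generations, constant = sqrt(2 * pi)) {
  stopifnot(all(sigma > 0), all(generations >= 0))
  constant * sigma * sqrt(generations)
}

#' Neutral-diffusion width envelope over parameter ranges
#'
#' Minimum and maximum expected widths over the Cartesian corners of the
#' dispersal-scale and generation-time ranges at a fixed zone age. A fitted
#' width below `min_km` is narrower than any neutral expectation in the
#' scenario — evidence for selection.
#'
#' @param sigma_km Length-2 numeric range of dispersal scales (km/generation),
#'   or a single value.
#' @param generation_time_yr Length-2 range of generation times (years), or a
#'   single value.
#' @param age_yr Years since contact (single positive value).
#' @param constant Passed to [expected_width()].
#' @return One-row tibble: `min_km`, `max_km`, `age_yr`, `constant`, plus the
#'   input ranges.
#' @export
width_envelope <- function(sigma_km, generation_time_yr, age_yr,
                           constant = sqrt(2 * pi)) {
  sigma_km <- range(sigma_km)
  generation_time_yr <- range(generation_time_yr)
  stopifnot(all(sigma_km > 0), all(generation_time_yr > 0), age_yr >= 0)
  corners <- expand.grid(sigma = sigma_km, gt = generation_time_yr)
  w <- expected_width(corners$sigma, age_yr / corners$gt, constant = constant)
  tibble(min_km = min(w), max_km = max(w), age_yr = age_yr,
         constant = constant,
         sigma_min = sigma_km[1], sigma_max = sigma_km[2],
         generation_time_min = generation_time_yr[1],
         generation_time_max = generation_time_yr[2],
         formula = "width = constant * sigma * sqrt(age / generation_time)")
}
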