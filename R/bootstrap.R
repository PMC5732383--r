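#' Filtered bootstrap of cline center and width
#'
#' Resamples specimens with replacement (sample size held constant), refits
#' the Hill cline to each replicate, and retains a replicate only if the fit
#' converged and its center lies within `bounds` (default 0-140 km) — the
#' filter used to discard non-clinal or geographically unrealistic
#' resamples. Replicate `r` uses the deterministic RNG substream
#' `derive_seed(seed, r)`, so runs are bit-reproducible and independent of
#' retention history. Width is never filtered, but replicates whose width
#' exceeds the transect length are counted and can trigger an omit-width-CI
#' flag mirroring cases where width bootstraps are too unstable to report.
#'
#' @inheritParams fit_hill
#' @param reps Number of bootstrap replicates requested (default 1000).
#' @param bounds Length-2 numeric: retention bounds on the center in km.
#' @param seed Master seed (mandatory, for reproducibility).
#' @param width_flag_km Widths above this are flagged as unrealistic
#'   (default `domain_end_km`).
#' @param point_fit Optional `hzc_cline` point fit reused as the optimiser's
#'   first start (computed internally when omitted).
#' @return Object of class `hzc_bootstrap`: tibble of retained
#'   `(replicate, center_km, width_km)` rows, means, 95% percentile limits,
#'   retention and convergence rates, and `omit_width_ci` flag (set when more
#'   than half the retained widths are unrealistic).
#' @export
bootstrap_cline <- function(data, response, distance = distance_km,
                            reps = 1000, bounds = c(0, 140), seed,
                            x_offset = 0.1, domain_end_km = 140,
                            width_flag_km = domain_end_km,
                            trait = NULL, period = NULL, point_fit = NULL) {
  if (missing(seed)) hzc_abort("seed is required for bootstrap_cline()",
                               "hzc_seed_error")
  y <- dplyr::pull(data, {{ response }})
  x <- dplyr::pull(data, {{ distance }})
  ok <- !is.na(x) & !is.na(y)
  df <- tibble(distance_km = x[ok], value = y[ok])
  n <- nrow(df)
  if (is.null(point_fit)) {
    point_fit <- fit_hill(df, value, distance_km, x_offset = x_offset,
                          domain_end_km = domain_end_km)
  }
  init <- point_fit$params

  centers <- numeric(reps); widths <- numeric(reps)
  keep <- logical(reps); conv <- logical(reps)
  for (r in seq_len(reps)) {
    idx <- with_seed(derive_seed(seed, r), sample.int(n, n, replace = TRUE))
    rep_fit <- tryCatch(
      fit_hill(df[idx, ], value, distance_km, x_offset = x_offset,
               domain_end_km = domain_end_km, starts = c(-5, 5),
               init = init, polish = FALSE),
      error = function(e) NULL)
    if (is.null(rep_fit) || !rep_fit$converged) next
    conv[r] <- TRUE
    ctr <- rep_fit$center_km
    if (ctr >= bounds[1] && ctr <= bounds[2]) {
      keep[r] <- TRUE
      centers[r] <- ctr
      widths[r] <- rep_fit$width_km
    }
  }
  retained <- tibble(replicate = which(keep), center_km = centers[keep],
                     width_km = widths[keep])
  if (nrow(retained) == 0) {
    hzc_abort("no bootstrap replicates retained", "hzc_bootstrap_error")
  }
  if (nrow(retained) < 50) {
    rlang::warn(paste0("only ", nrow(retained),
                       " bootstrap replicates retained; intervals are unstable"))
  }
  # width is never filtered (only centers are), so replicates with runaway
  # shallow slopes can carry unrealistically large or overflowing widths;
  # summaries use finite widths and report the unrealistic fraction
  finite_w <- retained$width_km[is.finite(retained$width_km)]
  wide_widths <- mean(!is.finite(retained$width_km) |
                        retained$width_km > width_flag_km)
  structure(
    list(replicates = retained,
         trait = trait %||% point_fit$trait, period = period %||% point_fit$period,
         requested = reps, retained = nrow(retained),
         retention_rate = nrow(retained) / reps,
         convergence_rate = mean(conv),
         bounds = bounds, seed = seed,
         point_fit = point_fit,
         center_mean = mean(retained$center_km),
         width_mean = if (length(finite_w) > 0) mean(finite_w) else NA_real_,
         center_ci = stats::quantile(retained$center_km, c(0.025, 0.975),
                                     names = FALSE),
         width_ci = if (length(finite_w) > 0)
           stats::quantile(finite_w, c(0.025, 0.975), names = FALSE)
         else c(NA_real_, NA_real_),
         unrealistic_width_rate = wide_widths,
         omit_width_ci = wide_widths > 0.5),
    class = "hzc_bootstrap")
}

#' @export
print.hzc_bootstrap <- function(x, ...) {
  cat("Bootstrap cline distribution",
      if (!is.null(x$trait)) paste0(" [", x$trait,
                                    if (!is.null(x$period)) paste0(", ", x$period), "]"),
      "\n", sep = "")
  cat(sprintf("  retained %d / %d replicates (centers filtered to [%g, %g] km)\n",
              x$retained, x$requested, x$bounds[1], x$bounds[2]))
  cat(sprintf("  center: %.2f km (95%% CI %.2f-%.2f)\n",
              x$center_mean, x$center_ci[1], x$center_ci[2]))
  if (x$omit_width_ci) {
    cat(sprintf("  width: %.2f km (CI omitted: %d%% of replicates unrealistic)\n",
                x$width_mean, round(100 * x$unrealistic_width_rate)))
  } else {
    cat(sprintf("  width: %.2f km (95%% CI %.2f-%.2f)\n",
                x$width_mean, x$width_ci[1], x$width_ci[2]))
  }
  invisible(x)
}

#' @rdname bootstrap_cline
#' @param x A `hzc_bootstrap` object.
#' @param ... Unused.
#' @export
tidy.hzc_bootstrap <- function(x, ...) x$replicates

#' @rdname bootstrap_cline
#' @export
glance.hzc_bootstrap <- function(x, ...) {
  tibble(trait = x$trait %||% NA_character_, period = x$period %||% NA_character_,
         center = x$center_mean, width = x$width_mean,
         center_ci_low = x$center_ci[1], center_ci_high = x$center_ci[2],
         width_ci_low = if (x$omit_width_ci) NA_real_ else x$width_ci[1],
         width_ci_high = if (x$omit_width_ci) NA_real_ else x$width_ci[2],
         retained = x$retained, requested = x$requested,
         retention_rate = x$retention_rate)
}

#' @rdname bootstrap_cline
#' @param object A `hzc_bootstrap` object.
#' @export
autoplot.hzc_bootstrap <- function(object, ...) {
  long <- tidyr::pivot_longer(object$replicates, c("center_km", "width_km"),
                              names_to = "parameter", values_to = "km")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$km)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "km", y = "bootstrap density") +
    ggplot2::theme_minimal()
}

#' One-way ANOVA across period groups
#'
#' Fixed-effects one-way ANOVA on (typically) bootstrap replicate values,
#' treating replicates as independent observations. Because bootstrap
#' replicates are pseudo-replicates, resulting P-values measure separation
#' relative to resampling noise, not specimen-level sampling error; outputs
#' are labelled accordingly.
#'
#' @param data Tibble with a value column and a grouping column.
#' @param value Value column (bare name or string).
#' @param group Group column.
#' @return One-row tibble: `statistic` (F), `p.value`, `df_between`,
#'   `df_within`, `method`.
#' @export
anova_periods <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  if (nlevels(droplevels(g)) < 2) hzc_abort("need >= 2 groups", "hzc_domain_error")
  if (any(table(g) < 2)) hzc_abort("each group needs >= 2 values", "hzc_domain_error")
  fit <- stats::aov(v ~ g)
  tab <- summary(fit)[[1]]
  ms_within <- tab["Residuals", "Mean Sq"]
  if (is.finite(ms_within) && ms_within < 1e-10 * max(stats::var(v), 1e-300)) {
    means <- tapply(v, g, mean)
    if (max(means) - min(means) > 0) {
      return(tibble(statistic = Inf, p.value = 0,
                    df_between = tab[1, "Df"], df_within = tab["Residuals", "Df"],
                    method = "bootstrap-replicate ANOVA"))
    }
    return(tibble(statistic = 0, p.value = 1,
                  df_between = tab[1, "Df"], df_within = tab["Residuals", "Df"],
                  method = "bootstrap-replicate ANOVA"))
  }
  tibble(statistic = tab[1, "F value"], p.value = tab[1, "Pr(>F)"],
         df_between = tab[1, "Df"], df_within = tab["Residuals", "Df"],
         method = "bootstrap-replicate ANOVA")
}

#' Tukey honest significant differences across period groups
#'
#' Studentized-range pairwise comparisons with the Tukey-Kramer unequal-n
#' correction, via [stats::TukeyHSD()]. Degenerate zero-variance groups are
#' handled explicitly: identical data give P = 1, separated constant groups
#' give P = 0.
#'
#' @inheritParams anova_periods
#' @return Tibble with `group1`, `group2`, `estimate` (mean difference),
#'   `conf.low`, `conf.high`, `p.value`.
#' @export
tukey_hsd <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  if (nlevels(droplevels(g)) < 2) hzc_abort("need >= 2 groups", "hzc_domain_error")
  if (any(table(g) < 2)) hzc_abort("each group needs >= 2 values", "hzc_domain_error")
  fit <- stats::aov(v ~ g)
  ms_within <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  pairs <- utils::combn(levels(droplevels(g)), 2)
  if (is.finite(ms_within) && ms_within < 1e-10 * max(stats::var(v), 1e-300)) {
    means <- tapply(v, g, mean)
    diffs <- means[pairs[2, ]] - means[pairs[1, ]]
    return(tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                  estimate = unname(diffs), conf.low = unname(diffs),
                  conf.high = unname(diffs),
                  p.value = ifelse(abs(diffs) > 0, 0, 1)))
  }
  th <- stats::TukeyHSD(fit)$g
  nm <- strsplit(rownames(th), "-", fixed = TRUE)
  tibble(group1 = vapply(nm, `[`, character(1), 2),
         group2 = vapply(nm, `[`, character(1), 1),
         estimate = unname(th[, "diff"]), conf.low = unname(th[, "lwr"]),
         conf.high = unname(th[, "upr"]), p.value = unname(th[, "p adj"]))
}

#' Summarise cline movement across collection periods
#'
#' Combines per-period bootstrap distributions for one trait into a movement
#' report: per-period mean centers/widths with percentile CIs, pairwise
#' center (and width) differences with CI-overlap flags, and
#' ANOVA + Tukey comparisons on the bootstrap replicates.
#'
#' @param bootstraps Named list of `hzc_bootstrap` objects (names = periods,
#'   or taken from each object's `period`).
#' @param parameters Which parameters to compare (`"center"`, `"width"`).
#' @return Object of class `hzc_movement` with `summary` (per-period tibble),
#'   `pairwise` (per parameter), `anova`, `tukey`.
#' @export
summarize_movement <- function(bootstraps, parameters = c("center", "width")) {
  if (inherits(bootstraps, "hzc_bootstrap")) bootstraps <- list(bootstraps)
  periods <- names(bootstraps) %||% vapply(bootstraps, function(b)
    b$period %||% NA_character_, character(1))
  if (is.null(names(bootstraps))) names(bootstraps) <- periods
  summary <- purrr::map_dfr(bootstraps, glance) |>
    mutate(period = periods)

  if (length(bootstraps) < 2) {
    return(structure(list(summary = summary, pairwise = tibble(),
                          anova = tibble(), tukey = tibble()),
                     class = "hzc_movement"))
  }

  reps <- purrr::imap_dfr(bootstraps, function(b, nm)
    mutate(b$replicates, period = nm))
  long <- tidyr::pivot_longer(reps, c("center_km", "width_km"),
                              names_to = "parameter", values_to = "km") |>
    mutate(parameter = sub("_km$", "", .data$parameter)) |>
    dplyr::filter(.data$parameter %in% parameters, is.finite(.data$km))

  anova_tab <- long |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(~anova_periods(.x, km, period)) |>
    dplyr::ungroup()
  tukey_tab <- long |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(~tukey_hsd(.x, km, period)) |>
    dplyr::ungroup()

  ci <- function(b, par) if (par == "center") b$center_ci else b$width_ci
  mean_of <- function(b, par) if (par == "center") b$center_mean else b$width_mean
  pairs <- utils::combn(names(bootstraps), 2)
  pairwise <- purrr::map_dfr(parameters, function(par) {
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      b1 <- bootstraps[[pairs[1, j]]]; b2 <- bootstraps[[pairs[2, j]]]
      tibble(parameter = par, period1 = pairs[1, j], period2 = pairs[2, j],
             difference_km = mean_of(b2, par) - mean_of(b1, par),
             ci_overlap = ci(b1, par)[1] <= ci(b2, par)[2] &&
               ci(b2, par)[1] <= ci(b1, par)[2])
    })
  })
  structure(list(summary = summary, pairwise = pairwise,
                 anova = anova_tab, tukey = tukey_tab),
            class = "hzc_movement")
}

#' @export
print.hzc_movement <- function(x, ...) {
  cat("Cline movement summary\n")
  print(x$summary[, c("period", "trait", "center", "width",
                      "center_ci_low", "center_ci_high")])
  if (nrow(x$tukey) > 0) {
    cat("\nTukey comparisons (bootstrap-replicate ANOVA; pseudo-replication caveat):\n")
    print(x$tukey[, c("parameter", "group1", "group2", "estimate", "p.value")])
  }
  invisible(x)
}

#' @rdname summarize_movement
#' @param object A `hzc_movement` object.
#' @param ... Unused.
#' @export
autoplot.hzc_movement <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$period, y = .data$center)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$center_ci_low,
                                          ymax = .data$center_ci_high)) +
    ggplot2::labs(x = NULL, y = "Cline center (km)",
                  title = "Bootstrap cline centers by period") +
    ggplot2::theme_minimal()
}
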