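#' Four-parameter log-logistic (Hill) response
#'
#' Evaluates `C + (D - C) / (1 + exp(B * (log(x) - log(E))))`. `C` and `D`
#' are the response plateaus at the two ends of the transect, `B` the signed
#' steepness, and `E` the km position of the inflection (the ED50, used as
#' the cline center). With `B < 0` the curve rises from `C` (coast) to `D`
#' (inland); with `B > 0` it falls from `D` to `C`.
#'
#' @param params Numeric vector or list with elements `C`, `D`, `B`, `E`
#'   (`E > 0`).
#' @param x Positive distances in km.
#' @return Numeric vector of predicted trait values.
#' @export
hill_predict <- function(params, x) {
  p <- unlist(params)
  if (is.null(names(p)) || !all(c("C", "D", "B", "E") %in% names(p))) {
    stopifnot(length(p) == 4) # unnamed vectors are taken in (C, D, B, E) order
    names(p) <- c("C", "D", "B", "E")
  } else {
    p <- p[c("C", "D", "B", "E")]
  }
  if (p[["E"]] <= 0) hzc_abort("E must be > 0", "hzc_domain_error")
  if (any(x <= 0)) hzc_abort("hill_predict() requires x > 0", "hzc_domain_error")
  f <- 1 / (1 + exp(p[["B"]] * (log(x) - log(p[["E"]]))))
  p[["C"]] + (p[["D"]] - p[["C"]]) * f
}

# profiled SSE: for fixed (B, logE) the model is linear in (C, D); solve the
# 2x2 normal equations exactly and return the optimal SSE and coefficients
profile_cd <- function(B, logE, lx, y) {
  f <- 1 / (1 + exp(B * (lx - logE)))
  g <- 1 - f
  a11 <- sum(g * g); a12 <- sum(f * g); a22 <- sum(f * f)
  b1 <- sum(y * g); b2 <- sum(y * f)
  det <- a11 * a22 - a12 * a12
  if (!is.finite(det) || det < 1e-12 * max(a11 * a22, 1)) {
    # plateau degenerate (f ~ constant): best constant fit
    mu <- mean(y)
    return(list(C = mu, D = mu, sse = sum((y - mu)^2), singular = TRUE))
  }
  C <- (b1 * a22 - b2 * a12) / det
  D <- (a11 * b2 - a12 * b1) / det
  resid <- y - (C * g + D * f)
  list(C = C, D = D, sse = sum(resid^2), singular = FALSE)
}

#' Fit a Hill-function cline to trait-by-distance data
#'
#' Least-squares fit of the four-parameter log-logistic curve
#' (see [hill_predict()]) to one trait along the transect. Because `log(x)`
#' is undefined at the coastal origin, all distances are shifted by
#' `x_offset` km before fitting and the offset is subtracted again from
#' reported centers and effective doses.
#'
#' The optimiser profiles out the linear parameters (`C`, `D` solve a 2x2
#' system exactly for fixed `B`, `E`), runs Nelder-Mead over `(B, log E)`
#' from multiple starts (`B0` in ±1, ±5, ±20 by default; ties broken by
#' smallest `|B|`), then polishes all four parameters with
#' Levenberg-Marquardt. The fit is flagged non-converged if the optimiser
#' fails or the fitted `E` leaves `(0, 10 * domain_end_km)`.
#'
#' @param data Tibble with the distance and response columns.
#' @param response Column with the trait value (bare name or string).
#' @param distance Column with the along-transect distance in km.
#' @param x_offset Km added to all distances before taking logs (default 0.1).
#' @param domain_end_km Transect domain end used in the convergence check
#'   (default 140).
#' @param starts Numeric vector of steepness starting values.
#' @param init Optional numeric `c(C, D, B, E)` used as an additional
#'   (first) start, e.g. a previous fit when bootstrapping.
#' @param polish Run the Levenberg-Marquardt refinement after the profiled
#'   search (default `TRUE`). Bootstrap resampling disables it for speed;
#'   the profiled optimum is already accurate to well below resampling noise.
#' @param trait,period Optional labels stored in the result.
#' @return Object of class `hzc_cline` with elements `params`
#'   (named `C`, `D`, `B`, `E` on the offset scale, reported in the canonical
#'   orientation `D >= C` — the curve is invariant under
#'   `(C, D, B) -> (D, C, -B)`), `center_km`, `width_km`
#'   (original scale), `sse`, `n`, `converged`, `x_offset`, `data`.
#' @export
fit_hill <- function(data, response, distance = distance_km, x_offset = 0.1,
                     domain_end_km = 140, starts = c(-1, 1, -5, 5, -20, 20),
                     init = NULL, polish = TRUE, trait = NULL, period = NULL) {
  y <- dplyr::pull(data, {{ response }})
  x <- dplyr::pull(data, {{ distance }})
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  if (n < 8) hzc_abort("need at least 8 observations for a 4-parameter fit",
                       "hzc_insufficient_data_error")
  if (any(x < 0)) hzc_abort("distances must be >= 0", "hzc_domain_error")
  if (stats::var(y) < 1e-20) hzc_abort("response is constant; data are not clinal",
                                       "hzc_non_clinal_error")
  xs <- x + x_offset
  lx <- log(xs)

  obj <- function(par) {
    pr <- profile_cd(par[1], par[2], lx, y)
    pr$sse
  }

  # initial E: x where y is closest to the midpoint of the 10th/90th percentiles
  q <- stats::quantile(y, c(0.1, 0.9), names = FALSE)
  mid <- (q[1] + q[2]) / 2
  E0 <- xs[which.min(abs(y - mid))]
  if (E0 <= 0) E0 <- stats::median(xs)

  start_list <- lapply(starts, function(b0) c(b0, log(E0)))
  if (!is.null(init)) {
    init <- unname(unlist(init))
    start_list <- c(list(c(init[3], log(max(init[4], 1e-6)))), start_list)
  }

  best <- NULL
  for (st in start_list) {
    o <- tryCatch(
      stats::optim(st, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 2000)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-12 * (1 + abs(best$value)) ||
        (abs(o$value - best$value) <= 1e-12 * (1 + abs(best$value)) &&
         abs(o$par[1]) < abs(best$par[1]))) {
      best <- o
    }
  }
  if (is.null(best)) hzc_abort("all optimiser starts failed", "hzc_fit_error")

  pr <- profile_cd(best$par[1], best$par[2], lx, y)
  pars <- c(C = pr$C, D = pr$D, B = best$par[1], E = exp(best$par[2]))

  # Levenberg-Marquardt polish on all four parameters
  polished <- if (!polish) NULL else tryCatch({
    df <- data.frame(lx = lx, y = y)
    fit <- minpack.lm::nlsLM(
      y ~ C + (D - C) / (1 + exp(B * (lx - logE))),
      data = df,
      start = list(C = pars[["C"]], D = pars[["D"]], B = pars[["B"]],
                   logE = log(pars[["E"]])),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))
    cf <- stats::coef(fit)
    list(pars = c(C = unname(cf["C"]), D = unname(cf["D"]), B = unname(cf["B"]),
                  E = exp(unname(cf["logE"]))),
         sse = sum(stats::resid(fit)^2))
  }, error = function(e) NULL)
  sse <- pr$sse
  if (!is.null(polished) && is.finite(polished$sse) && polished$sse <= sse) {
    pars <- polished$pars
    sse <- polished$sse
  }

  # the 4PL is invariant under (C, D, B) -> (D, C, -B); report the canonical
  # orientation with D as the upper plateau
  if (pars[["C"]] > pars[["D"]]) {
    pars <- c(C = unname(pars[["D"]]), D = unname(pars[["C"]]),
              B = -unname(pars[["B"]]), E = unname(pars[["E"]]))
  }

  converged <- is.finite(sse) && pars[["E"]] > 0 &&
    pars[["E"]] < 10 * domain_end_km && abs(pars[["B"]]) > 0

  fit <- structure(
    list(params = pars, sse = sse, n = n, converged = converged,
         x_offset = x_offset, domain_end_km = domain_end_km,
         trait = trait, period = period,
         data = tibble(distance_km = x, value = y)),
    class = "hzc_cline")
  fit$center_km <- cline_center(fit)
  fit$width_km <- if (converged) cline_width(fit) else NA_real_
  fit
}

#' Effective dose of a fitted cline
#'
#' `EDp` is the distance at which the fitted response has traversed `p`
#' percent of the span between the two asymptotes:
#' `EDp = E * (p / (100 - p))^(1/|B|)` (offset scale), so `ED50 = E` and
#' `ED10 < ED50 < ED90` for every valid fit. Values are reported on the
#' original distance scale (the fitting offset is subtracted).
#'
#' @param fit A converged `hzc_cline`.
#' @param p Percent(s) in (0, 100).
#' @return Distances in km (original scale), same length as `p`.
#' @export
effective_dose <- function(fit, p) {
  stopifnot(inherits(fit, "hzc_cline"))
  if (any(p <= 0 | p >= 100)) hzc_abort("p must lie in (0, 100)", "hzc_domain_error")
  B <- fit$params[["B"]]
  if (!is.finite(B) || B == 0) hzc_abort("effective dose undefined for B = 0",
                                         "hzc_undefined_ed_error")
  fit$params[["E"]] * (p / (100 - p))^(1 / abs(B)) - fit$x_offset
}

#' Cline center (ED50)
#' @param fit A converged `hzc_cline`.
#' @return Center in km on the original distance scale.
#' @export
cline_center <- function(fit) {
  stopifnot(inherits(fit, "hzc_cline"))
  fit$params[["E"]] - fit$x_offset
}

#' Cline width (ED90 - ED10)
#'
#' `width = E * (9^(1/|B|) - 9^(-1/|B|))`, the span of transect over which
#' the response moves from 10% to 90% of the distance between asymptotes;
#' beyond it essentially only parental phenotypes occur.
#'
#' @param fit A converged `hzc_cline`.
#' @return Width in km (> 0 for finite nonzero `B`).
#' @export
cline_width <- function(fit) {
  ed <- effective_dose(fit, c(10, 90))
  ed[2] - ed[1]
}

#' @export
print.hzc_cline <- function(x, ...) {
  cat("Hill-function cline fit",
      if (!is.null(x$trait)) paste0(" [", x$trait,
                                    if (!is.null(x$period)) paste0(", ", x$period),
                                    "]"), "\n", sep = "")
  cat(sprintf("  C = %.4g  D = %.4g  B = %.4g  E = %.4g km\n",
              x$params[["C"]], x$params[["D"]], x$params[["B"]], x$params[["E"]]))
  cat(sprintf("  center = %.2f km, width = %.2f km, SSE = %.4g, n = %d, converged: %s\n",
              x$center_km, x$width_km, x$sse, x$n, x$converged))
  invisible(x)
}

#' @rdname fit_hill
#' @param x A `hzc_cline` object.
#' @param ... Unused.
#' @export
tidy.hzc_cline <- function(x, ...) {
  tibble(term = c("C", "D", "B", "E"), estimate = unname(x$params))
}

#' @rdname fit_hill
#' @export
glance.hzc_cline <- function(x, ...) {
  tibble(trait = x$trait %||% NA_character_, period = x$period %||% NA_character_,
         center_km = x$center_km, width_km = x$width_km, sse = x$sse, n = x$n,
         converged = x$converged)
}

#' @rdname fit_hill
#' @param object A `hzc_cline` object.
#' @export
autoplot.hzc_cline <- function(object, ...) {
  grid <- tibble(distance_km = seq(min(object$data$distance_km),
                                   max(object$data$distance_km), length.out = 200))
  grid$value <- hill_predict(object$params, grid$distance_km + object$x_offset)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$distance_km, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$center_km, linetype = 2) +
    ggplot2::labs(x = "Distance along transect (km)",
                  y = object$trait %||% "trait value",
                  title = paste0("Cline fit",
                                 if (!is.null(object$period))
                                   paste0(" (", object$period, ")"))) +
    ggplot2::theme_minimal()
}

#' Serialise a cline fit to a JSON record
#'
#' @param fit A `hzc_cline`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
cline_to_json <- function(fit, path = NULL) {
  rec <- list(trait = fit$trait, period = fit$period,
              C = fit$params[["C"]], D = fit$params[["D"]],
              B = fit$params[["B"]], E = fit$params[["E"]],
              center_km = fit$center_km, width_km = fit$width_km,
              sse = fit$sse, n = fit$n, converged = fit$converged)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
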