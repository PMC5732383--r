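#' Default end-to-end run configuration
#'
#' Settings for [run_pipeline()]: either a simulation config (default) or
#' paths to real input files, plus sector bounds, traits to fit, bootstrap,
#' AMOVA and diffusion settings. Problem sizes default to values that keep a
#' full run fast while leaving every stage statistically meaningful.
#'
#' @param sim A [sim_config()], or `NULL` when real inputs are supplied.
#' @param specimens,spectra,sequences Paths to input files (`sequences` is a
#'   named list of FASTA paths keyed by period); ignored when `sim` is given.
#' @param traits Traits to fit clines for (`"PC1"`, `"chroma"`).
#' @param sector_bounds,domain_end_km Sector geometry in km.
#' @param bootstrap_reps,bootstrap_bounds Bootstrap settings.
#' @param n_perm AMOVA permutations.
#' @param trim Optional `c(start, end)` region applied to sequences before
#'   AMOVA.
#' @param diffusion List with `sigma_km`, `generation_time_yr`, `age_yr`.
#' @return A list of class `hzc_run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       specimens = NULL, spectra = NULL, sequences = NULL,
                       traits = c("PC1", "chroma"),
                       sector_bounds = c(45, 90), domain_end_km = 135,
                       bootstrap_reps = 200, bootstrap_bounds = c(0, 140),
                       n_perm = 999, trim = NULL,
                       diffusion = list(sigma_km = c(1, 20),
                                        generation_time_yr = c(1, 2),
                                        age_yr = 6000)) {
  structure(list(sim = sim, specimens = specimens, spectra = spectra,
                 sequences = sequences, traits = traits,
                 sector_bounds = sector_bounds, domain_end_km = domain_end_km,
                 bootstrap_reps = bootstrap_reps,
                 bootstrap_bounds = bootstrap_bounds,
                 n_perm = n_perm, trim = trim, diffusion = diffusion),
            class = "hzc_run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields override the [run_config()] defaults; the `sim` block (if
#' present) overrides [sim_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `hzc_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$n_per_period)) {
    sim_args$n_per_period <- unlist(sim_args$n_per_period)
  }
  sim <- if (identical(y$simulate, FALSE)) NULL else do.call(sim_config, sim_args)
  args <- y[setdiff(names(y), c("sim", "simulate"))]
  do.call(run_config, c(list(sim = sim), args))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load inputs),
#' transect fit and projection, phenotypes (PCA per sex plus colour metrics),
#' Hill cline fits per trait and period, filtered bootstrap, cross-period
#' comparisons, AMOVA per period with sequences, and the neutral-diffusion
#' width report — writing plain-text outputs (CSV/JSON) and a run manifest
#' (stage status, seeds, input/output MD5 hashes, package version; no
#' timestamps, so identical seeds give byte-identical bundles). A failing
#' stage leaves completed outputs intact, is recorded in the manifest, and
#' raises an error naming the stage. Missing spectra simply skip the chroma
#' stages with an explicit skip record.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param seed Master seed (mandatory); every stochastic stage derives its
#'   own substream from it.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir, seed) {
  if (missing(seed)) hzc_abort("seed is required", "hzc_seed_error")
  stopifnot(inherits(config, "hzc_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, package_version = as.character(
    utils::packageVersion("hzclines")), stages = list())
  results <- list()
  failed <- NULL

  run_stage <- function(name, fun) {
    if (!is.null(failed)) return(NULL)
    res <- tryCatch(fun(), error = function(e) {
      failed <<- list(stage = name, message = conditionMessage(e))
      NULL
    })
    manifest$stages[[name]] <<- if (is.null(failed)) list(status = "ok")
      else list(status = "failed", message = failed$message)
    res
  }

  # ---- inputs ----
  inputs <- run_stage("inputs", function() {
    if (!is.null(config$sim)) {
      sim_dir <- file.path(out_dir, "inputs")
      sim <- simulate_hybrid_zone(config$sim, sim_dir, seed = derive_seed(seed, 1))
      list(specimens = read_specimen_table(sim$paths$specimens),
           spectra = readr::read_csv(sim$paths$spectra, show_col_types = FALSE,
                                     progress = FALSE),
           sequences = lapply(
             sim$paths[grep("^seqs_", names(sim$paths))],
             read_fasta),
           truth = sim$truth)
    } else {
      list(
        specimens = read_specimen_table(config$specimens),
        spectra = if (!is.null(config$spectra))
          readr::read_csv(config$spectra, show_col_types = FALSE,
                          progress = FALSE) else NULL,
        sequences = if (!is.null(config$sequences))
          lapply(config$sequences, read_fasta) else NULL,
        truth = NULL)
    }
  })

  # ---- transect ----
  positions <- run_stage("transect", function() {
    model <- fit_transect(inputs$specimens)
    pos <- project_onto_transect(model, inputs$specimens,
                                 sector_bounds = config$sector_bounds,
                                 domain_end_km = config$domain_end_km)
    readr::write_csv(pos, file.path(out_dir, "positions.csv"))
    results$transect_model <<- model
    pos
  })

  # ---- phenotypes ----
  analysis <- run_stage("phenotypes", function() {
    complete <- complete_case_filter(inputs$specimens)
    pca <- compute_pca(complete, sex = "male")
    colors <- if (!is.null(inputs$spectra)) color_metrics(inputs$spectra) else NULL
    tab <- attach_phenotypes(positions, inputs$specimens, pca = pca,
                             colors = colors)
    readr::write_csv(tab, file.path(out_dir, "analysis_table.csv"))
    results$pca <<- pca
    tab
  })

  # ---- clines + bootstrap per trait and period ----
  boots <- run_stage("clines", function() {
    trait_cols <- c(PC1 = "PC1", chroma = "chroma")
    out <- list()
    skip <- list()
    fits <- list()
    ti <- 0
    for (trait in config$traits) {
      ti <- ti + 1
      col <- trait_cols[[trait]]
      if (all(is.na(analysis[[col]]))) {
        skip[[trait]] <- paste0("no ", trait, " data; stage skipped")
        next
      }
      periods <- setdiff(sort(unique(analysis$period)), "unassigned")
      for (pj in seq_along(periods)) {
        p <- periods[pj]
        dat <- analysis |>
          dplyr::filter(.data$period == p, .data$sex == "male",
                        !is.na(.data[[col]]))
        if (nrow(dat) < 8) {
          skip[[paste(trait, p, sep = "_")]] <- "fewer than 8 male specimens"
          next
        }
        fit <- fit_hill(dat, response = col, distance = distance_km,
                        domain_end_km = config$domain_end_km,
                        trait = trait, period = p)
        cline_to_json(fit, file.path(out_dir,
                                     sprintf("cline_%s_%s.json", trait, p)))
        bt <- bootstrap_cline(dat, response = col, distance = distance_km,
                              reps = config$bootstrap_reps,
                              bounds = config$bootstrap_bounds,
                              seed = derive_seed(seed, 1000 + 10 * ti + pj),
                              domain_end_km = config$domain_end_km,
                              trait = trait, period = p, point_fit = fit)
        readr::write_csv(bt$replicates,
                         file.path(out_dir,
                                   sprintf("bootstrap_%s_%s.csv", trait, p)))
        out[[trait]][[p]] <- bt
        fits[[trait]][[p]] <- fit
      }
    }
    if (length(skip) > 0) write_json_out(skip, file.path(out_dir, "skipped.json"))
    results$fits <<- fits
    out
  })

  # ---- comparisons ----
  run_stage("compare", function() {
    cmp <- list()
    for (trait in names(boots)) {
      if (length(boots[[trait]]) == 0) next
      mv <- summarize_movement(boots[[trait]])
      cmp[[trait]] <- list(
        summary = mv$summary, pairwise = mv$pairwise,
        anova = mv$anova, tukey = mv$tukey)
      results$movement[[trait]] <<- mv
    }
    write_json_out(cmp, file.path(out_dir, "comparisons.json"))
    cmp
  })

  # ---- AMOVA ----
  run_stage("amova", function() {
    if (is.null(inputs$sequences) || length(inputs$sequences) == 0) {
      write_json_out(list(skipped = "no sequence data"),
                     file.path(out_dir, "amova.json"))
      return(NULL)
    }
    res <- list()
    k <- 0
    for (nm in names(inputs$sequences)) {
      k <- k + 1
      seqs <- inputs$sequences[[nm]]
      if (!is.null(config$trim)) {
        seqs <- trim_to_region(seqs, config$trim[1], config$trim[2])
      }
      period <- sub("^seqs_", "", nm)
      am <- amova_from_positions(seqs, positions,
                                 period = if (period %in% positions$period)
                                   period else NULL,
                                 n_perm = config$n_perm,
                                 seed = derive_seed(seed, 2000 + k))
      res[[period]] <- list(table = tidy(am), summary = glance(am),
                            haplotypes = haplotype_summary(seqs))
      results$amova[[period]] <<- am
    }
    write_json_out(res, file.path(out_dir, "amova.json"))
    res
  })

  # ---- diffusion ----
  run_stage("diffusion", function() {
    dcfg <- config$diffusion
    env <- width_envelope(dcfg$sigma_km, dcfg$generation_time_yr, dcfg$age_yr)
    fitted_widths <- purrr::map_dfr(results$fits, function(byp)
      purrr::map_dfr(byp, glance))
    rep <- list(envelope = env,
                fitted = if (nrow(fitted_widths) > 0)
                  fitted_widths[, c("trait", "period", "width_km")] else NULL,
                narrower_than_neutral = if (nrow(fitted_widths) > 0)
                  all(fitted_widths$width_km < env$min_km, na.rm = TRUE)
                else NA)
    write_json_out(rep, file.path(out_dir, "diffusion.json"))
    rep
  })

  # ---- manifest ----
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest$outputs <- as.list(tools::md5sum(file.path(out_dir, files)) |>
                                stats::setNames(files))
  write_json_out(manifest, file.path(out_dir, "manifest.json"))

  if (!is.null(failed)) {
    hzc_abort(paste0("pipeline stage '", failed$stage, "' failed: ",
                     failed$message), "hzc_pipeline_error")
  }
  invisible(list(results = results, manifest = manifest, positions = positions,
                 analysis = analysis, bootstraps = boots))
}
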