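#' Read and validate a specimen table
#'
#' Loads a CSV of museum-specimen records. Required columns are `id`,
#' `latitude`, `longitude` and `year`; optional columns are `sex`, the six
#' morphometric characters in mm (`wing_mm`, `culmen_mm`, `bill_depth_mm`,
#' `bill_width_mm`, `tail_mm`, `tarsus_mm`), `spectrum_id` and `sequence_id`.
#' Rows violating the record invariants (latitude outside \[-90, 90\],
#' longitude outside \[-180, 180\], year before 1800, non-positive
#' morphometric values, unparseable numbers) are dropped and reported.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the column names actually present in the file (values),
#'   e.g. `c(latitude = "lat")`.
#' @return A tibble of validated specimen records with canonical column
#'   names, one row per accepted specimen. Attribute `rejected` holds a
#'   tibble describing every dropped row and the violated rule.
#' @export
read_specimen_table <- function(path, schema = NULL) {
  if (!file.exists(path)) hzc_abort(paste0("file not found: ", path), "hzc_io_error")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  validate_specimens(raw, schema = schema)
}

#' Validate an in-memory specimen table
#'
#' Same contract as [read_specimen_table()] but starting from a data frame,
#' so simulated tables can be pushed through the identical validation path.
#'
#' @inheritParams read_specimen_table
#' @param data A data frame of specimen records (columns may be character).
#' @return A validated tibble; see [read_specimen_table()].
#' @export
validate_specimens <- function(data, schema = NULL) {
  morph_cols <- c("wing_mm", "culmen_mm", "bill_depth_mm", "bill_width_mm",
                  "tail_mm", "tarsus_mm")
  required <- c("id", "latitude", "longitude", "year")
  optional <- c("sex", morph_cols, "spectrum_id", "sequence_id")

  data <- tibble::as_tibble(data)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(data)) {
        hzc_abort(paste0("schema maps '", canon, "' to missing column '",
                         schema[[canon]], "'"), "hzc_schema_error")
      }
      names(data)[names(data) == schema[[canon]]] <- canon
    }
  }
  missing_req <- setdiff(required, names(data))
  if (length(missing_req) > 0) {
    hzc_abort(paste0("missing required column(s): ",
                     paste(missing_req, collapse = ", ")), "hzc_schema_error")
  }
  for (col in setdiff(optional, names(data))) data[[col]] <- NA_character_
  data <- data[, c(required, optional)]

  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  out <- data |>
    mutate(
      id = as.character(.data$id),
      latitude = num_or_na(.data$latitude),
      longitude = num_or_na(.data$longitude),
      year = num_or_na(.data$year),
      sex = dplyr::case_when(
        tolower(as.character(.data$sex)) %in% c("m", "male") ~ "male",
        tolower(as.character(.data$sex)) %in% c("f", "female") ~ "female",
        TRUE ~ "unknown"
      ),
      across(all_of(morph_cols), num_or_na),
      spectrum_id = as.character(.data$spectrum_id),
      sequence_id = as.character(.data$sequence_id)
    )

  dup <- unique(out$id[duplicated(out$id)])
  if (length(dup) > 0) {
    hzc_abort(paste0("duplicate specimen id(s): ", paste(dup, collapse = ", ")),
              "hzc_duplicate_id_error")
  }

  reason <- rep(NA_character_, nrow(out))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(out$latitude), "unparseable latitude")
  reason <- bad(is.na(out$longitude), "unparseable longitude")
  reason <- bad(is.na(out$year), "unparseable year")
  reason <- bad(!is.na(out$latitude) & abs(out$latitude) > 90,
                "latitude outside [-90, 90]")
  reason <- bad(!is.na(out$longitude) & abs(out$longitude) > 180,
                "longitude outside [-180, 180]")
  reason <- bad(!is.na(out$year) & out$year < 1800, "year before 1800")
  morph_bad <- Reduce(`|`, lapply(morph_cols, function(cc) {
    !is.na(out[[cc]]) & out[[cc]] <= 0
  }))
  reason <- bad(morph_bad, "non-positive morphometric value")

  rejected <- tibble(id = out$id[!is.na(reason)], reason = reason[!is.na(reason)])
  if (nrow(rejected) > 0) {
    rlang::warn(paste0(nrow(rejected), " specimen row(s) rejected; ",
                       "see attr(., 'rejected')"))
  }
  res <- out[is.na(reason), , drop = FALSE]
  res$year <- as.integer(res$year)
  attr(res, "rejected") <- rejected
  res
}

#' Fit the study transect line to specimen localities
#'
#' Ordinary least-squares regression of latitude on longitude (decimal
#' degrees) defines the transect; coordinates are mapped to planar km with an
#' equirectangular projection about the mean latitude (1 degree latitude =
#' 111.32 km, 1 degree longitude = 111.32 * cos(mean latitude) km). The
#' origin (distance 0) is the perpendicular foot of the most-northwest
#' specimen, and the along-line unit direction points southeast/inland so all
#' specimen distances are non-negative.
#'
#' @param records Specimen tibble with `latitude` and `longitude` columns
#'   (e.g. from [read_specimen_table()]).
#' @return An object of class `hzc_transect`: slope/intercept of the
#'   degree-scale regression, planar scale factors, origin, and unit
#'   direction in km coordinates.
#' @export
fit_transect <- function(records) {
  lat <- records$latitude
  lon <- records$longitude
  keep <- !is.na(lat) & !is.na(lon)
  lat <- lat[keep]; lon <- lon[keep]
  if (length(lat) < 2 || nrow(unique(cbind(lat, lon))) < 2) {
    hzc_abort("need at least 2 distinct coordinates to fit a transect",
              "hzc_degenerate_geometry_error")
  }
  if (stats::var(lon) < 1e-12) {
    hzc_abort(paste0("longitude variance is ~0 (near-vertical point cloud); ",
                     "regress longitude on latitude instead (swap axes)"),
              "hzc_degenerate_geometry_error")
  }
  fit <- stats::lm(lat ~ lon)
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])

  mean_lat <- mean(lat)
  kx <- .KM_PER_DEG * cos(mean_lat * pi / 180)  # km per degree longitude
  ky <- .KM_PER_DEG                             # km per degree latitude

  # direction along the line in planar km, oriented eastward (NW -> SE)
  u <- c(kx, slope * ky)
  u <- u / sqrt(sum(u^2))

  # planar coordinates of specimen points and their along-line coordinate
  px <- kx * lon
  py <- ky * lat
  # reference point on the line at lon = 0 -> lat = intercept
  p0 <- c(0, ky * intercept)
  s <- (px - p0[1]) * u[1] + (py - p0[2]) * u[2]
  s_min <- min(s)
  origin <- p0 + s_min * u  # foot of the most-northwest specimen

  structure(
    list(slope = slope, intercept = intercept, mean_lat = mean_lat,
         km_per_deg_lon = kx, km_per_deg_lat = ky,
         origin = origin, direction = u, n = length(lat)),
    class = "hzc_transect"
  )
}

#' @export
print.hzc_transect <- function(x, ...) {
  cat("Transect line: lat =", format(x$intercept, digits = 6), "+",
      format(x$slope, digits = 6), "* lon\n")
  cat("Planar scale:", format(x$km_per_deg_lon, digits = 5),
      "km/deg lon,", format(x$km_per_deg_lat, digits = 5), "km/deg lat\n")
  cat("Origin (km):", format(x$origin, digits = 6),
      " direction:", format(x$direction, digits = 4), "\n")
  invisible(x)
}

#' Project specimens onto a fitted transect
#'
#' Each specimen is mapped to its perpendicular foot on the transect line;
#' `distance_km` is the along-line distance from the northwest origin and
#' `offset_km` the signed perpendicular distance (positive to the left of the
#' direction of travel). Sector and period labels are attached via
#' [assign_sector()] and [assign_period()], and localities are clustered with
#' [cluster_localities()].
#'
#' @param model A fitted `hzc_transect`.
#' @param records Specimen tibble with `id`, `latitude`, `longitude`, and
#'   optionally `year`.
#' @param sector_bounds Sector breakpoints in km, default `c(45, 90)` with
#'   domain end 135; see [assign_sector()].
#' @param domain_end_km End of the sector domain in km (default 135).
#' @param locality_radius_km Single-linkage threshold for locality grouping.
#' @return Tibble with `id`, `distance_km`, `offset_km`, `sector`,
#'   `locality_id`, `period`.
#' @export
project_onto_transect <- function(model, records, sector_bounds = c(45, 90),
                                  domain_end_km = 135, locality_radius_km = 1) {
  stopifnot(inherits(model, "hzc_transect"))
  px <- model$km_per_deg_lon * records$longitude
  py <- model$km_per_deg_lat * records$latitude
  dx <- px - model$origin[1]
  dy <- py - model$origin[2]
  u <- model$direction
  nvec <- c(-u[2], u[1])
  dist <- dx * u[1] + dy * u[2]
  # the origin specimen can land at -1e-15 by rounding; clamp true zeros
  dist[dist < 0 & dist > -1e-9] <- 0
  off <- dx * nvec[1] + dy * nvec[2]
  year <- if ("year" %in% names(records)) records$year else rep(NA_integer_, nrow(records))
  pos <- tibble(
    id = as.character(records$id),
    distance_km = dist,
    offset_km = off,
    sector = assign_sector(pmax(dist, 0), bounds = sector_bounds,
                           domain_end_km = domain_end_km),
    period = assign_period(year)
  )
  pos$locality_id <- cluster_localities(pos, radius_km = locality_radius_km)
  pos[, c("id", "distance_km", "offset_km", "sector", "locality_id", "period")]
}

#' Assign transect sectors from along-transect distance
#'
#' Sectors divide the transect into three equal-length stretches; with the
#' default bounds these are the half-open intervals \[0, 45), \[45, 90) and
#' \[90, 135\] km. Distances beyond the domain end get sector `NA` ("none").
#'
#' @param distance_km Numeric vector of non-negative distances in km.
#' @param bounds Ordered interior breakpoints in km (default `c(45, 90)`).
#' @param domain_end_km Closed end of the last sector (default 135).
#' @return Integer vector of sector indices (1-based), `NA` outside the domain.
#' @export
assign_sector <- function(distance_km, bounds = c(45, 90), domain_end_km = 135) {
  if (any(distance_km < 0, na.rm = TRUE)) {
    hzc_abort("negative distance passed to assign_sector()", "hzc_domain_error")
  }
  stopifnot(all(diff(c(0, bounds, domain_end_km)) > 0))
  breaks <- c(0, bounds, domain_end_km)
  sec <- findInterval(distance_km, breaks, rightmost.closed = TRUE)
  sec[distance_km > domain_end_km | is.na(distance_km)] <- NA_integer_
  as.integer(sec)
}

#' Assign collection periods from calendar year
#'
#' The three study periods reflect gaps in specimen collecting: everything up
#' to 1911, the 1956-1986 series, and the modern 2007-2010 series (labelled
#' "2010"). Years in the gaps are `"unassigned"` and are excluded from cline
#' analyses but retained in tables.
#'
#' @param year Integer vector of collection years.
#' @return Character vector with levels `P1911`, `P1956`, `P2010`,
#'   `unassigned`.
#' @export
assign_period <- function(year) {
  dplyr::case_when(
    is.na(year) ~ "unassigned",
    year <= 1911 ~ "P1911",
    year >= 1956 & year <= 1986 ~ "P1956",
    year >= 2007 & year <= 2010 ~ "P2010",
    TRUE ~ "unassigned"
  )
}

#' Group specimens into point localities
#'
#' Specimens collected within `radius_km` of each other belong to one
#' locality. Grouping is single-linkage clustering on planar distance, i.e.
#' the connected components of the graph joining pairs at most `radius_km`
#' apart (chains merge). Locality ids are stable under input order: they are
#' numbered by each cluster's minimum along-transect distance, ties broken by
#' smallest specimen id.
#'
#' @param positions Tibble with `distance_km` and `offset_km` (planar
#'   coordinates relative to the transect) and `id`.
#' @param radius_km Linkage threshold in km (default 1).
#' @return Integer vector of locality ids aligned with `positions` rows.
#' @export
cluster_localities <- function(positions, radius_km = 1) {
  n <- nrow(positions)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  pts <- cbind(positions$distance_km, positions$offset_km)
  d <- stats::dist(pts)
  cl <- stats::cutree(stats::hclust(d, method = "single"), h = radius_km)
  # renumber clusters by minimum member distance, ties by minimum id
  k <- max(cl)
  mind <- vapply(seq_len(k), function(g) min(positions$distance_km[cl == g]), numeric(1))
  minid <- vapply(seq_len(k), function(g) min(as.character(positions$id)[cl == g]),
                  character(1))
  new_id <- integer(k)
  new_id[order(mind, minid)] <- seq_len(k)
  new_id[cl]
}

#' Read an aligned FASTA file of haplotype sequences
#'
#' Sequences are normalised to uppercase and must contain only
#' `A, C, G, T, N, -`. Headers (up to the first whitespace) are the sequence
#' ids and must be unique. Equal lengths are not required at read time;
#' alignment length is checked by downstream analyses.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id`, `sequence` (uppercase), `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) hzc_abort(paste0("file not found: ", path), "hzc_io_error")
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    hzc_abort(paste0("duplicate FASTA header(s): ", paste(dup, collapse = ", ")),
              "hzc_duplicate_id_error")
  }
  seqs <- toupper(as.character(ss))
  bad <- stringr::str_locate(seqs, "[^ACGTN-]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    hzc_abort(paste0("illegal character in sequence '", ids[i],
                     "' at position ", bad[i]), "hzc_sequence_error")
  }
  tibble(id = ids, sequence = unname(seqs), length = nchar(seqs))
}
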