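#' Trim aligned sequences to a common region
#'
#' Cuts every sequence to the 1-based inclusive window `[start, end]`, e.g.
#' trimming long modern cytochrome-b sequences down to the ~210 bp region
#' recoverable from historical toepad samples so periods are comparable.
#'
#' @param seqs Tibble from [read_fasta()] (columns `id`, `sequence`) or a
#'   named character vector.
#' @param start,end 1-based inclusive coordinates within every sequence.
#' @return Tibble `id`, `sequence`, `length` with all lengths
#'   `end - start + 1`.
#' @export
trim_to_region <- function(seqs, start, end) {
  seqs <- as_sequence_tbl(seqs)
  if (end < start || start < 1) hzc_abort("invalid region coordinates",
                                          "hzc_coordinate_error")
  if (any(nchar(seqs$sequence) < end)) {
    hzc_abort("region extends beyond at least one sequence", "hzc_coordinate_error")
  }
  seqs$sequence <- substr(seqs$sequence, start, end)
  seqs$length <- nchar(seqs$sequence)
  seqs
}

as_sequence_tbl <- function(seqs) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) hzc_abort("sequences must be named",
                                        "hzc_sequence_error")
    seqs <- tibble(id = names(seqs), sequence = toupper(unname(seqs)),
                   length = nchar(seqs))
  }
  tibble::as_tibble(seqs)
}

check_alignment <- function(seqs) {
  if (nrow(seqs) < 2) hzc_abort("need >= 2 sequences", "hzc_insufficient_data_error")
  if (length(unique(nchar(seqs$sequence))) != 1) {
    hzc_abort("sequences are not aligned (unequal lengths)", "hzc_alignment_error")
  }
  invisible(seqs)
}

# alignment as a character matrix, one row per sequence
aln_matrix <- function(seqs) {
  seqs <- as_sequence_tbl(seqs)
  check_alignment(seqs)
  do.call(rbind, strsplit(toupper(seqs$sequence), ""))
}

#' Haplotype and polymorphism summary of an alignment
#'
#' Haplotypes are distinct sequences under exact string equality (after
#' uppercase normalisation). Segregating sites are alignment columns with at
#' least two observed unambiguous nucleotide states (`N` and `-` ignored).
#' Mean p-distance is the average pairwise proportion of differing sites,
#' with pairwise deletion of sites that are ambiguous in either sequence.
#'
#' @param seqs Aligned sequences (tibble from [read_fasta()] or named
#'   character vector).
#' @return One-row tibble: `n_sequences`, `n_haplotypes`,
#'   `segregating_sites`, `mean_p_distance`.
#' @export
haplotype_summary <- function(seqs) {
  seqs <- as_sequence_tbl(seqs)
  m <- aln_matrix(seqs)
  n_hap <- length(unique(seqs$sequence))
  seg <- sum(apply(m, 2, function(col) {
    states <- unique(col[col %in% c("A", "C", "G", "T")])
    length(states) >= 2
  }))
  n <- nrow(m)
  dsum <- 0; npair <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
      if (sum(ok) == 0) next
      dsum <- dsum + mean(m[i, ok] != m[j, ok])
      npair <- npair + 1
    }
  }
  tibble(n_sequences = n, n_haplotypes = n_hap, segregating_sites = seg,
         mean_p_distance = if (npair > 0) dsum / npair else NA_real_)
}

#' Pairwise nucleotide-difference matrix
#'
#' Entry (i, j) counts the sites at which sequences i and j differ, after
#' pairwise deletion of sites where either sequence has `N` or a gap. These
#' counts are the squared-distance input to [amova()].
#'
#' @inheritParams haplotype_summary
#' @return Symmetric numeric matrix with zero diagonal, dimnames = sequence
#'   ids.
#' @export
pairwise_diff_matrix <- function(seqs) {
  seqs <- as_sequence_tbl(seqs)
  m <- aln_matrix(seqs)
  n <- nrow(m)
  valid <- m == "A" | m == "C" | m == "G" | m == "T"
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok])
    }
  }
  d
}

# sums of squared deviations for a partition, from a squared-distance matrix:
# SSD(group g) = (1 / n_g) * sum_{i<j in g} d_ij
ssd_within <- function(d, groups) {
  tot <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) tot <- tot + sum(d[idx, idx]) / (2 * length(idx))
  }
  tot
}

# core three-level decomposition; returns variance components and F-statistics
amova_components <- function(d, sectors, localities) {
  N <- nrow(d)
  pop <- paste(sectors, localities, sep = "//")
  pops <- unique(pop)
  grp_of_pop <- sectors[match(pops, pop)]
  P <- length(pops)
  G <- length(unique(sectors))

  ssd_total <- sum(d) / (2 * N)
  ssd_wp <- ssd_within(d, pop)
  ssd_wg <- ssd_within(d, sectors)
  ssd_ap_wg <- ssd_wg - ssd_wp         # among populations within groups
  ssd_ag <- ssd_total - ssd_wg         # among groups

  df_ag <- G - 1
  df_ap <- P - G
  df_wp <- N - P

  n_p <- as.numeric(table(pop)[pops])
  n_g <- as.numeric(tapply(seq_len(N), sectors, length)[as.character(unique(sectors))])
  names(n_g) <- as.character(unique(sectors))
  sum_np2_by_g <- vapply(unique(sectors), function(g) {
    sum(n_p[grp_of_pop == g]^2) / sum(n_p[grp_of_pop == g])
  }, numeric(1))

  # unequal-n coefficients of the expected mean squares
  n_coef <- if (df_ap > 0) (N - sum(sum_np2_by_g)) / df_ap else NA_real_
  n1_coef <- if (df_ag > 0) (sum(sum_np2_by_g) - sum(n_p^2) / N) / df_ag else NA_real_
  n2_coef <- if (df_ag > 0) (N - sum(tapply(seq_len(N), sectors, length)^2) / N) / df_ag
             else NA_real_

  ms_wp <- if (df_wp > 0) ssd_wp / df_wp else NA_real_
  ms_ap <- if (df_ap > 0) ssd_ap_wg / df_ap else NA_real_
  ms_ag <- if (df_ag > 0) ssd_ag / df_ag else NA_real_

  sigma_c <- ms_wp
  sigma_b <- if (df_ap > 0) (ms_ap - sigma_c) / n_coef else NA_real_
  sigma_a <- if (df_ag > 0) {
    (ms_ag - sigma_c - n1_coef * ifelse(is.na(sigma_b), 0, sigma_b)) / n2_coef
  } else NA_real_

  total <- sum(c(sigma_a, sigma_b, sigma_c), na.rm = TRUE)
  list(
    ssd = c(total = ssd_total, among_sectors = ssd_ag,
            among_localities_within = ssd_ap_wg, within_localities = ssd_wp),
    df = c(among_sectors = df_ag, among_localities_within = df_ap,
           within_localities = df_wp),
    sigma = c(a = sigma_a, b = sigma_b, c = sigma_c),
    total_variance = total,
    F_CT = if (total > 0) sigma_a / total else NA_real_,
    F_SC = if (!is.na(sigma_b) && (sigma_b + sigma_c) > 0)
             sigma_b / (sigma_b + sigma_c) else NA_real_,
    F_ST = if (total > 0) (sigma_a + ifelse(is.na(sigma_b), 0, sigma_b)) / total
           else NA_real_
  )
}

#' Three-level analysis of molecular variance (AMOVA)
#'
#' Decomposes molecular variance among sectors, among localities within
#' sectors, and within localities, from a matrix of pairwise squared
#' distances (here: nucleotide difference counts). Variance components use
#' the standard unequal-sample-size mean-square equations; components may be
#' negative and are reported as computed. F-statistics:
#' `F_CT = sigma_a / total`, `F_SC = sigma_b / (sigma_b + sigma_c)`,
#' `F_ST = (sigma_a + sigma_b) / total`.
#'
#' Permutation nulls follow the conventional three schemes: `F_ST` permutes
#' individuals across all localities; `F_SC` permutes individuals among
#' localities within their sector; `F_CT` permutes whole localities among
#' sectors. P-values include the observed statistic in the null set, so they
#' are never 0. Monomorphic data return missing F-statistics with a
#' `monomorphic` flag.
#'
#' @param d Symmetric matrix of pairwise difference counts
#'   (see [pairwise_diff_matrix()]).
#' @param sectors Sector label per individual (rows of `d`).
#' @param localities Locality label per individual.
#' @param n_perm Number of permutations per statistic (default 10000).
#' @param seed Seed for the permutation RNG (mandatory when `n_perm > 0`).
#' @return Object of class `hzc_amova`: variance components, percent
#'   variation, F-statistics with permutation P-values, df and SSD tables.
#' @export
amova <- function(d, sectors, localities, n_perm = 10000, seed = NULL) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  N <- nrow(d)
  sectors <- as.character(sectors)
  localities <- as.character(localities)
  stopifnot(length(sectors) == N, length(localities) == N)
  if (any(is.na(sectors)) || any(is.na(localities))) {
    hzc_abort("every individual needs sector and locality labels",
              "hzc_label_error")
  }
  if (length(unique(sectors)) < 2) {
    hzc_abort("AMOVA needs >= 2 sectors", "hzc_domain_error")
  }
  if (is.null(seed) && n_perm > 0) hzc_abort("seed required for permutations",
                                             "hzc_seed_error")

  obs <- amova_components(d, sectors, localities)
  monomorphic <- obs$ssd[["total"]] <= 0
  if (monomorphic) {
    obs$F_CT <- NA_real_; obs$F_SC <- NA_real_; obs$F_ST <- NA_real_
  }

  pop <- paste(sectors, localities, sep = "//")
  pops <- unique(pop)
  pop_sector <- sectors[match(pops, pop)]
  one_loc_per_sector <- length(pops) == length(unique(sectors))

  p_fst <- p_fsc <- p_fct <- NA_real_
  if (!monomorphic && n_perm > 0) {
    ge <- function(a, b) !is.na(a) && !is.na(b) && (a >= b - 1e-12)
    cnt_fst <- cnt_fsc <- cnt_fct <- 0
    n_fsc <- 0
    with_seed(derive_seed(seed, 0), {
      for (k in seq_len(n_perm)) {
        # F_ST: individuals shuffled across everything (structure kept)
        perm <- sample.int(N)
        r <- amova_components(d, sectors[perm], localities[perm])
        if (ge(r$F_ST, obs$F_ST)) cnt_fst <- cnt_fst + 1
        # F_CT: whole localities shuffled among sectors
        psec <- sample(pop_sector)
        sec2 <- psec[match(pop, pops)]
        r <- amova_components(d, sec2, localities)
        if (ge(r$F_CT, obs$F_CT)) cnt_fct <- cnt_fct + 1
        # F_SC: individuals shuffled among localities within their sector
        if (!one_loc_per_sector && !is.na(obs$F_SC)) {
          loc2 <- localities
          for (g in unique(sectors)) {
            idx <- which(sectors == g)
            loc2[idx] <- localities[idx][sample.int(length(idx))]
          }
          r <- amova_components(d, sectors, loc2)
          n_fsc <- n_fsc + 1
          if (ge(r$F_SC, obs$F_SC)) cnt_fsc <- cnt_fsc + 1
        }
      }
    })
    p_fst <- (cnt_fst + 1) / (n_perm + 1)
    p_fct <- (cnt_fct + 1) / (n_perm + 1)
    p_fsc <- if (n_fsc > 0) (cnt_fsc + 1) / (n_fsc + 1) else NA_real_
  }

  pct <- 100 * obs$sigma / obs$total_variance
  structure(
    list(sigma = obs$sigma, percent_variation = pct,
         F_CT = obs$F_CT, F_SC = if (one_loc_per_sector) NA_real_ else obs$F_SC,
         F_ST = obs$F_ST,
         p_F_CT = p_fct, p_F_SC = p_fsc, p_F_ST = p_fst,
         ssd = obs$ssd, df = obs$df,
         n_individuals = N, n_localities = length(pops),
         n_sectors = length(unique(sectors)),
         n_perm = n_perm, monomorphic = monomorphic),
    class = "hzc_amova")
}

#' @export
print.hzc_amova <- function(x, ...) {
  cat(sprintf("AMOVA: %d individuals, %d localities, %d sectors\n",
              x$n_individuals, x$n_localities, x$n_sectors))
  if (x$monomorphic) {
    cat("  monomorphic data: F-statistics undefined\n")
    return(invisible(x))
  }
  print(tidy(x))
  invisible(x)
}

#' @rdname amova
#' @param x A `hzc_amova` object.
#' @param ... Unused.
#' @export
tidy.hzc_amova <- function(x, ...) {
  tibble(
    statistic = c("F_ST", "F_SC", "F_CT"),
    level = c("among localities among sectors",
              "among localities within sectors",
              "among sectors"),
    value = c(x$F_ST, x$F_SC, x$F_CT),
    p.value = c(x$p_F_ST, x$p_F_SC, x$p_F_CT),
    variance_component = c(unname(x$sigma["a"] + x$sigma["b"]),
                           unname(x$sigma["b"]), unname(x$sigma["a"])),
    percent_variation = c(unname(x$percent_variation["a"]) +
                            unname(x$percent_variation["b"]),
                          unname(x$percent_variation["b"]),
                          unname(x$percent_variation["a"]))
  )
}

#' @rdname amova
#' @export
glance.hzc_amova <- function(x, ...) {
  tibble(F_CT = x$F_CT, F_SC = x$F_SC, F_ST = x$F_ST,
         p_F_CT = x$p_F_CT, p_F_SC = x$p_F_SC, p_F_ST = x$p_F_ST,
         n_individuals = x$n_individuals, n_localities = x$n_localities,
         n_sectors = x$n_sectors, n_perm = x$n_perm,
         monomorphic = x$monomorphic)
}

#' Run an AMOVA from sequences and transect positions
#'
#' Convenience wrapper: joins aligned sequences to the positions table on
#' `id`, builds the pairwise difference matrix, and runs [amova()] using the
#' positions' `sector` and `locality_id` labels.
#'
#' @param seqs Aligned sequences (tibble or named character vector).
#' @param positions Tibble from [project_onto_transect()].
#' @param period Optional period filter applied to `positions$period`.
#' @inheritParams amova
#' @return A `hzc_amova` object.
#' @export
amova_from_positions <- function(seqs, positions, period = NULL,
                                 n_perm = 10000, seed = NULL) {
  seqs <- as_sequence_tbl(seqs)
  pos <- positions
  if (!is.null(period)) pos <- pos[pos$period == period, , drop = FALSE]
  common <- intersect(seqs$id, pos$id)
  if (length(common) < 2) hzc_abort("fewer than 2 sequences with positions",
                                    "hzc_insufficient_data_error")
  seqs <- seqs[match(common, seqs$id), ]
  pos <- pos[match(common, pos$id), ]
  if (any(is.na(pos$sector))) {
    rlang::warn("individuals outside the sector domain dropped from AMOVA")
    keep <- !is.na(pos$sector)
    seqs <- seqs[keep, ]; pos <- pos[keep, ]
  }
  d <- pairwise_diff_matrix(seqs)
  amova(d, pos$sector, pos$locality_id, n_perm = n_perm, seed = seed)
}
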