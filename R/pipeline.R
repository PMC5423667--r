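#' Run the full population-genetic workflow and write its report bundle
#'
#' Orchestrates the genotype analysis end to end: pooled per-locus summary,
#' per-population diversity table with Hardy-Weinberg tests flagged at the
#' Benjamini-Yekutieli threshold, pairwise linkage-disequilibrium tests,
#' chord-distance matrix, bootstrap neighbour-joining tree, principal
#' coordinates, and pairwise Weir-Cockerham theta with permutation
#' p-values. Writes one CSV (or Newick) per report plus a manifest that
#' records every setting and seed, so a run is exactly reproducible; the
#' same seed yields byte-identical outputs.
#'
#' All randomness flows from the single root `seed`, split per stage with
#' fixed offsets, so individual stages re-run in isolation match the full
#' pipeline.
#'
#' @param gt A [genotype_table()].
#' @param out_dir Output directory (created if needed).
#' @param g Rarefaction gene-copy number (default: per-locus minimum).
#' @param hwe_steps,ld_reps,fst_perms,boot_reps Monte-Carlo effort per
#'   stage.
#' @param alpha Family-wise level for the B-Y threshold.
#' @param seed Root seed.
#' @return Invisibly, a named list with every result object.
#' @export
run_popgen <- function(gt, out_dir, g = NULL, hwe_steps = 10000,
                       ld_reps = 1000, fst_perms = 1000, boot_reps = 2000,
                       alpha = 0.05, seed = 1) {
  stopifnot(is_genotype_tbl(gt))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  geno_path <- file.path(out_dir, "genotypes.csv")
  write_genotype_table(gt, geno_path)

  locus_sum <- locus_summary(gt)
  readr::write_csv(locus_sum, file.path(out_dir, "locus_summary.csv"))

  div <- diversity_table(gt, g = g, hwe_steps = hwe_steps, seed = seed + 10)
  hwe_flagged <- adjust_family(
    dplyr::rename(div, p = "hwe_p"), alpha = alpha
  )
  div$hwe_significant <- hwe_flagged$significant
  div$hwe_stars <- hwe_flagged$stars
  readr::write_csv(div, file.path(out_dir, "diversity.csv"))

  ld <- ld_test(gt, reps = ld_reps, seed = seed + 20)
  ld <- adjust_family(ld, alpha = alpha)
  readr::write_csv(ld, file.path(out_dir, "ld.csv"))

  results <- list(locus_summary = locus_sum, diversity = div, ld = ld,
                  hwe_alpha_adj = attr(hwe_flagged, "alpha_adj"),
                  ld_alpha_adj = attr(ld, "alpha_adj"))

  if (nlevels(gt$population) < 2) {
    warning("fewer than 2 populations: structure stages skipped")
    note("structure stages skipped: < 2 populations")
  } else {
    dce <- chord_distance(gt)
    readr::write_csv(tidy(dce), file.path(out_dir, "chord_dist.csv"))
    results$chord <- dce

    if (nlevels(gt$population) >= 3) {
      bnj <- bootstrap_nj(gt, reps = boot_reps, seed = seed + 30)
      write_support_tree(bnj, file.path(out_dir, "nj_bootstrap.nwk"))
      results$nj <- bnj
    } else {
      note("NJ skipped: < 3 populations")
    }

    ord <- pcoa(dce)
    readr::write_csv(tidy(ord), file.path(out_dir, "pcoa.csv"))
    results$pcoa <- ord

    fst <- fst_matrix(gt, perms = fst_perms, seed = seed + 40)
    readr::write_csv(tidy(fst), file.path(out_dir, "fst.csv"))
    results$fst <- fst
  }

  manifest <- list(
    workflow = "popgen",
    package_version = as.character(utils::packageVersion("skagerrak")),
    input = list(file = "genotypes.csv",
                 md5 = unname(tools::md5sum(geno_path)),
                 n_individuals = length(unique(gt$individual)),
                 populations = pop_levels(gt), loci = locus_levels(gt)),
    settings = list(g = g, hwe_steps = hwe_steps, ld_reps = ld_reps,
                    fst_perms = fst_perms, boot_reps = boot_reps,
                    alpha = alpha),
    seeds = list(root = seed, hwe = seed + 10, ld = seed + 20,
                 bootstrap = seed + 30, fst = seed + 40),
    adjusted_alpha = list(hwe = results$hwe_alpha_adj,
                          ld = results$ld_alpha_adj),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

#' Run a multi-year larval-drift simulation and write its report bundle
#'
#' Generates (or accepts) one ocean scenario per simulated year, runs the
#' deterministic drift model for each, and writes a per-year landing
#' summary in the conventional layout (one column per year plus an
#' `in_total` column), the per-50-km-cell landed counts, and a manifest.
#'
#' @param years Named character vector mapping year label to scenario
#'   preset (`"cold"`, `"moderate"`, `"warm"`); the default mirrors a
#'   six-year design with two cold, two warm and two moderately warm years.
#'   Alternatively a named list of lists `list(fields=, release=)` for
#'   externally built scenarios.
#' @param out_dir Output directory.
#' @param dt Time step in seconds.
#' @param dd_threshold,t_threshold,t_base,max_days Drift model parameters,
#'   see [run_scenario()].
#' @param cell_km Aggregation cell size.
#' @param scenario_args Extra arguments passed to
#'   [generate_ocean_scenario()] for preset years.
#' @return Invisibly, a list with `records`, `landings`
#'   (a `landing_summary`) and `table` (the wide per-year layout).
#' @export
run_simulation <- function(years = c("1990" = "cold", "1998" = "cold",
                                     "2002" = "warm", "2006" = "warm",
                                     "2007" = "moderate",
                                     "2010" = "moderate"),
                           out_dir, dt = 3600, dd_threshold = 225,
                           t_threshold = 18, t_base = 0, max_days = 60,
                           cell_km = 50, scenario_args = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_records <- vector("list", length(years))
  region <- NULL
  for (i in seq_along(years)) {
    yr <- names(years)[i]
    sc <- if (is.character(years)) {
      do.call(generate_ocean_scenario,
              c(list(preset = years[[i]]), scenario_args))
    } else {
      years[[i]]
    }
    if (is.null(region)) {
      # recipient-coast waters: the northern band of the basin
      ext <- domain_extent(sc$fields)
      region <- list(recipient = cbind(
        x = c(ext["xmin"] - 1, ext["xmax"] + 1, ext["xmax"] + 1,
              ext["xmin"] - 1),
        y = c(0.6 * ext["ymax"], 0.6 * ext["ymax"], ext["ymax"] + 1,
              ext["ymax"] + 1)
      ))
    }
    rec <- run_scenario(sc$fields, sc$release, dt = dt,
                        max_days = max_days, dd_threshold = dd_threshold,
                        t_threshold = t_threshold, t_base = t_base)
    rec$year <- yr
    all_records[[i]] <- rec
  }
  records <- dplyr::bind_rows(all_records)
  attr(records, "params") <- attr(all_records[[1]], "params")
  landings <- aggregate_landings(records, cell_km = cell_km,
                                 regions = region)

  wide <- landing_table(landings)
  readr::write_csv(wide, file.path(out_dir, "landing_summary.csv"))
  readr::write_csv(landings$cells, file.path(out_dir, "cell_counts.csv"))
  readr::write_csv(
    dplyr::select(records, -dplyr::any_of(c("time"))),
    file.path(out_dir, "larvae.csv")
  )

  manifest <- list(
    workflow = "simulation",
    package_version = as.character(utils::packageVersion("skagerrak")),
    years = as.list(if (is.character(years)) years else
      stats::setNames(rep("external", length(years)), names(years))),
    settings = list(dt = dt, dd_threshold = dd_threshold,
                    t_threshold = t_threshold, t_base = t_base,
                    max_days = max_days, cell_km = cell_km,
                    scenario_args = scenario_args),
    deterministic = TRUE
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(records = records, landings = landings, table = wide))
}

#' Wide per-year landing table
#'
#' Pivots a [aggregate_landings()] summary into the conventional layout:
#' one row per statistic, one column per year, plus an `in_total` column
#' (counts summed; fractions recomputed as total counts over total
#' released).
#'
#' @param landings A `landing_summary`.
#' @return A tibble with a `statistic` column and one column per year.
#' @export
landing_table <- function(landings) {
  s <- landings$summary
  stat_cols <- setdiff(names(s), "year")
  totals <- vapply(stat_cols, function(cn) {
    if (startsWith(cn, "fraction")) NA_real_ else sum(s[[cn]])
  }, numeric(1))
  released <- sum(s$n_released)
  for (cn in stat_cols) {
    if (startsWith(cn, "fraction")) {
      counterpart <- sub("^fraction", "n", cn)
      if (counterpart %in% names(s)) {
        totals[cn] <- sum(s[[counterpart]]) / released
      }
    }
  }
  long <- s |>
    tidyr::pivot_longer(-"year", names_to = "statistic") |>
    tidyr::pivot_wider(names_from = "year", values_from = "value")
  long$in_total <- unname(totals[long$statistic])
  long
}
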