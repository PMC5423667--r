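#' Observed heterozygosity per population and locus
#'
#' Fraction of non-missing individuals whose two alleles differ, for every
#' (population, locus) combination. Undefined (NA) where a population has no
#' calls at a locus.
#'
#' @param gt A [genotype_table()].
#' @return A tibble with `population`, `locus`, `n_ind`, `h_obs`.
#' @export
observed_heterozygosity <- function(gt) {
  stopifnot(is_genotype_tbl(gt))
  gt |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(
      n_ind = sum(!is.na(.data$allele_1)),
      h_obs = dplyr::if_else(
        .data$n_ind > 0,
        sum(.data$allele_1 != .data$allele_2, na.rm = TRUE) / .data$n_ind,
        NA_real_
      ),
      .groups = "drop"
    )
}

#' Expected heterozygosity (gene diversity)
#'
#' Gene diversity `1 - sum(p_i^2)` per (population, locus), with Nei's
#' small-sample correction `N / (N - 1)` (N = gene copies) reported
#' alongside. Which estimator a summary table should print is left to the
#' caller: per-population reports conventionally use the unbiased column,
#' pooled per-locus reports the uncorrected one.
#'
#' @param af An [allele_frequencies()] table.
#' @return A tibble with `population`, `locus`, `n`, `h_exp` (uncorrected)
#'   and `h_exp_u` (unbiased); `h_exp_u` is NA where `n < 2`.
#' @export
expected_heterozygosity <- function(af) {
  stopifnot(inherits(af, "allele_freq_tbl"))
  af |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(
      n = .data$n[1],
      h_exp = 1 - sum(.data$freq^2),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      h_exp_u = dplyr::if_else(.data$n >= 2,
                               .data$h_exp * .data$n / (.data$n - 1),
                               NA_real_)
    )
}

#' Rarefied allelic richness from allele copy counts
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, by hypergeometric rarefaction:
#' `A_R(g) = sum_i (1 - choose(N - N_i, g) / choose(N, g))` over alleles `i`
#' with copy counts `N_i`, `N = sum(N_i)`. Equals the exhaustive average of
#' distinct-allele counts over all `choose(N, g)` subsamples.
#'
#' @param counts Integer vector of allele copy counts (one entry per allele).
#' @param g Standardised number of gene copies, `1 <= g <= sum(counts)`.
#' @return The expected allele number, a scalar in `[1, length(counts)]`.
#' @export
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  n_total <- sum(counts)
  if (g < 1 || g > n_total) {
    stop("g must be between 1 and the total gene-copy count (", n_total, ")")
  }
  sum(1 - exp(lchoose(n_total - counts, g) - lchoose(n_total, g)))
}

#' Rarefied allelic richness per population and locus
#'
#' Rarefaction is at the gene-copy level, so missing data shrinks each
#' population's copy count per locus. By default the standardised `g` at
#' each locus is the minimum gene-copy count across populations at that
#' locus (populations entirely untyped at a locus are excluded from the
#' minimum and get an NA richness there).
#'
#' @param gt A [genotype_table()].
#' @param g Standardised gene-copy number; a single value for all loci or
#'   `NULL` (default) for the per-locus minimum across populations.
#' @return A tibble with `population`, `locus`, `n`, `n_alleles`, `g`, `a_r`.
#' @export
allelic_richness_table <- function(gt, g = NULL) {
  af <- allele_frequencies(gt)
  copies <- gene_copies(gt)
  g_per_locus <- copies |>
    dplyr::filter(.data$n > 0) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(g_default = min(.data$n), .groups = "drop")

  counts <- af |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(n = .data$n[1],
                     n_alleles = dplyr::n(),
                     counts = list(.data$count), .groups = "drop") |>
    dplyr::left_join(g_per_locus, by = "locus")
  counts$g <- if (is.null(g)) counts$g_default else as.integer(g)

  counts |>
    dplyr::mutate(
      a_r = purrr::map2_dbl(.data$counts, .data$g, function(cc, gg) {
        if (gg > sum(cc)) return(NA_real_)
        allelic_richness(cc, gg)
      })
    ) |>
    dplyr::select("population", "locus", "n", "n_alleles", "g", "a_r")
}

#' Private alleles per group and locus
#'
#' Counts (locus, allele) pairs observed in exactly one group of populations
#' and in no other group. The default grouping treats every population as
#' its own group (per-location private alleles); pass a named list of
#' population vectors to pool, e.g. the four recipient-coast samples against
#' a pooled donor-coast sample.
#'
#' Counts are raw presence/absence, not rarefied.
#'
#' @param gt A [genotype_table()] (or an [allele_frequencies()] table).
#' @param grouping Named list mapping group name to a character vector of
#'   population labels; must cover all populations, disjointly. `NULL` means
#'   one group per population.
#' @return A tibble with `group`, `locus`, `n_private` (zero rows filled in).
#' @export
private_alleles <- function(gt, grouping = NULL) {
  af <- if (inherits(gt, "allele_freq_tbl")) gt else allele_frequencies(gt)
  pops <- levels(af$population)
  if (is.null(grouping)) {
    grouping <- stats::setNames(as.list(pops), pops)
  }
  covered <- unlist(grouping)
  if (anyDuplicated(covered) > 0 || !setequal(covered, pops)) {
    stop("grouping must cover all populations exactly once")
  }
  group_of <- stats::setNames(
    rep(names(grouping), lengths(grouping)), unlist(grouping)
  )

  presence <- af |>
    dplyr::mutate(group = factor(group_of[as.character(.data$population)],
                                 levels = names(grouping))) |>
    dplyr::distinct(.data$group, .data$locus, .data$allele)

  presence |>
    dplyr::group_by(.data$locus, .data$allele) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::count(.data$group, .data$locus, name = "n_private",
                 .drop = FALSE) |>
    tidyr::complete(.data$group, .data$locus,
                    fill = list(n_private = 0L)) |>
    dplyr::arrange(.data$group, .data$locus)
}

# ---- Hardy-Weinberg exact test (Monte-Carlo) --------------------------------

# Ordering statistic: log conditional probability of the genotype array given
# the allele counts (Levene), up to constants fixed by the allele counts:
#   log P  =  h * log 2  -  sum_ij log(n_ij!)  + const
hwe_log_score <- function(a1, a2, k) {
  id <- (pmin(a1, a2) - 1L) * k + pmax(a1, a2)
  tab <- tabulate(id, nbins = k * k)
  nz <- tab[tab > 1L]              # lgamma(0!)=lgamma(1!)=0
  sum(a1 != a2) * log(2) - if (length(nz)) sum(lgamma(nz + 1)) else 0
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' For one locus in one population: repeatedly shuffles the `2n` observed
#' gene copies into `n` random diploid pairings and scores each arrangement
#' by its conditional probability given the allele counts; the p-value is
#' the (smoothed) proportion of arrangements no more probable than the
#' observed one. Two-sided by construction. Monomorphic or single-individual
#' data yield NA.
#'
#' @param a1,a2 Integer allele vectors for the called individuals (equal
#'   length, no NA).
#' @param steps Number of Monte-Carlo arrangements.
#' @param seed Optional integer seed for reproducibility.
#' @return A p-value in (0, 1], or NA if the test is undefined.
#' @export
hwe_exact_test <- function(a1, a2, steps = 100000, seed = NULL) {
  stopifnot(length(a1) == length(a2), !anyNA(a1), !anyNA(a2))
  pool <- c(a1, a2)
  alleles <- sort(unique(pool))
  if (length(alleles) < 2 || length(a1) < 2) return(NA_real_)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  k <- length(alleles)
  c1 <- match(a1, alleles)
  c2 <- match(a2, alleles)
  obs <- hwe_log_score(c1, c2, k)
  pool_idx <- c(c1, c2)
  n <- length(c1)
  odd <- seq(1, 2 * n, by = 2)
  even <- odd + 1
  hits <- 0L
  for (s in seq_len(steps)) {
    perm <- sample(pool_idx)
    if (hwe_log_score(perm[odd], perm[even], k) <= obs + 1e-9) {
      hits <- hits + 1L
    }
  }
  (hits + 1) / (steps + 1)
}

#' Hardy-Weinberg tests for every population and locus
#'
#' @param gt A [genotype_table()].
#' @param steps Monte-Carlo arrangements per test.
#' @param seed Root seed; each (population, locus) test gets a derived seed
#'   so the table is reproducible and tests can be re-run independently.
#' @return A tibble with `population`, `locus`, `p`.
#' @export
hwe_test <- function(gt, steps = 100000, seed = NULL) {
  stopifnot(is_genotype_tbl(gt))
  cells <- gt |>
    dplyr::filter(!is.na(.data$allele_1)) |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(a1 = list(.data$allele_1), a2 = list(.data$allele_2),
                     .groups = "drop")
  cells$p <- purrr::pmap_dbl(
    list(cells$a1, cells$a2, seq_len(nrow(cells))),
    function(a1, a2, i) {
      hwe_exact_test(a1, a2, steps = steps,
                     seed = if (is.null(seed)) NULL else seed + i)
    }
  )
  cells |>
    dplyr::select("population", "locus", "p") |>
    tidyr::complete(.data$population, .data$locus, fill = list(p = NA_real_))
}

# ---- Linkage disequilibrium permutation test --------------------------------

g_statistic <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  idx <- tab > 0
  2 * sum(tab[idx] * log(tab[idx] / e[idx]))
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' Association statistic is the G-statistic of the two-locus genotype
#' contingency table (single-locus genotypes as categories); the null
#' distribution is built by permuting one locus's genotypes across
#' individuals, which preserves both single-locus genotype distributions.
#'
#' @param a1,a2 Allele vectors at the first locus; `b1,b2` at the second;
#'   only individuals called at both loci should be supplied.
#' @param reps Number of permutations.
#' @param seed Optional integer seed.
#' @return Smoothed permutation p-value `(1 + hits) / (reps + 1)`, or NA if
#'   either locus is monomorphic.
#' @export
ld_permutation_test <- function(a1, a2, b1, b2, reps = 10000, seed = NULL) {
  stopifnot(length(a1) == length(a2), length(b1) == length(b2),
            length(a1) == length(b1))
  if (length(unique(c(a1, a2))) < 2 || length(unique(c(b1, b2))) < 2) {
    return(NA_real_)
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  ga <- factor(paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
  gb <- factor(paste(pmin(b1, b2), pmax(b1, b2), sep = "/"))
  g_obs <- g_statistic(table(ga, gb))
  hits <- 0L
  for (r in seq_len(reps)) {
    if (g_statistic(table(ga, sample(gb))) >= g_obs - 1e-9) hits <- hits + 1L
  }
  (hits + 1) / (reps + 1)
}

#' Linkage-disequilibrium tests for all locus pairs in all populations
#'
#' @param gt A [genotype_table()].
#' @param reps Permutations per test.
#' @param seed Root seed, split per test.
#' @return A tibble with `population`, `locus_a`, `locus_b`, `p`.
#' @export
ld_test <- function(gt, reps = 10000, seed = NULL) {
  stopifnot(is_genotype_tbl(gt))
  loci <- locus_levels(gt)
  if (length(loci) < 2) stop("need at least two loci")
  pairs <- utils::combn(loci, 2)
  grid <- tidyr::expand_grid(
    population = factor(pop_levels(gt), levels = pop_levels(gt)),
    pair = seq_len(ncol(pairs))
  )
  wide1 <- gt |> dplyr::select("individual", "population", "locus", "allele_1") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "allele_1")
  wide2 <- gt |> dplyr::select("individual", "population", "locus", "allele_2") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "allele_2")

  res <- purrr::pmap_dfr(grid, function(population, pair) {
    la <- pairs[1, pair]; lb <- pairs[2, pair]
    sel <- wide1$population == population
    a1 <- wide1[[la]][sel]; a2 <- wide2[[la]][sel]
    b1 <- wide1[[lb]][sel]; b2 <- wide2[[lb]][sel]
    ok <- !is.na(a1) & !is.na(b1)
    p <- if (sum(ok) < 2) NA_real_ else {
      ld_permutation_test(a1[ok], a2[ok], b1[ok], b2[ok], reps = reps,
                          seed = if (is.null(seed)) NULL else
                            seed + 1000L * pair + match(population, pop_levels(gt)))
    }
    tibble::tibble(population = population, locus_a = la, locus_b = lb, p = p)
  })
  res
}

# ---- Benjamini-Yekutieli family threshold -----------------------------------

#' Benjamini-Yekutieli adjusted significance threshold
#'
#' The single adjusted alpha used to flag every test in a family of `k`
#' tests while controlling the false-discovery rate under arbitrary
#' dependence: `alpha / sum(1/i, i = 1..k)`.
#'
#' @param alpha Family-wise level, in (0, 1).
#' @param k Number of tests in the family, `>= 1`.
#' @return The adjusted threshold.
#' @examples
#' by_fdr_alpha(0.05, 90) # the 15-locus-pair x 6-sample LD family: 0.00984
#' @export
by_fdr_alpha <- function(alpha, k) {
  if (k < 1) stop("k must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / sum(1 / seq_len(k))
}

#' Flag a family of tests at a B-Y adjusted threshold
#'
#' @param tests A data frame with a `p` column (one row per test; NA rows
#'   are kept but never flagged and do not count towards `k` unless
#'   `count_na = TRUE`).
#' @param alpha Family-wise level.
#' @param count_na Whether undefined tests still count towards the family
#'   size `k` (default FALSE).
#' @return The input tibble with a `significant` flag and `stars` column
#'   (`*`, `**`, `***` for the 5%, 1%, 0.1% family levels); the adjusted
#'   thresholds are attached as attributes `alpha_adj` and `k`.
#' @export
adjust_family <- function(tests, alpha = 0.05, count_na = FALSE) {
  stopifnot("p" %in% names(tests))
  k <- if (count_na) nrow(tests) else sum(!is.na(tests$p))
  if (k < 1) stop("no defined tests in the family")
  thr <- by_fdr_alpha(alpha, k)
  thr_levels <- vapply(c(0.05, 0.01, 0.001), by_fdr_alpha, numeric(1), k = k)
  out <- tests |>
    dplyr::mutate(
      significant = !is.na(.data$p) & .data$p <= thr,
      stars = dplyr::case_when(
        is.na(.data$p) ~ "",
        .data$p <= thr_levels[3] ~ "***",
        .data$p <= thr_levels[2] ~ "**",
        .data$p <= thr_levels[1] ~ "*",
        TRUE ~ "NS"
      )
    )
  attr(out, "alpha") <- alpha
  attr(out, "alpha_adj") <- round(thr, 5)
  attr(out, "k") <- k
  out
}

# ---- Assembled per-population summary ---------------------------------------

#' Per-population, per-locus diversity summary
#'
#' Assembles the standard microsatellite summary: allele counts, rarefied
#' allelic richness, private alleles, observed and expected heterozygosity
#' and a Monte-Carlo Hardy-Weinberg p-value, for every population and locus.
#'
#' @param gt A [genotype_table()].
#' @param g Standardised gene-copy number for rarefaction (default: per-locus
#'   minimum across populations).
#' @param hwe_steps Monte-Carlo arrangements per HWE test.
#' @param seed Root seed for the HWE tests.
#' @return A tibble of class `diversity_tbl`: `population`, `locus`, `n_ind`,
#'   `n_alleles`, `a_r`, `n_private`, `h_obs`, `h_exp`, `h_exp_u`, `hwe_p`.
#' @export
diversity_table <- function(gt, g = NULL, hwe_steps = 10000, seed = NULL) {
  af <- allele_frequencies(gt)
  ho <- observed_heterozygosity(gt)
  he <- expected_heterozygosity(af)
  ar <- allelic_richness_table(gt, g = g)
  pa <- private_alleles(gt) |>
    dplyr::rename(population = "group")
  hw <- hwe_test(gt, steps = hwe_steps, seed = seed) |>
    dplyr::rename(hwe_p = "p")

  out <- ho |>
    dplyr::left_join(dplyr::select(ar, "population", "locus", "n_alleles",
                                   "g", "a_r"),
                     by = c("population", "locus")) |>
    dplyr::left_join(dplyr::mutate(pa, population = factor(.data$population,
                                                           levels = pop_levels(gt))),
                     by = c("population", "locus")) |>
    dplyr::left_join(dplyr::select(he, "population", "locus", "h_exp",
                                   "h_exp_u"),
                     by = c("population", "locus")) |>
    dplyr::left_join(hw, by = c("population", "locus"))
  class(out) <- c("diversity_tbl", class(tibble::tibble()))
  out
}

#' Per-population means over loci
#'
#' Arithmetic means of the per-locus diversity statistics, over loci where
#' each statistic is defined.
#'
#' @param div A [diversity_table()].
#' @return One row per population with mean `n_alleles`, `a_r`, `n_private`,
#'   `h_obs`, `h_exp`, `h_exp_u`.
#' @export
diversity_means <- function(div) {
  stopifnot(inherits(div, "diversity_tbl"))
  div |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(dplyr::across(c("n_alleles", "a_r", "n_private",
                                     "h_obs", "h_exp", "h_exp_u"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
}

#' Pooled per-locus summary
#'
#' Marker-panel style summary over all populations pooled: total distinct
#' alleles, number of individuals amplified, overall observed
#' heterozygosity and pooled gene diversity (uncorrected).
#'
#' @param gt A [genotype_table()].
#' @return One row per locus: `locus`, `n_alleles`, `n_typed`, `h_obs`,
#'   `h_exp`.
#' @export
locus_summary <- function(gt) {
  stopifnot(is_genotype_tbl(gt))
  gt |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n_alleles = length(unique(stats::na.omit(c(.data$allele_1,
                                                 .data$allele_2)))),
      n_typed = sum(!is.na(.data$allele_1)),
      h_obs = sum(.data$allele_1 != .data$allele_2, na.rm = TRUE) /
        .data$n_typed,
      h_exp = {
        copies <- stats::na.omit(c(.data$allele_1, .data$allele_2))
        1 - sum((tabulate(factor(copies)) / length(copies))^2)
      },
      .groups = "drop"
    )
}

# ---- seed plumbing ----------------------------------------------------------

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
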