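#' Simulate microsatellite genotypes under the F-model
#'
#' Ancestral allele frequencies per locus are drawn from a flat Dirichlet
#' over the configured allele count; each population's frequencies are then
#' drawn from `Dirichlet(p0 * (1 - F) / F)`, so the divergence parameter `F`
#' is the expected Weir-Cockerham theta between populations and the
#' ancestral pool (the F-model). `F = 0` is a documented special case:
#' the population copies the ancestral frequencies exactly. Diploid
#' genotypes are drawn under within-population Hardy-Weinberg equilibrium;
#' missingness is applied completely at random. Allele labels are mapped to
#' plausible even fragment sizes in base pairs.
#'
#' @param n_pops Number of populations.
#' @param n Individuals per population (recycled to `n_pops`).
#' @param n_loci Number of loci.
#' @param n_alleles Ancestral allele count per locus (recycled to `n_loci`).
#' @param f Divergence parameter per population, `0 <= F < 1` (recycled).
#' @param missing_rate Per-genotype missing probability (completely at
#'   random), or use `missing_per_locus` for exact counts.
#' @param missing_per_locus Optional integer vector (length `n_loci`): make
#'   exactly this many individuals missing at each locus (overrides
#'   `missing_rate`).
#' @param pop_names,locus_names Optional label vectors.
#' @param size_start First fragment size per locus in bp (recycled);
#'   allele `k` at a locus gets label `size_start + 2 * (k - 1)`.
#' @param seed Optional integer seed (bit-reproducible output).
#' @return A [genotype_table()].
#' @export
simulate_genotypes <- function(n_pops = 6,
                               n = c(12, 50, 50, 50, 50, 50),
                               n_loci = 6, n_alleles = 10, f = 0.05,
                               missing_rate = 0, missing_per_locus = NULL,
                               pop_names = NULL, locus_names = NULL,
                               size_start = NULL, seed = NULL) {
  n <- rep_len(n, n_pops)
  n_alleles <- rep_len(n_alleles, n_loci)
  f <- rep_len(f, n_pops)
  if (any(f < 0 | f >= 1)) stop("F must satisfy 0 <= F < 1")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing rate must be in [0, 1)")
  }
  if (is.null(pop_names)) pop_names <- paste0("P", seq_len(n_pops))
  if (is.null(locus_names)) locus_names <- paste0("L", seq_len(n_loci))
  if (is.null(size_start)) size_start <- 100 + 60 * (seq_len(n_loci) - 1)
  size_start <- rep_len(size_start, n_loci)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }

  rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) g[which.max(alpha)] <- 1
    g / sum(g)
  }

  rows <- vector("list", n_pops * n_loci)
  cell <- 0L
  ancestral <- lapply(seq_len(n_loci), function(l) {
    rdirichlet1(rep(1, n_alleles[l]))
  })
  ids <- unlist(lapply(seq_len(n_pops), function(i) {
    sprintf("%s_%03d", pop_names[i], seq_len(n[i]))
  }))

  for (i in seq_len(n_pops)) {
    for (l in seq_len(n_loci)) {
      p0 <- ancestral[[l]]
      p <- if (f[i] == 0) p0 else rdirichlet1(p0 * (1 - f[i]) / f[i])
      labels <- size_start[l] + 2L * (seq_len(n_alleles[l]) - 1L)
      a1 <- sample(labels, n[i], replace = TRUE, prob = p)
      a2 <- sample(labels, n[i], replace = TRUE, prob = p)
      cell <- cell + 1L
      rows[[cell]] <- tibble::tibble(
        individual = sprintf("%s_%03d", pop_names[i], seq_len(n[i])),
        population = pop_names[i],
        locus = locus_names[l],
        allele_1 = a1, allele_2 = a2
      )
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(individual = factor(.data$individual, levels = ids)) |>
    dplyr::arrange(.data$individual,
                   factor(.data$locus, levels = locus_names)) |>
    dplyr::mutate(individual = as.character(.data$individual))

  if (!is.null(missing_per_locus)) {
    stopifnot(length(missing_per_locus) == n_loci)
    for (l in seq_len(n_loci)) {
      if (missing_per_locus[l] > 0) {
        drop_ids <- sample(ids, missing_per_locus[l])
        sel <- out$locus == locus_names[l] & out$individual %in% drop_ids
        out$allele_1[sel] <- NA_integer_
        out$allele_2[sel] <- NA_integer_
      }
    }
  } else if (missing_rate > 0) {
    sel <- stats::runif(nrow(out)) < missing_rate
    out$allele_1[sel] <- NA_integer_
    out$allele_2[sel] <- NA_integer_
  }
  genotype_table(out)
}

#' Synthetic stand-in for the six-sample oyster study genotype file
#'
#' Generates a genotype table whose *structure* copies the published study
#' design: six Scandinavian sampling locations (N_B n = 12; N_G, N_I, N_O,
#' S_S, D_A n = 50; 262 individuals in total), six microsatellite loci with
#' the study's marker-panel names, fragment-size ranges and total allele
#' counts, and exactly three untyped individuals at each of Cgsili44 and
#' CG49 (so 259 of 262 amplify there). The allele frequencies and genotypes
#' themselves are synthetic (F-model draws), not the real supplementary
#' data: per-allele results such as private-allele counts will differ from
#' the published ones.
#'
#' The westernmost sample (N_B) is given a larger divergence parameter than
#' the rest, mirroring the published pattern of one strongly differentiated
#' outlier population.
#'
#' @param seed Integer seed.
#' @return A [genotype_table()] with 262 individuals, 6 populations, 6 loci.
#' @export
simulate_study_genotypes <- function(seed = 1) {
  simulate_genotypes(
    n_pops = 6,
    n = c(12, 50, 50, 50, 50, 50),
    n_loci = 6,
    # total distinct alleles per locus in the published marker panel
    n_alleles = c(29, 12, 27, 26, 8, 26),
    f = c(0.05, 0.01, 0.01, 0.01, 0.01, 0.01),
    missing_per_locus = c(0, 3, 0, 0, 0, 3),
    pop_names = c("N_B", "N_G", "N_I", "N_O", "S_S", "D_A"),
    locus_names = c("L10", "Cgsili44", "AMY", "L48", "CGE009", "CG49"),
    size_start = c(109, 337, 196, 96, 102, 128),
    seed = seed
  )
}

#' Simulate a single population violating Hardy-Weinberg equilibrium
#'
#' Draws diploid genotypes at one locus with an inbreeding-like distortion
#' of heterozygosity: `P(het a,b) = 2 p_a p_b (1 - F_IS)` and homozygote
#' probabilities inflated (deficit, `F_IS > 0`) or deflated (excess,
#' `F_IS < 0`) accordingly. `F_IS = 0` recovers Hardy-Weinberg proportions.
#'
#' @param n Number of individuals (`>= 10`).
#' @param f_is Distortion in `(-1, 1)`; positive = heterozygote deficit.
#' @param freqs Allele frequencies (default two alleles at 0.5/0.5).
#' @param seed Optional integer seed.
#' @return A [genotype_table()] with one population (`P1`) and one locus
#'   (`L1`).
#' @export
make_hwe_violating_population <- function(n, f_is, freqs = c(0.5, 0.5),
                                          seed = NULL) {
  if (n < 10) stop("n must be >= 10")
  if (abs(f_is) > 1) stop("|F_IS| must be <= 1")
  stopifnot(abs(sum(freqs) - 1) < 1e-9)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  k <- length(freqs)
  labels <- 100L + 2L * (seq_len(k) - 1L)
  combos <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  probs <- apply(combos, 1, function(ij) {
    i <- ij[1]; j <- ij[2]
    if (i == j) {
      freqs[i]^2 + f_is * freqs[i] * (1 - freqs[i])
    } else {
      2 * freqs[i] * freqs[j] * (1 - f_is)
    }
  })
  if (any(probs < -1e-9)) {
    stop("F_IS = ", f_is, " is infeasible for these allele frequencies")
  }
  probs <- pmax(probs, 0)
  pick <- sample(nrow(combos), n, replace = TRUE, prob = probs)
  genotype_table(tibble::tibble(
    individual = sprintf("I%03d", seq_len(n)),
    population = "P1",
    locus = "L1",
    allele_1 = labels[combos[pick, 1]],
    allele_2 = labels[combos[pick, 2]]
  ))
}

# ---- Ocean scenario generator -----------------------------------------------

#' Generate a synthetic ocean scenario with a release schedule
#'
#' Builds a rectangular planar basin with a land strip on the donor (south)
#' coast and another on the recipient (north) coast, open (exiting)
#' east/west boundaries, and a divergence-free current carrying water from
#' donor to recipient. The current comes from a discrete stream function
#' (central differences), so its discrete divergence vanishes identically.
#' Patterns: `"channel"` (default) `v(x) = v0 sin(pi x / Lx)` — fastest
#' mid-basin, stagnant at the edges; `"uniform"` constant northward `v0`;
#' `"gyre"` a closed recirculation (for testing, transports nothing
#' ashore). `v0` is set so the fastest streamline crosses from release
#' line to recipient coast in `transit_days`.
#'
#' Temperature is `baseline + seasonal + gradient * northing + offset`
#' with a cosine seasonal cycle peaking on `peak_day`; the scenario presets
#' move only the offset (`cold` -4, `moderate` +1.5, `warm` +6 deg C), so
#' the temperature gate is the single difference between scenario years.
#' Under the defaults the cold preset stays below 18 deg C everywhere,
#' while the warm preset gives roughly 25 deg C along the crossing, hence
#' about `25 * transit_days` accumulated degree-days at landing.
#'
#' Release sites are evenly spaced on donor-coast water cells; the default
#' schedule releases one super-individual per site every second day over a
#' fortnight (days 1-14).
#'
#' @param preset `"cold"`, `"moderate"` or `"warm"`; or use `t_offset`.
#' @param n_sites Number of donor-coast release sites (default 44).
#' @param domain_km Basin size `c(Lx, Ly)` in km.
#' @param cell_km Grid cell size in km.
#' @param n_days Length of the field time axis in days.
#' @param field_step_s Field time step in seconds (default 6 h).
#' @param pattern Circulation pattern, see above.
#' @param transit_days Fastest crossing time in days.
#' @param baseline,seasonal_amp,peak_day,gradient_per_km Temperature model
#'   parameters (deg C; gradient is deg C per km of northing, negative =
#'   colder north).
#' @param t_offset Explicit scenario offset, overriding the preset.
#' @return A list with `fields` ([ocean_fields()]), `sites`, `release`
#'   (schedule for days 1-14 every 2 days) and `preset`.
#' @export
generate_ocean_scenario <- function(preset = c("warm", "moderate", "cold"),
                                    n_sites = 44,
                                    domain_km = c(200, 252),
                                    cell_km = 4,
                                    n_days = 80,
                                    field_step_s = 21600,
                                    pattern = c("channel", "uniform", "gyre"),
                                    transit_days = 10,
                                    baseline = 19,
                                    seasonal_amp = 1.5,
                                    peak_day = 14,
                                    gradient_per_km = -0.01,
                                    t_offset = NULL) {
  preset <- match.arg(preset)
  pattern <- match.arg(pattern)
  if (is.null(t_offset)) {
    t_offset <- c(cold = -4, moderate = 1.5, warm = 6)[[preset]]
  }
  dx <- dy <- cell_km * 1000
  nx <- round(domain_km[1] * 1000 / dx)
  ny <- round(domain_km[2] * 1000 / dy)
  times <- seq(0, n_days * 86400, by = field_step_s)
  nt <- length(times)

  mask <- matrix(TRUE, nx, ny)
  mask[, 1:2] <- FALSE          # donor (south) coast
  mask[, (ny - 1):ny] <- FALSE  # recipient (north) coast

  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  lx <- nx * dx

  # crossing distance: release line (row 3 centres) to the recipient strip
  y_release <- yc[3]
  y_coast <- (ny - 2) * dy
  v0 <- (y_coast - y_release) / (transit_days * 86400)

  # discrete stream function on a padded cell-centre grid; u, v by central
  # differences => discrete central-difference divergence is identically 0
  xpad <- (seq_len(nx + 2) - 1.5) * dx
  ypad <- (seq_len(ny + 2) - 1.5) * dy
  psi <- switch(pattern,
    uniform = outer(v0 * xpad, rep(1, ny + 2)),
    channel = outer(-v0 * lx / pi * cos(pi * xpad / lx), rep(1, ny + 2)),
    gyre = outer(sin(pi * xpad / lx), sin(pi * ypad / (ny * dy))) *
      v0 * lx / pi
  )
  u2 <- -(psi[2:(nx + 1), 3:(ny + 2)] - psi[2:(nx + 1), 1:ny]) / (2 * dy)
  v2 <- (psi[3:(nx + 2), 2:(ny + 1)] - psi[1:nx, 2:(ny + 1)]) / (2 * dx)
  u2[!mask] <- 0
  v2[!mask] <- 0

  u <- array(u2, dim = c(nx, ny, nt))
  v <- array(v2, dim = c(nx, ny, nt))
  temp <- array(0, dim = c(nx, ny, nt))
  north <- matrix(rep(yc, each = nx), nx, ny) / 1000  # km northing
  for (k in seq_len(nt)) {
    d <- times[k] / 86400
    seasonal <- seasonal_amp * cos(2 * pi * (d - peak_day) / 365)
    temp[, , k] <- baseline + seasonal + gradient_per_km * north + t_offset
  }

  x_sites <- seq(dx * 2, lx - dx * 2, length.out = n_sites)
  sites <- tibble::tibble(
    site = sprintf("S%02d", seq_len(n_sites)),
    x = x_sites,
    y = y_release
  )
  fields <- ocean_fields(u, v, temp, mask, dx, dy, times)
  release <- build_release_schedule(sites, 1, 14, every = 2, fields = fields)
  list(fields = fields, sites = sites, release = release, preset = preset,
       t_offset = t_offset)
}
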