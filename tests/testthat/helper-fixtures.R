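# Small in-code fixtures and independent oracles shared across test files.

# Quick genotype table from per-population lists of genotype pairs.
# calls: named list pop -> list of loci -> matrix/list of c(a1, a2) per ind.
make_gt <- function(pops) {
  rows <- list()
  for (pop in names(pops)) {
    loci <- pops[[pop]]
    n_ind <- length(loci[[1]])
    for (i in seq_len(n_ind)) {
      for (l in names(loci)) {
        g <- loci[[l]][[i]]
        rows[[length(rows) + 1]] <- tibble::tibble(
          individual = paste0(pop, "_", i), population = pop, locus = l,
          allele_1 = g[1], allele_2 = g[2]
        )
      }
    }
  }
  genotype_table(dplyr::bind_rows(rows))
}

# Independent Weir-Cockerham oracle: variance components from a nested
# ANOVA of gene-copy indicator variables (copies within individuals within
# populations), a different derivation than the package's moment formulas.
theta_anova_oracle <- function(gt) {
  w1 <- tidyr::pivot_wider(
    dplyr::select(gt, individual, population, locus, allele_1),
    names_from = locus, values_from = allele_1
  )
  w2 <- tidyr::pivot_wider(
    dplyr::select(gt, individual, population, locus, allele_2),
    names_from = locus, values_from = allele_2
  )
  num <- 0; den <- 0
  for (l in levels(gt$locus)) {
    a1 <- w1[[l]]; a2 <- w2[[l]]; pop <- w1$population
    ok <- !is.na(a1)
    a1 <- a1[ok]; a2 <- a2[ok]; pop <- droplevels(pop[ok])
    if (nlevels(pop) < 2) next
    n_i <- table(pop); r <- nlevels(pop); n_tot <- sum(n_i)
    n_c <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
    for (al in sort(unique(c(a1, a2)))) {
      y <- c(a1 == al, a2 == al) * 1
      ind <- rep(seq_along(a1), 2)
      popv <- rep(as.integer(pop), 2)
      ybar <- mean(y)
      ind_mean <- tapply(y, ind, mean)
      pop_of_ind <- tapply(popv, ind, `[`, 1)
      pop_mean <- tapply(y, popv, mean)
      ss_gam <- sum((y - ind_mean[as.character(ind)])^2)
      ss_ind <- 2 * sum((ind_mean - pop_mean[as.character(pop_of_ind)])^2)
      ss_pop <- sum(2 * as.vector(n_i) * (pop_mean - ybar)^2)
      ms_pop <- ss_pop / (r - 1)
      ms_ind <- ss_ind / (n_tot - r)
      ms_gam <- ss_gam / n_tot
      a <- (ms_pop - ms_ind) / (2 * n_c)
      b <- (ms_ind - ms_gam) / 2
      num <- num + a
      den <- den + a + b + ms_gam
    }
  }
  num / den
}

# Exhaustive rarefaction oracle: mean distinct-allele count over all
# subsamples of g copies (combn enumeration; only for small totals).
richness_enum_oracle <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# Set-difference oracle for private alleles of one group of populations.
private_count_oracle <- function(gt, group_pops) {
  af <- allele_frequencies(gt)
  mine <- af[af$population %in% group_pops, c("locus", "allele")]
  others <- af[!af$population %in% group_pops, c("locus", "allele")]
  key <- function(d) paste(d$locus, d$allele)
  length(setdiff(unique(key(mine)), unique(key(others))))
}

# Does an unrooted tree contain the bipartition separating `tips`?
has_split <- function(tree, tips) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  all_tips <- labs
  for (p in parts) {
    side <- labs[p]
    if (setequal(side, tips) || setequal(setdiff(all_tips, side), tips)) {
      return(TRUE)
    }
  }
  FALSE
}

# Constant-field basin: water channel between a southern land strip
# (rows 1:2) and a northern one (rows (ny-1):ny); constant velocity and
# temperature. Daily field steps.
uniform_fields <- function(nx = 20, ny = 30, cell = 10000, u0 = 0, v0 = 0.3,
                           temp0 = 25, n_days = 20) {
  times <- seq(0, n_days * 86400, by = 86400)
  nt <- length(times)
  mask <- matrix(TRUE, nx, ny)
  mask[, 1:2] <- FALSE
  mask[, (ny - 1):ny] <- FALSE
  ocean_fields(
    u = array(u0, c(nx, ny, nt)),
    v = array(v0, c(nx, ny, nt)),
    temp = array(temp0, c(nx, ny, nt)),
    mask = mask, dx = cell, dy = cell, times = times
  )
}
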