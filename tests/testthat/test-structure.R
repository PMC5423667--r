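test_that("chord distance matches its closed forms", {
  same <- make_gt(list(
    A = list(L1 = list(c(1, 2), c(1, 2))),
    B = list(L1 = list(c(1, 2), c(1, 2)))
  ))
  expect_equal(chord_distance(same)["A", "B"], 0)

  disjoint <- make_gt(list(
    A = list(L1 = list(c(1, 1), c(1, 1))),
    B = list(L1 = list(c(2, 2), c(3, 3)))
  ))
  expect_equal(chord_distance(disjoint)["A", "B"], (2 / pi) * sqrt(2),
               tolerance = 1e-12)

  # x = (1, 0), y = (0.5, 0.5): f = sqrt(0.5)
  partial <- make_gt(list(
    A = list(L1 = list(c(1, 1), c(1, 1))),
    B = list(L1 = list(c(1, 2), c(2, 1)))
  ))
  expect_equal(chord_distance(partial)["A", "B"],
               (2 / pi) * sqrt(2 * (1 - sqrt(0.5))), tolerance = 1e-12)
})

test_that("multi-locus chord combination averages per-locus distances and
           drops untyped loci with a warning", {
  gt <- make_gt(list(
    A = list(L1 = list(c(1, 1)), L2 = list(c(1, 1))),
    B = list(L1 = list(c(2, 2)), L2 = list(c(1, 1)))
  ))
  d <- chord_distance(gt)
  expect_equal(d["A", "B"], ((2 / pi) * sqrt(2) + 0) / 2, tolerance = 1e-12)
  d_rms <- chord_distance(gt, variant = "rms")
  expect_equal(d_rms["A", "B"], sqrt((2 / pi)^2 * 2 / 2), tolerance = 1e-12)

  miss <- make_gt(list(
    A = list(L1 = list(c(1, 1)), L2 = list(c(NA, NA))),
    B = list(L1 = list(c(2, 2)), L2 = list(c(1, 1)))
  ))
  expect_warning(dm <- chord_distance(miss), "dropped")
  expect_equal(dm["A", "B"], (2 / pi) * sqrt(2), tolerance = 1e-12)
})

test_that("chord distance is invariant to allele relabelling and population
           order", {
  gt <- simulate_genotypes(n_pops = 4, n = 15, n_loci = 3, n_alleles = 5,
                           f = 0.1, seed = 17)
  d <- chord_distance(gt)
  relab <- gt
  relab$allele_1 <- relab$allele_1 * 3 + 1
  relab$allele_2 <- relab$allele_2 * 3 + 1
  expect_equal(unclass(chord_distance(genotype_table(relab))), unclass(d))

  perm <- genotype_table(dplyr::arrange(gt, dplyr::desc(population)))
  d_perm <- chord_distance(perm)
  expect_equal(unclass(d_perm)[rownames(d), colnames(d)], unclass(d),
               ignore_attr = TRUE)
})

test_that("NJ solves the 3-taxon case exactly and recovers additive trees", {
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(d3)
  coph <- ape::cophenetic.phylo(tr3)
  expect_equal(coph[rownames(d3), colnames(d3)], d3, tolerance = 1e-12)

  # additive 4-taxon matrix from a known tree
  ref <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1.5,D:0.7):0.3);")
  d4 <- ape::cophenetic.phylo(ref)
  tr4 <- nj_tree(d4)
  expect_true(has_split(tr4, c("A", "B")))
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-12)
  expect_true(all(tr4$edge.length >= 0))

  # ultrametric 5-taxon: topology agrees with the generating clusters
  labs <- c("A", "B", "C", "D", "E")
  d5 <- matrix(6, 5, 5, dimnames = list(labs, labs))
  d5[1:4, 1:4] <- 4
  d5[1:2, 1:2] <- 2
  d5[3:4, 3:4] <- 2
  diag(d5) <- 0
  tr5 <- nj_tree(d5)
  expect_true(has_split(tr5, c("A", "B")))
  expect_true(has_split(tr5, c("C", "D")))

  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
})

test_that("bootstrap NJ gives near-certain support to a strong split,
           is seed-stable, and needs >= 2 loci", {
  strong <- simulate_genotypes(
    n_pops = 4, n = 40, n_loci = 6, n_alleles = 6,
    f = 0.02, seed = 101
  )
  # push P3, P4 far away: relabel their alleles to a disjoint set
  idx <- strong$population %in% c("P3", "P4")
  strong$allele_1[idx] <- strong$allele_1[idx] + 1000L
  strong$allele_2[idx] <- strong$allele_2[idx] + 1000L
  strong <- genotype_table(strong)

  bnj <- bootstrap_nj(strong, reps = 200, seed = 7)
  split_support <- max(bnj$supports$support[-1])
  expect_gt(split_support, 0.95)
  expect_true(any(bnj$supports$significant))

  bnj2 <- bootstrap_nj(strong, reps = 200, seed = 7)
  expect_identical(bnj$supports, bnj2$supports)

  one_locus <- simulate_genotypes(n_pops = 3, n = 10, n_loci = 1,
                                  n_alleles = 4, f = 0.05, seed = 1)
  expect_error(bootstrap_nj(one_locus), "degenerate")
})

test_that("Newick export carries percent supports as node labels", {
  gt <- simulate_genotypes(n_pops = 4, n = 20, n_loci = 4, n_alleles = 5,
                           f = 0.1, seed = 3)
  bnj <- bootstrap_nj(gt, reps = 50, seed = 1)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_support_tree(bnj, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, pop_levels(gt))
  expect_equal(back$node.label, bnj$tree$node.label)
})

test_that("PCoA recovers planar configurations and equal simplex axes", {
  pts <- cbind(c(0, 3, 3, 0), c(0, 0, 4, 4))
  rownames(pts) <- paste0("P", 1:4)
  d <- as.matrix(stats::dist(pts))
  ord <- pcoa(d)
  rec <- as.matrix(stats::dist(ord$points[, 1:2]))
  expect_equal(rec, d, tolerance = 1e-9)
  expect_equal(sum(ord$percent), 100, tolerance = 1e-9)

  # 4-point equidistant simplex: three equal positive eigenvalues
  ds <- matrix(1, 4, 4, dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  diag(ds) <- 0
  simp <- pcoa(ds)
  pos <- simp$eig[simp$eig > 1e-10]
  expect_equal(length(pos), 3)
  expect_true(max(pos) - min(pos) < 1e-10)
  expect_equal(simp$percent, rep(100 / 3, 3), tolerance = 1e-9)

  # percents match an independent eigen decomposition
  gt <- simulate_genotypes(n_pops = 5, n = 20, n_loci = 4, n_alleles = 5,
                           f = 0.1, seed = 23)
  dm <- unclass(chord_distance(gt))
  n <- nrow(dm)
  jc <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * jc %*% dm^2 %*% jc
  ev <- eigen((b + t(b)) / 2, symmetric = TRUE)$values
  ref_pct <- 100 * ev[ev > 1e-10] / sum(ev[ev > 1e-10])
  expect_equal(pcoa(dm)$percent, ref_pct, tolerance = 1e-8)
})

test_that("theta is 1 under fixation, near 0 under panmixia, and equals the
           nested-ANOVA oracle", {
  fixed <- make_gt(list(
    A = list(L1 = list(c(1, 1), c(1, 1), c(1, 1))),
    B = list(L1 = list(c(2, 2), c(2, 2), c(2, 2)))
  ))
  expect_equal(pairwise_fst(fixed), 1)

  null <- simulate_genotypes(n_pops = 2, n = 100, n_loci = 10,
                             n_alleles = 8, f = 0, seed = 12)
  expect_lt(abs(pairwise_fst(null)), 0.02)

  hand <- make_gt(list(
    A = list(L1 = list(c(1, 2), c(1, 1), c(2, 3), c(1, 3)),
             L2 = list(c(5, 5), c(5, 6), c(6, 6), c(NA, NA))),
    B = list(L1 = list(c(2, 2), c(2, 3), c(3, 3)),
             L2 = list(c(5, 6), c(5, 5), c(5, 5)))
  ))
  expect_equal(pairwise_fst(hand), theta_anova_oracle(hand),
               tolerance = 1e-10)

  rnd <- simulate_genotypes(n_pops = 2, n = c(9, 14), n_loci = 3,
                            n_alleles = 4, f = 0.1, missing_rate = 0.08,
                            seed = 42)
  expect_equal(pairwise_fst(rnd), theta_anova_oracle(rnd), tolerance = 1e-10)
})

test_that("theta is invariant to allele relabelling and may be negative", {
  gt <- simulate_genotypes(n_pops = 2, n = 20, n_loci = 3, n_alleles = 4,
                           f = 0.02, seed = 99)
  th <- pairwise_fst(gt)
  relab <- gt
  relab$allele_1 <- 1000L - relab$allele_1
  relab$allele_2 <- 1000L - relab$allele_2
  expect_equal(pairwise_fst(genotype_table(relab)), th, tolerance = 1e-12)

  # weakly differentiated pairs can legitimately go below zero; the
  # estimate is reported untruncated
  small <- simulate_genotypes(n_pops = 2, n = 8, n_loci = 2, n_alleles = 2,
                              f = 0, seed = 6)
  expect_true(is.finite(pairwise_fst(small)))
})

test_that("theta permutation test is maximal for fixed differences and
           reproducible", {
  # samples large enough that no permutation recreates the fixed split
  fixed <- make_gt(list(
    A = list(L1 = replicate(20, c(1, 1), simplify = FALSE)),
    B = list(L1 = replicate(20, c(2, 2), simplify = FALSE))
  ))
  res <- fst_permutation_test(fixed, "A", "B", reps = 199, seed = 3)
  expect_equal(res$theta, 1)
  expect_equal(res$p, 1 / 200)

  gt <- simulate_genotypes(n_pops = 2, n = 15, n_loci = 3, n_alleles = 4,
                           f = 0.05, seed = 2)
  r1 <- fst_permutation_test(gt, "P1", "P2", reps = 99, seed = 11)
  r2 <- fst_permutation_test(gt, "P1", "P2", reps = 99, seed = 11)
  expect_identical(r1, r2)
  expect_error(fst_permutation_test(gt, "P1", "P2", reps = 0), "reps")
})

test_that("the pairwise matrix mirrors theta and p across the diagonal", {
  gt <- simulate_genotypes(n_pops = 3, n = 12, n_loci = 3, n_alleles = 4,
                           f = 0.08, seed = 44)
  fm <- fst_matrix(gt, perms = 49, seed = 5)
  expect_equal(fm$theta, t(fm$theta))
  expect_equal(fm$theta["P1", "P2"], pairwise_fst(gt, c("P1", "P2")),
               tolerance = 1e-12)
  expect_true(all(fm$p[lower.tri(fm$p)] > 0 & fm$p[lower.tri(fm$p)] <= 1))
  td <- tidy(fm)
  expect_equal(nrow(td), 3)
  expect_true(all(c("theta", "p") %in% names(td)))
})
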