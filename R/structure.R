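#' Cavalli-Sforza-Edwards chord distances between populations
#'
#' For populations x and y and locus l with allele-frequency vectors on the
#' union of observed alleles, the per-locus chord distance is
#' `d_l = (2/pi) * sqrt(2 * (1 - f_l))` with `f_l = sum_a sqrt(x_a * y_a)`.
#' Loci combine either as the arithmetic mean of `d_l` (default) or as the
#' root of the mean squared `d_l` (`variant = "rms"`); the original
#' multi-locus convention is ambiguous across implementations, so both are
#' offered. A locus untyped (zero gene copies) in either population of a
#' pair is dropped from that pair's average, with a warning.
#'
#' @param gt A [genotype_table()] or an [allele_frequencies()] table.
#' @param variant `"mean"` or `"rms"` multi-locus combination.
#' @return A symmetric matrix of class `geno_dist` with `metric` attribute
#'   `"D_CE"`.
#' @export
chord_distance <- function(gt, variant = c("mean", "rms")) {
  variant <- match.arg(variant)
  af <- if (inherits(gt, "allele_freq_tbl")) gt else allele_frequencies(gt)
  per_locus <- chord_distance_by_locus(af)
  combine_chord(per_locus, seq_along(per_locus), variant)
}

# list over loci of pop x pop per-locus chord distance matrices (NA where a
# population is untyped at the locus)
chord_distance_by_locus <- function(af) {
  pops <- levels(af$population)
  loci <- levels(af$locus)
  lapply(loci, function(l) {
    sub <- af[af$locus == l, ]
    freq <- lapply(pops, function(p) {
      s <- sub[sub$population == p, ]
      stats::setNames(s$freq, s$allele)
    })
    k <- length(pops)
    d <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
    diag(d) <- ifelse(vapply(freq, length, 1L) > 0, 0, NA_real_)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (length(freq[[i]]) == 0 || length(freq[[j]]) == 0) next
        alleles <- union(names(freq[[i]]), names(freq[[j]]))
        x <- freq[[i]][alleles]; x[is.na(x)] <- 0
        y <- freq[[j]][alleles]; y[is.na(y)] <- 0
        f <- sum(sqrt(x * y))
        f <- min(f, 1)  # guard rounding above 1
        d[i, j] <- d[j, i] <- (2 / pi) * sqrt(2 * (1 - f))
      }
    }
    d
  })
}

combine_chord <- function(per_locus, which_loci, variant) {
  mats <- per_locus[which_loci]
  arr <- simplify2array(mats)
  n_def <- apply(!is.na(arr), c(1, 2), sum)
  if (any(n_def < length(mats) & n_def > 0)) {
    warning("locus undefined in one population of a pair; dropped from ",
            "that pair's chord average", call. = FALSE)
  }
  d <- if (variant == "mean") {
    apply(arr, c(1, 2), mean, na.rm = TRUE)
  } else {
    sqrt(apply(arr^2, c(1, 2), mean, na.rm = TRUE))
  }
  d[n_def == 0] <- NA_real_
  structure(d, class = "geno_dist", metric = "D_CE", variant = variant)
}

#' @export
print.geno_dist <- function(x, ...) {
  cat("# Pairwise population distances (", attr(x, "metric"), ")\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Tidy a pairwise distance matrix into a long tibble
#'
#' @param x A `geno_dist` matrix.
#' @param ... Unused.
#' @return A tibble with `pop_a`, `pop_b`, `distance` (lower triangle).
#' @method tidy geno_dist
#' @export
tidy.geno_dist <- function(x, ...) {
  m <- unclass(x)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble::tibble(
    pop_a = rownames(m)[idx[, 1]],
    pop_b = colnames(m)[idx[, 2]],
    distance = m[idx]
  )
}

# ---- Neighbour joining ------------------------------------------------------

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via \pkg{ape}). Negative branch lengths,
#' which NJ can produce on non-additive matrices, are set to zero and the
#' negative amount transferred to the adjacent branch so path lengths are
#' approximately preserved.
#'
#' @param d A `geno_dist` matrix, `dist`, or symmetric matrix over at least
#'   three populations.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(unclass(d))
  if (nrow(m) < 3) stop("neighbour joining needs at least 3 populations")
  tr <- ape::nj(stats::as.dist(m))
  clamp_negative_edges(tr)
}

clamp_negative_edges <- function(tr) {
  for (pass in seq_len(20)) {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[which.min(tr$edge.length[neg])]
    amount <- tr$edge.length[e]      # negative
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    # the deficit moves to the adjacent branch: the edge above the parent
    # node if one exists, otherwise a sibling edge
    up <- which(tr$edge[, 2] == parent)
    target <- if (length(up) > 0) up[1] else {
      setdiff(which(tr$edge[, 1] == parent), e)[1]
    }
    if (length(target) == 1 && !is.na(target)) {
      tr$edge.length[target] <- tr$edge.length[target] + amount
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap neighbour-joining tree over loci
#'
#' Computes the point-estimate chord-distance NJ tree, then resamples loci
#' with replacement `reps` times, recomputing the distance matrix and NJ
#' tree each time. The support of each internal split of the point-estimate
#' tree is the fraction of replicate trees containing that bipartition;
#' splits with support above 0.70 are flagged as significant (the
#' conventional 70% bootstrap rule).
#'
#' @param gt A [genotype_table()] with at least 3 populations and 2 loci.
#' @param reps Bootstrap replicates (default 2000).
#' @param seed Optional integer seed.
#' @param variant Multi-locus chord combination, see [chord_distance()].
#' @return A `support_tree`: list with `tree` (a `phylo` whose node labels
#'   are percent supports), `supports` (tibble of internal nodes with
#'   `support` and `significant`), `reps`.
#' @export
bootstrap_nj <- function(gt, reps = 2000, seed = NULL,
                         variant = c("mean", "rms")) {
  variant <- match.arg(variant)
  stopifnot(is_genotype_tbl(gt))
  if (nlevels(gt$population) < 3) stop("need at least 3 populations")
  n_loci <- nlevels(gt$locus)
  if (n_loci < 2) stop("bootstrap over loci is degenerate with one locus")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  af <- allele_frequencies(gt)
  per_locus <- chord_distance_by_locus(af)
  point <- nj_tree(combine_chord(per_locus, seq_len(n_loci), variant))

  boots <- vector("list", reps)
  for (r in seq_len(reps)) {
    pick <- sample.int(n_loci, n_loci, replace = TRUE)
    d <- suppressWarnings(combine_chord(per_locus, pick, variant))
    boots[[r]] <- nj_tree(d)
  }
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / reps
  point$node.label <- formatC(round(100 * support), format = "d")
  res <- list(
    tree = point,
    supports = tibble::tibble(
      node = length(point$tip.label) + seq_len(point$Nnode),
      support = support,
      significant = support > 0.70
    ),
    reps = reps
  )
  class(res) <- "support_tree"
  res
}

#' @export
print.support_tree <- function(x, ...) {
  cat("# Bootstrap NJ tree (", x$reps, " replicates); supports > 0.70 ",
      "flagged significant\n", sep = "")
  print(x$tree)
  print(x$supports)
  invisible(x)
}

#' Write a support tree to Newick
#'
#' Supports are carried as internal node labels (percent).
#'
#' @param x A `support_tree` from [bootstrap_nj()] (or a bare `phylo`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_support_tree <- function(x, path) {
  tr <- if (inherits(x, "support_tree")) x$tree else x
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' Tidy bootstrap supports
#' @param x A `support_tree`.
#' @param ... Unused.
#' @return The `supports` tibble.
#' @method tidy support_tree
#' @export
tidy.support_tree <- function(x, ...) x$supports

# ---- Principal coordinates --------------------------------------------------

#' Principal coordinates analysis of a population distance matrix
#'
#' Classical metric scaling: double-centre `-D^2/2`, eigendecompose, scale
#' eigenvectors by the root eigenvalues. Percent variance per axis is taken
#' over the positive eigenvalues only.
#'
#' @param d A `geno_dist`, `dist` or symmetric matrix.
#' @return A `pcoa_result`: list with `points` (populations x axes),
#'   `eig` (all eigenvalues) and `percent` (percent of positive-eigenvalue
#'   variance per retained axis).
#' @export
pcoa <- function(d) {
  m <- as.matrix(unclass(d))
  n <- nrow(m)
  sc <- stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE)
  eig <- sc$eig
  tol <- max(abs(eig)) * 1e-8
  pos <- which(eig > tol)
  if (length(pos) == 0) {
    res <- list(points = matrix(0, n, 0, dimnames = list(rownames(m), NULL)),
                eig = eig, percent = numeric(0))
  } else {
    pts <- sc$points[, pos, drop = FALSE]
    colnames(pts) <- paste0("axis_", seq_along(pos))
    rownames(pts) <- rownames(m)
    res <- list(points = pts, eig = eig,
                percent = 100 * eig[pos] / sum(eig[pos]))
  }
  class(res) <- "pcoa_result"
  res
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("# Principal coordinates:", ncol(x$points), "positive axes\n")
  cat("  percent variance:",
      paste(sprintf("%.1f", x$percent), collapse = ", "), "\n")
  print(round(x$points, 4))
  invisible(x)
}

#' Tidy PCoA coordinates
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @return Long tibble `population`, `axis`, `coordinate`, `percent`.
#' @method tidy pcoa_result
#' @export
tidy.pcoa_result <- function(x, ...) {
  if (ncol(x$points) == 0) {
    return(tibble::tibble(population = character(), axis = integer(),
                          coordinate = numeric(), percent = numeric()))
  }
  tibble::as_tibble(x$points, rownames = "population") |>
    tidyr::pivot_longer(-"population", names_to = "axis",
                        values_to = "coordinate") |>
    dplyr::mutate(axis = as.integer(sub("axis_", "", .data$axis)),
                  percent = x$percent[.data$axis])
}

#' @method glance pcoa_result
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(n_axes = ncol(x$points),
                 percent_axis1 = if (length(x$percent)) x$percent[1] else NA_real_,
                 percent_axis2 = if (length(x$percent) > 1) x$percent[2] else NA_real_)
}

#' Scatter plot of the first two principal coordinates
#' @param object A `pcoa_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, ...) {
  stopifnot(ncol(object$points) >= 2)
  df <- tibble::as_tibble(object$points, rownames = "population")
  ggplot2::ggplot(df, ggplot2::aes(.data$axis_1, .data$axis_2,
                                   label = .data$population)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8) +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%%)", object$percent[1]),
      y = sprintf("Axis 2 (%.1f%%)", object$percent[2])
    ) +
    ggplot2::theme_minimal()
}

# ---- Weir-Cockerham theta ---------------------------------------------------

# Integer-coded per-locus genotype matrices for fast resampling.
# Returns list(A1, A2: n_ind x L integer matrices of allele codes (NA =
# missing), pop: integer labels, pops: level names, loci: locus names).
geno_matrices <- function(gt) {
  loci <- locus_levels(gt)
  w1 <- gt |> dplyr::select("individual", "population", "locus", "allele_1") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "allele_1")
  w2 <- gt |> dplyr::select("individual", "population", "locus", "allele_2") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "allele_2")
  A1 <- as.matrix(w1[loci]); A2 <- as.matrix(w2[loci])
  # recode each locus to 1..K
  K <- integer(length(loci))
  for (l in seq_along(loci)) {
    alleles <- sort(unique(stats::na.omit(c(A1[, l], A2[, l]))))
    A1[, l] <- match(A1[, l], alleles)
    A2[, l] <- match(A2[, l], alleles)
    K[l] <- length(alleles)
  }
  list(A1 = A1, A2 = A2, pop = as.integer(w1$population),
       pops = levels(w1$population), loci = loci, K = K,
       individual = w1$individual)
}

# Weir-Cockerham (1984) variance components a, b, c summed over alleles and
# loci for the individuals selected by `labels` (integer 1..r, NA = excluded).
wc_theta_kernel <- function(A1, A2, labels, K, r) {
  sum_a <- 0; sum_abc <- 0
  for (l in seq_len(ncol(A1))) {
    a1 <- A1[, l]; a2 <- A2[, l]
    typed <- !is.na(a1) & !is.na(labels)
    lab <- labels[typed]
    n_i <- tabulate(lab, nbins = r)
    if (any(n_i == 0)) next                  # locus untyped in a population
    n_bar <- mean(n_i)
    if (n_bar <= 1) next
    n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
    if (n_c <= 0) next
    k <- K[l]
    t1 <- a1[typed]; t2 <- a2[typed]
    het <- t1 != t2
    p_mat <- matrix(0, r, k)    # allele freq per pop
    h_mat <- matrix(0, r, k)    # het-carrier freq per pop
    for (i in seq_len(r)) {
      in_i <- lab == i
      cnt <- tabulate(c(t1[in_i], t2[in_i]), nbins = k)
      p_mat[i, ] <- cnt / (2 * n_i[i])
      hh <- in_i & het
      h_mat[i, ] <- (tabulate(t1[hh], nbins = k) +
                       tabulate(t2[hh], nbins = k)) / n_i[i]
    }
    p_bar <- colSums(n_i * p_mat) / (r * n_bar)
    s2 <- colSums(n_i * (p_mat - rep(p_bar, each = r))^2) / ((r - 1) * n_bar)
    h_bar <- colSums(n_i * h_mat) / (r * n_bar)
    a_comp <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
    b_comp <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
         (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    c_comp <- h_bar / 2
    sum_a <- sum_a + sum(a_comp)
    sum_abc <- sum_abc + sum(a_comp + b_comp + c_comp)
  }
  if (sum_abc == 0) return(NA_real_)
  sum_a / sum_abc
}

#' Weir-Cockerham theta for a pair (or set) of populations
#'
#' Multi-allelic, multi-locus Weir-Cockerham (1984) estimator of F_ST:
#' variance components among populations (a), among individuals within
#' populations (b) and within individuals (c) are computed per allele and
#' locus from sample sizes, allele frequencies and observed heterozygote
#' frequencies, and combined as a ratio of sums,
#' `theta = sum(a) / sum(a + b + c)`. Missing genotypes reduce the per-locus
#' sample sizes; a locus untyped in one of the populations is excluded.
#' Theta may be negative in weakly differentiated data and is reported as
#' computed.
#'
#' @param gt A [genotype_table()].
#' @param pops Character vector of population labels to include (default:
#'   all populations in `gt`).
#' @return The theta estimate (scalar).
#' @export
pairwise_fst <- function(gt, pops = NULL) {
  gm <- geno_matrices(gt)
  if (is.null(pops)) pops <- gm$pops
  idx <- match(pops, gm$pops)
  if (anyNA(idx)) stop("unknown population(s): ",
                       paste(pops[is.na(idx)], collapse = ", "))
  labels <- match(gm$pop, idx)   # NA for excluded pops
  wc_theta_kernel(gm$A1, gm$A2, labels, gm$K, length(idx))
}

#' Permutation test for pairwise theta
#'
#' Pools the two samples' individuals (full multilocus genotypes), randomly
#' reassigns population labels preserving the two sample sizes, and
#' recomputes theta each time;
#' `p = (1 + #\{theta_perm >= theta_obs\}) / (reps + 1)`.
#'
#' @param gt A [genotype_table()].
#' @param pop_a,pop_b Population labels.
#' @param reps Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return A list with `theta`, `p`, `reps`.
#' @export
fst_permutation_test <- function(gt, pop_a, pop_b, reps = 10000,
                                 seed = NULL) {
  if (reps < 1) stop("reps must be >= 1")
  gm <- geno_matrices(gt)
  idx <- match(c(pop_a, pop_b), gm$pops)
  if (anyNA(idx)) stop("unknown population label")
  keep <- gm$pop %in% idx
  A1 <- gm$A1[keep, , drop = FALSE]
  A2 <- gm$A2[keep, , drop = FALSE]
  labels <- match(gm$pop[keep], idx)
  theta_obs <- wc_theta_kernel(A1, A2, labels, gm$K, 2L)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  hits <- 0L
  for (r in seq_len(reps)) {
    th <- wc_theta_kernel(A1, A2, sample(labels), gm$K, 2L)
    if (!is.na(th) && th >= theta_obs - 1e-12) hits <- hits + 1L
  }
  list(theta = theta_obs, p = (hits + 1) / (reps + 1), reps = reps)
}

#' All pairwise theta values with permutation p-values
#'
#' @param gt A [genotype_table()].
#' @param perms Permutations per pair (0 to skip testing).
#' @param seed Root seed, split per pair.
#' @return An `fst_result`: list with `theta` (matrix), `p` (matrix or
#'   NULL), `perms`.
#' @export
fst_matrix <- function(gt, perms = 10000, seed = NULL) {
  pops <- pop_levels(gt)
  k <- length(pops)
  theta <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  diag(theta) <- 0
  pmat <- if (perms > 0) theta else NULL
  if (!is.null(pmat)) diag(pmat) <- NA_real_
  pair_id <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pair_id <- pair_id + 1L
      if (perms > 0) {
        res <- fst_permutation_test(
          gt, pops[i], pops[j], reps = perms,
          seed = if (is.null(seed)) NULL else seed + pair_id
        )
        theta[i, j] <- theta[j, i] <- res$theta
        pmat[i, j] <- pmat[j, i] <- res$p
      } else {
        theta[i, j] <- theta[j, i] <- pairwise_fst(gt, c(pops[i], pops[j]))
      }
    }
  }
  structure(list(theta = theta, p = pmat, perms = perms),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("# Pairwise Weir-Cockerham theta (lower triangle)",
      if (!is.null(x$p)) paste0("; permutation p (upper, ", x$perms,
                                " perms)"), "\n", sep = "")
  m <- x$theta
  if (!is.null(x$p)) m[upper.tri(m)] <- x$p[upper.tri(m)]
  diag(m) <- NA
  print(round(m, 4))
  invisible(x)
}

#' Tidy pairwise theta results
#' @param x An `fst_result`.
#' @param ... Unused.
#' @return A tibble `pop_a`, `pop_b`, `theta`, `p`.
#' @method tidy fst_result
#' @export
tidy.fst_result <- function(x, ...) {
  idx <- which(lower.tri(x$theta), arr.ind = TRUE)
  tibble::tibble(
    pop_a = rownames(x$theta)[idx[, 1]],
    pop_b = colnames(x$theta)[idx[, 2]],
    theta = x$theta[idx],
    p = if (is.null(x$p)) NA_real_ else x$p[idx]
  )
}

#' @method glance fst_result
#' @export
glance.fst_result <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(n_pairs = nrow(td),
                 mean_theta = mean(td$theta, na.rm = TRUE),
                 max_theta = max(td$theta, na.rm = TRUE),
                 perms = x$perms)
}
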