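test_that("interpolation reproduces stored values at centres and blends
           linearly between cells", {
  f <- uniform_fields(u0 = 0.1, v0 = 0.2, temp0 = 17)
  # cell centre, on a time step
  at <- interpolate_fields(f, 5000 + 10000 * 4, 5000 + 10000 * 10, 86400)
  expect_equal(at$u, 0.1)
  expect_equal(at$v, 0.2)
  expect_equal(at$temp, 17)

  g <- f
  g$u[5, 11, ] <- 0.1
  g$u[6, 11, ] <- 0.3
  mid <- interp_array(g, g$u, 10000 * 5, 10000 * 10.5, 0)
  expect_equal(mid, 0.2)

  expect_error(interpolate_fields(f, -5, 1000, 0), "outside")
})

test_that("interpolation matches an independent per-point oracle on random
           probes", {
  set.seed(42)
  nx <- 12; ny <- 10; cell <- 1000
  times <- c(0, 3600, 7200)
  arr <- array(stats::rnorm(nx * ny * 3), c(nx, ny, 3))
  mask <- matrix(TRUE, nx, ny)
  mask[3, 4] <- FALSE   # one land cell to exercise renormalisation
  f <- ocean_fields(arr, arr, arr + 15, mask, cell, cell, times)

  oracle <- function(x, y, t) {
    k0 <- min(max(floor(t / 3600) + 1, 1), 2); ft <- (t - times[k0]) / 3600
    gx <- x / cell - 0.5; gy <- y / cell - 0.5
    i0 <- min(max(floor(gx) + 1, 1), nx - 1)
    j0 <- min(max(floor(gy) + 1, 1), ny - 1)
    fx <- gx - (i0 - 1); fy <- gy - (j0 - 1)
    tot <- 0; wtot <- 0
    for (di in 0:1) for (dj in 0:1) {
      w <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy)
      if (!mask[i0 + di, j0 + dj]) next
      vt <- (1 - ft) * arr[i0 + di, j0 + dj, k0] +
        ft * arr[i0 + di, j0 + dj, k0 + 1]
      tot <- tot + w * vt; wtot <- wtot + w
    }
    tot / wtot
  }
  for (rep in 1:30) {
    # probes between the outermost cell centres, where bilinear weights are
    # unambiguous (the outer half-cells use constant extrapolation)
    x <- stats::runif(1, 0.5 * cell, (nx - 0.5) * cell - 1)
    y <- stats::runif(1, 0.5 * cell, (ny - 0.5) * cell - 1)
    t <- stats::runif(1, 0, 7200)
    expect_equal(interp_array(f, f$u, x, y, t), oracle(x, y, t),
                 tolerance = 1e-9)
  }
})

test_that("release schedules do the bookkeeping of sites times days", {
  sites3 <- tibble::tibble(site = c("a", "b", "c"), x = 1:3, y = 1)
  expect_equal(nrow(build_release_schedule(sites3, 1, 5, every = 2)), 9)
  expect_equal(nrow(build_release_schedule(sites3[1, ], 4, 4)), 1)
  sched <- build_release_schedule(sites3, 1, 14, every = 2)
  expect_equal(unique(sched$day), c(1, 3, 5, 7, 9, 11, 13))
  expect_equal(sched$release_time, (sched$day - 1) * 86400)

  f <- uniform_fields()
  land_site <- tibble::tibble(site = "bad", x = 5000, y = 5000)  # on land
  expect_error(build_release_schedule(land_site, 1, 3, fields = f), "bad")
})

test_that("advection follows the closed-form step and accumulates
           degree-days from the pre-step temperature", {
  f <- uniform_fields(u0 = 0.1, v0 = 0, temp0 = 20)
  larva <- tibble::tibble(site = "s", release_time = 0, x = 50000, y = 50000,
                          time = 0, dd = 0, status = "PELAGIC",
                          landing_x = NA_real_, landing_y = NA_real_,
                          landing_time = NA_real_, t_land = NA_real_)
  out <- advect(larva, f, dt = 3600)
  expect_equal(out$x, 50000 + 0.1 * 3600)
  expect_equal(out$y, 50000)
  expect_equal(out$dd, 20 * 3600 / 86400)

  # stationary water: 1 day at 20 C with base 0 adds exactly 20 degree-days
  f0 <- uniform_fields(u0 = 0, v0 = 0, temp0 = 20)
  l2 <- larva
  for (s in 1:24) {
    l2 <- advect(l2, f0, dt = 3600)
  }
  expect_equal(l2$x, 50000)
  expect_equal(l2$dd, 20)

  # base temperature subtracts, floored at zero
  f15 <- uniform_fields(u0 = 0, v0 = 0, temp0 = 15)
  l3 <- advect(larva, f15, dt = 3600, t_base = 16)
  expect_equal(l3$dd, 0)
  expect_error(advect(larva, f, dt = 0), "positive")
})

test_that("landing classification applies both thresholds inclusively", {
  expect_equal(classify_landing(225, 18), "LANDED_SURVIVED")
  expect_equal(classify_landing(224.9, 20), "LANDED_FAILED")
  expect_equal(classify_landing(300, 17.9), "LANDED_FAILED")
  expect_equal(classify_landing(c(230, 100), c(19, 25)),
               c("LANDED_SURVIVED", "LANDED_FAILED"))
})

test_that("a uniform-flow crossing lands with degree-days equal to
           temperature times transit days", {
  # 255 km from the release line to the recipient land strip, crossed in
  # exactly 10 days at 25 C: DD at landing = 250, T_land = 25 >= 18
  v0 <- 255000 / (10 * 86400)
  f <- uniform_fields(u0 = 0, v0 = v0, temp0 = 25)
  sites <- tibble::tibble(site = "s1", x = 95000, y = 25000)
  rel <- build_release_schedule(sites, 1, 1, fields = f)
  rec <- run_scenario(f, rel, dt = 3600, max_days = 15)
  expect_equal(rec$status, "LANDED_SURVIVED")
  expect_equal(rec$dd, 250, tolerance = 1e-9)
  expect_equal(rec$t_land, 25)
  expect_equal(rec$landing_time - rec$release_time, 10 * 86400)

  # same crossing at 15 C: fails both gates (DD = 150 < 225, T < 18)
  f_cold <- uniform_fields(u0 = 0, v0 = v0, temp0 = 15)
  rec_cold <- run_scenario(f_cold, rel, dt = 3600, max_days = 15)
  expect_equal(rec_cold$status, "LANDED_FAILED")
  expect_equal(rec_cold$dd, 150, tolerance = 1e-9)

  # stagnant water: expiry at the maximum pelagic duration
  f_still <- uniform_fields(u0 = 0, v0 = 0, temp0 = 25)
  rec_still <- run_scenario(f_still, rel, dt = 3600, max_days = 5)
  expect_equal(rec_still$status, "EXPIRED")
})

test_that("trajectories are bit-reproducible and every larva is accounted
           for", {
  sc <- generate_ocean_scenario("moderate", n_sites = 10)
  r1 <- run_scenario(sc$fields, sc$release, dt = 7200)
  r2 <- run_scenario(sc$fields, sc$release, dt = 7200)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 70)
  expect_equal(sum(r1$status == "LANDED_SURVIVED") +
                 sum(r1$status == "LANDED_FAILED") +
                 sum(r1$status == "EXPIRED"), nrow(r1))
  expect_true(all(r1$dd >= 0))
  landed <- r1$status %in% c("LANDED_SURVIVED", "LANDED_FAILED")
  expect_true(all(!is.na(r1$t_land[landed])))
  expect_true(all(is.na(r1$t_land[!landed])))
})

test_that("warming a scenario pointwise never loses a survivor", {
  base <- generate_ocean_scenario("moderate", n_sites = 16)
  warm <- generate_ocean_scenario("moderate", n_sites = 16,
                                  t_offset = 1.5 + 2)
  rb <- run_scenario(base$fields, base$release, dt = 7200)
  rw <- run_scenario(warm$fields, warm$release, dt = 7200)
  expect_gte(sum(rw$status == "LANDED_SURVIVED"),
             sum(rb$status == "LANDED_SURVIVED"))
  # survivors at the base temperature remain survivors when warmed
  surv_base <- which(rb$status == "LANDED_SURVIVED")
  expect_true(all(rw$status[surv_base] == "LANDED_SURVIVED"))
})

test_that("halving dt shrinks the trajectory error like a first-order
           scheme", {
  sc <- generate_ocean_scenario("warm", pattern = "gyre", n_sites = 1)
  f <- sc$fields
  start <- tibble::tibble(site = "g", release_time = 0,
                          x = f$nx * f$dx * 0.3, y = f$ny * f$dy * 0.5,
                          time = 0, dd = 0, status = "PELAGIC",
                          landing_x = NA_real_, landing_y = NA_real_,
                          landing_time = NA_real_, t_land = NA_real_)
  drift <- function(dt, hours = 96) {
    l <- start
    for (s in seq_len(hours * 3600 / dt)) l <- advect(l, f, dt)
    c(l$x, l$y)
  }
  p1 <- drift(7200)
  p2 <- drift(3600)
  p3 <- drift(1800)
  e1 <- sqrt(sum((p1 - p3)^2))
  e2 <- sqrt(sum((p2 - p3)^2))
  expect_lt(e2, e1)              # refining dt converges
  # RK4 at the coarse step should beat Euler at the coarse step
  drift_rk <- function(dt, hours = 96) {
    l <- start
    for (s in seq_len(hours * 3600 / dt)) {
      l <- advect(l, f, dt, integrator = "rk4")
    }
    c(l$x, l$y)
  }
  ref <- drift(450)
  expect_lt(sqrt(sum((drift_rk(7200) - ref)^2)),
            sqrt(sum((p1 - ref)^2)))
})

test_that("aggregation bins survivors on a half-open 50 km grid and keeps
           totals consistent", {
  rec <- tibble::tibble(
    site = c("a", "b", "c", "d"), release_time = 0,
    x = 0, y = 0, time = 0, dd = c(250, 260, 230, 100),
    status = c("LANDED_SURVIVED", "LANDED_SURVIVED", "LANDED_SURVIVED",
               "LANDED_FAILED"),
    landing_x = c(10000, 20000, 50000, 1000),
    landing_y = c(5000, 8000, 5000, 1000),
    landing_time = 1, t_land = 20
  )
  ls <- aggregate_landings(rec, cell_km = 50, origin = c(0, 0))
  cells <- ls$cells
  expect_equal(sum(cells$n_landed), 3)      # failed landing not binned
  expect_equal(cells$n_landed[cells$cell_x == 0 & cells$cell_y == 0], 2)
  # landing exactly on the 50 km edge goes to the upper cell
  expect_equal(cells$n_landed[cells$cell_x == 1 & cells$cell_y == 0], 1)
  expect_equal(ls$summary$n_released, 4)
  expect_equal(ls$summary$fraction_landed, 3 / 4)

  # region counting via point-in-polygon
  box <- cbind(c(0, 30000, 30000, 0), c(0, 0, 30000, 30000))
  ls2 <- aggregate_landings(rec, cell_km = 50, regions = list(west = box),
                            origin = c(0, 0))
  expect_equal(ls2$summary$n_west, 2)
  expect_equal(ls2$summary$fraction_west, 0.5)

  # per-cell totals equal a per-record tally
  sc <- generate_ocean_scenario("warm", n_sites = 8)
  r <- run_scenario(sc$fields, sc$release, dt = 7200)
  lsr <- aggregate_landings(r)
  expect_equal(sum(lsr$cells$n_landed),
               sum(r$status == "LANDED_SURVIVED"))
})
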