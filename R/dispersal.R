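#' Gridded ocean fields for larval drift
#'
#' Container for time-stepped surface fields on a regular planar grid:
#' eastward and northward velocity (m/s) and temperature (deg C), plus a
#' static land mask. Coordinates are metres from the domain origin; cell
#' centres sit at `x0 + (i - 0.5) * dx`. Only a single (surface) layer is
#' represented: drifting oyster larvae are modelled as passive, so no
#' vertical structure is needed.
#'
#' @param u,v,temp Numeric arrays of dimension `c(nx, ny, nt)`.
#' @param mask Logical `nx x ny` matrix, `TRUE` for water.
#' @param dx,dy Cell size in metres.
#' @param times Strictly increasing, uniformly spaced time axis in seconds.
#' @param x0,y0 Domain origin in metres.
#' @return An object of class `ocean_fields`.
#' @export
ocean_fields <- function(u, v, temp, mask, dx, dy, times, x0 = 0, y0 = 0) {
  stopifnot(length(dim(u)) == 3, identical(dim(u), dim(v)),
            identical(dim(u), dim(temp)),
            identical(dim(u)[1:2], dim(mask)),
            dim(u)[3] == length(times), dx > 0, dy > 0)
  if (length(times) > 1) {
    steps <- diff(times)
    if (any(steps <= 0)) stop("time axis must be strictly increasing")
    if (max(steps) - min(steps) > 1e-6 * steps[1]) {
      stop("time axis must be uniform")
    }
  }
  wet <- which(mask)
  for (nm in c("u", "v", "temp")) {
    arr <- get(nm)
    for (k in seq_along(times)) {
      slab <- arr[, , k]
      if (any(!is.finite(slab[wet]))) {
        stop("non-finite ", nm, " on water cells at time step ", k)
      }
    }
  }
  structure(
    list(u = u, v = v, temp = temp, mask = mask,
         dx = dx, dy = dy, times = times, x0 = x0, y0 = y0,
         nx = dim(u)[1], ny = dim(u)[2], nt = length(times)),
    class = "ocean_fields"
  )
}

#' @export
print.ocean_fields <- function(x, ...) {
  cat("# Ocean fields: ", x$nx, " x ", x$ny, " cells (",
      x$dx / 1000, " km), ", x$nt, " time steps, ",
      round(100 * mean(x$mask)), "% water\n", sep = "")
  invisible(x)
}

domain_extent <- function(f) {
  c(xmin = f$x0, xmax = f$x0 + f$nx * f$dx,
    ymin = f$y0, ymax = f$y0 + f$ny * f$dy)
}

cell_index <- function(f, x, y) {
  ix <- floor((x - f$x0) / f$dx) + 1
  iy <- floor((y - f$y0) / f$dy) + 1
  cbind(ix, iy)
}

in_domain <- function(f, x, y) {
  ext <- domain_extent(f)
  x >= ext["xmin"] & x < ext["xmax"] & y >= ext["ymin"] & y < ext["ymax"]
}

is_water <- function(f, x, y) {
  idx <- cell_index(f, x, y)
  ok <- idx[, 1] >= 1 & idx[, 1] <= f$nx & idx[, 2] >= 1 & idx[, 2] <= f$ny
  out <- rep(FALSE, length(x))
  out[ok] <- f$mask[idx[ok, , drop = FALSE]]
  out
}

# Bilinear space / linear time interpolation of one field array at positions
# (x, y) and scalar time t. Land cells get zero weight and the remaining
# weights are renormalised, so values near the coast are water-only
# averages. Returns NA where all four surrounding cells are land.
interp_array <- function(f, arr, x, y, t) {
  n <- length(x)
  # time bracket
  if (t < f$times[1] - 1e-6 || t > f$times[f$nt] + 1e-6) {
    stop("time ", t, " outside the field time axis")
  }
  if (f$nt == 1) {
    k0 <- 1; k1 <- 1; ft <- 0
  } else {
    step <- f$times[2] - f$times[1]
    k0 <- pmin(pmax(floor((t - f$times[1]) / step) + 1, 1), f$nt - 1)
    k1 <- k0 + 1
    ft <- (t - f$times[k0]) / step
  }
  gx <- (x - f$x0) / f$dx - 0.5
  gy <- (y - f$y0) / f$dy - 0.5
  i0 <- pmin(pmax(floor(gx) + 1, 1), f$nx - 1)
  j0 <- pmin(pmax(floor(gy) + 1, 1), f$ny - 1)
  fx <- pmin(pmax(gx - (i0 - 1), 0), 1)
  fy <- pmin(pmax(gy - (j0 - 1), 0), 1)

  val <- numeric(n)
  wsum <- numeric(n)
  nxy <- f$nx * f$ny
  base0 <- (k0 - 1) * nxy
  base1 <- (k1 - 1) * nxy
  for (corner in 1:4) {
    di <- c(0, 1, 0, 1)[corner]
    dj <- c(0, 0, 1, 1)[corner]
    wi <- if (di == 0) 1 - fx else fx
    wj <- if (dj == 0) 1 - fy else fy
    ci <- i0 + di
    cj <- j0 + dj
    cidx <- ci + (cj - 1) * f$nx
    w <- wi * wj * f$mask[cidx]
    v0 <- arr[base0 + cidx]
    v1 <- arr[base1 + cidx]
    vt <- (1 - ft) * v0 + ft * v1
    vt[w == 0] <- 0
    val <- val + w * vt
    wsum <- wsum + w
  }
  out <- ifelse(wsum > 0, val / wsum, NA_real_)
  out
}

#' Interpolate velocity and temperature at positions
#'
#' Bilinear in space over the four surrounding cell centres, with land
#' cells given zero weight and the remaining weights renormalised; linear
#' in time.
#'
#' @param fields An [ocean_fields()] object.
#' @param x,y Positions in metres (vectors of equal length).
#' @param t Time in seconds (scalar), within the field time axis.
#' @return A tibble with `u`, `v`, `temp` (NA where every neighbouring cell
#'   is land).
#' @export
interpolate_fields <- function(fields, x, y, t) {
  if (any(!in_domain(fields, x, y))) {
    stop("position outside the model domain")
  }
  tibble::tibble(
    u = interp_array(fields, fields$u, x, y, t),
    v = interp_array(fields, fields$v, x, y, t),
    temp = interp_array(fields, fields$temp, x, y, t)
  )
}

#' Build a release schedule of super-individuals
#'
#' One super-individual per site per release day; release days run from
#' `start_day` to `end_day` in steps of `every` days. Day `d` maps to
#' release time `(d - 1) * 86400` seconds on the field time axis.
#'
#' @param sites A data frame with columns `site`, `x`, `y` (metres).
#' @param start_day,end_day First and last release day (inclusive bound).
#' @param every Release interval in days (default 2: every second day).
#' @param fields Optional [ocean_fields()]; if supplied, sites are checked
#'   to lie on water cells.
#' @return A tibble with `site`, `x`, `y`, `day`, `release_time`, one row
#'   per super-individual.
#' @export
build_release_schedule <- function(sites, start_day, end_day, every = 2,
                                   fields = NULL) {
  stopifnot(all(c("site", "x", "y") %in% names(sites)), nrow(sites) > 0)
  if (!is.null(fields)) {
    wet <- is_water(fields, sites$x, sites$y)
    if (any(!wet)) {
      stop("release site(s) on land: ",
           paste(sites$site[!wet], collapse = ", "))
    }
  }
  days <- seq(start_day, end_day, by = every)
  tidyr::expand_grid(sites[c("site", "x", "y")], day = days) |>
    dplyr::mutate(release_time = (.data$day - 1) * 86400) |>
    dplyr::arrange(.data$site, .data$day)
}

#' Classify a coast contact
#'
#' A larva contacting the coast has `LANDED_SURVIVED` status iff it has
#' accumulated at least `dd_threshold` degree-days (development to
#' settlement competence) and the water temperature at the landing site is
#' at least `t_threshold` (both thresholds inclusive); otherwise
#' `LANDED_FAILED`.
#'
#' @param dd Accumulated degree-days (deg C day), vectorised.
#' @param t_land Temperature at the landing site (deg C), vectorised.
#' @param dd_threshold Degree-day requirement (default 225).
#' @param t_threshold Landing temperature requirement (default 18).
#' @return Character vector of statuses.
#' @export
classify_landing <- function(dd, t_land, dd_threshold = 225,
                             t_threshold = 18) {
  ifelse(dd >= dd_threshold & t_land >= t_threshold,
         "LANDED_SURVIVED", "LANDED_FAILED")
}

#' Advect pelagic larvae one time step
#'
#' Deterministic passive transport: positions move by the local velocity
#' times `dt` (explicit Euler, or a 4th-order Runge-Kutta step with
#' `integrator = "rk4"`), and the degree-day clock advances by
#' `max(temp - t_base, 0) * dt / 86400` using the temperature at the
#' pre-step position. A step that would enter a land cell raises a coast
#' contact: the larva sticks at its last water position and is classified
#' immediately; a step leaving the domain expires the larva. No behaviour
#' and no random walk: trajectories are bit-reproducible.
#'
#' @param larvae A tibble of larva records (see [run_scenario()]).
#' @param fields An [ocean_fields()] object.
#' @param dt Time step in seconds, `> 0`.
#' @param t_base Degree-day base temperature (deg C), default 0.
#' @param dd_threshold,t_threshold Settlement thresholds, see
#'   [classify_landing()].
#' @param integrator `"euler"` (default) or `"rk4"`.
#' @return The updated larva records.
#' @export
advect <- function(larvae, fields, dt, t_base = 0,
                   dd_threshold = 225, t_threshold = 18,
                   integrator = c("euler", "rk4")) {
  integrator <- match.arg(integrator)
  if (dt <= 0) stop("dt must be positive")
  act <- which(larvae$status == "PELAGIC")
  if (length(act) == 0) return(larvae)
  x <- larvae$x[act]; y <- larvae$y[act]; t <- larvae$time[act][1]
  cur <- interpolate_fields(fields, x, y, t)

  larvae$dd[act] <- larvae$dd[act] +
    pmax(cur$temp - t_base, 0) * dt / 86400

  if (integrator == "euler") {
    nx <- x + cur$u * dt
    ny <- y + cur$v * dt
  } else {
    k1u <- cur$u; k1v <- cur$v
    probe <- function(px, py, pt) {
      ok <- in_domain(fields, px, py)
      px[!ok] <- x[!ok]; py[!ok] <- y[!ok]
      interpolate_fields(fields, px, py, min(pt, max(fields$times)))
    }
    s2 <- probe(x + k1u * dt / 2, y + k1v * dt / 2, t + dt / 2)
    s3 <- probe(x + s2$u * dt / 2, y + s2$v * dt / 2, t + dt / 2)
    s4 <- probe(x + s3$u * dt, y + s3$v * dt, t + dt)
    nx <- x + dt / 6 * (k1u + 2 * s2$u + 2 * s3$u + s4$u)
    ny <- y + dt / 6 * (k1v + 2 * s2$v + 2 * s3$v + s4$v)
  }

  t_next <- min(t + dt, max(fields$times))
  out <- !in_domain(fields, nx, ny)
  onto_land <- rep(FALSE, length(act))
  onto_land[!out] <- !is_water(fields, nx[!out], ny[!out])

  # coast contact: stick at the last water position, classify immediately
  if (any(onto_land)) {
    w <- act[onto_land]
    t_land <- interp_array(fields, fields$temp, larvae$x[w], larvae$y[w],
                           t_next)
    larvae$status[w] <- classify_landing(larvae$dd[w], t_land,
                                         dd_threshold, t_threshold)
    larvae$landing_x[w] <- nx[onto_land]
    larvae$landing_y[w] <- ny[onto_land]
    larvae$landing_time[w] <- t_next
    larvae$t_land[w] <- t_land
  }
  if (any(out)) {
    larvae$status[act[out]] <- "EXPIRED"
  }
  move <- !out & !onto_land
  larvae$x[act[move]] <- nx[move]
  larvae$y[act[move]] <- ny[move]
  larvae$time[act] <- t + dt
  larvae
}

#' Run a larval drift scenario
#'
#' Steps every super-individual from its release until coast contact,
#' domain exit, or the maximum pelagic duration. Fully deterministic:
#' identical inputs give bit-identical trajectories.
#'
#' @param fields An [ocean_fields()] object covering the full simulation
#'   window (`max(release_time) + max_days` days).
#' @param release A release schedule from [build_release_schedule()].
#' @param dt Time step in seconds (default 3600).
#' @param max_days Maximum pelagic duration in days from release
#'   (default 60); larvae still adrift then are `EXPIRED`.
#' @param dd_threshold,t_threshold Settlement thresholds, see
#'   [classify_landing()].
#' @param t_base Degree-day base temperature (default 0).
#' @param integrator `"euler"` or `"rk4"`.
#' @return A tibble of class `larva_records`: one row per super-individual
#'   with final `status` (`LANDED_SURVIVED`, `LANDED_FAILED`, `EXPIRED`),
#'   position, accumulated degree-days `dd`, and landing position, time and
#'   temperature where landed.
#' @export
run_scenario <- function(fields, release, dt = 3600, max_days = 60,
                         dd_threshold = 225, t_threshold = 18, t_base = 0,
                         integrator = c("euler", "rk4")) {
  integrator <- match.arg(integrator)
  if (dt <= 0) stop("dt must be positive")
  t_end_needed <- max(release$release_time) + max_days * 86400
  if (t_end_needed > max(fields$times)) {
    stop("fields end before the simulation window (need ",
         t_end_needed, " s, have ", max(fields$times), " s)")
  }
  wet <- is_water(fields, release$x, release$y)
  if (any(!wet)) {
    stop("release site(s) on land: ",
         paste(unique(release$site[!wet]), collapse = ", "))
  }

  larvae <- tibble::tibble(
    site = release$site,
    release_time = release$release_time,
    x = release$x, y = release$y,
    time = release$release_time,
    dd = 0,
    status = "PENDING",
    landing_x = NA_real_, landing_y = NA_real_,
    landing_time = NA_real_, t_land = NA_real_
  )

  t0 <- min(release$release_time)
  n_steps <- ceiling((t_end_needed - t0) / dt)
  t <- t0
  for (s in seq_len(n_steps)) {
    larvae$status[larvae$status == "PENDING" &
                    larvae$release_time <= t] <- "PELAGIC"
    if (any(larvae$status == "PELAGIC")) {
      larvae$time[larvae$status == "PELAGIC"] <- t
      larvae <- advect(larvae, fields, dt, t_base = t_base,
                       dd_threshold = dd_threshold,
                       t_threshold = t_threshold, integrator = integrator)
      expired <- larvae$status == "PELAGIC" &
        (larvae$time - larvae$release_time) >= max_days * 86400
      larvae$status[expired] <- "EXPIRED"
    }
    t <- t + dt
    if (all(larvae$status %in% c("LANDED_SURVIVED", "LANDED_FAILED",
                                 "EXPIRED"))) break
  }
  larvae$status[larvae$status %in% c("PELAGIC", "PENDING")] <- "EXPIRED"
  attr(larvae, "params") <- list(dt = dt, max_days = max_days,
                                 dd_threshold = dd_threshold,
                                 t_threshold = t_threshold, t_base = t_base,
                                 integrator = integrator,
                                 origin = c(fields$x0, fields$y0))
  class(larvae) <- c("larva_records", class(tibble::tibble()))
  larvae
}

# even-odd ray casting; vertices as a 2-column matrix
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Aggregate landings onto a coarse coastal grid
#'
#' Bins survived landings into square cells (default 50 x 50 km) anchored
#' at the domain origin with half-open `[x0, x0 + cell)` edges, and counts
#' landings inside named target regions (point-in-polygon on the landing
#' position). Landings outside every region count in the totals only.
#'
#' @param records A `larva_records` tibble from [run_scenario()], or a
#'   row-bound set of them with a `year` column for multi-year runs.
#' @param cell_km Aggregation cell size in km (default 50).
#' @param regions Optional named list of polygons (2-column matrices of
#'   x, y vertices in metres), e.g. the recipient-coast waters.
#' @param origin Grid anchor `c(x0, y0)`; defaults to the origin recorded
#'   by [run_scenario()].
#' @return A `landing_summary`: list with `summary` (per year: released,
#'   landed, fraction, per-region counts and fractions) and `cells`
#'   (per 50-km-cell survived-landing counts).
#' @export
aggregate_landings <- function(records, cell_km = 50, regions = NULL,
                               origin = NULL) {
  if (is.null(origin)) {
    p <- attr(records, "params")
    origin <- if (!is.null(p)) p$origin else c(0, 0)
  }
  cell <- cell_km * 1000
  if (!"year" %in% names(records)) records$year <- "all"

  landed <- records[records$status == "LANDED_SURVIVED", ]
  summary <- records |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      n_released = dplyr::n(),
      n_landed = sum(.data$status == "LANDED_SURVIVED"),
      n_failed = sum(.data$status == "LANDED_FAILED"),
      n_expired = sum(.data$status == "EXPIRED"),
      fraction_landed = .data$n_landed / .data$n_released,
      .groups = "drop"
    )
  if (!is.null(regions)) {
    for (nm in names(regions)) {
      in_reg <- point_in_polygon(landed$landing_x, landed$landing_y,
                                 regions[[nm]])
      reg_counts <- landed[in_reg, ] |>
        dplyr::count(.data$year, name = paste0("n_", nm))
      summary <- summary |>
        dplyr::left_join(reg_counts, by = "year") |>
        dplyr::mutate(dplyr::across(dplyr::all_of(paste0("n_", nm)),
                                    ~ tidyr::replace_na(.x, 0L))) |>
        dplyr::mutate("fraction_{nm}" := .data[[paste0("n_", nm)]] /
                        .data$n_released)
    }
  }
  cells <- landed |>
    dplyr::mutate(
      cell_x = floor((.data$landing_x - origin[1]) / cell),
      cell_y = floor((.data$landing_y - origin[2]) / cell)
    ) |>
    dplyr::count(.data$year, .data$cell_x, .data$cell_y, name = "n_landed")

  structure(list(summary = summary, cells = cells, cell_km = cell_km),
            class = "landing_summary")
}

#' @export
print.landing_summary <- function(x, ...) {
  cat("# Landing summary (", x$cell_km, " km aggregation cells)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Tidy a landing summary
#' @param x A `landing_summary`.
#' @param ... Unused.
#' @return The per-year summary tibble.
#' @method tidy landing_summary
#' @export
tidy.landing_summary <- function(x, ...) x$summary

#' @method glance landing_summary
#' @export
glance.landing_summary <- function(x, ...) {
  n_rel <- sum(x$summary$n_released)
  n_land <- sum(x$summary$n_landed)
  tibble::tibble(n_released = n_rel, n_landed = n_land,
                 fraction_landed = n_land / n_rel)
}

#' Bar chart of landings per scenario year
#' @param object A `landing_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot landing_summary
#' @export
autoplot.landing_summary <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(c("n_landed", "n_failed", "n_expired"),
                        names_to = "outcome", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$n,
                                   fill = .data$outcome)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "scenario year", y = "super-individuals") +
    ggplot2::theme_minimal()
}
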