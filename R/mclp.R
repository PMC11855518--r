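#' Binary coverage matrix between demand centroids and candidate sites
#'
#' Cell i is covered by candidate j when the straight-line distance from
#' the cell centroid to the site is within the pedestrian service radius
#' \code{speed * cutoff_s} (defaults: 10 km/h for 150 s, i.e. ~416.7 m,
#' giving a total time to defibrillation within 5 min for a round trip).
#' Only active (occupied) demand cells enter the matrix.
#'
#' @param grid a \code{demand_grid}.
#' @param candidates data.frame with \code{site_id}, \code{x}, \code{y}.
#' @param cutoff_s walking-time cut-off in seconds (default 150).
#' @param speed pedestrian speed in m/s (default 10 km/h).
#' @return object of class \code{coverage_matrix}: logical matrix
#'   (cells x sites) with cell/site metadata and demand weights attached.
#' @export
build_coverage <- function(grid, candidates, cutoff_s = 150,
                           speed = 10 / 3.6) {
  stopifnot(inherits(grid, "demand_grid"))
  if (cutoff_s <= 0) stop("cutoff_s must be positive")
  if (is.null(candidates) || nrow(candidates) == 0)
    stop("no candidate sites supplied")
  cells <- active_cells(grid)
  if (nrow(cells) == 0) stop("grid has no active demand cells")
  radius <- speed * cutoff_s
  dx <- outer(cells$cx, candidates$x, "-")
  dy <- outer(cells$cy, candidates$y, "-")
  a <- sqrt(dx^2 + dy^2) <= radius
  dimnames(a) <- list(cells$cell_id, candidates$site_id)
  structure(list(a = a, cells = cells, candidates = candidates,
                 cutoff_s = cutoff_s, speed = speed, radius = radius,
                 weights = cells$event_count),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf(
    "Coverage matrix: %d demand cells x %d candidates (radius %.1f m)\n",
    nrow(x$a), ncol(x$a), x$radius))
  cat(sprintf("  coverable cells: %d; total demand: %d\n",
              sum(rowSums(x$a) > 0), sum(x$weights)))
  invisible(x)
}

new_coverage_solution <- function(cov, selected_idx, p, optimal) {
  sel <- sort(selected_idx)
  covered <- if (length(sel)) rowSums(cov$a[, sel, drop = FALSE]) > 0
             else rep(FALSE, nrow(cov$a))
  structure(list(
    p = p,
    selected = colnames(cov$a)[sel],
    selected_idx = sel,
    covered_cells = rownames(cov$a)[covered],
    covered_demand = sum(cov$weights[covered]),
    n_covered_cells = sum(covered),
    n_active_cells = nrow(cov$a),
    coverage_fraction_cells = sum(covered) / nrow(cov$a),
    coverage_fraction_demand = sum(cov$weights[covered]) / sum(cov$weights),
    objective_is_optimal = optimal
  ), class = "coverage_solution")
}

#' @export
print.coverage_solution <- function(x, ...) {
  cat(sprintf(
    "MCLP solution (p = %d, %s): %d/%d centroids (%.0f%%), demand %d (%.0f%%)\n",
    x$p, if (x$objective_is_optimal) "optimal" else "greedy lower bound",
    x$n_covered_cells, x$n_active_cells, 100 * x$coverage_fraction_cells,
    x$covered_demand, 100 * x$coverage_fraction_demand))
  invisible(x)
}

#' Greedy MCLP solver
#'
#' Iteratively selects the candidate covering the most still-uncovered
#' weighted demand; ties are broken by lowest site id. Stops early once
#' full coverage is reached. By submodularity of the coverage objective
#' the greedy solution attains at least \eqn{1 - 1/e \approx 0.632} of
#' the optimal weighted coverage.
#'
#' @param cov a \code{coverage_matrix}.
#' @param p number of facilities to place (>= 1). If p exceeds the
#'   number of candidates it is clamped with a warning.
#' @param weights demand weights per cell (default: event counts).
#' @return a \code{coverage_solution}.
#' @export
solve_greedy <- function(cov, p, weights = cov$weights) {
  stopifnot(inherits(cov, "coverage_matrix"))
  p <- as.integer(p)
  if (p < 1) stop("p must be >= 1")
  n_cand <- ncol(cov$a)
  if (p > n_cand) {
    warning(sprintf("p = %d exceeds %d candidates; clamped", p, n_cand))
    p <- n_cand
  }
  uncovered <- rep(TRUE, nrow(cov$a))
  sel <- integer(0)
  order_ids <- order(colnames(cov$a))  # lexicographic tie-break
  for (k in seq_len(p)) {
    gain <- colSums(cov$a * (weights * uncovered))
    gain[sel] <- -1
    best <- order_ids[which.max(gain[order_ids])]
    if (gain[best] <= 0) break  # nothing left to gain
    sel <- c(sel, best)
    uncovered <- uncovered & !cov$a[, best]
    if (!any(uncovered)) break
  }
  new_coverage_solution(cov, sel, p, optimal = FALSE)
}

#' Exact MCLP solver (branch and bound)
#'
#' Solves the standard maximal-covering integer program
#' \deqn{\max \sum_i w_i y_i \quad \mathrm{s.t.}\ y_i \le
#'   \sum_{j \in N_i} x_j,\ \sum_j x_j = p,\ x, y \in \{0,1\}}
#' by depth-first branch and bound with a greedy/submodular upper bound.
#' Intended for desk-scale instances (<= 25 candidates); larger instances
#' raise a capability error naming the limit. Ties between
#' equal-objective optima are broken lexicographically by site id.
#'
#' @inheritParams solve_greedy
#' @param max_candidates guard on instance size (default 25).
#' @return a \code{coverage_solution} with
#'   \code{objective_is_optimal = TRUE}.
#' @export
solve_exact <- function(cov, p, weights = cov$weights,
                        max_candidates = 25L) {
  stopifnot(inherits(cov, "coverage_matrix"))
  p <- as.integer(p)
  if (p < 0) stop("p must be >= 0")
  n_cand <- ncol(cov$a)
  if (n_cand > max_candidates)
    stop(sprintf(
      "internal branch-and-bound handles <= %d candidates (got %d)",
      max_candidates, n_cand))
  if (p > n_cand) {
    warning(sprintf("p = %d exceeds %d candidates; clamped", p, n_cand))
    p <- n_cand
  }
  if (p == 0) return(new_coverage_solution(cov, integer(0), 0L, TRUE))

  # candidates in lexicographic site-id order so DFS finds the
  # lexicographically-smallest optimum first
  ord <- order(colnames(cov$a))
  a <- cov$a[, ord, drop = FALSE]
  w <- weights
  n_cell <- nrow(a)

  best_obj <- -1
  best_sel <- integer(0)

  cover_w <- function(mask) sum(w[mask])

  # upper bound: current coverage + top-(slots) greedy gains on remaining
  ub <- function(covered, from, slots) {
    if (slots == 0L) return(cover_w(covered))
    rem <- from:n_cand
    gains <- colSums(a[, rem, drop = FALSE] * (w * !covered))
    cover_w(covered) + sum(sort(gains, decreasing = TRUE)[seq_len(
      min(slots, length(gains)))])
  }

  dfs <- function(next_j, sel, covered) {
    slots <- p - length(sel)
    if (slots == 0L || next_j > n_cand) {
      obj <- cover_w(covered)
      if (obj > best_obj) {
        best_obj <<- obj
        best_sel <<- sel
      }
      return(invisible())
    }
    if (ub(covered, next_j, slots) <= best_obj) return(invisible())
    # branch: include next_j, then exclude it
    dfs(next_j + 1L, c(sel, next_j), covered | a[, next_j])
    if (n_cand - next_j >= slots) dfs(next_j + 1L, sel, covered)
    invisible()
  }
  dfs(1L, integer(0), rep(FALSE, n_cell))

  new_coverage_solution(cov, ord[best_sel], p, optimal = TRUE)
}

#' Coverage as a function of the number of AEDs
#'
#' Solves the MCLP at each value of p and reports the coverage curve and
#' the saturation point (smallest p attaining the union coverage of all
#' candidates). Coverage is non-decreasing in p.
#'
#' @param cov a \code{coverage_matrix}.
#' @param p_values strictly increasing vector of facility counts; by
#'   default increments of \code{by} up to saturation.
#' @param by default increment when \code{p_values} is NULL (default 20).
#' @param weights demand weights.
#' @param method \code{"greedy"} (default) or \code{"exact"}.
#' @return object of class \code{coverage_curve}: list of solutions plus
#'   a summary data.frame and the saturation p (NA if not reached).
#' @export
coverage_curve <- function(cov, p_values = NULL, by = 20L,
                           weights = cov$weights,
                           method = c("greedy", "exact")) {
  method <- match.arg(method)
  solver <- if (method == "greedy") solve_greedy else solve_exact
  union_cells <- sum(rowSums(cov$a) > 0)
  if (is.null(p_values)) {
    p_values <- seq(by, ncol(cov$a), by = by)
  }
  p_values <- as.integer(p_values)
  if (any(diff(p_values) <= 0)) stop("p_values must be strictly increasing")
  sols <- list()
  for (i in seq_along(p_values)) {
    sols[[i]] <- solver(cov, p_values[i], weights)
    if (sols[[i]]$n_covered_cells >= union_cells) {
      p_values <- p_values[seq_len(i)]
      break
    }
  }
  tab <- data.frame(
    p = p_values,
    covered_cells = vapply(sols, `[[`, integer(1), "n_covered_cells"),
    covered_demand = vapply(sols, function(s) as.numeric(s$covered_demand),
                            numeric(1)),
    coverage_fraction_cells = vapply(sols, `[[`, numeric(1),
                                     "coverage_fraction_cells")
  )
  sat <- tab$p[tab$covered_cells >= union_cells]
  structure(list(solutions = sols, table = tab,
                 saturation_p = if (length(sat)) min(sat) else NA_integer_,
                 union_cells = union_cells),
            class = "coverage_curve")
}

#' @export
print.coverage_curve <- function(x, ...) {
  cat("MCLP coverage curve\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  union coverage: %d cells; saturation at p = %s\n",
              x$union_cells, format(x$saturation_p)))
  invisible(x)
}

#' @export
plot.coverage_curve <- function(x, ...) {
  graphics::plot(x$table$p, 100 * x$table$coverage_fraction_cells,
                 type = "b", pch = 16, xlab = "number of AEDs (p)",
                 ylab = "centroids covered (%)", ...)
  invisible(x)
}

#' Bystander travel times to the nearest selected AED
#'
#' For each event, the round-trip walking time to the nearest selected
#' site, \eqn{2 d / v} (a bystander must reach the AED and return to the
#' victim); set \code{round_trip = FALSE} for one-way times.
#'
#' @param solution a \code{coverage_solution}.
#' @param events event data.frame with \code{x_m}, \code{y_m}.
#' @param candidates candidate table used to build the coverage matrix.
#' @param speed pedestrian speed in m/s.
#' @param round_trip logical (default TRUE).
#' @return numeric vector of seconds, one per event.
#' @export
aed_travel_times <- function(solution, events, candidates,
                             speed = 10 / 3.6, round_trip = TRUE) {
  stopifnot(inherits(solution, "coverage_solution"))
  if (length(solution$selected) == 0) stop("solution selects no sites")
  sel <- candidates[candidates$site_id %in% solution$selected, , drop = FALSE]
  d2 <- outer(events$x_m, sel$x, "-")^2 + outer(events$y_m, sel$y, "-")^2
  d <- sqrt(apply(d2, 1, min))
  (if (round_trip) 2 else 1) * d / speed
}

#' Engineered demand/candidate fixture with known coverage geometry
#'
#' Builds a deterministic synthetic instance on a 500 m lattice with 167
#' occupied demand cells and 624 candidate sites arranged so that, at the
#' default 150 s / 10 km/h service radius, 100 sites cover exactly 127 of
#' the 167 centroids (76%): 73 isolated cells each served by one on-site
#' candidate, 27 adjacent-cell pairs each served by one mid-point
#' candidate, 40 cells out of reach of every candidate, and 524 surplus
#' candidates far from all demand. Used to exercise the solver stack on
#' the published coverage geometry without the real establishment roster.
#'
#' @return list with \code{events}, \code{candidates},
#'   \code{cell_size_m}, \code{bbox}.
#' @export
mclp_fixture <- function() {
  cell <- 500
  slot_pitch <- 2000
  lat <- expand.grid(sx = 0:12, sy = 0:12)  # 169 slots, first 140 used
  sx <- 1000 + lat$sx * slot_pitch
  sy <- 1000 + lat$sy * slot_pitch

  ev_x <- numeric(0); ev_y <- numeric(0)
  cand_x <- numeric(0); cand_y <- numeric(0)

  centroid <- function(x) (floor(x / cell) + 0.5) * cell
  slot <- 0L
  add_cell_events <- function(cx, cy, k) {
    ev_x <<- c(ev_x, rep(cx, k)); ev_y <<- c(ev_y, rep(cy, k))
  }
  # 73 singles: candidate on the centroid
  for (i in 1:73) {
    slot <- slot + 1L
    cx <- centroid(sx[slot]); cy <- centroid(sy[slot])
    add_cell_events(cx, cy, 1L + (i %% 3L))
    cand_x <- c(cand_x, cx); cand_y <- c(cand_y, cy)
  }
  # 27 pairs: two adjacent cells, candidate at the shared midpoint
  for (i in 1:27) {
    slot <- slot + 1L
    cx <- centroid(sx[slot]); cy <- centroid(sy[slot])
    add_cell_events(cx, cy, 1L)
    add_cell_events(cx + cell, cy, 2L)
    cand_x <- c(cand_x, cx + cell / 2); cand_y <- c(cand_y, cy)
  }
  # 40 uncoverable cells: no candidate within reach
  for (i in 1:40) {
    slot <- slot + 1L
    cx <- centroid(sx[slot]); cy <- centroid(sy[slot])
    add_cell_events(cx, cy, 1L)
  }
  # 524 surplus candidates clustered far from all demand
  k <- 524L
  gx <- 28000 + 90 * (0:(k - 1L) %% 24L)
  gy <- 28000 + 90 * (0:(k - 1L) %/% 24L)
  cand_x <- c(cand_x, gx); cand_y <- c(cand_y, gy)

  events <- data.frame(
    event_id = sprintf("F%04d", seq_along(ev_x)),
    x_m = ev_x, y_m = ev_y,
    response_time_s = 700, dispatch_time_s = 440,
    age = 60L, sex = "male", traumatic = FALSE,
    call_hour = 12, call_datetime = "2020-06-01T12:00:00Z",
    bystander_cpr = "no", shockable = FALSE, death = TRUE,
    cpr_duration_s = 1800, complete = TRUE,
    stringsAsFactors = FALSE
  )
  candidates <- data.frame(
    site_id = sprintf("S%04d", seq_along(cand_x)),
    x = cand_x, y = cand_y,
    label = "fixture establishment",
    stringsAsFactors = FALSE
  )
  list(events = events, candidates = candidates, cell_size_m = cell,
       bbox = c(0, 0, 31000, 31000))
}
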