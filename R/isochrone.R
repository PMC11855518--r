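#' Ambulance travel-time field and isochrone bands
#'
#' Computes, for every grid cell, the ideal-condition travel time in
#' minutes from the nearest ambulance base (straight-line distance at
#' constant ambulance speed; no dispatch delay, no congestion), and
#' classifies cells into the conventional 5 / 10 / 15-minute service
#' bands. Setting \code{realistic = TRUE} adds the median dispatch delay
#' and the day-average congestion multiplier, for maps of expected rather
#' than ideal coverage.
#'
#' @param city a \code{synthetic_city} (needs \code{bases},
#'   \code{ambulance_speed}).
#' @param grid a \code{demand_grid}.
#' @param realistic include dispatch delay and mean congestion (default
#'   FALSE: ideal conditions).
#' @return object of class \code{travel_time_field}: the grid cells plus
#'   \code{minutes} and \code{band} columns.
#' @examples
#' city <- generate_city(city_config(seed = 1))
#' grid <- make_grid(city$bbox, 500)
#' field <- travel_time_field(city, grid)
#' band_areas(field)
#' @export
travel_time_field <- function(city, grid, realistic = FALSE) {
  if (is.null(city$bases) || nrow(city$bases) == 0)
    stop("city has no ambulance bases")
  stopifnot(inherits(grid, "demand_grid"))
  if (nrow(grid$cells) == 0) stop("grid is empty")

  xy <- cbind(grid$cells$cx, grid$cells$cy)
  d <- nearest_base_distance(xy, city$bases)
  secs <- d / city$ambulance_speed
  if (realistic) {
    mbar <- mean(congestion_multiplier(seq(0, 23.75, by = 0.25),
                                       city$congestion_harmonics))
    secs <- city$dispatch_median_s + secs * mbar
  }
  minutes <- secs / 60
  band <- cut(minutes, breaks = c(-Inf, 5, 10, 15, Inf),
              labels = c("<=5 min", "<=10 min", "<=15 min", ">15 min"))
  cells <- grid$cells
  cells$minutes <- minutes
  cells$band <- as.character(band)
  structure(list(cell_size_m = grid$cell_size_m, bbox = grid$bbox,
                 cells = cells, realistic = realistic),
            class = "travel_time_field")
}

#' Service-band areas
#'
#' Sums cell areas per isochrone band; bands partition the grid, so the
#' areas sum exactly to the grid's total area.
#'
#' @param field a \code{travel_time_field}.
#' @return named numeric vector of areas in square metres.
#' @export
band_areas <- function(field) {
  stopifnot(inherits(field, "travel_time_field"))
  bands <- c("<=5 min", "<=10 min", "<=15 min", ">15 min")
  cell_area <- field$cell_size_m^2
  out <- vapply(bands, function(b) sum(field$cells$band == b) * cell_area,
                numeric(1))
  names(out) <- bands
  out
}

#' @export
print.travel_time_field <- function(x, ...) {
  cat(sprintf("Travel-time field (%s conditions): %d cells\n",
              if (isTRUE(x$realistic)) "realistic" else "ideal",
              nrow(x$cells)))
  a <- band_areas(x)
  for (b in names(a))
    cat(sprintf("  %-8s %10.2f km^2\n", b, a[b] / 1e6))
  invisible(x)
}
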