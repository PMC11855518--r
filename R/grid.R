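#' Aggregate events onto a square demand grid
#'
#' Lays a lattice of square cells (default 500 m side) anchored at the
#' bounding box's minimum corner and counts events per cell; each cell's
#' demand is assumed to sit at its centroid. Cell membership is half-open
#' \code{[x0, x0 + size) x [y0, y0 + size)}, so a point exactly on a
#' shared right/top edge belongs to the next cell. Mean response time is
#' averaged per cell.
#'
#' @param events event data.frame with \code{x_m}, \code{y_m} (and
#'   optionally \code{response_time_s}).
#' @param cell_size_m cell side length in metres (default 500).
#' @param bbox optional \code{c(xmin, ymin, xmax, ymax)}; defaults to the
#'   events' bounding box. The lattice covers the bbox completely.
#' @param all_cells if TRUE, the returned grid carries every lattice cell
#'   (zero counts included); if FALSE (default) only occupied cells.
#' @return object of class \code{demand_grid}: list with \code{cell_size_m},
#'   \code{bbox}, and \code{cells} (data.frame: \code{cell_id}, \code{ix},
#'   \code{iy}, \code{cx}, \code{cy}, \code{event_count},
#'   \code{mean_response_s}).
#' @export
aggregate_demand <- function(events, cell_size_m = 500, bbox = NULL,
                             all_cells = FALSE) {
  if (is.null(events) || nrow(events) == 0) stop("events must be non-empty")
  if (cell_size_m <= 0) stop("cell_size_m must be positive")
  if (is.null(bbox)) {
    bbox <- c(min(events$x_m), min(events$y_m),
              max(events$x_m), max(events$y_m))
  }
  nx <- max(1L, ceiling((bbox[3] - bbox[1]) / cell_size_m))
  ny <- max(1L, ceiling((bbox[4] - bbox[2]) / cell_size_m))

  ix <- floor((events$x_m - bbox[1]) / cell_size_m)
  iy <- floor((events$y_m - bbox[2]) / cell_size_m)
  ix <- pmin(pmax(ix, 0), nx)  # points on the far edge open a fringe cell
  iy <- pmin(pmax(iy, 0), ny)

  if (all_cells) {
    cells <- expand.grid(ix = 0:(nx - 1L), iy = 0:(ny - 1L))
  } else {
    cells <- unique(data.frame(ix = ix, iy = iy))
    cells <- cells[order(cells$iy, cells$ix), , drop = FALSE]
  }
  key <- paste(ix, iy)
  ckey <- paste(cells$ix, cells$iy)
  cnt <- tabulate(match(key, ckey), nbins = nrow(cells))
  resp <- if ("response_time_s" %in% names(events)) events$response_time_s
          else rep(NA_real_, nrow(events))
  agg <- tapply(resp, match(key, ckey), mean)
  mean_resp <- rep(NA_real_, nrow(cells))
  mean_resp[as.integer(names(agg))] <- as.numeric(agg)

  cells$cell_id <- sprintf("c%d_%d", cells$ix, cells$iy)
  cells$cx <- bbox[1] + (cells$ix + 0.5) * cell_size_m
  cells$cy <- bbox[2] + (cells$iy + 0.5) * cell_size_m
  cells$event_count <- cnt
  cells$mean_response_s <- mean_resp
  rownames(cells) <- NULL

  structure(list(cell_size_m = cell_size_m, bbox = bbox,
                 cells = cells[, c("cell_id", "ix", "iy", "cx", "cy",
                                   "event_count", "mean_response_s")]),
            class = "demand_grid")
}

#' Full lattice over a bounding box, without events
#'
#' @param bbox \code{c(xmin, ymin, xmax, ymax)} in metres.
#' @param cell_size_m cell side length in metres.
#' @return a \code{demand_grid} with zero counts.
#' @export
make_grid <- function(bbox, cell_size_m = 500) {
  nx <- max(1L, ceiling((bbox[3] - bbox[1]) / cell_size_m))
  ny <- max(1L, ceiling((bbox[4] - bbox[2]) / cell_size_m))
  cells <- expand.grid(ix = 0:(nx - 1L), iy = 0:(ny - 1L))
  cells$cell_id <- sprintf("c%d_%d", cells$ix, cells$iy)
  cells$cx <- bbox[1] + (cells$ix + 0.5) * cell_size_m
  cells$cy <- bbox[2] + (cells$iy + 0.5) * cell_size_m
  cells$event_count <- 0L
  cells$mean_response_s <- NA_real_
  structure(list(cell_size_m = cell_size_m, bbox = bbox,
                 cells = cells[, c("cell_id", "ix", "iy", "cx", "cy",
                                   "event_count", "mean_response_s")]),
            class = "demand_grid")
}

#' Occupied (active) cells of a demand grid
#'
#' @param grid a \code{demand_grid}.
#' @return the cell rows with \code{event_count > 0}.
#' @export
active_cells <- function(grid) {
  stopifnot(inherits(grid, "demand_grid"))
  grid$cells[grid$cells$event_count > 0, , drop = FALSE]
}

#' @export
print.demand_grid <- function(x, ...) {
  cat(sprintf("Demand grid: %d cells of %g m, %d active, %d events\n",
              nrow(x$cells), x$cell_size_m,
              sum(x$cells$event_count > 0), sum(x$cells$event_count)))
  invisible(x)
}
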