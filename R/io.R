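#' Read and write OHCA event tables as CSV
#'
#' Canonical column order: event_id, x_m, y_m, call_datetime (ISO-8601),
#' age, sex, traumatic, response_time_s, dispatch_time_s, bystander_cpr,
#' shockable, death, cpr_duration_s, complete. \code{call_hour} is
#' re-derived from \code{call_datetime} on read.
#'
#' @param events event data.frame.
#' @param path file path.
#' @return \code{write_events_csv}: the path, invisibly;
#'   \code{read_events_csv}: the event data.frame.
#' @export
write_events_csv <- function(events, path) {
  cols <- c("event_id", "x_m", "y_m", "call_datetime", "age", "sex",
            "traumatic", "response_time_s", "dispatch_time_s",
            "bystander_cpr", "shockable", "death", "cpr_duration_s",
            "complete")
  utils::write.csv(events[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  dt <- as.POSIXct(ev$call_datetime, format = "%Y-%m-%dT%H:%M:%SZ",
                   tz = "UTC")
  ev$call_hour <- as.numeric(format(dt, "%H")) +
    as.numeric(format(dt, "%M")) / 60 + as.numeric(format(dt, "%S")) / 3600
  for (cl in c("traumatic", "shockable", "death", "complete"))
    ev[[cl]] <- as.logical(ev[[cl]])
  ev
}

#' Write point features as GeoJSON
#'
#' @param df data.frame with \code{x}/\code{y} (or \code{x_m}/\code{y_m})
#'   coordinates; remaining columns become feature properties.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_points_geojson <- function(df, path) {
  xc <- if ("x" %in% names(df)) "x" else "x_m"
  yc <- if ("y" %in% names(df)) "y" else "y_m"
  props <- setdiff(names(df), c(xc, yc))
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(df[[xc]][i], df[[yc]][i])),
      properties = as.list(df[i, props, drop = FALSE])
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_points_geojson
#' @export
read_points_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  rows <- lapply(gj$features, function(f) {
    cc <- unlist(f$geometry$coordinates)
    c(list(x = cc[1], y = cc[2]), f$properties)
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

#' Write grid cells as GeoJSON square polygons
#'
#' Each cell becomes a Polygon feature with its metric extent; extra
#' per-cell columns (e.g. \code{pep}, \code{minutes}, \code{band}) are
#' carried as properties.
#'
#' @param cells cell data.frame (\code{ix}, \code{iy}, plus properties).
#' @param cell_size_m cell side, metres.
#' @param bbox grid bounding box (min corner anchors the lattice).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_grid_geojson <- function(cells, cell_size_m, bbox, path) {
  props <- setdiff(names(cells), c("ix", "iy"))
  features <- lapply(seq_len(nrow(cells)), function(i) {
    x0 <- bbox[1] + cells$ix[i] * cell_size_m
    y0 <- bbox[2] + cells$iy[i] * cell_size_m
    ring <- list(c(x0, y0), c(x0 + cell_size_m, y0),
                 c(x0 + cell_size_m, y0 + cell_size_m),
                 c(x0, y0 + cell_size_m), c(x0, y0))
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = as.list(cells[i, props, drop = FALSE])
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the city's layers (bbox, bases, candidates) as GeoJSON
#'
#' @param city a \code{synthetic_city}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_city_geojson <- function(city, path) {
  b <- city$bbox
  ring <- list(c(b[1], b[2]), c(b[3], b[2]), c(b[3], b[4]),
               c(b[1], b[4]), c(b[1], b[2]))
  features <- list(list(
    type = "Feature",
    geometry = list(type = "Polygon", coordinates = list(ring)),
    properties = list(layer = "bbox")
  ))
  for (i in seq_len(nrow(city$bases))) {
    features[[length(features) + 1]] <- list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(city$bases[i, 1], city$bases[i, 2])),
      properties = list(layer = "base", base_id = sprintf("B%02d", i))
    )
  }
  for (i in seq_len(nrow(city$candidates))) {
    features[[length(features) + 1]] <- list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(city$candidates$x[i],
                                      city$candidates$y[i])),
      properties = list(layer = "candidate",
                        site_id = city$candidates$site_id[i],
                        label = city$candidates$label[i])
    )
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Flat key=value configuration files
#'
#' One \code{key = value} pair per line; blank lines and lines starting
#' with \code{#} are ignored. Values are parsed as numeric when
#' possible, \code{TRUE}/\code{FALSE} as logical, comma-separated values
#' as vectors.
#'
#' @param path config file path.
#' @return named list of values.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(parts %in% c("TRUE", "FALSE", "true", "false")))
        toupper(parts) == "TRUE"
      else if (length(parts) > 1) parts else val
  }
  out
}

#' @rdname read_config_file
#' @param config named list.
#' @export
write_config_file <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, paste(format(config[[k]], scientific = FALSE),
                                collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
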