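#' Synthetic city configuration
#'
#' Builds the parameter list describing a synthetic medium-sized city:
#' a planar bounding box in metres, a mixture of Gaussian population
#' centres, ambulance base locations, candidate AED host establishments,
#' travel speeds, a lognormal pre-travel (dispatch) delay, and two
#' independent diurnal curves -- one for call intensity (when arrests
#' happen) and one for traffic congestion (how slowly ambulances move).
#'
#' All coordinates are planar metres in a local projection; all times are
#' seconds. Defaults emulate a compact urban core of roughly 10 x 10 km
#' with events clustered centrally, 624 candidate establishments, and a
#' pedestrian speed of 10 km/h.
#'
#' @param bbox numeric length-4, \code{c(xmin, ymin, xmax, ymax)} in metres.
#' @param population_centres data.frame with columns \code{x}, \code{y}
#'   (centre, m), \code{spread} (bivariate normal sd, m) and \code{weight}
#'   (mixture weight; weights must sum to 1).
#' @param n_bases number of ambulance bases (used when \code{bases} is NULL).
#' @param bases optional matrix/data.frame of base coordinates (x, y in m).
#' @param n_candidates number of candidate AED host establishments.
#' @param pedestrian_speed walking speed in m/s (default 10 km/h).
#' @param ambulance_speed driving speed in m/s (default 40 km/h).
#' @param dispatch_median_s median of the lognormal dispatch delay, seconds.
#' @param dispatch_log_sd log-scale sd of the dispatch delay.
#' @param travel_log_sd log-scale sd of the multiplicative travel-time noise.
#' @param intensity_harmonics data.frame with columns \code{amplitude} and
#'   \code{phase_h} (hour of the harmonic's peak) for k = 1..K cycles/day,
#'   defining the diurnal call-intensity curve.
#' @param base_rate baseline call intensity, events per hour.
#' @param congestion_harmonics like \code{intensity_harmonics}, for the
#'   diurnal congestion multiplier applied to ambulance travel times.
#' @param seed integer RNG seed; every stochastic draw downstream is
#'   reproducible given the config.
#' @return a list of class \code{city_config}.
#' @seealso [generate_city()], [simulate_events()]
#' @export
city_config <- function(bbox = c(0, 0, 10000, 10000),
                        population_centres = default_population_centres(),
                        n_bases = 2L,
                        bases = NULL,
                        n_candidates = 624L,
                        pedestrian_speed = 10 / 3.6,
                        ambulance_speed = 40 / 3.6,
                        dispatch_median_s = 446,
                        dispatch_log_sd = 0.49,
                        travel_log_sd = 0.55,
                        intensity_harmonics = default_intensity_harmonics(),
                        base_rate = 0.33,
                        congestion_harmonics = default_congestion_harmonics(),
                        seed = 1L) {
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || bbox[3] <= bbox[1] || bbox[4] <= bbox[2])
    stop("bbox must be c(xmin, ymin, xmax, ymax) with positive extent")
  pc <- as.data.frame(population_centres)
  if (nrow(pc) == 0)
    stop("population_centres must contain at least one centre")
  if (!all(c("x", "y", "spread", "weight") %in% names(pc)))
    stop("population_centres needs columns x, y, spread, weight")
  if (abs(sum(pc$weight) - 1) > 1e-9)
    stop("population_centres weights must sum to 1")
  if (any(pc$weight <= 0) || any(pc$spread <= 0))
    stop("population centre weights and spreads must be positive")
  if (pedestrian_speed <= 0 || ambulance_speed <= 0)
    stop("speeds must be positive (m/s)")
  if (dispatch_median_s <= 0 || dispatch_log_sd < 0)
    stop("invalid dispatch delay parameters")
  lambda <- diurnal_intensity(seq(0, 23.75, by = 0.25),
                              intensity_harmonics, base_rate)
  if (any(lambda <= 0))
    stop("intensity harmonics produce non-positive intensity")
  m <- congestion_multiplier(seq(0, 23.75, by = 0.25), congestion_harmonics)
  if (any(m <= 0))
    stop("congestion harmonics produce a non-positive multiplier")
  structure(list(
    bbox = bbox,
    population_centres = pc,
    n_bases = as.integer(n_bases),
    bases = if (!is.null(bases)) as.matrix(bases),
    n_candidates = as.integer(n_candidates),
    pedestrian_speed = pedestrian_speed,
    ambulance_speed = ambulance_speed,
    dispatch_median_s = dispatch_median_s,
    dispatch_log_sd = dispatch_log_sd,
    travel_log_sd = travel_log_sd,
    intensity_harmonics = as.data.frame(intensity_harmonics),
    base_rate = base_rate,
    congestion_harmonics = as.data.frame(congestion_harmonics),
    seed = as.integer(seed)
  ), class = "city_config")
}

#' @rdname city_config
#' @export
default_population_centres <- function() {
  data.frame(
    x = c(5000, 6600, 3600),
    y = c(5000, 6400, 6200),
    spread = c(1400, 1000, 900),
    weight = c(0.55, 0.25, 0.20)
  )
}

#' Default diurnal harmonic parameter sets
#'
#' Two-harmonic (K = 2) parameterisations of the diurnal curves. The
#' call-intensity defaults place the daily minimum at midnight and peaks
#' near 06:00 and 16:00; the congestion defaults peak at 11:00, when
#' ambulance travel is slowest. A two-harmonic curve cannot place both
#' morning/afternoon peaks and the midnight trough exactly, so the
#' defaults are a compromise documented in the methods vignette.
#'
#' @return data.frame with columns \code{amplitude} and \code{phase_h}.
#' @export
default_intensity_harmonics <- function() {
  data.frame(amplitude = c(0.32, 0.40), phase_h = c(12.5, 5.4))
}

#' @rdname default_intensity_harmonics
#' @export
default_congestion_harmonics <- function() {
  data.frame(amplitude = c(0.25, 0.05), phase_h = c(11, 11))
}

#' Evaluate a harmonic diurnal curve
#'
#' \code{diurnal_intensity} returns the call intensity
#' \eqn{\lambda(h) = r (1 + \sum_k A_k \cos(2\pi k (h - p_k)/24))}
#' in events/hour; \code{congestion_multiplier} returns the analogous
#' unit-mean-free multiplier with r = 1. \code{phase_h} is the hour at
#' which harmonic k attains its own maximum.
#'
#' @param hours numeric vector of fractional hours in [0, 24).
#' @param harmonics data.frame with \code{amplitude}, \code{phase_h}.
#' @param base_rate baseline rate (events per hour).
#' @return numeric vector, same length as \code{hours}.
#' @export
diurnal_intensity <- function(hours, harmonics, base_rate = 1) {
  base_rate * harmonic_curve(hours, harmonics)
}

#' @rdname diurnal_intensity
#' @export
congestion_multiplier <- function(hours, harmonics) {
  harmonic_curve(hours, harmonics)
}

harmonic_curve <- function(hours, harmonics) {
  harmonics <- as.data.frame(harmonics)
  out <- rep(1, length(hours))
  for (k in seq_len(nrow(harmonics))) {
    out <- out + harmonics$amplitude[k] *
      cos(2 * pi * k * (hours - harmonics$phase_h[k]) / 24)
  }
  out
}

#' Generate a synthetic city
#'
#' Realises a \code{city_config} into concrete ambulance bases and
#' candidate AED host establishments. Bases are placed at high-density
#' quantile anchors of the population mixture unless supplied explicitly;
#' candidates are drawn from the same mixture (establishments track
#' population) and clipped to the bounding box. Deterministic for a fixed
#' config (the config's seed drives all draws).
#'
#' @param config a \code{city_config}.
#' @return an object of class \code{synthetic_city}: the config plus
#'   \code{bases} (matrix) and \code{candidates} (data.frame with
#'   \code{site_id}, \code{x}, \code{y}, \code{label}).
#' @examples
#' city <- generate_city(city_config(seed = 1))
#' nrow(city$candidates)  # 624
#' @export
generate_city <- function(config = city_config()) {
  if (!inherits(config, "city_config")) config <- do.call(city_config, config)
  rng <- local_rng(config$seed * 1000003L %% .Machine$integer.max)
  on.exit(rng())

  bases <- config$bases
  if (is.null(bases)) {
    # anchor bases near the heaviest centres, offset so travel is non-trivial
    pc <- config$population_centres[order(-config$population_centres$weight), ]
    nb <- max(1L, config$n_bases)
    idx <- rep(seq_len(nrow(pc)), length.out = nb)
    ang <- 2 * pi * seq_len(nb) / nb
    bases <- cbind(
      x = pc$x[idx] + 2.4 * pc$spread[idx] * cos(ang),
      y = pc$y[idx] + 2.4 * pc$spread[idx] * sin(ang)
    )
    bases[, 1] <- pmin(pmax(bases[, 1], config$bbox[1]), config$bbox[3])
    bases[, 2] <- pmin(pmax(bases[, 2], config$bbox[2]), config$bbox[4])
  } else {
    bases <- as.matrix(bases)
    colnames(bases) <- c("x", "y")
  }

  cand_xy <- sample_mixture(config$n_candidates, config$population_centres,
                            config$bbox)
  labels <- c("pharmacy", "school", "supermarket", "bank", "gym",
              "gas station", "mall", "clinic", "church", "public office")
  candidates <- data.frame(
    site_id = sprintf("S%04d", seq_len(config$n_candidates)),
    x = cand_xy[, 1],
    y = cand_xy[, 2],
    label = rep(labels, length.out = config$n_candidates),
    stringsAsFactors = FALSE
  )

  base_cfg <- unclass(config)
  base_cfg$bases <- NULL
  structure(c(base_cfg, list(bases = bases, candidates = candidates)),
            class = "synthetic_city")
}

# draw n points from the Gaussian mixture, rejection-clipped to bbox
sample_mixture <- function(n, centres, bbox) {
  out <- matrix(NA_real_, n, 2)
  filled <- 0L
  while (filled < n) {
    m <- n - filled
    comp <- sample.int(nrow(centres), m, replace = TRUE, prob = centres$weight)
    x <- stats::rnorm(m, centres$x[comp], centres$spread[comp])
    y <- stats::rnorm(m, centres$y[comp], centres$spread[comp])
    ok <- x >= bbox[1] & x <= bbox[3] & y >= bbox[2] & y <= bbox[4]
    k <- sum(ok)
    if (k > 0) {
      out[(filled + 1):(filled + k), ] <- cbind(x[ok], y[ok])
      filled <- filled + k
    }
  }
  out
}

# Run code under a temporary RNG state; returns a restore function.
local_rng <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% 2147483647))
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat("Synthetic city\n")
  cat(sprintf("  bbox: [%g, %g] x [%g, %g] m\n",
              x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  cat(sprintf("  population centres: %d; bases: %d; candidate sites: %d\n",
              nrow(x$population_centres), nrow(x$bases), nrow(x$candidates)))
  cat(sprintf("  speeds: ambulance %.2f m/s, pedestrian %.2f m/s\n",
              x$ambulance_speed, x$pedestrian_speed))
  invisible(x)
}

#' Simulate an OHCA call stream
#'
#' Draws \code{n_calls} out-of-hospital cardiac-arrest calls from the
#' synthetic city. Call hours follow the diurnal intensity curve; event
#' locations follow the population mixture. The response time is composed
#' as \deqn{T = D + \frac{d}{v} m(h) \epsilon,} where D is a lognormal
#' dispatch delay, d the straight-line distance to the nearest ambulance
#' base, v the ambulance speed, m(h) the diurnal congestion multiplier
#' (largest near 11:00), and \eqn{\epsilon} multiplicative lognormal
#' noise. Clinical flags (bystander CPR, shockable rhythm, death) are
#' drawn at registry-calibrated marginal rates; a configurable fraction
#' of records is flagged incomplete completely at random.
#'
#' @param city a \code{synthetic_city}.
#' @param n_calls number of calls to simulate (>= 1).
#' @param seed integer seed for this draw (overrides the config seed).
#' @param p_complete probability a record has complete information
#'   (default 287/476).
#' @param p_traumatic probability a call is traumatic (excluded downstream).
#' @return data.frame of event records with columns \code{event_id},
#'   \code{x_m}, \code{y_m}, \code{call_datetime}, \code{call_hour},
#'   \code{age}, \code{sex}, \code{traumatic}, \code{response_time_s},
#'   \code{dispatch_time_s}, \code{bystander_cpr}, \code{shockable},
#'   \code{death}, \code{cpr_duration_s}, \code{complete}.
#' @export
simulate_events <- function(city, n_calls = 476L, seed = city$seed,
                            p_complete = 287 / 476, p_traumatic = 0.06) {
  stopifnot(inherits(city, "synthetic_city"))
  n_calls <- as.integer(n_calls)
  if (is.na(n_calls) || n_calls < 1) stop("n_calls must be >= 1")
  rng <- local_rng(seed * 2000003L %% .Machine$integer.max + 7L)
  on.exit(rng())

  hours <- sample_diurnal_hours(n_calls, city$intensity_harmonics,
                                city$base_rate)
  xy <- sample_mixture(n_calls, city$population_centres, city$bbox)

  day <- sample.int(365L * 4L, n_calls, replace = TRUE) - 1L
  origin <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")
  call_dt <- origin + day * 86400 + round(hours * 3600)

  dist_base <- nearest_base_distance(xy, city$bases)
  dispatch <- stats::rlnorm(n_calls, log(city$dispatch_median_s),
                            city$dispatch_log_sd)
  m_h <- congestion_multiplier(hours, city$congestion_harmonics)
  travel <- dist_base / city$ambulance_speed * m_h *
    stats::rlnorm(n_calls, 0, city$travel_log_sd)
  response <- dispatch + travel

  age <- round(stats::rnorm(n_calls, 68, 14))
  age <- pmin(pmax(age, 1), 100)
  cpr_lv <- c("yes", "no", "unknown")
  data.frame(
    event_id = sprintf("E%05d", seq_len(n_calls)),
    x_m = xy[, 1],
    y_m = xy[, 2],
    call_datetime = format(call_dt, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    call_hour = hours,
    age = age,
    sex = sample(c("male", "female"), n_calls, TRUE, prob = c(0.5854, 0.4146)),
    traumatic = stats::runif(n_calls) < p_traumatic,
    response_time_s = response,
    dispatch_time_s = dispatch,
    bystander_cpr = sample(cpr_lv, n_calls, TRUE,
                           prob = c(149, 126, 12) / 287),
    shockable = stats::runif(n_calls) < 89 / 287,
    death = stats::runif(n_calls) < 221 / 287,
    cpr_duration_s = stats::rlnorm(n_calls, log(1800), 0.42),
    complete = stats::runif(n_calls) < p_complete,
    stringsAsFactors = FALSE
  )
}

# inverse-CDF sampling of call hours from the diurnal intensity
sample_diurnal_hours <- function(n, harmonics, base_rate) {
  grid <- seq(0, 24, by = 0.05)
  lam <- diurnal_intensity(pmin(grid, 23.999), harmonics, base_rate)
  cdf <- cumsum(lam)
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  idx <- findInterval(u, cdf) + 1L
  idx <- pmin(idx, length(grid))
  h <- grid[idx] + stats::runif(n, 0, 0.05)
  h %% 24
}

nearest_base_distance <- function(xy, bases) {
  bases <- as.matrix(bases)
  d2 <- outer(xy[, 1], bases[, 1], "-")^2 + outer(xy[, 2], bases[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}
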