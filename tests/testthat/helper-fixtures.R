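# shared helpers for building tiny deterministic inputs

tiny_city <- function(seed = 1L, ...) {
  generate_city(city_config(
    bbox = c(0, 0, 4000, 4000),
    population_centres = data.frame(x = 2000, y = 2000, spread = 700,
                                    weight = 1),
    n_bases = 1L,
    n_candidates = 20L,
    seed = seed,
    ...
  ))
}

# minimal event table with defaults overridable per-column
make_events <- function(n = 1, x = 1000, y = 1000, response = 400,
                        dispatch = 100, age = 60, traumatic = FALSE,
                        complete = TRUE, hour = 12, shockable = FALSE,
                        cpr = "no", death = TRUE) {
  data.frame(
    event_id = sprintf("T%03d", seq_len(n)),
    x_m = rep_len(x, n), y_m = rep_len(y, n),
    call_datetime = "2020-06-01T12:00:00Z",
    call_hour = rep_len(hour, n),
    age = rep_len(age, n),
    sex = "male",
    traumatic = rep_len(traumatic, n),
    response_time_s = rep_len(response, n),
    dispatch_time_s = rep_len(dispatch, n),
    bystander_cpr = rep_len(cpr, n),
    shockable = rep_len(shockable, n),
    death = rep_len(death, n),
    cpr_duration_s = 1800,
    complete = rep_len(complete, n),
    stringsAsFactors = FALSE
  )
}

# random small MCLP instance for oracle comparisons
random_instance <- function(seed, max_cells = 25, max_cand = 12) {
  set.seed(seed)
  n_cells <- sample(3:max_cells, 1)
  n_cand <- sample(2:max_cand, 1)
  span <- 3000
  cx <- runif(n_cells, 0, span); cy <- runif(n_cells, 0, span)
  ev <- make_events(n_cells, x = cx, y = cy)
  # several events in some cells so weights vary
  extra <- sample(n_cells, max(1, n_cells %/% 3))
  ev <- rbind(ev, make_events(length(extra), x = cx[extra], y = cy[extra]))
  grid <- aggregate_demand(ev, 500, bbox = c(0, 0, span + 500, span + 500))
  cand <- data.frame(
    site_id = sprintf("S%02d", seq_len(n_cand)),
    x = runif(n_cand, 0, span), y = runif(n_cand, 0, span),
    label = "x", stringsAsFactors = FALSE
  )
  cov <- build_coverage(grid, cand, cutoff_s = runif(1, 150, 700))
  list(cov = cov, p = min(sample(1:4, 1), n_cand))
}

# exhaustive MCLP optimum over all C(n, p) subsets
brute_force_mclp <- function(cov, p, weights = cov$weights) {
  n <- ncol(cov$a)
  p <- min(p, n)
  combs <- utils::combn(n, p)
  best <- -1
  for (j in seq_len(ncol(combs))) {
    covered <- rowSums(cov$a[, combs[, j], drop = FALSE]) > 0
    obj <- sum(weights[covered])
    if (obj > best) best <- obj
  }
  best
}
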