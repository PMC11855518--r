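test_that("coverage radius boundary sits at speed * cutoff", {
  # defaults: 10 km/h * 150 s = 416.67 m
  ev <- make_events(2, x = c(250, 5250), y = c(250, 250))
  grid <- aggregate_demand(ev, 500, bbox = c(0, 0, 6000, 500))
  cand <- data.frame(site_id = c("A", "B"),
                     x = c(250 + 416, 5250 + 417), y = c(250, 250),
                     label = "x")
  cov <- build_coverage(grid, cand)
  expect_true(cov$a[1, "A"])    # 416 m: inside
  expect_false(cov$a[2, "B"])   # 417 m: outside
  expect_true(cov$a["c0_0", "A"])
  # candidate on a centroid always covers that cell
  cand2 <- data.frame(site_id = "C", x = 250, y = 250, label = "x")
  expect_true(build_coverage(grid, cand2)$a[1, 1])
})

test_that("coverage grows entrywise with the cutoff", {
  inst <- random_instance(1)
  cov1 <- inst$cov
  cov2 <- build_coverage(
    structure(list(cell_size_m = 500, bbox = NULL,
                   cells = cov1$cells), class = "demand_grid"),
    cov1$candidates, cutoff_s = cov1$cutoff_s * 2, speed = cov1$speed)
  expect_true(all(cov2$a >= cov1$a))
  expect_error(build_coverage(
    structure(list(cell_size_m = 500, bbox = NULL, cells = cov1$cells),
              class = "demand_grid"),
    cov1$candidates[0, ]), "candidate")
})

test_that("greedy picks the heavier of two disjoint candidates and saturates", {
  ev <- make_events(13, x = c(rep(250, 10), rep(5250, 3)), y = 250)
  grid <- aggregate_demand(ev, 500, bbox = c(0, 0, 6000, 500))
  cand <- data.frame(site_id = c("S1", "S2"), x = c(250, 5250),
                     y = c(250, 250), label = "x")
  cov <- build_coverage(grid, cand)
  sol1 <- solve_greedy(cov, 1)
  expect_equal(sol1$selected, "S1")
  expect_equal(sol1$covered_demand, 10)
  # p beyond the useful candidates: coverage equals the union
  expect_warning(sol_all <- solve_greedy(cov, 5), "clamped")
  expect_equal(sol_all$covered_demand, 13)
  expect_equal(sol_all$n_covered_cells, 2)
})

test_that("exact solver handles trivial instances", {
  ev <- make_events(6, x = c(250, 750, 1250, 250, 750, 1250),
                    y = c(250, 250, 250, 250, 250, 250))
  grid <- aggregate_demand(ev, 500, bbox = c(0, 0, 1500, 500))
  cand <- data.frame(site_id = c("S1", "S2"), x = c(750, 750),
                     y = c(250, 250), label = "x")
  cov <- build_coverage(grid, cand, cutoff_s = 2000)  # everyone covers all
  sol <- solve_exact(cov, 1)
  expect_true(sol$objective_is_optimal)
  expect_equal(sol$covered_demand, 6)
  expect_equal(sol$selected, "S1")  # lexicographic tie-break
  sol0 <- solve_exact(cov, 0)
  expect_equal(sol0$covered_demand, 0)
  big <- data.frame(site_id = sprintf("S%02d", 1:30),
                    x = runif(30, 0, 1500), y = 250, label = "x")
  expect_error(solve_exact(build_coverage(grid, big), 2), "25")
})

test_that("exact solver matches brute force and greedy meets its guarantee", {
  for (s in 1:15) {
    inst <- random_instance(s)
    opt <- brute_force_mclp(inst$cov, inst$p)
    exact <- solve_exact(inst$cov, inst$p)
    expect_equal(exact$covered_demand, opt, label = sprintf("seed %d", s))
    greedy <- solve_greedy(inst$cov, inst$p)
    expect_gte(greedy$covered_demand + 1e-9, (1 - 1 / exp(1)) * opt)
    expect_lte(greedy$covered_demand, opt)
  }
})

test_that("weighted and unweighted objectives coincide for unit counts", {
  set.seed(99)
  pos <- expand.grid(x = c(250, 1250, 2250, 3250), y = c(250, 1250, 2250))
  ev <- make_events(nrow(pos), x = pos$x, y = pos$y)
  grid <- aggregate_demand(ev, 500, bbox = c(0, 0, 4500, 4500))
  cand <- data.frame(site_id = sprintf("S%02d", 1:8),
                     x = runif(8, 0, 4000), y = runif(8, 0, 4000),
                     label = "x")
  cov <- build_coverage(grid, cand, cutoff_s = 400)
  s_w <- solve_exact(cov, 3)                       # weights = counts = 1
  s_u <- solve_exact(cov, 3, weights = rep(1, nrow(cov$a)))
  expect_equal(s_w$covered_demand, s_w$n_covered_cells)
  expect_equal(s_w$selected, s_u$selected)
})

test_that("coverage curve is monotone, saturates, and has diminishing gains", {
  inst <- random_instance(7)
  crv <- coverage_curve(inst$cov, p_values = 1:ncol(inst$cov$a))
  cc <- crv$table$covered_demand
  expect_true(all(diff(cc) >= 0))
  union_w <- sum(inst$cov$weights[rowSums(inst$cov$a) > 0])
  expect_equal(max(cc), union_w)
  if (!is.na(crv$saturation_p)) {
    at_sat <- crv$table$covered_cells[crv$table$p >= crv$saturation_p]
    expect_true(all(at_sat == crv$union_cells))
  }
  # greedy marginal gains are non-increasing (submodularity)
  sol_full <- solve_greedy(inst$cov, ncol(inst$cov$a))
  gains <- diff(c(0, vapply(seq_along(sol_full$selected_idx), function(k) {
    covered <- rowSums(inst$cov$a[, sol_full$selected_idx[seq_len(k)],
                                  drop = FALSE]) > 0
    sum(inst$cov$weights[covered])
  }, numeric(1))))
  skip_if(length(gains) < 2)
  expect_true(all(diff(gains) <= 1e-9))
})

test_that("engineered fixture reproduces the 127/167 coverage geometry", {
  fx <- mclp_fixture()
  expect_equal(nrow(fx$candidates), 624)
  grid <- aggregate_demand(fx$events, fx$cell_size_m, bbox = fx$bbox)
  expect_equal(nrow(active_cells(grid)), 167)
  cov <- build_coverage(grid, fx$candidates)  # default 150 s at 10 km/h
  sol <- solve_greedy(cov, 100)
  expect_equal(sol$n_covered_cells, 127)
  expect_equal(round(sol$coverage_fraction_cells, 2), 0.76)
  # saturation: no more centroids are coverable however many AEDs
  sat <- solve_greedy(cov, 624)
  expect_equal(sat$n_covered_cells, 127)
})

test_that("AED travel times are round trips with expected boundary values", {
  ev <- make_events(3, x = c(1000, 1000 + 416.67, 5000), y = 1000)
  grid <- aggregate_demand(ev, 500)
  cand <- data.frame(site_id = c("A", "B"), x = c(1000, 4000),
                     y = c(1000, 1000), label = "x")
  cov <- build_coverage(grid, cand, cutoff_s = 10000)
  sol <- solve_greedy(cov, 2)
  tt <- aed_travel_times(sol, ev, cand, speed = 10 / 3.6)
  expect_equal(tt[1], 0)
  expect_equal(tt[2], 2 * 416.67 / (10 / 3.6), tolerance = 1e-6)
  one_way <- aed_travel_times(sol, ev, cand, speed = 10 / 3.6,
                              round_trip = FALSE)
  expect_equal(tt, 2 * one_way)
  # removing a site never decreases any event's time
  sol1 <- solve_greedy(cov, 1)
  tt1 <- aed_travel_times(sol1, ev, cand, speed = 10 / 3.6)
  expect_true(all(tt1 >= tt - 1e-9))
})
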