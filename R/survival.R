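#' Build a right-censored survival dataset from OHCA events
#'
#' Response times are treated as survival times (longer time = later
#' ambulance arrival) and right-censored at the recommended
#' defibrillation window (default 300 s): times above the threshold are
#' recorded as the threshold with \code{censored = TRUE}. Diurnal
#' covariates are K harmonic pairs of the call hour,
#' \eqn{(\sin 2\pi k h/24, \cos 2\pi k h/24)}, k = 1..K.
#'
#' @param events filtered event data.frame (see [filter_ohca()]).
#' @param K harmonic order (default 2).
#' @param threshold_s censoring threshold in seconds (default 300). Use
#'   \code{Inf} for a sensitivity fit on uncensored times.
#' @return object of class \code{survival_dataset}: data.frame with
#'   \code{time_s}, \code{censored}, \code{x_m}, \code{y_m},
#'   \code{call_hour} and an \code{X} attribute (n x 2K covariate matrix).
#' @export
build_survival_data <- function(events, K = 2L, threshold_s = 300) {
  K <- as.integer(K)
  if (is.na(K) || K < 1) stop("K must be a positive integer")
  if (any(events$response_time_s <= 0)) stop("response times must be positive")
  time_s <- pmin(events$response_time_s, threshold_s)
  censored <- events$response_time_s > threshold_s
  X <- harmonic_covariates(events$call_hour, K)
  d <- data.frame(time_s = time_s, censored = censored,
                  x_m = events$x_m, y_m = events$y_m,
                  call_hour = events$call_hour)
  attr(d, "X") <- X
  attr(d, "K") <- K
  attr(d, "threshold_s") <- threshold_s
  class(d) <- c("survival_dataset", "data.frame")
  d
}

#' Harmonic design matrix of time of day
#'
#' @param hours fractional hours in [0, 24).
#' @param K harmonic order.
#' @return matrix with columns sin1, cos1, ..., sinK, cosK.
#' @export
harmonic_covariates <- function(hours, K = 2L) {
  X <- do.call(cbind, lapply(seq_len(K), function(k) {
    cbind(sin(2 * pi * k * hours / 24), cos(2 * pi * k * hours / 24))
  }))
  colnames(X) <- as.vector(t(outer(seq_len(K), c("sin", "cos"),
                                   function(k, f) paste0(f, k))))
  X
}

# --- B-spline baseline hazard -------------------------------------------

# cubic B-spline basis on (0, upper] with n_interior equally spaced knots
make_basis <- function(upper = 300, n_interior = 5L, degree = 3L,
                       n_quad = 121L) {
  interior <- seq(0, upper, length.out = n_interior + 2L)[2:(n_interior + 1L)]
  knots <- c(rep(0, degree + 1L), interior, rep(upper, degree + 1L))
  tq <- seq(0, upper, length.out = n_quad)
  Bq <- splines::splineDesign(knots, tq, ord = degree + 1L)
  list(knots = knots, degree = degree, upper = upper, nbasis = ncol(Bq),
       tq = tq, Bq = Bq, dt = tq[2] - tq[1])
}

basis_at <- function(basis, t) {
  t <- pmin(pmax(t, 0), basis$upper)
  splines::splineDesign(basis$knots, t, ord = basis$degree + 1L)
}

#' Cumulative baseline hazard of the B-spline log-hazard
#'
#' \eqn{H_0(t) = \int_0^t \exp(B(u)^\top \omega)\,du}, integrated by the
#' trapezoid rule on the basis' quadrature grid (exact for a constant
#' log-hazard) and interpolated linearly at \code{t}.
#'
#' @param omega spline ordinates (log-hazard scale).
#' @param basis basis object from the fit (internal structure).
#' @param t evaluation times in seconds.
#' @return numeric vector \eqn{H_0(t)}.
#' @export
baseline_cumhaz <- function(omega, basis, t) {
  h0q <- exp(drop(basis$Bq %*% omega))
  H0q <- c(0, cumsum((h0q[-1] + h0q[-length(h0q)]) / 2 * basis$dt))
  stats::approx(basis$tq, H0q, xout = pmin(pmax(t, 0), basis$upper),
                rule = 2)$y
}

#' Log-likelihood of the spatial proportional-hazards model
#'
#' Hazard \eqn{h(t \mid x, s) = h_0(t) \exp(x^\top\beta + Y(s))} with
#' B-spline log baseline. Contributes \eqn{\log h(t_i) - H(t_i)} for
#' observed arrivals and \eqn{-H(t_i)} for censored ones, with the
#' cumulative hazard integrated numerically over the spline.
#'
#' @param model list with \code{beta} (length 2K), \code{omega} (spline
#'   ordinates) and \code{y} (per-cell frailty vector, or a scalar).
#' @param data a \code{survival_dataset} that has been attached to a grid
#'   (carries a \code{cell} attribute), or any dataset when \code{y} is
#'   scalar.
#' @param basis optional basis object; defaults to the standard cubic
#'   B-spline with 5 interior knots on (0, threshold].
#' @return the log-likelihood (scalar).
#' @export
survival_loglik <- function(model, data, basis = NULL) {
  X <- attr(data, "X")
  if (is.null(basis))
    basis <- make_basis(upper = max(attr(data, "threshold_s"),
                                    max(data$time_s)))
  y <- model$y
  if (length(y) == 1L) {
    yv <- rep(y, nrow(data))
  } else {
    cell <- attr(data, "cell")
    if (is.null(cell)) stop("data carries no cell assignment for frailties")
    yv <- y[cell]
  }
  lp <- drop(X %*% model$beta) + yv
  H0t <- baseline_cumhaz(model$omega, basis, data$time_s)
  lhaz <- drop(basis_at(basis, data$time_s) %*% model$omega)
  ll_terms <- ifelse(data$censored, 0, lhaz + lp) - H0t * exp(lp)
  if (any(!is.finite(ll_terms))) {
    bad <- which(!is.finite(ll_terms))[1]
    stop(sprintf("non-finite hazard contribution at event %d", bad))
  }
  sum(ll_terms)
}

# --- MCMC configuration --------------------------------------------------

#' MCMC control parameters
#'
#' Presets: \code{"paper"} is the full-scale chain (50,000 iterations,
#' 10,000 burn-in, thinning 490, retaining 81 samples); \code{"test"} is
#' a desk-scale chain (2,000 / 500 / 5, retaining 300).
#'
#' @param nits total iterations.
#' @param burn discarded initial iterations (adaptation happens here).
#' @param thin keep every \code{thin}-th post-burn-in iteration.
#' @param seed integer RNG seed for the chain.
#' @param preset \code{"paper"} or \code{"test"}; overrides nits/burn/thin.
#' @return object of class \code{mcmc_control}.
#' @examples
#' n_retained(mcmc_control(preset = "paper"))  # 81
#' @export
mcmc_control <- function(nits = 50000L, burn = 10000L, thin = 490L,
                         seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("paper", "test"))
    if (preset == "paper") {
      nits <- 50000L; burn <- 10000L; thin <- 490L
    } else {
      nits <- 2000L; burn <- 500L; thin <- 5L
    }
  }
  nits <- as.integer(nits); burn <- as.integer(burn); thin <- as.integer(thin)
  if (!(nits > burn) || burn < 0 || thin < 1)
    stop("require nits > burn >= 0 and thin >= 1")
  structure(list(nits = nits, burn = burn, thin = thin,
                 seed = as.integer(seed)),
            class = "mcmc_control")
}

#' @rdname mcmc_control
#' @param cfg an \code{mcmc_control}.
#' @export
n_retained <- function(cfg) {
  as.integer(floor((cfg$nits - cfg$burn) / cfg$thin))
}

#' Prior specification for the spatial survival model
#'
#' Regression coefficients beta are Normal(0, 100^2); spline ordinates
#' omega are Normal(0, 10^2); the spatial range eta (metres) has a
#' log-Gaussian prior with sd 0.5 centred, by default, at the log of the
#' geometric midpoint of the plausible 1-1000 m range; the frailty field
#' has an exponential-decay covariance with variance sigma2 (fixed at 1
#' by default).
#'
#' @param beta_sd,omega_sd prior standard deviations.
#' @param eta_log_mean,eta_log_sd log-scale prior for the range, metres.
#' @param sigma2 spatial field variance.
#' @return list of prior parameters.
#' @export
survival_priors <- function(beta_sd = 100, omega_sd = 10,
                            eta_log_mean = log(sqrt(1000)),
                            eta_log_sd = 0.5, sigma2 = 1) {
  list(beta_sd = beta_sd, omega_sd = omega_sd,
       eta_log_mean = eta_log_mean, eta_log_sd = eta_log_sd,
       sigma2 = sigma2)
}

# --- The fitting function ------------------------------------------------

#' Bayesian spatial survival model of ambulance response time
#'
#' Fits the proportional-hazards model
#' \deqn{h(t \mid x, s) = h_0(t)\, e^{x^\top \beta + Y(s)}}
#' to right-censored response times, where \eqn{h_0} has a cubic B-spline
#' log baseline, \eqn{x} are harmonic covariates of the call hour, and
#' \eqn{Y} is a zero-mean Gaussian frailty field on the demand grid with
#' exponential covariance \eqn{\sigma^2 e^{-d/\eta}}. Inference is by
#' Metropolis-within-Gibbs MCMC: adaptive random-walk updates for
#' \eqn{\beta} and \eqn{\omega} (adaptation during burn-in only),
#' elliptical slice sampling for \eqn{Y}, and a log-scale random walk for
#' \eqn{\eta} (proposals failing the covariance factorisation are
#' rejected, not fatal). Chains are reproducible under a fixed seed.
#'
#' @param data a \code{survival_dataset} (from [build_survival_data()]),
#'   or a raw event data.frame which will be filtered and built with the
#'   defaults.
#' @param grid a \code{demand_grid} defining the frailty field's cells;
#'   every event must fall inside the grid's bounding box.
#' @param priors list from [survival_priors()].
#' @param mcmc an [mcmc_control()].
#' @param n_knots interior spline knots on (0, threshold] (default 5).
#' @return object of class \code{spatial_delay_model} with posterior
#'   \code{samples} (\code{beta}, \code{omega}, \code{y}, \code{eta}),
#'   the data, grid, basis, priors, and acceptance rates.
#' @seealso [compute_pep()], [relative_risk_curve()],
#'   [simulate_survival_events()]
#' @export
spatial_delay_model <- function(data, grid, priors = survival_priors(),
                                mcmc = mcmc_control(preset = "test"),
                                n_knots = 5L) {
  if (!inherits(data, "survival_dataset")) {
    data <- build_survival_data(filter_ohca(data))
  }
  stopifnot(inherits(grid, "demand_grid"))
  if (nrow(data) < 30) stop("need at least 30 events for the default spline")

  cells <- grid$cells
  cell <- match_cells(data$x_m, data$y_m, grid)
  attr(data, "cell") <- cell

  basis <- make_basis(upper = max(attr(data, "threshold_s"),
                                  max(data$time_s)),
                      n_interior = n_knots)
  X <- attr(data, "X")
  p_beta <- ncol(X)
  p_omega <- basis$nbasis
  n_cell <- nrow(cells)
  D <- as.matrix(stats::dist(cbind(cells$cx, cells$cy)))

  rng <- local_rng(mcmc$seed * 48271L %% .Machine$integer.max + 11L)
  on.exit(rng())

  # initial state: constant hazard at the crude event rate
  crude <- max(sum(!data$censored), 1) / sum(data$time_s)
  beta <- rep(0, p_beta)
  omega <- rep(log(crude), p_omega)
  y <- rep(0, n_cell)
  logeta <- priors$eta_log_mean

  chol_for <- function(le) {
    S <- priors$sigma2 * exp(-D / exp(le))
    diag(S) <- diag(S) + 1e-8
    tryCatch(t(chol(S)), error = function(e) NULL)
  }
  L <- chol_for(logeta)
  if (is.null(L)) stop("initial spatial covariance is not positive definite")

  gp_logdens <- function(yv, Lm) {
    z <- forwardsolve(Lm, yv)
    -sum(log(diag(Lm))) - 0.5 * sum(z^2) - 0.5 * length(yv) * log(2 * pi)
  }

  ll_fun <- function(beta, omega, yv) {
    lp <- drop(X %*% beta) + yv[cell]
    H0t <- baseline_cumhaz(omega, basis, data$time_s)
    lhaz <- drop(basis_at(basis, data$time_s) %*% omega)
    sum(ifelse(data$censored, 0, lhaz + lp)) - sum(H0t * exp(lp))
  }

  ll <- ll_fun(beta, omega, y)
  steps <- c(beta = 0.08, omega = 0.08, logeta = 0.3)
  acc <- c(beta = 0, omega = 0, logeta = 0); try_n <- acc

  S <- n_retained(mcmc)
  out_beta <- matrix(NA_real_, S, p_beta,
                     dimnames = list(NULL, colnames(X)))
  out_omega <- matrix(NA_real_, S, p_omega)
  out_y <- matrix(NA_real_, S, n_cell, dimnames = list(NULL, cells$cell_id))
  out_eta <- numeric(S)
  s_idx <- 0L

  for (it in seq_len(mcmc$nits)) {
    adapting <- it <= mcmc$burn

    # beta: joint random walk
    prop <- beta + stats::rnorm(p_beta, 0, steps["beta"])
    ll_p <- ll_fun(prop, omega, y)
    lr <- ll_p - ll +
      sum(stats::dnorm(prop, 0, priors$beta_sd, log = TRUE)) -
      sum(stats::dnorm(beta, 0, priors$beta_sd, log = TRUE))
    try_n["beta"] <- try_n["beta"] + 1
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      beta <- prop; ll <- ll_p; acc["beta"] <- acc["beta"] + 1
      if (adapting) steps["beta"] <- steps["beta"] * exp(0.02)
    } else if (adapting) steps["beta"] <- steps["beta"] * exp(-0.006)

    # omega: joint random walk
    prop <- omega + stats::rnorm(p_omega, 0, steps["omega"])
    ll_p <- ll_fun(beta, prop, y)
    lr <- ll_p - ll +
      sum(stats::dnorm(prop, 0, priors$omega_sd, log = TRUE)) -
      sum(stats::dnorm(omega, 0, priors$omega_sd, log = TRUE))
    try_n["omega"] <- try_n["omega"] + 1
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      omega <- prop; ll <- ll_p; acc["omega"] <- acc["omega"] + 1
      if (adapting) steps["omega"] <- steps["omega"] * exp(0.02)
    } else if (adapting) steps["omega"] <- steps["omega"] * exp(-0.006)

    # Y: elliptical slice sampling under the GP prior
    nu <- drop(L %*% stats::rnorm(n_cell))
    ll_y <- function(yv) ll_fun(beta, omega, yv)
    logu <- ll + log(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    th_min <- th - 2 * pi; th_max <- th
    repeat {
      y_p <- y * cos(th) + nu * sin(th)
      ll_p <- ll_y(y_p)
      if (is.finite(ll_p) && ll_p > logu) {
        y <- y_p; ll <- ll_p
        break
      }
      if (th < 0) th_min <- th else th_max <- th
      th <- stats::runif(1, th_min, th_max)
      if (th_max - th_min < 1e-10) break  # degenerate bracket, keep current
    }

    # eta: log-scale random walk; likelihood does not involve eta, only
    # the GP prior density of the current field changes
    prop <- logeta + stats::rnorm(1, 0, steps["logeta"])
    L_p <- chol_for(prop)
    try_n["logeta"] <- try_n["logeta"] + 1
    if (!is.null(L_p)) {
      lr <- gp_logdens(y, L_p) - gp_logdens(y, L) +
        stats::dnorm(prop, priors$eta_log_mean, priors$eta_log_sd,
                     log = TRUE) -
        stats::dnorm(logeta, priors$eta_log_mean, priors$eta_log_sd,
                     log = TRUE)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        logeta <- prop; L <- L_p; acc["logeta"] <- acc["logeta"] + 1
        if (adapting) steps["logeta"] <- steps["logeta"] * exp(0.03)
      } else if (adapting) steps["logeta"] <- steps["logeta"] * exp(-0.017)
    }

    if (it > mcmc$burn && (it - mcmc$burn) %% mcmc$thin == 0 && s_idx < S) {
      s_idx <- s_idx + 1L
      out_beta[s_idx, ] <- beta
      out_omega[s_idx, ] <- omega
      out_y[s_idx, ] <- y
      out_eta[s_idx] <- exp(logeta)
    }
  }

  structure(list(
    samples = list(beta = out_beta, omega = out_omega, y = out_y,
                   eta = out_eta),
    data = data, grid = grid, basis = basis, priors = priors, mcmc = mcmc,
    threshold_s = attr(data, "threshold_s"), K = attr(data, "K"),
    acceptance = acc / pmax(try_n, 1), steps = steps,
    n_events = nrow(data), n_censored = sum(data$censored)
  ), class = "spatial_delay_model")
}

# map event coordinates to grid cell row indices; error when outside
match_cells <- function(x, y, grid) {
  b <- grid$bbox; cs <- grid$cell_size_m
  out <- x >= b[1] & y >= b[2] & x <= b[3] & y <= b[4]
  if (!all(out)) stop("event locations fall outside the spatial field")
  ix <- pmin(floor((x - b[1]) / cs), max(grid$cells$ix))
  iy <- pmin(floor((y - b[2]) / cs), max(grid$cells$iy))
  idx <- match(paste(ix, iy), paste(grid$cells$ix, grid$cells$iy))
  if (anyNA(idx)) stop("event location maps to a cell missing from the grid")
  idx
}

# --- Posterior summaries -------------------------------------------------

#' Posterior exceedance probability surface
#'
#' For every grid cell, the posterior mean of the survivor function at
#' the threshold, \eqn{PEP(s) = E[\,S(300 \mid \bar{x}, Y(s))\,]}, with
#' covariates at their day-average (zero for harmonics). A value of 0.8-1
#' means that in more than 80% of occurrences at that location the
#' ambulance does not arrive within the threshold.
#'
#' @param fit a \code{spatial_delay_model}.
#' @param threshold_s exceedance threshold in seconds (default: the
#'   fit's censoring threshold).
#' @return data.frame: grid cells plus a \code{pep} column in [0, 1].
#' @export
compute_pep <- function(fit, threshold_s = fit$threshold_s) {
  sm <- fit$samples
  if (is.null(sm) || nrow(sm$omega) == 0) stop("fit carries no samples")
  S_mat <- vapply(seq_len(nrow(sm$omega)), function(s) {
    H0 <- baseline_cumhaz(sm$omega[s, ], fit$basis, threshold_s)
    exp(-H0 * exp(sm$y[s, ]))
  }, numeric(ncol(sm$y)))
  pep <- rowMeans(S_mat)
  out <- fit$grid$cells
  out$pep <- pmin(pmax(pep, 0), 1)
  out
}

#' Diurnal relative-risk curve of threshold exceedance
#'
#' For each time of day h, the posterior distribution of
#' \eqn{P(T > 300 \mid x(h), Y = 0)} is normalised by its geometric
#' day-mean within each posterior draw, giving a relative risk whose
#' day-average is 1. Returns the posterior median and central 95% band.
#'
#' @param fit a \code{spatial_delay_model}.
#' @param step_h hour step of the curve (default 0.25).
#' @param level credible level for the band (default 0.95).
#' @return data.frame: \code{hour}, \code{median}, \code{lo}, \code{hi}.
#' @export
relative_risk_curve <- function(fit, step_h = 0.25, level = 0.95) {
  hours <- seq(0, 24 - step_h, by = step_h)
  Xh <- harmonic_covariates(hours, fit$K)
  sm <- fit$samples
  rr <- vapply(seq_len(nrow(sm$beta)), function(s) {
    H0 <- baseline_cumhaz(sm$omega[s, ], fit$basis, fit$threshold_s)
    risk <- exp(-H0 * exp(drop(Xh %*% sm$beta[s, ])))
    risk <- pmax(risk, 1e-300)
    risk / exp(mean(log(risk)))
  }, numeric(length(hours)))
  a <- (1 - level) / 2
  data.frame(
    hour = hours,
    median = apply(rr, 1, stats::median),
    lo = apply(rr, 1, stats::quantile, probs = a),
    hi = apply(rr, 1, stats::quantile, probs = 1 - a)
  )
}

#' Frequentist harmonic cross-check of diurnal exceedance
#'
#' A standalone logistic regression of the exceedance indicator
#' (response time above the threshold) on the harmonic covariates,
#' returning the fitted exceedance probability by hour normalised by its
#' geometric day-mean. Used as an independent check on the Bayesian
#' relative-risk curve.
#'
#' @param data a \code{survival_dataset}.
#' @param step_h hour step (default 0.25).
#' @return data.frame \code{hour}, \code{rr}, plus the \code{glm} fit as
#'   attribute \code{"fit"}.
#' @export
exceedance_glm <- function(data, step_h = 0.25) {
  X <- attr(data, "X")
  df <- data.frame(exceed = as.integer(data$censored), X)
  fit <- stats::glm(exceed ~ ., data = df, family = stats::binomial())
  hours <- seq(0, 24 - step_h, by = step_h)
  Xh <- as.data.frame(harmonic_covariates(hours, attr(data, "K")))
  p <- stats::predict(fit, newdata = Xh, type = "response")
  rr <- p / exp(mean(log(pmax(p, 1e-300))))
  out <- data.frame(hour = hours, rr = rr)
  attr(out, "fit") <- fit
  out
}

# --- Model-based simulation ---------------------------------------------

#' Simulate events from the spatial survival model
#'
#' Draws response times from the proportional-hazards model with a
#' constant baseline hazard \code{lambda0}, harmonic effect \code{beta},
#' and a fixed per-cell frailty field \code{y} on \code{grid}. Used for
#' parameter-recovery studies and by [simulate.spatial_delay_model()].
#'
#' @param n number of events.
#' @param grid a \code{demand_grid}.
#' @param beta harmonic coefficients (length 2K).
#' @param y per-cell frailty vector (length = cells) or single value.
#' @param lambda0 baseline hazard per second.
#' @param K harmonic order.
#' @param seed RNG seed.
#' @return event data.frame compatible with [build_survival_data()]
#'   (complete, non-traumatic, adult records).
#' @export
simulate_survival_events <- function(n, grid, beta, y = 0,
                                     lambda0 = 0.002, K = 2L, seed = 1L) {
  stopifnot(inherits(grid, "demand_grid"))
  rng <- local_rng(seed * 69621L %% .Machine$integer.max + 3L)
  on.exit(rng())
  cells <- grid$cells
  if (length(y) == 1L) y <- rep(y, nrow(cells))
  stopifnot(length(y) == nrow(cells))
  ci <- sample.int(nrow(cells), n, replace = TRUE)
  jit <- grid$cell_size_m * 0.49
  x_m <- cells$cx[ci] + stats::runif(n, -jit, jit)
  y_m <- cells$cy[ci] + stats::runif(n, -jit, jit)
  hours <- stats::runif(n, 0, 24)
  X <- harmonic_covariates(hours, K)
  rate <- lambda0 * exp(drop(X %*% beta) + y[ci])
  tt <- stats::rexp(n) / rate
  data.frame(
    event_id = sprintf("M%05d", seq_len(n)),
    x_m = x_m, y_m = y_m,
    call_datetime = format(as.POSIXct("2020-01-01", tz = "UTC") +
                             round(hours * 3600),
                           "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    call_hour = hours,
    age = 60L, sex = "male", traumatic = FALSE,
    response_time_s = tt,
    dispatch_time_s = 0,
    bystander_cpr = "no", shockable = FALSE, death = TRUE,
    cpr_duration_s = 1800, complete = TRUE,
    stringsAsFactors = FALSE
  )
}

# --- S3 methods ----------------------------------------------------------

#' @export
print.spatial_delay_model <- function(x, ...) {
  cat("Bayesian spatial survival model of ambulance response time\n")
  cat(sprintf("  events: %d (%d censored at %g s)\n",
              x$n_events, x$n_censored, x$threshold_s))
  cat(sprintf("  grid: %d cells of %g m; harmonics: K = %d\n",
              ncol(x$samples$y), x$grid$cell_size_m, x$K))
  cat(sprintf("  chain: %d iterations, %d burn-in, thin %d -> %d samples\n",
              x$mcmc$nits, x$mcmc$burn, x$mcmc$thin, nrow(x$samples$beta)))
  cat(sprintf("  acceptance: beta %.2f, omega %.2f, eta %.2f\n",
              x$acceptance["beta"], x$acceptance["omega"],
              x$acceptance["logeta"]))
  invisible(x)
}

#' @export
coef.spatial_delay_model <- function(object, ...) {
  colMeans(object$samples$beta)
}

#' @export
summary.spatial_delay_model <- function(object, ...) {
  b <- object$samples$beta
  qs <- t(apply(b, 2, stats::quantile, probs = c(0.05, 0.5, 0.95)))
  tab <- data.frame(mean = colMeans(b), q05 = qs[, 1], median = qs[, 2],
                    q95 = qs[, 3])
  eta <- stats::quantile(object$samples$eta, c(0.05, 0.5, 0.95))
  out <- list(beta = tab, eta = eta, acceptance = object$acceptance,
              n_events = object$n_events, n_censored = object$n_censored,
              n_samples = nrow(b))
  class(out) <- "summary.spatial_delay_model"
  out
}

#' @export
print.summary.spatial_delay_model <- function(x, ...) {
  cat(sprintf("Posterior summary (%d samples, %d events, %d censored)\n",
              x$n_samples, x$n_events, x$n_censored))
  print(round(x$beta, 4))
  cat("eta (m):", paste(sprintf("%.1f", x$eta), collapse = " / "), "\n")
  invisible(x)
}

#' @export
predict.spatial_delay_model <- function(object,
                                        type = c("pep", "rr"), ...) {
  type <- match.arg(type)
  if (type == "pep") compute_pep(object) else relative_risk_curve(object)
}

#' @export
plot.spatial_delay_model <- function(x, which = c("rr", "pep"), ...) {
  which <- match.arg(which)
  if (which == "rr") {
    rr <- relative_risk_curve(x)
    graphics::plot(rr$hour, rr$median, type = "l", lwd = 2,
                   ylim = range(rr$lo, rr$hi),
                   xlab = "hour of day",
                   ylab = "relative risk of exceeding threshold", ...)
    graphics::lines(rr$hour, rr$lo, lty = 2)
    graphics::lines(rr$hour, rr$hi, lty = 2)
    graphics::abline(h = 1, col = "grey")
  } else {
    pep <- compute_pep(x)
    nx <- max(pep$ix) + 1L; ny <- max(pep$iy) + 1L
    z <- matrix(NA_real_, nx, ny)
    z[cbind(pep$ix + 1L, pep$iy + 1L)] <- pep$pep
    graphics::image(seq_len(nx), seq_len(ny), z, xlab = "cell x",
                    ylab = "cell y", main = "posterior exceedance", ...)
  }
  invisible(x)
}

#' Simulate datasets from a fitted model
#'
#' Draws event sets from the posterior-mean parameters (constant-hazard
#' approximation of the fitted baseline at the threshold's crude rate).
#'
#' @param object a \code{spatial_delay_model}.
#' @param nsim number of datasets.
#' @param seed RNG seed.
#' @param n events per dataset (default: the fitted size).
#' @param ... unused.
#' @return a list of event data.frames.
#' @export
simulate.spatial_delay_model <- function(object, nsim = 1, seed = 1L,
                                         n = object$n_events, ...) {
  beta_hat <- colMeans(object$samples$beta)
  y_hat <- colMeans(object$samples$y)
  omega_hat <- colMeans(object$samples$omega)
  H0 <- baseline_cumhaz(omega_hat, object$basis, object$threshold_s)
  lambda0 <- H0 / object$threshold_s  # rate matching the fitted H0(300)
  lapply(seq_len(nsim), function(i) {
    simulate_survival_events(n, object$grid, beta_hat, y_hat, lambda0,
                             K = object$K, seed = seed + i - 1L)
  })
}
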