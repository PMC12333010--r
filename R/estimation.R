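free_par_names <- function(endpoint) {
  if (endpoint == "alertness") c("k_out", "e_max", "ec50", "hill", "baseline")
  else c("k_e0", "e_max", "ec50", "hill")
}

default_bounds <- function(endpoint) {
  if (endpoint == "alertness") {
    list(k_out = c(0.05, 20), e_max = c(1, 100), ec50 = c(1e-4, 50),
         hill = c(0.5, 5), baseline = c(1, 100))
  } else {
    list(k_e0 = c(0.05, 50), e_max = c(1, 200), ec50 = c(1e-4, 50),
         hill = c(0.5, 5))
  }
}

#' Fit specification for PD parameter estimation
#'
#' Declares which PD parameters are estimated, their bounds and starting
#' values, and which are held fixed. The loss is the (optionally
#' n-weighted) sum of squared residuals between the model mean VAS and the
#' observed mean VAS. All parameters are positive, so optimization runs in
#' log space by default; Hill coefficients are bounded to `[0.5, 5]`, a
#' plausible pharmacodynamic slope range.
#'
#' @param endpoint `"feeling_high"` or `"alertness"`.
#' @param free character vector of parameter names to estimate. For
#'   "feeling high": `k_e0` (shared by both compounds), `e_max`, `ec50`,
#'   `hill`. For alertness: `k_out`, `e_max`, `ec50`, `hill`, `baseline`.
#' @param fixed the full PD parameter set supplying fixed values (and
#'   starting values for free ones unless overridden in `init`).
#' @param init optional named list of starting values for free parameters.
#' @param bounds optional named list of `c(lower, upper)` per free
#'   parameter; defaults cover the plausible pharmacodynamic range.
#' @param log_scale optimize log-transformed parameters (default TRUE).
#' @param n_starts number of multistart points (first is `init`, the rest
#'   Latin-hypercube within bounds).
#' @param seed RNG seed for the multistart design.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(endpoint = c("feeling_high", "alertness"),
                     free = c("e_max", "ec50"),
                     fixed = NULL, init = NULL, bounds = NULL,
                     log_scale = TRUE, n_starts = 10, seed = 1L) {
  endpoint <- match.arg(endpoint)
  allowed <- free_par_names(endpoint)
  if (!all(free %in% allowed))
    stop(sprintf("free parameters for %s must be among: %s", endpoint,
                 paste(allowed, collapse = ", ")), call. = FALSE)
  if (is.null(fixed)) {
    fixed <- if (endpoint == "alertness") alertness_params()
             else feeling_high_params()
  }
  b <- default_bounds(endpoint)
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  b <- b[free]
  if (any(vapply(b, function(x) x[1] <= 0 || x[2] <= x[1], logical(1))))
    stop("bounds must be positive with lower < upper", call. = FALSE)
  iv <- lapply(free, function(nm) {
    v <- if (!is.null(init[[nm]])) init[[nm]]
         else if (nm == "k_e0") fixed$k_e0_thc else fixed[[nm]]
    min(max(v, b[[nm]][1]), b[[nm]][2])
  })
  names(iv) <- free
  structure(
    list(endpoint = endpoint, free = free, fixed = fixed, init = iv,
         bounds = b, log_scale = log_scale, n_starts = as.integer(n_starts),
         seed = as.integer(seed)),
    class = "fit_spec"
  )
}

# assemble a full parameter object with free values substituted in
assemble_params <- function(spec, theta) {
  p <- spec$fixed
  for (nm in names(theta)) {
    if (nm == "k_e0") {
      p$k_e0_thc <- theta[[nm]]
      p$k_e0_ohthc <- theta[[nm]]
    } else p[[nm]] <- theta[[nm]]
  }
  p
}

# model mean VAS at the observed times, given gridded concentrations
pd_predict <- function(spec, theta, conc, obs_times) {
  p <- assemble_params(spec, theta)
  vas <- if (spec$endpoint == "alertness") simulate_alertness(conc, p, clip = FALSE)
         else simulate_feeling_high(conc, p, clip = FALSE)
  stats::approx(vas$time_h, vas$vas_mm, xout = obs_times, rule = 2)$y
}

#' Estimate PD parameters from an observed mean VAS series
#'
#' Bounded nonlinear least squares ([minpack.lm::nls.lm]) of the PD model
#' against an observed mean VAS series, driven by simulated brain
#' concentrations. Deterministic given the spec (multistart design is
#' seeded); the best of all starts is returned. Non-convergence of every
#' start is flagged in the result, not raised.
#'
#' @param observed an [observed_series()].
#' @param conc a `conc_series` covering the observed time span.
#' @param spec a [fit_spec()].
#' @param weight_by_n weight residuals by `sqrt(n)` when the observed
#'   series records a subject count (a mean of n subjects has variance
#'   proportional to 1/n).
#' @return An object of class `fit_result`: list with `estimates` (named
#'   numeric), `loss` (sum of squared residuals at the optimum),
#'   `converged`, `residuals` (data frame `time_h`, `observed_mm`,
#'   `fitted_mm`, `residual_mm`), `n_starts`, `seed`.
#' @export
fit_pd <- function(observed, conc, spec, weight_by_n = FALSE) {
  stopifnot(inherits(spec, "fit_spec"))
  obs_t <- observed$time_h
  if (obs_t[1] < conc$time_h[1] - 1e-9 ||
      obs_t[length(obs_t)] > conc$time_h[nrow(conc)] + 1e-9)
    stop("observed series extends beyond the concentration time span",
         call. = FALSE)
  obs_y <- observed$vas_mm
  w <- if (weight_by_n && !is.na(attr(observed, "n")))
    sqrt(attr(observed, "n")) else 1

  k <- length(spec$free)
  tf <- if (spec$log_scale) log else identity
  itf <- if (spec$log_scale) exp else identity
  lo <- tf(vapply(spec$bounds, `[`, numeric(1), 1))
  hi <- tf(vapply(spec$bounds, `[`, numeric(1), 2))

  resid_fn <- function(par) {
    theta <- stats::setNames(as.list(itf(par)), spec$free)
    w * (pd_predict(spec, theta, conc, obs_t) - obs_y)
  }

  starts <- matrix(tf(unlist(spec$init)), nrow = 1)
  if (spec$n_starts > 1) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(spec$seed)
    u <- lhs::randomLHS(spec$n_starts - 1L, k)
    starts <- rbind(starts,
                    sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+"))
  }

  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lo, upper = hi,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    conv <- fit$info %in% 1:3
    any_conv <- any_conv || conv
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)

  est <- stats::setNames(itf(best$par), spec$free)
  fitted <- pd_predict(spec, as.list(est), conc, obs_t)
  structure(
    list(estimates = est, loss = sum((w * (fitted - obs_y))^2),
         converged = any_conv,
         residuals = data.frame(time_h = obs_t, observed_mm = obs_y,
                                fitted_mm = fitted,
                                residual_mm = fitted - obs_y),
         n_starts = spec$n_starts, seed = spec$seed),
    class = "fit_result"
  )
}

#' Profile the loss over one parameter
#'
#' Evaluates the sum-of-squares loss along a grid for one parameter while
#' re-optimizing the remaining free parameters at each grid point (an
#' identifiability diagnostic: flat valleys signal weakly identified
#' parameter combinations).
#'
#' @param observed,conc,spec as in [fit_pd()].
#' @param parameter name of the profiled parameter (must be free in
#'   `spec`).
#' @param grid values for the profiled parameter, all within its bounds.
#' @return data frame `value`, `loss` of class `profile_loss`.
#' @export
profile_loss <- function(observed, conc, spec, parameter, grid) {
  stopifnot(inherits(spec, "fit_spec"))
  if (!parameter %in% spec$free)
    stop("`parameter` must be one of the free parameters", call. = FALSE)
  b <- spec$bounds[[parameter]]
  if (any(grid < b[1] | grid > b[2]))
    stop("grid values outside the parameter bounds", call. = FALSE)
  others <- setdiff(spec$free, parameter)
  loss <- vapply(grid, function(v) {
    fx <- assemble_params(spec, stats::setNames(list(v), parameter))
    if (length(others) == 0L) {
      r <- pd_predict(spec, stats::setNames(list(v), parameter),
                      conc, observed$time_h) - observed$vas_mm
      sum(r^2)
    } else {
      sub <- fit_spec(endpoint = spec$endpoint, free = others, fixed = fx,
                      bounds = spec$bounds[others],
                      log_scale = spec$log_scale,
                      n_starts = max(3L, spec$n_starts %/% 2L),
                      seed = spec$seed)
      fit_pd(observed, conc, sub)$loss
    }
  }, numeric(1))
  structure(data.frame(value = grid, loss = loss),
            class = c("profile_loss", "data.frame"), parameter = parameter)
}
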