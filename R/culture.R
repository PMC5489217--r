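# Batch-culture kinetic model.
#
# State variables: biomass x, xylose S, ethanol P (g/L) and dissolved
# oxygen C_L (g/L).  Growth follows Monod kinetics with a logistic-type
# lag (delay) factor; ethanol formation follows Luedeking-Piret with its
# own delay; xylose uptake closes the substrate mass balance
#
#     qS = mu/Yo + m + qP/YP,
#
# and dissolved oxygen follows dC_L/dt = kLa (C* - C_L) - qO2 x, with
# the oxygen-limited quasi-steady simplification qO2 = kLa C* / x when
# all transferred oxygen is consumed.

#' Kinetic parameters of the batch-culture model
#'
#' @param mu_max maximum specific growth rate (1/h).
#' @param Ks substrate saturation constant (g/L).
#' @param Yo theoretical biomass yield from xylose (g/g).
#' @param YP theoretical ethanol yield from xylose (g/g); fixed at the
#'   stoichiometric maximum 0.511 by default and not fitted.
#' @param m maintenance coefficient (g xylose / g cell / h).
#' @param alpha growth-associated Luedeking-Piret coefficient (g/g).
#' @param beta non-growth-associated coefficient (g/g/h).
#' @param q1,v1 growth-lag delay parameters: f_r1 = q1/(q1 + e^(-v1 t)).
#' @param q2,v2 production-lag delay parameters.
#' @param kLa volumetric oxygen transfer coefficient (1/h).
#' @param Cstar dissolved-oxygen saturation (g/L; default 0.0075, water
#'   at 30 degrees C).
#' @return list of class `"culture_params"`.
#' @export
culture_params <- function(mu_max = 0.08, Ks = 0.5, Yo = 0.5, YP = 0.511,
                           m = 0.01, alpha = 1.2, beta = 0.01,
                           q1 = 0.1, v1 = 0.2, q2 = 0.05, v2 = 0.15,
                           kLa = 25, Cstar = 0.0075) {
  p <- list(mu_max = mu_max, Ks = Ks, Yo = Yo, YP = YP, m = m,
            alpha = alpha, beta = beta, q1 = q1, v1 = v1, q2 = q2, v2 = v2,
            kLa = kLa, Cstar = Cstar)
  with(p, stopifnot(mu_max > 0, Ks > 0, Yo > 0, YP > 0, YP <= 0.511,
                    m >= 0, alpha >= 0, beta >= 0, q1 > 0, v1 > 0,
                    q2 > 0, v2 > 0, kLa > 0, Cstar > 0))
  structure(p, class = "culture_params")
}

#' Lag delay factor
#'
#' `f = q / (q + exp(-v t))`: strictly increasing in `t`, from
#' `q/(q+1)` at `t = 0` towards 1.  The derived link `q1 = k mu_max`
#' gives `k = q1 / mu_max`.
#'
#' @param q dimensionless delay parameter (> 0).
#' @param v rate exponent (1/h, > 0).
#' @param t time (h, >= 0).
#' @return the delay factor, in `(q/(q+1), 1)`.
#' @export
delay_factor <- function(q, v, t) {
  stopifnot(all(q > 0), all(v > 0), all(t >= 0))
  q / (q + exp(-v * t))
}

#' Specific rates at a given substrate level and time
#'
#' `mu = mu_max S/(S+Ks) f_r1(t)`; `qP = (alpha mu + beta) f_r2(t)`;
#' `qS = mu/Yo + m + qP/YP`.
#'
#' @param params a [culture_params()].
#' @param S substrate concentration (g/L).
#' @param t time (h).
#' @return list with `mu` (1/h), `qP`, `qS` (g/gcell/h).
#' @export
specific_rates <- function(params, S, t) {
  p <- params
  if (p$Yo == 0 || p$YP == 0) stop("Yo and YP must be non-zero")
  S <- pmax(S, 0)
  f1 <- delay_factor(p$q1, p$v1, t)
  f2 <- delay_factor(p$q2, p$v2, t)
  mu <- p$mu_max * S / (S + p$Ks) * f1
  qP <- (p$alpha * mu + p$beta) * f2
  qS <- mu / p$Yo + p$m + qP / p$YP
  list(mu = mu, qP = qP, qS = qS)
}

#' Oxygen-limited specific oxygen uptake rate
#'
#' Under oxygen limitation all transferred oxygen is consumed, so
#' `qO2 = kLa C* / x`.
#'
#' @param kLa transfer coefficient (1/h).
#' @param Cstar saturation concentration (g/L).
#' @param x biomass concentration (g/L, > 0).
#' @return qO2 in g O2 / g cell / h.
#' @export
oxygen_limited_qO2 <- function(kLa, Cstar, x) {
  if (any(x <= 0)) stop("specific oxygen uptake is undefined at x = 0")
  kLa * Cstar / x
}

#' Oxygen transfer rate
#'
#' `OTR = kLa C*`, converted to mmol O2 / L / h (molar mass 32.00).
#'
#' @param kLa transfer coefficient (1/h).
#' @param Cstar saturation concentration (g/L).
#' @return OTR in mmol O2 / L / h.
#' @export
otr <- function(kLa, Cstar = 0.0075) {
  stopifnot(kLa >= 0, Cstar > 0)
  kLa * Cstar / 32.00 * 1000
}

#' Simulate the batch culture
#'
#' Integrates dx/dt = mu x, dS/dt = -qS x, dP/dt = qP x and (optionally)
#' the dissolved-oxygen balance with an adaptive stiff solver
#' ([deSolve::ode()], lsoda).  All consumption and production switches
#' off once the substrate is exhausted; concentrations are clipped at
#' zero in the returned trajectory.
#'
#' @param params a [culture_params()].
#' @param initial_state named vector `c(x = , S = , P = )` in g/L (an
#'   optional `C_L` entry seeds the oxygen state; default `Cstar`).
#' @param t_span times (h) at which to report the state.
#' @param oxygen_limited if `TRUE` (default) dissolved oxygen is held at
#'   the quasi-steady limit (C_L = 0, qO2 = kLa C*/x); if `FALSE` the
#'   full C_L balance is integrated with qO2 = kLa C*/x capped demand.
#' @param rtol,atol integrator tolerances.
#' @return a `data.frame` of class `"culture_trajectory"` with columns
#'   `t`, `x`, `S`, `P`, `C_L`, `mu`, `qS`, `qP`, `qO2`.
#' @export
simulate_culture <- function(params, initial_state, t_span,
                             oxygen_limited = TRUE,
                             rtol = 1e-8, atol = 1e-10) {
  p <- params
  stopifnot(all(initial_state[c("x", "S", "P")] >= 0), all(diff(t_span) > 0))
  y0 <- c(x = unname(initial_state[["x"]]),
          S = unname(initial_state[["S"]]),
          P = unname(initial_state[["P"]]),
          C_L = if ("C_L" %in% names(initial_state))
                  unname(initial_state[["C_L"]]) else p$Cstar)
  deriv <- function(t, y, parms) {
    # smooth exhaustion gate: all substrate-driven rates vanish as S -> 0
    # (half-saturation 1 mg/L keeps the system integrable at depletion)
    S_on <- max(y[["S"]], 0) / (max(y[["S"]], 0) + 1e-3)
    r <- specific_rates(p, y[["S"]], t)
    mu <- r$mu * S_on
    qP <- r$qP * S_on
    qS <- (mu / p$Yo + p$m * S_on + qP / p$YP)
    x <- max(y[["x"]], 0)
    qO2 <- if (x > 1e-12) p$kLa * p$Cstar / x else 0
    dC <- if (oxygen_limited) 0 else p$kLa * (p$Cstar - y[["C_L"]]) - qO2 * x
    list(c(mu * x, -qS * x, qP * x, dC))
  }
  t0 <- t_span[1]
  times <- if (t0 > 0) c(0, t_span) else t_span
  out <- deSolve::ode(y0, times, deriv, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (any(!is.finite(out)))
    stop("culture integration produced non-finite state; check parameters")
  out <- as.data.frame(out)
  if (t0 > 0) out <- out[-1, ]
  names(out)[1] <- "t"
  out$x <- pmax(out$x, 0); out$S <- pmax(out$S, 0); out$P <- pmax(out$P, 0)
  if (oxygen_limited) out$C_L <- 0
  r <- specific_rates(p, out$S, out$t)
  on <- out$S / (out$S + 1e-3)
  out$mu <- r$mu * on
  out$qP <- r$qP * on
  out$qS <- (out$mu / p$Yo + p$m * on + out$qP / p$YP)
  out$qO2 <- ifelse(out$x > 1e-12, p$kLa * p$Cstar / out$x, 0)
  class(out) <- c("culture_trajectory", "data.frame")
  attr(out, "params") <- p
  out
}

#' Overall yield and volumetric productivity of a culture
#'
#' `Y = dP / (-dS)` over the run and `Q = dP / dt` over the production
#' interval (start to the time of maximal ethanol).
#'
#' @param data a trajectory or data.frame with columns `t`, `S`, `P`.
#' @return list with `Y_etoh_xyl` (g/g) and `Q_etoh` (g/L/h).
#' @export
yield_and_productivity <- function(data) {
  dS <- data$S[1] - data$S[nrow(data)]
  iP <- which.max(data$P)
  dP <- data$P[iP] - data$P[1]
  if (dP <= 0) return(list(Y_etoh_xyl = 0, Q_etoh = 0))
  if (dS <= 0) stop("no substrate consumed; yield undefined")
  dt <- data$t[iP] - data$t[1]
  list(Y_etoh_xyl = dP / dS, Q_etoh = if (dt > 0) dP / dt else 0)
}

#' Relative change in percent
#'
#' `100 (a - b) / b`: the change of `a` relative to reference `b`, as
#' used when comparing inhibited and control cultures.
#'
#' @param a new value.
#' @param b reference value.
#' @return percent change.
#' @export
relative_change <- function(a, b) 100 * (a - b) / b

#' Write / read culture time series as TSV
#'
#' Column layout: `t_h`, `biomass_gL`, `xylose_gL`, `ethanol_gL`.
#'
#' @param data trajectory or dataset with columns `t`, `x`, `S`, `P`.
#' @param path file path.
#' @return `write_culture_tsv`: invisibly, the path;
#'   `read_culture_tsv`: a `data.frame` with columns `t`, `x`, `S`, `P`.
#' @export
write_culture_tsv <- function(data, path) {
  df <- data.frame(t_h = data$t, biomass_gL = data$x,
                   xylose_gL = data$S, ethanol_gL = data$P)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_culture_tsv
#' @export
read_culture_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  data.frame(t = df$t_h, x = df$biomass_gL, S = df$xylose_gL,
             P = df$ethanol_gL)
}

#' Generate a noisy synthetic batch-culture dataset
#'
#' Simulates the kinetic model at the sample times and adds independent
#' Gaussian observation noise per variable, clipped at zero.
#' Deterministic given the seed.
#'
#' @param params a [culture_params()].
#' @param initial_state named vector `c(x=, S=, P=)` (g/L).
#' @param sample_times strictly increasing sampling times (h).
#' @param noise_sd named vector of additive noise standard deviations
#'   for `x`, `S`, `P` (g/L); scalar recycled.
#' @param seed integer RNG seed.
#' @return `data.frame` with columns `t`, `x`, `S`, `P` and attribute
#'   `"truth"` (the noiseless trajectory).
#' @export
make_culture_dataset <- function(params,
                                 initial_state = c(x = 0.5, S = 15, P = 0),
                                 sample_times = seq(0, 48, length.out = 25),
                                 noise_sd = c(x = 0.07, S = 0.3, P = 0.08),
                                 seed = 1L) {
  stopifnot(!is.unsorted(sample_times, strictly = TRUE), all(noise_sd >= 0))
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, 3)
  if (is.null(names(noise_sd))) names(noise_sd) <- c("x", "S", "P")
  tr <- simulate_culture(params, initial_state, sample_times)
  n <- nrow(tr)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  obs <- data.frame(
    t = tr$t,
    x = pmax(tr$x + stats::rnorm(n, 0, noise_sd[["x"]]), 0),
    S = pmax(tr$S + stats::rnorm(n, 0, noise_sd[["S"]]), 0),
    P = pmax(tr$P + stats::rnorm(n, 0, noise_sd[["P"]]), 0))
  attr(obs, "truth") <- tr
  obs
}

# Internal: range-normalised residual vector between a simulation and data.
.culture_residuals <- function(params, data, initial_state) {
  tr <- tryCatch(
    simulate_culture(params, initial_state, data$t, rtol = 1e-6, atol = 1e-8),
    error = function(e) NULL)
  if (is.null(tr)) return(rep(1e3, 3L * nrow(data)))
  scale <- vapply(c("x", "S", "P"),
                  function(v) max(diff(range(data[[v]])), 1e-6), 0)
  c((tr$x - data$x) / scale[["x"]],
    (tr$S - data$S) / scale[["S"]],
    (tr$P - data$P) / scale[["P"]])
}

#' Fit the culture model to time-series data by least squares
#'
#' Minimises the per-variable range-normalised sum of squared residuals
#' between [simulate_culture()] output and the data over the free
#' parameters (by default the ten the model exposes: `mu_max`, `Ks`,
#' `Yo`, `m`, `alpha`, `beta`, `q1`, `q2`, `v1`, `v2`; `YP` stays at
#' its theoretical value).  Levenberg-Marquardt with box bounds
#' ([minpack.lm::nls.lm()]), multi-started from seeded log-normal
#' perturbations of the initial guess; the best converged start wins.
#'
#' @param data `data.frame` with columns `t`, `x`, `S`, `P` (at least
#'   as many rows as free parameters).
#' @param fixed named list of parameters to hold fixed (merged over the
#'   defaults of [culture_params()]); `YP`, `kLa` and `Cstar` are
#'   always taken from here or the defaults.
#' @param init_guess named vector of starting values for the free
#'   parameters (defaults to [culture_params()] defaults).
#' @param bounds list with named vectors `lower` and `upper` for the
#'   free parameters.
#' @param free character vector of parameter names to fit.
#' @param initial_state `c(x=, S=, P=)`; defaults to the first data row.
#' @param n_starts number of multi-start perturbations (default 20).
#' @param seed RNG seed for the multi-start perturbations.
#' @return list with `params` (a [culture_params()]), `k`
#'   (= q1/mu_max), `residual_report` (per-variable RMSE as a fraction
#'   of the observed range, per-start convergence codes) and `fit` (the
#'   best `nls.lm` object).
#' @export
fit_parameters <- function(data, fixed = list(), init_guess = NULL,
                           bounds = NULL,
                           free = c("mu_max", "Ks", "Yo", "m", "alpha",
                                    "beta", "q1", "q2", "v1", "v2"),
                           initial_state = NULL, n_starts = 20, seed = 1L) {
  stopifnot(all(c("t", "x", "S", "P") %in% names(data)))
  base <- utils::modifyList(unclass(culture_params()), fixed)
  if (is.null(initial_state))
    initial_state <- c(x = data$x[1], S = data$S[1], P = data$P[1])
  if (length(free) == 0L) {
    p <- do.call(culture_params, base)
    res <- .culture_residuals(p, data, initial_state)
    return(list(params = p, k = p$q1 / p$mu_max,
                residual_report = .residual_report(res, data, integer()),
                fit = NULL))
  }
  if (nrow(data) < length(free))
    stop("need at least as many observations as free parameters")
  default_lower <- c(mu_max = 0.005, Ks = 0.01, Yo = 0.05, m = 0,
                     alpha = 0, beta = 0, q1 = 0.005, q2 = 0.005,
                     v1 = 0.01, v2 = 0.01)
  default_upper <- c(mu_max = 1, Ks = 20, Yo = 1.5, m = 0.2,
                     alpha = 10, beta = 0.5, q1 = 20, q2 = 20,
                     v1 = 5, v2 = 5)
  lower <- default_lower[free]; upper <- default_upper[free]
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  if (is.null(init_guess)) init_guess <- unlist(base[free])
  init_guess <- pmin(pmax(init_guess[free], lower * 1.0001), upper * 0.9999)
  make_params <- function(theta) {
    pl <- base
    pl[free] <- as.list(pmin(pmax(theta, lower), upper))
    do.call(culture_params, pl)
  }
  fn <- function(theta) {
    p <- tryCatch(make_params(theta), error = function(e) NULL)
    if (is.null(p)) return(rep(1e3, 3L * nrow(data)))
    .culture_residuals(p, data, initial_state)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  starts <- list(init_guess)
  if (n_starts > 1L)
    for (k in seq_len(n_starts - 1L)) {
      th <- init_guess * exp(stats::rnorm(length(free), 0, 0.4))
      starts[[k + 1L]] <- pmin(pmax(th, lower), upper)
    }
  fits <- lapply(starts, function(th) {
    tryCatch(minpack.lm::nls.lm(
      par = th, lower = lower, upper = upper, fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok))
    stop("all ", n_starts, " starts failed to converge")
  ssq <- vapply(fits, function(f) if (is.null(f)) Inf else f$deviance, 0)
  best <- fits[[which.min(ssq)]]
  p <- make_params(best$par)
  res <- .culture_residuals(p, data, initial_state)
  codes <- vapply(fits, function(f) if (is.null(f)) -1L else f$info, 0L)
  list(params = p, k = p$q1 / p$mu_max,
       residual_report = .residual_report(res, data, codes),
       fit = best)
}

.residual_report <- function(res, data, codes) {
  n <- nrow(data)
  rmse <- function(v) sqrt(mean(v^2))
  list(rmse_fraction_of_range = c(
         x = rmse(res[seq_len(n)]),
         S = rmse(res[n + seq_len(n)]),
         P = rmse(res[2L * n + seq_len(n)])),
       n_obs = n, convergence_codes = codes)
}
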