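#' Three-compartment pharmacokinetic parameters
#'
#' Mammillary model with central volume `V1`, rapid and slow peripheral
#' volumes `V2`, `V3` (L), metabolic clearance `Cl` and intercompartmental
#' clearances `Q1`, `Q2` (L/min). Defaults are the published population
#' estimates for microemulsion propofol in healthy volunteers (central
#' volume scaled linearly in lean body mass around a 48 kg reference;
#' pass `lbm` to apply it).
#'
#' @param V1,V2,V3 volumes in L (> 0).
#' @param Cl,Q1,Q2 clearances in L/min (> 0).
#' @param lbm optional lean body mass (kg) scaling V1 by `lbm / 48`.
#' @return object of class `pk_params`.
#' @export
pk_params <- function(V1 = 17.5, V2 = 96.3, V3 = 1460,
                      Cl = 1.13, Q1 = 1.03, Q2 = 0.894, lbm = NULL) {
  if (!is.null(lbm)) V1 <- V1 * (lbm / 48)
  vals <- c(V1 = V1, V2 = V2, V3 = V3, Cl = Cl, Q1 = Q1, Q2 = Q2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all pharmacokinetic parameters must be positive")
  structure(as.list(vals), class = "pk_params")
}

#' Infusion schedule
#'
#' Piecewise-constant intravenous infusion segments. Rates are in mg/min
#' (e.g. 12 mg/kg/h at 70 kg is 14 mg/min).
#'
#' @param start_min segment start times (min).
#' @param rate_mg_min infusion rates (mg/min, >= 0).
#' @param duration_min segment durations (min, > 0).
#' @return data frame of class `infusion_schedule`.
#' @export
infusion_schedule <- function(start_min, rate_mg_min, duration_min) {
  s <- data.frame(start_min = start_min, rate_mg_min = rate_mg_min,
                  duration_min = duration_min)
  if (any(s$rate_mg_min < 0)) stop("negative infusion rate")
  if (any(s$duration_min <= 0)) stop("non-positive segment duration")
  s <- s[order(s$start_min), , drop = FALSE]
  ends <- s$start_min + s$duration_min
  if (nrow(s) > 1L && any(s$start_min[-1L] < ends[-nrow(s)] - 1e-9))
    stop("overlapping infusion segments")
  structure(s, class = c("infusion_schedule", "data.frame"))
}

infusion_rate_at <- function(schedule, t_min) {
  r <- numeric(length(t_min))
  for (i in seq_len(nrow(schedule))) {
    sel <- t_min >= schedule$start_min[i] &
           t_min < schedule$start_min[i] + schedule$duration_min[i]
    r[sel] <- schedule$rate_mg_min[i]
  }
  r
}

#' Simulate plasma concentration from a three-compartment model
#'
#' Integrates the mammillary amount ODEs
#' `dA1/dt = rate - (Cl + Q1 + Q2)/V1 A1 + Q1/V2 A2 + Q2/V3 A3`,
#' `dA2/dt = Q1/V1 A1 - Q1/V2 A2`, `dA3/dt = Q2/V1 A1 - Q2/V3 A3`
#' with a stiff-capable adaptive integrator, restarting at infusion
#' segment boundaries so piecewise-constant rates are exact. With mg
#' amounts and L volumes, `Cp = A1/V1` is in mg/L = ug/mL.
#'
#' @param params a [pk_params()].
#' @param schedule an [infusion_schedule()] (or `NULL` for no infusion).
#' @param t_grid increasing evaluation times in minutes.
#' @param bolus_mg optional initial bolus placed in the central
#'   compartment at t = 0.
#' @param rtol relative integrator tolerance.
#' @param amounts if `TRUE`, return the full compartment-amount matrix
#'   (columns A1, A2, A3 in mg) instead of `Cp`; useful for mass-balance
#'   checks.
#' @return numeric vector `Cp(t_grid)` in ug/mL, or an amount matrix when
#'   `amounts = TRUE`.
#' @export
simulate_pk <- function(params, schedule, t_grid, bolus_mg = 0,
                        rtol = 1e-8, amounts = FALSE) {
  if (is.unsorted(t_grid, strictly = FALSE)) stop("t_grid must be increasing")
  p <- params
  deriv <- function(t, A, parms) {
    rate <- parms$rate
    list(c(rate - (p$Cl + p$Q1 + p$Q2) / p$V1 * A[1] +
             p$Q1 / p$V2 * A[2] + p$Q2 / p$V3 * A[3],
           p$Q1 / p$V1 * A[1] - p$Q1 / p$V2 * A[2],
           p$Q2 / p$V1 * A[1] - p$Q2 / p$V3 * A[3]))
  }
  brk <- sort(unique(c(0, t_grid,
                       if (!is.null(schedule))
                         c(schedule$start_min,
                           schedule$start_min + schedule$duration_min))))
  brk <- brk[brk >= 0 & brk <= max(t_grid, 0)]
  A <- c(bolus_mg, 0, 0)
  out <- matrix(0, length(t_grid), 3L)
  if (any(t_grid <= 0)) out[t_grid <= 0, 1L] <- A[1L]
  seg_rate <- if (is.null(schedule)) function(t) 0 else
    function(t) infusion_rate_at(schedule, t)
  for (i in seq_len(length(brk) - 1L)) {
    t0 <- brk[i]; t1 <- brk[i + 1L]
    if (t1 <= t0) next
    rate <- seg_rate((t0 + t1) / 2)
    inner <- t_grid[t_grid > t0 & t_grid <= t1]
    times <- sort(unique(c(t0, inner, t1)))
    sol <- deSolve::lsoda(A, times, deriv, parms = list(rate = rate),
                          rtol = rtol, atol = 1e-10)
    if (length(inner))
      out[match(inner, t_grid), ] <- sol[match(inner, sol[, 1L]), 2:4]
    A <- as.numeric(sol[nrow(sol), 2:4])
  }
  if (amounts) {
    colnames(out) <- c("A1", "A2", "A3")
    out
  } else out[, 1L] / p$V1
}

#' Effect-site concentration
#'
#' Solves `dCe/dt = ke0 (Cp - Ce)`, `Ce(0) = 0`, for a plasma curve given
#' on a time grid, using the exact solution for linear interpolation of
#' `Cp` between grid points (so a piecewise-constant `Cp` on the grid is
#' reproduced to machine precision).
#'
#' @param t_min increasing time grid in minutes.
#' @param cp plasma concentrations on `t_min` (ug/mL).
#' @param ke0 effect-compartment rate constant (1/min, > 0).
#' @return `Ce(t_min)` in ug/mL.
#' @export
effect_site <- function(t_min, cp, ke0) {
  if (ke0 <= 0) stop("ke0 must be positive")
  n <- length(t_min)
  if (length(cp) != n) stop("t_min and cp must have equal length")
  ce <- numeric(n)
  for (i in seq_len(n - 1L)) {
    dt <- t_min[i + 1L] - t_min[i]
    a <- cp[i]
    b <- (cp[i + 1L] - cp[i]) / dt
    ek <- exp(-ke0 * dt)
    ce[i + 1L] <- ce[i] * ek + a * (1 - ek) + b * (dt - (1 - ek) / ke0)
  }
  ce
}

#' Sigmoid Emax pharmacodynamic model
#'
#' Hill-type concentration-effect relation
#' `E = E0 + (Emax - E0) Ce^gamma / (Ce50^gamma + Ce^gamma)`: baseline
#' `E0` at zero concentration, asymptote `Emax`, half effect at
#' `Ce = Ce50`, steepness `gamma`. `ke0` links plasma to the effect site
#' (see [effect_site()]).
#'
#' @param e0 baseline index value (no drug).
#' @param emax index value at maximal drug effect.
#' @param ce50 effect-site concentration at half effect (ug/mL, > 0).
#' @param gamma steepness (> 0).
#' @param ke0 effect-compartment rate (1/min, > 0).
#' @return object of class `pd_model`.
#' @export
pd_model <- function(e0, emax, ce50, gamma, ke0) {
  if (ce50 <= 0 || gamma <= 0 || ke0 <= 0)
    stop("ce50, gamma and ke0 must be positive")
  structure(list(e0 = e0, emax = emax, ce50 = ce50, gamma = gamma,
                 ke0 = ke0), class = "pd_model")
}

#' Evaluate the sigmoid Emax relation
#'
#' @param pd a [pd_model()].
#' @param ce effect-site concentrations (>= 0).
#' @return predicted index values.
#' @export
sigmoid_emax <- function(pd, ce) {
  if (any(ce < 0)) stop("ce must be non-negative")
  h <- ce^pd$gamma
  pd$e0 + (pd$emax - pd$e0) * h / (pd$ce50^pd$gamma + h)
}

#' Fit a sigmoid Emax / effect-compartment model to an index course
#'
#' Individual-level nonlinear least squares over (E0, Emax, Ce50, gamma,
#' ke0): for each candidate ke0 the effect-site curve is computed from the
#' supplied plasma curve, then the Hill relation is fit; positivity of
#' Ce50, gamma, ke0 is enforced by log-parameterization.
#' Levenberg-Marquardt with multistart initialization; the best
#' converged start (lowest SSE) is returned. A near-constant course is
#' flagged `degenerate` (Emax ~ E0 is then unidentifiable).
#'
#' @param times_min observation times (min).
#' @param values observed index values.
#' @param cp_times_min,cp plasma-concentration curve (minutes, ug/mL) on
#'   a grid covering `times_min`.
#' @param n_starts number of multistart initializations (default 6).
#' @return list with `pd` (a [pd_model()]), `sse`, `fitted`, `converged`,
#'   `degenerate`.
#' @export
fit_pd <- function(times_min, values, cp_times_min, cp, n_starts = 6L) {
  stopifnot(length(times_min) == length(values),
            length(cp_times_min) == length(cp))
  rng <- range(values)
  degenerate <- diff(rng) < 1e-8 * max(1, abs(mean(values)))
  resid_fun <- function(par) {
    e0 <- par[1]; emax <- par[2]
    ce50 <- exp(par[3]); gamma <- exp(par[4]); ke0 <- exp(par[5])
    ce <- effect_site(cp_times_min, cp, ke0)
    ce_obs <- stats::approx(cp_times_min, ce, xout = times_min,
                            rule = 2)$y
    h <- ce_obs^gamma
    values - (e0 + (emax - e0) * h / (ce50^gamma + h))
  }
  med_cp <- stats::median(cp[cp > 0])
  if (!is.finite(med_cp) || med_cp <= 0) med_cp <- 1
  starts <- list()
  ke0_grid <- c(0.05, 0.15, 0.5)
  gam_grid <- c(1.5, 4)
  k <- 0L
  for (ke0 in ke0_grid) for (g in gam_grid) {
    k <- k + 1L
    starts[[k]] <- c(values[1L], values[which.max(abs(values - values[1L]))],
                     log(med_cp), log(g), log(ke0))
  }
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = fit$par, sse = sse,
                   converged = fit$info %in% 1:4)
  }
  if (is.null(best))
    stop("pharmacodynamic fit failed to converge from any start")
  par <- best$par
  pd <- pd_model(par[1], par[2], exp(par[3]), exp(par[4]), exp(par[5]))
  list(pd = pd, sse = best$sse,
       fitted = values - resid_fun(par),
       converged = best$converged, degenerate = degenerate)
}

#' Likelihood-ratio test threshold
#'
#' Objective-function-value drop required of a nested model extension:
#' the `1 - alpha` quantile of the chi-square distribution with `df`
#' degrees of freedom (3.84 for alpha = 0.05, df = 1).
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (number of added parameters).
#' @return chi-square quantile.
#' @export
lrt_threshold <- function(alpha = 0.05, df = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stats::qchisq(1 - alpha, df)
}
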