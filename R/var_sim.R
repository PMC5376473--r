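#' First-order vector autoregressive model
#'
#' `x_t = F x_{t-1} + e_t` with Gaussian innovations `e_t ~ N(0, noise_cov)`.
#' `F[i, j]` is the coupling strength from source channel `j` into target
#' channel `i`. Stationarity requires the spectral radius of `F` to be
#' below 1.
#'
#' @param F n x n coupling matrix.
#' @param noise_cov n x n symmetric positive-definite innovation
#'   covariance; defaults to the identity.
#' @param labels channel names; default `ch1..chn`.
#' @return object of class `var_model`.
#' @export
var_model <- function(F, noise_cov = diag(nrow(F)),
                      labels = paste0("ch", seq_len(nrow(F)))) {
  F <- as.matrix(F)
  if (nrow(F) != ncol(F)) stop("F must be square")
  noise_cov <- as.matrix(noise_cov)
  if (!all(dim(noise_cov) == dim(F)))
    stop("noise_cov must match F in dimension")
  if (max(abs(noise_cov - t(noise_cov))) > 1e-10)
    stop("noise_cov must be symmetric")
  if (spectral_radius(F) >= 1)
    stop("unstable model: spectral radius of F must be < 1")
  labels <- as.character(labels)
  if (length(labels) != nrow(F) || anyDuplicated(labels))
    stop("labels must be unique, one per channel")
  structure(list(F = F, noise_cov = noise_cov, labels = labels),
            class = "var_model")
}

spectral_radius <- function(F) max(Mod(eigen(F, only.values = TRUE)$values))

#' Simulate a VAR(1) recording
#'
#' Gaussian innovations; the first `burn_in` samples are discarded so the
#' retained series is (approximately) stationary. Reproducible for a fixed
#' seed.
#'
#' @param model a [var_model()].
#' @param n_samples number of retained samples.
#' @param seed optional integer seed.
#' @param burn_in samples discarded before retention (default 1000).
#' @param fs sampling rate attached to the returned recording (default 256).
#' @return an [eeg_recording()].
#' @export
simulate_var <- function(model, n_samples, seed = NULL, burn_in = 1000L,
                         fs = 256) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(model$F)
  total <- n_samples + burn_in
  L <- t(chol(model$noise_cov))
  e <- L %*% matrix(stats::rnorm(n * total), n, total)
  x <- matrix(0, n, total)
  Fm <- model$F
  x[, 1L] <- e[, 1L]
  for (t in 2:total) x[, t] <- Fm %*% x[, t - 1L] + e[, t]
  eeg_recording(t(x[, (burn_in + 1L):total, drop = FALSE]),
                model$labels, fs = fs)
}

#' Stationary covariances of a VAR(1)
#'
#' The lag-0 covariance solves the discrete Lyapunov equation
#' `Sigma = F Sigma F' + noise_cov` (vectorized linear solve); the lag-tau
#' cross-covariance `Cov(x_{t+tau}, x_t)` is `F^tau Sigma`.
#'
#' @param model a [var_model()].
#' @param tau lag in samples (>= 0).
#' @return list with `lag0` (Sigma) and `lag_tau` (`F^tau` Sigma).
#' @export
stationary_covariance <- function(model, tau = 1L) {
  F <- model$F
  n <- nrow(F)
  vecS <- solve(diag(n * n) - kronecker(F, F), as.vector(model$noise_cov))
  S <- matrix(vecS, n, n)
  S <- (S + t(S)) / 2
  Ft <- diag(n)
  for (i in seq_len(tau)) Ft <- Ft %*% F
  list(lag0 = S, lag_tau = Ft %*% S)
}

# joint covariance of [x_{t+tau}; x_t] at stationarity
joint_lag_cov <- function(model, tau) {
  sc <- stationary_covariance(model, tau)
  rbind(cbind(sc$lag0, sc$lag_tau),
        cbind(t(sc$lag_tau), sc$lag0))
}

#' Analytic Gaussian transfer entropy of a VAR(1)
#'
#' Evaluates the transfer-entropy entropy combination on the model's
#' stationary (population) covariances instead of sample estimates; exact
#' up to linear-algebra tolerance, and exactly zero for a source channel
#' with no couplings into or out of the rest of the system.
#'
#' @param model a [var_model()].
#' @param target,source disjoint character vectors of channel labels.
#' @param tau lag in samples.
#' @return transfer entropy in nats.
#' @export
analytic_te <- function(model, target, source, tau = 1L) {
  a <- match(target, model$labels)
  b <- match(source, model$labels)
  if (anyNA(a) || anyNA(b)) stop("unknown channel labels")
  if (length(intersect(a, b))) stop("target and source must be disjoint")
  if (!length(a) || !length(b)) stop("groups must be non-empty")
  C2 <- joint_lag_cov(model, tau)
  te_from_pooled(C2, a, b, nrow(model$F))
}

#' Analytic transfer-entropy table over all bipartitions
#'
#' [te_table()] evaluated on the model's stationary covariances rather
#' than on data; used as an oracle for the index definitions.
#'
#' @param model a [var_model()].
#' @param tau lag in samples.
#' @param mode bipartition mode, see [enumerate_bipartitions()].
#' @return a `te_table` data frame (see [te_table()]).
#' @export
analytic_te_table <- function(model, tau = 1L,
                              mode = c("disjoint_pairs", "covering")) {
  mode <- match.arg(mode)
  bp <- enumerate_bipartitions(model$labels, mode)
  C2 <- joint_lag_cov(model, tau)
  n <- nrow(model$F)
  te <- vapply(seq_len(nrow(bp)), function(i)
    te_from_pooled(C2, match(bp$target[[i]], model$labels),
                   match(bp$source[[i]], model$labels), n), 0)
  structure(data.frame(source = I(bp$source), target = I(bp$target), te = te),
            mode = mode, tau = tau, class = c("te_table", "data.frame"))
}

#' Effect-site-modulated VAR anesthesia fixture
#'
#' Generates a 7-channel surrogate recording (Fp1, Fp2, F3, F4, P3, P4,
#' Cz) whose inter-channel couplings are attenuated by a simulated
#' effect-site concentration: designated entries of the coupling matrix
#' are scaled by `g(Ce) = 1 / (1 + (Ce / c50_mod)^h)`, emulating the
#' reduction of (frontoparietal) effective connectivity under propofol.
#' Ground-truth concentration and coupling-scale curves are returned for
#' parameter-recovery tests. This is a synthetic stand-in for clinical
#' EEG: it has VAR spectra (no 1/f shaping, no artifacts) and the
#' concentration-coupling link is a fixture choice, not an estimate.
#'
#' @param duration_s recording length in seconds (default 1200, i.e. a
#'   20-minute session).
#' @param fs sampling rate (default 256 Hz).
#' @param infusion an [infusion_schedule()]; default 12 mg/kg/h at a
#'   nominal 70 kg (14 mg/min) for the first 8 minutes, starting at 2 min.
#' @param pk [pk_params()] used for the plasma curve (defaults to the
#'   published propofol estimates).
#' @param ke0 effect-compartment rate constant, 1/min (default 0.155).
#' @param c50_mod concentration (ug/mL) at which couplings are halved.
#' @param hill steepness of the attenuation law.
#' @param base_F baseline coupling matrix; `NULL` for the built-in
#'   frontoparietal topology.
#' @param modulated logical matrix marking which F entries attenuate;
#'   `NULL` modulates every non-zero off-diagonal coupling.
#' @param seed integer seed fixing the realization.
#' @return list with `recording` (an [eeg_recording()] carrying
#'   infusion annotations), `ce` (data frame `time_s`, `ce`, ground truth
#'   on a 1 s grid), `g` (coupling scale per second), `model` (baseline
#'   [var_model()]).
#' @export
make_anesthesia_fixture <- function(duration_s = 1200, fs = 256,
                                    infusion = infusion_schedule(2, 14, 8),
                                    pk = pk_params(), ke0 = 0.155,
                                    c50_mod = 1.0, hill = 2,
                                    base_F = NULL, modulated = NULL,
                                    seed = 1L) {
  labels <- c("Fp1", "Fp2", "F3", "F4", "P3", "P4", "Cz")
  if (is.null(base_F)) base_F <- default_anesthesia_F()
  model <- var_model(base_F, labels = labels)
  if (is.null(modulated)) {
    modulated <- base_F != 0
    diag(modulated) <- FALSE
  }

  # ground-truth effect-site concentration on a 1 s grid (PK time in min)
  t_min <- seq(0, duration_s / 60, by = 1 / 60)
  cp <- simulate_pk(pk, infusion, t_min)
  ce <- effect_site(t_min, cp, ke0)
  g_sec <- 1 / (1 + (ce / c50_mod)^hill)

  # worst-case stability check at the strongest attenuation
  Fmin <- base_F
  Fmin[modulated] <- Fmin[modulated] * min(g_sec)
  if (spectral_radius(Fmin) >= 1)
    stop("modulated model unstable at peak attenuation")

  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  n_samp <- round(duration_s * fs)
  burn_in <- 1000L
  e <- matrix(stats::rnorm(n * (n_samp + burn_in)), n, n_samp + burn_in)
  x <- matrix(0, n, n_samp + burn_in)
  x[, 1L] <- e[, 1L]
  # g held constant within each second of the retained series
  g_of_t <- function(t) {
    sec <- max(0L, (t - burn_in - 1L)) %/% round(fs) + 1L
    g_sec[min(sec, length(g_sec))]
  }
  Fcur <- base_F
  g_prev <- NA_real_
  for (t in 2:(n_samp + burn_in)) {
    g <- if (t <= burn_in) 1 else g_of_t(t)
    if (!identical(g, g_prev)) {
      Fcur <- base_F
      Fcur[modulated] <- Fcur[modulated] * g
      g_prev <- g
    }
    x[, t] <- Fcur %*% x[, t - 1L] + e[, t]
  }
  ann <- data.frame(
    time_s = c(infusion$start_min * 60,
               (infusion$start_min + infusion$duration_min) * 60),
    label = c("infusion_start", "infusion_end"))
  ann <- ann[ann$time_s <= duration_s, , drop = FALSE]
  rec <- eeg_recording(t(x[, (burn_in + 1L):(n_samp + burn_in)]),
                       labels, fs = fs, annotations = ann)
  sec_grid <- seq_len(ceiling(duration_s))
  list(recording = rec,
       ce = data.frame(time_s = sec_grid - 1, ce = ce[pmin(sec_grid, length(ce))]),
       g = g_sec[pmin(sec_grid, length(g_sec))],
       model = model)
}

# Baseline 7-channel topology: frontoparietal feedback edges (frontal ->
# parietal) strongest, with weaker reciprocal feedforward and midline
# couplings so that every channel subset receives flow from its
# complement (otherwise the minimum information bipartition sits on a
# zero-flow cut and cannot respond to the modulation). Values are package
# choices reproducing the qualitative connectivity structure, not
# estimates from data.
default_anesthesia_F <- function() {
  labels <- c("Fp1", "Fp2", "F3", "F4", "P3", "P4", "Cz")
  F <- diag(0.35, 7)
  dimnames(F) <- list(labels, labels)
  edge <- function(to, from, w) F[to, from] <<- w
  edge("F3", "Fp1", 0.25); edge("F4", "Fp2", 0.25)   # prefrontal -> frontal
  edge("Fp1", "F3", 0.20); edge("Fp2", "F4", 0.20)   # frontal -> prefrontal
  edge("P3", "F3", 0.35);  edge("P4", "F4", 0.35)    # feedback (strongest)
  edge("F3", "P3", 0.18);  edge("F4", "P4", 0.18)    # feedforward
  edge("P3", "Cz", 0.20);  edge("P4", "Cz", 0.20)    # midline -> parietal
  edge("Cz", "F3", 0.18);  edge("Cz", "F4", 0.18)
  edge("Cz", "P3", 0.15);  edge("Cz", "P4", 0.15)
  edge("Fp2", "Fp1", 0.15); edge("Fp1", "Fp2", 0.15) # interhemispheric
  F
}
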