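# shared fixtures for the suite

withr_local_file <- function(name) {
  file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
}

# white-noise recording
noise_rec <- function(n, channels, fs = 256, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n * length(channels)), n), channels, fs)
}

# the unidirectional system y_{t+1} = x_t + e_t (TE x->y = log(2)/2)
xy_model <- function() {
  var_model(matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE),
            labels = c("x", "y"))
}

# two driver channels feeding a common sink: Y, Z -> X, X drives nothing
driver_sink_model <- function() {
  F <- matrix(0, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  diag(F) <- 0.5
  F["X", "Y"] <- 0.4; F["X", "Z"] <- 0.4; F["Z", "Y"] <- 0.3
  var_model(F, labels = c("X", "Y", "Z"))
}

# random stable VAR with spectral radius scaled to `radius`
random_stable_var <- function(n, seed, radius = 0.7) {
  set.seed(seed)
  F <- matrix(rnorm(n * n, sd = 0.5), n, n)
  F <- F * radius / max(Mod(eigen(F, only.values = TRUE)$values))
  var_model(F, labels = paste0("ch", seq_len(n)))
}

# brute-force bipartition enumeration by masks (independent of the
# package's canonical-order implementation)
brute_bipartition_count <- function(n, covering = FALSE) {
  cnt <- 0L
  for (s in 1:(2^n - 1)) for (t in 1:(2^n - 1)) {
    if (bitwAnd(s, t) != 0L) next
    if (covering && bitwOr(s, t) != 2^n - 1) next
    cnt <- cnt + 1L
  }
  cnt
}

# Granger form of Gaussian TE for a univariate target, from population
# covariances: 1/2 log of restricted over full conditional variance
granger_te_oracle <- function(model, target, source, tau = 1L) {
  sc <- stationary_covariance(model, tau)
  lab <- model$labels
  a <- match(target, lab); b <- match(source, lab)
  S <- sc$lag0; M <- sc$lag_tau   # M = Cov(x_{t+tau}, x_t)
  cond_var <- function(pred_idx) {
    c_ap <- M[a, pred_idx, drop = FALSE]          # Cov(a_next, x_t[pred])
    S_pp <- S[pred_idx, pred_idx, drop = FALSE]
    S[a, a] - c_ap %*% solve(S_pp, t(c_ap))
  }
  as.numeric(0.5 * log(cond_var(a) / cond_var(c(a, b))))
}
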