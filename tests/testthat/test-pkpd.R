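test_that("mass is conserved without clearance and Cp is non-negative", {
  p0 <- pk_params(Cl = 1e-12)
  am <- simulate_pk(p0, NULL, seq(0, 300, 10), bolus_mg = 50,
                    amounts = TRUE)
  expect_equal(rowSums(am), rep(50, nrow(am)), tolerance = 1e-6)
  cp <- simulate_pk(pk_params(), infusion_schedule(0, 14, 60),
                    seq(0, 140, 1))
  expect_true(all(cp >= 0))
})

test_that("constant infusion approaches the R/Cl asymptote", {
  R <- 10
  cp <- simulate_pk(pk_params(), infusion_schedule(0, R, 4e4),
                    c(0, 2e4, 4e4))
  expect_equal(cp[3], R / 1.13, tolerance = 0.01 * R / 1.13)
  expect_true(cp[2] < cp[3])   # still rising toward the asymptote
})

test_that("zero schedule gives zero concentration and bad schedules error", {
  expect_equal(simulate_pk(pk_params(), NULL, seq(0, 60, 5)),
               rep(0, 13))
  expect_error(infusion_schedule(0, -1, 10), "negative")
  expect_error(infusion_schedule(c(0, 5), c(1, 1), c(10, 10)), "overlap")
  expect_error(pk_params(Cl = -1), "positive")
})

test_that("effect site follows first-order kinetics exactly", {
  tg <- seq(0, 30, 0.25)
  ke0 <- 0.155
  ce <- effect_site(tg, rep(2, length(tg)), ke0)
  expect_equal(ce, 2 * (1 - exp(-ke0 * tg)), tolerance = 1e-9)
  # piecewise-constant plasma curve: analytic piecewise solution
  cp <- ifelse(tg < 10, 3, 1)
  ce2 <- effect_site(tg, cp, ke0)
  ana <- numeric(length(tg))
  for (i in seq_along(tg)[-1]) {
    dt <- tg[i] - tg[i - 1]
    cbar <- cp[i - 1] + (cp[i] - cp[i - 1]) / dt * 0  # left value
    # exact update for linear interpolation between grid values
    a <- cp[i - 1]; b <- (cp[i] - cp[i - 1]) / dt
    ek <- exp(-ke0 * dt)
    ana[i] <- ana[i - 1] * ek + a * (1 - ek) + b * (dt - (1 - ek) / ke0)
  }
  expect_equal(ce2, ana, tolerance = 1e-12)
  # large ke0: effect site tracks plasma
  ce3 <- effect_site(tg, rep(2, length(tg)), 100)
  expect_equal(ce3[-1], rep(2, length(tg) - 1), tolerance = 1e-6)
  # effect site lags plasma: never above the running plasma maximum
  cp4 <- simulate_pk(pk_params(), infusion_schedule(0, 14, 60),
                     seq(0, 140, 1))
  ce4 <- effect_site(seq(0, 140, 1), cp4, 0.155)
  expect_true(all(ce4 <= cummax(cp4) + 1e-9))
  expect_error(effect_site(tg, rep(1, length(tg)), -1), "positive")
})

test_that("sigmoid Emax hits its anchor points and is monotone", {
  pd <- pd_model(0.138, 0.0387, 1.04, 5.86, 0.155)
  expect_equal(sigmoid_emax(pd, 0), 0.138)
  expect_equal(sigmoid_emax(pd, 1.04), (0.138 + 0.0387) / 2)
  expect_equal(sigmoid_emax(pd, 1.04), 0.08835)
  ce <- seq(0, 8, 0.1)
  expect_true(all(diff(sigmoid_emax(pd, ce)) <= 0))   # Emax < E0: decreasing
  up <- pd_model(1, 5, 2, 3, 0.1)
  expect_true(all(diff(sigmoid_emax(up, ce)) >= 0))
  expect_error(sigmoid_emax(pd, -1), "non-negative")
  expect_error(pd_model(1, 2, -1, 3, 0.1), "positive")
})

test_that("PD fit recovers known parameters from a noiseless course", {
  truth <- pd_model(0.138, 0.0387, 1.04, 5.86, 0.155)
  tg <- seq(0, 129, length.out = 130)
  cp <- simulate_pk(pk_params(), infusion_schedule(0, 14, 60), tg)
  ce <- effect_site(tg, cp, truth$ke0)
  obs <- sigmoid_emax(truth, ce)
  fit <- fit_pd(tg, obs, tg, cp)
  for (par in c("e0", "emax", "ce50", "gamma", "ke0"))
    expect_equal(fit$pd[[par]], truth[[par]],
                 tolerance = 0.01 * abs(truth[[par]]))
  expect_lt(fit$sse, 1e-10)
  expect_false(fit$degenerate)
})

test_that("Ce50 is recovered within 15% under 5% noise (median of 20 seeds)", {
  truth <- pd_model(0.138, 0.0387, 1.04, 5.86, 0.155)
  tg <- seq(0, 129, length.out = 130)
  cp <- simulate_pk(pk_params(), infusion_schedule(0, 14, 60), tg)
  ce <- effect_site(tg, cp, truth$ke0)
  clean <- sigmoid_emax(truth, ce)
  noise_sd <- 0.05 * abs(truth$e0 - truth$emax)
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    fit <- fit_pd(tg, clean + rnorm(130, sd = noise_sd), tg, cp)
    abs(fit$pd$ce50 - truth$ce50) / truth$ce50
  }, 0)
  expect_lt(median(errs), 0.15)
})

test_that("a constant course is flagged degenerate", {
  tg <- seq(0, 129, 1)
  cp <- simulate_pk(pk_params(), infusion_schedule(0, 14, 60), tg)
  fit <- fit_pd(tg, rep(0.1, length(tg)), tg, cp)
  expect_true(fit$degenerate)
  expect_equal(fit$pd$e0, fit$pd$emax, tolerance = 1e-4)
})

test_that("likelihood-ratio thresholds match chi-square quantiles", {
  expect_equal(round(lrt_threshold(0.05, 1), 2), 3.84)
  expect_equal(round(lrt_threshold(0.05, 2), 2), 5.99)
  expect_lt(lrt_threshold(0.999), 1e-4)
  expect_error(lrt_threshold(1.2), "alpha")
})
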