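test_that("exponential MLE and its scale behaviour", {
  f <- fit_exponential(rep(0.1, 10))
  expect_equal(f$rate, 10)
  set.seed(31)
  d <- rexp(1000, 10)
  k_hat <- fit_exponential(d)$rate
  expect_equal(k_hat, 10, tolerance = 3 / sqrt(1000))
  expect_equal(fit_exponential(2 * d)$rate, k_hat / 2, tolerance = 1e-9)
  expect_error(fit_exponential(c(1, 2, 3)), "insufficient")
  # dead-time-truncated MLE removes the censoring offset
  set.seed(32)
  d_trunc <- rexp(2000, 5) + 0.2
  expect_equal(fit_exponential(d_trunc, t_dead = 0.2)$rate, 5,
               tolerance = 3 * 5 / sqrt(2000))
})

test_that("gamma confidence interval for the rate has 93-97% coverage", {
  n <- 50
  k <- 4
  hits <- vapply(1:500, function(s) {
    set.seed(s)
    ci <- fit_exponential(rexp(n, k))$ci95
    ci[1] <= k && k <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("mixture detection separates one from two exponential timescales", {
  # pure exponential: the single model must win for almost all seeds
  single_wins <- vapply(1:25, function(s) {
    set.seed(100 + s)
    detect_multiexponential(rexp(400, 5))$model == "single"
  }, logical(1))
  expect_gte(mean(single_wins), 0.95)
  # balanced fast/slow mixture: detected, with rates within factor 1.5
  set.seed(41)
  d <- c(rexp(250, 1), rexp(250, 100))
  fit <- detect_multiexponential(d)
  expect_identical(fit$model, "mixture")
  expect_lt(abs(log(fit$components$rate[1] / 1)), log(1.5))
  expect_lt(abs(log(fit$components$rate[2] / 100)), log(1.5))
  # vanishing weight reduces to a single component
  set.seed(42)
  d1 <- c(rexp(499, 5), rexp(1, 50))
  expect_identical(detect_multiexponential(d1)$model, "single")
  expect_error(detect_multiexponential(rexp(10, 1)), "at least 50")
})

test_that("conformational rates are transition counts over occupancy time", {
  dw <- data.frame(state = c(1, 2, 1, 2, 3, 2, 1),
                   t_start = cumsum(c(0, 2, 1, 2, 1, 1, 2)) [1:7],
                   duration = c(2, 1, 2, 1, 1, 2, 2),
                   mean_force = 10)
  r <- conformational_rates(dw, 1, 2)
  # two 1->2 transitions over 6 s in state 1; two 2->1 over 4 s in 2
  expect_equal(r$rate[r$from == 1], 2 / 6)
  expect_equal(r$rate[r$from == 2], 2 / 4)
  expect_true(all(r$ci_low <= r$rate & r$rate <= r$ci_high))
  # zero observed transitions: rate 0 with a one-sided interval
  dw2 <- data.frame(state = c(1, 3), t_start = c(0, 1),
                    duration = 1, mean_force = 10)
  r2 <- conformational_rates(dw2, 1, 3)
  expect_equal(r2$rate[r2$from == 3], 0)
  expect_gt(r2$ci_high[r2$from == 3], 0)
})

test_that("phase-filtered rates recover a bound-phase slowdown", {
  # hand-built dwells: unbound 2->1 fast, bound 2->1 slowed 5x
  set.seed(55)
  mk <- function(k21, n, phase) {
    st <- rep(c(2, 1), n)
    data.frame(state = st,
               t_start = 0,
               duration = ifelse(st == 2, rexp(2 * n, k21),
                                 rexp(2 * n, 4)),
               mean_force = 10, phase = phase)
  }
  dw <- rbind(mk(2, 150, "unbound"), mk(0.4, 150, "bound"))
  ru <- conformational_rates(dw, 2, 1, phase_filter = "unbound")
  rb <- conformational_rates(dw, 2, 1, phase_filter = "bound")
  ratio <- ru$rate[1] / rb$rate[1]
  expect_equal(ratio, 5, tolerance = 5 * 0.35)
  # pooled rate lies between the two phase rates
  ra <- conformational_rates(dw, 2, 1, phase_filter = "all")
  expect_true(ra$rate[1] < ru$rate[1] && ra$rate[1] > rb$rate[1])
})

test_that("off-rate force fit recovers two-contribution parameters", {
  # synthetic per-force bound events straight from the Bell law
  kT <- 4.114
  k_ind <- 0.02; k0 <- 0.005; dx <- 3
  set.seed(61)
  ev <- do.call(rbind, lapply(seq(8, 14, by = 1), function(f) {
    k <- k_ind + k0 * exp(f * dx / kT)
    data.frame(group = f, duration = rexp(40, k), force = f)
  }))
  fit <- protein_off_rates(ev)
  # the 0-pN extrapolation spans e^(8*3/kT) ~ 340x, so the point estimate
  # is ill-conditioned: require the CI to cover the truth and the
  # transition-state distance to come back within 50%
  expect_true(fit$ci95[1] <= k_ind + k0 && k_ind + k0 <= fit$ci95[2])
  expect_lt(abs(fit$fit$dx - dx) / dx, 0.5)
  # interpolation inside the measured range is accurate
  expect_lt(abs(log(predict(fit, 11) /
                      (k_ind + k0 * exp(11 * dx / kT)))), log(1.3))
  # k_off(0) >= k_ind by construction of the model form
  expect_gte(fit$k_off_zero_force, fit$fit$k_ind)
  # force-independent data: fitted dx interval includes 0 (flat fit)
  set.seed(62)
  ev0 <- do.call(rbind, lapply(seq(8, 14, by = 2), function(f) {
    data.frame(group = f, duration = rexp(60, 0.1), force = f)
  }))
  fit0 <- protein_off_rates(ev0)
  expect_lt(abs(log(fit0$k_off_zero_force / 0.1)), log(1.3))
  # fewer than 3 force points: points returned, fit refused
  expect_warning(f2 <- protein_off_rates(ev[ev$force <= 9, ]),
                 "fewer than 3")
  expect_null(f2$fit)
  expect_identical(nrow(f2$points), 2L)
})

test_that("on-rate estimation corrects for competent-state occupancy", {
  set.seed(71)
  k_on <- 1e7; conc <- 50e-9; occ <- 0.8
  ev <- do.call(rbind, lapply(1:4, function(g) {
    data.frame(group = g, duration = rexp(40, k_on * conc * occ),
               force = 8 + g, occupancy = occ)
  }))
  fit <- protein_on_rates(ev, protein_conc = conc)
  expect_equal(fit$k_on, k_on, tolerance = 0.2 * k_on)
  # halving the occupancy doubles the corrected rate
  ev2 <- ev; ev2$occupancy <- occ / 2
  fit2 <- protein_on_rates(ev2, protein_conc = conc)
  expect_equal(fit2$k_bind, 2 * fit$k_bind, tolerance = 1e-9)
  expect_error(protein_on_rates(transform(ev, occupancy = 0), conc),
               "positive")
})

test_that("K_D is the ratio of zero-force off-rate to on-rate", {
  off <- structure(list(k_off_zero_force = 0.1, se_zero_force = 0.01,
                        fit = list(k_ind = 0.1, k0 = 0, dx = 0),
                        kT = 4.114),
                   class = "binding_rate_fit")
  on <- structure(list(k_on = 2e7, k_bind = 1, se_bind = 0.1,
                       protein_conc = 5e-8),
                  class = "on_rate_fit")
  kd <- compute_kd(off, on)
  expect_equal(kd$kd, 5e-9)
  expect_true(kd$ci95[1] < 5e-9 && 5e-9 < kd$ci95[2])
})
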