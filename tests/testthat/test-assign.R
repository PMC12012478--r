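test_that("well-separated two-level trace is assigned almost perfectly", {
  m <- elastic_model()
  sc <- two_state_scheme(3, 3, n_unf = 30)
  D <- separation_for_force(11, m)
  gap <- passive_force(D, m, 0) - passive_force(D, m, 30)
  tr <- simulate_passive_trace(sc, m, D, duration = 60,
                               noise_sd = gap / 6, seed = 8,
                               sampling_hz = 1500)
  a <- fit_hmm(tr, n_states = 2)
  truth_idx <- ifelse(tr$truth_state == "A", 1L, 2L)
  expect_gte(mean(a$path == truth_idx), 0.99)
  # levels sorted descending: state 1 most folded
  expect_gt(a$levels$mean[1], a$levels$mean[2])
})

test_that("a noiseless multi-state trace is decoded exactly", {
  p <- otfold_preset("ADE_six_state")
  tr <- simulate_passive_trace(p$scheme, p$model, p$trap_separation,
                               duration = 20, noise_sd = 0, seed = 12,
                               sampling_hz = 1500)
  a <- fit_hmm(tr, n_states = 6)
  expect_identical(ade_level_names[a$path], tr$truth_state)
})

test_that("single-state model returns the sample mean", {
  x <- rnorm(500, 10, 0.3)
  a <- fit_hmm(x, n_states = 1)
  expect_identical(a$path, rep(1L, 500))
  expect_equal(a$levels$mean, mean(x))
})

test_that("six-state fixture recovery: level order and occupancy", {
  p <- otfold_preset("ADE_six_state")
  tr <- simulate_passive_trace(p$scheme, p$model, p$trap_separation,
                               duration = 60, noise_sd = p$noise_sd,
                               seed = 7, sampling_hz = p$sampling_hz)
  a <- fit_hmm(tr, n_states = 6)
  expect_identical(a$n_states, 6L)
  # recovered levels match the model's passive-force predictions
  st <- p$scheme$states
  f_pred <- sort(vapply(seq_len(nrow(st)), function(i) {
    passive_force(p$trap_separation, p$model, st$n_unfolded_nt[i],
                  st$n_closed_stems[i])
  }, numeric(1)), decreasing = TRUE)
  expect_equal(a$levels$mean, f_pred, tolerance = 0.05)
  truth_occ <- vapply(ade_level_names, function(s) {
    mean(tr$truth_state == s)
  }, numeric(1))
  est_occ <- tabulate(a$path, 6) / length(a$path)
  expect_lt(max(abs(est_occ - truth_occ)), 0.05)
})

test_that("EM log-likelihood is non-decreasing", {
  p <- otfold_preset("ADE_six_state")
  tr <- simulate_passive_trace(p$scheme, p$model, p$trap_separation,
                               duration = 15, noise_sd = p$noise_sd,
                               seed = 3, sampling_hz = p$sampling_hz)
  a <- fit_hmm(tr, n_states = 6)
  expect_true(all(diff(a$loglik_trace) > -1e-6 *
                    abs(a$loglik_trace[-length(a$loglik_trace)])))
})

test_that("assignment is invariant to a constant force offset", {
  m <- elastic_model()
  sc <- two_state_scheme(4, 4, n_unf = 30)
  D <- separation_for_force(11, m)
  tr <- simulate_passive_trace(sc, m, D, duration = 20, noise_sd = 0.3,
                               seed = 6, sampling_hz = 1500)
  a1 <- fit_hmm(tr$force, n_states = 2)
  a2 <- fit_hmm(tr$force + 5, n_states = 2)
  expect_identical(a1$path, a2$path)
  expect_equal(a2$levels$mean, a1$levels$mean + 5, tolerance = 1e-6)
})

test_that("BIC selection identifies the number of levels", {
  m <- elastic_model()
  sc <- two_state_scheme(4, 4, n_unf = 30)
  D <- separation_for_force(11, m)
  tr <- simulate_passive_trace(sc, m, D, duration = 15, noise_sd = 0.3,
                               seed = 2, sampling_hz = 1500)
  a <- suppressWarnings(fit_hmm(tr))
  expect_identical(a$n_states, 2L)
})

test_that("dwell extraction tiles the trace and respects the dead-time filter", {
  m <- elastic_model()
  sc <- two_state_scheme(4, 4, n_unf = 30)
  D <- separation_for_force(11, m)
  tr <- simulate_passive_trace(sc, m, D, duration = 30, noise_sd = 0,
                               seed = 4, sampling_hz = 1500)
  a <- fit_hmm(tr, n_states = 2)
  dw <- extract_dwells(a, tr)
  expect_equal(sum(dw$duration), length(tr$force) * otfold:::trace_dt(tr),
               tolerance = 1e-9)
  expect_true(all(dw$state[-1] != head(dw$state, -1)))
  # noiseless: dwell count equals the number of truth changes + 1 (within
  # the sampled grid)
  truth_changes <- sum(tr$truth_state[-1] !=
                         head(tr$truth_state, -1))
  expect_identical(nrow(dw), truth_changes + 1L)
  # constant path collapses to a single dwell
  dw1 <- extract_dwells(rep(1L, length(tr$force)), tr)
  expect_identical(nrow(dw1), 1L)
  # min_dwell merging only ever reduces the dwell count
  trn <- simulate_passive_trace(sc, m, D, 30, noise_sd = 0.6, seed = 4,
                                sampling_hz = 1500)
  an <- fit_hmm(trn, n_states = 2)
  expect_lte(nrow(extract_dwells(an, trn, min_dwell = 5)),
             nrow(extract_dwells(an, trn)))
})

test_that("bound-phase segmentation matches the simulator's truth flags", {
  m <- elastic_model()
  sc <- roq_binding_scheme(kd_nM = 5, k_on = 2e7, protein_conc = 30e-9,
                           dx_off = 0, k_ind_frac = 1, k_unfold = 20,
                           k_fold = 80)
  D <- separation_for_force(9, m)
  tr <- simulate_binding_trace(sc, m, D, duration = 250, noise_sd = 0.35,
                               seed = 17, sampling_hz = 3000)
  a <- fit_hmm(tr, n_states = 2)
  dw <- segment_bound_phases(extract_dwells(a, tr, min_dwell = 3),
                             list(state = 1, min_duration = 0.5))
  # per-sample comparison against the truth bound flag
  dt <- otfold:::trace_dt(tr)
  lab <- rep(dw$phase, round(dw$duration / dt))
  lab <- lab[seq_along(tr$truth_bound)]
  bound_acc <- sum(lab == "bound" & tr$truth_bound) /
    sum(tr$truth_bound)
  expect_gte(bound_acc, 0.90)
  # no bound phases without protein
  sc0 <- kinetic_scheme(sc$states, sc$transitions)
  tr0 <- simulate_passive_trace(sc0, m, D, 30, noise_sd = 0.35,
                                seed = 18, sampling_hz = 3000)
  a0 <- fit_hmm(tr0, n_states = 2)
  dw0 <- segment_bound_phases(extract_dwells(a0, tr0, min_dwell = 3),
                              list(state = 1, min_duration = 3))
  expect_identical(sum(dw0$phase == "bound"), 0L)
  # decreasing the threshold monotonically increases labeled bound time
  bt <- vapply(c(2, 1, 0.5), function(thr) {
    d <- segment_bound_phases(extract_dwells(a, tr, min_dwell = 3),
                              list(state = 1, min_duration = thr))
    sum(d$duration[d$phase == "bound"])
  }, numeric(1))
  expect_true(all(diff(bt) >= 0))
})
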