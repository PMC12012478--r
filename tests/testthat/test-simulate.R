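test_that("kinetic scheme validation catches malformed inputs", {
  st <- data.frame(name = c("A", "B"), n_unfolded_nt = c(0, 10),
                   dG0_kcal = c(0, 3))
  tr <- data.frame(from = "A", to = "B", k0 = 1, dx = 0, sign = 0)
  expect_s3_class(kinetic_scheme(st, tr), "kinetic_scheme")
  expect_error(kinetic_scheme(st[c(1, 1), ], tr), "unique")
  expect_error(kinetic_scheme(
    data.frame(name = c("A", "B"), n_unfolded_nt = c(5, 10),
               dG0_kcal = 0), tr), "fully folded")
  expect_error(kinetic_scheme(
    st, data.frame(from = "A", to = "C", k0 = 1, dx = 0, sign = 0)),
    "unknown states")
  expect_error(kinetic_scheme(st, tr, binding = list(k_on = 1e7)),
               "binding block missing")
  expect_error(kinetic_scheme(st, tr, binding = list(
    k_on = 1e7, protein_conc = 1e-8, k_off0 = 0.1, dx_off = 1,
    k_off_force_independent = 0, competent_state = "Z")),
    "not a state")
})

test_that("Gillespie dwells are exponential with the exit rate", {
  sc <- two_state_scheme(10, 10)
  path <- simulate_state_path(sc, c(A = 10, B = 9), duration = 1000,
                              seed = 11)
  d <- path$duration[-nrow(path)]        # last dwell is right-censored
  expect_equal(mean(d), 0.1, tolerance = 3 / sqrt(length(d)) * 0.1 * 3)
  # dwells tile the interval
  expect_equal(sum(path$duration), 1000, tolerance = 1e-9)
  expect_true(all(path$state[-1] != head(path$state, -1)))
})

test_that("state paths are reproducible by seed and distinct across seeds", {
  sc <- two_state_scheme(5, 5)
  p1 <- simulate_state_path(sc, c(A = 10, B = 9), 50, seed = 3)
  p2 <- simulate_state_path(sc, c(A = 10, B = 9), 50, seed = 3)
  p3 <- simulate_state_path(sc, c(A = 10, B = 9), 50, seed = 4)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
})

test_that("an absorbing state yields a single censored dwell with a warning", {
  sc <- kinetic_scheme(
    data.frame(name = "A", n_unfolded_nt = 0, dG0_kcal = 0),
    data.frame(from = character(0), to = character(0), k0 = numeric(0),
               dx = numeric(0), sign = numeric(0)))
  expect_warning(p <- simulate_state_path(sc, c(A = 10), 5, seed = 1),
                 "absorbing")
  expect_identical(nrow(p), 1L)
  expect_equal(p$duration, 5)
})

test_that("passive traces encode states as force levels with truth labels", {
  m <- elastic_model()
  sc <- two_state_scheme(3, 3, n_unf = 30)
  D <- separation_for_force(11, m)
  tr <- simulate_passive_trace(sc, m, D, duration = 20, noise_sd = 0,
                               seed = 5, sampling_hz = 1500)
  expect_s3_class(tr, "ot_trace")
  expect_identical(length(tr$truth_state), length(tr$force))
  fA <- passive_force(D, m, 0, n_closed_stems = 1)
  fB <- passive_force(D, m, 30, n_closed_stems = 0)
  expect_equal(sort(unique(round(tr$force, 9))), sort(c(fA, fB)),
               tolerance = 1e-6)
  # more folded state sits at the higher force
  expect_gt(mean(tr$force[tr$truth_state == "A"]),
            mean(tr$force[tr$truth_state == "B"]))
  # single-state, zero-noise trace is constant
  sc1 <- kinetic_scheme(
    data.frame(name = "A", n_unfolded_nt = 0, dG0_kcal = 0),
    data.frame(from = character(0), to = character(0), k0 = numeric(0),
               dx = numeric(0), sign = numeric(0)))
  tr1 <- suppressWarnings(simulate_passive_trace(sc1, m, D, 2,
                                                 noise_sd = 0, seed = 1,
                                                 sampling_hz = 1500))
  expect_equal(diff(range(tr1$force)), 0)
  # indistinguishable levels trigger a warning
  sc_close <- kinetic_scheme(
    data.frame(name = c("A", "B"), n_unfolded_nt = c(0, 1),
               dG0_kcal = c(0, 0.5), n_closed_stems = c(1, 1)),
    data.frame(from = c("A", "B"), to = c("B", "A"), k0 = 3, dx = 0,
               sign = 0))
  expect_warning(simulate_passive_trace(sc_close, m, D, 1, noise_sd = 0.35,
                                        seed = 1, sampling_hz = 1500),
                 "noise_sd/2")
})

test_that("six-state occupancies converge to Boltzmann weights of total energy", {
  p <- otfold_preset("ADE_six_state")
  E <- otfold:::scheme_state_energies(p$scheme, p$model,
                                      p$trap_separation)
  w <- exp(-(E - min(E)) / p$model$kT)
  pi_expected <- w / sum(w)
  path <- simulate_state_path(p$scheme, duration = 400, seed = 21,
    force_of_state = otfold:::scheme_state_forces(p$scheme, p$model,
                                                  p$trap_separation))
  occ <- vapply(p$scheme$states$name, function(s) {
    sum(path$duration[path$state == s])
  }, numeric(1)) / sum(path$duration)
  # 3-sigma band: each state visited ~ hundreds of times in 400 s
  n_vis <- vapply(p$scheme$states$name, function(s) {
    sum(path$state == s)
  }, numeric(1))
  tol <- 3 * pi_expected / sqrt(pmax(n_vis, 1))
  expect_true(all(abs(occ - pi_expected) < pmax(tol, 0.02)))
})

test_that("binding trace with zero concentration equals the passive trace", {
  p <- otfold_preset("ADE_extROQ_binding")
  p$scheme$binding$protein_conc <- 0
  tr1 <- simulate_binding_trace(p$scheme, p$model, p$trap_separation, 5,
                                noise_sd = 0.2, seed = 9,
                                sampling_hz = 1500)
  sc_nb <- kinetic_scheme(p$scheme$states, p$scheme$transitions)
  tr2 <- simulate_passive_trace(sc_nb, p$model, p$trap_separation, 5,
                                noise_sd = 0.2, seed = 9,
                                sampling_hz = 1500)
  expect_equal(tr1$force, tr2$force)
  expect_identical(tr1$truth_state, tr2$truth_state)
})

test_that("bound lifetimes and binding flux match the injected rates", {
  m <- elastic_model()
  sc <- roq_binding_scheme(kd_nM = 10, k_on = 2e7, protein_conc = 50e-9,
                           dx_off = 0, k_ind_frac = 1)
  D <- separation_for_force(9, m)
  tr <- simulate_binding_trace(sc, m, D, duration = 1500, noise_sd = 0,
                               seed = 14, sampling_hz = 300)
  td <- tr$truth_dwells
  r <- rle(td$bound)
  ends <- cumsum(r$lengths); starts <- c(1, head(ends, -1) + 1)
  epi <- vapply(seq_along(r$values), function(i) {
    sum(td$duration[starts[i]:ends[i]])
  }, numeric(1))
  k_off_true <- 10e-9 * 2e7   # force-independent by construction
  mb <- mean(epi[r$values])
  nb <- sum(r$values)
  expect_equal(mb, 1 / k_off_true, tolerance = 3 / sqrt(nb) / k_off_true)
  # flux balance: bindings per unbound second in the competent state
  t_unb_I3 <- sum(td$duration[!td$bound & td$state == "I3"])
  n_bind <- sum(diff(as.integer(td$bound)) == 1)
  expect_equal(n_bind / t_unb_I3, 2e7 * 50e-9,
               tolerance = 3 / sqrt(n_bind))
})

test_that("titration simulator reproduces the Hill curve", {
  t0 <- simulate_titration(kd = 300, hill_n = 1, noise_sd = 0, seed = 1,
                           concentrations = c(0, 300, 600))
  expect_equal(t0$fraction_bound, c(0, 0.5, 2 / 3), tolerance = 1e-12)
  t2 <- simulate_titration(kd = 100, hill_n = 2, noise_sd = 0,
                           concentrations = 200)
  expect_equal(t2$fraction_bound, 0.8)
  tn <- simulate_titration(kd = 300, noise_sd = 0.5, seed = 2)
  expect_true(all(tn$fraction_bound >= 0 & tn$fraction_bound <= 1))
})

test_that("melting-curve simulator is a double sigmoid with correct limits", {
  mc <- simulate_melting_curve(tm1 = 65, tm2 = 76.7, noise_sd = 0,
                               seed = 1)
  expect_true(all(diff(mc$signal) <= 1e-12))
  # zero second amplitude reduces to a single sigmoid
  m1 <- simulate_melting_curve(tm1 = 60, tm2 = 80,
                               amplitudes = c(2, 0), noise_sd = 0)
  expect_equal(m1$signal,
               2 / (1 + exp((m1$temperature - 60) / 3)),
               tolerance = 1e-12)
})
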