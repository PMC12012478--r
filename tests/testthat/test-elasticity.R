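test_that("Marko-Siggia force matches direct evaluation and is monotone", {
  expect_equal(wlc_force(0, persistence = 1), 0)
  # direct evaluation: 4.114 * (1/(4*0.25) - 0.25 + 0.5)
  expect_equal(wlc_force(0.5, persistence = 1, kT = 4.114), 5.1425,
               tolerance = 1e-12)
  z <- seq(0, 0.99, by = 0.01)
  f <- wlc_force(z, persistence = 1)
  expect_true(all(diff(f) > 0))
  expect_gt(wlc_force(0.9, 1), wlc_force(0.5, 1))
  expect_error(wlc_force(1, 1), "finitely extensible")
  expect_error(wlc_force(1.2, 1), "finitely extensible")
})

test_that("wlc_extension inverts wlc_force to 1e-6 pN over (0, 60] pN", {
  for (p in c(1, 40)) {
    f <- c(0.01, 0.1, 0.5, 1, 2, 5, 10, 20, 40, 60)
    x <- wlc_extension(f, contour = 100, persistence = p)
    back <- wlc_force(x / 100, persistence = p)
    expect_lt(max(abs(back - f)), 1e-6)
  }
  expect_equal(wlc_extension(0, 100, 1), 0)
  # inverse of the direct-evaluation example
  expect_equal(wlc_extension(5.1425, contour = 10, persistence = 1), 5,
               tolerance = 1e-7)
})

test_that("extensible-WLC term adds L*F/K to the handle extension", {
  x_inext <- wlc_extension(10, 600, 40, stretch_modulus = Inf)
  x_ext <- wlc_extension(10, 600, 40, stretch_modulus = 1000)
  expect_equal(x_ext - x_inext, 600 * 10 / 1000, tolerance = 1e-9)
})

test_that("construct extension is monotone in force and released length", {
  m <- elastic_model()
  expect_equal(construct_extension(0, m, 0, n_closed_stems = 0), 0)
  # zero force: only the rigid folded offset spans the tether
  expect_equal(construct_extension(0, m, 0, n_closed_stems = 1),
               m$folded_offset)
  f <- seq(0.5, 30, by = 0.5)
  x <- construct_extension(f, m, 20)
  expect_true(all(diff(x) > 0))
  # releasing 30 nt lengthens by about the stretched 19.5 nm ssRNA contour
  gain <- construct_extension(10, m, 30) - construct_extension(10, m, 0)
  expect_equal(gain, wlc_extension(10, 30 * 0.65, 1.0), tolerance = 1e-9)
  expect_gt(construct_extension(10, m, 30), construct_extension(10, m, 0))
})

test_that("passive force drops when contour is released and roots are consistent", {
  m <- elastic_model()
  D <- separation_for_force(12, m)
  expect_equal(passive_force(D, m, 0), 12, tolerance = 1e-6)
  f0 <- passive_force(D, m, 0)
  f15 <- passive_force(D, m, 15)
  f30 <- passive_force(D, m, 30)
  expect_gt(f0, f15)
  expect_gt(f15, f30)
  # force balance is satisfied at the root
  x <- construct_extension(f15, m, 15)
  expect_equal(f15, m$trap_stiffness * (D - x), tolerance = 1e-6)
  expect_error(passive_force(1, m, 0), "zero-force construct length")
})

test_that("contour gain inverts passive force across trap stiffnesses", {
  for (k in c(0.15, 0.25, 0.40)) {
    m <- elastic_model(trap_stiffness = k)
    D <- separation_for_force(12, m)
    f_hi <- passive_force(D, m, 0, 1)
    # full 15-nt hairpin opening: offset swapped for ssRNA contour
    f_lo <- passive_force(D, m, 15, 0)
    gain <- contour_gain_from_force_jump(f_hi, f_lo, D, m,
                                         opens_last_stem = TRUE)
    expect_equal(gain, expected_contour_gain(15, m, TRUE),
                 tolerance = 0.05)
    # partial opening: pure ssRNA contour release
    f_mid <- passive_force(D, m, 10, 1)
    gain2 <- contour_gain_from_force_jump(f_hi, f_mid, D, m)
    expect_equal(gain2, 10 * m$ss_contour_per_nt, tolerance = 0.05)
  }
  m <- elastic_model()
  D <- separation_for_force(12, m)
  expect_equal(contour_gain_from_force_jump(10, 10, D, m), 0)
  # larger jumps -> larger gains
  f_hi <- passive_force(D, m, 0, 1)
  g <- vapply(c(5, 10, 20), function(n) {
    contour_gain_from_force_jump(f_hi, passive_force(D, m, n, 1), D, m)
  }, numeric(1))
  expect_true(all(diff(g) > 0))
})

test_that("nucleotide counting matches the 15-nt / 7.75-nm convention", {
  m <- elastic_model()
  r <- nt_from_contour_gain(7.75, m, closes_hairpin = TRUE)
  expect_identical(r$n_nt, 15L)
  expect_equal(r$n_exact, 15, tolerance = 1e-12)
  expect_identical(nt_from_contour_gain(0.65, m)$n_nt, 1L)
  expect_equal(expected_contour_gain(15, m, closes_hairpin = TRUE),
               15 * 0.65 - 2.0)
  # measured gain near 7.8 nm still rounds to 15 nt
  expect_identical(nt_from_contour_gain(7.8, m, TRUE)$n_nt, 15L)
})

test_that("stretch free energy agrees with an independent trapezoid quadrature", {
  for (f_top in c(5, 12)) {
    q <- stretch_free_energy(f_top, contour = 50, persistence = 1)
    # independent route: trapezoid integration of F dx at 1e4 points
    x_top <- wlc_extension(f_top, 50, 1)
    xg <- seq(1e-9, x_top, length.out = 1e4)
    fg <- wlc_force(xg / 50, 1)
    trap <- sum(diff(xg) * (fg[-1] + fg[-length(fg)]) / 2)
    expect_lt(abs(q - trap) / trap, 1e-3)
  }
  expect_equal(stretch_free_energy(0, 50, 1), 0)
  expect_gt(stretch_free_energy(10, 50, 1), stretch_free_energy(5, 50, 1))
})

test_that("elastic model validates its parameter ranges", {
  expect_error(elastic_model(trap_stiffness = 50), "band")
  expect_silent(elastic_model(trap_stiffness = 50,
                              allow_unusual_stiffness = TRUE))
  expect_error(elastic_model(ss_contour_per_nt = -1))
  expect_error(elastic_model(kT = 0))
})

test_that("energy unit conversions are a consistent round trip", {
  expect_equal(kcalmol_to_pNnm(1), 6.948)
  expect_equal(pNnm_to_kcalmol(kT_25C_pNnm), 0.5921, tolerance = 1e-3)
  x <- c(0.3, 1.3, 9.5)
  expect_equal(pNnm_to_kcalmol(kcalmol_to_pNnm(x)), x)
})
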